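#' Validate a submitted decision tree
#'
#' Drafts collected from participants are routinely incomplete or logically
#' inconsistent; the refinement loop depends on reporting *every* structural
#' defect, never the first one, and never repairing or judging content.
#' Five defect categories are detected:
#' \describe{
#'   \item{unknown-level}{a branch names a level (or a node a criterion)
#'     absent from the governing criteria set;}
#'   \item{overlap}{branch level subsets at a node intersect, so a scenario
#'     could take two paths;}
#'   \item{gap}{a scenario reaches no leaf (a combination of parameters with
#'     no stated recommendation);}
#'   \item{conflict}{a leaf holds several recommendations with multiplicity
#'     `single` — multiple options whose status (equivalent? ranked?) the
#'     participant never declared;}
#'   \item{unreachable-branch}{a branch whose level subset is emptied by the
#'     constraints accumulated above it (reported, but does not by itself
#'     invalidate the tree).}
#' }
#' `is_valid` is `TRUE` iff no gap, conflict, overlap or unknown-level issue
#' exists; exactly then the tree expands over the full scenario space without
#' error.
#'
#' @param tree A `tc_decision_tree`, possibly built with `check = FALSE`.
#' @param criteria Governing criteria set; defaults to the tree's own.
#' @return A `tc_validation_report`: list with `participant_id`, `issues`
#'   (data.frame: category, position, scenario, message) and `is_valid`.
#' @seealso [validate_table()], [write_report_csv()]
#' @export
validate_tree <- function(tree, criteria = tree$criteria) {
  issues <- list()
  add <- function(category, position, scenario, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      category = category, position = position, scenario = scenario,
      message = message, stringsAsFactors = FALSE)
  }

  # structural walk: unknown levels/criteria, overlaps, unreachable branches.
  # `allowed` tracks the level constraints accumulated along the path.
  walk <- function(node, pos, allowed) {
    if (node$type == "leaf") {
      if (length(node$rec$members) > 1L && node$rec$multiplicity == "single")
        add("conflict", pos, "",
            sprintf("leaf offers %d recommendations (%s) without declared multiplicity",
                    length(node$rec$members), paste(node$rec$members, collapse = ", ")))
      return(invisible(NULL))
    }
    cname <- node$criterion
    if (!cname %in% cs_names(criteria)) {
      add("unknown-level", pos, "",
          sprintf("node tests criterion '%s' absent from the criteria set", cname))
      return(invisible(NULL))
    }
    lvls <- cs_levels(criteria, cname)
    nb <- length(node$branches)
    for (i in seq_len(nb)) {
      bad <- setdiff(node$branches[[i]]$levels, lvls)
      if (length(bad))
        add("unknown-level", sprintf("%s/%s[%d]", pos, cname, i), "",
            sprintf("branch levels not among levels of '%s': %s",
                    cname, paste(bad, collapse = ", ")))
    }
    if (nb > 1L) {
      for (i in seq_len(nb - 1L)) for (j in seq(i + 1L, nb)) {
        inter <- intersect(node$branches[[i]]$levels, node$branches[[j]]$levels)
        if (length(inter))
          add("overlap", sprintf("%s/%s", pos, cname), "",
              sprintf("branches %d and %d of '%s' both capture: %s",
                      i, j, cname, paste(inter, collapse = ", ")))
      }
    }
    reach <- allowed[[cname]] %||% lvls
    for (i in seq_len(nb)) {
      b <- node$branches[[i]]
      eff <- intersect(intersect(b$levels, lvls), reach)
      if (length(eff) == 0L && length(intersect(b$levels, lvls)) > 0L) {
        add("unreachable-branch", sprintf("%s/%s[%d]", pos, cname, i), "",
            sprintf("branch {%s} of '%s' is emptied by ancestor constraints",
                    paste(b$levels, collapse = ","), cname))
      }
      allowed2 <- allowed
      allowed2[[cname]] <- eff
      walk(b$node, sprintf("%s/%s={%s}", pos, cname, paste(b$levels, collapse = ",")),
           allowed2)
    }
  }
  walk(tree$root, "root", list())

  # scenario sweep: a gap is a scenario from which no leaf is reachable under
  # permissive matching (all matching branches followed, so overlaps do not
  # mask gaps elsewhere)
  space <- scenario_space(criteria)
  nms <- cs_names(criteria)
  reaches_leaf <- function(node, scenario) {
    if (node$type == "leaf") return(TRUE)
    if (!node$criterion %in% nms) return(FALSE)
    lvl <- scenario[[node$criterion]]
    for (b in node$branches)
      if (lvl %in% b$levels && reaches_leaf(b$node, scenario)) return(TRUE)
    FALSE
  }
  for (r in seq_len(nrow(space))) {
    scen <- as.character(space[r, nms])
    names(scen) <- nms
    if (!reaches_leaf(tree$root, scen))
      add("gap", "root", paste(scen, collapse = KEY_SEP),
          sprintf("no recommendation stated for scenario (%s)",
                  paste(sprintf("%s=%s", nms, scen), collapse = ", ")))
  }

  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(category = character(0L), position = character(0L),
               scenario = character(0L), message = character(0L),
               stringsAsFactors = FALSE)
  invalidating <- c("gap", "conflict", "overlap", "unknown-level")
  structure(
    list(participant_id = tree$participant_id, issues = issues,
         is_valid = !any(issues$category %in% invalidating)),
    class = "tc_validation_report"
  )
}

#' Validate a decision table
#'
#' Table-level counterpart of [validate_tree()]: a *gap* is a scenario with
#' no row, a *conflict* is either duplicate rows for one scenario with
#' different recommendation sets or a multi-member cell whose multiplicity
#' was left `single`, and *unknown-level* flags row values outside the
#' criteria set.
#'
#' @param table A `tc_decision_table`, possibly built with `check = FALSE`.
#' @return A `tc_validation_report`.
#' @export
validate_table <- function(table) {
  criteria <- table$criteria
  nms <- cs_names(criteria)
  df <- table$data
  issues <- list()
  add <- function(category, position, scenario, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      category = category, position = position, scenario = scenario,
      message = message, stringsAsFactors = FALSE)
  }

  bad_rows <- rep(FALSE, nrow(df))
  for (n in nms) {
    bad <- !(df[[n]] %in% cs_levels(criteria, n))
    if (any(bad)) {
      bad_rows <- bad_rows | bad
      for (i in which(bad))
        add("unknown-level", sprintf("row %d", i), "",
            sprintf("level '%s' is not a level of criterion '%s'", df[[n]][i], n))
    }
  }

  keys <- row_keys(df, nms)
  space_keys <- row_keys(scenario_space(criteria), nms)

  miss <- setdiff(space_keys, keys)
  for (k in miss)
    add("gap", "table", k,
        sprintf("no row for scenario (%s)",
                paste(sprintf("%s=%s", nms, strsplit(k, KEY_SEP, fixed = TRUE)[[1L]]),
                      collapse = ", ")))

  dup <- unique(keys[duplicated(keys)])
  for (k in dup) {
    rows <- which(keys == k)
    cells <- unique(mapply(function(m, mult) paste_key(mult, m),
                           df$recommendations[rows], df$multiplicity[rows]))
    if (length(cells) > 1L)
      add("conflict", sprintf("rows %s", paste(rows, collapse = ",")), k,
          "duplicate scenario rows with different recommendation sets")
  }

  for (i in seq_len(nrow(df))) {
    if (df$excluded[i] || bad_rows[i]) next
    members <- strsplit(df$recommendations[i], "|", fixed = TRUE)[[1L]]
    if (length(members) > 1L && df$multiplicity[i] == "single")
      add("conflict", sprintf("row %d", i), keys[i],
          sprintf("%d recommendations without declared multiplicity", length(members)))
    if (!df$multiplicity[i] %in% c("single", "equivalent-alternatives", "ranked"))
      add("conflict", sprintf("row %d", i), keys[i],
          sprintf("unknown multiplicity '%s'", df$multiplicity[i]))
  }

  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(category = character(0L), position = character(0L),
               scenario = character(0L), message = character(0L),
               stringsAsFactors = FALSE)
  invalidating <- c("gap", "conflict", "overlap", "unknown-level")
  structure(
    list(participant_id = table$participant_id, issues = issues,
         is_valid = !any(issues$category %in% invalidating)),
    class = "tc_validation_report"
  )
}

#' @export
print.tc_validation_report <- function(x, ...) {
  cat(sprintf("Validation report for '%s': %s\n", x$participant_id,
              if (x$is_valid) "VALID" else "NOT VALID"))
  if (nrow(x$issues) == 0L) {
    cat("  no issues\n")
  } else {
    tab <- table(x$issues$category)
    cat(sprintf("  %d issue(s): %s\n", nrow(x$issues),
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
    for (i in seq_len(min(nrow(x$issues), 25L)))
      cat(sprintf("  [%s] %s: %s\n", x$issues$category[i], x$issues$position[i],
                  x$issues$message[i]))
  }
  invisible(x)
}

#' Write a validation report as machine-readable CSV
#'
#' One row per issue: category, position, scenario, message.
#'
#' @param report A `tc_validation_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  df <- report$issues
  df$scenario <- gsub(KEY_SEP, "/", df$scenario, fixed = TRUE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
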