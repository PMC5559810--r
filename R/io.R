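TREE_SCHEMA_VERSION <- "1.0"
RULES_SCHEMA_VERSION <- "1.0"

criterion_to_list <- function(c) {
  out <- list(name = c$name, levels = as.list(c$levels),
              description = c$description, kind = c$kind)
  if (!is.null(c$source)) out$source <- c$source
  out
}

criterion_from_list <- function(x) {
  if (is.null(x$name) || is.null(x$levels))
    tc_error("tc_schema_error", "criterion entry needs 'name' and 'levels'")
  criterion(x$name, unlist(x$levels), description = x$description %||% "",
            kind = x$kind %||% "categorical", source = x$source)
}

node_to_list <- function(node, criteria) {
  if (node$type == "leaf") {
    list(recommendations = as.list(node$rec$members),
         multiplicity = node$rec$multiplicity)
  } else {
    lvls <- if (node$criterion %in% cs_names(criteria))
      cs_levels(criteria, node$criterion) else character(0L)
    list(criterion = node$criterion,
         branches = lapply(node$branches, function(b) {
           # canonical: subsets serialized in declared level order
           ord <- order(match(b$levels, lvls))
           list(levels = as.list(b$levels[ord]),
                node = node_to_list(b$node, criteria))
         }))
  }
}

node_from_list <- function(x, where) {
  if (!is.null(x$recommendations)) {
    labels <- unlist(x$recommendations)
    if (is.null(labels) || length(labels) == 0L)
      tc_error("tc_schema_error", sprintf("empty recommendations at %s", where))
    mult <- x$multiplicity %||% if (length(labels) == 1L) "single" else NULL
    # a multi-label leaf with no declared multiplicity is stored as 'single'
    # so that validation can flag it as the conflict it is
    if (is.null(mult)) mult <- "single"
    tree_leaf(labels, mult)
  } else if (!is.null(x$criterion)) {
    if (is.null(x$branches) || length(x$branches) == 0L)
      tc_error("tc_schema_error", sprintf("internal node without branches at %s", where))
    branches <- lapply(seq_along(x$branches), function(i) {
      b <- x$branches[[i]]
      if (is.null(b$levels) || is.null(b$node))
        tc_error("tc_schema_error",
                 sprintf("branch %d at %s needs 'levels' and 'node'", i, where))
      tree_branch(unlist(b$levels),
                  node_from_list(b$node, sprintf("%s/%s[%d]", where, x$criterion, i)))
    })
    tree_node(x$criterion, branches)
  } else {
    tc_error("tc_schema_error",
             sprintf("node at %s is neither a leaf ('recommendations') nor internal ('criterion')", where))
  }
}

#' Read and write decision-tree documents
#'
#' Trees travel as versioned JSON documents carrying the criteria block, the
#' participant block (id, finalisation date, ISO-8601) and the nested node
#' structure. Serialization is canonical — fixed key order, criteria sorted
#' by name, branch subsets in level order — so equal in-memory trees produce
#' byte-identical documents, and `parse_tree(write_tree(t))` returns `t`.
#'
#' Parsing distinguishes *schema* errors (malformed document,
#' `tc_schema_error`) from *semantic* errors (level not in the criteria set,
#' branches not a partition; `tc_semantic_error`). With `check = FALSE` the
#' semantic checks are skipped so that defective drafts can be loaded for
#' [validate_tree()].
#'
#' @param path File path (or, for `parse_tree_string`, a JSON string).
#' @param check Enforce tree structural invariants on parse?
#' @return `parse_tree()` returns a `tc_decision_tree`; `write_tree()`
#'   returns `path` invisibly.
#' @export
parse_tree <- function(path, check = TRUE) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    tc_error("tc_schema_error",
                             sprintf("malformed tree document: %s", conditionMessage(e))))
  for (field in c("schema_version", "participant", "criteria", "root"))
    if (is.null(doc[[field]]))
      tc_error("tc_schema_error", sprintf("tree document lacks '%s'", field))
  if (is.null(doc$participant$id))
    tc_error("tc_schema_error", "participant block lacks 'id'")
  criteria <- criteria_set(lapply(doc$criteria, criterion_from_list))
  root <- node_from_list(doc$root, "root")
  decision_tree(doc$participant$id, root, criteria,
                finalisation_date = doc$participant$finalisation_date %||% Sys.Date(),
                check = check)
}

#' @rdname parse_tree
#' @param tree A `tc_decision_tree`.
#' @export
write_tree <- function(tree, path) {
  doc <- list(
    schema_version = TREE_SCHEMA_VERSION,
    participant = list(id = tree$participant_id,
                       finalisation_date = format(tree$finalisation_date)),
    criteria = lapply(unname(tree$criteria), criterion_to_list),
    root = node_to_list(tree$root, tree$criteria)
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2L, null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname parse_tree
#' @param text JSON text of a tree document.
#' @export
parse_tree_string <- function(text, check = TRUE) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(text, tmp, useBytes = TRUE)
  parse_tree(tmp, check = check)
}

#' Read and write decision tables as CSV
#'
#' RFC-4180 CSV, UTF-8, header required: one column per criterion (any
#' order on input; canonical sorted order on output), then
#' `recommendations` (cell members joined by `|`; for ranked cells the
#' order is the ranking), `multiplicity`, and optionally `excluded` /
#' `reason`. One row per scenario. Parsers reject rather than repair: with
#' `check = TRUE` (default) an incomplete or duplicated table raises; with
#' `check = FALSE` the defects are left for [validate_table()] to report.
#'
#' @param path CSV file path.
#' @param criteria Governing [criteria_set()].
#' @param participant_id Participant recorded on the parsed table.
#' @param finalisation_date Provenance date.
#' @param check Enforce completeness on parse?
#' @return `parse_table()` returns a `tc_decision_table`; `write_table()`
#'   returns `path` invisibly.
#' @export
parse_table <- function(path, criteria, participant_id,
                        finalisation_date = Sys.Date(), check = TRUE) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                 colClasses = "character", check.names = FALSE),
                 error = function(e)
                   tc_error("tc_schema_error",
                            sprintf("malformed table CSV: %s", conditionMessage(e))))
  need <- c(cs_names(criteria), "recommendations", "multiplicity")
  missing <- setdiff(need, names(df))
  if (length(missing))
    tc_error("tc_schema_error",
             sprintf("table CSV lacks columns: %s", paste(missing, collapse = ", ")))
  if ("excluded" %in% names(df))
    df$excluded <- tolower(df$excluded) %in% c("true", "t", "1", "yes")
  decision_table(participant_id, criteria, df,
                 finalisation_date = finalisation_date, check = check)
}

#' @rdname parse_table
#' @param table A `tc_decision_table`.
#' @export
write_table <- function(table, path) {
  df <- table$data
  df$excluded <- ifelse(df$excluded, "true", "false")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and write harmonization rule files
#'
#' JSON documents with a `target_criteria` block (the shared harmonized
#' criteria, fixing level order) and a `rules` list (participant scope,
#' source criterion, level map, optional source scale / cut-off provenance
#' and note).
#'
#' @param path File path.
#' @return `parse_rules()` returns a `tc_harmonization_rules`;
#'   `write_rules()` returns `path` invisibly.
#' @export
parse_rules <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    tc_error("tc_schema_error",
                             sprintf("malformed rules document: %s", conditionMessage(e))))
  if (is.null(doc$target_criteria) || is.null(doc$rules))
    tc_error("tc_schema_error", "rules document needs 'target_criteria' and 'rules'")
  target <- criteria_set(lapply(doc$target_criteria, criterion_from_list))
  rules <- lapply(doc$rules, function(r) {
    if (is.null(r$participant) || is.null(r$source) || is.null(r$target) || is.null(r$map))
      tc_error("tc_schema_error",
               "each rule needs 'participant', 'source', 'target', 'map'")
    harmonization_rule(r$participant, r$source, r$target,
                       unlist(r$map), source_scale = r$source_scale,
                       cutoff = r$cutoff, note = r$note %||% "")
  })
  harmonization_rules(target, rules)
}

#' @rdname parse_rules
#' @param ruleset A `tc_harmonization_rules` object.
#' @export
write_rules <- function(ruleset, path) {
  doc <- list(
    schema_version = RULES_SCHEMA_VERSION,
    target_criteria = lapply(unname(ruleset$target_criteria), criterion_to_list),
    rules = lapply(ruleset$rules, function(r) {
      out <- list(participant = r$participant, source = r$source,
                  target = r$target, map = as.list(r$map))
      if (!is.null(r$source_scale)) out$source_scale <- r$source_scale
      if (!is.null(r$cutoff)) out$cutoff <- r$cutoff
      if (nzchar(r$note %||% "")) out$note <- r$note
      out
    })
  )
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2L), path,
             useBytes = TRUE)
  invisible(path)
}

#' Export a decision tree as Graphviz DOT
#'
#' Renders internal nodes as criterion boxes, edges labelled with their
#' level subsets, and leaves as recommendation boxes; suitable for
#' `dot -Tpdf`. When a `congruency` map (scenario-independent per-leaf
#' annotation is not attempted; the consensus CSV carries per-scenario
#' detail) is wanted, annotate downstream.
#'
#' @param tree A `tc_decision_tree`.
#' @param path Output DOT file.
#' @return `path`, invisibly.
#' @export
write_dot <- function(tree, path) {
  lines <- c(sprintf("digraph \"%s\" {", tree$participant_id),
             "  node [shape=box, fontname=\"Helvetica\"];")
  counter <- 0L
  esc <- function(x) gsub("\"", "\\\"", x, fixed = TRUE)
  emit <- function(node) {
    counter <<- counter + 1L
    id <- sprintf("n%d", counter)
    if (node$type == "leaf") {
      lines <<- c(lines, sprintf("  %s [label=\"%s\", style=filled, fillcolor=lightgrey];",
                                 id, esc(paste(node$rec$members, collapse = " | "))))
    } else {
      lines <<- c(lines, sprintf("  %s [label=\"%s\"];", id, esc(node$criterion)))
      for (b in node$branches) {
        cid <- emit(b$node)
        lines <<- c(lines, sprintf("  %s -> %s [label=\"%s\"];", id, cid,
                                   esc(paste(b$levels, collapse = ", "))))
      }
    }
    id
  }
  emit(tree$root)
  lines <- c(lines, "}")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
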