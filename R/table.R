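#' Decision tables
#'
#' The flat form of a participant's algorithm: one row per scenario of the
#' governing criteria set, each carrying a recommendation set (pipe-joined
#' members plus a multiplicity flag). Scenarios may instead be marked
#' excluded (not applicable) with a reason; excluded scenarios contribute no
#' vote to the consensus and shrink that cell's denominator.
#'
#' A complete table covers the full Cartesian product exactly once; with
#' `check = TRUE` this is enforced, `check = FALSE` admits draft tables whose
#' defects [validate_table()] reports.
#'
#' @param participant_id Identifier of the participant.
#' @param criteria Governing [criteria_set()].
#' @param data `data.frame` with one character column per criterion plus
#'   `recommendations` (members joined by `|`), `multiplicity`, and
#'   optionally `excluded` (logical) and `reason`.
#' @param finalisation_date Provenance date, as for [decision_tree()].
#' @param check Enforce completeness and level validity?
#' @return An object of class `tc_decision_table`.
#' @export
decision_table <- function(participant_id, criteria, data,
                           finalisation_date = Sys.Date(), check = TRUE) {
  assert_string(participant_id, "participant_id")
  if (!inherits(criteria, "tc_criteria_set"))
    tc_error("tc_semantic_error", "criteria must be a criteria set")
  nms <- cs_names(criteria)
  missing_cols <- setdiff(c(nms, "recommendations", "multiplicity"), names(data))
  if (length(missing_cols))
    tc_error("tc_schema_error",
             sprintf("table is missing columns: %s", paste(missing_cols, collapse = ", ")))
  if (!"excluded" %in% names(data)) data$excluded <- FALSE
  if (!"reason" %in% names(data)) data$reason <- ""
  data <- data[, c(nms, "recommendations", "multiplicity", "excluded", "reason"),
               drop = FALSE]
  for (n in nms) data[[n]] <- trim_label(data[[n]])
  data$recommendations <- as.character(data$recommendations)
  data$multiplicity <- as.character(data$multiplicity)
  data$excluded <- as.logical(data$excluded)
  data$reason <- as.character(data$reason)

  # canonical row order = scenario_space order
  space <- scenario_space(criteria)
  ord <- order(match(row_keys(data, nms), row_keys(space, nms)))
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL

  tab <- structure(
    list(participant_id = participant_id,
         finalisation_date = as.Date(finalisation_date),
         criteria = criteria,
         data = data),
    class = "tc_decision_table"
  )
  if (check) {
    rep <- validate_table(tab)
    if (!rep$is_valid)
      tc_error("tc_semantic_error",
               sprintf("table of '%s' is not a complete decision table: %s",
                       participant_id,
                       paste(utils::head(rep$issues$message, 5L), collapse = "; ")))
  }
  tab
}

# canonical cell encoding (multiplicity + sorted-or-ranked members) per row
table_cell_keys <- function(tab) {
  mapply(function(m, mult, ex) {
    if (isTRUE(ex)) return(paste_key("excluded", ""))
    rec_key(rec_from_string(m, mult))
  }, tab$data$recommendations, tab$data$multiplicity, tab$data$excluded,
  USE.NAMES = FALSE)
}

table_scenario_keys <- function(tab) row_keys(tab$data, cs_names(tab$criteria))

# recommendation set at one scenario (named character vector of levels)
table_lookup <- function(tab, scenario) {
  nms <- cs_names(tab$criteria)
  key <- paste(scenario[nms], collapse = KEY_SEP)
  i <- match(key, table_scenario_keys(tab))
  if (is.na(i))
    tc_error("tc_semantic_error", "scenario not present in table")
  if (tab$data$excluded[i]) return(NULL)
  rec_from_string(tab$data$recommendations[i], tab$data$multiplicity[i])
}

# TRUE iff two tables map every scenario to equal cells (same criteria universe)
tables_equal <- function(a, b) {
  cs_equal(a$criteria, b$criteria) &&
    identical(table_scenario_keys(a), table_scenario_keys(b)) &&
    identical(table_cell_keys(a), table_cell_keys(b))
}

#' @export
print.tc_decision_table <- function(x, ...) {
  cat(sprintf("Decision table of participant '%s': %d criteria, %d scenarios (%d excluded)\n",
              x$participant_id, length(x$criteria), nrow(x$data), sum(x$data$excluded)))
  print(utils::head(x$data, 10L))
  if (nrow(x$data) > 10L) cat(sprintf("... %d more rows\n", nrow(x$data) - 10L))
  invisible(x)
}
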