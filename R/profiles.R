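#' Criteria-usage profile of an ensemble
#'
#' Binary matrix with one row per participant and one column per criterion:
#' `TRUE` iff the participant's recommendations actually *depend* on the
#' criterion — there exist two scenarios differing only in that criterion
#' with different recommendation sets. This is semantic dependence on the
#' expanded table, not syntactic presence in the submitted tree, so a
#' vacuous split (same sub-table on both sides) does not inflate the
#' profile.
#'
#' @param ensemble List of complete `tc_decision_table`s over one shared
#'   criteria set.
#' @return Logical matrix, rows sorted by participant id, columns
#'   lexicographic by criterion name (class `tc_profile_matrix`).
#' @export
criteria_usage <- function(ensemble) {
  stopifnot(length(ensemble) > 0L)
  criteria <- ensemble[[1L]]$criteria
  for (tab in ensemble)
    if (!cs_equal(tab$criteria, criteria))
      tc_error("tc_semantic_error", "ensemble tables must share one criteria set")
  ids <- vapply(ensemble, `[[`, character(1L), "participant_id")
  nms <- cs_names(criteria)
  m <- matrix(FALSE, nrow = length(ensemble), ncol = length(nms),
              dimnames = list(ids, nms))
  for (i in seq_along(ensemble))
    for (cname in nms)
      m[i, cname] <- table_depends_on(ensemble[[i]], cname)
  m <- m[order(rownames(m)), , drop = FALSE]
  class(m) <- c("tc_profile_matrix", class(m))
  m
}

# TRUE iff some pair of scenarios differing only in `cname` maps to
# different cells (exclusion status counts as part of the cell)
table_depends_on <- function(tab, cname) {
  others <- setdiff(cs_names(tab$criteria), cname)
  cells <- table_cell_keys(tab)
  groups <- row_keys(tab$data, others)
  any(vapply(split(cells, groups), function(g) length(unique(g)) > 1L, logical(1L)))
}

#' Treatment-portfolio profile of an ensemble
#'
#' Binary matrix with one row per participant and one column per
#' recommendation label: `TRUE` iff the participant offers that treatment in
#' any (non-excluded) scenario. The column universe is the union of labels
#' over the ensemble.
#'
#' @inheritParams criteria_usage
#' @return Logical matrix (class `tc_profile_matrix`), rows sorted by
#'   participant id, columns lexicographic.
#' @export
treatment_portfolio <- function(ensemble) {
  stopifnot(length(ensemble) > 0L)
  ids <- vapply(ensemble, `[[`, character(1L), "participant_id")
  per <- lapply(ensemble, function(tab)
    sort(unique(unlist(strsplit(tab$data$recommendations[!tab$data$excluded],
                                "|", fixed = TRUE)))))
  labels <- sort(unique(unlist(per)))
  m <- matrix(FALSE, nrow = length(ensemble), ncol = length(labels),
              dimnames = list(ids, labels))
  for (i in seq_along(per)) m[i, per[[i]]] <- TRUE
  m <- m[order(rownames(m)), , drop = FALSE]
  class(m) <- c("tc_profile_matrix", class(m))
  m
}

#' Write a profile matrix as CSV
#'
#' Rows = participants, columns = criteria or treatments, cells true/false.
#' The conventional rendering paints true cells green and false cells red;
#' a hints line recording that convention can be prepended.
#'
#' @param m A `tc_profile_matrix`.
#' @param path Output file path.
#' @param hints Prepend the rendering-hint comment line?
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(m, path, hints = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (hints) writeLines("# rendering: true=green false=red", con)
  df <- as.data.frame(unclass(m))
  df <- cbind(participant = rownames(m), df)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
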