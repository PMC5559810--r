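#' Induce a compact decision tree from a complete decision table
#'
#' Inverse of [expand_tree()]: builds a valid decision tree whose expansion
#' over the same criteria set reproduces the input table exactly. Levels of a
#' criterion that lead to identical sub-tables are merged into one branch
#' subset, and criteria on which the table does not depend are absent from
#' the tree altogether — the induced tree never tests a vacuous criterion.
#' Applied to the modal projection of a consensus table this yields the
#' compact consensus ("mode") tree.
#'
#' Split order is deterministic: at each node the criterion splitting the
#' current sub-table into the fewest distinct sub-tables (>= 2) is chosen,
#' ties broken lexicographically by criterion name.
#'
#' @param table A complete `tc_decision_table` without excluded scenarios.
#' @return A `tc_decision_tree` with `expand_tree(result)` equal to `table`.
#' @export
induce_tree <- function(table) {
  if (!inherits(table, "tc_decision_table"))
    tc_error("tc_semantic_error", "induce_tree needs a decision table")
  if (any(table$data$excluded))
    tc_error("tc_semantic_error",
             "cannot induce a tree from a table with excluded scenarios")
  rep <- validate_table(table)
  if (!rep$is_valid)
    tc_error("tc_semantic_error", "cannot induce a tree from an incomplete table")

  criteria <- table$criteria
  df <- table$data
  df$.cell <- paste_key(df$multiplicity, df$recommendations)

  build <- function(df, remaining) {
    if (length(unique(df$.cell)) == 1L)
      return(tree_leaf(rec_from_string(df$recommendations[1L], df$multiplicity[1L])))
    # per-criterion level signatures; rows stay in scenario order, so equal
    # signatures mean identical sub-tables over the other criteria
    best <- NULL
    best_d <- Inf
    best_sigs <- NULL
    for (cname in remaining) {  # remaining is sorted: lexicographic tie-break
      lvls <- cs_levels(criteria, cname)
      sigs <- vapply(lvls, function(l)
        paste(df$.cell[df[[cname]] == l], collapse = KEY_SEP), character(1L))
      d <- length(unique(sigs))
      if (d >= 2L && d < best_d) {
        best <- cname; best_d <- d; best_sigs <- sigs
      }
    }
    # distinct cells with no distinguishing criterion cannot happen on a
    # complete table; guard anyway
    if (is.null(best))
      tc_error("tc_semantic_error", "table inconsistent: no criterion separates distinct cells")
    lvls <- cs_levels(criteria, best)
    groups <- split(lvls, factor(best_sigs, levels = unique(best_sigs)))
    branches <- lapply(groups, function(g) {
      sub <- df[df[[best]] == g[1L], setdiff(names(df), best), drop = FALSE]
      tree_branch(g, build(sub, setdiff(remaining, best)))
    })
    tree_node(best, unname(branches))
  }

  root <- build(df, cs_names(criteria))
  decision_tree(table$participant_id, root, criteria,
                finalisation_date = table$finalisation_date, check = TRUE)
}
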