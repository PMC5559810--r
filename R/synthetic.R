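#' Specification of a synthetic expert ensemble
#'
#' The generator stands in for real multi-center collections: a ground-truth
#' algorithm (given or randomly drawn) is perturbed into `n_participants`
#' complete decision tables. Two independent noise processes emulate the
#' heterogeneity observed in practice:
#' \describe{
#'   \item{deviation_rate}{probability that a participant's cell
#'     recommendation is replaced by a uniformly random *different* label
#'     from the universe (i.i.d. per cell);}
#'   \item{omission_rate}{probability that a participant ignores a given
#'     criterion entirely — their table is made independent of it by the
#'     union rule before deviations are applied.}
#' }
#' The random stream is split per participant, so enlarging the panel never
#' perturbs earlier participants' tables.
#'
#' @param n_participants Panel size (>= 1).
#' @param criteria [criteria_set()] of the decision problem.
#' @param labels Character vector (>= 2) of possible recommendation labels.
#' @param truth Optional ground-truth `tc_decision_tree`; drawn at random
#'   from `criteria` and `labels` when `NULL`.
#' @param deviation_rate,omission_rate Probabilities in `[0, 1]`.
#' @param seed Integer seed; the generator is byte-reproducible from it.
#' @return A `tc_synthetic_spec`.
#' @export
synthetic_spec <- function(n_participants, criteria, labels, truth = NULL,
                           deviation_rate = 0.2, omission_rate = 0, seed = 1L) {
  if (n_participants < 1L)
    tc_error("tc_semantic_error", "n_participants must be >= 1")
  if (length(labels) < 2L)
    tc_error("tc_semantic_error", "label universe must contain >= 2 labels")
  if (deviation_rate < 0 || deviation_rate > 1 || omission_rate < 0 || omission_rate > 1)
    tc_error("tc_semantic_error", "rates must lie in [0, 1]")
  if (!inherits(criteria, "tc_criteria_set"))
    tc_error("tc_semantic_error", "criteria must be a criteria set")
  structure(
    list(n_participants = as.integer(n_participants), criteria = criteria,
         labels = trim_label(labels), truth = truth,
         deviation_rate = deviation_rate, omission_rate = omission_rate,
         seed = as.integer(seed)),
    class = "tc_synthetic_spec"
  )
}

#' Draw a random valid decision tree
#'
#' Recursively either stops with a leaf (probability `p_leaf`, always at
#' exhausted criteria) or splits on a random unused criterion, grouping its
#' levels into 2..k random branch subsets. Uses the current RNG state.
#'
#' @param criteria [criteria_set()].
#' @param labels Recommendation label universe.
#' @param participant_id Id stamped on the tree.
#' @param p_leaf Stopping probability at each node.
#' @return A valid `tc_decision_tree`.
#' @export
random_tree <- function(criteria, labels, participant_id = "random", p_leaf = 0.3) {
  pick1 <- function(x) x[sample.int(length(x), 1L)]
  int_between <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L
  split_node <- function(cname, remaining) {
    lvls <- cs_levels(criteria, cname)
    k <- int_between(2L, length(lvls))
    grp <- sample(rep_len(seq_len(k), length(lvls)))  # each group nonempty
    tree_node(cname, lapply(seq_len(k), function(g)
      tree_branch(lvls[grp == g], grow(setdiff(remaining, cname)))))
  }
  grow <- function(remaining) {
    if (length(remaining) == 0L || stats::runif(1L) < p_leaf)
      return(tree_leaf(pick1(labels)))
    split_node(pick1(remaining), remaining)
  }
  # root always splits when possible, so trees are rarely trivial
  root <- if (length(criteria) > 0L)
    split_node(pick1(cs_names(criteria)), cs_names(criteria))
  else tree_leaf(pick1(labels))
  decision_tree(participant_id, root, criteria, check = TRUE)
}

#' Draw a random complete decision table
#'
#' Independent uniform singleton recommendations per scenario (with optional
#' equivalent-alternative pairs at rate `p_multi`). Uses the current RNG
#' state.
#'
#' @inheritParams random_tree
#' @param p_multi Probability of an equivalent-alternatives pair in a cell.
#' @return A complete `tc_decision_table`.
#' @export
random_table <- function(criteria, labels, participant_id = "random", p_multi = 0) {
  space <- scenario_space(criteria)
  n <- nrow(space)
  recs <- character(n)
  mult <- rep("single", n)
  for (r in seq_len(n)) {
    if (p_multi > 0 && length(labels) >= 2L && stats::runif(1L) < p_multi) {
      recs[r] <- paste(sort(sample(labels, 2L)), collapse = "|")
      mult[r] <- "equivalent-alternatives"
    } else {
      recs[r] <- sample(labels, 1L)
    }
  }
  df <- space
  df$recommendations <- recs
  df$multiplicity <- mult
  decision_table(participant_id, criteria, df, check = TRUE)
}

#' Generate a synthetic expert ensemble
#'
#' Expands the ground truth over the full scenario space, then derives each
#' participant's table by (1) marginalizing the criteria that participant
#' omits (union rule, keeping the shared criteria axes) and (2) flipping
#' each cell independently with probability `deviation_rate` to a uniformly
#' random different label. Fully reproducible from `spec$seed`; participant
#' `i`'s sub-stream is fixed regardless of panel size.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `ensemble` (list of `tc_decision_table`s), `truth`
#'   (the `tc_decision_tree`) and `truth_table` (its expansion).
#' @export
generate_ensemble <- function(spec) {
  set.seed(spec$seed)
  truth <- spec$truth %||% random_tree(spec$criteria, spec$labels, "truth")
  truth_table <- expand_tree(truth, spec$criteria)
  # participant sub-streams: the first k seeds are identical for any panel
  # size >= k, so adding participants never perturbs earlier ones
  part_seeds <- sample.int(.Machine$integer.max, spec$n_participants)
  nms <- cs_names(spec$criteria)

  ensemble <- lapply(seq_len(spec$n_participants), function(i) {
    set.seed(part_seeds[i])
    pid <- sprintf("P%02d", i)
    tab <- decision_table(pid, spec$criteria, truth_table$data, check = FALSE)
    omit <- nms[stats::runif(length(nms)) < spec$omission_rate]
    if (length(omit) == length(nms)) {
      # participant ignores everything: one constant cell, union of all
      members <- sort(unique(unlist(strsplit(tab$data$recommendations, "|", fixed = TRUE))))
      tab$data$recommendations <- paste(members, collapse = "|")
      tab$data$multiplicity <- if (length(members) > 1L) "equivalent-alternatives" else "single"
    } else if (length(omit) > 0L) {
      tab <- marginalize_table(tab, omit, keep_axes = TRUE)
    }
    df <- tab$data
    flip <- stats::runif(nrow(df)) < spec$deviation_rate
    for (r in which(flip)) {
      current <- strsplit(df$recommendations[r], "|", fixed = TRUE)[[1L]]
      pool <- setdiff(spec$labels, current)
      if (length(pool) == 0L) next
      df$recommendations[r] <- sample(pool, 1L)
      df$multiplicity[r] <- "single"
    }
    decision_table(pid, spec$criteria, df, check = TRUE)
  })
  list(ensemble = ensemble, truth = truth, truth_table = truth_table)
}
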