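#' Expand a decision tree over the full scenario space
#'
#' Evaluates the tree on every permutation of decision criteria, yielding the
#' participant's complete decision table. Criteria the tree never tests
#' simply replicate the recommendation across their levels.
#'
#' @param tree A valid `tc_decision_tree`.
#' @param criteria Criteria set to expand over; must contain every criterion
#'   the tree uses. Defaults to the tree's own set.
#' @return A complete `tc_decision_table`.
#' @export
expand_tree <- function(tree, criteria = tree$criteria) {
  missing <- setdiff(tree$criteria_used, cs_names(criteria))
  if (length(missing))
    tc_error("tc_semantic_error",
             sprintf("expansion criteria lack criteria used by the tree: %s",
                     paste(missing, collapse = ", ")))
  # gate on the validation report (not the stricter construction check):
  # exactly the trees validate_tree calls valid are expandable
  rep <- validate_tree(tree, criteria)
  if (!rep$is_valid)
    tc_error("tc_semantic_error",
             sprintf("tree of '%s' is not valid (%s); resolve the report first",
                     tree$participant_id,
                     paste(unique(rep$issues$category), collapse = ", ")))
  space <- scenario_space(criteria)
  nms <- cs_names(criteria)
  recs <- character(nrow(space))
  mult <- character(nrow(space))
  for (r in seq_len(nrow(space))) {
    scen <- as.character(space[r, nms]); names(scen) <- nms
    rs <- tryCatch(evaluate_tree(tree, scen), tc_error = function(e)
      tc_error(class(e)[1L], sprintf("at scenario (%s): %s",
                                     paste(sprintf("%s=%s", nms, scen), collapse = ", "),
                                     conditionMessage(e))))
    recs[r] <- rec_members_string(rs)
    mult[r] <- rs$multiplicity
  }
  df <- space
  df$recommendations <- recs
  df$multiplicity <- mult
  decision_table(tree$participant_id, criteria, df,
                 finalisation_date = tree$finalisation_date, check = FALSE)
}

#' Vote weights of one recommendation cell
#'
#' Converts one participant's recommendation set at a scenario into votes
#' under the configured multiplicity policy:
#' \describe{
#'   \item{any-recommended}{every member gets a vote; with
#'     `whole_votes = FALSE` (default) each of the k members receives 1/k so
#'     that each participant casts total weight 1 (keeping ensemble size as
#'     the congruency denominator), with `whole_votes = TRUE` each member
#'     receives a full vote;}
#'   \item{main-recommended}{one full vote for the single or top-ranked
#'     member; several members without a ranking are a policy error.}
#' }
#'
#' @param rec A `tc_rec_set`.
#' @param policy `"any-recommended"` or `"main-recommended"`.
#' @param whole_votes Give each member a full vote under `any-recommended`?
#' @return Named numeric vector of vote weights per label.
#' @examples
#' vote_weights(rec_set(c("SUN", "PAZ"), "equivalent-alternatives"),
#'              "any-recommended")
#' @export
vote_weights <- function(rec, policy = c("any-recommended", "main-recommended"),
                         whole_votes = FALSE) {
  policy <- match.arg(policy)
  m <- rec$members
  if (policy == "main-recommended") {
    if (length(m) > 1L && rec$multiplicity != "ranked")
      tc_error("tc_policy_error",
               "main-recommended policy needs a ranking (or a single recommendation)")
    w <- 1
    names(w) <- m[1L]  # ranked members are stored in preference order
    return(w)
  }
  w <- rep(if (whole_votes) 1 else 1 / length(m), length(m))
  names(w) <- m
  w
}

#' Per-scenario consensus across an ensemble
#'
#' For every scenario of the shared criteria set, sums each participant's
#' vote weights ([vote_weights()]) into per-label counts and derives the
#' descriptive consensus statistics:
#' \describe{
#'   \item{mode set}{all labels attaining the maximum count — ties are never
#'     broken, the method's premise being the absence of moderator bias;}
#'   \item{congruency rate}{maximum count divided by the number of voting
#'     participants (a fraction; multiply by 100 for the usual percentage);}
#'   \item{strict majority}{the label supported by *more than* 50% of voting
#'     participants, or none — an exact 50/50 split is no majority.}
#' }
#' Participants whose table marks a scenario excluded abstain there: they
#' contribute no vote and the cell's denominator `n_voting` shrinks.
#'
#' @param ensemble List of complete `tc_decision_table`s over one shared
#'   criteria set.
#' @param policy,whole_votes Passed to [vote_weights()].
#' @return A `tc_consensus_table`: the criteria set, a `cells` data.frame
#'   (scenario levels, `n_voting`, `mode` pipe-joined, `congruency` fraction,
#'   `majority` or `NA`), a `counts` matrix (scenarios x labels), and
#'   ensemble metadata (ids, finalisation dates, the policy).
#' @export
consensus_table <- function(ensemble, policy = c("any-recommended", "main-recommended"),
                            whole_votes = FALSE) {
  policy <- match.arg(policy)
  if (length(ensemble) == 0L)
    tc_error("tc_semantic_error", "ensemble must be nonempty")
  criteria <- ensemble[[1L]]$criteria
  for (tab in ensemble) {
    if (!cs_equal(tab$criteria, criteria)) {
      a <- cs_names(criteria); b <- cs_names(tab$criteria)
      tc_error("tc_semantic_error",
               sprintf("criteria sets differ (participant '%s'); symmetric difference: %s",
                       tab$participant_id,
                       paste(union(setdiff(a, b), setdiff(b, a)), collapse = ", ")))
    }
  }

  space <- scenario_space(criteria)
  nms <- cs_names(criteria)
  n_scen <- nrow(space)
  labels <- sort(unique(unlist(lapply(ensemble, function(tab)
    unlist(strsplit(tab$data$recommendations[!tab$data$excluded], "|", fixed = TRUE))))))
  counts <- matrix(0, nrow = n_scen, ncol = length(labels),
                   dimnames = list(NULL, labels))
  n_voting <- rep(0L, n_scen)

  for (tab in ensemble) {
    df <- tab$data  # rows already in scenario_space order
    for (r in seq_len(n_scen)) {
      if (df$excluded[r]) next
      w <- vote_weights(rec_from_string(df$recommendations[r], df$multiplicity[r]),
                        policy, whole_votes)
      counts[r, names(w)] <- counts[r, names(w)] + w
      n_voting[r] <- n_voting[r] + 1L
    }
  }

  # fractional weights make exact ties float-fragile; compare at 1e-9
  eps <- 1e-9
  mode_chr <- character(n_scen)
  congruency <- rep(NA_real_, n_scen)
  majority <- rep(NA_character_, n_scen)
  for (r in seq_len(n_scen)) {
    if (n_voting[r] == 0L) { mode_chr[r] <- ""; next }
    top <- max(counts[r, ])
    modes <- labels[counts[r, ] >= top - eps]
    mode_chr[r] <- paste(modes, collapse = "|")
    congruency[r] <- top / n_voting[r]
    if (length(modes) == 1L && top > n_voting[r] / 2 + eps)
      majority[r] <- modes
  }

  cells <- space
  cells$n_voting <- n_voting
  cells$mode <- mode_chr
  cells$congruency <- congruency
  cells$majority <- majority

  structure(
    list(criteria = criteria, cells = cells, counts = counts,
         meta = list(
           participant_ids = vapply(ensemble, `[[`, character(1L), "participant_id"),
           finalisation_dates = as.Date(vapply(ensemble, function(t)
             format(t$finalisation_date), character(1L))),
           policy = policy, whole_votes = whole_votes,
           n_participants = length(ensemble))),
    class = "tc_consensus_table"
  )
}

#' Project a consensus table onto its modal recommendations
#'
#' Yields a decision table whose cell at each scenario is the mode set
#' (multiplicity `equivalent-alternatives` when tied) — the input from which
#' the compact consensus ("mode") tree is induced.
#'
#' @param ct A `tc_consensus_table`.
#' @param participant_id Id recorded on the projected table.
#' @return A complete `tc_decision_table`.
#' @export
mode_projection <- function(ct, participant_id = "consensus-mode") {
  cells <- ct$cells
  if (any(cells$n_voting == 0L))
    tc_error("tc_semantic_error",
             "cannot project: some scenario received no votes at all")
  nms <- cs_names(ct$criteria)
  df <- cells[, nms, drop = FALSE]
  df$recommendations <- cells$mode
  df$multiplicity <- ifelse(grepl("|", cells$mode, fixed = TRUE),
                            "equivalent-alternatives", "single")
  decision_table(participant_id, ct$criteria, df, check = TRUE)
}

#' @export
print.tc_consensus_table <- function(x, ...) {
  cat(sprintf("Consensus table: %d participants, %d scenarios, policy %s%s\n",
              x$meta$n_participants, nrow(x$cells), x$meta$policy,
              if (x$meta$whole_votes) " (whole votes)" else ""))
  maj <- sum(!is.na(x$cells$majority))
  cat(sprintf("  strict majority reached in %d/%d scenarios; mean congruency %.1f%%\n",
              maj, nrow(x$cells), 100 * mean(x$cells$congruency, na.rm = TRUE)))
  invisible(x)
}

#' Export a consensus table as CSV
#'
#' One row per scenario: criterion levels, per-label vote counts, number of
#' voting participants, mode set, congruency in percent, strict-majority
#' label (empty when none). The policy in force is recorded in a leading
#' comment line.
#'
#' @param ct A `tc_consensus_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_consensus_csv <- function(ct, path) {
  df <- ct$cells
  counts <- as.data.frame(ct$counts)
  names(counts) <- paste0("votes.", names(counts))
  out <- cbind(df[, cs_names(ct$criteria), drop = FALSE], counts,
               n_voting = df$n_voting, mode = df$mode,
               congruency_pct = round(100 * df$congruency, 4L),
               majority = ifelse(is.na(df$majority), "", df$majority))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# policy=%s whole_votes=%s participants=%s finalisation_dates=%s",
                     ct$meta$policy, ct$meta$whole_votes,
                     paste(ct$meta$participant_ids, collapse = "|"),
                     paste(format(ct$meta$finalisation_dates), collapse = "|")), con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}
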