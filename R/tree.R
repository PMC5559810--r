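#' Build decision tree nodes
#'
#' `tree_leaf()` makes a terminal node carrying a recommendation set;
#' `tree_node()` makes an internal node testing one criterion, with branches
#' built by `tree_branch()`. Branches carry level *subsets* (not single
#' levels) so groupings such as "KPS below the cut-off" encode directly; at a
#' valid internal node the subsets are nonempty, pairwise disjoint, and
#' jointly cover the criterion's level set (a partition).
#'
#' @param labels,multiplicity Passed to [rec_set()]; `labels` may also be a
#'   ready-made `tc_rec_set`.
#' @param levels Character vector: the subset of criterion levels this branch
#'   captures.
#' @param node The child node (leaf or internal).
#' @param criterion Name of the criterion tested at this node.
#' @param branches List of branches created with `tree_branch()`.
#' @return Node objects of class `tc_node`.
#' @examples
#' tree_node("fitness",
#'           list(tree_branch("fit", tree_leaf("chemo")),
#'                tree_branch("unfit", tree_leaf("BSC"))))
#' @export
tree_leaf <- function(labels, multiplicity = NULL) {
  rs <- if (inherits(labels, "tc_rec_set")) labels else rec_set(labels, multiplicity)
  structure(list(type = "leaf", rec = rs), class = "tc_node")
}

#' @rdname tree_leaf
#' @export
tree_branch <- function(levels, node) {
  levels <- trim_label(levels)
  if (length(levels) == 0L)
    tc_error("tc_semantic_error", "branch level subset must be nonempty")
  if (!inherits(node, "tc_node"))
    tc_error("tc_semantic_error", "branch child must be a tree node")
  list(levels = levels, node = node)
}

#' @rdname tree_leaf
#' @export
tree_node <- function(criterion, branches) {
  assert_string(criterion, "criterion name")
  if (length(branches) == 0L)
    tc_error("tc_semantic_error", "internal node needs at least one branch")
  structure(list(type = "internal", criterion = trim_label(criterion),
                 branches = branches),
            class = "tc_node")
}

# names of criteria tested anywhere in the node's subtree
node_criteria <- function(node) {
  if (node$type == "leaf") return(character(0L))
  unique(c(node$criterion,
           unlist(lapply(node$branches, function(b) node_criteria(b$node)))))
}

#' Construct a participant decision tree
#'
#' One participant's treatment algorithm: internal nodes test criteria from a
#' governing criteria set, leaves carry recommendation sets. Provenance
#' (participant id and the tree finalisation date, recorded to fix the
#' analysis context) travels with the tree.
#'
#' With `check = TRUE` (default) the structural invariants are enforced at
#' construction: branch subsets at every node partition the criterion's level
#' set, no criterion repeats on a root-to-leaf path, and every tested
#' criterion belongs to `criteria`. Pass `check = FALSE` to hold a
#' structurally parseable but defective draft (the whole point of
#' [validate_tree()]).
#'
#' @param participant_id Identifier of the contributing participant.
#' @param root Root node, from [tree_node()] / [tree_leaf()].
#' @param criteria Governing [criteria_set()].
#' @param finalisation_date `Date` (or ISO-8601 string) on which the tree was
#'   frozen.
#' @param check Enforce structural invariants at construction?
#' @return An object of class `tc_decision_tree`.
#' @export
decision_tree <- function(participant_id, root, criteria,
                          finalisation_date = Sys.Date(), check = TRUE) {
  assert_string(participant_id, "participant_id")
  if (!inherits(root, "tc_node"))
    tc_error("tc_semantic_error", "root must be a tree node")
  if (!inherits(criteria, "tc_criteria_set"))
    tc_error("tc_semantic_error", "criteria must be a criteria set")
  finalisation_date <- as.Date(finalisation_date)
  tree <- structure(
    list(participant_id = participant_id,
         finalisation_date = finalisation_date,
         criteria = criteria,
         criteria_used = sort(node_criteria(root)),
         root = root),
    class = "tc_decision_tree"
  )
  if (check) check_tree_structure(tree)
  tree
}

# hard structural check: partition at every node, no repeats on a path,
# criteria known. Used at construction and before expansion.
check_tree_structure <- function(tree) {
  cs <- tree$criteria
  walk <- function(node, path_criteria) {
    if (node$type == "leaf") return(invisible(NULL))
    cname <- node$criterion
    if (!cname %in% cs_names(cs))
      tc_error("tc_semantic_error",
               sprintf("node tests unknown criterion '%s'", cname))
    if (cname %in% path_criteria)
      tc_error("tc_semantic_error",
               sprintf("criterion '%s' repeats on a root-to-leaf path", cname))
    lvls <- cs_levels(cs, cname)
    seen <- unlist(lapply(node$branches, `[[`, "levels"))
    bad <- setdiff(seen, lvls)
    if (length(bad))
      tc_error("tc_semantic_error",
               sprintf("branch levels not in criterion '%s': %s",
                       cname, paste(bad, collapse = ", ")))
    if (anyDuplicated(seen))
      tc_error("tc_semantic_error",
               sprintf("overlapping branch subsets at criterion '%s'", cname))
    missing <- setdiff(lvls, seen)
    if (length(missing))
      tc_error("tc_semantic_error",
               sprintf("branches at criterion '%s' do not cover levels: %s",
                       cname, paste(missing, collapse = ", ")))
    for (b in node$branches) walk(b$node, c(path_criteria, cname))
  }
  walk(tree$root, character(0L))
  invisible(tree)
}

#' Evaluate a decision tree on one scenario
#'
#' Follows, at each internal node, the unique branch whose level subset
#' contains the scenario's level for the tested criterion, and returns the
#' recommendation set at the leaf reached. Deterministic; criteria the tree
#' does not test cannot affect the path.
#'
#' @param tree A valid `tc_decision_tree`.
#' @param scenario Named character vector assigning one level to every
#'   criterion of the governing criteria set (extra names are ignored).
#' @return The leaf's `tc_rec_set`.
#' @examples
#' cs <- criteria_set(criterion("fitness", c("fit", "unfit")))
#' tr <- decision_tree("A",
#'   tree_node("fitness", list(tree_branch("fit", tree_leaf("chemo")),
#'                             tree_branch("unfit", tree_leaf("BSC")))), cs)
#' evaluate_tree(tr, c(fitness = "unfit"))
#' @export
evaluate_tree <- function(tree, scenario) {
  node <- tree$root
  while (node$type == "internal") {
    cname <- node$criterion
    if (!cname %in% names(scenario))
      tc_error("tc_unknown_criterion_error",
               sprintf("scenario assigns no level to criterion '%s'", cname))
    lvl <- scenario[[cname]]
    hit <- NULL
    for (b in node$branches) {
      if (lvl %in% b$levels) { hit <- b$node; break }
    }
    if (is.null(hit))
      tc_error("tc_missing_branch_error",
               sprintf("no branch at criterion '%s' matches level '%s'", cname, lvl))
    node <- hit
  }
  node$rec
}

#' Enumerate the scenario space
#'
#' Every permutation of decision criteria: the Cartesian product of the
#' criteria's level sets, one row per scenario. Order is deterministic —
#' criteria sorted by name left to right, rows in lexicographic order with
#' the leftmost criterion most significant and levels in their declared
#' order — so tables, diffs and reports are reproducible across runs and
#' platforms.
#'
#' @param criteria A [criteria_set()].
#' @return A `data.frame` with one character column per criterion and
#'   `prod(levels)` rows.
#' @examples
#' scenario_space(criteria_set(criterion("A", c("a1", "a2")),
#'                             criterion("B", c("b1", "b2", "b3"))))
#' @export
scenario_space <- function(criteria) {
  if (!inherits(criteria, "tc_criteria_set"))
    tc_error("tc_semantic_error", "criteria must be a criteria set")
  nms <- cs_names(criteria)
  lvls <- lapply(nms, function(n) cs_levels(criteria, n))
  names(lvls) <- nms
  # expand.grid varies the first factor fastest; reverse so the first
  # criterion (alphabetically) is most significant
  grid <- expand.grid(rev(lvls), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(nms)), drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' @export
print.tc_decision_tree <- function(x, ...) {
  cat(sprintf("Decision tree of participant '%s' (finalised %s)\n",
              x$participant_id, format(x$finalisation_date)))
  cat(sprintf("Criteria used: %s\n",
              if (length(x$criteria_used)) paste(x$criteria_used, collapse = ", ")
              else "(none - constant recommendation)"))
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(sprintf("%s-> [%s] %s\n", pad, node$rec$multiplicity,
                  paste(node$rec$members, collapse = " | ")))
    } else {
      for (b in node$branches) {
        cat(sprintf("%s%s in {%s}\n", pad, node$criterion,
                    paste(b$levels, collapse = ",")))
        show(b$node, indent + 1L)
      }
    }
  }
  show(x$root, 0L)
  invisible(x)
}
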