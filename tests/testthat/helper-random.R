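# random-case generators for property-style tests (use the current RNG
# state; tests wrap them in withr::with_seed-style set.seed calls)

rand_between <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

random_criteria_set <- function(n_criteria = rand_between(2L, 4L),
                                max_levels = 3L) {
  criteria_set(lapply(seq_len(n_criteria), function(i)
    criterion(sprintf("c%d", i),
              sprintf("c%d_l%d", i, seq_len(rand_between(2L, max_levels))))))
}

default_labels <- c("SUN", "PAZ", "BSC", "Gem")

# drop one randomly chosen branch from a node with >= 2 branches; NULL when
# the tree has no such node (single-leaf trees)
delete_random_branch <- function(tree) {
  nodes_with_choice <- 0L
  count <- function(node) {
    if (node$type == "leaf") return(invisible(NULL))
    if (length(node$branches) >= 2L) nodes_with_choice <<- nodes_with_choice + 1L
    for (b in node$branches) count(b$node)
  }
  count(tree$root)
  if (nodes_with_choice == 0L) return(NULL)
  target <- sample.int(nodes_with_choice, 1L)
  seen <- 0L
  prune <- function(node) {
    if (node$type == "leaf") return(node)
    if (length(node$branches) >= 2L) {
      seen <<- seen + 1L
      if (seen == target) {
        node$branches <- node$branches[-sample.int(length(node$branches), 1L)]
        return(node)
      }
    }
    node$branches <- lapply(node$branches, function(b) {
      b$node <- prune(b$node); b
    })
    node
  }
  root <- prune(tree$root)
  decision_tree(tree$participant_id, root, tree$criteria, check = FALSE)
}

# a scenario (named character vector) for row r of a table's space
scenario_at <- function(criteria, r) {
  space <- scenario_space(criteria)
  s <- as.character(space[r, names(criteria)])
  names(s) <- names(criteria)
  s
}
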