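# Independent brute-force oracles. These deliberately avoid the package's
# own traversal/counting code paths: paths are enumerated and constraints
# intersected by hand, votes are tallied with nested loops.

# all root-to-leaf paths of a tree as (constraints, rec) pairs;
# constraints: named list criterion -> allowed levels (intersected top-down)
oracle_paths <- function(tree) {
  out <- list()
  walk <- function(node, constraints) {
    if (node$type == "leaf") {
      out[[length(out) + 1L]] <<- list(constraints = constraints, rec = node$rec)
      return(invisible(NULL))
    }
    for (b in node$branches) {
      con2 <- constraints
      prev <- con2[[node$criterion]]
      con2[[node$criterion]] <- if (is.null(prev)) b$levels else intersect(prev, b$levels)
      walk(b$node, con2)
    }
  }
  walk(tree$root, list())
  out
}

# recommendation sets reachable from a scenario via path enumeration
oracle_evaluate <- function(tree, scenario) {
  hits <- Filter(function(p) {
    all(vapply(names(p$constraints), function(cn)
      scenario[[cn]] %in% p$constraints[[cn]], logical(1L)))
  }, oracle_paths(tree))
  lapply(hits, `[[`, "rec")
}

# scenario count by explicit nested recursion (no expand.grid)
oracle_scenario_count <- function(criteria) {
  nms <- names(criteria)
  count <- function(i) {
    if (i > length(nms)) return(1L)
    sum(vapply(criteria[[nms[i]]]$levels, function(l) count(i + 1L), integer(1L)))
  }
  count(1L)
}

# brute-force per-scenario consensus over decision tables
oracle_consensus_cell <- function(ensemble, scenario, policy = "any-recommended",
                                  whole_votes = FALSE) {
  counts <- stats::setNames(numeric(0L), character(0L))
  n_voting <- 0L
  for (tab in ensemble) {
    nms <- names(tab$criteria)
    df <- tab$data
    hit <- rep(TRUE, nrow(df))
    for (n in nms) hit <- hit & df[[n]] == scenario[[n]]
    r <- which(hit)
    stopifnot(length(r) == 1L)
    if (df$excluded[r]) next
    n_voting <- n_voting + 1L
    members <- strsplit(df$recommendations[r], "|", fixed = TRUE)[[1L]]
    if (policy == "main-recommended") {
      counts[members[1L]] <- (counts[members[1L]] %||0% 0) + 1
    } else {
      w <- if (whole_votes) 1 else 1 / length(members)
      for (m in members) counts[m] <- (counts[m] %||0% 0) + w
    }
  }
  if (n_voting == 0L)
    return(list(counts = counts, n_voting = 0L, mode = character(0L),
                congruency = NA_real_, majority = NA_character_))
  top <- max(counts)
  modes <- sort(names(counts)[counts >= top - 1e-9])
  list(counts = counts, n_voting = n_voting, mode = modes,
       congruency = top / n_voting,
       majority = if (length(modes) == 1L && top > n_voting / 2 + 1e-9)
         modes else NA_character_)
}

`%||0%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a

# semantic dependence by exhaustive pairwise scenario comparison
oracle_depends <- function(tab, cname) {
  nms <- names(tab$criteria)
  df <- tab$data
  cell <- paste(df$multiplicity, df$recommendations, df$excluded)
  for (i in seq_len(nrow(df) - 1L)) for (j in seq((i + 1L), nrow(df))) {
    differ <- vapply(nms, function(n) df[[n]][i] != df[[n]][j], logical(1L))
    if (sum(differ) == 1L && names(differ)[differ] == cname && cell[i] != cell[j])
      return(TRUE)
  }
  FALSE
}

# exact P(truth label is the unique mode) for n voters each keeping the
# truth with prob 1-eps and switching to one of L-1 other labels with prob
# eps/(L-1) each: enumerate all multinomial count vectors
oracle_recovery_prob <- function(n, L, eps) {
  p <- c(1 - eps, rep(eps / (L - 1), L - 1))
  total <- 0
  rec <- function(i, left, counts) {
    if (i == L) {
      counts <- c(counts, left)
      if (counts[1L] > max(counts[-1L]))
        total <<- total + exp(lgamma(n + 1) - sum(lgamma(counts + 1)) +
                                sum(counts * log(p)))
      return(invisible(NULL))
    }
    for (k in 0:left) rec(i + 1L, left - k, c(counts, k))
  }
  rec(1L, n, numeric(0L))
  total
}
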