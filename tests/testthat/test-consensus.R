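test_that("vote weights follow the multiplicity policy", {
  expect_equal(vote_weights(rec_set("SUN"), "any-recommended"), c(SUN = 1))
  expect_equal(vote_weights(rec_set("SUN"), "main-recommended"), c(SUN = 1))
  expect_equal(vote_weights(rec_set(c("SUN", "PAZ"), "equivalent-alternatives"),
                            "any-recommended"),
               c(SUN = 0.5, PAZ = 0.5))
  expect_equal(vote_weights(rec_set(c("PAZ", "SUN"), "ranked"), "main-recommended"),
               c(PAZ = 1))
  expect_equal(vote_weights(rec_set(c("SUN", "PAZ"), "equivalent-alternatives"),
                            "any-recommended", whole_votes = TRUE),
               c(SUN = 1, PAZ = 1))
  expect_error(vote_weights(rec_set(c("SUN", "PAZ"), "equivalent-alternatives"),
                            "main-recommended"),
               class = "tc_policy_error")
})

test_that("expansion replicates over unused criteria and matches an evaluate sweep", {
  cs <- criteria_set(criterion("age", c("<70", ">=70")),
                     criterion("fitness", c("fit", "unfit")))
  tr <- decision_tree("A", tree_node("fitness", list(
    tree_branch("fit", tree_leaf("chemo")), tree_branch("unfit", tree_leaf("BSC")))), cs)
  tab <- expand_tree(tr)
  expect_equal(nrow(tab$data), 4L)
  expect_equal(sort(unique(tab$data$recommendations)), c("BSC", "chemo"))

  const <- expand_tree(decision_tree("B", tree_leaf("X"), cs))
  expect_equal(unique(const$data$recommendations), "X")

  set.seed(407)
  for (i in 1:100) {
    cs <- random_criteria_set()
    tr <- random_tree(cs, default_labels)
    tab <- expand_tree(tr)
    for (r in seq_len(nrow(tab$data))) {
      rs <- evaluate_tree(tr, scenario_at(cs, r))
      expect_equal(tab$data$recommendations[r], rec_members_string(rs))
      expect_equal(tab$data$multiplicity[r], rs$multiplicity)
    }
  }
})

test_that("consensus cells: counts, mode, congruency, strict majority", {
  cs <- criteria_set(criterion("a", c("x", "y")))
  tab <- function(id, rx, ry) {
    df <- scenario_space(cs)
    df$recommendations <- c(rx, ry)
    df$multiplicity <- "single"
    decision_table(id, cs, df)
  }
  ct <- consensus_table(list(tab("P1", "A", "A"), tab("P2", "A", "B"),
                             tab("P3", "B", "B")))
  # at scenario x: A,A,B
  expect_equal(ct$counts[1L, ], c(A = 2, B = 1))
  expect_equal(ct$cells$mode[1L], "A")
  expect_equal(ct$cells$congruency[1L], 2 / 3)
  expect_equal(ct$cells$majority[1L], "A")

  # mismatched criteria sets are rejected with the symmetric difference
  cs2 <- criteria_set(criterion("b", c("x", "y")))
  df <- scenario_space(cs2); df$recommendations <- "A"; df$multiplicity <- "single"
  err <- tryCatch(consensus_table(list(tab("P1", "A", "A"),
                                       decision_table("P4", cs2, df))),
                  tc_error = function(e) conditionMessage(e))
  expect_match(err, "a")
  expect_match(err, "b")
})

test_that("an even split yields tied modes, 50% congruency and no majority", {
  cs <- criteria_set(criterion("a", c("x", "y")))
  mk <- function(id, r) {
    df <- scenario_space(cs)
    df$recommendations <- r
    df$multiplicity <- "single"
    decision_table(id, cs, df)
  }
  ensemble <- c(lapply(1:12, function(i) mk(sprintf("P%02d", i), "A")),
                lapply(13:24, function(i) mk(sprintf("P%02d", i), "B")))
  ct <- consensus_table(ensemble)
  expect_equal(ct$cells$n_voting, c(2L, 2L) * 12L)
  expect_equal(ct$cells$mode, c("A|B", "A|B"))
  expect_equal(ct$cells$congruency, c(0.5, 0.5))
  expect_true(all(is.na(ct$cells$majority)))
})

test_that("consensus matches the brute-force counting oracle on random ensembles", {
  set.seed(408)
  for (i in 1:40) {
    cs <- random_criteria_set(n_criteria = rand_between(1L, 3L))
    n <- rand_between(2L, 8L)
    policy <- sample(c("any-recommended", "main-recommended"), 1L)
    ensemble <- lapply(seq_len(n), function(j)
      random_table(cs, default_labels, sprintf("P%02d", j),
                   p_multi = if (policy == "any-recommended") 0.3 else 0))
    # sprinkle exclusions
    ensemble <- lapply(ensemble, function(tab) {
      ex <- runif(nrow(tab$data)) < 0.1
      tab$data$excluded[ex] <- TRUE
      tab$data$reason[ex] <- "not applicable"
      tab
    })
    ct <- consensus_table(ensemble, policy = policy)
    sp <- scenario_space(cs)
    for (r in seq_len(nrow(sp))) {
      want <- oracle_consensus_cell(ensemble, scenario_at(cs, r), policy)
      expect_equal(ct$cells$n_voting[r], want$n_voting)
      got_counts <- ct$counts[r, ct$counts[r, ] > 0]
      expect_equal(sort(names(got_counts)), sort(names(want$counts[want$counts > 0])))
      expect_equal(got_counts[sort(names(got_counts))],
                   want$counts[sort(names(got_counts))], tolerance = 1e-9)
      expect_equal(sort(strsplit(ct$cells$mode[r], "|", fixed = TRUE)[[1L]]),
                   want$mode)
      expect_equal(ct$cells$congruency[r], want$congruency, tolerance = 1e-9)
      expect_equal(ct$cells$majority[r], want$majority)
      # vote conservation: total weight equals the number of voters
      if (want$n_voting > 0L)
        expect_equal(sum(ct$counts[r, ]), want$n_voting, tolerance = 1e-9)
      # congruency bounds
      if (want$n_voting > 0L) {
        expect_lte(ct$cells$congruency[r], 1)
        expect_gte(ct$cells$congruency[r], 1 / ncol(ct$counts))
      }
    }
  }
})

test_that("adding a participant who votes the unique mode keeps it modal", {
  set.seed(409)
  cs <- criteria_set(criterion("a", c("x", "y")), criterion("b", c("u", "v")))
  for (i in 1:10) {
    ensemble <- lapply(1:5, function(j)
      random_table(cs, default_labels, sprintf("P%d", j)))
    ct <- consensus_table(ensemble)
    modes <- strsplit(ct$cells$mode, "|", fixed = TRUE)
    unique_mode <- vapply(modes, length, integer(1L)) == 1L
    if (!any(unique_mode)) next
    df <- scenario_space(cs)
    df$recommendations <- vapply(seq_len(nrow(df)), function(r)
      if (unique_mode[r]) modes[[r]][1L] else sample(default_labels, 1L),
      character(1L))
    df$multiplicity <- "single"
    ct2 <- consensus_table(c(ensemble, list(decision_table("P6", cs, df))))
    for (r in which(unique_mode))
      expect_true(modes[[r]][1L] %in% strsplit(ct2$cells$mode[r], "|", fixed = TRUE)[[1L]])
  }
})

test_that("induced trees are lossless and minimal", {
  cs <- criteria_set(criterion("a", c("x", "y")), criterion("b", c("u", "v", "w")))

  # constant table -> single leaf
  df <- scenario_space(cs); df$recommendations <- "Z"; df$multiplicity <- "single"
  tr <- induce_tree(decision_table("C", cs, df))
  expect_equal(tr$root$type, "leaf")
  expect_length(tr$criteria_used, 0L)

  # table depending on exactly one criterion -> one internal node
  df$recommendations <- ifelse(df$a == "x", "L", "R")
  tr <- induce_tree(decision_table("C", cs, df))
  expect_equal(tr$root$type, "internal")
  expect_equal(tr$criteria_used, "a")
  expect_true(all(vapply(tr$root$branches, function(b) b$node$type == "leaf", logical(1L))))

  set.seed(410)
  for (i in 1:50) {
    cs <- random_criteria_set()
    # biased label pools make vacuous criteria common enough to exercise
    tab <- random_table(cs, default_labels[seq_len(rand_between(2L, 3L))],
                        "T", p_multi = 0.2)
    tr <- induce_tree(tab)
    back <- expand_tree(tr, cs)
    expect_identical(back$data$recommendations, tab$data$recommendations)
    expect_identical(back$data$multiplicity, tab$data$multiplicity)
    for (cname in names(cs))
      if (!oracle_depends(tab, cname))
        expect_false(cname %in% tr$criteria_used)
  }
})
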