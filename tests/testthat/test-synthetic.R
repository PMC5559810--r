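base_spec <- function(n = 5L, eps = 0, omit = 0, seed = 11L,
                      labels = c("A", "B", "C", "D")) {
  synthetic_spec(
    n_participants = n,
    criteria = criteria_set(criterion("c1", c("l1", "l2")),
                            criterion("c2", c("l1", "l2")),
                            criterion("c3", c("l1", "l2"))),
    labels = labels, deviation_rate = eps, omission_rate = omit, seed = seed)
}

test_that("a noiseless panel reproduces the truth with unanimous consensus", {
  gen <- generate_ensemble(base_spec(n = 5L, eps = 0))
  for (tab in gen$ensemble)
    expect_identical(tab$data[, c("recommendations", "multiplicity")],
                     gen$truth_table$data[, c("recommendations", "multiplicity")])
  ct <- consensus_table(gen$ensemble)
  expect_true(all(ct$cells$congruency == 1))
  expect_identical(mode_projection(ct)$data$recommendations,
                   gen$truth_table$data$recommendations)
})

test_that("generation is byte-reproducible and prefix-stable in panel size", {
  g1 <- generate_ensemble(base_spec(n = 6L, eps = 0.3, omit = 0.2, seed = 42L))
  g2 <- generate_ensemble(base_spec(n = 6L, eps = 0.3, omit = 0.2, seed = 42L))
  expect_identical(lapply(g1$ensemble, `[[`, "data"),
                   lapply(g2$ensemble, `[[`, "data"))

  # adding participants never perturbs earlier ones
  g3 <- generate_ensemble(base_spec(n = 9L, eps = 0.3, omit = 0.2, seed = 42L))
  expect_identical(lapply(g1$ensemble, `[[`, "data"),
                   lapply(g3$ensemble[1:6], `[[`, "data"))

  # a different seed changes the draw
  g4 <- generate_ensemble(base_spec(n = 6L, eps = 0.3, omit = 0.2, seed = 43L))
  expect_false(identical(lapply(g1$ensemble, `[[`, "data"),
                         lapply(g4$ensemble, `[[`, "data")))
})

test_that("omitted criteria leave participants semantically independent of them", {
  gen <- generate_ensemble(base_spec(n = 8L, eps = 0, omit = 1, seed = 7L))
  for (tab in gen$ensemble) {
    # omission 1: independent of every criterion (constant union table)
    for (cname in names(tab$criteria))
      expect_false(table_depends_on(tab, cname))
    expect_equal(nrow(tab$data), 8L)  # axes retained for the shared space
  }
})

test_that("deviations replace cells by a different label at the stated rate", {
  set.seed(1)
  gen <- generate_ensemble(base_spec(n = 60L, eps = 0.25, seed = 99L))
  truth <- gen$truth_table$data$recommendations
  flips <- vapply(gen$ensemble, function(tab)
    sum(tab$data$recommendations != truth), numeric(1L))
  rate <- sum(flips) / (60L * length(truth))
  # binomial(480, 0.25): 3 sigma around the mean
  expect_lt(abs(rate - 0.25), 3 * sqrt(0.25 * 0.75 / (60 * length(truth))))
  # flipped cells never keep the truth label
  for (tab in gen$ensemble[1:5]) {
    changed <- tab$data$recommendations != truth
    expect_true(all(tab$data$recommendations[changed] != truth[changed]))
    expect_true(all(tab$data$multiplicity[changed] == "single"))
  }
})

test_that("the six-center cut-off census matches the collected encodings", {
  ps <- performance_status_cutoffs()
  expect_equal(nrow(ps$census), 6L)
  expect_equal(ps$census$center, LETTERS[1:6])
  expect_equal(ps$census$cutoff[ps$census$scale == "KPS"], c(50L, 60L, 70L, 90L))
  expect_equal(ps$census$scale, c("KPS", "KPS", "KPS", "KPS", "ECOG", "none"))

  # every encoding maps totally onto fit/unfit
  expect_equal(length(ps$rules$rules), 6L)
  for (r in ps$rules$rules) {
    expect_equal(r$target, "fitness")
    expect_setequal(unname(r$map), c("fit", "unfit"))
  }
  # the unscaled center maps good/bad 1:1 with an explanatory note
  f <- ps$rules$rules[[6L]]
  expect_equal(unname(f$map[c("good", "bad")]), c("fit", "unfit"))
  expect_match(f$note, "moderation")
})
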