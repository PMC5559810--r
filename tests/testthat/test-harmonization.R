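test_that("a KPS-keyed table harmonizes to fit/unfit via the cut-off rule", {
  kps <- criteria_set(criterion("KPS", c("<50", ">=50")),
                      criterion("site", c("local", "metastatic")))
  df <- scenario_space(kps)
  df$recommendations <- ifelse(df$KPS == ">=50", "chemo", "BSC")
  df$multiplicity <- "single"
  tab <- decision_table("A", kps, df)

  harmonized <- apply_rules(tab, performance_status_cutoffs()$rules)
  expect_setequal(names(harmonized$criteria), c("fitness", "site"))
  expect_equal(cs_levels(harmonized$criteria, "fitness"), c("fit", "unfit"))
  hd <- harmonized$data
  expect_equal(hd$recommendations[hd$fitness == "fit"], c("chemo", "chemo"))
  expect_equal(hd$recommendations[hd$fitness == "unfit"], c("BSC", "BSC"))
})

test_that("identity rules leave a table unchanged", {
  cs <- criteria_set(criterion("a", c("x", "y")), criterion("b", c("u", "v")))
  set.seed(411)
  tab <- random_table(cs, default_labels, "P")
  ident <- harmonization_rules(cs, list(
    harmonization_rule("*", "a", "a", c(x = "x", y = "y")),
    harmonization_rule("*", "b", "b", c(u = "u", v = "v"))))
  out <- apply_rules(tab, ident)
  expect_identical(out$data, tab$data)
})

test_that("harmonized cells equal brute-force regrouping by preimage", {
  set.seed(412)
  for (i in 1:30) {
    # source criterion with 3-4 levels surjectively mapped onto 2 target levels
    k <- rand_between(3L, 4L)
    src_lvls <- sprintf("s%d", seq_len(k))
    cs <- criteria_set(criterion("grade", src_lvls),
                       criterion("other", c("o1", "o2")))
    tab <- random_table(cs, default_labels, "P")
    tgt <- c("low", "high")
    map <- stats::setNames(sample(c(tgt, sample(tgt, k - 2L, replace = TRUE))), src_lvls)
    rules <- harmonization_rules(
      criteria_set(criterion("grade2", tgt)),
      list(harmonization_rule("P", "grade", "grade2", map)))
    out <- apply_rules(tab, rules)

    expect_setequal(names(out$criteria), c("grade2", "other"))
    # completeness over the harmonized product
    expect_equal(nrow(out$data), 4L)
    for (t in tgt) for (o in c("o1", "o2")) {
      pre <- names(map)[map == t]
      rows <- tab$data$grade %in% pre & tab$data$other == o
      members <- sort(unique(unlist(strsplit(tab$data$recommendations[rows],
                                             "|", fixed = TRUE))))
      got <- out$data[out$data$grade2 == t & out$data$other == o, ]
      expect_equal(sort(strsplit(got$recommendations, "|", fixed = TRUE)[[1L]]), members)
      if (length(members) > 1L)
        expect_equal(got$multiplicity, "equivalent-alternatives")
    }
    # merge notes recorded whenever a union is non-singleton from distinct cells
    notes <- attr(out, "notes")
    expect_true(all(grepl("merged", notes$message)))
  }
})

test_that("partial rule sets and contradictory double mappings are errors", {
  cs <- criteria_set(criterion("KPS", c("<50", ">=50")))
  df <- scenario_space(cs); df$recommendations <- "X"; df$multiplicity <- "single"
  tab <- decision_table("A", cs, df)
  partial <- harmonization_rules(
    criteria_set(criterion("fitness", c("fit", "unfit"))),
    list(harmonization_rule("A", "KPS", "fitness", c("<50" = "unfit"))))
  expect_error(apply_rules(tab, partial), class = "tc_partial_rules_error")

  # two source criteria onto one target, disagreeing on some rows
  cs2 <- criteria_set(criterion("age", c("young", "old")),
                      criterion("ps", c("good", "bad")))
  df2 <- scenario_space(cs2); df2$recommendations <- "X"; df2$multiplicity <- "single"
  tab2 <- decision_table("B", cs2, df2)
  both <- harmonization_rules(
    criteria_set(criterion("fitness", c("fit", "unfit"))),
    list(harmonization_rule("B", "age", "fitness", c(young = "fit", old = "unfit")),
         harmonization_rule("B", "ps", "fitness", c(good = "fit", bad = "unfit"))))
  expect_error(apply_rules(tab2, both), class = "tc_merge_ambiguity_error")
})

test_that("rules can introduce a collective criterion by replication", {
  # the Zugzwang pattern: a participant who never used the criterion gets
  # explicit non-dependence across its levels
  cs <- criteria_set(criterion("fitness", c("fit", "unfit")))
  df <- scenario_space(cs)
  df$recommendations <- c("SUN", "BSC")
  df$multiplicity <- "single"
  tab <- decision_table("P", cs, df)
  rules <- harmonization_rules(
    criteria_set(criterion("fitness", c("fit", "unfit")),
                 criterion("zugzwang", c("yes", "no"))),
    list())
  out <- apply_rules(tab, rules)
  expect_setequal(names(out$criteria), c("fitness", "zugzwang"))
  expect_equal(nrow(out$data), 4L)
  expect_false(table_depends_on(out, "zugzwang"))
  expect_true(table_depends_on(out, "fitness"))
})

test_that("criterion census counts semantic dependence against the oracle", {
  cs <- criteria_set(criterion("a", c("x", "y")), criterion("b", c("u", "v")))
  # participant ignoring b entirely
  df <- scenario_space(cs)
  df$recommendations <- ifelse(df$a == "x", "L", "R")
  df$multiplicity <- "single"
  dep_a <- decision_table("P1", cs, df)
  df$recommendations <- "L"
  const <- decision_table("P2", cs, df)
  cen <- criterion_census(list(dep_a, const))
  expect_equal(cen$a, "P1")
  expect_equal(cen$b, character(0L))

  set.seed(413)
  for (i in 1:10) {
    cs <- random_criteria_set(n_criteria = rand_between(2L, 3L))
    ensemble <- lapply(1:4, function(j)
      random_table(cs, c("L", "R"), sprintf("P%d", j)))
    cen <- criterion_census(ensemble)
    for (cname in names(cs)) {
      want <- sort(vapply(ensemble, `[[`, character(1L), "participant_id")[
        vapply(ensemble, oracle_depends, logical(1L), cname)])
      expect_equal(sort(cen[[cname]]), want)
    }
  }
})

test_that("inclusion filtering drops under-used criteria and documents it", {
  cs <- criteria_set(criterion("a", c("x", "y")), criterion("rare", c("p", "q")))
  mk <- function(id, use_rare) {
    df <- scenario_space(cs)
    df$recommendations <- if (use_rare)
      ifelse(df$rare == "p", "L", "R") else ifelse(df$a == "x", "L", "R")
    df$multiplicity <- "single"
    decision_table(id, cs, df)
  }
  ensemble <- list(mk("P1", TRUE), mk("P2", TRUE), mk("P3", FALSE),
                   mk("P4", FALSE), mk("P5", FALSE), mk("P6", FALSE))

  # 'rare' used by 2 of 6 < k = 3: dropped and logged
  filt <- inclusion_filter(ensemble, k = 3L)
  expect_equal(filt$exclusions$criterion, "rare")
  expect_equal(filt$exclusions$n_users, 2L)
  expect_setequal(names(filt$ensemble[[1L]]$criteria), "a")
  # marginalized users of 'rare' now hold unioned equivalent alternatives
  expect_equal(unique(filt$ensemble[[1L]]$data$multiplicity), "equivalent-alternatives")
  expect_gt(nrow(filt$notes), 0L)

  # k = 1 is the identity, with an empty log
  filt1 <- inclusion_filter(ensemble, k = 1L)
  expect_equal(nrow(filt1$exclusions), 0L)
  expect_identical(filt1$ensemble, ensemble)

  set.seed(414)
  for (i in 1:10) {
    cs <- random_criteria_set(n_criteria = rand_between(2L, 3L))
    ensemble <- lapply(1:5, function(j) random_table(cs, c("L", "R"), sprintf("P%d", j)))
    k <- rand_between(1L, 5L)
    cen <- criterion_census(ensemble)
    kept_want <- names(cen)[vapply(cen, length, integer(1L)) >= k]
    res <- tryCatch(inclusion_filter(ensemble, cen, k), tc_error = function(e) e)
    if (length(kept_want) == 0L) {
      # degenerate: everything under threshold; the filter refuses to
      # marginalize away the whole space
      expect_s3_class(res, "tc_semantic_error")
    } else {
      expect_setequal(names(res$ensemble[[1L]]$criteria), kept_want)
      expect_setequal(res$exclusions$criterion, setdiff(names(cs), kept_want))
    }
  }
})
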