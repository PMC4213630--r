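test_that("homozygosity table counts exposure by outcome correctly", {
  rec <- make_records(c("1/1", "1/2", "2/3"),
                      c("case", "case", "control"))
  tab <- build_homozygosity_table(rec)
  expect_equal(unlist(tab[c("a", "b", "c", "d")]),
               c(a = 1, b = 0, c = 1, d = 1))
  # empty case group still yields a valid table
  rec2 <- make_records(c("1/1", "1/2"), c("control", "control"))
  tab2 <- build_homozygosity_table(rec2)
  expect_equal(tab2$a + tab2$c, 0)
  # cells always sum to the record count on simulated data
  rec3 <- simulate_cohort(sim_config(n_animals = 200, seed = 3))
  expect_equal(build_homozygosity_table(rec3)$n, 200)
})

test_that("allele strata assign heterozygotes to both carrier strata", {
  rec <- make_records(c("1/1", "1/2"), c("case", "control"))
  st <- build_allele_strata(rec)
  expect_equal(st$labels, c("1", "2"))
  expect_equal(unlist(st$tables[[1]][c("a", "b", "c", "d")]),
               c(a = 1, b = 0, c = 0, d = 1))
  expect_equal(unlist(st$tables[[2]][c("a", "b", "c", "d")]),
               c(a = 0, b = 0, c = 0, d = 1))
  # all-homozygote input: each animal in exactly one stratum
  rec2 <- make_records(c("1/1", "2/2", "2/2"), c("case", "control", "case"))
  st2 <- build_allele_strata(rec2)
  expect_equal(sum(vapply(st2$tables, `[[`, 0, "n")), 3)
  # counting identity: total stratum size = n_hom + 2 * n_het
  rec3 <- simulate_cohort(sim_config(n_animals = 150, seed = 5))
  st3 <- build_allele_strata(rec3)
  expect_equal(sum(vapply(st3$tables, `[[`, 0, "n")),
               sum(rec3$is_homozygous) + 2 * sum(!rec3$is_homozygous))
})

test_that("logistic OR equals the cross-product ratio and is symmetric", {
  r <- fit_logit_or(table2x2(10, 10, 10, 10))
  expect_equal(r$odds_ratio, 1, tolerance = 1e-8)
  expect_equal(r$p_value, 1, tolerance = 1e-8)
  r2 <- fit_logit_or(table2x2(20, 10, 10, 20))
  expect_equal(r2$odds_ratio, 4, tolerance = 1e-8)
  set.seed(101)
  for (i in 1:50) {
    tab <- random_table(200, min_cell = 1)
    fit <- fit_logit_or(tab)
    expect_equal(fit$odds_ratio, tab$a * tab$d / (tab$b * tab$c),
                 tolerance = 1e-8)
    expect_false(fit$corrected)
    expect_true(fit$ci_low <= fit$odds_ratio &&
                  fit$odds_ratio <= fit$ci_high)
    expect_true(fit$p_value >= 0 && fit$p_value <= 1)
  }
})

test_that("zero cells trigger the Haldane-Anscombe policy and are flagged", {
  tab <- table2x2(5, 0, 3, 7)
  r <- fit_logit_or(tab)
  expect_true(r$corrected)
  expect_equal(r$odds_ratio, (5.5 * 7.5) / (0.5 * 3.5), tolerance = 1e-12)
  expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)
})

test_that("Fisher two-sided p agrees with enumeration and stats::fisher.test", {
  expect_equal(fisher_exact_two_sided(table2x2(1, 0, 6, 26))$p_value,
               7 / 33, tolerance = 1e-12)
  # degenerate margins: only one table possible
  expect_equal(fisher_exact_two_sided(table2x2(0, 4, 0, 9))$p_value, 1)
  set.seed(202)
  for (i in 1:100) {
    tab <- random_table(30)
    p <- fisher_exact_two_sided(tab)$p_value
    expect_equal(p, fisher_enum_p(tab), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(as.matrix(tab))$p.value,
                 tolerance = 1e-7)
  }
})

test_that("Mantel-Haenszel common OR matches the direct formula and reductions", {
  single <- stratified_tables(list(table2x2(20, 10, 10, 20)))
  expect_equal(mh_common_or(single)$odds_ratio, 4)
  # replication invariance
  twin <- stratified_tables(list(table2x2(20, 10, 10, 20),
                                 table2x2(20, 10, 10, 20)))
  expect_equal(mh_common_or(twin)$odds_ratio, 4)
  set.seed(303)
  for (i in 1:50) {
    st <- random_strata(sample(1:3, 1))
    r <- mh_common_or(st)
    expect_equal(r$odds_ratio, mh_or_direct(st), tolerance = 1e-12)
    expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)
    # invariant under stratum reordering
    perm <- sample(seq_along(st$tables))
    st_perm <- stratified_tables(st$tables[perm], st$labels[perm])
    expect_equal(mh_common_or(st_perm)$odds_ratio, r$odds_ratio)
  }
  # cross-check estimate and interval against stats::mantelhaen.test
  set.seed(304)
  st <- random_strata(3, 80)
  arr <- array(unlist(lapply(st$tables,
                             function(t) c(t$a, t$c, t$b, t$d))),
               dim = c(2, 2, 3))
  mt <- stats::mantelhaen.test(arr)
  r <- mh_common_or(st)
  expect_equal(r$odds_ratio, unname(mt$estimate), tolerance = 1e-10)
  expect_equal(c(r$ci_low, r$ci_high), as.numeric(mt$conf.int),
               tolerance = 1e-3)
})

test_that("CMH chi-squared matches the direct formula and mantelhaen.test", {
  # perfectly balanced strata: statistic 0 without continuity
  bal <- stratified_tables(list(table2x2(10, 10, 10, 10),
                                table2x2(5, 5, 5, 5)))
  r0 <- cmh_chi2(bal, continuity = FALSE)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  set.seed(404)
  for (i in 1:50) {
    st <- random_strata(sample(1:3, 1))
    for (cc in c(TRUE, FALSE)) {
      r <- cmh_chi2(st, continuity = cc)
      expect_equal(r$statistic, cmh_stat_direct(st, cc), tolerance = 1e-12)
    }
    # continuity-corrected statistic never exceeds the uncorrected one
    expect_lte(cmh_chi2(st, TRUE)$statistic,
               cmh_chi2(st, FALSE)$statistic)
    # invariance under simultaneous exposure/outcome label swap
    swapped <- stratified_tables(lapply(st$tables, function(t) {
      table2x2(t$d, t$c, t$b, t$a)
    }), st$labels)
    expect_equal(cmh_chi2(swapped)$statistic, cmh_chi2(st)$statistic,
                 tolerance = 1e-12)
  }
  set.seed(405)
  st <- random_strata(3, 80)
  arr <- array(unlist(lapply(st$tables,
                             function(t) c(t$a, t$c, t$b, t$d))),
               dim = c(2, 2, 3))
  expect_equal(cmh_chi2(st, TRUE)$statistic,
               unname(stats::mantelhaen.test(arr, correct = TRUE)$statistic),
               tolerance = 1e-10)
})

test_that("Tarone homogeneity is null on identical strata and solves its quadratic", {
  same <- stratified_tables(replicate(4, table2x2(12, 8, 9, 11),
                                      simplify = FALSE))
  r <- tarone_homogeneity(same)
  expect_lt(r$statistic, 1e-10)
  expect_equal(r$p_value, 1, tolerance = 1e-6)
  expect_equal(r$df, 3)
  # the fitted expected cell satisfies the common-OR quadratic exactly
  set.seed(505)
  for (i in 1:25) {
    st <- random_strata(3, 80)
    psi <- mh_common_or(st)$odds_ratio
    for (t in st$tables) {
      atil <- msatcc:::expected_cell_common_or(t$a, t$b, t$c, t$d, psi)
      btil <- (t$a + t$b) - atil
      ctil <- (t$a + t$c) - atil
      dtil <- t$n - (t$a + t$b) - (t$a + t$c) + atil
      expect_lt(abs(atil * dtil - psi * btil * ctil) / t$n^2, 1e-10)
    }
    expect_gte(tarone_homogeneity(st)$statistic, 0)
  }
  expect_error(tarone_homogeneity(
    stratified_tables(list(table2x2(1, 2, 3, 4)))), "2 strata")
})

test_that("the association stage emits one tidy row per analysis", {
  rec <- simulate_cohort(sim_config(n_animals = 300, seed = 8))
  res <- associate_homozygosity(rec)
  expect_true(all(c("homozygosity_glm_lrt", "homozygosity_fisher",
                    "mh_common_or", "cmh_chi2", "tarone_homogeneity")
                  %in% res$analysis))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1, na.rm = TRUE))
  expect_true(all(res$statistic >= 0, na.rm = TRUE))
  n_alleles <- length(unique(c(rec$allele_a, rec$allele_b)))
  expect_equal(sum(res$analysis == "allele_glm_lrt"), n_alleles)
})
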