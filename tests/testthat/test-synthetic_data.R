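test_that("genotype sampling follows the inbreeding-adjusted frequencies", {
  # F = 1: every animal homozygous
  cfg1 <- sim_config(n_animals = 100, inbreeding_f = 1 - 1e-12, seed = 1)
  g1 <- sample_genotypes(cfg1)
  expect_true(all(g1$allele_a == g1$allele_b))
  # F = 0, two equifrequent alleles: homozygote fraction near 1/2
  cfg2 <- sim_config(n_animals = 20000, allele_freqs = c(0.5, 0.5),
                     inbreeding_f = 0, seed = 2)
  g2 <- sample_genotypes(cfg2)
  expect_equal(mean(g2$allele_a == g2$allele_b), 0.5,
               tolerance = 3 * sqrt(0.25 / 20000) / 0.5)
  # empirical genotype frequencies match the formula within 3 binomial SE
  cfg3 <- sim_config(n_animals = 1e5, inbreeding_f = 0.1, seed = 3)
  g3 <- sample_genotypes(cfg3)
  p <- cfg3$allele_freqs
  for (al in names(p)) {
    expected <- p[[al]]^2 + 0.1 * p[[al]] * (1 - p[[al]])
    observed <- mean(g3$allele_a == al & g3$allele_b == al)
    se <- sqrt(expected * (1 - expected) / 1e5)
    expect_lt(abs(observed - expected), 3 * se + 1e-12)
  }
})

test_that("disease assignment follows the homozygosity logit model", {
  cfg <- sim_config(n_animals = 40000, inbreeding_f = 0.1,
                    hom_log_or = 0, seed = 4)
  rec <- assign_disease(sample_genotypes(cfg), cfg)
  hom <- rec$allele_a == rec$allele_b
  # null effect: case fraction independent of homozygosity
  p_hom <- mean(rec$status[hom] == "case")
  p_het <- mean(rec$status[!hom] == "case")
  expect_lt(abs(p_hom - p_het), 3 * sqrt(0.3 * 0.7 * (1 / sum(hom) +
                                                        1 / sum(!hom))))
  # strong negative baseline: essentially no cases
  cfg0 <- sim_config(n_animals = 500, baseline_logit = -30, seed = 5)
  rec0 <- simulate_cohort(cfg0)
  expect_equal(sum(rec0$status == "case"), 0)
  # effect recovery at large n: fitted OR close to the truth
  cfgr <- sim_config(n_animals = 30000, hom_log_or = log(1.8), seed = 6)
  fit <- fit_logit_or(build_homozygosity_table(simulate_cohort(cfgr)))
  expect_true(fit$ci_low <= 1.8 && 1.8 <= fit$ci_high)
})

test_that("simulated peaks have unit ratios without noise and 2.27 under loss", {
  rec <- make_records(rep("1/2", 10), rep(c("case", "control"), 5))
  cfg <- sim_config(n_animals = 10, peak_cv = 0, loh_fraction = 0,
                    replicate_fraction = 0, seed = 7)
  pk <- simulate_peaks(rec, cfg)
  expect_equal(nrow(pk), 10)
  expect_true(all(abs(apply(pk[, c("N1", "N2", "T1", "T2")], 1, function(h)
    loh_ratio(h[1], h[2], h[3], h[4])) - 1) < 1e-12))
  # loss_factor 0.44, no noise: affected animals at exactly 1/0.44
  cfg2 <- sim_config(n_animals = 10, peak_cv = 0, loh_fraction = 1,
                     loss_factor = 0.44, replicate_fraction = 0, seed = 8)
  pk2 <- simulate_peaks(rec, cfg2)
  calls <- call_loh(pk2)
  truth <- attr(pk2, "loss_truth")
  expect_setequal(truth$animal_id, rec$animal_id[rec$status == "case"])
  affected <- calls$ratio[calls$animal_id %in% truth$animal_id]
  expect_true(all(abs(affected - 100 / 44) < 1e-9 |
                    abs(affected - 44 / 100) < 1e-9))
  # injected loss recovered with sensitivity 1 at low noise
  cfg3 <- sim_config(n_animals = 10, peak_cv = 0.05, loh_fraction = 1,
                     loss_factor = 0.4, replicate_fraction = 0.5, seed = 9)
  pk3 <- simulate_peaks(rec, cfg3)
  calls3 <- call_loh(pk3)
  lost <- attr(pk3, "loss_truth")$animal_id
  expect_true(all(calls3$call[calls3$animal_id %in% lost] ==
                    "loss_suggested"))
})

test_that("a full dataset is deterministic under a fixed seed", {
  cfg <- sim_config(n_animals = 60, seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_dataset(cfg, d1)
  f2 <- write_dataset(cfg, d2)
  for (k in names(f1)) {
    expect_equal(readLines(f1[[k]]), readLines(f2[[k]]), info = k)
  }
  # a different seed changes the data
  f3 <- write_dataset(sim_config(n_animals = 60, seed = 100),
                      withr::local_tempdir())
  expect_false(identical(readLines(f1[["genotypes"]]),
                         readLines(f3[["genotypes"]])))
  # ground truth is consistent with the files
  truth <- jsonlite::read_json(f1[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$hom_log_or, log(1.8))
  rec <- read_genotype_table(f1[["genotypes"]])
  expect_equal(nrow(rec), 60)
})

test_that("stratified-table sampling respects sizes and produces valid strata", {
  set.seed(555)
  st <- sample_stratified_tables(K = 5, n_per_stratum = 80)
  expect_length(st$tables, 5)
  expect_true(all(vapply(st$tables, `[[`, 0, "n") == 80))
})
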