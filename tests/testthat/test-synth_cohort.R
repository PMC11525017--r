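test_that("invalid configurations are rejected with a message", {
  expect_error(cohort_config(prevalence_mmrd = 1.2), "prevalence_mmrd")
  expect_error(cohort_config(pattern_mix = numeric(0)), "empty")
  expect_error(cohort_config(pattern_mix = c("MLH1+PMS2" = 0.5)), "sum to 1")
  expect_error(cohort_config(pattern_mix = c(BRAF = 1)), "unknown proteins")
  expect_error(cohort_config(stain_fail_rate = -0.1), "stain_fail_rate")
  expect_error(cohort_config(cores_per_case = c("5" = 1)), "among 3, 4, 8")
})

test_that("generation is deterministic and prefix-stable in n_cases", {
  a <- generate_cohort(cohort_config(n_cases = 60, seed = 5))
  b <- generate_cohort(cohort_config(n_cases = 60, seed = 5))
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth, b$truth)

  small <- generate_cohort(cohort_config(n_cases = 25, seed = 5))
  expect_identical(small$truth, a$truth[seq_len(25), ])
  expect_identical(small$cells,
                   a$cells[a$cells$case_id %in% small$truth$case_id, ])
})

test_that("configured marginals are recovered", {
  fx <- default_cohort()
  truth <- fx$cohort$truth
  cells <- fx$cohort$cells
  n <- nrow(truth)

  prev <- mean(truth$mmr_status == "MMRd")
  expect_gte(prev, 0.10)
  expect_lte(prev, 0.13)

  # cores per case: within 3 binomial SE of the configured 76/24 split
  p4 <- mean(truth$n_cores == 4)
  expect_lt(abs(p4 - 0.76), 3 * sqrt(0.76 * 0.24 / n))
  expect_true(all(truth$n_cores %in% c(4, 8)))

  # loss patterns track the configured mix among MMRd cases
  mix <- table(truth$lost_proteins[truth$mmr_status == "MMRd"])
  expect_equal(unname(mix["MLH1+PMS2"] / sum(mix)), 0.75, tolerance = 0.05)

  # section-level failure rate: stain failures plus whole-core failures
  p_fail_cfg <- 1 - (1 - 0.004) * (1 - 0.002)
  p_fail <- mean(cells$stain_fail)
  expect_lt(abs(p_fail - p_fail_cfg),
            3 * sqrt(p_fail_cfg * (1 - p_fail_cfg) / nrow(cells)) + 5e-4)

  # failed sections carry fewer than 20 positive cells
  failed <- cells[cells$stain_fail, ]
  expect_true(all(failed$pos_tumor + failed$pos_stroma < 20))
})

test_that("expression calibration matches the configured mixture", {
  fx <- default_cohort()
  pr <- fx$scored$profiles
  means <- sapply(c("MLH1", "PMS2", "MSH2", "MSH6"),
                  function(p) pr[[paste0("mean_", p)]])
  all_high <- apply(means, 1, function(v) all(!is.na(v) & v >= 90))
  expect_gt(mean(all_high), 2 / 3 - 0.05)
  expect_lt(mean(all_high), 2 / 3 + 0.05)

  # roughly one case in ten has < 10% expression of >= 1 protein
  # (prevalence times the probability that a lost protein falls below 10%)
  any_low <- apply(means, 1, function(v) any(!is.na(v) & v < 10))
  expect_gt(mean(any_low), 0.115 - 0.04)
  expect_lt(mean(any_low), 0.115 + 0.04)
})

test_that("dimer partners are independent when coupling is zero and no joint loss exists", {
  coh <- generate_cohort(cohort_config(
    n_cases = 2000, seed = 7, prevalence_mmrd = 0,
    dimer_coupling = c("MLH1+PMS2" = 0, "MSH2+MSH6" = 0),
    stain_fail_rate = 0, core_fail_rate = 0))
  pr <- score_cohort(coh$cells)$profiles
  r <- cor(pr$mean_MLH1, pr$mean_PMS2, use = "complete.obs")
  expect_lt(abs(r), 0.05)
})

test_that("heterodimer correlation increases with dimer coupling", {
  rs <- vapply(c(0, 0.5, 0.95), function(rho) {
    coh <- generate_cohort(cohort_config(
      n_cases = 600, seed = 11, prevalence_mmrd = 0,
      dimer_coupling = c("MLH1+PMS2" = rho, "MSH2+MSH6" = rho)))
    pr <- score_cohort(coh$cells)$profiles
    cor(pr$mean_MSH2, pr$mean_MSH6, use = "complete.obs")
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("stromal correlations sit in the configured band and lymphocytes are enriched in MMRd", {
  fx <- default_cohort()
  sr <- correlation_report(fx$scored$profiles)$stromal$pearson_r
  expect_true(all(sr >= 0.68 - 0.05 & sr <= 0.76 + 0.05))

  truth <- fx$cohort$truth
  wt <- t.test(lymph_frac ~ mmr_status, data = truth)
  expect_lt(wt$p.value, 0.01)
  expect_gt(mean(truth$lymph_frac[truth$mmr_status == "MMRd"]),
            mean(truth$lymph_frac[truth$mmr_status == "MMRp"]))
})

test_that("raters reproduce truth when error-free, and discordances concentrate on stain-failed cases", {
  fx <- default_cohort()
  truth <- fx$cohort$truth
  cells <- fx$cohort$cells

  clean <- simulate_raters(truth, cells,
                           rater_error_model(fail_error = 0, base_error = 0))
  for (r in c("R1", "R2", "consensus")) {
    sub <- clean[clean$rater == r, ]
    expect_identical(sub$mmr_status, truth$mmr_status)
    expect_identical(sub$lost_proteins, truth$lost_proteins)
  }

  # errors confined to stain-failed cases, but none simulated: kappa = 1
  nofail <- generate_cohort(cohort_config(n_cases = 300, seed = 13,
                                          stain_fail_rate = 0,
                                          core_fail_rate = 0))
  rc <- simulate_raters(nofail$truth, nofail$cells,
                        rater_error_model(fail_error = 0.05, base_error = 0))
  r1 <- rc[rc$rater == "R1", ]
  r2 <- rc[rc$rater == "R2", ]
  expect_equal(cohen_kappa(r1$mmr_status, r2$mmr_status)$kappa, 1)

  # default error model: ~90% of rater-vs-truth discordances on failed cases
  rr <- simulate_raters(truth, cells, rater_error_model())
  affected <- truth$case_id %in% unique(cells$case_id[cells$stain_fail])
  disc_frac <- vapply(c("R1", "R2"), function(r) {
    sub <- rr[rr$rater == r, ]
    disc <- sub$mmr_status != truth$mmr_status
    c(sum(disc & affected), sum(disc))
  }, numeric(2))
  frac_on_failed <- sum(disc_frac[1, ]) / sum(disc_frac[2, ])
  expect_equal(frac_on_failed, 0.9, tolerance = 0.1)
})

test_that("MSI labels reproduce configured discordance rates", {
  truth0 <- data.frame(case_id = sprintf("c%d", 1:5000),
                       mmr_status = rep(c("MMRd", "MMRp"), c(2500, 2500)),
                       stringsAsFactors = FALSE)
  exact <- simulate_msi(truth0, p_mss_given_mmrd = 0, p_msi_given_mmrp = 0)
  expect_identical(exact$msi_status == "MSI", truth0$mmr_status == "MMRd")

  lab <- simulate_msi(truth0, p_mss_given_mmrd = 0.1, p_msi_given_mmrp = 0,
                      seed = 3)
  rate <- mean(lab$msi_status[truth0$mmr_status == "MMRd"] == "MSS")
  expect_lt(abs(rate - 0.1), 0.02)

  allp <- data.frame(case_id = "x", mmr_status = "MMRp")
  expect_identical(simulate_msi(allp, 0, 0)$msi_status, "MSS")
  expect_error(simulate_msi(allp, -0.1, 0), "\\[0, 1\\]")
})

test_that("cohorts round-trip to plain-text files", {
  coh <- generate_cohort(cohort_config(n_cases = 5, seed = 2))
  dir <- file.path(tempdir(), "mmrscreen-cohort")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  write_cohort(coh, dir, msi = simulate_msi(coh$truth))
  expect_true(all(file.exists(file.path(dir,
    c("cells.csv", "truth.csv", "config.yaml", "msi.csv")))))
  back <- read.csv(file.path(dir, "cells.csv"))
  expect_equal(nrow(back), nrow(coh$cells))
  expect_equal(back$pos_tumor, coh$cells$pos_tumor)
})
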