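test_that("AUROC equals the pair-counting oracle and external rank implementations", {
  # separable scores
  sep <- roc_auc(c(1, 2, 3, 40, 50, 60), c("MMRd", "MMRd", "MMRd",
                                           "MMRp", "MMRp", "MMRp"),
                 n_boot = 0)
  expect_equal(sep$auc, 1)

  # eight-case toy set with ties, against brute-force pair counting
  scores <- c(5, 5, 12, 3, 40, 12, 70, 55)
  truth <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  r <- roc_auc(scores, truth, n_boot = 0)
  expect_equal(r$auc, auc_by_pairs(scores, truth), tolerance = 1e-12)

  # property: random toy instances (n <= 12), ties common
  set.seed(42)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    s <- sample(0:6, n, replace = TRUE)
    p <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    expect_equal(roc_auc(s, p, n_boot = 0)$auc, auc_by_pairs(s, p),
                 tolerance = 1e-12)
  }

  # independent implementation: pROC on one instance
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(7)
    s <- round(runif(60, 0, 100)); p <- rep(c(TRUE, FALSE), 30)
    ref <- as.numeric(pROC::auc(pROC::roc(response = p, predictor = s,
                                          direction = ">", quiet = TRUE)))
    expect_equal(roc_auc(s, p, n_boot = 0)$auc, ref, tolerance = 1e-12)
  }

  expect_error(roc_auc(1:5, rep("MMRp", 5)), "both classes")
})

test_that("AUROC is near 0.5 for permuted labels and the bootstrap CI is seeded", {
  fx <- default_cohort()
  pr <- fx$scored$profiles
  truth <- fx$cohort$truth[match(pr$case_id, fx$cohort$truth$case_id), ]
  set.seed(9)
  perm <- sample(truth$mmr_status)
  r0 <- roc_auc(pr$mmr_min, perm, n_boot = 0)
  expect_lt(abs(r0$auc - 0.5), 0.03)

  r1 <- roc_auc(pr$mmr_min[1:300], truth$mmr_status[1:300],
                n_boot = 200, seed = 4)
  r2 <- roc_auc(pr$mmr_min[1:300], truth$mmr_status[1:300],
                n_boot = 200, seed = 4)
  expect_identical(r1$ci, r2$ci)
  expect_true(r1$ci[1] <= r1$auc && r1$auc <= r1$ci[2])
})

test_that("threshold calibration honours fixed-sensitivity and Youden rules", {
  scores <- c(2, 4, 6, 8, 35, 45, 55, 65, 75, 85)
  truth <- rep(c("MMRd", "MMRp"), c(4, 6))
  op <- calibrate_threshold(scores, truth, mode = "sens95")
  expect_gte(op$sensitivity, 0.95)
  expect_equal(op$specificity, 1)
  expect_true(op$threshold > 8 && op$threshold <= 35)

  opy <- calibrate_threshold(scores, truth, mode = "youden")
  expect_equal(opy$youden_index, 1) # sens + spec - 1 on separable data

  # exhaustive-scan oracle on a 12-case toy vector
  s12 <- c(3, 9, 14, 22, 6, 18, 25, 33, 41, 52, 64, 78)
  t12 <- rep(c("MMRd", "MMRp"), c(4, 8))
  pos <- t12 == "MMRd"
  cand <- c(sort(unique(s12)), max(s12) + 1)
  j <- vapply(cand, function(th)
    mean(s12[pos] < th) + mean(s12[!pos] >= th) - 1, numeric(1))
  best <- cand[which(j == max(j))[1]]
  expect_equal(calibrate_threshold(s12, t12, "youden")$threshold, best)

  # threshold monotonicity along the full curve
  curve <- roc_auc(s12, t12, n_boot = 0)$curve
  expect_true(all(diff(curve$sensitivity) >= 0))
  expect_true(all(diff(curve$specificity) <= 0))

  expect_error(calibrate_threshold(s12, rep("MMRp", 12), "sens95"),
               "no positive")
})

test_that("case classification uses a strict threshold on score and per-protein means", {
  pr <- data.frame(case_id = c("a", "b", "c"),
                   mean_MLH1 = c(12, 20, 5), mean_PMS2 = c(95, 96, 4),
                   mean_MSH2 = c(96, 97, 95), mean_MSH6 = c(97, 98, 96),
                   mmr_min = c(12, 20, 4))
  calls <- classify_cases(pr, 20)
  expect_equal(calls$mmr_status, c("MMRd", "MMRp", "MMRd"))
  expect_equal(calls$lost_proteins, c("MLH1", "", "MLH1+PMS2"))
})

test_that("performance metrics satisfy their defining identities", {
  # printed-table identities: F1 and Fowlkes-Mallows from sens and PPV
  expect_equal(round(f1_score(0.93, 0.90), 2), 0.91)
  expect_equal(round(fowlkes_mallows(0.93, 0.90), 2), 0.91)
  expect_equal(round(f1_score(0.95, 0.84), 2), 0.89)

  perfect <- perf_report(rep(c("MMRd", "MMRp"), c(10, 30)),
                         rep(c("MMRd", "MMRp"), c(10, 30)))
  for (m in c("sensitivity", "specificity", "ppv", "npv", "f1",
              "fowlkes_mallows"))
    expect_equal(perfect[[m]], 1)
  expect_equal(perfect$fn_fraction, 0)

  # identities on random confusion matrices
  set.seed(11)
  for (i in 1:25) {
    ct <- sample(1:200, 4)
    pr <- perf_from_counts(ct[1], ct[2], ct[3], ct[4])
    expect_equal(pr$rule_out_fraction,
                 pr$specificity * (1 - pr$prevalence), tolerance = 1e-12)
    expect_equal(pr$fn_fraction, (1 - pr$sensitivity) * pr$prevalence,
                 tolerance = 1e-12)
    expect_equal(pr$f1, 2 / (1 / pr$ppv + 1 / pr$sensitivity),
                 tolerance = 1e-12)
    expect_equal(pr$fowlkes_mallows, sqrt(pr$ppv * pr$sensitivity),
                 tolerance = 1e-12)
    expect_equal(sum(pr$counts), pr$n)
  }
  expect_error(perf_report(character(0), character(0)), "empty")
})

test_that("whole-cohort extrapolation counts unreviewed screen-negatives as true negatives", {
  # review set shaped like a screening study: 229 of 685 reviewed cases
  # MMRd, at a fixed-sensitivity-95 operating point (TN = 404)
  rev <- perf_from_counts(tp = 218, fp = 52, tn = 404, fn = 11)
  expect_equal(rev$prevalence, 229 / 685, tolerance = 1e-12)

  whole <- extrapolate_cohort(rev, n_unreviewed = 1303)
  expect_equal(whole$n, 1988)
  expect_equal(round(100 * whole$prevalence, 1), 11.5)
  expect_equal(round(whole$rule_out_fraction, 2), 0.86)
  expect_equal(whole$sensitivity, rev$sensitivity)

  same <- extrapolate_cohort(rev, 0)
  expect_equal(same$counts, rev$counts)
  expect_error(extrapolate_cohort(rev, -1), "non-negative")
})

test_that("pattern-level PPV distinguishes any-loss from identical-pattern agreement", {
  calls <- data.frame(case_id = sprintf("c%d", 1:12),
                      mmr_status = rep(c("MMRd", "MMRp"), c(10, 2)),
                      lost_proteins = c(rep("MLH1+PMS2", 10), "", ""))
  cons <- data.frame(case_id = sprintf("c%d", 1:12),
                     mmr_status = rep(c("MMRd", "MMRp", "MMRp"), c(9, 1, 2)),
                     lost_proteins = c(rep("MLH1+PMS2", 8), "MSH2+MSH6",
                                       "", "", ""))
  pp <- pattern_ppv(calls, cons)
  expect_equal(pp$n_called, 10)
  expect_equal(pp$ppv_any_loss, 0.9)
  expect_equal(pp$ppv_identical, 0.8)

  # perfect caller against consensus equal to truth
  pp2 <- pattern_ppv(calls, calls)
  expect_true(all(pp2$ppv_any_loss == 1 & pp2$ppv_identical == 1))
})

test_that("kappa and AC1 match hand-computed values and diverge under skew", {
  a <- rep(c("pos", "pos", "neg", "neg"), c(40, 5, 5, 50))
  b <- rep(c("pos", "neg", "pos", "neg"), c(40, 5, 5, 50))
  k <- cohen_kappa(a, b)
  g <- gwet_ac1(a, b)
  # po = 0.9; kappa chance = .45*.45+.55*.55; AC1 chance = 2*.45*.55
  expect_equal(k$kappa, (0.9 - 0.505) / (1 - 0.505), tolerance = 1e-10)
  expect_equal(g$ac1, (0.9 - 0.495) / (1 - 0.495), tolerance = 1e-10)

  expect_equal(cohen_kappa(a, a)$kappa, 1)
  expect_equal(gwet_ac1(a, a)$ac1, 1)

  # the kappa paradox: high raw agreement, skewed prevalence
  a2 <- rep(c("pos", "pos", "neg", "neg"), c(1, 4, 5, 90))
  b2 <- rep(c("pos", "neg", "pos", "neg"), c(1, 4, 5, 90))
  expect_gt(gwet_ac1(a2, b2)$ac1, cohen_kappa(a2, b2)$kappa)

  expect_warning(cohen_kappa(rep("x", 5), rep("x", 5)), "undefined")
})

test_that("the agreement suite covers status, per-protein loss and exact patterns", {
  ca <- data.frame(case_id = sprintf("c%d", 1:6),
                   mmr_status = c("MMRd", "MMRd", "MMRd", "MMRp", "MMRp",
                                  "MMRp"),
                   lost_proteins = c("MLH1+PMS2", "MLH1+PMS2", "MSH6", "",
                                     "", ""))
  cb <- ca
  cb$lost_proteins[3] <- "MSH2+MSH6" # pattern differs, status agrees
  st <- agreement_stats(ca, cb)
  expect_setequal(st$measure, c("mmr_status", "loss_MLH1", "loss_PMS2",
                                "loss_MSH2", "loss_MSH6", "exact_pattern"))
  expect_equal(st$kappa[st$measure == "mmr_status"], 1)
  expect_equal(st$ac1[st$measure == "mmr_status"], 1)
  expect_lt(st$percent_agreement[st$measure == "exact_pattern"], 1)
})

test_that("MSI cross-tabulation is conservative and decomposes by consensus", {
  calls <- data.frame(case_id = sprintf("c%d", 1:10),
                      mmr_status = rep(c("MMRd", "MMRp"), c(4, 6)))
  msi <- data.frame(case_id = sprintf("c%d", 1:10),
                    msi_status = rep(c("MSI", "MSS"), c(4, 6)))
  xt <- msi_crosstab(calls, msi)
  expect_equal(sum(xt$table), 10)
  expect_equal(unname(xt$table["MMRd", "MSS"]), 0)
  expect_equal(unname(xt$table["MMRp", "MSI"]), 0)

  cons <- data.frame(case_id = sprintf("c%d", 1:10),
                     mmr_status = c(rep("MMRd", 3), "MMRp", rep("MMRp", 6)))
  xt2 <- msi_crosstab(calls, msi, cons)
  expect_equal(sum(xt2$breakdown$n), 10)

  # configured discordance appears in the off-diagonal cell
  truth0 <- data.frame(case_id = sprintf("t%d", 1:5000),
                       mmr_status = rep(c("MMRd", "MMRp"), c(1000, 4000)))
  m2 <- simulate_msi(truth0, p_mss_given_mmrd = 0.1, p_msi_given_mmrp = 0,
                     seed = 8)
  calls2 <- data.frame(case_id = truth0$case_id,
                       mmr_status = truth0$mmr_status) # perfect caller
  xt3 <- msi_crosstab(calls2, m2)
  expect_equal(unname(xt3$table["MMRd", "MSS"]) / 1000, 0.1,
               tolerance = 0.25)
})
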