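test_that("QC excludes low-epithelium sections per protein, not per core", {
  tab <- rbind(
    cells_core("c1", "c1_core1",
               MLH1 = list(pos_tumor = 49, neg_tumor = 50)), # 99 epithelial
    cells_core("c1", "c1_core2"))
  res <- apply_qc(tab)
  kept <- res$cells
  expect_false(any(kept$core_id == "c1_core1" & kept$protein == "MLH1"))
  expect_equal(sum(kept$core_id == "c1_core1"), 3) # other proteins kept
  expect_equal(res$report$excluded$sections_low_epithelium, 1L)
})

test_that("QC drops whole cores negative for all four proteins", {
  neg <- list(pos_tumor = 2, pos_stroma = 3) # 5 positives per section
  tab <- rbind(
    cells_core("c1", "c1_core1", MLH1 = neg, PMS2 = neg, MSH2 = neg,
               MSH6 = neg),
    cells_core("c1", "c1_core2"),
    cells_core("c2", "c2_core1", MLH1 = neg)) # one negative section only
  res <- apply_qc(tab)
  expect_false("c1_core1" %in% res$cells$core_id)
  expect_equal(sum(res$cells$core_id == "c2_core1"), 4) # core retained
  expect_equal(res$report$excluded$cores_negative_staining, 1L)
})

test_that("QC drops uninformative cases and conserves counts at every level", {
  neg <- list(pos_tumor = 0, pos_stroma = 0)
  tab <- rbind(
    cells_core("c1", "c1_core1", MLH1 = neg, PMS2 = neg, MSH2 = neg,
               MSH6 = neg),
    cells_core("c2", "c2_core1"))
  res <- apply_qc(tab)
  expect_false("c1" %in% res$cells$case_id)
  rp <- res$report
  expect_equal(rp$excluded$cases_uninformative, 1L)
  expect_equal(rp$input$sections,
               rp$retained$sections + rp$excluded$sections_low_epithelium +
                 rp$excluded$sections_in_negative_cores)
  expect_equal(rp$input$cases,
               rp$retained$cases + rp$excluded$cases_uninformative)

  # and on a full synthetic cohort
  fx <- default_cohort()
  rp2 <- fx$scored$qc
  expect_equal(rp2$input$sections,
               rp2$retained$sections + rp2$excluded$sections_low_epithelium +
                 rp2$excluded$sections_in_negative_cores)
  expect_equal(rp2$input$cases,
               rp2$retained$cases + rp2$excluded$cases_uninformative)
})

test_that("core percentages use epithelial cells only", {
  m <- score_cores(cells_row(pos_tumor = 150, neg_tumor = 50))
  expect_equal(m$pct_pos_epithelial, 75)

  m0 <- score_cores(cells_row(pos_tumor = 0, neg_tumor = 200))
  expect_equal(m0$pct_pos_epithelial, 0)

  # 300 positive lymphocytes must not contaminate the 50% epithelial score
  ml <- score_cores(cells_row(pos_tumor = 100, neg_tumor = 100,
                              lymphocyte = 300, strong_bg = 40, weak_bg = 60))
  expect_equal(ml$pct_pos_epithelial, 50)

  mz <- score_cores(cells_row(pos_tumor = 0, neg_tumor = 0))
  expect_true(is.na(mz$pct_pos_epithelial))
  expect_equal(mz$qc_status, "fail_zero_epithelium")
})

test_that("case profiles take the minimum of per-protein means over informative proteins", {
  mk <- function(case, core, protein, pct) {
    pos <- round(pct * 10); cells_row(case_id = case, core_id = core,
                                      protein = protein, pos_tumor = pos,
                                      neg_tumor = 1000 - pos)
  }
  tab <- rbind(mk("c1", "k1", "MLH1", 95), mk("c1", "k1", "PMS2", 94),
               mk("c1", "k1", "MSH2", 12), mk("c1", "k1", "MSH6", 90))
  pr <- build_case_profiles(score_cores(tab))
  expect_equal(pr$mmr_min, 12)
  expect_equal(pr$n_informative, 4)

  # MSH6 section missing: the minimum is over the three informative proteins
  pr3 <- build_case_profiles(score_cores(tab[tab$protein != "MSH2", ]))
  expect_equal(pr3$mmr_min, 90)
  expect_equal(pr3$informative_proteins, "MLH1+PMS2+MSH6")

  # a single passing core per protein: the mean equals that core's value
  expect_equal(pr$mean_MLH1, 95)
  expect_equal(pr$min_MLH1, pr$max_MLH1)

  # several cores: mean, min, max across cores
  tab2 <- rbind(mk("c2", "k1", "MLH1", 80), mk("c2", "k2", "MLH1", 90),
                mk("c2", "k1", "PMS2", 70), mk("c2", "k2", "PMS2", 70))
  pr2 <- build_case_profiles(score_cores(tab2))
  expect_equal(pr2$mean_MLH1, 85)
  expect_equal(pr2$min_MLH1, 80)
  expect_equal(pr2$max_MLH1, 90)
  expect_equal(pr2$mmr_min, 70)
})

test_that("mmr_min is invariant to lymphocyte/background perturbations and count scaling", {
  coh <- generate_cohort(cohort_config(n_cases = 40, seed = 21))
  qc_cells <- apply_qc(coh$cells)$cells
  base_pr <- build_case_profiles(score_cores(qc_cells))

  pert <- qc_cells
  set.seed(1)
  pert$lymphocyte <- pert$lymphocyte + sample(0:500, nrow(pert), TRUE)
  pert$strong_bg <- pert$strong_bg + sample(0:100, nrow(pert), TRUE)
  pert$weak_bg <- 0L
  expect_equal(build_case_profiles(score_cores(pert))$mmr_min,
               base_pr$mmr_min)

  # doubling every class count leaves all percentages unchanged (QC is
  # applied once beforehand: its rules are absolute cell counts)
  doubled <- qc_cells
  for (cl in c("pos_tumor", "neg_tumor", "pos_stroma", "neg_stroma",
               "lymphocyte", "strong_bg", "weak_bg"))
    doubled[[cl]] <- 2L * doubled[[cl]]
  dp <- build_case_profiles(score_cores(doubled))
  expect_equal(dp$mmr_min, base_pr$mmr_min)
  expect_equal(dp$mean_MLH1, base_pr$mean_MLH1)
})

test_that("correlation report matches the direct formula and handles degenerate input", {
  # x = y exactly
  tab <- do.call(rbind, lapply(1:4, function(i)
    cells_core(paste0("c", i), paste0("c", i, "_k"),
               MLH1 = list(pos_tumor = 100 * i, neg_tumor = 500),
               PMS2 = list(pos_tumor = 100 * i, neg_tumor = 500))))
  cr <- correlation_report(build_case_profiles(score_cores(tab)))
  e <- cr$epithelial
  expect_equal(e$pearson_r[e$protein_a == "MLH1" & e$protein_b == "PMS2"], 1)
  expect_equal(e$spearman_rho[e$protein_a == "MLH1" & e$protein_b == "PMS2"], 1)
  expect_true(isSymmetric(cr$r_epithelial))

  # five-case toy table against the explicit product-moment formula
  coh <- generate_cohort(cohort_config(n_cases = 5, seed = 33))
  pr <- score_cohort(coh$cells)$profiles
  cr2 <- correlation_report(pr)
  x <- pr$mean_MSH2; y <- pr$mean_MSH6
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  e2 <- cr2$epithelial
  expect_equal(e2$pearson_r[e2$protein_a == "MSH2" & e2$protein_b == "MSH6"],
               r_direct, tolerance = 1e-12)

  expect_error(correlation_report(pr[1:2, ]), "fewer than 3")
})
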