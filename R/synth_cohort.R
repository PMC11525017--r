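#' Configuration for the synthetic MMR IHC cohort generator
#'
#' Builds and validates the parameter set for [generate_cohort()].  Defaults
#' emulate a large adjuvant colorectal-cancer trial tissue-microarray (TMA)
#' cohort: MMR-deficiency (MMRd) prevalence 11.5%, four or eight cores per
#' case (tumour centre + invasive margin), roughly two thirds of cases with
#' homogeneous (>= 90% cells positive) expression of all four MMR proteins,
#' about one in ten with low or absent (< 10%) expression of at least one
#' protein, heterodimer-coupled expression (MLH1-PMS2 case-level Pearson
#' r near 0.88, MSH2-MSH6 near 0.69), lymphocyte enrichment in MMRd tumours,
#' and sporadic per-section staining failures.
#'
#' @param n_cases number of cases to simulate.
#' @param prevalence_mmrd probability a case is MMR deficient.
#' @param pattern_mix named probabilities over loss patterns
#'   (`"MLH1+PMS2"`, `"MSH2+MSH6"`, or isolated proteins); must sum to 1.
#' @param cores_per_case named probabilities over cores per case; names must
#'   be among `"3"`, `"4"`, `"8"`.  Three-core cases use central cores only
#'   (region `CT3`); four/eight-core cases split evenly between tumour-centre
#'   (`TC`) and invasive-margin (`IM`) cores.
#' @param cells_per_core mean and negative-binomial size of the number of
#'   objects per stained section.
#' @param epithelial_fraction Beta shape parameters of the per-case
#'   epithelial fraction of non-background cells.
#' @param lymphocyte_fraction_base mean lymphocyte fraction in MMR-proficient
#'   cases.
#' @param lymphocyte_mmrd_multiplier multiplicative lymphocyte enrichment in
#'   MMRd cases (> 1 reproduces the immune infiltration of MMRd tumours).
#' @param retained_positivity list with `weight_high` (probability that a
#'   retained protein draws from the homogeneous-high component) and Beta
#'   shape pairs `high` and `moderate` for the two mixture components of the
#'   latent epithelial percent-positive fraction.
#' @param lost_positivity list with `weight_absent` (probability that loss is
#'   complete) and Beta shape pairs `absent` and `partial` for the latent
#'   epithelial positivity of a lost protein: complete loss leaves almost no
#'   positive cells, partial loss (e.g. residual missense protein or clonal
#'   heterogeneity) leaves a low but non-trivial fraction.  The component is
#'   drawn independently per lost protein.
#' @param sporadic_low_rate probability that an MMR-proficient case carries a
#'   biologically low (lost-type) expression of one random protein without
#'   being MMRd.
#' @param dimer_coupling named latent Gaussian-copula correlations within the
#'   two heterodimer pairs; `0` makes partner proteins independent.
#' @param stroma_coupling correlation between the case-level epithelial and
#'   stromal latent factors.
#' @param stromal_positivity Beta shape pair of the latent stromal
#'   percent-positive fraction (stromal cells retain expression in MMRd).
#' @param stromal_pair_coupling shared-factor latent correlation between the
#'   four proteins' stromal positivities.
#' @param overdispersion Beta-binomial concentration for core-level
#'   realisation of the latent positivity (larger = less extra-binomial
#'   variation between cores of one case).
#' @param stain_fail_rate per core-x-protein (section) probability of a
#'   staining failure, leaving fewer than 20 positive cells in the section.
#' @param core_fail_rate per-core probability that all four sections fail
#'   (damaged/missing tissue), the event the whole-core QC rule removes.
#' @param low_epithelium_rate per-section probability of an epithelium-poor
#'   section (< 100 epithelial cells), the event the per-section QC rule
#'   removes.
#' @param artifact_rates named per-object probabilities `strong` and `weak`
#'   of strong-background (folds, debris) and weak-background (mucus, matrix)
#'   objects.
#' @param seed master seed; per-case substreams are derived with
#'   [substream_seed()], so enlarging `n_cases` leaves earlier cases
#'   unchanged.
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_cases = 2000,
                          prevalence_mmrd = 0.115,
                          pattern_mix = c("MLH1+PMS2" = 0.75,
                                          "MSH2+MSH6" = 0.10,
                                          "PMS2" = 0.06,
                                          "MSH6" = 0.06,
                                          "MLH1" = 0.02,
                                          "MSH2" = 0.01),
                          cores_per_case = c("4" = 0.76, "8" = 0.24),
                          cells_per_core = c(mean = 1500, size = 10),
                          epithelial_fraction = c(shape1 = 11, shape2 = 9),
                          lymphocyte_fraction_base = 0.10,
                          lymphocyte_mmrd_multiplier = 2,
                          retained_positivity = list(
                            weight_high = 0.92,
                            high = c(110, 3.5),
                            moderate = c(16, 4)),
                          lost_positivity = list(
                            weight_absent = 0.8,
                            absent = c(0.5, 20),
                            partial = c(2, 5)),
                          sporadic_low_rate = 0,
                          dimer_coupling = c("MLH1+PMS2" = 0.2,
                                             "MSH2+MSH6" = 0.8),
                          stroma_coupling = 0.5,
                          stromal_positivity = c(9, 2.5),
                          stromal_pair_coupling = 0.75,
                          overdispersion = 150,
                          stain_fail_rate = 0.004,
                          core_fail_rate = 0.002,
                          low_epithelium_rate = 0.02,
                          artifact_rates = c(strong = 0.02, weak = 0.05),
                          seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases),
              prevalence_mmrd = prevalence_mmrd,
              pattern_mix = pattern_mix,
              cores_per_case = cores_per_case,
              cells_per_core = cells_per_core,
              epithelial_fraction = epithelial_fraction,
              lymphocyte_fraction_base = lymphocyte_fraction_base,
              lymphocyte_mmrd_multiplier = lymphocyte_mmrd_multiplier,
              retained_positivity = retained_positivity,
              lost_positivity = lost_positivity,
              sporadic_low_rate = sporadic_low_rate,
              dimer_coupling = dimer_coupling,
              stroma_coupling = stroma_coupling,
              stromal_positivity = stromal_positivity,
              stromal_pair_coupling = stromal_pair_coupling,
              overdispersion = overdispersion,
              stain_fail_rate = stain_fail_rate,
              core_fail_rate = core_fail_rate,
              low_epithelium_rate = low_epithelium_rate,
              artifact_rates = artifact_rates,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  chk01 <- function(x, what) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
      stopf("`%s` must be numeric in [0, 1]", what)
  }
  if (!is.numeric(cfg$n_cases) || cfg$n_cases < 1)
    stopf("`n_cases` must be a positive integer")
  chk01(cfg$prevalence_mmrd, "prevalence_mmrd")
  if (length(cfg$pattern_mix) == 0)
    stopf("`pattern_mix` must not be empty")
  chk01(cfg$pattern_mix, "pattern_mix")
  if (abs(sum(cfg$pattern_mix) - 1) > 1e-8)
    stopf("`pattern_mix` must sum to 1 (got %.4f)", sum(cfg$pattern_mix))
  ok <- vapply(names(cfg$pattern_mix), function(p)
    all(split_pattern(p) %in% PROTEINS), logical(1))
  if (!all(ok))
    stopf("unknown proteins in pattern_mix: %s",
          paste(names(cfg$pattern_mix)[!ok], collapse = ", "))
  if (!all(names(cfg$cores_per_case) %in% c("3", "4", "8")))
    stopf("`cores_per_case` names must be among 3, 4, 8")
  chk01(cfg$cores_per_case, "cores_per_case")
  if (abs(sum(cfg$cores_per_case) - 1) > 1e-8)
    stopf("`cores_per_case` must sum to 1")
  chk01(cfg$dimer_coupling, "dimer_coupling")
  chk01(cfg$retained_positivity$weight_high, "retained_positivity$weight_high")
  chk01(cfg$lost_positivity$weight_absent, "lost_positivity$weight_absent")
  chk01(cfg$stroma_coupling, "stroma_coupling")
  chk01(cfg$stromal_pair_coupling, "stromal_pair_coupling")
  chk01(cfg$stain_fail_rate, "stain_fail_rate")
  chk01(cfg$core_fail_rate, "core_fail_rate")
  chk01(cfg$low_epithelium_rate, "low_epithelium_rate")
  chk01(cfg$artifact_rates, "artifact_rates")
  chk01(cfg$lymphocyte_fraction_base, "lymphocyte_fraction_base")
  chk01(cfg$sporadic_low_rate, "sporadic_low_rate")
  if (cfg$lymphocyte_mmrd_multiplier <= 0)
    stopf("`lymphocyte_mmrd_multiplier` must be positive")
  lf_max <- cfg$lymphocyte_fraction_base * max(1, cfg$lymphocyte_mmrd_multiplier)
  if (lf_max > 0.6)
    stopf("lymphocyte fraction with multiplier exceeds 0.6")
  invisible(cfg)
}

#' Generate a synthetic MMR IHC trial cohort
#'
#' Simulates the case -> core -> stained-section hierarchy of an MMR IHC TMA
#' study and returns per-section seven-class cell counts together with the
#' per-case ground truth.  Each case draws a latent percent-positive fraction
#' per protein and compartment from a Gaussian copula (heterodimer partners
#' coupled through `dimer_coupling`); each core x protein section then
#' realises Beta-binomial counts around the latent fraction, with sporadic
#' section/core staining failures and epithelium-poor sections.
#'
#' @param config a [cohort_config()] object.
#' @return a list of class `mmr_cohort` with elements
#'   * `cells`: data frame with one row per case x core x protein section and
#'     columns `case_id, core_id, region, protein`, the seven class counts
#'     (`r paste(CELL_CLASSES, collapse = ", ")`), and the ground-truth
#'     `stain_fail` flag (not used by scoring);
#'   * `truth`: data frame with one row per case: `case_id, mmr_status,
#'     lost_proteins, expr_component`, latent epithelial/stromal positivities
#'     (`latent_<protein>`, `latent_str_<protein>`), `lymph_frac`, `n_cores`;
#'   * `config`: the configuration used.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  validate_cohort_config(config)
  cfg <- config
  n <- cfg$n_cases
  qret <- qbetamix_fun(cfg$retained_positivity$weight_high,
                       cfg$retained_positivity$high,
                       cfg$retained_positivity$moderate)
  rho <- cfg$dimer_coupling[DIMER_OF[PROTEINS]]

  truth_rows <- vector("list", n)
  cell_rows <- vector("list", n)

  # MMR status and loss pattern are assigned by seed-offset Kronecker
  # (golden-ratio) sequences rather than independent Bernoulli draws: the
  # realised prevalence and pattern mix then match the configured marginals
  # to O(1/n) for any n, without sacrificing prefix stability (case i's
  # assignment depends only on the master seed and on cases 1..i).
  offs <- with_seed(substream_seed(cfg$seed, 0), runif(2))
  g1 <- (sqrt(5) - 1) / 2
  g2 <- sqrt(2) - 1
  pat_cum <- cumsum(cfg$pattern_mix)
  n_mmrd_seen <- 0L
  for (i in seq_len(n)) {
    mmrd <- ((i * g1 + offs[1]) %% 1) < cfg$prevalence_mmrd
    pattern <- ""
    if (mmrd) {
      n_mmrd_seen <- n_mmrd_seen + 1L
      u_pat <- (n_mmrd_seen * g2 + offs[2]) %% 1
      pattern <- names(pat_cum)[which(u_pat < pat_cum)[1]]
    }
    res <- with_seed(substream_seed(cfg$seed, i),
                     simulate_case(i, cfg, qret, rho, mmrd, pattern))
    truth_rows[[i]] <- res$truth
    cell_rows[[i]] <- res$cells
  }

  truth <- do.call(rbind, truth_rows)
  cells <- do.call(rbind, cell_rows)
  rownames(truth) <- rownames(cells) <- NULL
  structure(list(cells = cells, truth = truth, config = cfg),
            class = "mmr_cohort")
}

# One case: latent draws plus per-section counts.  Called under the case's
# own RNG substream so the per-case output is independent of n_cases.
simulate_case <- function(i, cfg, qret, rho, mmrd, pattern) {
  case_id <- sprintf("case_%05d", i)
  lost <- split_pattern(pattern)
  # sporadic biologically-low expression in an MMRp case (not MMRd)
  sporadic <- !mmrd && runif(1) < cfg$sporadic_low_rate
  low_set <- if (sporadic) sample(PROTEINS, 1) else lost
  is_low <- PROTEINS %in% low_set

  # Gaussian copula: one shared latent per heterodimer pair
  d <- setNames(rnorm(2), c("MLH1+PMS2", "MSH2+MSH6"))
  e <- rnorm(4)
  z <- sqrt(rho) * d[DIMER_OF[PROTEINS]] + sqrt(1 - rho) * e
  u <- pnorm(z)
  lp <- cfg$lost_positivity
  absent <- runif(4) < lp$weight_absent
  pi_lost <- ifelse(absent,
                    qbeta(u, lp$absent[1], lp$absent[2]),
                    qbeta(u, lp$partial[1], lp$partial[2]))
  pi_epi <- ifelse(is_low, pi_lost, qret(u))
  # which mixture component the retained draws fell in (diagnostic only)
  comp <- if (all(!is_low) &&
              all(pi_epi >= qret(1 - cfg$retained_positivity$weight_high)))
    "high" else "mixed"

  # stromal compartment: expression retained regardless of MMR status
  # standardized case-level epithelial factor (mean of the four latents)
  v_mean_z <- (4 + 2 * (rho[1] + rho[3])) / 16
  u_c <- mean(z) / sqrt(v_mean_z)
  u_s <- cfg$stroma_coupling * u_c +
    sqrt(max(0, 1 - cfg$stroma_coupling^2)) * rnorm(1)
  as_ <- cfg$stromal_pair_coupling
  zs <- sqrt(as_) * u_s + sqrt(1 - as_) * rnorm(4)
  pi_str <- qbeta(pnorm(zs), cfg$stromal_positivity[1], cfg$stromal_positivity[2])

  lf_mean <- min(0.6, cfg$lymphocyte_fraction_base *
                   if (mmrd) cfg$lymphocyte_mmrd_multiplier else 1)
  lf <- rbeta(1, lf_mean * 80, (1 - lf_mean) * 80)
  ef <- rbeta(1, cfg$epithelial_fraction[1], cfg$epithelial_fraction[2])

  k <- as.integer(sample(names(cfg$cores_per_case), 1,
                         prob = cfg$cores_per_case))
  regions <- switch(as.character(k),
                    "3" = rep("CT3", 3),
                    "4" = c("TC", "TC", "IM", "IM"),
                    "8" = c(rep("TC", 4), rep("IM", 4)))
  core_fail <- runif(k) < cfg$core_fail_rate

  nsec <- k * 4L
  core_idx <- rep(seq_len(k), each = 4L)
  protein <- rep(PROTEINS, times = k)
  n_cells <- pmax(200L, rnbinom(nsec, mu = cfg$cells_per_core["mean"],
                                size = cfg$cells_per_core["size"]))
  n_lym <- rbinom(nsec, n_cells, lf)
  n_sbg <- rbinom(nsec, n_cells, cfg$artifact_rates["strong"])
  n_wbg <- rbinom(nsec, n_cells, cfg$artifact_rates["weak"])
  rem <- pmax(0L, n_cells - n_lym - n_sbg - n_wbg)
  ef_sec <- rbeta(nsec, ef * 200, (1 - ef) * 200)
  n_epi <- as.integer(round(rem * ef_sec))
  low_epi <- runif(nsec) < cfg$low_epithelium_rate
  n_epi[low_epi] <- sample(10:99, sum(low_epi), replace = TRUE)
  n_epi <- pmin(n_epi, rem)
  n_str <- rem - n_epi

  kap <- cfg$overdispersion
  clamp <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)
  p_epi <- rbeta(nsec, clamp(pi_epi[match(protein, PROTEINS)]) * kap,
                 (1 - clamp(pi_epi[match(protein, PROTEINS)])) * kap)
  p_str <- rbeta(nsec, clamp(pi_str[match(protein, PROTEINS)]) * kap,
                 (1 - clamp(pi_str[match(protein, PROTEINS)])) * kap)
  pos_t <- rbinom(nsec, n_epi, p_epi)
  pos_s <- rbinom(nsec, n_str, p_str)

  fail <- core_fail[core_idx] | runif(nsec) < cfg$stain_fail_rate
  if (any(fail)) {
    nf <- sum(fail)
    tot_pos <- sample(0:10, nf, replace = TRUE)
    pt <- rbinom(nf, tot_pos, 0.7)
    pos_t[fail] <- pmin(pt, n_epi[fail])
    pos_s[fail] <- pmin(tot_pos - pt, n_str[fail])
  }

  cells <- data.frame(
    case_id = case_id,
    core_id = sprintf("%s_core%d", case_id, core_idx),
    region = regions[core_idx],
    protein = protein,
    pos_tumor = pos_t,
    neg_tumor = n_epi - pos_t,
    pos_stroma = pos_s,
    neg_stroma = n_str - pos_s,
    lymphocyte = n_lym,
    strong_bg = n_sbg,
    weak_bg = n_wbg,
    stain_fail = fail,
    stringsAsFactors = FALSE)

  truth <- data.frame(
    case_id = case_id,
    mmr_status = if (mmrd) "MMRd" else "MMRp",
    lost_proteins = pattern,
    expr_component = comp,
    lymph_frac = lf,
    n_cores = k,
    stringsAsFactors = FALSE)
  truth[paste0("latent_", PROTEINS)] <- as.list(pi_epi)
  truth[paste0("latent_str_", PROTEINS)] <- as.list(pi_str)

  list(truth = truth, cells = cells)
}

#' Simulate two expert raters and their consensus call
#'
#' Emulates blinded pathologist review of a cohort: each rater independently
#' reproduces the ground truth except for misclassification concentrated on
#' cases affected by staining failure (the dominant cause of discordance in
#' IHC review), plus a small baseline error rate.  Discrepant raters are
#' resolved to a consensus that equals truth with probability
#' `consensus_fidelity`.
#'
#' @param truth truth data frame from [generate_cohort()].
#' @param cells cell-count table from the same cohort (used to locate
#'   stain-failed cases).
#' @param error_model list from [rater_error_model()].
#' @return data frame of class `rater_calls` with one row per case x rater
#'   (`R1`, `R2`, `consensus`): `case_id, rater, mmr_status, lost_proteins,
#'   fail_flag`.
#' @export
simulate_raters <- function(truth, cells,
                            error_model = rater_error_model()) {
  em <- error_model
  stopifnot(is.list(em))
  for (nm in c("fail_error", "base_error", "consensus_fidelity")) {
    v <- em[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stopf("error_model$%s must be in [0, 1]", nm)
  }
  affected_cases <- unique(cells$case_id[cells$stain_fail])
  affected <- truth$case_id %in% affected_cases

  flip_one <- function(status, lost, p_err) {
    n <- length(status)
    flip <- runif(n) < p_err
    out_status <- status
    out_lost <- lost
    # MMRp flipped to MMRd gets a plausible single/dimer pattern; MMRd
    # flipped to MMRp loses its pattern.
    to_d <- flip & status == "MMRp"
    to_p <- flip & status == "MMRd"
    out_status[to_d] <- "MMRd"
    out_status[to_p] <- "MMRp"
    out_lost[to_p] <- ""
    if (any(to_d))
      out_lost[to_d] <- sample(c("MLH1+PMS2", "PMS2", "MSH6", "MLH1", "MSH2"),
                               sum(to_d), replace = TRUE,
                               prob = c(0.5, 0.2, 0.15, 0.1, 0.05))
    list(status = out_status, lost = out_lost)
  }

  rate <- ifelse(affected, em$fail_error, em$base_error)
  out <- with_seed(substream_seed(em$seed, 1), {
    r1 <- flip_one(truth$mmr_status, truth$lost_proteins, rate)
    r2 <- flip_one(truth$mmr_status, truth$lost_proteins, rate)
    agree <- r1$status == r2$status & r1$lost == r2$lost
    keep_truth <- runif(nrow(truth)) < em$consensus_fidelity
    cs <- ifelse(agree, r1$status,
                 ifelse(keep_truth, truth$mmr_status, r1$status))
    cl <- ifelse(agree, r1$lost,
                 ifelse(keep_truth, truth$lost_proteins, r1$lost))
    list(r1 = r1, r2 = r2, cs = cs, cl = cl)
  })

  res <- rbind(
    data.frame(case_id = truth$case_id, rater = "R1",
               mmr_status = out$r1$status, lost_proteins = out$r1$lost,
               fail_flag = FALSE, stringsAsFactors = FALSE),
    data.frame(case_id = truth$case_id, rater = "R2",
               mmr_status = out$r2$status, lost_proteins = out$r2$lost,
               fail_flag = FALSE, stringsAsFactors = FALSE),
    data.frame(case_id = truth$case_id, rater = "consensus",
               mmr_status = out$cs, lost_proteins = out$cl,
               fail_flag = FALSE, stringsAsFactors = FALSE))
  rownames(res) <- NULL
  class(res) <- c("rater_calls", "data.frame")
  res
}

#' Rater error model
#'
#' @param fail_error per-rater misclassification probability on cases with at
#'   least one stain-failed section.  The default pair of rates is chosen so
#'   that, at the generator's default staining-failure rates, about 90% of
#'   rater-versus-truth discordances arise on stain-failed cases.
#' @param base_error per-rater misclassification probability on clean cases.
#' @param consensus_fidelity probability that a rater discrepancy is resolved
#'   to the ground truth.
#' @param seed RNG seed for the rater simulation.
#' @export
rater_error_model <- function(fail_error = 0.25, base_error = 0.0025,
                              consensus_fidelity = 1, seed = 99L) {
  list(fail_error = fail_error, base_error = base_error,
       consensus_fidelity = consensus_fidelity, seed = as.integer(seed))
}

#' Simulate microsatellite-instability (MSI) PCR labels
#'
#' MSI status tracks MMR truth up to configured discordance rates, mirroring
#' the imperfect concordance between MMR IHC and MSI PCR (a tumour is called
#' MSI when a sufficient share of microsatellite markers is unstable, which
#' can disagree with protein-level MMR status).
#'
#' @param truth truth data frame from [generate_cohort()].
#' @param p_mss_given_mmrd probability an MMRd case tests MSS.
#' @param p_msi_given_mmrp probability an MMRp case tests MSI.
#' @param seed RNG seed.
#' @return data frame with `case_id`, `msi_status` (`"MSI"`/`"MSS"`).
#' @export
simulate_msi <- function(truth, p_mss_given_mmrd = 0.05,
                         p_msi_given_mmrp = 0.01, seed = 7L) {
  for (p in c(p_mss_given_mmrd, p_msi_given_mmrp))
    if (!is.numeric(p) || p < 0 || p > 1)
      stopf("discordance rates must be in [0, 1]")
  with_seed(substream_seed(seed, 1), {
    mmrd <- truth$mmr_status == "MMRd"
    u <- runif(nrow(truth))
    msi <- ifelse(mmrd, u >= p_mss_given_mmrd, u < p_msi_given_mmrp)
    data.frame(case_id = truth$case_id,
               msi_status = ifelse(msi, "MSI", "MSS"),
               stringsAsFactors = FALSE)
  })
}

#' Write a cohort to plain-text files
#'
#' Writes `cells.csv`, `truth.csv` and `config.yaml` into `dir`; optional
#' rater and MSI tables are written when supplied.
#'
#' @param cohort an `mmr_cohort` object.
#' @param dir output directory (created if needed).
#' @param raters,msi optional tables from [simulate_raters()]/[simulate_msi()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, raters = NULL, msi = NULL) {
  stopifnot(inherits(cohort, "mmr_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  cfg <- cohort$config
  class(cfg) <- NULL
  yaml::write_yaml(lapply(cfg, function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x),
    file.path(dir, "config.yaml"))
  if (!is.null(raters))
    write.csv(raters, file.path(dir, "raters.csv"), row.names = FALSE)
  if (!is.null(msi))
    write.csv(msi, file.path(dir, "msi.csv"), row.names = FALSE)
  invisible(dir)
}

#' @export
print.mmr_cohort <- function(x, ...) {
  cat(sprintf("Synthetic MMR IHC cohort: %d cases, %d sections (%d cores)\n",
              nrow(x$truth), nrow(x$cells),
              length(unique(x$cells$core_id))))
  cat(sprintf("  MMRd: %d (%.1f%%)\n", sum(x$truth$mmr_status == "MMRd"),
              100 * mean(x$truth$mmr_status == "MMRd")))
  invisible(x)
}
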