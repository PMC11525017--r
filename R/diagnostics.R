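#' AUROC for MMRd detection with bootstrap confidence interval
#'
#' Area under the ROC curve of a case-level score against binary MMR truth,
#' computed as the tie-corrected rank (Mann-Whitney) statistic.  The score is
#' oriented so that *lower* values indicate MMR deficiency (as for the
#' minimum percent-positive score); internally the score is negated so the
#' usual "higher = more diseased" convention applies.  The 95% CI is a
#' percentile bootstrap over cases.
#'
#' @param scores numeric case scores (lower = more likely MMRd).
#' @param truth binary truth; `"MMRd"`/`"MMRp"`, logical, or 0/1 with 1 =
#'   MMRd.
#' @param n_boot bootstrap resamples (default 1000); 0 skips the CI.
#' @param seed RNG seed for the bootstrap.
#' @return list of class `roc_result`: `auc`, `ci` (length-2, or `NULL`),
#'   `curve` (data frame `threshold, sensitivity, specificity`, thresholds on
#'   the original score scale classifying `score < threshold` as MMRd),
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, truth, n_boot = 1000, seed = 1L) {
  pos <- as_mmrd(truth)
  ok <- !is.na(scores) & !is.na(pos)
  scores <- scores[ok]; pos <- pos[ok]
  if (!any(pos) || all(pos))
    stopf("AUROC undefined: both classes must be present")

  auc_of <- function(s, p) {
    # rank statistic on the negated score (higher = MMRd)
    r <- rank(-s)
    n1 <- sum(p); n0 <- sum(!p)
    (sum(r[p]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  auc <- auc_of(scores, pos)

  ci <- NULL
  if (n_boot > 0) {
    boot <- with_seed(substream_seed(seed, 1), {
      n <- length(scores)
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        p <- pos[idx]
        if (!any(p) || all(p)) return(NA_real_)
        auc_of(scores[idx], p)
      }, numeric(1))
    })
    ci <- unname(quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  }

  thr <- c(sort(unique(scores)), max(scores) + 1)
  sens <- vapply(thr, function(t) mean(scores[pos] < t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  structure(list(auc = auc, ci = ci,
                 curve = data.frame(threshold = thr, sensitivity = sens,
                                    specificity = spec),
                 n_pos = sum(pos), n_neg = sum(!pos)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUROC = %.3f", x$auc))
  if (!is.null(x$ci)) cat(sprintf(" (bootstrap 95%% CI %.3f-%.3f)", x$ci[1], x$ci[2]))
  cat(sprintf(" [%d MMRd / %d MMRp]\n", x$n_pos, x$n_neg))
  invisible(x)
}

as_mmrd <- function(truth) {
  if (is.logical(truth)) return(truth)
  if (is.numeric(truth)) return(truth != 0)
  truth <- as.character(truth)
  bad <- !truth %in% c("MMRd", "MMRp", NA)
  if (any(bad)) stopf("truth labels must be 'MMRd'/'MMRp'")
  truth == "MMRd"
}

#' Calibrate a classification threshold on the score scale
#'
#' A case is called MMRd when `score < threshold` (strict).  Modes:
#' * `"youden"` — maximise Youden's J = sensitivity + specificity - 1,
#'   breaking ties toward the smaller threshold (higher specificity);
#' * `"sens95"`, `"sens98"`, `"fixed_sens"` — the smallest threshold whose
#'   sensitivity reaches the target (0.95, 0.98, or `target`), i.e. the
#'   qualifying threshold of maximal specificity.
#'
#' @param scores case scores (lower = MMRd).
#' @param truth binary truth as in [roc_auc()].
#' @param mode one of `"youden"`, `"sens95"`, `"sens98"`, `"fixed_sens"`.
#' @param target target sensitivity for `mode = "fixed_sens"`.
#' @return list of class `operating_point`: `threshold`, `mode`,
#'   `sensitivity`, `specificity`, `youden_index`
#'   (J = sensitivity + specificity - 1).
#' @export
calibrate_threshold <- function(scores, truth,
                                mode = c("youden", "sens95", "sens98",
                                         "fixed_sens"),
                                target = NULL) {
  mode <- match.arg(mode)
  pos <- as_mmrd(truth)
  if (!any(pos)) stopf("no positive (MMRd) cases: target sensitivity unattainable")
  if (all(pos)) stopf("no negative (MMRp) cases")
  target <- switch(mode, sens95 = 0.95, sens98 = 0.98,
                   fixed_sens = target %||% stopf("`target` required"),
                   youden = NA_real_)

  thr <- c(sort(unique(scores)), max(scores) + 1)
  sens <- vapply(thr, function(t) mean(scores[pos] < t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))

  i <- if (mode == "youden") {
    j <- sens + spec
    which(j == max(j))[1] # thresholds ascending: first max = smallest
  } else {
    cand <- which(sens >= target)
    if (length(cand) == 0) stopf("target sensitivity %.2f unattainable", target)
    cand[1]
  }
  structure(list(threshold = thr[i], mode = mode,
                 sensitivity = sens[i], specificity = spec[i],
                 youden_index = sens[i] + spec[i] - 1),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("Operating point (%s): threshold %.3f, sens %.3f, spec %.3f\n",
              x$mode, x$threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' Classify cases from their profiles at a threshold
#'
#' A case is MMRd when its `mmr_min` is strictly below the threshold; the
#' lost proteins are those whose case-level mean percent-positive is strictly
#' below the same threshold (a single threshold keeps per-protein calls
#' consistent with the case call).
#'
#' @param profiles case profiles from [build_case_profiles()], or any data
#'   frame with `case_id`, `mmr_min` and `mean_<protein>` columns.
#' @param threshold percent threshold (0-100).
#' @return data frame of class `mmr_calls`: `case_id, mmr_status,
#'   lost_proteins, threshold`.
#' @export
classify_cases <- function(profiles, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  means <- sapply(PROTEINS, function(p) profiles[[paste0("mean_", p)]])
  if (is.null(dim(means))) means <- matrix(means, nrow = 1)
  lost <- apply(means, 1, function(v)
    canonical_pattern(PROTEINS[!is.na(v) & v < threshold]))
  status <- ifelse(profiles$mmr_min < threshold, "MMRd", "MMRp")
  out <- data.frame(case_id = profiles$case_id, mmr_status = status,
                    lost_proteins = lost, threshold = threshold,
                    stringsAsFactors = FALSE)
  class(out) <- c("mmr_calls", "data.frame")
  out
}

#' Diagnostic performance report from calls against truth
#'
#' Full operating-point metric suite on the confusion matrix of binary MMR
#' calls against truth: sensitivity (recall), specificity, PPV (precision),
#' NPV, the true-negative ("rule-out") fraction TN/n, false-negative fraction
#' FN/n, false-negative rate FN/positives, F1 (harmonic mean of PPV and
#' sensitivity) and the Fowlkes-Mallows score (their geometric mean).
#'
#' @param calls `mmr_calls` data frame or character vector of
#'   `"MMRd"`/`"MMRp"` calls.
#' @param truth truth aligned with `calls` (same order or matched by
#'   `case_id` when both are data frames).
#' @return object of class `perf_report`: confusion counts and metrics.
#' @export
perf_report <- function(calls, truth) {
  call_vec <- if (is.data.frame(calls)) calls$mmr_status else calls
  truth_vec <- if (is.data.frame(truth)) {
    if (is.data.frame(calls) && !is.null(truth$case_id))
      truth$mmr_status[match(calls$case_id, truth$case_id)]
    else truth$mmr_status
  } else truth
  if (length(call_vec) == 0) stopf("empty input")
  if (length(call_vec) != length(truth_vec))
    stopf("calls and truth have different lengths")
  cp <- as_mmrd(call_vec); tp_ <- as_mmrd(truth_vec)
  ok <- !is.na(cp) & !is.na(tp_)
  cp <- cp[ok]; tp_ <- tp_[ok]
  perf_from_counts(tp = sum(cp & tp_), fp = sum(cp & !tp_),
                   tn = sum(!cp & !tp_), fn = sum(!cp & tp_))
}

#' Build a performance report directly from confusion counts
#'
#' @param tp,fp,tn,fn confusion-matrix counts.
#' @return object of class `perf_report`.
#' @export
perf_from_counts <- function(tp, fp, tn, fn) {
  tp <- unname(tp); fp <- unname(fp); tn <- unname(tn); fn <- unname(fn)
  for (v in c(tp, fp, tn, fn))
    if (v < 0 || v != round(v)) stopf("confusion counts must be non-negative integers")
  n <- tp + fp + tn + fn
  if (n == 0) stopf("empty confusion matrix")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  ppv <- tp / (tp + fp)
  npv <- tn / (tn + fn)
  structure(list(
    counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
    n = n,
    prevalence = (tp + fn) / n,
    sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
    rule_out_fraction = tn / n,
    fn_fraction = fn / n,
    fn_rate = fn / (tp + fn),
    f1 = f1_score(sens, ppv),
    fowlkes_mallows = fowlkes_mallows(sens, ppv)),
    class = "perf_report")
}

#' F1 score from sensitivity (recall) and PPV (precision)
#' @param sensitivity,ppv operating-point recall and precision.
#' @export
f1_score <- function(sensitivity, ppv) {
  2 * sensitivity * ppv / (sensitivity + ppv)
}

#' Fowlkes-Mallows score (geometric mean of PPV and sensitivity)
#' @param sensitivity,ppv operating-point recall and precision.
#' @export
fowlkes_mallows <- function(sensitivity, ppv) sqrt(sensitivity * ppv)

#' @export
print.perf_report <- function(x, ...) {
  cat(sprintf("n = %d (prevalence %.1f%%): TP %d  FP %d  TN %d  FN %d\n",
              x$n, 100 * x$prevalence, x$counts["tp"], x$counts["fp"],
              x$counts["tn"], x$counts["fn"]))
  cat(sprintf("  sens %.3f  spec %.3f  PPV %.3f  NPV %.3f\n",
              x$sensitivity, x$specificity, x$ppv, x$npv))
  cat(sprintf("  rule-out %.3f  FN fraction %.4f  FN rate %.3f  F1 %.3f  FM %.3f\n",
              x$rule_out_fraction, x$fn_fraction, x$fn_rate, x$f1,
              x$fowlkes_mallows))
  invisible(x)
}

#' Extrapolate reviewed-set performance to a whole cohort
#'
#' In a screening design the review set is enriched for screen-positive
#' cases; cases never reviewed because they passed the screen (score at or
#' above the screening threshold) are counted as true negatives, and all
#' fractions are recomputed over the full cohort.
#'
#' @param reviewed_report `perf_report` on the reviewed set.
#' @param n_unreviewed number of unreviewed screen-negative cases.
#' @return a new `perf_report` over reviewed + unreviewed cases.
#' @export
extrapolate_cohort <- function(reviewed_report, n_unreviewed) {
  stopifnot(inherits(reviewed_report, "perf_report"))
  if (n_unreviewed < 0) stopf("n_unreviewed must be non-negative")
  ct <- reviewed_report$counts
  perf_from_counts(tp = ct["tp"], fp = ct["fp"],
                   tn = ct["tn"] + n_unreviewed, fn = ct["fn"])
}

#' Positive predictive value by called loss pattern
#'
#' For each distinct lost-protein pattern among MMRd calls: the PPV for any
#' MMR loss (consensus MMRd of any pattern) and for the identical pattern.
#'
#' @param calls `mmr_calls` data frame.
#' @param consensus reference calls (e.g. the consensus rater rows from
#'   [simulate_raters()]): data frame with `case_id, mmr_status,
#'   lost_proteins`.
#' @return data frame: `pattern, n_called, ppv_any_loss, ppv_identical`.
#' @export
pattern_ppv <- function(calls, consensus) {
  if ("rater" %in% names(consensus))
    consensus <- consensus[consensus$rater == "consensus", , drop = FALSE]
  called <- calls[calls$mmr_status == "MMRd", , drop = FALSE]
  idx <- match(called$case_id, consensus$case_id)
  if (anyNA(idx)) stopf("consensus missing for %d called cases", sum(is.na(idx)))
  ref_status <- consensus$mmr_status[idx]
  ref_lost <- consensus$lost_proteins[idx]
  pats <- sort(unique(called$lost_proteins))
  rows <- lapply(pats, function(p) {
    sel <- called$lost_proteins == p
    data.frame(pattern = p, n_called = sum(sel),
               ppv_any_loss = mean(ref_status[sel] == "MMRd"),
               ppv_identical = mean(ref_status[sel] == "MMRd" &
                                      ref_lost[sel] == p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohen's kappa
#'
#' Chance-corrected agreement with chance defined by the product of the two
#' raters' marginal distributions.  Undefined (returns `NA` with a warning)
#' when expected agreement is 1 (both raters constant and identical).
#'
#' @param a,b category vectors of equal length.
#' @return list: `kappa`, `po` (observed agreement), `pe` (expected).
#' @export
cohen_kappa <- function(a, b) {
  stopifnot(length(a) == length(b))
  lev <- union(unique(a), unique(b))
  pa <- table(factor(a, lev)) / length(a)
  pb <- table(factor(b, lev)) / length(b)
  po <- mean(a == b)
  pe <- sum(pa * pb)
  if (pe >= 1 - 1e-12) {
    warning("kappa undefined: expected agreement is 1")
    return(list(kappa = NA_real_, po = po, pe = pe))
  }
  list(kappa = (po - pe) / (1 - pe), po = po, pe = pe)
}

#' Gwet's AC1 agreement coefficient
#'
#' Chance-corrected agreement robust to skewed prevalence.  With K
#' categories, chance agreement is `sum_k pi_k (1 - pi_k) / (K - 1)` where
#' `pi_k` is the mean of the two raters' marginal proportions; in the binary
#' case this is `2 pi (1 - pi)`.
#'
#' @param a,b category vectors of equal length.
#' @return list: `ac1`, `po`, `pe`.
#' @export
gwet_ac1 <- function(a, b) {
  stopifnot(length(a) == length(b))
  lev <- union(unique(a), unique(b))
  if (length(lev) < 2) lev <- c(lev, ".other")
  pik <- (table(factor(a, lev)) / length(a) +
            table(factor(b, lev)) / length(b)) / 2
  po <- mean(a == b)
  pe <- sum(pik * (1 - pik)) / (length(lev) - 1)
  if (pe >= 1 - 1e-12) {
    warning("AC1 undefined: degenerate marginals")
    return(list(ac1 = NA_real_, po = po, pe = pe))
  }
  list(ac1 = (po - pe) / (1 - pe), po = po, pe = pe)
}

#' Inter-rater agreement suite for MMR calls
#'
#' Cohen's kappa, Gwet's AC1 and raw percent agreement for: binary MMR
#' status, per-protein loss (binary per protein), and the exact loss pattern
#' (multicategory, identity weighting — no partial credit for overlapping
#' protein sets).
#'
#' @param calls_a,calls_b data frames with `case_id, mmr_status,
#'   lost_proteins`, matched by `case_id`.
#' @return data frame: `measure, kappa, ac1, percent_agreement`.
#' @export
agreement_stats <- function(calls_a, calls_b) {
  idx <- match(calls_a$case_id, calls_b$case_id)
  if (anyNA(idx)) stopf("calls are not aligned on case_id")
  b <- calls_b[idx, , drop = FALSE]
  one <- function(x, y, measure) {
    k <- suppressWarnings(cohen_kappa(x, y))
    g <- suppressWarnings(gwet_ac1(x, y))
    data.frame(measure = measure, kappa = k$kappa, ac1 = g$ac1,
               percent_agreement = k$po, stringsAsFactors = FALSE)
  }
  rows <- list(one(calls_a$mmr_status, b$mmr_status, "mmr_status"))
  for (p in PROTEINS) {
    la <- vapply(calls_a$lost_proteins, function(s) p %in% split_pattern(s),
                 logical(1))
    lb <- vapply(b$lost_proteins, function(s) p %in% split_pattern(s),
                 logical(1))
    rows[[length(rows) + 1]] <- one(ifelse(la, "lost", "retained"),
                                    ifelse(lb, "lost", "retained"),
                                    paste0("loss_", p))
  }
  rows[[length(rows) + 1]] <- one(calls_a$lost_proteins, b$lost_proteins,
                                  "exact_pattern")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-tabulate MMR calls against MSI status
#'
#' @param calls `mmr_calls` data frame.
#' @param msi data frame with `case_id, msi_status`.
#' @param consensus optional reference calls; when given, each cell of the
#'   2x2 table is decomposed by consensus MMR status.
#' @return list: `table` (2x2, MMR call x MSI status), and when `consensus`
#'   is supplied `breakdown`, a data frame `call, msi, consensus, n`.
#' @export
msi_crosstab <- function(calls, msi, consensus = NULL) {
  idx <- match(calls$case_id, msi$case_id)
  if (anyNA(idx)) stopf("MSI labels missing for some called cases")
  m <- msi$msi_status[idx]
  tab <- table(call = factor(calls$mmr_status, c("MMRd", "MMRp")),
               msi = factor(m, c("MSI", "MSS")))
  out <- list(table = tab)
  if (!is.null(consensus)) {
    if ("rater" %in% names(consensus))
      consensus <- consensus[consensus$rater == "consensus", , drop = FALSE]
    cidx <- match(calls$case_id, consensus$case_id)
    cons <- consensus$mmr_status[cidx]
    bd <- as.data.frame(table(call = factor(calls$mmr_status, c("MMRd", "MMRp")),
                              msi = factor(m, c("MSI", "MSS")),
                              consensus = factor(cons, c("MMRd", "MMRp"))),
                        stringsAsFactors = FALSE)
    names(bd)[4] <- "n"
    out$breakdown <- bd
  }
  out
}
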