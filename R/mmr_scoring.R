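#' Apply the QC cascade to a cell-count table
#'
#' Three rules, applied in order, mirroring routine TMA IHC quality control:
#'
#' 1. **Low epithelium** — a core x protein section with fewer than
#'    `min_epithelial` epithelial cells is excluded (each protein is a
#'    separate stained section of the core, so the rule is per section).
#' 2. **Negative staining** — a core whose sections for *all four* proteins
#'    have fewer than `min_positive` positive cells summed over epithelium
#'    and stroma is excluded entirely (tissue/staining failure).
#' 3. **Uninformative case** — a case with no passing section for any
#'    protein is excluded.
#'
#' @param cells cell-count table (as in [generate_cohort()]`$cells`).
#' @param min_epithelial minimum epithelial cells per section (default 100).
#' @param min_positive minimum positive cells (epithelial + stromal) below
#'   which a section counts as negatively stained (default 20).
#' @return list with `cells` (the filtered table) and `report`, a `qc_report`
#'   list of excluded/retained counts per rule; at every level
#'   excluded + retained equals the input count.
#' @export
apply_qc <- function(cells, min_epithelial = 100, min_positive = 20) {
  required <- c("case_id", "core_id", "protein", CELL_CLASSES)
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0)
    stopf("cell table is missing columns: %s",
          paste(missing_cols, collapse = ", "))

  n_rows_in <- nrow(cells)
  n_cores_in <- length(unique(cells$core_id))
  n_cases_in <- length(unique(cells$case_id))

  # cores with fewer than 4 protein sections are section-loss events: kept,
  # but reported
  sec_per_core <- table(cells$core_id)
  n_section_loss <- sum(sec_per_core < 4)

  # rule 2 is evaluated on the input table so that a wholly negative core is
  # removed even if some of its sections also fail rule 1
  pos_total <- cells$pos_tumor + cells$pos_stroma
  neg_sec <- pos_total < min_positive
  core_all_neg <- tapply(neg_sec, cells$core_id, all)
  failed_cores <- names(core_all_neg)[core_all_neg]

  epi <- cells$pos_tumor + cells$neg_tumor
  low_epi_row <- epi < min_epithelial & !(cells$core_id %in% failed_cores)

  keep <- !low_epi_row & !(cells$core_id %in% failed_cores)
  out <- cells[keep, , drop = FALSE]

  # rule 3: cases left with no sections at all
  kept_cases <- unique(out$case_id)
  dropped_cases <- setdiff(unique(cells$case_id), kept_cases)

  report <- list(
    input = list(sections = n_rows_in, cores = n_cores_in,
                 cases = n_cases_in),
    section_loss_cores = as.integer(n_section_loss),
    excluded = list(
      sections_low_epithelium = as.integer(sum(low_epi_row)),
      cores_negative_staining = length(failed_cores),
      sections_in_negative_cores =
        as.integer(sum(cells$core_id %in% failed_cores)),
      cases_uninformative = length(dropped_cases)),
    retained = list(sections = nrow(out),
                    cores = length(unique(out$core_id)),
                    cases = length(kept_cases)))
  class(report) <- "qc_report"
  rownames(out) <- NULL
  list(cells = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  input: %d sections / %d cores / %d cases\n",
              x$input$sections, x$input$cores, x$input$cases))
  cat(sprintf("  excluded: %d low-epithelium sections; %d negative cores (%d sections); %d uninformative cases\n",
              x$excluded$sections_low_epithelium,
              x$excluded$cores_negative_staining,
              x$excluded$sections_in_negative_cores,
              x$excluded$cases_uninformative))
  cat(sprintf("  retained: %d sections / %d cores / %d cases\n",
              x$retained$sections, x$retained$cores, x$retained$cases))
  invisible(x)
}

#' Score cores: percent-positive per compartment
#'
#' Computes, for each core x protein section, the percentage of epithelial
#' (tumour) and stromal cells that are DAB-positive.  Lymphocytes and
#' background objects are excluded from numerator and denominator — the
#' misclassification of MMR-expressing intraepithelial lymphocytes as tumour
#' is precisely the confounder the class taxonomy exists to remove.
#'
#' @param cells (QC-passed) cell-count table.
#' @return data frame of core metrics: `case_id, core_id, region, protein,
#'   pct_pos_epithelial, pct_pos_stromal, epithelial_cells, qc_status`.
#'   Percentages are `NA` (flagged in `qc_status`) when the compartment
#'   denominator is zero.
#' @export
score_cores <- function(cells) {
  epi <- cells$pos_tumor + cells$neg_tumor
  str <- cells$pos_stroma + cells$neg_stroma
  pct_e <- ifelse(epi > 0, 100 * cells$pos_tumor / epi, NA_real_)
  pct_s <- ifelse(str > 0, 100 * cells$pos_stroma / str, NA_real_)
  data.frame(case_id = cells$case_id,
             core_id = cells$core_id,
             region = cells$region %||% NA_character_,
             protein = cells$protein,
             pct_pos_epithelial = pct_e,
             pct_pos_stromal = pct_s,
             epithelial_cells = epi,
             qc_status = ifelse(epi > 0, "pass", "fail_zero_epithelium"),
             stringsAsFactors = FALSE)
}

#' Build case-level MMR profiles and the minimum percent-positive score
#'
#' Aggregates core metrics to cases: per protein, the mean (and min/max)
#' percent-positive epithelial cells across passing cores, pooling
#' tumour-centre and invasive-margin cores without weighting; the case score
#' `mmr_min` is the minimum of the per-protein means over the *informative*
#' proteins (those with at least one passing core).  Low `mmr_min` indicates
#' loss of at least one MMR protein, i.e. likely MMR deficiency.
#'
#' @param metrics core metrics from [score_cores()].
#' @return data frame with one row per case: per-protein
#'   `mean_/min_/max_/ncores_<protein>` epithelial summaries, per-protein
#'   `str_mean_<protein>` stromal means, `informative_proteins` (string),
#'   `n_informative`, and `mmr_min`.
#' @export
build_case_profiles <- function(metrics) {
  m <- metrics[!is.na(metrics$pct_pos_epithelial), , drop = FALSE]
  if (nrow(m) == 0) stopf("no scoreable core metrics")
  cases <- sort(unique(metrics$case_id))

  agg <- function(f, x, case, prot) {
    t <- tapply(x, list(factor(case, cases), factor(prot, PROTEINS)), f)
    t[cases, PROTEINS, drop = FALSE]
  }
  mean_e <- agg(mean, m$pct_pos_epithelial, m$case_id, m$protein)
  min_e <- agg(min, m$pct_pos_epithelial, m$case_id, m$protein)
  max_e <- agg(max, m$pct_pos_epithelial, m$case_id, m$protein)
  n_e <- agg(length, m$pct_pos_epithelial, m$case_id, m$protein)
  ms <- metrics[!is.na(metrics$pct_pos_stromal), , drop = FALSE]
  mean_s <- agg(mean, ms$pct_pos_stromal, ms$case_id, ms$protein)

  informative <- !is.na(mean_e)
  mmr_min <- suppressWarnings(apply(mean_e, 1, min, na.rm = TRUE))
  mmr_min[!is.finite(mmr_min)] <- NA_real_

  out <- data.frame(case_id = cases, stringsAsFactors = FALSE)
  for (p in PROTEINS) {
    out[[paste0("mean_", p)]] <- mean_e[, p]
    out[[paste0("min_", p)]] <- min_e[, p]
    out[[paste0("max_", p)]] <- max_e[, p]
    out[[paste0("ncores_", p)]] <- ifelse(is.na(n_e[, p]), 0L,
                                          as.integer(n_e[, p]))
    out[[paste0("str_mean_", p)]] <- mean_s[, p]
  }
  out$informative_proteins <- apply(informative, 1, function(r)
    paste(PROTEINS[r], collapse = "+"))
  out$n_informative <- rowSums(informative)
  out$mmr_min <- mmr_min
  # a case uninformative for all four proteins carries no score
  out <- out[out$n_informative > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise correlation of case-level MMR protein expression
#'
#' Pearson r and Spearman rho (with two-sided p-values) between case-level
#' percent-positive values for every protein pair, for the epithelial and
#' stromal compartments.
#'
#' @param profiles case profiles from [build_case_profiles()].
#' @return object of class `correlation_report`: list with `epithelial` and
#'   `stromal` data frames (`protein_a, protein_b, n, pearson_r, pearson_p,
#'   spearman_rho, spearman_p`) and symmetric correlation matrices
#'   `r_epithelial`, `r_stromal`.
#' @export
correlation_report <- function(profiles) {
  pair_table <- function(prefix) {
    vals <- sapply(PROTEINS, function(p) profiles[[paste0(prefix, p)]])
    rows <- list()
    rmat <- diag(1, 4)
    dimnames(rmat) <- list(PROTEINS, PROTEINS)
    for (i in 1:3) for (j in (i + 1):4) {
      x <- vals[, i]; y <- vals[, j]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3)
        stopf("fewer than 3 complete cases for %s-%s", PROTEINS[i], PROTEINS[j])
      if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        r <- rp <- rho <- sp <- NA_real_
      } else {
        ct_p <- cor.test(x[ok], y[ok], method = "pearson")
        ct_s <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman"))
        r <- unname(ct_p$estimate); rp <- ct_p$p.value
        rho <- unname(ct_s$estimate); sp <- ct_s$p.value
      }
      rmat[i, j] <- rmat[j, i] <- r
      rows[[length(rows) + 1]] <- data.frame(
        protein_a = PROTEINS[i], protein_b = PROTEINS[j], n = sum(ok),
        pearson_r = r, pearson_p = rp, spearman_rho = rho, spearman_p = sp,
        stringsAsFactors = FALSE)
    }
    list(table = do.call(rbind, rows), rmat = rmat)
  }
  e <- pair_table("mean_")
  s <- pair_table("str_mean_")
  structure(list(epithelial = e$table, stromal = s$table,
                 r_epithelial = e$rmat, r_stromal = s$rmat),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("Case-level expression correlations (epithelial):\n")
  print(x$epithelial, digits = 3)
  invisible(x)
}

#' One-call scoring pipeline: QC, core scoring, case profiles
#'
#' @param cells raw cell-count table.
#' @param ... passed to [apply_qc()].
#' @return list with `profiles`, `core_metrics`, `qc` (the report).
#' @export
score_cohort <- function(cells, ...) {
  qc <- apply_qc(cells, ...)
  metrics <- score_cores(qc$cells)
  profiles <- build_case_profiles(metrics)
  list(profiles = profiles, core_metrics = metrics, qc = qc$report)
}
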