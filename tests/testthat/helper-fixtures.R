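# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# Default synthetic cohort (n = 2000) plus its scored profiles; several test
# files reuse it, so it is generated lazily and cached.
default_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    coh <- generate_cohort(cohort_config(n_cases = 2000, seed = 101))
    sc <- score_cohort(coh$cells)
    .fixtures$cohort <- list(cohort = coh, scored = sc)
  }
  .fixtures$cohort
}

# One cell-count-table row with overridable counts.
cells_row <- function(case_id = "c1", core_id = "c1_core1", region = "TC",
                      protein = "MLH1", pos_tumor = 800, neg_tumor = 100,
                      pos_stroma = 150, neg_stroma = 50, lymphocyte = 80,
                      strong_bg = 10, weak_bg = 20, stain_fail = FALSE) {
  data.frame(case_id = case_id, core_id = core_id, region = region,
             protein = protein, pos_tumor = pos_tumor, neg_tumor = neg_tumor,
             pos_stroma = pos_stroma, neg_stroma = neg_stroma,
             lymphocyte = lymphocyte, strong_bg = strong_bg,
             weak_bg = weak_bg, stain_fail = stain_fail,
             stringsAsFactors = FALSE)
}

# A full core (all four proteins) with per-protein count overrides.
cells_core <- function(case_id, core_id, ...) {
  over <- list(...)
  do.call(rbind, lapply(c("MLH1", "PMS2", "MSH2", "MSH6"), function(p) {
    args <- c(list(case_id = case_id, core_id = core_id, protein = p),
              over[[p]] %||% list())
    do.call(cells_row, args)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force AUROC by counting concordant/discordant/tied pairs, oriented
# so that lower scores indicate the positive class.
auc_by_pairs <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a < b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}
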