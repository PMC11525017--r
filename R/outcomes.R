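#' Build recurrence-free-interval (RFI) records
#'
#' RFI is the time from randomization to cancer relapse; cases are censored
#' at death without relapse or at last contact.  Records with missing or
#' non-positive follow-up are rejected (reported, not imputed).
#'
#' @param raw data frame with `case_id`, and per case (months from
#'   randomization, `NA` when the event did not occur): `relapse_time`,
#'   `death_time`, `last_contact_time`.
#' @return list: `records` (data frame `case_id, time, event` with `event`
#'   1 = relapse, 0 = censored, plus any extra covariable columns carried
#'   through from `raw`) and `rejected` (data frame `case_id, reason`).
#' @export
make_rfi <- function(raw) {
  stopifnot(is.data.frame(raw), "case_id" %in% names(raw))
  relapse <- raw$relapse_time
  death <- raw$death_time
  last <- raw$last_contact_time
  time <- ifelse(!is.na(relapse), relapse,
                 ifelse(!is.na(death), death, last))
  event <- as.integer(!is.na(relapse))
  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(time)] <- "no follow-up time"
  reason[!is.na(time) & time <= 0] <- "non-positive time"
  bad <- !is.na(reason)
  extra <- setdiff(names(raw), c("case_id", "relapse_time", "death_time",
                                 "last_contact_time"))
  records <- data.frame(case_id = raw$case_id[!bad],
                        time = time[!bad], event = event[!bad],
                        stringsAsFactors = FALSE)
  records[extra] <- raw[!bad, extra, drop = FALSE]
  list(records = records,
       rejected = data.frame(case_id = raw$case_id[bad],
                             reason = reason[bad], stringsAsFactors = FALSE))
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit estimates (Greenwood variance) per group and, with two or
#' more groups, the log-rank chi-square test on k - 1 degrees of freedom.
#'
#' @param records data frame with `time`, `event`, and the grouping column.
#' @param group name of the grouping column.
#' @return list: `fit` (a [survival::survfit] object), and with >= 2 groups
#'   `chisq`, `df`, `p`.
#' @export
km_logrank <- function(records, group) {
  stopifnot(all(c("time", "event", group) %in% names(records)))
  f <- as.formula(paste("survival::Surv(time, event) ~", group))
  fit <- survival::survfit(f, data = records)
  out <- list(fit = fit)
  if (length(unique(records[[group]])) >= 2) {
    if (sum(records$event) < 1) stopf("log-rank needs at least one event")
    sd_ <- survival::survdiff(f, data = records)
    df <- length(sd_$n) - 1
    out$chisq <- sd_$chisq
    out$df <- df
    out$p <- 1 - stats::pchisq(sd_$chisq, df)
  }
  out
}

#' Cox proportional-hazards fit with Wald CIs and Schoenfeld diagnostics
#'
#' Partial-likelihood fit (Efron tie handling by default) on complete cases
#' only, with per-term hazard ratios, Wald 95% CIs and p-values, and the
#' scaled-Schoenfeld-residual trend test of proportional hazards per term.
#' Constant covariables are dropped with a flag rather than fit; warns when
#' there are fewer than 10 events per estimated term.
#'
#' @param records data frame with `time`, `event` and covariables.
#' @param formula right-hand side, e.g. `~ mmr * duration + age`.
#' @param ties tie-handling method for [survival::coxph()].
#' @return object of class `cox_fit`: `table` (term, hr, ci_lo, ci_hi, p,
#'   ph_p), `fit` (the coxph object), `dropped` (constant terms), `n`,
#'   `n_events`, `converged`.
#' @export
cox_fit <- function(records, formula, ties = "efron") {
  rhs <- if (inherits(formula, "formula")) formula else as.formula(formula)
  vars <- all.vars(rhs)
  stopifnot(all(c("time", "event") %in% names(records)))
  miss <- setdiff(vars, names(records))
  if (length(miss)) stopf("missing covariables: %s", paste(miss, collapse = ", "))
  dat <- records[complete.cases(records[c("time", "event", vars)]), , drop = FALSE]

  constant <- vars[vapply(vars, function(v) length(unique(dat[[v]])) < 2,
                          logical(1))]
  keep <- setdiff(vars, constant)
  if (length(keep) == 0) stopf("no non-constant covariables to fit")
  rhs_txt <- paste(deparse(rhs[[length(rhs)]]), collapse = " ")
  if (length(constant) > 0) {
    warning(sprintf("dropping constant covariables: %s",
                    paste(constant, collapse = ", ")))
    rhs_txt <- paste(keep, collapse = " + ")
  }
  f <- as.formula(paste("survival::Surv(time, event) ~", rhs_txt))
  fit <- survival::coxph(f, data = dat, ties = ties)
  if (sum(dat$event) < 10 * length(fit$coefficients))
    warning("fewer than 10 events per model term; estimates may be unstable")
  converged <- is.null(fit$info) && !any(is.na(fit$coefficients)) &&
    all(is.finite(sqrt(diag(fit$var))))
  if (!converged) warning("Cox fit did not converge cleanly")

  s <- summary(fit)
  zph <- tryCatch(survival::cox.zph(fit), error = function(e) NULL)
  ph_p <- rep(NA_real_, length(fit$coefficients))
  if (!is.null(zph)) {
    zt <- zph$table
    zt <- zt[rownames(zt) != "GLOBAL", , drop = FALSE]
    # cox.zph reports per covariable (not per coefficient); map by prefix
    for (i in seq_along(fit$coefficients)) {
      term <- names(fit$coefficients)[i]
      hit <- which(vapply(rownames(zt), function(r)
        startsWith(term, r) || startsWith(r, term), logical(1)))
      if (length(hit) >= 1) ph_p[i] <- zt[hit[1], "p"]
    }
  }
  tab <- data.frame(term = names(fit$coefficients),
                    hr = unname(s$conf.int[, "exp(coef)"]),
                    ci_lo = unname(s$conf.int[, "lower .95"]),
                    ci_hi = unname(s$conf.int[, "upper .95"]),
                    p = unname(s$coefficients[, "Pr(>|z|)"]),
                    ph_p = ph_p,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, fit = fit, dropped = constant,
                 n = nrow(dat), n_events = sum(dat$event),
                 converged = converged),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit: n = %d, events = %d%s\n", x$n, x$n_events,
              if (length(x$dropped)) paste0(" (dropped: ",
                                            paste(x$dropped, collapse = ", "), ")")
              else ""))
  print(x$table, digits = 3)
  invisible(x)
}

#' Association tests between a grouping and clinicopathological variables
#'
#' Two-sided tests: Welch t for continuous variables, Fisher's exact test
#' for 2x2 tables, chi-square for larger tables.
#'
#' @param data data frame.
#' @param group name of the (categorical) grouping column.
#' @param vars variable names to test against `group`.
#' @return data frame: `variable, test, statistic, p`.
#' @export
association_tests <- function(data, group, vars) {
  g <- factor(data[[group]])
  rows <- lapply(vars, function(v) {
    x <- data[[v]]
    if (is.numeric(x)) {
      if (nlevels(g) != 2) stopf("Welch t test needs 2 groups for %s", v)
      tt <- t.test(x ~ g)
      data.frame(variable = v, test = "welch_t",
                 statistic = unname(tt$statistic), p = tt$p.value,
                 stringsAsFactors = FALSE)
    } else {
      tab <- table(factor(x), g)
      if (any(dim(tab) < 2) || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        return(data.frame(variable = v, test = "degenerate",
                          statistic = NA_real_, p = NA_real_,
                          stringsAsFactors = FALSE))
      if (all(dim(tab) == 2)) {
        ft <- fisher.test(tab)
        data.frame(variable = v, test = "fisher",
                   statistic = NA_real_, p = ft$p.value,
                   stringsAsFactors = FALSE)
      } else {
        ct <- suppressWarnings(chisq.test(tab))
        data.frame(variable = v, test = "chisq",
                   statistic = unname(ct$statistic), p = ct$p.value,
                   stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Design of a simulated adjuvant-chemotherapy trial
#'
#' Parameters of the interaction power simulation: exponential event times
#' with administrative censoring at a common horizon, the baseline hazard
#' calibrated so the expected number of recurrences matches
#' `n_recurrences`; MMR status Bernoulli(`prevalence`); 3- vs 6-month
#' duration arm Bernoulli(0.5), independent of MMR status.  The interaction
#' `effect_ratio` is the ratio between the MMR-group-specific hazard ratios
#' for 3 vs 6 months of chemotherapy.
#'
#' @param n_cases trial size (default 2000).
#' @param n_recurrences expected number of recurrence events (default 500).
#' @param prevalence MMRd prevalence (default 0.1).
#' @param effect_ratio interaction: ratio of the duration-effect HR in MMRd
#'   vs MMRp patients (1 = no interaction).
#' @param hr_mmrd main-effect HR of MMRd (default 2.08, the elevated
#'   recurrence hazard of MMRd tumours under oxaliplatin-based adjuvant
#'   therapy).
#' @param hr_duration main-effect HR of the 3-month arm in MMRp patients
#'   (default 1, consistent with duration non-inferiority).
#' @param horizon administrative censoring horizon in months (default 72).
#' @param alpha two-sided significance level.
#' @return object of class `trial_design` including the calibrated baseline
#'   hazard `lambda0`.
#' @export
trial_design <- function(n_cases = 2000, n_recurrences = 500,
                         prevalence = 0.1, effect_ratio = 2.3,
                         hr_mmrd = 2.08, hr_duration = 1,
                         horizon = 72, alpha = 0.05) {
  stopifnot(n_cases > 0, n_recurrences > 0, n_recurrences < n_cases,
            prevalence > 0, prevalence < 1, effect_ratio > 0,
            hr_mmrd > 0, hr_duration > 0, horizon > 0,
            alpha > 0, alpha < 1)
  # group multipliers and weights: (mmrd, dur3) in {0,1}^2, arms 50:50
  mult <- c(1, hr_duration, hr_mmrd, hr_mmrd * hr_duration * effect_ratio)
  w <- c((1 - prevalence) / 2, (1 - prevalence) / 2,
         prevalence / 2, prevalence / 2)
  target <- n_recurrences / n_cases
  f <- function(l0) sum(w * (1 - exp(-l0 * mult * horizon))) - target
  if (f(10) < 0) stopf("infeasible event target")
  lambda0 <- stats::uniroot(f, c(1e-9, 10), tol = 1e-12)$root
  structure(list(n_cases = as.integer(n_cases),
                 n_recurrences = n_recurrences, prevalence = prevalence,
                 effect_ratio = effect_ratio, hr_mmrd = hr_mmrd,
                 hr_duration = hr_duration, horizon = horizon,
                 alpha = alpha, lambda0 = lambda0),
            class = "trial_design")
}

#' Simulate one trial under a design
#'
#' @param design a [trial_design()] object.
#' @param seed RNG seed.
#' @return data frame of survival records: `case_id, time, event, mmr_status,
#'   mmrd, duration, dur3`, plus neutral covariables (`age, gender, pN, pT,
#'   sidedness, regimen`) for exercising multivariable fits.
#' @export
simulate_trial <- function(design, seed = 1L) {
  stopifnot(inherits(design, "trial_design"))
  d <- design
  with_seed(substream_seed(seed, 1), {
    n <- d$n_cases
    mmrd <- as.integer(runif(n) < d$prevalence)
    dur3 <- as.integer(runif(n) < 0.5)
    loghr <- log(d$hr_mmrd) * mmrd + log(d$hr_duration) * dur3 +
      log(d$effect_ratio) * mmrd * dur3
    rate <- d$lambda0 * exp(loghr)
    t_event <- rexp(n, rate)
    event <- as.integer(t_event <= d$horizon)
    time <- pmin(t_event, d$horizon)
    data.frame(case_id = sprintf("pt_%05d", seq_len(n)),
               time = time, event = event,
               mmr_status = ifelse(mmrd == 1, "MMRd", "MMRp"),
               mmrd = mmrd,
               duration = ifelse(dur3 == 1, "3m", "6m"),
               dur3 = dur3,
               age = round(rnorm(n, 63, 9)),
               gender = sample(c("F", "M"), n, replace = TRUE),
               pN = sample(c("N1", "N2"), n, replace = TRUE, prob = c(0.7, 0.3)),
               pT = sample(c("T1-2", "T3", "T4"), n, replace = TRUE,
                           prob = c(0.15, 0.6, 0.25)),
               sidedness = sample(c("right", "left"), n, replace = TRUE,
                                  prob = c(0.4, 0.6)),
               regimen = sample(c("CAPOX", "FOLFOX"), n, replace = TRUE,
                                prob = c(0.65, 0.35)),
               stringsAsFactors = FALSE)
  })
}

#' Monte-Carlo power of the MMR-by-duration interaction test
#'
#' Simulates replicate trials under a [trial_design()], fits the Cox model
#' `~ mmrd * dur3` per replicate, and estimates power as the fraction of
#' replicates whose interaction Wald p-value falls below `design$alpha`.
#' Replicates whose fit fails are counted and excluded from the denominator
#' only when they are fewer than 1% of replicates (otherwise an error).
#'
#' @param design a [trial_design()] object.
#' @param n_reps number of replicate trials (>= 200).
#' @param seed master seed; replicate r uses substream `r`.
#' @return list of class `power_estimate`: `power`, `ci` (95% binomial),
#'   `n_reps`, `n_failed`, `alpha`.
#' @export
estimate_power <- function(design, n_reps = 500, seed = 1L) {
  stopifnot(inherits(design, "trial_design"))
  if (n_reps < 200) stopf("n_reps must be at least 200")
  pvals <- vapply(seq_len(n_reps), function(r) {
    dat <- simulate_trial(design, seed = substream_seed(seed, r))
    tryCatch({
      fit <- survival::coxph(survival::Surv(time, event) ~ mmrd * dur3,
                             data = dat, ties = "efron")
      summary(fit)$coefficients["mmrd:dur3", "Pr(>|z|)"]
    }, error = function(e) NA_real_, warning = function(w) NA_real_)
  }, numeric(1))
  n_failed <- sum(is.na(pvals))
  if (n_failed >= 0.01 * n_reps)
    stopf("%d of %d replicate fits failed", n_failed, n_reps)
  ok <- !is.na(pvals)
  k <- sum(pvals[ok] < design$alpha)
  m <- sum(ok)
  ci <- as.numeric(binom.test(k, m)$conf.int)
  structure(list(power = k / m, ci = ci, n_reps = m, n_failed = n_failed,
                 alpha = design$alpha),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("Power = %.3f (95%% CI %.3f-%.3f) over %d replicates (alpha = %g)\n",
              x$power, x$ci[1], x$ci[2], x$n_reps, x$alpha))
  invisible(x)
}
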