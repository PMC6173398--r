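#' Proportional-hazards fit with explicit failure modes
#'
#' Cox partial-likelihood maximization (Breslow tie handling by default,
#' Efron available) via the survival package, wrapped to enforce the
#' contracts the trial analyses rely on: at least one event, full-rank
#' designs (rank deficiency errors and names the offending terms rather than
#' silently dropping them), an explicit error on monotone likelihood
#' (a covariate that perfectly separates events), and an error rather than a
#' silent result on non-convergence.
#'
#' @param time Non-negative follow-up times.
#' @param event 0/1 event indicators.
#' @param X Numeric design matrix (no intercept; the baseline hazard absorbs
#'   it) with column names.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return A `survival_fit` object: tibble of per-term log hazard ratios
#'   with SEs and two-sided p-values via `tidy()`, counts via `glance()`.
#' @examples
#' cohort <- gen_stratum(trial_cohort_specs(n = 500)[[1]], seed = 1)
#' fit <- fit_cox(cohort$time, cohort$mce,
#'                cbind(dosage = cohort$dosage, treatment = cohort$treatment))
#' tidy(fit)
#' @export
fit_cox <- function(time, event, X, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyNA(time) || anyNA(event) || anyNA(X)) {
    abort("complete cases required: NA in time, event or X")
  }
  if (any(time < 0)) abort("follow-up times must be >= 0")
  if (!all(event %in% c(0, 1))) abort("`event` must be coded 0/1")
  if (sum(event) < 1) abort("at least one event is required")
  # constant columns can never be estimated from a partial likelihood
  const <- colnames(X)[apply(X, 2, function(v) length(unique(v)) < 2)]
  if (length(const)) {
    abort(sprintf("rank-deficient design: constant column(s) %s",
                  paste(const, collapse = ", ")))
  }
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ X, ties = ties,
                    control = survival::coxph.control(eps = 1e-12,
                                                      iter.max = 50)),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("infinite|did not converge|beta may be infinite", msg)) {
        abort(paste("monotone partial likelihood (a covariate separates",
                    "events):", msg))
      }
      invokeRestart("muffleWarning")
    })
  co <- coef(fit)
  if (anyNA(co)) {
    bad <- colnames(X)[is.na(co)]
    abort(sprintf("rank-deficient design: collinear column(s) %s",
                  paste(bad, collapse = ", ")))
  }
  se <- sqrt(diag(vcov(fit)))
  terms <- tibble::tibble(term = colnames(X), estimate = unname(co),
                          se = unname(se),
                          statistic = unname(co / se),
                          p.value = wald_p(unname(co), unname(se)))
  structure(
    list(terms = terms, n = length(time), events = sum(event),
         loglik = fit$loglik[2], loglik_null = fit$loglik[1],
         ties = ties, converged = TRUE),
    class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("<survival_fit> Cox PH (%s ties), n = %d, events = %d\n",
              x$ties, x$n, x$events))
  print(x$terms)
  invisible(x)
}

#' Tidiers for Cox fits
#'
#' `tidy()` returns per-term log hazard ratios; `glance()` the fit-level
#' summary (n, events, partial log-likelihoods).
#'
#' @param x A `survival_fit` from [fit_cox()] or [cox_interaction()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy survival_fit
#' @export
tidy.survival_fit <- function(x, ...) x$terms

#' @rdname tidy.survival_fit
#' @method glance survival_fit
#' @export
glance.survival_fit <- function(x, ...) {
  tibble::tibble(n = x$n, events = x$events, loglik = x$loglik,
                 loglik_null = x$loglik_null, ties = x$ties)
}

# assemble the pooled-analysis design: dosage, treatment, their product,
# covariates, and stratum indicator columns (region analog)
interaction_design <- function(cohort, covariates, stratum_indicators) {
  rhs <- c("dosage", "treatment", "dosage:treatment", covariates,
           if (stratum_indicators && length(unique(cohort$stratum)) > 1)
             "stratum")
  model.matrix(as.formula(paste("~", paste(rhs, collapse = " + "))),
               data = cohort)[, -1, drop = FALSE]
}

#' Gene-by-treatment interaction in a survival model
#'
#' Pools all subjects and fits a Cox model with SNP dosage, randomized
#' treatment arm, their product term, optional covariates, and stratum
#' indicator columns (the region-analog adjustment for pooled multi-ethnic
#' analyses). The Wald p-value of the `dosage:treatment` term tests whether
#' treatment modifies the per-allele hazard.
#'
#' @inheritParams snp_assoc
#' @param time,event,treatment Column names for follow-up time, event
#'   indicator, and the binary treatment arm.
#' @param stratum_indicators Include stratum indicator covariates when more
#'   than one stratum is present (default TRUE).
#' @param ties Tie handling passed to [fit_cox()].
#' @return A `survival_fit` including the `dosage:treatment` term.
#' @examples
#' cohort <- gen_multiethnic(trial_cohort_specs(n = 400), seed = 1)
#' fit <- cox_interaction(cohort)
#' tidy(fit)
#' @export
cox_interaction <- function(cohort, time = "time", event = "mce",
                            treatment = "treatment",
                            covariates = character(),
                            stratum_indicators = TRUE,
                            ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  need <- c("stratum", "dosage", time, event, treatment, covariates)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    abort(sprintf("cohort lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  sub <- cohort[complete.cases(cohort[, need]), need, drop = FALSE]
  if (!all(sub[[treatment]] %in% c(0, 1))) {
    abort("treatment column must be binary 0/1")
  }
  if (length(unique(sub[[treatment]])) < 2) {
    abort("rank-deficient design: treatment arm is constant")
  }
  X <- interaction_design(sub, covariates, stratum_indicators)
  fit_cox(sub[[time]], sub[[event]], X, ties = ties)
}

#' Per-stratum baseline biomarker association with pooled meta-analysis
#'
#' The trial-style baseline analysis: within each race/ethnic stratum the
#' baseline biomarker is regressed on SNP dosage (plus covariates), and the
#' per-stratum estimates are combined by DerSimonian-Laird random-effects
#' meta-analysis.
#'
#' @inheritParams snp_assoc
#' @param biomarker Name of the baseline biomarker column.
#' @return List with `strata` (the per-stratum association tibble) and
#'   `meta` (a `meta_fit` from [meta_random()]).
#' @examples
#' cohort <- gen_multiethnic(trial_cohort_specs(n = 400), seed = 1)
#' res <- baseline_biomarker_assoc(cohort, "lppla2_activity")
#' tidy(res$meta)
#' @export
baseline_biomarker_assoc <- function(cohort, biomarker,
                                     covariates = character(),
                                     strata = NULL) {
  assoc <- snp_assoc(cohort, biomarker, covariates = covariates,
                     kind = "linear", strata = strata)
  est <- tibble::tibble(label = assoc$stratum, n = assoc$n,
                        beta = assoc$beta, se = assoc$se)
  list(strata = assoc, meta = meta_random(est))
}
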