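# build the per-stratum complete-case design matrices shared by Model 1
# (outcome ~ SNP + covariates) and Model 2 (same + mediator); both models
# are always fit on the identical subset
mediation_design <- function(cohort, stratum, outcome, mediator, covariates,
                             transform) {
  cols <- c("dosage", outcome, mediator, covariates)
  missing_cols <- setdiff(c("stratum", cols), names(cohort))
  if (length(missing_cols)) {
    abort(sprintf("cohort lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  sub <- cohort[cohort$stratum == stratum, cols, drop = FALSE]
  if (!nrow(sub)) abort(sprintf("stratum '%s' not present in cohort", stratum))
  sub <- sub[complete.cases(sub), , drop = FALSE]
  if (!nrow(sub)) abort(sprintf("stratum '%s': empty complete-case subset",
                                stratum))
  if (length(unique(sub$dosage)) < 2) {
    abort(sprintf("stratum '%s': monomorphic SNP in the analysis subset",
                  stratum))
  }
  med <- sub[[mediator]]
  if (transform == "sqrt") {
    if (any(med < 0)) abort("sqrt transform requires a non-negative mediator")
    med <- sqrt(med)
  }
  X1 <- build_design(sub, covariates)
  list(y = sub[[outcome]], X1 = X1,
       X2 = cbind(X1, mediator = med), n = nrow(sub))
}

# fast SNP-coefficient difference used inside the bootstrap loop; returns NA
# when either model is rank-deficient in the resample
diff_on_rows <- function(y, X1, X2, rows) {
  f1 <- .lm.fit(X1[rows, , drop = FALSE], y[rows])
  f2 <- .lm.fit(X2[rows, , drop = FALSE], y[rows])
  if (f1$rank < ncol(X1) || f2$rank < ncol(X2)) return(NA_real_)
  # "dosage" is always column 2 of both designs (after the intercept);
  # .lm.fit permutes coefficients by its pivot
  c1 <- f1$coefficients[match(2L, f1$pivot)]
  c2 <- f2$coefficients[match(2L, f2$pivot)]
  c2 - c1
}

#' Difference-in-coefficients mediation estimate
#'
#' For each stratum, fits Model 1 (outcome on SNP dosage + covariates) and
#' Model 2 (the same plus the candidate mediator) on the identical
#' complete-case subset, and reports the change in the SNP coefficient.
#' Under the linear structural model the population value of this difference
#' is minus the indirect effect, \eqn{-(a \cdot b)}.
#'
#' @inheritParams snp_assoc
#' @param outcome Name of the continuous outcome column (cIMT-like).
#' @param mediator Name of the candidate mediator column.
#' @param transform `"identity"` or `"sqrt"` applied to the mediator before
#'   fitting (right-skewed fatty-acid ratios are square-root transformed).
#' @return Tibble with one row per stratum: `stratum`, `n`, `coef_model1`,
#'   `coef_model2`, `diff`.
#' @examples
#' cohort <- gen_multiethnic(mesa_cohort_specs(n = 400), seed = 1)
#' mediation_diff(cohort, outcome = "cimt", mediator = "lppla2_activity",
#'                covariates = c("age", "sex"))
#' @export
mediation_diff <- function(cohort, outcome, mediator,
                           covariates = character(),
                           transform = c("identity", "sqrt"),
                           strata = NULL) {
  transform <- match.arg(transform)
  strata <- strata %||% unique(cohort$stratum)
  purrr::map_dfr(strata, function(st) {
    d <- mediation_design(cohort, st, outcome, mediator, covariates,
                          transform)
    # fit_linear performs the rank checks and names collinear columns
    f1 <- fit_linear(d$y, d$X1)
    f2 <- fit_linear(d$y, d$X2)
    c1 <- f1$estimate[f1$term == "dosage"]
    c2 <- f2$estimate[f2$term == "dosage"]
    tibble::tibble(stratum = st, n = d$n, coef_model1 = c1,
                   coef_model2 = c2, diff = c2 - c1)
  })
}

# bias-corrected interval endpoints and p-value from bootstrap draws
bc_interval <- function(theta_hat, theta_star, level) {
  B <- length(theta_star)
  prop <- (sum(theta_star < theta_hat) +
             0.5 * sum(theta_star == theta_hat)) / B
  # all draws strictly on one side of the estimate: clamp to the resolution
  # of the bootstrap rather than return an infinite correction
  prop <- min(max(prop, 1 / (2 * B)), 1 - 1 / (2 * B))
  z0 <- qnorm(prop)
  ci_at <- function(alpha) {
    a1 <- pnorm(2 * z0 + qnorm(alpha / 2))
    a2 <- pnorm(2 * z0 + qnorm(1 - alpha / 2))
    quantile(theta_star, c(a1, a2), names = FALSE, type = 7)
  }
  ci <- ci_at(1 - level)
  excludes0 <- function(alpha) {
    b <- ci_at(alpha)
    b[1] > 0 || b[2] < 0
  }
  # smallest two-sided alpha whose BC interval excludes zero, by bisection;
  # exclusion is monotone in alpha because both endpoints are
  tol <- 1 / B
  if (!excludes0(1 - tol)) {
    p <- 1
  } else if (excludes0(tol)) {
    p <- tol
  } else {
    lo <- tol; hi <- 1 - tol
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (excludes0(mid)) hi <- mid else lo <- mid
    }
    p <- hi
  }
  list(ci_low = ci[1], ci_high = ci[2], p = p, z0 = z0)
}

#' Bias-corrected bootstrap mediation analysis
#'
#' Nonparametric pairs bootstrap of the difference-in-coefficients mediation
#' estimate: whole subject rows are resampled with replacement within each
#' stratum, the coefficient difference is recomputed on each resample, and a
#' bias-corrected (BC) percentile interval is formed. The bias-correction
#' constant is \eqn{z_0 = \Phi^{-1}(\#\{\theta^* < \hat\theta\}/B)} with a
#' half-count convention for ties, and the interval endpoints are the
#' empirical bootstrap quantiles at \eqn{\Phi(2z_0 + z_{\alpha/2})} and
#' \eqn{\Phi(2z_0 + z_{1-\alpha/2})}. The two-sided p-value is the smallest
#' alpha at which the BC interval excludes zero (bisection, tolerance
#' `1/B`). Resamples in which either model is singular are redrawn, counted,
#' and capped at 10% of `B`.
#'
#' @inheritParams mediation_diff
#' @param B Number of bootstrap resamples (>= 200; default 1000).
#' @param seed Integer seed (mandatory); each stratum draws from a
#'   label-derived sub-seed so stratum order never changes results.
#' @param level Confidence level of the interval (default 0.95).
#' @return A `mediation_fit` object; `tidy()` gives the per-stratum table
#'   (point estimates, BC interval, bootstrap p, `z0`, bootstrap SE).
#' @examples
#' cohort <- gen_multiethnic(mesa_cohort_specs(n = 300), seed = 1)
#' fit <- mediation_boot(cohort, outcome = "cimt",
#'                       mediator = "lppla2_activity",
#'                       covariates = c("age", "sex"), B = 200, seed = 2)
#' tidy(fit)
#' @export
mediation_boot <- function(cohort, outcome, mediator,
                           covariates = character(),
                           transform = c("identity", "sqrt"),
                           strata = NULL, B = 1000, seed, level = 0.95) {
  transform <- match.arg(transform)
  if (missing(seed)) abort("`seed` is required for a reproducible bootstrap")
  if (B < 200) abort("`B` must be at least 200")
  if (level <= 0 || level >= 1) abort("`level` must lie in (0, 1)")
  strata <- strata %||% unique(cohort$stratum)

  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))

  rows <- purrr::map(strata, function(st) {
    d <- mediation_design(cohort, st, outcome, mediator, covariates,
                          transform)
    f1 <- fit_linear(d$y, d$X1)
    f2 <- fit_linear(d$y, d$X2)
    c1 <- f1$estimate[f1$term == "dosage"]
    c2 <- f2$estimate[f2$term == "dosage"]
    theta_hat <- c2 - c1

    set.seed(stratum_seed(seed, st))
    theta_star <- numeric(B)
    degenerate <- 0L
    max_degenerate <- ceiling(0.1 * B)
    b <- 1L
    while (b <= B) {
      th <- diff_on_rows(d$y, d$X1, d$X2,
                         sample.int(d$n, d$n, replace = TRUE))
      if (is.na(th)) {
        degenerate <- degenerate + 1L
        if (degenerate > max_degenerate) {
          abort(sprintf(
            "stratum '%s': more than 10%% of bootstrap resamples degenerate",
            st))
        }
      } else {
        theta_star[b] <- th
        b <- b + 1L
      }
    }
    bc <- bc_interval(theta_hat, theta_star, level)
    list(
      summary = tibble::tibble(
        stratum = st, n = d$n, coef_model1 = c1, coef_model2 = c2,
        diff = theta_hat, ci_low = bc$ci_low, ci_high = bc$ci_high,
        p = bc$p, z0 = bc$z0, boot_se = sd(theta_star),
        degenerate_resamples = degenerate),
      theta_star = theta_star)
  })

  structure(
    list(results = purrr::map_dfr(rows, "summary"),
         theta_star = setNames(purrr::map(rows, "theta_star"), strata),
         outcome = outcome, mediator = mediator, covariates = covariates,
         transform = transform, B = B, seed = seed, level = level),
    class = "mediation_fit")
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf("<mediation_fit> %s as mediator of dosage -> %s (B = %d, %g%% BC CI)\n",
              x$mediator, x$outcome, x$B, 100 * x$level))
  print(x$results)
  invisible(x)
}

#' Tidiers for mediation fits
#'
#' `tidy()` returns the per-stratum mediation table; `glance()` returns the
#' inverse-variance fixed-effects meta-analysis of the per-stratum
#' coefficient differences (bootstrap SDs as SEs) in one row, with
#' heterogeneity.
#'
#' @param x A `mediation_fit` from [mediation_boot()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mediation_fit
#' @export
tidy.mediation_fit <- function(x, ...) x$results

#' @rdname tidy.mediation_fit
#' @method glance mediation_fit
#' @export
glance.mediation_fit <- function(x, ...) {
  m <- mediation_meta(x)
  dplyr::bind_cols(tidy(m)[, c("beta", "se", "z", "p")], glance(m))
}

#' Meta-analysis of per-stratum mediation effects
#'
#' Combines the per-stratum coefficient differences by inverse-variance
#' fixed-effects meta-analysis, using each stratum's bootstrap SD as its
#' standard error (the only self-consistent weight when no analytic SE of
#' the difference is available).
#'
#' @param results A `mediation_fit`, or a data frame with columns `diff` and
#'   `boot_se` (optionally `stratum`).
#' @return A `meta_fit` object.
#' @export
mediation_meta <- function(results) {
  if (inherits(results, "mediation_fit")) results <- results$results
  if (!all(c("diff", "boot_se") %in% names(results))) {
    abort("`results` needs columns `diff` and `boot_se`")
  }
  if (nrow(results) < 2) abort("at least 2 strata required for meta-analysis")
  assert_positive_se(results$boot_se, "boot_se")
  est <- tibble::tibble(label = results$stratum %||%
                          paste0("stratum", seq_len(nrow(results))),
                        beta = results$diff, se = results$boot_se)
  meta_fixed(est)
}

#' Bootstrap distribution plot for a mediation fit
#'
#' Histogram of the bootstrap coefficient differences per stratum with the
#' point estimate and BC interval marked.
#'
#' @param object A `mediation_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mediation_fit
#' @export
autoplot.mediation_fit <- function(object, ...) {
  draws <- purrr::imap_dfr(object$theta_star, function(th, st) {
    tibble::tibble(stratum = st, theta = th)
  })
  marks <- object$results
  ggplot2::ggplot(draws, ggplot2::aes(x = .data$theta)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$diff),
                        colour = "firebrick") +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$ci_low),
                        linetype = 2) +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$ci_high),
                        linetype = 2) +
    ggplot2::facet_wrap(~stratum, scales = "free") +
    ggplot2::labs(x = "Bootstrap coefficient difference (Model 2 - Model 1)",
                  y = "Count") +
    ggplot2::theme_minimal()
}
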