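#' Ordinary least-squares fit with Wald inference
#'
#' Thin wrapper around R's QR-based linear-model machinery that enforces the
#' contracts the association pipeline relies on: complete full-rank designs,
#' an explicit singular-design error naming the collinear columns, SEs from
#' the unbiased residual-variance estimator, and two-sided p-values from the
#' t distribution on `n - k` degrees of freedom.
#'
#' @param y Numeric response vector.
#' @param X Numeric design matrix with column names (include an intercept
#'   column explicitly if wanted).
#' @return A tibble with columns `term`, `estimate`, `se`, `statistic`,
#'   `p.value`, plus attributes `sigma2` and `df.residual`.
#' @export
fit_linear <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  k <- ncol(X)
  if (nrow(X) != n) abort("`y` and `X` must have matching rows")
  if (anyNA(y) || anyNA(X)) abort("complete cases required: NA in y or X")
  if (n <= k) abort(sprintf("insufficient data: n = %d <= %d parameters", n, k))
  qx <- qr(X)
  if (qx$rank < k) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):k]]
    abort(sprintf("singular design: collinear column(s) %s",
                  paste(bad, collapse = ", ")))
  }
  fit <- lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  df <- n - k
  sigma2 <- rss / df
  XtX_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- sqrt(sigma2 * diag(XtX_inv))
  est <- fit$coefficients[colnames(X)]
  stat <- est / se
  out <- tibble::tibble(term = colnames(X), estimate = unname(est),
                        se = unname(se), statistic = unname(stat),
                        p.value = 2 * pt(-abs(unname(stat)), df))
  attr(out, "sigma2") <- sigma2
  attr(out, "df.residual") <- df
  out
}

#' Logistic regression fit with Wald inference
#'
#' Maximum-likelihood logistic regression by iteratively reweighted least
#' squares, with explicit errors for rank deficiency, non-convergence and
#' (quasi-)complete separation, SEs from the inverse observed information,
#' and two-sided normal-reference p-values.
#'
#' @inheritParams fit_linear
#' @param y Binary (0/1) response vector.
#' @param max_iter IRLS iteration cap before a non-convergence error.
#' @return A tibble as in [fit_linear()].
#' @export
fit_logistic <- function(y, X, max_iter = 100) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyNA(y) || anyNA(X)) abort("complete cases required: NA in y or X")
  if (!all(y %in% c(0, 1))) abort("`y` must be binary 0/1")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    abort(sprintf("singular design: collinear column(s) %s",
                  paste(bad, collapse = ", ")))
  }
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = list(maxit = max_iter, epsilon = 1e-10)))
  if (!fit$converged) abort("logistic fit did not converge")
  mu <- fit$fitted.values
  coefs <- fit$coefficients
  # diverging coefficients with fitted probabilities collapsing to 0/1
  # indicate (quasi-)complete separation
  if (max(abs(coefs)) > 15 && (min(mu) < 1e-8 || max(mu) > 1 - 1e-8)) {
    abort("perfect separation detected: coefficient estimates diverge")
  }
  w <- mu * (1 - mu)
  info <- crossprod(X * sqrt(w))
  se <- sqrt(diag(chol2inv(chol(info))))
  stat <- coefs / se
  tibble::tibble(term = colnames(X), estimate = unname(coefs),
                 se = unname(se), statistic = unname(stat),
                 p.value = 2 * pnorm(-abs(unname(stat))))
}

# build a design matrix for dosage + covariates, expanding factors to
# indicator columns with first-level reference
build_design <- function(data, covariates) {
  rhs <- paste(c("dosage", covariates), collapse = " + ")
  model.matrix(as.formula(paste("~", rhs)), data = data)
}

#' Per-stratum additive SNP association
#'
#' Fits `trait ~ dosage + covariates` within each requested stratum under the
#' additive genetic model (trait regressed on the 0/1/2 count of effect
#' alleles), with complete-case filtering per model, an optional square-root
#' transform for right-skewed quantitative traits, and categorical
#' covariates expanded to indicators. Returns one summary row per stratum —
#' the per-allele effect, its SE, the two-sided Wald p-value, and the number
#' of subjects used.
#'
#' @param cohort A cohort tibble (see [gen_multiethnic()] or
#'   [read_cohort()]): must contain `stratum`, `dosage`, the trait, and all
#'   covariates.
#' @param trait Name of the response column.
#' @param covariates Character vector of adjustment columns (default none).
#' @param kind `"linear"` for quantitative traits, `"logistic"` for binary.
#' @param transform `"identity"` or `"sqrt"` (quantitative traits only).
#' @param strata Which strata to analyse (default: all present, in order of
#'   first appearance).
#' @return A tibble with columns `stratum`, `trait`, `n`, `beta`, `se`, `p`,
#'   `model`.
#' @examples
#' cohort <- gen_multiethnic(mesa_cohort_specs(n = 300), seed = 1)
#' snp_assoc(cohort, "lppla2_activity", covariates = c("age", "sex"))
#' @export
snp_assoc <- function(cohort, trait, covariates = character(),
                      kind = c("linear", "logistic"),
                      transform = c("identity", "sqrt"),
                      strata = NULL) {
  kind <- match.arg(kind)
  transform <- match.arg(transform)
  missing_cols <- setdiff(c("stratum", "dosage", trait, covariates),
                          names(cohort))
  if (length(missing_cols)) {
    abort(sprintf("cohort lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (transform == "sqrt" && kind != "linear") {
    abort("`sqrt` transform applies to quantitative traits only")
  }
  strata <- strata %||% unique(cohort$stratum)
  purrr::map_dfr(strata, function(st) {
    sub <- cohort[cohort$stratum == st,
                  c("dosage", trait, covariates), drop = FALSE]
    if (!nrow(sub)) abort(sprintf("stratum '%s' not present in cohort", st))
    sub <- sub[complete.cases(sub), , drop = FALSE]
    if (!nrow(sub)) abort(sprintf("stratum '%s': empty complete-case subset", st))
    if (length(unique(sub$dosage)) < 2) {
      abort(sprintf("stratum '%s': monomorphic SNP in the analysis subset", st))
    }
    y <- sub[[trait]]
    if (kind == "linear") {
      if (transform == "sqrt") {
        if (any(y < 0)) abort("sqrt transform requires a non-negative trait")
        y <- sqrt(y)
      }
      if (sd(y) == 0) {
        abort(sprintf("stratum '%s': zero-variance response '%s'", st, trait))
      }
      fit <- fit_linear(y, build_design(sub, covariates))
    } else {
      if (!all(y %in% c(0, 1))) {
        abort(sprintf("binary trait '%s' must be coded 0/1", trait))
      }
      fit <- fit_logistic(y, build_design(sub, covariates))
    }
    row <- fit[fit$term == "dosage", ]
    tibble::tibble(stratum = st, trait = trait, n = nrow(sub),
                   beta = row$estimate, se = row$se, p = row$p.value,
                   model = kind)
  })
}
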