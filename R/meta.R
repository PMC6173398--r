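#' Inverse-variance fixed-effects meta-analysis
#'
#' Combines per-stratum estimates with weights \eqn{w_i = 1/se_i^2}:
#' \eqn{\hat\beta = \sum w_i \beta_i / \sum w_i},
#' \eqn{se = (\sum w_i)^{-1/2}}, two-sided normal p-value — the METAL
#' convention. With at least two studies the result also carries Cochran's Q
#' heterogeneity statistic, its chi-square p-value, and
#' \eqn{I^2 = \max(0, (Q - df)/Q) \cdot 100} (percent, floored at zero).
#'
#' @param data Data frame with numeric columns `beta` and `se` (one row per
#'   study/stratum) and optionally `label` and `n`.
#' @return A `meta_fit` object; see [tidy.meta_fit()] and
#'   [glance.meta_fit()].
#' @examples
#' studies <- tibble::tibble(beta = c(1.541, 1.469, 3.573, 4.328),
#'                           se = c(1.356, 1.366, 1.384, 2.206))
#' tidy(meta_fixed(studies))
#' @export
meta_fixed <- function(data) {
  est <- check_estimates(data, min_k = 1)
  w <- 1 / est$se^2
  beta <- sum(w * est$beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  het <- if (nrow(est) >= 2) cochran_q(est) else NULL
  new_meta_fit("fixed", beta, se, tau2 = 0, het = het, estimates = est)
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Moment estimator of the between-study variance,
#' \eqn{\tau^2 = \max(0, (Q - df)/C)} with
#' \eqn{C = \sum w_i - \sum w_i^2 / \sum w_i}, followed by inverse-variance
#' combination under weights \eqn{w_i^* = 1/(se_i^2 + \tau^2)}. When
#' \eqn{Q \le df} the estimator truncates to zero and the result equals the
#' fixed-effects analysis exactly.
#'
#' @inheritParams meta_fixed
#' @return A `meta_fit` object.
#' @examples
#' studies <- tibble::tibble(beta = c(3.305, 5.823, -2.661, 0.977),
#'                           se = c(0.76, 4.44, 3.51, 1.63))
#' tidy(meta_random(studies))
#' @export
meta_random <- function(data) {
  est <- check_estimates(data, min_k = 2)
  w <- 1 / est$se^2
  het <- cochran_q(est)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (het$Q - het$df) / C)
  ws <- 1 / (est$se^2 + tau2)
  beta <- sum(ws * est$beta) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  new_meta_fit("DL-random", beta, se, tau2 = tau2, het = het,
               estimates = est)
}

#' Cochran's Q heterogeneity test
#'
#' \eqn{Q = \sum w_i (\beta_i - \hat\beta_{FE})^2} on `k - 1` degrees of
#' freedom, with the upper-tail chi-square p-value and the I-squared percent
#' of between-study variance.
#'
#' @inheritParams meta_fixed
#' @return One-row tibble with `Q`, `df`, `het_p`, `I2`.
#' @examples
#' studies <- tibble::tibble(beta = c(2.934, -1.252, 3.224, 1.781),
#'                           se = c(1.665, 1.728, 1.561, 2.358))
#' cochran_q(studies)
#' @export
cochran_q <- function(data) {
  est <- check_estimates(data, min_k = 2)
  w <- 1 / est$se^2
  beta_fe <- sum(w * est$beta) / sum(w)
  Q <- sum(w * (est$beta - beta_fe)^2)
  df <- nrow(est) - 1L
  tibble::tibble(
    Q = Q, df = df,
    het_p = pchisq(Q, df, lower.tail = FALSE),
    I2 = if (Q > 0) max(0, (Q - df) / Q) * 100 else 0)
}

check_estimates <- function(data, min_k) {
  if (!is.data.frame(data)) abort("`data` must be a data frame of estimates")
  if (!all(c("beta", "se") %in% names(data))) {
    abort("`data` needs numeric columns `beta` and `se`")
  }
  if (nrow(data) < min_k) {
    abort(sprintf("at least %d estimates required (got %d)",
                  min_k, nrow(data)))
  }
  if (anyNA(data$beta) || any(!is.finite(data$beta))) {
    abort("all `beta` values must be finite")
  }
  assert_positive_se(data$se)
  est <- tibble::as_tibble(data[, intersect(c("label", "n", "beta", "se"),
                                            names(data))])
  if (!"label" %in% names(est)) {
    est$label <- paste0("study", seq_len(nrow(est)))
  }
  est
}

new_meta_fit <- function(method, beta, se, tau2, het, estimates) {
  z <- beta / se
  structure(
    list(method = method, beta = beta, se = se, z = z, p = wald_p(beta, se),
         Q = het$Q %||% NA_real_, df = het$df %||% NA_integer_,
         het_p = het$het_p %||% NA_real_, I2 = het$I2 %||% NA_real_,
         tau2 = tau2, k = nrow(estimates), estimates = estimates),
    class = "meta_fit")
}

#' @export
print.meta_fit <- function(x, ...) {
  cat(sprintf("<meta_fit> %s meta-analysis of %d estimates\n", x$method, x$k))
  cat(sprintf("  combined beta %.4g (se %.4g), z = %.3f, p = %.3g\n",
              x$beta, x$se, x$z, x$p))
  if (!is.na(x$Q)) {
    cat(sprintf("  heterogeneity: Q = %.3f (df %d), p = %.3g, I2 = %.1f%%, tau2 = %.4g\n",
                x$Q, x$df, x$het_p, x$I2, x$tau2))
  }
  invisible(x)
}

#' Tidiers for meta-analysis fits
#'
#' `tidy()` returns the combined estimate as a one-row tibble; `glance()`
#' returns the model-level heterogeneity summary.
#'
#' @param x A `meta_fit` from [meta_fixed()] or [meta_random()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy meta_fit
#' @export
tidy.meta_fit <- function(x, ...) {
  tibble::tibble(method = x$method, beta = x$beta, se = x$se, z = x$z,
                 p = x$p)
}

#' @rdname tidy.meta_fit
#' @method glance meta_fit
#' @export
glance.meta_fit <- function(x, ...) {
  tibble::tibble(k = x$k, Q = x$Q, df = x$df, het_p = x$het_p, I2 = x$I2,
                 tau2 = x$tau2)
}

#' Forest plot of a meta-analysis
#'
#' Per-study estimates with 95% Wald intervals and the combined estimate as
#' the bottom row.
#'
#' @param object A `meta_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot meta_fit
#' @export
autoplot.meta_fit <- function(object, ...) {
  est <- object$estimates
  rows <- dplyr::bind_rows(
    tibble::tibble(label = est$label, beta = est$beta, se = est$se,
                   combined = FALSE),
    tibble::tibble(label = paste0("Combined (", object$method, ")"),
                   beta = object$beta, se = object$se, combined = TRUE))
  rows$label <- factor(rows$label, levels = rev(rows$label))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$beta, y = .data$label,
                                     colour = .data$combined)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(shape = 18, size = 3) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$beta - 1.96 * .data$se,
                   xmax = .data$beta + 1.96 * .data$se),
      height = 0.2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "Effect per effect-allele copy", y = NULL) +
    ggplot2::theme_minimal()
}
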