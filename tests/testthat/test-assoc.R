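test_that("linear fit is exact on noiseless data and matches the normal-equations oracle", {
  # exact line through 6 points
  x <- c(0, 0, 1, 1, 2, 2)
  y <- c(1, 1, 2, 2, 3, 3)
  fit <- fit_linear(y, cbind(intercept = 1, x = x))
  expect_equal(fit$estimate, c(1, 1), tolerance = 1e-12)
  expect_equal(attr(fit, "sigma2"), 0, tolerance = 1e-20)

  # arbitrary exact fit: y = X w recovers w with zero residual SS
  set.seed(1)
  X <- cbind(1, matrix(rnorm(50 * 2), 50, 2))
  colnames(X) <- c("b0", "b1", "b2")
  w <- c(0.5, -1.2, 2)
  fit2 <- fit_linear(drop(X %*% w), X)
  expect_equal(fit2$estimate, w, tolerance = 1e-10)

  # independent oracle: explicit normal equations (X'X)^-1 X'y
  yy <- drop(X %*% w) + rnorm(50)
  fit3 <- fit_linear(yy, X)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% yy)
  sigma2 <- sum((yy - X %*% beta_oracle)^2) / (50 - 3)
  se_oracle <- sqrt(sigma2 * diag(solve(t(X) %*% X)))
  expect_equal(fit3$estimate, unname(drop(beta_oracle)), tolerance = 1e-8)
  expect_equal(fit3$se, unname(se_oracle), tolerance = 1e-8)
})

test_that("linear fit errors on singular designs (naming columns) and tiny n", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = rnorm(4))
  expect_error(fit_linear(rnorm(4), X), "singular design.*b")
  expect_error(fit_linear(rnorm(2), cbind(1, rnorm(2), rnorm(2))),
               "insufficient data")
})

test_that("logistic fit matches the 2x2 closed form and recovers true slopes", {
  # contingency table (20,30; 40,10): slope = log OR = log(1/6)
  # exposed group (x = 1): 20 events / 30 non-events; unexposed: 40 / 10
  y <- c(rep(1, 20), rep(0, 30), rep(1, 40), rep(0, 10))
  x <- c(rep(1, 50), rep(0, 50))
  fit <- fit_logistic(y, cbind(1, x = x))
  expect_equal(fit$estimate[2], log((20 * 10) / (30 * 40)), tolerance = 1e-6)

  # ML consistency at n = 10^4, true slope 0.5
  set.seed(2)
  x2 <- rnorm(10000)
  y2 <- rbinom(10000, 1, plogis(-1 + 0.5 * x2))
  fit2 <- fit_logistic(y2, cbind(1, x = x2))
  expect_lt(abs(fit2$estimate[2] - 0.5) / fit2$se[2], 3)

  # null recovery
  set.seed(3)
  y0 <- rbinom(5000, 1, 0.3)
  fit0 <- fit_logistic(y0, cbind(1, x = rnorm(5000)))
  expect_lt(abs(fit0$estimate[2]) / fit0$se[2], 3)
})

test_that("logistic fit matches a brute-force ML oracle on a toy problem", {
  set.seed(4)
  x <- rnorm(60)
  y <- rbinom(60, 1, plogis(0.3 + 0.8 * x))
  fit <- fit_logistic(y, cbind(1, x = x))
  nll <- function(b) -sum(y * (b[1] + b[2] * x) - log1p(exp(b[1] + b[2] * x)))
  opt <- optim(c(0, 0), nll, method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(fit$estimate, opt$par, tolerance = 1e-4)
})

test_that("logistic fit detects complete separation", {
  x <- c(rep(-1, 20), rep(1, 20)) + runif(40, -0.1, 0.1)
  y <- as.integer(x > 0)
  expect_error(fit_logistic(y, cbind(1, x = x)), "separation")
})

test_that("snp_assoc recovers a known per-allele mediator effect", {
  spec <- sem_spec(5000, a = 3.5, b = 0, c_prime = 0)
  cohort <- gen_stratum(spec, seed = 21)
  res <- snp_assoc(cohort, "m")
  expect_equal(res$n, 5000)
  expect_lt(abs(res$beta - 3.5) / res$se, 3)
})

test_that("snp_assoc errors on degenerate inputs", {
  cohort <- gen_stratum(sem_spec(200), seed = 1)
  cohort$flat <- 1.5
  expect_error(snp_assoc(cohort, "flat"), "zero-variance")
  mono <- cohort
  mono$dosage <- 0L
  expect_error(snp_assoc(mono, "m"), "monomorphic")
  allna <- cohort
  allna$m <- NA_real_
  expect_error(snp_assoc(allna, "m"), "complete-case")
  expect_error(snp_assoc(cohort, "nope"), "lacks column")
})

test_that("association p-values are uniform under a permutation null", {
  cohort <- gen_stratum(sem_spec(800, a = 3.5), seed = 31)
  set.seed(32)
  reps <- 400
  pvals <- vapply(seq_len(reps), function(i) {
    shuffled <- cohort
    shuffled$dosage <- sample(shuffled$dosage)
    snp_assoc(shuffled, "m")$p
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("scaling equivariance and allele-flip antisymmetry hold", {
  cohort <- gen_stratum(sem_spec(1500, a = 3.5), seed = 41)
  base_fit <- snp_assoc(cohort, "m")
  scaled <- cohort
  scaled$m <- scaled$m * 7
  s_fit <- snp_assoc(scaled, "m")
  expect_equal(s_fit$beta, 7 * base_fit$beta, tolerance = 1e-10)
  expect_equal(s_fit$se, 7 * base_fit$se, tolerance = 1e-10)
  expect_equal(s_fit$p, base_fit$p, tolerance = 1e-12)

  flipped <- cohort
  flipped$dosage <- 2L - flipped$dosage
  f_fit <- snp_assoc(flipped, "m")
  expect_equal(f_fit$beta, -base_fit$beta, tolerance = 1e-10)
  expect_equal(f_fit$se, base_fit$se, tolerance = 1e-10)
  expect_equal(f_fit$p, base_fit$p, tolerance = 1e-12)
})

test_that("sqrt transform and categorical covariates are handled", {
  specs <- mesa_cohort_specs(n = 600)
  cohort <- gen_multiethnic(specs, seed = 51)
  cohort$site <- factor(sample(c("s1", "s2", "s3"), nrow(cohort), TRUE))
  res <- snp_assoc(cohort, "lppla2_activity",
                   covariates = c("age", "sex", "site"),
                   transform = "sqrt")
  expect_equal(nrow(res), 4)
  expect_true(all(res$se > 0))
  expect_error(
    snp_assoc(cohort, "cvd_all", kind = "logistic", transform = "sqrt"),
    "quantitative")
})
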