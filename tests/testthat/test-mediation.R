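test_that("coefficient difference recovers minus the indirect effect", {
  cohort <- gen_stratum(sem_spec(5000, a = 5, b = 0.01, c_prime = 0.01),
                        seed = 81)
  d <- mediation_diff(cohort, outcome = "y", mediator = "m")
  # population difference is -(a b) = -0.05; compare against 3 bootstrap-free
  # SEs obtained from the Model 1 fit scale
  expect_lt(abs(d$diff - (-0.05)), 3 * 0.01)
  expect_equal(d$coef_model2 - d$coef_model1, d$diff)
})

test_that("no mediation under a = 0", {
  cohort <- gen_stratum(sem_spec(5000, a = 0, b = 0.01, c_prime = 0.02),
                        seed = 82)
  d <- mediation_diff(cohort, outcome = "y", mediator = "m")
  expect_lt(abs(d$diff), 3 * 0.005)
})

test_that("a mediator duplicating a covariate raises a singular-design error", {
  cohort <- gen_stratum(
    population_spec("S", 300, 0.3,
                    covariates = list(age = cov_normal(60, 10)),
                    mediator = mediator_model(name = "m", snp_effect = 1,
                                              noise_sd = 1),
                    outcome = outcome_model(name = "y", snp_effect = 0.1,
                                            mediator_effect = 0.1,
                                            noise_sd = 1)),
    seed = 83)
  cohort$m <- cohort$age  # mediator collinear with an adjustment covariate
  expect_error(
    mediation_diff(cohort, "y", "m", covariates = "age"),
    "singular design")
})

test_that("bias-corrected bootstrap is reproducible and degenerates gracefully", {
  cohort <- gen_stratum(sem_spec(400, a = 5, b = 0.01), seed = 84)
  f1 <- mediation_boot(cohort, "y", "m", B = 250, seed = 9)
  f2 <- mediation_boot(cohort, "y", "m", B = 250, seed = 9)
  expect_identical(tidy(f1), tidy(f2))
  expect_error(mediation_boot(cohort, "y", "m", B = 100, seed = 1),
               "at least 200")
  expect_error(mediation_boot(cohort, "y", "m", B = 250), "seed")
})

test_that("degenerate bootstrap distribution collapses the interval with z0 = 0", {
  theta_star <- rep(0.5, 400)
  bc <- transmeta:::bc_interval(0.5, theta_star, 0.95)
  expect_equal(bc$z0, 0)
  expect_equal(bc$ci_low, 0.5)
  expect_equal(bc$ci_high, 0.5)
})

test_that("with median-centred draws the BC interval equals the percentile interval", {
  set.seed(85)
  draws <- rnorm(1001)
  theta_hat <- median(draws)  # exactly the bootstrap median, so z0 = 0
  bc <- transmeta:::bc_interval(theta_hat, draws, 0.95)
  expect_equal(bc$z0, 0, tolerance = 1e-3)
  pct <- quantile(draws, c(0.025, 0.975), names = FALSE, type = 7)
  expect_equal(c(bc$ci_low, bc$ci_high), pct, tolerance = 1e-6)
})

test_that("interval width shrinks roughly as 1/sqrt(n)", {
  widths <- sapply(c(500, 2000), function(n) {
    ws <- vapply(1:12, function(i) {
      cohort <- gen_stratum(sem_spec(n, a = 5, b = 0.01), seed = 8000 + i)
      td <- tidy(mediation_boot(cohort, "y", "m", B = 300, seed = i))
      td$ci_high - td$ci_low
    }, numeric(1))
    median(ws)
  })
  # quadrupling n should halve the width: ratio within [1.4, 2.8]
  ratio <- widths[1] / widths[2]
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.8)
})

test_that("mediation meta-analysis combines strata by bootstrap-weighted FE", {
  res <- tibble::tibble(stratum = paste0("s", 1:4),
                        diff = rep(-0.002, 4), boot_se = rep(0.001, 4))
  m <- mediation_meta(res)
  expect_equal(m$beta, -0.002, tolerance = 1e-12)
  expect_equal(m$se, 0.001 / 2, tolerance = 1e-12)
  expect_error(mediation_meta(res[1, ]), "at least 2")
})

test_that("4-stratum SEM recovers a common indirect effect through the meta step", {
  specs <- purrr::map(paste0("s", 1:4), function(lab) {
    sem_spec(1200, a = 4, b = 5e-4, label = lab)
  })
  cohort <- gen_multiethnic(specs, seed = 86)
  fit <- mediation_boot(cohort, "y", "m", B = 300, seed = 87)
  m <- mediation_meta(fit)
  expect_lt(abs(m$beta - (-0.002)) / m$se, 3)
})

test_that("adjusting for a shared confounder attenuates spurious mediation", {
  # U drives both mediator and outcome; M has no direct outcome effect, so
  # any apparent mediation in the unadjusted model is confounding
  specs <- purrr::map(paste0("s", 1:2), function(lab) {
    population_spec(
      lab, 2500, 0.35,
      covariates = list(u = cov_normal(0, 1)),
      mediator = mediator_model(name = "m", intercept = 150, snp_effect = 3,
                                covariate_effects = c(u = 30), noise_sd = 20),
      outcome = outcome_model(name = "y", intercept = 0.8, snp_effect = 0.01,
                              mediator_effect = 0,
                              covariate_effects = c(u = 0.1),
                              noise_sd = 0.15))
  })
  cohort <- gen_multiethnic(specs, seed = 88)
  basic <- mediation_meta(mediation_boot(cohort, "y", "m", B = 300,
                                         seed = 89))
  full <- mediation_meta(mediation_boot(cohort, "y", "m", covariates = "u",
                                        B = 300, seed = 89))
  expect_lt(basic$p, 0.01)                 # confounded model looks mediated
  expect_lt(abs(full$beta), abs(basic$beta) / 3)  # adjustment attenuates
  expect_gt(full$p, 0.05)
})
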