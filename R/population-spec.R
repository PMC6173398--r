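#' Covariate distribution specifications
#'
#' Small constructors describing how a baseline covariate is simulated within
#' a population stratum. `cov_normal()` draws from a Gaussian, `cov_binary()`
#' from a Bernoulli (0/1), and `cov_categorical()` from a finite label set
#' (returned as a factor so downstream models expand it to indicators).
#'
#' @param mean,sd Gaussian location and spread (`sd > 0`).
#' @param p Success probability in `[0, 1]`.
#' @param levels Character vector of category labels.
#' @param probs Sampling probabilities, recycled uniform when `NULL`.
#' @return A covariate specification list used by [population_spec()].
#' @export
cov_normal <- function(mean = 0, sd = 1) {
  stopifnot(is.finite(mean), is.finite(sd), sd > 0)
  list(dist = "normal", mean = mean, sd = sd)
}

#' @rdname cov_normal
#' @export
cov_binary <- function(p = 0.5) {
  stopifnot(is.finite(p), p >= 0, p <= 1)
  list(dist = "binary", p = p)
}

#' @rdname cov_normal
#' @export
cov_categorical <- function(levels, probs = NULL) {
  stopifnot(is.character(levels), length(levels) >= 2)
  if (is.null(probs)) probs <- rep(1 / length(levels), length(levels))
  stopifnot(length(probs) == length(levels), all(probs >= 0), sum(probs) > 0)
  list(dist = "categorical", levels = levels, probs = probs / sum(probs))
}

#' Structural models for a simulated stratum
#'
#' `mediator_model()` and `outcome_model()` define the linear structural
#' equations the generator obeys:
#' \deqn{M = \alpha_M + a G + \gamma^T X + \varepsilon,\qquad
#'       Y = \alpha_Y + c' G + b M + \delta^T X + \eta,}
#' with `G` the effect-allele dosage, Gaussian noise by default and an
#' optional lognormal hook for skewed biomarkers. `event_model()` defines a
#' Bernoulli event with logistic mean; with all coefficients at their zero
#' defaults the intercept is `qlogis(prevalence)` so the configured
#' prevalence is the exact marginal target. `survival_model()` defines
#' exponential proportional-hazards event times with uniform administrative
#' censoring at `censor_time` and a randomized binary treatment arm.
#'
#' @param name Column name the simulated variable receives.
#' @param intercept Structural intercept, in trait units.
#' @param snp_effect Per-allele effect (`a` for the mediator, `c'` for the
#'   direct path in the outcome model).
#' @param mediator_effect Outcome-model coefficient `b` on the mediator.
#' @param covariate_effects Named numeric vector of coefficients on declared
#'   covariates (categorical covariates are not supported in structural
#'   equations; use numeric ones).
#' @param noise_sd Residual standard deviation (> 0).
#' @param noise Residual family, `"gaussian"` (default) or `"lognormal"`
#'   (multiplicative `exp(N(0, noise_sd))` noise for skewed traits).
#' @param prevalence Target marginal event probability in `(0, 1)`.
#' @param coefficients Named log-odds (event) or log-hazard (survival)
#'   coefficients on dosage, treatment, covariates, or `"dosage:treatment"`.
#' @param baseline_hazard Exponential baseline hazard rate per year (> 0).
#' @param censor_time Administrative censoring horizon in years (> 0);
#'   censoring times are uniform on `(0, censor_time]`.
#' @param treatment_allocation Proportion randomized to active arm.
#' @return A model specification list consumed by [population_spec()].
#' @export
mediator_model <- function(name = "lppla2_activity", intercept = 0,
                           snp_effect = 0, covariate_effects = NULL,
                           noise_sd = 1, noise = c("gaussian", "lognormal")) {
  noise <- match.arg(noise)
  stopifnot(is.character(name), nzchar(name), is.finite(noise_sd), noise_sd > 0)
  list(name = name, intercept = intercept, snp_effect = snp_effect,
       covariate_effects = covariate_effects, noise_sd = noise_sd,
       noise = noise)
}

#' @rdname mediator_model
#' @export
outcome_model <- function(name = "cimt", intercept = 0, snp_effect = 0,
                          mediator_effect = 0, covariate_effects = NULL,
                          noise_sd = 1) {
  stopifnot(is.character(name), nzchar(name), is.finite(noise_sd), noise_sd > 0)
  list(name = name, intercept = intercept, snp_effect = snp_effect,
       mediator_effect = mediator_effect,
       covariate_effects = covariate_effects, noise_sd = noise_sd)
}

#' @rdname mediator_model
#' @export
event_model <- function(name = "cvd_all", prevalence = 0.1,
                        coefficients = NULL) {
  stopifnot(is.character(name), nzchar(name),
            is.finite(prevalence), prevalence > 0, prevalence < 1)
  list(name = name, prevalence = prevalence, coefficients = coefficients)
}

#' @rdname mediator_model
#' @export
survival_model <- function(time = "time", event = "mce",
                           baseline_hazard = 0.03, coefficients = NULL,
                           censor_time = 3.7, treatment_allocation = 0.5) {
  stopifnot(is.finite(baseline_hazard), baseline_hazard > 0,
            is.finite(censor_time), censor_time > 0,
            treatment_allocation >= 0, treatment_allocation <= 1)
  list(time = time, event = event, baseline_hazard = baseline_hazard,
       coefficients = coefficients, censor_time = censor_time,
       treatment_allocation = treatment_allocation)
}

#' Define a population stratum for cohort simulation
#'
#' Bundles everything the generator needs for one ancestry stratum: sample
#' size, effect-allele frequency (genotypes are drawn under Hardy-Weinberg
#' equilibrium), baseline covariate distributions, and the structural models
#' for the mediator, continuous outcome, binary event, and optional
#' trial-style survival data.
#'
#' @param label Stratum label (unique across a cohort).
#' @param n Number of subjects (>= 1).
#' @param effect_allele_freq Effect-allele frequency in `[0, 1]`.
#' @param covariates Named list of covariate specifications
#'   ([cov_normal()] and friends).
#' @param mediator,outcome,event Structural models; see [mediator_model()].
#'   Any of them may be `NULL` to omit that variable.
#' @param survival Optional [survival_model()]; when present the stratum also
#'   gets a randomized `treatment` column, follow-up time, and event status.
#' @param missing_rate Optional MCAR missingness rate in `[0, 1)` applied to
#'   the mediator and outcome columns (default 0, i.e. complete data).
#' @return An object of class `population_spec`.
#' @examples
#' spec <- population_spec("EUR", n = 500, effect_allele_freq = 0.18)
#' cohort <- gen_stratum(spec, seed = 1)
#' @export
population_spec <- function(label, n, effect_allele_freq,
                            covariates = default_covariates(),
                            mediator = mediator_model(),
                            outcome = outcome_model(),
                            event = event_model(),
                            survival = NULL,
                            missing_rate = 0) {
  stopifnot(is.character(label), length(label) == 1, nzchar(label))
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != floor(n)) {
    abort("`n` must be a positive integer")
  }
  if (!is.numeric(effect_allele_freq) || effect_allele_freq < 0 ||
      effect_allele_freq > 1) {
    abort("`effect_allele_freq` must lie in [0, 1]")
  }
  stopifnot(missing_rate >= 0, missing_rate < 1)
  if (length(covariates) && is.null(names(covariates))) {
    abort("`covariates` must be a named list")
  }
  spec <- structure(
    list(label = label, n = as.integer(n),
         effect_allele_freq = effect_allele_freq,
         covariates = covariates, mediator = mediator, outcome = outcome,
         event = event, survival = survival, missing_rate = missing_rate),
    class = "population_spec")
  validate_structural_refs(spec)
  spec
}

# every covariate named in a structural equation must be declared
validate_structural_refs <- function(spec) {
  declared <- names(spec$covariates)
  models <- list(spec$mediator, spec$outcome, spec$event,
                 spec$survival)
  for (m in models) {
    eff <- m$covariate_effects %||% m$coefficients
    if (is.null(eff)) next
    refs <- setdiff(names(eff),
                    c("dosage", "treatment", "dosage:treatment",
                      spec$mediator$name, declared))
    if (length(refs)) {
      abort(sprintf("structural model references undeclared covariates: %s",
                    paste(refs, collapse = ", ")))
    }
  }
  invisible(spec)
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec> %s: n = %d, effect-allele freq = %.3f\n",
              x$label, x$n, x$effect_allele_freq))
  cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  if (!is.null(x$survival)) cat("  with trial-style survival data\n")
  invisible(x)
}

#' Default baseline covariates
#'
#' Age (Gaussian, years), sex (Bernoulli), and two Gaussian "ancestry PC"
#' columns — the basic adjustment set used throughout the package examples.
#'
#' @return Named list of covariate specifications.
#' @export
default_covariates <- function() {
  list(age = cov_normal(62, 10), sex = cov_binary(0.47),
       pc1 = cov_normal(0, 1), pc2 = cov_normal(0, 1))
}

#' MESA-like multi-ethnic cohort presets
#'
#' Four population strata mirroring the published MESA/MESA-Family
#' characteristics for the SCARB1 rs10846744 analyses: sample sizes
#' 2470/2507/2071/758, effect-allele (C) frequencies 0.18/0.62/0.35/0.57,
#' an Lp-PLA2-activity-like mediator (per-allele effect `a`, nmol/min/ml), a
#' cIMT-like continuous outcome (mm) with direct per-allele effect `c_prime`
#' and mediator coefficient `b`, and binary cardiovascular events with
#' prevalences 12.7/11.0/12.1/8.4%.
#'
#' @param n Optional common per-stratum sample size overriding the published
#'   counts (used by large-n moment checks).
#' @param a Per-allele effect on the mediator (nmol/min/ml per C allele).
#' @param b Outcome coefficient on the mediator (mm per nmol/min/ml).
#' @param c_prime Direct per-allele effect on the outcome (mm).
#' @param missing_rate MCAR missingness rate passed to each stratum.
#' @return List of four [population_spec()] objects.
#' @export
mesa_cohort_specs <- function(n = NULL, a = 3.5, b = 3e-4, c_prime = 0.012,
                              missing_rate = 0) {
  base <- tibble::tribble(
    ~label,              ~n_pub, ~freq, ~prev,  ~med_int,
    "Caucasian",           2470L,  0.18, 0.127,  154,
    "African-American",    2507L,  0.62, 0.110,  136,
    "Hispanic",            2071L,  0.35, 0.121,  151,
    "Chinese-American",     758L,  0.57, 0.084,  153)
  purrr::pmap(base, function(label, n_pub, freq, prev, med_int) {
    population_spec(
      label = label,
      n = n %||% n_pub,
      effect_allele_freq = freq,
      mediator = mediator_model(
        name = "lppla2_activity", intercept = med_int, snp_effect = a,
        covariate_effects = c(age = 0.2), noise_sd = 36),
      outcome = outcome_model(
        name = "cimt", intercept = 0.56 - b * med_int, snp_effect = c_prime,
        mediator_effect = b, covariate_effects = c(age = 0.004),
        noise_sd = 0.17),
      event = event_model(name = "cvd_all", prevalence = prev),
      survival = NULL,
      missing_rate = missing_rate)
  })
}

#' Darapladib-trial-like cohort presets
#'
#' Four race/ethnic strata shaped like the STABILITY or SOLID-TIMI 52
#' genotyped subsets (sample sizes and effect-allele frequencies from the
#' published baseline tables), with an Lp-PLA2-activity-like baseline
#' biomarker, exponential proportional-hazards major-coronary-event times,
#' 1:1 randomized treatment, and administrative censoring at the trial's
#' median follow-up (3.7 y STABILITY, 2.5 y SOLID-TIMI 52).
#'
#' @param study `"stability"` or `"solid"`.
#' @param n Optional common per-stratum size override.
#' @param biomarker_effect Per-allele effect on the baseline biomarker.
#' @param snp_loghr,treatment_loghr,interaction_loghr Log-hazard-ratio
#'   coefficients for dosage, treatment arm, and their product.
#' @return List of four [population_spec()] objects.
#' @export
trial_cohort_specs <- function(study = c("stability", "solid"), n = NULL,
                               biomarker_effect = 3.5, snp_loghr = 0.1,
                               treatment_loghr = 0,
                               interaction_loghr = 0) {
  study <- match.arg(study)
  tab <- if (study == "stability") {
    tibble::tribble(
      ~label,             ~n_pub, ~freq,
      "Caucasian",          9448L,  0.17,
      "African-American",    254L,  0.53,
      "Asian",              1257L,  0.64,
      "Other",              1637L,  0.25)
  } else {
    tibble::tribble(
      ~label,             ~n_pub, ~freq,
      "Caucasian",          7503L,  0.16,
      "African-American",    185L,  0.59,
      "Asian",               408L,  0.62,
      "Other",              1303L,  0.27)
  }
  censor <- if (study == "stability") 3.7 else 2.5
  purrr::pmap(tab, function(label, n_pub, freq) {
    population_spec(
      label = label,
      n = n %||% n_pub,
      effect_allele_freq = freq,
      mediator = mediator_model(
        name = "lppla2_activity", intercept = 150,
        snp_effect = biomarker_effect, noise_sd = 36),
      outcome = NULL,
      event = NULL,
      survival = survival_model(
        time = "time", event = "mce", baseline_hazard = 0.035,
        coefficients = c(dosage = snp_loghr, treatment = treatment_loghr,
                         "dosage:treatment" = interaction_loghr),
        censor_time = censor, treatment_allocation = 0.5))
  })
}
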