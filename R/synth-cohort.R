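#' Simulate effect-allele dosages under Hardy-Weinberg equilibrium
#'
#' Draws per-subject genotype dosages (count of the effect allele, 0/1/2) as
#' i.i.d. Binomial(2, freq), the sampling model implied by Hardy-Weinberg
#' equilibrium at a biallelic site.
#'
#' @param n Number of subjects (>= 1).
#' @param freq Effect-allele frequency in `[0, 1]`.
#' @param seed Integer seed; identical inputs give identical dosages.
#' @return Integer vector of length `n` with values in `{0, 1, 2}`.
#' @examples
#' table(gen_genotypes(1000, 0.18, seed = 1))
#' @export
gen_genotypes <- function(n, freq, seed) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != floor(n)) {
    abort("`n` must be a positive integer")
  }
  if (!is.numeric(freq) || length(freq) != 1 || freq < 0 || freq > 1) {
    abort("`freq` must lie in [0, 1]")
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  as.integer(rbinom(n, size = 2L, prob = freq))
}

# save/restore the global RNG state so generators do not perturb the caller
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# evaluate a named coefficient vector against the columns of a tibble,
# supporting the "dosage:treatment" product term
linear_predictor <- function(data, coefficients) {
  if (is.null(coefficients)) return(rep(0, nrow(data)))
  lp <- rep(0, nrow(data))
  for (nm in names(coefficients)) {
    col <- if (nm == "dosage:treatment") {
      data$dosage * data$treatment
    } else {
      if (!nm %in% names(data)) {
        abort(sprintf("structural coefficient references missing column '%s'", nm))
      }
      v <- data[[nm]]
      if (is.factor(v)) abort(
        sprintf("categorical covariate '%s' cannot enter a structural equation", nm))
      v
    }
    lp <- lp + coefficients[[nm]] * col
  }
  lp
}

#' Simulate one population stratum
#'
#' Generates a complete per-subject table for a single stratum under the
#' linear structural model
#' \deqn{M = \alpha_M + aG + \gamma^T X + \varepsilon,\qquad
#'       Y = \alpha_Y + c'G + bM + \delta^T X + \eta,}
#' with logistic binary events and, when a survival model is declared,
#' exponential proportional-hazards event times with uniform administrative
#' censoring and a randomized treatment arm. All randomness derives from
#' `seed`; the caller's RNG state is left untouched.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed.
#' @return A tibble with columns `id`, `stratum`, `dosage`, the declared
#'   covariates, and whichever of mediator / outcome / event / survival
#'   columns the spec declares.
#' @examples
#' spec <- population_spec("EUR", n = 200, effect_allele_freq = 0.3)
#' gen_stratum(spec, seed = 7)
#' @export
gen_stratum <- function(spec, seed) {
  stopifnot(inherits(spec, "population_spec"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- spec$n

  out <- tibble::tibble(
    id = sprintf("%s_%05d", gsub("[^A-Za-z0-9]", "", spec$label), seq_len(n)),
    stratum = spec$label,
    dosage = as.integer(rbinom(n, 2L, spec$effect_allele_freq)))

  for (nm in names(spec$covariates)) {
    cv <- spec$covariates[[nm]]
    out[[nm]] <- switch(cv$dist,
      normal = rnorm(n, cv$mean, cv$sd),
      binary = as.integer(rbinom(n, 1L, cv$p)),
      categorical = factor(sample(cv$levels, n, replace = TRUE,
                                  prob = cv$probs), levels = cv$levels),
      abort(sprintf("unknown covariate distribution '%s'", cv$dist)))
  }

  if (!is.null(spec$mediator)) {
    m <- spec$mediator
    mu <- m$intercept + m$snp_effect * out$dosage +
      linear_predictor(out, m$covariate_effects)
    out[[m$name]] <- if (m$noise == "lognormal") {
      mu * exp(rnorm(n, 0, m$noise_sd))
    } else {
      mu + rnorm(n, 0, m$noise_sd)
    }
  }

  if (!is.null(spec$outcome)) {
    o <- spec$outcome
    mu <- o$intercept + o$snp_effect * out$dosage +
      linear_predictor(out, o$covariate_effects)
    if (!is.null(spec$mediator)) {
      mu <- mu + o$mediator_effect * out[[spec$mediator$name]]
    }
    out[[o$name]] <- mu + rnorm(n, 0, o$noise_sd)
  }

  if (!is.null(spec$event)) {
    e <- spec$event
    lp <- qlogis(e$prevalence) + linear_predictor(out, e$coefficients)
    out[[e$name]] <- as.integer(rbinom(n, 1L, plogis(lp)))
  }

  if (!is.null(spec$survival)) {
    s <- spec$survival
    out$treatment <- as.integer(rbinom(n, 1L, s$treatment_allocation))
    lp <- linear_predictor(out, s$coefficients)
    latent <- rexp(n, rate = s$baseline_hazard * exp(lp))
    censor <- runif(n, 0, s$censor_time)
    out[[s$time]] <- pmin(latent, censor)
    out[[s$event]] <- as.integer(latent <= censor)
  }

  if (spec$missing_rate > 0) {
    targets <- c(spec$mediator$name, spec$outcome$name)
    for (nm in targets) {
      out[[nm]][runif(n) < spec$missing_rate] <- NA_real_
    }
  }

  out
}

#' Deterministic per-stratum sub-seed
#'
#' Derives the seed a stratum receives inside [gen_multiethnic()] from the
#' master seed and the stratum label (not its position), so reordering the
#' spec list never changes any stratum's data.
#'
#' @param seed Master integer seed.
#' @param label Stratum label.
#' @return An integer seed below 2^31.
#' @export
stratum_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 2147483647
  derive_seed(seed, h)
}

#' Simulate a multi-ethnic cohort
#'
#' Concatenates independently generated strata, each on its own
#' label-derived sub-seed (see [stratum_seed()]).
#'
#' @param specs List of [population_spec()] objects with unique labels.
#' @param seed Master integer seed.
#' @return A tibble; union of the per-stratum columns.
#' @examples
#' cohort <- gen_multiethnic(mesa_cohort_specs(n = 100), seed = 1)
#' dplyr::count(cohort, stratum)
#' @export
gen_multiethnic <- function(specs, seed) {
  if (!length(specs)) abort("`specs` must contain at least one population_spec")
  labels <- purrr::map_chr(specs, "label")
  if (anyDuplicated(labels)) abort("stratum labels must be unique")
  strata <- purrr::map(specs, function(sp) {
    gen_stratum(sp, seed = stratum_seed(seed, sp$label))
  })
  dplyr::bind_rows(strata)
}
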