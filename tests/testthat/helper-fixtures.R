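# shared fixtures: small structural-model strata with known ground truth

# one stratum obeying M = a G + eps, Y = c' G + b M + eta, no covariates;
# noise scales match the package's cohort presets
sem_spec <- function(n, a = 5, b = 0.01, c_prime = 0, label = "S",
                     freq = 0.3, med_sd = 36, out_sd = 0.17) {
  population_spec(
    label = label, n = n, effect_allele_freq = freq,
    covariates = list(),
    mediator = mediator_model(name = "m", intercept = 150, snp_effect = a,
                              noise_sd = med_sd),
    outcome = outcome_model(name = "y", intercept = 0.8, snp_effect = c_prime,
                            mediator_effect = b, noise_sd = out_sd),
    event = NULL, survival = NULL)
}

# published per-stratum estimates for one trait as a (label, beta, se) tibble
published_trait <- function(trait) {
  tab <- mesa_published_assoc()
  tab <- tab[tab$trait == trait, ]
  tibble::tibble(label = tab$stratum, beta = tab$beta, se = tab$se)
}

published_trial <- function(which_study) {
  tab <- trial_published_biomarker()
  tab <- tab[tab$study == which_study & tab$row == "stratum", ]
  tibble::tibble(label = tab$stratum, beta = tab$beta, se = tab$se)
}
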