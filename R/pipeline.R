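#' Read and validate a cohort table
#'
#' Reads a tab-delimited per-subject cohort file (header required) and
#' enforces the cohort invariants: `stratum` and `dosage` columns present,
#' dosages in `{0, 1, 2}` or missing (violations are reported with their row
#' numbers), follow-up times non-negative, and 0/1 coding for any column
#' declared binary. Missing values are permitted and left as `NA`, never
#' imputed.
#'
#' @param path Path to a TSV file with one row per subject.
#' @param binary_columns Columns required to be 0/1/NA (event indicators,
#'   treatment arms).
#' @param time_column Optional follow-up time column checked to be >= 0.
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path, binary_columns = character(),
                        time_column = NULL) {
  cohort <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort(cohort, binary_columns = binary_columns,
                  time_column = time_column)
}

validate_cohort <- function(cohort, binary_columns = character(),
                            time_column = NULL) {
  missing_cols <- setdiff(c("stratum", "dosage"), names(cohort))
  if (length(missing_cols)) {
    abort(sprintf("cohort lacks mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!is.na(cohort$dosage) & !cohort$dosage %in% c(0, 1, 2))
  if (length(bad)) {
    abort(sprintf("invalid dosage value(s) at row(s): %s",
                  paste(head(bad, 10), collapse = ", ")))
  }
  if (!is.null(time_column) && time_column %in% names(cohort)) {
    tv <- cohort[[time_column]]
    if (any(!is.na(tv) & tv < 0)) {
      abort(sprintf("negative follow-up time in column '%s'", time_column))
    }
  }
  for (bc in intersect(binary_columns, names(cohort))) {
    v <- cohort[[bc]]
    if (any(!is.na(v) & !v %in% c(0, 1))) {
      abort(sprintf("column '%s' must be coded 0/1", bc))
    }
  }
  tibble::as_tibble(cohort)
}

#' @rdname read_cohort
#' @param cohort A cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(cohort, path, progress = FALSE)
  invisible(path)
}

#' The 27-trait candidate-mediator registry
#'
#' Column names of the standard screening panel: Lp-PLA2 mass and activity,
#' six inflammatory markers, LDL particle number, eight phospholipid fatty
#' acids, and ten fatty-acid ratios.
#'
#' @return Character vector of 27 trait names.
#' @export
trait_registry <- function() {
  c("lppla2_mass", "lppla2_activity", "hscrp", "homocysteine", "il6",
    "eselectin", "pai1", "sicam1", "ldl_particles",
    "ala", "epa", "dha", "dpa", "la", "gla", "dgla", "aa",
    "aa_la", "gla_la", "dgla_gla", "aa_dgla", "dgla_la", "dha_ala",
    "epa_ala", "dpa_epa", "dha_epa", "dha_dpa")
}

#' Bonferroni per-test threshold
#'
#' @param alpha Family-wise error level in (0, 1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 27)  # 0.00185..., i.e. <= 0.0019
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1)")
  }
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m != floor(m)) {
    abort("`m` must be a positive integer")
  }
  alpha / m
}

#' Carry-forward selection of candidate mediators
#'
#' Applies the screening rule that decides which traits proceed to mediation
#' analysis: a trait is selected when its meta-analysis p-value is at or
#' below the Bonferroni threshold `alpha / m` (with `m` the number of traits
#' screened), OR its trans-ethnic log10 Bayes factor exceeds `bf_threshold`.
#'
#' @param meta_results Data frame with columns `trait`, `p`, and optionally
#'   `log10_bf` (traits without a Bayes factor are judged on `p` alone).
#' @param alpha Family-wise level (default 0.05).
#' @param bf_threshold log10 Bayes factor cut-off (default 1.5).
#' @param m Number of traits screened (default `nrow(meta_results)`).
#' @return The input with logical columns `bonferroni_sig`, `bf_sig`,
#'   `selected`, and the threshold recorded in attribute
#'   `"bonferroni_threshold"`.
#' @examples
#' pub <- mesa_published_meta()
#' sel <- carry_forward(pub)
#' sel$trait[sel$selected]
#' @export
carry_forward <- function(meta_results, alpha = 0.05, bf_threshold = 1.5,
                          m = nrow(meta_results)) {
  if (!all(c("trait", "p") %in% names(meta_results))) {
    abort("`meta_results` needs columns `trait` and `p`")
  }
  if (m < 1) abort("empty trait registry")
  thr <- bonferroni_threshold(alpha, m)
  out <- tibble::as_tibble(meta_results)
  if (!"log10_bf" %in% names(out)) out$log10_bf <- NA_real_
  out$bonferroni_sig <- !is.na(out$p) & out$p <= thr
  out$bf_sig <- !is.na(out$log10_bf) & out$log10_bf > bf_threshold
  out$selected <- out$bonferroni_sig | out$bf_sig
  attr(out, "bonferroni_threshold") <- thr
  out
}

#' Run the full stratified-association analysis pipeline
#'
#' End-to-end orchestration on a cohort table (simulated or read from disk):
#' per-stratum additive SNP association for every registered trait;
#' fixed-effects meta-analysis with Cochran heterogeneity and a
#' trans-ethnic Bayes factor per trait; carry-forward selection (Bonferroni
#' OR Bayes factor rule); bias-corrected bootstrap mediation for each
#' selected trait against the continuous outcome; and, when trial-style
#' columns are present, the survival stage (per-stratum baseline biomarker
#' association with random-effects meta, plus the gene-by-treatment Cox
#' interaction test). When `out_dir` is given all tables are written as TSV
#' together with a `run.log` carrying the seed, package version, and a
#' configuration hash; identical configuration and seed give byte-identical
#' outputs.
#'
#' @param cohort A validated cohort tibble (see [read_cohort()]); or `NULL`
#'   to simulate one from `specs`.
#' @param specs List of [population_spec()] used when `cohort` is `NULL`.
#' @param traits Traits to screen (default: registry traits present in the
#'   cohort).
#' @param covariates Adjustment set for the association and mediation models.
#' @param outcome Continuous outcome column for the mediation stage (`NULL`
#'   to skip mediation).
#' @param sigma Effect-prior SD for the Bayes factor; default `NULL` uses
#'   0.2 x the observed trait SD, trait by trait.
#' @param alpha,bf_threshold Carry-forward rule parameters.
#' @param B Bootstrap replicates for the mediation stage.
#' @param seed Integer seed governing simulation and bootstrap.
#' @param out_dir Optional output directory.
#' @param survival_stage Run the survival stage if the needed columns exist
#'   (default TRUE).
#' @return List with tibbles `assoc`, `meta`, `selection`, `mediation`
#'   (per-stratum + `mediation_meta`), `survival` (or `NULL`), and `config`
#'   metadata including the hash.
#' @export
run_pipeline <- function(cohort = NULL, specs = NULL, traits = NULL,
                         covariates = c("age", "sex", "pc1", "pc2"),
                         outcome = "cimt", sigma = NULL, alpha = 0.05,
                         bf_threshold = 1.5, B = 400, seed,
                         out_dir = NULL, survival_stage = TRUE) {
  if (missing(seed)) abort("`seed` is required")
  if (is.null(cohort)) {
    if (is.null(specs)) abort("provide either `cohort` or `specs`")
    cohort <- gen_multiethnic(specs, seed = seed)
  }
  cohort <- validate_cohort(cohort)
  traits <- traits %||% intersect(trait_registry(), names(cohort))
  if (!length(traits)) abort("empty trait registry: no screenable traits")
  covariates <- intersect(covariates, names(cohort))

  config <- list(traits = traits, covariates = covariates,
                 outcome = outcome, sigma = sigma, alpha = alpha,
                 bf_threshold = bf_threshold, B = B, seed = seed,
                 n = nrow(cohort),
                 version = as.character(utils::packageVersion("transmeta")))
  config$hash <- rlang::hash(config)

  assoc <- purrr::map_dfr(traits, function(tr) {
    snp_assoc(cohort, tr, covariates = covariates, kind = "linear")
  })

  meta <- purrr::map_dfr(traits, function(tr) {
    est <- assoc[assoc$trait == tr, ]
    est <- tibble::tibble(label = est$stratum, beta = est$beta, se = est$se)
    fe <- meta_fixed(est)
    sig <- sigma %||% (0.2 * sd(cohort[[tr]], na.rm = TRUE))
    bf <- if (nrow(est) >= 2) transethnic_bf(est, sigma = sig) else NULL
    dplyr::bind_cols(tibble::tibble(trait = tr), tidy(fe)[, -1],
                     glance(fe),
                     tibble::tibble(log10_bf = bf$log10_bf %||% NA_real_,
                                    sigma = sig))
  })

  selection <- carry_forward(meta[, c("trait", "p", "log10_bf")],
                             alpha = alpha, bf_threshold = bf_threshold,
                             m = length(traits))
  carried <- setdiff(selection$trait[selection$selected], outcome)

  mediation <- NULL
  if (!is.null(outcome) && outcome %in% names(cohort) && length(carried)) {
    mediation <- purrr::map(setNames(carried, carried), function(med) {
      mediation_boot(cohort, outcome = outcome, mediator = med,
                     covariates = covariates, B = B,
                     seed = derive_seed(seed, 7L))
    })
  }
  mediation_tbl <- if (length(mediation)) {
    purrr::imap_dfr(mediation, function(f, med) {
      dplyr::bind_cols(tibble::tibble(mediator = med), tidy(f))
    })
  } else NULL
  mediation_meta_tbl <- if (length(mediation)) {
    purrr::imap_dfr(mediation, function(f, med) {
      dplyr::bind_cols(tibble::tibble(mediator = med), glance(f))
    })
  } else NULL

  surv <- NULL
  if (survival_stage &&
      all(c("time", "treatment") %in% names(cohort))) {
    event_col <- intersect(c("mce", "mace"), names(cohort))[1]
    if (!is.na(event_col)) {
      fit <- cox_interaction(cohort, time = "time", event = event_col,
                             treatment = "treatment",
                             covariates = covariates)
      surv <- tidy(fit)
    }
  }

  results <- list(assoc = assoc, meta = meta, selection = selection,
                  mediation = mediation_tbl,
                  mediation_meta = mediation_meta_tbl,
                  survival = surv, config = config)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_tsv(assoc, file.path(out_dir, "assoc.tsv"), progress = FALSE)
    readr::write_tsv(meta, file.path(out_dir, "meta.tsv"), progress = FALSE)
    readr::write_tsv(selection, file.path(out_dir, "selection.tsv"),
                     progress = FALSE)
    if (!is.null(mediation_tbl)) {
      readr::write_tsv(mediation_tbl, file.path(out_dir, "mediation.tsv"),
                       progress = FALSE)
      readr::write_tsv(mediation_meta_tbl,
                       file.path(out_dir, "mediation_meta.tsv"),
                       progress = FALSE)
    }
    if (!is.null(surv)) {
      readr::write_tsv(surv, file.path(out_dir, "survival.tsv"),
                       progress = FALSE)
    }
    writeLines(c(sprintf("transmeta %s", config$version),
                 sprintf("seed: %d", seed),
                 sprintf("config hash: %s", config$hash),
                 sprintf("subjects: %d", nrow(cohort)),
                 sprintf("traits screened: %d", length(traits)),
                 sprintf("carried forward: %s",
                         paste(carried, collapse = ", "))),
               file.path(out_dir, "run.log"))
  }
  results
}
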