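#' Published rs10846744 summary statistics
#'
#' Per-ethnicity summary statistics transcribed from the published MESA
#' candidate-mediator analyses of the SCARB1 intronic variant rs10846744
#' (effect allele C vs reference G, additive coding, models adjusted for
#' age, sex, study site and ancestry PCs), and the darapladib-trial baseline
#' Lp-PLA2-activity analyses. These printed numbers are the inputs from
#' which the meta-analytic stages of this package can be reproduced without
#' individual-level data.
#'
#' `mesa_published_assoc()` returns the per-stratum (Caucasian,
#' African-American, Hispanic, Chinese-American) association estimates for
#' the 27-trait candidate-mediator registry; `mesa_published_meta()` the
#' corresponding published fixed-effects meta-analysis rows (combined beta,
#' SE, p), trans-ethnic log10 Bayes factors, and Cochran heterogeneity
#' summaries; `trial_published_biomarker()` the per-stratum, pooled, and
#' random-effects meta rows for baseline Lp-PLA2 activity in the STABILITY
#' and SOLID-TIMI 52 trials.
#'
#' Values carry the precision at which they were printed (in particular some
#' small SEs round to 0.000); treat the published trans-ethnic Bayes factors
#' as qualitative references, since the prior behind them is not stated.
#' Note one quirk preserved as printed: under the stated carry-forward rule
#' (fixed-effects meta p below the 27-trait Bonferroni threshold, or log10
#' Bayes factor above 1.5) the selected mediators are Lp-PLA2 activity and
#' the DPA/EPA ratio, although the accompanying narrative names DHA/EPA.
#'
#' @return A tibble.
#' @examples
#' act <- dplyr::filter(mesa_published_assoc(), trait == "lppla2_activity")
#' tidy(meta_fixed(act))
#' @export
mesa_published_assoc <- function() {
  read_extdata("mesa_rs10846744_strata.tsv")
}

#' @rdname mesa_published_assoc
#' @export
mesa_published_meta <- function() {
  read_extdata("mesa_rs10846744_meta.tsv")
}

#' @rdname mesa_published_assoc
#' @export
trial_published_biomarker <- function() {
  read_extdata("trial_rs10846744_biomarker.tsv")
}

read_extdata <- function(file) {
  path <- system.file("extdata", file, package = "transmeta",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
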