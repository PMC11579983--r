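#' Prediction error of a semi-quantified concentration
#'
#' The ratio of the concentration estimated by surrogate calibration to
#' the concentration determined with the compound's own authentic
#' standard. A ratio of 1 is a perfect estimate; ratios are reported
#' untransformed (no logarithm), and values above and below 1 both enter
#' any averaging.
#'
#' @param conc_semi Numeric vector of semi-quantified concentrations.
#' @param conc_authentic Numeric vector of authentic-standard
#'   concentrations (must be positive).
#' @return Numeric vector of ratios.
#' @export
#' @examples
#' prediction_error(2.0, 1.0)
prediction_error <- function(conc_semi, conc_authentic) {
  if (any(conc_authentic <= 0 | !is.finite(conc_authentic))) {
    stop("authentic concentrations must be positive and finite")
  }
  conc_semi / conc_authentic
}

#' Fraction of prediction errors within a factor of k
#'
#' The proportion of ratios r with 1/k <= r <= k (bounds inclusive): a
#' ratio of exactly 0.5 or 2 counts as "within a factor of 2".
#'
#' @param ratios Numeric vector of prediction-error ratios (non-empty).
#' @param k Factor (> 1, default 2).
#' @return Proportion in \[0, 1\].
#' @export
#' @examples
#' within_factor(c(0.5, 1, 2, 3)) # 0.75
within_factor <- function(ratios, k = 2) {
  if (length(ratios) == 0L) {
    stop("cannot compute coverage of an empty ratio set")
  }
  if (!is.finite(k) || k <= 1) {
    stop("k must exceed 1")
  }
  mean(ratios >= 1 / k & ratios <= k)
}

#' Matrix effect as a calibration-gradient ratio
#'
#' Ratio of the internal (standard-addition, in-matrix) calibration
#' gradient to the external (pure-solvent) gradient per compound: 1 means
#' no matrix effect, below 1 suppression, above 1 enhancement. The same
#' ratio applied to concentrations gives the concentration-ratio variant.
#'
#' @param internal Numeric vector of in-matrix gradients (or externally
#'   calibrated concentrations for the concentration variant).
#' @param external Numeric vector of pure-solvent gradients (or
#'   standard-addition concentrations); must be positive.
#' @return Numeric vector of ratios.
#' @export
matrix_effect <- function(internal, external) {
  if (any(external <= 0 | !is.finite(external))) {
    stop("external gradients must be positive and finite")
  }
  internal / external
}

#' Summarise matrix effects across compounds
#'
#' @inheritParams matrix_effect
#' @return One-row tibble: `mean`, `sd`, `n`.
#' @export
matrix_effect_summary <- function(internal, external) {
  r <- matrix_effect(internal, external)
  tibble::tibble(mean = mean(r), sd = stats::sd(r), n = length(r))
}

#' Spike recovery
#'
#' Percent of a known spiked amount recovered from a blank filter:
#' 100 * measured / spiked.
#'
#' @param measured Numeric vector of measured amounts.
#' @param spiked Numeric vector of spiked amounts (positive).
#' @return Numeric vector of recoveries in percent.
#' @export
recovery <- function(measured, spiked) {
  if (any(spiked <= 0 | !is.finite(spiked))) {
    stop("spiked amounts must be positive and finite")
  }
  100 * measured / spiked
}

#' Summarise spike recoveries per compound
#'
#' Per-compound mean recovery and relative standard deviation across
#' replicate spikes, with the conventional 20% RSD acceptability flag,
#' plus the overall mean and standard deviation of the per-compound mean
#' recoveries.
#'
#' @param measured,spiked Numeric vectors (see [recovery()]).
#' @param compound Character vector grouping replicates by compound.
#' @return List with `per_compound` (tibble `compound`, `mean_recovery`,
#'   `rsd_pct`, `acceptable`) and `overall` (tibble `mean`, `sd`, `n`).
#' @export
recovery_summary <- function(measured, spiked, compound) {
  rec <- tibble::tibble(compound = compound,
                        recovery = recovery(measured, spiked))
  per <- rec |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(
      mean_recovery = mean(.data$recovery),
      rsd_pct = ifelse(dplyr::n() > 1L,
                       100 * stats::sd(.data$recovery) / mean(.data$recovery),
                       NA_real_)
    ) |>
    dplyr::mutate(acceptable = is.na(.data$rsd_pct) | .data$rsd_pct < 20)
  list(per_compound = per,
       overall = tibble::tibble(mean = mean(per$mean_recovery),
                                sd = stats::sd(per$mean_recovery),
                                n = nrow(per)))
}

#' Validation report for a set of quantified compounds
#'
#' Computes per-record prediction errors and summarises them as the
#' median error, mean error and factor-of-k coverage, per sample and per
#' compound (compounds detected in several samples are additionally
#' aggregated as the arithmetic mean of their per-sample concentrations
#' before the ratio is recomputed).
#'
#' @param records Tibble with columns `compound`, `conc_semi`,
#'   `conc_authentic`; optional `sample_id` (defaults to a single
#'   sample) and `compound_class` (enables per-class medians).
#' @param k Factor for the coverage band (default 2).
#' @return List with `median_error`, `mean_error`,
#'   `fraction_within_factor`, `k`, `n`, `per_compound` (tibble with the
#'   mean-aggregated ratio per compound), `per_sample_errors` (tibble of
#'   raw per-record ratios) and `per_class` (tibble `compound_class`,
#'   `median_error`, or `NULL` when no class column is present).
#' @export
validation_report <- function(records, k = 2) {
  stopifnot(all(c("compound", "conc_semi", "conc_authentic")
                %in% names(records)))
  if (nrow(records) == 0L) {
    stop("no validation records supplied")
  }
  if (!"sample_id" %in% names(records)) {
    records$sample_id <- "sample_1"
  }
  records$error <- prediction_error(records$conc_semi, records$conc_authentic)
  per_compound <- records |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(
      conc_semi = mean(.data$conc_semi),
      conc_authentic = mean(.data$conc_authentic)
    ) |>
    dplyr::mutate(error = .data$conc_semi / .data$conc_authentic)
  per_class <- NULL
  if ("compound_class" %in% names(records)) {
    per_class <- records |>
      dplyr::group_by(.data$compound_class) |>
      dplyr::summarise(median_error = stats::median(.data$error),
                       n = dplyr::n())
  }
  list(
    median_error = stats::median(records$error),
    mean_error = mean(records$error),
    fraction_within_factor = within_factor(records$error, k),
    k = k,
    n = nrow(records),
    per_compound = per_compound,
    per_sample_errors = tibble::as_tibble(
      records[, c("compound", "sample_id", "error")]
    ),
    per_class = per_class
  )
}

#' Head-to-head comparison with an external predictive model
#'
#' Produces parallel validation reports for the surrogate-calibration
#' concentrations and externally supplied model-predicted concentrations
#' (for example from a relative-ionization-efficiency model), against the
#' same authentic-standard concentrations, plus a per-compound
#' ratio-of-methods table.
#'
#' @param records Tibble with columns `compound`, `conc_semi`,
#'   `conc_authentic` and `conc_rie`; optional `sample_id`,
#'   `compound_class`.
#' @inheritParams validation_report
#' @return List with `semi` and `rie` (each a [validation_report()]
#'   list) and `method_ratio` (tibble `compound`,
#'   `semi_to_rie` = mean semi-quantified over mean model-predicted
#'   concentration). If `conc_rie` is absent the comparison is skipped
#'   with a warning and only `semi` is returned.
#' @export
compare_methods <- function(records, k = 2) {
  semi <- validation_report(records, k)
  if (!"conc_rie" %in% names(records) || all(is.na(records$conc_rie))) {
    warning("no model-predicted concentrations supplied; comparison skipped")
    return(list(semi = semi, rie = NULL, method_ratio = NULL))
  }
  rie_records <- records[!is.na(records$conc_rie), ]
  rie_records$conc_semi <- rie_records$conc_rie
  rie <- validation_report(rie_records, k)
  method_ratio <- records[!is.na(records$conc_rie), ] |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(semi_to_rie = mean(.data$conc_semi) /
                       mean(.data$conc_rie))
  list(semi = semi, rie = rie, method_ratio = method_ratio)
}
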