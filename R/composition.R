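#' Class-resolved mass abundance with gradient-envelope uncertainty
#'
#' For each of the five gradient statistics (median, lower quartile,
#' upper quartile, minimum, maximum) the per-feature concentrations under
#' that statistic are summed per compound class and normalised to
#' percent of the total quantified mass. The method uncertainty on a
#' class's relative abundance is the width of its interquartile band,
#' i.e. the absolute difference between the upper- and lower-quartile
#' scenario percentages.
#'
#' Only quantified classes (CHO, CHON, CHOS) enter the denominator.
#' Envelope fields are named by concentration ordering (see
#' [quantify_features()]), so the lower-quartile *scenario* uses the
#' `conc_lq` column and so on.
#'
#' @param results Quantification results tibble from
#'   [quantify_features()]; an optional `sample_id` column yields
#'   per-sample summaries.
#' @return Tibble with one row per (sample, class): `sample_id`,
#'   `compound_class`, `median_pct`, `lq_pct`, `uq_pct`, `min_pct`,
#'   `max_pct`, `iqr_pct`.
#' @export
class_abundance <- function(results) {
  cols <- c("conc_median", "conc_lq", "conc_uq", "conc_min", "conc_max")
  stopifnot(all(c("compound_class", cols) %in% names(results)))
  if (nrow(results) == 0L) {
    stop("empty quantification table")
  }
  if (!"sample_id" %in% names(results)) {
    results$sample_id <- "sample_1"
  }
  one_sample <- function(tab) {
    totals <- vapply(cols, function(cl) sum(tab[[cl]]), numeric(1L))
    if (any(totals <= 0)) {
      stop("total quantified mass is zero under at least one scenario")
    }
    per_class <- tab |>
      dplyr::group_by(.data$compound_class) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(cols), sum))
    for (cl in cols) {
      per_class[[cl]] <- 100 * per_class[[cl]] / totals[[cl]]
    }
    names(per_class) <- c("compound_class", "median_pct", "lq_pct", "uq_pct",
                          "min_pct", "max_pct")
    per_class$iqr_pct <- abs(per_class$uq_pct - per_class$lq_pct)
    per_class
  }
  results |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(~ one_sample(.x)) |>
    dplyr::ungroup()
}

#' Class-resolved peak-area abundance
#'
#' The conventional alternative to mass-based abundance: class sums of
#' raw peak area normalised to percent over the quantified classes.
#'
#' @param features Tibble with `compound_class` and `area` columns
#'   (a quantification results table works as-is); optional `sample_id`.
#' @return Tibble `sample_id`, `compound_class`, `area_pct`.
#' @export
peak_area_abundance <- function(features) {
  stopifnot(all(c("compound_class", "area") %in% names(features)))
  features <- features[features$compound_class %in% c("CHO", "CHON", "CHOS"), ]
  if (nrow(features) == 0L || sum(features$area) <= 0) {
    stop("no quantifiable peak area")
  }
  if (!"sample_id" %in% names(features)) {
    features$sample_id <- "sample_1"
  }
  features |>
    dplyr::group_by(.data$sample_id, .data$compound_class) |>
    dplyr::summarise(area = sum(.data$area), .groups = "drop_last") |>
    dplyr::mutate(area_pct = 100 * .data$area / sum(.data$area)) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "compound_class", "area_pct")
}

#' Gap between mass-based and peak-area abundance
#'
#' Signed difference (mass percent minus area percent) per class: a
#' positive value means peak area underestimates that class's
#' contribution to total mass.
#'
#' @param mass_abundance Tibble from [class_abundance()] (uses
#'   `median_pct`).
#' @param area_abundance Tibble from [peak_area_abundance()].
#' @return Tibble `sample_id`, `compound_class`, `mass_pct`, `area_pct`,
#'   `gap_pct`.
#' @export
abundance_gap <- function(mass_abundance, area_abundance) {
  key_m <- paste(mass_abundance$sample_id, mass_abundance$compound_class)
  key_a <- paste(area_abundance$sample_id, area_abundance$compound_class)
  if (!setequal(key_m, key_a)) {
    stop("mass and area summaries cover different sample/class sets")
  }
  mass_abundance |>
    dplyr::select("sample_id", "compound_class", mass_pct = "median_pct") |>
    dplyr::left_join(area_abundance, by = c("sample_id", "compound_class")) |>
    dplyr::mutate(gap_pct = .data$mass_pct - .data$area_pct)
}

#' Concentration-weighted bulk molecular descriptors
#'
#' The concentration-weighted mean molecular formula of the quantified
#' mixture and the elemental ratios of that mean formula (O:C, H:C),
#' descriptors commonly used to characterise organic-aerosol oxidation
#' state. A peak-area-weighted variant is available for comparison with
#' area-based workflows.
#'
#' @param results Quantification results tibble with `best_formula` and
#'   `conc_median` (and `area` for the area-weighted variant).
#' @param weight `"concentration"` (default) or `"area"`.
#' @return One-row tibble: `mean_C`, `mean_H`, `mean_N`, `mean_O`,
#'   `O_to_C`, `H_to_C`, `n_features`, `weight`.
#' @export
bulk_descriptors <- function(results, weight = c("concentration", "area")) {
  weight <- match.arg(weight)
  wcol <- if (weight == "concentration") "conc_median" else "area"
  stopifnot(all(c("best_formula", wcol) %in% names(results)))
  p <- parse_formula(results$best_formula)
  ok <- p$valid & is.finite(results[[wcol]])
  w <- results[[wcol]][ok]
  if (sum(w) <= 0) {
    stop("total weight is zero; cannot form weighted-mean formula")
  }
  wmean <- function(x) sum(w * x) / sum(w)
  mean_C <- wmean(p$C[ok])
  tibble::tibble(
    mean_C = mean_C, mean_H = wmean(p$H[ok]), mean_N = wmean(p$N[ok]),
    mean_O = wmean(p$O[ok]),
    O_to_C = wmean(p$O[ok]) / mean_C, H_to_C = wmean(p$H[ok]) / mean_C,
    n_features = sum(ok), weight = weight
  )
}

#' Full compositional summary
#'
#' Bundles mass abundance, peak-area abundance, their gap and bulk
#' descriptors, with a pooled across-sample mean and standard deviation
#' of each class's mass and area percentages.
#'
#' @inheritParams class_abundance
#' @return List with `mass_abundance`, `area_abundance`, `gap`,
#'   `pooled` (tibble `compound_class`, `mass_mean_pct`, `mass_sd_pct`,
#'   `area_mean_pct`, `area_sd_pct`, `gap_mean_pct`, `gap_sd_pct`,
#'   `n_samples`) and `bulk` (concentration- and area-weighted rows).
#' @export
composition_summary <- function(results) {
  mass <- class_abundance(results)
  area <- peak_area_abundance(results)
  gap <- abundance_gap(mass, area)
  pooled <- gap |>
    dplyr::group_by(.data$compound_class) |>
    dplyr::summarise(
      mass_mean_pct = mean(.data$mass_pct),
      mass_sd_pct = stats::sd(.data$mass_pct),
      area_mean_pct = mean(.data$area_pct),
      area_sd_pct = stats::sd(.data$area_pct),
      gap_mean_pct = mean(.data$gap_pct),
      gap_sd_pct = stats::sd(.data$gap_pct),
      n_samples = dplyr::n()
    )
  list(
    mass_abundance = mass,
    area_abundance = area,
    gap = gap,
    pooled = pooled,
    bulk = dplyr::bind_rows(bulk_descriptors(results, "concentration"),
                            bulk_descriptors(results, "area"))
  )
}
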