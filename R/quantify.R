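#' Convert peak areas to concentrations with an uncertainty envelope
#'
#' Scaling is concentration = peak area / calibration gradient (fitted
#' intercepts are ignored at this stage). Three routes, in order of
#' precedence:
#'
#' * a feature identified to Level 1 whose `level1_id` matches an
#'   authentic standard's curve is scaled by that standard's own gradient
#'   (all five envelope fields equal; provenance `"authentic_standard"`);
#' * a CHOS feature is scaled by the single organosulfate surrogate
#'   gradient (provenance `"chos_single_standard"`);
#' * any other CHO/CHON feature is scaled by the statistics of the
#'   retention-time window containing its elution time (provenance
#'   `"window_median"`).
#'
#' For window-scaled features the gradient statistics invert into the
#' concentration envelope in reversed order: the *upper*-quartile
#' gradient gives the *lower*-quartile concentration and vice versa, and
#' the maximum gradient gives the minimum concentration, since
#' concentration is area divided by gradient. Envelope fields are named
#' by concentration ordering, so `conc_min <= conc_lq <= conc_median <=
#' conc_uq <= conc_max` always holds.
#'
#' @param features Post-processed feature tibble: `feature_id`, `rt`,
#'   `area` (named `peak_area` also accepted), `compound_class`,
#'   `best_formula`; optional `level1_id`.
#' @param stats Window statistics tibble from [window_stats()].
#' @param windows Windows tibble from [build_windows()] (needed only for
#'   the `out_of_window = "nearest"` policy; otherwise taken from
#'   `stats`).
#' @param curves Optional curve tibble from [fit_calibration_curves()];
#'   matched against `level1_id` by standard `name`.
#' @param chos_gradient Gradient of the single CHOS surrogate standard
#'   (signal per ppm), or `NA` to leave CHOS features unquantified.
#' @param unit_factor Multiplicative conversion from extract
#'   concentration (ppm, i.e. ug/mL) to the reporting unit, e.g. extract
#'   volume (mL) divided by sampled air volume (m^3) to obtain ug/m^3.
#'   Identity by default.
#' @param out_of_window `"unquantified"` (default: features eluting
#'   outside every window of their class are flagged with a reason) or
#'   `"nearest"` (scaled by the nearest window of their class, with a
#'   warning).
#' @return List with `results` (tibble: `feature_id`, `best_formula`,
#'   `compound_class`, `rt`, `area`, `conc_median`, `conc_lq`, `conc_uq`,
#'   `conc_min`, `conc_max`, `provenance`, `window_id`) and
#'   `unquantified` (tibble `feature_id`, `reason`).
#' @export
quantify_features <- function(features, stats, windows = NULL, curves = NULL,
                              chos_gradient = NA_real_, unit_factor = 1,
                              out_of_window = c("unquantified", "nearest")) {
  out_of_window <- match.arg(out_of_window)
  if (!"area" %in% names(features) && "peak_area" %in% names(features)) {
    features$area <- features$peak_area
  }
  stopifnot(all(c("feature_id", "rt", "area", "compound_class")
                %in% names(features)))
  if (any(features$area < 0, na.rm = TRUE)) {
    stop("peak areas must be non-negative")
  }
  if (!"best_formula" %in% names(features)) {
    features$best_formula <- NA_character_
  }
  if (!"level1_id" %in% names(features)) {
    features$level1_id <- NA_character_
  }
  if (is.null(windows)) {
    windows <- stats[, c("window_id", "compound_class", "start", "end")] |>
      dplyr::group_by(.data$compound_class) |>
      dplyr::mutate(is_last = .data$end == max(.data$end)) |>
      dplyr::ungroup()
  }

  results <- list()
  unq <- list()
  envelope <- function(area, g_med, g_lq, g_uq, g_min, g_max) {
    if (any(c(g_med, g_lq, g_uq, g_min, g_max) <= 0)) {
      stop("calibration gradients must be positive")
    }
    c(conc_median = area / g_med,
      conc_lq = area / g_uq, conc_uq = area / g_lq,
      conc_min = area / g_max, conc_max = area / g_min) * unit_factor
  }

  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    cls <- f$compound_class
    if (!cls %in% c("CHO", "CHON", "CHOS")) {
      unq[[length(unq) + 1L]] <- c(f$feature_id, "class_not_quantified")
      next
    }
    env <- NULL
    provenance <- NA_character_
    window_id <- NA_character_

    if (!is.na(f$level1_id) && !is.null(curves) &&
        f$level1_id %in% curves$name[curves$usable]) {
      g <- curves$gradient[curves$name == f$level1_id & curves$usable][1L]
      env <- envelope(f$area, g, g, g, g, g)
      provenance <- "authentic_standard"
    } else if (cls == "CHOS") {
      if (!is.finite(chos_gradient)) {
        unq[[length(unq) + 1L]] <- c(f$feature_id, "no_chos_standard")
        next
      }
      env <- envelope(f$area, chos_gradient, chos_gradient, chos_gradient,
                      chos_gradient, chos_gradient)
      provenance <- "chos_single_standard"
    } else {
      wid <- find_window(f$rt, cls, windows)
      if (is.na(wid) && out_of_window == "nearest") {
        w <- windows[windows$compound_class == cls, ]
        if (nrow(w) > 0L) {
          d <- pmax(w$start - f$rt, f$rt - w$end, 0)
          wid <- w$window_id[which.min(d)]
          warning("feature ", f$feature_id, " at rt ", f$rt,
                  " assigned to nearest window ", wid)
        }
      }
      if (is.na(wid)) {
        unq[[length(unq) + 1L]] <- c(f$feature_id, "outside_windows")
        next
      }
      s <- stats[stats$window_id == wid, ]
      if (nrow(s) == 0L || s$n_standards == 0L) {
        unq[[length(unq) + 1L]] <- c(f$feature_id, "empty_window")
        next
      }
      env <- envelope(f$area, s$median_g, s$lq_g, s$uq_g, s$min_g, s$max_g)
      provenance <- "window_median"
      window_id <- wid
    }
    results[[length(results) + 1L]] <- tibble::tibble(
      feature_id = f$feature_id, best_formula = f$best_formula,
      compound_class = cls, rt = f$rt, area = f$area,
      conc_median = env[["conc_median"]], conc_lq = env[["conc_lq"]],
      conc_uq = env[["conc_uq"]], conc_min = env[["conc_min"]],
      conc_max = env[["conc_max"]],
      provenance = provenance, window_id = window_id
    )
  }

  empty_res <- tibble::tibble(
    feature_id = character(), best_formula = character(),
    compound_class = character(), rt = numeric(), area = numeric(),
    conc_median = numeric(), conc_lq = numeric(), conc_uq = numeric(),
    conc_min = numeric(), conc_max = numeric(),
    provenance = character(), window_id = character()
  )
  list(
    results = if (length(results)) dplyr::bind_rows(results) else empty_res,
    unquantified = if (length(unq)) {
      tibble::tibble(feature_id = vapply(unq, `[`, character(1L), 1L),
                     reason = vapply(unq, `[`, character(1L), 2L))
    } else {
      tibble::tibble(feature_id = character(), reason = character())
    }
  )
}
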