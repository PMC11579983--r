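# Synthetic fixture generation ------------------------------------------------
#
# Emulates the statistical structure the semi-quantification method assumes:
# a library of authentic standards spread across the retention-time window
# schemes with gradients spanning orders of magnitude, and sample feature
# tables whose unknowns have known (recorded) true gradients and
# concentrations, so parameter recovery can be checked against a truth table.
# All randomness flows from the single seed in the config; draws happen in a
# fixed documented order (library: per window rt, then gradient, then formula;
# sample: unknowns, level-1 swaps, contaminants, low-S/N, exclusions,
# duplicates, polarity pairs).

CAL_LEVELS <- c(5, 2.5, 1, 0.5, 0.25, 0.125, 0.0625)

#' Configuration for synthetic fixture generation
#'
#' @param seed Integer seed governing every draw.
#' @param n_standards_per_window Authentic standards placed in each CHO and
#'   CHON window (default 5).
#' @param gradient_log10_spread Width, in orders of magnitude, of the
#'   log-uniform distribution standard gradients are drawn from (default 4,
#'   the widest within-window spread the method contends with).
#' @param gradient_log10_center Center of that distribution in log10 signal
#'   counts per ppm (default 4).
#' @param noise_sd Relative standard deviation of calibration-signal noise
#'   (0 = noiseless, signals exactly on the line).
#' @param n_unknowns Number of core unknown features in a generated sample.
#' @param class_mix Named proportions of CHO/CHON/CHOS among unknowns
#'   (must sum to 1).
#' @param blank_contamination_rate Fraction of `n_unknowns` added as
#'   blank-contaminated features (half below, half above the removal ratio).
#' @param gradient_mode How unknown true gradients relate to their window:
#'   `"window_median"` (exactly the window's median -- identity recovery) or
#'   `"lognormal"` (median times `10^N(0, gradient_sigma_log10)`).
#' @param gradient_sigma_log10 Log10 standard deviation for
#'   `gradient_mode = "lognormal"` (default 0.3).
#' @param level1_rate Fraction of unknowns that are library standards carrying
#'   a Level-1 identification tag (default 0.1).
#' @param class_gradient_log10_offset Named per-class shift, in orders of
#'   magnitude, added to the gradient distribution center: lets one class
#'   (e.g. CHON nitroaromatics) ionize systematically more efficiently than
#'   another.
#' @return A list of class `nta_fixture_config`.
#' @export
fixture_config <- function(seed = 1L, n_standards_per_window = 5L,
                           gradient_log10_spread = 4,
                           gradient_log10_center = 4,
                           noise_sd = 0, n_unknowns = 200L,
                           class_mix = c(CHO = 0.75, CHON = 0.2, CHOS = 0.05),
                           blank_contamination_rate = 0.1,
                           gradient_mode = c("window_median", "lognormal"),
                           gradient_sigma_log10 = 0.3,
                           level1_rate = 0.1,
                           class_gradient_log10_offset =
                             c(CHO = 0, CHON = 0, CHOS = 0)) {
  stopifnot(gradient_log10_spread >= 0, noise_sd >= 0,
            abs(sum(class_mix) - 1) < 1e-9,
            all(c("CHO", "CHON", "CHOS") %in% names(class_mix)))
  structure(list(
    seed = as.integer(seed),
    n_standards_per_window = as.integer(n_standards_per_window),
    gradient_log10_spread = gradient_log10_spread,
    gradient_log10_center = gradient_log10_center,
    noise_sd = noise_sd,
    n_unknowns = as.integer(n_unknowns),
    class_mix = class_mix,
    blank_contamination_rate = blank_contamination_rate,
    gradient_mode = match.arg(gradient_mode),
    gradient_sigma_log10 = gradient_sigma_log10,
    level1_rate = level1_rate,
    class_gradient_log10_offset = class_gradient_log10_offset
  ), class = "nta_fixture_config")
}

# Deterministic pool of ratio-valid formulas per class; sampled without
# replacement so no two fixture entities share a formula unless intended.
formula_pool <- function(class) {
  grid <- expand.grid(C = 5:30, H_off = c(0L, 2L, 4L), O = 2:7,
                      KEEP.OUT.ATTRS = FALSE)
  H <- grid$C + grid$H_off
  switch(class,
    CHO = sprintf("C%dH%dO%d", grid$C, H, grid$O),
    CHON = sprintf("C%dH%dNO%d", grid$C, H, grid$O),
    CHOS = sprintf("C%dH%dO%dS", grid$C, H, grid$O),
    stop("no formula pool for class ", class)
  )
}

# [M-H]- m/z from a molecular formula (monoisotopic masses).
formula_mz <- function(formula) {
  p <- parse_formula(formula)
  mass <- p$C * 12 + p$H * 1.0078250319 + p$N * 14.0030740052 +
    p$O * 15.9949146221 + p$S * 31.97207069 + p$Cl * 34.96885271
  mass - 1.00727646
}

#' Generate a synthetic authentic-standard library
#'
#' Places `n_standards_per_window` standards in every window of the default
#' CHO and CHON schemes (plus one CHOS surrogate standard), draws each
#' standard's true gradient log-uniformly over the configured spread, and
#' produces raw 7-level x 3-replicate calibration points with
#' `signal = gradient * concentration + noise`.
#'
#' @param config A [fixture_config()].
#' @return List with `standards` (tibble: `name`, `formula`,
#'   `compound_class`, `rt_min`, `true_gradient`), `points` (long-format
#'   calibration data: `name`, `concentration`, `signal`, `replicate`) and
#'   `scheme` (the window scheme used).
#' @export
make_standard_library <- function(config) {
  stopifnot(inherits(config, "nta_fixture_config"))
  set.seed(config$seed)
  scheme <- dplyr::bind_rows(default_window_scheme("CHO"),
                             default_window_scheme("CHON"))
  windows <- build_windows(scheme)
  pools <- list(CHO = sample(formula_pool("CHO")),
                CHON = sample(formula_pool("CHON")),
                CHOS = sample(formula_pool("CHOS")))
  pool_pos <- c(CHO = 0L, CHON = 0L, CHOS = 0L)
  take_formula <- function(class, n) {
    idx <- pool_pos[[class]] + seq_len(n)
    if (max(idx) > length(pools[[class]])) {
      stop("formula pool for ", class, " exhausted")
    }
    pool_pos[[class]] <<- pool_pos[[class]] + n
    pools[[class]][idx]
  }

  half <- config$gradient_log10_spread / 2
  n_per <- config$n_standards_per_window
  offset <- config$class_gradient_log10_offset
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    center <- config$gradient_log10_center + offset[[w$compound_class]]
    rt <- stats::runif(n_per, w$start, w$end - 0.01)
    g <- 10^stats::runif(n_per, center - half, center + half)
    tibble::tibble(
      name = sprintf("std_%s_%d", w$window_id, seq_len(n_per)),
      formula = take_formula(w$compound_class, n_per),
      compound_class = w$compound_class,
      rt_min = rt, true_gradient = g
    )
  })
  chos <- tibble::tibble(
    name = "std_CHOS_surrogate",
    formula = take_formula("CHOS", 1L),
    compound_class = "CHOS",
    rt_min = stats::runif(1, 0, 20),
    true_gradient = 10^stats::runif(
      1, config$gradient_log10_center + offset[["CHOS"]] - half,
      config$gradient_log10_center + offset[["CHOS"]] + half)
  )
  standards <- dplyr::bind_rows(c(rows, list(chos)))

  points <- tidyr::crossing(name = standards$name,
                            concentration = CAL_LEVELS,
                            replicate = 1:3) |>
    dplyr::left_join(standards[, c("name", "true_gradient")], by = "name") |>
    dplyr::arrange(.data$name, -.data$concentration, .data$replicate)
  mu <- points$true_gradient * points$concentration
  points$signal <- pmax(0, mu + stats::rnorm(nrow(points),
                                             0, config$noise_sd * mu))
  points <- dplyr::select(points, "name", "concentration", "signal",
                          "replicate")
  list(standards = standards, points = points, scheme = scheme)
}

# True per-window gradient statistics from generator-side bookkeeping
# (independent of any fitting done by the pipeline).
true_window_medians <- function(standards, windows) {
  st <- standards[standards$compound_class %in% windows$compound_class, ]
  st$window_id <- find_window(st$rt_min, st$compound_class, windows)
  st <- st[!is.na(st$window_id), ]
  stats::setNames(
    vapply(windows$window_id, function(wid) {
      g <- st$true_gradient[st$window_id == wid]
      if (length(g)) stats::median(g) else NA_real_
    }, numeric(1L)),
    windows$window_id
  )
}

#' Generate a synthetic sample with blanks and a truth table
#'
#' Builds a negative-mode feature table around `n_unknowns` core unknowns
#' (true concentration log-uniform over 0.01--5 ppm, peak area = true
#' gradient x true concentration), then injects, with generator-side
#' bookkeeping of every parameter:
#'
#' * Level-1 identified features that are library standards;
#' * blank-contaminated features at sample-to-blank ratios straddling the
#'   removal threshold of 10 (low-ratio ones must be removed in blank
#'   subtraction step 1, high-ratio ones kept);
#' * low signal-to-noise features (S/N below 3, removed in step 3);
#' * features on the exclusion list (removed in step 2);
#' * alignment duplicates (same formula, retention time within tolerance,
#'   smaller area -- collapsed by deduplication);
#' * cross-polarity pairs whose positive-mode twin has a smaller
#'   (retained) or larger (excluded) peak area.
#'
#' Injected background entities carry synthetic m/z values above the
#' formula-derived mass range so they never collide with genuine unknowns
#' during m/z matching.
#'
#' @param config A [fixture_config()].
#' @param library Output of [make_standard_library()] under the same config.
#' @return List with `features`, `positive`, `filter_blank`,
#'   `chamber_blank`, `exclusions` and `truth`. The truth tibble records,
#'   per feature: `role`, class, formula, `rt`, `area`, `snr`, `g_true`,
#'   `conc_true`, `window_id`, `window_median_g` (true-gradient window
#'   median), `level1_id`, and the expected fate flags `removed_step`,
#'   `absorbed_by`, `positive_preferred`, `expect_quantified`.
#' @export
make_sample <- function(config, library) {
  stopifnot(inherits(config, "nta_fixture_config"))
  set.seed(config$seed + 1L)
  standards <- library$standards
  windows <- build_windows(library$scheme)
  med <- true_window_medians(standards, windows)
  chos_g <- standards$true_gradient[standards$compound_class == "CHOS"][1L]

  # unused formulas remaining in the pools (standards consumed the head)
  used <- standards$formula
  pools <- list(CHO = setdiff(formula_pool("CHO"), used),
                CHON = setdiff(formula_pool("CHON"), used),
                CHOS = setdiff(formula_pool("CHOS"), used))
  pool_pos <- c(CHO = 0L, CHON = 0L, CHOS = 0L)
  take_formula <- function(class, n) {
    idx <- pool_pos[[class]] + seq_len(n)
    if (max(idx) > length(pools[[class]])) {
      stop("formula pool for ", class, " exhausted")
    }
    pool_pos[[class]] <<- pool_pos[[class]] + n
    pools[[class]][idx]
  }

  draw_gradient <- function(class, window_id) {
    base <- if (class == "CHOS") chos_g else med[[window_id]]
    if (config$gradient_mode == "window_median") {
      base
    } else {
      base * 10^stats::rnorm(length(base), 0, config$gradient_sigma_log10)
    }
  }

  # --- core unknowns -----------------------------------------------------
  n <- config$n_unknowns
  cls <- sample(names(config$class_mix), n, replace = TRUE,
                prob = config$class_mix)
  new_feature <- function(i, class, role) {
    if (class == "CHOS") {
      rt <- stats::runif(1, 0, 20)
      wid <- NA_character_
    } else {
      w <- windows[windows$compound_class == class, ]
      w <- w[sample(nrow(w), 1L), ]
      rt <- stats::runif(1, w$start, w$end - 0.001)
      wid <- w$window_id
    }
    g <- draw_gradient(class, wid)
    conc <- 10^stats::runif(1, -2, log10(5))
    f <- take_formula(class, 1L)
    tibble::tibble(
      feature_id = sprintf("%s_%04d", role, i), role = role,
      compound_class = class, formula = f, rt = rt,
      mz = formula_mz(f), area = g * conc,
      snr = stats::runif(1, 10, 100), g_true = g, conc_true = conc,
      window_id = wid,
      window_median_g = if (class == "CHOS") chos_g else med[[wid]],
      level1_id = NA_character_
    )
  }
  unknowns <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    new_feature(i, cls[i], "unknown")
  }))

  # --- level-1 identified features (library standards) -------------------
  n_l1 <- floor(config$level1_rate * n)
  if (n_l1 > 0L) {
    picks <- standards[sample(nrow(standards), n_l1), ]
    wid <- find_window(picks$rt_min, picks$compound_class, windows)
    conc <- 10^stats::runif(n_l1, -2, log10(5))
    l1 <- tibble::tibble(
      feature_id = sprintf("level1_%04d", seq_len(n_l1)), role = "level1",
      compound_class = picks$compound_class, formula = picks$formula,
      rt = picks$rt_min, mz = formula_mz(picks$formula),
      area = picks$true_gradient * conc,
      snr = stats::runif(n_l1, 10, 100),
      g_true = picks$true_gradient, conc_true = conc, window_id = wid,
      window_median_g = ifelse(picks$compound_class == "CHOS", chos_g,
                               unname(med[wid])),
      level1_id = picks$name
    )
    unknowns <- dplyr::bind_rows(unknowns, l1)
  }

  # --- blank contaminants (synthetic m/z above the formula mass range) ---
  n_cont <- round(config$blank_contamination_rate * n)
  n_low <- ceiling(n_cont / 2)
  contam <- NULL
  blank_rows <- list(filter = list(), chamber = list())
  if (n_cont > 0L) {
    contam <- dplyr::bind_rows(lapply(seq_len(n_cont), function(i) {
      low <- i <= n_low
      f <- new_feature(i, "CHO", if (low) "contaminant_low" else
        "contaminant_high")
      f$mz <- 600 + i * 1.3
      ratio <- if (low) stats::runif(1, 2, 8) else stats::runif(1, 15, 30)
      target <- if (low && i %% 2L == 0L) "chamber" else "filter"
      blank_rows[[target]][[length(blank_rows[[target]]) + 1L]] <<-
        tibble::tibble(mz = f$mz, rt = f$rt, area = f$area / ratio)
      if (!low) { # kept features sit in both blanks at a safe ratio
        blank_rows$chamber[[length(blank_rows$chamber) + 1L]] <<-
          tibble::tibble(mz = f$mz, rt = f$rt, area = f$area / ratio)
      }
      f
    }))
  }

  # --- low signal-to-noise features --------------------------------------
  n_snr <- max(2L, round(0.05 * n))
  low_snr <- dplyr::bind_rows(lapply(seq_len(n_snr), function(i) {
    f <- new_feature(i, "CHO", "low_snr")
    f$snr <- stats::runif(1, 0.5, 2.9)
    f
  }))

  # --- exclusion-list features -------------------------------------------
  n_excl <- 3L
  excluded <- dplyr::bind_rows(lapply(seq_len(n_excl), function(i) {
    new_feature(i, "CHO", "excluded")
  }))
  exclusions <- tibble::tibble(formula = excluded$formula)

  # --- alignment duplicates (smaller-area twins of unknowns) -------------
  n_dup <- 3L
  dup_src <- unknowns[unknowns$role == "unknown", ][
    sample(sum(unknowns$role == "unknown"), n_dup), ]
  duplicates <- dup_src |>
    dplyr::mutate(
      feature_id = sprintf("duplicate_%04d", seq_len(n_dup)),
      role = "duplicate",
      rt = .data$rt + stats::runif(n_dup, 0.01, 0.08),
      area = .data$area * stats::runif(n_dup, 0.2, 0.8),
      absorbed_by = dup_src$feature_id
    )

  # --- cross-polarity pairs ----------------------------------------------
  n_pol <- 4L
  pol <- dplyr::bind_rows(lapply(seq_len(n_pol), function(i) {
    retained <- i <= n_pol / 2
    new_feature(i, "CHO", if (retained) "pol_retained" else "pol_excluded")
  }))
  positive <- pol |>
    dplyr::mutate(
      feature_id = sprintf("pos_%04d", seq_len(n_pol)),
      area = ifelse(.data$role == "pol_retained",
                    .data$area * stats::runif(n_pol, 0.3, 0.9),
                    .data$area * stats::runif(n_pol, 1.1, 2.0)),
      polarity = "positive"
    )

  truth <- dplyr::bind_rows(unknowns, contam, low_snr, excluded,
                            duplicates, pol)
  if (!"absorbed_by" %in% names(truth)) {
    truth$absorbed_by <- NA_character_
  }
  truth$removed_step <- dplyr::case_match(truth$role,
    "contaminant_low" ~ 1L, "excluded" ~ 2L, "low_snr" ~ 3L,
    .default = NA_integer_)
  truth$positive_preferred <- truth$role == "pol_excluded"
  truth$expect_quantified <- truth$role %in%
    c("unknown", "level1", "contaminant_high", "pol_retained")

  as_feature_table <- function(tab, polarity = "negative") {
    tibble::tibble(
      feature_id = tab$feature_id, mz = tab$mz, rt = tab$rt,
      area = tab$area, polarity = polarity, snr = tab$snr,
      candidates = sprintf("%s:%.2f", tab$formula,
                           stats::runif(nrow(tab), 0.1, 2)),
      level1_id = tab$level1_id
    )
  }
  backdrop <- function(offset, k = 3L) { # blank-only background rows
    tibble::tibble(mz = offset + seq_len(k) * 1.7,
                   rt = stats::runif(k, 0, 20),
                   area = stats::runif(k, 1e3, 1e5))
  }
  list(
    features = as_feature_table(truth),
    positive = as_feature_table(positive, "positive"),
    filter_blank = dplyr::bind_rows(c(blank_rows$filter,
                                      list(backdrop(700)))),
    chamber_blank = dplyr::bind_rows(c(blank_rows$chamber,
                                       list(backdrop(800)))),
    exclusions = exclusions,
    truth = truth
  )
}

#' Write a complete fixture bundle to disk
#'
#' Emits every table of a generated fixture as CSV plus the config as JSON,
#' so any module can be exercised from files alone.
#'
#' @param dir Output directory (created if needed).
#' @param config A [fixture_config()].
#' @param library Output of [make_standard_library()].
#' @param sample Output of [make_sample()].
#' @return Invisibly, the vector of file paths written.
#' @export
write_fixture_bundle <- function(dir, config, library, sample) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    standards = file.path(dir, "standards.csv"),
    points = file.path(dir, "calibration_points.csv"),
    scheme = file.path(dir, "window_scheme.csv"),
    features = file.path(dir, "sample_features.csv"),
    positive = file.path(dir, "positive_features.csv"),
    filter_blank = file.path(dir, "filter_blank.csv"),
    chamber_blank = file.path(dir, "chamber_blank.csv"),
    exclusions = file.path(dir, "exclusions.csv"),
    truth = file.path(dir, "truth.csv"),
    config = file.path(dir, "config.json")
  )
  utils::write.csv(library$standards, paths["standards"], row.names = FALSE)
  utils::write.csv(library$points, paths["points"], row.names = FALSE)
  utils::write.csv(library$scheme, paths["scheme"], row.names = FALSE)
  utils::write.csv(sample$features, paths["features"], row.names = FALSE)
  utils::write.csv(sample$positive, paths["positive"], row.names = FALSE)
  utils::write.csv(sample$filter_blank, paths["filter_blank"],
                   row.names = FALSE)
  utils::write.csv(sample$chamber_blank, paths["chamber_blank"],
                   row.names = FALSE)
  utils::write.csv(sample$exclusions, paths["exclusions"], row.names = FALSE)
  utils::write.csv(sample$truth, paths["truth"], row.names = FALSE)
  jsonlite::write_json(unclass(config), paths["config"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
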