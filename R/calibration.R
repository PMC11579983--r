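#' Fit a linear calibration curve for one authentic standard
#'
#' Ordinary least squares of signal on concentration over all replicate
#' points (the fit is not forced through zero). The intercept is retained
#' for reporting but is never used when scaling peak areas to
#' concentration. Curves with a non-positive slope, or a coefficient of
#' determination below `r_squared_floor`, are flagged unusable rather than
#' raising an error: such standards are excluded from window membership
#' with a warning downstream.
#'
#' @param points Data frame of calibration points with columns
#'   `concentration` (ppm, > 0) and `signal` (peak area); a `replicate`
#'   column may be present and is ignored by the fit (every point enters
#'   individually).
#' @param r_squared_floor Minimum R^2 for a curve to count as usable
#'   (default 0.8, the conventional linearity floor for standard-addition
#'   acceptance).
#' @return A one-row tibble: `gradient` (signal per ppm), `intercept`,
#'   `r_squared`, `n_points`, `n_levels`, `usable`.
#' @export
#' @examples
#' pts <- data.frame(concentration = rep(c(1, 2, 4), each = 3))
#' pts$signal <- 1000 * pts$concentration + 50
#' fit_calibration(pts)
fit_calibration <- function(points, r_squared_floor = 0.8) {
  stopifnot(is.data.frame(points),
            all(c("concentration", "signal") %in% names(points)))
  points <- points[is.finite(points$concentration) & is.finite(points$signal), ]
  if (any(points$concentration <= 0)) {
    stop("calibration concentrations must be positive")
  }
  n_levels <- length(unique(points$concentration))
  if (n_levels < 2L) {
    stop("need at least 2 distinct concentration levels, got ", n_levels)
  }
  fit <- stats::lm(signal ~ concentration, data = points)
  co <- stats::coef(fit)
  # r.squared is 0/0 for an exactly constant response; define it as 0 there
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) r2 <- 0
  gradient <- unname(co[["concentration"]])
  tibble::tibble(
    gradient = gradient,
    intercept = unname(co[["(Intercept)"]]),
    r_squared = r2,
    n_points = nrow(points),
    n_levels = n_levels,
    usable = gradient > 0 & r2 >= r_squared_floor
  )
}

#' Fit calibration curves for a table of standards
#'
#' @param standards Tibble of authentic standards: `name`, `formula`,
#'   `rt_min`; `compound_class` is derived from the formula when absent.
#'   A precomputed `gradient` column, when present, is used directly for
#'   standards that have no raw points (with `usable = gradient > 0`).
#' @param points Long-format calibration data: `name`, `concentration`,
#'   `signal` (optionally `replicate`). May be `NULL` if all standards
#'   carry precomputed gradients.
#' @inheritParams fit_calibration
#' @return Tibble of curves: one row per standard with the fit columns of
#'   [fit_calibration()] plus the standard's identity columns.
#' @export
fit_calibration_curves <- function(standards, points = NULL,
                                   r_squared_floor = 0.8) {
  stopifnot(all(c("name", "formula", "rt_min") %in% names(standards)))
  if (!"compound_class" %in% names(standards)) {
    standards$compound_class <- classify_formula(standards$formula)
  }
  fit_one <- function(nm) {
    pts <- if (is.null(points)) NULL else points[points$name == nm, ]
    if (!is.null(pts) && nrow(pts) > 0L) {
      return(fit_calibration(pts, r_squared_floor))
    }
    g <- standards$gradient[standards$name == nm][1L]
    if (is.null(standards$gradient) || !is.finite(g)) {
      stop("standard '", nm, "' has neither calibration points nor a gradient")
    }
    tibble::tibble(gradient = g, intercept = NA_real_, r_squared = NA_real_,
                   n_points = 0L, n_levels = 0L, usable = g > 0)
  }
  fits <- dplyr::bind_rows(lapply(standards$name, fit_one))
  out <- dplyr::bind_cols(
    standards[, setdiff(names(standards), names(fits)), drop = FALSE],
    fits
  )
  if (any(!out$usable)) {
    warning(sum(!out$usable), " calibration curve(s) flagged unusable ",
            "(non-positive slope or R^2 below ", r_squared_floor, "): ",
            paste(out$name[!out$usable], collapse = ", "))
  }
  tibble::as_tibble(out)
}

#' Default retention-time window schemes
#'
#' The built-in CHO scheme has fourteen 1-minute windows spanning
#' 0--14 min plus three 2-minute windows spanning 14--20 min (17 windows
#' in total). The CHON scheme, reflecting the smaller number of available
#' nitroaromatic standards, has eight windows of 2--3 minutes tiling
#' 0--20 min. CHOS compounds are scaled by a single surrogate standard
#' and have no windows.
#'
#' @param class `"CHO"` or `"CHON"`.
#' @return Tibble with columns `compound_class`, `start`, `end` (minutes).
#' @export
#' @examples
#' nrow(default_window_scheme("CHO")) # 17
default_window_scheme <- function(class = c("CHO", "CHON")) {
  class <- match.arg(class)
  breaks <- switch(class,
    CHO = c(0:14, 16, 18, 20),
    CHON = c(0, 2, 4, 6, 8, 11, 14, 17, 20)
  )
  tibble::tibble(
    compound_class = class,
    start = breaks[-length(breaks)],
    end = breaks[-1L]
  )
}

#' Build validated retention-time windows from a scheme
#'
#' Windows are half-open `[start, end)`; the final window of each class is
#' closed at its end so the scheme covers its full range. Windows of the
#' same class must not overlap.
#'
#' @param scheme Tibble with columns `compound_class`, `start`, `end`
#'   (minutes), e.g. from [default_window_scheme()] or
#'   [read_window_scheme()].
#' @return Tibble of ordered windows with `window_id` (e.g. `"CHO_03"`),
#'   `compound_class`, `start`, `end` and `is_last` (whether the window
#'   closes its class's range).
#' @export
build_windows <- function(scheme) {
  stopifnot(is.data.frame(scheme),
            all(c("compound_class", "start", "end") %in% names(scheme)))
  if (nrow(scheme) == 0L) {
    stop("empty window scheme")
  }
  if (any(!is.finite(scheme$start) | !is.finite(scheme$end))) {
    stop("window boundaries must be finite")
  }
  if (any(scheme$start >= scheme$end)) {
    stop("every window must satisfy start < end")
  }
  scheme <- dplyr::arrange(scheme, .data$compound_class, .data$start)
  out <- scheme |>
    dplyr::group_by(.data$compound_class) |>
    dplyr::mutate(
      window_id = sprintf("%s_%02d", .data$compound_class, dplyr::row_number()),
      is_last = dplyr::row_number() == dplyr::n()
    ) |>
    dplyr::ungroup()
  overlaps <- out |>
    dplyr::group_by(.data$compound_class) |>
    dplyr::summarise(
      bad = dplyr::n() > 1L && any(.data$start[-1L] < .data$end[-dplyr::n()])
    )
  if (any(overlaps$bad)) {
    stop("overlapping windows for class(es): ",
         paste(overlaps$compound_class[overlaps$bad], collapse = ", "))
  }
  dplyr::select(out, "window_id", "compound_class", "start", "end", "is_last")
}

#' Locate the window containing a retention time
#'
#' Vectorised membership lookup under the half-open convention:
#' `start <= rt < end`, with the final window of each class closed at its
#' end.
#'
#' @param rt Numeric retention times (minutes).
#' @param class Character compound classes, recycled against `rt`.
#' @param windows Windows tibble from [build_windows()].
#' @return Character vector of `window_id`s (`NA` where the retention time
#'   falls outside every window of its class).
#' @export
find_window <- function(rt, class, windows) {
  n <- max(length(rt), length(class))
  rt <- rep_len(rt, n)
  class <- rep_len(class, n)
  vapply(seq_len(n), function(i) {
    w <- windows[windows$compound_class == class[i], ]
    if (nrow(w) == 0L || !is.finite(rt[i])) {
      return(NA_character_)
    }
    hit <- rt[i] >= w$start & (rt[i] < w$end | (w$is_last & rt[i] <= w$end))
    if (!any(hit)) NA_character_ else w$window_id[which(hit)[1L]]
  }, character(1L))
}

#' Assign calibration standards to retention-time windows
#'
#' Each usable curve whose retention time falls inside a window of its
#' class becomes a member of that window. Standards of a class that has no
#' window family raise an error; standards inside a window family but
#' outside every interval are returned (not silently dropped).
#'
#' @param curves Curve tibble from [fit_calibration_curves()].
#' @param windows Windows tibble from [build_windows()].
#' @return List with `members` (tibble `window_id`, `name`, `gradient`,
#'   `rt_min`) and `unassigned` (curves excluded, with a `reason` column:
#'   `"unusable_curve"` or `"outside_windows"`).
#' @export
assign_standards <- function(curves, windows) {
  stopifnot(all(c("name", "compound_class", "rt_min", "gradient", "usable")
                %in% names(curves)))
  no_family <- setdiff(unique(curves$compound_class),
                       unique(windows$compound_class))
  if (length(no_family) > 0L) {
    stop("no window family for class(es): ", paste(no_family, collapse = ", "))
  }
  if (any(curves$rt_min < 0)) {
    stop("retention times must be non-negative")
  }
  curves$window_id <- find_window(curves$rt_min, curves$compound_class, windows)
  assigned <- curves$usable & !is.na(curves$window_id)
  unassigned <- curves[!assigned, , drop = FALSE]
  unassigned$reason <- ifelse(!unassigned$usable, "unusable_curve",
                              "outside_windows")
  list(
    members = tibble::as_tibble(
      curves[assigned, c("window_id", "name", "gradient", "rt_min")]
    ),
    unassigned = tibble::as_tibble(
      unassigned[, c("window_id", "name", "gradient", "rt_min", "reason")]
    )
  )
}

#' Per-window gradient statistics
#'
#' For every window, the median, lower quartile, upper quartile, minimum
#' and maximum of its member gradients. The median becomes the scaling
#' factor for unknowns eluting in the window; the other four span the
#' uncertainty envelope. Quartiles use linear interpolation between order
#' statistics (`stats::quantile` type 7), so with a single member all five
#' statistics coincide.
#'
#' @param windows Windows tibble from [build_windows()].
#' @param members Member tibble from [assign_standards()].
#' @return Tibble with one row per window: `window_id`, `compound_class`,
#'   `start`, `end`, `n_standards`, `median_g`, `lq_g`, `uq_g`, `min_g`,
#'   `max_g`. Windows without members carry `n_standards = 0` and `NA`
#'   statistics; quantifying against them is an error downstream.
#' @export
window_stats <- function(windows, members) {
  stopifnot(all(c("window_id", "gradient") %in% names(members)))
  if (any(members$gradient <= 0)) {
    stop("member gradients must be positive")
  }
  stat_one <- function(wid) {
    g <- members$gradient[members$window_id == wid]
    if (length(g) == 0L) {
      return(tibble::tibble(n_standards = 0L, median_g = NA_real_,
                            lq_g = NA_real_, uq_g = NA_real_,
                            min_g = NA_real_, max_g = NA_real_))
    }
    q <- stats::quantile(g, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble::tibble(n_standards = length(g), median_g = q[2L],
                   lq_g = q[1L], uq_g = q[3L],
                   min_g = min(g), max_g = max(g))
  }
  dplyr::bind_cols(
    windows[, c("window_id", "compound_class", "start", "end")],
    dplyr::bind_rows(lapply(windows$window_id, stat_one))
  )
}

#' Calibrate: curves, windows and window statistics in one call
#'
#' Convenience wrapper running [fit_calibration_curves()],
#' [build_windows()], [assign_standards()] and [window_stats()].
#'
#' @inheritParams fit_calibration_curves
#' @param scheme Window scheme tibble; defaults to the built-in CHO and
#'   CHON schemes combined.
#' @return List with `curves`, `windows`, `members`, `unassigned`,
#'   `stats` and `chos_gradient` (the gradient of the single CHOS
#'   surrogate standard, or `NA` if none is present).
#' @export
calibrate <- function(standards, points = NULL, scheme = NULL,
                      r_squared_floor = 0.8) {
  curves <- fit_calibration_curves(standards, points, r_squared_floor)
  if (is.null(scheme)) {
    scheme <- dplyr::bind_rows(default_window_scheme("CHO"),
                               default_window_scheme("CHON"))
  }
  windows <- build_windows(scheme)
  windowed <- curves[curves$compound_class %in% unique(windows$compound_class), ]
  asg <- assign_standards(windowed, windows)
  chos <- curves[curves$compound_class == "CHOS" & curves$usable, ]
  chos_gradient <- if (nrow(chos) > 0L) {
    stats::median(chos$gradient)
  } else {
    NA_real_
  }
  list(curves = curves, windows = windows, members = asg$members,
       unassigned = asg$unassigned,
       stats = window_stats(windows, asg$members),
       chos_gradient = chos_gradient)
}
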