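cal_levels <- c(5, 2.5, 1, 0.5, 0.25, 0.125, 0.0625)

test_that("noiseless linear data recovers slope and intercept", {
  pts <- data.frame(concentration = rep(cal_levels, each = 3))
  pts$signal <- 1000 * pts$concentration + 50
  fit <- fit_calibration(pts)
  expect_equal(fit$gradient, 1000)
  expect_equal(fit$intercept, 50)
  expect_equal(fit$r_squared, 1)
  expect_true(fit$usable)
  expect_equal(fit$n_points, 21L)
})

test_that("a constant response is flagged unusable, not an error", {
  pts <- data.frame(concentration = rep(cal_levels, each = 3), signal = 500)
  fit <- fit_calibration(pts)
  expect_false(fit$usable)
  expect_equal(fit$gradient, 0)
})

test_that("fewer than two concentration levels is a degenerate input", {
  expect_error(
    fit_calibration(data.frame(concentration = rep(1, 3),
                               signal = c(10, 11, 12))),
    "2 distinct"
  )
  expect_error(
    fit_calibration(data.frame(concentration = c(-1, 1), signal = c(1, 2))),
    "positive"
  )
})

test_that("noisy fits match closed-form least squares", {
  set.seed(11)
  for (rep in 1:20) {
    g <- 10^stats::runif(1, 2, 6)
    x <- rep(cal_levels, each = 3)
    y <- g * x + stats::rnorm(21, 0, 0.05 * g)
    fit <- fit_calibration(data.frame(concentration = x, signal = y))
    want <- oracle_ols(x, y)
    expect_equal(fit$gradient, want$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, want$intercept, tolerance = 1e-8)
  }
})

test_that("unusable curves are excluded from windows with a warning", {
  standards <- tibble::tibble(
    name = c("a", "b"), formula = c("C6H10O5", "C7H12O5"),
    rt_min = c(1.5, 2.5), gradient = c(1000, -5)
  )
  expect_warning(curves <- fit_calibration_curves(standards), "unusable")
  asg <- assign_standards(curves, build_windows(default_window_scheme("CHO")))
  expect_equal(asg$members$name, "a")
  expect_equal(asg$unassigned$reason, "unusable_curve")
})

test_that("the default CHO scheme yields 17 windows and CHON 8", {
  cho <- build_windows(default_window_scheme("CHO"))
  chon <- build_windows(default_window_scheme("CHON"))
  expect_equal(nrow(cho), 17L)
  expect_equal(nrow(chon), 8L)
  expect_equal(min(cho$start), 0)
  expect_equal(max(cho$end), 20)
  # fourteen 1-min then three 2-min windows
  expect_equal(cho$end - cho$start, c(rep(1, 14), rep(2, 3)))
  expect_true(all(chon$end - chon$start >= 2 & chon$end - chon$start <= 3))
})

test_that("invalid schemes are rejected", {
  expect_error(build_windows(tibble::tibble(compound_class = character(),
                                            start = numeric(),
                                            end = numeric())), "empty")
  expect_error(build_windows(tibble::tibble(compound_class = "CHO",
                                            start = 2, end = 1)), "start")
  expect_error(build_windows(tibble::tibble(compound_class = "CHO",
                                            start = c(0, 1), end = c(2, 3))),
               "overlap")
})

test_that("single-interval scheme produces one window covering everything", {
  w <- build_windows(tibble::tibble(compound_class = "CHO",
                                    start = 0, end = 20))
  expect_equal(nrow(w), 1L)
  expect_equal(find_window(c(0, 10, 20), "CHO", w), rep("CHO_01", 3))
})

test_that("window membership is half-open with a closed final window", {
  w <- build_windows(default_window_scheme("CHO"))
  expect_equal(find_window(0, "CHO", w), "CHO_01")
  # 14.0 belongs to the 14-16 window, not 13-14
  expect_equal(find_window(14, "CHO", w), "CHO_15")
  expect_equal(find_window(20, "CHO", w), "CHO_17")
  expect_true(is.na(find_window(20.5, "CHO", w)))
  expect_true(is.na(find_window(5, "CHON", w)))
})

test_that("random schemes tile their range with no gaps or double cover", {
  set.seed(21)
  for (rep in 1:20) {
    breaks <- sort(c(0, stats::runif(sample(2:8, 1), 0, 20), 20))
    breaks <- unique(round(breaks, 2))
    if (length(breaks) < 3) next
    scheme <- tibble::tibble(compound_class = "CHO",
                             start = breaks[-length(breaks)],
                             end = breaks[-1])
    w <- build_windows(scheme)
    probe <- seq(0, 20, by = 0.01)
    hits <- vapply(probe, function(rt) {
      sum(rt >= w$start & (rt < w$end | (w$is_last & rt <= w$end)))
    }, numeric(1))
    expect_true(all(hits == 1))
    expect_equal(find_window(probe, "CHO", w),
                 w$window_id[vapply(probe, function(rt) {
                   which(rt >= w$start & (rt < w$end | (w$is_last & rt <= w$end)))
                 }, integer(1))])
  }
})

test_that("standard assignment counts match a brute-force interval test", {
  set.seed(31)
  w <- build_windows(default_window_scheme("CHO"))
  rts <- stats::runif(200, 0, 22)
  curves <- tibble::tibble(
    name = sprintf("s%03d", 1:200), compound_class = "CHO",
    rt_min = rts, gradient = stats::runif(200, 10, 1e5), usable = TRUE
  )
  asg <- assign_standards(curves, w)
  for (i in seq_len(nrow(w))) {
    want <- sum(rts >= w$start[i] &
                  (rts < w$end[i] | (w$is_last[i] & rts <= w$end[i])))
    expect_equal(sum(asg$members$window_id == w$window_id[i]), want)
  }
  expect_equal(nrow(asg$members) + nrow(asg$unassigned), 200L)
  expect_true(all(asg$unassigned$rt_min > 20))
})

test_that("a standard class without a window family is an error", {
  curves <- tibble::tibble(name = "x", compound_class = "CHON", rt_min = 1,
                           gradient = 10, usable = TRUE)
  expect_error(
    assign_standards(curves, build_windows(default_window_scheme("CHO"))),
    "no window family"
  )
})

test_that("window statistics follow the interpolated-quartile convention", {
  w <- build_windows(tibble::tibble(compound_class = "CHO",
                                    start = 0, end = 20))
  mk <- function(g) {
    members <- tibble::tibble(window_id = "CHO_01",
                              name = paste0("s", seq_along(g)), gradient = g,
                              rt_min = 1)
    window_stats(w, members)
  }
  one <- mk(10)
  expect_equal(unlist(one[, c("median_g", "lq_g", "uq_g", "min_g", "max_g")],
                      use.names = FALSE), rep(10, 5))
  s <- mk(c(1, 10, 100, 1000, 10000))
  expect_equal(s$median_g, 100)
  expect_equal(s$min_g, 1)
  expect_equal(s$max_g, 10000)
  expect_equal(s$lq_g, 10)
  expect_equal(s$uq_g, 1000)
})

test_that("window statistics match the quantile oracle on random sets", {
  set.seed(51)
  w <- build_windows(tibble::tibble(compound_class = "CHO",
                                    start = 0, end = 20))
  for (rep in 1:200) {
    g <- 10^stats::runif(sample(1:12, 1), 0, 4)
    members <- tibble::tibble(window_id = "CHO_01",
                              name = paste0("s", seq_along(g)),
                              gradient = g, rt_min = 1)
    s <- window_stats(w, members)
    want <- oracle_window_stats(g)
    expect_equal(s$median_g, want$median)
    expect_equal(s$lq_g, want$lq)
    expect_equal(s$uq_g, want$uq)
    expect_equal(s$min_g, want$min)
    expect_equal(s$max_g, want$max)
    # ordering invariant
    expect_true(s$min_g <= s$lq_g && s$lq_g <= s$median_g &&
                  s$median_g <= s$uq_g && s$uq_g <= s$max_g)
    # duplicating the median never moves it
    members2 <- dplyr::bind_rows(members, tibble::tibble(
      window_id = "CHO_01", name = "dup", gradient = s$median_g, rt_min = 1))
    expect_equal(window_stats(w, members2)$median_g, s$median_g)
  }
})

test_that("removing an extreme minimum shrinks the window spread by its order", {
  # gradients spanning 4 orders of magnitude; dropping the minimum leaves 3
  w <- build_windows(tibble::tibble(compound_class = "CHO",
                                    start = 0, end = 20))
  g <- c(1, 50, 200, 5000, 10000)
  members <- tibble::tibble(window_id = "CHO_01",
                            name = paste0("s", 1:5), gradient = g, rt_min = 1)
  full <- window_stats(w, members)
  expect_equal(log10(full$max_g / full$min_g), 4)
  trimmed <- window_stats(w, members[-1, ])
  expect_true(log10(trimmed$max_g / trimmed$min_g) <= 3)
})
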