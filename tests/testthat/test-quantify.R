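# A minimal calibration: one CHO window 0-20 with 5 member gradients, one
# CHON window, and a CHOS surrogate gradient.
toy_calibration <- function(gradients = c(100, 200, 1000, 5000, 10000)) {
  windows <- build_windows(tibble::tibble(
    compound_class = c("CHO", "CHON"), start = 0, end = 20))
  members <- tibble::tibble(
    window_id = "CHO_01", name = paste0("s", seq_along(gradients)),
    gradient = gradients, rt_min = 5)
  members <- dplyr::bind_rows(members, tibble::tibble(
    window_id = "CHON_01", name = "ns1", gradient = 500, rt_min = 5))
  list(windows = windows, stats = window_stats(windows, members))
}

feature_row <- function(id = "f1", rt = 5, area = 5000, class = "CHO",
                        formula = "C6H10O5", level1 = NA_character_) {
  tibble::tibble(feature_id = id, rt = rt, area = area,
                 compound_class = class, best_formula = formula,
                 level1_id = level1)
}

test_that("window scaling divides area by the five gradient statistics", {
  cal <- toy_calibration()
  q <- quantify_features(feature_row(area = 5000), cal$stats, cal$windows)
  r <- q$results
  expect_equal(r$conc_median, 5000 / 1000)
  expect_equal(r$conc_min, 5000 / 10000)
  expect_equal(r$conc_max, 5000 / 100)
  expect_equal(r$conc_lq, 5000 / 5000)  # upper-quartile gradient
  expect_equal(r$conc_uq, 5000 / 200)   # lower-quartile gradient
  expect_equal(r$provenance, "window_median")
  expect_equal(r$window_id, "CHO_01")
})

test_that("a Level-1 identification collapses the envelope onto its own curve", {
  cal <- toy_calibration()
  curves <- tibble::tibble(name = "vanillin_std", gradient = 250,
                           usable = TRUE)
  q <- quantify_features(feature_row(area = 250, level1 = "vanillin_std"),
                         cal$stats, cal$windows, curves)
  r <- q$results
  expect_equal(r$conc_median, 1)
  expect_equal(r$conc_min, 1)
  expect_equal(r$conc_max, 1)
  expect_equal(r$provenance, "authentic_standard")
})

test_that("CHOS features use the single surrogate gradient", {
  cal <- toy_calibration()
  q <- quantify_features(
    feature_row(class = "CHOS", formula = "C10H16O5S", area = 300),
    cal$stats, cal$windows, chos_gradient = 150)
  expect_equal(q$results$conc_median, 2)
  expect_equal(q$results$conc_lq, 2)
  expect_equal(q$results$provenance, "chos_single_standard")
  # without a surrogate, CHOS stays unquantified with a reason
  q2 <- quantify_features(
    feature_row(class = "CHOS", formula = "C10H16O5S"),
    cal$stats, cal$windows)
  expect_equal(q2$unquantified$reason, "no_chos_standard")
})

test_that("out-of-window and non-quantifiable features are ledgered", {
  cal <- toy_calibration()
  feats <- dplyr::bind_rows(
    feature_row("in_win", rt = 5),
    feature_row("out_win", rt = 25),
    feature_row("hydrocarbon", class = "other", formula = "C10H22")
  )
  q <- quantify_features(feats, cal$stats, cal$windows)
  expect_equal(nrow(q$results), 1L)
  expect_equal(sort(q$unquantified$reason),
               c("class_not_quantified", "outside_windows"))
  # nearest-window policy pulls the stray feature in, with a warning
  expect_warning(
    q3 <- quantify_features(feats[2, ], cal$stats, cal$windows,
                            out_of_window = "nearest"),
    "nearest"
  )
  expect_equal(q3$results$window_id, "CHO_01")
})

test_that("empty tables and empty windows are handled explicitly", {
  cal <- toy_calibration()
  q <- quantify_features(feature_row()[0, ], cal$stats, cal$windows)
  expect_equal(nrow(q$results), 0L)
  expect_equal(nrow(q$unquantified), 0L)
  empty_stats <- cal$stats
  empty_stats$n_standards <- 0L
  q2 <- quantify_features(feature_row(), empty_stats, cal$windows)
  expect_equal(q2$unquantified$reason, "empty_window")
})

test_that("scaling is linear in peak area and the envelope stays ordered", {
  set.seed(101)
  cal <- toy_calibration(10^stats::runif(7, 1, 5))
  for (rep in 1:100) {
    area <- stats::runif(1, 1, 1e6)
    f1 <- quantify_features(feature_row(area = area),
                            cal$stats, cal$windows)$results
    f2 <- quantify_features(feature_row(area = 2 * area),
                            cal$stats, cal$windows)$results
    cols <- c("conc_median", "conc_lq", "conc_uq", "conc_min", "conc_max")
    expect_equal(unlist(f2[, cols]), 2 * unlist(f1[, cols]))
    env <- unlist(f1[, c("conc_min", "conc_lq", "conc_median",
                         "conc_uq", "conc_max")], use.names = FALSE)
    expect_true(all(diff(env) >= 0))
  }
})

test_that("a single-standard window agrees exactly with authentic scaling", {
  windows <- build_windows(tibble::tibble(compound_class = "CHO",
                                          start = 0, end = 20))
  members <- tibble::tibble(window_id = "CHO_01", name = "only_std",
                            gradient = 777, rt_min = 5)
  stats_tab <- window_stats(windows, members)
  curves <- tibble::tibble(name = "only_std", gradient = 777, usable = TRUE)
  f <- feature_row(area = 3885)
  via_window <- quantify_features(f, stats_tab, windows)$results
  via_own <- quantify_features(
    dplyr::mutate(f, level1_id = "only_std"),
    stats_tab, windows, curves)$results
  cols <- c("conc_median", "conc_lq", "conc_uq", "conc_min", "conc_max")
  expect_equal(unlist(via_window[, cols]), unlist(via_own[, cols]))
})

test_that("unknown prediction error equals the gradient ratio exactly", {
  set.seed(111)
  for (rep in 1:50) {
    g_members <- 10^stats::runif(5, 1, 5)
    cal <- toy_calibration(g_members)
    g_true <- 10^stats::runif(1, 1, 5)
    c_true <- stats::runif(1, 0.05, 5)
    q <- quantify_features(feature_row(area = g_true * c_true),
                           cal$stats, cal$windows)$results
    expect_equal(q$conc_median / c_true,
                 g_true / sort(g_members)[3])
  }
})

test_that("the unit conversion factor rescales every concentration field", {
  cal <- toy_calibration()
  base <- quantify_features(feature_row(), cal$stats, cal$windows)$results
  scaled <- quantify_features(feature_row(), cal$stats, cal$windows,
                              unit_factor = 0.25)$results
  cols <- c("conc_median", "conc_lq", "conc_uq", "conc_min", "conc_max")
  expect_equal(unlist(scaled[, cols]), 0.25 * unlist(base[, cols]))
})

test_that("per-class quantified counts match a brute-force classification", {
  cfg <- fixture_config(seed = 13, n_unknowns = 150)
  lib <- make_standard_library(cfg)
  samp <- make_sample(cfg, lib)
  cal <- calibrate(lib$standards, lib$points, lib$scheme)
  proc <- process_features(samp$features, samp$filter_blank,
                           samp$chamber_blank, samp$exclusions, samp$positive)
  q <- quantify_features(proc$features, cal$stats, cal$windows, cal$curves,
                         cal$chos_gradient)
  want <- table(classify_formula(proc$features$best_formula))
  got <- table(q$results$compound_class)
  for (cls in c("CHO", "CHON", "CHOS")) {
    expect_equal(unname(got[cls]), unname(want[cls]))
  }
})
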