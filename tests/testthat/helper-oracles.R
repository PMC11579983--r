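# Independent brute-force oracles, deliberately written without reference to
# the package implementations they check.

# Closed-form OLS via the normal equations.
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  list(slope = slope, intercept = intercept)
}

# Quantile with linear interpolation between order statistics (type 7),
# computed from first principles.
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_window_stats <- function(g) {
  list(median = oracle_quantile7(g, 0.5),
       lq = oracle_quantile7(g, 0.25),
       uq = oracle_quantile7(g, 0.75),
       min = min(g), max = max(g))
}

# Elemental-ratio filter then argmin |ppm|, by explicit enumeration.
oracle_best_formula <- function(formulas, ppm) {
  counts <- function(f) {
    toks <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1]]
    if (paste(toks, collapse = "") != f || !nzchar(f)) return(NULL)
    out <- c(C = 0, H = 0, N = 0, O = 0, S = 0, Cl = 0, X = 0)
    for (tok in toks) {
      el <- gsub("[0-9]", "", tok)
      k <- gsub("[A-Za-z]", "", tok)
      k <- if (nzchar(k)) as.numeric(k) else 1
      if (el %in% names(out)) out[el] <- out[el] + k else out["X"] <- out["X"] + k
    }
    out
  }
  passes <- function(f) {
    ct <- counts(f)
    if (is.null(ct) || ct["C"] == 0) return(FALSE)
    hc <- ct["H"] / ct["C"]; oc <- ct["O"] / ct["C"]
    hc > 0.5 && hc < 3.0 && oc > 0.05 && oc < 2.0 &&
      ct["N"] / ct["C"] < 1.0 && ct["S"] / ct["C"] < 0.5 &&
      ct["Cl"] / ct["C"] < 0.2
  }
  best <- NA_character_
  best_ppm <- Inf
  for (i in seq_along(formulas)) {
    if (passes(formulas[i]) && is.finite(ppm[i]) && abs(ppm[i]) < best_ppm) {
      best <- formulas[i]
      best_ppm <- abs(ppm[i])
    }
  }
  best
}

# Blank subtraction by explicit per-feature scan; matching by m/z ppm and rt.
oracle_blank_subtract <- function(sample, filter_blank, chamber_blank,
                                  exclusion_formulas, ratio = 10, snr = 3,
                                  ppm_tol = 5, rt_tol = 0.1) {
  blank_area <- function(i, blank) {
    if (is.null(blank) || nrow(blank) == 0) return(NA_real_)
    d <- abs(blank$mz - sample$mz[i]) / sample$mz[i] * 1e6
    hit <- which(d <= ppm_tol & abs(blank$rt - sample$rt[i]) <= rt_tol)
    if (length(hit) == 0) NA_real_ else blank$area[hit[which.min(d[hit])]]
  }
  keep <- rep(TRUE, nrow(sample))
  for (i in seq_len(nrow(sample))) {
    for (blank in list(filter_blank, chamber_blank)) {
      ba <- blank_area(i, blank)
      if (!is.na(ba) && ba > 0 && sample$area[i] / ba < ratio) keep[i] <- FALSE
    }
  }
  for (i in seq_len(nrow(sample))) {
    if (keep[i] && sample$best_formula[i] %in% exclusion_formulas) {
      keep[i] <- FALSE
    }
  }
  for (i in seq_len(nrow(sample))) {
    if (keep[i] && !(sample$snr[i] > snr)) keep[i] <- FALSE
  }
  sample$feature_id[keep]
}

# Greedy duplicate collapse: repeatedly keep the largest-area feature of a
# formula and discard same-formula features within rt_tol of it.
oracle_deduplicate <- function(features, rt_tol = 0.1) {
  survivors <- character()
  for (f in unique(features$best_formula)) {
    if (is.na(f)) next
    grp <- features[!is.na(features$best_formula) & features$best_formula == f, ]
    grp <- grp[order(-grp$area), ]
    while (nrow(grp) > 0) {
      survivors <- c(survivors, grp$feature_id[1])
      grp <- grp[abs(grp$rt - grp$rt[1]) > rt_tol, ]
    }
  }
  no_formula <- features$feature_id[is.na(features$best_formula)]
  c(survivors, no_formula)
}

oracle_within_factor <- function(r, k = 2) {
  hits <- 0
  for (x in r) if (x >= 1 / k && x <= k) hits <- hits + 1
  hits / length(r)
}

# Random generators used across property tests --------------------------------

random_formula_string <- function() {
  els <- c("C", "H", "N", "O", "S", "Cl")
  n <- sample(1:4, 1)
  picked <- sample(els, n)
  paste0(picked, sample(0:12, n, replace = TRUE), collapse = "")
}

random_feature_table <- function(n, id_prefix = "f") {
  tibble::tibble(
    feature_id = sprintf("%s%03d", id_prefix, seq_len(n)),
    mz = stats::runif(n, 100, 500),
    rt = stats::runif(n, 0, 20),
    area = stats::runif(n, 10, 1e6),
    snr = stats::runif(n, 1, 20),
    best_formula = sprintf("C%dH%dO%d", sample(5:12, n, TRUE),
                           sample(6:20, n, TRUE), sample(2:6, n, TRUE))
  )
}
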