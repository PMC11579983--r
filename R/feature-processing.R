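#' Match features between two tables by m/z and retention time
#'
#' For each feature in `x`, finds the feature in `y` whose m/z lies within
#' `ppm_tol` parts per million and whose retention time lies within
#' `rt_tol` minutes. When several candidates match, the one closest in
#' m/z wins (ambiguity beyond the best match is tolerated silently: with
#' a 5 ppm window on centroided Orbitrap data it is rare).
#'
#' @param x,y Feature tibbles with `mz` and `rt` columns.
#' @param ppm_tol m/z tolerance in ppm (default 5).
#' @param rt_tol Retention-time tolerance in minutes (default 0.1).
#' @return Integer vector of length `nrow(x)`: the matching row index in
#'   `y`, or `NA` where nothing matches.
#' @export
match_features <- function(x, y, ppm_tol = 5, rt_tol = 0.1) {
  if (nrow(y) == 0L) {
    return(rep(NA_integer_, nrow(x)))
  }
  vapply(seq_len(nrow(x)), function(i) {
    dppm <- abs(y$mz - x$mz[i]) / x$mz[i] * 1e6
    hit <- which(dppm <= ppm_tol & abs(y$rt - x$rt[i]) <= rt_tol)
    if (length(hit) == 0L) NA_integer_ else hit[which.min(dppm[hit])]
  }, integer(1L))
}

#' Three-step blank subtraction
#'
#' Removes background features from a sample feature table in the printed
#' order: (1) features whose sample-to-blank area ratio is below
#' `ratio_threshold` against either the filter blank or the chamber
#' blank; (2) features matching an explicit exclusion list of known
#' background species (large-signal surfactants and the like that survive
#' step 1); (3) features whose signal-to-noise ratio does not exceed
#' `snr_threshold`. Thresholds are strict as printed: ratio < 10 removes,
#' S/N > 3 keeps (S/N exactly 3 is removed). A blank area of zero gives an
#' infinite ratio, so absence from the blank never removes a feature.
#'
#' @param sample Feature tibble (`feature_id`, `mz`, `rt`, `area`, `snr`,
#'   and `best_formula` if the exclusion list uses formulas).
#' @param filter_blank,chamber_blank Blank feature tibbles (`mz`, `rt`,
#'   `area`), or `NULL` to skip that blank with a warning.
#' @param exclusions Exclusion list tibble with a `formula` column and/or
#'   `mz` + `rt` columns, or `NULL`.
#' @param ratio_threshold Minimum sample/blank area ratio to keep a
#'   matched feature (default 10).
#' @param snr_threshold Signal-to-noise value a feature must exceed
#'   (default 3).
#' @inheritParams match_features
#' @return List with `features` (survivors), `removed` (tibble
#'   `feature_id`, `step`, `reason`) and `ledger` (per-step removal
#'   counts).
#' @export
blank_subtract <- function(sample, filter_blank = NULL, chamber_blank = NULL,
                           exclusions = NULL, ratio_threshold = 10,
                           snr_threshold = 3, ppm_tol = 5, rt_tol = 0.1) {
  stopifnot(all(c("feature_id", "mz", "rt", "area", "snr") %in% names(sample)))
  removed <- tibble::tibble(feature_id = character(), step = integer(),
                            reason = character())
  drop <- function(tab, idx, step, reason) {
    removed <<- dplyr::bind_rows(removed, tibble::tibble(
      feature_id = tab$feature_id[idx], step = step, reason = reason))
    tab[setdiff(seq_len(nrow(tab)), idx), , drop = FALSE]
  }

  # step 1: sample-to-blank ratio against each blank in turn
  blank_ratio <- function(tab, blank) {
    m <- match_features(tab, blank, ppm_tol, rt_tol)
    ratio <- rep(Inf, nrow(tab))
    hit <- !is.na(m)
    ba <- blank$area[m[hit]]
    ratio[hit] <- ifelse(ba > 0, tab$area[hit] / ba, Inf)
    ratio
  }
  for (nm in c("filter_blank", "chamber_blank")) {
    blank <- switch(nm, filter_blank = filter_blank,
                    chamber_blank = chamber_blank)
    if (is.null(blank)) {
      warning("no ", gsub("_", " ", nm),
              " table supplied; ratio check against it skipped")
      next
    }
    low <- which(blank_ratio(sample, blank) < ratio_threshold)
    sample <- drop(sample, low, 1L, paste0("low_ratio_", nm))
  }

  # step 2: explicit exclusion list (formula and/or m/z + rt entries)
  if (!is.null(exclusions) && nrow(exclusions) > 0L) {
    excl <- rep(FALSE, nrow(sample))
    if ("formula" %in% names(exclusions) && "best_formula" %in% names(sample)) {
      f <- exclusions$formula[!is.na(exclusions$formula)]
      excl <- excl | sample$best_formula %in% f
    }
    if (all(c("mz", "rt") %in% names(exclusions))) {
      ex_mz <- exclusions[is.finite(exclusions$mz) & is.finite(exclusions$rt), ]
      if (nrow(ex_mz) > 0L) {
        excl <- excl | !is.na(match_features(sample, ex_mz, ppm_tol, rt_tol))
      }
    }
    sample <- drop(sample, which(excl), 2L, "exclusion_list")
  }

  # step 3: signal-to-noise gate (S/N must strictly exceed the threshold)
  sample <- drop(sample, which(!(sample$snr > snr_threshold)), 3L, "low_snr")

  ledger <- removed |>
    dplyr::count(.data$step, name = "n_removed") |>
    dplyr::right_join(tibble::tibble(step = 1:3), by = "step") |>
    dplyr::mutate(n_removed = dplyr::coalesce(.data$n_removed, 0L)) |>
    dplyr::arrange(.data$step)
  list(features = tibble::as_tibble(sample), removed = removed,
       ledger = ledger)
}

#' Merge negative- and positive-mode feature tables
#'
#' A compound detected in both polarities is retained for negative-mode
#' quantification only when its negative-mode peak area strictly exceeds
#' its positive-mode area (i.e. negative ionization is the better of the
#' two). Ties go to positive mode. Matching is by best formula and
#' retention-time tolerance.
#'
#' @param negative,positive Feature tibbles with `best_formula`, `rt`,
#'   `area`.
#' @param rt_tol Retention-time matching tolerance in minutes.
#' @return List with `features` (negative-mode features retained) and
#'   `positive_preferred` (negative features excluded because the
#'   positive-mode area was at least as large).
#' @export
merge_polarity <- function(negative, positive, rt_tol = 0.1) {
  stopifnot(all(c("best_formula", "rt", "area") %in% names(negative)))
  if (is.null(positive) || nrow(positive) == 0L) {
    return(list(features = tibble::as_tibble(negative),
                positive_preferred = negative[0L, , drop = FALSE]))
  }
  best_pos_area <- vapply(seq_len(nrow(negative)), function(i) {
    f <- negative$best_formula[i]
    if (is.na(f)) {
      return(NA_real_)
    }
    hit <- !is.na(positive$best_formula) & positive$best_formula == f &
      abs(positive$rt - negative$rt[i]) <= rt_tol
    if (!any(hit)) NA_real_ else max(positive$area[hit])
  }, numeric(1L))
  keep <- is.na(best_pos_area) | negative$area > best_pos_area
  list(features = tibble::as_tibble(negative[keep, , drop = FALSE]),
       positive_preferred = tibble::as_tibble(negative[!keep, , drop = FALSE]))
}

#' Collapse duplicated features
#'
#' Features sharing a best formula with retention times within `rt_tol`
#' of each other are alignment duplicates of one compound; isomers of the
#' same formula at distinct retention times are kept apart. Within each
#' formula the rule is greedy by peak area: the largest-area feature
#' absorbs every same-formula feature within `rt_tol` of it, then the
#' next-largest remaining, and so on.
#'
#' @param features Feature tibble with `feature_id`, `best_formula`,
#'   `rt`, `area`.
#' @param rt_tol Retention-time tolerance in minutes (default 0.1).
#' @return List with `features` (survivors, original order) and
#'   `collapsed` (tibble `feature_id`, `absorbed_by`).
#' @export
deduplicate <- function(features, rt_tol = 0.1) {
  stopifnot(all(c("feature_id", "best_formula", "rt", "area")
                %in% names(features)))
  drop_ids <- character()
  absorbed_by <- character()
  for (f in unique(features$best_formula)) {
    if (is.na(f)) next
    idx <- which(!is.na(features$best_formula) & features$best_formula == f)
    if (length(idx) < 2L) next
    pending <- idx[order(-features$area[idx])]
    while (length(pending) > 0L) {
      keeper <- pending[1L]
      near <- pending[abs(features$rt[pending] - features$rt[keeper]) <= rt_tol]
      dup <- setdiff(near, keeper)
      drop_ids <- c(drop_ids, features$feature_id[dup])
      absorbed_by <- c(absorbed_by,
                       rep(features$feature_id[keeper], length(dup)))
      pending <- setdiff(pending, near)
    }
  }
  keep <- !(features$feature_id %in% drop_ids)
  list(features = tibble::as_tibble(features[keep, , drop = FALSE]),
       collapsed = tibble::tibble(feature_id = drop_ids,
                                  absorbed_by = absorbed_by))
}

#' Full feature post-processing pipeline
#'
#' Best-formula selection, three-step blank subtraction, duplicate
#' removal and polarity merging, in that order, with a per-stage count
#' ledger.
#'
#' @param sample Raw negative-mode feature tibble with a `candidates`
#'   column.
#' @param positive Optional positive-mode feature tibble (with
#'   `candidates`); `NULL` skips polarity merging.
#' @inheritParams blank_subtract
#' @inheritParams deduplicate
#' @param dup_rt_tol Retention-time tolerance for duplicate collapsing.
#' @return List with `features` (processed table), `stage_counts` (tibble
#'   `stage`, `n_features`), `removed` (blank-subtraction ledger),
#'   `collapsed` and `positive_preferred`.
#' @export
process_features <- function(sample, filter_blank = NULL,
                             chamber_blank = NULL, exclusions = NULL,
                             positive = NULL, ratio_threshold = 10,
                             snr_threshold = 3, ppm_tol = 5, rt_tol = 0.1,
                             dup_rt_tol = 0.1) {
  counts <- list(input = nrow(sample))
  sample <- choose_best_formulas(sample)
  bs <- blank_subtract(sample, filter_blank, chamber_blank, exclusions,
                       ratio_threshold, snr_threshold, ppm_tol, rt_tol)
  counts$blank_subtracted <- nrow(bs$features)
  dd <- deduplicate(bs$features, dup_rt_tol)
  counts$deduplicated <- nrow(dd$features)
  if (!is.null(positive)) {
    positive <- choose_best_formulas(positive)
    mp <- merge_polarity(dd$features, positive, rt_tol)
  } else {
    mp <- list(features = dd$features,
               positive_preferred = dd$features[0L, , drop = FALSE])
  }
  counts$polarity_merged <- nrow(mp$features)
  list(
    features = mp$features,
    stage_counts = tibble::tibble(stage = names(counts),
                                  n_features = unlist(counts, use.names = FALSE)),
    removed = bs$removed,
    collapsed = dd$collapsed,
    positive_preferred = mp$positive_preferred
  )
}
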