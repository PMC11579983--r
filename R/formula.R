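#' Parse molecular formulas into element counts
#'
#' Tokenizes Hill-notation molecular formulas (e.g. `"C6H10O5"`,
#' `"C7H5NO4"`) into per-element atom counts. Only single-token element
#' symbols are supported (no brackets, hydrates or charges): that is the
#' vocabulary of formula candidates exported by small-molecule feature
#' finders.
#'
#' @param formula Character vector of molecular formulas.
#' @return A tibble with one row per input: `formula`, integer columns
#'   `C`, `H`, `N`, `O`, `S`, `Cl`, `other` (total atoms of any other
#'   element) and logical `valid` (`FALSE` for strings that do not parse).
#' @export
#' @examples
#' parse_formula(c("C6H10O5", "C7H5NO4", "not a formula"))
parse_formula <- function(formula) {
  stopifnot(is.character(formula))
  tracked <- c("C", "H", "N", "O", "S", "Cl")
  parse_one <- function(f) {
    counts <- stats::setNames(numeric(7L), c(tracked, "other"))
    if (is.na(f) || !nzchar(f)) {
      return(c(counts, valid = 0))
    }
    toks <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1L]]
    if (paste(toks, collapse = "") != f) {
      return(c(counts, valid = 0))
    }
    for (tok in toks) {
      el <- sub("[0-9]*$", "", tok)
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(n)) as.numeric(n) else 1
      if (el %in% tracked) {
        counts[el] <- counts[el] + n
      } else {
        counts["other"] <- counts["other"] + n
      }
    }
    c(counts, valid = 1)
  }
  mat <- t(vapply(formula, parse_one, numeric(8L), USE.NAMES = FALSE))
  colnames(mat) <- c(tracked, "other", "valid")
  out <- tibble::as_tibble(mat)
  out$valid <- out$valid > 0
  tibble::tibble(formula = formula) |> dplyr::bind_cols(out)
}

#' Classify a molecular formula into a quantification class
#'
#' Compound classes drive which calibration windows apply: `CHO` (carbon,
#' hydrogen, oxygen only), `CHON` (adds nitrogen), `CHOS` (adds sulfur).
#' Anything else -- no carbon, both N and S, halogens, unparsable strings --
#' is `"other"` and is excluded from quantification.
#'
#' @param formula Character vector of molecular formulas.
#' @return Character vector of the same length with values `"CHO"`,
#'   `"CHON"`, `"CHOS"` or `"other"`.
#' @export
#' @examples
#' classify_formula(c("C6H10O5", "C7H5NO4", "C10H16O5S", "C2H3NO2S"))
classify_formula <- function(formula) {
  p <- parse_formula(formula)
  out <- rep("other", nrow(p))
  base_ok <- p$valid & p$C > 0 & p$other == 0 & p$Cl == 0
  out[base_ok & p$N == 0 & p$S == 0] <- "CHO"
  out[base_ok & p$N > 0 & p$S == 0] <- "CHON"
  out[base_ok & p$N == 0 & p$S > 0] <- "CHOS"
  out
}

#' Elemental-ratio plausibility filter for formula candidates
#'
#' Applies the ratio bounds used to screen candidate assignments of
#' atmospheric organic compounds: 0.5 < H/C < 3.0, 0.05 < O/C < 2.0,
#' N/C < 1.0, S/C < 0.5 and Cl/C < 0.2, all bounds exclusive. Formulas
#' without carbon, or that fail to parse, fail the filter.
#'
#' @param formula Character vector of molecular formulas.
#' @return Logical vector: does each formula pass every bound?
#' @export
#' @examples
#' element_ratios_ok(c("C6H10O5", "CH4", "C3H2N4O"))
element_ratios_ok <- function(formula) {
  p <- parse_formula(formula)
  with(p, valid & C > 0 &
    H / C > 0.5 & H / C < 3.0 &
    O / C > 0.05 & O / C < 2.0 &
    N / C < 1.0 &
    S / C < 0.5 &
    Cl / C < 0.2)
}

#' Select the best formula among ranked candidates
#'
#' Candidates failing any elemental-ratio bound (see
#' [element_ratios_ok()]) are discarded; among the survivors the candidate
#' with the smallest absolute mass error (ppm) wins. Unparsable candidate
#' strings are skipped with a warning.
#'
#' @param candidates A data frame with columns `formula` (character) and
#'   `ppm_error` (numeric mass deviation in parts per million).
#' @return The winning formula as a length-1 character vector, or `NA`
#'   if no candidate survives the filter.
#' @export
#' @examples
#' select_best_formula(data.frame(
#'   formula = c("C6H10O5", "C3H2N4O"),
#'   ppm_error = c(1.2, 0.8)
#' ))
select_best_formula <- function(candidates) {
  stopifnot(is.data.frame(candidates),
            all(c("formula", "ppm_error") %in% names(candidates)))
  if (nrow(candidates) == 0L) {
    return(NA_character_)
  }
  parsed <- parse_formula(candidates$formula)
  if (any(!parsed$valid)) {
    warning("skipping unparsable formula candidate(s): ",
            paste(unique(candidates$formula[!parsed$valid]), collapse = ", "))
  }
  ok <- element_ratios_ok(candidates$formula) & is.finite(candidates$ppm_error)
  if (!any(ok)) {
    return(NA_character_)
  }
  surv <- candidates[ok, , drop = FALSE]
  surv$formula[which.min(abs(surv$ppm_error))]
}

#' Parse inline candidate strings
#'
#' Feature tables carry formula candidates inline as
#' `"formula:ppm;formula:ppm"` pairs (e.g. `"C6H10O5:1.2;C3H2N4O:0.8"`).
#'
#' @param x Length-1 character string (may be `NA` or empty).
#' @return Tibble with columns `formula`, `ppm_error`, `rank`.
#' @export
parse_candidates <- function(x) {
  empty <- tibble::tibble(formula = character(), ppm_error = numeric(),
                          rank = integer())
  if (length(x) == 0L || is.na(x) || !nzchar(x)) {
    return(empty)
  }
  parts <- strsplit(x, ";", fixed = TRUE)[[1L]]
  parts <- parts[nzchar(trimws(parts))]
  if (length(parts) == 0L) {
    return(empty)
  }
  fields <- strsplit(parts, ":", fixed = TRUE)
  tibble::tibble(
    formula = trimws(vapply(fields, `[`, character(1L), 1L)),
    ppm_error = as.numeric(vapply(fields, `[`, character(1L), 2L)),
    rank = seq_along(parts)
  )
}

#' Format candidate tibbles back to the inline representation
#' @param candidates Tibble as returned by [parse_candidates()].
#' @return Length-1 character string.
#' @export
format_candidates <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    return("")
  }
  paste(sprintf("%s:%g", candidates$formula, candidates$ppm_error),
        collapse = ";")
}

#' Assign the best formula and compound class to each feature
#'
#' Runs [select_best_formula()] over each feature's inline candidate list
#' and derives the compound class of the winner.
#'
#' @param features Feature tibble with a `candidates` column of inline
#'   `formula:ppm;...` strings (see [parse_candidates()]).
#' @return `features` with `best_formula` and `compound_class` columns
#'   filled in.
#' @export
choose_best_formulas <- function(features) {
  stopifnot("candidates" %in% names(features))
  best <- vapply(features$candidates, function(x) {
    select_best_formula(parse_candidates(x))
  }, character(1L), USE.NAMES = FALSE)
  features$best_formula <- best
  features$compound_class <- ifelse(is.na(best), "other",
                                    classify_formula(best))
  features
}
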