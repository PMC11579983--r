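#' Read an aligned feature table from CSV
#'
#' Accepts the exported-CSV conventions of feature-alignment software via
#' an optional column-name dialect map. Mandatory canonical columns are
#' `feature_id`, `mz`, `rt`, `area`, `polarity`, `snr`; `candidates` and
#' `level1_id` are optional. Rows with unparsable or missing mandatory
#' values are collected into a problem report, never silently dropped.
#'
#' @param path CSV file path.
#' @param dialect Optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(mz = "row m/z", rt = "row retention time")`.
#' @return List with `features` (validated tibble) and `problems`
#'   (tibble `row`, `issue` for rejected rows).
#' @export
read_feature_table <- function(path, dialect = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      if (dialect[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == dialect[[canon]]] <- canon
      }
    }
  }
  mandatory <- c("feature_id", "mz", "rt", "area", "polarity", "snr")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing) > 0L) {
    stop("feature table ", path, " lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in c("mz", "rt", "area", "snr")) {
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  raw$feature_id <- as.character(raw$feature_id)
  bad <- !is.finite(raw$mz) | !is.finite(raw$rt) | !is.finite(raw$area) |
    !is.finite(raw$snr) | is.na(raw$feature_id) |
    !(raw$polarity %in% c("negative", "positive"))
  problems <- tibble::tibble(
    row = which(bad),
    issue = "missing or unparsable mandatory value"
  )
  features <- tibble::as_tibble(raw[!bad, , drop = FALSE])
  if (!"candidates" %in% names(features)) {
    features$candidates <- NA_character_
  }
  if (!"level1_id" %in% names(features)) {
    features$level1_id <- NA_character_
  } else {
    features$level1_id <- dplyr::na_if(as.character(features$level1_id), "")
  }
  list(features = features, problems = problems)
}

#' Read an authentic-standards table
#'
#' Columns: `name`, `formula`, `rt_min`, optionally `compound_class`
#' (derived from the formula otherwise) and `gradient` (precomputed).
#'
#' @param path CSV file path.
#' @return Standards tibble.
#' @export
read_standards <- function(path) {
  raw <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("name", "formula", "rt_min")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0L) {
    stop("standards table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!"compound_class" %in% names(raw)) {
    raw$compound_class <- classify_formula(raw$formula)
  }
  raw
}

#' Read long-format calibration points
#' @param path CSV with columns `name`, `concentration`, `signal` and
#'   optionally `replicate`.
#' @return Tibble of calibration points.
#' @export
read_calibration_points <- function(path) {
  raw <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("name", "concentration", "signal")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0L) {
    stop("calibration points table lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  raw
}

#' Read a retention-time window scheme
#'
#' Either a CSV with columns `compound_class`, `start`, `end`, or a YAML
#' file mapping class names to lists of `[start, end]` pairs:
#' ```yaml
#' CHO: [[0, 1], [1, 2]]
#' CHON: [[0, 3]]
#' ```
#'
#' @param path File path (`.yaml`/`.yml` or CSV).
#' @return Scheme tibble suitable for [build_windows()].
#' @export
read_window_scheme <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    conf <- yaml::read_yaml(path)
    rows <- lapply(names(conf), function(cls) {
      iv <- conf[[cls]]
      tibble::tibble(
        compound_class = cls,
        start = vapply(iv, function(x) as.numeric(x[[1L]]), numeric(1L)),
        end = vapply(iv, function(x) as.numeric(x[[2L]]), numeric(1L))
      )
    })
    return(dplyr::bind_rows(rows))
  }
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write window statistics as CSV and JSON
#' @param stats Tibble from [window_stats()].
#' @param path_csv,path_json Output paths (either may be `NULL`).
#' @return Invisibly, `stats`.
#' @export
write_window_stats <- function(stats, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv)) {
    utils::write.csv(stats, path_csv, row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(stats, path_json, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(stats)
}

#' Run the full semi-quantification pipeline from a config
#'
#' Stages: calibrate (standards + optional raw points + window scheme),
#' process (blank subtraction, deduplication, polarity merge), quantify,
#' and compose; optionally validate when a table of authentic
#' concentrations is supplied. All outputs land in `config$out_dir`
#' together with a JSON run manifest recording thresholds, input paths
#' and per-stage feature counts. The pipeline itself is deterministic;
#' all randomness lives in fixture generation.
#'
#' @param config A named list (or path to a YAML file parsed with
#'   [yaml::read_yaml()]) with elements: `standards`, `sample` (paths,
#'   required); `calibration_points`, `scheme`, `filter_blank`,
#'   `chamber_blank`, `exclusions`, `positive`, `authentic` (paths,
#'   optional); `out_dir` (required); and optional thresholds
#'   `ratio_threshold` (10), `snr_threshold` (3), `ppm_tol` (5),
#'   `rt_tol` (0.1), `dup_rt_tol` (0.1), `r_squared_floor` (0.8),
#'   `unit_factor` (1), `k` (2).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(ratio_threshold = 10, snr_threshold = 3, ppm_tol = 5,
                   rt_tol = 0.1, dup_rt_tol = 0.1, r_squared_floor = 0.8,
                   unit_factor = 1, k = 2)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (nm in c("standards", "sample", "out_dir")) {
    if (is.null(config[[nm]])) stop("config lacks required entry '", nm, "'")
  }
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  read_opt <- function(nm, reader) {
    if (is.null(config[[nm]])) NULL else reader(config[[nm]])
  }

  # calibrate
  standards <- read_standards(config$standards)
  points <- read_opt("calibration_points", read_calibration_points)
  scheme <- read_opt("scheme", read_window_scheme)
  cal <- calibrate(standards, points, scheme,
                   r_squared_floor = config$r_squared_floor)
  utils::write.csv(cal$curves, file.path(out, "curves.csv"),
                   row.names = FALSE)
  write_window_stats(cal$stats, file.path(out, "window_stats.csv"),
                     file.path(out, "window_stats.json"))

  # process
  sample_tab <- read_feature_table(config$sample)
  blanks <- function(nm) {
    if (is.null(config[[nm]])) {
      return(NULL)
    }
    tibble::as_tibble(utils::read.csv(config[[nm]], stringsAsFactors = FALSE))
  }
  exclusions <- read_opt("exclusions", function(p) {
    tibble::as_tibble(utils::read.csv(p, stringsAsFactors = FALSE))
  })
  positive <- if (is.null(config$positive)) NULL else
    read_feature_table(config$positive)$features
  proc <- process_features(
    sample_tab$features, blanks("filter_blank"), blanks("chamber_blank"),
    exclusions, positive,
    ratio_threshold = config$ratio_threshold,
    snr_threshold = config$snr_threshold,
    ppm_tol = config$ppm_tol, rt_tol = config$rt_tol,
    dup_rt_tol = config$dup_rt_tol
  )
  utils::write.csv(proc$features, file.path(out, "processed_features.csv"),
                   row.names = FALSE)

  # quantify
  quant <- quantify_features(proc$features, cal$stats, cal$windows,
                             cal$curves, cal$chos_gradient,
                             unit_factor = config$unit_factor)
  utils::write.csv(quant$results, file.path(out, "quant_results.csv"),
                   row.names = FALSE)
  utils::write.csv(quant$unquantified, file.path(out, "unquantified.csv"),
                   row.names = FALSE)

  # compose
  comp <- composition_summary(quant$results)
  utils::write.csv(comp$mass_abundance,
                   file.path(out, "mass_abundance.csv"), row.names = FALSE)
  utils::write.csv(comp$area_abundance,
                   file.path(out, "area_abundance.csv"), row.names = FALSE)
  utils::write.csv(comp$gap, file.path(out, "abundance_gap.csv"),
                   row.names = FALSE)
  utils::write.csv(comp$bulk, file.path(out, "bulk_descriptors.csv"),
                   row.names = FALSE)

  # validate (optional)
  validation <- NULL
  if (!is.null(config$authentic)) {
    records <- tibble::as_tibble(utils::read.csv(config$authentic,
                                                 stringsAsFactors = FALSE))
    validation <- validation_report(records, k = config$k)
    utils::write.csv(validation$per_compound,
                     file.path(out, "validation_per_compound.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ntaquant")),
    thresholds = config[names(defaults)],
    inputs = config[intersect(names(config),
                              c("standards", "calibration_points", "scheme",
                                "sample", "filter_blank", "chamber_blank",
                                "exclusions", "positive", "authentic"))],
    stage_counts = stats::setNames(as.list(proc$stage_counts$n_features),
                                   proc$stage_counts$stage),
    n_quantified = nrow(quant$results),
    n_unquantified = nrow(quant$unquantified),
    n_windows = nrow(cal$windows),
    n_usable_curves = sum(cal$curves$usable),
    validation = if (is.null(validation)) NULL else list(
      median_error = validation$median_error,
      mean_error = validation$mean_error,
      fraction_within_factor = validation$fraction_within_factor,
      k = validation$k, n = validation$n
    )
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(manifest)
}
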