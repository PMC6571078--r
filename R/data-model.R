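# Core record schema, reading, validation and writing of the observation table.

#' @keywords internal
"_PACKAGE"

## Canonical enumerations for the observation schema.
.sex_levels         <- c("male", "female")
.environment_levels <- c("aquatic", "terrestrial")
.voltinism_levels   <- c("semelvoltine_or_less", "multivoltine")
.gradient_levels    <- c("latitude", "altitude", "seasonal_temperature")
.metric_levels      <- c("dry_mass", "wet_mass", "length", "volume", "other_mass")

.obs_required_cols <- c(
  "study_id", "class", "order", "family", "species", "sex", "environment",
  "voltinism", "gradient_type", "gradient_value", "size_metric", "size_value"
)

#' Read a body-size observation table
#'
#' Reads a delimited text file of sex-specific body-size records (one row per
#' population-mean observation at one gradient position within one study) into
#' the canonical observation data frame used by the whole pipeline.
#'
#' @param path Path to a CSV file (UTF-8, header row).
#' @param schema_config Optional named character vector mapping canonical
#'   column names (names of the vector) to the column names actually present
#'   in the file. Columns not mentioned are assumed to carry their canonical
#'   name already.
#'
#' @return A `data.frame` with columns `study_id`, `class`, `order`, `family`,
#'   `species`, `sex`, `environment`, `voltinism`, `gradient_type`,
#'   `gradient_value`, `size_metric`, `size_value` and, when present in the
#'   file, `conversion_id` and `dry_mass_mg`.
#'
#' @details Enumerated columns are checked against their closed label sets
#'   (`sex`: male/female; `environment`: aquatic/terrestrial; `voltinism`:
#'   semelvoltine_or_less/multivoltine; `gradient_type`: latitude/altitude/
#'   seasonal_temperature; `size_metric`: dry_mass/wet_mass/length/volume/
#'   other_mass). Unknown labels and non-numeric size or gradient values are
#'   reported as row-level errors; a missing required column is a schema error
#'   naming the column.
#' @export
read_observations <- function(path, schema_config = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema_config)) {
    for (canonical in names(schema_config)) {
      actual <- schema_config[[canonical]]
      if (!actual %in% names(raw))
        stop("schema error: mapped column '", actual, "' (for '", canonical,
             "') not present in file")
      names(raw)[names(raw) == actual] <- canonical
    }
  }
  missing <- setdiff(.obs_required_cols, names(raw))
  if (length(missing))
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "))

  obs <- raw[, intersect(c(.obs_required_cols, "conversion_id", "dry_mass_mg"),
                         names(raw)), drop = FALSE]
  for (col in c("study_id", "class", "order", "family", "species", "sex",
                "environment", "voltinism", "gradient_type", "size_metric"))
    obs[[col]] <- as.character(obs[[col]])

  problems <- character(0)
  check_enum <- function(col, levels) {
    bad <- which(!obs[[col]] %in% levels)
    if (length(bad))
      problems <<- c(problems, paste0(
        "row ", bad, ": unknown ", col, " label '", obs[[col]][bad], "'"))
  }
  check_enum("sex", .sex_levels)
  check_enum("environment", .environment_levels)
  check_enum("voltinism", .voltinism_levels)
  check_enum("gradient_type", .gradient_levels)
  check_enum("size_metric", .metric_levels)

  for (col in c("gradient_value", "size_value")) {
    val <- suppressWarnings(as.numeric(obs[[col]]))
    bad <- which(is.na(val) & !is.na(obs[[col]]))
    if (length(bad))
      problems <- c(problems, paste0(
        "row ", bad, ": non-numeric ", col, " '", obs[[col]][bad], "'"))
    obs[[col]] <- val
  }
  if (length(problems))
    stop("row-level parse errors:\n", paste(problems, collapse = "\n"))
  rownames(obs) <- NULL
  obs
}

#' Write an observation table
#'
#' Inverse of [read_observations()]: writes the canonical observation data
#' frame back to CSV so that a write-then-read round trip is the identity on
#' record content.
#'
#' @param obs Observation data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(obs, path, row.names = FALSE)
  invisible(path)
}

#' Validate a body-size observation table
#'
#' Checks the structural rules the downstream analysis relies on: both sexes
#' measured within every cline group (the sexes are only compared within
#' single studies), at least three distinct gradient positions per sex-specific
#' cline (below three the slope-variance weight is undefined), strictly
#' positive sizes, a single gradient type per study, and multivoltinism for
#' every seasonal-temperature record (seasonal clines are only meaningful for
#' species with multiple generations per year).
#'
#' @param obs Observation data frame as returned by [read_observations()].
#' @return An object of class `validation_report`: a list with `n_records`,
#'   `n_clines` (distinct study x species x sex x gradient-type groups),
#'   `errors` and `warnings` (character vectors). A dataset whose report
#'   carries errors is rejected by the downstream stages.
#' @export
validate_dataset <- function(obs) {
  stopifnot(is.data.frame(obs), nrow(obs) > 0)
  errors <- character(0)
  warnings <- character(0)

  bad_size <- which(!is.finite(obs$size_value) | obs$size_value <= 0)
  if (length(bad_size))
    errors <- c(errors, paste0("row ", bad_size, ": non-positive size_value"))
  if ("dry_mass_mg" %in% names(obs)) {
    bad_dm <- which(!is.na(obs$dry_mass_mg) & obs$dry_mass_mg <= 0)
    if (length(bad_dm))
      errors <- c(errors, paste0("row ", bad_dm, ": non-positive dry_mass_mg"))
  }

  bad_volt <- which(obs$gradient_type == "seasonal_temperature" &
                      obs$voltinism != "multivoltine")
  if (length(bad_volt))
    errors <- c(errors, paste0(
      "row ", bad_volt,
      ": seasonal_temperature cline requires multivoltine species"))

  ## One gradient type per study.
  gt_per_study <- tapply(obs$gradient_type, obs$study_id,
                         function(g) length(unique(g)))
  mixed <- names(gt_per_study)[gt_per_study > 1]
  if (length(mixed))
    errors <- c(errors, paste0("study ", sort(mixed),
                               ": mixed gradient_type within one study"))

  ## Both sexes present per cline group (study x species x gradient type).
  pair_key <- paste(obs$study_id, obs$species, obs$gradient_type, sep = "\r")
  sexes <- tapply(obs$sex, pair_key, function(s) length(unique(s)))
  lone <- names(sexes)[sexes < 2]
  if (length(lone)) {
    parts <- strsplit(sort(lone), "\r", fixed = TRUE)
    errors <- c(errors, vapply(parts, function(p) paste0(
      "study ", p[1], ", species ", p[2], " (", p[3],
      "): missing counterpart sex"), character(1)))
  }

  ## >= 3 distinct gradient levels per sex-specific cline.
  cline_key <- paste(obs$study_id, obs$species, obs$sex, obs$gradient_type,
                     sep = "\r")
  n_levels <- tapply(obs$gradient_value, cline_key,
                     function(x) length(unique(x)))
  thin <- names(n_levels)[n_levels < 3]
  if (length(thin)) {
    parts <- strsplit(sort(thin), "\r", fixed = TRUE)
    errors <- c(errors, vapply(parts, function(p) paste0(
      "study ", p[1], ", species ", p[2], ", ", p[3], " (", p[4],
      "): insufficient gradient levels (< 3 distinct)"), character(1)))
  }

  structure(
    list(n_records = nrow(obs),
         n_clines = length(unique(cline_key)),
         errors = sort(errors),
         warnings = warnings),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Body-size dataset validation report\n")
  cat("  records:", x$n_records, "  clines:", x$n_clines, "\n")
  cat("  errors:", length(x$errors), "  warnings:", length(x$warnings), "\n")
  if (length(x$errors)) cat(paste0("  - ", x$errors, collapse = "\n"), "\n")
  invisible(x)
}

#' Write a validation report as JSON
#'
#' @param report A `validation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
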