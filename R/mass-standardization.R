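# Conversion of heterogeneous size metrics to dry mass (mg) via a registry of
# published regressions.

.conversion_forms <- c("identity", "power_law", "log_log_linear", "dry_fraction")

#' Build a single mass-conversion record
#'
#' A conversion maps one size metric to dry mass in mg. Supported forms:
#' `identity` (input already mg dry mass), `power_law` (`a * L^b`, the usual
#' length-mass allometry with length in mm), `log_log_linear`
#' (`exp(a + b * ln L)` -- the same model parameterised on the log scale) and
#' `dry_fraction` (`a * wet_mass`, `0 < a <= 1`).
#'
#' @param conversion_id Identifier referenced from the observation table.
#' @param form One of `identity`, `power_law`, `log_log_linear`,
#'   `dry_fraction`.
#' @param a,b Coefficients; `b` is ignored for `identity` and `dry_fraction`.
#' @param input_metric Size metric the conversion applies to.
#' @param source_note Free-text provenance (literature source, units).
#' @return A list of class `mass_conversion`.
#' @export
mass_conversion <- function(conversion_id, form, a = NA_real_, b = NA_real_,
                            input_metric, source_note = "") {
  form <- match.arg(form, .conversion_forms)
  input_metric <- match.arg(input_metric, .metric_levels)
  if (form %in% c("power_law") && (!is.finite(a) || a <= 0))
    stop("power_law conversion requires coefficient a > 0")
  if (form == "dry_fraction" && (!is.finite(a) || a <= 0 || a > 1))
    stop("dry_fraction conversion requires 0 < a <= 1")
  if (form == "identity" && input_metric != "dry_mass")
    stop("identity conversion requires input already in mg dry mass")
  structure(list(conversion_id = as.character(conversion_id), form = form,
                 a = a, b = b, input_metric = input_metric,
                 source_note = source_note),
            class = "mass_conversion")
}

#' Read a conversion registry from CSV or YAML
#'
#' The registry file has fields `conversion_id`, `form`, `a`, `b`,
#' `input_metric`, `source_note` (CSV columns, or a YAML list of mappings).
#'
#' @param path Registry file; format decided by extension (`.yml`/`.yaml`
#'   vs anything else = CSV).
#' @return A named list of `mass_conversion` objects keyed by `conversion_id`.
#' @export
read_conversion_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    rows <- yaml::read_yaml(path)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  }
  reg <- lapply(rows, function(r) mass_conversion(
    conversion_id = r$conversion_id, form = r$form,
    a = if (is.null(r$a)) NA_real_ else as.numeric(r$a),
    b = if (is.null(r$b)) NA_real_ else as.numeric(r$b),
    input_metric = r$input_metric,
    source_note = if (is.null(r$source_note)) "" else r$source_note))
  names(reg) <- vapply(reg, `[[`, character(1), "conversion_id")
  if (anyDuplicated(names(reg)))
    stop("duplicate conversion_id in registry")
  reg
}

#' Convert one size value to dry mass (mg)
#'
#' @param size_value Positive size in the metric's native units.
#' @param size_metric The metric of `size_value`.
#' @param conv A `mass_conversion` whose `input_metric` matches.
#' @return Dry mass in mg (always positive).
#' @export
to_dry_mass <- function(size_value, size_metric, conv) {
  stopifnot(inherits(conv, "mass_conversion"))
  if (!identical(size_metric, conv$input_metric))
    stop("configuration error: conversion '", conv$conversion_id,
         "' expects metric '", conv$input_metric, "', got '", size_metric, "'")
  if (any(!is.finite(size_value) | size_value <= 0))
    stop("size_value must be positive and finite")
  out <- switch(conv$form,
    identity       = size_value,
    power_law      = conv$a * size_value ^ conv$b,
    log_log_linear = exp(conv$a + conv$b * log(size_value)),
    dry_fraction   = conv$a * size_value)
  stopifnot(all(out > 0))
  out
}

#' Fill `dry_mass_mg` for a whole observation table
#'
#' Rows whose `size_metric` is already `dry_mass` and which carry no
#' `conversion_id` are taken as-is; every other row must reference a registered
#' conversion through its `conversion_id` column.
#'
#' @param obs Observation data frame.
#' @param registry Named list from [read_conversion_registry()] (may be empty
#'   for an all-dry-mass dataset).
#' @return `obs` with a `dry_mass_mg` column filled for every row and a
#'   `conversion_id` column recording provenance (`"identity"` where no
#'   conversion was applied).
#' @export
apply_conversions <- function(obs, registry = list()) {
  if (!"conversion_id" %in% names(obs)) obs$conversion_id <- NA_character_
  obs$conversion_id <- as.character(obs$conversion_id)
  blank <- is.na(obs$conversion_id) | obs$conversion_id == ""
  native_dry <- blank & obs$size_metric == "dry_mass"

  unresolved <- blank & !native_dry
  if (any(unresolved)) {
    pairs <- unique(paste0(obs$species[unresolved], " [",
                           obs$size_metric[unresolved], "]"))
    stop("no registered conversion for: ", paste(sort(pairs), collapse = "; "))
  }
  unknown <- !blank & !obs$conversion_id %in% names(registry)
  if (any(unknown))
    stop("unknown conversion_id: ",
         paste(sort(unique(obs$conversion_id[unknown])), collapse = ", "))

  obs$dry_mass_mg <- NA_real_
  obs$dry_mass_mg[native_dry] <- obs$size_value[native_dry]
  obs$conversion_id[native_dry] <- "identity"
  for (id in unique(obs$conversion_id[!blank])) {
    rows <- which(!blank & obs$conversion_id == id)
    conv <- registry[[id]]
    metrics <- unique(obs$size_metric[rows])
    if (length(metrics) != 1L || metrics != conv$input_metric)
      stop("configuration error: conversion '", id, "' applied to metric(s) ",
           paste(metrics, collapse = ", "), " but expects '",
           conv$input_metric, "'")
    obs$dry_mass_mg[rows] <- to_dry_mass(obs$size_value[rows], metrics, conv)
  }
  stopifnot(all(is.finite(obs$dry_mass_mg) & obs$dry_mass_mg > 0))
  obs
}
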