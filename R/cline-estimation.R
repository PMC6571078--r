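# Exponential (log-linear) body-size cline fitting and the percent-change
# transform of slopes.

#' Reporting unit scale for a gradient type
#'
#' Percent size change is reported per degree latitude, per degree C of
#' seasonal temperature, and per 150 m of elevation (a 150 m rise approximates
#' a 1 degree C cooling), so altitudinal slopes (per metre) are multiplied by
#' 150 before exponentiation.
#'
#' @param gradient_type One of `latitude`, `altitude`, `seasonal_temperature`.
#' @return The multiplier applied to the per-native-unit slope (1 or 150).
#' @export
unit_scale_for <- function(gradient_type) {
  gradient_type <- match.arg(gradient_type, .gradient_levels)
  if (gradient_type == "altitude") 150 else 1
}

#' Fit one exponential body-size cline
#'
#' Ordinary least squares of `ln(dry_mass_mg)` on the gradient value for a
#' single study x species x sex series. The exponential form measures relative
#' size change and is unbiased by absolute size differences between the sexes.
#'
#' @param gradient_value Numeric gradient positions (>= 3 distinct values).
#' @param dry_mass_mg Positive dry masses (mg), same length.
#' @param conf_level Confidence level for the slope interval (default 0.95).
#' @return A list of class `cline_fit`: `slope` (per native gradient unit),
#'   `intercept` (ln mg), `slope_variance` (residual mean square /
#'   sum((x - xbar)^2)), `n_points`, `residual_df`, `r_squared`,
#'   `ci_low`/`ci_high` (t-based slope bounds), and the observed
#'   `gradient_min`/`gradient_max`.
#' @export
fit_cline <- function(gradient_value, dry_mass_mg, conf_level = 0.95) {
  stopifnot(length(gradient_value) == length(dry_mass_mg))
  keep <- is.finite(gradient_value) & is.finite(dry_mass_mg)
  x <- gradient_value[keep]
  m <- dry_mass_mg[keep]
  if (length(x) < 3) stop("cline fit needs >= 3 points")
  if (length(unique(x)) < 3) stop("cline fit needs >= 3 distinct gradient values")
  if (any(m <= 0)) stop("dry masses must be positive")
  y <- log(m)

  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  df <- length(x) - 2L
  sxx <- sum((x - mean(x))^2)
  ms_res <- sum(res^2) / df
  slope_var <- ms_res / sxx
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  se <- sqrt(slope_var)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)

  structure(list(
    slope = unname(cf[2]), intercept = unname(cf[1]),
    slope_variance = slope_var, n_points = length(x), residual_df = df,
    r_squared = r2,
    ci_low = unname(cf[2]) - tcrit * se, ci_high = unname(cf[2]) + tcrit * se,
    gradient_min = min(x), gradient_max = max(x)),
    class = "cline_fit")
}

#' @export
print.cline_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential size cline: slope %.5g (var %.3g, n = %d, r2 = %.3f)\n",
    x$slope, x$slope_variance, x$n_points, x$r_squared))
  invisible(x)
}

#' Transform a ln-mass slope to percent change per reporting unit
#'
#' `(exp(slope * unit_scale) - 1) * 100`: the percent change in dry mass per
#' degree latitude, per degree C, or per 150 m of elevation. Negative values
#' indicate a size decrease along the gradient.
#'
#' @param slope Per-native-unit slope of ln dry mass.
#' @param unit_scale Multiplier from native gradient units to the reporting
#'   unit ([unit_scale_for()]).
#' @return Percent change per reporting unit (always > -100).
#' @export
percent_change <- function(slope, unit_scale = 1) {
  stopifnot(all(is.finite(slope)), is.finite(unit_scale))
  (exp(slope * unit_scale) - 1) * 100
}

#' Inverse of [percent_change()]
#'
#' @param percent Percent change per reporting unit.
#' @param unit_scale As in [percent_change()].
#' @return The per-native-unit slope `ln(1 + percent/100) / unit_scale`.
#' @export
slope_from_percent <- function(percent, unit_scale = 1) {
  log(1 + percent / 100) / unit_scale
}

#' Predicted dry mass at a gradient position
#'
#' Evaluates a fitted cline at (typically) the study's gradient midpoint to
#' obtain the mean body mass used for the dimorphism index and as the
#' species-size covariate.
#'
#' @param fit A `cline_fit`.
#' @param gradient_midpoint Position in native gradient units; a warning (not
#'   an error) is raised outside the observed range.
#' @return Predicted dry mass in mg: `exp(intercept + slope * midpoint)`.
#' @export
species_mid_mass <- function(fit, gradient_midpoint) {
  stopifnot(inherits(fit, "cline_fit"), is.finite(gradient_midpoint))
  if (gradient_midpoint < fit$gradient_min ||
      gradient_midpoint > fit$gradient_max)
    warning("gradient_midpoint outside the observed gradient range; ",
            "prediction is an extrapolation")
  exp(fit$intercept + fit$slope * gradient_midpoint)
}

#' Fit every cline in an observation table
#'
#' Groups a standardized observation table by (study_id, species, sex,
#' gradient_type), fits [fit_cline()] per group, and returns one row per
#' cline with its taxonomy and covariates carried along. Groups with fewer
#' than three distinct gradient values are dropped with a warning.
#'
#' @param obs Observation data frame with `dry_mass_mg` filled
#'   (see [apply_conversions()]).
#' @return A `data.frame` with key and taxonomy columns, `slope`, `intercept`,
#'   `slope_variance`, `n_points`, `residual_df`, `r_squared`,
#'   `percent_change_per_unit`, `ci95_low`, `ci95_high`, `gradient_min`,
#'   `gradient_max`, `gradient_mid`.
#' @export
fit_all_clines <- function(obs) {
  stopifnot("dry_mass_mg" %in% names(obs))
  key <- paste(obs$study_id, obs$species, obs$sex, obs$gradient_type,
               sep = "\r")
  groups <- split(seq_len(nrow(obs)), key)
  rows <- lapply(groups, function(idx) {
    g <- obs[idx, ]
    if (length(unique(g$gradient_value)) < 3) return(NULL)
    fit <- fit_cline(g$gradient_value, g$dry_mass_mg)
    scale <- unit_scale_for(g$gradient_type[1])
    data.frame(
      study_id = g$study_id[1], class = g$class[1], order = g$order[1],
      family = g$family[1], species = g$species[1], sex = g$sex[1],
      environment = g$environment[1], voltinism = g$voltinism[1],
      gradient_type = g$gradient_type[1],
      slope = fit$slope, intercept = fit$intercept,
      slope_variance = fit$slope_variance, n_points = fit$n_points,
      residual_df = fit$residual_df, r_squared = fit$r_squared,
      percent_change_per_unit = percent_change(fit$slope, scale),
      ci95_low = fit$ci_low, ci95_high = fit$ci_high,
      gradient_min = fit$gradient_min, gradient_max = fit$gradient_max,
      gradient_mid = (fit$gradient_min + fit$gradient_max) / 2,
      stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    warning(dropped, " cline group(s) with < 3 distinct gradient values ",
            "excluded from fitting")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
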