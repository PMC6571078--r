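# Pairwise sex-comparison statistics: size-cline ratio, sexual dimorphism
# index, inverse-variance weights, sign concordance and the IQR outlier fence.

#' Size cline ratio
#'
#' `(larger size cline / smaller size cline) - 1`, computed on the
#' percent-change-per-unit scale and signed positive when the male response is
#' the greater in magnitude, negative when the female response is greater.
#' The statistic is symmetrical around zero regardless of which sex responds
#' more, and compares proportional (not absolute) size change, so it is not
#' inflated in strongly dimorphic species.
#'
#' When the smaller-magnitude cline is exactly zero the ratio is undefined
#' (the quotient diverges); `NA_real_` is returned as a flagged sentinel.
#' Two exactly-zero clines are identical null responses and give 0.
#'
#' @param male_pct,female_pct Percent change in mass per reporting unit for
#'   each sex (vectorised).
#' @return Signed dimensionless ratio; `NA_real_` where undefined.
#' @export
size_cline_ratio <- function(male_pct, female_pct) {
  stopifnot(length(male_pct) == length(female_pct))
  m <- abs(male_pct)
  f <- abs(female_pct)
  out <- ifelse(m >= f, m / f - 1, -(f / m - 1))
  out[m == 0 & f == 0] <- 0
  out[xor(m == 0, f == 0)] <- NA_real_
  out[!is.finite(male_pct) | !is.finite(female_pct)] <- NA_real_
  out
}

#' Sexual Dimorphism Index (Lovich-Gibbons)
#'
#' `(mass of larger sex / mass of smaller sex) - 1`, signed positive when
#' males are the larger sex and negative when females are larger; varies
#' symmetrically around zero and is invariant to mass units.
#'
#' @param male_mass_mg,female_mass_mg Positive masses (vectorised); any
#'   common unit.
#' @return Signed dimensionless index.
#' @export
sdi <- function(male_mass_mg, female_mass_mg) {
  stopifnot(length(male_mass_mg) == length(female_mass_mg))
  if (any(!is.finite(male_mass_mg) | male_mass_mg <= 0 |
          !is.finite(female_mass_mg) | female_mass_mg <= 0))
    stop("masses must be positive and finite")
  ifelse(male_mass_mg >= female_mass_mg,
         male_mass_mg / female_mass_mg - 1,
         -(female_mass_mg / male_mass_mg - 1))
}

#' Inverse-variance weight for a cline pair
#'
#' Ratios derived from noisier slope estimates carry less information; each
#' pair is weighted by the inverse of the variance of the size-cline slopes it
#' was calculated from. The default combiner is the sum of the two sexes'
#' slope variances (the variance of the slope difference, down-weighting pairs
#' where either sex is noisy); `"mean"` is offered as an alternative.
#'
#' @param male_variance,female_variance Slope variances (vectorised).
#' @param combiner `"sum"` (default) or `"mean"`.
#' @param max_weight Cap applied (with a warning) when both variances are
#'   exactly zero, i.e. both clines fit perfectly.
#' @return Positive weights.
#' @export
cline_weight <- function(male_variance, female_variance,
                         combiner = c("sum", "mean"), max_weight = 1e6) {
  combiner <- match.arg(combiner)
  stopifnot(all(is.finite(male_variance)), all(is.finite(female_variance)),
            all(male_variance >= 0), all(female_variance >= 0))
  v <- male_variance + female_variance
  if (combiner == "mean") v <- v / 2
  w <- ifelse(v > 0, 1 / v, Inf)
  if (any(v == 0)) {
    warning("weight capped at max_weight for pair(s) whose clines both fit ",
            "exactly (zero slope variance)")
    w[v == 0] <- max_weight
  }
  w
}

#' Classify sign concordance of a cline pair
#'
#' A pair is concordant when the male and female slopes share a sign (an
#' exactly-zero slope matches either sign); otherwise it is discordant,
#' sub-classified by how many of the two 95% slope confidence intervals
#' exclude zero.
#'
#' @param male_slope,female_slope Fitted slopes.
#' @param male_ci,female_ci Length-2 numeric `c(low, high)` slope confidence
#'   intervals.
#' @return One of `"concordant"`, `"discordant_both_ns"`,
#'   `"discordant_one_ns"`, `"discordant_both_sig"`.
#' @export
classify_concordance <- function(male_slope, female_slope, male_ci, female_ci) {
  if (male_slope == 0 || female_slope == 0 ||
      sign(male_slope) == sign(female_slope))
    return("concordant")
  excludes <- function(ci) ci[1] > 0 || ci[2] < 0
  n_sig <- excludes(male_ci) + excludes(female_ci)
  switch(n_sig + 1L,
         "discordant_both_ns", "discordant_one_ns", "discordant_both_sig")
}

#' Build matched male-female cline pairs
#'
#' Joins the male and female fits of each (study, species, gradient type)
#' group and computes the pair statistics: percent changes, size-cline ratio,
#' SDI from the predicted masses of both sexes at the study's gradient
#' midpoint, inverse-variance weight, mean species mass (female midpoint
#' mass), gradient direction (sign of the female percent change, falling back
#' to the male's when the female slope is exactly zero), and the concordance
#' class.
#'
#' @param fits Data frame from [fit_all_clines()].
#' @param weight_combiner Passed to [cline_weight()].
#' @param max_weight Passed to [cline_weight()].
#' @return A `data.frame`, one row per pair, with `size_cline_ratio` set to
#'   `NA` (and `ratio_defined = FALSE`) for undefined-sentinel pairs.
#' @export
build_cline_pairs <- function(fits, weight_combiner = "sum",
                              max_weight = 1e6) {
  males <- fits[fits$sex == "male", ]
  females <- fits[fits$sex == "female", ]
  key <- function(d) paste(d$study_id, d$species, d$gradient_type, sep = "\r")
  mk <- key(males); fk <- key(females)
  shared <- intersect(mk, fk)
  males <- males[match(shared, mk), ]
  females <- females[match(shared, fk), ]
  if (!nrow(males)) return(NULL)

  mid <- (pmin(males$gradient_min, females$gradient_min) +
          pmax(males$gradient_max, females$gradient_max)) / 2
  male_mid_mass <- exp(males$intercept + males$slope * mid)
  female_mid_mass <- exp(females$intercept + females$slope * mid)

  ratio <- size_cline_ratio(males$percent_change_per_unit,
                            females$percent_change_per_unit)
  fem_pct <- females$percent_change_per_unit
  direction <- ifelse(fem_pct != 0, ifelse(fem_pct > 0, "positive", "negative"),
                      ifelse(males$percent_change_per_unit >= 0,
                             "positive", "negative"))
  concordance <- vapply(seq_len(nrow(males)), function(i) {
    classify_concordance(males$slope[i], females$slope[i],
                         c(males$ci95_low[i], males$ci95_high[i]),
                         c(females$ci95_low[i], females$ci95_high[i]))
  }, character(1))

  out <- data.frame(
    study_id = males$study_id, class = males$class, order = males$order,
    family = males$family, species = males$species,
    gradient_type = males$gradient_type,
    male_percent = males$percent_change_per_unit,
    female_percent = females$percent_change_per_unit,
    male_slope = males$slope, female_slope = females$slope,
    male_slope_variance = males$slope_variance,
    female_slope_variance = females$slope_variance,
    size_cline_ratio = ratio,
    ratio_defined = !is.na(ratio),
    sdi = sdi(male_mid_mass, female_mid_mass),
    weight = cline_weight(males$slope_variance, females$slope_variance,
                          combiner = weight_combiner,
                          max_weight = max_weight),
    mean_species_mass_mg = female_mid_mass,
    environment = males$environment, voltinism = males$voltinism,
    gradient_direction = direction,
    concordance = concordance,
    is_outlier = FALSE,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Interquartile-range outlier fence for size-cline ratios
#'
#' Single-pass exclusion of extreme ratios: values below `Q1 - 1.5 IQR` or
#' above `Q3 + 1.5 IQR` are removed, with quartiles by linear interpolation
#' between order statistics ([stats::quantile()] type 7). Undefined-sentinel
#' ratios (`NA`) are always removed. Fences are computed once from the full
#' set and not re-derived after removal.
#'
#' @param pairs Cline-pair data frame for one gradient type
#'   (see [build_cline_pairs()]).
#' @param k Fence multiplier (default 1.5).
#' @return A list with `kept` and `removed` data frames (removed rows have
#'   `is_outlier = TRUE`), and `fences = c(lower, upper)`. With fewer than 4
#'   finite ratios the input passes through unfiltered with a warning
#'   (sentinels are still removed).
#' @export
iqr_outlier_filter <- function(pairs, k = 1.5) {
  r <- pairs$size_cline_ratio
  finite <- is.finite(r)
  if (sum(finite) < 4) {
    warning("fewer than 4 finite ratios; outlier fence not applied")
    kept <- pairs[finite, ]
    removed <- pairs[!finite, ]
    if (nrow(removed)) removed$is_outlier <- FALSE  # sentinels, not fenced
    return(list(kept = kept, removed = removed,
                fences = c(-Inf, Inf)))
  }
  q <- stats::quantile(r[finite], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lower <- q[1] - k * iqr
  upper <- q[2] + k * iqr
  out <- !finite | r < lower | r > upper
  removed <- pairs[out, ]
  if (nrow(removed)) removed$is_outlier <- is.finite(removed$size_cline_ratio)
  list(kept = pairs[!out, ], removed = removed, fences = c(lower, upper))
}
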