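# Allometric comparison of the sexes' size plasticity: reduced major axis
# regression of log10 male size on log10 female size, slope-classification
# counts with a continuity-corrected chi-square, and coefficients of
# variation among environments.

#' Reduced major axis regression of male on female size
#'
#' RMA line through matched (log10 female mass, log10 male mass) points:
#' slope = sign(correlation) x sd(male)/sd(female), intercept through the
#' means. With male size on the y axis, a slope below 1 means females are the
#' more size-responsive (plastic) sex, above 1 males.
#'
#' @param female_log10,male_log10 Matched log10 sizes (>= 3 pairs, nonzero
#'   variance in both).
#' @return A list of class `rma_result`: `slope`, `intercept`, `n_pairs`,
#'   `correlation`, `classification` (`female_more_plastic`,
#'   `male_more_plastic`, or `indeterminate` at slope exactly 1).
#' @export
rma_slope <- function(female_log10, male_log10) {
  stopifnot(length(female_log10) == length(male_log10))
  keep <- is.finite(female_log10) & is.finite(male_log10)
  x <- female_log10[keep]; y <- male_log10[keep]
  if (length(x) < 3) stop("RMA needs >= 3 matched pairs")
  sdx <- stats::sd(x); sdy <- stats::sd(y)
  if (sdx == 0 || sdy == 0) stop("zero variance in one sex's sizes")
  r <- stats::cor(x, y)
  slope <- if (r < 0) -sdy / sdx else sdy / sdx
  structure(list(
    slope = slope,
    intercept = mean(y) - slope * mean(x),
    n_pairs = length(x),
    correlation = r,
    classification = if (slope < 1) "female_more_plastic"
                     else if (slope > 1) "male_more_plastic"
                     else "indeterminate"),
    class = "rma_result")
}

#' Chi-square test of equal study counts
#'
#' Goodness-of-fit of two counts against equal expected counts, with the Yates
#' continuity correction on by default:
#' `X^2 = 2 * (max(0, |a - (a+b)/2| - 1/2))^2 / ((a+b)/2)`. With
#' `correct = FALSE` the classical uncorrected statistic
#' `2 * (a - (a+b)/2)^2 / ((a+b)/2)` is returned, for comparison with sources
#' that did not apply the correction.
#'
#' @param count_a,count_b Non-negative integer counts, `count_a + count_b
#'   >= 1`.
#' @param correct Apply the continuity correction (default `TRUE`).
#' @return List with `statistic`, `df` (= 1), `p`.
#' @export
chi_square_equal <- function(count_a, count_b, correct = TRUE) {
  stopifnot(count_a >= 0, count_b >= 0, count_a + count_b >= 1)
  expected <- (count_a + count_b) / 2
  dev <- abs(count_a - expected)
  if (correct) dev <- max(0, dev - 0.5)
  stat <- 2 * dev^2 / expected
  list(statistic = stat, df = 1L, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Coefficient of variation of body size among environments
#'
#' `100 * sd / mean` of one sex's sizes across a study's stations or sampling
#' times, with the sample (n - 1) standard deviation.
#'
#' @param sizes Positive sizes (>= 2 values, positive mean).
#' @return CV in percent.
#' @export
cv_among_environments <- function(sizes) {
  sizes <- sizes[is.finite(sizes)]
  if (length(sizes) < 2) stop("CV needs >= 2 values")
  m <- mean(sizes)
  if (m <= 0) stop("CV requires a positive mean size")
  100 * stats::sd(sizes) / m
}

#' Compare male and female size plasticity across studies
#'
#' For each study with matched per-station male and female masses: the RMA
#' slope of log10 male on log10 female mass and per-sex CVs among stations.
#' Across studies: counts of female- vs male-more-plastic slopes, the
#' continuity-corrected chi-square against equal counts, mean CV per sex, and
#' a paired t statistic on the per-study (female CV - male CV) differences.
#'
#' Pairing rule: male and female observations are matched on identical
#' gradient positions within a study; studies with fewer than 3 matched
#' stations are excluded from this comparison (it relies entirely on paired
#' data, unlike the size-cline ratio).
#'
#' @param obs Standardized observation table (with `dry_mass_mg`) for one
#'   gradient type.
#' @param correct Continuity correction for the chi-square (default `TRUE`).
#' @return A list of class `plasticity_comparison`: `per_study` data frame
#'   (study, species, slope, classification, cv_female, cv_male, n_stations),
#'   `count_female_more`, `count_male_more`, `count_indeterminate`,
#'   `chi_square`, `chi_square_p`, `cv_female_mean`, `cv_male_mean`,
#'   `t_paired`, `t_df`, `t_p`, `n_studies`.
#' @export
compare_plasticity <- function(obs, correct = TRUE) {
  key <- paste(obs$study_id, obs$species, sep = "\r")
  groups <- split(seq_len(nrow(obs)), key)
  rows <- lapply(groups, function(idx) {
    g <- obs[idx, ]
    m <- g[g$sex == "male", ]
    f <- g[g$sex == "female", ]
    ## one value per sex per station; average duplicates
    mm <- tapply(m$dry_mass_mg, m$gradient_value, mean)
    fm <- tapply(f$dry_mass_mg, f$gradient_value, mean)
    shared <- intersect(names(mm), names(fm))
    if (length(shared) < 3) return(NULL)
    mv <- as.numeric(mm[shared]); fv <- as.numeric(fm[shared])
    if (stats::sd(log10(fv)) == 0 || stats::sd(log10(mv)) == 0) return(NULL)
    res <- rma_slope(log10(fv), log10(mv))
    data.frame(study_id = g$study_id[1], species = g$species[1],
               slope = res$slope, classification = res$classification,
               cv_female = cv_among_environments(fv),
               cv_male = cv_among_environments(mv),
               n_stations = length(shared), stringsAsFactors = FALSE)
  })
  per_study <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(per_study) || nrow(per_study) < 2)
    stop("plasticity comparison needs >= 2 studies with matched stations")
  rownames(per_study) <- NULL
  per_study <- per_study[order(per_study$study_id, per_study$species), ]

  n_f <- sum(per_study$classification == "female_more_plastic")
  n_m <- sum(per_study$classification == "male_more_plastic")
  chi <- chi_square_equal(n_f, n_m, correct = correct)
  tt <- stats::t.test(per_study$cv_female, per_study$cv_male, paired = TRUE)
  structure(list(
    per_study = per_study,
    count_female_more = n_f, count_male_more = n_m,
    count_indeterminate = sum(per_study$classification == "indeterminate"),
    chi_square = chi$statistic, chi_square_p = chi$p,
    cv_female_mean = mean(per_study$cv_female),
    cv_male_mean = mean(per_study$cv_male),
    t_paired = unname(tt$statistic), t_df = unname(tt$parameter),
    t_p = tt$p.value,
    n_studies = nrow(per_study)),
    class = "plasticity_comparison")
}

#' @export
print.plasticity_comparison <- function(x, ...) {
  cat("Sex-specific plasticity comparison (RMA + CV), n =", x$n_studies,
      "studies\n")
  cat(sprintf("  female more plastic: %d, male more plastic: %d (X2 = %.2f, p = %.3f)\n",
              x$count_female_more, x$count_male_more, x$chi_square,
              x$chi_square_p))
  cat(sprintf("  mean CV female %.1f%%, male %.1f%% (paired t = %.2f, df = %d, p = %.3f)\n",
              x$cv_female_mean, x$cv_male_mean, x$t_paired, x$t_df, x$t_p))
  invisible(x)
}
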