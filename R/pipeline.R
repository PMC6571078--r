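# End-to-end orchestration: validate -> standardize -> fit clines -> pair ->
# synthesis -> outlier re-run -> allometric comparison, with file outputs.

#' Run the full sex-specific size-cline analysis
#'
#' Executes every stage on one observation table and returns (and optionally
#' writes) the headline statistics per gradient type: case percentages,
#' the overall weighted-mean ratio with its t test, the AICc model-selection
#' table and full model-averaged coefficients, the between-orders F test,
#' the IQR outlier re-run, sign-concordance counts, and the RMA/CV
#' plasticity comparison. The analysis is deterministic given its inputs.
#'
#' @param obs Observation data frame ([read_observations()]) or a CSV path.
#' @param registry Conversion registry (named list); empty for an
#'   all-dry-mass dataset.
#' @param gradient_types Gradient types to analyse (default: those present).
#' @param global_terms Global fixed-term set for model selection; `voltinism`
#'   is dropped automatically for seasonal-temperature clines (all
#'   multivoltine by construction).
#' @param weight_combiner Passed to [build_cline_pairs()].
#' @param outlier_analysis,rma_analysis Toggle those stages.
#' @param output_dir If non-`NULL`, per-cline and per-pair CSVs, model tables
#'   and a `summary.json` are written there.
#' @return A list of class `ssd_run` keyed by gradient type, plus
#'   `validation`; each gradient entry carries `clines`, `pairs`,
#'   `n_pairs`, `n_finite_ratios`, `pct_male_stronger`, `pct_female_stronger`,
#'   `weighted_mean`, `model_selection`, `averaged_coefficients`,
#'   `order_f`, `outliers` (`n_removed`, `fences`, `weighted_mean_post`),
#'   `concordance_counts`, and `plasticity` (or `NULL` where skipped).
#' @export
run_full_analysis <- function(obs, registry = list(),
                              gradient_types = NULL,
                              global_terms = c("environment", "voltinism",
                                               "mean_species_mass",
                                               "gradient_direction", "sdi"),
                              weight_combiner = "sum",
                              outlier_analysis = TRUE,
                              rma_analysis = TRUE,
                              output_dir = NULL) {
  if (is.character(obs)) obs <- read_observations(obs)
  report <- validate_dataset(obs)
  if (length(report$errors))
    stop("stage 'validate': dataset rejected with ", length(report$errors),
         " error(s); first: ", report$errors[1])
  obs <- apply_conversions(obs, registry)
  if (is.null(gradient_types)) gradient_types <- unique(obs$gradient_type)
  stopifnot(all(gradient_types %in% .gradient_levels))

  results <- list(validation = report)
  for (gt in gradient_types) {
    g_obs <- obs[obs$gradient_type == gt, ]
    fits <- fit_all_clines(g_obs)
    pairs <- build_cline_pairs(fits, weight_combiner = weight_combiner)
    if (is.null(pairs))
      stop("stage 'ratios': no matched male-female cline pairs for ", gt)
    finite <- is.finite(pairs$size_cline_ratio)
    terms <- global_terms
    if (gt == "seasonal_temperature") terms <- setdiff(terms, "voltinism")

    sel <- tryCatch(suppressWarnings(model_selection_table(pairs, terms)),
                    error = function(e) NULL)
    avg <- if (!is.null(sel)) model_average(sel) else NULL
    ftest <- tryCatch(order_f_test(pairs), error = function(e) NULL)

    outliers <- NULL
    if (outlier_analysis) {
      filt <- suppressWarnings(iqr_outlier_filter(pairs))
      wm_post <- tryCatch(weighted_mean_ratio(filt$kept),
                          error = function(e) NULL)
      outliers <- list(n_removed = sum(filt$removed$is_outlier),
                       n_sentinel_removed =
                         sum(!is.finite(filt$removed$size_cline_ratio)),
                       fences = filt$fences, kept = filt$kept,
                       weighted_mean_post = wm_post)
    }
    plasticity <- if (rma_analysis)
      tryCatch(compare_plasticity(g_obs), error = function(e) NULL)
    else NULL

    results[[gt]] <- list(
      clines = fits, pairs = pairs,
      n_pairs = nrow(pairs), n_finite_ratios = sum(finite),
      pct_male_stronger = 100 * mean(pairs$size_cline_ratio[finite] > 0),
      pct_female_stronger = 100 * mean(pairs$size_cline_ratio[finite] < 0),
      weighted_mean = weighted_mean_ratio(pairs),
      model_selection = sel,
      averaged_coefficients = avg,
      order_f = ftest,
      outliers = outliers,
      concordance_counts = table(factor(pairs$concordance, levels = c(
        "concordant", "discordant_both_ns", "discordant_one_ns",
        "discordant_both_sig"))),
      plasticity = plasticity)
  }
  class(results) <- "ssd_run"
  if (!is.null(output_dir)) .write_run_outputs(results, output_dir)
  results
}

#' Condense a run into its headline numbers
#'
#' @param run An `ssd_run`.
#' @return A nested list (JSON-ready) with one block per gradient type.
#' @export
run_summary <- function(run) {
  out <- list()
  for (gt in setdiff(names(run), "validation")) {
    r <- run[[gt]]
    wm <- r$weighted_mean
    block <- list(
      n_pairs = r$n_pairs, n_finite_ratios = r$n_finite_ratios,
      pct_male_stronger = r$pct_male_stronger,
      pct_female_stronger = r$pct_female_stronger,
      weighted_mean = wm$estimate, ci_halfwidth = wm$ci_halfwidth,
      t = wm$t, df = wm$df, p = wm$p,
      best_model = if (!is.null(r$model_selection))
        r$model_selection$table$terms[1] else NA,
      order_f = if (!is.null(r$order_f)) r$order_f$F else NA,
      order_f_p = if (!is.null(r$order_f)) r$order_f$p else NA,
      concordance = as.list(r$concordance_counts))
    if (!is.null(r$outliers)) {
      block$outliers_removed <- r$outliers$n_removed
      wp <- r$outliers$weighted_mean_post
      if (!is.null(wp)) {
        block$weighted_mean_post_outlier <- wp$estimate
        block$ci_halfwidth_post_outlier <- wp$ci_halfwidth
        block$p_post_outlier <- wp$p
      }
    }
    if (!is.null(r$plasticity)) {
      p <- r$plasticity
      block$rma <- list(count_female_more = p$count_female_more,
                        count_male_more = p$count_male_more,
                        chi_square = p$chi_square,
                        cv_female_mean = p$cv_female_mean,
                        cv_male_mean = p$cv_male_mean,
                        t_paired = p$t_paired, n_studies = p$n_studies)
    }
    out[[gt]] <- block
  }
  out
}

#' @export
print.ssd_run <- function(x, ...) {
  for (gt in setdiff(names(x), "validation")) {
    r <- x[[gt]]
    wm <- r$weighted_mean
    cat(sprintf("%s: %d pairs; male stronger in %.0f%% of cases; ",
                gt, r$n_pairs, r$pct_male_stronger))
    cat(sprintf("weighted mean %.2f (+/- %.2f 95%% CI), t(%d) = %.2f, p = %.2g\n",
                wm$estimate, wm$ci_halfwidth, wm$df, wm$t, wm$p))
  }
  invisible(x)
}

.write_run_outputs <- function(run, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (gt in setdiff(names(run), "validation")) {
    r <- run[[gt]]
    utils::write.csv(r$clines, file.path(output_dir,
                                         paste0("clines_", gt, ".csv")),
                     row.names = FALSE)
    utils::write.csv(r$pairs, file.path(output_dir,
                                        paste0("pairs_", gt, ".csv")),
                     row.names = FALSE)
    if (!is.null(r$model_selection))
      utils::write.csv(r$model_selection$table,
                       file.path(output_dir, paste0("models_", gt, ".csv")),
                       row.names = FALSE)
    if (!is.null(r$averaged_coefficients))
      utils::write.csv(r$averaged_coefficients,
                       file.path(output_dir,
                                 paste0("averaged_coefficients_", gt, ".csv")),
                       row.names = FALSE)
  }
  jsonlite::write_json(run_summary(run), file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(output_dir)
}
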