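# Inverse-variance-weighted mixed-model synthesis of size-cline ratios:
# nested taxonomic random intercepts, all-subsets AICc model selection,
# full model averaging, and the between-orders F test.

## Canonical fixed-term names -> model-frame columns.
.term_map <- c(environment = "environment",
               voltinism = "voltinism",
               mean_species_mass = "ln_mass",
               gradient_direction = "gradient_direction",
               sdi = "sdi")

#' Prepare a cline-pair table for mixed modelling
#'
#' Drops undefined-sentinel ratios, sets factor codings (reference levels:
#' aquatic, semelvoltine_or_less, negative), log-transforms the species-mass
#' covariate (masses span orders of magnitude) and builds explicitly nested
#' taxonomic grouping factors.
#'
#' @param pairs Cline-pair data frame ([build_cline_pairs()]).
#' @return A model-ready `data.frame` with columns `ratio`, `weight`,
#'   `environment`, `voltinism`, `ln_mass`, `gradient_direction`, `sdi`,
#'   `g_class`, `g_order`, `g_family`, `g_species`.
#' @export
prep_model_data <- function(pairs) {
  d <- pairs[is.finite(pairs$size_cline_ratio), ]
  data.frame(
    ratio = d$size_cline_ratio,
    weight = d$weight,
    environment = factor(d$environment, levels = .environment_levels),
    voltinism = factor(d$voltinism, levels = .voltinism_levels),
    ln_mass = log(d$mean_species_mass_mg),
    gradient_direction = factor(d$gradient_direction,
                                levels = c("negative", "positive")),
    sdi = d$sdi,
    g_class = factor(d$class),
    g_order = factor(paste(d$class, d$order, sep = "/")),
    g_family = factor(paste(d$class, d$order, d$family, sep = "/")),
    g_species = factor(paste(d$class, d$order, d$family, d$species,
                             sep = "/")),
    stringsAsFactors = FALSE)
}

## Terms that can actually be estimated on this data (factors need >= 2
## observed levels; numeric covariates need nonzero variance).
.estimable_terms <- function(data, terms) {
  ok <- vapply(terms, function(tm) {
    col <- data[[.term_map[[tm]]]]
    if (is.factor(col)) length(unique(as.character(col))) >= 2
    else stats::var(col) > 0
  }, logical(1))
  terms[ok]
}

.lmer_ctrl <- function(optimizer) {
  lme4::lmerControl(
    optimizer = optimizer,
    optCtrl = if (optimizer == "bobyqa") list(maxfun = 50000) else list(),
    check.nobs.vs.nlev = "ignore", check.nobs.vs.rankZ = "ignore",
    check.nobs.vs.nRE = "ignore",
    check.conv.singular = "ignore",
    calc.derivs = FALSE)
}

## Few-level grouping factors (e.g. 2 taxonomic classes) give nearly flat
## profiled criteria with local optima; fit with two optimizers and keep the
## better criterion value.
.fit_lmer_multistart <- function(form, data, REML) {
  fits <- lapply(c("bobyqa", "nloptwrap"), function(opt)
    tryCatch(
      suppressMessages(lme4::lmer(form, data = data, weights = weight,
                                  REML = REML, control = .lmer_ctrl(opt))),
      error = function(e) NULL))
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) stop("mixed-model fit failed with every optimizer")
  lls <- vapply(fits, function(f) as.numeric(stats::logLik(f)), numeric(1))
  fits[[which.max(lls)]]
}

#' Fit one inverse-variance-weighted hierarchical model
#'
#' Linear mixed model of the size-cline ratio with the requested fixed terms
#' and nested taxonomic random intercepts, fitted with lme4. Weights enter as
#' known inverse relative variances: the residual variance of observation i
#' is the common scale divided by its weight. Variance components are
#' estimated on the non-negative orthant and may legitimately hit zero
#' (boundary fits are kept, not treated as errors). With an empty
#' `random_levels` the model collapses to weighted least squares.
#'
#' @param data Model frame from [prep_model_data()].
#' @param fixed_terms Character subset of `environment`, `voltinism`,
#'   `mean_species_mass`, `gradient_direction`, `sdi` (empty = null model).
#' @param random_levels Ordered taxonomic nesting, default
#'   `c("class", "order", "family", "species")`.
#' @param REML Use restricted maximum likelihood (default `TRUE`); candidate
#'   sets compared by AICc are fitted with `REML = FALSE` so likelihoods are
#'   comparable across fixed-effect structures.
#' @return A list of class `model_fit`: `terms`, `coefficients` (data frame
#'   with `name`, `estimate`, `se`), `variance_components` (named, one per
#'   random level plus `residual`), `log_likelihood`, `k` (fixed effects +
#'   variance components + residual), `n`, `aicc`, `REML`.
#' @export
fit_weighted_lmm <- function(data, fixed_terms = character(0),
                             random_levels = c("class", "order", "family",
                                               "species"),
                             REML = TRUE) {
  stopifnot(all(fixed_terms %in% names(.term_map)))
  n <- nrow(data)
  if (n < length(fixed_terms) + 2L)
    stop("too few observations for the requested fixed terms")
  bad <- setdiff(fixed_terms, .estimable_terms(data, fixed_terms))
  if (length(bad))
    stop("inestimable fixed term(s) on this data: ",
         paste(bad, collapse = ", "))
  rhs_fixed <- if (length(fixed_terms))
    paste(.term_map[fixed_terms], collapse = " + ") else "1"

  if (length(random_levels)) {
    rterms <- paste0("(1 | g_", random_levels, ")")
    form <- stats::as.formula(paste("ratio ~", rhs_fixed, "+",
                                    paste(rterms, collapse = " + ")))
    fit <- .fit_lmer_multistart(form, data, REML)
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    comp <- stats::setNames(vc$vcov, sub("^g_", "", vc$grp))
    names(comp)[names(comp) == "Residual"] <- "residual"
    comp <- comp[c(random_levels, "residual")]
    ll <- as.numeric(stats::logLik(fit))
    k <- length(beta) + length(random_levels) + 1L
  } else {
    form <- stats::as.formula(paste("ratio ~", rhs_fixed))
    fit <- stats::lm(form, data = data, weights = weight)
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    comp <- c(residual = stats::sigma(fit)^2)
    ll <- as.numeric(stats::logLik(fit))
    k <- length(beta) + 1L
  }

  out <- list(
    terms = fixed_terms,
    coefficients = data.frame(name = names(beta), estimate = unname(beta),
                              se = unname(se), stringsAsFactors = FALSE),
    variance_components = comp,
    log_likelihood = ll,
    k = k, n = n,
    aicc = aicc_value(ll, k, n),
    REML = REML)
  class(out) <- "model_fit"
  out
}

#' @export
print.model_fit <- function(x, ...) {
  cat("Weighted hierarchical model (",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "null",
      ")\n", sep = "")
  cat(sprintf("  n = %d, k = %d, logLik = %.3f, AICc = %.3f (%s)\n",
              x$n, x$k, x$log_likelihood, x$aicc,
              if (x$REML) "REML" else "ML"))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`; `k` counts fixed effects,
#' variance components and the residual variance.
#'
#' @param fit A `model_fit`; or use [aicc_value()] on raw numbers.
#' @return AICc value; `NA` (with a warning) when `n - k - 1 <= 0`, in which
#'   case the model should be dropped from the candidate set.
#' @export
aicc <- function(fit) {
  stopifnot(inherits(fit, "model_fit"))
  aicc_value(fit$log_likelihood, fit$k, fit$n)
}

#' @rdname aicc
#' @param loglik Log-likelihood.
#' @param k Parameter count.
#' @param n Observation count.
#' @export
aicc_value <- function(loglik, k, n) {
  if (n - k - 1 <= 0) {
    warning("AICc undefined for n - k - 1 <= 0")
    return(NA_real_)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Enumerate the all-subsets candidate model set
#'
#' All `2^k` subsets of the global fixed terms, the null (intercept-only)
#' model included, in a deterministic order: by subset size, then
#' lexicographically.
#'
#' @param global_terms Character vector of at most 5 fixed terms.
#' @return List of character vectors (the null model is `character(0)`).
#' @export
candidate_set <- function(global_terms) {
  stopifnot(length(global_terms) <= 5,
            all(global_terms %in% names(.term_map)))
  terms <- sort(unique(global_terms))
  subsets <- list(character(0))
  for (size in seq_along(terms)) {
    combos <- utils::combn(terms, size, simplify = FALSE)
    combos <- combos[order(vapply(combos, paste, character(1),
                                  collapse = " "))]
    subsets <- c(subsets, combos)
  }
  subsets
}

#' Fit and rank the candidate model set by AICc
#'
#' Fits every subset of the global fixed terms with maximum likelihood
#' (likelihoods are then comparable across fixed-effect structures), computes
#' AICc, Akaike differences and Akaike weights, and ranks the set. Global
#' terms that are inestimable on the data (e.g. a factor observed at a single
#' level) are dropped from the global model with a warning before enumeration.
#' AICc ties are broken by fewer parameters, then by the lexical term string.
#'
#' @param pairs Cline-pair data frame.
#' @param global_terms Global fixed-term set (see [fit_weighted_lmm()]).
#' @param random_levels Taxonomic nesting.
#' @return A list of class `model_selection`: `table` (data frame with
#'   `terms`, `k`, `log_likelihood`, `aicc`, `delta_aicc`, `akaike_weight`,
#'   ranked), `fits` (the `model_fit` objects in table order) and
#'   `dropped_terms`.
#' @export
model_selection_table <- function(pairs,
                                  global_terms = c("environment", "voltinism",
                                                   "mean_species_mass",
                                                   "gradient_direction",
                                                   "sdi"),
                                  random_levels = c("class", "order",
                                                    "family", "species")) {
  data <- prep_model_data(pairs)
  keep <- .estimable_terms(data, global_terms)
  dropped <- setdiff(global_terms, keep)
  if (length(dropped))
    warning("dropping inestimable global term(s): ",
            paste(dropped, collapse = ", "))
  specs <- candidate_set(keep)
  fits <- lapply(specs, function(tm)
    fit_weighted_lmm(data, fixed_terms = tm, random_levels = random_levels,
                     REML = FALSE))
  aiccs <- vapply(fits, `[[`, numeric(1), "aicc")
  usable <- is.finite(aiccs)
  if (!all(usable)) {
    warning(sum(!usable), " candidate model(s) dropped (AICc undefined)")
    fits <- fits[usable]; specs <- specs[usable]; aiccs <- aiccs[usable]
  }
  ks <- vapply(fits, `[[`, numeric(1), "k")
  labels <- vapply(specs, function(tm)
    if (length(tm)) paste(tm, collapse = " + ") else "(null)", character(1))
  ord <- order(aiccs, ks, labels)
  fits <- fits[ord]; aiccs <- aiccs[ord]; ks <- ks[ord]
  labels <- labels[ord]
  delta <- aiccs - min(aiccs)
  w <- exp(-delta / 2); w <- w / sum(w)
  table <- data.frame(terms = labels, k = ks,
                      log_likelihood = vapply(fits, `[[`, numeric(1),
                                              "log_likelihood"),
                      aicc = aiccs, delta_aicc = delta, akaike_weight = w,
                      stringsAsFactors = FALSE)
  structure(list(table = table, fits = fits, dropped_terms = dropped),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Candidate model set (", nrow(x$table), " models, ML + AICc)\n",
      sep = "")
  print(x$table, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Full model-averaged coefficients
#'
#' Akaike-weight-weighted average of each coefficient over the whole candidate
#' set, with the coefficient (and its variance) set to zero in models where
#' the term is absent -- the "full" average, which shrinks weakly supported
#' effects towards zero. The unconditional standard error per coefficient is
#' `sum_m w_m * sqrt(se_m^2 + (beta_m - beta_bar)^2)`; significance is a
#' two-sided normal z test.
#'
#' @param selection A `model_selection`, or a plain list of `model_fit`
#'   objects (Akaike weights then recomputed from their AICc values).
#' @return Data frame with `term` (coefficient name), `estimate`, `se`, `z`,
#'   `p`, rows ordered intercept first.
#' @export
model_average <- function(selection) {
  if (inherits(selection, "model_selection")) {
    fits <- selection$fits
    w <- selection$table$akaike_weight
  } else {
    fits <- selection
    if (!length(fits)) stop("empty candidate set")
    a <- vapply(fits, `[[`, numeric(1), "aicc")
    d <- a - min(a)
    w <- exp(-d / 2); w <- w / sum(w)
  }
  all_names <- unique(unlist(lapply(fits, function(f) f$coefficients$name)))
  all_names <- c("(Intercept)", setdiff(all_names, "(Intercept)"))

  est_mat <- sapply(fits, function(f) {
    v <- stats::setNames(rep(0, length(all_names)), all_names)
    v[f$coefficients$name] <- f$coefficients$estimate
    v
  })
  se_mat <- sapply(fits, function(f) {
    v <- stats::setNames(rep(0, length(all_names)), all_names)
    v[f$coefficients$name] <- f$coefficients$se
    v
  })
  est_mat <- matrix(est_mat, nrow = length(all_names))
  se_mat <- matrix(se_mat, nrow = length(all_names))

  avg <- as.numeric(est_mat %*% w)
  se <- vapply(seq_along(all_names), function(i)
    sum(w * sqrt(se_mat[i, ]^2 + (est_mat[i, ] - avg[i])^2)), numeric(1))
  z <- avg / se
  data.frame(term = all_names, estimate = avg, se = se, z = z,
             p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
}

#' Overall weighted-mean size-cline ratio
#'
#' The intercept of the null (constant-mean) hierarchical model: an overall
#' weighted-mean ratio that accounts for taxonomic non-independence and
#' information quality. Tested against zero with a two-sided t test on
#' `df = n - (#fixed effects) - (#variance components)` (a transparent rule;
#' denominator-df conventions differ between mixed-model tools).
#'
#' @param pairs Cline-pair data frame.
#' @param random_levels Taxonomic nesting.
#' @param conf_level Confidence level (default 0.95).
#' @return A list: `estimate`, `se`, `ci_low`, `ci_high`, `ci_halfwidth`,
#'   `t`, `df`, `p`, `n`, `test_computable` (FALSE when a single pair leaves
#'   no degrees of freedom), and the underlying `fit` (REML).
#' @export
weighted_mean_ratio <- function(pairs,
                                random_levels = c("class", "order", "family",
                                                  "species"),
                                conf_level = 0.95) {
  data <- prep_model_data(pairs)
  n <- nrow(data)
  if (n == 0) stop("no finite size-cline ratios")
  if (n == 1)
    return(list(estimate = data$ratio[1], se = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, ci_halfwidth = NA_real_, t = NA_real_,
                df = 0L, p = NA_real_, n = 1L, test_computable = FALSE,
                fit = NULL))
  fit <- fit_weighted_lmm(data, character(0), random_levels = random_levels,
                          REML = TRUE)
  est <- fit$coefficients$estimate[1]
  se <- fit$coefficients$se[1]
  df <- n - 1L - length(random_levels)
  computable <- df > 0
  tstat <- if (computable) est / se else NA_real_
  tcrit <- if (computable) stats::qt(1 - (1 - conf_level) / 2, df) else NA_real_
  list(estimate = est, se = se,
       ci_low = est - tcrit * se, ci_high = est + tcrit * se,
       ci_halfwidth = tcrit * se,
       t = tstat, df = df,
       p = if (computable) 2 * stats::pt(-abs(tstat), df) else NA_real_,
       n = n, test_computable = computable, fit = fit)
}

#' Weighted one-way F test of the ratio across taxonomic orders
#'
#' Weighted analysis of variance of the size-cline ratio between taxonomic
#' orders, using the pair weights.
#'
#' @param pairs Cline-pair data frame (>= 2 orders represented).
#' @return List with `F`, `df_between`, `df_within`, `p`, `n_orders`.
#' @export
order_f_test <- function(pairs) {
  data <- prep_model_data(pairs)
  data$g_order <- droplevels(data$g_order)
  n_orders <- nlevels(data$g_order)
  if (n_orders < 2) stop("order F test needs >= 2 taxonomic orders")
  fit <- stats::lm(ratio ~ g_order, data = data, weights = weight)
  av <- stats::anova(fit)
  list(F = av[1, "F value"], df_between = av[1, "Df"],
       df_within = av[2, "Df"], p = av[1, "Pr(>F)"], n_orders = n_orders)
}
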