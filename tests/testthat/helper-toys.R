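# Shared fixtures: tiny observation tables built in code.

## One fully paired study: both sexes at the same stations, exact
## log-linear masses unless noise is supplied.
toy_study <- function(study_id = "s1", species = "sp1",
                      stations = c(0, 1, 2, 3),
                      female_slope = -0.1, female_intercept = 1,
                      male_slope = -0.2, male_intercept = 0.5,
                      gradient_type = "latitude",
                      environment = "terrestrial",
                      voltinism = "multivoltine",
                      taxonomy = c(class = "Insecta", order = "Diptera",
                                   family = "Muscidae")) {
  n <- length(stations)
  data.frame(
    study_id = study_id,
    class = taxonomy[["class"]], order = taxonomy[["order"]],
    family = taxonomy[["family"]], species = species,
    sex = rep(c("female", "male"), each = n),
    environment = environment, voltinism = voltinism,
    gradient_type = gradient_type,
    gradient_value = c(stations, stations),
    size_metric = "dry_mass",
    size_value = exp(c(female_intercept + female_slope * stations,
                       male_intercept + male_slope * stations)),
    stringsAsFactors = FALSE)
}

## Small, fast generator configuration for structural tests.
quick_config <- function(n_studies = 12, ...) {
  generator_config(n_studies = n_studies, stations_per_study = 5,
                   taxonomy_shape = c(classes = 2, orders = 3, families = 4,
                                      species = 6), ...)
}

## Minimal model_fit stand-in for model-averaging arithmetic tests.
fake_fit <- function(names, estimates, ses, aicc, n = 50) {
  structure(list(terms = setdiff(names, "(Intercept)"),
                 coefficients = data.frame(name = names, estimate = estimates,
                                           se = ses,
                                           stringsAsFactors = FALSE),
                 variance_components = c(residual = 1),
                 log_likelihood = NA_real_, k = length(names) + 1, n = n,
                 aicc = aicc, REML = FALSE),
            class = "model_fit")
}

## Linear-interpolation quartile, written independently of stats::quantile.
interp_quartile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
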