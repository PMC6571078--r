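# The weighted synthesis machinery, checked against closed-form oracles.

## Minimal model frame builder (bypasses pair construction).
model_frame <- function(y, w, species = seq_along(y)) {
  data.frame(ratio = y, weight = w,
             environment = factor("terrestrial", .env_levels()),
             voltinism = factor("multivoltine", .volt_levels()),
             ln_mass = 0, gradient_direction = factor("negative",
                                                      c("negative", "positive")),
             sdi = 0,
             g_class = factor("c1"), g_order = factor("o1"),
             g_family = factor("f1"),
             g_species = factor(paste0("sp", species)))
}
.env_levels <- function() c("aquatic", "terrestrial")
.volt_levels <- function() c("semelvoltine_or_less", "multivoltine")

test_that("with no random effects the model collapses to weighted least squares", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(5:20, 1)
    y <- rnorm(n); w <- runif(n, 0.1, 10)
    fit <- fit_weighted_lmm(model_frame(y, w), random_levels = character(0))
    expect_equal(fit$coefficients$estimate, sum(w * y) / sum(w),
                 tolerance = 1e-10)
  }
  ## equal weights: arithmetic mean and classical t interval
  y <- rnorm(12); d <- model_frame(y, rep(1, 12))
  fit <- fit_weighted_lmm(d, random_levels = character(0))
  expect_equal(fit$coefficients$estimate, mean(y), tolerance = 1e-12)
  tt <- t.test(y)
  expect_equal(fit$coefficients$se, unname(tt$stderr), tolerance = 1e-10)
})

test_that("AICc follows the small-sample correction and its large-n limit", {
  expect_equal(aicc_value(-5, k = 2, n = 10), 14 + 12 / 7, tolerance = 1e-12)
  expect_equal(aicc_value(-5, k = 2, n = 1e9), -2 * -5 + 2 * 2,
               tolerance = 1e-6)
  expect_warning(bad <- aicc_value(-5, k = 9, n = 10), "undefined")
  expect_true(is.na(bad))
  f <- fake_fit("(Intercept)", 1, 0.1, aicc = NA, n = 10)
  f$log_likelihood <- -5; f$k <- 2
  expect_equal(aicc(f), 14 + 12 / 7, tolerance = 1e-12)
})

test_that("the candidate set enumerates every subset deterministically", {
  expect_equal(candidate_set(character(0)), list(character(0)))
  expect_length(candidate_set(c("environment", "sdi")), 4)
  all5 <- c("environment", "voltinism", "mean_species_mass",
            "gradient_direction", "sdi")
  cs <- candidate_set(all5)
  expect_length(cs, 32)
  expect_identical(cs[[1]], character(0))            # null first
  expect_identical(cs[[32]], sort(all5))             # global last
  expect_identical(cs, candidate_set(rev(all5)))     # order-insensitive input
})

test_that("full model averaging matches a brute-force oracle", {
  ## single candidate returns its own coefficients
  one <- fake_fit(c("(Intercept)", "sdi"), c(1.5, -0.3), c(0.2, 0.1),
                  aicc = 10)
  avg <- model_average(list(one))
  expect_equal(avg$estimate, c(1.5, -0.3))
  expect_equal(avg$se, c(0.2, 0.1))

  ## two equal-AICc models, term present in one -> half the estimate
  two <- list(fake_fit("(Intercept)", 1, 0.2, aicc = 12),
              fake_fit(c("(Intercept)", "sdi"), c(1, 0.8), c(0.2, 0.1),
                       aicc = 12))
  avg <- model_average(two)
  expect_equal(avg$estimate[avg$term == "sdi"], 0.4, tolerance = 1e-12)

  ## random candidate sets against an independent enumeration oracle
  set.seed(31)
  terms <- c("x1", "x2", "x3")
  for (rep in 1:100) {
    subsets <- list(character(0), "x1", "x2", "x3", c("x1", "x2"),
                    c("x1", "x3"), c("x2", "x3"), terms)
    fits <- lapply(subsets, function(s) {
      nm <- c("(Intercept)", s)
      fake_fit(nm, rnorm(length(nm)), runif(length(nm), 0.05, 0.5),
               aicc = runif(1, 100, 110))
    })
    avg <- model_average(fits)
    a <- vapply(fits, `[[`, numeric(1), "aicc")
    w <- exp(-(a - min(a)) / 2); w <- w / sum(w)
    for (tm in terms) {
      beta <- vapply(fits, function(f) {
        i <- match(tm, f$coefficients$name)
        if (is.na(i)) 0 else f$coefficients$estimate[i]
      }, numeric(1))
      sei <- vapply(fits, function(f) {
        i <- match(tm, f$coefficients$name)
        if (is.na(i)) 0 else f$coefficients$se[i]
      }, numeric(1))
      est <- sum(w * beta)
      se <- sum(w * sqrt(sei^2 + (beta - est)^2))
      row <- avg[avg$term == tm, ]
      expect_equal(row$estimate, est, tolerance = 1e-10)
      expect_equal(row$se, se, tolerance = 1e-10)
      ## bounded by the largest coefficient across models containing the term
      expect_lte(abs(row$estimate), max(abs(beta)) + 1e-12)
    }
    ## Akaike weights: sum to one, invariant to constant AICc shifts
    shifted <- lapply(fits, function(f) { f$aicc <- f$aicc + 37; f })
    expect_equal(model_average(shifted)$estimate, avg$estimate,
                 tolerance = 1e-10)
  }
})

test_that("variance components are recovered on data simulated from the model", {
  set.seed(61)
  n_sp <- 100
  b <- rnorm(n_sp, 0, sqrt(0.5))
  y <- 2 + rep(b, each = 2) + rnorm(2 * n_sp, 0, 1)
  d <- model_frame(y, rep(1, 2 * n_sp), species = rep(seq_len(n_sp), each = 2))
  fit <- fit_weighted_lmm(d, random_levels = "species")
  expect_equal(unname(fit$variance_components[["species"]]), 0.5,
               tolerance = 0.5)  # simulation tolerance
  expect_equal(unname(fit$variance_components[["residual"]]), 1,
               tolerance = 0.35)
  expect_equal(fit$coefficients$estimate[1], 2, tolerance = 0.3)
})

test_that("REML fits are invariant to row order and weight rescaling", {
  set.seed(71)
  n <- 40
  y <- rnorm(n); w <- runif(n, 0.5, 5)
  d <- model_frame(y, w, species = rep(1:20, each = 2))
  f1 <- fit_weighted_lmm(d, random_levels = "species")
  f2 <- fit_weighted_lmm(d[sample(n), ], random_levels = "species")
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-6)
  d3 <- d; d3$weight <- d3$weight * 17
  f3 <- fit_weighted_lmm(d3, random_levels = "species")
  expect_equal(f1$coefficients$estimate, f3$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(f1$coefficients$se, f3$coefficients$se, tolerance = 1e-5)
})

test_that("the weighted-mean ratio handles the degenerate single pair", {
  pair <- data.frame(size_cline_ratio = 0.7, weight = 3,
                     environment = "terrestrial", voltinism = "multivoltine",
                     mean_species_mass_mg = 5,
                     gradient_direction = "negative", sdi = -0.5,
                     class = "c", order = "o", family = "f", species = "s")
  wm <- weighted_mean_ratio(pair)
  expect_equal(wm$estimate, 0.7)
  expect_false(wm$test_computable)
})

test_that("the between-orders F test matches the weighted sums-of-squares oracle", {
  set.seed(81)
  for (rep in 1:100) {
    n <- sample(10:30, 1)
    k <- sample(2:4, 1)
    g <- sample(k, n, replace = TRUE)
    if (length(unique(g)) < 2) next
    y <- rnorm(n); w <- runif(n, 0.2, 5)
    pairs <- data.frame(size_cline_ratio = y, weight = w,
                        environment = "terrestrial",
                        voltinism = "multivoltine",
                        mean_species_mass_mg = 1,
                        gradient_direction = "negative", sdi = 0,
                        class = "c", order = paste0("o", g), family = "f",
                        species = paste0("s", seq_len(n)))
    res <- order_f_test(pairs)
    grand <- sum(w * y) / sum(w)
    means <- tapply(w * y, g, sum) / tapply(w, g, sum)
    ssb <- sum(tapply(w, g, sum) * (means - grand)^2)
    ssw <- sum(w * (y - means[as.character(g)])^2)
    kk <- length(unique(g))
    expect_equal(res$F, (ssb / (kk - 1)) / (ssw / (n - kk)),
                 tolerance = 1e-8)
    expect_equal(res$df_between, kk - 1)
    expect_equal(res$df_within, n - kk)
  }
  ## two groups, equal weights: F is the square of the pooled t statistic
  y <- rnorm(16); g <- rep(1:2, each = 8)
  pairs <- data.frame(size_cline_ratio = y, weight = 1,
                      environment = "terrestrial", voltinism = "multivoltine",
                      mean_species_mass_mg = 1, gradient_direction = "negative",
                      sdi = 0, class = "c", order = paste0("o", g),
                      family = "f", species = paste0("s", 1:16))
  res <- order_f_test(pairs)
  tt <- t.test(y[g == 1], y[g == 2], var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
})
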