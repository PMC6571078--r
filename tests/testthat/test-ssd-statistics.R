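test_that("the size-cline ratio follows the signed larger/smaller rule", {
  expect_equal(size_cline_ratio(10, 5), 1)
  expect_equal(size_cline_ratio(-5, -10), -1)
  expect_equal(size_cline_ratio(7, 7), 0)
  expect_equal(size_cline_ratio(0, 0), 0)
  ## zero denominator -> undefined sentinel
  expect_true(is.na(size_cline_ratio(0, -8)))
  expect_true(is.na(size_cline_ratio(3, 0)))
  ## sign conventions: positive when the male response is greater in magnitude
  expect_gt(size_cline_ratio(-20, -10), 0)
  expect_lt(size_cline_ratio(10, -20), 0)
})

test_that("ratio anti-symmetry and scale invariance hold on random pairs", {
  set.seed(11)
  a <- rnorm(500, 0, 10); b <- rnorm(500, 0, 10)
  keep <- a != 0 & b != 0
  a <- a[keep]; b <- b[keep]
  expect_equal(size_cline_ratio(a, b), -size_cline_ratio(b, a),
               tolerance = 1e-12)
  for (k in c(0.2, -3, 7)) {
    expect_equal(size_cline_ratio(k * a, k * b), size_cline_ratio(a, b),
                 tolerance = 1e-12)
  }
  expect_true(all(abs(size_cline_ratio(a, b)) >= 0))
  expect_equal(size_cline_ratio(a, b) == 0, abs(a) == abs(b))
})

test_that("the dimorphism index is signed by the larger sex and unit-free", {
  expect_equal(sdi(2, 1), 1)
  expect_equal(sdi(1, 2), -1)
  expect_equal(sdi(3, 3), 0)
  expect_error(sdi(-1, 2), "positive")
  set.seed(12)
  m <- exp(rnorm(100)); f <- exp(rnorm(100))
  expect_equal(sdi(m, f), sdi(1000 * m, 1000 * f), tolerance = 1e-12)
})

test_that("pair weights are inverse summed slope variances", {
  expect_equal(cline_weight(0.01, 0.03), 25)
  v <- runif(50, 1e-4, 1)
  expect_equal(cline_weight(v, v), 1 / (2 * v), tolerance = 1e-12)
  expect_equal(cline_weight(2 * v, 2 * v), cline_weight(v, v) / 2,
               tolerance = 1e-12)
  expect_equal(cline_weight(0.01, 0.03, combiner = "mean"), 50)
  expect_warning(w <- cline_weight(0, 0), "capped")
  expect_equal(w, 1e6)
})

test_that("concordance classes follow slope signs and CI coverage of zero", {
  expect_equal(classify_concordance(0.1, 0.2, c(0.05, 0.15), c(0.1, 0.3)),
               "concordant")
  expect_equal(classify_concordance(0, -0.2, c(-0.1, 0.1), c(-0.3, -0.1)),
               "concordant")
  expect_equal(classify_concordance(0.1, -0.1, c(-0.1, 0.3), c(-0.3, 0.1)),
               "discordant_both_ns")
  expect_equal(classify_concordance(0.1, -0.1, c(0.05, 0.15), c(-0.3, 0.1)),
               "discordant_one_ns")
  expect_equal(classify_concordance(0.1, -0.1, c(0.05, 0.15), c(-0.3, -0.05)),
               "discordant_both_sig")
})

test_that("the IQR fence removes extreme ratios in a single pass", {
  mk <- function(r) data.frame(size_cline_ratio = r,
                               is_outlier = FALSE)
  res <- iqr_outlier_filter(mk(1:9))
  expect_equal(nrow(res$removed), 0)

  res <- iqr_outlier_filter(mk(c(1, 2, 3, 4, 100)))
  expect_equal(res$removed$size_cline_ratio, 100)
  expect_equal(res$fences, c(2 - 1.5 * 2, 4 + 1.5 * 2))
  expect_true(all(res$removed$is_outlier))

  ## undefined sentinels are always removed but not fenced as outliers
  res <- iqr_outlier_filter(mk(c(1, 2, 3, 4, 100, NA)))
  expect_setequal(res$removed$size_cline_ratio, c(100, NA))
  expect_equal(sum(res$removed$is_outlier), 1)

  expect_warning(res <- iqr_outlier_filter(mk(c(1, 2, 100))), "fewer than 4")
  expect_equal(nrow(res$kept), 3)

  ## single pass: fences are not re-derived after removal
  r <- c(0, 0, 0, 0, 10, 100)
  one <- iqr_outlier_filter(mk(r))
  expect_equal(one$removed$size_cline_ratio, 100)
  expect_true(10 %in% one$kept$size_cline_ratio)
  ## a second pass on the kept set would also remove 10 -- and must not run
  two <- iqr_outlier_filter(one$kept)
  expect_equal(two$removed$size_cline_ratio, 10)
})

test_that("pairs are built with midpoint SDI, direction and sentinel flags", {
  obs <- apply_conversions(toy_study())
  fits <- fit_all_clines(obs)
  pairs <- suppressWarnings(build_cline_pairs(fits))  # exact fits cap weights
  expect_equal(nrow(pairs), 1)
  ## exact data: ratio of percent changes, male stronger and both negative
  f_pct <- (exp(-0.1) - 1) * 100
  m_pct <- (exp(-0.2) - 1) * 100
  expect_equal(pairs$size_cline_ratio, abs(m_pct) / abs(f_pct) - 1,
               tolerance = 1e-10)
  expect_gt(pairs$size_cline_ratio, 0)
  expect_equal(pairs$gradient_direction, "negative")
  ## SDI from the two sexes' predicted masses at the midpoint (1.5)
  fm <- exp(1 - 0.1 * 1.5); mm <- exp(0.5 - 0.2 * 1.5)
  expect_equal(pairs$sdi, -(fm / mm - 1), tolerance = 1e-10)
  expect_equal(pairs$mean_species_mass_mg, fm, tolerance = 1e-10)
  expect_equal(pairs$concordance, "concordant")
})
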