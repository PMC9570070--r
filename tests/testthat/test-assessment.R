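make_profile <- function(eei1) {
  # a profile whose type-1 index reproduces `eei1` up to scale
  eei_from_scores(ta = max(eei1) * 1.01 / eei1,
                  lcil = rep(0.01, length(eei1)),
                  lcie = rep(0.05, length(eei1)),
                  locus_tag = sprintf("g%03d", seq_along(eei1)))
}

test_that("abundance-index correlation is Spearman with bootstrap CI", {
  n <- 40
  set.seed(70)
  eei <- sort(runif(n, 0.1, 10))
  prof <- make_profile(eei)
  ab <- data.frame(locus_tag = prof$locus_tag,
                   abundance_ppm = seq_len(n) * 2.5)

  res <- correlate_abundance_eei(ab, prof, type = 1, b = 200, seed = 1)
  expect_equal(res$rho, 1)
  ab$abundance_ppm <- rev(ab$abundance_ppm)
  expect_equal(correlate_abundance_eei(ab, prof, 1, b = 50, seed = 1)$rho, -1)

  # rank-formula oracle + CI sanity at n = 200, latent correlation 0.5
  set.seed(71)
  x <- rnorm(200)
  y <- x + rnorm(200, sd = sqrt(3))  # Pearson ~ 0.5
  prof <- make_profile(rank(y) + runif(200) * 0.01)
  prof$eei1 <- y - min(y) + 0.1
  ab <- data.frame(locus_tag = prof$locus_tag, abundance_ppm = x - min(x))
  res <- correlate_abundance_eei(ab, prof, 1, b = 1000, seed = 5)
  expect_equal(res$rho, oracle_spearman(x, y), tolerance = 1e-12)
  expect_true(res$ci_lower <= res$rho && res$rho <= res$ci_upper)

  for (s in c(2, 3, 4)) {
    r2 <- correlate_abundance_eei(ab, prof, 1, b = 300, seed = s)
    expect_true(r2$ci_lower <= r2$rho && r2$rho <= r2$ci_upper)
  }
  # determinism
  expect_identical(correlate_abundance_eei(ab, prof, 1, b = 100, seed = 9),
                   correlate_abundance_eei(ab, prof, 1, b = 100, seed = 9))

  expect_error(correlate_abundance_eei(ab[1:5, ], prof, 1), "insufficient")
})

test_that("Spearman rho is invariant under monotone transforms", {
  set.seed(72)
  x <- runif(50); y <- runif(50)
  prof <- make_profile(y * 9 + 0.5)
  ab1 <- data.frame(locus_tag = prof$locus_tag, abundance_ppm = x)
  ab2 <- data.frame(locus_tag = prof$locus_tag, abundance_ppm = exp(5 * x))
  expect_equal(correlate_abundance_eei(ab1, prof, 1, b = 1, seed = 1)$rho,
               correlate_abundance_eei(ab2, prof, 1, b = 1, seed = 1)$rho,
               tolerance = 1e-12)
})

test_that("welch_compare reproduces the textbook statistic", {
  res <- welch_compare(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)

  set.seed(73)
  x <- rnorm(11, 70, 15); y <- rnorm(7, 45, 10)
  res <- welch_compare(c(x, y), rep(c("f", "s"), c(11, 7)))
  want <- oracle_welch(x, y)
  expect_equal(abs(res$t), abs(want$t), tolerance = 1e-12)
  expect_equal(res$df, want$df, tolerance = 1e-12)
  expect_equal(res$p_value, want$p, tolerance = 1e-12)

  expect_error(welch_compare(1:4, c("a", "b", "b", "b")), ">= 2 values")
  expect_error(welch_compare(1:4, c("a", "b", "c", "c")), "two groups")
})

test_that("fit_m_regression is exact OLS with an F test", {
  m <- c(30, 50, 70, 90)
  rho <- 0.1 + 0.002 * m
  fit <- fit_m_regression(m, rho)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-12)
  expect_equal(fit$slope, 0.002, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  set.seed(74)
  m <- runif(20, 30, 95); rho <- 0.04 + 0.005 * m + rnorm(20, sd = 0.08)
  fit <- fit_m_regression(m, rho)
  want <- oracle_ols(m, rho)
  expect_equal(fit$intercept, unname(want["intercept"]), tolerance = 1e-10)
  expect_equal(fit$slope, unname(want["slope"]), tolerance = 1e-10)
  # training R^2 equals squared Pearson correlation
  expect_equal(fit$r_squared, oracle_pearson(m, rho)^2, tolerance = 1e-12)
  expect_gte(fit$mse, 0)

  expect_error(fit_m_regression(rep(1, 5), runif(5)), "singular")
  expect_error(fit_m_regression(1:2, 1:2), ">= 3")
})

test_that("monte_carlo_cv is seeded, exact on noiseless data", {
  m <- seq(30, 95, length.out = 10)
  rho <- 0.05 + 0.004 * m
  cv <- monte_carlo_cv(m, rho, n_splits = 100, seed = 3)
  expect_equal(cv$cv_r_squared, 1, tolerance = 1e-9)
  expect_equal(cv$cv_mse, 0, tolerance = 1e-12)
  expect_equal(cv$n_test, 2)

  set.seed(75)
  rho <- rho + rnorm(10, sd = 0.05)
  a <- monte_carlo_cv(m, rho, n_splits = 500, seed = 11)
  b <- monte_carlo_cv(m, rho, n_splits = 500, seed = 11)
  expect_identical(a, b)
  c <- monte_carlo_cv(m, rho, n_splits = 500, seed = 12)
  expect_false(identical(a$cv_mse, c$cv_mse))

  expect_error(monte_carlo_cv(1:4, 1:4), ">= 5 pairs")
})

test_that("growth classes use the printed 2 h and 5 h boundaries", {
  expect_equal(as.character(classify_growth(0.5)), "fast")
  expect_equal(as.character(classify_growth(2.7)), "medium")
  expect_equal(as.character(classify_growth(5.0)), "slow")
  expect_equal(as.character(classify_growth(2.0)), "medium")
  expect_equal(as.character(classify_growth(c(1.99, 4.99))),
               c("fast", "medium"))
  expect_error(classify_growth(0), "positive")
  expect_error(classify_growth(-1), "positive")
})

test_that("meta_summary aggregates and warns about missing doubling times", {
  df <- data.frame(rho = c(0.3, 0.5, 0.7), m = c(30, 50, 70),
                   r = c(40, 30, 20))
  expect_warning(ms <- meta_summary(df), "doubling")
  expect_equal(ms$mean_rho, 0.5)
  expect_equal(ms$correlations$r[ms$correlations$pair == "m_vs_rho"], 1,
               tolerance = 1e-12)

  df$doubling_time_h <- c(0.5, 2, 8)
  ms <- meta_summary(df)
  expect_setequal(ms$correlations$pair,
                  c("m_vs_rho", "r_vs_rho", "log10_dt_vs_rho", "dt_vs_rho"))
  expect_error(meta_summary(df[1:2, ]), ">= 3")
})
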