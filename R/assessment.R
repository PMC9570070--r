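#' Spearman correlation between protein abundance and an index
#'
#' Joins an abundance table to an index profile on locus tags and computes
#' Spearman's rank correlation with its asymptotic p-value, plus a
#' percentile bootstrap confidence interval from `b` nonparametric
#' resamples of gene pairs (protein abundances are far from normal, so the
#' bootstrap provides the significance check).
#'
#' @param abundance an `abundance_table` (see [aggregate_abundance()]).
#' @param profile an `eei_profile` (see [compute_eei_table()]).
#' @param type index type 1..5 to correlate against.
#' @param b number of bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap; `NULL` uses the current stream.
#' @param conf_level confidence level of the percentile interval.
#' @return list with `rho`, `p_value`, `n`, `ci_lower`, `ci_upper`, `type`,
#'   `b`.
#' @export
correlate_abundance_eei <- function(abundance, profile, type, b = 1000,
                                    seed = NULL, conf_level = 0.95) {
  stopifnot(is.data.frame(abundance), inherits(profile, "eei_profile"),
            type %in% EEI_TYPES, b >= 1)
  col <- paste0("eei", as.integer(type))
  df <- merge(abundance[, c("locus_tag", "abundance_ppm")],
              profile[, c("locus_tag", col)], by = "locus_tag")
  n <- nrow(df)
  if (n < 10)
    stop("insufficient data: only ", n,
         " joined gene-abundance pairs (need >= 10)", call. = FALSE)
  x <- df$abundance_ppm
  y <- df[[col]]
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  boots <- with_seed(seed, vapply(seq_len(b), function(i) {
    idx <- sample.int(n, replace = TRUE)
    suppressWarnings(cor(x[idx], y[idx], method = "spearman"))
  }, numeric(1)))
  qs <- quantile(boots, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                 na.rm = TRUE, names = FALSE)
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n,
       ci_lower = qs[1], ci_upper = qs[2], type = as.integer(type), b = b)
}

#' Cross-organism meta-statistics
#'
#' Mean per-organism Spearman correlation, and Pearson correlations of that
#' correlation against the normalized ribosomal rank statistics `m` and
#' `r`, and against the minimal doubling time (log10-transformed, with the
#' raw-scale correlation also reported for transparency).
#'
#' @param summaries data.frame with columns `rho`, `m`, `r` and optionally
#'   `doubling_time_h` (one row per organism, insignificant organisms
#'   already excluded).
#' @return list with `n`, `mean_rho` and `correlations`, a data.frame with
#'   rows `m_vs_rho`, `r_vs_rho`, `log10_dt_vs_rho`, `dt_vs_rho` and
#'   columns `pair`, `r`, `p`.
#' @export
meta_summary <- function(summaries) {
  stopifnot(is.data.frame(summaries),
            all(c("rho", "m", "r") %in% names(summaries)))
  if (nrow(summaries) < 3)
    stop("need >= 3 organism summaries", call. = FALSE)
  pear <- function(x, y, label) {
    ct <- cor.test(x, y, method = "pearson")
    data.frame(pair = label, r = unname(ct$estimate), p = ct$p.value)
  }
  out <- rbind(pear(summaries$m, summaries$rho, "m_vs_rho"),
               pear(summaries$r, summaries$rho, "r_vs_rho"))
  dt <- summaries$doubling_time_h
  if (!is.null(dt) && !anyNA(dt)) {
    out <- rbind(out,
                 pear(log10(dt), summaries$rho, "log10_dt_vs_rho"),
                 pear(dt, summaries$rho, "dt_vs_rho"))
  } else {
    warning("doubling times missing; growth-rate correlations skipped",
            call. = FALSE)
  }
  list(n = nrow(summaries), mean_rho = mean(summaries$rho),
       correlations = out)
}

#' Welch's unequal-variance two-sample t-test
#'
#' @param values numeric vector.
#' @param groups vector of two group labels parallel to `values`; both
#'   groups need at least two values.
#' @return list with `t`, `df`, `p_value`, `means` (named group means).
#' @export
welch_compare <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) != 2)
    stop("welch_compare needs exactly two groups, got ", nlevels(groups),
         call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2))
    stop("each group needs >= 2 values; sizes: ",
         paste(sizes, collapse = ", "), call. = FALSE)
  tt <- t.test(values ~ groups, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       means = setNames(as.numeric(tt$estimate), levels(groups)))
}

#' Linear regression of abundance correlation on the M statistic
#'
#' Ordinary least squares of per-organism correlation coefficients on the
#' normalized mean ribosomal rank `m`, with an F-test for the slope.
#'
#' @param m,rho numeric vectors (one entry per organism).
#' @return list of class `m_regression` with `intercept`, `slope`,
#'   `r_squared`, `mse`, `mae`, `f_statistic`, `p_value`, `n`.
#' @export
fit_m_regression <- function(m, rho) {
  stopifnot(length(m) == length(rho))
  if (length(m) < 3) stop("need >= 3 (m, rho) pairs", call. = FALSE)
  if (var(m) == 0) stop("singular design: m is constant", call. = FALSE)
  fit <- lm(rho ~ m)
  sm <- suppressWarnings(summary(fit))  # noiseless input is legitimate here
  fs <- sm$fstatistic
  structure(list(
    intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
    r_squared = sm$r.squared,
    mse = mean(fit$residuals^2), mae = mean(abs(fit$residuals)),
    f_statistic = unname(fs[1]),
    p_value = unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
    n = length(m)), class = "m_regression")
}

#' Monte-Carlo (repeated random subsampling) cross-validation
#'
#' Repeatedly splits the (m, rho) pairs into training and held-out parts
#' (test size `ceiling(n * test_fraction)`), fits the one-predictor OLS on
#' the training part and scores the held-out part.  Reported values are
#' means over splits of the held-out determination coefficient
#' `R^2 = 1 - SS_res / SS_tot`, mean squared error and mean absolute
#' error.  `SS_tot` is centred on the training-fold mean (the Q^2-style
#' convention): the fitted line is compared against the null model
#' actually available at training time.  Centring on the test-fold mean
#' instead is catastrophically unstable for the tiny held-out folds used
#' here (5 points) and drives the mean R^2 towards zero even for a clearly
#' predictive model.  Fully determined by `seed`.
#'
#' @param m,rho numeric vectors (one entry per organism).
#' @param n_splits number of random splits (default 2000).
#' @param test_fraction held-out fraction per split (default 0.2).
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return list with `cv_r_squared`, `cv_mse`, `cv_mae`, `n_splits`,
#'   `n_test`.
#' @export
monte_carlo_cv <- function(m, rho, n_splits = 2000, test_fraction = 0.2,
                           seed = NULL) {
  n <- length(m)
  stopifnot(length(rho) == n, n_splits >= 1,
            test_fraction > 0, test_fraction < 1)
  if (n < 5) stop("need >= 5 pairs for cross-validation", call. = FALSE)
  n_test <- as.integer(ceiling(n * test_fraction))
  if (n_test < 1) stop("test partition smaller than 1", call. = FALSE)
  if (n - n_test < 3)
    stop("training partition too small (", n - n_test, ")", call. = FALSE)

  res <- with_seed(seed, {
    r2 <- mse <- mae <- numeric(n_splits)
    for (i in seq_len(n_splits)) {
      test <- sample.int(n, n_test)
      xtr <- m[-test]; ytr <- rho[-test]
      xb <- mean(xtr); yb <- mean(ytr)
      sxx <- sum((xtr - xb)^2)
      slope <- if (sxx > 0) sum((xtr - xb) * (ytr - yb)) / sxx else 0
      pred <- yb + slope * (m[test] - xb)
      err <- rho[test] - pred
      ssres <- sum(err^2)
      sstot <- sum((rho[test] - yb)^2)
      r2[i] <- if (sstot > 0) 1 - ssres / sstot else
        if (ssres < 1e-12) 1 else NA_real_
      mse[i] <- mean(err^2)
      mae[i] <- mean(abs(err))
    }
    list(r2 = r2, mse = mse, mae = mae)
  })
  list(cv_r_squared = mean(res$r2, na.rm = TRUE),
       cv_mse = mean(res$mse), cv_mae = mean(res$mae),
       n_splits = as.integer(n_splits), n_test = n_test)
}

#' Growth class from minimal doubling time
#'
#' Fast growers double in under 2 h, slow growers in 5 h or more,
#' medium growers in between (boundaries: 2 h is medium, 5 h is slow).
#'
#' @param doubling_time_h positive numeric vector of minimal doubling
#'   times in hours.
#' @return factor with levels `fast`, `medium`, `slow`.
#' @export
classify_growth <- function(doubling_time_h) {
  if (any(!is.finite(doubling_time_h) | doubling_time_h <= 0))
    stop("doubling times must be positive", call. = FALSE)
  factor(ifelse(doubling_time_h < 2, "fast",
                ifelse(doubling_time_h < 5, "medium", "slow")),
         levels = c("fast", "medium", "slow"))
}
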