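#' Pipeline configuration
#'
#' Validated bundle of paths and parameters for [run_pipeline()].  Exactly
#' one of two modes applies: single-organism mode (a `genome`, optionally
#' with `abundance` files) or meta mode (a `meta_table` of per-organism
#' summaries; `"fixture"` selects the packaged 25-organism table).
#'
#' @param genome GenBank flat file of the organism (single mode).
#' @param abundance character vector of PaxDb-style abundance files.
#' @param ribosomal_list optional one-locus-per-line text file overriding
#'   the ribosomal product-annotation pattern.
#' @param meta_table per-organism summary TSV (meta mode), or `"fixture"`.
#' @param eei_type `"auto"` (use the base type) or an integer 1..5.
#' @param structure a [structure_params()] object.
#' @param b bootstrap resamples for the abundance correlation.
#' @param cv_splits,test_fraction Monte-Carlo cross-validation settings.
#' @param seed integer seed recorded in every output header.
#' @param out_dir output directory (created if missing).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome = NULL, abundance = NULL,
                            ribosomal_list = NULL, meta_table = NULL,
                            eei_type = "auto",
                            structure = structure_params(),
                            b = 1000, cv_splits = 2000, test_fraction = 0.2,
                            seed = 1L, out_dir = ".") {
  if (is.null(genome) && is.null(meta_table))
    stop("config needs a genome (single mode) or a meta_table (meta mode)",
         call. = FALSE)
  if (!identical(eei_type, "auto")) {
    eei_type <- as.integer(eei_type)
    stopifnot(eei_type %in% EEI_TYPES)
  }
  stopifnot(inherits(structure, "structure_params"),
            b >= 1, cv_splits >= 1, test_fraction > 0, test_fraction < 1)
  structure(list(genome = genome, abundance = abundance,
                 ribosomal_list = ribosomal_list, meta_table = meta_table,
                 eei_type = eei_type, structure = structure,
                 b = as.integer(b), cv_splits = as.integer(cv_splits),
                 test_fraction = test_fraction, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the end-to-end pipeline
#'
#' Single-organism mode: parse the genome, flag ribosomal genes, estimate
#' codon decoding times, score all five indices, compute rank statistics
#' and the base type, and - when abundance files are given - aggregate them
#' and correlate abundance with the selected index.  Writes `scores.tsv`,
#' `type_report.tsv`, `correlation.tsv` (if applicable) and `report.txt`.
#'
#' Meta mode: read a per-organism summary table (or the packaged fixture)
#' and compute the cross-organism statistics: mean correlation, Pearson
#' meta-correlations, the M-regression with Monte-Carlo cross-validation,
#' and the Welch test of `m` between fast and slow growers.  Writes
#' `meta_stats.tsv` and `report.txt`.
#'
#' Every output carries a '#' header with the package version, seed and a
#' config hash; outputs are byte-identical across runs with the same
#' config and seed.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `status` (0 on success), `outputs`
#'   (named file paths) and mode-specific results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  # hash the scientific parameters only: where the outputs land must not
  # change what is in them
  hash <- config_hash(unclass(config)[setdiff(names(config), "out_dir")])
  outputs <- character(0)
  path_of <- function(name) file.path(config$out_dir, name)

  if (!is.null(config$genome)) {
    genes <- parse_genome(config$genome)
    if (!is.null(config$ribosomal_list)) {
      loci <- readLines(config$ribosomal_list, warn = FALSE)
      loci <- trimws(loci[nzchar(trimws(loci))])
      genes <- flag_ribosomal_genes(genes, custom_list = loci)
    } else if (sum(genes$is_ribosomal) == 0) {
      stop("stage flag_ribosomal: no ribosomal genes found; supply ",
           "--ribosomal-list", call. = FALSE)
    }
    time_table <- build_codon_time_table(genes$cds)
    profile <- compute_eei_table(genes, time_table, config$structure)
    stats <- rank_stats_all(profile, genes$is_ribosomal)
    base_type <- attr(stats, "base_type")
    message("base index type: ", base_type)

    write_tsv_report(profile, path_of("scores.tsv"), config$seed, hash)
    type_rep <- data.frame(type = stats$type, mrank = stats$mrank,
                           rrank = stats$rrank, M = stats$m, R = stats$r,
                           is_base = stats$is_base)
    write_tsv_report(type_rep, path_of("type_report.tsv"), config$seed, hash)
    outputs <- c(scores = path_of("scores.tsv"),
                 type_report = path_of("type_report.tsv"))

    corr <- NULL
    if (!is.null(config$abundance)) {
      datasets <- lapply(config$abundance, load_paxdb)
      agg <- aggregate_abundance(datasets, genes)
      use_type <- if (identical(config$eei_type, "auto")) base_type
                  else config$eei_type
      corr <- correlate_abundance_eei(agg, profile, use_type,
                                      b = config$b, seed = config$seed)
      corr_df <- data.frame(
        type = corr$type, n = corr$n,
        coverage_percent = attr(agg, "coverage_percent"),
        rho = corr$rho, p_value = corr$p_value,
        ci_lower = corr$ci_lower, ci_upper = corr$ci_upper)
      write_tsv_report(corr_df, path_of("correlation.tsv"), config$seed, hash)
      outputs <- c(outputs, correlation = path_of("correlation.tsv"))
    }

    ft <- genome_features(genes)
    rpt <- c(sprintf("elongeff single-organism report (config=%s seed=%d)",
                     hash, config$seed),
             sprintf("genome: %s", config$genome),
             sprintf("genes=%d ribosomal=%d tRNA=%d GC=%.4f length=%d",
                     ft$n_genes, ft$n_ribosomal, ft$n_trna, ft$gc_content,
                     ft$genome_length_nt),
             sprintf("base type: %d (M=%.2f R=%.2f)", base_type,
                     stats$m[stats$type == base_type],
                     stats$r[stats$type == base_type]))
    if (!is.null(corr))
      rpt <- c(rpt, sprintf(
        "corr(PA|EEI%d): rho=%.4f p=%.3g n=%d coverage=%.1f%% CI95=[%.4f, %.4f]",
        corr$type, corr$rho, corr$p_value, corr$n,
        attr(agg, "coverage_percent"), corr$ci_lower, corr$ci_upper))
    writeLines(rpt, path_of("report.txt"))
    outputs <- c(outputs, report = path_of("report.txt"))
    return(invisible(list(status = 0L, outputs = outputs,
                          base_type = base_type, stats = stats,
                          correlation = corr)))
  }

  ## meta mode
  meta <- if (identical(config$meta_table, "fixture")) table1_fixture()
          else read_tsv_report(config$meta_table)
  need <- c("rho", "m", "r")
  if (!all(need %in% names(meta)))
    stop("stage meta: summary table must have columns rho, m, r",
         call. = FALSE)
  ms <- meta_summary(meta)
  reg <- fit_m_regression(meta$m, meta$rho)
  cv <- monte_carlo_cv(meta$m, meta$rho, n_splits = config$cv_splits,
                       test_fraction = config$test_fraction,
                       seed = config$seed)
  welch <- NULL
  if ("doubling_time_h" %in% names(meta)) {
    cls <- classify_growth(meta$doubling_time_h)
    keep <- cls != "medium"
    if (sum(cls[keep] == "fast") >= 2 && sum(cls[keep] == "slow") >= 2)
      welch <- welch_compare(meta$m[keep], droplevels(cls[keep]))
  }

  stat_rows <- rbind(
    data.frame(statistic = "mean_rho", value = ms$mean_rho),
    data.frame(statistic = paste0("pearson_", ms$correlations$pair),
               value = ms$correlations$r),
    data.frame(statistic = c("ols_intercept", "ols_slope", "ols_r_squared",
                             "ols_mse", "ols_f", "ols_p"),
               value = c(reg$intercept, reg$slope, reg$r_squared, reg$mse,
                         reg$f_statistic, reg$p_value)),
    data.frame(statistic = c("cv_r_squared", "cv_mse", "cv_mae"),
               value = c(cv$cv_r_squared, cv$cv_mse, cv$cv_mae)))
  if (!is.null(welch))
    stat_rows <- rbind(stat_rows,
                       data.frame(statistic = c("welch_t_fast_vs_slow",
                                                "welch_p_fast_vs_slow"),
                                  value = c(welch$t, welch$p_value)))
  write_tsv_report(stat_rows, path_of("meta_stats.tsv"), config$seed, hash)

  rpt <- c(sprintf("elongeff meta report (config=%s seed=%d, n=%d organisms)",
                   hash, config$seed, ms$n),
           sprintf("mean Spearman rho: %.4f", ms$mean_rho),
           sprintf("Pearson %s: r=%.4f p=%.3g", ms$correlations$pair,
                   ms$correlations$r, ms$correlations$p),
           sprintf("OLS rho ~ m: intercept=%.4f slope=%.5f R2=%.4f F=%.3f p=%.3g",
                   reg$intercept, reg$slope, reg$r_squared, reg$f_statistic,
                   reg$p_value),
           sprintf("Monte-Carlo CV (%d splits, %.0f%% test): R2=%.4f MSE=%.4f MAE=%.4f",
                   cv$n_splits, 100 * config$test_fraction, cv$cv_r_squared,
                   cv$cv_mse, cv$cv_mae))
  if (!is.null(welch))
    rpt <- c(rpt, sprintf("Welch m fast-vs-slow growers: t=%.3f p=%.3g",
                          welch$t, welch$p_value))
  writeLines(rpt, path_of("report.txt"))
  outputs <- c(meta_stats = path_of("meta_stats.tsv"),
               report = path_of("report.txt"))
  invisible(list(status = 0L, outputs = outputs, meta_summary = ms,
                 regression = reg, cv = cv, welch = welch))
}
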