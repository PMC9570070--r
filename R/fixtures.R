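#' Packaged 25-organism meta-table
#'
#' The published cross-organism table used by the meta-analyses: for each
#' of 25 prokaryotes (24 bacteria plus one archaeon and one archaeal
#' extremophile; the one organism whose abundance correlation was not
#' significant is excluded), the base index type, proteome coverage (%),
#' the Spearman correlation between protein abundance and the base index
#' (`rho`) with its p-value, the minimal doubling time in hours (raw and
#' log10), and the normalized ribosomal rank statistics `m` and `r` of the
#' base type.  A `growth_class` column is derived via [classify_growth()].
#'
#' @return data.frame of class `fixture_table` with 25 rows and columns
#'   `organism`, `eei_type`, `coverage`, `rho`, `p_value`,
#'   `doubling_time_h`, `log10_dt`, `m`, `r`, `growth_class`.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "organism_meta.tsv", package = "elongeff")
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$growth_class <- classify_growth(df$doubling_time_h)
  stopifnot(nrow(df) == 25,
            all(df$rho >= 0.12 & df$rho <= 0.66),
            all(df$m >= 34 & df$m <= 94),
            all(df$eei_type %in% EEI_TYPES))
  class(df) <- c("fixture_table", "data.frame")
  df
}
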