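DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Scalar fast path for short fragments in simulation inner loops, where
# DNAStringSet construction overhead dominates.
#' @noRd
revcomp1 <- function(x) {
  intToUtf8(rev(utf8ToInt(chartr("ACGT", "TGCA", x))))
}

#' @noRd
translate_cds <- function(x) {
  as.character(Biostrings::translate(
    Biostrings::DNAStringSet(x),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "error"
  ))
}

# Codons of a CDS, 5'->3'. Assumes nchar %% 3 == 0.
#' @noRd
split_codons <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq.int(1L, n - 2L, by = 3L), seq.int(3L, n, by = 3L))
}

# Run code under a seed without disturbing the caller's RNG stream.
# seed = NULL means "use the current stream as-is".
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Small stable fingerprint for run headers (not cryptographic).
#' @noRd
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  h <- 17
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 67108864
  sprintf("%07x", as.integer(h))
}

# TSV writer used by the pipeline: '#'-prefixed header block carrying the
# package version, seed and config hash, then a plain tab-separated table.
#' @noRd
write_tsv_report <- function(df, path, seed = NULL, hash = NULL, extra = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("elongeff"))
  writeLines(sprintf("# elongeff %s", ver), con)
  if (!is.null(seed)) writeLines(sprintf("# seed=%s", format(seed)), con)
  if (!is.null(hash)) writeLines(sprintf("# config=%s", hash), con)
  if (!is.null(extra)) writeLines(paste0("# ", extra), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
read_tsv_report <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
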