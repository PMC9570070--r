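# Synonymous codon families under the bacterial/archaeal code (table 11).
#' @noRd
codon_families <- function() {
  code <- Biostrings::getGeneticCode("11")
  sense <- names(code)[code != "*"]
  split(sense, code[sense])
}

#' Estimate per-codon decoding times from a reference CDS set
#'
#' The decoding time of a codon is modelled as the inverse of its relative
#' frequency within its synonymous family, estimated over a reference CDS
#' set (conventionally all protein-coding genes, or only the ribosomal
#' ones).  For codon `c` in family `F`:
#' `t(c) = 1 / p(c)`, `p(c) = (count(c) + alpha) / sum_{c' in F}(count(c') + alpha)`
#' with pseudo-count `alpha` guarding against unobserved codons.  Relative
#' within-family frequency is the standard proxy for isoacceptor tRNA
#' availability when measured tRNA abundances are unavailable; rare
#' synonymous codons are presumed slow to decode.  Stop codons are
#' excluded; single-codon families (ATG, TGG) always get `t = 1`.
#'
#' @param reference_cds character vector of CDS sequences (coding strand).
#' @param alpha pseudo-count added to every codon count (default 0.5).
#' @param reference_set label recorded on the table (e.g. `"all"`,
#'   `"ribosomal"`).
#' @return an object of class `codon_time_table`: list with `t` (named
#'   numeric over the 62 sense codons, all >= 1), `alpha`, `reference_set`.
#' @export
build_codon_time_table <- function(reference_cds, alpha = 0.5,
                                   reference_set = "all") {
  if (length(reference_cds) == 0)
    stop("empty reference CDS set", call. = FALSE)
  stopifnot(alpha > 0)
  fams <- codon_families()
  counts <- table(factor(unlist(lapply(reference_cds, split_codons),
                                use.names = FALSE),
                         levels = unlist(fams, use.names = FALSE)))
  t <- numeric(0)
  for (fam in fams) {
    cc <- as.numeric(counts[fam]) + alpha
    t <- c(t, setNames(sum(cc) / cc, fam))
  }
  structure(list(t = t, alpha = alpha, reference_set = reference_set),
            class = "codon_time_table")
}

#' Mean codon decoding time of a gene
#'
#' Arithmetic mean of the table's decoding-time estimates over the gene's
#' sense codons; a terminal stop codon is excluded.
#'
#' @param cds a CDS sequence (character scalar) or a vector of them.
#' @param table a [build_codon_time_table()] result.
#' @return numeric vector of per-gene mean decoding times (all >= 1).
#' @export
compute_ta <- function(cds, table) {
  stopifnot(inherits(table, "codon_time_table"))
  vapply(cds, function(s) {
    codons <- split_codons(s)
    if (codons[length(codons)] %in% STOP_CODONS)
      codons <- codons[-length(codons)]
    tv <- table$t[codons]
    if (anyNA(tv))
      stop("codon absent from decoding-time table: ",
           paste(unique(codons[is.na(tv)]), collapse = ", "), call. = FALSE)
    mean(tv)
  }, numeric(1), USE.NAMES = FALSE)
}
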