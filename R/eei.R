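EEI_TYPES <- 1:5

#' Elongation efficiency indices from per-gene scores
#'
#' Core index computation: `EEI(i) = K / (w1 * Ta'(i) + w2 * Te'(i))` where
#' the five types switch the codon-time term `Ta` and the structure term
#' `Te` (hairpin count load `LCIL` or energy load `LCIE`) on and off:
#' type 1 uses `Ta` only, type 2 `LCIL` only, type 3 `LCIE` only, type 4
#' `Ta + LCIL`, type 5 `Ta + LCIE`.  Because `Ta` (around 1-60) and the
#' per-nucleotide structure loads (around 0-0.2) live on incommensurable
#' scales, every term is first divided by its genome-wide mean (primed
#' values), making unit weights meaningful.  Per type, `K` is 10 times the
#' smallest positive denominator, so indices fall in (0, 10] and the most
#' efficient gene scores exactly 10; structure-free genes under a pure
#' structure type have their zero denominator clamped to that smallest
#' positive value and share the top score.
#'
#' @param ta,lcil,lcie numeric vectors of per-gene scores (same length).
#' @param locus_tag gene identifiers.
#' @return data.frame of class `eei_profile` with columns `locus_tag`,
#'   `ta`, `lcil`, `lcie`, `eei1`..`eei5`; attribute `K` holds the five
#'   normalization constants.
#' @export
eei_from_scores <- function(ta, lcil, lcie, locus_tag = NULL) {
  n <- length(ta)
  stopifnot(n >= 2, length(lcil) == n, length(lcie) == n,
            all(is.finite(ta)), all(is.finite(lcil)), all(is.finite(lcie)),
            all(ta >= 0), all(lcil >= 0), all(lcie >= 0))
  if (is.null(locus_tag)) locus_tag <- sprintf("gene%04d", seq_len(n))

  unit_mean <- function(x) {
    mx <- mean(x)
    if (mx > 0) x / mx else rep(0, length(x))
  }
  tan <- unit_mean(ta); lln <- unit_mean(lcil); len <- unit_mean(lcie)
  den <- cbind(tan, lln, len, tan + lln, tan + len)

  eei <- matrix(NA_real_, n, 5,
                dimnames = list(NULL, paste0("eei", EEI_TYPES)))
  K <- setNames(numeric(5), paste0("eei", EEI_TYPES))
  for (k in EEI_TYPES) {
    d <- den[, k]
    pos <- d > 0
    if (!any(pos))
      stop(sprintf("degenerate index type eei%d: all denominators are zero", k),
           call. = FALSE)
    minpos <- min(d[pos])
    d[!pos] <- minpos
    K[k] <- 10 * minpos
    eei[, k] <- K[k] / d
  }
  out <- data.frame(locus_tag = locus_tag, ta = ta, lcil = lcil, lcie = lcie,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(eei))
  attr(out, "K") <- K
  class(out) <- c("eei_profile", "data.frame")
  out
}

#' Score a gene set with all five elongation efficiency indices
#'
#' Computes per-gene mean codon decoding time (`Ta`), hairpin count and
#' energy loads (`LCIL`, `LCIE`), then the five indices via
#' [eei_from_scores()].
#'
#' @param genes a `gene_set` data.frame (see [parse_genome()]).
#' @param time_table optional [build_codon_time_table()] result; by default
#'   one is estimated from all of `genes`' CDS.
#' @param params [structure_params()] controlling hairpin enumeration.
#' @return an `eei_profile` data.frame (see [eei_from_scores()]).
#' @export
compute_eei_table <- function(genes, time_table = NULL,
                              params = structure_params()) {
  stopifnot(is.data.frame(genes), nrow(genes) >= 2)
  if (is.null(time_table))
    time_table <- build_codon_time_table(genes$cds)
  ta <- compute_ta(genes$cds, time_table)
  lci <- vapply(genes$cds, function(s) compute_lci(s, params = params),
                c(lcil = 0, lcie = 0), USE.NAMES = FALSE)
  eei_from_scores(ta, lci[1L, ], lci[2L, ], locus_tag = genes$locus_tag)
}
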