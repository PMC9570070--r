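PAIR_WEIGHTS <- c(gc = 3, at = 2, gu = 1)

#' Structure-scan parameter set
#'
#' Parameters of the hairpin (perfect local inverted repeat) enumeration.
#' Defaults: minimum stem of 5 base pairs, loop of 3-10 nt, total span of at
#' most 50 nt, Watson-Crick pairs only.
#'
#' @param stem_min minimum stem length in base pairs.
#' @param loop_min,loop_max allowed loop length range in nucleotides.
#' @param max_span maximum hairpin footprint (2*stem + loop) in nucleotides.
#' @param allow_gu include the G:T wobble pair in the allowed pair set.
#' @return list of class `structure_params`.
#' @export
structure_params <- function(stem_min = 5L, loop_min = 3L, loop_max = 10L,
                             max_span = 50L, allow_gu = FALSE) {
  stopifnot(stem_min >= 1, loop_min >= 0, loop_max >= loop_min,
            max_span >= 2 * stem_min + loop_min, is.logical(allow_gu))
  structure(list(stem_min = as.integer(stem_min),
                 loop_min = as.integer(loop_min),
                 loop_max = as.integer(loop_max),
                 max_span = as.integer(max_span),
                 allow_gu = isTRUE(allow_gu)),
            class = "structure_params")
}

#' Enumerate perfect hairpins in a sequence
#'
#' Scans 5'->3' for maximal-stem perfect hairpins: two arms that are exact
#' (reverse) complements under the allowed pair set, separated by a loop
#' within `[loop_min, loop_max]`, with total span at most `max_span`.  A
#' reported hairpin is maximal (its stem can be extended neither outward nor
#' into the loop without violating a constraint) and the accepted set is
#' mutually non-overlapping, chosen greedily leftmost-longest.
#'
#' @param seq DNA sequence (A/C/G/T character scalar).
#' @param params a [structure_params()] object.
#' @return data.frame with 0-based `start_5p`, `start_3p` (arm starts),
#'   `stem_len`, `loop_len`, pair counts `n_gc`, `n_at`, `n_gu`, and
#'   `energy_weight` = 3*n_gc + 2*n_at + 1*n_gu.
#' @export
enumerate_hairpins <- function(seq, params = structure_params()) {
  stopifnot(is.character(seq), length(seq) == 1,
            inherits(params, "structure_params"))
  enc <- match(strsplit(seq, "", fixed = TRUE)[[1]], DNA_BASES) - 1L
  if (anyNA(enc)) stop("sequence alphabet must be A/C/G/T", call. = FALSE)
  m <- scan_hairpins_cpp(enc, params$stem_min, params$loop_min,
                         params$loop_max, params$max_span, params$allow_gu)
  df <- as.data.frame(m)
  df$energy_weight <- PAIR_WEIGHTS[["gc"]] * df$n_gc +
    PAIR_WEIGHTS[["at"]] * df$n_at + PAIR_WEIGHTS[["gu"]] * df$n_gu
  df
}

#' Local complementarity indices of a gene
#'
#' `lcil` is the hairpin count per nucleotide of coding sequence; `lcie` is
#' the energy-weighted hairpin load per nucleotide, with per-pair weights
#' G:C = 3, A:T = 2, G:T = 1 (a simple monotone proxy for pair stability).
#'
#' @param cds the gene's CDS sequence.
#' @param hairpins result of [enumerate_hairpins()] on `cds` (computed if
#'   missing).
#' @param params structure parameters, used only when `hairpins` is missing.
#' @return named numeric vector `c(lcil = , lcie = )`.
#' @export
compute_lci <- function(cds, hairpins = NULL, params = structure_params()) {
  if (is.null(hairpins)) hairpins <- enumerate_hairpins(cds, params)
  n <- nchar(cds)
  c(lcil = nrow(hairpins) / n, lcie = sum(hairpins$energy_weight) / n)
}
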