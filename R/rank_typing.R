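#' Rank genes by index value
#'
#' Rank 1 is the least efficient gene (smallest index), rank `Ntot` the most
#' efficient; ties receive the average of the tied positions.
#'
#' @param eei_values numeric vector of per-gene index values.
#' @return numeric vector of ranks.
#' @export
rank_genes <- function(eei_values) {
  stopifnot(length(eei_values) >= 2, all(is.finite(eei_values)))
  rank(eei_values, ties.method = "average")
}

#' Ribosomal-gene rank statistics for one index type
#'
#' Mean (`mrank`) and population standard deviation (`rrank`, divisor
#' `Nrib`) of the ranks of ribosomal protein genes, plus their normalized
#' forms: `m = 100 * (2 * (mrank - 1) / (Ntot - 1) - 1)` maps the mean rank
#' onto \[-100, 100\] (positive when ribosomal genes sit near the efficient
#' top of the ranking) and `r = 100 * 2 * (rrank - 1) / (Ntot - 1)`
#' normalizes the spread (slightly negative values are possible when
#' `rrank < 1` and are retained as a literal consequence of the formula).
#'
#' @param ranks numeric vector of all gene ranks (see [rank_genes()]).
#' @param is_ribosomal logical vector parallel to `ranks`.
#' @param n_total total number of protein-coding genes (defaults to
#'   `length(ranks)`).
#' @return list with `mrank`, `rrank`, `m`, `r`, `n_rib`, `n_total`.
#' @export
rank_stats <- function(ranks, is_ribosomal, n_total = length(ranks)) {
  stopifnot(length(ranks) == length(is_ribosomal), n_total >= 2)
  x <- ranks[is_ribosomal]
  n_rib <- length(x)
  if (n_rib == 0)
    stop("no ribosomal genes: rank statistics undefined", call. = FALSE)
  mrank <- mean(x)
  rrank <- sqrt(sum((mrank - x)^2) / n_rib)
  list(mrank = mrank, rrank = rrank,
       m = 100 * (2 * (mrank - 1) / (n_total - 1) - 1),
       r = 100 * 2 * (rrank - 1) / (n_total - 1),
       n_rib = n_rib, n_total = n_total)
}

#' Rank statistics for all five index types
#'
#' @param profile an `eei_profile` (see [compute_eei_table()]).
#' @param is_ribosomal logical vector parallel to the profile rows.
#' @return data.frame with columns `type`, `mrank`, `rrank`, `m`, `r`,
#'   `is_base`; attribute `base_type` carries the selected type.
#' @export
rank_stats_all <- function(profile, is_ribosomal) {
  stopifnot(inherits(profile, "eei_profile"),
            length(is_ribosomal) == nrow(profile))
  rows <- lapply(EEI_TYPES, function(k) {
    rs <- rank_stats(rank_genes(profile[[paste0("eei", k)]]), is_ribosomal)
    data.frame(type = k, mrank = rs$mrank, rrank = rs$rrank,
               m = rs$m, r = rs$r)
  })
  out <- do.call(rbind, rows)
  base <- select_base_type(out)
  out$is_base <- out$type == base
  attr(out, "base_type") <- base
  out
}

#' Select the genome's base optimization type
#'
#' The base type is the index variant whose ranking places ribosomal genes
#' highest: the maximum `m`; ties are broken by the minimum `r`, remaining
#' exact ties by the smallest type number (reported via a message).
#'
#' @param stats data.frame with columns `type`, `m`, `r` for all five types.
#' @return integer base type in 1..5.
#' @export
select_base_type <- function(stats) {
  stopifnot(is.data.frame(stats), nrow(stats) == 5,
            all(c("type", "m", "r") %in% names(stats)))
  o <- order(-stats$m, stats$r, stats$type)
  top <- stats[o[1], ]
  tied_m <- sum(stats$m == top$m)
  if (tied_m > 1) {
    if (sum(stats$m == top$m & stats$r == top$r) > 1)
      message("exact m/r tie between types; selecting the smallest type ",
              top$type)
    else
      message("m tie between ", tied_m, " types; broken by minimum r -> type ",
              top$type)
  }
  as.integer(top$type)
}
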