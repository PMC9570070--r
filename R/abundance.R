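#' Load a PaxDb-style protein abundance file
#'
#' Tab-separated dialect: optional '#'-prefixed header lines; data columns
#' either `internal_id  external_id  abundance` (3 columns) or
#' `external_id  abundance` (2 columns), auto-detected from the first data
#' line.  External IDs of the form `taxid.locus` have the numeric taxon
#' prefix stripped so the locus joins the genome annotation directly.
#'
#' @param path file path.
#' @return data.frame with columns `locus_tag`, `abundance` (ppm).
#' @export
load_paxdb <- function(path) {
  if (!file.exists(path)) stop("cannot read abundance file: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("no data lines in abundance file: ", path,
                       call. = FALSE)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncol1 <- length(fields[[1]])
  if (!ncol1 %in% c(2L, 3L))
    stop("expected 2 or 3 tab-separated columns, found ", ncol1,
         " at line ", lineno[1], call. = FALSE)
  idcol <- if (ncol1 == 3L) 2L else 1L
  abcol <- idcol + 1L
  bad_shape <- which(lengths(fields) < abcol)
  if (length(bad_shape) > 0)
    stop("malformed abundance line ", lineno[bad_shape[1]], call. = FALSE)
  ids <- vapply(fields, `[[`, "", idcol)
  ab <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", abcol)))
  bad <- which(!is.finite(ab) | ab < 0)
  if (length(bad) > 0)
    stop("non-numeric abundance at line ", lineno[bad[1]], ": ",
         vapply(fields, `[[`, "", abcol)[bad[1]], call. = FALSE)
  data.frame(locus_tag = sub("^[0-9]+\\.", "", ids), abundance = ab,
             stringsAsFactors = FALSE)
}

#' Aggregate abundance datasets and join to a genome
#'
#' Per-locus median abundance across datasets (a locus absent from a
#' dataset contributes nothing to its median; datasets of unequal breadth
#' are not zero-filled).  Duplicated loci within one dataset are first
#' collapsed to their within-dataset median.  The result is joined against
#' the genome's locus tags, and proteome coverage is the percentage of
#' protein-coding genes with abundance data.
#'
#' @param datasets a data.frame as returned by [load_paxdb()] /
#'   [simulate_abundance()], or a list of them.
#' @param genes a `gene_set` data.frame (see [parse_genome()]).
#' @return data.frame of class `abundance_table` with columns `locus_tag`,
#'   `abundance_ppm`, `n_datasets`; attribute `coverage_percent`.
#' @export
aggregate_abundance <- function(datasets, genes) {
  if (is.data.frame(datasets)) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1, is.data.frame(genes),
            nrow(genes) >= 1)
  per_ds <- lapply(datasets, function(d) {
    stopifnot(all(c("locus_tag", "abundance") %in% names(d)))
    v <- tapply(d$abundance, d$locus_tag, median)
    data.frame(locus_tag = names(v), abundance = as.numeric(v),
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, per_ds)
  med <- tapply(long$abundance, long$locus_tag, median)
  ndat <- tapply(long$abundance, long$locus_tag, length)
  agg <- data.frame(locus_tag = names(med), abundance_ppm = as.numeric(med),
                    n_datasets = as.integer(ndat), stringsAsFactors = FALSE)
  agg <- agg[agg$locus_tag %in% genes$locus_tag, , drop = FALSE]
  if (nrow(agg) == 0)
    stop("no abundance loci match the genome; check that external IDs map ",
         "to locus tags", call. = FALSE)
  agg <- agg[order(match(agg$locus_tag, genes$locus_tag)), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "coverage_percent") <- 100 * nrow(agg) / nrow(genes)
  class(agg) <- c("abundance_table", "data.frame")
  agg
}
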