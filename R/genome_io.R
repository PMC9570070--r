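RIBOSOMAL_PATTERN <- "ribosomal protein"
RIBOSOMAL_EXCLUDE <- "modification|methyltransferase|pseudo|hibernation"

#' Parse an annotated genome into a gene table
#'
#' Reads a GenBank flat file and extracts one record per protein-coding gene
#' (CDS feature), together with genome-level features.  Reverse-strand CDS
#' are reverse-complemented so that `cds` is always the coding strand,
#' 5'->3'.  Records failing quality filters are dropped with a warning:
#' compound/partial locations, missing locus tags, pseudo genes, lengths not
#' divisible by 3, fewer than 2 sense codons, ambiguity codes outside
#' A/C/G/T, internal stop codons (translation table 11), and duplicated
#' locus tags (first occurrence kept).
#'
#' @param path GenBank flat file.
#' @param flag_ribosomal if `TRUE` (default), ribosomal protein genes are
#'   flagged from their `/product` annotation via [flag_ribosomal_genes()]
#'   (`zero_ok = TRUE`: parsing does not fail on genomes without matches).
#' @return A `data.frame` of class `gene_set` with columns `locus_tag`,
#'   `cds`, `product`, `strand`, `is_ribosomal`, `length_nt`, and attribute
#'   `features`: a list with `n_genes`, `n_ribosomal`, `n_trna`,
#'   `gc_content`, `genome_length_nt`.
#' @export
parse_genome <- function(path, flag_ribosomal = TRUE) {
  gb <- read_genbank(path)
  keys <- vapply(gb$features, `[[`, "", "key")
  n_trna <- sum(keys == "tRNA")
  cds <- gb$features[keys == "CDS"]
  if (length(cds) == 0)
    stop("no CDS features in ", path, call. = FALSE)

  rows <- vector("list", length(cds))
  dropped <- character(0)
  for (k in seq_along(cds)) {
    f <- cds[[k]]
    tag <- f$qualifiers$locus_tag
    lab <- if (is.null(tag)) sprintf("<CDS #%d>", k) else tag
    if (isTRUE(f$qualifiers$pseudo)) {
      dropped <- c(dropped, paste0(lab, " (pseudo)")); next
    }
    loc <- gb_parse_location(f$location)
    if (is.null(loc)) {
      dropped <- c(dropped, paste0(lab, " (compound/partial location)")); next
    }
    if (is.null(tag)) { dropped <- c(dropped, paste0(lab, " (no locus_tag)")); next }
    seq <- substr(gb$sequence, loc$start, loc$end)
    if (loc$strand == "-") seq <- revcomp(seq)
    if (nchar(seq) %% 3 != 0) {
      dropped <- c(dropped, paste0(lab, " (length not divisible by 3)")); next
    }
    if (grepl("[^ACGT]", seq)) {
      dropped <- c(dropped, paste0(lab, " (ambiguity codes)")); next
    }
    codons <- split_codons(seq)
    sense <- if (codons[length(codons)] %in% STOP_CODONS)
      codons[-length(codons)] else codons
    if (length(sense) < 2) {
      dropped <- c(dropped, paste0(lab, " (fewer than 2 sense codons)")); next
    }
    if (any(sense %in% STOP_CODONS)) {
      dropped <- c(dropped, paste0(lab, " (internal stop codon)")); next
    }
    prod <- f$qualifiers$product
    rows[[k]] <- data.frame(
      locus_tag = tag, cds = seq,
      product = if (is.null(prod)) "" else prod,
      strand = loc$strand, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(genes) || nrow(genes) == 0)
    stop("genome contains zero valid CDS records: ", path, call. = FALSE)
  if (anyDuplicated(genes$locus_tag)) {
    dup <- unique(genes$locus_tag[duplicated(genes$locus_tag)])
    dropped <- c(dropped, paste0(dup, " (duplicate locus_tag)"))
    genes <- genes[!duplicated(genes$locus_tag), , drop = FALSE]
  }
  if (length(dropped) > 0)
    warning("dropped ", length(dropped), " CDS record(s): ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ..." else "", call. = FALSE)

  genes$is_ribosomal <- FALSE
  genes$length_nt <- nchar(genes$cds)
  rownames(genes) <- NULL
  class(genes) <- c("gene_set", "data.frame")
  if (flag_ribosomal)
    genes <- flag_ribosomal_genes(genes, zero_ok = TRUE)

  gseq <- gb$sequence
  attr(genes, "features") <- list(
    n_genes = nrow(genes),
    n_ribosomal = sum(genes$is_ribosomal),
    n_trna = n_trna,
    gc_content = if (nchar(gseq) > 0)
      nchar(gsub("[^GC]", "", gseq)) / nchar(gseq) else NA_real_,
    genome_length_nt = nchar(gseq))
  genes
}

#' @export
#' @rdname parse_genome
genome_features <- function(genes) attr(genes, "features")

#' Flag ribosomal protein genes
#'
#' Marks the highly expressed reference set used by the rank statistics.
#' With no `custom_list`, a gene is flagged when its product annotation
#' contains "ribosomal protein" (case-insensitive) and none of the exclusion
#' terms ("modification", "methyltransferase", "pseudo", "hibernation") that
#' betray enzymes or regulators merely acting on ribosomal proteins.  A
#' user-supplied locus-tag list overrides the pattern entirely.
#'
#' @param genes a `gene_set` data.frame.
#' @param custom_list optional character vector of locus tags to flag
#'   instead of pattern matching.
#' @param zero_ok internal: permit zero flagged genes (used during parsing).
#' @return `genes` with the `is_ribosomal` column set.
#' @export
flag_ribosomal_genes <- function(genes, custom_list = NULL, zero_ok = FALSE) {
  stopifnot(is.data.frame(genes), nrow(genes) >= 1)
  if (!is.null(custom_list)) {
    unknown <- setdiff(custom_list, genes$locus_tag)
    if (length(unknown) > 0)
      stop("custom ribosomal list contains unknown loci: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    genes$is_ribosomal <- genes$locus_tag %in% custom_list
  } else {
    genes$is_ribosomal <-
      grepl(RIBOSOMAL_PATTERN, genes$product, ignore.case = TRUE) &
      !grepl(RIBOSOMAL_EXCLUDE, genes$product, ignore.case = TRUE)
  }
  if (!zero_ok && sum(genes$is_ribosomal) == 0)
    stop("no ribosomal protein genes identified; supply a custom ",
         "highly-expressed gene list", call. = FALSE)
  ft <- attr(genes, "features")
  if (!is.null(ft)) {
    ft$n_ribosomal <- sum(genes$is_ribosomal)
    attr(genes, "features") <- ft
  }
  genes
}

#' Correlate genome features with per-organism abundance correlations
#'
#' Pearson correlation of each genome-level feature against the
#' per-organism Spearman correlation between protein abundance and the base
#' elongation efficiency index.  A feature that is constant across
#' organisms yields an undefined-correlation flag rather than an error.
#'
#' @param features data.frame with columns `organism`, `genome_length`,
#'   `n_genes`, `n_trna`, `n_ribosomal`, `gc_content`.
#' @param summaries data.frame with columns `organism`, `rho`.
#' @return data.frame with one row per feature: `feature`, `r`, `p`,
#'   `undefined`.
#' @export
genome_features_correlation <- function(features, summaries) {
  stopifnot(is.data.frame(features), is.data.frame(summaries),
            "organism" %in% names(features), "organism" %in% names(summaries),
            "rho" %in% names(summaries))
  df <- merge(features, summaries[, c("organism", "rho")], by = "organism")
  if (nrow(df) < 3)
    stop("need >= 3 organisms with both features and summaries", call. = FALSE)
  feats <- intersect(
    c("genome_length", "n_genes", "n_trna", "n_ribosomal", "gc_content"),
    names(df))
  out <- lapply(feats, function(fn) {
    x <- df[[fn]]
    if (length(unique(x)) < 2)
      return(data.frame(feature = fn, r = NA_real_, p = NA_real_,
                        undefined = TRUE))
    ct <- cor.test(x, df$rho, method = "pearson")
    data.frame(feature = fn, r = unname(ct$estimate), p = ct$p.value,
               undefined = FALSE)
  })
  do.call(rbind, out)
}
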