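# Independent oracles used by the unit and property tests.  These
# deliberately re-derive results from first principles (formula
# transcriptions, brute-force enumeration) rather than calling the package
# code paths they check.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# Exhaustive enumeration of maximal perfect hairpins under Watson-Crick
# pairing, vectorized over the (i, s, l) candidate grid, followed by the
# same greedy leftmost-longest non-overlap rule stated in the docs.
oracle_hairpins <- function(seq, stem_min = 5, loop_min = 3, loop_max = 10,
                            max_span = 50) {
  n <- nchar(seq)
  empty <- data.frame(start_5p = integer(0), start_3p = integer(0),
                      stem_len = integer(0), loop_len = integer(0),
                      energy_weight = numeric(0))
  s_hi <- (max_span - loop_min) %/% 2
  if (n < 2 * stem_min + loop_min || s_hi < stem_min) return(empty)
  rc <- oracle_revcomp(seq)
  grid <- expand.grid(i = seq_len(n), s = stem_min:s_hi,
                      l = loop_min:loop_max)
  grid <- grid[2 * grid$s + grid$l <= max_span &
                 grid$i + 2 * grid$s + grid$l - 1 <= n, , drop = FALSE]
  if (nrow(grid) == 0) return(empty)
  j <- grid$i + grid$s + grid$l
  arm2 <- substring(seq, j, j + grid$s - 1)
  rc1 <- substring(rc, n - (grid$i + grid$s - 1) + 1, n - grid$i + 1)
  keep <- arm2 == rc1
  grid <- grid[keep, , drop = FALSE]
  j <- j[keep]
  if (nrow(grid) == 0) return(empty)
  wc <- c("AT", "TA", "CG", "GC")
  chr <- function(k) substring(seq, k, k)
  end <- grid$i + 2 * grid$s + grid$l - 1
  out_ext <- grid$i > 1 & end < n &
    paste0(chr(grid$i - 1), chr(end + 1)) %in% wc &
    2 * (grid$s + 1) + grid$l <= max_span
  in_ext <- (grid$l - 2) >= loop_min &
    paste0(chr(grid$i + grid$s), chr(j - 1)) %in% wc
  grid <- grid[!out_ext & !in_ext, , drop = FALSE]
  if (nrow(grid) == 0) return(empty)
  oracle_greedy(seq, grid)
}

# Character-by-character variant supporting the G:T wobble pair; O(n^3),
# only for short sequences.
oracle_hairpins_gu <- function(seq, stem_min = 5, loop_min = 3,
                               loop_max = 10, max_span = 50) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  pairs <- c("AT", "TA", "CG", "GC", "GT", "TG")
  pr <- function(a, b) paste0(a, b) %in% pairs
  rows <- list()
  for (i in seq_len(n)) for (l in loop_min:loop_max) {
    s_hi <- (max_span - l) %/% 2
    if (s_hi < stem_min) next
    for (s in stem_min:s_hi) {
      j <- i + s + l
      end <- j + s - 1
      if (end > n) break
      ok <- all(vapply(0:(s - 1), function(t) pr(ch[i + t], ch[end - t]),
                       TRUE))
      if (!ok) next
      if (i > 1 && end < n && pr(ch[i - 1], ch[end + 1]) &&
          2 * (s + 1) + l <= max_span) next
      if (l - 2 >= loop_min && pr(ch[i + s], ch[j - 1])) next
      rows[[length(rows) + 1]] <- data.frame(i = i, s = s, l = l)
    }
  }
  if (length(rows) == 0)
    return(data.frame(start_5p = integer(0), start_3p = integer(0),
                      stem_len = integer(0), loop_len = integer(0),
                      energy_weight = numeric(0)))
  oracle_greedy(seq, do.call(rbind, rows), gu = TRUE)
}

# Greedy leftmost-longest selection plus per-pair energy bookkeeping,
# shared by both oracle variants.  `grid` has 1-based columns i, s, l.
oracle_greedy <- function(seq, grid, gu = FALSE) {
  grid <- grid[order(grid$i, -grid$s, grid$l), , drop = FALSE]
  ch <- strsplit(seq, "")[[1]]
  acc <- list()
  spans <- matrix(numeric(0), ncol = 2)
  for (r in seq_len(nrow(grid))) {
    i <- grid$i[r]; s <- grid$s[r]; l <- grid$l[r]
    lo <- i; hi <- i + 2 * s + l - 1
    if (nrow(spans) > 0 && any(lo <= spans[, 2] & hi >= spans[, 1])) next
    w <- 0
    for (t in 0:(s - 1)) {
      duo <- paste(sort(c(ch[i + t], ch[hi - t])), collapse = "")
      w <- w + switch(duo, "CG" = 3, "AT" = 2, "GT" = 1, 0)
    }
    acc[[length(acc) + 1]] <- data.frame(
      start_5p = i - 1, start_3p = i + s + l - 1, stem_len = s,
      loop_len = l, energy_weight = w)
    spans <- rbind(spans, c(lo, hi))
  }
  do.call(rbind, acc)
}

# Literal transcription of the rank-statistic formulas.
oracle_rank_stats <- function(ranks, rib, n_total) {
  x <- ranks[rib]
  n_rib <- length(x)
  mrank <- (1 / n_rib) * sum(x)
  rrank <- sqrt((1 / n_rib) * sum((mrank - x)^2))
  list(mrank = mrank, rrank = rrank,
       m = 100 * (2 * (mrank - 1) / (n_total - 1) - 1),
       r = 100 * 2 * (rrank - 1) / (n_total - 1))
}

# Textbook Welch statistic.
oracle_welch <- function(x, y) {
  v1 <- var(x) / length(x)
  v2 <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Closed-form Pearson correlation.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - n * mean(x) * mean(y)
  sxx <- sum(x^2) - n * mean(x)^2
  syy <- sum(y^2) - n * mean(y)^2
  sxy / sqrt(sxx * syy)
}

oracle_spearman <- function(x, y) {
  oracle_pearson(rank(x), rank(y))
}

# Normal-equations OLS.
oracle_ols <- function(x, y) {
  slope <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
    (sum(x^2) - length(x) * mean(x)^2)
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Five-column transcription of the index formula with unit-mean scaling,
# K = 10 * min positive denominator, zero clamping.
oracle_eei <- function(ta, lcil, lcie) {
  pr <- function(x) if (mean(x) > 0) x / mean(x) else rep(0, length(x))
  tan <- pr(ta); lln <- pr(lcil); len <- pr(lcie)
  dens <- list(tan, lln, len, tan + lln, tan + len)
  sapply(dens, function(d) {
    mp <- min(d[d > 0])
    d[d == 0] <- mp
    10 * mp / d
  })
}

# Hand-written GenBank fixture exercising forward/reverse CDS, tRNA,
# pseudo genes, compound locations, ambiguity codes and wrapped
# qualifiers.  Layout (1-based):
#   1..12   geneA  ATGAAAGGGTAA       (+)  30S ribosomal protein S4
#   19..30  geneB  revcomp slice      (-)  cds ATGCCCGTTTAG
#   34..45  geneC  ATGTTTAAATGA       (+)  wrapped product
#   46..57  geneD  /pseudo            dropped
#   join CDS and an ambiguity-code CDS  dropped
#   one tRNA feature
write_mini_genbank <- function(path) {
  gene_b <- "ATGCCCGTTTAG"
  seg <- paste0("ATGAAAGGGTAA", "CCCCCC", oracle_revcomp(gene_b), "AAA",
                "ATGTTTAAATGA", "ATGCCCCCCTAA")
  contig <- paste0(seg, "ATGNNNAAATAA", strrep("A", 30))
  q <- function(s) paste0("                     ", s)
  lines <- c(
    sprintf("LOCUS       MINI1 %d bp    DNA     linear   BCT", nchar(contig)),
    "DEFINITION  hand-written parser fixture.",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(contig)),
    q("/organism=\"synthetic construct\""),
    "     CDS             1..12",
    q("/locus_tag=\"gA\""),
    q("/product=\"30S ribosomal protein S4\""),
    "     CDS             complement(19..30)",
    q("/locus_tag=\"gB\""),
    q("/product=\"16S rRNA (adenine(1518)-N(6))-methyltransferase\""),
    "     CDS             34..45",
    q("/locus_tag=\"gC\""),
    q("/product=\"hypothetical"),
    q("protein-like polypeptide\""),
    "     CDS             46..57",
    q("/locus_tag=\"gD\""),
    q("/product=\"pseudo thing\""),
    q("/pseudo"),
    "     CDS             join(1..6,7..12)",
    q("/locus_tag=\"gJ\""),
    q("/product=\"joined protein\""),
    "     CDS             58..69",
    q("/locus_tag=\"gN\""),
    q("/product=\"ambiguous protein\""),
    "     tRNA            80..95",
    q("/locus_tag=\"tr1\""),
    q("/product=\"tRNA-Ala\""),
    "ORIGIN")
  sq <- tolower(contig)
  for (off in seq.int(1L, nchar(sq), by = 60L)) {
    chunk <- substr(sq, off, min(off + 59L, nchar(sq)))
    lines <- c(lines, sprintf("%9d %s", off, chunk))
  }
  writeLines(c(lines, "//"), path)
  path
}

# Minimal hand-built gene table for tests that do not need simulation.
tiny_gene_set <- function() {
  g <- data.frame(
    locus_tag = c("g1", "g2", "g3"),
    cds = c("ATGAAAGGGTAA", "ATGCCCGTTTAG", "ATGTTTAAATGA"),
    product = c("30S ribosomal protein S4", "hypothetical protein",
                "elongation factor Tu"),
    strand = "+", is_ribosomal = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  g$length_nt <- nchar(g$cds)
  class(g) <- c("gene_set", "data.frame")
  g
}
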