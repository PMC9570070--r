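# Minimal GenBank flat-file reader/writer.
#
# No pre-installed R package parses GenBank flat files, so the subset needed
# here is implemented directly: FEATURES entries (key, location, qualifiers,
# with wrapped qualifier/location lines) and the ORIGIN sequence.  Locations
# are 1-based inclusive; `complement(a..b)` is honoured; compound (`join`),
# partial (`<`/`>`) and external references are rejected per record.

#' @noRd
gb_parse_location <- function(loc) {
  loc <- gsub("[[:space:]]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("join|order|,|<|>|:", loc)) return(NULL)
  m <- regmatches(loc, regexec("^([0-9]+)\\.\\.([0-9]+)$", loc))[[1]]
  if (length(m) != 3) return(NULL)
  start <- as.integer(m[2]); end <- as.integer(m[3])
  if (is.na(start) || is.na(end) || start > end) return(NULL)
  list(start = start, end = end, strand = strand)
}

# Returns list(features = list(key, location, qualifiers), sequence).
#' @noRd
read_genbank <- function(path) {
  if (!file.exists(path)) stop("cannot read GenBank file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty GenBank file: ", path, call. = FALSE)

  feat_from <- which(grepl("^FEATURES", lines))[1]
  origin_at <- which(grepl("^ORIGIN", lines))[1]
  if (is.na(feat_from) || is.na(origin_at))
    stop("not a GenBank flat file (missing FEATURES/ORIGIN): ", path,
         call. = FALSE)

  ## features block
  features <- list()
  cur <- NULL
  qual_name <- NULL
  for (ln in lines[seq.int(feat_from + 1L, origin_at - 1L)]) {
    if (grepl("^ {5}[^ ]", ln)) {                     # new feature
      if (!is.null(cur)) features[[length(features) + 1L]] <- cur
      key <- trimws(substr(ln, 6, 20))
      cur <- list(key = key, location = trimws(substring(ln, 22)),
                  qualifiers = list())
      qual_name <- NULL
    } else if (grepl("^ {21}/", ln)) {                # new qualifier
      q <- sub("^ +/", "", ln)
      eq <- regexpr("=", q, fixed = TRUE)
      if (eq > 0) {
        qual_name <- substr(q, 1, eq - 1)
        val <- substring(q, eq + 1)
        cur$qualifiers[[qual_name]] <- gsub("^\"|\"$", "", val)
      } else {                                        # flag qualifier
        qual_name <- q
        cur$qualifiers[[qual_name]] <- TRUE
      }
    } else if (grepl("^ {21}", ln) && !is.null(cur)) { # continuation
      txt <- trimws(ln)
      if (is.null(qual_name)) {
        cur$location <- paste0(cur$location, txt)
      } else if (!isTRUE(cur$qualifiers[[qual_name]])) {
        cur$qualifiers[[qual_name]] <-
          paste(cur$qualifiers[[qual_name]], gsub("^\"|\"$", "", txt))
      }
    }
  }
  if (!is.null(cur)) features[[length(features) + 1L]] <- cur

  ## sequence block
  seq_lines <- lines[seq.int(origin_at + 1L, length(lines))]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  list(features = features, sequence = sequence)
}

#' Write a gene set as a GenBank flat file
#'
#' Serializes a gene table (see [simulate_genome()] or [parse_genome()]) as a
#' single-contig GenBank record.  Genes are laid out in order along the
#' contig, separated by a fixed intergenic spacer; genes whose `strand` is
#' `"-"` are reverse-complemented into genomic orientation and annotated with
#' a `complement()` location.  Each gene gets `gene` and `CDS` features with
#' `/locus_tag` and `/product` qualifiers.
#'
#' @param genes data.frame with columns `locus_tag`, `cds`, `product` and
#'   optionally `strand` (`"+"`/`"-"`, default `"+"`).
#' @param path output file path.
#' @param organism organism name written to the SOURCE/source fields.
#' @param spacer intergenic spacer sequence inserted between genes.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genes, path, organism = "synthetic construct",
                          spacer = strrep("ACT", 7)) {
  stopifnot(is.data.frame(genes), nrow(genes) >= 1,
            all(c("locus_tag", "cds", "product") %in% names(genes)))
  strand <- if ("strand" %in% names(genes)) genes$strand else
    rep("+", nrow(genes))

  n <- nrow(genes)
  segs <- character(0)
  starts <- ends <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    if (nzchar(spacer)) { segs <- c(segs, spacer); pos <- pos + nchar(spacer) }
    g <- genes$cds[i]
    starts[i] <- pos + 1L
    ends[i] <- pos + nchar(g)
    segs <- c(segs, if (strand[i] == "-") revcomp(g) else g)
    pos <- ends[i]
  }
  if (nzchar(spacer)) { segs <- c(segs, spacer); pos <- pos + nchar(spacer) }
  contig <- paste(segs, collapse = "")

  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   BCT",
                     "SYNCONTIG1", nchar(contig)), con)
  writeLines(sprintf("DEFINITION  %s, elongeff serialization.", organism), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", nchar(contig)), con)
  writeLines(sprintf("                     /organism=\"%s\"", organism), con)
  for (i in seq_len(n)) {
    loc <- sprintf("%d..%d", starts[i], ends[i])
    if (strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    for (key in c("gene", "CDS")) {
      writeLines(sprintf("     %-15s %s", key, loc), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"",
                         genes$locus_tag[i]), con)
      if (key == "CDS")
        writeLines(sprintf("                     /product=\"%s\"",
                           genes$product[i]), con)
    }
  }
  writeLines("ORIGIN", con)
  sq <- tolower(contig)
  for (off in seq.int(1L, nchar(sq), by = 60L)) {
    chunk <- substr(sq, off, min(off + 59L, nchar(sq)))
    blocks <- substring(chunk, seq.int(1L, nchar(chunk), 10L),
                        pmin(seq.int(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", off, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
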