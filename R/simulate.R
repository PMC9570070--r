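SIM_REGIMES <- c("codon", "structure_count", "structure_energy", "mixed")

#' Specification of a synthetic genome / abundance experiment
#'
#' A seeded description of the generative world: a genome of `n_genes`
#' protein-coding genes, `n_ribosomal` of which form the highly expressed
#' top tier (default 5%, the typical ribosomal-protein share of a
#' prokaryotic gene complement), with per-gene expression tiers in
#' \[0, 1\] and one of four optimization regimes.  Under `"codon"`, high-tier
#' genes draw synonymous codons from a sharpened within-family distribution
#' (sharpness proportional to `bias_strength`) while hairpin insertion is
#' tier-independent.  Under `"structure_count"` per-gene codon bias is
#' random with respect to tier and the hairpin insertion rate drops with
#' tier (from `hairpin_rate_per_100nt["low"]` for the least expressed genes
#' to `["high"]` for the top tier); inserted stems have random,
#' tier-independent GC and length, so the count - not the energy - carries
#' the clean signal.  Under `"structure_energy"` the insertion rate is flat
#' and the stems of high-tier genes are shorter, so the energy load carries
#' the signal.  `"mixed"` applies the codon and structure-count mechanisms
#' together.
#'
#' @param n_genes number of protein-coding genes.
#' @param n_ribosomal size of the ribosomal (top-tier) subset; default 5%
#'   of `n_genes`.
#' @param gene_length_codons length range (sense codons incl. start).
#' @param regime one of `"codon"`, `"structure_count"`,
#'   `"structure_energy"`, `"mixed"`.
#' @param bias_strength codon-usage sharpening in \[0, 1\] for the top tier.
#' @param hairpin_rate_per_100nt named vector `c(low = , high = )`:
#'   inserted-hairpin rate per 100 nt for the lowest and highest tier.
#' @param rho_target target Spearman correlation between latent efficiency
#'   and simulated abundance, in \[-1, 1\].
#' @param noise_sd spread of log10 abundance (decades); monotone in the
#'   copula score, so it does not affect rank correlations.
#' @param seed integer seed; the same spec and seed give byte-identical
#'   output.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genes = 500, n_ribosomal = NULL,
                            gene_length_codons = c(100, 400),
                            regime = c("codon", "structure_count",
                                       "structure_energy", "mixed"),
                            bias_strength = 0.8,
                            hairpin_rate_per_100nt = c(low = 1.5, high = 0.2),
                            rho_target = 0.5, noise_sd = 1, seed = 1L) {
  regime <- match.arg(regime)
  if (is.null(n_ribosomal)) n_ribosomal <- max(2L, round(0.05 * n_genes))
  stopifnot(n_genes >= 4, n_ribosomal >= 1, n_ribosomal < n_genes,
            length(gene_length_codons) == 2,
            gene_length_codons[1] >= 3,
            gene_length_codons[1] <= gene_length_codons[2],
            bias_strength >= 0, bias_strength <= 1,
            all(c("low", "high") %in% names(hairpin_rate_per_100nt)),
            all(hairpin_rate_per_100nt >= 0),
            rho_target >= -1, rho_target <= 1, noise_sd >= 0)
  structure(list(n_genes = as.integer(n_genes),
                 n_ribosomal = as.integer(n_ribosomal),
                 gene_length_codons = as.integer(gene_length_codons),
                 regime = regime, bias_strength = bias_strength,
                 hairpin_rate_per_100nt = hairpin_rate_per_100nt,
                 rho_target = rho_target, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# Per-gene insertion plan: a list of stem geometries (s = stem length in
# bp, gc = stem GC fraction), one entry per hairpin to insert.
#
# Per-gene insertion plan: a list of segment geometries (s = stem length
# in bp, gc = stem GC fraction, hairpin = fold into a perfect inverted
# repeat or insert as scrambled filler of the same footprint).
#
# "structure_count"/"mixed": every gene receives random segments at the
# SAME total rate (rates["low"]), but only a tier-graded fraction of them
# folds into hairpins (falling from all of them at tier 0 to
# rates["high"]/rates["low"] at tier 1); the remainder is scrambled
# filler.  Inserted random material dilutes a gene's own codon bias, so a
# tier-graded amount of it would leak a spurious codon-time signal; with a
# flat total the dilution is tier-independent and only the hairpin COUNT
# carries the signal.  Graded stems are minimal with per-arm random GC
# (mean weight 12.5, matching chance background hairpins); a flat-rate
# component of long variable-GC stems supplies energy variance independent
# of the count, so the energy load is only a noisy echo of the count and
# the count regime stays identifiable.
#
# "structure_energy": flat insertion rate at the midpoint of the two
# rates; the gradient is carried by the stems themselves, whose GC
# richness (and length) decrease with tier.
#
# "codon": flat rate, moderate stems with random tier-independent GC.
#' @noRd
hairpin_plan <- function(regime, tau, nt, rates) {
  lo <- rates[["low"]]; hi <- rates[["high"]]; mid <- (lo + hi) / 2
  geom <- function(s, gc, hairpin = TRUE)
    list(s = as.integer(s), gc = gc, hairpin = hairpin)
  if (regime %in% c("structure_count", "mixed")) {
    n_tot <- rpois(1, lo * nt / 100)
    p_fold <- if (lo > 0) (lo + tau * (hi - lo)) / lo else 0
    fold <- runif(n_tot) < p_fold
    n_noise <- rpois(1, 0.5 * nt / 100)
    c(lapply(seq_len(n_tot),
             function(i) geom(5L, runif(1), hairpin = fold[i])),
      replicate(n_noise, geom(sample(5:12, 1), runif(1)), simplify = FALSE))
  } else if (regime == "structure_energy") {
    replicate(rpois(1, mid * nt / 100),
              geom(round(11 - 5 * tau), 0.9 - 0.8 * tau), simplify = FALSE)
  } else {
    replicate(rpois(1, mid * nt / 100),
              geom(sample(5:8, 1), runif(1)), simplify = FALSE)
  }
}

# In-place insertion of planned perfect hairpins into a CDS, preserving
# the start codon, the terminal stop, and the absence of internal stops.
#' @noRd
insert_hairpins <- function(cds, plan) {
  if (length(plan) == 0) return(cds)
  nt <- nchar(cds)
  w_min <- 2L * 5L + 3L
  if (nt - 3L - w_min < 4L)
    stop("gene too short (", nt, " nt) for hairpin insertion", call. = FALSE)
  occupied <- matrix(numeric(0), ncol = 2)
  for (geom in plan) {
    placed <- FALSE
    for (try in 1:25) {
      l <- sample(3:8, 1)
      w <- 2L * geom$s + l
      hi <- nt - 3L - w + 1L
      if (hi < 4L) break
      start <- sample(4:hi, 1)
      end <- start + w - 1L
      if (nrow(occupied) > 0 &&
          any(start <= occupied[, 2] & end >= occupied[, 1])) next
      arm <- paste(sample(DNA_BASES, geom$s, replace = TRUE,
                          prob = c((1 - geom$gc) / 2, geom$gc / 2,
                                   geom$gc / 2, (1 - geom$gc) / 2)),
                   collapse = "")
      loop <- paste(sample(DNA_BASES, l, replace = TRUE), collapse = "")
      insert <- if (isFALSE(geom$hairpin)) {
        # same footprint and composition process, but no complementarity:
        # a second independent arm instead of the reverse complement
        arm2 <- paste(sample(DNA_BASES, geom$s, replace = TRUE,
                             prob = c((1 - geom$gc) / 2, geom$gc / 2,
                                      geom$gc / 2, (1 - geom$gc) / 2)),
                      collapse = "")
        paste0(arm, loop, arm2)
      } else {
        paste0(arm, loop, revcomp1(arm))
      }
      cand <- cds
      substr(cand, start, end) <- insert
      c1 <- (start - 1L) %/% 3L + 1L
      c2 <- (end - 1L) %/% 3L + 1L
      touched <- substring(cand, 3L * (c1:c2) - 2L, 3L * (c1:c2))
      if (any(touched %in% STOP_CODONS)) next
      cds <- cand
      occupied <- rbind(occupied, c(start, end))
      placed <- TRUE
      break
    }
    # an unplaceable hairpin (crowded gene) is skipped; the realized count
    # is what the structure scan sees, so this only thins the signal
  }
  cds
}

#' Simulate an annotated genome
#'
#' Generates a gene set with the statistical structure assumed by the
#' elongation efficiency analysis (see [simulation_spec()] for the regime
#' semantics).  Every CDS starts with ATG, ends with a stop codon, has
#' length divisible by 3 and no internal stop under translation table 11.
#' The result can be serialized with [write_genbank()] and re-read with
#' [parse_genome()].
#'
#' @param spec a [simulation_spec()].
#' @return a `gene_set` data.frame with columns `locus_tag`, `cds`,
#'   `product`, `strand`, `is_ribosomal`, `length_nt`, `tier`,
#'   `latent_efficiency`; attribute `spec` keeps the generating spec.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  fams <- codon_families()
  aa_names <- names(fams)
  with_seed(spec$seed, {
    pref <- vapply(fams, function(f) sample(f, 1), "")
    n <- spec$n_genes
    rib <- logical(n)
    rib[sample.int(n, spec$n_ribosomal)] <- TRUE
    tier <- runif(n)
    tier[rib] <- 1
    rates <- spec$hairpin_rate_per_100nt

    lens <- sample(seq.int(spec$gene_length_codons[1],
                           spec$gene_length_codons[2]),
                   n, replace = TRUE)
    cds <- character(n)
    for (g in seq_len(n)) {
      tau <- tier[g]
      # under structure regimes, genes still vary in codon usage - real
      # genomes do, for reasons other than expression (drift, horizontal
      # transfer, regulatory use of non-optimal codons) - but the
      # variation is independent of tier, so the codon term carries no
      # signal: bias strength is random per gene and, family by family, a
      # gene may prefer a codon other than the genome-wide favourite
      # (misaligned genes end up enriched in globally rare codons and get
      # high decoding times)
      if (spec$regime %in% c("codon", "mixed")) {
        beta <- spec$bias_strength * tau
        pref_g <- pref
      } else {
        beta <- spec$bias_strength * runif(1)
        pref_g <- pref
        # gene-level atypicality: most genes follow the genome-wide codon
        # preferences, a minority deviate in many families at once
        q_g <- 0.8 * runif(1)^2
        misal <- runif(length(fams)) < q_g
        for (fi in which(misal)) {
          alt <- setdiff(fams[[fi]], pref[[fi]])
          if (length(alt) > 0) pref_g[[fi]] <- alt[sample.int(length(alt), 1)]
        }
      }
      # per-gene amino-acid composition drawn from a Dirichlet: proteins
      # differ widely in composition, which spreads Ta across genes
      # independently of tier (mean codon family size varies by gene)
      aa_freq <- rgamma(length(aa_names), shape = 3)
      aas <- sample(aa_names, lens[g] - 1L, replace = TRUE,
                    prob = aa_freq / sum(aa_freq))
      codons <- character(length(aas))
      for (a in unique(aas)) {
        f <- fams[[a]]
        k <- length(f)
        idx <- which(aas == a)
        if (k == 1) { codons[idx] <- f; next }
        p_pref <- 1 / k + beta * (1 - 1 / k)
        p <- rep((1 - p_pref) / (k - 1), k)
        p[match(pref_g[[a]], f)] <- p_pref
        codons[idx] <- sample(f, length(idx), replace = TRUE, prob = p)
      }
      g_cds <- paste0("ATG", paste(codons, collapse = ""),
                      sample(STOP_CODONS, 1))
      plan <- hairpin_plan(spec$regime, tau, nchar(g_cds), rates)
      cds[g] <- insert_hairpins(g_cds, plan)
    }

    rib_names <- c(sprintf("50S ribosomal protein L%d", 1:36),
                   sprintf("30S ribosomal protein S%d", 1:21))
    product <- rep("hypothetical protein", n)
    product[rib] <- rep_len(rib_names, sum(rib))
    genes <- data.frame(
      locus_tag = sprintf("SYN_%04d", seq_len(n)),
      cds = cds, product = product,
      strand = sample(c("+", "-"), n, replace = TRUE),
      is_ribosomal = rib, length_nt = nchar(cds),
      tier = tier, latent_efficiency = tier,
      stringsAsFactors = FALSE)
    attr(genes, "spec") <- spec
    class(genes) <- c("gene_set", "data.frame")
    genes
  })
}

#' Simulate a protein abundance profile
#'
#' Gaussian-copula model: the latent elongation efficiency is converted to
#' normal scores, mixed with independent Gaussian noise at the Pearson
#' level `rho_z = 2 * sin(pi * rho_target / 6)` (the inverse of the
#' Spearman correlation of a bivariate Gaussian, `(6 / pi) * asin(rho / 2)`,
#' so the expected Spearman correlation between latent efficiency and
#' abundance equals `rho_target` exactly), then pushed through a monotone
#' log-normal transform onto a ppm-like scale.
#'
#' @param latent_efficiency numeric vector of per-gene latent efficiencies.
#' @param rho_target target Spearman correlation in \[-1, 1\].
#' @param noise_sd spread of log10 abundance (monotone; rank-free).
#' @param seed RNG seed; `NULL` uses the current stream.
#' @param locus_tags gene identifiers (defaults to
#'   `names(latent_efficiency)`).
#' @return data.frame with columns `locus_tag`, `abundance`, ready for
#'   [aggregate_abundance()].
#' @export
simulate_abundance <- function(latent_efficiency, rho_target, noise_sd = 1,
                               seed = NULL,
                               locus_tags = names(latent_efficiency)) {
  n <- length(latent_efficiency)
  stopifnot(n >= 2, rho_target >= -1, rho_target <= 1, noise_sd >= 0)
  if (is.null(locus_tags)) locus_tags <- sprintf("gene%04d", seq_len(n))
  z1 <- qnorm((rank(latent_efficiency, ties.method = "average") - 0.5) / n)
  rho_z <- 2 * sin(pi * rho_target / 6)
  z2 <- with_seed(seed, rho_z * z1 + sqrt(1 - rho_z^2) * rnorm(n))
  data.frame(locus_tag = locus_tags,
             abundance = 10^(1.5 + noise_sd * z2),
             stringsAsFactors = FALSE)
}
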