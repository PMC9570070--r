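make_cds <- function(codons) paste(c("ATG", codons, "TAA"), collapse = "")

test_that("codon decoding times are inverse within-family frequencies", {
  # alpha -> 0 recovers the textbook values
  ref <- make_cds(c(rep("GAA", 50), rep("GAG", 50),
                    rep("AAA", 75), rep("AAG", 25)))
  tt <- build_codon_time_table(ref, alpha = 1e-9)
  expect_equal(tt$t[["GAA"]], 2, tolerance = 1e-6)
  expect_equal(tt$t[["GAG"]], 2, tolerance = 1e-6)
  expect_equal(tt$t[["AAA"]], 4 / 3, tolerance = 1e-6)
  expect_equal(tt$t[["AAG"]], 4, tolerance = 1e-6)

  # single-codon families are pinned at 1 whatever the counts
  tt <- build_codon_time_table(c(ref, make_cds(rep("TGG", 30))))
  expect_equal(tt$t[["ATG"]], 1)
  expect_equal(tt$t[["TGG"]], 1)

  # every sense codon of table 11 present, all t >= 1
  expect_length(tt$t, 61)
  expect_true(all(tt$t >= 1))
  expect_error(build_codon_time_table(character(0)), "empty")
})

test_that("compute_ta averages decoding times over sense codons", {
  ref <- make_cds(c(rep("GAA", 50), rep("GAG", 50)))
  tt <- build_codon_time_table(ref, alpha = 1e-9)
  expect_equal(compute_ta("ATGTGGTAA", tt), 1)
  expect_equal(compute_ta(paste(c(rep("GAA", 100), "TAA"), collapse = ""), tt),
               2, tolerance = 1e-6)

  # brute-force oracle on a random 300-codon gene (sense codons only;
  # internal stops are a parser-level concern, not a scoring one)
  set.seed(5)
  sense <- names(tt$t)
  tt <- build_codon_time_table(vapply(1:20, function(i)
    make_cds(sample(sense, 50, replace = TRUE)), ""))
  codons <- sample(sense, 300, replace = TRUE)
  gene <- make_cds(codons)
  all_codons <- c("ATG", codons)  # terminal stop excluded from the mean
  expect_equal(compute_ta(gene, tt),
               sum(tt$t[all_codons]) / length(all_codons), tolerance = 1e-12)

  # invariant under permutation of codon order
  perm <- make_cds(sample(codons))
  expect_equal(compute_ta(perm, tt), compute_ta(gene, tt), tolerance = 1e-12)
})

test_that("enumerate_hairpins finds constructed hairpins and nothing else", {
  hp <- enumerate_hairpins("GCGCGCAAAAGCGCGC")
  expect_equal(nrow(hp), 1)
  expect_equal(hp$stem_len, 6)
  expect_equal(hp$loop_len, 4)
  expect_equal(hp$start_5p, 0)
  expect_equal(hp$energy_weight, 18)  # six G:C pairs

  expect_equal(nrow(enumerate_hairpins(strrep("A", 40))), 0)
  expect_equal(nrow(enumerate_hairpins("ACGTACG")), 0)  # too short
  expect_error(enumerate_hairpins("ACGTN"), "alphabet")
})

test_that("hairpin enumeration matches the brute-force oracle", {
  set.seed(101)
  for (rep in 1:300) {
    seq <- random_dna(sample(30:300, 1))
    got <- enumerate_hairpins(seq)
    want <- oracle_hairpins(seq)
    expect_equal(nrow(got), nrow(want), info = seq)
    if (nrow(want) > 0) {
      expect_equal(got$start_5p, want$start_5p, info = seq)
      expect_equal(got$start_3p, want$start_3p, info = seq)
      expect_equal(got$stem_len, want$stem_len, info = seq)
      expect_equal(got$loop_len, want$loop_len, info = seq)
      expect_equal(got$energy_weight, want$energy_weight, info = seq)
    }
  }
})

test_that("G:U wobble mode agrees with the character-level oracle", {
  set.seed(77)
  params <- structure_params(allow_gu = TRUE)
  for (rep in 1:40) {
    seq <- random_dna(80)
    got <- enumerate_hairpins(seq, params)
    want <- oracle_hairpins_gu(seq)
    expect_equal(nrow(got), nrow(want), info = seq)
    if (nrow(want) > 0)
      expect_equal(got$energy_weight, want$energy_weight, info = seq)
  }
})

test_that("local complementarity indices are per-nucleotide loads", {
  expect_equal(compute_lci(strrep("A", 40)), c(lcil = 0, lcie = 0))
  expect_equal(compute_lci("GCGCGCAAAAGCGCGC"),
               c(lcil = 1 / 16, lcie = 18 / 16))

  set.seed(9)
  seq <- random_dna(400)
  want <- oracle_hairpins(seq)
  got <- compute_lci(seq)
  expect_equal(got[["lcil"]], nrow(want) / 400, tolerance = 1e-12)
  expect_equal(got[["lcie"]], sum(want$energy_weight) / 400,
               tolerance = 1e-12)
})

test_that("eei_from_scores implements the five-type index formula", {
  # two genes whose type-1 denominators are in ratio 1:2
  p <- eei_from_scores(ta = c(1, 2), lcil = c(0.01, 0.02),
                       lcie = c(0.03, 0.06))
  for (k in 1:5) expect_equal(p[[paste0("eei", k)]], c(10, 5))
  expect_equal(unname(attr(p, "K")[1]), 10 * (1 / 1.5))

  # full formula transcription on random scores
  set.seed(3)
  ta <- runif(10, 1, 6); lcil <- runif(10, 0, 0.1); lcie <- runif(10, 0, 0.3)
  p <- eei_from_scores(ta, lcil, lcie)
  want <- oracle_eei(ta, lcil, lcie)
  for (k in 1:5)
    expect_equal(p[[paste0("eei", k)]], want[, k], tolerance = 1e-12)

  # normalization contract: max exactly 10, min > 0
  for (k in 1:5) {
    expect_equal(max(p[[paste0("eei", k)]]), 10, tolerance = 1e-12)
    expect_gt(min(p[[paste0("eei", k)]]), 0)
  }

  # structure-free genes clamp to the shared top score
  p <- eei_from_scores(ta = c(2, 3, 4), lcil = c(0, 0.02, 0.01),
                       lcie = c(0, 0.06, 0.02))
  expect_equal(p$eei2[1], 10)
  expect_equal(max(p$eei2), 10)

  expect_error(eei_from_scores(ta = c(1, 2), lcil = c(0, 0), lcie = c(1, 2)),
               "eei2")
})

test_that("adding a hairpin never raises structure indices, never moves eei1", {
  set.seed(31)
  n <- 20
  ta <- runif(n, 1, 5); lcil <- runif(n, 0, 0.08); lcie <- lcil * 16
  base <- eei_from_scores(ta, lcil, lcie)
  for (g in sample(n, 5)) {
    for (extra in c(1 / 600, 5 / 600)) {
      lcil2 <- lcil; lcie2 <- lcie
      lcil2[g] <- lcil2[g] + extra        # one more hairpin per 600 nt
      lcie2[g] <- lcie2[g] + extra * 15   # with a typical energy weight
      pert <- eei_from_scores(ta, lcil2, lcie2)
      expect_equal(pert$eei1, base$eei1, tolerance = 1e-12)
      for (k in 2:5)
        expect_lte(pert[[paste0("eei", k)]][g],
                   base[[paste0("eei", k)]][g] + 1e-12)
    }
  }
})

test_that("compute_eei_table scores a gene table end to end", {
  spec <- simulation_spec(n_genes = 40, n_ribosomal = 3,
                          gene_length_codons = c(60, 120), seed = 2)
  genes <- simulate_genome(spec)
  prof <- compute_eei_table(genes)
  expect_s3_class(prof, "eei_profile")
  expect_equal(prof$locus_tag, genes$locus_tag)

  # profile columns agree with independently composed per-gene scores
  tt <- build_codon_time_table(genes$cds)
  expect_equal(prof$ta, compute_ta(genes$cds, tt), tolerance = 1e-12)
  i <- which.max(genes$length_nt)
  expect_equal(unname(prof$lcil[i]),
               nrow(oracle_hairpins(genes$cds[i])) / genes$length_nt[i],
               tolerance = 1e-12)
  for (k in 1:5)
    expect_equal(max(prof[[paste0("eei", k)]]), 10, tolerance = 1e-12)
})
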