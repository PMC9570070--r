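test_that("simulated genes honour the construction contract", {
  spec <- simulation_spec(n_genes = 100, n_ribosomal = 5,
                          gene_length_codons = c(30, 80), seed = 1)
  g <- simulate_genome(spec)
  expect_equal(nrow(g), 100)
  expect_equal(sum(g$is_ribosomal), 5)
  expect_true(all(startsWith(g$cds, "ATG")))
  expect_true(all(substring(g$cds, g$length_nt - 2, g$length_nt) %in%
                    c("TAA", "TAG", "TGA")))
  expect_true(all(g$length_nt %% 3 == 0))
  expect_true(all(g$tier[g$is_ribosomal] == 1))

  # no internal stops anywhere
  internal <- vapply(g$cds, function(s) {
    cod <- substring(s, seq(1, nchar(s) - 5, 3), seq(3, nchar(s) - 3, 3))
    any(cod[-1] %in% c("TAA", "TAG", "TGA"))
  }, TRUE)
  expect_false(any(internal))

  # same spec + seed -> byte-identical output
  expect_identical(simulate_genome(spec), g)
  g2 <- simulate_genome(simulation_spec(n_genes = 100, n_ribosomal = 5,
                                        gene_length_codons = c(30, 80),
                                        seed = 2))
  expect_false(identical(g2$cds, g$cds))
})

test_that("regimes imprint the intended per-gene score gradients", {
  score_means <- function(regime, seed, col) {
    spec <- simulation_spec(n_genes = 150, gene_length_codons = c(80, 160),
                            regime = regime, seed = seed)
    g <- simulate_genome(spec)
    prof <- compute_eei_table(g)
    top <- g$tier >= 0.9
    bottom <- g$tier <= 0.4
    c(top = mean(prof[[col]][top]), bottom = mean(prof[[col]][bottom]))
  }
  for (seed in c(3, 4)) {
    ta <- score_means("codon", seed, "ta")
    expect_lt(ta[["top"]], ta[["bottom"]])
    lc <- score_means("structure_count", seed, "lcil")
    expect_lt(lc[["top"]], lc[["bottom"]])
    en <- score_means("structure_energy", seed, "lcie")
    expect_lt(en[["top"]], en[["bottom"]])
  }
})

test_that("hairpin insertion into impossibly short genes errors", {
  spec <- simulation_spec(n_genes = 10, n_ribosomal = 2,
                          gene_length_codons = c(3, 4),
                          hairpin_rate_per_100nt = c(low = 60, high = 60),
                          seed = 6)
  expect_error(simulate_genome(spec), "too short")
})

test_that("the abundance copula hits its Spearman target", {
  lat <- runif(1000)

  ab <- simulate_abundance(lat, rho_target = 1, seed = 1)
  expect_equal(cor(lat, ab$abundance, method = "spearman"), 1)

  ab <- simulate_abundance(lat, rho_target = 0.5, seed = 2)
  expect_lt(abs(cor(lat, ab$abundance, method = "spearman") - 0.5), 0.06)

  ab <- simulate_abundance(lat, rho_target = 0, seed = 3)
  expect_lt(abs(cor(lat, ab$abundance, method = "spearman")), 0.08)

  ab <- simulate_abundance(lat, rho_target = -1, seed = 4)
  expect_equal(cor(lat, ab$abundance, method = "spearman"), -1)

  # monotone log-normal output on a ppm-like scale, seed-determined
  expect_true(all(ab$abundance > 0))
  expect_identical(simulate_abundance(lat, 0.5, seed = 9),
                   simulate_abundance(lat, 0.5, seed = 9))
})

test_that("the packaged meta-table matches its published digits", {
  fx <- table1_fixture()
  expect_equal(nrow(fx), 25)

  sa <- fx[fx$organism == "Staphylococcus aureus", ]
  expect_equal(sa$rho, 0.66)
  expect_equal(sa$m, 83)
  expect_equal(sa$r, 25)
  expect_equal(sa$eei_type, 1)

  af <- fx[fx$organism == "Acidithiobacillus ferrooxidans", ]
  expect_equal(af$doubling_time_h, 5)
  expect_equal(af$log10_dt, 0.69897)
  expect_equal(as.character(af$growth_class), "slow")

  expect_true(all(fx$rho >= -1 & fx$rho <= 1))
  # printed log10 column is consistent with the hour column
  expect_equal(fx$log10_dt, log10(fx$doubling_time_h), tolerance = 1e-4)

  # dual-entry check: column sums re-derived independently from the
  # published tables
  expect_equal(sum(fx$rho), 10.45, tolerance = 1e-9)
  expect_equal(sum(fx$m), 1740)
  expect_equal(sum(fx$r), 913)
  expect_equal(sum(fx$coverage), 1329.2, tolerance = 1e-9)
  expect_equal(sum(fx$doubling_time_h), 125.996667, tolerance = 1e-6)
  expect_equal(sum(fx$eei_type), 53)
  expect_equal(as.vector(table(fx$growth_class)), c(11, 7, 7))
})
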