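# elongeff

Translation elongation efficiency indices for prokaryotic genomes, and
their correlation with measured protein abundance.

## What this is for

Protein abundance in bacteria and archaea is partly encoded in the coding
sequence itself: highly expressed genes use synonymous codons matched to
the abundant isoacceptor tRNAs (fast decoding), and tend to avoid stable
local mRNA secondary structure (fast translocation).  `elongeff` turns
these two signals into per-gene **elongation efficiency indices**

    EEI_k(i) = K_k / (w1 * Ta'(i) + w2 * Te'(i)),   k = 1..5

where `Ta` is the mean inverse within-family codon frequency (a decoding
time proxy), `Te` is a hairpin load — either the count of perfect local
inverted repeats per nucleotide (`LCIL`) or their energy-weighted count
(`LCIE`) — and the five types switch the two terms on/off (1: codon only,
2: count only, 3: energy only, 4: codon+count, 5: codon+energy).  Each
term is scaled by its genome-wide mean and `K_k` pins scores into
`(0, 10]`.

Because ribosomal protein genes are intensely expressed in essentially all
prokaryotes, the genome's **base optimization type** is called from their
rank statistics: genes are ranked by increasing index, the normalized mean
rank `M` (in [-100, 100]) and normalized rank spread `R` of the ribosomal
genes are computed per type, and the type with maximal `M` (ties: minimal
`R`) wins.  The package then measures how well the base index predicts
PaxDb-style protein abundance (Spearman correlation with bootstrap CI) and,
across organisms, how that correlation relates to `M`, `R`, growth rate and
genome features (Pearson meta-correlations, Welch tests, OLS with
Monte-Carlo cross-validation).  A seeded synthetic genome/abundance
simulator and a packaged 25-organism meta-table make the whole pipeline
testable offline.

Audience: bioinformaticians working on expression prediction from sequence,
codon usage, or comparative genomics of non-model prokaryotes.

## Worked example

```r
library(elongeff)

## simulate a codon-usage-optimized genome and matching abundance profile
spec  <- simulation_spec(n_genes = 300, regime = "codon",
                         rho_target = 0.6, seed = 42)
genes <- simulate_genome(spec)
write_genbank(genes, "demo_genome.gbk")
ab <- simulate_abundance(genes$latent_efficiency, rho_target = 0.6,
                         seed = 43, locus_tags = genes$locus_tag)
writeLines(sprintf("%s\t%.4f", ab$locus_tag, ab$abundance),
           "demo_abundance.tsv")

## score the genome and call its base type
genes2  <- parse_genome("demo_genome.gbk")
profile <- compute_eei_table(genes2)
stats   <- rank_stats_all(profile, genes2$is_ribosomal)
round(stats[, c("mrank", "rrank", "m", "r")], 2)
#>    mrank rrank     m     r
#> 1 260.60 31.75 73.65 20.57
#> 2 145.40 91.78 -3.41 60.73
#> 3 144.07 86.79 -4.30 57.39
#> 4 190.47 79.79 26.73 52.70
#> 5 187.33 76.14 24.64 50.26
attr(stats, "base_type")
#> [1] 1
```

Type 1 (codon usage only) ranks the ribosomal genes highest (`M = 73.7`,
mean rank 260.6 of 300), exactly the regime the simulation imprinted; the
structure-only types carry no signal (`M ~ 0`).

```r
## correlate abundance with the base index
agg <- aggregate_abundance(load_paxdb("demo_abundance.tsv"), genes2)
res <- correlate_abundance_eei(agg, profile, type = attr(stats, "base_type"),
                               seed = 1)
#> rho = 0.507  p = 5.1e-21  n = 300  CI95 = [0.411, 0.580]  coverage = 100%
```

The observed Spearman correlation (0.51) sits near the simulated target
(0.6 between abundance and the *latent* efficiency; the index is an
imperfect estimate of it).

```r
## cross-organism statistics on the packaged 25-organism meta-table
fx <- table1_fixture()
ms <- meta_summary(fx)
ms$mean_rho
#> [1] 0.418
ms$correlations
#>              pair          r            p
#> 1        m_vs_rho  0.7571870 1.177721e-05
#> 2        r_vs_rho -0.4990957 1.109049e-02
#> 3 log10_dt_vs_rho -0.6672294 2.692163e-04
#> 4       dt_vs_rho -0.4459493 2.546082e-02
monte_carlo_cv(fx$m, fx$rho, seed = 1)[c("cv_r_squared", "cv_mse")]
#> $cv_r_squared
#> [1] 0.372218
#> $cv_mse
#> [1] 0.0114973
```

Organisms whose ribosomal genes rank high on their base index (`M`) have
markedly higher abundance correlations (r = 0.76); fast growers beat slow
growers; and the `M`-only regression predicts the achievable correlation
with held-out R² ≈ 0.37.

## Command line

```sh
inst/cli/elongeff simulate  --n-genes 500 --regime codon --seed 1 --out sim/
inst/cli/elongeff score     --genome sim/simulated_genome.gbk --out scores/
inst/cli/elongeff correlate --genome sim/simulated_genome.gbk \
    --abundance sim/simulated_abundance.tsv --eei-type auto --out corr/
inst/cli/elongeff meta      --seed 1 --out meta/
```

Structure-scan flags: `--stem-min`, `--loop-min`, `--loop-max`,
`--max-span`, `--allow-gu`; all stochastic stages take `--seed`, and every
output carries a header with the package version, seed and config hash
(identical config + seed ⇒ byte-identical outputs).

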