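# kinrecon

Marker-based reconstruction of kinship and social structure in
multi-layered cooperative breeding groups, built for the kind of data
produced by field studies of polygynous lamprologine cichlids (e.g.
*Neolamprologus savoryi*): microsatellite genotypes for every member of
dozens of territorial groups, each group a breeder male's "harem" of one
to several breeder-female subgroups with subordinate helpers.

The package answers, from a genotype table plus body sizes and social
metadata, the questions such studies pose:

* How related is everybody? Queller–Goodnight pairwise relatedness
  `r = [Σ_l num_l(x|y) + num_l(y|x)] / [Σ_l den_l(x) + den_l(y)]`,
  referenced to population allele frequencies optionally corrected for
  overall sample relatedness.
* Who is kin to whom? Likelihood-ratio classification of dyads under
  k-coefficient hypotheses (U, HS, FS, PO), with p-values simulated from
  null dyads, and a greedy partition of each group into kin clusters.
* Who produced whom? Pairwise parentage under a zero-or-one Mendelian
  mismatch rule, with a growth model `g(s) = α + β·ln(s)` (mm/day)
  back-calculating whether a candidate was big enough (≥ 31 mm SL) to
  have spawned at the offspring's estimated birth date.
* Who immigrated, who inherited, and how long have breeders held their
  position? The threefold demographic reconstruction: immigrant classes
  (non-immigrant / possible immigrant / immigrant), matrilineal and
  patrilineal inheritance flags, and tenure as the mean of a
  pedigree-based minimum and an age-rank-based maximum (censored when no
  older non-immigrant exists).
* The study-specific statistics: composite workload, 2×2 chi-square
  without continuity correction, one-sample t from printed moments,
  bootstrap ANOVA with averaged Dunnett's C intervals, and the
  Gehan–Wilcoxon survival comparison of breeder tenures.

A forward simulator (`simulate_population()`) generates whole populations
of such groups — Mendelian genotypes, growth-consistent sizes, breeder
turnover with a median-calibrated geometric hazard, inheritance vs.
takeover, immigrant recruitment — together with truth tables, so every
reconstruction stage is testable without any field data.

## Worked example

```r
library(kinrecon)

# printed-count tables bundled with the package
skew <- read.csv(system.file("extdata", "savoryi_parentage_counts.csv",
                             package = "kinrecon"))
chi_square_2x2(skew_2x2(skew, "breeder male"))$statistic
#> [1] 23.33338
parentage_shares(skew)$pct_helper_paternity
#> [1] 20.4969
one_sample_t(mean = 0.135, sd = 0.125, n = 81, mu0 = 0)$t
#> [1] 9.72
```

Breeder males produced far more offspring inside their main subgroup
than in other subgroups of the same territory (χ² = 23.3, df = 1); large
helper males nonetheless sired 20.5% of the offspring whose father could
be identified; and mean within-subgroup relatedness (0.135) is clearly
above zero (t = 9.72, df = 80) — a mixed kin structure.

An end-to-end simulated run:

```r
cfg <- pipeline_config(simulation = simulation_config(n_groups = 6, seed = 1),
                       hwe_alpha = 0, n_null = 500, n_reps = 20, seed = 1,
                       out_dir = "run1")
res <- run_pipeline(cfg)
#> stage simulate: 83 individuals, 10 loci
#> stage frequencies: corrected block over 10 loci
#> stage relatedness: 896 within-group dyads
#> stage parentage: 67 accepted of 703 candidate pairs
#> stage demography: 83 members reconstructed
head(res$demography[, c("id", "status", "immigrant_class", "tenure_mean")])
#>          id         status    immigrant_class tenure_mean
#> 1 G04_I0010   breeder male possible immigrant   659.70042
#> 2 G04_I0022 breeder female      non-immigrant    29.86217
#> 3 G04_I0030         helper      non-immigrant          NA
```

The bundle (`dyads.csv`, `parentage.csv`, `demography.csv`,
`immigration.csv`, `skew.csv`, `comparisons.csv`, `manifest.json`) is
byte-identical under a fixed config and seed.

## Command line

```sh
Rscript inst/cli/kinrecon.R simulate --out sim_out --seed 7
Rscript inst/cli/kinrecon.R run --input sim_out/genotypes.csv --out run_out
Rscript inst/cli/kinrecon.R stats-only \
  --immigration inst/extdata/savoryi_immigration_counts.csv \
  --skew inst/extdata/savoryi_parentage_counts.csv
```

See `vignettes/kin-reconstruction.Rmd` for the model, parameter and
design discussion.
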