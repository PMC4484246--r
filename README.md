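# degnet

Biodegradation meta-network reconstruction for microbial communities in
hydrocarbon-polluted environments.

Metagenomes from oil-polluted sediments carry genes for catabolic enzyme
families — alkane hydroxylases (AlkB, P450), ring-activating dioxygenases
(Ndo, Bph, OphA, ...), and extradiol (XylE) or intradiol (CatA)
ring-cleavage dioxygenases. degnet turns per-sample annotations of such
genes into an analysis-ready picture of a community's degradation
potential, for microbial ecologists comparing sites along environmental
gradients:

* **Screening and profiles.** Hits are kept when bit score > 45 and
  e-value < 1e-3 (both strict). Each family's retained count becomes a
  percentage of the sample's total predicted genes; the sum is the
  **DEGgp** aggregate, `DEGgp = 100 · Σ_f n_f / N_genes`, which is
  comparable across sequencing depths.
* **16S-based imputation.** OTUs mapped to reference genomes contribute
  gene-equivalents (`count × genome family counts` over
  `count × genome size`), filling pathway gaps left by shallow
  metagenomes; DNA and imputed evidence merge by count pooling.
* **Meta-networks.** Every supported catalog reaction (family,
  substrate → product over 3-character chemical codes, e.g. catechol
  "CAT" → ring-fission product "124") becomes a directed edge weighted per
  sample by the family's relative abundance; export to TSV, GraphML or DOT
  (penwidth linear in abundance).
* **Degradation confidence.** Metabolite outcomes from enrichment
  validations calibrate a monotone step function conf(k) — the probability
  a chemical is degraded given k supporting genes (Laplace-smoothed
  frequencies + pool-adjacent-violators). Chemicals with an active outgoing
  edge and conf ≥ 0.90 form each sample's degradable set.
* **Comparative layer.** Shannon diversity, Bray–Curtis / Hellinger PCoA,
  best contiguous two-cluster split along MDS1 (Welch t), OLS regressions
  against temperature, Welch fold contrasts, and the LC-MS feature filter
  (full within-group presence, then raw P < 0.05).
* **Synthetic benchmark.** `generate_study()` plants a linear
  temperature→DEGgp law (1.8 % at 13 °C to 4.21 % at 26.5 °C), a
  richness–temperature anticorrelation, two-cluster community structure and
  a known gene-count→degradation curve, all recoverable by the pipeline.

## Worked example

```r
library(degnet)
st   <- generate_study(study_design(seed = 7))     # 8 samples, 13.0-26.5 degC
prof <- catabolic_profile(screen_hits(st$annotations))
regress_on(vapply(prof, `[[`, 0, "degp_total"), st$metadata$temperature)
#> <regression_fit> slope = 0.155 (SE 0.0443), r^2 = 0.671, P = 0.0129, n = 8
```

The fitted slope (0.155 %/°C) recovers the planted temperature dependence
of catabolic gene content (truth 0.17852 %/°C, well inside the interval);
warmer synthetic sediments carry proportionally more degradation genes.

```r
ord <- pcoa_ordination(community_distance(t(st$otus$counts), "bray_curtis"))
split_on_axis(ord)
#> <cluster_split> axis 1: {S08,S07,S06,S05} vs {S01,S02,S04,S03},
#>   Welch t = -79.324, P = 3.758e-09
```

The MDS1 split recovers the two planted community clusters exactly
(adjusted Rand index 1.0) — the warm-site samples separate from the cold
ones, and Shannon diversity falls with temperature
(`regress_on(apply(st$otus$counts, 2, shannon_index), st$metadata$temperature)`
gives slope −0.036, r² = 0.879).

```r
counts <- chemical_gene_counts(screen_hits(st$annotations), st$catalog)
model  <- fit_confidence(st$evidence, counts, st$catalog, k_cap = 8)
net    <- build_network(prof, st$catalog)
degradable_set(net, model, counts)
#> <degradable_set> threshold 0.90: 7 chemicals in the union; per sample:
#>   S01=7, S02=7, S03=7, S04=7, S05=7, S06=7, S07=7, S08=7
```

Seven chemicals clear the 90 % confidence bar in every sample: these are
the substrates with both an active consuming reaction and consistently
"degraded" metabolite evidence.

## Command line

```sh
Rscript inst/cli/degnet.R simulate --out study/ --seed 4
Rscript inst/cli/degnet.R screen --hits study/hits.tsv --totals study/totals.tsv \
    --out screened.tsv --out-totals screened_totals.tsv
Rscript inst/cli/degnet.R stats --profiles profiles.tsv --metadata study/metadata.tsv \
    --otus study/otus.tsv --out stats.tsv
```

Subcommands: `simulate`, `screen`, `impute`, `merge`, `network`,
`confidence`, `stats`, `report`; global flags `--config`, `--seed`,
`--log-level`. All I/O is header-carrying TSV with `NA` for missing.

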