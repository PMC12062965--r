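# tecapture

Transposable elements (TEs) and viruses occasionally donate protein-coding
domains to their host genomes: a TE-derived exon lands inside a host gene and
its domain — a transposase helix-turn-helix, an integrase, a
reverse-transcriptase — becomes a permanent part of a host protein.
Multicopy host gene families (F-box, ankyrin repeats, BTB/POZ, kinases) are
frequent recipients. `tecapture` is an R package for studying this process
with three tabular, fully seeded pipelines:

1. **Domain co-occurrence screen** — cross-references a protein
   domain-annotation table (InterPro-style) against curated lists of
   multicopy and TE/viral domains, and reports co-occurrence proteins, their
   taxonomic spread per domain pair, the split between single- and
   multi-TE-domain architectures, the Spearman association between family
   size and TE-domain diversity, and the N-terminal positional bias of the
   captured domain (exact two-sided binomial sign test on leftmost relative
   midpoints, ties excluded).
2. **TE-proximity enrichment** — tests whether TE copies cluster near genes
   of a PFAM family. Per gene the statistic is
   `min(10, #classified TE copies overlapping the gene ±500 bp)`, summed
   per family; the null is B bootstrap replicates with every TE re-placed
   uniformly (scaffold chosen length-proportionally); empirical p-values use
   the add-one ECDF rule `p = (1 + #{null ≥ obs}) / (1 + B)`; q-values are
   Benjamini–Hochberg and are reported as signed `−log10(q)` scores.
3. **Structural interaction triage** — post-processes a complex-prediction
   screen: ROC/AUC of pTM and ipTM on a labelled benchmark,
   Kolmogorov–Smirnov threshold selection
   (`D(t) = ECDF_neg(t⁻) − ECDF_pos(t⁻)`), conjunctive high-confidence
   calling, van der Waals clash filtering (strict `d < r₁ + r₂`, Bondi
   radii, inter-chain pairs only), per-bait-residue minimum-distance
   profiles, and per-domain median-distance contact summaries.

A synthetic-data module generates seeded inputs with planted truth for all
three pipelines (domain tables, genomes with planted TE enrichment,
benchmark score sets, toy two-chain complexes), so everything runs and tests
without downloads. `run_pipeline()` orchestrates the stages from one YAML
config and writes a checksummed manifest.

All user-facing functions take a data frame first and return tibbles;
results have `tidy()`/`glance()` methods and `plot_*()`/`autoplot()`
visualisations.

## Worked example

```r
library(tecapture)
library(dplyr)

# 1. screen a synthetic domain table with a planted F-box / Tc1-mariner-HTH pair
planted <- tibble(
  multicopy_accession = "IPR001810",  # F-box
  te_accession        = "IPR041426",  # Tc1/mariner HTH
  n_carriers = 40L, te_position_mode = "nterm")
sim  <- sim_domain_table(n_proteins = 200, planted_pairs = planted, seed = 42)
cooc <- screen_cooccurrence(sim$domains)
positional_bias(cooc)
#> Positional bias: 40 proteins (0 ties excluded)
#>   TE/viral domain N-terminal in 100.0% (exact binomial p = 1.82e-12)

# 2. TE enrichment near a planted focal family (lambda = 5 extra copies/gene)
gen <- sim_genome_with_tes(n_genes = 100, n_tes = 300, n_pfams = 10,
                           n_focal_genes = 20, lambda = 5, seed = 1)
run_te_enrichment(gen$genes, gen$tes, gen$scaffold_lengths,
                  replicates = 200, seed = 2) |> arrange(q) |> head(1)
#>   pfam_id  stratum observed null_mean null_sd p_enrich p_deplete      q score
#> 1 PF_focal all           97      6.03    2.34  0.00498    1      0.0498  1.30

# 3. triage: thresholds from a benchmark, contacts from a planted complex
bench <- sim_benchmark_scores(seed = 3)        # 255 + 490 pairs
glance(roc_analysis(bench, "iptm"))$auc        # 0.9999...
select_threshold_ks(bench, "iptm")$threshold   # 0.561
cx   <- sim_complex("HTH", prey_offset = 4, seed = 4)
prof <- min_distance_profile(cx$model, clash_filter(cx$model))
domain_contact_summary(prof, cx$domain_map)
#> <domain_contact_summary> preferred domain: HTH
#>   domain_label median_dist ...
#> 1 F-box             500.
#> 2 FTH              1000.
#> 3 HTH                 4.00
```

The planted family's observed count (97) sits far above its bootstrap null
(mean 6.0), giving the smallest attainable add-one p at B = 200
(1/201 ≈ 0.005); the planted contact domain is recovered as the argmin of
the per-domain median distances.

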