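---
title: "Methods: screening and statistics for TE-derived domain capture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening and statistics for TE-derived domain capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tecapture)
library(dplyr)
library(tibble)
```

`tecapture` implements three statistical pipelines around one biological
question: what happens when a transposable element (TE) or virus donates a
protein domain to a host multicopy gene family? This vignette documents the
models, the tunable parameters, the numerical choices, and what the
synthetic test beds do — and do not — establish.

## 1. The domain co-occurrence screen

A protein is a *co-occurrence hit* when it carries at least one domain from
a curated multicopy set and at least one from a curated TE/viral set. The
screen is set intersection, so its correctness burden lies in the
bookkeeping around it, which the package pins down as follows.

**Counting convention.** A protein carrying several multicopy and/or
TE/viral accessions contributes to *every* (multicopy, TE) accession pair it
hosts — groups count shared architectures, not proteins. Proteins with
multiple copies of the same TE accession count once per accession
(distinct-accession counting); this is the simpler of the two defensible
conventions and is applied consistently in the partition into
single-TE-domain versus multi-TE-domain architectures (1 vs ≥ 2 distinct
TE/viral accessions).

**Taxonomic spread.** Clade counts are tallied at every rank present in the
taxonomy table. Taxa missing from the table are binned as `"unclassified"`
and kept in denominators, so counts at any rank always sum to the group
size. Reported percentages are rounded half-up to one decimal, matching the
printed style of screen reports (e.g. 808/828 → 97.6%). Ties in ranked
spread lists are broken lexicographically so output is reproducible.

**Positional bias.** The hypothesis is that captured TE/viral domains sit
N-terminally of their multicopy partners. Each hit protein is reduced to two
numbers: the relative midpoint `((start + end) / 2) / length` of its
*leftmost* TE/viral and *leftmost* multicopy annotation. Whether the
original analyses used domain starts, midpoints or span fractions is not
determinable from published summaries; the midpoint was chosen as the least
edge-sensitive single-number reduction, and the choice is isolated in one
place should a sensitivity analysis be wanted. A protein is an N-terminal
case when the TE midpoint is strictly smaller; exact ties are excluded from
both numerator and denominator, and the test is an exact two-sided binomial
against 0.5 (a sign test — exact at any n, no distributional assumptions).
One caveat is documented rather than engineered away: with the leftmost
rule, mirror-image invariance (fraction f → 1 − f under coordinate
reflection) is exact only when each protein carries one annotation per
category; with several copies of one accession, reflection can exchange
which copy is leftmost.

**Family-size association.** Family size (distinct proteins carrying a
multicopy accession anywhere in the table) versus the number of distinct
TE/viral partner accessions is summarised by Spearman's ρ, robust to the
heavy-tailed family-size distributions typical of domain families. When
either variable is constant the correlation does not exist; the result is
flagged `undefined = TRUE` rather than coerced to a number.

## 2. TE-proximity enrichment

**The statistic.** For each gene, the window is the gene body extended
`flank` bp both sides (default 500, clipped at scaffold ends); the per-gene
count is the number of *classified* TE copies overlapping the window by
≥ 1 bp, capped at `cap` (default 10). Because every overlapping copy is at
distance zero, "the capped number overlapping the window" and "up to `cap`
nearest copies within the window" coincide. Per-family statistics are sums
of per-gene counts over the genes carrying that PFAM; a multi-domain gene
contributes to each of its families. Unclassified copies (empty or
`"Unknown"` classification) are removed at load time and tallied.

**The null.** Each bootstrap replicate independently re-places every TE
copy: a scaffold is chosen with probability proportional to its number of
legal start positions (`scaffold length − TE length + 1`) and the start is
uniform among them. Copy number, lengths and classifications are preserved;
shuffled copies may overlap each other and genes — no exclusion zones,
since the marginal TE density is exactly what the null must mimic. The
shuffle randomises positions with copies fixed (no resampling with
replacement): resampling would confound positional enrichment with
copy-number noise, which is not the quantity under test.

**Inference.** With B replicates (default 1000), the enrichment p-value is
the add-one ECDF tail `p = (1 + #{null ≥ obs}) / (1 + B)`, and symmetrically
for depletion; p = 0 is impossible at finite B and the floor is
`1/(B + 1)`. Enrichment p-values are corrected across families by
Benjamini–Hochberg (Bonferroni available) and reported as signed
`−log10(q)`, positive when the observed count exceeds its null mean. Both
tails are always computed and reported. Stratified runs repeat the entire
procedure per TE classification prefix (`DNA`, `LTR`, `RC`, `LINE`, ...).

**Seeding.** Replicate b uses `seed XOR b`, so replicates are independent,
individually reproducible, and insensitive to reordering. Identical inputs
and seed give byte-identical output tables.

**Coordinates.** Internally everything is 0-based half-open; GFF3 (1-based
inclusive) is converted once at the load boundary, BED is native.

## 3. Structural interaction triage

**Thresholding.** On a benchmark of labelled interactor/noninteractor pairs,
each confidence metric (pTM, ipTM) gets a ROC curve over the unique observed
scores with the classifier `score ≥ t ⇒ interactor`; the AUC is the
trapezoidal integral, identical to the Mann–Whitney U statistic scaled by
`n_pos · n_neg` with ties counted ½. The operating threshold is placed by
the Kolmogorov–Smirnov statistic `D(t) = ECDF_neg(t⁻) − ECDF_pos(t⁻)`,
maximised over candidate thresholds. Because the scores are oriented
(interactors high), the one-sided difference is used rather than the
two-sided KS statistic; a negative-everywhere D means the benchmark is not
separable in the oriented direction, which is flagged with an infinite
threshold (nothing passes) instead of silently picking a meaningless
cutoff. At equal separation the *smallest* threshold is taken — the most
inclusive rule. High-confidence calls require both metrics to pass
(conjunction); `any_metric = TRUE` gives the disjunction.

**Clash filter.** Atoms on opposite chains closer than the sum of their van
der Waals radii (strict inequality) are clashed and both are excluded from
distance analysis. Radii default to the Bondi set (C 1.70, N 1.55, O 1.52,
S 1.80, H 1.20, P 1.80 Å) and are overridable via a two-column table.
Intra-chain pairs are not evaluated: internal geometry is the structure
predictor's concern, and the rule exists to protect interface-distance
analysis.

**Distance profiles.** Per bait residue, the minimum Euclidean distance
between its non-excluded atoms and all non-excluded prey atoms — all atoms,
not Cα or centroids, and hydrogens when present, since contact distances are
an atom-level notion. A residue left with no eligible atom pair is encoded
as `NA` ("no contact partner"), never 0 Å, which would fake a perfect
contact. Domain summaries take per-domain medians over contact-bearing
residues; unmapped residues fall under `"other"`; a domain with no
contact-bearing residue is excluded from the argmin with a warning; an exact
tie for the minimum yields `"ambiguous"` rather than an arbitrary pick.

## 4. What the synthetic generators emulate

Each generator is a pure function of its arguments, seed included, and
returns a machine-readable truth record.

- `sim_domain_table()` plants carriers of configured (multicopy, TE)
  accession pairs among background proteins. Background proteins carry decoy
  domains and at most one *categorised* domain — never both categories — so
  the planted truth is exactly the set of screen hits. Planted TE midpoints
  are drawn per position mode (`nterm`: relative position U(0.05, 0.30) with
  the multicopy partner at U(0.70, 0.95); `cterm` mirrored; `uniform`
  independent), making N-terminal recovery near-certain by construction in
  `nterm` mode.
- `sim_genome_with_tes()` places non-overlapping genes uniformly, background
  TEs by the *same* placement model as the bootstrap null (so λ = 0 is an
  exact null for the test), and Poisson(λ) extra copies inside the windows
  of the focal family's genes. Scaffold defaults (3 × 1 Mb) keep gene
  windows a small fraction of the genome so planted signal is not diluted.
- `sim_benchmark_scores()` draws pTM/ipTM from truncated normals on [0, 1]
  with configurable means/sd; the defaults mirror the size of a curated
  benchmark (255 interactors, 490 noninteractors). The distribution family
  is a modelling convenience, not a claim about real predictor score
  distributions.
- `sim_complex()` builds a Cα-trace bait of three labelled segments (HTH,
  F-box, FTH) 500 Å apart, with a prey chain running parallel to the planted
  segment at the requested offset, so every planted-domain residue's minimum
  distance equals the offset (± a ≤ 0.3 Å along-chain jitter). Optional
  clash injection places one prey atom 1 Å from a bait atom. Coordinates are
  rounded to PDB's three decimals so files round-trip bit-identically.
  Side-chain-free toys are sufficient for distance/clash geometry; they do
  not exercise element variety beyond the radius table.

What passing on these beds shows: the set logic, counting rules, tail
probabilities, thresholds and geometry are implemented exactly as specified,
and planted signal of realistic magnitude is recovered. What it does not
show: robustness to the messiness of real annotations (overlapping or
nested domain calls, chimeric scaffolds, fragmented TE models, predictor
score miscalibration). Full-scale published screen results additionally
depend on live UniProt/InterPro snapshots, many genome assemblies and a real
structure screen, and are out of scope here.

## 5. Problem sizes and numerical checks

The test suite checks every operation against an independent brute-force
oracle (naive loops, exhaustive enumeration, hand-counted ECDF tails,
rank-then-Pearson Spearman, O(N²) geometry scans, pROC as an external AUC
cross-check). The standing study sizes, chosen to give the statistics room
to move while keeping the suite quick: co-occurrence oracles on 100 random
1,000-protein tables; enrichment calibration on 200 families (400 genes,
5,000 TEs, B = 200), where the fraction of null families with p ≤ 0.05 must
sit inside the 99% binomial envelope of 0.05; planted recovery (λ = 5, 20
focal genes, B = 200) over 20 seeds; geometry oracles on 100 random ≤
200-atom complexes plus rigid-motion invariance at 10⁻⁶ Å; planted-contact
recovery over 100 seeds. Because counts are discrete, the empirical p-values
are mildly conservative (ties inflate the tail count); the calibration
envelope accommodates this, and at the chosen TE densities the observed
type-I fraction stays well inside it.

Degenerate inputs are errors or flags, never silent numbers: empty null
distributions, zero usable proteins, constant correlation inputs,
non-separable benchmarks, domains with no contacts, zero denominators.

## 6. Pipeline orchestration

`run_pipeline()` executes declared stages from one YAML config. Per-stage
seeds are derived from the global seed by stage-name hashing, so adding or
reordering stages does not reshuffle another stage's randomness. The
manifest records parameters, per-stage seeds, package version and an md5
checksum of every file written; identical configs yield identical manifests
(bar file paths). Paths referenced by a stage must exist before the run
starts unless the run itself produces them (outputs under the configured
output directory).
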