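---
title: "Methods: multi-taxonomy assignment and community phenotype profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-taxonomy assignment and community phenotype profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scfaprof)
```

# The problem

In-vitro fecal cultures supplemented with a single short-chain fatty acid
(SCFA) — formate, acetate, propionate, butyrate, D-lactate, valerate,
succinate, isobutyrate or isovalerate — shift the relative abundance of
community members, because some taxa can consume the supplemented acid
(cross-feeding) while others are inhibited by it. `scfaprof` implements the
complete analysis chain for such experiments, starting from denoised 16S
amplicon sequence variants (ASVs) and per-sample count tables:

1. **Taxonomy** — multi-taxonomy assignment (MTA) of each ASV against a
   reference 16S database;
2. **Abundance** — relative abundance, rank aggregation, and 16S
   copy-number renormalization;
3. **Phenotype** — probabilistic propagation of binary genome phenotypes
   to taxa, and Community Phenotype Indices (CPI) per sample;
4. **Statistics** — Shannon alpha diversity, Bray–Curtis ordination,
   fivefold modulation classification and exact two-tailed Mann–Whitney
   contrasts of each condition against control cultures.

A seeded synthetic-data generator plants known per-strain effects so every
stage can be checked against ground truth without any external download.

# Multi-taxonomy assignment

Each ASV is aligned globally against every reference sequence. With the
best identity denoted $M$, every reference hit with identity strictly
greater than

$$\tau = M - \frac{1 - M}{4}$$

is accepted, and the accepted references' lineages are merged rank by
rank: distinct names are deduplicated, sorted alphabetically and joined
with `"/"` (e.g. genus *Blautia*, species `obeum/wexlerae`). The
multi-name encodes assignment ambiguity among near-equidistant references,
not a mixture.

Numerical choices, fixed and documented here because the threshold rule
alone does not determine them:

* **Strictness.** "Higher than $\tau$" is read as a strict inequality;
  hits exactly at $\tau$ are excluded. Maximal hits (identity $= M$) are
  always included as an explicit rule — at $M = 1$, $\tau = M$, and an
  ASV must still receive its best match. Ties at $M$ are all kept; there
  is no basis to drop either.
* **Identity denominator.** Identity is matches / alignment length under a
  global alignment with unit mismatch and gap costs, so gap columns count
  against identity. The formula is scale-covariant, and is applied on
  fractional identities.
* **Ordering.** Multi-name constituents are sorted alphabetically; no cap
  is applied to the number of accepted hits.
* **Provider.** The built-in aligner (Needleman–Wunsch via `Biostrings`)
  is intended for desk-scale references; for large databases a precomputed
  identity TSV can be supplied instead (`read_identity_tsv()`), keeping
  the thresholding and merging logic identical.

```{r}
compute_mta_threshold(c(1.0, 0.98, 0.9))
```

# Abundance tables and copy-number correction

Counts are closed per sample (`to_relative()`); taxa sharing a (possibly
"/"-joined) name at the analysis rank are summed (`aggregate_to_rank()`).
Because 16S gene copy numbers vary several-fold between taxa, read
fractions over-represent high-copy organisms; `copy_number_renormalize()`
divides each taxon by its mean copy number at a stated rank (an
rrnDB-style table) and re-closes the sample, converting read fractions
into cell fractions.

Choices: the correction rank is an explicit parameter (default species)
so that every analysis states the level at which means were taken;
multi-name taxa average their constituents' entries; taxa missing from
the copy-number table fall back to the table's grand mean and are flagged
(coverage of copy-number references is incomplete in practice), or raise
an error when the fallback is disabled. Phylotype-level analyses run on
uncorrected read fractions by default; correction applies to rank-level
tables where copy-number means are defined. The detection threshold for
"observed" taxa is 0 with strict inequality: a zero count is below the
limit of detection.

# Community phenotype indices

A binary phenotype matrix (BPM) marks, for every reference genome,
whether a complete metabolic pathway is present (1) or absent (0) —
fermentation end-products (butyrate, propionate, acetate, formate,
ethanol, both lactate isoforms), B-vitamin/cofactor biosynthesis, and
amino acid biosynthesis/degradation. For a taxon $t$ the probability of
carrying phenotype $f$ is the pooled mean of the bit over all genomes
whose lineage at the analysis rank matches any constituent name of $t$.
The Community Phenotype Index of sample $s$ is

$$\mathrm{CPI}(s, f) = 100 \times \sum_t P(t, f)\, a_{t,s},$$

the predicted percentage of cells in the community possessing the
pathway, with $a_{t,s}$ the (copy-number corrected) relative abundance.

Two policies matter:

* **Multi-name pooling.** Genomes of all constituent names are pooled
  unweighted. The published form of the probabilistic estimate may weight
  genomes or ranks differently; the pooled mean is a documented stand-in
  and is isolated behind `phenotype_probability()` for replacement.
* **Missing probabilities.** Taxa with no reference genome get an NA
  probability — never a silent 0, which would bias CPI downward. Before
  the weighted sum, such taxa are excluded and the remaining abundances
  re-closed; the excluded mass is reported per sample so users can judge
  coverage.

CPI is bounded in $[0, 100]$ and linear in the abundance vector.

# Differential statistics

All condition-vs-control contrasts use an exact two-tailed Mann–Whitney
test, reflecting the tiny group sizes (typically 4 vs 4 technical
replicates) where asymptotic tests are meaningless. U is computed from
rank sums with mid-ranks for ties; for $n_a + n_b \le 12$ the permutation
null is enumerated completely and the smaller one-sided tail is doubled
and capped at 1. Doubling (rather than summing both tails of an
asymmetric tie distribution) is a documented dialect; for tie-free data
the null is symmetric and the two conventions coincide. The attainable
floor at 4 vs 4 is $p = 2/70 \approx 0.0286$, i.e. $P = 0.03$ at two
decimals — complete separation of the replicate groups. Larger groups
fall back to a tie-corrected normal approximation with continuity
correction.

```{r}
mann_whitney_exact(c(1, 2, 3, 4), c(5, 6, 7, 8))$p.value
```

Fold modulation uses the arithmetic mean of replicate relative abundances
(not geometric means): a feature whose mean changes more than fivefold in
either direction is "altered" (increased/decreased), otherwise
"unaltered"; a feature undetected in control but detected under treatment
is "increased" and marked `new`, the reverse `lost`. Raw p values are
reported at full precision; no multiple-testing correction gates any
output (a Benjamini–Hochberg column is emitted alongside for the user's
hygiene). Shannon diversity is reported in natural-log units; Bray–Curtis
dissimilarity is $1 - \sum_i \min(a_i, b_i)$ on closed compositions, and
ordination is classical PCoA (double-centering + spectral decomposition)
with negative eigenvalues reported, never dropped — Bray–Curtis is not
Euclidean in general, so only range and identity properties are asserted
for it, not the triangle inequality.

# The synthetic-data generator

`generate_reference_database()` builds strain-level phylotypes nested in
species groups under a strict seven-rank taxonomy: strains carry 1–5
substitutions relative to their species consensus (within the resolution
of a single V3–V4 amplicon read), species differ at ≥ 3% of positions,
and each strain contributes one reference genome with the same lineage.
Copy numbers are drawn uniformly from 1–7 per species and shared by its
strains, mirroring species-scale averages. Sequences are 450 nt over
A/C/G/T with uniform substitution positions; no ambiguity codes, no
chimeras, no sequencing error — denoising is upstream of this pipeline's
scope, so ASVs enter as exact phylotype sequences.

`simulate_experiment()` emulates the culture design: a control plus nine
SCFA conditions, four technical replicates each. Its model, chosen once
and documented here:

* **Baseline.** Strain abundances are log-normal, drawn once and shared
  across conditions. The default `sdlog = 0.6` places the most abundant
  of ~30 strains near 9% of the community — the scale of the most
  abundant species group in real control cultures (~8.7%). A scaled-down
  community of 30 strains cannot reproduce the long rare tail of a real
  fecal community (hundreds of phylotypes down to 0.001%); it preserves
  the dominant structure instead, which is what the fold and CPI
  statistics exercise.
* **Planted effects.** In each non-control condition, a configured
  fraction of strains (default 10%) has its abundance multiplied by a
  log-uniform multiplier (default fixed at 10×). Effects are planted at
  strain level, not species level, because SCFA-induced fitness shifts
  are strain-dependent phenomena.
* **Replicate noise.** Each replicate's true cell composition is a
  Dirichlet perturbation of the condition composition with
  $\mathrm{Var}(\pi_i) = p_i(1-p_i)\,\theta$, default $\theta = 0.001$
  (~30% CV on minor taxa) — culture-to-culture variation tight enough
  that a tenfold effect separates replicate groups completely, matching
  the ubiquitous $P = 0.03$ floor in real data. $\theta = 0$ degenerates
  cleanly to a plain multinomial.
* **Sequencing.** Reads are multinomial at the configured depth (default
  100,000) with weights proportional to cell abundance × 16S copy
  number, so raw counts carry the copy-number bias that the pipeline's
  renormalization corrects. Counts sum exactly to the depth
  (sampling-with-replacement convention).
* **Ground truth.** Per-sample true cell compositions (post-Dirichlet,
  pre-sequencing) and per-(condition, strain) multipliers are returned;
  when a BPM is supplied, true CPI expectations are computed directly as
  $100 \sum_i a_i\,\mathrm{bit}_i$ per sample, independently of the
  pipeline. Residual pipeline error against this truth is multinomial
  sampling noise only.
* **Phenotypes.** `generate_phenotype_matrix()` draws a species-level
  majority state per phenotype at a configured prevalence; genomes follow
  their species with probability `coherence`. The default
  `coherence = 1` treats pathway presence as a species-level trait —
  within-species pathway content is largely conserved in genome
  reconstructions, and the probabilistic taxon estimate exists chiefly to
  absorb cross-taxon ambiguity from multi-name assignments. Lower
  coherence models strain-variable pathways; note that with incoherent
  species the species-rank CPI deviates from strain-resolved truth by the
  within-species covariance of abundance and bits, which is a property of
  rank aggregation, not an implementation error.
* **Determinism.** All randomness flows from the configuration seed;
  identical seeds reproduce every artifact byte for byte, and the
  caller's RNG state is left untouched.
* **Inter-individual variation is not modeled** — the emulated design
  pools donors into a single inoculum, so there is one community, varied
  only by condition and replicate noise.

## What passing tests do and do not show

Because the generator writes every input format the pipeline reads, the
test suite can verify end-to-end properties: planted tenfold effects are
recovered with the exact-test floor $p = 2/70$ for 100% of planted
strains, the null design flags essentially nothing as altered, and
pipeline CPIs track ground-truth expectations to well under 2 percentage
points at depth 100,000. These checks validate the *mechanics* —
thresholding, closure, correction, pooling, enumeration. They do not
validate biological fidelity: real communities have richer taxonomies,
reference databases are incomplete and unevenly resolved, real ASVs
carry denoising artifacts, and real phenotype matrices have gaps — all
features the synthetic model deliberately omits.

One quantitative caveat deserves emphasis. Relative abundance is
compositional: planting 10× effects on strains holding a combined
baseline share $m$ inflates the condition's total mass by $1 + 9m$, so
the *observed* fold of a planted strain is compressed to $10/(1 + 9m)$.
With 10% of strains affected, $E[m] = 0.1$ and the expected observed
fold is ≈ 5.3 — right at the conventional fivefold threshold, so the
fold-based "altered" call recovers only ~60–70% of planted strains even
though the exact test separates 100% of them. Detection by significance
is robust to closure; detection by fold is not. The same compression
affects real supplementation experiments.

## Problem sizes used by the shipped checks

The packaged tests and the acceptance script run the full design at
10 species × 3 strains, depth 100,000, 4 replicates, 10 conditions,
repeated over 20 seeds for the recovery and null-calibration statistics,
with smaller 3–5-species studies for IO and pipeline round-trips. These
sizes give stable Monte-Carlo estimates (540 planted features, 5,400
null features) while keeping a complete run in well under a minute on a
single CPU.

# Pipeline and formats

`run_pipeline()` (and the `scfaprof` CLI script under
`inst/scripts/`) chains the stages, validates the configuration before
any stage runs, writes all result tables as tab-delimited UTF-8 with
header rows (abundance tables carry a `#mode=` line), and records a JSON
manifest of input/output MD5 hashes and parameters; reruns on identical
inputs are hash-identical, and every output is re-readable by the
package's own readers.

# Known limitations

* The pooled-mean phenotype probability is a stand-in for the published
  probabilistic estimate, whose exact weighting is not reproduced here.
* The built-in aligner is quadratic per pair; large references should use
  the precomputed-identity path.
* The log-normal/Dirichlet-multinomial simulator is a statistical
  stand-in, not a growth model of anaerobic cultures.
* No rarefaction, variance-stabilizing transforms, PERMANOVA or chimera
  handling — deliberately out of scope.
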