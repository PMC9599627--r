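---
title: "Models and methods in bloomshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in bloomshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

`bloomshift` analyzes nutrient-manipulation bloom experiments: replicate
barrels of a natural phytoplankton community are sampled **mid bloom**
(nutrient replete) and **late bloom** (nutrient depleted), once for a
nitrogen treatment (barrels B1/B3, samples MB1–MB4) and once for an iron
treatment (barrels B2/B4, samples MB5–MB8). The pipeline consumes reference
ORF sequences (FASTA), per-sample read alignments to those ORFs (SAM with
CIGAR and `NM:i` tags), an ORF annotation table (taxon group, genus,
functional label), and a sample sheet. Internally all coordinates are
0-based half-open; SAM and VCF boundaries are 1-based. Only primary
alignments feed counting, identity summaries and pileups, so no read is
counted twice.

By default the late sample of the unchelated iron-replete barrel (MB6) is
excluded from differential expression: it is a "late" sample under replete
conditions and belongs to neither side of the depleted-vs-replete contrast.

# Differential expression

The expression model is the classic two-group negative binomial:
counts $y_{gij} \sim \mathrm{NB}(\mu_{gi}, \phi)$ with variance
$\mu + \phi\mu^2$.

* **TMM normalization.** Between-sample scaling factors are the trimmed
  mean of M-values: the reference column is the sample whose 75th
  count-fraction percentile is closest to the mean; for each sample, log
  ratios $M$ and abundances $A$ are computed over ORFs positive in both
  columns, the extreme 30% of $M$ and 5% of $A$ (per side) are trimmed,
  and the factor is $2$ to the inverse-variance-weighted mean $M$ (binomial
  asymptotic weights). Factors are rescaled to geometric mean 1.
* **Dispersion.** The common dispersion maximizes the negative binomial
  conditional log-likelihood (conditioning on group totals) after counts
  are quantile-adjusted to equalized effective library sizes, searched on
  $\phi \in [10^{-6}, 10]$ by a log grid plus golden-section refinement
  (tolerance $10^{-4}$); adjustment and maximization are iterated twice.
  Tagwise estimates (off by default) shrink per-gene likelihoods toward the
  common value with a prior weight equivalent to 10 degrees of freedom; the
  iron contrast has a single depleted replicate and cannot support stable
  tagwise estimates, which is why the common dispersion is the default.
* **Exact test.** Conditioned on the total of the pooled group counts, the
  split is negative hypergeometric (group sums are NB with sizes
  $n_A/\phi$, $n_B/\phi$; the success probability cancels). The two-sided
  p-value sums all splits no more probable than the observed one, with
  symmetry ties honored via a $1+10^{-10}$ relative tolerance; $\phi = 0$
  degenerates to the exact binomial test. ORFs with total contrast count
  below 5 are not tested (the exact test is degenerate at tiny totals; the
  threshold is configurable).
* **Fold change and FDR.** $\log_2\mathrm{FC}$ is oriented
  depleted/replete — positive means up under limitation — computed from
  normalized group fractions with a half-count pseudo-fraction
  $0.5/N_\mathrm{eff}$ so zero counts stay finite. FDR is
  Benjamini–Hochberg within the tested set.

Three modes separate "physiology" from "abundance": **global** tests ORFs
against full library sizes; **groupwise** restricts to one taxon group and
recomputes library sizes as within-group sums, normalizing away the group's
bloom trajectory; **taxon_proportion** aggregates counts to taxon group ×
sample, so a group that doubles in relative abundance is flagged even when
its internal physiology is unchanged.

# Population-level identity shifts

Per-read percent identity is $100(1 - \mathrm{NM}/\text{aligned columns})$,
aligned columns being the summed M, I and D CIGAR lengths (soft clips are
unaligned and excluded). Histograms use 1-point, left-closed bins on
$[50, 100]$ with the final bin closed. The conserved-shift table keeps an
ORF when (i) it has at least `min_reads` (default 10) reads in every
involved sample, (ii) each replicate barrel's identity delta
(late − mid; positive = closer to the reference late bloom) has the same
sign, (iii) overall mean identity is at least 60%, and (iv) the ORF is
significantly differentially expressed (FDR < 0.05). The 60% floor,
FDR threshold and same-direction rule are the published filters; the read
floor and the use of the mean (rather than median) identity are this
package's choices, both configurable.

# SNVs, density and sweeps

Pileups count A/C/G/T per covered ORF site honoring CIGAR semantics
(deletions consume reference silently, insertions and soft clips consume
read only). A site yields one call per alternate allele at depth ≥ 4,
alternate count ≥ 2 and alternate frequency ≥ 0.05 — the source analysis
states no thresholds, so these conservative defaults are exposed as
configuration. Calling is per sample; the cross-sample site union is taken
afterwards for trajectories, avoiding joint-genotyping machinery. Effects
use the standard genetic code on frame-1 codons: equal amino acids are
synonymous, stop gain/loss is nonsynonymous, positions in an incomplete
trailing codon are `NA` and excluded from effect fractions. SNV density is
distinct called sites divided by the group's ORFs with mean coverage ≥ 4 in
that sample ("total ORFs" is read as *covered* ORFs, flagged as a choice —
an uncovered ORF can contribute no variant, and an all-annotated
denominator would deflate density in shallow samples). A sweep is flagged
when a site's mean alternate frequency rises from ≤ 0.5 (mid) to ≥ 0.9
(late) within an experiment; uncovered stages stay missing and are never
imputed.

# Ortholog clustering

An inverted-index k-mer graph (shared distinct peptide 4-mers, edges below
3 dropped) stands in for the all-vs-all sequence search that fed the
original Markov clustering; real similarity edge lists can be supplied in
its place. MCL canonicalizes node order, adds self-loops at the maximum
incident weight (standard regularization against bipartite oscillation),
and alternates expansion and inflation (default 1.5, the orthoMCL
convention; the source states no parameter) with pruning at $10^{-5}$ until
the matrix stabilizes; clusters are the weakly connected components of the
converged nonzero structure, so the output is order-invariant. Cluster
retention follows the published figure criteria literally: strictly more
than 10 ORFs, at least one significantly DE member in either contrast, and
mean cluster $|\log_2\mathrm{FC}| > 2.5$ for N or Fe; cluster labels are
the modal member annotation with ties concatenated.

# Nutrient-status indices

Within a taxon-group (or genus) scope, marker expression is within-scope
TMM-adjusted CPM summed over labeled ORFs; group-wise normalization makes
the indices invariant to the group's abundance trajectory and to uniform
count rescaling. The indices are
$\log_2\frac{\text{numerator} + c}{\text{denominator} + c}$ with
pseudocount $c = 1$ CPM (bounding the index when a marker is undetected;
the source states no pseudocount): NRT2:GSII for nitrogen (with NR
optionally accepted in the numerator), ISIP1+ISIP2+ISIP3:thiC for iron,
plus the comparison ratios flavodoxin:ferredoxin and ISIP2:ferritin. No
absolute replete/depleted cutoff exists, so only *relative* calls between
samples are made, with a configurable indistinguishability margin (default
0.5 log2 units). Dinoflagellates are a documented exception for the
nitrogen index and are excluded from default reporting sets.

# The synthetic world

The generator emulates, with planted truth: NB ORF expression with
log-normal baselines (sdlog 1 by default) and planted ±3 log2FC effects on
10% of ORFs; per-group bloom trajectories (+2 for diatom groups, +0.5 for
dinoflagellates, +1 for viruses, matching the qualitative narrative of a
diatom-dominated bloom); one reference-diverged subpopulation per taxon
group (5% divergence) whose mixing weight drops 0.8 → 0.2 mid → late, so
the reference-like strain "wins" and identity histograms shift toward the
reference; planted SNVs with stage-specific allele frequencies; and a
uniform 0.1% per-base substitution error. Reads are ungapped substrings
(CIGAR always `<L>M`): percent identity and pileup logic are fully
exercised without indel realignment, which is out of scope. Each sample
draws from an RNG stream derived from the root seed and the sample name,
so adding a sample never perturbs the others and bundles are byte-stable.

What the generator does **not** emulate: indels and structural variation,
paired-end reads, base-quality profiles, coverage biases along transcripts,
chimeric or contaminating reads, and mapping ambiguity (truth alignments
are perfect). A green test therefore establishes algorithmic correctness
against the stated model, not robustness to aligner artifacts. The
within-species diversity parameters (divergence, mixing weights) are
illustrative, not calibrated to any field measurement — the source data do
not constrain them.

Two deliberate world choices in the acceptance experiments: the SNV-calling
experiment uses uniform expression (`expr_sdlog = 0`) and low dispersion so
planted sites actually sit at the stated ~50× depth (under log-normal
spread, low-coverage ORF tails dominate both misses and error-driven
doubleton calls, which measures the coverage distribution rather than the
caller); and the type-I-error experiment uses equal library sizes, where
the conditional exact test is exactly calibrated and the quantile
adjustment is the identity. The iron-index robustness check measures the
systematic index shift as a mean over seeds at low dispersion, because the
claim concerns the expected displacement of the index, not per-sample
sampling noise.

# Numerical notes

Exact-test tie comparison uses a $1+10^{-10}$ relative tolerance so exact
symmetry ties are summed on both sides; the implementation (negative
hypergeometric via `lgamma`) is tested against an independent
`dnbinom`-product enumeration to $10^{-12}$. The golden-section dispersion
search brackets the best grid point; `q2q` count adjustment averages gamma
and normal tail approximations (upper-tail formulation above the mean) and
floors at zero. MCL determinism comes from lexicographic node ordering
before the matrix is built. Degenerate inputs are defined, not patched
around: empty contrasts, zero library sizes, alignments overrunning the
reference, and unknown samples in replicate maps all raise errors naming
the offender; groups with no eligible ORFs report missing (not zero) SNV
density.

# Known limitations

Single-factor contrasts only (no GLMs, batch covariates or multi-factor
designs); no indel or haplotype support; the k-mer graph is a coarse proxy
for alignment-based similarity and is expected to fragment distant
homologs; biomarker indices are relative instruments without absolute
thresholds, and the iron index is expected to be less informative for taxa
that acquire thiamine from the environment rather than synthesizing it.
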