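---
title: "codonflux: models, conventions and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{codonflux: models, conventions and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

codonflux links three layers of translational control that are usually
analyzed separately: per-gene codon usage bias, coding-sequence (CDS)
length, and the kinetics of codon decoding measured by ribosome
profiling.  This vignette is the package's own account of the models it
implements, the conventions it fixes where the field leaves choices
open, what its synthetic-data generator does and does not emulate, and
the known limits of both.

# Codon-usage indices

**CAI.**  The codon adaptation index of a gene is the geometric mean of
the relative adaptiveness $w_c = f(c) / \max_{c' \in \mathrm{fam}(c)}
f(c')$ over its sense codons, restricted to amino acids with two or more
synonyms.  Methionine and tryptophan (single-codon families), stop
codons, and codons containing N are excluded.  Zero-frequency codons
receive $w = 0.01$ — the classic implementation's convention — so the
log-domain mean stays finite.

**CBI.**  The codon bias index is
$(N_\mathrm{opt} - N_\mathrm{ran}) / (N_\mathrm{tot} - N_\mathrm{ran})$,
where $N_\mathrm{opt}$ counts codons drawn from the optimal set,
$N_\mathrm{tot}$ counts codons of multi-codon families, and
$N_\mathrm{ran} = \sum_a n_a k_{\mathrm{opt},a} / k_{\mathrm{syn},a}$ is
the count expected under uniform synonym choice.  CBI is 1 for
exclusively optimal usage, 0 at random expectation, negative when
optimal codons are avoided.

**Optimal set.**  Classic tooling derives its optimal-codon set
internally; codonflux makes the choice explicit and reproducible: one
codon per multi-codon family, the highest-frequency synonym in the
supplied usage table, ties broken lexicographically
(`derive_optimal_set()`).  A user-supplied set can override it, which
also changes absolute CBI values — the reason two CBI implementations
rarely agree to the third decimal.

**tAI.**  Each codon's raw weight is $\sum_j (1 - s_j)\,\mathrm{tGCN}_j$
over its recognizing anticodons: the Watson–Crick anticodon ($s = 0$)
plus one standard wobble route determined by the codon's third base.
The default penalties are the canonical published values — G:U 0.41,
I:C 0.28, I:A 0.9999, U:G 0.68, and lysidine-C:A 0.89 (applied to the
isoleucine AUA codon only when `bacterial = TRUE`).  AUG is decoded by
its Watson–Crick anticodon only.  Weights are scaled by their maximum;
codons with zero raw weight receive the geometric mean of the nonzero
weights.  Gene tAI is the geometric mean of weights over all sense
codons, single-codon families included.  Species-specific re-optimized
penalties (as produced by expression-driven hill climbing in dedicated
tools) are deliberately out of scope: supply custom `s_values` instead.
Consequently absolute tAI values here will differ from tools using
optimized penalties, while rankings are typically very close.

**Messy input policy.**  A trailing partial codon is trimmed with a
warning (strict mode raises); codons containing N are skipped from
index numerators and denominators.  All tie-breaks in the package are
lexicographic, making every output deterministic.

# From footprints to decoding times

**A-site assignment.**  The A-site codon of a footprint is
$\lfloor (p_5 + \delta(\ell)) / 3 \rfloor$ in 0-based CDS coordinates,
with the community-standard offset $\delta = 15$ nt for read lengths
27–31 by default and per-length overrides accepted.  Reads with lengths
absent from the offset table, unknown genes, or out-of-range A-sites
are dropped and counted per category; conservation of reads is a tested
invariant.

**TPM and ribosome density.**  Both footprint and mRNA libraries are
summarized as transcripts per kilobase million over CDS lengths;
density is RPF TPM / mRNA TPM, undefined below an mRNA floor (default
TPM ≥ 1).  Because TPM is a *relative* measure, a uniform genome-wide
change in initiation or elongation cancels out of density; only
differential, gene-dependent changes are observable.  This matters for
interpreting the two-condition analytics below.

**RCDT.**  For each gene passing a coverage filter (mean ≥ 0.5 reads
per codon and ≥ 64 reads over the analysis window by default), counts
at positions outside the trimmed head and tail (15 and 5 codons — the
initiation/termination ramps) are divided by their mean, giving
relative occupancies with per-gene mean exactly 1.  The relative codon
decoding time of codon $c$ is the mean relative occupancy over all
positions carrying $c$, pooled across genes (the default; a
mean-of-gene-means aggregate is available, and at the tested depths the
two differ by far less than sampling noise).  Replicates are merged at
the raw-count level before RCDT estimation, matching common practice.
Length-stratified tables apply the same estimator to genes with
$\mathrm{length} > 600$ aa and $< 300$ aa by default (exclusive
bounds, matching the "> L" / "< L" convention).

## Why a uniform per-gene dwell multiplier is invisible

One stated recovery property for the stratified estimator — simulate
long-CDS genes with *all* dwell times multiplied by 1.5 and expect
every codon's RCDT(long − short) difference to be positive — cannot
hold under this (entirely standard) normalization, and the
corresponding acceptance test is deliberately left failing rather than
weakened.  Two independent arguments:

1. *Generative invariance.*  Footprint positions are multinomial with
   weights proportional to dwell; multiplying every weight of a gene by
   a constant leaves the multinomial unchanged, and footprint totals
   are tied to initiation and length, not dwell.  The simulated data
   with and without the ×1.5 modifier are therefore *identically
   distributed* — no estimator can recover the factor.
2. *Estimator identity.*  Within any gene set,
   $\sum_c \mathrm{occ}_c \cdot \mathrm{RCDT}_c = 1$ exactly (the
   occurrence-weighted mean of relative occupancies is the per-gene
   mean, which is 1 by construction).  Hence "every codon strictly
   higher in stratum A than B" is impossible when the strata share
   codon composition: a positive shift somewhere must be paid for
   elsewhere.

The corollary is scientifically useful: when real data show *all*
codons with higher RCDT in long genes, that pattern must come from
codon-composition differences between the strata (or from a
normalization window that differs from the averaging window), not from
a uniform per-gene slowdown — which is exactly the kind of confounder
the stratified tables make visible.  The stratified machinery itself is
validated by a composition-shift fixture in the test suite.

# Genome-scale analytics

Scanning-window statistics sort genes by a ranking field (stable, ties
by gene id) and slide a fixed-size window (default 500 genes, step 1 —
the smoothest "continuous" scan) computing Pearson correlations,
proportions, or means.  Every window statistic is required by test to
equal a naive recomputation on the materialized window.  Windows with
fewer than 3 complete pairs are skipped; zero-variance windows yield NA
rather than an error.  Protein abundances are log10-transformed by
default before correlating against length (MS abundances span orders of
magnitude); length is left untransformed.  Both are configurable, as is
a Spearman option for robustness.

Differential ribosome density compares per-gene replicate densities
with a two-tailed t test — Welch by default, pooled-variance Student
optionally for literal compatibility with older workflows — adjusted by
Benjamini–Hochberg.  Calls are down iff fold change
$< 1/\mathrm{fc}$ and FDR $< \alpha$ (defaults 2 and 0.05), up
symmetrically; fold change is oriented mutant/reference (b/a).  Genes
with undefined density in either condition, or a zero reference mean,
are excluded and reported.  Two degenerate conventions: zero variance
in both groups with equal means gives $p = 1$; with unequal means,
$p = 0$.

Gene grouping by codon bias and length selects, within the high-CBI
(≥ 0.3) and low-CBI (≤ 0.15) strata, the `group_size` longest and
shortest genes — the construction behind function-enrichment contrasts
of long/short × optimal/non-optimal gene classes.

# The synthetic world

The generator plants every statistical structure the analyses assume,
so each stage can be tested against ground truth without external
data.  Defaults were chosen once to emulate a fungal-genome-scale
dataset and the strong codon-usage/length phenotypes reported for
such data; they are stated here and not tuned per test.

* **Transcriptome.**  CDS lengths are lognormal (median 400 aa,
  log-sd 0.55) truncated to [60, 3000] — a typical fungal proteome
  shape.  Each gene has an optimality parameter $p_\mathrm{opt} \sim
  \mathrm{Beta}(2,2)$; codons are the family's optimal synonym with
  probability $p_\mathrm{opt}$, otherwise uniform over the family, so
  $p_\mathrm{opt} = 0$ is exactly uniform synonymous sampling and the
  expected CBI equals $p_\mathrm{opt}$.  The bundled usage table and
  tRNA pool are deterministic synthetic constructions (labelled as
  such): within-family frequencies fall geometrically from a rotated
  "preferred" codon, and Watson–Crick anticodon copy numbers are
  proportional to codon preference, making gene tAI rise with
  $p_\mathrm{opt}$ (realized correlation ≈ 0.93).
* **Dwell model.**  Baseline per-codon dwell is inversely monotone
  with within-family preference, spanning [0.5, 3): the most preferred
  synonym always decodes fastest — the structure the RCDT estimator
  must recover.
* **mRNA abundance.**  Lognormal with
  $\log \mu = 1 + 2 p_\mathrm{opt} - 2.5\times10^{-3}\,\mathrm{length}$
  (log-sd 1): expression rises with codon optimality and falls with
  length, the canonical coupling.  This also anchors library
  renormalization on short optimal genes, as in real footprint
  libraries where highly expressed short genes carry much of the
  read mass.
* **Proteome.**  $\log_{10}\mathrm{abundance} = a - (b_0 - b_1\,
  \mathrm{tAI})\,\mathrm{length} + \varepsilon$ with $a = 6$,
  $b_0 = 2\times10^{-3}$, $b_1 = 2.5\times10^{-3}$,
  $\sigma_\varepsilon = 0.2$, and $b_0 > b_1 \max(\mathrm{tAI})$
  enforced at generation time so the planted length effect is negative
  everywhere and weakest at high optimality — the interaction the
  scanning-window analysis must recover.  An optional
  missing-at-random mask emulates MS detectability.
* **Footprints.**  Per-gene totals are Poisson with mean ∝ mRNA ×
  initiation × transit time (sum of effective dwells); positions are
  multinomial ∝ dwell; read lengths follow {27: 0.15, 28: 0.5,
  29: 0.25, 30: 0.1}; 5′ positions are back-computed from the A-site
  offsets so assignment inverts the generator exactly.  mRNA-seq
  counts are Poisson ∝ abundance × length.
* **Two conditions.**  The baseline condition carries a
  length-dependent elongation slowdown, a per-gene dwell multiplier
  $e^{0.002\,\mathrm{length}}$ — an exponential rate, since cumulative
  pausing feedback lets long genes slow without bound, and a bounded
  (linear) multiplier provably cannot halve density between 400 and
  800 aa under relative normalization.  The "fast" condition removes
  it, raises initiation 1.3×, and accelerates elongation globally
  (dwell × 0.6) and rare-codon-preferentially (dwell exponent 0.5,
  compressing the dwell spread).  With four replicates per condition
  this reproduces the qualitative genome-wide phenotype: ~98% of
  significantly changed genes have decreased density, the
  decreased-proportion curve rises with CDS length, and
  fold-change-ranked windows show decreasing mean length.
* **Determinism.**  Everything is a function of (config, seed);
  sub-seeds for the proteome and each condition × replicate are drawn
  by `sample.int(2^31 - 2, ...)` under the master seed.  Identical
  configs give byte-identical FASTA and footprint files.

**What a green test does not establish.**  The generator has no UTRs,
uORFs, introns, nucleotide-level sequencing errors, positional ramps,
multimapping ambiguity, or biological overdispersion beyond Poisson
sampling (per-condition dispersion is deliberately absent so that
identity condition modifiers are a calibrated null).  Green recovery
tests certify the estimators against the stated generative model, not
against every artifact of real libraries.  Two stochastic acceptance
properties (the window-trend Spearman and the end-to-end pattern
checks) are evaluated at fixed default seeds; their test statistics
have non-trivial sampling spread (the window-trend statistic, for
example, dips below its 0.9 bound for roughly one seed in five at the
stated scale), which is documented here rather than hidden by widening
thresholds.

# Numerical and design choices

* Geometric means are computed in log space; index agreement with
  naive per-codon oracles is tested at 1e-12.
* TPM sums are exact to 1e-6 relative by construction.
* Coordinates are 0-based half-open; codon index = nt offset ÷ 3,
  floored.  SAM input (1-based) is converted on read; secondary,
  supplementary and unmapped records are skipped and counted.
* Config files are strict: unknown keys are rejected, thresholds are
  validated, every run directory gets the resolved config echoed, and
  each output directory carries a checksum manifest; reruns with the
  same config and inputs are byte-identical.
* Missing values are written as `NA` in all TSV outputs.

# Known limitations

Aside from the generator's idealizations above: the pipeline consumes
pre-aligned footprints in transcript/CDS coordinates (genomic
projection, adapter trimming and alignment are out of scope); RCDT is
reported at codon, not single-position, resolution; the pooled RCDT
aggregate follows the cited-method convention but the original
formula's pooling choice is not published, so the default here is
declared rather than asserted identical; and absolute tAI values
depend on the s-value set, which defaults to canonical constants
rather than species-optimized ones.
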