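---
title: "Peptide location fingerprinting: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide location fingerprinting: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plfr)
```

## What the method measures

Peptide location fingerprinting (PLF) compares the *distribution* of
peptide spectral counts along a protein's primary structure between two
groups, rather than the protein's total abundance. The premise: a
structural modification — oxidation, glycation, partial unfolding,
protease cleavage — changes how readily tryptic peptides are released
and detected from the affected region, so a locally altered region
shows a locally altered peptide yield even when whole-protein abundance
is constant. The analysis unit is a (protein, tissue region) pair; each
region is an independent comparison, and each protein is treated as its
own experiment.

The input is deliberately modest: per-sample peptide lists (sequence,
parent accession, spectral count) of the kind any PSM-scoring tool
exports, plus the protein sequences. Everything upstream — searching,
FDR control, protein inference — is assumed done; `plfr` applies only
the two input filters that matter for the method's validity (exclusive
peptide-to-protein mapping is assumed from upstream, and records below
the minimum identification probability, default 0.95, are dropped;
records with no probability column are presumed pre-filtered).

## The pipeline, step by step

**Segmentation.** Proteins are tiled into consecutive segments of 50
residues (`nominal_size`). The terminal segment keeps its actual
(shorter) length and is never merged into its neighbour: the C-terminus
is where biologically interesting signals such as propeptide retention
live, and merging would dilute them. A peptide is counted in *every*
segment its residue interval intersects, with its full spectral count —
no fractional proration. A boundary-spanning peptide therefore
contributes twice; this double counting is intentional and means segment
totals are not a partition of the raw count total.

**Normalisation.** For one (protein, region) table with per-sample row
totals $T_s$, the anchor is $M = \mathrm{median}\{T_s : T_s > 0\}$ over
*all* samples of both groups, and each retained row is scaled by
$M/T_s$. Every retained row then sums exactly to $M$, so any
whole-protein, whole-row abundance factor cancels. Two consequences
worth knowing:

* Samples with $T_s = 0$ admit no scale factor. They are dropped and
  recorded as absences rather than imputed; whether a protein is
  analysable at all is governed by the separate one-group exclusion
  rule below. The median is computed over positive totals only.
* Scaling one sample's raw row by a constant leaves all normalised rows
  literally unchanged whenever the scaling does not move the median
  anchor (e.g. scaling the largest total upward); if it does move the
  anchor, all normalised rows rescale by the same common factor, so
  group contrasts, t statistics and p-values are still exactly
  invariant. The test suite asserts both forms.
* A single-segment protein is degenerate: after normalisation every
  sample has the identical value $M$, so PLF can say nothing about
  proteins shorter than one segment — by design, since there is no
  "along the structure" to compare.

**Exclusion rules.** Proteins detected (positive total) in only one
group are excluded entirely — a presence/absence difference is an
abundance statement, not a location statement. A group with a single
retained sample leaves the difference profile available (with a
warning) but blocks testing, which needs within-group variance.

**Per-segment test.** Normalised per-sample values in each segment are
compared between groups with an unpaired pooled-variance one-way
comparison: the F statistic with one numerator degree of freedom,
identical to the square of the pooled two-sample t, reported as a
two-sided p. With exactly two groups and two-to-three replicates per
group, a richer mixed or repeated-measures structure is not
identifiable, and the published star annotations this package mirrors
are per segment; we therefore test each segment separately and make no
attempt to model segments jointly. Degenerate cases are defined, not
guessed: a segment with all values identical across both groups has
p = 1; zero pooled variance with differing means gives p = 0; a segment
with zero counts in every sample of both groups is untestable and drops
out of the correction family.

**Multiplicity.** Bonferroni within the protein:
$p_{\mathrm{corr}} = \min(1, p \cdot m)$ with $m$ the protein's number
of *testable* segments in that region (excluding all-zero segments, so
sparse proteins are not over-penalised). Stars on the corrected value:
\* ≤ 0.05, \*\* ≤ 0.01, \*\*\* ≤ 0.001. A protein is flagged for a
region when any segment reaches corrected p ≤ 0.05. No FDR alternative
is offered: the family is small and the field's convention for this
analysis is family-wise control per protein.

**Difference profiles.** Per segment, (mean aged − mean young) divided
by the segment length, giving a per-residue yield difference; positive
means higher yield in aged. The default divides the terminal segment by
its *actual* length (avoids deflating C-terminal signal);
`tail_mode = "strict"` divides by the nominal 50 everywhere for
compatibility with tools that do. For cross-region overlays each
region's profile is divided by its own maximum absolute value, mapping
onto [−1, 1]; all-zero profiles stay at zero. Max-absolute scaling was
chosen for being parameter-free and preserving sign and shape; nothing
downstream depends on the choice.

**Peptide location.** Exact, case-insensitive substring search.
Peptides occurring more than once in their parent default to the first
(lowest) position with a warning — upstream exclusivity filtering makes
this rare, and counting every occurrence would double-count spectra;
`"all"` and `"error"` policies are available. Isoleucine and leucine
are *not* conflated: the input derives from database search and is
already sequence-exact. Bracketed modification tags are stripped by the
reader before matching.

## The synthetic-study generator

The generator exists so that every pipeline stage, and the method's
operating characteristics, can be verified with known ground truth:

* **Proteome**: random sequences with K+R frequency near 11% (so
  tryptic peptide lengths are realistic), or any user FASTA.
* **Digestion**: cleavage C-terminal to K/R except before P, up to 2
  missed cleavages (configurable), peptides kept in a 7–35-residue
  detectability window.
* **Detectability**: each peptide is detectable with probability 0.6
  and carries a fixed uniform weight, drawn once per study and
  normalised within protein — uneven but reproducible coverage along
  the structure, with no claim to model ionisation physics.
* **Counts**: the expected count of peptide *i* of protein *p* in
  sample *s* is baseline$_p$ × weight$_i$ × (effect folds), multiplied
  by a per-(sample, protein) Gamma(size, size) factor shared across the
  protein's peptides; the realised count is Poisson. Marginally each
  count is negative-binomial with the configured dispersion
  (default size 25, i.e. replicate whole-protein coefficient of
  variation ≈ 20%), and the overdispersion is *shared* within a
  protein-sample — the realistic structure for spectral counting,
  where replicate noise is dominated by whole-protein abundance
  variation, and exactly the component the median normalisation is
  designed to cancel. Baselines are log-normal across proteins
  (meanlog log 300, sdlog 0.7) spanning low-coverage to abundant
  proteins.
* **Effects**: a fold change applied wholesale to the expectation of
  every peptide overlapping a stated residue interval, in a stated
  group (optionally one region) — mirroring how a structural
  modification blocks or enhances release of whole peptides. Fold 1 is
  no effect; fold 0 silences the region; a whole-protein interval is an
  abundance shift, the confound PLF must ignore.
* The study seed fully determines the dataset, and generation leaves
  the caller's RNG state untouched.

What the generator does **not** emulate: retention-time or m/z
structure, post-translational modifications, shared peptides between
proteins, correlated effects between neighbouring regions, or
identification errors. Passing the validation suite therefore
demonstrates the statistical machinery under the stated count model; it
does not certify behaviour under search-engine artefacts or chimeric
identifications.

## Validation scenarios and sizes

The test suite and `scripts/acceptance.R` validate on three scenarios,
sized to give stable rates while keeping a full run in well under a
minute of simulation time:

* **Null**: 500 proteins of 300 residues, 3 vs 3 replicates, log-normal
  baselines, no effects — measures the per-protein family-wise flag
  rate at corrected 0.05.
* **Recovery**: 500 proteins carrying a 4-fold aged-group suppression
  over residues 101–200 (segments 3–4 of 6) at a fixed baseline of 400
  expected counts (~65 per segment), plus 250 effect-free proteins in
  the same experiment — measures per-segment sensitivity and
  effect-free specificity. The scenario was designed once from a
  segment-level pilot oracle (power as a function of per-segment
  baseline and segment count under this noise model) and then frozen.
* **Confound**: 300 proteins with a whole-protein 3-fold aged shift —
  the flag rate must be indistinguishable from null, the property that
  separates PLF from label-free quantification.

Exactness checks (segment-mapping against a per-residue oracle,
normalisation conservation to 1e-9 relative, p-values against a
closed-form pooled-t oracle to 1e-10, Bonferroni/star grids against
`p.adjust`) run on fuzzed cases alongside.

## Known limitations

* **Compositional closure.** Because every sample is renormalised to
  the same total, a strong suppression in one region necessarily
  inflates the others; large effects produce significant
  opposite-signed segments elsewhere in the same protein. Read
  profiles as redistribution of yield, not as independent per-segment
  abundances.
* **Small-sample t.** With 3 vs 3 replicates of discrete counts the
  pooled-t null is approximate; the realised family-wise error sits
  near, and can slightly exceed, the nominal 0.05 (the acceptance
  script measures it). Bonferroni's guarantee is only as good as the
  per-segment p-values.
* **Power.** With two-to-three replicates and ~20% replicate CV, only
  multi-fold regional changes are reliably detectable; subtle
  modifications need more replicates.
* **Coordinates.** All coordinates are 1-based and inclusive at both
  ends throughout the package.
* The original analyses this method descends from ran on
  webtool-processed exports; where their unstated internal conventions
  could not be known (within-protein multi-occurrence handling,
  trailing-segment treatment, composite scaling scheme), this package
  documents its own choice above and exposes it as an option where
  reasonable.
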