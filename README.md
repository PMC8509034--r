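# plfr — peptide location fingerprinting for spectral-count proteomics

Long-lived extracellular-matrix proteins (collagens, proteoglycans,
elastic-fibre proteins) accumulate structural damage with age —
glycation, oxidation, protease cleavage — that often leaves whole-protein
abundance unchanged. Peptide location fingerprinting (PLF) detects such
changes from ordinary label-free LC–MS/MS peptide lists: if a region of a
protein becomes locally modified, unfolded or cleaved, the tryptic
peptides released from that region change in yield even when the rest of
the protein does not. `plfr` implements the PLF analysis as a tested,
scriptable R package for proteomics researchers comparing two groups
(e.g. young vs aged donors) across one or more tissue regions.

## The method

For each protein and tissue region:

1. **Segment** the primary structure into consecutive 50-aa segments
   (the last segment may be shorter).
2. **Map** each identified peptide (exclusive to its protein, ≥95%
   identification probability) to every segment its residue interval
   intersects; a peptide spanning a boundary is counted in both
   segments. Spectral counts are summed per segment per sample.
3. **Normalise** each sample's whole-protein count to the
   experiment-wide median: sample *s* with row total *T<sub>s</sub>* is
   scaled by *M*/*T<sub>s</sub>*, where *M* is the median of the
   positive totals over all samples of both groups. Per-segment
   comparisons are thereby independent of whole-protein abundance.
4. **Test** each segment between groups with an unpaired
   pooled-variance comparison (one-way F with 1 numerator df, the square
   of the pooled two-sample t), Bonferroni-corrected within the protein:
   *p*<sub>corr</sub> = min(1, *p* · *m*) with *m* the protein's
   testable segments. Stars: \* ≤ 0.05, \*\* ≤ 0.01, \*\*\* ≤ 0.001.
5. **Profile**: per segment, (mean aged − mean young) / segment length —
   the per-residue peptide-yield difference along the structure;
   positive = higher yield in aged.
6. **Compare regions**: proteins with ≥1 significant segment are
   intersected across tissue regions (full Venn partition), and the
   PLF-flagged union can be differenced against an abundance-based
   significant list to find proteins whose change is structural, not
   quantitative.

A seeded synthetic-study generator (tryptic digestion with missed
cleavages, per-peptide detectability, negative-binomial spectral counts
with shared replicate overdispersion, implanted region-specific yield
perturbations) makes every stage verifiable without any external data.

## Worked example

Simulate a 20-protein, three-region study with a 4-fold aged-specific
suppression implanted in residues 151–250 of one protein, then analyse
it:

```r
library(plfr)

prot <- random_proteome(20, c(200, 500), seed = 8)
eff  <- data.frame(accession = "SYNP0003", start = 151, end = 250,
                   group = "aged", fold_change = 0.25)
sim  <- simulate_study(plf_study_spec(proteome = prot, effects = eff, seed = 42))

fit <- plf(sim$peptides, sim$proteins, samples = sim$samples)
fit
#> PLF analysis: 3 region(s), 20 tested protein(s)
#>   anterior: 1 / 20 proteins flagged (corrected p <= 0.05)
#>   left_lateral: 1 / 20 proteins flagged (corrected p <= 0.05)
#>   posterior: 4 / 20 proteins flagged (corrected p <= 0.05)

dplyr::filter(tidy(fit), accession == "SYNP0003", region == "posterior")
#>   segment seg_start seg_end mean_young mean_aged   diff     raw_p corrected_p stars
#> 1       1         1      50       49.8      88.9  0.783 0.000632     0.00379  "**"
#> 2       2        51     100       73.4     128.   1.08  0.00123      0.00737  "**"
#> 3       3       101     150       55.4      61.1  0.114 0.317        1        ""
#> 4       4       151     200      102.       36.2 -1.31  0.0000561    0.000336 "***"
#> 5       5       201     250       88.2      31.8 -1.13  0.000382     0.00229  "**"
#> 6       6       251     278       79.7     103.   0.828 0.00979      0.0587   ""
```

The implanted suppression sits exactly in segments 4–5 (residues
151–250): aged yield drops ~3-fold there with \*\*\*/\*\* significance
and strongly negative difference values. Because each sample is
renormalised to the same whole-protein total, the suppressed region also
pushes the remaining segments up (segments 1–2 significant in the
opposite direction) — PLF reports a redistribution of yield along the
structure, not absolute abundance.

```r
intersect_regions(glance(fit))
#> PLF region sets (3 regions)
#>   anterior: 1 flagged (0 exclusive)
#>   left_lateral: 1 flagged (0 exclusive)
#>   posterior: 4 flagged (3 exclusive)
#>   shared by all regions: 1
#>   union: 4
```

The perturbed protein is recovered in all three regions; the three
posterior-exclusive flags are chance hits on this small example.
`autoplot(fit, accession = "SYNP0003")` draws the per-segment group
means with stars, and `plot_difference_profile()` overlays the
region-scaled difference profiles. A thin command-line wrapper with
`run`, `simulate` and `compare` subcommands is installed under
`scripts/plf.R` in the package library.

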