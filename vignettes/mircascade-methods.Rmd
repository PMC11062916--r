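---
title: "Methods: prioritising transcription-factor-regulated miRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prioritising transcription-factor-regulated miRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircascade)
```

## The problem and the model

Post-pubertal testicular germ cell tumours retain a pluripotency programme,
and the transcription factor NANOG is both highly expressed in these
tumours and located on the recurrently gained 12p arm. If NANOG controls
microRNA transcription, candidate miRNAs should satisfy several independent
lines of evidence at once: reproducible NANOG binding immediately upstream
of the miRNA locus in pluripotent cells, expression that tracks NANOG
levels across tumours, the same direction of dysregulation in independent
tumour-versus-normal cohorts, binding close enough to a plausible
transcription start site, and — for the clinically interesting subset —
association with progression markers (GCNIS, stage).

`mircascade` formalises that argument as a cascade of explicit, auditable
filters over four evidence layers. No single layer is treated as proof; the
cascade's output is a tiered candidate list in which every decision is
recorded, including why each miRNA was *not* retained.

## Interval conventions and binding assignment

All coordinates are held 0-based, half-open (the BED convention);
annotation tables declared 1-based inclusive are converted on read. One
internal convention eliminates off-by-one drift between peak files and
prose coordinates.

Consensus peaks are the **strict per-base intersection** of all replicate
peak sets: a base is consensus only if every replicate covers it. This is
deliberately conservative; a minimum-replicate-fraction rule would admit
irreproducible peaks into a analysis whose next stages cannot correct for
them. Strand is ignored for peaks (ChIP enrichment is unstranded
evidence).

Upstream windows of 1, 2, 5 and 10 kb abut the locus 5' end without
overlapping it: `[max(0, s - k), s)` on the plus strand, `[e, e + k)` on
the minus strand. "Bound" means at least 1 bp of consensus peak inside the
10 kb window (`min_overlap_bp` is configurable; no biological minimum is
defensible a priori, so the default is the weakest). The binding distance
is the gap from the nearest qualifying peak edge to the 5' end, zero when
a peak covers it. Because a locus's own 5' end stands proxy for its TSS —
host-gene TSS annotations are deliberately not required — the
genomic-class distance rule (below) absorbs the difference between
intergenic and intronic promoter architecture.

## Expression strata and differential expression

Counts are normalised to counts-per-million and transformed with
`log2(x + 1)`; the pseudo-count avoids log-of-zero while keeping the unit
of log2 counts. Driver stratification is by tertiles (descending sort,
ties broken by stable sample-id order; sizes differ by at most one) or by
fixed cutoffs, where boundary values go to the upper stratum — both
choices exist purely to make stratification deterministic.

Differential expression between the high and low strata is a two-sided
Wilcoxon rank-sum test per feature on the normalised values, with
Benjamini–Hochberg adjustment across all features and two significance
thresholds: FDR < 0.05 **and** mean log2 expression > 1. The rank-sum test
is a deliberate design choice, not an approximation of a count model: it
is distribution-free, exactly antisymmetric under group exchange, and
fully specified here, so the cascade's decision structure does not depend
on dispersion-estimation internals. The cost is some power at small group
sizes relative to count-model tests; at the default simulated study sizes
(30 samples per tertile) a 2-unit log2 shift is detected with near
certainty, as the tests demonstrate. The expression floor exists because a
fold change computed between two near-zero means is numerically real but
biologically uninterpretable.

Sample-structure summaries use Spearman correlation (average ranks for
ties), complete-linkage clustering on `1 - rho`, and PCA on centred data
with each component's sign fixed by making its largest-magnitude loading
positive — again pure determinism choices.

## Cohort consistency

External cohorts provide linear tumour-over-normal fold changes. The
filter keeps `fc >= 1.5` (up) or `fc <= 1/1.5` (down) — applied exactly on
the linear ratio scale. Cohort calls are consolidated by union; a miRNA
called up in one cohort and down in another is flagged discordant and can
never be direction-consistent, but remains in the table for audit.
Direction consistency then requires presence, non-discordance and a match
with the tumour H/L direction.

## The cascade and its tiers

Stages, in order: (1) bound within 10 kb; (2) significant H/L differential
expression; (3) cohort direction consistency; (4) the TSS-distance rule —
binding within 2 kb for intergenic, 4 kb for intronic loci; (5) removal of
an explicit known-miRNA exclusion list. Tier 1 passes 1–4; tier 2 passes
1, 2 and 4; tier 3 passes only 1–2. Within tiers, ordering is by ascending
DE FDR then ascending distance (a deterministic tie-break; no biological
claim is attached to it). The exclusion list exists because real analyses
always contain a judgment step ("this miRNA is already well studied");
encoding it as data keeps that judgment reproducible and reversible —
removing the list never changes any other record's tier.

Clinical association contrasts GCNIS present vs absent and stages II and
III against stage I (stage I as reference). Each contrast runs the same DE
machinery over **all** features so that the focal feature's FDR comes from
the full-family BH adjustment of that contrast; a level with fewer than
two samples renders the contrast "not evaluable" rather than silently
passing.

## Downstream utilities

Target-prediction consensus counts votes across algorithm output lists
(default `min_votes = 2` of 4 — inclusive, because prediction algorithms
have poor pairwise agreement and unanimity would empty most lists; the
threshold is configurable). Cytoband filtering is a band-label prefix
match with unmapped genes reported, never dropped. Reference-gene
stability ranks candidates by the standard deviation of Ct across samples
(replicates averaged first), with ties by coefficient of variation; ΔΔCt
quantification fixes amplification efficiency at 2.0 and uses a single
reference gene per analysis.

## What the generator emulates — and what it does not

`simulate_study()` produces: ~200 non-overlapping loci on one synthetic
chromosome (70 % intergenic / 30 % intronic), spaced ~50 kb so neighbouring
windows cannot interact; 30 planted regulated miRNAs, half induced and
half repressed, with replicate ChIP peaks at uniform 0–1800 bp upstream,
per-replicate jitter of ±25 bp (always surviving strict intersection,
since jitter is far below the 400 bp peak width); 20 bound-but-unregulated
decoys at 3–20 kb; negative-binomial counts (dispersion 0.3) over 90
samples in four subtypes (SEM 40, EC 30, TERA 10, YST 10); a continuous
driver axis with subtype-level means (SEM/EC ≈ 13, TERA/YST ≈ 10.7, log2
scale, so the conventional 12.288 cutoff is directly usable and the high
stratum is SEM/EC-dominated); two fold-change cohorts with planted ±2 log2
effects plus 0.2 SD log-noise; and GCNIS/stage probabilities increasing
with the driver percentile, which induces the expected clinical
associations for repressed candidates.

The coupling between driver and planted miRNAs is
`2^(sign * 1.5 * lfc * (u - 1/2))` where `u` is the sample's driver
percentile; the factor 1.5 makes the *realised* top-versus-bottom tertile
contrast equal the nominal `planted_log2fc` (the mean percentile gap
between extreme tertiles is 2/3).

Deliberately **not** modelled: multi-chromosome genomes, copy-number gain
of the driver locus, library-size imbalance, microarray probe effects,
overlapping or clustered miRNA loci, and host-gene TSS positions. Passing
tests on this generator therefore demonstrate the pipeline's logical and
statistical correctness under a clean planted-truth regime, not robustness
to annotation errors or technical batch structure in real data.

## Numerical choices and degenerate inputs

Problem sizes in the test suite and acceptance script (200 features, 90 or
80 samples, 10–20 seeds) were chosen as the smallest sizes at which the
planted effects are comfortably detectable and calibration estimates are
stable. Other behaviour worth knowing: a rank-sum test on identically
constant data returns p = 1; a zero log2 fold change has direction `NA`; a
plus-strand locus starting at the chromosome origin has an empty (clipped)
upstream window and is simply unbound on that side; all-zero samples are a
hard error in normalisation (they indicate a broken input, not a datum);
and BED writing always emits plain integers and newline-terminated
records so write-then-read is the identity.

## Known limitations

The DE stand-in trades power for specification completeness; effect sizes
below ~1 log2 unit at tertile sizes under ~20 will often be missed. The
5'-end TSS proxy mislocates promoters of intronic miRNAs transcribed from
distant host promoters — the 4 kb allowance is a blunt correction. Strict
replicate intersection is sensitive to one bad replicate. Cohort
consolidation treats cohorts as exchangeable votes and does not weight by
cohort size or platform. None of these affect the auditability guarantees:
every decision the cascade makes is recorded with the evidence that
produced it.
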