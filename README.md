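# mircascade

Testicular germ cell tumours (TGCTs) arise from germ cells locked in a
pluripotent state, and the master pluripotency factor NANOG — sitting on the
recurrently amplified 12p locus — is a prime suspect for enforcing that
block. One way it could act is by switching microRNAs on or off from their
promoters. `mircascade` implements, as a reusable and fully tested R
pipeline, the integrative analysis that turns that hypothesis into a ranked
candidate list: which miRNAs carry reproducible transcription-factor binding
just upstream of their locus, respond to the driver's expression level in
tumours, behave consistently in independent tumour-versus-normal cohorts,
and associate with clinical progression.

The pipeline is aimed at computational biologists who have (i) replicate
ChIP-seq peak calls for a transcription factor, (ii) a miRNA count matrix
with clinical metadata, and (iii) external fold-change cohorts — and who
want an auditable, deterministic prioritisation rather than a pile of ad hoc
spreadsheet filters.

## The method

For each annotated miRNA locus with 5' end $t$ on strand $s$, graded
upstream windows $W_k$ of size $k \in \{1, 2, 5, 10\}$ kb are built
strand-aware ($[t-k, t)$ on `+`, $[t, t+k)$ on `-`; half-open, 0-based).
Consensus peaks are the strict per-base intersection of all ChIP replicates.
A locus is *bound* if a consensus peak overlaps $W_{10}$ by at least 1 bp;
its binding distance is the gap from the nearest peak edge to $t$.

Samples are stratified by driver expression into tertiles H/M/L (or at a
fixed cutoff such as 12.288 log2 normalized counts). Differential expression
between H and L uses a two-sided Wilcoxon rank-sum test on log2-CPM with
Benjamini–Hochberg FDR; a miRNA is significant when
$\mathrm{FDR} < 0.05$ **and** mean $\log_2(\mathrm{CPM}+1) > 1$.
Tumour-versus-normal cohorts are filtered at a minimum 1.5-fold change
(either direction, linear scale), consolidated across cohorts, and a
candidate is *direction-consistent* when its H/L direction matches the
non-discordant cohort direction. Finally a TSS-distance rule admits binding
within 2 kb for intergenic and 4 kb for intronic miRNAs, and well-known
miRNAs can be excluded explicitly. Candidates passing every stage are tier
1; the full evidence trail (binding, DE, cohort, distance, clinical flags,
exclusion reasons) is retained for every input miRNA.

A synthetic-study generator (`simulate_study()`) plants known regulated
miRNAs (negative-binomial counts coupled to a continuous driver axis),
replicate ChIP peaks at controlled upstream distances, noisy fold-change
cohorts and driver-coupled clinical covariates, so the whole cascade is
testable end to end against ground truth.

## Worked example

```r
library(mircascade)

st  <- simulate_study(sim_config(seed = 1))
res <- run_pipeline(st)
st
#> <sim_study> 200 miRNAs x 90 samples, 3 ChIP replicates, 2 cohorts (seed 1)
res
#> <pipeline_result>
#>   consensus peaks: 70 | DE significant: 33 | cohort-unified: 32
#> <cascade_result>
#>   200 miRNAs in -> 37 bound -> 30 bound+DE -> tiers 30/0/0 (known excluded: 0)
#>   tier-1 candidates: sim-mir-093 sim-mir-057 sim-mir-012 sim-mir-158 ...

head(res$candidates[, c("mirna_id", "genomic_class", "distance_bp",
                        "de_direction", "de_fdr")], 3)
#>      mirna_id genomic_class distance_bp de_direction       de_fdr
#> 1 sim-mir-093      intronic         316         down 7.389083e-09
#> 2 sim-mir-057      intronic        1446         down 7.389083e-09
#> 3 sim-mir-012    intergenic        1039         down 1.304520e-08
```

Reading the numbers: of 200 simulated miRNAs, 37 have consensus binding
within 10 kb (the 30 planted regulated loci plus bound decoys), 33 pass the
H/L DE thresholds, and exactly the 30 planted miRNAs survive all four
evidence stages into tier 1 — recall and precision 1.0 against the planted
truth for this seed. Each candidate row shows why it is there: its genomic
class, how far the consensus peak sits from its 5' end, and its DE direction
and FDR.

The downstream helpers work the same way on plain inputs:
`target_consensus()` votes over per-algorithm prediction lists,
`cytoband_filter()` restricts gene sets to a chromosome band such as `12p`,
and `ddct_fold_change()` / `reference_stability()` implement relative qPCR
quantification with reference-gene selection.

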