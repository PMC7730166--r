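---
title: "Methods: consensus target discovery and Ct-based candidate evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus target discovery and Ct-based candidate evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakcons)
```

This vignette documents the models and the design choices behind
`peakcons`: what each stage assumes, which parameters matter and why the
defaults are what they are, what the synthetic generators do and do not
emulate, and where the implementation had to make a call that its
interface does not force on the user.

## Coordinates and the peak data model

All intervals are half-open `[start, end)`, so `end - start` is the
length in bp. This convention was chosen because the packaged published
peak table satisfies `Length = End - Start` exactly on all 38 rows, which
would not hold under 1-based closed coordinates. Peaks carry a score on
the `-10*log10(p)` scale, a fold enrichment, a pool index, and a library
role (`chip`, `input`, `igg`); strand lives on gene models only — peaks
are never strand-aware.

IgG subtraction (`subtract_overlapping()`) removes a ChIP peak when it
overlaps any IgG peak by at least `min_bp` bases. The default is 1 bp:
the source protocol states only that overlapping IgG peaks were
eliminated, with no overlap fraction, so the most conservative reading is
used and the parameter is exposed.

Binding-region collapse (`collapse_shared_regions()`) groups genes by
*exact* coordinate-set equality, not by overlap merging. The packaged
table forces this choice: the two replicate peaks of Il10ra do not
overlap each other, so any merge-based region definition would split or
join regions incorrectly; only exact sharing reproduces the printed
19-genes-to-17-regions reduction (the Acadm/Rabggtb and Gm15997/Wdr95
divergent pairs each share one region).

## The simplified peak caller

`call_peaks()` is a deliberately small stand-in for a production ChIP-seq
caller, and is documented as such: no read shifting, no duplicate
filtering, no fragment-length model. It exists so the pipeline can run
end-to-end from raw (synthetic) coverage. Control counts are scaled by
the treatment/control total-read ratio; the expected background for a bin
is the maximum of the genome-wide rate and the mean control rate in 1, 5
and 10 kb windows centred on the bin (windows truncate at chromosome
ends); bins are scored by the Poisson upper tail on the `-10*log10`
scale, and maximal runs of bins at or above the threshold become peaks.
The default threshold of 50 (p = 1e-5) matches the scale of the published
scores, all of which exceed 50. The summit is the first bin attaining the
run's maximum score — a deterministic tie-break — and fold enrichment is
the treatment rate over the local lambda at that summit. No attempt is
made to reproduce the original study's peak scores numerically: the raw
sequencing data are not deposited, and the contribution this package
implements begins at the peak table.

## Three annotators, one consensus rule

The original analysis used three external peak-to-gene tools whose
internals are not described in the source. The package therefore
implements three *documented, parameterized* strategies that play the
same role — independent annotators that can disagree:

* `annotate_nearest_tss()` — the gene with smallest |signed TSS distance|
  within 300 kb; distance is measured from the peak midpoint
  (`floor((start+end)/2)`), positive downstream of the TSS in the gene's
  reading direction. Equidistant genes break lexicographically and the
  record is flagged. The midpoint was chosen because the reference point
  the original tools used (summit vs boundary) cannot be inferred from
  the printed table, whose replicate rows show slightly different TSS
  distances.
* `annotate_window()` — every gene whose footprint (body extended 5 kb
  upstream, 1 kb downstream, strand-oriented) the peak overlaps by
  ≥ 1 bp.
* `annotate_decay()` — a regulatory-potential score: every peak within
  100 kb of the TSS contributes `exp(-(0.5 + 4*|d|/window))`, so a peak
  at the TSS contributes `exp(-0.5) ≈ 0.607` and a peak at the window
  edge `exp(-4.5) ≈ 0.011`.

The consensus rule — the core of the package — selects a gene reported by
at least `min_tools = 2` annotators in at least `min_pools = 2` of the 3
pools. The phrase "2 of the 3 tools in 2 of the 3 pools" admits two
readings; the default evaluates the tool quorum *within* each pool (a
pool supports a gene only if ≥ 2 tools report it there), which is the
stricter and, we judged, more natural reading. The laxer
reading — ≥ 2 tools overall and ≥ 2 pools overall — is available as
`quorum = "global"`. Both are tested against exhaustive enumeration on
all small instances.

## Motif discovery

`em_motif_search()` fits a PWM by ZOOPS EM (each sequence contributes
zero or one site) over both strands, from `n_starts` seeded random
restarts, with a 0.01 pseudocount per base keeping every PWM row on the
simplex, convergence when the log-likelihood-ratio gain drops below 1e-6
(200 iterations cap), and the background estimated from the input
sequences. ZOOPS was chosen over OOPS/ANR because the published motif
table reports fewer sites than regions, which is what a ZOOPS fit
produces. Two numerical points are worth stating:

* With both-strand scanning, the background is strand-symmetrized (A/T
  and C/G averaged). This is what makes the fit exactly invariant under
  reverse-complementing all inputs — a property the test suite asserts
  to 1e-9 from a shared explicit start (`init_pwm`).
* EM recovers a planted motif only up to a small phase shift (a start
  one position off the true frame is a nearly-as-good local optimum, and
  for periodic motifs like `GT`-repeats almost exactly as good). Motif
  comparisons in the tests therefore score the best ungapped offset
  within ±2, on the overlap only — the standard motif-alignment
  convention — while still requiring 12 of 14 compatible positions.

The E-value (`motif_evalue()`) is an add-one permutation p-value over
mononucleotide shuffles: `(1 + #{shuffled LLR ≥ observed}) / (1 + n)`.
It is *not* comparable to the analytic E-values printed by full motif
suites (e.g. 2.6e-50), which are not reproduction targets here; it
answers the same qualitative question — is the motif stronger than the
sequence composition alone explains — at desk scale.

## Expression workflow

Expression calling uses the strict rule mean Ct < 35 across non-missing
wells, the threshold recommended for the array platform the source data
came from; a mean of exactly 35.0 is *not expressed*. The mean across
replicates was chosen because the source states only the 35-cycle rule;
a per-replicate-majority variant would be a straightforward extension
behind the same interface. Missing (undetermined) wells are treated as
missing, not imputed to 40 — imputation would bias ΔCt toward
non-expression calls — and samples missing the endogenous-control Ct are
dropped with a warning.

The differential test is a two-sided two-sample t-test on per-sample ΔCt
(Student's pooled-variance by default, matching the source's stated
analysis; Welch behind a flag). ΔCt is the additive-scale quantity in a
ΔΔCt design, which is why the test is not run on `2^-ΔCt`. No
multiple-testing correction is applied by default, again matching the
stated `p ≤ 0.05` rule on a small candidate panel; a Benjamini–Hochberg
option exists. Fold change is `2^-ΔΔCt` of the group means — the other
reading (per-patient RQ averaged) would differ slightly for skewed
noise, and the group-mean form is the one the closed-form identities in
the tests pin down. Direction is `up` iff the fold change exceeds 1 and
the gene is significant.

Gene clustering uses `1 - Pearson r` between ΔCt profiles with average
linkage, the layout of the source's heat map. Zero-variance profiles
have undefined correlation; their distance is defined as 1 and they are
flagged rather than dropped. Genes are sorted alphabetically before
clustering so that ties resolve deterministically.

## The synthetic world

The generators state one world and the defaults are not tuned:

* 3 pools, 3 tools, 19 true targets of which 2 divergent pairs share a
  binding region (so 17 distinct regions) — the structure of the
  published funnel.
* qPCR cohort of 6 control vs 17 case samples — the source cohort
  sizes — with well noise sd 0.3 cycles (a typical TaqMan replicate sd),
  planted shifts of 1.5 cycles for differential genes, and non-expressed
  genes drawn uniformly in 36–40 cycles so the 35-cycle rule separates
  cleanly at that noise level.
* peak centre jitter sd 20 bp between pools, ~5 false peaks per pool,
  and an IgG mirror fraction of 0.15 in the analysis scripts (0 in the
  zero-noise recovery tests, whose stated world is exact recovery).
* planted motif `GTATRTGTGTGTGT` at probability 0.9 per region sequence
  (1.0 in recovery tests).

What the generators do **not** emulate: genomic sequence composition
(background is uniform), read-level artefacts (duplicates, mappability),
inter-gene correlation in Ct noise, and pool-specific depth differences.
A green recovery test therefore establishes that the selection logic is
correct on data with the assumed statistical structure — not that the
pipeline is robust to every artefact of real libraries.

## Known limitations

* The peak caller and the three annotators are functional stand-ins;
  none claims numerical agreement with MACS or the original annotation
  tools.
* The sequencing-scale figures of the source study (total peak and
  nearest-gene counts) are not reproducible without the undeposited raw
  data and are not targets of this package.
* The permutation E-value is desk-scale (default 100 shuffles) and has a
  resolution floor of `1/(n_shuffles + 1)`.
* Ortholog mapping and related-gene lists are static packaged tables;
  no live database queries are performed, by design.
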