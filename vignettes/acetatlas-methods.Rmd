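---
title: "Methods: differential histone-acetylation atlases and motif enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential histone-acetylation atlases and motif enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetatlas)
```

`acetatlas` implements a genome-scale procedure for detecting
transcriptional reprogramming from histone-acetylation (H3K9ac) ChIP-seq
in a multi-condition progression design, together with the matching
expression-side set logic and a synthetic-data generator that provides
planted ground truth for every stage. This vignette is the package's own
account of the statistical model, its assumptions, the tunable parameters,
and the design decisions taken where more than one reading was defensible.

## The experimental design being modelled

The default `sample_design()` encodes a six-condition leukaemia
progression layout: two non-leukaemic baselines (primary lin⁻/kit⁺ marrow,
`WT`, and the FDCP-mix progenitor line, `FDCP`), an initiation and an
overt-leukaemia stage for each of two oncogene models (MLL-ENL: `ME-I`,
`ME-L`; MOZ-TIF2: `MT-I`, `MT-L`), with two biological ChIP replicates and
three expression replicates per condition. For group testing the
conditions are partitioned by their expression phenotype into group A
(`WT`, `FDCP`, `MT-I` — non-leukaemic) versus group B (`ME-I`, `ME-L`,
`MT-L` — leukaemic), giving 6 vs 6 ChIP samples.

## Peak calling and the region atlas

Tags are 5′-end positions plus strand; each is extended in its sequencing
direction to `L = 200` bp, the modelled fragment length. Parameterizing by
the 5′ end keeps read length out of all downstream arithmetic. Coverage at
a base is the number of extended intervals containing it (0-based
half-open coordinates throughout, the BED convention).

Peaks are maximal runs of coverage at or above a height `h` chosen to
control an empirical FDR at `peak_fdr = 0.05`: the expected number of
false peaks under a uniform-tag null, divided by the observed peak count
at `h`, capped at 1. The default null is analytic — with
`lambda = library_size * L / G`, the expected false-peak count at height
`h` is `(G / L) * P(Poisson(lambda) >= h)`, i.e. window counts over
non-overlapping `L`-bp windows — and `h` is the smallest height passing
the criterion. A Monte-Carlo null (simulated uniform tag sets of the same
library size) is available; because run counts are uninformative at
heights below the mean coverage (the whole genome merges into a handful
of runs, which can make a meaninglessly low threshold "pass"), the
Monte-Carlo mode requires the criterion to hold at the chosen height and
every height above it. The two nulls agree to within one height unit in
the sparse-coverage regime (`lambda << 1`) that tag-level peak callers
operate in; at high background coverage they measure genuinely different
null quantities (windows versus runs) and can diverge. Summits are the
leftmost base attaining the run maximum (a deterministic tie-break), and
adjacent runs separated by at least one sub-threshold base are distinct
peaks.

Every peak contributes a fixed-width window `[summit - W/2, summit + W/2)`
with `W = 400` bp, clipped at chromosome ends. Windows from all samples
are reduced to a non-redundant atlas by greedy height-ranked selection:
sort by decreasing source peak height (ties by chromosome, start, sample
id), accept a window iff it overlaps no accepted window. This keeps the
fixed width that unbiased motif counting requires, favours the strongest
summit wherever samples disagree about a locus, and guarantees that every
rejected window overlaps an accepted region. Regions are scored per
sample by counting extended reads that overlap the region by at least
1 bp (full containment is available via `mode = "within"`; overlap is the
default because containment discards reads at region edges) and
normalized as reads per million. The normalization scale is irrelevant to
the t-statistic, which is scale-invariant.

## The regularized t-test

With two or three replicates per condition, per-region variance estimates
are unstable. The package uses a Bayesian-regularized t-statistic: each
group's variance is shrunk toward a background variance `sigma0²`
estimated from the `w = 101` regions nearest in rank of within-group mean
(window truncated at the rank edges), under the assumption that regions
of similar mean intensity have similar measurement variance:

```
s~² = (nu0 * sigma0² + (n - 1) * s²) / (nu0 + n - 1)
t   = (mean_B - mean_A) / sqrt(s~²_A / n_A + s~²_B / n_B)
df  = n_A + n_B - 2 + 2 * nu0
```

`nu0 = 10` pseudo-replicates by default. The `nu0 + n - 1` denominator is
chosen so that `nu0 = 0` reduces *exactly* to the classical pooled
two-sample t-test at equal group sizes — a clean, testable identity; the
alternative `nu0 + n - 2` convention is available via `var_mode`. The df
formula credits the prior pseudo-replicates symmetrically in both groups.
Regions at raw `p <= 0.05` are "variable" and are split by the sign of
the group-mean difference into enriched and deprived sets; no multiple-
testing correction is applied at this stage by default (an optional BH
mode exists), since the variable-region definition is a screening rule
feeding the motif analysis, not an inferential endpoint.

A consequence of fixing df at `n_A + n_B - 2 + 2 nu0` is bounded power:
with n = 3 per condition, a 4-standard-deviation shift, and BH control at
FDR 0.001 across 10,000 probes, per-transition sensitivity is ~0.36 (an
adaptive-df moderated test reaches ~0.79 on identical data). The package
accepts this deliberately — the df formula is simple, explicit and
symmetric — and the planted effects used for end-to-end validation are
sized accordingly (see below).

Replicate concordance is displayed with `replicate_density_grid()`, a 2-D
Gaussian kernel density of paired log10 scores normalized to unit mass;
degenerate inputs (a single point, zero spread) fall back to a fixed
bandwidth floor of 0.1.

## Motif enrichment by bootstrap Z-score

Motifs are IUPAC consensus strings; occurrences are counted at every
position where the pattern matches the forward strand plus every position
where its reverse complement does, with overlapping matches all counted
and palindromic patterns counted once per position. Total occurrence
counts (not regions-with-a-match) are the default statistic, with a
presence/absence mode behind `count_mode = "regions"`. The shipped
`consensus_motifs()` table (Gata2 `WGATAR`, Gfi1, Lyl1, Sfpi1/Pu.1, plus
the expression-stable controls Cebpa and Meis1) contains editable
stand-ins in the style of UniProbe/Jaspar consensus calls, not database
exports.

The null distribution for a target set of `k` regions is built by drawing
`B = 1000` random sets of `k` regions from the full atlas with
replacement and recording total occurrences per motif; `Z = (observed -
mean) / sd` with calls at `Z >= +3` / `Z <= -3` (inclusive). Because
atlas regions are all `W` bp wide, length matching between target and
null sets is automatic; GC matching is deliberately not attempted. A
degenerate null (`sd = 0`) yields `Z = 0` when observed equals the mean
and a flagged signed-infinity sentinel otherwise.

## Expression-side set logic

Probes are kept when detected in at least one sample; following the
platform convention adopted here, a cell is detected when its detection
score *exceeds* 0.01. Detection-score conventions differ between chip
platforms (some report small-is-detected p-values), so the comparison
direction is configurable (`direction = "less"`). Per transition, the
shared regularized t is applied to the two conditions' replicates, BH
adjusted across all tested probes, and called at FDR ≤ 0.001. The
packaged transition table covers six pairwise comparisons (the two
baselines; baseline→initiation and initiation→progression per model; the
two leukaemias); this enumeration is the package's own choice of
representative comparisons for the design. Non-redundant DE sets are
unions over a model's transitions ("called in at least one transition"),
annotated with per-transition directions. The shared progression set
intersects the MLL-ENL baseline→initiation calls with the MOZ-TIF2
initiation→progression calls, keeping only direction-concordant probes.
Probe-to-gene collapsing is available when a mapping table is supplied;
otherwise results stay at probe level.

## What the synthetic generator emulates — and what it does not

`generate_genome()` draws i.i.d. bases at 42% GC. `plant_regions()`
places non-overlapping fixed-width regions, marks a chosen fraction with
a group-B effect fold, and writes concrete motif instances into the
sequence at recorded positions. `simulate_chip_tags()` draws each
sample's tags from a multinomial over background (uniform) and per-region
enriched components, with fragment midpoints Gaussian around region
centers (SD = width/4) and forward/reverse tags offset by half the
fragment length on either side of the midpoint — the strand asymmetry
that extension corrects. Per-sample streams are derived from the master
seed by a fixed affine map modulo a prime, so runs are reproducible and
samples independent. `simulate_expression()` adds planted condition
shifts and Gaussian replicate noise to per-probe baselines; truth labels
are derived from the planted condition-mean matrix per transition, so
they remain correct where planted shifts spill into overlapping
comparisons. Undetected probes are drawn from the unplanted pool: a truly
differential probe is expressed and hence detectable.

Generator defaults are fixed once, from the design being emulated and
from power analysis, and are not tuned per run: 1 Mb genome, 200 planted
regions of 400 bp at 10-fold enrichment; 40% of regions carry a 0.25-fold
group effect; 100,000 tags per sample (library depth is not dictated by
the emulated design and was chosen to give sparse background coverage
with clearly separable peaks); GATA motifs at 3 instances per deprived
region versus 1 elsewhere with a uniformly planted control; 20,000
probes, 45.8% detectable, 400 DE probes per transition at a 4-sd log
fold change, and 40 shared-up / 88 shared-down probes at a 6-sd shift
(the shared-set analysis is validated at a strong effect because, at the
fixed-df test's power, a 4-sd effect recovers only a third of planted
probes at FDR 0.001).

Two realism caveats matter when reading test results. First, fixed
per-sample depth makes scores compositional: when many strong regions
lose signal in group B, the freed tags land everywhere else, so regions
*without* a planted effect show mild but statistically real enrichment in
group B. This mirrors real RPM normalization under global signal loss and
is why end-to-end recovery is asserted on the deprived set while
false-positive calibration is asserted on independent pure-null score
matrices. Second, the generator models no mappability structure,
duplicate reads, sequencing error or GC bias; passing recovery tests
demonstrates the statistical machinery, not robustness to those
artefacts.

## Numerical choices and degenerate inputs

* Coverage, thresholds and peak calls are exact integer arithmetic; peak
  FDR estimates are capped at 1 so `peak_fdr = 1` accepts height 1.
* Summit and atlas tie-breaks are deterministic (leftmost maximum;
  height, then chromosome, start, sample id), making every stage
  invariant to input ordering.
* `t = 0, p = 1` when both shrunken variances and the mean difference
  vanish; a zero denominator with a nonzero difference yields a signed
  infinite t with `p = 0`.
* Bootstrap and tag simulation restore the caller's RNG state; all
  randomness flows through explicit seeds.
* Region width must be even; windows and extensions clip at chromosome
  bounds rather than erroring.

## Problem sizes used in the test suite

The packaged validation runs at desk scale, chosen so the full suite and
the acceptance script each complete in minutes on one CPU: oracle
equivalence on 8,000-tag instances; 1,000 random instances for the
classical-t reduction; 5,000 pure-null regions for type-I calibration
(observed fraction at `p <= 0.05` within 3 binomial SDs of 0.05); 200
bootstrap repetitions at `B = 200` for null self-consistency; the full
synthetic pipeline at the defaults above for planted-signal recovery; and
10,000 probes for the expression recovery runs. Genome-scale inputs
(tens of millions of tags, mammalian genome sizes) are outside what the
pure-R coverage representation is designed for.

## Known limitations

* The peak caller is a fully specified stand-in with an explicit null; it
  does not model local background (input subtraction) or sub-peak
  structure, and no numerical equivalence with any external caller is
  claimed.
* The regularized t fixes its df by formula; it does not estimate the
  prior weight from the data, and its power at very small n is bounded
  accordingly.
* Bootstrap null sets match the target set in cardinality and (by
  construction) region length, but not GC or chromatin context.
* Consensus-string motif scanning has no position-weight scoring; a
  single mismatch is a non-match.
* The expression module's moderated test is the in-package regularized t;
  no fidelity to any external DE tool's numbers is claimed.
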