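---
title: "Methods: variant-to-gene mapping and cross-species sleep scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant-to-gene mapping and cross-species sleep scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepv2g)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the numerical choices made where a
design was genuinely open, and what the synthetic-data validation does and
does not demonstrate.

## 1. In-silico restriction digestion

A genome is digested by scanning each sequence for the enzyme's
recognition site on the forward strand and cutting at
`site start + cut_offset`. Only palindromic sites are accepted, which
makes the single-strand scan complete; non-palindromic enzymes are
rejected rather than silently half-digested. Offsets are fixed by enzyme
chemistry: DpnII cleaves 5′ of GATC (`cut_offset = 0`) and HindIII cuts
A^AGCTT (`cut_offset = 1`).

Coordinates are 0-based half-open throughout the package (the BED
convention); fragments tile each chromosome exactly, which is asserted by
property tests at every resolution. `concat_fragments(map, 4)` merges runs
of four consecutive fragments — the coarse resolution at which promoter
interactions are also called — leaving a shorter terminal fragment when
the count is not divisible by four.

Two choices deserve a note:

* **N handling.** Sites containing N never match, so assembly gaps become
  long fragments instead of being masked out. This is the simplest
  deterministic behavior; genome-wide statistics computed on an assembly
  with long N runs therefore include a small number of very long
  gap-spanning fragments.
* **Sequence subset.** Genome-wide fragment statistics are computed over
  all records of the input FASTA. Whether published genome-wide values
  for specific assemblies include alternate/unplaced contigs is generally
  not stated; restricting the input FASTA is the caller's control.

## 2. Variant-to-gene mapping

The mapping composes four filters, all strict inequalities, all exposed in
`pipeline_config()`:

| step | rule | default |
|---|---|---|
| LD expansion | keep r² **>** cutoff; sentinel is its own proxy (r² = 1) | 0.7 |
| open chromatin | SNP base inside a peak (`start <= pos < end`) | — |
| loop | interaction score **>** cutoff at the interaction's resolution | 5 |
| expression | TPM **>** min AND percentile **>** min | 1.5, 50 |

A link is emitted for every gene of every bait such that (i) the proxy is
open, (ii) the proxy position is not inside *any* baited region (the
non–bait-to-bait rule is evaluated against all bait intervals, not only
the linked bait), (iii) a qualifying interaction's other end overlaps the
proxy's restriction fragment at the interaction's stated resolution, and
(iv) the bait overlaps open chromatin. Openness of a proxy is evaluated at
the single SNP base, not its whole fragment, because peak intersection is
defined on variant positions. Fragment/other-end overlap uses any-overlap
(≥ 1 bp): interactions are fragment-based, so when maps agree containment
and overlap coincide, and any-overlap is robust to off-by-one dialect
differences.

Links are deduplicated on (proxy, bait, gene), keeping the
highest-scoring interaction; the distinct qualifying interactions before
deduplication are retained for the summary's interaction count, which
counts distinct (bait, other-end interval, resolution) triples. Multiple
genes on one bait each yield their own link, which is why summaries can
report more genes than baits. When the expression table lacks a
percentile column it is computed internally as the average-tie percent
rank of TPM among all genes (top gene = 100).

Degenerate inputs are defined, not special-cased: no peaks means every
proxy is closed; no interactions means no links; an interaction naming an
unknown bait is an error rather than a dropped row.

## 3. Drosophila sleep

Sleep is scored from per-minute beam-crossing counts: a minute is
immobile iff its count is zero, and any maximal immobile run of at least
5 minutes is a sleep bout. Scoring therefore depends only on the
zero/nonzero pattern (a property test scales counts and asserts
invariance) and is monotone: adding activity never increases sleep.

Attribution choices:

* A bout truncated by the trace end still counts if its run length
  reaches the threshold; sleep minutes are attributed to day (ZT0–720) or
  night (ZT720–1440) minute by minute, while bout *counts* go to the
  phase of the bout's start minute. This keeps phase sleep totals and
  bout numbers independently well defined.
* Multi-day traces are combined by averaging per-day values per animal.
* Waking activity is total counts over waking minutes divided by waking
  minutes; a fully asleep trace leaves it undefined (flagged, not zero).
* Animals whose trace ends in an all-zero run of a full day are flagged
  as dead (`flag_dead()`, threshold configurable) — standard
  activity-monitor practice; the threshold is a judgment call because a
  day-long sleep bout is physiologically implausible but not impossible.

**Screen calling.** The reference band is the pooled per-animal mean ± 2
pooled per-animal SDs of total sleep; lines whose mean falls outside are
called long/short. Whether the pool is every animal tested or only
control lines is genuinely ambiguous in screen designs of this kind; both
modes are provided (`reference = "all_animals"` is the default,
`"control_lines"` the alternative) and neither is asserted as canonical.
Pooling all animals slightly inflates the band when many lines carry real
effects; with screen-scale line counts and sparse hits the inflation is
negligible, which is the regime the calibration tests exercise.

**Deprivation rebound** consumes paired baseline/recovery daytime sleep
and reports per-animal percent change; animals with zero baseline are
excluded (flagged) because percent change is undefined. The deprivation
window itself is the caller's choice — published descriptions of such
protocols vary between 12-h (lights-off) and 24-h windows, so no default
is claimed.

**Arousal threshold and reactivity.** A response is displacement > 3 mm
within a 60-s window after a stimulus (window configurable; 60 s matches
1-frame/s tracking granularity). Threshold = lowest responding intensity
among escalating stimuli; no response right-censors at the maximum
intensity; trials where the animal was not asleep at first-stimulus onset
are excluded. "Asleep at onset" is operationalized as ≥ 5 min of
immobility immediately before the stimulus. Reactivity bins sleeping
trials by prior immobility (5-min bins from 5 min, configurable), omits
empty bins, and compares groups by a weighted linear fit of bin
proportion on bin midpoint plus group — the covariate-adjusted elevation
comparison.

## 4. Zebrafish sleep

A minute with strictly less than 0.5 s of movement is a sleep minute; any
maximal run of sleep minutes (length ≥ 1 — no 5-min rule here) is a bout.
Day is 09:00–23:00 and night 23:00–09:00, matching a 14:10 rearing cycle;
both are configurable. `trim_acclimation()` drops everything before the
first lights-on after recording start and keeps exactly two full cycles
by default. Cumulative day/night sleep sums across the analyzed cycles
per larva; waking activity is seconds per awake minute per hour, averaged
over hours that have at least one waking minute (the global
all-waking-minutes reduction is also returned, since which reduction a
given analysis used is often unstated).

Group comparisons report the mean difference ± SE with a t statistic.
The Welch form (Welch–Satterthwaite df) is the default even when
variances look equal: an unspecified variance pre-test is avoided, and
Welch is conservative under equality. An optional pre-test mode
(`pretest = TRUE`, F-test at 0.05) is provided for workflows that gate
the correction. The implementation is closed-form and is cross-checked
against `stats::t.test` in the test suite, keeping implementation and
oracle separate.

The CRISPR inclusion filter is the ratio of headloop to standard PCR
product intensity, with strict `efficiency > 0.9` required for inclusion;
a zero standard-product intensity is an error, not an infinite
efficiency.

## 5. The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions of the analyses above.

**Landscape.** A random uniform-base genome (400 kb by default) is
digested and, per locus, a sentinel with LD proxies, peaks, a baited
promoter, an interaction and an expression record are planted so that a
known subset of (proxy, gene) pairs passes all four link conditions.
Locus slots are spaced at least eight fragments apart so distinct loci
never share a four-fragment bin. Decoy loci each violate exactly one
condition (closed proxy, proxy inside a baited region, sub-threshold
score, closed bait); every fifth planted locus additionally carries low
expression to exercise the expression flag; every locus also carries one
r² = 0.5 record the LD expansion must drop. Defaults
(`fraction_open = 0.75`, `fraction_looped = 0.75`, 36 loci) give a mix of
planted links and all four decoy modes in one dataset. The ledger is the
oracle: recovery tests assert that `annotate_loops()` emits exactly the
planted pairs, and the acceptance checks repeat this over 20 seeds.

**Behavior.** Sleep/wake is a two-state discrete-time Markov chain per
minute with separate day and night transition matrices — the minimal
structure that makes run-length scoring and day/night contrasts
meaningful. Fly wake minutes draw Poisson counts truncated to ≥ 1 (so a
waking minute is never miscalled immobile); fly defaults give roughly
29% immobility by day and 78% by night. Zebrafish sleep minutes draw
uniform movement in [0, 0.5) s and wake minutes Gamma movement clipped to
[0.5, 60] s, so the scoring boundary is respected on both sides and the
latent state is exactly recoverable; group sizes default to 42 scramble
vs 48 KO, the scale of a typical one-plate F0 crispant experiment.

Planted effects are calibrated as follows. For flies, a "+k SD" line
scales its wake→sleep probabilities by f² with f chosen so the stationary
immobility increase equals k reference SDs, where the reference mean and
SD of *scored* sleep come from an internal 100-animal simulation under
the same spec. Matching the stationary increase rather than absolute
levels cancels most of the bias the 5-min rule introduces; the residual
calibration error is a small fraction of an SD, well inside what the
±2 SD screen tolerates, and the recovery tests bound it empirically. For
zebrafish, the night stationary sleep fraction is shifted exactly in
closed form so the expected cumulative night-sleep difference equals the
planted delta (30 min over two nights by default — a clearly resolvable
effect at these group sizes, chosen once; direction KO > control). The
only approximation is the relaxation transient at lights transitions,
which is shared between groups and empirically negligible against the
estimator's standard error.

**What passing these tests shows — and does not.** The generator
validates the *rules*: that the pipeline implements its stated conditions
exactly (100% recall of planted links, zero condition violations), that
scoring matches independent oracles, that the screen's false-call rate
matches its own rule's Monte-Carlo expectation, and that planted effects
are recovered unbiasedly. It does not emulate realistic LD decay,
GC-structured genomes, circadian waveforms, ultradian rhythmicity, or
tracking artifacts; agreement on synthetic data therefore says nothing
about, for example, peak-calling quality or interaction-calling power on
real assays, which are upstream of this package's scope.

## 6. Determinism and problem sizes

Every generator takes a mandatory seed and restores the session RNG state
afterwards; `run_pipeline()` derives all stage seeds from one configured
seed and writes outputs with fixed sort keys, so reruns are
byte-identical — asserted file-by-file in the tests. Validation scales
were chosen to bound Monte-Carlo error tightly while staying
desk-interactive: exhaustive binary traces to length 12 plus 10⁴ random
traces for scoring equivalence, 20 seeded landscapes for recovery, 5000
lines × 16 flies for screen calibration, 10⁴ null replicates for the
Welch type-I error, and 100 seeded replicates for behavioral-effect
recovery.

## 7. Known limitations

* Bait intervals are consumed as given; the package does not verify that
  baits coincide with restriction fragments of the supplied map.
* `overlap_peaks()` records the first covering peak when peaks overlap
  each other; peak sets are assumed non-redundant.
* The genome-wide digestion check against published human-genome fragment
  statistics requires a local genome FASTA; it is part of the acceptance
  tests but cannot run self-contained.
* The reactivity comparison fits proportions with bin-count weights
  rather than a binomial GLM; with the trial counts the analyses use, the
  two give practically identical elevation tests, and the linear form
  mirrors the classical ANCOVA presentation.
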