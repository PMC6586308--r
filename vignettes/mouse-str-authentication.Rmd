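---
title: "Mouse cell line authentication with tetranucleotide STR profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mouse cell line authentication with tetranucleotide STR profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstrkit)
```

## The problem

Misidentified and cross-contaminated cell lines corrupt downstream biology.
For human lines, short tandem repeat (STR) profiling is the accepted
authentication standard; mouse lines long lacked an equivalent.  `mstrkit`
implements the analysis side of a multiplex mouse STR assay: 19 mouse
tetranucleotide markers plus two human markers (D8S1106, D4S2408) that only
amplify human DNA and therefore act as a contamination screen.  The package
starts from *sized peak tables* — the tabular exports a fragment-analysis
package (GeneMapper, GeneMarker) produces after sizing capillary
electrophoresis (CE) peaks against the LIZ-600 internal standard — and runs
through allele calling, stutter-filter derivation, profile matching, and
interlaboratory concordance scoring.  Raw `.fsa` trace processing, primer
design, and wet-lab protocol are out of scope.

## From sizes to alleles: calibrant-anchored bins

An STR allele is named by its count of full 4 bp repeats, with microvariant
suffixes for partial repeats (allele `20.3` = 20 repeats + 3 bases).
Measured fragment sizes are instrument specific, so bins (size windows
mapped to alleles) are anchored on *calibrants*: sequenced diploid DNA whose
allele designations are known.  `buildBinSet()` lays a ladder per marker and
per microvariant class:

* anchored bins sit exactly at the calibrant sizes;
* the remaining rungs are extrapolated one repeat unit per step.  With two
  or more anchors in a class the step is the locally observed anchor
  spacing (CE mobility drifts slightly, so the observed spacing beats the
  nominal value); with a single anchor the step is exactly 4.0 bp.
  Interior gaps are interpolated linearly.
* each class ladder covers the marker's known allele range and up to
  `extensionLimit` (default 10) repeats beyond the outermost anchor.  The
  default is deliberately generous: a test sample can carry an allele six
  repeats above the highest sequenced calibrant allele and must still be
  callable, flagged `extrapolated`.
* microvariant ladders are independent: a `.3` query is never assigned to a
  full-repeat bin.  Repeat structure, not proximity, defines the allele.

`sizeToAllele()` assigns a query to the nearest bin whose window contains
it.  The half-width defaults to 0.5 bp — the conventional ±0.5 bp
genotyping window; the width actually used by any given lab's software is
not standardized, which is why it is an explicit parameter rather than a
constant.  A query exactly equidistant between two bins resolves to the
smaller allele and warns (ties are pathological and deserve eyes).  Sizes
outside every window return `off_ladder` with the nearest allele as a
suggestion.

The packaged anchor table (`loadFixture("anchors")`) is synthetic: real
anchor sizes are instrument specific and unpublished, so the fixture places
each marker's ladder at plausible CE coordinates (flank + 4·repeats +
microvariant + a fixed per-marker mobility offset).  Calibrant allele
*designations* follow the published Calibrant 1 profile, extended with a
few extra class anchors so that every allele class appearing in the
published profile tables is representable.

## Stutter rules in calling

PCR strand slippage at a tetranucleotide locus produces a minor "stutter"
peak one repeat (4 bp) below — and more weakly above — each true allele.
The calling rules used here, applied by `callSample()`:

* peaks below `minHeightRfu` (default 100 RFU) are ignored; a marker losing
  every peak is flagged `low_signal`;
* a peak in the −4 position is an allele only when its stutter ratio
  (candidate height / parent height) **strictly exceeds 20 %**, a +4 peak
  only above **10 %**;
* when a candidate has several parents at a position, the tallest parent
  governs — its ratio is smallest, so this is the conservative choice;
* a ratio-passing peak that sits in a stutter position is still called,
  flagged `stutter_overlap` (stacked stutter under a true allele is
  resolved by ratio alone, never suppressed silently);
* stutter pairing is purely size-based at ±4 bp ± `stutterTolBp`; because
  slippage removes whole repeats, a microvariant's stutter lands on its own
  class ladder automatically.

The 100 RFU floor is applied both to allele eligibility and inside the
ratio computation.  The source guidance only states it for ratios; applying
one analytical threshold uniformly is simpler to reason about and is the
package's choice (both are parameters if a lab disagrees).

Marker 11-1 suffers incomplete adenylation, producing ±1 bp "shoulder"
peaks that make its calls unreliable; the core panel (`core18`, the
default) drops it, and under `full19` its calls always carry a
`shoulder_risk` flag.  Mixtures are out of scope by design — stutter
filters are meaningless when contributors have different template amounts —
so strong sister-allele height imbalance (min/max below
`imbalanceRatio = 0.3`, a documented package choice, not a published
threshold) is only *flagged* (`peak_imbalance`), never deconvolved.

## Stutter filter statistics

`markerFilters()`/`alleleFilters()` derive filter recommendations as the
mean observed minus-4 ratio plus three standard deviations, the convention
carried over from human STR practice.  Choices worth stating:

* only −4 observations from diploid samples feed the filters (aneuploid
  cancer lines distort ratio distributions); +4 stutter is summarized
  separately if needed;
* the SD is the sample (n−1) estimator; a single-observation group returns
  its mean, flagged `low_n`;
* allele-specific filters may legitimately exceed their marker filter when
  one allele's ratios are unusually variable — the test suite constructs
  such a counterexample on purpose.

`instrumentEffect()` asks whether instruments shift stutter.  Each ratio is
first normalized for allele length (divided by the mean ratio of its
(marker, allele) group), then averaged per (marker, instrument) cell;
markers act as blocks and instruments as treatments in a Friedman rank
test.  The chi-square statistic and asymptotic p-value come from
`stats::friedman.test`; an exact permutation p-value (enumerating
within-block treatment permutations, feasible up to about a million
permutations) is the package's own code, and the all-tied degenerate case
is defined as statistic 0, p = 1.

## Profile comparison and concordance

`mastersMatch()` implements Master's percent match: 100 × shared alleles /
total alleles of the *questioned* profile, set semantics per marker
(a homozygous allele counts once, matching how published profile tables
write single entries).  The measure is asymmetric; `pairwiseMatrix()`
surfaces both directions rather than averaging.  For parental/derivative
comparisons the parental line is taken as questioned.  Classification
defaults: > 85 % same-or-derivative, > 80 % related.
`nearestNeighbor()` uses the symmetric allele-difference count, whose zero
distance flags duplicate lines.  Human markers never enter either measure.

Concordance scoring (`callAgreement()`, `markerAgreement()`,
`lineAgreement()`, `concordanceReport()`): each individual allele call's
agreement proportion is the fraction of the *other* labs whose call set
contains that allele; marker and line scores average over all calls made
(so the denominator is calls made, not calls expected).  A line is
concordant only when every lab's call set is identical at every marker.
"Correct calls" relative to expectation are operationalized through
`consensusCalls()` (alleles called by more than half the labs).  Reported
means are rounded to three decimals for display only.

## The synthetic generator

`syntheticConfig()` fixes the simulated study conditions; they are chosen
once to mirror a 12-laboratory, four-instrument-class study and are not
tuning knobs:

| parameter | default | rationale |
|---|---|---|
| minus-4 stutter | `0.01 + 0.005·repeats + N(0, 0.015)` | monotone increase with repeat count; puts mean+3SD filters in the ≈11–23 % band typical for this assay |
| plus-4 stutter | `0.002 + 0.0015·repeats + N(0, 0.005)` | several-fold weaker than minus stutter |
| peak heights | lognormal, mean 2000 RFU, CV 0.3 | comfortable margin over the 100 RFU floor |
| sizing error | shared N(0, 0.15) bp per marker/injection + N(0, 0.05) bp per peak | CE sizing error is strongly correlated between neighboring fragments of one injection; the *relative* position of stutter to parent is much more precise than absolute size |
| instrument offsets | 3130xl/3500xl −0.01, 3730/3730xl 0 | the one-percentage-point class difference pattern |
| labs | 12 | study roster size |
| dropout, artifacts | 0 | enabled explicitly per experiment |

The linear stutter model is the simplest form consistent with a monotone
repeat-count effect; the true functional form for this chemistry is not
published, so the triple is a declared assumption and fully replaceable.
Artifact models are deliberately coarse: shoulder = ±1 bp satellite at 35 %
of the parent (marker 11-1 by default), pull-up = same-size low peak
assigned to another marker, dye blob = off-grid mid-height peak, spike =
random-size peak.  The generator does **not** emulate raw fluorescence,
baseline noise, spectral overlap, inter-lab size-calibration bias, or
mixture profiles — so passing closed-loop tests demonstrate the pipeline's
internal consistency under the modeled error structure, not performance on
arbitrary real exports.

`simulateInterlabStudy()` injects interpretation errors tagged with the
discordance reason codes used in study reporting (a low signal, b
stutter-ratio error, c at-threshold stutter, d missed allele, e artifact),
keeping ground truth for scoring.

## Numerical and interface choices

* Alleles in files are `";"`-separated within a cell (published tables use
  commas inside cells, which collide with CSV).
* Marker names normalize en dashes to ASCII hyphens on input.
* The long profile dialect is lossless including QC flags; the wide
  (published-table-shaped) dialect carries calls only and warns if flags
  would drop.
* Every CLI output starts with comment lines recording package version,
  subcommand and parameters; exit codes are 0 / 1 (data error) / 2 (usage).
* All simulation is seeded; generation restores the caller's RNG state.

## Problem sizes used in validation

The shipped test suite validates against the published worked examples
(the 12-lab agreement example, the NIH/3T3 replay, the RAW 264.7 pair) and
then uses simulation scales chosen to keep the full suite in the
single-digit minutes on one core: ≥200 stutter observations per marker for
filter recovery (±10 % relative), 50 observations per allele for the
monotonicity check, 200 replicates for Friedman power at a −0.01 offset
across 19 blocks, 500 random profile pairs against the brute-force matching
oracle, and 1000 closed-loop generator→caller→matcher replicates.

## Known limitations

* Published marker-specific filter values ship as a fixture
  (`loadFixture("table2")`) for reference but cannot be re-derived here:
  the underlying multi-laboratory raw observations are not public.
* Anchor sizes are synthetic; calling real exports requires the lab's own
  calibrant anchor table.
* The bin half-width actually used by the consortium labs is unrecorded;
  0.5 bp is the package default, exposed as a parameter.
* Mixture deconvolution is explicitly refused, and aneuploid lines make
  stutter filters unreliable — flags are raised instead of answers.
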