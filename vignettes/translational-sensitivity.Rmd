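---
title: "Estimating codon translation rates and the sensitivity of speed profiles to fluctuating tRNA availability"
author: "transens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating codon translation rates and profile sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transens)
```

## The model

Translation elongation speed varies along an mRNA because codons are
decoded by tRNA isoacceptors of very different availability. `transens`
estimates a per-codon translation rate from a condition-specific tRNA
pool, turns coding sequences into smoothed speed profiles, and asks how
much each gene's profile moves when the pool shifts — between growth
rates, or over a time course of amino-acid starvation where tRNA
*charging* (aminoacylation) collapses selectively.

### Codon adaptiveness and rates

For each sense codon $i$ the adaptiveness is an availability-weighted
sum over the isoacceptors that decode it,

$$W_i = \sum_{j} (1 - s_{ij})\, c_j,$$

where $c_j$ is the concentration (or charging-adjusted availability) of
the $j$-th recognizing tRNA and $s_{ij} \in [0,1]$ is a selective
constraint on that codon–anticodon coupling. Which species decode which
codon follows Crick wobble geometry, organised in codon boxes sharing
the first two bases: a codon ending in U is read by anticodon wobble
base A (Watson–Crick) and G (G:U wobble); ending in C by G and by A
read as inosine; ending in A by U and weakly by inosine; ending in G by
C and by U. Two bacterial modifications override the generic rules:
AUA is decoded only by the lysidine-modified Ile isoacceptor
(anticodon CAU, constraint 0.89), and AUG only by elongator Met.

The default constraints are the standard prokaryotic tRNA-adaptation-
index set: Watson–Crick pairings 0, G34:U3 = 0.41, I34:C3 = 0.28,
I34:A3 = 0.9999, U34:G3 = 0.68. One per-interaction override is on by
default: decoding of CGA by the ACG anticodon uses $s = 0.9172$. Under
the generic inosine:A value, CGA would be roughly two orders of
magnitude slower than any other codon and would dominate every
downstream statistic; the retuned value agrees better with measured
elongation. All constraints and overrides are configurable
(`wobble_rules()`, `read_wobble_config()`).

Adaptiveness values are normalised to coupling probabilities and scaled
back to the pool size,

$$r_i = \frac{W_i}{\sum_k W_k} \, \sum_j c_j,$$

so rates sum exactly to the total tRNA concentration and inherit the
input units — concentrations are carried opaquely, and every rate, time
and threshold downstream is expressed in the units the pool table used.
The expected dwell time on a codon is $t_i = 1/r_i$, the mean of an
exponential waiting time for a matching charged tRNA. This is why
low-abundance codons are disproportionately sensitive: a small absolute
change in a small $r_i$ moves $1/r_i$ a lot.

One consequence of the pool-size normalisation is worth stating
plainly: because $\sum_k W_k$ and $\sum_j c_j$ both change when any one
isoacceptor changes, perturbing a single tRNA rescales *every* codon's
rate by a common factor, not only the codons it decodes. A gene that
contains none of the perturbed isoacceptor's codons therefore keeps its
profile *shape* exactly (its smoothed profile changes by one
multiplicative constant) but acquires a small nonzero sensitivity. The
test suite asserts the shape invariance; treating such genes' absolute
sensitivity as exactly zero would be wrong under this normalisation.

### Charging-adjusted availability

Starvation-style data sets report charged fractions per isoacceptor
over time against one reference concentration measurement. The
availability usable in elongation is their product, species by species
(`effective_availability()`, `charge_adjust_set()`). Setting every
fraction to 1 reproduces the concentration-only rate table bit for bit.
Measurement sets that report two isoacceptors collectively are split by
gene copy number ratio before use (`split_grouped_isoacceptors()`; for
*E. coli*, Gly1:Gly2 = 1:1 and Ile1:Ile2 = 3:1), conserving the pool
total exactly.

### Speed profiles

A coding sequence is split into codons 5'→3', the trailing stop codon
is stripped (stop codons have no cognate elongator tRNA and terminate
profiles), and each remaining codon is assigned its expected time. The
raw series is averaged over a centered sliding window, 19 codons by
default — the scale of the ribosomal footprint, so single-codon noise
is suppressed while local slowdowns remain visible. Speed is the
reciprocal of the smoothed time.

Window edges are handled by truncation: the effective window shrinks
near the termini so the smoothed profile keeps the full codon count.
This keeps the sensitivity statistic's length normalisation well
defined and comparable across genes; padding or discarding edges would
either invent data or make short genes incomparable. Window 1 is the
identity, and smoothing never leaves the range of the raw values. A
single codon $k\times$ slower than a uniform background depresses the
smoothed profile over exactly one window width — a geometry the
acceptance checks verify end to end, and the reason a sharp peak
appears at the window size in genome-wide distributions of the maximal
drop length.

Codons with no recognizing species at positive availability get
$W = 0$, an undefined rate and infinite time; any profile containing
one is flagged unusable and excluded with a warning rather than
silently smoothed over.

### Threshold and the four profile features

To compare a profile against the genome, a single threshold per data
set captures the average codon speed of all smoothed profiles under the
reference condition: the mean over the *concatenation* of per-position
values (so it is length-weighted — a position-level average, not a mean
of per-gene means, which the wording "average codon speed of all
smoothed profiles" implies; the choice is explicit in the code and
switchable by computing per-gene summaries first). Both a time-scale
and a speed-scale threshold are available, since a threshold value is
only reusable together with its scale convention; drops are evaluated
on the speed scale by default, with strict inequality — a position exactly at the
threshold is not "below". A per-condition mode simply recomputes the
threshold from each condition's own profiles; under uniform rate
scaling the drop statistics are then exactly invariant, which is the
expected growth-rate behaviour.

Per gene and condition, four features are reported: the average
(smoothed) translation time; the slowest point (longest smoothed time);
the drop count — the number of maximal contiguous runs slower than the
threshold, pinned to 1 when the whole profile is below it; and the
maximal drop length in codons, excluded (NA) for entirely-below
profiles since no boundary exists to delimit a run.

### Sensitivity

For one gene under a reference condition $c_1$ and a shifted condition
$c_2$, the sensitivity is the length-normalised L1 distance between the
smoothed time profiles,

$$S = \frac{1}{l} \sum_{j=1}^{l} \left| t_j^{c_1} - t_j^{c_2} \right|,$$

with $l$ the number of smoothed positions (the translated codon count —
the only length both profiles share by construction). $S$ is a metric:
nonnegative, symmetric, zero exactly for identical profiles, and
triangle-inequality-consistent, all property-tested. It scales linearly
with a uniform time scaling, so comparisons are meaningful within one
data set's units.

Genes are ranked by $S$; the top and bottom `ceiling(fraction * n)`
genes (default 10%) form the most/least sensitive slices, with
untranslated and pseudo genes excluded and ties at a cut broken by
lexicographic gene id so slices are reproducible. Group contrasts
(essential vs non-essential, untranslated vs coding) use a one-sided
Wilcoxon rank-sum test — sensitivity distributions are heavily skewed,
so a rank test is the defensible default; the test's identity is
recorded in the output. Genome binning tiles the chromosome into equal
stretches (200 by default; the last bin absorbs the integer-division
remainder) and averages $S$, CAI and GC% over the genes starting in
each bin. CAI is the Sharp–Li geometric mean of relative adaptiveness
weights; weights are reference-set dependent and user-supplied, with a
convenience derivation from a rate table and a bundled example. Zero
weights are floored at 0.01 so one unused codon cannot annihilate the
index. Covariate–sensitivity association uses Spearman's rank
correlation with tie handling; the goodness of fit of the rank–rank
relation is the squared rank correlation.

## The synthetic study conditions

The generators (`fixture_spec()`, `make_pool()`, `perturb_pool()`,
`make_cds_set()`) are first-class, fully seed-deterministic code, not
test scaffolding. They emulate the *statistical structure* of the two
experimental regimes:

* **uniform mode** multiplies every concentration by a schedule factor —
  the growth-rate regime, where slower growth shrinks the whole pool
  nearly uniformly;
* **targeted mode** sets charged fractions of named species (e.g. a
  leucine family member to 0.05, near-depletion) and applies the
  charging adjustment — the starvation regime, where rate changes are
  heterogeneous and some codons even speed up through the
  normalisation.

The bundled toy organism has 8 isoacceptors chosen so every wobble
pairing kind and the CGA override are exercised at least once, with an
*E. coli*-like five-member leucine family. Its reference concentrations
are drawn log-normally (median ~400, spread matching the roughly
order-of-magnitude range of measured isoacceptor abundances) and then
calibrated so the low-rate leucine trio CUU/CUC/CUA and the robust trio
CUG/UUG/UUA have equal summed expected times at reference. The paired
"twin" constructs — identical amino-acid sequences differing only in
which synonymous trio encodes their leucines, with synonyms cycled so
each is used equally often — then have *identical* sensitivities under
any uniform scaling (up to a ~10⁻⁴ relative residual from window edge
truncation), while a targeted collapse of the isoacceptors reading the
sensitive trio separates them severalfold. Differential charging
between isoacceptors of one amino acid is precisely what starvation
measurements show, so the contrast is realistic, not contrived.

Bundled alongside are two condition tables with clearly synthetic
values mirroring the shapes of the real data sets (five growth rates,
concentrations only; five starvation time points, concentrations plus
charged fractions with the leucine family collapsing and a broad dip at
one time point), and an editable isoacceptor→anticodon map for the
*E. coli* K-12 elongator set covering all 61 sense codons.

What the generators do **not** emulate: real codon usage frequencies,
operon structure, mRNA secondary structure, ribosome collisions, or
re-charging kinetics. Passing tests therefore demonstrate the
correctness of the rate→profile→sensitivity machinery and its invariant
structure, not genome-scale biological conclusions; those require real
concentration/charging tables and annotated sequences supplied by the
user.

## Numerical and interface choices

* Codons are RNA 5'→3' internally; DNA input is accepted, T≡U.
  Positions are 0-based internally and 1-based in all exported tables.
* Concentration units are opaque and never rescaled; thresholds are
  unit-dependent, so thresholds from differently scaled tables are not
  comparable.
* Start codons are retained with their elongator time (AUG with
  elongator Met; profiles model elongation only, so initiator tRNA must
  not appear in pools).
* Untranslated sequences are profiled as if coding, in frame from their
  annotated start, skipping codon validation — that is what makes them
  directly comparable with coding genes in group contrasts.
* Sliding-window means use a cumulative-sum formulation (O(n)); tests
  compare it against a literal O(n·w) loop.
* The rank-and-slice tie rule, strict drop inequality, `ceiling` slice
  size and the 0.01 CAI floor are all deliberately fixed so repeated
  runs and reimplementations agree to the digit.

Problem sizes in the shipped tests and acceptance script — 200 random
pools of 3–10 species for oracle equivalence, 500 random vectors for
smoothing/drop oracles, 12–40 synthetic genes of 60–120 codons for
pipeline checks — were chosen as the smallest sets that exercise every
branch while keeping each property check well-powered.

## Known limitations

* Rates are deterministic expectations; no stochastic elongation,
  ribosome queueing or initiation limitation is modelled.
* tRNA pools are static per condition; transient depletion during a
  shift, and demand-side effects of the transcriptome, are out of
  scope.
* Post-transcriptional wobble modifications beyond inosine and lysidine
  (e.g. uridine methylation states) are representable only through
  custom s-values per pairing, not per species.
* The pool-size normalisation couples all codons (see above); absolute
  sensitivities of genes untouched by a perturbation are small but not
  zero, and analyses should rank genes rather than interpret tiny
  absolute S values.
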