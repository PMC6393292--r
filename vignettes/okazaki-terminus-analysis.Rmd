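---
title: "Methods: strand-aware Okazaki fragment terminus analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strand-aware Okazaki fragment terminus analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(okazakir)
```

## Scope and model

Okazaki fragment maturation on the lagging strand proceeds by nick
translation: strand-displacement synthesis by Pol δ creates short 5′ flaps
on the downstream fragment, nucleases (Rad27/FEN1, with contributions from
Exo1 and Dna2) cleave them, and ligase seals the resulting nick. Two
genome-scale observables constrain this process, and this package computes
both from mapped fragment intervals:

1. the distribution of fragment 5′ and 3′ termini relative to nucleosome
   dyads and transcription-factor binding sites, oriented by synthesis
   direction; and
2. the fraction of fragment junctions that are ligatable nicks, read out by
   an in-silico analog of end-labeling plus T4 ligase treatment.

Everything operates on 0-based half-open intervals with mandatory strand.
The 3′ terminus is defined as the last synthesized nucleotide (`end − 1` on
`+`, `start` on `−`), not the open endpoint, so 5′ and 3′ offsets are
integer-symmetric and a length-1 fragment has both termini on the same
base. Fragments without strand are rejected outright rather than split:
synthesis orientation is the entire point of the analysis, and a
strand-less record cannot be oriented.

## Oriented aggregation

A terminus at position $t$ on a fragment of strand $s$ contributes to a
feature midpoint $m$ on the same chromosome at offset

$$\mathrm{off} = \begin{cases} t - m & s = {+}\\ m - t & s = {-}\end{cases}$$

whenever $|t - m| \le W$. Profiles therefore read left to right in the
direction of fork movement regardless of genomic strand, and mirroring the
entire genome (coordinates and strands) leaves them bit-identical — a
property the test suite checks exactly.

Two conventions here were genuinely open and are fixed as follows:

- **Window $W$.** Published meta-profiles do not state their x-axis extent.
  Defaults are $W = 100$ nt for dyads (covers the 147-nt nucleosome core
  plus linkers) and $W = 250$ nt for TF sites (their terminus structure
  spreads over a fragment length). Both are arguments, and every output
  header records the value used.
- **Multiplicity.** A terminus within $W$ of several features counts toward
  each of them; there is no nearest-feature assignment. This is the
  simplest rule consistent with a composite profile, and it makes the mass
  identity `sum(counts) == n_termini` exact, with `n_termini` counting
  terminus–feature pairs. With dyads tiled every repeat length and
  $W = 100$, a terminus can match at most two dyads.
- **Feature orientation is ignored.** TF motif strand is not used to flip
  offsets; orientation comes from synthesis only. Motif-strand handling in
  published profiles is unstated, and mixing two orientation rules would
  make profiles irreproducible from their parameters.

Occupancy filtering keeps the `ceiling(fraction * n)` highest-scoring dyads
(default fraction 0.5, the conventional top half by occupancy); ties at the
cutoff break by `(chrom, midpoint)` order so the selection is deterministic.

## Smoothing and normalization

Smoothing is a centered moving average of odd width (default 5 bp, the
conventional display smoothing; even widths are rejected because they have
no center). At profile edges the window truncates and the average is taken
over the available offsets, so edge mass is not conserved — a deliberate
trade against padding artifacts.

Dyad profiles are normalized to the maximum over the range (peak = 1
exactly); TF-site profiles to the median (median = 1 exactly), which
expresses enrichment relative to surrounding sequence rather than peak
height. An all-zero profile cannot be normalized and errors; a zero median
with nonzero maximum (signal too sparse for median scaling to mean
anything) errors with a message naming the condition rather than returning
infinities.

## Shift and decoupling statistics

The displacement between two profiles is the argmax over integer lags of
their cross-correlation (both max-normalized first), refined to sub-bin
resolution by parabolic interpolation through the three points around the
best lag. Cross-correlation was chosen over peak-position or
mean-difference because it remains stable when the peak *shape* changes
between conditions, which is exactly the situation the comparison is for.
Negative values mean the second profile is displaced toward negative
offsets — the fork-proximal direction. The lag search spans $\pm W/2$ by
default; at a search boundary the parabolic refinement is skipped.

The decoupling statistic is the same estimator applied between a
condition's own 5′ and 3′ dyad profiles. Because a mature fragment's 5′
end sits one fragment length upstream of its 3′ end, and fragments tile the
nucleosome repeat, *coupled* maturation leaves the two profiles nearly
superimposable (the residual offset is the repeat minus the mean length,
about +1 nt here). Flap accumulation that displaces only 5′ ends drives
the statistic negative by the mean flap length. The verdict threshold is
5 nt: comfortably above the coupled residual and sampling noise at the
ensemble sizes used, and well below any flap regime worth calling. It is a
package default, not a measured constant, and is exposed as an argument.

## Fragment-length periodicity

Chromatin-patterned fragments produce a ladder of lengths at multiples of
the nucleosome repeat. The periodicity statistic builds a 1-nt length
histogram over 50–2000 nt, subtracts a 201-nt moving-average baseline, and
returns the lag in [100, `max_lag`] maximizing the autocorrelation of the
residual, with the score normalized to the zero-lag value. The baseline
subtraction matters: without it, any unimodal or block-shaped histogram
correlates with itself over long lags and gross histogram shape masquerades
as periodicity. The 201-nt window is wider than any plausible repeat, so
it removes shape without touching the ladder. On the simulated ladder the
estimator recovers 165 nt within 3 nt; a flat-length control scores an
order of magnitude lower.

## In-silico ligation

Junctions between genomically adjacent same-strand fragments are labeled
from coordinates: `nick` when intervals abut exactly (3′-OH and 5′-phosphate
precisely juxtaposed), `gap` when separated, `flap_overlap` when they
overlap. Near-abutment (±1 nt) is *not* treated as a nick: the assay models
purified DNA plus T4 ligase with no nuclease or polymerase present, so only
exact juxtaposition is sealable, and flaps are never trimmed-then-ligated.
When fragments carry simulated junction-state annotations these take
precedence (they are the ground truth the coordinates cannot encode, since
simulated fragments are drawn independently), and the coordinate-derived
label is kept alongside for cross-checking.

Ligation merges maximal runs of nick-joined neighbors and repeats until no
nick remains: a merged product whose new 3′ end comes to abut a downstream
5′ start is itself sealable. The fixpoint is what makes the operation
idempotent on arbitrary input; on coordinate-consistent data it converges
in one pass and the count drops by exactly the number of nick junctions.
The merged record keeps the junction annotation of its 5′-most constituent
— the one junction still unsealed.

The signal model is one labeled end per fragment, independent of length,
with the quantified region being fragments shorter than 1000 nt. Whether
gel signal scales per labeled end or per incorporated nucleotide is not
derivable from end-labeling alone; per-end is the stated simplification,
and the percent-lost statistic `100(S₋ − S₊)/S₋` only compares the same
model to itself. Replicate pairs with and without ligase are compared by a
standard two-sided paired t-test (`stats::t.test`), df = n − 1.

## The simulator

The generator emulates the statistical structure the analysis assumes,
with full ground truth:

- **Genome and forks.** Two chromosomes (400 and 350 kb) with three
  replication origins; forks move rightward right of the nearest origin and
  leftward left of it, with the divide between adjacent origins at their
  midpoint. This is the minimal structure sufficient to exercise strand
  orientation — there is no replication-timing model. Lagging-strand
  fragments take the fork direction as their strand, so synthesis runs left
  to right under rightward forks.
- **Dyads and TF sites.** Dyads tile every 165 nt (the budding-yeast
  nucleosome repeat) with lognormal occupancy scores (meanlog 0, sdlog 0.5)
  so the top-occupancy filter is exercisable; TF sites sit every 6 kb,
  roughly the genomic density of general regulatory factors.
- **Termini.** The 3′ terminus is `dyad + s·(shift + N(0, sd))` with
  condition-specific shift and sd (default sd 15 nt); the 5′ terminus rides
  one fragment length upstream. Negative shifts point to the fork-proximal
  nucleosome edge. Per-condition defaults encode the qualitative regimes
  of nuclease loss — 0 nt (WT, Dna2 depletion), −10 nt (Exo1 loss), −20 nt
  (Rad27 depletion), −30 nt (Rad27+Exo1) — as free parameters: the
  published profiles are not tabulated, so magnitudes are the simulator's
  own, chosen once to be resolvable at the default ensemble size and
  ordered as observed.
- **Lengths.** `span × 165 + N(0, 15)` nt, floored at 50, where `span` is
  geometric (continuation probability 0.25, capped at 5). The multi-span
  ladder is what gives the length histogram its repeat periodicity, the
  in-vivo gel banding pattern.
- **Junctions.** Each 5′ junction is a nick with the condition's ligatable
  fraction (0.8 for Rad27-proficient strains, where most fragments are
  poised for ligation; 0.05 without Rad27), else a gap or flap (equal odds)
  of length `1 + Poisson(4)` nt — gaps and flaps are short, but no length
  distribution is published, so a guaranteed-positive short draw is used.
  In the default (reduced-nick-translation) mode junction states do not
  move coordinates: both termini shift together. In `decoupled_flap_mode`
  flap lengths displace only the 5′ terminus upstream, the
  strand-displacement alternative; with mean flap 16 nt the decoupling
  statistic lands at −15 nt (the −16 nt flap plus the +1 nt coupled
  residual).
- **TF hard barriers.** A fragment assigned within one repeat of a TF site
  has its 3′ terminus relocated to the fork-proximal site edge (8 nt
  upstream of the midpoint, half a 16-nt footprint) with probability 0.3,
  keeping its 5′ end — a barrier stops synthesis early. Relocations that
  would invert the fragment are skipped.
- **Determinism.** All draws run under seeds derived deterministically from
  the config seed (one sub-stream per component), so identical configs give
  byte-identical output and a panel re-run from its manifest reproduces
  every file exactly. Manifests serialize numbers so they round-trip
  exactly.

What the generator does **not** emulate: sequence context, mappability,
read-level errors or duplicates, replication timing, origin efficiency,
inter-fragment coordination along a tract (fragments are drawn
independently, so genomic neighbors are not the chain a real lagging strand
produces — junction states are carried as annotations instead), and any
nuclease kinetics. Passing tests therefore show that the *statistics
recover what the generative model encodes*, not that the biology has these
parameter values; on real data the same code applies but the shifts,
fractions and thresholds are the measurements, not inputs.

## Numerical choices and degenerate inputs

- Peak location ties break toward the smallest absolute offset, then the
  negative one (deterministic, fork-proximal-leaning).
- `smooth(bp = 1)` is the identity; normalization is idempotent;
  max-normalized maxima and median-normalized medians equal 1 exactly (the
  defining element divides by itself).
- Empty fragment sets aggregate to an all-zero profile flagged
  `empty_input`; empty feature sets are an error (a meta-profile over
  nothing is meaningless).
- Unsorted input to junction classification is an error, not silently
  sorted: order encodes adjacency, and sorting on the caller's behalf
  could mask an upstream bug.
- Paired t-tests require ≥ 2 pairs and nonzero difference variance.

## Problem sizes

Ensemble sizes were chosen so every stochastic check resolves its effect
with wide margin: 50 000 fragments per condition for shift recovery (CLT
standard error ~0.07 nt on the mean 3′ offset; cross-correlation recovery
within ±0.4 nt in practice), decoupling and periodicity; 20 000 for the
ligatable-fraction monotonicity sweep and replicate-level ligation
analysis. The full eight-condition panel (simulate, profile, ligate,
compare, twice for the byte-identity check) completes in well under two
minutes on one core.

## Known limitations

- Shift estimates assume the two profiles share a dominant peak within the
  lag search range; profiles with comparable secondary peaks one repeat
  away could lock onto the wrong lag if the true shift approached half a
  repeat. The ±W/2 default search bounds this.
- The decoupling residual (+1 nt here) depends on the repeat-minus-length
  offset; organisms with linker lengths very different from 18 nt would
  shift the coupled baseline, though not near the 5-nt threshold.
- Median normalization requires a nonzero median: very sparse TF profiles
  (small ensembles, wide windows) error by design rather than rescale
  meaninglessly; dyad-style max normalization is the fallback a user can
  choose explicitly.
- The per-end signal model makes percent-lost insensitive to how much
  *length* exits the quantified window; an intensity-per-nucleotide model
  would weight long products differently.
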