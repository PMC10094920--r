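---
title: "Network analysis of developing cultures on high-density MEAs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network analysis of developing cultures on high-density MEAs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(hdmeanet)
```

## What this package models

Dissociated cortical neurons plated on a high-density multielectrode array
(HD MEA; a 64 x 64 CMOS grid of 4096 electrodes at 42 um pitch, sampled at
10 kHz) develop spontaneous network activity over days in vitro (DIV):
firing rates rise, interspike intervals (ISIs) shrink, synchronized
population events ("network bursts") emerge, and the functional network
acquires small-world organisation.  Chronic exposure to amyloid-beta(1-42)
oligomers -- an Alzheimer's-disease model perturbation -- distorts this
program: activity is initially hyperexcitable but declines after mid-culture,
firing stays spatially localized, clustering stays abnormally high while the
network fragments, and population events stay flat in number with fast,
disoriented centre-of-activity trajectories.

`hdmeanet` implements the full analysis chain for such recordings --
firing/ISI statistics, spike-burst and network-burst detection,
cross-correlation connectivity with graph metrics, and centre-of-activity
trajectory (CAT) analysis -- together with a synthetic spike-raster
generator that emulates a control and a perturbed ("abeta42") phenotype
across DIVs 1, 4, 7, 10, 13 and 16.  Because real recordings of this kind
are rarely shareable, the generator is a first-class module: it emits the
latent ground truth (graph, burst windows, rates, spatial weights) beside
every raster, so each analysis stage can be validated as a recovery problem
rather than by eyeball.

## The synthetic generator

A recording is simulated in three layers (`simulate_recording()`):

1. **Baseline firing.**  Each electrode fires as an independent homogeneous
   Poisson process with rate `base_rate_hz * w_i * g_i`, where `w_i` is a
   spatial weight map (mean 1) and `g_i` a per-electrode gamma multiplier
   with coefficient of variation `rate_dispersion` (default 0.3) capturing
   electrode-to-electrode heterogeneity.  The control weight map is
   homogeneous from DIV7 on (a broad centred Gaussian before); the abeta42
   map is a narrow off-centre Gaussian hotspot at every age.  The hotspot
   position and width are the package's own modelling choice: the source
   phenomenology ("localized off the centre") gives no quantitative
   description, so a Gaussian at 45% / 33% of the half-extent with sd 30% of
   the half-extent was fixed once and documented here.

2. **The ground-truth graph.**  Control: a directed ring lattice over
   grid-ordered electrodes (even mean degree rising from 2 at DIV1 to 12 at
   DIV16) with 10% uniform rewiring -- the classic small-world construction,
   whose characteristic path length falls as the degree grows.  abeta42:
   consecutive distance-from-hotspot modules of `round(0.15 * n)` electrodes,
   each fully connected, with two random links between adjacent modules.
   Near-cliques give the perturbed graph a clustering coefficient near 1 at
   every age, far above the rewired lattice, while staying fragmented.

3. **Network bursts.**  `n_network_bursts` windows (control: 0 at DIV1
   rising to 55 at DIV16; abeta42: 25 at every age) are placed without
   overlap (>= 0.5 s separation, 1 s margins; remaining slack distributed as
   random gaps, so placement either succeeds deterministically or raises an
   explicit error).  Durations are drawn around `burst_duration_mean_ms`
   (control 400 -> 260 ms; abeta42 250 -> 160 ms; sd 8% of the mean, clipped
   at +-2 sd).  Within a window, recruited electrodes emit a 3-spike volley
   time-locked to their onset (0/3/6 ms) and then fire Poisson at
   `within_burst_rate_hz` until the window ends.  Onsets are staggered by 5
   ms per ground-truth graph hop, so lagged cross-correlation can recover
   the direction of propagation.  Control recruitment is a breadth-first
   ball grown from one seeded origin (participation 0.4 -> 0.9 of the
   electrodes); abeta42 recruitment alternates every 30 ms between the
   hotspot module and the most distal module.

The alternating-compartment model deserves a note.  The perturbed phenotype
is described as fragmented and "disoriented": population events do not
converge on the arena centre, trajectories are fast and short.  A single
focal compartment reproduces the off-centre trajectories but not reliably
the speed: once focal events are strong enough for the detector, the
centre-of-activity jitter inside one compartment is comparable to the
control's.  Letting the event hop between two spatially separated
compartments reproduces all three signatures at once -- speed (the CA jumps
between compartment centroids), brevity (short windows), and eccentricity
(both centroids are off-centre) -- and is the package's operationalisation
of a fractured network.  The within-burst rates (60 Hz control, 45 Hz
abeta42) were chosen so that burst bins stand far above the detector's own
threshold under each phenotype's baseline.

The two baseline rates at DIV1/DIV4 are calibrated so the pooled average
ISI ratio between those ages reproduces the reported developmental drops:
0.5 -> 1.4014 Hz (ratio 35.68%) for control and 0.5 -> 0.781 Hz (64.02%)
for abeta42.  The expected pooled mean ISI of a Poisson raster is 1/rate,
so the ratio target equals the inverse rate ratio; the residual finite-
recording bias (~+0.3 percentage points at 300 s) is well inside the +-2
point calibration band.

All generator parameters live in a documented YAML file
(`default_phenotype_config()`); every random draw flows from one explicit
seed per recording and the generator is bit-reproducible.

What the generator does **not** emulate: biophysical membrane dynamics,
synaptic plasticity, refractoriness, electrode crosstalk, spike-sorting
errors, or day-to-day nonstationarity within a recording.  Tests passing on
this generator therefore demonstrate that the analysis chain recovers known
structure of the stated forward model -- not that it is robust to every
artefact of real recordings.

## Analysis conventions and tunable parameters

**Activity metrics.**  MFR is spike count / duration per electrode (silent
electrodes included, so the map integrates to the total spike count).  ISIs
are successive-spike differences within an electrode, in ms; "average ISI"
pools all intervals across electrodes by default (one distribution per
culture), with per-electrode averaging available.  Whether inter-burst
intervals should be excluded is unstated in the source phenomenology; all
intervals are retained.  Quartiles use linear interpolation between order
statistics (R type 7), SEM is `sd/sqrt(n)` with the n-1 denominator, and
group comparisons use the unpaired two-tailed Welch t-test with tiers
`***` p < 0.005, `**` p < 0.01, `*` p < 0.05.

**Spike bursts.**  The max-interval convention: a burst is a maximal run of
spikes with every ISI <= `max_isi_ms` (default 100 ms) and at least
`min_spikes` (default 5).  These defaults are the simplest widely used MEA
convention; the commercial acquisition software's algorithm is proprietary
and no exact numerical match is attempted.

**Network bursts.**  Population spike counts in 25 ms bins; candidate bins
exceed mean + k sd of the binned series (k = 3); candidates within 100 ms
merge into one event; an event must contain at least `min_bins = 4`
candidate bins and recruit >= 10% of the active electrodes (>= 0.02
spikes/s, i.e. 6 spikes per 5 min -- needed for participation fractions to
be meaningful on sparse DIV1 rasters).  The `min_bins` floor is a deliberate
addition to the classic threshold rule: a 5-minute Poisson raster at these
rates crosses a 3-sd threshold in ~50 single bins by chance, so without a
minimum event extent the false-positive rate is far from the intended
"essentially zero on stationary baselines".  Four bins (100 ms) suppresses
chance chains while leaving the shortest embedded events (>= ~130 ms) with
full recall.

**Connectivity.**  Binned cross-correlograms (2 ms bins, +-25 ms lags,
bins centred on multiples of the bin width with half-away rounding).
Significance is assessed per pair against spike-jitter surrogates: each of
20 surrogates displaces every spike of the target train uniformly within
+-25 ms; the threshold is mean + 4 sd of the surrogate peaks.  Jitter at
the lag scale preserves slow co-modulation (common burst participation)
while destroying millisecond locking, so the threshold adapts per pair and
only time-locked structure survives.  A significant peak at positive lag
yields a directed edge (source leads target); an exactly zero-lag peak is
stored as two directed edges flagged `mutual`.  Edge weight is the peak
count over the geometric mean of the two spike counts.  Node roles follow
the degree balance: sender (out > in), receiver (in > out), broker (equal,
nonzero); isolated nodes are excluded from the partition.  These role
criteria are a convention, not an inference.

**Graph metrics.**  Computed on the undirected projection (the development
analysis treats a link as a link regardless of direction; directed variants
are out of scope).  Local clustering is `2T/(k(k-1))`, averaged over nodes
with k >= 2.  Path lengths are unweighted BFS distances; per-node averages
are taken over reachable targets only, because the perturbed graphs are
expected to fragment and dropping disconnected nodes would bias the degree
comparison (a largest-component-only mode exists behind a flag).  Per-node
average path lengths are binned at 0.25 links -- chosen because reported
median path lengths of 2.25/2.75/3.25 links are non-integer, implying
sub-integer binning of per-node averages.  A fully disconnected graph
raises a distinct no-path error rather than returning an empty result.

**Centre-of-activity trajectories.**  CA per 10 ms bin is the spike-count-
weighted centroid of electrode positions relative to the arena centre,
defined as the centroid of the grid (exact for the symmetric layout; the
distinction between the electrode array and the larger working area is
deliberately collapsed onto the array centroid and documented here).  CAT
is computed within detected network-burst windows (whole-recording CA is
available directly through `center_of_activity()`).  Empty bins are
skipped, never interpolated -- interpolation would fabricate motion -- and
velocity uses the actual time gaps between defined points.  A trajectory
with fewer than two defined points is degenerate: it is flagged, its
velocity is undefined, and condition summaries exclude it with `n`
reflecting the exclusion.

**Pipeline.**  `run_experiment()` simulates every condition x DIV cell
(per-cell seeds derived from the run seed), runs all stages, and emits a
long metrics table plus Welch comparisons.  Sampling units for the tests
are electrodes (rates, ISIs), bursts (durations) and trajectories (CAT
metrics); which unit the source figures used is unstated, so both are
documented here and the tables carry `n`.  No multiple-testing correction
is applied by default, matching per-panel testing practice; a
Benjamini-Hochberg option exists because six DIVs x several metrics is a
respectable family size.  Graph metrics are reported for both the inferred
graph and the ground-truth graph (`*_inferred` / `*_truth` metric
suffixes); phenotype contrasts in clustering and path length are asserted
on the ground-truth graphs, which the generator controls directly, while
the inference stage is validated separately by chain recovery, direction
accuracy (> 0.9 against the embedded propagation order) and the
edge-count correlation across DIVs.

## Problem sizes and reproducibility

The packaged demo and the test suite run on a 10 x 10 grid (100
electrodes) with 5-minute recordings -- the package's desk-scale default,
at which every stage (including all-pairs connectivity with 20 surrogates,
~100k compiled correlogram evaluations per recording) completes in seconds
to a couple of minutes per cell.  The full 64 x 64 geometry is exercised
where it matters structurally (layout construction) and is supported
throughout, with connectivity inference cost growing quadratically in
active electrodes.  Everything downstream of a seed is deterministic:
identical configuration and seed give byte-identical metrics tables.

## Known limitations

- The burst, connectivity and role conventions are reasonable defaults,
  not reverse-engineered matches of any commercial analysis suite.
- Connectivity inference recovers the propagation structure the generator
  embeds (onset-order lags); it is a lagged-correlation method and inherits
  its usual blind spots (common input, unobserved mediators), and no
  transfer-entropy or model-based alternative is provided.
- The generator's phenotype is a caricature calibrated to a handful of
  published summary numbers; DIV-by-DIV burst counts and durations of real
  cultures are not reproducible from summary statistics alone and are
  emulated only in trend.
- Welch tests on per-electrode samples treat electrodes as independent,
  which burst correlations violate; the tests are descriptive here, as in
  common practice, and the BH option does not repair that dependence.
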