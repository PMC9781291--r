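---
title: "Calcium signal propagation graphs from fluorescence traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calcium signal propagation graphs from fluorescence traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capnet)
library(dplyr)
```

## The problem

Cultured astrocytes and neurons signal to their neighbours with transient
rises of cytosolic calcium. In a fluorescence recording (one frame every
0.5 s at the 2 Hz acquisition this package assumes by default), each
segmented region of the field yields one intensity trace — the mean pixel
intensity of that region per frame. The scientific questions are: *when* is
a cell active, *where* does activity travel, and *how much* does a culture
transmit. capnet answers them in four stages, each usable on its own:

1. **Event detection** per trace, from crossings of two exponential moving
   averages and an interpolated baseline.
2. **Dynamic directed graph**: a frame-resolved graph whose edges connect
   spatially adjacent cells during the overlap of staggered events.
3. **Compressed transmission graph** with per-direction transmission
   counts, degree and HITS centralities, and summary metrics.
4. **Group histograms**: per-100-cells distributions of per-cell
   transmission counts across the cultures of an experimental group, with
   rank-sum comparisons of binned shares.

A synthetic-culture simulator with full ground truth makes every stage
testable without any recording.

## Event detection

For a trace $I_j$, $j = 1..T$, the forward exponential moving average is

$$EMA^F_j = EMA^F_{j-1}\,k + (1-k)\,I_j, \qquad EMA^F_1 = I_1,$$

and the backward average is its mirror image starting at the last frame.
The coefficient $k \in (0,1)$ sets how slowly the average follows the
signal; the default 0.97 at 2 Hz corresponds to a time constant of roughly
17 s, slow against transient rise times but fast against baseline drift.
The initialisation at the first sample is our choice (it avoids a start-up
transient); the value of $k$ should be calibrated per recording setup with
`calibrate_k()`, which grid-searches $k$ against manually marked event
boundaries using an order-preserving matching of events (unmatched events
are penalised by their own duration, so over- and under-detection both
count).

Event candidates are maximal runs of frames where the trace lies strictly
above the forward EMA; each run contributes one peak (first frame of the
run's maximum on ties). The event start is the upward crossing (the first
frame of the run); the finish is the first frame at or after the peak where
the trace falls to or below the *backward* EMA. "Crossing" means a sign
change of trace minus EMA between consecutive frames, with exact equality
terminating a run; the crossing frame is the first frame on the new side.
If a finish would reach into the next event of the same cell it is clipped
to the frame before that event's start, so one cell's events never overlap.

The baseline interpolates linearly between the per-run minima of the
sub-EMA runs and continues horizontally beyond the outermost anchors; a
trace that never dips below its EMA (a constant trace) degenerates to the
trace itself. An event is significant when its peak lies strictly more
than a threshold above the baseline at the peak. The conventional
threshold is three standard deviations of *biological noise*: the pooled
deviations (trace minus baseline) of a non-signalling control culture,
via `estimate_noise_threshold()`.

Two properties worth knowing: detection is exactly invariant to adding a
constant to a trace, and raising the threshold can only remove events.
With an honest 3-SD rule on unsmoothed Gaussian noise a small rate of
short, marginal false events is expected (the rule bounds amplitude, not
run-maximum statistics); the threshold should be taken from a control
whose fluctuations dominate the residual measurement noise of the
recordings, which is what the biological-noise control provides.

## The dynamic graph

Only *adjacent* cells are compared — contact-mediated propagation is
short-range, and all-pairs comparison is known to produce false long-range
links. Adjacency comes from the label image: two regions are adjacent when
their pixels touch (8-connectivity by default, diagonal contact counts;
configurable to 4). For events $a$ in cell $i$ and $b$ in cell $j$:

* $start_a < start_b \le finish_a \le finish_b$: **staggered overlap**,
  a directed edge $i \to j$ spanning the overlap interval
  $[start_b,\, finish_a]$ (inclusive frames);
* equal starts with intersecting intervals: **simultaneous** — no
  direction can be read, but both cells count as active;
* nested events (one interval strictly inside the other): **no edge**.
  The stagger that justifies a direction is absent; these pairs are
  reported in a diagnostics table so they can be audited.

Starts are compared strictly (they set the direction); the two
finish comparisons admit ties, which are common on integer frames.

The dynamic graph is stored as a sparse interval edge list; `to_dense()`
expands it to the cells x cells x frames array (one adjacency matrix per
frame) under a memory budget, and is used as the cross-checking
representation in the tests.

All frame indices, everywhere in the package and in every file it reads or
writes, are 1-based and inclusive.

## Compression and metrics

The per-frame edge sets give the dynamic metrics: total edge count over
all frames (each edge counted on each frame of its interval), the number
and percentage of active cells (senders, receivers, and simultaneous
participants), and the maximum number of transmissions on any single
frame.

Compression counts each transmission once regardless of duration:
$c_{ij}$ is the number of *onsets* of the edge $i \to j$ — frames where
the edge is present but was absent on the previous frame — computed on the
union of the pair's edge intervals. Directions are counted separately; the
arc-label matrix $b = c - c^\top$ records the net balance and drives the
line-contrast rendering (`autoplot(cg, centers, mode = "contrast")`).
Out-degree $\sum_j c_{ij}$ and in-degree $\sum_j c_{ji}$ both sum to the
total transmission count. The *periodic connection* metric discards
ordered pairs with fewer than two transmissions; by default each
qualifying pair contributes one to each endpoint's degree
(`count_mode = "repetitions"` counts every repetition instead — the
formula admits both readings, so both are implemented).

HITS hub/authority scores are computed by L2-normalised power iteration
on the count-weighted graph (tolerance 1e-8, at most 1000 iterations);
a graph with no edges gets all-zero scores with a warning. The tests
cross-check the scores against the principal eigenvectors of $C^\top C$
and $C C^\top$ and against igraph.

## Group analysis

A cell's transfer count is its in- plus out-degree on the compressed
graph. The group histogram pools the cells of all cultures of a group
*before* normalising: $n_i$ is the number of cells with exactly $i$
transfers per hundred pooled cells, for $i = 1..50$ (cells with zero
transfers dilute the histogram but add no bar; counts above 50 are
retained only by the binned ">40" share). The per-culture *binned shares*
— percentages of a culture's cells with 2–4, 5–10, 11–24, 25–40 and more
than 40 transfers (closed intervals; 0 and 1 fall in no bin) — are the
statistical unit: groups are compared by two-sided Mann–Whitney–Wilcoxon
tests on per-culture shares with Holm–Bonferroni correction, exact null
for group sizes up to 10 without ties, normal approximation with tie
correction otherwise. Comparing cultures rather than cells avoids
pseudo-replication.

## The simulator

`simulate_culture()` generates: a Voronoi tessellation of the field
around sampled seed points (the label image); spontaneous initiator
events per cell as a Poisson process; propagation of each event to each
adjacent region with a configured probability after a uniform 2–5 frame
delay, recursively (one activation per cell per wave); traces as resting
level + slow sinusoidal drift + difference-of-exponentials transients
(1 s rise, 10 s decay at 2 Hz) + iid Gaussian noise. Defaults are a
desk-scale version of the acquisition the package targets: 25 cells on a
128 x 128 px field, 2400 frames (20 min at 2 Hz), transient amplitude 30
intensity units over noise SD 3, drift amplitude 2 over a 5 min period,
propagation probability 0.3, two initiator events per cell per recording
— within the range of spontaneous astrocyte event rates. Everything is
reproducible from the seed.

Ground truth records every event (with its wave), every direct
parent-to-child propagation, and the *wave pairs*: adjacent cell pairs
co-activated by the same wave, ordered by activation time. Wave pairs are
the reference for recovery scoring (`evaluate_recovery()`): a wave that
reaches two adjacent cells through a relay still propagates signal
between them in a definite order, and the overlap algorithm is expected
to see it — scoring against direct parent-child pairs only would count
those correct detections as errors.

What the simulator does *not* emulate: spatial intensity structure within
regions (traces are generated at region level unless a full stack is
requested), photon-level camera noise, bleaching chemistry, biophysical
IP3/ER calcium kinetics, and the spatio-temporal prefiltering that real
recordings receive upstream of this package. Consequently, passing the
recovery tests shows the graph construction is sound under the stated
signal-to-noise and delay conditions — not that event detection is robust
to every artefact of raw microscopy data.

### Validation study designs

The package's own validation (the test suite and `scripts/acceptance.R`)
uses three designs, whose problem sizes were chosen to exercise the full
default recording scale:

* **Noise threshold**: 10 noise-only traces of 2400 frames, drift-free;
  the 3-SD estimate must land within 5% of three times the generating SD.
* **Recovery**: 20 replicate cultures at transient amplitude/noise = 5
  and 2–5 frame delays, threshold from a matched-level noise culture;
  aggregated over replicates, at least 90% of true wave pairs must be
  recovered, at most 10% of recovered pairs spurious, and at least 95% of
  recovered pairs on truly co-activated cell pairs must carry the correct
  direction.
* **Group contrast**: six "synchronous" (propagation probability 0.6)
  versus six "asynchronous" (0.05) cultures, 10% parameter jitter within
  each group. The detection threshold is taken from a biological-noise
  control culture with fluctuation SD 5 against signal-culture
  measurement noise SD 3, mirroring the experimental design this package
  supports: the control line's spontaneous cytoplasmic fluctuations
  exceed residual measurement noise, and the threshold is deliberately
  set to skip sub-threshold spontaneous activity. The share of cells with
  more than five transfers must be significantly larger in the
  synchronous group (rank-sum + Holm at 0.05).

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
sim <- simulate_culture(cfg)
thr <- estimate_noise_threshold(
  simulate_noise_culture(sim_config(seed = 2, n_cells = 10)))

events <- detect_events(sim$traces, k = 0.97, threshold = thr)
g <- build_dynamic_graph(events, sim$adjacency, n_frames = cfg$n_frames)
cg <- compress_graph(g)

glance(g)                        # edge totals, active share, NEC
degree_centrality(cg)            # per-cell in/out transmissions
hits_centrality(cg)              # hub / authority scores
autoplot(g)                      # |E_t| transmission dynamics
autoplot(cg, sim$centers, mode = "contrast")
```

## Numerical choices and edge cases

* EMA initialised at the first (last) sample; the recursion is computed
  so that the initial value is exact to the bit, since strict crossing
  comparisons are sensitive to one-ulp drift.
* Ties: peak = first maximum of a run; baseline anchor = first minimum
  of a run; calibration returns the smallest coefficient on tied errors.
* Degenerate baselines (no sub-EMA run) equal the trace; a single anchor
  extends horizontally everywhere.
* `compress_graph()` counts onsets on the union of a pair's intervals, so
  two transmissions that abut exactly (one starts the frame after the
  other ends) merge into one count — consistent with the frame-wise onset
  definition.
* Thresholds are compared strictly (`amplitude > threshold`).
* Zero-variance rank-sum comparisons (all shares identical) report p = 1.

## Limitations

Direction is inferred from event boundary order only; sub-frame
propagation (under 0.5 s at 2 Hz) is invisible, simultaneous starts are
recorded but carry no direction, and nested events yield no edge.
Adjacency reflects region contact in the label image, not physical
coupling. Coincident spontaneous events in adjacent cells are counted as
transmissions — at the default event rates this inflates counts by a
small amount, which the group design absorbs by comparing cultures, but
single-culture transmission counts should be read as upper bounds.
Segmentation, registration, denoising and ΔF/F normalisation are all
upstream of this package.
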