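---
title: "Ordinal ground truth from continuous annotations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordinal ground truth from continuous annotations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

A continuous annotation is a real-time trace of a subjective construct —
perceived violence, arousal, engagement — produced by a human moving a
bounded slider while watching a stimulus. Fusing several such traces into a
single "ground truth" label is harder than averaging, because the errors are
not exchangeable noise. Two empirical regularities drive everything in this
package:

* each rater perceives the construct through their own strictly monotone
  mapping onto the annotation scale, so the *direction* of change is
  reported reliably;
* the *values* are unreliable: raters overshoot when a change completes,
  revalue the same intensity differently at different times (slow drift),
  react with a lag, exhaust the top of the scale early, and calibrate to
  the range of the stimulus at hand.

A sample-wise average inherits all of the value errors. The pipeline here
instead trusts only ordinal information in the traces, and repairs the
values with a second, cheaper kind of human judgement: pairwise "which of
these two excerpts is lower?" comparisons.

## Trend-based agreement (SDA)

For two equally long traces $x$ and $y$, signed differential agreement is

$$\mathrm{SDA}(x,y) \;=\; \frac{1}{M}\sum_{t}
\delta\!\big[\mathrm{sgn}(x_t - x_{t-1}),\, \mathrm{sgn}(y_t - y_{t-1})\big],
\qquad \delta(p,q) = \begin{cases} +1 & p = q \\ -1 & p \ne q\end{cases}$$

over the $M$ steps in which all four samples are present. Differences with
magnitude at most `zero_tol` take sign 0; the default `1e-9` treats only
exact holds as "no change", which suits interpolated traces. When traces
come from a stepped input device it can be sensible to raise `zero_tol` to
the device's step size so that single-notch revaluations do not count as
trends. SDA is invariant to any strictly increasing revaluation of either
trace and equals 1 exactly when the two traces agree in the sign of every
step. A pair of sign pattern $(0, \pm1)$ counts as full disagreement —
deliberately, as printed in the defining formula: a rater who holds while
another moves is disagreeing about whether anything changed.

## Selection and alignment

Annotation selection is a binary clustering problem on the pairwise SDA
matrix. Each unordered pair is first aligned by dynamic time warping
(symmetric step pattern with diagonal weight 2, Sakoe–Chiba band of
`band_s = 5` seconds, squared-difference local cost, missing samples at
zero cost, and a per-pair random choice of reference), then SDA fills an
affinity matrix through the transform $(\mathrm{SDA}+1)/2$, which makes the
entries nonnegative as spectral methods require; undefined entries impute
zero affinity. Two-class spectral clustering (normalized symmetric
Laplacian, two eigenvectors, row normalization, k-means with seeded
restarts) bipartitions the raters.

The inlier group is the cluster whose members have the highest mean SDA
*against all other annotations*, not merely against their cluster-mates.
The distinction matters: a small coherent minority — e.g., two raters who
perceive the construct inverted — can agree almost perfectly with each
other while disagreeing with everyone else, and a within-cluster mean would
crown them the consensus. Scoring members against the whole panel makes the
majority percept win whenever one exists. With three or fewer annotations a
bipartition is meaningless and everything is kept.

Inliers are then re-aligned: the member with the highest mean agreement
serves as the reference and the rest are DTW-warped onto its grid. A
mutual-information uniform-shift aligner (16 equal-width value bins,
coordinate ascent over integer shifts) is provided as an alternative; on
flat-heavy traces it legitimately fails, and it reports that rather than
guessing.

## Trapezoidal segmented regression

Each inlier trace is approximated by a continuous piecewise-linear signal
whose segments strictly alternate between zero slope (flat) and free slope,
with breakpoints restricted to sample positions — the trapezoidal family.
"Sloped" segments are fit with unconstrained slope (zero allowed as a
degenerate case); constraining them to strictly nonzero slope would make
the feasible set open, so the least-squares problem could fail to attain
its infimum, and would break the monotonicity of error in the budget $T$.
The one-segment member of the family is the least-squares constant.

Two engines share one evaluator (per-segment quadratic costs assembled from
prefix sums; levels solved by a small linear system):

* when at most `exact_limit` (20,000) breakpoint placements exist, full
  enumeration over placements and both parities (flat-first and
  sloped-first) gives the global optimum — this covers every instance the
  optimality tests check and any short trace;
* otherwise a dynamic program over (position, discretized breakpoint value)
  states — `n_levels = 25` equally spaced values — proposes breakpoints,
  the levels are re-solved exactly, and coordinate descent moves each
  breakpoint within its neighbors until no single move improves the fit.
  This is a refined heuristic, not a certified global optimum; in practice
  it reproduces realizable trapezoids to numerical zero.

### Choosing the segment budget

The initial estimate $\hat T$ counts macro trend runs: smooth with a
5-sample moving average, take step signs with a "no change" threshold of
0.5% of the value range per step, demote runs whose *total* change is under
5% of the range (a human counting peaks, valleys, plateaus and trends would
not count a one-notch wiggle), and count the remaining sign runs. A manual
count can always be supplied instead.

Candidates then range over
$\{\lfloor \tfrac{4}{5}\hat T\rfloor, \dots, \lceil \tfrac{6}{5}\hat T\rceil\}$
(floored at 1). Each candidate fit is scored against the raw samples by SDA
and by Kendall's $\tau_b$ (ties are guaranteed on flats, hence the b
variant). Scanning upward, the first local maximum of the SDA profile is
located, and from there the next local maximum of the $\tau$ profile; that
candidate is the selected budget. A plateau's first point and the scan's
endpoint both count as local maxima, so monotone profiles select cleanly.

## Trend voting, flat regions, and ordinal correction

Each fitted model becomes a trapezoidal segment sequence (TSS): per-sample
codes in $\{-1, 0, +1\}$, zero exactly on flat segments, with boundary
samples belonging to the segment starting at them. Majority voting across
inliers merges the sequences; ties resolve to 0, the conservative choice,
since flats are exactly what the ordinal machinery can still repair.
Maximal all-zero runs of at least `min_len_samples` (default 2 — a
one-sample excerpt cannot be shown to a judge) become flat regions, the
excerpts whose construct level the comparisons will determine.

Every "which is lower" judgement between regions $j$ and $k$ becomes a
triplet against a hypothetical dummy excerpt $r$ of minimal construct
value: the lower region is the one more similar to $r$. No extra
comparisons are needed for this conversion, and contradictory duplicates
are passed through for the embedder to absorb.

### 1-D t-STE, and two numerical facts worth knowing

The embedding maximizes the t-STE likelihood with heavy-tailed kernels
($\alpha = 1$; the conventional $d - 1$ choice degenerates at $d = 1$) by
gradient descent with an adaptive step, best of 30 seeded restarts — the
one-dimensional landscape is genuinely multimodal under contradictory
triplets, and restarts are cheap at these sizes.

Two properties of the dummy-reference construction shape the
implementation. First, when every triplet is anchored at the dummy, the
likelihood depends on each item only through its *distance* to the dummy;
the sign of each item's offset is unidentified. The orientation step
("reverse so the dummy is minimal") is therefore implemented by folding the
configuration onto distances from the dummy, which is equivalent to a
reflection when the solution is one-sided and strictly more robust when it
is not. Second, on a satisfiable triplet set the unpenalized likelihood has
no finite maximizer — the configuration spreads indefinitely with
geometrically growing gaps, so the returned spacing would reflect the
stopping iteration rather than anything in the data. A small L2 penalty
(`lambda = 0.01`, scaled by the triplet-to-item ratio) pins a well-defined
optimum with evenly behaved gaps. Positions remain identified only up to
monotone transforms either way; the penalty chooses a canonical
representative, it does not add information.

### Reconstruction and the collection loop

The ground truth is constant on each flat region at its embedded value,
linearly interpolated between consecutive regions, and held at the nearest
region's value before the first and after the last. Comparisons are
collected in batches (the study-scale default is 5000) with uniform
sampling among unasked pairs; after each batch the embedding and
reconstruction are recomputed, and collection stops when consecutive
candidates reach a Spearman correlation of `rho_stop = 0.8` for every
stimulus, or the pairs run out. When several stimuli are processed
together, all their regions enter one joint embedding, which is what makes
ground-truth values comparable across stimuli; per-stimulus embeddings are
available by running stimuli separately.

## The simulator

The simulator is first-class, tested code: it generates the latent signal,
the raters, and the comparison oracle so that every stage of the pipeline
can be verified against a known truth.

The latent signal is itself trapezoidal — alternating flat/sloped runs with
randomized durations and levels (consecutive node levels at least 15% of
the range apart so slopes are visible), with the flat windows and levels
recorded. An annotator is a strictly monotone 4-knot piecewise-linear
perception map plus a documented error structure, with panel defaults
drawn once per rater:

* perception maps are compressive toward the top ($y = x^\gamma$ at the
  knots, $\gamma \sim U(0.35, 0.85)$): continuous raters exhaust the upper
  scale early and discriminate high levels poorly;
* by default raters are *range-adaptive*: the map applies to the construct
  range observed in the stimulus at hand, so every stimulus gets rated up
  to the top of the scale however mild it is in absolute terms
  (`range_adapt = FALSE` gives an absolutely anchored rater);
* reaction lag $U(0.5, 2.5)$ s; overshoot gain $U(0.2, 0.5)$, applied as a
  4-sample exponentially decaying pulse when a trend reaches its level;
  revaluation drift, a random walk of $U(2, 5)$ units/step low-pass
  filtered at 0.02 Hz (a slow wander of roughly 5–20% of the
  $-100..100$ scale); move noise $U(0.5, 2)$ units;
* a dead-zone motor model with dead zones of $U(1, 3)$ units: the rater
  holds the current value until the intended value departs by more than the
  dead zone, then moves to it plus noise. Flat stretches are therefore
  exactly constant, which is how a changes-only logging interface records
  real raters, and which white per-sample noise would destroy (it makes
  every flat step's sign random, contradicting the reliable-trend premise
  the simulator exists to emulate).

An adversarial rater differs only in a strictly decreasing perception map —
a planted outlier for selection tests. The comparison oracle answers from
the latent levels, choosing the truly lower region with probability
$1/(1 + e^{-\beta\,|\Delta|})$; $\beta = \infty$ is the noiseless judge,
$\beta = 0$ answers at chance, and exact ties are answered at random and
flagged.

What the simulator does *not* emulate: structured attention lapses beyond
event-log gap injection, multi-dimensional simultaneous annotation, any
semantics of real stimuli, and rater learning over time. Passing tests
therefore demonstrate correctness of the machinery under the stated error
model, not performance on any particular real dataset.

## Validation designs and problem sizes

The package's own validation (test suite) uses stimuli of 120 samples at
1 Hz with 7 latent runs, panels of 8 regular plus 2 adversarial raters, and
a noiseless oracle. Two designs mirror the two claims a trend-trusting
pipeline makes:

* *within-study recovery*: three stimuli of graded construct range
  ($[0, 0.5]$, $[0, 0.75]$, $[0, 1]$), each annotated by its own fresh
  panel — as in crowd studies, where no rater sees every clip. The
  proposed and baseline ground truths are stitched across stimuli and
  compared to the stitched latent truth by Kendall's $\tau$. Range-adaptive
  panels make the stitched baseline's values incomparable across stimuli,
  while the joint embedding keeps them comparable; the proposed method wins
  in at least 9 of 10 seeded replicates, with planted adversaries rejected
  in at least 9 of 10.
* *aggregate ranking*: five stimuli whose maximum latent levels are
  proportional to $1\ldots5$, processed end-to-end; the Spearman
  correlation between max-aggregates of the proposed ground truth and the
  true levels is 1.0, while the baseline's aggregate ranking collapses.

Within a *single* stimulus annotated by one shared panel, the sample-wise
average of monotone perceptions is itself rank-consistent up to drift and
overshoot, and its $\tau$ against the latent truth is statistically tied
with the proposed method's at these panel sizes — the ordinal pipeline's
advantage is value comparability across time and stimuli, not within-clip
sample ordering. This is worth remembering when choosing a fusion method:
if only within-clip dynamics matter and raters share a panel, averaging is
a strong baseline.

## Event-log conventions and degenerate inputs

Event logs are changes-only. Resampling interpolates linearly onto the grid
starting at the first event (how a recorder behaved before its first event
is unknowable, so the grid does not extend earlier); a gap between events
with equal values is a valid hold, while a gap with different endpoint
values longer than `max_gap_s` (default two sampling periods) is a data
lapse whose interior grid points become missing. Steps touching missing
samples are excluded from SDA with renormalization; TSR fits the longest
contiguous present block and codes other samples 0; the sample-wise
baseline averages whatever is present at each instant.

Other degenerate cases are handled explicitly rather than silently:
constant traces make correlation-based measures error, not return `NA`;
an empty flat-region set makes reconstruction error; exhausted pair
budgets error; a comparison loop whose threshold is unattainable runs to
pair exhaustion and says so in its history.

## Known limitations

* Embedded values are ordinal: any strictly increasing transform of them is
  an equally valid ground truth, so downstream consumers should use
  rank-based statistics, as the evaluation module does.
* The large-instance TSR engine is a refined heuristic; only enumerable
  instances carry a global-optimality guarantee.
* DTW aligns values, not trends; raters with very different perception maps
  can in principle be warped imperfectly even when their trends agree.
* The segment-budget heuristic inherits the quality of $\hat T$; traces
  whose macro structure is genuinely ambiguous (drift comparable to trend
  amplitudes) get budgets off by a few segments, which blurs flat-region
  boundaries by a few samples.
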