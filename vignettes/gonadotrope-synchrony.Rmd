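---
title: "Quantifying gap-junction-mediated synchrony in gonadotrope networks"
author: "gonadosync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gap-junction-mediated synchrony in gonadotrope networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gonadosync)
```

## The scientific problem

Gonadotropes of the anterior pituitary release luteinizing hormone in sharp
pulses. Pulsatility requires many cells to activate together, and one
candidate mechanism for this coordination is direct electrotonic coupling
through connexin-36 gap junctions. Two experimental readouts probe this
mechanism in acute pituitary slices:

1. **Calcium imaging.** Cells loaded with a calcium indicator are imaged
   while GnRH is washed in. If gonadotropes are coupled, their calcium
   responses should be synchronized — most strongly between neighboring
   cells — and this synchrony should collapse when the gap-junction protein
   is knocked out.
2. **Paired current-clamp recordings.** A current step injected into one
   cell of a neighboring pair produces a voltage deflection in the other
   cell only if the two are electrically coupled; the ratio of the two
   steady-state deflections is the *coupling coefficient*.

`gonadosync` implements the full quantitative workflow for both readouts —
trace normalization, responder calling, all-pairs rank-correlation
synchrony, distance-resolved regression, coupling-coefficient estimation —
plus a generic position-weight-matrix promoter scan (used in this system to
search for estrogen-response elements in the connexin promoter), and a
ground-truth simulator so that every stage can be validated end to end
without access to raw recordings.

## Trace normalization and responder calling

Raw fluorescence is normalized per cell as $R_i(t) = F_i(t) / F_{0,i}$,
where $F_{0,i}$ is the mean of the first 50 frames (configurable). The
baseline of each normalized trace therefore averages exactly 1, and the
normalization is exactly invariant to positive rescaling of the raw signal.
Recordings longer than 10 minutes are truncated to their first 600 s; all
windows below refer to that clock.

There is no universally agreed criterion for "responding" in this
preparation, so the package uses an explicit, configurable one: a cell is a
responder when its smoothed normalized trace (boxcar, default 5 frames)
stays above *baseline mean + 3 SD* (both computed from the pre-stimulus
frames of the smoothed trace) for at least 10 s within the response horizon
(stimulus onset to onset + stimulus duration + 120 s). The sustained-crossing
requirement exists because a single-frame max criterion applied over a
~240 s horizon fires on noise alone in a substantial fraction of silent
cells; the required duration exceeds the correlation time of slow basal
calcium fluctuations, which restores specificity without costing
sensitivity for real responses, which last tens of seconds. Against
simulator ground truth at the default noise level, sensitivity and
specificity are both above 0.95.

Responders are classified by counting local maxima of the smoothed trace
above the responder threshold after onset, with a minimum inter-peak
interval of 10 s and a prominence of at least half the peak elevation over
baseline: one or two peaks is a *biphasic* response (fast rise, slow decay
to a plateau), three or more is *oscillatory*. These are the two waveform
classes observed in GnRH-stimulated gonadotropes.

## Synchrony analysis

Synchrony between two responding cells is the Spearman rank correlation of
their normalized traces inside a time window. The implementation computes
the Pearson correlation of mid-ranks (average ranks on ties); p-values use
the large-sample t approximation on $n-2$ degrees of freedom, with an exact
permutation option for short tie-free series. Because ranks are invariant
under strictly increasing transforms, correlating $F_i/F_0$ is exactly
equivalent to correlating $\Delta F/F_0$.

Three canonical windows bracket the stimulation protocol: **before**
(100–200 s), **during** (250–350 s) and **after** (500–600 s). Windows are
half-open $[\mathrm{start}, \mathrm{end})$; the endpoint convention is a
package decision since verbal descriptions such as "between 100 and 200 s"
do not fix it. All $n(n-1)/2$ unordered responder pairs are evaluated;
pairs with a zero-variance trace in the window are kept in the table but
flagged degenerate and excluded from statistics. Distributions of
coefficients are compared between groups (e.g. wild-type vs knockout) with
the two-sided Mann–Whitney rank-sum test (normal approximation with tie
correction), reporting medians and interquartile ranges. Sliding-window
correlation matrices (default 50 s windows, 10 s steps — a resolution
choice, not a measurement) provide the temporal heat-map view, and
`exportCorrelationMap()` emits the node/edge structure of pairs significant
at the per-pair level (default p < 0.001).

## Distance-resolved analysis

Each pair carries an intercellular distance, by default the *membrane*
convention (centroid distance minus both radii, floored at zero); centroid
distance is available by flag. The correlation-versus-distance relationship
is summarized by ordinary least squares on pairs with positive
coefficients (the documented filtering; a full-range fit is available for
sensitivity analysis). A Pearson correlation screen between coefficient and
distance is reported alongside; the slope comparison is meaningful when
that screen is significant. Two groups' lines are compared with the
two-sample t statistic on independent fits,

$$t = \frac{b_1 - b_2}{\sqrt{SE_1^2 + SE_2^2}},\qquad df = n_1 + n_2 - 4,$$

and analogously for intercepts, at a significance threshold of 0.001.
This equals the interaction-term test of a pooled model under equal
residual variance. Finally, the short-range analysis restricts both groups
to pairs closer than 5 μm (membrane convention) and repeats the
Mann–Whitney comparison per window — the test that isolates coupling
between immediate neighbors under basal as well as stimulated conditions.

## Coupling coefficients from paired recordings

For each sweep the steady-state deflection is the mean voltage over the
last 20 % of the current step minus the mean over the 100 ms preceding
step onset (both configurable; intervals straddling a step edge are
rejected). Deflections are averaged across sweeps first, and the coupling
coefficient is the ratio of follower to injected mean deflection; its SEM
comes from the spread of the per-sweep ratios. A mean injected deflection
below 1 mV makes the ratio numerically unstable and is an error. "Detectably
coupled" is operationalized as coefficient > 3 SEM, positively, in both
directions. The sign convention reports same-sign deflections as positive
coupling; opposite signs produce a negative coefficient and a warning.

## Promoter scanning

The scan slides a position weight matrix over the window upstream of an
annotated TSS on both strands. Raw scores are sums of
$\log_2((f + p\,b)/b)$ per position (pseudocount $p = 0.8$ split by the
background $b$, uniform by default), and the reported *relative score* is
min–max normalized to percent of maximum, so a "minimal matching score" of
75 % has the conventional meaning: the consensus scores 100, the
per-position-worst sequence 0. Positions are reported as bp upstream of the
TSS, 1-based, measured to the hit edge nearest the TSS. Sites containing N
are skipped. The package deliberately ships no genome or matrix database;
reproducing any specific genomic coordinate depends on external genome and
matrix versions and is out of scope.

## The simulator: what it emulates

`simulateNetwork()` generates one slice experiment with known ground truth.
Its defaults are the study conditions used throughout the package's
validation:

* **Field and cells.** 60 cells of radius 4–6 μm in a 150 × 150 μm field,
  placed by a hard-core process (no overlapping ROIs). 40 % of cells
  respond to the stimulus; 1908/1951-scale pair counts arise when seven
  such experiments are pooled per group.
* **Timeline.** 600 s at 1 frame/s: 120 s baseline, then the stimulus
  valve switches; the agonist reaches the slice after a 120 s perfusion
  dead time (`perfusion_delay`), so responses develop from ~240 s — this
  is the only timing under which the canonical windows (before 100–200 s,
  during 250–350 s) make sense together with a 2-min recorded baseline.
* **Waveforms.** Biphasic responses (60 % of responders) rise with
  $\tau = 4$ s and decay with $\tau = 80$ s to a 30 % plateau, peak
  amplitude 1.5 ± 0.3 above baseline; oscillatory responses are raised
  cosines with period 40 ± 8 s under a slow envelope, amplitude 0.8 ± 0.2.
  The quantitative waveform parameters are free choices (the source
  observations are qualitative) made so responses complete within the
  10-min window.
* **Onset latencies.** A perfusion wave crosses the field (latency
  gradient 40 s edge-to-edge) plus per-cell Gaussian jitter (SD 3 s): even
  without coupling, neighboring cells respond at more similar times than
  distant ones, which produces the baseline negative
  correlation-versus-distance slope.
* **Coupling.** Pairwise weights
  $w_{ij} = 2\,e^{-d_{ij}/15\,\mu m}$ on membrane distances. Coupling acts
  twice: responder onset latencies are entrained toward the
  degree-weighted network mean, and responder signals undergo per-frame
  diffusive averaging, iterated four rounds so that influence percolates
  along chains of neighbors and connected subnetworks converge on a common
  pattern. This is an explicitly phenomenological model — mixing and
  entrainment, not a biophysical conductance model — sufficient to
  generate the correlation structure the analysis measures: higher
  during-window synchrony and a *flatter* distance slope in the coupled
  condition (the entrained network responds as one unit), versus the
  steeper distance decay of the uncoupled condition driven by the
  perfusion wave.
* **Tonic mode.** With `coupling_mode = "tonic"` the slow baseline calcium
  fluctuations (Ornstein–Uhlenbeck, SD 3 % of baseline, correlation time
  10 s) are mixed as well, and each cell's basal amplitude is rescaled to
  its stationary value afterwards — coupling correlates basal activity
  between neighbors without damping its magnitude. This mode produces the
  short-range basal coactivity signature: pairs < 5 μm apart are more
  correlated than distant pairs in *every* window, while the default
  ("evoked") mode confines coupling effects to the stimulated period.
  These two modes split two properties that cannot coexist in one
  parameterization: a globally entrained (flat-slope) evoked response and
  a strictly short-range synchrony excess.
* **Noise.** Multiplicative log-normal noise (unit mean, SD 5 % of
  baseline) plus additive Gaussian noise (1 a.u. on a ~500 a.u. baseline);
  per-cell baseline brightness is log-normal with 20 % CV.
* **Reproducibility.** One global seed feeds named sub-streams (layout,
  classes, latency, waveform, slow, baseline, noise), so identical
  configurations give bit-identical datasets and individual components can
  be varied without scrambling the rest.

Mixing and entrainment are restricted to responder cells so that the
ground-truth responder labels remain well defined; the analysis only ever
uses responder pairs, so this restriction costs nothing downstream.

`simulatePairedRecording()` generates the electrophysiology counterpart: a
current step into cell 1 (default −10 pA) across a fixed 1 GΩ input
resistance gives a −10 mV steady-state deflection with single-exponential
charging (τ = 20 ms); cell 2 sees the deflection attenuated by the true
coupling coefficient; both channels carry independent Gaussian sample noise.
Sweeps are sampled at 2 kHz over 0.8 s (0.1 s baseline, 0.5 s step). At the
reference setting (true coefficient 0.025, 60 sweeps, 0.1 mV noise) the
estimator recovers the truth within ±0.005 in essentially every run, and
with zero noise it is exact to machine precision.

### What the simulator does *not* emulate

No hormone secretion, no estrous-cycle or estradiol feedback, no
biophysical membrane model, no photobleaching or focus drift, no ROI
segmentation errors (ROIs are inputs throughout), and no spatial
correlation in the measurement noise. Passing the package's validation
therefore shows that the *analysis* recovers known structure of the kinds
listed above; it does not certify performance against artifacts absent
from the model.

## Numerical choices and degenerate inputs

* Half-open windows everywhere; windows are specified in seconds and
  mapped to frames, so variable frame intervals (0.5–2 s) need no
  resampling.
* Zero-variance series make rank correlation undefined: flagged, never
  silently dropped at table level, always excluded from statistics.
* Regression requires ≥ 3 pairs at ≥ 2 distinct distances after filtering;
  anything less is an error stating the counts.
* The coupling-coefficient ratio requires a ≥ 1 mV mean injected
  deflection.
* Degenerate PWMs (all columns equal) score 100 by convention (the
  min–max range is empty).
* CSV writers emit 17 significant digits so write→read round-trips are
  exact.

## Validation scale

The test-suite and acceptance-script simulations use the study conditions
above: 7 simulated experiments of 60 cells per arm for the group-level
contrasts (≈ 1 900 pooled pairs per arm), 10 replicate cohorts for the
slope-direction recovery, and 100 Monte-Carlo seeds for the
coupling-coefficient operating characteristics. These sizes were chosen to
match the pooled scale of the motivating experiments while keeping a full
validation run in the minutes range on one CPU.

## Limitations

The responder criterion and the "detectable coupling" z-threshold are
operational definitions; results near their boundaries should be read with
that in mind. Group comparisons treat cell pairs as exchangeable units, but
pairs sharing a cell are not independent — with ~270 pairs per experiment
drawn from ~24 responders the effective sample size is smaller than the
pair count, so borderline p-values (especially in null windows) fluctuate
more than their nominal level suggests. This mirrors the practice the
workflow reproduces; a hierarchical treatment is out of scope.
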