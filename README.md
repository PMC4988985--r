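# gonadosync

Synchrony analysis of gap-junction-coupled gonadotrope networks.

Anterior-pituitary gonadotropes secrete luteinizing hormone in sharp pulses,
which requires many cells to activate together. One candidate mechanism is
direct electrotonic coupling through connexin-36 gap junctions. `gonadosync`
implements the complete quantitative workflow used to test that hypothesis
from two kinds of recordings, for experimenters analyzing acute-slice
calcium imaging and paired patch-clamp data:

* **Calcium imaging.** Per-cell normalization to relative fluorescence
  (F<sub>i</sub>/F<sub>0</sub>, with F<sub>0</sub> the mean of the first 50
  frames), detection and classification (biphasic vs oscillatory) of
  GnRH-responding cells, and all-pairs **Spearman rank correlation** ρ of
  responder traces within three canonical windows — before (100–200 s),
  during (250–350 s) and after (500–600 s) stimulation. Coefficient
  distributions are compared between groups (e.g. wild-type vs knockout)
  with the Mann–Whitney rank-sum test.
* **Distance structure.** Each pair carries a membrane (or centroid)
  distance; positive coefficients are regressed on distance by OLS
  (ρ = a + b·d), and two groups' lines are compared with
  t = (b₁ − b₂)/√(SE₁² + SE₂²), df = n₁ + n₂ − 4. A dedicated short-range
  analysis compares only pairs < 5 μm apart, per window.
* **Electrophysiology.** The gap-junction **coupling coefficient**
  CC = ΔV_follower / ΔV_injected from steady-state deflections of paired
  current-clamp sweeps (sweep-averaged, SEM from per-sweep ratios), with a
  z-score criterion for "detectably coupled".
* **Promoter scanning.** A generic position-weight-matrix scan of a
  5 kb window upstream of a TSS with min–max-normalized ("% of maximum")
  log-odds scores, both strands, JASPAR-format input.
* **Ground-truth simulation.** A coupled/uncoupled network generator
  (hard-core cell placement, biphasic/oscillatory waveforms, perfusion-wave
  latencies, distance-decaying coupling with diffusive mixing and latency
  entrainment, multiplicative + additive noise) and a paired-recording
  simulator, so the whole pipeline is validated end to end with no external
  data.

See the methods vignette (`vignettes/gonadotrope-synchrony.Rmd`) for the
model details and design decisions.

## Worked example

Simulate three coupled ("wt") and three uncoupled ("ko") slice experiments
and run the full pipeline:

```r
library(gonadosync)

wt <- lapply(1:3, function(s) simulateNetwork(
  simConfig(seed = s, coupling_enabled = TRUE), label = "wt"))
ko <- lapply(4:6, function(s) simulateNetwork(
  simConfig(seed = s), label = "ko"))

report <- runPipeline(wt, ko, pipelineConfig(labels = c("wt", "ko")))
report
#> RunReport (gonadosync 0.1.0 )
#>   responders per dataset:
#>     a: 23, 20, 22
#>     b: 25, 26, 26
#>   pooled pairs per window: before=1624, during=1624, after=1624
#>   group comparisons:
#>  window n_a n_b   median_a    median_b       p_value
#>  before 674 950 0.00319832 0.004914491  6.522655e-01
#>  during 674 950 0.75209121 0.272655266 1.271580e-144
#>   after 674 950 0.05131113 0.010009001  2.458278e-10
#>   regression slope comparisons:
#>  window       slope_a       slope_b      p_slope significant
#>  before -1.732800e-04  1.431363e-05 1.817425e-01       FALSE
#>  during -1.111416e-03 -2.536989e-03 1.234119e-06        TRUE
#>   after -7.481243e-05  1.528289e-04 2.098249e-01       FALSE
#>   short-range (< 5 um):
#>  window n_a n_b   median_a    median_b    p_value
#>  before  13  22 0.06163816  0.02739874 0.28219914
#>  during  13  22 0.81576958  0.59704170 0.00485495
#>   after  13  22 0.07678368 -0.00379838 0.48401570
```

Reading the output: baseline synchrony is indistinguishable between arms
(before-window medians ≈ 0, p = 0.65), the stimulus drives much stronger
pairwise synchrony in the coupled arm (median ρ 0.75 vs 0.27,
p ≈ 10⁻¹⁴⁴), and the correlation-versus-distance line is significantly
steeper (more negative slope, −0.0025 vs −0.0011 per μm, p ≈ 10⁻⁶) in the
uncoupled arm — synchrony decays with distance once gap-junction coupling
is gone, and only during stimulation.

Estimate a coupling coefficient from paired sweeps (ground truth 0.025):

```r
ps12 <- simulatePairedRecording(true_cc = 0.025, n_sweeps = 60, seed = 1)
ps21 <- swapChannels(simulatePairedRecording(true_cc = 0.025, n_sweeps = 60,
                                             seed = 2))
classifyCoupled(couplingCoefficient(ps12, ps21))
#> CouplingEstimate
#>   1to2: cc = 0.02473 +/- 0.00011 (SEM), dV_inj = -10 mV, dV_fol = -0.247 mV, n = 60
#>   2to1: cc = 0.02521 +/- 0.00014 (SEM), dV_inj = -10 mV, dV_fol = -0.252 mV, n = 60
#>   coupled: TRUE
```

Both directions recover the true coefficient (symmetrical electrical
coupling) and the pair is classified as coupled at the default 3-SEM
threshold.

Scan a promoter for a motif:

```r
pwms <- readJaspar("matrices.jaspar")
prom <- readPromoterFasta("promoter.fa", window_length = 5000)
hits <- scanPromoter(pwms[[1]], prom, min_score = 75)
```

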