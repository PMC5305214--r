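# replicount

Single-molecule tools for asking how stable the bacterial replisome is in
living cells. Two measurements drive the analysis:

* **Stoichiometry by photobleaching.** A fluorescently tagged replisome
  subunit (e.g. the replicative helicase) concentrates at a
  diffraction-limited *replication factory*. Under continuous illumination
  its fluorophores bleach one by one, so the focus intensity decays in
  discrete steps. Counting the initial intensity in units of the
  single-fluorophore step gives the copy number: with initial intensity
  `I0` (from an exponential fit `I(t) = I0 exp(-t/tb)`) and unitary step
  `ΔI` (from the spectrum of the pairwise-difference distribution of the
  idealized trace), the estimate is `n = I0 / ΔI`. A factory holding two
  intact replisomes carries twice the single-complex count (12 vs 6
  helicase subunits), so the population histogram of `n` — fitted with an
  unbinned two-Gaussian mixture — reports the fraction of cells that have
  lost one complex.

* **Complex lifetimes by time-lapse tracking.** Scored foci are linked
  into trajectories under explicit rules (no member below score 3, ≤350 nm
  movement per frame, mean score ≥4, one score ≥5, single-frame gaps
  allowed, ≥3 frames, factory localization). Complexes still present in
  the final frame are right-censored at the window `T`. Modeling
  disassembly as a Poisson process with shortest observable lifetime
  `τ_min`, the maximum-likelihood disassembly rate has the closed form

  ```
  k = N_obs / [ N_obs (τ̄ − τ_min) + N_cens (T − τ_min) ]
  ```

  and `N_c = k × 40 min` converts it into disassembly (conflict) events
  per replication cycle.

Both halves sit on a calibrated, parameter-free change-point filter:
recursive binary segmentation whose acceptance threshold is the Monte-Carlo
95% quantile of the null maximal log-likelihood-ratio statistic, so a
constant trace acquires a false level in only 5% of cases. The
over-segmenting BIC change-point filter is included as the comparison
baseline. A synthetic-data generator (bleaching traces, focus image
stacks, censored lifetimes, stoichiometry mixtures) provides ground truth
for every stage, so the whole pipeline is testable without microscopy
data.

## Worked example

Simulate the bleaching trace of a six-subunit helicase (unitary step 51
intensity units, step-to-noise ratio 2.5, bleaching rate 1/41 per frame),
then run the full stoichiometry pipeline:

```r
library(replicount)

table <- calibrateThreshold(120L, confidence = 0.95, nSim = 5000L, seed = 1)
sim   <- simulateBleachTrace(nFluorophores = 6, stepSize = 51,
                             noiseRatio = 2.5, seed = 12)
res   <- stoichiometryPipeline(sim$trace, table, inVitroStep = 51)
res$idealization
#> Idealization: 120 frames, 6 level(s)
#>  start duration       mean  variance uncertainty
#>      0        7 315.869512 1499.7279   14.637173
#>      7       19 230.256223 1712.5898    9.494014
#>     26       15 157.091399  897.4435    7.734957
#>     41       37 110.679251  575.7016    3.944554
#>     78       19  45.476186  612.7388    5.678857
#>     97       23  -2.687587  423.2231    4.289639
res$step
#> UnitaryStep: deltaI = 57.43 (peak 0.463, runner-up 0.333)
res$record
#> StoichiometryRecord: n = 5.67 (I0 = 325.7 / deltaI = 57.43)
#>   QC: pass
```

The filter reduced the noisy trace to six levels; the spectrum of the
pairwise differences put the single-fluorophore step at 57.4 (true value
51), the exponential fit put the initial intensity at 326 (true value
306), and the copy number comes out at 5.7 of a true 6. The QC gates
(step size within a factor 2.5 of the independent reference, dominant
spectral peak, initial intensity consistent with the first frame) all
pass.

Lifetimes work the same way from the other end of the pipeline:

```r
ds  <- simulateLifetimes(kTrue = 0.12, nComplexes = 327, windowT = 22,
                         tauMin = 4, frameInterval = 2, seed = 1)
est <- rateError(estimateRate(ds), ds, nSim = 10000, seed = 2)
est
#> RateEstimate: k = 0.1322 /min (tau = 7.57 min), Nc = 5.29 per 40 min cycle
#>   k error (bootstrap): 0.0101 /min
```

With 291 observed disassemblies of mean lifetime 9.3 min and 36 complexes
censored at the 22-minute window, the closed-form estimate is
k = 0.13/min — a mean complex lifetime under 8 minutes and roughly five
disassembly events per 40-minute replication cycle.

Image stacks enter through `simulateImageStack()` / `readStack()`,
`quantifyStack()` (bleaching) or `quantifyFrames()` + `linkTrajectories()`
(time lapse); `runPipeline()` drives either route from a YAML config and
`makeReport()` renders the figures. A thin command-line wrapper lives at
`inst/scripts/replicount.R`.

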