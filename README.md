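# densim

Simulation-based evaluation of wildlife population-density estimators for
camera-trap grids combined with removal (corral) trapping.

Estimating density — abundance per unit area — is central to wildlife
management, but every estimator rests on assumptions about animal movement
and detection. `densim` simulates the whole data-generating chain for a
social, wide-ranging species (the motivating case is the wild pig,
*Sus scrofa*) and measures how accuracy and precision of four common
estimator families respond to the **scale of animal movement**, the **true
population density** and the **baseline detection probability**.

## The model

**Generative (observation) model.** Home-range centroids are stationary
points from a partial Poisson cluster process (social groups). An animal
whose centroid is a distance *d* (km) from a detector is *available* to it
on a given day with probability

    p(avail) = min{1, (2πσ²)^{-1/2} exp(−d²/2σ²)}     (truncated at r_max)

where σ is the scale of movement. Detection given availability is a flat
rate g₀, so the per-occasion encounter probability is a scaled truncated
Gaussian `g₀ · p(avail)`. Corral traps have a baseline 75 % lower than
cameras (`g₀_trap = g₀/4`) but a larger truncation radius. Per night, the
number of distinct cameras an animal visits is multinomial over {1, 2, 3}
with probabilities (0.82, 0.15, 0.03); a site-specific trap-happiness
effect multiplies g₀ at cameras where the animal was seen before. Trapped
animals are removed on first capture (depletion). The default layout is a
5 × 4 camera grid at 750 m spacing (13 daily occasions) followed by 10
spatially balanced corral traps (14 nights, 140 trap-nights).

**Estimators.**

* **Camera LPE** — two-sample Lincoln–Petersen with the Chapman
  correction, N̂ = (n₁+1)(n₂+1)/(m+1) − 1 (cameras mark, traps recapture),
  converted to density by the MMDM-buffered detector hull and the delta
  method.
* **Camera SECR / trap SECR** — maximum-likelihood spatially explicit
  capture–recapture for binary proximity detectors: homogeneous Poisson
  activity centres with density D, half-normal detection
  p(d) = g₀ exp(−d²/2σ²), likelihood integrated over a habitat mask;
  optional behavioural ("bk") and detector-type effects compared by AICc
  weights. The trap variant pools camera and corral-trap occasions.
* **Removal** — Bayesian hierarchical depletion model: yₜ ~
  Binomial(Nₜ, pₜ) with pₜ = 1 − (1 − θ)^{Eₜ} tying capture to nightly
  trap effort, fitted by a custom Metropolis-within-Gibbs sampler, plus
  MMDM buffering to reach density.

**Evaluation.** `run_grid()` crosses σ ∈ {0.1, …, 1.2} km, D ∈ {0.25, …,
15} /km² and g₀ ∈ {0.1, …, 0.9} (588 combinations, 5 replicates by
default) and reports per-cell **scaled bias** `(D̂ − D)/D` and **CV**
`SE(D̂)/D̂`, keeping failed fits as explicit failure records.

## Worked example

```r
library(densim)

cfg <- simulation_config(sigma = 0.6, g0_camera = 0.5, density = 2.5,
                         seed = 42)
ds <- simulate_dataset(cfg)
ds
#> Simulated camera + removal-trap dataset
#>   population: 373 individuals (density 2.50 /km^2)
#>   detectors: 20 cameras, 10 traps
#>   camera records: 482 (63 individuals)
#>   removals: 21 over 140 trap-nights

# Lincoln-Petersen + MMDM buffer
cnt <- build_lpe_counts(ds$camera_history, ds$trap_history)
cmb <- combine_histories(ds$camera_history, ds$trap_history)
w <- mmdm(cmb, ds$detectors)                    # 1.43 km
A <- effective_area(ds$detectors, w)            # 28.2 km^2
to_density(chapman_estimate(cnt), A)
#> Density (chapman, MMDM buffer): 2.236 /km^2  SE 0.000  CI [2.236, 2.236]  A = 28.18 km^2

# camera SECR
cams <- ds$detectors[ds$detectors$type == "camera", ]
fit <- fit_secr(ds$camera_history, cams, build_mask(cams, 2.5, 0.3))
fit
#> SECR fit [null]: converged
#>   D = 2.688 /km^2 (SE 0.347, CI 2.088-3.461)
#>   g0 = 0.393  sigma = 0.523 km  logLik = -1558.41  AICc = 3123.23
```

The LPE sits a little below the generating density of 2.5 /km² (all 21
trapped animals were also camera-identified, so the two samples were
highly dependent and the Chapman variance degenerates to zero), while the
SECR interval covers the truth and the fitted σ tracks the movement scale
— slightly shrunk, since the fitted half-normal does not know about the
simulator's availability clamp or nightly visit cap.

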