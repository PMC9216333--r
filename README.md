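# marrowscope

Quantitative imaging of the bone-marrow vascular niche, for researchers
studying how cardiovascular disease remodels the marrow's blood vessels.
Cardiovascular risk states (hypertension, atherosclerosis, myocardial
infarction) change marrow vascular structure and function — leakier
vessels, altered flow, angiogenic sprouting — and those changes are read
out with a small set of quantitative imaging statistics. `marrowscope`
implements that toolbox as tested, reusable R code:

- **DCE-MRI pharmacokinetics** — variable flip-angle R1 mapping with the
  spoiled gradient-echo model
  `S(α) = S₀ sin α (1−E)/(1−E cos α)`, `E = exp(−TR·R1)`; conversion of
  ΔR1 to contrast concentration via the agent relaxivity (default
  145 mM⁻¹ s⁻¹); blood-pool normalization; and the two-parameter linear
  model `C_t/C_b = FBV + PS·t` whose intercept at contrast administration
  is the **fractional blood volume** and whose slope is the
  **permeability × surface-area product** (min⁻¹). Scalar ROIs and
  pixelwise parametric maps.
- **Vascular leakage** — the intravital `I_out/I_in` statistic: Otsu
  segmentation of the first post-injection frame, intensity means inside
  and outside the vasculature per frame, leak rate as the slope of the
  ratio over time (min⁻¹).
- **Target-to-background ratios** on maximum-intensity projections.
- **Velocimetry** — erythrocyte velocity from line-scan kymographs by
  Radon-style sheared-projection variance maximization, and the
  acetylcholine **Δvelocity** statistic (negative Δ = endothelial
  vasomotor dysfunction).
- **Morphometry** — skeleton branch points, vessel area fraction, sprout
  detection under the strict >8 μm protrusion rule, and cell-to-vessel
  proximity by exact Euclidean distance transform with <40/≥40 μm bins,
  excluding osseous regions.
- **Synthetic phantoms** for every input (leakage stacks, kymographs,
  VFA/DCE series, morphometry scenes) with known ground truth, so the
  entire pipeline is testable by parameter recovery with no data
  downloads.

See `vignettes/marrowscope-methods.Rmd` for the models, assumptions, and
design decisions.

## Worked example

```r
library(marrowscope)

## vascular leakage on a phantom with a known extravasation rate
sim <- generate_leakage_stack(leakage_phantom_spec(
  vessel_phantom_spec(
    vessel_segments = list(
      list(start = c(20, 30), end = c(108, 30), radius = 4,
           intensity = 1000)),
    osseous_polygon = rbind(c(0, 110), c(127, 110), c(127, 127),
                            c(0, 127)),
    seed = 1),
  outside_slope = 5))   # 5 a.u./s of albumin extravasation
seg <- segment_vessels_first_frame(sim$stack, injection_frame = 1,
                                   sim$regions)
res <- leakage_rate(sim$stack, seg$mask, sim$regions, injection_frame = 1)
sprintf("leak rate: %.3f /min (truth %.3f)", res$leak_rate, 5 / 1000 * 60)
#> "leak rate: 0.300 /min (truth 0.300)"

## the healthy-marrow DCE cohort through the full chain
cohort <- generate_dce_cohort(dce_phantom_spec(noise_sd = 0.1, seed = 0),
                              n = 6)
fbv <- sapply(cohort, function(ph)
  dce_analyze(ph$vfa_tissue, ph$vfa_blood, ph$dce)$fit$fbv)
round(fbv, 3)
#> 0.265 0.195 0.268 0.267 0.226 0.140
sprintf("cohort mean FBV: %.1f%%", 100 * mean(fbv))
#> "cohort mean FBV: 22.7%"

## blood velocity from a kymograph
k <- generate_kymograph(kymograph_spec(true_velocity = 1.5, seed = 42))
est <- estimate_velocity(k)
sprintf("velocity: %.3f um/ms (truth 1.500), confidence %.2f",
        est$velocity, est$confidence)
#> "velocity: 1.500 um/ms (truth 1.500), confidence 0.98"
```

The leak rate is the slope of `I_out/I_in` per minute: `0.300` here means
the extravascular-to-intravascular intensity ratio grows by 0.3 per
minute — exactly `outside_slope / inside_intensity × 60` for this
phantom. The cohort-mean fractional blood volume of 22.7% estimates the
fraction of marrow volume occupied by blood; the generating cohort drew
six "animals" from the healthy distribution 20.8% ± 4.4%. The velocity
estimate recovers the constructed 1.5 μm/ms streak slope to 0.1%.

## Command-line use

Every stage is scriptable through one entry point (JSON configs, full
determinism per config, run report and resolved config written next to
the outputs):

```sh
Rscript -e 'marrowscope::marrowscope_main()' simulate \
    --preset healthy-dce --n 6 --seed 0 --out_dir sim
Rscript -e 'marrowscope::marrowscope_main()' dce \
    --dir sim --out_dir out      # writes dce.csv + dce_summary.json
```

Commands: `simulate`, `leakage`, `tbr`, `velocity`, `dce`, `morpho`,
`proximity`.

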