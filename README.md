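# pulpscan

Internal mechanical damage in mandarins — pulp rupture from compression
during picking, sorting and transport — is invisible from the outside but
shows clearly on CT section images as an enlargement of the dark central
cavity, with displaced pulp ("blockage") appearing as bright fragments
inside it at larger deformations. `pulpscan` is for postharvest and
food-engineering researchers who want to quantify that damage from section
images and relate it to storage outcomes.

The package implements:

* a **mask-and-region-growing segmentation pipeline** for the central
  cavity: Otsu binarization → erosion-based fruit-interior mask → image
  multiplication → background conversion and centroid-based cavity
  isolation → morphological refinement → seeded region growing that fills
  blocked cavities → pixel-area measurement;
* the **damage-rate statistic** computed from pre/post cavity areas
  `S1`, `S2`:

  `A = (S2 − S1) / S1 × 100%`

* **storage-quality metrics**: respiration rate
  `(C1 − C2)·V / (m·t)` (mL kg⁻¹ h⁻¹), decay rate (% of fruits with
  visible *Penicillium* mold), and percent change versus control;
* **linear models** `Y1 = aX + b` (damage rate on deformation) and
  `Y2 = aX + b` (decay rate on deformation) with R², slope t-test, and
  honest reporting when group means cannot reproduce a per-sample fit;
* a **synthetic phantom generator** with exact pixel-level ground truth
  (peel annulus, pulp wedges, septa, lobed dark cavity, blockage
  fragments, ruptures, noise), so the whole pipeline is testable without
  any CT data.

See `vignettes/cavity-damage-pipeline.Rmd` for the model, parameter and
calibration details.

## Worked example

Simulate one fruit compressed by 12 mm, segment the pre- and
post-compression sections, and measure the damage rate:

```r
library(pulpscan)

pair <- generatePair(PhantomSpec(seed = 42), deformationMm = 12)
pair
#> PhantomPair: deformation 12 mm, S1 = 9112 px, S2 = 10110 px, true A = 10.953%

res1 <- extractCavity(pair@preImage)
res2 <- extractCavity(pair@postImage)
res2
#> CavityResult: area 10111 px, blocked (threshold 29.95, stages: binarized -> mask -> masked -> candidate -> refined -> filled)

damageRate(areaPx(res1), areaPx(res2))
#> [1] 10.96356
```

The generator's truth says this fruit's cavity grew from 9112 to 10110
pixels (true A = 10.95%); segmentation recovers 10.96% from the noisy
images — the post-compression cavity was classified *blocked* (pulp
fragments inside), so its area came from the region-growing fill. A batch
of pairs plus a decay table yields the full report:

```r
pairs <- lapply(1:3, function(i) generatePair(PhantomSpec(seed = i), 12))
decay <- data.frame(deformation_mm = c(4, 8, 12, 16),
                    decayed_count = c(3, 4, 7, 9))   # of 20 fruits
rep <- runPipeline(pairs, decayTable = decay)
writeLines(renderReport(rep))
#> Damage rate by compression deformation
#> Deformation(mm)  n   Damage Rate(%)
#>             12   3   10.84 ± 1.49
#>
#> Fitted deformation-rate models
#>   Y2 = 2.625X + 2.5  (R^2 = 0.97, slope p = 0.0155, n = 4)
```

The decay model says every added millimetre of compression deformation
costs about 2.6 percentage points of extra storage decay; predictions
interpolate and flag extrapolation:

```r
m <- fitRateModel(c(4, 8, 12, 16), decayRate(c(3, 4, 7, 9)), "Y2")
predictRate(m, 10)
#> [1] 28.75
#> attr(,"extrapolated")
#> [1] FALSE
```

A command-line wrapper over the same functions lives at
`inst/scripts/pulpscan.R`
(`phantom | segment | damage | storage | regress | run` subcommands).

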