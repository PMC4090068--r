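# polarcensus

Abundance of polar bears on an ice-free Arctic island, estimated two
independent ways and compared:

- **Satellite census** — two analysts independently review one
  very-high-resolution satellite image; their reviews form a two-occasion
  closed-population mark–recapture experiment (M_t with observer-specific
  detection), fitted by full likelihood with lognormal f0 confidence
  intervals and Lincoln–Petersen / Chapman closed forms as cross-checks.
- **Aerial line-transect survey** — perpendicular sighting distances are
  fitted with conventional and covariate distance sampling (uniform+cosine,
  half-normal, half-normal×VIS/LIGHT, hazard-rate), selected and averaged by
  AICc (Δ < 3) with unconditional variance, after a Huggins double-observer
  check that detection on the line is effectively perfect.

The package is aimed at quantitative wildlife ecologists who want the full
analysis chain — matching, estimation, variance decomposition, model
averaging, platform comparison — reproducible from flat files or from the
bundled synthetic scene generator (island, bears, rock and foam confusers,
transects, target/reference image pairs), since the original imagery is
commercial and the sighting data unpublished.

## The core models

Satellite census, with `n1`, `n2` the analysts' counts, `m` seen by both and
`M = n1 + n2 − m` distinct:

    L(N, p1, p2) ∝ N!/(N−M)! · Π_t p_t^{n_t} (1−p_t)^{N−n_t}
    CI: (M + f0/C, M + f0·C),  C = exp(1.96·√ln(1 + var(f0)/f0²))

Aerial survey, with g(x) the detection function, μ = ∫₀ʷ g, effort L,
stratum area A and mean group size s̄:

    N̂ = n/(2μL) · A · s̄,   CV² = CV(n/L)² + CV(μ)² + CV(s̄)²
    N̄ = Σ wᵢ N̂ᵢ,  SE_u = Σ wᵢ √(varᵢ + (N̂ᵢ − N̄)²)   (Akaike weights wᵢ)

## Worked example

```r
library(polarcensus)

# satellite census from the reconstructed capture counts
fit <- fit_closed_mt(capture_summary(n1 = 90, n2 = 40, m = 38))
fit
#> Closed-population M_t fit (two observers)
#>   N-hat = 94 (continuous 93.48); 95% CI (92.6, 105.3); CV 2.8%
#>   detection: p1 = 0.963, p2 = 0.428; f0 = 2.74 (SE 2.61)

# aerial model averaging over the per-model estimates
avg <- model_average(data.frame(n_hat = c(97, 104, 105, 108, 100),
                                se = c(17.8, 21.0, 21.3, 22.1, 22.5)),
                     c(0, 0.15, 1.12, 1.38, 2.62))
avg
#> Model-averaged abundance: 102.3 (SE 20.8, CV 20.3%), 95% CI (69.0, 151.7)
```

94 bears (CI upper ≈ 105) from the image census versus 102 (CI 69–152) from
the aerial survey: the two platforms agree closely, and the census CV
(~2.8%, detection-only, full coverage) is an order of magnitude smaller than
the survey CV (~20%, which adds encounter-rate and group-size variance).

A fully synthetic end-to-end run:

```r
cfg <- run_config(seed = 7)
sat <- run_satellite_pipeline(cfg)
aer <- run_aerial_pipeline(cfg)
compare_estimates(sat, aer)
#> == Platform comparison ==
#>   satellite: 94 (93.4 - 103.3), CV 2.1%
#>   aerial:    84 (40.1 - 174.5), CV 38.9%
#>   CIs overlap: TRUE; CV ratio (aerial/satellite): 18.4
```

A thin CLI over the same functions lives at `inst/cli/polarcensus-cli.R`
(subcommands `simulate`, `detect`, `mr-fit`, `ds-fit`, `compare`, `all`).

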