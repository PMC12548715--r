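# axonquant

Quantification of excitatory and inhibitory afferent organization in 3D
confocal fluorescence z-stacks, built for tract-tracing studies of the
midline thalamus (paraventricular nucleus, PVT) but applicable to any
bright-on-dark neurite imaging at isotropic resolution.

The package implements, as tested reusable components:

* **Axon length density.** For a z-stack of voxel size *h* (default
  0.09 µm, isotropic), the pipeline removes axonal boutons with a
  random-forest voxel classifier (mask multiplication), scores each voxel
  with the Hessian tubeness measure √(λ₂λ₃) for λ₂, λ₃ < 0 after
  Gaussian smoothing at σ = 0.32 µm (the minimum axon diameter),
  binarizes by two-level hysteresis, thins the foreground to a
  one-voxel curve skeleton by topology-preserving distance-ordered
  peeling, and reports

  density = Σ_(adjacent skeleton pairs) h·{1, √2, √3} / (stack volume, µm³),

  i.e. µm of axon midline per µm³ of tissue.
* **ROI-grid parcellation.** Systematic square sampling windows
  (89.51 µm side, 100 µm spacing) with majority-label region assignment
  (MDm / MDm–PVT transition / PVT core; ties excluded), per-window mean
  fluorescence, and perpendicular-band line-intensity profiles.
* **Retrograde count analysis.** Per-animal normalization of labeled
  cell counts to the subcortical total, mean ± SEM region summaries
  with a 3 % reporting threshold, and the afferent phenotype rule on
  r = vGLUT2⁺/vGAT⁺: r < 0.2 → GABAergic, r > 5 → glutamatergic,
  0.2 ≤ r ≤ 5 → mixed.
* **Statistics.** Pearson/Spearman correlation, pooled and paired
  t-tests, one-way ANOVA with Tukey HSD, and one-way repeated-measures
  ANOVA with Greenhouse–Geisser-corrected degrees of freedom.
* **Synthetic ground truth.** A generator for tube phantoms (Gaussian
  cross-sections on smooth random centerlines, Poisson-placed bouton
  swellings, confocal-style noise) with exact centerlines and lengths,
  plus region-intensity fields and multinomial count tables — the test
  substrate for every stage.

## Worked example

```r
library(axonquant)

# a noiseless synthetic stack with known ground truth
p   <- sim_params(stack_shape = c(64, 64, 64), n_axons = 3,
                  noise_sd = 0, bouton_rate_per_um = 0, seed = 3)
sim <- generate_axon_stack(p)
sim$stack
#> VolumeStack 64 x 64 x 64 voxels (z,y,x), 0.09 um/voxel, channel 'synthetic'
#>   intensity range [10, 208.2], volume 191.1 um^3

axon_density(sim$stack)
#> Axon density: 0.1221 um / um^3 (length 23.33 um in 191.1 um^3)

sim$truth$total_length_um / stack_volume_um3(sim$stack)
#> [1] 0.1135
```

The recovered density (0.1221 µm/µm³) sits within the thinning/
digitization tolerance of the ground truth (0.1135 µm/µm³): a digital
curve measured with (1, √2, √3) steps slightly overestimates oblique
lengths, which cancels in the regional density ratios the measure is
used for.

Count-table analysis on a synthetic cohort generated at the published
per-region profile:

```r
tab <- generate_count_table(lapply(pvt_input_fractions(), `/`, 100),
                            totals = list(vGLUT2 = 476, vGAT = 469),
                            n_animals = 3, seed = 1)
s <- summarize_regions(normalize_counts(tab))
head(s[order(-s$mean_pct), ], 5)
#>             region genotype mean_pct sem_pct n     phenotype ratio
#>    scattered/other     vGAT     20.1      NA 3          <NA>    NA
#>    scattered/other   vGLUT2     20.1      NA 3          <NA>    NA
#>                LPB   vGLUT2     17.2   0.505 3 glutamatergic   Inf
#>                PAG   vGLUT2     15.3   0.505 3         mixed  1.84
#>               BNST     vGAT     12.2   0.213 3     GABAergic  0.00
```

`LPB` (no vGAT⁺ cells) is called glutamatergic, `PAG` (both genotypes
well represented, ratio 1.84) mixed, `BNST` GABAergic — the 0.2/5 ratio
rule applied to the recovered fractions.

A thin command-line wrapper over the same functions ships at
`inst/scripts/axonquant.R`
(subcommands `simulate`, `quantify`, `train-boutons`, `segment-boutons`,
`grid`, `classify-inputs`, `stats`).

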