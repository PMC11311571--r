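# oralmark

Quantitative imaging biomarkers from endoscopic optical coherence
tomography (OCT) of oral mucosa.

Rotary-pullback OCT catheters produce centimetres-long cylindrical
volumes of the oral epithelium and stroma — far too much data for
frame-by-frame expert reading. Given the intensity volume and per-frame
segmentations of the epithelium top and the epithelial–stromal boundary,
`oralmark` computes seven per-A-line biomarkers, presents them as en face
maps, reduces each volume to per-biomarker medians, and compares groups
of volumes with a normality-routed statistical protocol. It is aimed at
OCT researchers building quantitative readouts for dysplasia/carcinoma
assessment, biopsy-site selection, and margin delineation.

The seven biomarkers:

| Category | Biomarker | Definition |
|---|---|---|
| Morphologic | Epithelial depth [µm] | height of the epithelium mask per A-line |
| Morphologic | Loss of epithelial–stromal boundary [%] | tissue A-lines with no resolvable boundary, excluding artifacts |
| Attenuation | μ overall / μ epithelium / μ stroma [mm⁻¹] | mean depth-resolved attenuation coefficient over each region |
| Stratification | Epithelial–stromal [a.u.] | (μ_E − μ_S)/(μ_E + μ_S) per A-line |
| Stratification | Intraepithelial [a.u.] | (μ_UE − μ_LE)/(μ_UE + μ_LE), upper vs lower epithelium halves |

The depth-resolved attenuation coefficient is estimated per pixel from
the single-scattering relation between local signal and the energy
remaining below it, in its exact discrete form
μᵢ = (2Δ)⁻¹ · log(1 + Iᵢ / (Σ₍ⱼ₎₌ᵢ₊₁ Iⱼ + T)), with a log-linear tail
fit supplying the boundary term T; the visualized region of every A-line
ends 6 dB above the per-frame noise floor. A-lines where no boundary is resolvable treat
the whole visualized depth as epithelium and are themselves counted by
the loss biomarker. Since no clinical data ships with the package, a
seeded two-layer speckle phantom generator (`phantom_spec()`,
`generate_phantom()`) provides volumes with exact ground truth for every
stage.

## Worked example

Generate a reference-tissue ("contralateral") phantom at the working
geometry (64 frames × 512 A-lines × 2 mm depth, speckle on), run the
full biomarker pipeline on its ground-truth surfaces, and summarize:

```r
library(oralmark)
ph   <- generate_phantom(phantom_preset("contralateral", seed = 1))
maps <- compute_biomarkers(ph$volume, ph$truth$surfaces, ph$truth$masks)
volume_summary(maps, ph$truth$masks, role = "contralateral", id = "demo")
#>     id          role depth_um loss_pct mu_overall   mu_epi mu_stroma   es_strat
#> 1 demo contralateral      160        0   3.644045 1.193354  4.071407 -0.5411768
#>       ie_strat n_alines
#> 1 -0.007130047    10752
```

The phantom was generated with epithelial depth 160 µm,
μ_epithelium = 1.20 mm⁻¹ and μ_stroma = 3.97 mm⁻¹: the summary recovers
the depth exactly, both attenuation coefficients within a few percent
under fully developed speckle, and a strongly negative epithelial–stromal
stratification (dark, weakly attenuating epithelium over bright,
strongly attenuating stroma). `loss_pct = 0` says every retained A-line
had a resolvable boundary; `n_alines` counts A-lines surviving the
azimuthal edge erosion and artifact exclusion.

Single values work too:

```r
round(stratification(1.22, 3.71), 2)
#> [1] -0.51
```

A thin CLI over the same functions is provided at
`inst/cli/oralmark.R` (`simulate`, `compute`, `summarize`, `compare`
subcommands), and `vignettes/oralmark-methods.Rmd` documents the model,
the numerical choices, and their rationale.

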