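# nailfold

Fully automated measurement of nailfold capillary **structure and blood
flow** from high-frame-rate capillaroscopy video, in R.

At the nailfold, distal-row capillaries run parallel to the skin and appear
as hairpin loops. Systemic sclerosis (SSc) dilates, distorts and depletes
these loops and slows the blood moving through them, while primary
Raynaud's phenomenon (PRP) leaves them structurally normal — so objective
capillary measurements can separate SSc from PRP and healthy controls
(HC). `nailfold` is for researchers who need those measurements end to
end: it registers overlapping video frames into a still mosaic, detects
every distal-row capillary, traces its path 100 µm down both limbs,
measures width and orientation at each point, estimates red-blood-cell
speed by optical flow, and reduces each nailfold to six parameters:

| parameter | definition |
|---|---|
| capillary density | apices per mm, `n / span` over the left-most to right-most apex |
| mean width | mean over capillaries of the mean per-point width (µm) |
| max width | largest capillary mean width (µm) |
| shape score | mean per-capillary dispersion `R = \|mean(exp(2iθ))\|` of path orientations ∈ [0, 1]; low = tortuous |
| derangement score | the same dispersion applied to the capillaries' principal orientations; low = disorganised |
| mean flow velocity | mean along-path cell speed over capillaries (mm/s) |

Per-digit values are averaged into participant-level parameters, and the
cohort module reproduces the standard analysis: one-way ANOVA with Tukey's
range test, per-parameter ROC areas (A_z, Hanley–McNeil SE) for SSc vs
pooled HC/PRP, and stepwise logistic combinations (structure only, and
structure + flow) scored by leave-one-out cross-validation.

Because clinical images cannot ship with the package, a **software
phantom** renders hairpin capillaries with exact ground truth — geometry,
widths, orientations, cell speeds, stage offsets — and every stage is
validated against it.

## Worked example

Generate a healthy-control-like phantom digit (four 11.8 µm capillaries,
cells moving at 0.311 mm/s, 120 fps video) and run the full chain:

```r
library(nailfold)

spec  <- phantom_spec(n_capillaries = 4, seed = 7)
truth <- phantom_truth(spec)
video <- render_video(spec, truth)
res   <- run_digit(video, pipeline_config(), digit_id = "demo")
res$metrics
```

which prints (numbers from this exact run):

```
capillaries: 4
density: 9.53 /mm (truth 9.47)
mean width: 11.0 um (truth 11.8)
max width: 11.4 um
shape: 0.672
derangement: 0.877
flow: 0.308 mm/s (truth 0.311)
```

All four capillaries are found; density and flow recover their ground
truth within a few percent, and the width is recovered to within 1 µm (the
mosaic is composited from frames containing moving cells, which slightly
thins the apparent lumen). A whole synthetic cohort goes the same way:

```r
man <- phantom_cohort(n_per_group = 2, digits_per_subject = 2, seed = 1)
res <- run_cohort(man, pipeline_config())
print(res$report)   # Table-1-style report: group means ± SE, flags, A_z
```

For cohort-level statistics on their own, `simulate_cohort()` draws
participant-level parameter tables with realistic group profiles, and
`cohort_report()` produces the full report from any such table.

A thin CLI wraps the same functions
(`inst/cli/nailfold.R phantom-generate | mosaic-build | detect-run |
flow-run | stats-report | pipeline-run-digit | pipeline-run-cohort`);
frames are PNG stacks with CSV offset sidecars, results CSV/JSON, configs
YAML.

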