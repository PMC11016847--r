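# isobud

Quantifying winter bud dormancy in temperate deciduous trees from
twig-cutting assays: stable-water-isotope labelling arithmetic, budburst
phenology metrics, and the mixed-model statistics that link them.

## The problem

Temperate trees pass through winter dormancy in stages — endodormancy
(controlled from inside the bud), then ecodormancy (limited only by
temperature) — and the timing of spring budburst depends on how much chilling
and forcing the buds have accumulated. Two inexpensive physiological proxies
can track this progression on detached twigs forced at constant temperature:

* **Short-term uptake of ²H-labelled water.** A twig segment stands for 24 h
  in strongly deuterium-enriched water (δ²H ≈ 2000 ‰). The fraction of label
  water reaching the bud measures how well the vascular pathway into the bud
  conducts. A sharp collapse of this uptake in late autumn marks the onset of
  endodormancy, when the bud becomes symplastically isolated.
* **Bud water content**, from fresh and dry mass, which declines after leaf
  senescence and rises again weeks before budburst, tracking dormancy
  release.

Dormancy status itself is read from forcing assays: **budburst success** (the
fraction of a twig's buds reaching the budburst stage, stage 2 on the 0–4
scale) and **thermal time to budburst** (degree-days at 20 °C forcing until
stage 2 — the dormancy depth).

`isobud` implements the complete analysis chain for such an experiment (two
sites, five species, fortnightly campaigns October–April), plus a synthetic
experiment generator with known ground truth, so every stage is testable by
parameter recovery.

## The isotope arithmetic at the core

For each species, a natural-abundance background line is fitted by ordinary
least squares across unlabelled samples:

    δ²H_background = β₀ + β₁ · δ¹⁸O_sample

(bud-water slopes fall below the global meteoric water line slope of 8,
the signature of Rayleigh-type evaporative enrichment). Deltas are converted
to atom percent using the VSMOW ratio R:

    atom% = 100 · R·(δ²H/1000 + 1) / (1 + R·(δ²H/1000 + 1))

and the short-term uptake of labelled water is the excess of the sample over
its predicted background, normalized to the label end member:

    uptake% = (atom%_sample − atom%_background) / (atom%_label − atom%_background) · 100

The statistical stage mirrors the standard design: a binomial mixed model for
budburst success (date × species × site two-way interactions, random tree
intercept, type II ANOVA), a Gaussian mixed model for log thermal time with a
quadratic date polynomial after the first frost (type III), campaign-factor
models for water content and uptake (type III), Tukey HSD post-hoc
contrasts, species-specific Pearson correlations between the four proxies
(excluding the leafy autumn campaigns 1–3), and a change-point rule for the
endodormancy onset (first campaign after the uptake peak that falls below
10 % of the peak and stays there).

## Worked example

```r
library(isobud)

sim <- simulate_experiment(sim_config(seed = 1))  # 2 sites x 5 species x 5 trees
rep <- run_pipeline(sim)

rep$background_lines$beech
#> Background line [beech]: d2H = -24.662 + 5.1604 * d18O  (n = 30, residual sd = 1.379)
```

The fitted slope 5.16 sits 2.84 below the meteoric water line slope of 8
(`line_vs_gmwl()` flags the line as evaporative), so bud water is losing
light isotopologues by cuticular evaporation — exactly what the generator
programmed (true slope 5.2).

```r
rep$onset$beech
#> Endodormancy onset [beech]: campaign 4 (peak 44.2% at campaign 3, post-drop mean 2.72%)
```

Label uptake peaked at 44 % of the label end member during leaf senescence
(campaign 3, early November) and collapsed to ~3 % from campaign 4 (late
November) onward: the onset of endodormancy.

```r
subset(rep$correlations, var1 == "depth" & var2 == "water_content")
#>     species          r            p  n
#> 4     beech -0.4763341 2.079332e-06 90
#> 10 hornbeam -0.4927121 8.092160e-07 90
#> 16     lime -0.4511215 8.107459e-06 90
#> 22    maple -0.5417542 3.505274e-08 90
#> 28      oak -0.5251313 1.074171e-07 90
```

Bud water content anticorrelates with dormancy depth for every species —
water content rises as the thermal time needed for budburst falls — making
it the better proxy for dormancy *release*, while the uptake collapse marks
dormancy *onset*.

`run_pipeline(sim, out_dir = "results/")` additionally writes the per-sample
uptake and outcome tables, one CSV per fitted model (χ², df, P), the
correlation and onset tables, a plain-text report, and a manifest with a
configuration fingerprint; outputs are byte-identical across runs on the
same inputs.

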