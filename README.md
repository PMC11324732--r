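# heatnuc

Quantitative analysis of nuclear protein accumulation kinetics under heat
stress, for proteomics groups studying how a plant nucleus remodels its
proteome during and after a temperature shift. The input is a label-free
LC-MS/MS abundance table over four conditions — control 22 °C (`T22`),
4 h at 37 °C (`H4`), 24 h at 37 °C (`H24`), and a 24 h recovery at 22 °C
(`R22`) — with three biological replicates each, optionally matched with
RNA-seq counts from the same design.

## What it computes

**Differential abundance.** For each of the six pairwise contrasts
(C1 = H4 vs T22, C2 = H24 vs T22, C3 = R22 vs T22, C4 = H24 vs H4,
C5 = R22 vs H4, C6 = R22 vs H24) an empirical-Bayes moderated t-test:
the per-protein pooled variance s²_g is shrunk toward a prior s²₀ with
d₀ prior degrees of freedom estimated across proteins,

    s̃²_g = (d₀ s²₀ + d_g s²_g) / (d₀ + d_g),
    t̃_g = log2FC / sqrt(s̃²_g (1/n_x + 1/n_y)) ~ t(d_g + d₀),

with Benjamini–Hochberg adjustment calibrated by Storey's π̂₀. The
default operating point thresholds raw p-values per contrast at
α = (0.0005, 0.001, 0.001, 0.0004, 0.0007, 0.0005), a family tuned to a
realized FDR near 1%.

**Kinetic classification.** Each differentially accumulated protein
(DAP) yields a significance pattern in {−1, 0, +1}⁶; a rule table maps
patterns to kinetic groups — Early (EG), Late (LG), Transient (TG),
Early-Persistent (EPG), Late-Persistent (LPG), Recovery (RG) — in both
directions.

**Profile clustering.** DAPs matching no rule are clustered on their
z-scored 4-condition abundance profiles (Pearson distance d = 1 − r,
complete linkage), with the number of clusters chosen by the gap
statistic; clusters are matched to template shapes and labelled
Early-Like (ELG), Late-Like (LLG), Transient-Like (TLG), Recovery-Like
(RLG) or Continuous (CG).

**Protein–mRNA correlation.** Per-gene Pearson r between 4-condition
protein and transcript (log2 rpm) profiles, categorized positive
(0.5 ≤ r ≤ 1), negative (r ≤ −0.5), or uncorrelated.

A seeded synthetic-data generator with planted kinetic classes,
left-censored missingness, and negative-binomial transcripts backs the
test suite; see the methods vignette
(`vignettes/nuclear-heat-stress-kinetics.Rmd`) for models, defaults, and
limitations.

## Worked example

```r
library(heatnuc)
res <- run_all(default_config(seed = 42), out_dir = "heatnuc_demo")
```

Stage logs (stderr):

```
[heatnuc:simulate] 2800 proteins simulated (seed 42)
[heatnuc:quantify] 2708 proteins retained; PC1 33.5% of variance
[heatnuc:diff] C1: 250 up, 55 down (pi0=0.86)
[heatnuc:diff] C2: 382 up, 78 down (pi0=0.83)
[heatnuc:diff] C3: 300 up, 68 down (pi0=0.84)
[heatnuc:diff] C4: 185 up, 111 down (pi0=0.86)
[heatnuc:diff] C5: 264 up, 203 down (pi0=0.83)
[heatnuc:diff] C6: 124 up, 175 down (pi0=0.86)
[heatnuc:diff] 668 DAPs (significant in >= 1 contrast)
[heatnuc:classify] 591 of 668 DAPs in the six kinetic groups
[heatnuc:cluster] k = 8 clusters over 73 proteins
[heatnuc:correlate] positive 35.9%, uncorrelated 45.6%, negative 18.5%
```

The simulation planted 100 proteins per kinetic class (plus 100
continuous and 2,100 flat) at effect size 2 log2 units and replicate
noise 0.3: the six contrasts call 668 DAPs — the planted 700 minus
borderline cases plus ~1% false discoveries — of which 591 match a
kinetic rule, e.g.

```r
s <- attr(res$assignments, "summary"); s[s$n > 0, ]
#>         group direction  n
#>            EG         1 76
#>            LG         1 79
#>            TG         1 79
#>           EPG         1 90
#>           LPG         1 89
#>            RG         1 76
#>            EG        -1 19
#>            ...
#>    UNASSIGNED         0 77
```

The 77 unassigned proteins (mostly the planted continuous class, whose
monotone rise matches no significance rule) are re-clustered; the gap
statistic picks k = 8 and the two dominant clusters map to CG with
template correlation > 0.999:

```r
res$clustering$like_groups[res$clustering$like_groups$n > 10, ]
#>   cluster like_group best_template template_r low_confidence  n
#> 3       3         CG    continuous -0.9998600          FALSE 11
#> 8       8         CG    continuous  0.9996929          FALSE 48
```

The manifest (`heatnuc_demo/manifest.json`) records the structural
identity classified + reclustered = DAPs (591 + 77 = 668) along with
every threshold and seed. Outputs (`contrasts.tsv`, `groups.tsv`,
`clusters.tsv`, `correlations.tsv`) are plain TSV.

The same stages are scriptable:

```sh
./exec/heatnuc simulate --seed 5 --out-prefix sim
./exec/heatnuc diff --proteins sim_proteins.tsv --design sim_design.tsv \
    --out contrasts.tsv
./exec/heatnuc classify --contrasts contrasts.tsv --out groups.tsv
```

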