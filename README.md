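# immunotopo

Spatial immune topography of the tumor microenvironment from multiplex
immunohistochemistry (mIHC) label masks.

Pancreatic ductal adenocarcinoma (PDAC) resists immunotherapy, and keratin
17 (K17) — the biomarker of its most aggressive (basal) molecular subtype —
appears to reshape the immune contexture around tumor cells. Given
multi-class segmentation masks (one class code per pixel: stroma, K17+
tumor, K17− tumor, CD4+, CD8+, CD16+CD163−, CD16+CD163+), `immunotopo`
answers: *are immune cells differentially distributed around K17-positive
versus K17-negative tumor?*

The core statistic is the **Tumor/Stromal Zone Score**. An exact Euclidean
distance transform assigns every stromal pixel to the influence zone of its
nearest tumor boundary (K17+ or K17−), split into a contact shell
(intratumoral compartment) and a peritumoral band (default depth 25 µm).
For immune class *i* and marker *M*:

    ZS(i, M) = CellCount(i, M) / ZoneArea(M)

with cell counts estimated from stained pixel area normalized by average
cell size (8 µm circles for lymphocytes, 16 µm for macrophages), and scores
reported in cells/mm². Around the statistic the package provides:

* **mask I/O** — indexed PNG/TIFF masks with JSON sidecars, GeoJSON ROI
  restriction, dot-annotation CSVs, patch tiling;
* **synthetic cohorts** — a generator with known tumor-nest geometry and
  zone-dependent immune intensities, giving ground truth for every
  downstream stage;
* **cohort statistics** — paired t tests, fraction-of-cases summaries,
  Spearman correlation, and a randomization null that re-places each
  case's cells uniformly over the admissible territory;
* **segmentation evaluation** — dot-annotation seeds dilated to 10/5 µm
  disks, component-wise TP/FP/FN, micro-averaged PPV/recall/F1;
* tidyverse-native results (tibbles, `tidy()`/`glance()`, `autoplot()`
  and `plot_*()` builders).

## Worked example

Simulate a small cohort in which CD8+ T cells are excluded from
K17-positive influence territory (intensity modulation 0.2 in every case),
score it, and summarise:

```r
library(immunotopo)
library(dplyr)

cfg <- synthetic_config()          # 1000x1000 px @ 0.346 um/px, lambda_CD8 = 500/mm2
coh <- simulate_cohort(cfg, n_cases = 8, seed = 42,
                       effect = list(role = "CD8", modulation = 0.2, prevalence = 1))
scores <- purrr::map_dfr(coh$cases, function(cs) {
  compute_zone_scores(cs$mask, assign_zones(cs$mask, depth_um = 25),
                      case_id = cs$truth$case_id[1])
})
cohort_summary(scores) |> tidy() |> filter(class == "CD8")
#> # A tibble: 2 × 8
#>   class compartment n_cases fraction_higher_in_neg mean_diff t_statistic p_value
#>   <chr> <chr>         <int>                  <dbl>     <dbl>       <dbl>   <dbl>
#> 1 CD8   intra             8                      1      36.7        8.39 6.73e-5
#> 2 CD8   peri              8                      1     393.         6.20 4.44e-4
```

Every case scored higher in K17-negative territory
(`fraction_higher_in_neg = 1`) in both compartments, with paired-t p values
of 6.7e-5 (intra) and 4.4e-4 (peri) — the generator's exclusion effect,
recovered. Per-case ratio records show the same picture:

```r
normalized_ratios(scores) |> filter(class == "CD8", compartment == "peri") |> head(4)
#> # A tibble: 4 × 7
#>   case_id  class compartment zs_pos zs_neg ratio status
#>   <chr>    <chr> <chr>        <dbl>  <dbl> <dbl> <chr>
#> 1 case_001 CD8   peri         146.    446.  3.06 valid
#> 2 case_002 CD8   peri          68.9   466.  6.76 valid
#> 3 case_003 CD8   peri         257.    446.  1.74 valid
#> 4 case_004 CD8   peri          33.3   671. 20.1  valid
```

`zs_pos`/`zs_neg` are CD8 densities (cells/mm²) in the K17+/K17−
peritumoral bands; ratios above 1 mean more CD8 near K17-negative tumor.
`plot_ratio_ranks(normalized_ratios(scores))` draws the ranked-ratio bar
plot, `autoplot()` on a mask or zone map renders the QC images, and
`depth_sweep()` profiles densities across band depths (5–200 µm).

A thin command-line front-end over the same functions lives at
`inst/scripts/immune-topo.R` (subcommands `run`, `partition`, `score`,
`eval`).

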