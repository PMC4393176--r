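# dyskindex

Quantifying regional left-ventricular (LV) wall motion, chamber volumes
and wall thinning from short-axis echocardiographic contour cines — the
analysis chain used to assess early infarct-zone dyskinesia and post-MI
remodeling in the mouse heart.

After a myocardial infarction the infarct zone becomes structurally
weak and can bulge **outward** during systole while the healthy wall
contracts inward (early dyskinesia). `dyskindex` measures this from the
same inputs a speckle-tracking workstation produces: per-segment radial
endocardial displacement tables, or traced endocardial/epicardial
contours from which it derives those displacements geometrically.

## The dyskinesia index

For M angular segments with mean radial displacement d(i, t) at frame
t (inward positive), the *efficiency* of wall motion at each time point
is the ratio of the summed signed to the summed unsigned displacements,

    eff(t) = | Σᵢ d(i, t) | / Σᵢ | d(i, t) |

and the **dyskinesia index** (DI) is the average of eff(t) over the
cardiac cycle (frames with no measurable motion — in particular the
reference frame — are excluded from the average). DI ranges over
[0, 1]: unity means completely polar (fully coherent) motion, and
values fall toward 0 as the dyskinetic share of wall motion grows. DI
is invariant to segment order, to positive rescaling and to a global
sign flip of the field.

Around the index, the package provides:

- **kinematics** — per-segment radial displacements from traced
  contours, by ray casting from a fixed end-diastolic centroid
  (`segment_radial_displacements()`), 96 segments by default;
- **volumetrics** — 3D LV volumes by short-axis disc summation with
  per-slice ED/ES detection, plus EF, SV and fold changes vs baseline
  (`lv_volumes()`, `ef_sv()`, `relative_change()`);
- **wall geometry** — wall-thickness profiles between endo- and
  epicardial traces and the percent of wall at or below the 0.5 mm
  thinning threshold (`thickness_profile()`, `thinning_extent()`);
- **cohort statistics** — mean ± SEM summaries, pooled-variance
  Student's t-tests, and mixed-design repeated-measures ANOVA with
  Bonferroni post tests (`summarize_metric()`, `unpaired_t_test()`,
  `rm_anova_bonferroni()`);
- **a synthetic motion phantom** — seeded mouse-LV contour cines and
  displacement fields with closed-form ground truth (`motion_params()`,
  `simulate_cine_stack()`, `analytic_di()`, `simulate_cohort()`), so
  the whole chain is testable without any imaging data;
- **I/O** — JSON contour cines and CSV displacement tables
  (`read_cine_stack()`, `read_displacement_table()`, `write_report()`).

## Worked example

A phantom with a 24-segment dyskinetic sector (outward 0.3 mm against
0.4 mm inward contraction elsewhere):

```r
library(dyskindex)

p <- motion_params(
  amplitudes = dyskinetic_amplitudes(96, n_dyskinetic = 24,
                                     inward = 0.4, outward = 0.3),
  noise_sd = 0)

analytic_di(p)
#> [1] 0.6

stack <- simulate_cine_stack(p)
field <- segment_radial_displacements(stack$slices[[2]],
                                      frame_times = stack$frame_times)
dyskinesia_index(field)
#> Dyskinesia index: 0.6000  (1 = fully polar motion)
#>   averaged over 34 frames (1 excluded for zero motion)

lv_volumes(stack)
#> LV volumetrics (6 slices @ 1.00 mm):
#>   LVEDV 27.93 uL   LVESV 20.42 uL   SV 7.52 uL   EF 26.9%
```

The closed-form DI of this phantom is (72·0.4 − 24·0.3)/(72·0.4 +
24·0.3) = 0.6, and the geometric route — contours → ray-cast
displacements → DI — reproduces it. The measured EF of 26.9 % reflects
the net inward motion left after the dyskinetic sector's bulge.

A full two-group longitudinal study (volumetrics at five timepoints,
DI at day 2, wall thinning, group statistics) runs from one seeded
configuration:

```r
rep <- run_study(demo_config(seed = 42, n_per_group = c(4, 4)))
rep
#> Phantom study report: control vs treated, 8 animals x 5 timepoints
#>   DI (d2): 0.658 vs 0.831, t = -13.94, p = 8.5e-06
```

Here the treated group's smaller dyskinetic sector yields the higher
DI, and the pooled-variance t-test resolves the difference at n = 4
per group.

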