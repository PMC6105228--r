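# gravikine

Space–time kinematics of gravitropic bending from time-lapse imaging.

When a dark-grown seedling is turned on its side, the hypocotyl bends back
toward the vertical, overshoots, straightens, and — if a bioluminescent
auxin-response reporter is present — develops a measurable expression
gradient across its width. `gravikine` turns a time-lapse recording of such
an organ (bright-field frames plus luminescence frames) into quantitative
fields over time *t* and arc length *s*, and asks which bending law the
organ obeys.

The two candidate laws are the classical **sine law**,

    ∂C/∂t = −β sin A,

and the **graviproprioception (GP) model**,

    ∂C/∂t = −β sin A − γ C,        β > 0, γ > 0,

where *A*(*s*,*t*) is the local deflection angle from the vertical,
*C* = ∂*A*/∂*s* is the local curvature, β is the gravitropic gain and γ a
proprioceptive term by which the organ senses and removes its own
curvature. Setting γ = 0 recovers the sine law; a positive γ explains
autostraightening (decurving of bent regions before the vertical is
reached).

## What the package does

- **Simulate** (`simulate_gp_rod()`, `render_frames()`, `write_fixture()`):
  forward-integrates the GP bending law for a clamped rod turned to 90°,
  and renders bright-field silhouettes plus luminescence frames whose
  transverse log-ratio is pinned to a known ground truth — a fully
  controlled stand-in for a microscope recording.
- **Midline extraction** (`binarize()`, `extract_contours()`,
  `midpoints()`, `fit_principal_curve()`, `resample_median()`,
  `extract_midline()`): contour the organ, build the flank-midpoint cloud,
  fit a Hastie–Stuetzle principal curve (df 10), and parameterize the
  median every 19.9 µm from the base.
- **Kinematics** (`deflection_angle()`, `curvature()`,
  `curvature_rate()`, `see_ratio_map()`, `detect_extremal_paths()`,
  `align_with_angle()`): *A*(*s*,*t*) and *C*(*s*,*t*) maps via cubic
  smoothing splines at df = *n*/2, the curvature rate ∂*C*/∂*t* with its
  standard error of the estimate, and trough/height paths in the *t–s*
  plane snapped to deflection-angle contours at 5° resolution.
- **Luminescence** (`assign_sides()`, `inset_contour()`,
  `sample_profiles()`, `smooth_profiles()`, `lrl_map()`): intensity along
  the median (L_m) and at 1/8-diameter inset contours on the convex (L_v)
  and concave (L_c) flanks, and the differential-expression ratio
  LRL = log10(L_c / L_v).
- **Model selection** (`fit_gp()`, `fit_sine()`, `compare_models()`,
  `fit_models_by_time()`, `scan_sine_segments()`, `beta_map()`):
  per-timepoint regression of ∂*C*/∂*t* (or LRL) on sin *A* and *C*, AIC
  and adjusted R² comparison, and a scan for arc segments (> 0.76 mm,
  R² > 0.95) where LRL follows the sine law.
- **Orchestration** (`run_pipeline()`, `render_map()`): YAML-configurable
  end-to-end runs writing long-format CSV maps, fit tables, contour-map
  images and a provenance manifest.

Fitted models come with broom-style `tidy()` and `glance()` methods; *t–s*
fields are `ts_map` objects with `as_tibble()` and `autoplot()`.

## Worked example

Simulate the study scene, push it through the image pipeline, and ask which
model the data prefer:

```r
library(gravikine)
library(dplyr)

params <- gp_params(beta = 0.4, gamma = 1.5,
                    initial_curvature = function(s) 0.25 * sin(2 * pi * s / 2.2 + 0.7))
traj   <- simulate_gp_rod(params, sim_grid())        # 36 frames, 6.1 h
frames <- render_frames(traj, lum_model(), seed = 1)

midlines <- list(); anchor <- NULL
for (i in seq_along(frames$times)) {
  midlines[[i]] <- extract_midline(frames$bright[[i]], frames$pixel_scale,
                                   base_px = frames$base_px, anchor = anchor,
                                   frame_time = frames$times[i])
  anchor <- attr(midlines[[i]], "pair")$base
}
fields <- kinematics_fields(midlines, frames$times)
rate   <- curvature_rate(fields$C)

fits <- fit_models_by_time(rate$dCdt, fields$A_smooth, fields$C,
                           s_min = 0.5, s_max = 3.2)
fits %>% filter(model == "gp", t >= 0.3, t <= 1.6) %>%
  summarise(beta = median(beta), gamma = median(gamma),
            gp_preferred = mean(selected == "gp"))
#> # A tibble: 1 × 3
#>    beta gamma gp_preferred
#>   <dbl> <dbl>        <dbl>
#> 1 0.372  1.34            1
```

The generating parameters were β = 0.4 mm⁻¹ h⁻¹ and γ = 1.5 h⁻¹: the full
image pipeline recovers them within about 10 %, and the AIC prefers the GP
model over the sine law at every timepoint in the transient window. The
map of ∂*C*/∂*t* with deflection-angle contours overlaid is one line:

```r
autoplot(rate$dCdt, a_map = fields$A_smooth)
```

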