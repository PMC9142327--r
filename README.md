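# helaxis

Finite helical axis analysis of serial 3D surface scans.

`helaxis` is for researchers who track the movement of individual rigid
structures — the motivating case is orthodontic tooth movement measured on
serial dental-cast scans — and want each movement expressed in the most
compact description a rigid displacement admits. Given labelled point
clouds of the same dentition at successive timepoints, it:

1. registers every scan onto the first scan using a stable reference
   structure (e.g. the first molars), so all timepoints share one
   anatomical frame;
2. estimates, per tooth and per interval, the rigid map `m = A n + o`
   (rotation matrix `A`, translation vector `o`) by iterative closest
   point registration with an SVD (Kabsch) least-squares inner fit;
3. decomposes each `(A, o)` into its **finite helical (screw) axis**: by
   Chasles' theorem the displacement equals a rotation of angle θ about a
   unique line with unit direction `h` through a point `q`, plus a signed
   translation `t` along that line. The axis is the locus of minimal
   displacement, found from the on-axis condition
   `(A + Aᵀ − 2K) n + (K − Aᵀ) o = 0`; θ comes from
   `cos θ = (tr A − 1)/2`, `h` from the skew part of `A`, and `t = o · h`.

Quality metrics from the same workflow are included: the mean fitting
error of a registration (mean nearest-neighbour distance between the
registered sets) and a total-least-squares calibration-plane fit with
maximum/RMS deviation for scanner accuracy checks. A deterministic
synthetic generator builds crown-like arches displaced by known screw
motions with anisotropic scanner noise, so the whole chain is testable
against ground truth. Readers/writers cover PLY (ascii and binary), OBJ
and XYZ point clouds.

## Worked example

Simulate a two-timepoint arch in which only the central incisor moves — a
screw of 2.5° about an axis tilted toward the occlusal direction with
0.15 mm translation along it — then recover that motion blind:

```r
library(helaxis)

layout <- arch_layout(n_points_tooth = 300, n_points_reference = 300)
sp <- screw_motion_spec(c(0, 0.3, 1), c(0, 22, 0), theta = 2.5, t = 0.15,
                        label = "central_incisor")
ser <- generate_series(layout, list(sp), n_timepoints = 2, seed = 11)

cfg <- analysis_config(c(T0 = "", T1 = ""),
                       reference_label = "first_molars",
                       tooth_labels = c("central_incisor", "canine"),
                       icp = list(trim_fraction = 0))
run_pipeline(cfg, scans = ser$scans)
```

```
Per-tooth helical-axis motion report (reference: first_molars)
           tooth interval theta_deg  t_mm    h_x   h_y    h_z   q_x    q_y
 central_incisor   T0->T1     2.475 0.141 -0.007 0.303  0.953 0.237 19.231
          canine   T0->T1     0.041 0.019 -0.162 0.026 -0.987    NA     NA
    q_z mean_fitting_error_mm degenerate unreliable
 -6.104                 0.034      FALSE      FALSE
     NA                 0.033       TRUE       TRUE
```

The incisor's row reads: a rotation of 2.47° about an axis with direction
`(h_x, h_y, h_z)` through the point `(q_x, q_y, q_z)` (in the T0 scanner
frame), with 0.141 mm of translation along that axis — the simulated screw
recovered to within the scanner-noise floor (the remaining
0.03°/0.01 mm gap reflects the simulated 0.1 mm-resolution axis). The
unmoved canine is `degenerate`: its recovered rotation (0.04°) is below
the axis-definition threshold, so only a translation magnitude at the
noise level is reported, and `q` is undefined. `mean_fitting_error_mm` is
the per-tooth ICP registration quality, here at the noise floor of the
simulated scanner.

Single transforms decompose directly:

```r
tr <- screw_transform(c(0, 0, 1), c(5, 0, 0), theta_deg = 2, t_mm = 0.1)
helical_axis_from_transform(tr)
#> Finite helical axis
#>   direction h: (0.0000, 0.0000, 1.0000)
#>   point q:     (5.000, 0.000, 0.000) mm
#>   rotation:    2.00 deg about h (right-hand rule)
#>   translation: 0.100 mm along h
```

A thin command-line interface (`inst/cli/helaxis`) exposes the same
stages as `simulate`, `analyze`, `axis` and `calibrate-plane`
subcommands; see `?cli_main`.

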