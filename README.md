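# tmaes

Simulation of **multi-target transcranial magneto-acoustic electrical
stimulation (TMAES)** — a noninvasive neuromodulation approach in which a
phased-array ultrasound transducer focuses acoustic energy on several deep
targets at once while a static magnetic field converts the local particle
motion into an electric field via the Lorentz force.

The package is for researchers designing or analysing multi-focus
magneto-acoustic stimulation: it answers how a given array, element-to-target
partition, frequency and magnetic field translate into focal electric-field
spots — where they are, how big they are, how well two targets separate, and
how intensity trades off against the number of targets.

## Model

For a medium of density ρ, sound speed c₀ and conductivity σ under a static
field B perpendicular to the particle motion:

- plane-wave impedance: `P = ρ c₀ v`
- induced electric field: `E = v B = P B / (ρ c₀)`
- current density: `J = σ v B`

Multi-focus delay laws: element *i* assigned to a target at distance *d*
fires after `delay_i = t_max − d_i / c₀`, where `t_max` is the longest time
of flight among active elements (the reference element), so each target's
subset arrives in phase. The steady-state pressure is a free-field
source summation over sub-sources tiling each element,
`p(r) = A Σ ΔA/(2πR) · exp(−αR) · exp(i(kR + ωτ))`.

Focal metrics follow the −3 dB convention (amplitude factor `10^(−3/20)`):
connected −3 dB components, areas (cells × step²), long/short axis lengths,
peak separation, and the separation index
`R = (E_max − E_{x=0}) / (E_max − E_min)` on the through-focus profile
(R = 1: fully separated, R = 0: merged).

## Worked example

The symmetric dual-target scenario — the 8×8, 4.5 mm-pitch array at 500 kHz
focusing on (±9, 0, −50) mm with a 32/32 block split under 0.5 T, calibrated
to the measured 2.5 MPa peak:

```r
library(tmaes)

cfg <- system.file("extdata", "scenarios", "dual_symmetric.yaml", package = "tmaes")
cfg <- unclass(as_simulation_config(cfg))
cfg$drive <- list(amplitude = 1, calibrate_peak_pa = 2.5e6)

res <- run_scenario(cfg)
glance(res)
#>   scenario       frequency_khz b_tesla peak_pressure peak_efield total_area_mm2
#> 1 dual_symmetric           500     0.5       2500000       0.833           57.8

tidy(res)[, c("label", "peak_x_mm", "peak_y_mm", "area_mm2",
              "long_axis_mm", "short_axis_mm", "peak_value")]
#>   label peak_x_mm peak_y_mm area_mm2 long_axis_mm short_axis_mm peak_value
#> 1  left        -9         0   28.875          8.5          4.25  0.8333333
#> 2 right         9         0   28.875          8.5          4.25  0.8333333

res$separation
#>       e_max       e_min  e_midline         R peak_distance_mm
#> 1 0.8333333 0.004239407 0.09657105 0.8886355               18
```

Reading this: both −3 dB electric-field spots sit exactly on their set
targets, each covers 28.9 mm² (8.5 mm along x — the halved aperture — by
4.25 mm along y), the two peaks are 18 mm apart, and the separation index
R = 0.89 says the field between the targets dips nearly to the profile
minimum. With the pressure peak calibrated to 2.5 MPa, the peak induced
field is 0.83 V/m at 0.5 T. `autoplot(res$fields$efield)` maps the plane;
`frequency_sweep()` and `b_sweep()` tabulate the 300–700 kHz and
0.2–0.5 T studies.

A small command-line runner wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "tmaes.R", package = "tmaes"))') \
  simulate --config inst/extdata/scenarios/dual_symmetric.yaml --out out/
```

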