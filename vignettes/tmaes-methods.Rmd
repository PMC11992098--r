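---
title: "Simulating multi-target magneto-acoustic electrical stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating multi-target magneto-acoustic electrical stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The physical model

Transcranial magneto-acoustic electrical stimulation (TMAES) combines
focused ultrasound with a static magnetic field. Charge carriers in a
conductive medium vibrate with the acoustic wave at particle velocity $v$;
a static field $\mathbf{B}$ perpendicular to the motion exerts a Lorentz
force that separates positive and negative carriers, and the force balance
leaves an induced electric field

$$E = v\,B = \frac{P\,B}{\rho c_0},$$

where $P$ is the acoustic pressure amplitude, $\rho$ the medium density and
$c_0$ the sound speed ($P = \rho c_0 v$ is the plane-wave impedance
relation). The corresponding current density is $J = \sigma v B$ with
$\sigma$ the bulk conductivity. Because the conversion is a pointwise
scalar multiple, the spatial distribution of $|E|$ is exactly that of
$|P|$ under a uniform field, and $E$ is linear in $B$ at fixed acoustics —
both facts the package exploits and tests.

`tmaes` simulates this chain for a planar phased-array transducer driving
several focal targets at once:

1. **Delay law** (`build_planar_array()`, `assign_elements()`,
   `compute_delay_law()`). Each element is assigned to one target; its time
   of flight is the Euclidean distance to that target over $c_0$. The
   active element with the globally longest time of flight is the reference
   (delay zero) and every other element is delayed so that
   $\text{delay} + \text{time of flight}$ is constant within each target's
   subset — all contributions arrive at their focus in phase on a shared
   clock.
2. **Acoustic field** (`pressure_field()`). The steady-state complex
   pressure on an evaluation grid is the sum of free-field monopole
   contributions from sub-sources tiling each element,
   $p(\mathbf{r}) = A \sum_s \frac{\Delta A_s}{2\pi R_s}
   e^{-\alpha R_s} e^{i(kR_s + \omega\tau_s)}$,
   with $k = \omega/c_0$ and $\tau_s$ the element's firing delay.
3. **Coupling** (`particle_velocity()`, `efield_from_pressure()`,
   `current_density()`), the pointwise relations above.
4. **Metrics** (`threshold_mask()`, `focal_metrics()`,
   `separation_index()`, sweep harnesses), described below.

## Coordinate and unit conventions

The transducer face lies in the $z = 0$ plane and the beam propagates
toward negative $z$; focal targets therefore have $z < 0$ and
configuration validation rejects anything else. All geometry is expressed
in mm and delays in µs at the interface; conversion to SI happens once,
inside the solver. Report values follow the field's customary units (MPa,
V/m, T, mm²).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `pitch_mm`, `kerf_mm` | 4.5, 0.2 | element centre spacing and gap; active width = pitch − kerf = 4.3 mm |
| `rows × cols` | 8 × 8 | element grid (64 elements) |
| `frequency_khz` | 500 | carrier frequency; $\lambda = 3$ mm in water |
| `density`, `sound_speed`, `conductivity` | 1000 kg/m³, 1500 m/s, 0.5 S/m | tissue-like water bath; $\sigma$ matches neural tissue |
| `attenuation` | 0 Np/m | water over a ~50 mm path is effectively lossless; configurable |
| `b_tesla` | 0.5 | uniform static field, perpendicular to particle motion |
| grid | $x, y \in [-37.5, 37.5]$ mm, $z = -50$ mm, step 0.25 mm | focal plane of the 75 mm water body; 0.0625 mm² area resolution |
| `subsource_spacing_fraction` | 0.25 | sub-source lattice spacing $\le \lambda/4$ |

The default grid and spacing were chosen once as the package's study
conditions: 0.25 mm resolves mm-scale focal spots with better than 1%
area granularity, and halving the $\lambda/4$ sub-source spacing moves
focal-plane amplitudes by less than 1% (a property test and the
`oracle_field()` refinement run keep this honest). The default evaluation
problem is 301 × 301 grid samples against 2304 sub-sources, a few seconds
of compiled summation on one core; the full test suite and sweeps run in
minutes.

## Element-to-target partition

The partition of elements among targets is not uniquely determined by the
physics, so several strategies are provided:

* `block` (default): each element joins its nearest target, ties broken
  toward the lower target index. For symmetric target sets this produces
  the contiguous column/quadrant blocks (32/32 for two lateral targets,
  16 per quadrant for four) that make the per-target spots symmetric.
* `explicit_counts`: each target in order takes its requested number of
  nearest unassigned elements, the remainder stays inactive — this is how
  deliberately unequal stimulation intensities (e.g. a 32/16 split) are
  configured.
* `interleaved`: round-robin by element index, an alternative when a
  spatially interleaved aperture is preferred.
* `custom`: an explicit element-to-target mapping.

## Focal metrics

The focus area is the region within a 3 dB drop of the field peak. The
threshold is applied to amplitude as the factor $10^{-3/20} \approx
0.708$; at 3 dB the amplitude-vs-intensity ambiguity is numerically
immaterial (0.7079 vs 0.7071) but the choice is fixed and documented here.
By default one global peak defines the threshold across the whole
multi-target plane; `reference = "component"` instead re-grows each spot
from its own peak, for unequal-intensity scenarios. Cells above threshold
are grouped by 4-connectivity (via `igraph`), component areas are cell
counts times step², and each component is matched to its nearest set
target — surplus components are reported separately as side/grating lobes.
Axis lengths are the contiguous mask runs along the two in-plane axis
lines through a component's peak, reported sorted (long ≥ short).

Two separation measures serve dual-target work: the Euclidean distance
between the two largest components' peaks (raising a "not separated"
condition when only one component exists, as happens at 300 kHz), and the
separation index on the $y = 0$ profile,

$$R = \frac{E_{\max} - E_{x=0}}{E_{\max} - E_{\min}},$$

which is 1 when the midline falls to the profile minimum and 0 when the
two foci have merged. $R$ is invariant under affine rescaling of the
profile, and all region metrics are invariant under positive rescaling of
the field, so normalisation conventions cannot move them.

`frequency_sweep()` re-runs the pipeline per frequency (the delay law is
frequency-independent) and tabulates per-target $x$-axis focusing lengths
(the −3 dB extent of the $y = 0$ profile), peak distance, total area and
$R$. `b_sweep()` runs the acoustics once and rescales $E$ linearly in $B$,
which is exact under the model.

## Absolute amplitudes

The element drive amplitude behind published absolute pressures is not a
model input, so solver outputs are on an arbitrary linear scale.
`calibrate_amplitude()` pins a run's peak to a stated reference (e.g.
2.7 MPa for a single-target run), after which comparisons at identical
drive — such as the decrease of the peak with the number of targets — are
meaningful. Every metrics report records whether it is calibrated; areas,
axis lengths, $R$ and peak positions never depend on the scale.

## Design choices where the design was open

* **Continuous-wave phasor model.** The experimental systems emit short
  pulses, but every reported focal metric depends on the amplitude
  distribution at the carrier frequency, and the measurement chain
  band-passes 400–600 kHz around it; a single-frequency steady-state model
  is therefore the simplest faithful representation. Transient waveforms
  are out of scope.
* **Monopole sub-sources, no obliquity factor.** At F-number ≈ 1.4 the
  focal-plane pattern is dominated by aperture geometry; baffled-piston
  obliquity corrections are omitted and documented as an approximation
  relative to full FEM fields.
* **Free-field water medium.** Matching the tank configuration; skull and
  tissue layering are explicitly not modelled.
* **One shared reference element.** The globally farthest active element
  sets delay zero for all targets, giving a single emission clock rather
  than per-target clocks; only delay differences matter physically
  (a shift-invariance the tests assert).
* **Deterministic tie-breaks.** Nearest-target ties go to the lower target
  index; equal-distance reference candidates to the lower element index.
  The pipeline contains no randomness at all, and reports are regenerable
  byte-identically from the configuration (each carries a config digest).

## What the shipped scenarios emulate — and what they do not

The bundled fixtures (`make_fixtures()`, also under
`inst/extdata/scenarios/`) encode the studied conditions: a single centred
focus, the symmetric dual foci at (±9, 0, −50) mm, four quadrant foci at
(±9, ±9, −50) mm at 0.5 T and 0.7 T, an unequal 32/16-element dual
scenario, a 300–700 kHz frequency sweep and a 0.2/0.3/0.5 T field sweep.
The quad fixture places all four targets at $z = -50$ mm (one published
coordinate has a positive $z$ that validation would reject as being behind
the transducer). The asymmetric fixture keeps its published target
coordinates verbatim even though they put the two foci only 4.5 mm apart,
where the −3 dB regions merge; it exercises the unequal-split pipeline,
not separation claims.

Against published finite-element results, this solver reproduces the
dual-target focal geometry well (two components at the set targets,
per-target symmetry, total area and separation index within the tested
tolerances) and the frequency-sweep behaviour (merged foci at 300 kHz,
areas shrinking from 400 to 700 kHz). Absolute single-target and
quad-target areas, however, disagree beyond their tolerance bands in our
acceptance tests: a full 35.8 mm aperture at 500 kHz is
diffraction-limited to a ~3.7 mm wide, ~14 mm² spot, which is what this
free-field CW model yields, while the published single-target area is
larger than its own half-aperture dual-target spots — not reachable by any
scaling of this model. Those checks are kept failing rather than widened.
Passing tests show fidelity of the model as specified, on water-bath
conditions; they do not validate predictions through skull or tissue.

## Degenerate inputs and numerical details

All-zero fields cannot be thresholded or calibrated (error rather than
NaN); constant profiles have no separation index; a volume grid refuses
area metrics; an observation point coinciding with a sub-source is an
error (grids must avoid the $z = 0$ plane, which validation enforces);
distances beyond the last magnet-profile anchor clamp to the last value
with a warning; coincident element and target is a valid zero time of
flight. Sub-source lattices always cover each element exactly (areas sum
to the element area), so the radiated power is independent of the
discretisation level.

## Known limitations

Free-field, linear, homogeneous, lossless-by-default propagation; no
element cross-talk or directivity; scalar amplitude coupling with the
$\hat v \times \hat B$ direction carried only as metadata; areas defined
on planes, not volumes; absolute pressures only via calibration. These are
the boundaries of the specification, not accidents of implementation.
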