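---
title: "nanotwin: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nanotwin: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanotwin)
```

`nanotwin` is a digital twin of a dual-function nanoprobe: an
amperometric ROS/RNS sensor and a dielectrophoretic (DEP) nanotweezer
integrated at one tip, driven by an automation loop that senses single
cells and extracts mitochondria.  This vignette records the models, the
parameters that matter (with units and defaults), the numerical
decisions, what the synthetic world does and does not emulate, and the
design choices made where the design was genuinely open.

## 1. DEP physics

### Polarizability

Materials are described by complex relative permittivities
$\varepsilon^* = \varepsilon - j\,\sigma/(\omega\varepsilon_0)$ and
particles by the Clausius-Mossotti (CM) factor
$K = (\varepsilon_p^*-\varepsilon_m^*)/(\varepsilon_p^*+2\varepsilon_m^*)$.
For membrane-bounded organelles the particle permittivity is the
standard single-shell effective value
$\varepsilon_p^* = \varepsilon_s^*\,(\gamma^3 + 2K_{is})/(\gamma^3 - K_{is})$
with $\gamma$ the outer/inner radius ratio and $K_{is}$ the
interior-shell contrast.  $\mathrm{Re}[K]\in[-0.5,1]$ for passive
materials; its sign sets the DEP direction.

**Default mitochondrion** (`body_mitochondrion()`): radius 0.5 um,
interior $\varepsilon_r$ 60 / 0.4 S/m, effective membrane 5 nm with
$\varepsilon_r$ 12 / 1e-6 S/m.  The working medium for trapping is
$\varepsilon_r$ 80, 0.03 S/m, 1.0 mPa s, 298.15 K.  The membrane pair
(5 nm, $\varepsilon_r$ 12) is an *effective* single shell standing in
for the organelle's double membrane; it was chosen, within the
literature range for organelle covers, so that the CM spectrum is
positive around the 1 MHz trapping drive in the 0.03 S/m medium —
the regime in which the instrument traps mitochondria.  A thinner or
lower-permittivity membrane (e.g. 7 nm at $\varepsilon_r$ 8) pushes
the low-frequency crossover above 1 MHz and predicts repulsion where
attraction is observed, so it is not a usable default here.  All four
numbers are plain fields on `nt_body()` and can be overridden.

**Polystyrene beads** (`body_ps_bead()`): radius 0.15 um,
$\varepsilon_r$ 2.5, bulk conductivity 0.  By bulk properties such
beads are negative-DEP in water at 1 MHz; the physical reason trapped
bead experiments work is surface conductance, which matters strongly at
sub-micron radii.  `body_ps_bead(surface_conductance = Ks)` applies
$\sigma_{eff} = \sigma_{bulk} + 2K_s/a$; $K_s \approx 2$ nS makes a
300-nm bead positive-DEP ($\mathrm{Re}[K]\approx 0.84$) in the
deionized bead bath (`medium_di_water()`, 1e-4 S/m).  The default is
$K_s = 0$ so the bare dielectric sphere remains available.

### Tip field

The real tip field would require finite-element electrostatics of the
milled electrode geometry.  The twin replaces it with a one-parameter
analytic surrogate,
$$|\nabla E_{rms}^2| = G_0\,V_{pp}^2/(s + r_0)^7,$$
the far-field decay of a point-dipole tip, where $s$ is the distance
from the apex to the particle centre and $r_0$ the effective apex
radius (default 50 nm, consistent with a ~100 nm tip diameter).
$G_0$ is fixed once by `calibrate_tip()`: the reference mitochondrion
at contact ($s = a$) under the reference drive (7 V$_{pp}$, 1 MHz)
feels exactly `force_calibration` = 1 nN.  This preserves every scaling
the instrument exhibits — $V^2$ dependence, rapid decay with distance,
nanonewton contact forces, a micrometre-scale trap — without a field
solver.  The peak-to-peak-to-rms conversion is absorbed into $G_0$, so
all user-facing formulas carry $V_{pp}^2$.

The interaction energy is the time-averaged induced-dipole energy
$U = -2\pi\varepsilon_0\varepsilon_m a^3\mathrm{Re}[K]\,E_{rms}^2$ with
$E_{rms}^2$ the integral of the force law, so $F = -dU/ds$ holds
identically (verified to 1e-6 by central differences in the tests).
The **trapping radius** is the energy criterion $|U(s^*)| = k_BT$
(`threshold_kT` configurable); with the defaults it evaluates to
~2.9 um at 7 V$_{pp}$, the same order as the ~1.8 um trapping region of
the physical probe.  A force-balance criterion would be an equally
defensible definition; the energy criterion was chosen because escape
from the trap is thermally activated.

Distance convention, fixed once: `distance` is apex-to-particle-centre;
contact means `distance = radius`.

## 2. Brownian-dynamics trapping

Overdamped Euler-Maruyama:
$x \mathrel{+}= (F/\gamma)\,dt + \sqrt{2D\,dt}\,\xi$, with
$\gamma = 6\pi\eta a$ and $D = k_BT/\gamma$; inertia is negligible at
these scales (particle Reynolds and Stokes numbers $\ll 1$).
Boundaries reflect (cubic box, default half-width 10 um, and the apex
sphere $r \ge a$).  With the drive on and `contact_sticking`, a
particle reaching contact is pinned and co-moves with the probe;
switching the drive off releases everything instantly, matching the
instrument's immediate force collapse.

Numerical decisions:

* default `dt` = 10 us, halved automatically until the deterministic
  drift at the trap-region boundary is below $a/5$;
* inside the near field the per-step drift is additionally capped at
  $a/5$ — the force diverges as $(s+r_0)^{-7}$ at contact and any
  finite `dt` would otherwise overshoot; capped particles end up at
  contact, where they stick anyway, so the cap does not bias
  steady-state outcomes;
* pure-diffusion runs (release) are exact at any `dt` because Gaussian
  increments are the exact propagator; dispersal times are
  first-passage times of the in-region count, checked every step.

Release dispersal is defined as the first time fewer than 10% of the
initially trapped particles remain within the 1.8-um trap region
(`disperse_frac` configurable).  Translation retention uses the
quasi-static drag balance: a particle held at distance $r$ is shed when
$6\pi\eta a v > |F(r)|$.  The biopsy success surface uses a
semi-analytic capture model (diffusion to an absorbing sphere of
voltage-dependent radius, Smoluchowski flux) rather than a full BD run
per grid point, to keep Monte-Carlo surfaces fast; the full BD path is
exercised separately by its own tests.

For the released-cluster benchmark (20 beads of radius 0.15 um in
water at 298 K) the twin uses water's tabulated viscosity at 298 K,
0.8937 mPa s.  Pure-diffusion clearance of a 1.8-um region by such
beads has a median first-passage time of ~1.0-1.3 s depending on seed;
the physical cluster disperses slightly faster than the pure-Brownian
model because charged polystyrene beads in deionized water also repel
each other electrostatically at release, a mechanism deliberately
outside this model.

## 3. Electrochemistry

Calibration is linear, `current = slope * concentration + intercept`,
with default slope 25 pA/mM, intercept 0 and bias 0.85 V; selectivity
weights (H2O2 = 1, interferents ~0.5-3%) weight mixtures.  The numeric
slope is a fixture-regime choice (the instrument's calibration plots
are in pA over 0.05-2.4 mM); it makes the median cell's step ~20 pA,
comfortably above the 8-pA decision threshold.

Inside a cell the sealed-chamber model $V\,dC/dt = -AC$ gives
$i(t) = b + i_0 e^{-t/\tau}$, $\tau = V/A$ (fixture median 12 s).
`fit_depletion()` runs nonlinear least squares (port algorithm,
log-linear start values, Nelder-Mead fallback), normalizes the current
scale first so the fit is exactly scale-equivariant, and reports
`volume_estimate = A * tau` in arbitrary volume units — the
electrons-per-molecule conversion is not modelled, so no absolute
volume is claimed.

Detectors:

* penetration — derivative of a `runmed`-filtered trace thresholded at
  $k\,\mathrm{MAD}$ (default $k = 6$) of the *raw* derivative (the raw
  scale is the honest per-sample noise floor; the filtered derivative's
  own MAD is deflated by the median filter and would false-trigger);
* mitochondrion — filtered, baseline-corrected current above 8 pA
  sustained for a 50-ms debounce; the threshold is interpreted as
  baseline-relative because the instrument's baseline is nulled before
  insertion;
* withdrawal separation — current back within 2 noise-SD of the
  pre-insertion baseline;
* `filter_trace()` — hand-rolled 2nd-order Butterworth biquad applied
  forward-backward (zero phase, exact unit DC gain), default cutoff
  50 Hz at the 1-kHz sensor rate.

## 4. Vision

The tip locator subtracts a background model (supplied, or the temporal
median over ≥11 frames), thresholds the residual with Otsu's method,
takes the largest connected component and returns its extreme point
along the principal axis on the side away from the image border (the
needle enters from an edge).  It is invariant to additive illumination
and to anything present in the background model; on rendered fixtures
it is accurate to ≤2 px.

Cell detection is a pluggable interface; the default classical detector
smooths, double-Otsu-thresholds (bright cytoplasm plus dark nuclei —
the second threshold separates nuclei from the mid-gray background, so
no hole-filling pass is needed), closes the nucleus-boundary transition
ring, splits touching cells at distance-transform peaks with seeded
geodesic propagation (a watershed equivalent built from vectorized
raster primitives), and segments the darker nucleus within each cell.
A learned detector can be dropped in as `detector = function(frame)`.

Contact detection: the motion history image refreshes a pixel to 255 on
inter-frame change above 10/255 and decays by 25.5 per frame otherwise;
PMV is the mean MHI in a circular ROI at the tip, and PMV > 1 sustained
for 3 frames is a contact.  The MHI scale, decay and ROI are config
values — only the threshold "1" is anchored to the instrument.

## 5. Controller

`plan_insertion_point()` rasterizes the cell at unit resolution and
returns the cytoplasmic medial point: inside the cell eroded by
`margin`, outside the nucleus dilated by `margin`, maximizing the
smaller boundary distance.  Targets are visited in greedy
nearest-neighbour order.  The protocol per cell: one penetration
attempt (the cell escapes with its own probability — escape is modelled
as a per-cell Bernoulli tied to adhesion, since poorly adherent cells
are the observed failure mode); on success, sensing for `sense_window`
(default 1 s) at 1 kHz; threshold decision; on detection, the DEP drive
(7 V$_{pp}$, 1 MHz) holds for `dep_dwell` (default 60 s) and retraction
proceeds with the drive on; on no detection, the probe repositions at
least 2 um away (a declared convention — the instrument's repositioning
rule is not published) up to `max_attempts_per_cell` (default 7).
Escaped cells are terminal failures, so per-dish penetration successes
are Binomial(n, 1-p_escape).  All sensing intervals are logged at the
full sensor rate; simulated time advances deterministically from speeds
and dwells (wall-clock performance of the instrument is not modelled).
Survival is drawn per attempt from the cell's death probability
(fixture default 0.04, i.e. 96% single-attempt survival) and aggregated
as a Kaplan-Meier-style curve, monotone by construction.

## 6. The synthetic world

`make_dish()` rejection-samples non-overlapping elliptical cells
(semi-axes 12-20 um) with nuclei in a 620 x 500 um default field, and
draws per-cell physiology: $\tau \sim$ log-normal (median 12 s, sdlog
0.35), $C_0 \sim$ log-normal (median 0.8 mM, sdlog 0.4 — sized so the
median cell is detectable at 8 pA), escape probability 15/47, death
probability 0.04, membrane compliance 1.5-3 um.  ROS/RNS is uniform in
the cytoplasm and suppressed to 8% in the nucleus, reflecting the
observed low nuclear signal.  50 cells in the default field reproduces
the density regime of a real large-scale run.

`render_frames()` draws textured bright ellipses with darker nuclei on
a gray background, the needle as an oriented bright ridge ending at the
tip, a flickering local deformation during contact frames, and Gaussian
sensor noise; it emits per-frame tip positions, label masks and contact
intervals as ground truth.  It is *not* photorealistic: no PSF beyond
smoothing, no shading, no debris, no focus drift.  A green vision test
therefore establishes correctness of the algorithms on their stated
model, not robustness to real micrographs — that is what the pluggable
detector interface is for.

`make_trace()` synthesizes the full penetration current/position pair:
baseline, spike and exponential depletion while inside (with cumulative
depletion across repeated attempts on the same cell), return to
baseline at the withdrawal separation point, and a position channel
driven by insertion speed and membrane compliance.  Fluorescence in
`make_paired_measurements()` is a latent-density readout with noises
sized so the population Pearson correlation equals `coupling_rho`
exactly; no optics are modelled.

Every generator is a pure function of (config, seed): identical outputs
across runs, with ground truth sufficient to score every detector in
the package.

## 7. Known limitations

* One-parameter tip field: no electrode-geometry anisotropy,
  electrothermal flow, or electroosmosis.
* No hydrodynamic or electrostatic particle-particle interactions; the
  released-cluster benchmark therefore runs slightly slower than the
  physical cluster (see section 2).
* Cluster geometry is ignored for forces (no shielding); membrane
  penetration is kinematic, not mechanical.
* Image I/O is plain text (the environment provides no TIFF bindings
  for R); the in-memory `nt_stack` is the contract.
* Absolute cell volumes from depletion fits are in arbitrary units.
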