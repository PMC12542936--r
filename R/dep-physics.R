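# Dielectrophoresis physics: Clausius-Mossotti polarizability and the
# calibrated analytic tip-field model of the nanoprobe.
#
# Conventions used throughout (documented once, used everywhere):
#  * `distance` is measured along the tip axis from the apex (treated as a
#    point) to the particle CENTRE.  A particle touching the apex has
#    distance == its radius, so "contact" evaluations use
#    distance = body$radius (this is the calibration point).
#  * voltage_pp is peak-to-peak; the pp -> rms conversion is absorbed into
#    the calibration constant G0, so all formulas below carry voltage_pp^2.

#' Suspension medium
#'
#' @param rel_permittivity relative permittivity (dimensionless, >= 1).
#' @param conductivity electrical conductivity in S/m (>= 0).
#' @param viscosity dynamic viscosity in Pa.s (> 0).
#' @param temperature absolute temperature in K (> 0).
#' @return an object of class `nt_medium`.
#' @examples
#' medium_water()
#' @export
nt_medium <- function(rel_permittivity = 80, conductivity = 0.03,
                      viscosity = 1.0e-3, temperature = 298.15) {
  stopifnot_scalar(rel_permittivity, "rel_permittivity")
  stopifnot_scalar(conductivity, "conductivity", nonneg = TRUE)
  stopifnot_scalar(viscosity, "viscosity", positive = TRUE)
  stopifnot_scalar(temperature, "temperature", positive = TRUE)
  if (rel_permittivity < 1)
    stop("rel_permittivity must be >= 1", call. = FALSE)
  structure(list(rel_permittivity = rel_permittivity,
                 conductivity = conductivity,
                 viscosity = viscosity,
                 temperature = temperature),
            class = "nt_medium")
}

#' @rdname nt_medium
#' @export
medium_water <- function() nt_medium(80, 0.03, 1.0e-3, 298.15)

#' @rdname nt_medium
#' @details `medium_di_water()` is the deionized-water bath used for
#'   bead trapping (conductivity ~1e-4 S/m).
#' @export
medium_di_water <- function() nt_medium(80, 1e-4, 1.0e-3, 298.15)

#' Polarizable dielectric particle, optionally single-shelled
#'
#' A homogeneous sphere, or a single-shell sphere (membrane-bounded
#' organelle model) when `shell` is supplied.
#'
#' @param radius outer radius in m.
#' @param rel_permittivity relative permittivity of the (core) material.
#' @param conductivity conductivity of the (core) material, S/m.
#' @param shell optional list with `thickness` (m), `rel_permittivity`,
#'   `conductivity` describing a thin outer shell (0 < thickness < radius).
#' @return an object of class `nt_body`.
#' @examples
#' body_ps_bead()
#' body_mitochondrion()
#' @export
nt_body <- function(radius, rel_permittivity, conductivity, shell = NULL) {
  stopifnot_scalar(radius, "radius", positive = TRUE)
  stopifnot_scalar(rel_permittivity, "rel_permittivity", positive = TRUE)
  stopifnot_scalar(conductivity, "conductivity", nonneg = TRUE)
  if (!is.null(shell)) {
    stopifnot_scalar(shell$thickness, "shell$thickness", positive = TRUE)
    if (shell$thickness >= radius)
      stop("shell thickness must be < radius", call. = FALSE)
    stopifnot_scalar(shell$rel_permittivity, "shell$rel_permittivity",
                     positive = TRUE)
    stopifnot_scalar(shell$conductivity, "shell$conductivity", nonneg = TRUE)
  }
  structure(list(radius = radius, rel_permittivity = rel_permittivity,
                 conductivity = conductivity, shell = shell),
            class = "nt_body")
}

#' @rdname nt_body
#' @param surface_conductance surface conductance Ks in S.  Sub-micron
#'   polystyrene beads carry an effective conductivity
#'   `sigma_eff = sigma_bulk + 2 Ks / radius`; with the default `Ks = 0`
#'   the bead is the bare dielectric sphere (eps 2.5, sigma 0), which is
#'   negative-DEP in water.  `Ks` around 1-2 nS makes 300-nm beads
#'   positive-DEP at 1 MHz in low-conductivity media, as observed when
#'   they are trapped at the tip.
#' @export
body_ps_bead <- function(radius = 0.15e-6, surface_conductance = 0)
  nt_body(radius, rel_permittivity = 2.5,
          conductivity = 2 * surface_conductance / radius)

#' @rdname nt_body
#' @param radius outer radius in m.
#' @details `body_mitochondrion()` is a single-shell sphere with
#'   literature-range organelle defaults: 0.5 um radius, an effective 5 nm
#'   membrane (eps 12, 1e-6 S/m) standing in for the double membrane,
#'   around a conductive interior (eps 60, 0.4 S/m).  These give a positive
#'   Clausius-Mossotti factor (~0.29) at the 1 MHz trapping drive in the
#'   0.03 S/m working medium, i.e. attraction to the tip.
#' @export
body_mitochondrion <- function(radius = 0.5e-6)
  nt_body(radius, rel_permittivity = 60, conductivity = 0.4,
          shell = list(thickness = 5e-9, rel_permittivity = 12,
                       conductivity = 1e-6))

#' AC drive applied between the nanoprobe electrodes
#'
#' @param voltage_pp peak-to-peak voltage in V (>= 0).
#' @param frequency frequency in Hz (> 0).
#' @param enabled logical; a disabled drive exerts no force.
#' @return an object of class `nt_drive`.
#' @export
nt_drive <- function(voltage_pp = 7, frequency = 1e6, enabled = TRUE) {
  stopifnot_scalar(voltage_pp, "voltage_pp", nonneg = TRUE)
  stopifnot_scalar(frequency, "frequency", positive = TRUE)
  structure(list(voltage_pp = voltage_pp, frequency = frequency,
                 enabled = isTRUE(enabled)),
            class = "nt_drive")
}

#' Analytic tip-field model
#'
#' One-parameter surrogate for the finite-element field of the real tip
#' geometry: the gradient of the squared rms field follows a point-dipole
#' power law `|grad E_rms^2| = G0 * Vpp^2 / (s + r0)^7` along the tip axis
#' (`s` = distance from apex surface, `r0` = effective apex radius).  G0 is
#' fixed by requiring that the reference body at contact under the
#' reference drive feels `force_calibration` newtons; see
#' [calibrate_tip()].
#'
#' @param tip_radius effective apex rounding r0 in m.
#' @param gap electrode separation in m (bookkeeping; the one-parameter
#'   power law does not use it).
#' @param force_calibration force on the reference body at contact under
#'   the reference drive, in N.
#' @param reference_drive an [nt_drive()].
#' @param reference_body an [nt_body()].
#' @param reference_medium an [nt_medium()] for evaluating the reference
#'   Clausius-Mossotti factor.
#' @return an object of class `nt_tip` (uncalibrated: `G0` is `NA` until
#'   [calibrate_tip()] runs).
#' @export
nt_tip <- function(tip_radius = 50e-9, gap = 100e-9,
                   force_calibration = 1.0e-9,
                   reference_drive = nt_drive(7, 1e6),
                   reference_body = body_mitochondrion(),
                   reference_medium = medium_water()) {
  stopifnot_scalar(tip_radius, "tip_radius", positive = TRUE)
  stopifnot_scalar(gap, "gap", positive = TRUE)
  stopifnot_scalar(force_calibration, "force_calibration", positive = TRUE)
  stopifnot(inherits(reference_drive, "nt_drive"),
            inherits(reference_body, "nt_body"),
            inherits(reference_medium, "nt_medium"))
  structure(list(tip_radius = tip_radius, gap = gap,
                 force_calibration = force_calibration,
                 reference_drive = reference_drive,
                 reference_body = reference_body,
                 reference_medium = reference_medium,
                 G0 = NA_real_),
            class = "nt_tip")
}

#' Complex relative permittivity at a given frequency
#'
#' `eps* = eps_r - j sigma / (2 pi f eps0)`, in relative (dimensionless)
#' units; the imaginary part is always <= 0 for passive materials.
#'
#' @param x an [nt_medium()] or [nt_body()] (core material for shelled
#'   bodies; use [clausius_mossotti()] for the shell-effective value).
#' @param frequency frequency in Hz (> 0).
#' @return a complex scalar.
#' @export
complex_permittivity <- function(x, frequency) {
  stopifnot_scalar(frequency, "frequency", positive = TRUE)
  complex(real = x$rel_permittivity,
          imaginary = -x$conductivity / (2 * pi * frequency * EPS0))
}

# Single-shell effective complex permittivity: outer radius a, core radius
# a - t, shell material eps_s*, core eps_i*.
shell_effective_permittivity <- function(body, frequency) {
  eps_i <- complex(real = body$rel_permittivity,
                   imaginary = -body$conductivity / (2 * pi * frequency * EPS0))
  if (is.null(body$shell)) return(eps_i)
  sh <- body$shell
  eps_s <- complex(real = sh$rel_permittivity,
                   imaginary = -sh$conductivity / (2 * pi * frequency * EPS0))
  g3 <- (body$radius / (body$radius - sh$thickness))^3
  k_is <- (eps_i - eps_s) / (eps_i + 2 * eps_s)
  eps_s * (g3 + 2 * k_is) / (g3 - k_is)
}

#' Clausius-Mossotti factor
#'
#' `K = (eps_p* - eps_m*) / (eps_p* + 2 eps_m*)` with the particle
#' permittivity replaced by the single-shell effective permittivity for
#' shelled bodies.  `Re[K]` lies in `[-0.5, 1]` for passive materials and
#' sets the DEP direction (positive: attraction toward high field).
#'
#' @param body an [nt_body()].
#' @param medium an [nt_medium()].
#' @param frequency frequency in Hz (> 0); may be a vector.
#' @return complex vector the length of `frequency`.
#' @examples
#' Re(clausius_mossotti(body_ps_bead(), medium_water(), 1e8))
#' @export
clausius_mossotti <- function(body, medium, frequency) {
  stopifnot(inherits(body, "nt_body"), inherits(medium, "nt_medium"))
  if (any(!is.finite(frequency)) || any(frequency <= 0))
    stop("frequency must be > 0", call. = FALSE)
  vapply(frequency, function(f) {
    eps_p <- shell_effective_permittivity(body, f)
    eps_m <- complex_permittivity(medium, f)
    den <- eps_p + 2 * eps_m
    if (Mod(den) == 0)
      stop("degenerate Clausius-Mossotti denominator", call. = FALSE)
    (eps_p - eps_m) / den
  }, complex(1))
}

#' Calibrate the tip-field model
#'
#' Solves for the geometry constant G0 such that the reference body at
#' contact (distance = body radius) under the reference drive feels exactly
#' `force_calibration`:
#' `G0 = Fc (a + r0)^7 / (2 pi eps0 eps_m a^3 Re[K] Vpp^2)`.
#'
#' @param tip an [nt_tip()].
#' @return the tip with `G0` filled in.
#' @export
calibrate_tip <- function(tip) {
  stopifnot(inherits(tip, "nt_tip"))
  body <- tip$reference_body
  drive <- tip$reference_drive
  reK <- Re(clausius_mossotti(body, tip$reference_medium, drive$frequency))
  if (reK <= 0)
    stop("reference configuration has Re[K] <= 0: cannot calibrate an attractive trap",
         call. = FALSE)
  a <- body$radius
  pref <- 2 * pi * EPS0 * tip$reference_medium$rel_permittivity * a^3 * reK
  tip$G0 <- tip$force_calibration * (a + tip$tip_radius)^7 /
    (pref * drive$voltage_pp^2)
  tip
}

is_calibrated <- function(tip) is.finite(tip$G0)

#' Gradient of the squared rms field along the tip axis
#'
#' @param tip a calibrated [nt_tip()].
#' @param drive an [nt_drive()].
#' @param distance distance(s) from the apex surface in m (>= 0).
#' @return `|grad E_rms^2|` in V^2/m^3, directed toward the apex.
#' @export
grad_E2 <- function(tip, drive, distance) {
  stopifnot(inherits(tip, "nt_tip"), inherits(drive, "nt_drive"))
  if (!is_calibrated(tip))
    stop("tip model is uncalibrated; run calibrate_tip() first", call. = FALSE)
  if (any(distance < 0)) stop("distance must be >= 0", call. = FALSE)
  tip$G0 * drive$voltage_pp^2 / (distance + tip$tip_radius)^7
}

# E_rms^2 consistent with grad_E2 (integral of the power law to infinity)
field_E2 <- function(tip, drive, distance) {
  tip$G0 * drive$voltage_pp^2 / (6 * (distance + tip$tip_radius)^6)
}

#' Time-averaged DEP force on a particle
#'
#' Point-dipole law `F = 2 pi eps0 eps_m a^3 Re[K] grad|E_rms|^2`, signed
#' along the tip axis: negative values point toward the tip (attraction
#' when `Re[K] > 0`).
#'
#' @param body,medium,tip,drive model components; `tip` must be calibrated.
#' @param distance distance(s) from the apex surface in m.
#' @return signed force in N (vector over `distance`).  If the drive is
#'   disabled, returns 0 with attribute `drive_off = TRUE` and a warning.
#' @export
dep_force <- function(body, medium, tip, drive, distance) {
  if (!drive$enabled) {
    warning("drive disabled: DEP force is zero")
    return(structure(rep(0, length(distance)), drive_off = TRUE))
  }
  reK <- Re(clausius_mossotti(body, medium, drive$frequency))
  pref <- 2 * pi * EPS0 * medium$rel_permittivity * body$radius^3 * reK
  -pref * grad_E2(tip, drive, distance)
}

#' Time-averaged DEP interaction energy
#'
#' `U = -2 pi eps0 eps_m a^3 Re[K] E_rms^2` with `E_rms^2` the integral of
#' the calibrated power-law gradient, so that `force = -dU/d(distance)`
#' holds identically and `U -> 0` as `distance -> Inf`.
#'
#' @inheritParams dep_force
#' @return potential energy in J (vector over `distance`).
#' @export
dep_potential <- function(body, medium, tip, drive, distance) {
  if (!drive$enabled) {
    warning("drive disabled: DEP potential is zero")
    return(structure(rep(0, length(distance)), drive_off = TRUE))
  }
  reK <- Re(clausius_mossotti(body, medium, drive$frequency))
  pref <- 2 * pi * EPS0 * medium$rel_permittivity * body$radius^3 * reK
  -pref * field_E2(tip, drive, distance)
}

#' Thermal trapping radius
#'
#' Distance `s*` from the apex at which the magnitude of the DEP
#' interaction energy equals `threshold_kT` thermal units, i.e. the edge of
#' the region where the trap dominates Brownian motion.  Closed form from
#' the power law: `s* = (C / (threshold_kT kB T))^(1/6) - r0` with
#' `C = 2 pi eps0 eps_m a^3 Re[K] G0 Vpp^2 / 6`.
#'
#' @inheritParams dep_force
#' @param threshold_kT energy threshold in units of kB*T (default 1).
#' @return radius in m; 0 with attribute `repulsive = TRUE` if `Re[K] <= 0`.
#' @export
trapping_radius <- function(body, medium, tip, drive, threshold_kT = 1) {
  stopifnot_scalar(threshold_kT, "threshold_kT", positive = TRUE)
  if (!is_calibrated(tip))
    stop("tip model is uncalibrated; run calibrate_tip() first", call. = FALSE)
  reK <- Re(clausius_mossotti(body, medium, drive$frequency))
  if (reK <= 0 || !drive$enabled || drive$voltage_pp == 0)
    return(structure(0, repulsive = TRUE))
  C <- 2 * pi * EPS0 * medium$rel_permittivity * body$radius^3 * reK *
    tip$G0 * drive$voltage_pp^2 / 6
  s <- (C / (threshold_kT * KB * medium$temperature))^(1 / 6) - tip$tip_radius
  max(s, 0)
}
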