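# Overdamped Brownian dynamics of particle capture, release and transport
# at the nanoprobe tip.  The apex sits at the origin; particle positions are
# centre coordinates in metres, so the radial coordinate r = |x| is exactly
# the `distance` argument of dep_force()/dep_potential().

#' Particle ensemble for Brownian-dynamics simulation
#'
#' @param positions n x 3 numeric matrix of particle centres in m, apex at
#'   the origin.
#' @param body an [nt_body()] shared by all particles (monodisperse).
#' @param trapped logical vector (default all FALSE); trapped particles are
#'   pinned to the probe and co-move with it.
#' @return an object of class `nt_ensemble`.
#' @export
nt_ensemble <- function(positions, body, trapped = NULL) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  if (any(!is.finite(positions))) stop("positions must be finite", call. = FALSE)
  stopifnot(inherits(body, "nt_body"))
  if (is.null(trapped)) trapped <- rep(FALSE, nrow(positions))
  stopifnot(length(trapped) == nrow(positions))
  structure(list(positions = positions, body = body,
                 trapped = as.logical(trapped)),
            class = "nt_ensemble")
}

#' Loaded cluster of trapped particles at the apex
#'
#' Places `n` particles already stuck to the tip in a close-packed radial
#' arrangement (particle k at radial distance `a * max(1, (k/0.64)^(1/3))`,
#' random directions), the initial condition for release and translation
#' runs.
#'
#' @param n number of particles.
#' @param body an [nt_body()].
#' @param seed integer seed for the random directions.
#' @return an `nt_ensemble` with all particles trapped.
#' @export
loaded_cluster <- function(n, body, seed = 1) {
  a <- body$radius
  with_seed(seed, {
    u <- matrix(stats::rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    r <- a * pmax(1, (seq_len(n) / 0.64)^(1 / 3))
    nt_ensemble(u * r, body, trapped = rep(TRUE, n))
  })
}

#' Brownian-dynamics configuration
#'
#' @param dt time step in s (default 10 us; halved automatically until the
#'   deterministic drift at the trap-region boundary is below a/5).
#' @param n_steps number of steps.
#' @param seed integer RNG seed.
#' @param box_half_width reflecting cubic box half-width in m.
#' @param contact_sticking if TRUE and the drive is on, particles reaching
#'   contact (r <= a) become trapped and co-move with the probe.
#' @param probe_velocity probe translation speed along +x in m/s.
#' @param trap_region_radius radius of the counting region around the apex
#'   in m (default the 1.8 um trapping region).
#' @param record_every record the in-trap count every this many steps.
#' @return an object of class `nt_bdconfig`.
#' @export
nt_bdconfig <- function(dt = 1e-5, n_steps = 1000L, seed = 1L,
                        box_half_width = 10e-6, contact_sticking = TRUE,
                        probe_velocity = 0, trap_region_radius = 1.8e-6,
                        record_every = 100L) {
  stopifnot_scalar(dt, "dt", positive = TRUE)
  if (n_steps < 1) stop("n_steps must be >= 1", call. = FALSE)
  stopifnot_scalar(box_half_width, "box_half_width", positive = TRUE)
  stopifnot_scalar(trap_region_radius, "trap_region_radius", positive = TRUE)
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 seed = as.integer(seed),
                 box_half_width = box_half_width,
                 contact_sticking = isTRUE(contact_sticking),
                 probe_velocity = probe_velocity,
                 trap_region_radius = trap_region_radius,
                 record_every = as.integer(record_every)),
            class = "nt_bdconfig")
}

# Deterministic drift per step at the trap boundary must stay below a/5;
# halve dt until it does (returns the possibly-modified config).
ensure_dt_stable <- function(config, body, medium, tip, drive) {
  if (is.null(tip) || !drive$enabled || drive$voltage_pp == 0) return(config)
  a <- body$radius
  gamma <- 6 * pi * medium$viscosity * a
  f <- abs(dep_force(body, medium, tip, drive, config$trap_region_radius))
  halvings <- 0L
  while (f / gamma * config$dt > a / 5) {
    config$dt <- config$dt / 2
    config$n_steps <- config$n_steps * 2L
    config$record_every <- config$record_every * 2L
    halvings <- halvings + 1L
    if (halvings > 30L)
      stop("dt stability cannot be reached: drift at the trap boundary exceeds a/5",
           call. = FALSE)
  }
  config
}

# One vectorized Euler-Maruyama update over all particles; called inside
# the run_* loops with RNG state managed by the caller.
bd_step <- function(pos, trapped, a, gamma, sqrt2Ddt, dt, pref, r0, box,
                    sticking, probe_dx) {
  free <- !trapped
  if (any(free)) {
    p <- pos[free, , drop = FALSE]
    r <- sqrt(rowSums(p^2))
    r <- pmax(r, a)            # never inside the apex
    if (pref != 0) {
      # signed force is -pref/(r+r0)^7 (toward apex for pref > 0)
      fmag <- pref / (r + r0)^7
      drift <- fmag / gamma * dt
      drift <- pmin(drift, a / 5)          # drift cap inside the near field
      p <- p - p / r * drift
    }
    p <- p + matrix(stats::rnorm(length(p)), ncol = 3) * sqrt2Ddt
    # reflect at the box walls
    p[p > box] <- 2 * box - p[p > box]
    p[p < -box] <- -2 * box - p[p < -box]
    # probe surface: reflect or stick at contact (r = a)
    r2 <- sqrt(rowSums(p^2))
    hit <- r2 < a
    if (any(hit)) {
      if (sticking) {
        scl <- a / r2[hit]
        p[hit, ] <- p[hit, , drop = FALSE] * scl
        tf <- which(free)[hit]
        trapped[tf] <- TRUE
      } else {
        scl <- (2 * a - r2[hit]) / r2[hit]
        p[hit, ] <- p[hit, , drop = FALSE] * scl
      }
    }
    pos[free, ] <- p
  }
  if (probe_dx != 0) {
    # probe frame: the probe advances; free particles recede relative to it
    pos[!trapped, 1] <- pos[!trapped, 1] - probe_dx
  }
  list(pos = pos, trapped = trapped)
}

#' Advance an ensemble by Euler-Maruyama steps
#'
#' Overdamped update `x += (F_dep/gamma) dt + sqrt(2 D dt) xi` with
#' `gamma = 6 pi eta a`, `D = kB T / gamma`, reflecting walls at the box
#' boundary and at the probe apex, and contact sticking when enabled.
#' RNG state is taken from `config$seed`.
#'
#' @param ensemble an [nt_ensemble()].
#' @param medium an [nt_medium()].
#' @param tip calibrated [nt_tip()] (may be NULL when the drive is off).
#' @param drive an [nt_drive()].
#' @param config an [nt_bdconfig()]; `config$n_steps` steps are taken.
#' @return the updated ensemble.
#' @export
step_brownian <- function(ensemble, medium, tip, drive, config) {
  res <- run_trapping(ensemble, medium, tip, drive, config)
  res$ensemble
}

#' Simulate DEP capture and cluster accumulation
#'
#' Runs the Brownian dynamics and records the number of particles inside
#' the trap region (the trapped count when sticking is active and the
#' drive is on, else the occupancy of the counting sphere) at a fixed
#' cadence.
#'
#' @inheritParams step_brownian
#' @return an object of class `nt_trapsim`: list with `time` (s), `count`
#'   (in-trap count per record), `cluster_size_final`, `retained_fraction`,
#'   `ensemble` (final state), `config`.
#' @export
run_trapping <- function(ensemble, medium, tip, drive, config) {
  stopifnot(inherits(ensemble, "nt_ensemble"), inherits(config, "nt_bdconfig"))
  body <- ensemble$body
  a <- body$radius
  use_force <- drive$enabled && drive$voltage_pp > 0 && !is.null(tip)
  if (use_force && !is_calibrated(tip))
    stop("tip model is uncalibrated; run calibrate_tip() first", call. = FALSE)
  config <- ensure_dt_stable(config, body, medium, tip, drive)
  gamma <- 6 * pi * medium$viscosity * a
  D <- KB * medium$temperature / gamma
  sqrt2Ddt <- sqrt(2 * D * config$dt)
  pref <- if (use_force) {
    reK <- Re(clausius_mossotti(body, medium, drive$frequency))
    2 * pi * EPS0 * medium$rel_permittivity * a^3 * reK * tip$G0 *
      drive$voltage_pp^2
  } else 0
  sticking <- config$contact_sticking && use_force
  probe_dx <- config$probe_velocity * config$dt
  pos <- ensemble$positions
  trapped <- ensemble$trapped
  n_rec <- max(1L, config$n_steps %/% config$record_every)
  count <- integer(n_rec)
  tvec <- numeric(n_rec)
  with_seed(config$seed, {
    k <- 0L
    for (i in seq_len(config$n_steps)) {
      st <- bd_step(pos, trapped, a, gamma, sqrt2Ddt, config$dt, pref,
                    tip$tip_radius %||% 0, config$box_half_width,
                    sticking, probe_dx)
      pos <- st$pos; trapped <- st$trapped
      if (i %% config$record_every == 0L) {
        k <- k + 1L
        tvec[k] <- i * config$dt
        count[k] <- if (sticking) sum(trapped)
                    else sum(rowSums(pos^2) <= config$trap_region_radius^2)
      }
    }
  })
  out <- nt_ensemble(pos, body, trapped)
  n <- nrow(pos)
  structure(list(time = tvec[seq_len(max(k, 0L))],
                 count = count[seq_len(max(k, 0L))],
                 cluster_size_final = sum(trapped),
                 dispersal_time = NA_real_,
                 retained_fraction = if (n > 0) sum(trapped) / n else NA_real_,
                 ensemble = out, config = config),
            class = "nt_trapsim")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate cluster release after switching the drive off
#'
#' Pure diffusion of an initially trapped cluster; the dispersal time is
#' the first time fewer than `disperse_frac` (default 10%) of the initially
#' trapped particles remain inside the trap region.
#'
#' @inheritParams step_brownian
#' @param disperse_frac dispersal threshold as a fraction of the initial
#'   cluster size.
#' @return an `nt_trapsim` whose `dispersal_time` is in s (NA if the
#'   cluster never disperses within the simulated window).
#' @export
run_release <- function(ensemble, medium, tip, config, disperse_frac = 0.1) {
  stopifnot(inherits(ensemble, "nt_ensemble"), inherits(config, "nt_bdconfig"))
  body <- ensemble$body
  a <- body$radius
  n0 <- sum(ensemble$trapped)
  if (n0 == 0) n0 <- nrow(ensemble$positions)
  gamma <- 6 * pi * medium$viscosity * a
  D <- KB * medium$temperature / gamma
  sqrt2Ddt <- sqrt(2 * D * config$dt)
  pos <- ensemble$positions
  trapped <- rep(FALSE, nrow(pos))   # drive off: everything is released
  r2max <- config$trap_region_radius^2
  n_rec <- max(1L, config$n_steps %/% config$record_every)
  count <- integer(n_rec); tvec <- numeric(n_rec)
  dispersal <- NA_real_
  with_seed(config$seed, {
    k <- 0L
    for (i in seq_len(config$n_steps)) {
      st <- bd_step(pos, trapped, a, gamma, sqrt2Ddt, config$dt, 0,
                    0, config$box_half_width, FALSE, 0)
      pos <- st$pos
      inside <- sum(rowSums(pos^2) <= r2max)
      if (is.na(dispersal) && inside < disperse_frac * n0)
        dispersal <- i * config$dt
      if (i %% config$record_every == 0L) {
        k <- k + 1L
        tvec[k] <- i * config$dt
        count[k] <- inside
      }
      if (!is.na(dispersal) && i %% config$record_every == 0L) break
    }
  })
  keep <- which(tvec > 0)
  structure(list(time = tvec[keep], count = count[keep],
                 cluster_size_final = 0L,
                 dispersal_time = dispersal,
                 retained_fraction = 0,
                 ensemble = nt_ensemble(pos, body, rep(FALSE, nrow(pos))),
                 config = config),
            class = "nt_trapsim")
}

#' Retention of a trapped cluster during probe translation
#'
#' Quasi-static drag-balance criterion: a trapped particle held at radial
#' distance r is shed when the Stokes drag `6 pi eta a v` of the imposed
#' speed exceeds the local DEP restoring force `|F(r)|`.
#'
#' @inheritParams step_brownian
#' @param speed translation speed in m/s.
#' @param distance translated distance in m (recorded; the quasi-static
#'   criterion is independent of it).
#' @return retained fraction in `[0, 1]`.
#' @export
run_translation <- function(ensemble, medium, tip, drive, speed,
                            distance = 50e-6) {
  stopifnot(inherits(ensemble, "nt_ensemble"))
  stopifnot_scalar(speed, "speed", nonneg = TRUE)
  if (speed == 0) return(1)
  body <- ensemble$body
  idx <- which(ensemble$trapped)
  if (length(idx) == 0) return(NA_real_)
  r <- sqrt(rowSums(ensemble$positions[idx, , drop = FALSE]^2))
  r <- pmax(r, body$radius)
  fhold <- abs(dep_force(body, medium, tip, drive, r))
  drag <- 6 * pi * medium$viscosity * body$radius * speed
  mean(fhold >= drag)
}

#' Biopsy success surface over voltage and dwell time
#'
#' Semi-analytic Monte-Carlo surface: organelles are scattered around the
#' tip; each is captured within the dwell with the diffusion-to-absorbing-
#' sphere probability `p = (R/r) erfc((r - R) / sqrt(4 D t))` where R is
#' the voltage-dependent trapping radius, and a captured organelle is
#' retained through a standard retraction if the drag at the retraction
#' speed does not exceed the holding force at contact.  Success = at least
#' one organelle captured and retained.
#'
#' @param medium,tip,body model components (`tip` calibrated).
#' @param voltages vector of peak-to-peak voltages in V.
#' @param dwells vector of dwell times in s.
#' @param n_rep Monte-Carlo repetitions per grid point.
#' @param seed integer seed.
#' @param n_particles organelles scattered per repetition.
#' @param frequency drive frequency in Hz.
#' @param retraction_speed standard retraction speed in m/s.
#' @param scatter_radius radius of the scatter shell around the tip in m.
#' @return matrix `length(voltages) x length(dwells)` of success
#'   probabilities, dimnames set to the axis values.
#' @export
success_surface <- function(medium, tip, body, voltages, dwells,
                            n_rep = 50L, seed = 1L, n_particles = 8L,
                            frequency = 1e6,
                            retraction_speed = 200e-6,
                            scatter_radius = 8e-6) {
  stopifnot(length(voltages) >= 1, length(dwells) >= 1)
  a <- body$radius
  gamma <- 6 * pi * medium$viscosity * a
  D <- KB * medium$temperature / gamma
  drag <- gamma * retraction_speed
  out <- matrix(NA_real_, length(voltages), length(dwells),
                dimnames = list(voltage = voltages, dwell = dwells))
  with_seed(seed, {
    for (vi in seq_along(voltages)) {
      V <- voltages[vi]
      drv <- nt_drive(V, frequency, enabled = V > 0)
      R <- if (V > 0) trapping_radius(body, medium, tip, drv) else 0
      fhold <- if (V > 0) abs(dep_force(body, medium, tip, drv, a)) else 0
      retained <- fhold >= drag
      for (di in seq_along(dwells)) {
        tt <- dwells[di]
        succ <- 0L
        for (rep in seq_len(n_rep)) {
          r <- a + (scatter_radius - a) * stats::runif(n_particles)
          p <- if (R <= 0) rep(0, n_particles) else {
            pc <- (pmin(R, r) / r) *
              ifelse(r <= R, 1,
                     2 * stats::pnorm(-(r - R) / sqrt(2 * D * tt)))
            pmin(pc, 1)
          }
          captured <- stats::runif(n_particles) < p
          if (retained && any(captured)) succ <- succ + 1L
        }
        out[vi, di] <- succ / n_rep
      }
    }
  })
  out
}
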