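test_that("frozen dynamics: enormous viscosity leaves positions in place", {
  bead <- body_ps_bead()
  med <- nt_medium(80, 1e-4, viscosity = 1e9, temperature = 298)
  pos0 <- matrix(rep(c(2e-6, 0, 0), each = 5), 5, 3)
  ens <- nt_ensemble(pos0, bead)
  cfg <- nt_bdconfig(dt = 1e-4, n_steps = 200L, seed = 1,
                     contact_sticking = FALSE)
  out <- step_brownian(ens, med, NULL, nt_drive(0, 1e6, FALSE), cfg)
  expect_lt(max(abs(out$positions - pos0)), 1e-9)
})

test_that("drive-off ensemble diffusion satisfies the Einstein relation", {
  bead <- body_ps_bead()
  med <- water_298()
  a <- bead$radius
  D <- 1.380649e-23 * 298 / (6 * pi * med$viscosity * a)
  start <- matrix(rep(c(50e-6, 50e-6, 50e-6), each = 400), 400, 3)
  ens <- nt_ensemble(start, bead)
  cfg <- nt_bdconfig(dt = 1e-4, n_steps = 1000L, seed = 11,
                     box_half_width = 1e-3, contact_sticking = FALSE)
  out <- step_brownian(ens, med, NULL, nt_drive(0, 1e6, FALSE), cfg)
  msd <- mean(rowSums((out$positions - start)^2))
  expect_equal(msd / (6 * D * 0.1), 1, tolerance = 0.1)
})

test_that("seeded runs are bit-reproducible and conserve particles", {
  s <- default_setup()
  bead <- body_ps_bead(surface_conductance = 2e-9)
  med <- medium_di_water()
  set.seed(3)
  pos <- matrix(runif(60, -4e-6, 4e-6), 20, 3)
  ens <- nt_ensemble(pos, bead)
  cfg <- nt_bdconfig(dt = 1e-5, n_steps = 500L, seed = 9, record_every = 50L)
  r1 <- run_trapping(ens, med, s$tip, s$drive, cfg)
  r2 <- run_trapping(ens, med, s$tip, s$drive, cfg)
  expect_identical(r1$ensemble$positions, r2$ensemble$positions)
  expect_identical(r1$count, r2$count)
  expect_equal(nrow(r1$ensemble$positions), 20)
  expect_true(all(is.finite(r1$ensemble$positions)))
  expect_true(all(r1$count >= 0 & r1$count <= 20))
})

test_that("sticking accumulation is nondecreasing and beats drive-off", {
  s <- default_setup()
  bead <- body_ps_bead(surface_conductance = 2e-9)
  med <- medium_di_water()
  mk <- function(seed, n = 30) {
    set.seed(seed)
    nt_ensemble(matrix(runif(3 * n, -3e-6, 3e-6), n, 3), bead)
  }
  cfg <- nt_bdconfig(dt = 1e-5, n_steps = 20000L, seed = 5,
                     box_half_width = 5e-6, record_every = 1000L)
  r_on <- run_trapping(mk(5), med, s$tip, s$drive, cfg)
  expect_true(all(diff(r_on$count) >= 0))
  expect_gt(r_on$cluster_size_final, 0)
  # paired seeds, sign test: trap-on occupancy beats pure diffusion
  wins <- 0L; ties <- 0L
  for (seed in 1:20) {
    cfg_i <- nt_bdconfig(dt = 2e-5, n_steps = 8000L, seed = seed,
                         box_half_width = 5e-6, record_every = 8000L,
                         contact_sticking = FALSE)
    on <- run_trapping(mk(seed, 15), med, s$tip, s$drive, cfg_i)
    off <- run_trapping(mk(seed, 15), med, s$tip,
                        nt_drive(0, 1e6, FALSE), cfg_i)
    wins <- wins + (tail(on$count, 1) > tail(off$count, 1))
    ties <- ties + (tail(on$count, 1) == tail(off$count, 1))
  }
  # >= 16/20 wins is a p < 0.01 one-sided sign test
  expect_gte(wins, 16)
})

test_that("release: no diffusion never disperses; dispersal scales with 1/D", {
  bead <- body_ps_bead()
  frozen <- nt_medium(80, 1e-4, viscosity = 1e9, temperature = 298)
  ens <- contact_cluster(20, bead, seed = 2)
  cfg <- nt_bdconfig(dt = 1e-4, n_steps = 2000L, seed = 2)
  r <- run_release(ens, frozen, NULL, cfg)
  expect_true(is.na(r$dispersal_time))
  # doubling viscosity roughly doubles the dispersal time; paired seeds
  # at the half-dispersal point, where the count crossing is steep and
  # the diffusive time scaling is read off with little noise
  t1 <- t2 <- numeric(10)
  for (k in 1:10) {
    cfg_k <- nt_bdconfig(dt = 2e-4, n_steps = 30000L, seed = 20 + k,
                         record_every = 3000L)
    m1 <- water_298()
    m2 <- nt_medium(80, 1e-4, 2 * m1$viscosity, 298)
    t1[k] <- run_release(contact_cluster(20, bead, k), m1, NULL,
                         cfg_k, disperse_frac = 0.5)$dispersal_time
    t2[k] <- run_release(contact_cluster(20, bead, k), m2, NULL,
                         cfg_k, disperse_frac = 0.5)$dispersal_time
  }
  expect_equal(median(t2 / t1), 2, tolerance = 0.3)
})

test_that("translation retention: trivial, monotone and drag-balance exact", {
  s <- default_setup()
  med <- s$medium
  ens <- loaded_cluster(20, s$body, seed = 4)
  expect_equal(run_translation(ens, med, s$tip, s$drive, 0), 1)
  grid <- seq(0.05e-3, 4e-3, length.out = 12)
  rf <- vapply(grid, function(v)
    run_translation(ens, med, s$tip, s$drive, v), numeric(1))
  expect_true(all(diff(rf) <= 0))
  # closed-form drag balance for one particle held at contact
  single <- nt_ensemble(matrix(c(s$body$radius, 0, 0), 1, 3), s$body,
                        trapped = TRUE)
  fhold <- abs(dep_force(s$body, med, s$tip, s$drive, s$body$radius))
  vstar <- fhold / (6 * pi * med$viscosity * s$body$radius)
  expect_equal(run_translation(single, med, s$tip, s$drive, 0.999 * vstar), 1)
  expect_equal(run_translation(single, med, s$tip, s$drive, 1.001 * vstar), 0)
})

test_that("success surface is monotone in voltage and dwell", {
  s <- default_setup()
  surf <- success_surface(s$medium, s$tip, s$body,
                          voltages = c(0, 2, 4, 7), dwells = c(1, 10, 60),
                          n_rep = 40L, seed = 31L, n_particles = 6L)
  expect_equal(dim(surf), c(4L, 3L))
  expect_true(all(surf >= 0 & surf <= 1))
  # no trap at 0 V
  expect_equal(unname(surf[1, ]), rep(0, 3))
  # stochastically monotone along both axes (small MC slack)
  expect_true(all(apply(surf, 2, diff) >= -0.15))
  expect_true(all(apply(surf, 1, diff) >= -0.15))
  # a particle already inside the trap with a long dwell is always caught
  R <- trapping_radius(s$body, s$medium, s$tip, s$drive)
  surf1 <- success_surface(s$medium, s$tip, s$body, voltages = 7,
                           dwells = 1e6, n_rep = 50L, seed = 8L,
                           n_particles = 1L, scatter_radius = 0.9 * R)
  expect_equal(as.numeric(surf1), 1)
})

test_that("dt stability guard halves the step or errors out", {
  s <- default_setup()
  # a drive strong enough that the boundary drift violates a/5 at dt = 1 s
  ens <- nt_ensemble(matrix(c(3e-6, 0, 0), 1, 3), s$body)
  cfg <- nt_bdconfig(dt = 1, n_steps = 2L, seed = 1, record_every = 1L)
  r <- run_trapping(ens, s$medium, s$tip, s$drive, cfg)
  expect_lt(r$config$dt, 1)
})
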