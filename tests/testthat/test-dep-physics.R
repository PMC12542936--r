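test_that("complex permittivity follows eps - j sigma/(omega eps0)", {
  eps0 <- 8.8541878128e-12
  m0 <- nt_medium(80, 0)
  expect_equal(complex_permittivity(m0, 1e6), complex(real = 80))
  m <- nt_medium(80, 0.03)
  # closed-form arithmetic oracle
  expect_equal(Im(complex_permittivity(m, 1e6)),
               -0.03 / (2 * pi * 1e6 * eps0), tolerance = 1e-12)
  expect_lt(abs(Im(complex_permittivity(m, 1e6)) + 539.26), 0.5)
  # high-frequency limit
  expect_lt(abs(Im(complex_permittivity(m, 1e15))), 1e-6)
  expect_error(complex_permittivity(m, 0), "frequency")
})

test_that("Clausius-Mossotti factor: closed-form cases and bounds", {
  med <- nt_medium(80, 0.01)
  # index-matched body
  same <- nt_body(1e-6, 80, 0.01)
  expect_equal(Mod(clausius_mossotti(same, med, 1e6)), 0, tolerance = 1e-15)
  # PS bead in conductivity-free water at 100 MHz: (2.5-80)/(2.5+160)
  k <- clausius_mossotti(body_ps_bead(), nt_medium(80, 0), 1e8)
  expect_equal(Re(k), -77.5 / 162.5, tolerance = 1e-6)
  # default mitochondrion is positive-DEP at the 1 MHz trapping drive
  expect_gt(Re(clausius_mossotti(body_mitochondrion(), medium_water(), 1e6)),
            0)
})

test_that("Re[K] stays in [-0.5, 1] over 1e2..1e10 Hz for random media", {
  set.seed(42)
  freqs <- 10^seq(2, 10, length.out = 9)
  for (i in 1:120) {
    body <- nt_body(runif(1, 0.05e-6, 2e-6),
                    runif(1, 2, 100), runif(1, 0, 2),
                    shell = if (runif(1) < 0.5)
                      list(thickness = runif(1, 2e-9, 20e-9),
                           rel_permittivity = runif(1, 2, 20),
                           conductivity = runif(1, 0, 1e-4)) else NULL)
    med <- nt_medium(runif(1, 2, 100), runif(1, 0, 2))
    reK <- Re(clausius_mossotti(body, med, freqs))
    expect_true(all(reK >= -0.5 - 1e-12 & reK <= 1 + 1e-12))
  }
})

test_that("single-shell model converges to the homogeneous sphere", {
  med <- medium_water()
  core <- nt_body(0.5e-6, 60, 0.4)
  thin <- nt_body(0.5e-6, 60, 0.4,
                  shell = list(thickness = 1e-21, rel_permittivity = 8,
                               conductivity = 1e-6))
  samecoat <- nt_body(0.5e-6, 60, 0.4,
                      shell = list(thickness = 50e-9, rel_permittivity = 60,
                                   conductivity = 0.4))
  for (f in c(1e4, 1e6, 1e8)) {
    k0 <- clausius_mossotti(core, med, f)
    expect_lt(Mod(clausius_mossotti(thin, med, f) - k0), 1e-9)
    expect_lt(Mod(clausius_mossotti(samecoat, med, f) - k0), 1e-9)
  }
})

test_that("tip field model: power law, calibration and V^2 scaling", {
  s <- default_setup()
  tip <- s$tip
  # uncalibrated model is a state error
  expect_error(grad_E2(nt_tip(), s$drive, 1e-6), "uncalibrated")
  # V^2 by construction
  expect_equal(grad_E2(tip, nt_drive(14, 1e6), 1e-6) /
               grad_E2(tip, nt_drive(7, 1e6), 1e-6), 4)
  # strictly decreasing in distance
  g <- grad_E2(tip, s$drive, seq(0, 5e-6, length.out = 50))
  expect_true(all(diff(g) < 0))
  # power-law arithmetic: distance 9 r0 vs 0 -> 1e-7
  r0 <- tip$tip_radius
  expect_equal(grad_E2(tip, s$drive, 9 * r0) / grad_E2(tip, s$drive, 0),
               1e-7, tolerance = 1e-12)
  # calibration anchor: reference body at contact feels exactly 1 nN
  f <- dep_force(s$body, s$medium, tip, s$drive, s$body$radius)
  expect_equal(abs(f), 1.0e-9, tolerance = 1e-12)
  expect_lt(f, 0)   # attractive: toward the tip
  # 7 V vs 3.5 V force ratio is exactly 4
  expect_equal(dep_force(s$body, s$medium, tip, nt_drive(7, 1e6), 1e-6) /
               dep_force(s$body, s$medium, tip, nt_drive(3.5, 1e6), 1e-6), 4)
  # scaling the calibration force scales G0 linearly
  tip2 <- calibrate_tip(nt_tip(force_calibration = 2e-9))
  expect_equal(tip2$G0 / tip$G0, 2, tolerance = 1e-12)
  # index-matched body feels nothing
  same <- nt_body(0.5e-6, s$medium$rel_permittivity, s$medium$conductivity)
  expect_equal(dep_force(same, s$medium, tip, s$drive, 1e-6), 0)
  # disabled drive: zero force with a warning
  expect_warning(f0 <- dep_force(s$body, s$medium, tip,
                                 nt_drive(7, 1e6, enabled = FALSE), 1e-6),
                 "disabled")
  expect_equal(as.numeric(f0), 0)
})

test_that("force equals -dU/ds within 1e-6 relative (finite differences)", {
  set.seed(7)
  for (i in 1:100) {
    med <- nt_medium(runif(1, 40, 90), runif(1, 0, 0.1))
    body <- nt_body(runif(1, 0.1e-6, 1e-6), runif(1, 2, 80), runif(1, 0, 1))
    tip <- calibrate_tip(nt_tip(tip_radius = runif(1, 20e-9, 200e-9)))
    drive <- nt_drive(runif(1, 1, 10), 10^runif(1, 4, 8))
    sdist <- runif(1, 0.2e-6, 4e-6)
    h <- 1e-4 * (sdist + tip$tip_radius)
    fd <- -(dep_potential(body, med, tip, drive, sdist + h) -
            dep_potential(body, med, tip, drive, sdist - h)) / (2 * h)
    f <- dep_force(body, med, tip, drive, sdist)
    expect_lt(abs(fd - f) / abs(f), 1e-6)
  }
})

test_that("potential vanishes at infinity and matches the contact formula", {
  s <- default_setup()
  expect_lt(abs(dep_potential(s$body, s$medium, s$tip, s$drive, 1)), 1e-30)
  # |U(contact)| = Fc (a + r0) / 6, from the power law
  u <- dep_potential(s$body, s$medium, s$tip, s$drive, s$body$radius)
  expect_equal(abs(u), 1.0e-9 * (s$body$radius + s$tip$tip_radius) / 6,
               tolerance = 1e-12)
  # ~1e4-1e5 kT at room temperature
  kT <- 1.380649e-23 * s$medium$temperature
  expect_gt(abs(u) / kT, 1e4)
  expect_lt(abs(u) / kT, 1e6)
})

test_that("trapping radius: limits, voltage scaling, magnitude", {
  s <- default_setup()
  r1 <- trapping_radius(s$body, s$medium, s$tip, s$drive)
  # order of magnitude of the ~1.8 um trapping region
  expect_gt(r1, 0.5e-6)
  expect_lt(r1, 5e-6)
  # larger energy threshold shrinks the region toward zero
  r_hi <- trapping_radius(s$body, s$medium, s$tip, s$drive,
                          threshold_kT = 1e6)
  expect_lt(r_hi, r1 / 5)
  # doubling the voltage grows (s* + r0) by 4^(1/6)
  r2 <- trapping_radius(s$body, s$medium, s$tip, nt_drive(14, 1e6))
  r0 <- s$tip$tip_radius
  expect_equal((r2 + r0) / (r1 + r0), 4^(1 / 6), tolerance = 1e-9)
  # monotone in voltage
  rr <- vapply(c(1, 3, 5, 7),
               function(v) trapping_radius(s$body, s$medium, s$tip,
                                           nt_drive(v, 1e6)), numeric(1))
  expect_true(all(diff(rr) > 0))
  # repulsive configuration flags zero
  bead <- body_ps_bead()        # negative DEP in the working medium
  rneg <- trapping_radius(bead, s$medium, s$tip, s$drive)
  expect_equal(as.numeric(rneg), 0)
  expect_true(attr(rneg, "repulsive"))
})
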