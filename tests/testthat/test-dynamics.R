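# a small random mixed system used by the force checks
small_system <- function(seed = 8, kappa = 0, confine = NULL) {
  set.seed(seed)
  gs <- generate_random_string(8, c("red", "green"), 0.4, seed = seed)
  sps <- list(
    factor_species("red", 3, switch_off_rate = 0, switch_on_rate = 0),
    factor_species("green", 2, nonspecific_affinity_kT = 0.5,
                   switch_off_rate = 0, switch_on_rate = 0))
  ff <- force_field(bending_rigidity_kT = kappa,
                    confinement_radius_nm = confine)
  fr <- initial_conformation(gs, sps, ff)
  # nudge particles so several pairs sit inside wells and cores
  fr$factor_positions <- fr$bead_positions[c(1, 3, 5, 2, 7), ] +
    matrix(rnorm(15, sd = 15), 5, 3)
  list(gs = gs, sps = sps, ff = ff, fr = fr)
}

test_that("two bonded beads at rest length feel zero net force", {
  gs <- generate_random_string(2, "red", 0, seed = 1)
  fr <- bridgesim:::new_frame(0, rbind(c(0, 0, 0), c(30, 0, 0)),
                              matrix(0, 0, 3), character(0), logical(0))
  F <- compute_forces(fr, gs, list(), force_field())
  expect_equal(max(abs(F$bead_forces)), 0, tolerance = 1e-12)
})

test_that("a competent factor and its cognate bead attract symmetrically", {
  gs <- generate_random_string(1, "red", 1, seed = 1)
  sp <- factor_species("red", 1, switch_off_rate = 0, switch_on_rate = 0)
  fr <- bridgesim:::new_frame(0, matrix(0, 1, 3),
                              matrix(c(40, 0, 0), 1, 3), "red", TRUE)
  F <- compute_forces(fr, gs, sp, force_field())
  expect_equal(F$bead_forces[1, ], -F$factor_forces[1, ],
               tolerance = 1e-12)
  expect_gt(F$bead_forces[1, 1], 0)  # bead pulled towards the factor
  # incompetent factor: no attraction, and no repulsion at 40 nm
  fr$binding_competent <- FALSE
  F0 <- compute_forces(fr, gs, sp, force_field())
  expect_equal(max(abs(F0$bead_forces)), 0, tolerance = 1e-12)
})

test_that("internal forces sum to zero without confinement", {
  for (seed in c(8, 9, 10)) {
    ss <- small_system(seed, kappa = 2)
    F <- compute_forces(ss$fr, ss$gs, ss$sps, ss$ff)
    total <- colSums(rbind(F$bead_forces, F$factor_forces))
    scale <- max(1, max(abs(rbind(F$bead_forces, F$factor_forces))))
    expect_lt(max(abs(total)) / scale, 1e-9)
  }
})

test_that("forces are the negative gradient of the energy", {
  ss <- small_system(11, kappa = 3, confine = 150)
  F <- compute_forces(ss$fr, ss$gs, ss$sps, ss$ff)
  Fall <- rbind(F$bead_forces, F$factor_forces)
  h <- 1e-6
  n <- nrow(ss$fr$bead_positions)
  for (p in c(1, 4, 9, 12)) {  # a few beads and factors
    for (c3 in 1:3) {
      up <- ss$fr; dn <- ss$fr
      if (p <= n) {
        up$bead_positions[p, c3] <- up$bead_positions[p, c3] + h
        dn$bead_positions[p, c3] <- dn$bead_positions[p, c3] - h
      } else {
        up$factor_positions[p - n, c3] <-
          up$factor_positions[p - n, c3] + h
        dn$factor_positions[p - n, c3] <-
          dn$factor_positions[p - n, c3] - h
      }
      num <- -(total_energy(up, ss$gs, ss$sps, ss$ff) -
                 total_energy(dn, ss$gs, ss$sps, ss$ff)) / (2 * h)
      expect_equal(Fall[p, c3], num, tolerance = 1e-4)
    }
  }
})

test_that("overlapping identical coordinates produce finite forces", {
  gs <- generate_random_string(2, "red", 0, seed = 1)
  fr <- bridgesim:::new_frame(0, rbind(c(0, 0, 0), c(30, 0, 0), c(0, 0, 0))[1:2, ],
                              matrix(0, 1, 3), "red", TRUE)
  sp <- factor_species("red", 1, switch_off_rate = 0, switch_on_rate = 0)
  F <- compute_forces(fr, gs, sp, force_field())
  expect_true(all(is.finite(F$bead_forces)))
  expect_true(all(is.finite(F$factor_forces)))
})

test_that("free diffusion reproduces MSD = 6 D t", {
  st <- free_msd_stats()
  expect_equal(st$msd, st$expected, tolerance = 0.05)
})

test_that("bd_step with dt = 0 leaves the frame unchanged", {
  ss <- small_system(12)
  out <- bd_step(ss$fr, ss$gs, ss$sps, ss$ff, dt = 0)
  expect_equal(out$bead_positions, ss$fr$bead_positions)
  expect_equal(out$factor_positions, ss$fr$factor_positions)
})

test_that("bd_step is deterministic under a fixed seed", {
  ss <- small_system(13)
  set.seed(99); a <- bd_step(ss$fr, ss$gs, ss$sps, ss$ff, dt = 0.01)
  set.seed(99); b <- bd_step(ss$fr, ss$gs, ss$sps, ss$ff, dt = 0.01)
  expect_identical(a, b)
})

test_that("noise-free stepping never increases the potential energy", {
  ss <- small_system(14, kappa = 1, confine = 120)
  fr <- ss$fr
  e <- total_energy(fr, ss$gs, ss$sps, ss$ff)
  for (k in 1:50) {
    fr <- bd_step(fr, ss$gs, ss$sps, ss$ff, dt = 0.002, noise = FALSE)
    e2 <- total_energy(fr, ss$gs, ss$sps, ss$ff)
    expect_lte(e2, e + 1e-8)
    e <- e2
  }
})

test_that("switching rates of zero leave competence untouched", {
  ss <- small_system(15)
  fr <- ss$fr
  fr$binding_competent <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  out <- switch_states(fr, ss$sps, dt = 0.01)
  expect_identical(out$binding_competent, fr$binding_competent)
})

test_that("equal switching rates reach a half-competent steady state", {
  sp <- factor_species("x", 600, switch_off_rate = 0.05,
                       switch_on_rate = 0.05)
  fr <- bridgesim:::new_frame(0, matrix(0, 1, 3), matrix(0, 600, 3),
                              rep("x", 600), rep(TRUE, 600))
  set.seed(21)
  for (k in 1:2000) fr <- switch_states(fr, list(sp), dt = 1)
  frac <- mean(fr$binding_competent)
  se <- sqrt(0.25 / 600)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("the printed switching rate maps to the stated physical rate", {
  # 1e-5 per Brownian time at tauB = 0.01 s is 1e-3 per second, and the
  # per-step flip probability at dt = 0.01 tauB is 1e-7
  expect_equal(rate_per_second(1e-5, 0.01), 1e-3)
  expect_equal(1e-5 * 0.01, 1e-7)
})

test_that("switching probabilities above 1 are rejected", {
  sp <- factor_species("x", 2, switch_off_rate = 150, switch_on_rate = 0)
  fr <- bridgesim:::new_frame(0, matrix(0, 1, 3), matrix(0, 2, 3),
                              rep("x", 2), rep(TRUE, 2))
  expect_error(switch_states(fr, list(sp), dt = 0.01), "< 1")
})

test_that("an unstable timestep aborts with the offending particle", {
  gs <- generate_random_string(5, "red", 0, seed = 2)
  cfg <- sim_config(n_steps = 100, timestep_tauB = 50, seed = 3)
  expect_error(run_simulation(gs, list(), force_field(), cfg),
               "unstable")
})

test_that("simulations are reproducible and conserve particles", {
  tr <- demo_trajectory()
  m <- nrow(tr$frames[[1]]$factor_positions)
  n <- nrow(tr$frames[[1]]$bead_positions)
  for (fr in tr$frames) {
    expect_identical(nrow(fr$factor_positions), m)
    expect_identical(nrow(fr$bead_positions), n)
    expect_true(all(is.finite(fr$bead_positions)))
    expect_true(all(is.finite(fr$factor_positions)))
  }
  times <- vapply(tr$frames, `[[`, numeric(1), "time")
  expect_true(all(diff(times) > 0))
  # frame spacing equals frame_interval x timestep
  expect_equal(unique(round(diff(times), 9)),
               tr$config$frame_interval * tr$config$timestep_tauB)
  # bit-for-bit reproducibility from the same seed
  tr2 <- run_simulation(tr$string, tr$species, tr$field, tr$config)
  expect_equal(tr$frames[[length(tr$frames)]]$bead_positions,
               tr2$frames[[length(tr2$frames)]]$bead_positions)
})

test_that("confined particles stay near the confinement sphere", {
  tr <- demo_trajectory()
  R <- tr$field$confinement_radius_nm
  for (fr in tr$frames[c(1, 10, 20)]) {
    r <- sqrt(rowSums(fr$bead_positions^2))
    expect_true(all(r < R + 30))
  }
})

test_that("a polymer-only run shows monotone internal-distance growth", {
  # mean-squared internal distances over log-spaced contour
  # separations up to half the chain (end effects and the slow global
  # modes dominate beyond that on desk-scale runs)
  tr <- polymer_trajectory()
  n <- n_beads(tr$string)
  seps <- c(2, 4, 8, 16, 32, 64)
  msd_internal <- vapply(seps, function(s) {
    v <- 0; cnt <- 0
    for (fr in tr$frames) {
      d <- fr$bead_positions[1:(n - s), , drop = FALSE] -
        fr$bead_positions[(1 + s):n, , drop = FALSE]
      v <- v + sum(rowSums(d^2)); cnt <- cnt + (n - s)
    }
    v / cnt
  }, numeric(1))
  expect_true(all(diff(msd_internal) > 0))
})

test_that("bound factors follow Boltzmann statistics (two-particle oracle)", {
  st <- two_particle_stats()
  expect_lt(abs(st$p_bd - st$p_mc), 3 * st$se_bd)
})

test_that("binding stays reversible: no factor is trapped for good", {
  # pair level, default 7 kT affinity: a single factor at a single
  # cognate bead binds and unbinds repeatedly over ~20000 Brownian
  # times (inside a multi-bead cluster the escape time stretches far
  # beyond desk-scale runs — the bridging feedback at work — so the
  # pair system is where the thermal reversibility itself is visible)
  gs <- generate_random_string(1, "red", 1, seed = 1)
  sp <- factor_species("red", 1, switch_off_rate = 0,
                       switch_on_rate = 0)
  ff <- force_field(confinement_radius_nm = 150)
  tr <- run_simulation(gs, sp, ff,
                       sim_config(n_steps = 2e6,
                                  equilibration_steps = 0,
                                  frame_interval = 2500, seed = 17),
                       pin_beads = TRUE)
  bm <- bound_matrix(tr)
  expect_gt(sum(bm), 0)                 # binds
  expect_gt(sum(!bm), 0)                # unbinds
  flips <- sum(diff(as.numeric(bm[1, ])) != 0)
  expect_gte(flips, 2)                  # and exchanges repeatedly

  # system level at the differential experiment's 6 kT operating
  # point: every factor in a clustered many-bead system unbinds
  gs2 <- generate_random_string(60, "red", 0.1, seed = 9)
  sp2 <- factor_species("red", 4, specific_affinity_kT = 6,
                        switch_off_rate = 0, switch_on_rate = 0)
  ff2 <- force_field(
    confinement_radius_nm = confinement_for_fraction(gs2, list(sp2), 0.02))
  tr2 <- run_simulation(gs2, sp2, ff2,
                        sim_config(n_steps = 1e6,
                                   equilibration_steps = 0,
                                   frame_interval = 2500, seed = 17))
  bm2 <- bound_matrix(tr2)
  expect_true(all(rowSums(bm2) > 0))
  expect_true(all(rowSums(!bm2) > 0))
  expect_true(all(apply(bm2, 1, function(x) sum(diff(x) != 0)) >= 2))
})
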