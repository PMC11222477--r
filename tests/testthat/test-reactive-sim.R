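# The reactive CG simulator: system building, forces, integration,
# stochastic bonding.

test_that("build_system honours composition, placement and the empty case", {
  cfg <- sim_config(c(12, 12, 12))
  empty <- build_system(cfg, c(monomer = 0))
  expect_identical(empty$topology$n_beads, 0L)
  expect_identical(nrow(empty$frame$positions), 0L)

  set.seed(1)
  sys <- build_system(cfg, c(peptide = 30, monomer = 20), "random")
  expect_identical(sum(sys$topology$mol_type == "peptide"), 30L)
  expect_identical(sum(sys$topology$mol_type == "monomer"), 20L)
  expect_identical(nrow(sys$topology$sites), 40L)      # 2 thiols per monomer
  expect_true(all(sys$topology$sites$partner == 0))
  expect_identical(sys$topology$n_beads, 30L * 6L + 20L * 3L)

  # droplet placement: all molecule centres inside the sphere
  set.seed(2)
  dro <- build_system(cfg, c(monomer = 50), "droplet", droplet_radius = 4)
  cen <- t(vapply(split(seq_len(dro$topology$n_beads), dro$topology$molecule),
                  function(ix) colMeans(dro$frame$positions[ix, , drop = FALSE]),
                  numeric(3)))
  expect_true(all(sqrt(rowSums(sweep(cen, 2, c(6, 6, 6))^2)) <= 4 + 0.26))

  expect_error(build_system(cfg, c(monomer = 5), "ellipsoid"), "placement")
  expect_error(build_system(cfg, c(monomer = 5), "droplet", droplet_radius = 7),
               "droplet_radius")
  expect_error(build_system(cfg, c(gas = 5)), "unknown species")
})

test_that("packing failure reports the density", {
  cfg <- sim_config(c(3, 3, 3))
  set.seed(1)
  expect_error(build_system(cfg, c(peptide = 400), max_retries = 20L),
               "density")
})

test_that("pair force vanishes at the LJ minimum and beyond the cutoff", {
  sp <- species_table()
  cfg <- sim_config(c(10, 10, 10))
  topo <- free_bead_topology(2)
  rmin <- 2^(1 / 6) * sp$sigma["W"]
  fr <- md_frame(rbind(c(2, 2, 2), c(2 + rmin, 2, 2)), box = cfg$box_lengths)
  f <- compute_forces(fr, topo, sp, cfg)
  expect_lt(max(abs(f$forces)), 1e-9)

  fr2 <- md_frame(rbind(c(2, 2, 2), c(2 + 1.2 * cfg$pair_cutoff, 2, 2)),
                  box = cfg$box_lengths)
  f2 <- compute_forces(fr2, topo, sp, cfg)
  expect_identical(unname(f2$forces), matrix(0, 2, 3))
  expect_identical(f2$energy, 0)
})

test_that("forces and energy are invariant under box-vector translation", {
  sys <- small_monomer_system(12, seed = 3)
  f0 <- compute_forces(sys$frame, sys$topology, species_table(), sys$config)
  fr2 <- sys$frame
  fr2$positions[, 1] <- fr2$positions[, 1] + sys$config$box_lengths[1]
  fr2 <- md_frame(fr2$positions, fr2$velocities, sys$config$box_lengths,
                  time = fr2$time)
  f1 <- compute_forces(fr2, sys$topology, species_table(), sys$config)
  expect_equal(f1$forces, f0$forces, tolerance = 1e-12)
  expect_equal(f1$energy, f0$energy, tolerance = 1e-12)
})

test_that("analytic forces equal the central-difference energy gradient", {
  cfg <- sim_config(c(6, 6, 6), charge_screening = list(enabled = TRUE))
  set.seed(3)
  sys <- build_system(cfg, c(monomer = 5, peptide = 3), "random",
                      peptide_termini = "charged")
  # jitter off the templates so bonds and angles are strained
  sys$frame$positions <- sys$frame$positions +
    matrix(rnorm(3 * sys$topology$n_beads, 0, 0.03), ncol = 3)
  sp <- species_table()
  f <- compute_forces(sys$frame, sys$topology, sp, cfg)
  h <- 1e-6
  idx <- seq_len(min(10L, sys$topology$n_beads))
  for (i in idx) for (d in 1:3) {
    fp <- sys$frame; fp$positions[i, d] <- fp$positions[i, d] + h
    fm <- sys$frame; fm$positions[i, d] <- fm$positions[i, d] - h
    g <- -(compute_forces(fp, sys$topology, sp, cfg)$energy -
             compute_forces(fm, sys$topology, sp, cfg)$energy) / (2 * h)
    expect_equal(f$forces[i, d], g,
                 tolerance = 1e-6 * max(1, abs(f$forces[i, d])))
  }
})

test_that("kT = 0 with friction damps velocities monotonically to zero", {
  cfg <- sim_config(c(10, 10, 10), temperature_kT = 0, friction_gamma = 2,
                    timestep = 0.01)
  topo <- free_bead_topology(5)
  attr(cfg, "species") <- ideal_species()
  fr <- md_frame(matrix(runif(15) * 10, 5, 3),
                 velocities = matrix(rnorm(15, 0, 0.3), 5, 3),
                 box = cfg$box_lengths)
  sp <- ideal_species()
  speeds <- sqrt(sum(fr$velocities^2))
  for (k in 1:5) {
    fr <- step_langevin(fr, topo, sp, cfg, n_steps = 50L)
    s <- sqrt(sum(fr$velocities^2))
    expect_lt(s, speeds[length(speeds)])
    speeds <- c(speeds, s)
  }
  expect_lt(tail(speeds, 1) / speeds[1], 0.2)
})

test_that("free-particle diffusion obeys the Einstein relation", {
  # D = kT/(m*gamma) = 2.494/(72*1) for W beads
  cfg <- sim_config(c(10, 10, 10), n_steps = 20000L, timestep = 0.02,
                    output_interval = 100L)
  attr(cfg, "species") <- ideal_species()
  topo <- free_bead_topology(150)
  set.seed(11)
  fr <- md_frame(matrix(runif(450) * 10, 150, 3), box = cfg$box_lengths)
  run <- run_simulation(cfg, topo, fr, react = FALSE)
  un <- unwrap(run$trajectory)
  t <- run$trajectory$times
  msd <- vapply(seq_along(un), function(f)
    mean(rowSums((un[[f]] - un[[1]])^2)), 0)
  fitD <- unname(coef(lm(msd[-(1:50)] ~ t[-(1:50)]))[2]) / 6
  expect_equal(fitD, 2.494 / 72, tolerance = 0.05)
})

test_that("equilibrated speeds follow Maxwell-Boltzmann at the set kT", {
  cfg <- sim_config(c(10, 10, 10), n_steps = 2000L, timestep = 0.02)
  attr(cfg, "species") <- ideal_species()
  topo <- free_bead_topology(400)
  set.seed(12)
  fr <- md_frame(matrix(runif(1200) * 10, 400, 3), box = cfg$box_lengths)
  run <- run_simulation(cfg, topo, fr, react = FALSE)
  v <- run$trajectory$velocities[[n_frames(run$trajectory)]]
  # each velocity component ~ N(0, sqrt(kT/m))
  ks <- ks.test(as.vector(v) / sqrt(2.494 / 72), "pnorm")
  expect_gt(ks$p.value, 0.01)
})

test_that("react_step forms no bonds without candidates and saturates valence", {
  cfg <- sim_config(c(10, 10, 10))
  set.seed(5)
  sys <- build_system(cfg, c(monomer = 4), "random")
  params <- react_params(k_on = 1e6)      # p_form -> 1
  # spread monomers far apart: no candidate pairs
  far <- md_frame(sys$frame$positions + 0, box = cfg$box_lengths)
  for (m in 1:4) {
    ix <- which(sys$topology$molecule == m)
    shift <- c((m - 1) %% 2, (m - 1) %/% 2, 0) * 5 + 1
    far$positions[ix, ] <- sweep(sys$frame$positions[ix, ] -
      matrix(colMeans(sys$frame$positions[ix, ]), 3, 3, byrow = TRUE), 2,
      shift, "+")
  }
  out <- react_step(far, sys$topology, params, kT = 2.494)
  expect_identical(nrow(out$events), 0L)
  expect_identical(out$topology$sites$partner, sys$topology$sites$partner)

  # two sites in range, p_form -> 1: exactly one formation, then saturation
  near <- far
  s <- sys$topology$sites
  b1 <- s$bead[1]; b2 <- s$bead[3]      # site 1 of monomer 1 and 2
  near$positions[b2, ] <- near$positions[b1, ] + c(0.2, 0, 0)
  out1 <- react_step(near, sys$topology, params, kT = 2.494)
  expect_identical(nrow(out1$events), 1L)
  expect_identical(out1$events$kind, "formation")
  expect_identical(out1$topology$sites$partner[1], 3L)
  expect_identical(out1$topology$sites$partner[3], 1L)
  expect_identical(nrow(out1$topology$bonds), nrow(sys$topology$bonds) + 1L)
  out2 <- react_step(near, out1$topology, params, kT = 2.494)
  expect_identical(nrow(out2$events), 0L)
})

test_that("breakage follows the Arrhenius factor of the well depth", {
  # direct evaluation of the per-attempt factor
  expect_equal(exp(-60 / 2.494), 3.55e-11, tolerance = 0.01)
  expect_equal(exp(-20 / 2.494), 3.28e-4, tolerance = 0.01)

  # 1e5 attempts on bonded pairs: none break at E=60, binomial count at E=20
  cfg <- sim_config(c(40, 12, 12))
  set.seed(6)
  n_mono <- 200
  sys <- build_system(cfg, c(monomer = n_mono), "random")
  topo <- sys$topology
  pr60 <- react_params(well_depth_E = 60, k0_off = 100)
  for (m in seq(1, n_mono, by = 2))   # bond site pairs across monomer pairs
    topo <- crxn:::.apply_formation(topo, 2 * m - 1, 2 * m + 1, pr60)
  n_bonded_pairs <- sum(topo$sites$partner > 0) / 2
  expect_identical(n_bonded_pairs, 100)
  dt_att <- 0.2
  n_calls <- 1000L   # 1000 calls x 100 pairs = 1e5 attempts
  count_breaks <- function(E, k0, seed) {
    set.seed(seed)
    p <- react_params(well_depth_E = E, k0_off = k0, k_on = 0)
    tot <- 0L
    for (i in seq_len(n_calls)) {
      out <- react_step(sys$frame, topo, p, kT = 2.494, dt_attempt = dt_att)
      tot <- tot + sum(out$events$kind == "breakage")
    }
    tot
  }
  expect_identical(count_breaks(60, 100, 7), 0L)
  n20 <- count_breaks(20, 100, 8)
  p20 <- 1 - exp(-100 * exp(-20 / 2.494) * dt_att)
  expected <- n_calls * 100 * p20
  sigma <- sqrt(n_calls * 100 * p20 * (1 - p20))
  expect_lt(abs(n20 - expected), 3 * sigma)
})

test_that("runs are reproducible, conservative and monotone when irreversible", {
  cfg <- sim_config(c(8, 8, 8), n_steps = 0L, seed = 42L)
  set.seed(1)
  sys <- build_system(cfg, c(monomer = 10), "random")
  null_run <- run_simulation(cfg, sys$topology, sys$frame)
  expect_identical(n_frames(null_run$trajectory), 1L)
  expect_identical(nrow(null_run$events), 0L)

  cfg$n_steps <- 4000L
  cfg$output_interval <- 500L
  r1 <- run_simulation(cfg, sys$topology, sys$frame)
  r2 <- run_simulation(cfg, sys$topology, sys$frame)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$trajectory$positions, r2$trajectory$positions)

  # species and bead counts conserved; bond count non-decreasing
  expect_identical(r1$topology$species, sys$topology$species)
  expect_identical(r1$topology$n_beads, sys$topology$n_beads)
  mono <- vapply(census_series(r1), function(cns) cns$monomer_count, 0L)
  expect_true(all(diff(mono) <= 0))
})

test_that("near-zero friction conserves energy in the symplectic limit", {
  set.seed(4)
  relax <- sim_config(c(8, 8, 8), n_steps = 15000L, timestep = 0.01,
                      friction_gamma = 2, output_interval = 15000L)
  sys <- build_system(relax, c(monomer = 25), "random")
  r0 <- run_simulation(relax, sys$topology, sys$frame, react = FALSE)
  fr <- crxn:::.traj_frame(r0$trajectory, n_frames(r0$trajectory))
  nve <- sim_config(c(8, 8, 8), n_steps = 10000L, timestep = 0.002,
                    friction_gamma = 0, output_interval = 100L)
  r <- run_simulation(nve, sys$topology, fr, react = FALSE)
  m <- species_table()$mass[sys$topology$species]
  ke <- vapply(seq_along(r$trajectory$times), function(f)
    0.5 * sum(m * rowSums(r$trajectory$velocities[[f]]^2)), 0)
  etot <- ke + r$trajectory$pe
  expect_lt((max(etot) - min(etot)) / abs(mean(etot)), 1e-3)
})
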