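# Umbrella sampling, WHAM, Boltzmann inversion and transfer free energies.

test_that("stiff umbrella windows sample the equipartition width", {
  kT <- 2.494
  cfg <- sim_config(c(6, 6, 6), n_steps = 20000L, timestep = 0.005,
                    output_interval = 20L, temperature_kT = kT)
  topo <- free_bead_topology(1)
  fr <- md_frame(matrix(c(3, 3, 3), 1, 3), box = cfg$box_lengths)
  set.seed(51)
  k_umb <- 1e4
  w <- sample_windows(cfg, topo, fr, centers = 0.7, k_umb = k_umb,
                      tracer_bead = 1L, species = ideal_species())
  xi <- w[[1]]$xi
  expect_equal(mean(xi), 0.7, tolerance = 0.02)
  expect_equal(sd(xi), sqrt(kT / k_umb), tolerance = 0.15)

  cfg0 <- cfg; cfg0$n_steps <- 0L
  expect_error(sample_windows(cfg0, topo, fr, centers = 0.7,
                              tracer_bead = 1L, species = ideal_species()),
               "zero samples")
})

test_that("an unbiased free tracer follows the bias Boltzmann weight", {
  kT <- 2.494
  cfg <- sim_config(c(6, 6, 6), n_steps = 60000L, timestep = 0.01,
                    output_interval = 30L, temperature_kT = kT)
  topo <- free_bead_topology(1)
  fr <- md_frame(matrix(c(3, 3, 3), 1, 3), box = cfg$box_lengths)
  set.seed(52)
  k_umb <- 300
  w <- sample_windows(cfg, topo, fr, centers = 0, k_umb = k_umb,
                      tracer_bead = 1L, species = ideal_species())
  xi <- w[[1]]$xi
  # thin to approximately independent samples before the KS test
  xi <- xi[seq(1, length(xi), by = 8)]
  ks <- ks.test(xi, "pnorm", 0, sqrt(kT / k_umb))
  expect_gt(ks$p.value, 0.01)
})

test_that("single-window zero-bias WHAM equals Boltzmann inversion exactly", {
  set.seed(53)
  xi <- rnorm(4000, 0, 0.8)
  win <- list(structure(list(center = 0, k_umb = 0, xi = xi, n = length(xi)),
                        class = "umbrella_window"))
  kT <- 2.494
  pmf <- wham(win, kT = kT, bin_width = 0.2)
  h <- pmf$counts
  direct <- -kT * log(h / sum(h))
  direct <- direct - min(direct[h > 0])
  expect_equal(pmf$free_energy[h > 0], direct[h > 0], tolerance = 1e-9)
})

test_that("WHAM recovers a known double-well from biased samples", {
  kT <- 2.494
  U <- function(x) 4 * ((x / 3)^4 - (x / 3)^2) * kT
  centers <- seq(-4.5, 4.5, length.out = 9)
  k_umb <- 5
  set.seed(54)
  wins <- lapply(centers, function(c0) {
    Ub <- function(x) U(x) + 0.5 * k_umb * (x - c0)^2
    xi <- sample_1d(4000, Ub, c0 - 3, c0 + 3, kT = kT)
    structure(list(center = c0, k_umb = k_umb, xi = xi, n = length(xi)),
              class = "umbrella_window")
  })
  pmf <- wham(wins, kT = kT, bin_width = 0.25)
  ok <- is.finite(pmf$free_energy) & abs(pmf$bin_centers) <= 4
  truth <- U(pmf$bin_centers[ok])
  rmsd <- pmf_rmsd(pmf$free_energy[ok], truth)
  expect_lt(rmsd, 0.3 * kT)

  # invariance under window permutation and a redundant window
  pmf_perm <- wham(wins[sample(length(wins))], kT = kT, bin_width = 0.25)
  expect_lt(max(abs(pmf_perm$free_energy[ok] - pmf$free_energy[ok]),
                na.rm = TRUE), 0.1 * kT)
  pmf_red <- wham(c(wins, wins[5]), kT = kT, bin_width = 0.25)
  expect_lt(pmf_rmsd(pmf_red$free_energy[ok], truth), 0.3 * kT)

  # discretization robustness: halving the bin width barely moves the wells
  pmf_fine <- wham(wins, kT = kT, bin_width = 0.125)
  well <- function(p) min(p$free_energy[p$bin_centers > 1 & p$bin_centers < 3],
                          na.rm = TRUE) -
    min(p$free_energy[abs(p$bin_centers) < 0.5], na.rm = TRUE)
  expect_lt(abs(well(pmf_fine) - well(pmf)), 0.15 * kT)

  # non-overlapping windows are rejected with the gap named
  gap <- wins[c(1, 9)]
  expect_error(wham(gap, kT = kT, bin_width = 0.25), "overlap")
})

test_that("Boltzmann inversion recovers an imposed cosine potential", {
  kT <- 2.494
  A <- 2 * kT
  L <- 10
  U <- function(z) A * cos(2 * pi * z / L)
  set.seed(55)
  z <- sample_1d(40000, U, 0, L, kT = kT)
  edges <- seq(0, L, length.out = 41)
  h <- hist(z, breaks = edges, plot = FALSE)
  prof <- list(centers = h$mids, density = h$counts / sum(h$counts))
  pmf <- boltzmann_invert(prof, kT = kT)
  truth <- U(h$mids)
  ok <- is.finite(pmf$free_energy)
  expect_lt(pmf_rmsd(pmf$free_energy[ok], truth[ok]), 0.2 * kT)

  flat <- boltzmann_invert(list(centers = 1:10, density = rep(2, 10)), kT = kT)
  expect_true(all(flat$free_energy == 0))
  expect_error(boltzmann_invert(list(centers = 1:5, density = rep(0, 5))),
               "all-zero")
})

test_that("transfer free energy is the plateau difference", {
  pmf <- structure(list(bin_centers = seq(0, 10, by = 0.5),
                        free_energy = c(rep(0, 8), 3, 5, 3,
                                        rep(-5, 10))[1:21],
                        counts = rep(10, 21), kT = 2.494),
                   class = "pmf_profile")
  flat <- pmf; flat$free_energy <- rep(1, 21)
  expect_equal(transfer_free_energy(flat, c(6, 10), c(0, 3))$dG, 0)
  got <- transfer_free_energy(pmf, dense_range = c(5.5, 10),
                              dilute_range = c(0, 3.5))
  expect_equal(got$dG, -5)
  expect_error(transfer_free_energy(pmf, c(2, 6), c(5, 9)), "overlap")

  reps <- list(pmf, pmf, pmf)
  agg <- transfer_free_energy(reps, c(5.5, 10), c(0, 3.5))
  expect_equal(agg$dG, -5)
  expect_equal(agg$err, 0)
})

test_that("the umbrella bias holds a tracer at a set distance from a group", {
  kT <- 2.494
  cfg <- sim_config(c(8, 8, 8), n_steps = 20000L, timestep = 0.01,
                    output_interval = 40L, temperature_kT = kT)
  # bonded bead pair as the reference group, free tracer biased 1.5 nm away
  topo <- crxn:::.empty_topology()
  topo$n_beads <- 3L
  topo$species <- c(7L, 7L, 7L)
  topo$molecule <- c(1L, 1L, 2L)
  topo$mol_type <- c("solvent", "solvent")
  topo$bonds <- matrix(c(1, 2, 0.4, 2500), 1, 4,
                       dimnames = list(NULL, c("i", "j", "r0", "k")))
  fr <- md_frame(rbind(c(4, 4, 4), c(4, 4, 4.4), c(4, 4, 5.5)),
                 box = cfg$box_lengths)
  set.seed(57)
  w <- sample_windows(cfg, topo, fr, centers = 1.5, k_umb = 800,
                      tracer_bead = 3L, ref_group = c(1L, 2L),
                      species = ideal_species())
  xi <- w[[1]]$xi
  # the group's centroid itself diffuses, widening xi beyond the bare
  # equipartition width; the mean must still sit at the window centre
  expect_equal(mean(xi), 1.5, tolerance = 0.05)
  expect_lt(sd(xi), 4 * sqrt(kT / 800))
})
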