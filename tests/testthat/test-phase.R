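# Density profiles, interface fits, partitioning, water fraction and
# droplet clustering.

# a synthetic trajectory with beads placed by hand
hand_trajectory <- function(pos_list, box, species) {
  structure(list(times = seq_along(pos_list) - 1,
                 positions = pos_list,
                 images = lapply(pos_list, function(p) matrix(0L, nrow(p), 3)),
                 velocities = lapply(pos_list, function(p) matrix(0, nrow(p), 3)),
                 pe = rep(0, length(pos_list)), box = box, species = species),
            class = "trajectory")
}

test_that("density profile bin arithmetic and mass conservation are exact", {
  # 10 W beads (mass 72) in one bin of volume 8 nm^3: density 90 amu/nm^3
  box <- c(2, 2, 20)
  topo <- free_bead_topology(10)
  pos <- cbind(runif(10) * 2, runif(10) * 2, runif(10) * 0.4 + 10.1)
  tr <- hand_trajectory(list(pos), box, rep("W", 10))
  prof <- density_profile(tr, topo, "W", n_bins = 10L, center = FALSE)
  expect_equal(prof$bin_volume, 8)
  expect_equal(max(prof$density), 90)
  expect_equal(sum(prof$density * prof$bin_volume), 720)
  expect_error(density_profile(tr, topo, "Z", n_bins = 10L), "empty species")
})

test_that("a uniform ideal gas yields a flat profile", {
  set.seed(21)
  n <- 4000
  box <- c(5, 5, 10)
  topo <- free_bead_topology(n)
  pos <- cbind(runif(n) * 5, runif(n) * 5, runif(n) * 10)
  tr <- hand_trajectory(list(pos), box, rep("W", n))
  prof <- density_profile(tr, topo, "W", n_bins = 20L, center = FALSE)
  counts <- prof$density[, 1] * prof$bin_volume / 72
  expect_true(all(abs(counts - n / 20) < 3 * sqrt(n / 20)))
})

test_that("centering makes the profile invariant to slab translation", {
  set.seed(22)
  box <- c(4, 4, 16)
  n <- 500
  topo <- free_bead_topology(n)
  z0 <- rnorm(n, 8, 1)
  mk <- function(shift) {
    p <- cbind(runif(n) * 4, runif(n) * 4, (z0 + shift) %% 16)
    hand_trajectory(list(p), box, rep("W", n))
  }
  p1 <- density_profile(mk(0), topo, "W", n_bins = 32L)
  p2 <- density_profile(mk(6.3), topo, "W", n_bins = 32L)  # slab crosses the boundary
  expect_equal(p1$density, p2$density, tolerance = 1e-12)
})

test_that("tanh interface fit recovers known parameters and flags flat profiles", {
  z <- seq(0.1, 19.9, length.out = 100)
  zc <- 10
  truth <- c(rho_d = 300, rho_l = 10, z0 = 4, w = 0.8)
  rho <- truth["rho_l"] + (truth["rho_d"] - truth["rho_l"]) / 2 *
    (1 - tanh((abs(z - zc) - truth["z0"]) / truth["w"]))
  set.seed(23)
  rho_noisy <- rho * (1 + rnorm(100, 0, 0.02))
  prof <- structure(list(centers = z, density = cbind(rho_noisy),
                         axis = "z", box = c(4, 4, 20), n_frames = 1),
                    class = "density_profile")
  fit <- fit_interface(prof)
  expect_equal(fit$rho_dense, 300, tolerance = 0.05)
  expect_equal(fit$rho_dilute, 10, tolerance = 0.05 * 300 / 10)
  expect_equal(fit$z0, 4, tolerance = 0.05)
  expect_equal(fit$w, 0.8, tolerance = 0.05)

  flat <- structure(list(centers = z, density = cbind(rep(50, 100)),
                         axis = "z", box = c(4, 4, 20), n_frames = 1),
                    class = "density_profile")
  ffit <- fit_interface(flat)
  expect_lt(ffit$contrast, 1.05)
})

test_that("partition coefficients convert to transfer free energies", {
  z <- seq(0.1, 19.9, length.out = 100)
  mkprof <- function(rho) structure(list(centers = z, density = cbind(rho),
                                         axis = "z", box = c(4, 4, 20),
                                         n_frames = 1),
                                    class = "density_profile")
  fit <- structure(list(rho_dense = 300, rho_dilute = 10, z0 = 4, w = 0.8,
                        zc = 10, contrast = 30), class = "interface_fit")
  # uniform tracer: K = 1, dG = 0
  pu <- partition_from_profile(mkprof(rep(2, 100)), fit, kT = 2.494)
  expect_equal(pu$K, 1)
  expect_equal(pu$dG, 0)
  # K = e gives dG = -kT exactly
  rho_e <- ifelse(abs(z - 10) <= 4 - 0.8, exp(1), 1)
  pe <- partition_from_profile(mkprof(rho_e), fit, kT = 2.494)
  expect_equal(pe$K, exp(1), tolerance = 1e-12)
  expect_equal(pe$dG, -2.494, tolerance = 1e-9)
  # zero dilute density is an error
  rho_z <- ifelse(abs(z - 10) <= 4 - 0.8, 5, 0)
  expect_error(partition_from_profile(mkprof(rho_z), fit), "undefined")
  # the measured K = 5.6 corresponds to -4.3 kJ/mol at 300 K
  expect_equal(dG_from_K(5.6, 300), -4.3, tolerance = 0.01)
})

test_that("water weight fraction is the solvent mass share of the dense region", {
  z <- seq(0.25, 19.75, length.out = 40)
  dense <- abs(z - 10) <= 3
  # 100 solvent beads (mass 72) + 10 chains (mass 1000) inside the dense region
  vol <- sum(dense) * (4 * 4 * 0.5)
  dens <- cbind(peptide = ifelse(dense, 10 * 1000 / vol, 0),
                solvent = ifelse(dense, 100 * 72 / vol, 0))
  prof <- structure(list(centers = z, density = dens, axis = "z",
                         box = c(4, 4, 20), n_frames = 1),
                    class = "density_profile")
  expect_equal(water_weight_fraction(prof, dense_bins = dense),
               7200 / 17200, tolerance = 1e-12)
  all_w <- prof; all_w$density[, "peptide"] <- 0
  expect_equal(water_weight_fraction(all_w, dense_bins = dense), 1)
  empty <- prof; empty$density[, "solvent"] <- 0
  expect_equal(water_weight_fraction(empty, dense_bins = dense), 0)
  nosolv <- prof; colnames(nosolv$density) <- c("peptide", "monomer")
  expect_error(water_weight_fraction(nosolv, dense_bins = dense), "solvent")
})

test_that("droplet clustering matches a breadth-first oracle under PBC", {
  box <- c(10, 10, 10)
  # all beads far apart: N singletons
  set.seed(31)
  topoN <- free_bead_topology(8)
  pos <- as.matrix(expand.grid(c(1, 6), c(1, 6), c(1, 6)))
  frN <- md_frame(pos, box = box)
  clN <- cluster_droplets(frN, topoN, "solvent", cutoff = 0.8, min_size = 1L)
  expect_identical(length(clN$sizes), 8L)

  # two blobs separated by 3x cutoff, sizes preserved
  blob <- function(c0, n) sweep(matrix(rnorm(3 * n, 0, 0.2), n, 3), 2, c0, "+")
  pos2 <- rbind(blob(c(2, 2, 2), 12), blob(c(2, 2, 2 + 3 * 0.8 + 1), 7))
  topo2 <- free_bead_topology(19)
  fr2 <- md_frame(pos2, box = box)
  cl2 <- cluster_droplets(fr2, topo2, "solvent", cutoff = 0.8, min_size = 1L)
  expect_identical(sort(cl2$sizes), c(7L, 12L))

  # random configurations agree with the BFS oracle up to relabelling
  for (rep in 1:5) {
    n <- 40
    posr <- matrix(runif(3 * n) * 10, n, 3)
    topor <- free_bead_topology(n)
    frr <- md_frame(posr, box = box)
    cl <- cluster_droplets(frr, topor, "solvent", cutoff = 1.2, min_size = 1L)
    oracle <- bfs_cluster_oracle(posr, box, 1.2)
    # same partition: cross-tabulation is a permutation matrix
    tab <- table(cl$labels, oracle)
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("co-assembly runs recruit monomers and droplets only coalesce", {
  run <- cached_run("coassembly-phase", function()
    run_scenario("coassembly-2500", seed = 1, n_steps = 160000L))
  nf <- n_frames(run$trajectory)
  marks <- round(seq(0.25, 1, by = 0.25) * nf)
  counts <- vapply(marks, function(f) {
    fr <- crxn:::.traj_frame(run$trajectory, f)
    cluster_droplets(fr, run$topology, "peptide", cutoff = 0.8,
                     min_size = 5L)$n_droplets
  }, 0L)
  expect_true(all(diff(counts) <= 0))

  # monomers are enriched around the largest peptide droplet: K > 1, dG < 0
  fr <- crxn:::.traj_frame(run$trajectory, nf)
  cl <- cluster_droplets(fr, run$topology, "peptide", cutoff = 0.8,
                         min_size = 5L)
  big_lab <- as.integer(names(which.max(table(cl$labels))))
  big <- cl$beads[cl$labels == big_lab]
  mono <- which(run$topology$mol_type[run$topology$molecule] == "monomer")
  near <- vapply(mono, function(i) {
    d <- sweep(fr$positions[big, , drop = FALSE], 2, fr$positions[i, ], "-")
    for (k in 1:3) d[, k] <- d[, k] - fr$box[k] * round(d[, k] / fr$box[k])
    min(rowSums(d * d)) <= 1
  }, TRUE)
  f_in <- mean(near)
  V_c <- length(big) / 4.5          # dense-phase bead density ~4.5 / nm^3
  V <- prod(fr$box)
  K <- (f_in / (1 - f_in)) / (V_c / (V - V_c))
  expect_gt(K, 1)
  expect_lt(-2.494 * log(K), 0)
})

test_that("condensate-forming peptides act as chaperones for the reaction", {
  # both elevated peptide fractions consume monomers faster than the dilute
  # reference preset
  t50_500 <- median(median_t50("coassembly-500"))
  expect_lt(median(median_t50("coassembly-1500")), t50_500)
  expect_lt(median(median_t50("coassembly-2500")), t50_500)
})
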