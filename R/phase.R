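# Slab density profiles, tanh interface fits, phase assignment, simulated
# partition coefficients, water weight fraction and droplet clustering.

# resolve a species/mol_type selection to a bead index vector
.select_beads <- function(topology, traj, sel) {
  lab <- traj$species
  hit <- lab %in% sel | topology$mol_type[topology$molecule] %in% sel
  which(hit)
}

#' Mass density profile along a box axis
#'
#' Per-frame binned mass density of the selected bead groups, averaged
#' over frames. With `center = TRUE` each frame is first shifted so the
#' dense-phase mass centroid of `center_species` -- a circular mean over
#' the periodic axis, which is well defined even when the slab crosses the
#' boundary -- sits at the box centre.
#'
#' @param traj a trajectory
#' @param topology the matching topology
#' @param species character vector of group selections; each element may
#'   name bead species ("B") or molecule types ("peptide"); one profile
#'   column is produced per element
#' @param species_tab a [species_table()]
#' @param axis `"x"`, `"y"` or `"z"`
#' @param n_bins number of bins (>= 10)
#' @param center logical, centre the dense phase before binning
#' @param center_species selection used for the centring shift (default:
#'   the first element of `species`)
#' @param frames frame indices to average (default all)
#' @return object of class `density_profile`: list with `centers`,
#'   `edges` (nm), `density` (bins x groups matrix, amu/nm^3), `axis`,
#'   `box`, `n_frames`, `bin_volume`
#' @export
density_profile <- function(traj, topology, species, species_tab = species_table(),
                            axis = "z", n_bins = 60L, center = TRUE,
                            center_species = NULL, frames = NULL) {
  if (!length(species)) stop("empty species selection")
  ax <- match(axis, c("x", "y", "z"))
  if (is.na(ax)) stop("axis must be x, y or z")
  if (n_bins < 10) stop("n_bins must be >= 10")
  L <- traj$box[ax]
  if (is.null(frames)) frames <- seq_along(traj$times)
  edges <- seq(0, L, length.out = n_bins + 1)
  binvol <- prod(traj$box) / n_bins
  mass <- unname(species_tab$mass[topology$species])
  groups <- lapply(species, function(s) .select_beads(topology, traj, s))
  if (any(vapply(groups, length, 0L) == 0))
    stop("empty species selection: ",
         paste(species[vapply(groups, length, 0L) == 0], collapse = ", "))
  if (is.null(center_species)) center_species <- species[[1]]
  cbeads <- .select_beads(topology, traj, center_species)
  dens <- matrix(0, n_bins, length(species),
                 dimnames = list(NULL, vapply(species, paste, "", collapse = "+")))
  for (f in frames) {
    z <- traj$positions[[f]][, ax]
    if (center && length(cbeads)) {
      th <- 2 * pi * z[cbeads] / L
      m <- mass[cbeads]
      zc <- atan2(sum(m * sin(th)), sum(m * cos(th))) * L / (2 * pi)
      z <- (z - zc + L / 2) %% L
    }
    for (g in seq_along(groups)) {
      b <- groups[[g]]
      h <- .bincount(z[b], edges, mass[b])
      dens[, g] <- dens[, g] + h / binvol
    }
  }
  dens <- dens / length(frames)
  structure(list(centers = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                 edges = edges, density = dens, axis = axis, box = traj$box,
                 n_frames = length(frames), bin_volume = binvol),
            class = "density_profile")
}

.bincount <- function(x, edges, w) {
  idx <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
              length(edges) - 1L)
  v <- numeric(length(edges) - 1L)
  for (k in seq_along(idx)) v[idx[k]] <- v[idx[k]] + w[k]
  v
}

#' @export
print.density_profile <- function(x, ...) {
  cat("density_profile along", x$axis, ":", length(x$centers), "bins,",
      ncol(x$density), "group(s), averaged over", x$n_frames, "frames\n")
  invisible(x)
}

#' @export
plot.density_profile <- function(x, ...) {
  graphics::matplot(x$centers, x$density, type = "l", lty = 1,
                    xlab = paste(x$axis, "(nm)"),
                    ylab = expression(rho ~ (amu/nm^3)), ...)
  graphics::legend("topright", legend = colnames(x$density), lty = 1,
                   col = seq_len(ncol(x$density)), bty = "n")
  invisible(x)
}

#' Fit a symmetric tanh interface model to a centred slab profile
#'
#' Model: `rho(z) = rho_l + (rho_d - rho_l)/2 * (1 - tanh((|z - zc| - z0)/w))`
#' with the slab centre `zc` fixed at the box middle (profiles are centred
#' before fitting). A profile with relative spread below 5% is treated as
#' single-phase and returned with `rho_dense == rho_dilute`.
#'
#' @param profile a [density_profile()] (>= 20 bins)
#' @param group profile column to fit (default 1)
#' @return object of class `interface_fit`: `rho_dense`, `rho_dilute`
#'   (amu/nm^3), `z0` (half-width of the dense region, nm), `w` (interface
#'   width, nm), `rms`, `contrast` (= rho_dense/rho_dilute), `zc`
#' @export
fit_interface <- function(profile, group = 1L) {
  z <- profile$centers
  if (length(z) < 20) stop("need >= 20 bins for an interface fit")
  rho <- profile$density[, group]
  zc <- profile$box[match(profile$axis, c("x", "y", "z"))] / 2
  m <- mean(rho)
  if (m <= 0 || (max(rho) - min(rho)) < 0.05 * max(m, 1e-12)) {
    return(structure(list(rho_dense = m, rho_dilute = m, z0 = NA_real_,
                          w = NA_real_, rms = stats::sd(rho), contrast = 1,
                          zc = zc, fitted = rep(m, length(z))),
                     class = "interface_fit"))
  }
  df <- data.frame(z = z, rho = rho)
  start <- list(rho_d = max(rho), rho_l = max(min(rho), 1e-3 * max(rho)),
                z0 = diff(range(z)) / 4, w = 0.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rho ~ rho_l + (rho_d - rho_l) / 2 * (1 - tanh((abs(z - zc) - z0) / w)),
      data = df, start = start,
      lower = c(rho_d = 0, rho_l = 0, z0 = 0.05, w = 0.01),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    stop("interface fit did not converge; residual profile spread = ",
         signif(sd(rho), 3))
  p <- as.list(coef(fit))
  res <- rho - predict(fit)
  structure(list(rho_dense = p$rho_d, rho_dilute = p$rho_l, z0 = p$z0,
                 w = p$w, rms = sqrt(mean(res^2)),
                 contrast = if (p$rho_l > 0) p$rho_d / p$rho_l else Inf,
                 zc = zc, fitted = predict(fit)),
            class = "interface_fit")
}

#' @export
print.interface_fit <- function(x, ...) {
  cat(sprintf(paste0("interface_fit: rho_dense = %.1f, rho_dilute = %.2f ",
                     "amu/nm^3 (contrast %.2f)\n"),
              x$rho_dense, x$rho_dilute, x$contrast))
  if (!is.na(x$z0))
    cat(sprintf("  slab half-width z0 = %.2f nm, interface width w = %.2f nm, rms = %.2f\n",
                x$z0, x$w, x$rms))
  invisible(x)
}

# bin masks for the two plateaus, one interface width inside each
.phase_masks <- function(profile, fit, margin = 1) {
  z <- profile$centers
  d <- abs(z - fit$zc)
  dense <- d <= fit$z0 - margin * fit$w
  dilute <- d >= fit$z0 + margin * fit$w
  list(dense = dense, dilute = dilute)
}

#' Partition coefficient of a tracer from its density profile
#'
#' K is the ratio of the mean tracer density over the dense-phase bins to
#' the mean over the dilute-phase bins, with both regions kept one
#' interface width away from the fitted interface. The transfer free
#' energy is `dG = -kT ln K`.
#'
#' @param tracer_profile [density_profile()] of the tracer species
#' @param fit [fit_interface()] of the condensate-forming species on the
#'   same (centred) axis
#' @param kT thermal energy, kJ/mol
#' @param margin interface-width multiples excluded on both sides
#' @return object of class `partition_result`: `K`, `dG` (kJ/mol),
#'   `rho_dense`, `rho_dilute`, bin masks
#' @export
partition_from_profile <- function(tracer_profile, fit, kT = 2.494,
                                   margin = 1) {
  m <- .phase_masks(tracer_profile, fit, margin)
  if (sum(m$dense) < 3 || sum(m$dilute) < 3)
    stop("dense and dilute regions must each span >= 3 bins clear of the interface")
  rho <- tracer_profile$density[, 1]
  rd <- mean(rho[m$dense]); rl <- mean(rho[m$dilute])
  if (rl <= 0)
    stop("zero tracer density in the dilute phase: K undefined; sample longer")
  K <- rd / rl
  structure(list(K = K, dG = -kT * log(K), rho_dense = rd, rho_dilute = rl,
                 dense_bins = m$dense, dilute_bins = m$dilute, kT = kT),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("partition_result: K = %.2f, dG = %.2f kJ/mol (kT = %.3f)\n",
              x$K, x$dG, x$kT))
  invisible(x)
}

#' Water weight fraction of the dense phase
#'
#' Solvent mass over total mass, integrated over the dense-phase bins of a
#' multi-group profile that includes a solvent column.
#'
#' @param profile [density_profile()] whose columns include a solvent
#'   group (named `"solvent"` or `"W"`)
#' @param fit [fit_interface()] defining the dense region; alternatively a
#'   logical bin mask via `dense_bins`
#' @param dense_bins optional logical mask overriding `fit`
#' @return solvent weight fraction in `[0, 1]`
#' @export
water_weight_fraction <- function(profile, fit = NULL, dense_bins = NULL) {
  cols <- colnames(profile$density)
  wcol <- which(cols %in% c("solvent", "W"))
  if (!length(wcol)) stop("profile has no solvent group")
  if (is.null(dense_bins)) {
    if (is.null(fit)) stop("supply an interface fit or dense_bins")
    dense_bins <- .phase_masks(profile, fit)$dense
  }
  tot <- sum(profile$density[dense_bins, ])
  if (tot <= 0) return(0)
  sum(profile$density[dense_bins, wcol]) / tot
}

#' Single-linkage droplet clustering under periodic boundaries
#'
#' Beads of the selected species closer than `cutoff` (minimum image) are
#' linked; connected components are clusters. Beads of one molecule are
#' always kept together. Droplets are clusters holding at least `min_size`
#' molecules.
#'
#' @param frame an [md_frame()]
#' @param topology the topology
#' @param species selection as in [density_profile()]
#' @param cutoff linkage distance, nm
#' @param min_size minimum molecules for a cluster to count as a droplet
#' @param species_tab a [species_table()]
#' @return list with `labels` (cluster id per selected bead), `beads`
#'   (their indices), `sizes` (molecules per cluster, sorted decreasing),
#'   `n_droplets`
#' @export
cluster_droplets <- function(frame, topology, species, cutoff = 0.8,
                             min_size = 5L, species_tab = species_table()) {
  sel <- which(topology$mol_type[topology$molecule] %in% species |
                 (topology$species %in% which(species_tab$name %in% species)))
  if (!length(sel)) return(list(labels = integer(0), beads = integer(0),
                                sizes = integer(0), n_droplets = 0L))
  pos <- frame$positions[sel, , drop = FALSE]
  pairs <- .neighbor_pairs_cpp(pos, frame$box, cutoff)
  parent <- seq_along(sel)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  if (nrow(pairs)) for (r in seq_len(nrow(pairs))) union2(pairs[r, 1], pairs[r, 2])
  # beads of one molecule always share a cluster
  mol <- topology$molecule[sel]
  for (m in unique(mol)) {
    idx <- which(mol == m)
    if (length(idx) > 1) for (k in idx[-1]) union2(idx[1], k)
  }
  roots <- vapply(seq_along(sel), find, 0L)
  labels <- match(roots, unique(roots))
  sizes <- sort(vapply(split(mol, labels), function(v) length(unique(v)), 0L),
                decreasing = TRUE)
  list(labels = labels, beads = sel, sizes = unname(sizes),
       n_droplets = sum(sizes >= min_size))
}
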