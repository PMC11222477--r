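# Umbrella sampling along the slab normal, WHAM reweighting, Boltzmann
# inversion and transfer free energies.

#' Run umbrella-sampling windows for a tagged tracer
#'
#' A harmonic bias `U_k(xi) = k_umb/2 (xi - c_k)^2` is applied to the
#' tracer bead only, where `xi` is the minimum-image distance along the
#' chosen axis between the tracer and a reference: the mass-weighted
#' circular mean of `ref_group` (typically all condensate beads) or, when
#' `ref_group` is empty, the box centre. Windows are run in sequence, each
#' starting from the final frame of the previous one.
#'
#' @param config a [sim_config()] (per-window steps taken from `n_steps`)
#' @param topology,frame a pre-equilibrated system state
#' @param centers window centres along the axis, nm
#' @param k_umb bias stiffness, kJ/mol/nm^2
#' @param tracer_bead bead index the bias acts on
#' @param ref_group bead indices of the reference group (default: empty,
#'   reference is the box centre)
#' @param axis `"x"`, `"y"` or `"z"`
#' @param equil_fraction initial fraction of each window discarded
#' @param species a [species_table()]
#' @return list of class `umbrella_window` objects: `center`, `k_umb`,
#'   `xi` (sampled coordinate, nm), `n`
#' @export
sample_windows <- function(config, topology, frame, centers, k_umb = 500,
                           tracer_bead, ref_group = integer(0), axis = "z",
                           equil_fraction = 0.2, species = species_table()) {
  if (config$n_steps <= 0 || config$n_steps < config$output_interval)
    stop("window with zero samples: increase n_steps")
  ax <- match(axis, c("x", "y", "z"))
  L <- config$box_lengths[ax]
  cur <- frame
  out <- vector("list", length(centers))
  for (k in seq_along(centers)) {
    bias <- list(bead = as.integer(tracer_bead), k = k_umb,
                 center = centers[k], axis = ax - 1L,
                 ref_group = as.integer(ref_group))
    res <- .run_core(cur, topology, species, config, react_params(),
                     react_on = FALSE, bias = bias)
    tr <- res$trajectory
    nf <- n_frames(tr)
    keep <- seq_len(nf) > max(1, ceiling(equil_fraction * nf))
    xi <- vapply(which(keep), function(f) {
      z <- tr$positions[[f]][, ax]
      zref <- if (length(ref_group)) {
        m <- species$mass[topology$species[ref_group]]
        th <- 2 * pi * z[ref_group] / L
        atan2(sum(m * sin(th)), sum(m * cos(th))) * L / (2 * pi)
      } else L / 2
      d <- z[tracer_bead] - zref
      d - L * round(d / L)
    }, 0)
    out[[k]] <- structure(list(center = centers[k], k_umb = k_umb, xi = xi,
                               n = length(xi)), class = "umbrella_window")
    cur <- .traj_frame(tr, nf)
  }
  out
}

#' Weighted histogram analysis of umbrella windows
#'
#' Standard self-consistent WHAM: iterates the per-window free-energy
#' shifts until the largest change is below `tol`, then reports the
#' unbiased profile `-kT ln P(xi)` shifted so its minimum is zero. A
#' single window with zero bias reduces exactly to Boltzmann inversion of
#' its histogram.
#'
#' @param windows list of `umbrella_window` objects (fields `center`,
#'   `k_umb`, `xi`)
#' @param kT thermal energy, kJ/mol
#' @param bin_width histogram bin width, nm
#' @param tol convergence tolerance on the shifts, kJ/mol
#' @param max_iter iteration cap
#' @return object of class `pmf_profile`: `bin_centers`, `free_energy`
#'   (kJ/mol, min 0, NA on unvisited bins), `counts`, `n_iter`, `f_shifts`
#' @export
wham <- function(windows, kT = 2.494, bin_width = 0.1, tol = 1e-6,
                 max_iter = 10000L) {
  if (!length(windows)) stop("no windows")
  for (w in windows) if (!length(w$xi)) stop("window with zero samples")
  rng <- range(unlist(lapply(windows, `[[`, "xi")))
  edges <- seq(rng[1] - bin_width / 2, rng[2] + bin_width, by = bin_width)
  nb <- length(edges) - 1
  mids <- (edges[-1] + edges[-(nb + 1)]) / 2
  K <- length(windows)
  H <- matrix(0, K, nb)
  for (k in seq_len(K))
    H[k, ] <- .bincount(windows[[k]]$xi, edges, rep(1, length(windows[[k]]$xi)))
  Nk <- rowSums(H)
  # overlap check between windows adjacent in centre order
  ord <- order(vapply(windows, `[[`, 0, "center"))
  if (K > 1) for (q in seq_len(K - 1)) {
    a <- ord[q]; b <- ord[q + 1]
    if (!any(H[a, ] > 0 & H[b, ] > 0))
      stop(sprintf("no histogram overlap between windows at %.3g and %.3g nm",
                   windows[[a]]$center, windows[[b]]$center))
  }
  h <- colSums(H)
  # bias Boltzmann factors c[k, b] = exp(-U_k(x_b)/kT)
  Cb <- matrix(0, K, nb)
  for (k in seq_len(K)) {
    u <- 0.5 * windows[[k]]$k_umb * (mids - windows[[k]]$center)^2
    Cb[k, ] <- exp(-u / kT)
  }
  f <- rep(0, K)   # dimensionless shifts: exp(f_k) normalizers
  for (it in seq_len(max_iter)) {
    denom <- colSums(Nk * Cb * exp(f))   # recycles over columns
    P <- ifelse(h > 0, h / denom, 0)
    fn <- -log(pmax(Cb %*% P, 1e-300))[, 1]
    fn <- fn - fn[1]
    delta <- max(abs(fn - f)) * kT
    f <- fn
    if (delta < tol) break
  }
  if (delta >= tol)
    stop("WHAM did not converge in ", max_iter,
         " iterations (residual ", signif(delta, 3), " kJ/mol)")
  P <- P / sum(P)
  Fe <- ifelse(h > 0, -kT * log(pmax(P, 1e-300)), NA_real_)
  Fe <- Fe - min(Fe, na.rm = TRUE)
  structure(list(bin_centers = mids, free_energy = Fe, counts = h,
                 n_iter = it, f_shifts = f * kT, kT = kT),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  ok <- is.finite(x$free_energy)
  cat("pmf_profile:", sum(ok), "populated bins over [",
      signif(min(x$bin_centers[ok]), 3), ",", signif(max(x$bin_centers[ok]), 3),
      "] nm; range", signif(max(x$free_energy[ok]), 3), "kJ/mol\n")
  invisible(x)
}

#' @export
plot.pmf_profile <- function(x, ...) {
  graphics::plot(x$bin_centers, x$free_energy, type = "l",
                 xlab = "xi (nm)", ylab = "F (kJ/mol)", ...)
  invisible(x)
}

#' Boltzmann inversion of an unbiased density profile
#'
#' `F(xi) = -kT ln rho(xi)`, minimum shifted to zero; bins never visited
#' are returned as NA. Serves as the unbiased cross-check of the WHAM
#' result.
#'
#' @param profile a [density_profile()] of the tracer, or a list with
#'   `centers` and `density` (vector)
#' @param kT thermal energy, kJ/mol
#' @param group profile column (default 1)
#' @return a `pmf_profile`
#' @export
boltzmann_invert <- function(profile, kT = 2.494, group = 1L) {
  rho <- if (is.matrix(profile$density)) profile$density[, group]
         else profile$density
  if (all(rho <= 0)) stop("all-zero density profile")
  Fe <- ifelse(rho > 0, -kT * log(rho), NA_real_)
  Fe <- Fe - min(Fe, na.rm = TRUE)
  structure(list(bin_centers = profile$centers, free_energy = Fe,
                 counts = rho, n_iter = 0L, f_shifts = numeric(0), kT = kT),
            class = "pmf_profile")
}

#' Transfer free energy between two plateaus of a PMF
#'
#' `dG = mean(F over dense range) - mean(F over dilute range)`. When a
#' list of replica profiles is supplied the replica mean and standard
#' error are reported.
#'
#' @param pmf a `pmf_profile` or a list of them (replicas)
#' @param dense_range,dilute_range coordinate intervals `c(lo, hi)` in nm;
#'   must not overlap
#' @return list with `dG` (kJ/mol), `err` (replica SE, NA for a single
#'   profile), `per_replica`
#' @export
transfer_free_energy <- function(pmf, dense_range, dilute_range) {
  if (max(dense_range) > min(dilute_range) &&
      max(dilute_range) > min(dense_range))
    stop("dense and dilute ranges overlap the interface region")
  one <- function(p) {
    dd <- p$bin_centers >= dense_range[1] & p$bin_centers <= dense_range[2]
    dl <- p$bin_centers >= dilute_range[1] & p$bin_centers <= dilute_range[2]
    fd <- p$free_energy[dd]; fl <- p$free_energy[dl]
    if (!any(is.finite(fd)) || !any(is.finite(fl)))
      stop("a plateau range contains no populated bins")
    mean(fd, na.rm = TRUE) - mean(fl, na.rm = TRUE)
  }
  if (inherits(pmf, "pmf_profile")) {
    return(list(dG = one(pmf), err = NA_real_, per_replica = one(pmf)))
  }
  per <- vapply(pmf, one, 0)
  list(dG = mean(per), err = sd(per) / sqrt(length(per)), per_replica = per)
}
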