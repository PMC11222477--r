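# Force evaluation, Langevin integration and the reactive run loop.

# assemble per-bead arrays + pair tables for the C++ core
.core_args <- function(frame, topology, species, config) {
  idx <- topology$species
  list(pos = frame$positions, img = frame$images, vel = frame$velocities,
       box = config$box_lengths,
       type = idx,
       mass = unname(species$mass[idx]),
       charge = unname(species$charge[idx]) *
         as.numeric(config$charge_screening$enabled),
       epsM = unname(species$epsilon), sigM = unname(.pair_sigma(species)),
       cutoff = config$pair_cutoff,
       coulomb = isTRUE(config$charge_screening$enabled),
       debye = config$charge_screening$debye_length,
       bjerrum = config$charge_screening$bjerrum_prefactor,
       bonds = topology$bonds, angles = topology$angles)
}

#' Compute forces and potential energy
#'
#' Truncated-and-shifted Lennard-Jones plus optional Yukawa screened
#' Coulomb between non-excluded pairs (1-2 and 1-3 neighbours excluded),
#' harmonic bonds and angles, all under the minimum-image convention.
#'
#' @param frame an [md_frame()]
#' @param topology a topology
#' @param species a [species_table()]
#' @param config a [sim_config()]
#' @return list with `forces` (N x 3, kJ/mol/nm) and `energy` (kJ/mol)
#' @export
compute_forces <- function(frame, topology, species, config) {
  a <- .core_args(frame, topology, species, config)
  .forces_cpp(a$pos, a$img, a$vel, a$box, a$type, a$mass, a$charge,
              a$epsM, a$sigM, a$cutoff, a$coulomb, a$debye, a$bjerrum,
              a$bonds, a$angles)
}

#' Advance the system by BAOAB Langevin steps
#'
#' With `friction_gamma = 0` this reduces to velocity Verlet. Reactions are
#' not attempted; see [run_simulation()] for the full reactive loop.
#'
#' @inheritParams compute_forces
#' @param n_steps number of steps to take (default: `config$n_steps`)
#' @return the advanced [md_frame()]
#' @export
step_langevin <- function(frame, topology, species, config, n_steps = 1L) {
  run <- .run_core(frame, topology, species, config, react_params(),
                   n_steps = n_steps, react_on = FALSE,
                   out_interval = max(1L, as.integer(n_steps)))
  .traj_frame(run$trajectory, length(run$trajectory$times))
}

# shared driver used by step_langevin / run_simulation / umbrella sampling
.run_core <- function(frame, topology, species, config, params,
                      n_steps = config$n_steps, react_on = TRUE,
                      out_interval = config$output_interval,
                      bias = NULL, skin = 0.35) {
  stopifnot(inherits(frame, "md_frame"), inherits(topology, "topology"),
            inherits(params, "react_params"))
  .check_species(species)
  if (react_on && params$r_react >= config$pair_cutoff)
    stop("r_react must be smaller than pair_cutoff")
  s <- topology$sites
  b <- if (is.null(bias)) list(bead = 0L, k = 0, center = 0, axis = 2L,
                               ref_group = integer(0)) else bias
  res <- .run_core_cpp(frame$positions, frame$images, frame$velocities,
                       config$box_lengths,
                       topology$species,
                       unname(species$mass[topology$species]),
                       unname(species$charge[topology$species]),
                       unname(species$epsilon), unname(.pair_sigma(species)),
                       config$pair_cutoff,
                       isTRUE(config$charge_screening$enabled),
                       config$charge_screening$debye_length,
                       config$charge_screening$bjerrum_prefactor,
                       topology$bonds, topology$angles,
                       s$bead, s$monomer, s$core, s$partner,
                       params$r_react, params$k_on, params$well_depth_E,
                       params$k0_off, params$attempt_interval,
                       params$bond_r0, params$bond_k,
                       params$angle_theta0 * pi / 180, params$angle_k,
                       react_on,
                       config$timestep, config$friction_gamma,
                       config$temperature_kT, as.integer(n_steps),
                       as.integer(out_interval), skin, frame$time,
                       b$bead, b$k, b$center, b$axis, b$ref_group)
  topo2 <- topology
  topo2$bonds <- res$bonds
  colnames(topo2$bonds) <- c("i", "j", "r0", "k")
  topo2$angles <- res$angles
  colnames(topo2$angles) <- c("i", "j", "k", "theta0", "k_theta")
  topo2$sites$partner <- res$site_partner
  traj <- structure(list(times = res$times,
                         positions = res$positions,
                         images = res$images,
                         velocities = res$velocities,
                         pe = res$pe,
                         box = config$box_lengths,
                         species = species$name[topology$species]),
                    class = "trajectory")
  events <- data.frame(time_ps = res$event_time,
                       site_i = res$event_i, site_j = res$event_j,
                       kind = c("formation", "breakage")[res$event_kind])
  list(trajectory = traj, events = events, topology = topo2)
}

# extract frame f of a trajectory as an md_frame
.traj_frame <- function(traj, f) {
  md_frame(positions = traj$positions[[f]], velocities = traj$velocities[[f]],
           box = traj$box, images = traj$images[[f]], time = traj$times[f])
}

#' Number of frames in a trajectory
#' @param traj a trajectory
#' @return integer frame count
#' @export
n_frames <- function(traj) length(traj$times)

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", n_frames(x), "frames,", length(x$species), "beads,",
      "t =", x$times[1], "..", x$times[n_frames(x)], "ps\n")
  invisible(x)
}

#' Run a reactive coarse-grained simulation
#'
#' Integrates BAOAB Langevin dynamics at fixed box (NVT), attempting
#' stochastic disulfide formation (and breakage when enabled) every
#' `params$attempt_interval` steps. With a fixed `config$seed` the run is
#' bit-reproducible: identical trajectory and event log.
#'
#' @inheritParams compute_forces
#' @param params a [react_params()]
#' @param react logical; set `FALSE` to disable the reaction sweeps
#' @param bias optional umbrella bias: list(bead, k, center, axis,
#'   ref_group) -- used internally by [sample_windows()]
#' @return object of class `crxn_run`: list with `trajectory`, `events`
#'   (data.frame time_ps/site_i/site_j/kind), `topology` (final),
#'   `topology_initial`, `config`, `params`
#' @export
run_simulation <- function(config, topology, frame, params = react_params(),
                           react = TRUE, bias = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- .run_core(frame, topology, species_of(config), config, params,
                   react_on = react, bias = bias)
  structure(list(trajectory = res$trajectory, events = res$events,
                 topology = res$topology, topology_initial = topology,
                 config = config, params = params),
            class = "crxn_run")
}

# species table associated with a config (scenario presets may override)
#' @keywords internal
species_of <- function(config) {
  if (!is.null(attr(config, "species"))) attr(config, "species")
  else species_table()
}

#' @export
print.crxn_run <- function(x, ...) {
  cat("crxn_run (scenario:", x$config$scenario, ")\n")
  print(x$trajectory)
  cat(" ", nrow(x$events), "bond events (",
      sum(x$events$kind == "formation"), "formations,",
      sum(x$events$kind == "breakage"), "breakages )\n")
  invisible(x)
}

#' Attempt one sweep of stochastic disulfide formation/breakage
#'
#' Candidate pairs are free thiol sites of different monomers within the
#' capture radius; they are processed nearest first (ties broken by lower
#' site index) and each site participates in at most one event per call.
#' Formation succeeds with probability `1 - exp(-k_on * dt_attempt)`;
#' bonded pairs break with probability
#' `1 - exp(-k0_off * exp(-E/kT) * dt_attempt)`.
#'
#' @param frame an [md_frame()]
#' @param topology a topology
#' @param params a [react_params()]
#' @param kT thermal energy, kJ/mol
#' @param dt_attempt time between sweeps, ps (default
#'   `params$attempt_interval * 0.02`)
#' @return list with updated `topology` and `events` data.frame
#' @export
react_step <- function(frame, topology, params, kT,
                       dt_attempt = params$attempt_interval * 0.02) {
  s <- topology$sites
  box <- frame$box
  ns <- nrow(s)
  events <- data.frame(time_ps = numeric(0), site_i = integer(0),
                       site_j = integer(0), kind = character(0))
  if (ns == 0) return(list(topology = topology, events = events))
  bonded <- s$partner > 0
  for (a in which(bonded))
    if (s$partner[a] < 1 || s$partner[a] > ns)
      stop("inconsistent site state: site ", a, " bonded with no partner")

  pos <- frame$positions[s$bead, , drop = FALSE]
  free <- which(!bonded)
  cand <- NULL
  if (length(free) > 1) {
    cp <- t(utils::combn(free, 2))
    keep <- s$monomer[cp[, 1]] != s$monomer[cp[, 2]]
    cp <- cp[keep, , drop = FALSE]
    if (nrow(cp)) {
      d <- pos[cp[, 1], , drop = FALSE] - pos[cp[, 2], , drop = FALSE]
      for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
      dist <- sqrt(rowSums(d * d))
      inr <- dist <= params$r_react
      cand <- cbind(cp[inr, , drop = FALSE], dist[inr])
      if (nrow(cand))
        cand <- cand[order(cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
    }
  }
  p_form <- 1 - exp(-params$k_on * dt_attempt)
  used <- rep(FALSE, ns)
  topo <- topology
  if (!is.null(cand) && nrow(cand)) for (r in seq_len(nrow(cand))) {
    a <- cand[r, 1]; b <- cand[r, 2]
    if (used[a] || used[b] || topo$sites$partner[a] > 0 ||
        topo$sites$partner[b] > 0) next
    if (runif(1) < p_form) {
      topo <- .apply_formation(topo, a, b, params)
      used[a] <- used[b] <- TRUE
      events <- rbind(events, data.frame(time_ps = frame$time, site_i = a,
                                         site_j = b, kind = "formation"))
    }
  }
  if (params$k0_off > 0 && kT > 0) {
    p_break <- 1 - exp(-params$k0_off * exp(-params$well_depth_E / kT) *
                         dt_attempt)
    for (a in seq_len(ns)) {
      b <- topo$sites$partner[a]
      if (b <= a || used[a] || used[b]) next
      if (runif(1) < p_break) {
        topo <- .apply_breakage(topo, a, b)
        used[a] <- used[b] <- TRUE
        events <- rbind(events, data.frame(time_ps = frame$time, site_i = a,
                                           site_j = b, kind = "breakage"))
      }
    }
  }
  list(topology = topo, events = events)
}

.apply_formation <- function(topo, a, b, params) {
  s <- topo$sites
  if (s$partner[a] > 0 || s$partner[b] > 0)
    stop("formation event references a bonded site")
  ti <- s$bead[a]; tj <- s$bead[b]; ci <- s$core[a]; cj <- s$core[b]
  topo$bonds <- rbind(topo$bonds, c(ti, tj, params$bond_r0, params$bond_k))
  th0 <- params$angle_theta0 * pi / 180
  topo$angles <- rbind(topo$angles,
                       c(ci, ti, tj, th0, params$angle_k),
                       c(ti, tj, cj, th0, params$angle_k))
  topo$sites$partner[a] <- as.integer(b)
  topo$sites$partner[b] <- as.integer(a)
  topo
}

.apply_breakage <- function(topo, a, b) {
  s <- topo$sites
  if (s$partner[a] != b || s$partner[b] != a)
    stop("breakage event references a pair that is not bonded")
  ti <- s$bead[a]; tj <- s$bead[b]
  bm <- topo$bonds
  hit <- which((bm[, 1] == ti & bm[, 2] == tj) |
                 (bm[, 1] == tj & bm[, 2] == ti))[1]
  topo$bonds <- bm[-hit, , drop = FALSE]
  am <- topo$angles
  has_i <- am[, 1] == ti | am[, 2] == ti | am[, 3] == ti
  has_j <- am[, 1] == tj | am[, 2] == tj | am[, 3] == tj
  topo$angles <- am[!(has_i & has_j), , drop = FALSE]
  topo$sites$partner[a] <- 0L
  topo$sites$partner[b] <- 0L
  topo
}

#' Continue a finished run for more steps
#'
#' Restarts from the final frame and topology; frames and events are
#' appended. The RNG state carries over, so a chunked run with one initial
#' seed is reproducible.
#'
#' @param run a `crxn_run`
#' @param n_steps additional steps
#' @return the extended `crxn_run`
#' @export
continue_run <- function(run, n_steps) {
  cfg <- run$config
  cfg$seed <- NULL   # keep the current RNG stream
  cfg$n_steps <- as.integer(n_steps)
  last <- .traj_frame(run$trajectory, n_frames(run$trajectory))
  res <- .run_core(last, run$topology, species_of(cfg), cfg, run$params,
                   react_on = TRUE)
  tr <- run$trajectory
  keep <- -1L  # drop duplicated first frame of the continuation
  tr$times <- c(tr$times, res$trajectory$times[keep])
  tr$positions <- c(tr$positions, res$trajectory$positions[keep])
  tr$images <- c(tr$images, res$trajectory$images[keep])
  tr$velocities <- c(tr$velocities, res$trajectory$velocities[keep])
  tr$pe <- c(tr$pe, res$trajectory$pe[keep])
  run$trajectory <- tr
  run$events <- rbind(run$events, res$events)
  run$topology <- res$topology
  run$config <- cfg
  run
}
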