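# File formats and run provenance: extended-XYZ trajectories, CSV bond
# event logs, JSON topologies, YAML configs, run manifests, event replay.

#' Write a trajectory as extended XYZ
#'
#' One block per frame: the bead count, a comment line carrying
#' `Lattice`, `Properties` and `Time`, then one line per bead with
#' species, wrapped position (nm), image counts and velocity (nm/ps).
#' Numeric fields use 6 decimals, so a read/write round trip is lossless
#' at 1e-6 nm.
#'
#' @param traj a trajectory
#' @param path output file
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  box <- traj$box
  lattice <- sprintf("%.6f 0.0 0.0 0.0 %.6f 0.0 0.0 0.0 %.6f",
                     box[1], box[2], box[3])
  props <- "species:S:1:pos:R:3:image:I:3:velo:R:3"
  for (f in seq_along(traj$times)) {
    p <- traj$positions[[f]]; v <- traj$velocities[[f]]; im <- traj$images[[f]]
    writeLines(as.character(nrow(p)), con)
    writeLines(sprintf('Lattice="%s" Properties=%s Time=%.6f', lattice, props,
                       traj$times[f]), con)
    if (nrow(p))
      writeLines(sprintf("%s %.6f %.6f %.6f %d %d %d %.6f %.6f %.6f",
                         traj$species, p[, 1], p[, 2], p[, 3],
                         im[, 1], im[, 2], im[, 3], v[, 1], v[, 2], v[, 3]),
                 con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' @param path file written by [write_trajectory()]
#' @return a trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  i <- 1L; f <- 0L
  times <- numeric(0); box <- NULL
  positions <- list(); images <- list(); velocities <- list(); species <- NULL
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop("malformed frame header at line ", i,
           " (last complete frame: ", f, ")")
    n <- as.integer(lines[i])
    if (i + 1 + n > length(lines))
      stop("truncated file at line ", length(lines),
           " (last complete frame: ", f, ")")
    hdr <- lines[i + 1]
    lat <- regmatches(hdr, regexpr('Lattice="[^"]*"', hdr))
    if (!length(lat)) stop("missing Lattice record at line ", i + 1)
    latv <- as.numeric(strsplit(sub('Lattice="([^"]*)"', "\\1", lat), "\\s+")[[1]])
    box <- latv[c(1, 5, 9)]
    tm <- regmatches(hdr, regexpr("Time=[-0-9.eE+]+", hdr))
    times <- c(times, if (length(tm)) as.numeric(sub("Time=", "", tm)) else NA)
    block <- lines[i + 1 + seq_len(n)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(parts, length, 0L) != 10)
    if (length(bad))
      stop("malformed bead line at line ", i + 1 + bad[1],
           " (last complete frame: ", f, ")")
    m <- matrix(unlist(parts), ncol = 10, byrow = TRUE)
    if (is.null(species)) species <- m[, 1]
    num <- function(cols) {
      x <- suppressWarnings(matrix(as.numeric(m[, cols]), ncol = length(cols)))
      if (anyNA(x)) stop("non-numeric field in frame ", f + 1)
      x
    }
    positions[[f + 1]] <- num(2:4)
    img <- num(5:7); storage.mode(img) <- "integer"
    images[[f + 1]] <- img
    velocities[[f + 1]] <- num(8:10)
    f <- f + 1L
    i <- i + 2L + n
  }
  structure(list(times = times, positions = positions, images = images,
                 velocities = velocities, pe = rep(NA_real_, f), box = box,
                 species = species),
            class = "trajectory")
}

#' Write / read a bond event log as CSV
#' @param events data.frame with columns time_ps, site_i, site_j, kind
#' @param path file path
#' @return `path` / the events data.frame
#' @export
write_bond_events <- function(events, path) {
  write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bond_events
#' @export
read_bond_events <- function(path) {
  ev <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_ps", "site_i", "site_j", "kind")
  if (!all(need %in% names(ev))) stop("event log misses columns: ",
                                      paste(setdiff(need, names(ev)), collapse = ", "))
  ev[order(ev$time_ps), , drop = FALSE]
}

#' Serialize / restore a topology as JSON
#' @param topology a topology
#' @param path file path
#' @return `path` / the topology
#' @export
write_topology <- function(topology, path) {
  obj <- list(n_beads = topology$n_beads, species = topology$species,
              molecule = topology$molecule, mol_type = topology$mol_type,
              bonds = unname(as.matrix(topology$bonds)),
              angles = unname(as.matrix(topology$angles)),
              sites = topology$sites)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  topo <- .empty_topology()
  topo$n_beads <- as.integer(obj$n_beads)
  topo$species <- as.integer(obj$species)
  topo$molecule <- as.integer(obj$molecule)
  topo$mol_type <- as.character(obj$mol_type)
  if (length(obj$bonds)) {
    topo$bonds <- matrix(unlist(obj$bonds), ncol = 4,
                         dimnames = list(NULL, c("i", "j", "r0", "k")))
  }
  if (length(obj$angles)) {
    topo$angles <- matrix(unlist(obj$angles), ncol = 5,
                          dimnames = list(NULL, c("i", "j", "k", "theta0", "k_theta")))
  }
  if (length(obj$sites)) {
    topo$sites <- as.data.frame(obj$sites)
    topo$sites$partner <- as.integer(topo$sites$partner)
  }
  validate_topology(topo)
}

#' Replay a bond event log onto an initial topology
#'
#' Applies all events with `time_ps <= t` in chronological order,
#' reproducing the valence-valid topology at that instant. Replaying the
#' full log of a run yields the simulator's final topology exactly.
#'
#' @param events event log (columns time_ps, site_i, site_j, kind)
#' @param topology the initial topology
#' @param params the [react_params()] of the run (bond/angle geometry of
#'   formed disulfides)
#' @param t replay horizon in ps (default: all events)
#' @return the topology at time `t`
#' @export
replay_events <- function(events, topology, params, t = Inf) {
  ev <- events[order(events$time_ps), , drop = FALSE]
  ev <- ev[ev$time_ps <= t, , drop = FALSE]
  topo <- topology
  for (r in seq_len(nrow(ev))) {
    a <- ev$site_i[r]; b <- ev$site_j[r]
    topo <- if (ev$kind[r] == "formation") .apply_formation(topo, a, b, params)
            else .apply_breakage(topo, a, b)
  }
  validate_topology(topo)
}

#' Save / load a complete run directory
#'
#' Writes trajectory (`traj.xyz`), event log (`events.csv`), initial and
#' final topologies (JSON), the configuration (`config.yaml`) and a run
#' manifest (`manifest.json`) holding the config hash, master seed,
#' package version, scenario name and the file inventory, so the seed in
#' the manifest reproduces the run.
#'
#' @param run a `crxn_run`
#' @param dir output directory (created if needed)
#' @return `dir` / the restored `crxn_run` (without reaction parameters
#'   beyond those recorded in the manifest)
#' @export
save_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  write_trajectory(run$trajectory, file.path(dir, "traj.xyz"))
  write_bond_events(run$events, file.path(dir, "events.csv"))
  write_topology(run$topology_initial, file.path(dir, "topology_initial.json"))
  write_topology(run$topology, file.path(dir, "topology_final.json"))
  cfgfile <- file.path(dir, "config.yaml")
  yaml::write_yaml(c(unclass(run$config),
                     list(react = unclass(run$params)[
                       c("r_react", "k_on", "well_depth_E", "k0_off",
                         "attempt_interval", "bond_r0", "bond_k",
                         "angle_theta0", "angle_k")])), cfgfile)
  files <- c("traj.xyz", "events.csv", "topology_initial.json",
             "topology_final.json", "config.yaml")
  manifest <- list(config_hash = unname(tools::md5sum(cfgfile)),
                   master_seed = run$config$seed,
                   package_version = as.character(utils::packageVersion("crxn")),
                   scenario = run$config$scenario,
                   wall_time_start = t_start,
                   wall_time_end = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   outputs = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_run
#' @export
load_run <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  params <- do.call(react_params, cfg$react)
  cfg$react <- NULL
  config <- do.call(sim_config, cfg[setdiff(names(cfg), "scenario")])
  config$scenario <- cfg$scenario
  structure(list(trajectory = read_trajectory(file.path(dir, "traj.xyz")),
                 events = read_bond_events(file.path(dir, "events.csv")),
                 topology = read_topology(file.path(dir, "topology_final.json")),
                 topology_initial = read_topology(file.path(dir, "topology_initial.json")),
                 config = config, params = params, manifest = manifest),
            class = "crxn_run")
}
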