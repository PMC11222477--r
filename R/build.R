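# System construction: topology and frame objects, molecule templates,
# random/slab/droplet placement.

#' Create an (empty) topology object
#' @keywords internal
.empty_topology <- function() {
  structure(list(n_beads = 0L,
                 species = integer(0),       # index into species_table$name
                 molecule = integer(0),      # molecule id per bead
                 mol_type = character(0),    # per molecule
                 bonds = matrix(numeric(0), 0, 4,
                                dimnames = list(NULL, c("i", "j", "r0", "k"))),
                 angles = matrix(numeric(0), 0, 5,
                                 dimnames = list(NULL, c("i", "j", "k", "theta0", "k_theta"))),
                 sites = data.frame(bead = integer(0), monomer = integer(0),
                                    core = integer(0), partner = integer(0))),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  nb <- sum(x$sites$partner > 0) / 2
  cat("topology:", x$n_beads, "beads,", length(x$mol_type), "molecules (",
      paste(names(table(x$mol_type)), table(x$mol_type), collapse = ", "),
      "),", nrow(x$bonds), "bonds,", nrow(x$sites), "reactive sites (",
      nb, "disulfide bonds )\n")
  invisible(x)
}

#' Validate topology invariants (valence, partner symmetry)
#' @param topology a topology object
#' @return the topology, invisibly; errors on violation
#' @export
validate_topology <- function(topology) {
  s <- topology$sites
  if (nrow(s)) {
    bonded <- which(s$partner > 0)
    for (a in bonded) {
      p <- s$partner[a]
      if (s$partner[p] != a) stop("site partner relation is not symmetric")
      if (s$monomer[p] == s$monomer[a])
        stop("the two sites of one monomer must never be partners")
    }
    mono_sites <- table(s$monomer)
    if (any(mono_sites != 2)) stop("each monomer must own exactly 2 reactive sites")
  }
  if (nrow(topology$bonds)) {
    idx <- topology$bonds[, 1:2]
    if (any(idx < 1) || any(idx > topology$n_beads)) stop("bond index out of range")
  }
  invisible(topology)
}

# molecule templates: local coordinates, species names, bonds, angles -----

.peptide_template <- function(termini = c("neutral", "charged"),
                              bond_k = 2500) {
  termini <- match.arg(termini)
  term <- if (termini == "charged") "Q" else "L"
  species <- c(term, "F", "S", "S", "F", term)
  n <- length(species)
  pos <- cbind((seq_len(n) - (n + 1) / 2) * 0.38, 0, 0)
  bonds <- cbind(1:(n - 1), 2:n, 0.38, bond_k)
  angles <- cbind(1:(n - 2), 2:(n - 1), 3:n, pi, 10)
  list(species = species, pos = pos, bonds = bonds, angles = angles,
       type = "peptide", sites = NULL)
}

.monomer_template <- function(bond_k = 2500, tbt_angle_k = 100) {
  a <- 120 * pi / 180
  pos <- rbind(c(0, 0, 0),
               0.25 * c(cos(a / 2), sin(a / 2), 0),
               0.25 * c(cos(a / 2), -sin(a / 2), 0))
  bonds <- rbind(c(1, 2, 0.25, bond_k), c(1, 3, 0.25, bond_k))
  angles <- rbind(c(2, 1, 3, a, tbt_angle_k))
  list(species = c("B", "T", "T"), pos = pos, bonds = bonds, angles = angles,
       type = "monomer", sites = rbind(c(2, 1), c(3, 1)))  # (site bead, core bead)
}

.solvent_template <- function() {
  list(species = "W", pos = matrix(0, 1, 3), bonds = NULL, angles = NULL,
       type = "solvent", sites = NULL)
}

.random_rotation <- function() {
  # uniform random rotation from a normalized quaternion
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Build a simulation system
#'
#' Places molecules in the periodic box and assembles the topology. The
#' reference composition of the co-assembly study is 1500 peptides and 216
#' reactive monomers; the scenario presets use proportionally scaled-down
#' counts.
#'
#' @param config a [sim_config()]
#' @param composition named counts, e.g. `c(peptide = 100, monomer = 216)`;
#'   recognized names: `peptide`, `monomer`, `solvent`
#' @param placement `"random"`, `"slab"` (peptides restricted to a central
#'   slab along z) or `"droplet"` (all non-solvent molecule centres inside
#'   a sphere at the box centre)
#' @param species a [species_table()]
#' @param peptide_termini `"neutral"` (high-pH, sticky L termini) or
#'   `"charged"` (neutral-pH, +1 Q termini)
#' @param droplet_radius sphere radius in nm for droplet placement
#' @param slab_fraction fraction of the z edge occupied by the initial slab
#' @param overlap_tol minimum allowed distance between beads of different
#'   molecules during placement, nm
#' @param max_retries placement attempts per molecule before giving up
#' @return list with elements `topology` and `frame` (velocities drawn from
#'   the Maxwell-Boltzmann distribution at the configured kT)
#' @export
build_system <- function(config, composition, placement = "random",
                         species = species_table(),
                         peptide_termini = "neutral",
                         droplet_radius = NULL, slab_fraction = 0.35,
                         overlap_tol = 0.35, max_retries = 300L) {
  stopifnot(inherits(config, "sim_config"))
  .check_species(species)
  composition <- unlist(composition)
  if (any(composition < 0)) stop("composition counts must be >= 0")
  known <- c("peptide", "monomer", "solvent")
  if (length(composition) && !all(names(composition) %in% known))
    stop("unknown species in composition: ",
         paste(setdiff(names(composition), known), collapse = ", "))
  if (!placement %in% c("random", "slab", "droplet"))
    stop("invalid placement: ", placement)
  box <- config$box_lengths
  if (placement == "droplet") {
    if (is.null(droplet_radius)) stop("droplet placement requires droplet_radius")
    if (droplet_radius >= min(box) / 2)
      stop("droplet_radius must be < min(box)/2")
  }

  topo <- .empty_topology()
  n_tot <- sum(composition)
  if (n_tot == 0) {
    frame <- md_frame(positions = matrix(numeric(0), 0, 3), box = box)
    return(list(topology = topo, frame = frame))
  }

  templates <- list(peptide = .peptide_template(peptide_termini),
                    monomer = .monomer_template(),
                    solvent = .solvent_template())
  # build plan: solvent placed last so the solutes get first claim on space
  plan <- character(0)
  for (nm in c("peptide", "monomer", "solvent"))
    if (!is.na(composition[nm]) && composition[nm] > 0)
      plan <- c(plan, rep(nm, composition[nm]))

  pos_all <- matrix(NA_real_, 0, 3)
  spec_idx <- integer(0); mol_of <- integer(0)
  bonds <- list(); angles <- list(); sites <- list()
  mol_type <- character(0)
  half_slab <- slab_fraction * box[3] / 2

  for (m in seq_along(plan)) {
    tpl <- templates[[plan[m]]]
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      if (placement == "droplet" && plan[m] != "solvent") {
        repeat {
          cen <- runif(3, -droplet_radius, droplet_radius)
          if (sum(cen^2) <= droplet_radius^2) break
        }
        cen <- cen + box / 2
      } else if (placement == "slab" && plan[m] == "peptide") {
        cen <- c(runif(2) * box[1:2],
                 box[3] / 2 + runif(1, -half_slab, half_slab))
      } else {
        cen <- runif(3) * box
      }
      p <- tpl$pos %*% t(.random_rotation())
      p <- sweep(p, 2, cen, "+")
      if (nrow(pos_all)) {
        ok <- TRUE
        for (d in 1:3) { # wrap candidate for the distance check
          p[, d] <- p[, d] %% box[d]
        }
        dmin <- .min_dist_to(p, pos_all, box)
        ok <- dmin >= overlap_tol
      } else {
        for (d in 1:3) p[, d] <- p[, d] %% box[d]
        ok <- TRUE
      }
      if (ok) {
        off <- nrow(pos_all)
        pos_all <- rbind(pos_all, p)
        spec_idx <- c(spec_idx, match(tpl$species, species$name))
        mol_of <- c(mol_of, rep(m, nrow(p)))
        mol_type <- c(mol_type, tpl$type)
        if (!is.null(tpl$bonds)) {
          b <- tpl$bonds; b[, 1:2] <- b[, 1:2] + off; bonds[[length(bonds) + 1]] <- b
        }
        if (!is.null(tpl$angles)) {
          a <- tpl$angles; a[, 1:3] <- a[, 1:3] + off; angles[[length(angles) + 1]] <- a
        }
        if (!is.null(tpl$sites)) {
          s <- tpl$sites
          sites[[length(sites) + 1]] <-
            data.frame(bead = s[, 1] + off, monomer = m, core = s[, 2] + off,
                       partner = 0L)
        }
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf(paste0("packing failure after %d retries at number density ",
                          "%.3f beads/nm^3; reduce composition or enlarge the box"),
                   max_retries, nrow(pos_all) / prod(box)))
  }

  topo$n_beads <- nrow(pos_all)
  topo$species <- spec_idx
  topo$molecule <- mol_of
  topo$mol_type <- mol_type
  if (length(bonds)) topo$bonds <- do.call(rbind, bonds)
  if (length(angles)) topo$angles <- do.call(rbind, angles)
  if (length(sites)) topo$sites <- do.call(rbind, sites)
  colnames(topo$bonds) <- c("i", "j", "r0", "k")
  colnames(topo$angles) <- c("i", "j", "k", "theta0", "k_theta")
  validate_topology(topo)

  kT <- config$temperature_kT
  mass <- species$mass[spec_idx]
  vel <- matrix(rnorm(3 * topo$n_beads), ncol = 3) * sqrt(kT / mass)
  frame <- md_frame(positions = pos_all, velocities = vel, box = box)
  list(topology = topo, frame = frame)
}

# minimum over rows of p of the min-image distance to any row of q
.min_dist_to <- function(p, q, box) {
  best <- Inf
  for (r in seq_len(nrow(p))) {
    d <- sweep(q, 2, p[r, ], "-")
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    best <- min(best, sqrt(min(rowSums(d * d))))
  }
  best
}

#' Construct a frame (positions + periodic bookkeeping)
#'
#' @param positions N x 3 matrix, nm; wrapped into the box
#' @param velocities N x 3 matrix, nm/ps (default zero)
#' @param box periodic box lengths, nm
#' @param images N x 3 integer matrix of image counts (unwrapped position =
#'   wrapped + images * box)
#' @param time frame time, ps
#' @return an object of class `md_frame`
#' @export
md_frame <- function(positions, velocities = NULL, box, images = NULL,
                     time = 0) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  if (is.null(images)) images <- matrix(0L, n, 3)
  storage.mode(images) <- "integer"
  if (n) for (d in 1:3) {
    w <- floor(positions[, d] / box[d])
    positions[, d] <- positions[, d] - w * box[d]
    images[, d] <- images[, d] + as.integer(w)
  }
  structure(list(time = time, positions = positions,
                 images = images, velocities = as.matrix(velocities),
                 box = as.numeric(box)),
            class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  cat("md_frame: t =", x$time, "ps,", nrow(x$positions), "beads, box",
      paste(format(x$box), collapse = " x "), "nm\n")
  invisible(x)
}
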