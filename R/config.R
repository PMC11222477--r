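#' Simulation configuration
#'
#' Bundles the box, thermostat, integration and output settings of a run.
#' Units: nm, ps, amu, kJ/mol.
#'
#' @param box_lengths numeric length-3, periodic box edge lengths in nm
#' @param temperature_kT thermal energy in kJ/mol (2.494 corresponds to 300 K)
#' @param timestep integration timestep in ps (0.02 ps = 20 fs)
#' @param n_steps number of integration steps
#' @param friction_gamma Langevin friction in 1/ps; 0 gives velocity Verlet
#' @param pair_cutoff nonbonded cutoff in nm (Lennard-Jones and screened
#'   Coulomb are truncated and shifted here)
#' @param seed master RNG seed, or NULL to use the current RNG state
#' @param output_interval frames are stored every this many steps
#' @param explicit_solvent logical, whether solvent beads are present
#' @param charge_screening list with elements `enabled` (logical),
#'   `debye_length` (nm) and `bjerrum_prefactor` (kJ nm/mol per unit charge
#'   pair) controlling the Yukawa electrostatics
#' @param scenario optional preset name this config was derived from
#' @return an object of class `sim_config`
#' @export
sim_config <- function(box_lengths,
                       temperature_kT = 2.494,
                       timestep = 0.02,
                       n_steps = 10000L,
                       friction_gamma = 1,
                       pair_cutoff = 1.1,
                       seed = NULL,
                       output_interval = 1000L,
                       explicit_solvent = FALSE,
                       charge_screening = list(enabled = FALSE,
                                               debye_length = 0.8,
                                               bjerrum_prefactor = 5.0),
                       scenario = NA_character_) {
  box_lengths <- as.numeric(box_lengths)
  stopifnot(length(box_lengths) == 3, all(is.finite(box_lengths)))
  if (any(box_lengths <= 2 * pair_cutoff))
    stop("box_lengths must exceed 2*pair_cutoff in every dimension")
  if (timestep <= 0) stop("timestep must be positive")
  if (temperature_kT < 0) stop("temperature_kT must be >= 0")
  if (output_interval < 1) stop("output_interval must be >= 1")
  cs <- utils::modifyList(list(enabled = FALSE, debye_length = 0.8,
                               bjerrum_prefactor = 5.0), charge_screening)
  structure(list(box_lengths = box_lengths,
                 temperature_kT = temperature_kT,
                 timestep = timestep,
                 n_steps = as.integer(n_steps),
                 friction_gamma = friction_gamma,
                 pair_cutoff = pair_cutoff,
                 seed = seed,
                 output_interval = as.integer(output_interval),
                 explicit_solvent = isTRUE(explicit_solvent),
                 charge_screening = cs,
                 scenario = scenario),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: box", paste(format(x$box_lengths), collapse = " x "),
      "nm, kT =", x$temperature_kT, "kJ/mol\n")
  cat("  dt =", x$timestep, "ps, n_steps =", x$n_steps,
      ", gamma =", x$friction_gamma, "/ps, cutoff =", x$pair_cutoff, "nm\n")
  cat("  screening:", if (x$charge_screening$enabled) "on" else "off",
      " solvent:", if (x$explicit_solvent) "explicit" else "implicit", "\n")
  invisible(x)
}

#' Bead species table of the reduced model
#'
#' Seven bead types make up the model. The peptide is a 6-bead
#' sticker-spacer chain L-F-S-S-F-L: leucine/phenylalanine stickers carry
#' the attractive epsilons and the disulfide spacer is two weak S beads.
#' At neutral pH the two terminal beads are replaced by charged,
#' hydrophilic Q beads (+1 each), which both removes their sticker
#' attraction and adds screened-Coulomb repulsion, suppressing phase
#' separation; at high pH they are neutral sticky L beads. The bifunctional
#' reactive monomer is a benzene core bead B with two thiol site beads T at
#' 120 degrees (meta substitution). W is an optional explicit solvent bead.
#'
#' The pairwise well depths were parameterized once so that (i) the
#' high-pH peptide slab is a stable condensed liquid at kT = 2.494 while
#' the charged-termini variant dissolves, and (ii) monomers preferentially
#' partition into the peptide-rich phase, mirroring the phenomenology of
#' chemically detailed (Martini-style) models of the same system.
#'
#' @param sticker_eps well depth (kJ/mol) for sticker-sticker contacts
#' @param core_sticker_eps well depth for benzene-core/sticker contacts
#' @return an object of class `species_table`: vectors `name`, `mass`
#'   (amu), `sigma` (nm), `charge` (e) and the symmetric pair matrix
#'   `epsilon` (kJ/mol)
#' @export
species_table <- function(sticker_eps = 2.6, core_sticker_eps = 3.0) {
  name <- c("L", "F", "S", "Q", "B", "T", "W")
  mass <- c(72, 72, 54, 72, 78, 33, 72)
  sigma <- c(0.47, 0.47, 0.41, 0.47, 0.43, 0.35, 0.47)
  charge <- c(0, 0, 0, 1, 0, 0, 0)
  n <- length(name)
  eps <- matrix(0.5, n, n, dimnames = list(name, name))
  stick <- c("L", "F")
  eps[stick, stick] <- sticker_eps
  eps[stick, "S"] <- eps["S", stick] <- 1.2
  eps["S", "S"] <- 0.8
  eps["Q", ] <- eps[, "Q"] <- 0.8          # hydrophilic terminus: weak LJ
  eps["B", stick] <- eps[stick, "B"] <- core_sticker_eps
  eps["B", "B"] <- 1.8
  eps["B", c("S", "Q")] <- eps[c("S", "Q"), "B"] <- 0.8
  # thiol sites are pure bonded satellites (no nonbonded term): the core bead
  # provides the excluded volume, and bond scission then never uncovers a
  # compressed LJ contact
  eps["T", ] <- eps[, "T"] <- 0
  eps["W", ] <- eps[, "W"] <- 0.9
  eps["W", "W"] <- 1.0
  eps["W", "Q"] <- eps["Q", "W"] <- 1.2
  eps["W", "T"] <- eps["T", "W"] <- 0
  structure(list(name = name, mass = setNames(mass, name),
                 sigma = setNames(sigma, name),
                 charge = setNames(charge, name), epsilon = eps),
            class = "species_table")
}

#' @export
print.species_table <- function(x, ...) {
  cat("species_table with", length(x$name), "bead types:",
      paste(x$name, collapse = " "), "\n")
  cat("epsilon (kJ/mol):\n")
  print(round(x$epsilon, 2))
  invisible(x)
}

# validated access: pair sigma by Lorentz mixing
.pair_sigma <- function(sp) outer(sp$sigma, sp$sigma, function(a, b) (a + b) / 2)

.check_species <- function(sp) {
  stopifnot(inherits(sp, "species_table"))
  if (!isTRUE(all.equal(sp$epsilon, t(sp$epsilon))))
    stop("epsilon matrix must be symmetric")
  if (any(sp$sigma <= 0) || any(sp$mass <= 0))
    stop("sigma and mass must be positive")
  invisible(sp)
}

#' Parameters of the stochastic disulfide reaction scheme
#'
#' Thiol sites within the capture radius of each other attempt to form an
#' intermolecular bond with probability `1 - exp(-k_on * dt_attempt)`. A
#' formed bond breaks with probability
#' `1 - exp(-k0_off * exp(-well_depth_E/kT) * dt_attempt)`: the stated well
#' depth enters an Arrhenius factor, so the default 60 kJ/mol is
#' effectively irreversible on simulation time scales while 20 kJ/mol
#' gives observable disulfide exchange. On formation a harmonic
#' thiol-thiol bond plus two core-thiol-thiol angle terms are added.
#'
#' @param r_react capture radius in nm (must stay below the pair cutoff)
#' @param k_on attempt rate in 1/ps
#' @param well_depth_E effective well depth in kJ/mol (60 default; 20 for
#'   the reversible preset)
#' @param k0_off Arrhenius prefactor in 1/ps; 0 disables breakage
#' @param attempt_interval reaction sweep every this many steps
#' @param bond_r0,bond_k formed-bond rest length (nm) and stiffness
#'   (kJ/mol/nm^2)
#' @param angle_theta0,angle_k formed core-thiol-thiol angle (degrees) and
#'   stiffness (kJ/mol/rad^2)
#' @return an object of class `react_params`; element `reversible` is
#'   derived as `k0_off > 0`
#' @export
react_params <- function(r_react = 0.4, k_on = 50, well_depth_E = 60,
                         k0_off = 0, attempt_interval = 10L,
                         bond_r0 = 0.30, bond_k = 2500,
                         angle_theta0 = 150, angle_k = 100) {
  if (well_depth_E <= 0) stop("well_depth_E must be positive")
  if (r_react <= 0) stop("r_react must be positive")
  if (k0_off < 0) stop("k0_off must be >= 0")
  structure(list(r_react = r_react, k_on = k_on, well_depth_E = well_depth_E,
                 k0_off = k0_off, attempt_interval = as.integer(attempt_interval),
                 bond_r0 = bond_r0, bond_k = bond_k,
                 angle_theta0 = angle_theta0, angle_k = angle_k,
                 reversible = k0_off > 0),
            class = "react_params")
}

#' @export
print.react_params <- function(x, ...) {
  cat("react_params: r_react =", x$r_react, "nm, k_on =", x$k_on, "/ps,",
      "E =", x$well_depth_E, "kJ/mol,",
      if (x$reversible) paste("k0_off =", x$k0_off, "/ps (reversible)")
      else "irreversible", "\n")
  invisible(x)
}
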