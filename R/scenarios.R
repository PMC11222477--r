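# Scenario presets: the study conditions at desk scale.
#
# The reference compositions (216 reactive monomers; co-assembly systems
# of 500/1500/2500 peptides; ~94 mM reactant concentration matched inside
# condensates) are retained where feasible and scaled down proportionally
# where the full system would be out of desk reach; box sizes set the
# concentrations. See the methods vignette for the sizing rationale.

.SCENARIOS <- c("aqueous", "aqueous-concentrated", "droplet-prepartitioned",
                "coassembly-500", "coassembly-1500", "coassembly-2500",
                "slab", "neutral-ph", "high-ph")

#' Scenario presets
#'
#' Returns the configuration, composition, placement and reaction
#' parameters of a named study condition:
#' \describe{
#'   \item{aqueous}{216 monomers alone, dilute (about 16 mM)}
#'   \item{aqueous-concentrated}{216 monomers at the condensate-interior
#'     concentration (about 94 mM)}
#'   \item{droplet-prepartitioned}{monomers pre-placed inside a peptide
#'     droplet}
#'   \item{coassembly-500/1500/2500}{dispersed peptides + monomers at
#'     increasing peptide fraction (2/6/12 weight percent); reactions and
#'     phase separation proceed together}
#'   \item{slab, high-ph}{peptide slab with neutral (sticky) termini:
#'     stable condensate; a few monomer tracers included}
#'   \item{neutral-ph}{same slab but charged termini with screening on:
#'     the slab dissolves}
#' }
#'
#' @param name one of the preset names (see above)
#' @return list with `config` (carrying the species table as an
#'   attribute), `composition`, `placement`, `params`, `build_args`
#' @export
scenario <- function(name) {
  if (!name %in% .SCENARIOS)
    stop("unknown scenario: ", name, " (available: ",
         paste(.SCENARIOS, collapse = ", "), ")")
  sp <- species_table()
  base <- function(box, n_steps, out = 2000L, screening = FALSE) {
    cfg <- sim_config(box_lengths = box, n_steps = n_steps,
                      output_interval = out, scenario = name,
                      charge_screening = list(enabled = screening))
    attr(cfg, "species") <- sp
    cfg
  }
  irrev <- react_params()
  # co-assembly runs are reaction-limited (small per-contact probability) so
  # the observed rate couples to the local reactant concentration that the
  # condensates build up; the monomer-only presets are capture-limited
  slow <- react_params(k_on = 0.01)
  switch(name,
    "aqueous" = list(
      config = base(c(28, 28, 28), 300000L),
      composition = c(monomer = 216), placement = "random",
      params = irrev, build_args = list()),
    "aqueous-concentrated" = list(
      config = base(c(15.6, 15.6, 15.6), 300000L),
      composition = c(monomer = 216), placement = "random",
      params = irrev, build_args = list()),
    "droplet-prepartitioned" = list(
      config = base(c(14, 14, 14), 200000L),
      composition = c(peptide = 60, monomer = 16), placement = "droplet",
      params = irrev, build_args = list(droplet_radius = 4.5)),
    "coassembly-500" = list(
      config = base(c(9.5, 9.5, 9.5), 40000L),
      composition = c(peptide = 12, monomer = 24), placement = "random",
      params = slow, build_args = list()),
    "coassembly-1500" = list(
      config = base(c(9.5, 9.5, 9.5), 40000L),
      composition = c(peptide = 36, monomer = 24), placement = "random",
      params = slow, build_args = list()),
    "coassembly-2500" = list(
      config = base(c(9.5, 9.5, 9.5), 40000L),
      composition = c(peptide = 72, monomer = 24), placement = "random",
      params = slow, build_args = list()),
    "slab" = ,
    "high-ph" = list(
      config = base(c(5.5, 5.5, 16.5), 150000L, out = 1000L),
      composition = c(peptide = 110, monomer = 10), placement = "slab",
      params = irrev,
      build_args = list(peptide_termini = "neutral", slab_fraction = 0.32)),
    "neutral-ph" = list(
      config = base(c(5.5, 5.5, 16.5), 150000L, out = 1000L,
                    screening = TRUE),
      composition = c(peptide = 110, monomer = 10), placement = "slab",
      params = irrev,
      build_args = list(peptide_termini = "charged", slab_fraction = 0.32))
  )
}

#' Run a scenario preset
#'
#' Builds the system and runs it. With `until_consumed` set, the run
#' proceeds in chunks of `config$n_steps` until the requested fraction of
#' monomers has reacted (or `max_steps` is hit). The master seed makes
#' the whole run, including placement, reproducible.
#'
#' @param name preset name, see [scenario()]
#' @param seed master RNG seed
#' @param n_steps override of the preset step count
#' @param react logical, enable the reaction sweeps (default TRUE)
#' @param until_consumed target consumed-monomer fraction in (0, 1), or
#'   NULL for a fixed-length run
#' @param max_steps cap on the total steps in chunked mode
#' @return a `crxn_run`
#' @export
run_scenario <- function(name, seed = 1L, n_steps = NULL, react = TRUE,
                         until_consumed = NULL, max_steps = 1500000L) {
  sc <- scenario(name)
  if (!is.null(n_steps)) sc$config$n_steps <- as.integer(n_steps)
  sc$config$seed <- NULL
  set.seed(seed)
  sys <- do.call(build_system,
                 c(list(config = sc$config, composition = sc$composition,
                        placement = sc$placement,
                        species = attr(sc$config, "species")),
                   sc$build_args))
  run <- run_simulation(sc$config, sys$topology, sys$frame, sc$params,
                        react = react)
  run$config$seed <- seed
  if (!is.null(until_consumed) && react) {
    steps_done <- sc$config$n_steps
    while (consumed_fraction(run$topology) < until_consumed &&
           steps_done < max_steps) {
      run <- continue_run(run, sc$config$n_steps)
      steps_done <- steps_done + sc$config$n_steps
    }
    run$config$seed <- seed
  }
  run
}

#' Fraction of monomers consumed (at least one site bonded)
#' @param topology a topology with reactive sites
#' @return fraction in `[0, 1]`
#' @export
consumed_fraction <- function(topology) {
  s <- topology$sites
  if (!nrow(s)) return(0)
  reacted <- tapply(s$partner > 0, s$monomer, any)
  mean(reacted)
}
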