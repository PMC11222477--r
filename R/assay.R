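# Experimental partition-assay arithmetic: calibration curves,
# mass-balance condensate concentrations, partition coefficients, and
# conversion to transfer free energies.

#' Fit a linear calibration curve
#'
#' Ordinary least squares of peak area against standard concentration,
#' with a free intercept. Concentrations are recovered from areas by
#' inverse prediction `conc = (area - intercept)/slope`.
#'
#' @param concentration standard concentrations, mM (>= 2 distinct values;
#'   the assay standards are 0.05, 0.1, 0.15 and 0.2 mM)
#' @param peak_area measured peak areas, a.u.
#' @return object of class `calibration_curve`: `slope`, `intercept`,
#'   `r_squared`, plus the underlying `lm` fit
#' @export
fit_calibration <- function(concentration, peak_area) {
  if (length(unique(concentration)) < 2)
    stop("calibration needs >= 2 distinct concentrations")
  fit <- lm(peak_area ~ concentration)
  tss <- sum((peak_area - mean(peak_area))^2)
  r2 <- if (tss > 0) 1 - sum(residuals(fit)^2) / tss else 1
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2, fit = fit,
                 standards = data.frame(concentration = concentration,
                                        peak_area = peak_area)),
            class = "calibration_curve")
}

#' Inverse prediction from a calibration curve
#' @param curve a [fit_calibration()] result
#' @param peak_area areas to convert
#' @return concentrations in mM
#' @export
predict_concentration <- function(curve, peak_area) {
  (peak_area - curve$intercept) / curve$slope
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve: area = %.4g * conc %+.4g (r^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Partition coefficient from the centrifugation mass balance
#'
#' The condensate concentration follows from the printed mass-balance
#' formula `C_condensate = (C_total - n C_supernatant) * (V_total /
#' V_condensate)` with `n = V_supernatant / V_total` and `V_condensate =
#' V_total - V_supernatant`. Then `K = C_condensate / C_supernatant` and
#' `dG = -R T ln K`. The identity `C_total V_total = C_sup V_sup +
#' C_cond V_cond` holds exactly by construction and is re-checked.
#'
#' @param C_total,C_supernatant concentrations, mM
#' @param V_total,V_supernatant volumes, uL (V_supernatant < V_total)
#' @param temperature kelvin (default 300)
#' @param species,replicate optional identifiers (vectorized)
#' @return data.frame of class `assay_record` with columns `species`,
#'   `replicate`, `C_total`, `C_supernatant`, `C_condensate`, `V_total`,
#'   `V_supernatant`, `V_condensate`, `n`, `K`, `dG`
#' @export
compute_partition <- function(C_total, C_supernatant, V_total, V_supernatant,
                              temperature = 300, species = NA, replicate = NA) {
  if (any(C_total < 0) || any(C_supernatant < 0))
    stop("concentrations must be >= 0")
  if (any(V_total <= 0) || any(V_supernatant <= 0))
    stop("volumes must be positive")
  if (any(V_supernatant >= V_total))
    stop("V_supernatant must be smaller than V_total")
  if (any(C_supernatant == 0))
    stop("C_supernatant = 0: K undefined")
  n <- V_supernatant / V_total
  V_cond <- V_total - V_supernatant
  C_cond <- (C_total - n * C_supernatant) * (V_total / V_cond)
  if (any(C_cond < 0))
    stop("negative condensate concentration: inconsistent inputs")
  balance <- C_total * V_total - (C_supernatant * V_supernatant + C_cond * V_cond)
  if (any(abs(balance) > 1e-9 * C_total * V_total))
    stop("mass balance violated")   # cannot happen by construction
  K <- C_cond / C_supernatant
  dG <- -.R_GAS * temperature * log(K)
  structure(data.frame(species = species, replicate = replicate,
                       C_total = C_total, C_supernatant = C_supernatant,
                       C_condensate = C_cond, V_total = V_total,
                       V_supernatant = V_supernatant, V_condensate = V_cond,
                       n = n, K = K, dG = dG),
            class = c("assay_record", "data.frame"))
}

#' Summarize assay replicates per species
#'
#' Reports the replicate mean and SD of K, the transfer free energy of the
#' mean, and its first-order propagated error `RT * SD(K) / mean(K)`.
#'
#' @param records an `assay_record` data.frame (>= 2 replicates per
#'   species)
#' @param temperature kelvin
#' @return data.frame with one row per species: `K_mean`, `K_sd`, `dG`,
#'   `dG_err` (kJ/mol), `n_replicates`
#' @export
summarize_replicates <- function(records, temperature = 300) {
  sp <- split(records, records$species)
  out <- do.call(rbind, lapply(sp, function(r) {
    if (nrow(r) < 2) stop("need >= 2 replicates per species")
    RT <- .R_GAS * temperature
    km <- mean(r$K); ks <- sd(r$K)
    data.frame(species = r$species[1], n_replicates = nrow(r),
               K_mean = km, K_sd = ks,
               dG = -RT * log(km), dG_err = RT * ks / km)
  }))
  rownames(out) <- NULL
  out
}

#' Transfer free energy from a partition coefficient
#'
#' `dG = -R T ln K`; at 300 K a measured K = 5.6 corresponds to
#' -4.3 kJ/mol.
#'
#' @param K partition coefficient (> 0)
#' @param temperature kelvin
#' @return dG in kJ/mol
#' @export
#' @examples
#' dG_from_K(5.6)   # about -4.3
dG_from_K <- function(K, temperature = 300) {
  stopifnot(all(K > 0))
  -.R_GAS * temperature * log(K)
}
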