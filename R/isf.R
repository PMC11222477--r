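# Incoherent (self) intermediate scattering functions, exponential-decay
# fits with AIC model selection, and a synthetic Brownian track generator.

#' Unwrap a trajectory across periodic boundaries
#'
#' Uses the stored image counts (unwrapped = wrapped + images * box). If
#' the trajectory carries no image counts, images are reconstructed from
#' frame-to-frame minimum-image displacements, which requires every
#' per-frame displacement to stay below half the box.
#'
#' @param traj a trajectory
#' @return list of N x 3 matrices of continuous coordinates, one per frame
#' @export
unwrap <- function(traj) {
  box <- traj$box
  nf <- n_frames(traj)
  if (!is.null(traj$images)) {
    return(lapply(seq_len(nf), function(f)
      traj$positions[[f]] + sweep(traj$images[[f]], 2, box, "*")))
  }
  out <- vector("list", nf)
  out[[1]] <- traj$positions[[1]]
  for (f in seq_len(nf - 1)) {
    d <- traj$positions[[f + 1]] - traj$positions[[f]]
    for (k in 1:3) {
      shift <- round(d[, k] / box[k])
      if (any(abs(d[, k] - shift * box[k]) >= box[k] / 2))
        stop("displacement >= box/2 between frames ", f, " and ", f + 1,
             ": output interval too sparse to unwrap")
      d[, k] <- d[, k] - shift * box[k]
    }
    out[[f + 1]] <- out[[f]] + d
  }
  out
}

#' Re-wrap unwrapped coordinates into the box
#' @param unwrapped list of N x 3 matrices
#' @param box box lengths, nm
#' @return list of wrapped N x 3 matrices
#' @export
wrap_positions <- function(unwrapped, box) {
  lapply(unwrapped, function(p) {
    for (k in 1:3) p[, k] <- p[, k] %% box[k]
    p
  })
}

#' Incoherent intermediate scattering function
#'
#' Isotropic self-ISF estimator
#' `F_s(q, t) = < sin(q |dr|) / (q |dr|) >` averaged over particles and
#' evenly spaced time origins. `F_s(q, 0) = 1` exactly; for Fickian
#' diffusion `F_s(q, t) = exp(-q^2 D t)`.
#'
#' @param x a trajectory, or a list of N x 3 unwrapped coordinate matrices
#' @param q wavevector magnitude, 1/nm (> 0); the default probes
#'   bead-scale displacements, q = 2*pi/0.47 nm^-1 (about 13.4)
#' @param times frame times in ps (taken from the trajectory if omitted)
#' @param species optional selection (as in [density_profile()] selections
#'   by bead species label) restricting the particles; requires a
#'   trajectory input
#' @param n_origins number of evenly spaced time origins
#' @param lags integer frame lags to evaluate (default: up to 40 lags
#'   spanning half the trajectory)
#' @return object of class `isf_curve`: data.frame with `lag_ps`, `value`,
#'   `n_samples`; attribute `q`
#' @export
compute_isf <- function(x, q = 2 * pi / 0.47, times = NULL, species = NULL,
                        n_origins = 20L, lags = NULL) {
  if (q <= 0) stop("q must be positive")
  if (inherits(x, "trajectory")) {
    if (is.null(times)) times <- x$times
    pick <- if (is.null(species)) seq_along(x$species)
            else which(x$species %in% species)
    if (!length(pick)) stop("species selection matched no particles")
    un <- lapply(unwrap(x), function(p) p[pick, , drop = FALSE])
  } else if (inherits(x, "brownian_tracks")) {
    un <- x$positions
    if (is.null(times)) times <- x$times
  } else {
    un <- x
    if (is.null(times)) stop("supply frame times for raw coordinate input")
  }
  nf <- length(un)
  if (is.null(lags)) {
    lmax <- max(1L, nf %/% 2)
    lags <- unique(round(seq(0, lmax, length.out = min(lmax + 1L, 41L))))
  }
  lags <- sort(unique(as.integer(lags)))
  if (max(lags) >= nf) stop("lags exceed the trajectory span")
  vals <- numeric(length(lags)); ns <- integer(length(lags))
  for (il in seq_along(lags)) {
    lag <- lags[il]
    if (lag == 0) { vals[il] <- 1; ns[il] <- nrow(un[[1]]) * n_origins; next }
    origins <- unique(round(seq(1, nf - lag, length.out = n_origins)))
    acc <- 0; cnt <- 0L
    for (o in origins) {
      dr <- un[[o + lag]] - un[[o]]
      r <- sqrt(rowSums(dr * dr))
      sinc <- ifelse(r < 1e-12, 1, sin(q * r) / (q * r))
      acc <- acc + sum(sinc); cnt <- cnt + length(r)
    }
    vals[il] <- acc / cnt; ns[il] <- cnt
  }
  if (any(ns < 10))
    warning("fewer than 10 particle-origin samples at some lags")
  dt_lag <- if (length(times) > 1) times[2] - times[1] else 1
  out <- data.frame(lag_ps = lags * dt_lag, value = vals, n_samples = ns)
  structure(out, class = c("isf_curve", "data.frame"), q = q)
}

#' Synthetic Brownian (Fickian) tracks
#'
#' Generates independent Gaussian random walks, optionally as a mixture of
#' diffusion populations: per step each coordinate gains an increment with
#' variance `2 D_i dt`. Population labels are deterministic (the first
#' `round(n * fraction_1)` particles belong to population 1, and so on).
#'
#' @param n_particles number of particles
#' @param D diffusion coefficient(s), nm^2/ps (vector for a mixture)
#' @param dt frame spacing, ps
#' @param n_steps number of steps (frames = n_steps + 1)
#' @param fractions population fractions summing to 1 (required when D has
#'   length > 1)
#' @param box optional box lengths; positions then start uniformly in the
#'   box (coordinates remain unwrapped)
#' @param seed optional RNG seed
#' @return list of class `brownian_tracks`: `positions` (list of N x 3
#'   unwrapped matrices), `times`, `labels`, `D`
#' @export
generate_brownian_tracks <- function(n_particles, D, dt, n_steps,
                                     fractions = NULL, box = NULL,
                                     seed = NULL) {
  if (any(D < 0)) stop("negative D")
  if (!is.null(seed)) set.seed(seed)
  if (length(D) > 1) {
    if (is.null(fractions) || length(fractions) != length(D))
      stop("supply one fraction per D")
    if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
    counts <- round(n_particles * fractions)
    counts[length(counts)] <- n_particles - sum(counts[-length(counts)])
    labels <- rep(seq_along(D), counts)
  } else labels <- rep(1L, n_particles)
  Dp <- D[labels]
  p0 <- if (is.null(box)) matrix(0, n_particles, 3)
        else cbind(runif(n_particles) * box[1], runif(n_particles) * box[2],
                   runif(n_particles) * box[3])
  pos <- vector("list", n_steps + 1)
  pos[[1]] <- p0
  sdv <- sqrt(2 * Dp * dt)
  for (s in seq_len(n_steps))
    pos[[s + 1]] <- pos[[s]] + matrix(rnorm(3 * n_particles), ncol = 3) * sdv
  structure(list(positions = pos, times = (0:n_steps) * dt, labels = labels,
                 D = D), class = "brownian_tracks")
}

#' Fit single and weighted-double exponential decays, select by AIC
#'
#' Both models, `A exp(-t/tau)` (k = 2 parameters) and
#' `A (w exp(-t/tau1) + (1 - w) exp(-t/tau2))` (k = 4), are fitted by
#' nonlinear least squares with multiple starting points; the model with
#' the lower `AIC = n log(RSS/n) + 2k` is selected. A double fit is
#' degenerate -- and falls back to the single model -- when its time
#' constants agree within 5% or when one component carries less than 5%
#' of the weight (an unidentifiable second population).
#'
#' @param curve an [compute_isf()] result, or a data.frame with columns
#'   `lag_ps` and `value` (>= 8 points, decayed below 0.9 somewhere)
#' @return object of class `decay_fit`: `single` and `double` component
#'   fits (parameters, `rss`, `aic`), `selected` (`"single"` or
#'   `"double"`), `delta_aic` (AIC_double - AIC_single), `note`
#' @export
fit_decay <- function(curve) {
  t <- curve$lag_ps; y <- curve$value
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 8) stop("need >= 8 lag points")
  if (min(y) > 0.9) stop("curve has not decayed below 0.9: extend the lags")
  n <- length(t)
  # tau guess: first crossing of 1/e (linear interpolation)
  tau_e <- {
    below <- which(y < exp(-1))
    if (length(below)) {
      i <- below[1]
      if (i == 1) t[1] else {
        t[i - 1] + (t[i] - t[i - 1]) * (y[i - 1] - exp(-1)) / (y[i - 1] - y[i])
      }
    } else max(t)
  }
  tau_e <- max(tau_e, 1e-6)
  df <- data.frame(t = t, y = y)
  fit1 <- tryCatch(minpack.lm::nlsLM(y ~ A * exp(-t / tau), data = df,
                                     start = list(A = 1, tau = tau_e),
                                     lower = c(A = 0, tau = 1e-9),
                                     control = minpack.lm::nls.lm.control(maxiter = 200)),
                   error = function(e) NULL)
  if (is.null(fit1)) stop("single-exponential fit failed")
  rss1 <- sum(residuals(fit1)^2)
  single <- c(as.list(coef(fit1)), rss = rss1, aic = n * log(rss1 / n) + 2 * 2)

  best <- NULL
  for (w0 in c(0.3, 0.5, 0.7)) for (sp in c(4, 10)) {
    f2 <- tryCatch(minpack.lm::nlsLM(
      y ~ A * (w * exp(-t / tau1) + (1 - w) * exp(-t / tau2)), data = df,
      start = list(A = 1, w = w0, tau1 = tau_e / sp, tau2 = tau_e * sp / 2),
      lower = c(A = 0, w = 0.01, tau1 = 1e-9, tau2 = 1e-9),
      upper = c(A = Inf, w = 0.99, tau1 = Inf, tau2 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(f2)) {
      r <- sum(residuals(f2)^2)
      if (is.null(best) || r < best$rss) best <- list(fit = f2, rss = r)
    }
  }
  note <- NULL
  if (is.null(best)) {
    double <- list(rss = Inf, aic = Inf)
    selected <- "single"
    note <- "double fit did not converge"
  } else {
    p <- as.list(coef(best$fit))
    if (p$tau1 > p$tau2) {  # enforce tau1 <= tau2
      tmp <- p$tau1; p$tau1 <- p$tau2; p$tau2 <- tmp; p$w <- 1 - p$w
    }
    rss2 <- best$rss
    double <- c(p, rss = rss2, aic = n * log(rss2 / n) + 2 * 4)
    if (abs(p$tau2 - p$tau1) / p$tau2 < 0.05) {
      selected <- "single"
      note <- "degenerate double fit (tau1 ~ tau2): single model retained"
    } else if (p$w < 0.05 || p$w > 0.95) {
      selected <- "single"
      note <- "degenerate double fit (component weight < 5%): single model retained"
    } else {
      selected <- if (double$aic < single$aic) "double" else "single"
    }
  }
  structure(list(single = single, double = double, selected = selected,
                 delta_aic = double$aic - single$aic, note = note,
                 n = n),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("decay_fit: selected", x$selected, "model (dAIC =",
      signif(x$delta_aic, 4), ")\n")
  cat(sprintf("  single: A = %.3f, tau = %.3g ps (AIC %.1f)\n",
              x$single$A, x$single$tau, x$single$aic))
  if (is.finite(x$double$aic))
    cat(sprintf("  double: w = %.2f, tau1 = %.3g, tau2 = %.3g ps (AIC %.1f)\n",
                x$double$w, x$double$tau1, x$double$tau2, x$double$aic))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Diffusion coefficient from an ISF decay time
#'
#' For Fickian decay `F_s = exp(-q^2 D t)`, `D = 1 / (q^2 tau)`.
#'
#' @param q wavevector, 1/nm
#' @param tau decay time, ps
#' @return D in nm^2/ps
#' @export
diffusion_from_tau <- function(q, tau) {
  stopifnot(q > 0, tau > 0)
  1 / (q^2 * tau)
}
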