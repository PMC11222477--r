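# Monomer-level disulfide bond graph and the ring/chain/monomer census.

#' Project site bonds onto a monomer-level multigraph
#'
#' Nodes are reactive monomers; every bonded thiol-site pair becomes one
#' edge. Parallel edges are preserved (two monomers joined by both of
#' their thiol pairs form the 2-ring). Valence guarantees degree <= 2.
#'
#' @param topology a topology with reactive sites
#' @return object of class `monomer_graph`: list with `nodes` (monomer
#'   ids) and `edges` (two-column matrix of monomer ids)
#' @export
build_bond_graph <- function(topology) {
  s <- topology$sites
  nodes <- sort(unique(s$monomer))
  a <- which(s$partner > 0 & s$partner > seq_len(nrow(s)))
  edges <- matrix(integer(0), 0, 2)
  if (length(a)) {
    b <- s$partner[a]
    if (any(s$monomer[a] == s$monomer[b]))
      stop("site bonded to a partner on the same monomer (forbidden state)")
    edges <- cbind(s$monomer[a], s$monomer[b])
  }
  structure(list(nodes = nodes, edges = edges), class = "monomer_graph")
}

#' @export
print.monomer_graph <- function(x, ...) {
  cat("monomer_graph:", length(x$nodes), "monomers,", nrow(x$edges),
      "disulfide bonds\n")
  invisible(x)
}

#' Census of rings, open chains and free monomers
#'
#' Classifies every connected component of the monomer graph exactly once:
#' an isolated node is an unreacted monomer, a component with two
#' degree-one ends is an open chain, and a component in which every node
#' has degree two is a closed ring (the 2-node parallel-edge component is
#' the 2-ring). The conservation identity
#' `sum(size * rings) + sum(length * chains) + monomers == total monomers`
#' is checked on every call.
#'
#' @param graph a [build_bond_graph()] result
#' @param time optional time stamp (ps) carried into the census
#' @return object of class `ring_census`: list with `rings` and `chains`
#'   (named count vectors, names are sizes), `monomer_count`,
#'   `n_monomers`, `time`
#' @export
census <- function(graph, time = NA_real_) {
  nodes <- graph$nodes
  n <- length(nodes)
  id <- match(graph$edges, nodes)
  e1 <- id[seq_len(nrow(graph$edges))]
  e2 <- id[nrow(graph$edges) + seq_len(nrow(graph$edges))]
  deg <- tabulate(c(e1, e2), nbins = n)
  if (any(deg > 2))
    stop("monomer degree > 2: impossible under disulfide valence")
  adj <- vector("list", n)
  for (k in seq_along(e1)) {
    adj[[e1[k]]] <- c(adj[[e1[k]]], e2[k])
    adj[[e2[k]]] <- c(adj[[e2[k]]], e1[k])
  }
  seen <- rep(FALSE, n)
  rings <- integer(0); chains <- integer(0); monomers <- 0L
  for (v in seq_len(n)) {
    if (seen[v]) next
    # breadth-first sweep over the component
    comp <- v; seen[v] <- TRUE; queue <- v
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[u]]) if (!seen[w]) {
        seen[w] <- TRUE; comp <- c(comp, w); queue <- c(queue, w)
      }
    }
    size <- length(comp)
    ends <- sum(deg[comp] == 1)
    if (size == 1 && deg[v] == 0) {
      monomers <- monomers + 1L
    } else if (ends == 2) {
      key <- as.character(size)
      chains[key] <- if (key %in% names(chains)) chains[key] + 1L else 1L
    } else if (ends == 0) {
      key <- as.character(size)
      rings[key] <- if (key %in% names(rings)) rings[key] + 1L else 1L
    } else stop("component with a single degree-1 end: corrupt graph")
  }
  out <- structure(list(time = time, rings = rings, chains = chains,
                        monomer_count = monomers, n_monomers = n),
                   class = "ring_census")
  tot <- sum(as.integer(names(rings)) * rings) +
    sum(as.integer(names(chains)) * chains) + monomers
  if (n > 0 && tot != n)
    stop("census conservation violated: ", tot, " != ", n)
  out
}

#' @export
print.ring_census <- function(x, ...) {
  cat("ring_census (t =", x$time, "ps):", x$n_monomers, "monomers total\n")
  cat("  rings: ", if (length(x$rings))
    paste0(names(x$rings), "mer x", x$rings, collapse = ", ") else "none", "\n")
  cat("  chains:", if (length(x$chains))
    paste0("len", names(x$chains), " x", x$chains, collapse = ", ") else "none", "\n")
  cat("  unreacted monomers:", x$monomer_count, "\n")
  invisible(x)
}

#' Ring census for every frame of a run
#'
#' Replays the bond-event log against the initial topology so the census
#' at each stored frame reflects the bond graph at that instant.
#'
#' @param run a `crxn_run`
#' @return list of [census()] objects, one per frame
#' @export
census_series <- function(run) {
  lapply(seq_along(run$trajectory$times), function(f) {
    t <- run$trajectory$times[f]
    topo <- replay_events(run$events, run$topology_initial, run$params, t)
    census(build_bond_graph(topo), time = t)
  })
}

#' Monomer consumption curve and reaction rate
#'
#' The unreacted-monomer fraction over time, with the rate as its smoothed
#' negative time derivative (central differences, one-sided at the
#' endpoints, boxcar smoothing).
#'
#' @param censuses list of [census()] objects (>= 2 frames)
#' @param window boxcar smoothing window in frames (default 5)
#' @param reversible logical; when FALSE a non-monotone fraction triggers a
#'   warning (it flags a census/event-log mismatch)
#' @return object of class `kinetics_curve`: data.frame with columns
#'   `time_ps`, `fraction`, `rate` (1/ps)
#' @export
consumption_curve <- function(censuses, window = 5L, reversible = FALSE) {
  if (length(censuses) < 2) stop("need at least 2 frames")
  t <- vapply(censuses, function(cns) cns$time, 0)
  frac <- vapply(censuses, function(cns)
    if (cns$n_monomers > 0) cns$monomer_count / cns$n_monomers else 0, 0)
  if (!reversible && any(diff(frac) > 1e-12))
    warning("monomer fraction increased although breakage is disabled")
  n <- length(t)
  rate <- numeric(n)
  rate[1] <- -(frac[2] - frac[1]) / (t[2] - t[1])
  rate[n] <- -(frac[n] - frac[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    rate[i] <- -(frac[i + 1] - frac[i - 1]) / (t[i + 1] - t[i - 1])
  }
  if (window > 1 && n >= window) {
    sm <- stats::filter(rate, rep(1 / window, window), sides = 2)
    rate <- ifelse(is.na(sm), rate, as.numeric(sm))
  }
  structure(data.frame(time_ps = t, fraction = frac, rate = rate),
            class = c("kinetics_curve", "data.frame"))
}

#' Aggregate final ring censuses over independent replicas
#'
#' @param censuses list of [census()] objects, one per replica (>= 2)
#' @return data.frame with columns `size`, `mean`, `se` (SD/sqrt(n); sizes
#'   absent in a replica count as 0)
#' @export
aggregate_replicas <- function(censuses) {
  if (length(censuses) < 2) stop("need >= 2 replicas")
  sizes <- sort(unique(as.integer(unlist(lapply(censuses, function(cns)
    names(cns$rings))))))
  if (!length(sizes))
    return(data.frame(size = integer(0), mean = numeric(0), se = numeric(0)))
  counts <- sapply(censuses, function(cns) {
    v <- rep(0, length(sizes))
    got <- match(as.integer(names(cns$rings)), sizes)
    v[got] <- as.numeric(cns$rings)
    v
  })
  counts <- matrix(counts, nrow = length(sizes))
  data.frame(size = sizes,
             mean = rowMeans(counts),
             se = apply(counts, 1, sd) / sqrt(ncol(counts)))
}

#' Modal (most frequent) closed-ring size
#'
#' Ring counts are pooled over the supplied censuses; ties resolve to the
#' smaller size.
#'
#' @param censuses a single [census()] or a list of them
#' @return integer modal ring size (NA if no rings closed)
#' @export
modal_ring_size <- function(censuses) {
  if (inherits(censuses, "ring_census")) censuses <- list(censuses)
  pooled <- numeric(0)
  for (cns in censuses) for (k in names(cns$rings))
    pooled[k] <- if (k %in% names(pooled)) pooled[k] + cns$rings[k] else
      as.numeric(cns$rings[k])
  if (!length(pooled)) return(NA_integer_)
  sizes <- as.integer(names(pooled))
  best <- sizes[pooled == max(pooled)]
  min(best)
}

#' Mean closed-ring size of a census (count-weighted)
#' @param cns a [census()]
#' @return mean ring size, NA if no rings
#' @export
mean_ring_size <- function(cns) {
  if (!length(cns$rings)) return(NA_real_)
  s <- as.integer(names(cns$rings))
  sum(s * cns$rings) / sum(cns$rings)
}
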