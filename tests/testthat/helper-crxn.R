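# shared builders and independent oracles for the test suite

# topology of n non-interacting point beads (species W)
free_bead_topology <- function(n) {
  topo <- crxn:::.empty_topology()
  topo$n_beads <- as.integer(n)
  topo$species <- rep(7L, n)          # W
  topo$molecule <- seq_len(n)
  topo$mol_type <- rep("solvent", n)
  topo
}

# species table with all nonbonded interactions switched off
ideal_species <- function() {
  sp <- species_table()
  sp$epsilon[, ] <- 0
  sp
}

# a hand-made monomer graph from an explicit edge list
graph_from_edges <- function(n, edges) {
  structure(list(nodes = seq_len(n),
                 edges = matrix(as.integer(edges), ncol = 2, byrow = TRUE)),
            class = "monomer_graph")
}

# independent census oracle built on igraph's component machinery
census_oracle <- function(graph) {
  skip_if_not_installed("igraph")
  n <- length(graph$nodes)
  g <- igraph::graph_from_edgelist(
    matrix(match(graph$edges, graph$nodes), ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  rings <- integer(0); chains <- integer(0); monomers <- 0L
  for (cid in seq_len(comp$no)) {
    nodes <- which(comp$membership == cid)
    size <- length(nodes)
    nedge <- sum(deg[nodes]) / 2
    if (size == 1 && nedge == 0) monomers <- monomers + 1L
    else if (nedge == size) {          # cycle: edges == nodes
      k <- as.character(size)
      rings[k] <- if (k %in% names(rings)) rings[k] + 1L else 1L
    } else {                           # tree path: edges == nodes - 1
      k <- as.character(size)
      chains[k] <- if (k %in% names(chains)) chains[k] + 1L else 1L
    }
  }
  list(rings = rings, chains = chains, monomer_count = monomers)
}

# random multigraph with all degrees <= 2 (edges may be parallel)
random_valence_graph <- function(n) {
  cap <- rep(2L, n)
  edges <- NULL
  for (try in seq_len(3 * n)) {
    avail <- which(cap > 0)
    if (length(avail) < 2) break
    pair <- sample(avail, 2)
    edges <- rbind(edges, pair)
    cap[pair] <- cap[pair] - 1L
  }
  structure(list(nodes = seq_len(n),
                 edges = if (is.null(edges)) matrix(integer(0), 0, 2) else edges),
            class = "monomer_graph")
}

expect_census_equal <- function(cns, oracle) {
  norm <- function(v) {
    v <- v[order(as.integer(names(v)))]
    storage.mode(v) <- "integer"
    v[v > 0]
  }
  expect_identical(norm(cns$rings), norm(oracle$rings))
  expect_identical(norm(cns$chains), norm(oracle$chains))
  expect_identical(cns$monomer_count, oracle$monomer_count)
}

# small monomer-only system used by several dynamics tests
small_monomer_system <- function(n = 20, box = c(8, 8, 8), seed = 1,
                                 n_steps = 1000L, ...) {
  cfg <- sim_config(box, n_steps = n_steps, ...)
  set.seed(seed)
  sys <- build_system(cfg, c(monomer = n), "random")
  list(config = cfg, topology = sys$topology, frame = sys$frame)
}

# breadth-first clustering oracle under minimum image
bfs_cluster_oracle <- function(pos, box, cutoff) {
  n <- nrow(pos)
  adj <- vector("list", n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- pos[i, ] - pos[j, ]
    d <- d - box * round(d / box)
    if (sqrt(sum(d^2)) <= cutoff) {
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  label <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (label[s] > 0) next
    cur <- cur + 1L
    queue <- s; label[s] <- cur
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      for (v in adj[[u]]) if (label[v] == 0) { label[v] <- cur; queue <- c(queue, v) }
    }
  }
  label
}

# exact rejection sampler for a 1D Boltzmann density (independent oracle)
sample_1d <- function(n, U, lo, hi, kT = 2.494) {
  out <- numeric(0)
  grid <- seq(lo, hi, length.out = 2001)
  umin <- min(U(grid))
  while (length(out) < n) {
    x <- runif(4 * n, lo, hi)
    keep <- runif(4 * n) < exp(-(U(x) - umin) / kT)
    out <- c(out, x[keep])
  }
  out[seq_len(n)]
}

# profiles are defined up to a constant: align by the mean and compare
pmf_rmsd <- function(est, truth) {
  d <- est - truth
  sqrt(mean((d - mean(d))^2))
}

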