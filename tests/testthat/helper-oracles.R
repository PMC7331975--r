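# Independent oracles used to cross-check the package implementation.
# They deliberately use different machinery (igraph path search, explicit
# O(n^3) agglomeration, numerical ODE integration) from the code under test.

# ion + substrate machine (8 classes)
make_space8 <- function() {
  state_space(machine_spec(species = list(species_spec("ion", "N"),
                                          species_spec("substrate", "S"))))
}

# ion + substrate + mutually exclusive decoy (12 classes)
make_space12 <- function() {
  state_space(machine_spec(species = list(
    species_spec("ion", "N"),
    species_spec("substrate", "S", exclusive_group = "sub"),
    species_spec("decoy", "W", exclusive_group = "sub",
                 decoy_of = "substrate"))))
}

# All simple directed cycles via igraph path search: for the anchor (minimum)
# node v, every simple path v -> u inside the subgraph of nodes >= v, closed
# by the edge u-v, is one directed cycle anchored at v. Returns canonical
# node-sequence strings "v-a-b-...-u".
oracle_cycle_set <- function(space) {
  tr <- space$transitions
  n <- nrow(space$classes)
  if (!nrow(tr)) return(character())
  out <- character()
  for (v in seq_len(n)) {
    keep <- v:n
    sub <- igraph::graph_from_data_frame(
      data.frame(from = as.character(tr$from), to = as.character(tr$to))[
        tr$from %in% keep & tr$to %in% keep, , drop = FALSE],
      directed = FALSE, vertices = data.frame(name = as.character(keep)))
    if (!as.character(v) %in% igraph::V(sub)$name) next
    nbrs <- tryCatch(
      as.integer(igraph::V(sub)$name[igraph::neighbors(sub, as.character(v))]),
      error = function(e) integer())
    for (u in nbrs) {
      paths <- igraph::all_simple_paths(sub, from = as.character(v),
                                        to = as.character(u))
      for (p in paths) {
        nodes <- as.integer(igraph::V(sub)$name[p])
        if (length(nodes) >= 3L)
          out <- c(out, paste(nodes, collapse = "-"))
      }
    }
  }
  sort(unique(out))
}

# net species transport of a node-sequence cycle, recomputed from the bound
# patterns alone (uptake from outside = bound-count increase in the
# outside-facing conformation)
oracle_net_transport <- function(space, nodes) {
  b <- space$bound
  sides <- space$spec$conformations
  conf <- space$classes$conf
  nt <- stats::setNames(numeric(ncol(b)), colnames(b))
  seqn <- c(nodes, nodes[1])
  for (k in seq_len(length(seqn) - 1L)) {
    i <- seqn[k]; j <- seqn[k + 1L]
    dif <- which(b[i, ] != b[j, ])
    if (length(dif) == 1L && sides[conf[i]] == "outside")
      nt[dif] <- nt[dif] + if (b[j, dif]) 1 else -1
  }
  nt
}

# explicit O(n^3) complete-linkage agglomeration with a distance cut
oracle_complete_linkage <- function(V, h) {
  n <- nrow(V)
  D <- as.matrix(stats::dist(V))
  clusters <- as.list(seq_len(n))
  repeat {
    k <- length(clusters)
    if (k == 1L) break
    bd <- Inf; bi <- bj <- NA_integer_
    for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
      d <- max(D[clusters[[i]], clusters[[j]]])
      if (d < bd) { bd <- d; bi <- i; bj <- j }
    }
    if (bd > h) break
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  labels <- integer(n)
  for (i in seq_along(clusters)) labels[clusters[[i]]] <- i
  labels
}

# do two labelings define the same partition?
same_partition <- function(a, b) {
  identical(outer(a, a, `==`), outer(b, b, `==`))
}

# long-time integration of the master equation dP/dt = -K P
oracle_ode_steady <- function(K, t_end = 1e6) {
  y0 <- rep(1 / nrow(K), nrow(K))
  f <- function(t, y, p) list(as.vector(-K %*% y))
  o <- deSolve::ode(y0, c(0, t_end / 10, t_end), f, NULL, method = "lsoda",
                    rtol = 1e-12, atol = 1e-14)
  P <- o[nrow(o), -1]
  P / sum(P)
}

# node balance residual of a steady solution, relative to the largest flow
node_balance <- function(sol, space) {
  n <- nrow(space$classes)
  nb <- numeric(n)
  f <- sol$flows
  for (e in seq_len(nrow(f))) {
    nb[f$from[e]] <- nb[f$from[e]] - f$flow[e]
    nb[f$to[e]] <- nb[f$to[e]] + f$flow[e]
  }
  max(abs(nb)) / max(abs(f$flow), .Machine$double.xmin)
}
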