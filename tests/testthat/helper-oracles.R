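# Shared test helpers: quick constructors, a random-network generator, and
# an independent shortest-temporal-path oracle built on an explicit
# time-expanded layered graph solved with igraph's Dijkstra.

upper_tri_idx <- function(N, T) {
  array(upper.tri(matrix(0, N, N)), c(N, N, T))
}

tn_from_contacts <- function(i, j, t, N = NULL, T = NULL) {
  contacts_to_graphlets(contact_sequence(i, j, t, N = N, T = T))
}

random_tn <- function(N, T, density = runif(1, 0.1, 0.6)) {
  A <- array(0, c(N, N, T))
  for (t in seq_len(T)) {
    m <- matrix(stats::runif(N * N) < density, N, N)
    m[lower.tri(m, diag = TRUE)] <- FALSE
    A[, , t] <- (m | t(m)) * 1
  }
  temporal_network(A)
}

# Exhaustive shortest-duration search over the time-expanded graph:
# nodes (v, u, round r), zero-weight traversal/stay arcs within a time
# point (r -> r + 1, up to the hop limit), unit-weight waiting arcs
# (v, u, k) -> (v, u + 1, 0). The duration from (i, t) to j is the
# minimal number of waiting arcs to any copy of j, plus one.
oracle_paths <- function(tn, steps_per_t = "unbounded") {
  N <- dim(tn)[1]; TT <- dim(tn)[3]
  k <- if (identical(steps_per_t, "unbounded")) N else as.integer(steps_per_t)
  nid <- function(v, u, r) ((u - 1) * (k + 1) + r) * N + v
  total <- TT * (k + 1) * N
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  for (u in seq_len(TT)) {
    e <- which(tn[, , u] > 0 & upper.tri(matrix(0, N, N)), arr.ind = TRUE)
    for (r in 0:(k - 1)) {
      if (nrow(e)) {
        from <- c(from, nid(e[, 1], u, r), nid(e[, 2], u, r))
        to <- c(to, nid(e[, 2], u, r + 1), nid(e[, 1], u, r + 1))
        wt <- c(wt, rep(0, 2 * nrow(e)))
      }
      from <- c(from, nid(seq_len(N), u, r))
      to <- c(to, nid(seq_len(N), u, r + 1))
      wt <- c(wt, rep(0, N))
    }
    if (u < TT) {
      from <- c(from, nid(seq_len(N), u, k))
      to <- c(to, nid(seq_len(N), u + 1, 0))
      wt <- c(wt, rep(1, N))
    }
  }
  g <- igraph::make_graph(edges = rbind(from, to), n = total, directed = TRUE)
  src <- as.vector(outer(seq_len(N), seq_len(TT),
                         function(v, t) nid(v, t, 0)))
  dm <- igraph::distances(g, v = src, to = igraph::V(g), mode = "out",
                          weights = wt)
  d <- array(Inf, c(N, N, TT))
  copies <- function(j) {  # all layered copies of node j
    as.vector(outer(0:k, seq_len(TT), function(r, u) nid(j, u, r)))
  }
  cop <- lapply(seq_len(N), copies)
  for (t in seq_len(TT)) {
    for (i in seq_len(N)) {
      row <- dm[(t - 1) * N + i, ]
      for (j in seq_len(N)) {
        d[i, j, t] <- if (j == i) 0 else min(row[cop[[j]]]) + 1
      }
    }
  }
  d
}
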