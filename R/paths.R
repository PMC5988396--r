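# Shortest temporal paths and intercontact times: the two primitives behind
# closeness centrality, reachability latency, temporal efficiency, and
# burstiness.

#' Shortest temporal paths
#'
#' For every source node `i` and start time `t`, computes the duration (in
#' time steps) of the shortest temporal path to every node `j`, travelling
#' edges only forward in time. The expansion starts in the graphlet at the
#' start time itself: a reached set `S = {i}` is grown within each graphlet
#' `A^u` for `u = t, t + 1, ..., T`, either to full connectivity closure
#' (`steps_per_t = "unbounded"`) or by exactly `steps_per_t` rounds of
#' one-hop neighbour addition. A node first entering `S` at time `u` gets
#' duration `u - t + 1`, so a hop made at the start time costs 1;
#' `d[i, i, t] = 0`. Unreachable targets are `Inf`.
#'
#' The hop limit should reflect the temporal resolution of the data: for
#' slow signals such as BOLD fMRI it is reasonable to let several edges be
#' travelled per time step (the default), whereas for millisecond-scale
#' recordings a small limit is more appropriate.
#'
#' @param tn a binary [temporal_network()].
#' @param steps_per_t `"unbounded"` (default) or an integer >= 1 limiting
#'   the number of edges that may be travelled within one time step.
#' @return A `path_tensor`: list with `d` (array `N x N x T` of durations,
#'   indexed source, target, start time), `steps_per_t`, `N`, `T`.
#' @export
#' @examples
#' cs <- contact_sequence(c(1, 2), c(2, 3), c(1, 1), N = 3, T = 2)
#' pt <- shortest_temporal_paths(contacts_to_graphlets(cs))
#' pt$d[1, 3, 1]  # node 1 reaches node 3 within the first time step
shortest_temporal_paths <- function(tn, steps_per_t = "unbounded") {
  assert_binary(tn, "shortest_temporal_paths()")
  k <- if (identical(steps_per_t, "unbounded")) {
    Inf
  } else {
    ks <- as.integer(steps_per_t)
    if (is.na(ks) || ks < 1L) {
      stop("`steps_per_t` must be \"unbounded\" or an integer >= 1",
           call. = FALSE)
    }
    ks
  }
  N <- n_nodes(tn); TT <- n_times(tn)
  d <- array(Inf, c(N, N, TT))
  for (t0 in seq_len(TT)) {
    slice <- matrix(Inf, N, N)
    diag(slice) <- 0
    reach <- diag(N) > 0  # reach[src, node]
    for (u in t0:TT) {
      adj <- matrix(tn[, , u] > 0, N, N)
      before <- reach
      r <- 0L
      repeat {
        newr <- ((reach %*% adj) > 0) & !reach
        if (!any(newr)) break
        reach <- reach | newr
        r <- r + 1L
        if (r >= k) break
      }
      entered <- reach & !before
      if (any(entered)) slice[entered] <- u - t0 + 1
      if (all(reach)) break
    }
    d[, , t0] <- slice
  }
  structure(list(d = d, steps_per_t = steps_per_t, N = N, T = TT),
            class = "path_tensor")
}

#' @export
print.path_tensor <- function(x, ...) {
  cat(sprintf(
    "<path_tensor> %d x %d x %d durations (steps_per_t = %s), %.1f%% finite\n",
    x$N, x$N, x$T, as.character(x$steps_per_t),
    100 * mean(is.finite(x$d))))
  invisible(x)
}

#' Intercontact times per node pair
#'
#' For every unordered node pair, the ordered list of differences between
#' consecutive activation times. A pair active at time points 2, 4 and 6
#' has intercontact times `c(2, 2)`; pairs with fewer than two activations
#' have an empty list.
#'
#' @param tn a binary [temporal_network()].
#' @return An `intercontact_table`: list with `N`, data-frame component
#'   `pairs` (columns `i`, `j`, `n_active`) covering all pairs `i < j`, and
#'   `taus`, a list of integer vectors parallel to `pairs`.
#' @export
intercontact_times <- function(tn) {
  assert_binary(tn, "intercontact_times()")
  N <- n_nodes(tn)
  ut <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  taus <- vector("list", nrow(ut))
  n_active <- integer(nrow(ut))
  for (p in seq_len(nrow(ut))) {
    times <- which(tn[ut[p, 1], ut[p, 2], ] > 0)
    n_active[p] <- length(times)
    taus[[p]] <- if (length(times) >= 2L) diff(times) else integer()
  }
  structure(list(N = N,
                 pairs = data.frame(i = ut[, 1], j = ut[, 2],
                                    n_active = n_active),
                 taus = taus),
            class = "intercontact_table")
}

#' @export
print.intercontact_table <- function(x, ...) {
  cat(sprintf("<intercontact_table> %d nodes, %d pairs (%d with >= 1 gap)\n",
              x$N, nrow(x$pairs), sum(lengths(x$taus) > 0)))
  invisible(x)
}

#' Export a path tensor as JSON
#'
#' Durations are written per source and start time; unreachable entries
#' (`Inf`) are encoded as `null`.
#'
#' @param pt a `path_tensor`.
#' @param path optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
path_tensor_json <- function(pt, path = NULL) {
  d <- pt$d
  d[!is.finite(d)] <- NA
  measure_json("shortest_temporal_paths",
               values = lapply(seq_len(pt$T), function(t) d[, , t]),
               params = list(steps_per_t = pt$steps_per_t),
               path = path)
}
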