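# Nodal temporal centrality measures.

#' Temporal degree centrality
#'
#' The number of edges incident to each node summed across all time
#' points: `D_i = sum_j sum_t A[i, j, t]`. Blind to temporal order —
#' permuting the time axis leaves it unchanged.
#'
#' @param tn a binary [temporal_network()].
#' @return Named numeric vector of length `N` (names are node labels when
#'   present, otherwise indices).
#' @export
temporal_degree_centrality <- function(tn) {
  assert_binary(tn, "temporal_degree_centrality()")
  v <- apply(tn, 1, sum)
  names(v) <- node_names(tn)
  v
}

#' Temporal closeness centrality
#'
#' The average inverse mean shortest temporal duration to every other
#' node: `C_i = (1 / (N - 1)) * sum_{j != i} 1 / dbar_ij`, where `dbar_ij`
#' averages `d[i, j, t]` over the start times at which a temporal path
#' exists. Pairs never connected contribute 0 (the `1 / Inf = 0`
#' convention), keeping values in `[0, 1]` and comparable across networks.
#' Unlike temporal degree, closeness is sensitive to temporal order.
#'
#' @param pt a `path_tensor` from [shortest_temporal_paths()] (any hop
#'   limit).
#' @return Numeric vector of length `N` with values in `[0, 1]`.
#' @export
temporal_closeness_centrality <- function(pt) {
  stopifnot(inherits(pt, "path_tensor"))
  N <- pt$N
  dbar <- apply(pt$d, c(1, 2), function(x) {
    f <- x[is.finite(x)]
    if (length(f)) mean(f) else Inf
  })
  inv <- 1 / dbar
  inv[!is.finite(inv) | is.nan(inv)] <- 0
  diag(inv) <- 0  # exclude self-distances (d = 0) from the sum
  rowSums(inv) / (N - 1)
}

node_names <- function(tn) {
  lbl <- attr(tn, "node_labels")
  if (is.null(lbl)) as.character(seq_len(n_nodes(tn))) else lbl
}
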