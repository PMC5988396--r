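# Whole-network temporal measures: fluctuability, volatility, reachability
# latency, temporal efficiency. Sums over "edges" use unordered pairs (the
# upper triangle) throughout.

#' Fluctuability
#'
#' The ratio of the number of unordered node pairs that are ever active to
#' the total number of activations over pairs and time. `F = 1` exactly
#' when every active pair occurs once only; repeated edges push `F` towards
#' 0. Fluctuability measures the spatial diversity of connections and is
#' blind to temporal order.
#'
#' @param tn a binary [temporal_network()] with at least one contact.
#' @return Scalar in `(0, 1]`.
#' @export
fluctuability <- function(tn) {
  assert_binary(tn, "fluctuability()")
  ut <- upper.tri(matrix(0, n_nodes(tn), n_nodes(tn)))
  per_pair <- apply(tn, c(1, 2), sum)[ut]
  total <- sum(per_pair)
  if (total == 0) {
    stop("fluctuability is undefined on a network with no contacts",
         call. = FALSE)
  }
  sum(per_pair > 0) / total
}

#' Nodal fluctuability
#'
#' Per node: the number of distinct partners it is ever connected to,
#' divided by its total number of edge activations over time; 0 for nodes
#' with no contacts at all.
#'
#' @param tn a binary [temporal_network()].
#' @return Numeric vector of length `N` with values in `[0, 1]`.
#' @export
nodal_fluctuability <- function(tn) {
  assert_binary(tn, "nodal_fluctuability()")
  per_pair <- apply(tn, c(1, 2), sum)
  partners <- rowSums(per_pair > 0)
  total <- rowSums(per_pair)
  ifelse(total > 0, partners / total, 0)
}

#' Volatility
#'
#' The mean distance between consecutive graphlets,
#' `V = (1 / (T - 1)) * sum_t D(A^t, A^{t+1})`. For binary networks the
#' Hamming distance is used: the number of unordered pairs whose state
#' differs between `t` and `t + 1` (diagonal excluded). High volatility
#' means the network reconfigures quickly; `V` is invariant under time
#' reversal but not under general reordering of the time axis.
#'
#' @param tn a binary [temporal_network()] with `T >= 2`.
#' @param distance distance function name; only `"hamming"` is supported.
#' @return Non-negative scalar.
#' @export
volatility <- function(tn, distance = "hamming") {
  assert_binary(tn, "volatility()")
  if (!identical(distance, "hamming")) {
    stop("only the Hamming distance is supported for binary graphlets",
         call. = FALSE)
  }
  TT <- n_times(tn)
  if (TT < 2L) {
    stop("volatility is undefined for a single time point (T must be >= 2)",
         call. = FALSE)
  }
  ut <- upper.tri(matrix(0, n_nodes(tn), n_nodes(tn)))
  steps <- vapply(seq_len(TT - 1L), function(t) {
    sum((tn[, , t] != tn[, , t + 1L])[ut])
  }, numeric(1))
  mean(steps)
}

#' Edge-wise volatility and volatility centrality
#'
#' Per unordered pair: the mean of `|A[i, j, t] - A[i, j, t + 1]|` over the
#' `T - 1` transitions. Volatility centrality is the mean edge volatility
#' over each node's `N - 1` partners. The pairwise values decompose global
#' volatility: their sum equals `V` from [volatility()].
#'
#' @param tn a binary [temporal_network()] with `T >= 2`.
#' @return List with `edges` (data frame `i`, `j`, `value`) and `nodes`
#'   (numeric vector of length `N`).
#' @export
edge_volatility <- function(tn) {
  assert_binary(tn, "edge_volatility()")
  N <- n_nodes(tn); TT <- n_times(tn)
  if (TT < 2L) {
    stop("edge volatility is undefined for a single time point", call. = FALSE)
  }
  flips <- apply(tn, c(1, 2), function(x) mean(abs(diff(x))))
  ut <- which(upper.tri(flips), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  nodal <- (rowSums(flips) - diag(flips)) / (N - 1)
  list(edges = data.frame(i = ut[, 1], j = ut[, 2], value = flips[ut]),
       nodes = nodal)
}

#' Reachability latency
#'
#' The average time needed for a node to reach a fraction `r` of all nodes
#' via shortest temporal paths. For each source and start time, the `N`
#' durations (including the self-distance 0) are sorted ascending and the
#' element at rank `round(r * N)` (half-up, 1-based) is taken; `r = 1`
#' selects the maximum, giving the temporal diameter. Terms where that
#' rank is unreachable (`Inf`) are dropped from the numerator while the
#' denominator stays `T * N` by default; `normalization = "Tstar"` divides
#' by the count of defined terms instead. When no term is defined the
#' measure is undefined and `NA` is returned.
#'
#' @param pt a `path_tensor`.
#' @param r reachability ratio in `(0, 1]`.
#' @param normalization `"T"` (default) or `"Tstar"`.
#' @return Scalar `>= 1`, or `NA` when undefined.
#' @export
reachability_latency <- function(pt, r = 1, normalization = c("T", "Tstar")) {
  stopifnot(inherits(pt, "path_tensor"))
  normalization <- match.arg(normalization)
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r > 1) {
    stop("`r` must be a single value in (0, 1]", call. = FALSE)
  }
  N <- pt$N; TT <- pt$T
  k <- floor(r * N + 0.5)  # round half-up
  k <- max(1L, min(N, k))
  vals <- apply(pt$d, c(1, 3), function(x) sort(x)[k])  # Inf sorts last
  defined <- is.finite(vals)
  if (!any(defined)) return(NA_real_)
  denom <- if (normalization == "T") TT * N else sum(defined)
  sum(vals[defined]) / denom
}

#' Temporal efficiency
#'
#' The average inverse shortest temporal duration over all ordered node
#' pairs and start times:
#' `E = (1 / (T (N^2 - N))) * sum_{i != j, t} 1 / d[i, j, t]`, with
#' `1 / Inf = 0` for unreachable entries so the measure stays defined on
#' sparse networks. `E = 1` when every node reaches every other in one
#' step at every start time; `E = 0` for a network with no contacts.
#'
#' @param pt a `path_tensor`.
#' @return Scalar in `[0, 1]`.
#' @export
temporal_efficiency <- function(pt) {
  stopifnot(inherits(pt, "path_tensor"))
  N <- pt$N; TT <- pt$T
  inv <- 1 / pt$d
  inv[!is.finite(pt$d)] <- 0
  for (t in seq_len(TT)) {
    slice <- inv[, , t]
    diag(slice) <- 0  # exclude i == j (d = 0)
    inv[, , t] <- slice
  }
  sum(inv) / (TT * (N^2 - N))
}
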