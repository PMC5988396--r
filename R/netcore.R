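#' tempnet: temporal network measures for dynamic functional connectivity
#'
#' Represents time-varying binary networks either as a stack of per-time
#' connectivity matrices ("t-graphlets") or as a contact sequence of
#' (i, j, t) events, and quantifies them with nodal, edge, and global
#' temporal measures. Includes a weighted-correlation pipeline that derives
#' t-graphlets from multivariate node time series, permutation statistics,
#' surrogate network generation, and seeded synthetic data generators.
#'
#' @keywords internal
"_PACKAGE"

# ---- temporal_network -------------------------------------------------------

#' Construct a temporal network (graphlet stack)
#'
#' A temporal network is a stack of symmetric connectivity matrices, one per
#' time point ("t-graphlets"). Edges are undirected, self-loops are
#' forbidden, and values are non-negative; all measures in this package
#' consume the binary form (values in \{0, 1\}).
#'
#' @param A numeric array with dimensions `c(N, N, T)`; slice `A[, , t]` is
#'   the connectivity matrix at time `t`. Node and time indices are 1-based.
#' @param node_labels optional character vector of length `N`.
#' @return An object of class `temporal_network`: the validated array with
#'   attributes `node_labels`.
#' @export
#' @examples
#' A <- array(0, c(3, 3, 2))
#' A[1, 2, 1] <- A[2, 1, 1] <- 1
#' tn <- temporal_network(A)
#' n_nodes(tn); n_times(tn)
temporal_network <- function(A, node_labels = NULL) {
  if (!is.array(A) || length(dim(A)) != 3L) {
    stop("`A` must be a 3-way array indexed (node, node, time)", call. = FALSE)
  }
  d <- dim(A)
  if (d[1] != d[2]) stop("first two dimensions of `A` must be equal", call. = FALSE)
  N <- d[1]; TT <- d[3]
  if (N < 2L) stop("a temporal network needs at least 2 nodes", call. = FALSE)
  if (TT < 1L) stop("a temporal network needs at least 1 time point", call. = FALSE)
  if (anyNA(A)) stop("`A` must not contain missing values", call. = FALSE)
  if (any(A < 0)) stop("edge values must be non-negative", call. = FALSE)
  if (!isTRUE(all.equal(A, aperm(A, c(2, 1, 3)), check.attributes = FALSE))) {
    stop("symmetry violation: A[i, j, t] must equal A[j, i, t] for all t",
         call. = FALSE)
  }
  diag_idx <- cbind(rep(seq_len(N), TT), rep(seq_len(N), TT),
                    rep(seq_len(TT), each = N))
  if (any(A[diag_idx] != 0)) {
    stop("self-loops are forbidden: A[i, i, t] must be 0", call. = FALSE)
  }
  if (!is.null(node_labels)) {
    node_labels <- as.character(node_labels)
    if (length(node_labels) != N) {
      stop("`node_labels` must have length N = ", N, call. = FALSE)
    }
  }
  structure(A, node_labels = node_labels, class = "temporal_network")
}

#' @rdname temporal_network
#' @param tn a `temporal_network`.
#' @export
n_nodes <- function(tn) dim(tn)[1]

#' @rdname temporal_network
#' @export
n_times <- function(tn) dim(tn)[3]

#' @rdname temporal_network
#' @export
is_binary <- function(tn) all(tn == 0 | tn == 1)

#' @export
print.temporal_network <- function(x, ...) {
  cat(sprintf("<temporal_network> %d nodes x %d time points, %d contacts%s\n",
              n_nodes(x), n_times(x), sum(x[upper_tri_stack(x)] != 0),
              if (is_binary(x)) " (binary)" else " (weighted)"))
  invisible(x)
}

# logical index of the upper triangle replicated across time slices
upper_tri_stack <- function(tn) {
  N <- dim(tn)[1]; TT <- dim(tn)[3]
  array(upper.tri(matrix(0, N, N)), c(N, N, TT))
}

# measures in this package are defined for binary stacks only
assert_binary <- function(tn, what) {
  if (!inherits(tn, "temporal_network")) {
    stop(what, " requires a `temporal_network`", call. = FALSE)
  }
  if (!is_binary(tn)) {
    stop(what, " requires a binary temporal network (values in {0, 1}); ",
         "binarize weighted stacks first", call. = FALSE)
  }
  invisible(tn)
}

# ---- contact_sequence -------------------------------------------------------

#' Construct a contact sequence
#'
#' The event-based representation of a temporal network: an ordered list of
#' contacts `(i, j, t)` (optionally weighted) with `i < j`, sorted by time,
#' then `i`, then `j`. Lossless alternative to the graphlet stack and more
#' compact for sparse networks.
#'
#' @param i,j 1-based node indices (any order; canonicalized to `i < j`).
#' @param t 1-based integer time indices.
#' @param w optional positive weights; omitted for binary networks.
#' @param N,T node and time-point counts; inferred from the maximum index
#'   when missing.
#' @return A `contact_sequence`: a data frame with columns `i`, `j`, `t`
#'   (and `w` when weighted) plus attributes `N` and `T`.
#' @export
contact_sequence <- function(i, j, t, w = NULL, N = NULL, T = NULL) {
  i <- as.integer(i); j <- as.integer(j); t <- as.integer(t)
  stopifnot(length(i) == length(j), length(j) == length(t))
  if (!is.null(w) && length(w) != length(i)) {
    stop("`w` must match the number of contacts", call. = FALSE)
  }
  if (any(i == j)) stop("self-loop: contacts must link distinct nodes", call. = FALSE)
  if (length(i) && (min(i, j) < 1L || min(t) < 1L)) {
    stop("node and time indices must be positive", call. = FALSE)
  }
  ii <- pmin(i, j); jj <- pmax(i, j)
  N <- if (is.null(N)) if (length(i)) max(jj) else 2L else as.integer(N)
  T <- if (is.null(T)) if (length(t)) max(t) else 1L else as.integer(T)
  if (length(i) && max(jj) > N) stop("node index exceeds N = ", N, call. = FALSE)
  if (length(t) && max(t) > T) stop("time index exceeds T = ", T, call. = FALSE)
  key <- paste(ii, jj, t)
  if (anyDuplicated(key)) {
    stop("duplicate contact for pair (", ii[duplicated(key)][1], ", ",
         jj[duplicated(key)][1], ") at t = ", t[duplicated(key)][1],
         call. = FALSE)
  }
  ord <- order(t, ii, jj)
  cs <- data.frame(i = ii[ord], j = jj[ord], t = t[ord])
  if (!is.null(w)) cs$w <- as.numeric(w)[ord]
  structure(cs, N = N, T = T, class = c("contact_sequence", "data.frame"))
}

#' @export
print.contact_sequence <- function(x, ...) {
  cat(sprintf("<contact_sequence> %d contacts, N = %d, T = %d\n",
              nrow(x), attr(x, "N"), attr(x, "T")))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

# ---- conversions ------------------------------------------------------------

#' Convert between contact sequences and graphlet stacks
#'
#' The two representations are lossless for discrete-time networks: the
#' round trip contacts -> graphlets -> contacts is the identity on canonical
#' sequences, and the total activation count of the stack (over the upper
#' triangle and time) equals the contact-list length.
#'
#' @param cs a `contact_sequence`.
#' @return `contacts_to_graphlets()`: a `temporal_network`;
#'   `graphlets_to_contacts()`: a `contact_sequence`.
#' @export
contacts_to_graphlets <- function(cs) {
  stopifnot(inherits(cs, "contact_sequence"))
  N <- attr(cs, "N"); TT <- attr(cs, "T")
  A <- array(0, c(N, N, TT))
  if (nrow(cs)) {
    val <- if (is.null(cs$w)) rep(1, nrow(cs)) else cs$w
    A[cbind(cs$i, cs$j, cs$t)] <- val
    A[cbind(cs$j, cs$i, cs$t)] <- val
  }
  temporal_network(A)
}

#' @rdname contacts_to_graphlets
#' @param tn a `temporal_network`.
#' @export
graphlets_to_contacts <- function(tn) {
  stopifnot(inherits(tn, "temporal_network"))
  idx <- which(tn != 0 & upper_tri_stack(tn), arr.ind = TRUE)
  w <- if (is_binary(tn)) NULL else tn[idx]
  contact_sequence(i = idx[, 1], j = idx[, 2], t = idx[, 3], w = w,
                   N = n_nodes(tn), T = n_times(tn))
}
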