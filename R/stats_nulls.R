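# Permutation statistics for paired condition comparisons, max-null nodal
# thresholding, rank correlation, and surrogate (null) network generation.

#' Paired group permutation test
#'
#' Two-tailed permutation test for paired condition values (one value per
#' subject and condition). The statistic is `mean(a) - mean(b)`; the null
#' distribution is built by independently swapping each subject's pair of
#' condition labels (sign-flipping the within-subject differences). The
#' p-value counts the observed statistic among the null values
#' (`p = (1 + #{|null| >= |observed|}) / (1 + n_perm)`), so it is never 0.
#'
#' @param a,b numeric vectors of per-subject values, paired by position.
#' @param n_perm number of permutations (default 100000).
#' @param seed integer seed; the global RNG state is left untouched.
#' @return List of class `permutation_test`: `observed`, `p`, `n_perm`,
#'   `seed`, `tail = "two"`.
#' @export
group_permutation_test <- function(a, b, n_perm = 100000L, seed = 1L) {
  stopifnot(length(a) == length(b), length(a) >= 1L)
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) {
    stop("`n_perm` must be a positive integer", call. = FALSE)
  }
  d <- as.numeric(a) - as.numeric(b)
  n <- length(d)
  observed <- mean(d)
  null <- withr::with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    as.vector(signs %*% d) / n
  })
  p <- (1 + sum(abs(null) >= abs(observed))) / (1 + n_perm)
  structure(list(observed = observed, p = p, n_perm = n_perm, seed = seed,
                 tail = "two"),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Paired permutation test (two-tailed, %d permutations)\n",
              x$n_perm))
  cat(sprintf("  observed mean difference: %.6g\n  p = %.6g\n",
              x$observed, x$p))
  invisible(x)
}

#' Max-null threshold for nodal centrality
#'
#' Determines which nodes have higher-than-chance subject-averaged
#' centrality. For each permutation, every subject's node order is
#' shuffled independently and the shuffled values are averaged over
#' subjects, giving one null distribution per node position. The
#' threshold is the maximum across node positions of the
#' `(1 - alpha)`-quantile (the `ceiling((1 - alpha) * n_perm)`-th order
#' statistic — with 1000 permutations and `alpha = 0.05`, the largest
#' 950th value). Nodes whose observed subject-averaged centrality exceeds
#' the threshold are flagged.
#'
#' @param M subjects-x-nodes matrix of centrality values.
#' @param n_perm number of permutations (default 1000); must be at least
#'   `1 / alpha`.
#' @param alpha significance level in `(0, 1)` (default 0.05).
#' @param seed integer seed.
#' @return List: `threshold`, `flags` (logical per node), `observed`
#'   (subject-averaged centralities), `n_perm`, `alpha`, `seed`.
#' @export
nodal_centrality_threshold <- function(M, n_perm = 1000L, alpha = 0.05,
                                       seed = 1L) {
  M <- as.matrix(M)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  n_perm <- as.integer(n_perm)
  if (n_perm < ceiling(1 / alpha)) {
    stop("`n_perm` must be at least 1 / alpha = ", ceiling(1 / alpha),
         call. = FALSE)
  }
  S <- nrow(M); N <- ncol(M)
  null <- withr::with_seed(seed, {
    out <- matrix(0, n_perm, N)
    for (p in seq_len(n_perm)) {
      acc <- numeric(N)
      for (s in seq_len(S)) acc <- acc + M[s, sample.int(N)]
      out[p, ] <- acc / S
    }
    out
  })
  ord <- ceiling((1 - alpha) * n_perm)
  q <- apply(null, 2, function(x) sort(x)[ord])
  threshold <- max(q)
  observed <- colMeans(M)
  list(threshold = threshold, flags = observed > threshold,
       observed = observed, n_perm = n_perm, alpha = alpha, seed = seed)
}

#' Spearman rank correlation
#'
#' Correlation of mid-rank-transformed values, with the p-value from the
#' large-sample t approximation.
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @return List with `rho` and `p`.
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: constant vector", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Surrogate (null) temporal networks and edge series
#'
#' Three surrogate schemes for testing whether a temporal measure exceeds
#' chance level:
#' \describe{
#'   \item{`time_shuffle`}{one random permutation of the time axis,
#'     applied jointly to all edges. Destroys autocorrelation but
#'     preserves the multiset of graphlets, so order-blind measures
#'     (temporal degree, fluctuability) are unchanged.}
#'   \item{`phase`}{per edge series, randomizes the phases of the discrete
#'     Fourier spectrum while preserving amplitudes and conjugate
#'     symmetry. Only meaningful before thresholding, so it requires an
#'     `edge_series_set` and errors on a binary network.}
#'   \item{`block`}{partitions the time axis into consecutive blocks of
#'     `block_len` (a shorter final block is kept) and permutes block
#'     order, jointly across edges, preserving short-range structure
#'     within blocks. Not appropriate for every measure (e.g.
#'     volatility, which is sensitive to block seams).}
#' }
#'
#' @param x a [temporal_network()] or an `edge_series_set`.
#' @param method `"time_shuffle"`, `"phase"`, or `"block"`.
#' @param block_len block length for `method = "block"`.
#' @param seed integer seed; the global RNG state is left untouched.
#' @return Object of the same class as `x`.
#' @export
null_network <- function(x, method = c("time_shuffle", "phase", "block"),
                         block_len = NULL, seed = 1L) {
  method <- match.arg(method)
  UseMethod("null_network")
}

#' @export
null_network.temporal_network <- function(x, method = c("time_shuffle",
                                                        "phase", "block"),
                                          block_len = NULL, seed = 1L) {
  method <- match.arg(method)
  if (method == "phase") {
    stop("phase randomization applies to pre-threshold edge series, ",
         "not to a binary temporal network", call. = FALSE)
  }
  perm <- withr::with_seed(seed, time_permutation(n_times(x), method, block_len))
  temporal_network(unclass(x)[, , perm, drop = FALSE],
                   node_labels = attr(x, "node_labels"))
}

#' @export
null_network.edge_series_set <- function(x, method = c("time_shuffle",
                                                       "phase", "block"),
                                         block_len = NULL, seed = 1L) {
  method <- match.arg(method)
  TT <- ncol(x$values)
  out <- x
  if (method == "phase") {
    out$values <- withr::with_seed(seed, {
      t(apply(x$values, 1, phase_randomize))
    })
  } else {
    perm <- withr::with_seed(seed, time_permutation(TT, method, block_len))
    out$values <- x$values[, perm, drop = FALSE]
  }
  out
}

time_permutation <- function(TT, method, block_len) {
  if (method == "time_shuffle") return(sample.int(TT))
  if (is.null(block_len) || block_len < 1L || block_len > TT) {
    stop("`block_len` must be an integer in [1, T]", call. = FALSE)
  }
  blocks <- split(seq_len(TT), ceiling(seq_len(TT) / block_len))
  unlist(blocks[sample.int(length(blocks))], use.names = FALSE)
}

# Phase-randomized surrogate of a real series: amplitudes preserved, DC and
# (for even length) Nyquist components untouched.
phase_randomize <- function(x) {
  n <- length(x)
  f <- stats::fft(x)
  half <- floor((n - 1) / 2)
  if (half >= 1) {
    idx <- 2:(half + 1)
    ph <- stats::runif(half, 0, 2 * pi)
    f[idx] <- Mod(f[idx]) * exp(1i * ph)
    f[n + 2 - idx] <- Conj(f[idx])
  }
  Re(stats::fft(f, inverse = TRUE)) / n
}
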