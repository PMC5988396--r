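# Derivation of t-graphlets from node time series: per-time-point weighted
# Pearson correlation followed by Fisher and Box-Cox transforms,
# standardization, and variance-based binarization.

#' Standardize node time series
#'
#' Z-scores each node's series (demeaning and scaling the standard
#' deviation to 1). Standardizing twice equals standardizing once.
#'
#' @param Y nodes-x-time numeric matrix.
#' @return The standardized matrix with attribute `standardized = TRUE`.
#' @export
standardize_series <- function(Y) {
  Y <- as.matrix(Y)
  if (!is.numeric(Y) || anyNA(Y)) {
    stop("`Y` must be a complete numeric matrix", call. = FALSE)
  }
  sds <- apply(Y, 1, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate series: node ", which(sds == 0)[1],
         " is constant and cannot be standardized", call. = FALSE)
  }
  Z <- (Y - rowMeans(Y)) / sds
  attr(Z, "standardized") <- TRUE
  Z
}

#' Temporal weight matrix from global spatial similarity
#'
#' For every pair of time points `t != v`, the raw weight is the inverse
#' Euclidean distance between the two length-`N` activation columns of the
#' series, so time points whose global spatial pattern resembles the
#' pattern at `t` receive a large weight when the connectivity at `t` is
#' estimated. All off-diagonal raw weights are then jointly min-max scaled
#' to `[0, 1]` over the whole `T x T` matrix, and the diagonal is set
#' to 1 (the time point of interest always gets full weight).
#'
#' Two distinct time points with identical columns (distance 0) would give
#' an infinite raw weight; such entries are set to the maximum finite
#' off-diagonal raw weight, with a warning, preserving "most similar gets
#' most weight". If all off-diagonal raw weights are equal they are set
#' to 1.
#'
#' @param Y nodes-x-time numeric matrix, normally standardized via
#'   [standardize_series()] (not enforced, so degenerate cases can be
#'   exercised directly); `T >= 3`.
#' @return Symmetric `T x T` matrix with unit diagonal and off-diagonal
#'   values in `[0, 1]`.
#' @export
temporal_weight_matrix <- function(Y) {
  Y <- as.matrix(Y)
  TT <- ncol(Y)
  if (TT < 3L) stop("at least 3 time points are required", call. = FALSE)
  D <- as.matrix(stats::dist(t(Y)))
  off <- !diag(TT)
  W <- matrix(0, TT, TT)
  W[off] <- 1 / D[off]
  if (any(!is.finite(W[off]))) {
    warning("identical activation columns at distinct time points; ",
            "their weights were set to the maximum finite weight")
    mx <- max(W[off][is.finite(W[off])], -Inf)
    if (!is.finite(mx)) mx <- 1
    W[off & !is.finite(W)] <- mx
  }
  rng <- range(W[off])
  W[off] <- if (rng[1] == rng[2]) 1 else (W[off] - rng[1]) / (rng[2] - rng[1])
  diag(W) <- 1
  W
}

#' Weighted Pearson correlation
#'
#' `r(x, y; w) = S_xy / sqrt(S_xx * S_yy)` where `S_ab` is the weighted
#' covariance `sum_i w_i (a_i - mu_a)(b_i - mu_b) / sum_i w_i` and `mu_a`
#' is the weighted mean `sum_i w_i a_i / sum_i w_i`. With identical
#' weights this reduces exactly to the ordinary Pearson coefficient.
#'
#' @param x,y numeric series of equal length.
#' @param w non-negative weights with positive sum, same length.
#' @return Scalar in `[-1, 1]`.
#' @export
weighted_pearson <- function(x, y, w) {
  n <- length(x)
  stopifnot(length(y) == n, length(w) == n)
  if (any(w < 0) || sum(w) <= 0) {
    stop("weights must be non-negative with a positive sum", call. = FALSE)
  }
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  sxx <- sum(w * (x - mx)^2) / sw
  syy <- sum(w * (y - my)^2) / sw
  if (sxx == 0 || syy == 0) {
    stop("degenerate correlation: zero weighted variance", call. = FALSE)
  }
  sxy <- sum(w * (x - mx) * (y - my)) / sw
  max(-1, min(1, sxy / sqrt(sxx * syy)))
}

#' Derive per-edge connectivity time series
#'
#' For every unordered node pair and every time point `t`, the weighted
#' Pearson correlation of the two full node series under weight vector
#' `W[t, ]` — a unique weight vector per time point yields a unique
#' connectivity estimate per time point, producing for each edge a
#' connectivity series with fluctuating covariance. With a uniform weight
#' matrix every time point reproduces the static Pearson correlation.
#'
#' @param Y standardized nodes-x-time matrix (see [standardize_series()]).
#' @param W `T x T` weight matrix, normally from
#'   [temporal_weight_matrix()] on the same `Y`.
#' @return An `edge_series_set`: list with `values` (pairs x T matrix),
#'   `pairs` (data frame `i`, `j`), `N`, and `stage = "raw_r"`.
#' @export
derive_edge_series <- function(Y, W) {
  Y <- as.matrix(Y)
  N <- nrow(Y); TT <- ncol(Y)
  W <- as.matrix(W)
  stopifnot(nrow(W) == TT, ncol(W) == TT)
  ut <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  vals <- matrix(NA_real_, nrow(ut), TT)
  for (t in seq_len(TT)) {
    w <- W[t, ]
    sw <- sum(w)
    if (sw <= 0) stop("weight row ", t, " has non-positive sum", call. = FALSE)
    mu <- as.vector(Y %*% w) / sw
    Yc <- Y - mu
    C <- (Yc %*% (w * t(Yc))) / sw          # weighted covariance, N x N
    v <- diag(C)
    if (any(v <= 0)) {
      stop("degenerate correlation: zero weighted variance for node ",
           which(v <= 0)[1], " at t = ", t, call. = FALSE)
    }
    R <- C / sqrt(v %o% v)
    vals[, t] <- pmax(-1, pmin(1, R[ut]))
  }
  structure(list(values = vals,
                 pairs = data.frame(i = ut[, 1], j = ut[, 2]),
                 N = N, stage = "raw_r"),
            class = "edge_series_set")
}

#' @export
print.edge_series_set <- function(x, ...) {
  cat(sprintf("<edge_series_set> %d edges x %d time points (stage: %s)\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' Box-Cox profile log-likelihood and grid-search lambda
#'
#' Profile log-likelihood of the one-parameter power transform
#' `y(lambda) = (y^lambda - 1) / lambda` (`log(y)` at `lambda = 0`):
#' `ll(lambda) = -(n / 2) log(sigma_hat^2(lambda)) +
#' (lambda - 1) sum(log(y))`. `boxcox_lambda()` returns the grid value
#' maximizing it (ties broken towards the first, i.e. smallest, lambda).
#'
#' @param y positive numeric vector.
#' @param lambda single lambda (for `boxcox_loglik`) or grid (for
#'   `boxcox_lambda`; default -5 to 5 in steps of 0.1).
#' @return Log-likelihood value, or the selected lambda.
#' @export
boxcox_loglik <- function(y, lambda) {
  stopifnot(all(y > 0))
  n <- length(y)
  yt <- boxcox_transform(y, lambda)
  s2 <- mean((yt - mean(yt))^2)
  -n / 2 * log(s2) + (lambda - 1) * sum(log(y))
}

#' @rdname boxcox_loglik
#' @export
boxcox_lambda <- function(y, lambda = seq(-5, 5, by = 0.1)) {
  ll <- vapply(lambda, function(l) boxcox_loglik(y, l), numeric(1))
  lambda[which.max(ll)]
}

boxcox_transform <- function(y, lambda) {
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

#' Post-process edge connectivity series
#'
#' Applies, per edge series and in order: (1) the Fisher transform
#' `z = atanh(r)`, with `|r|` clipped to `1 - 1e-15` so the transform stays
#' finite; (2) a Box-Cox transform, after shifting the series so its
#' minimum equals 1 (keeping the transform comparable across series), with
#' `lambda` selected per edge by maximum profile log-likelihood over a
#' grid from -5 to 5 in increments of 0.1; (3) standardization to mean 0,
#' standard deviation 1. Either transform can be switched off.
#'
#' @param es an `edge_series_set` at stage `"raw_r"`.
#' @param fisher,boxcox logical switches for the two transforms.
#' @param boxcox_grid lambda grid for the Box-Cox search.
#' @return An `edge_series_set` at stage `"zscored"`, with the selected
#'   lambdas in the `lambda` component (when Box-Cox is applied).
#' @export
postprocess_edge_series <- function(es, fisher = TRUE, boxcox = TRUE,
                                    boxcox_grid = seq(-5, 5, by = 0.1)) {
  stopifnot(inherits(es, "edge_series_set"))
  if (!identical(es$stage, "raw_r")) {
    stop("`es` must be at stage \"raw_r\"", call. = FALSE)
  }
  vals <- es$values
  lambdas <- rep(NA_real_, nrow(vals))
  for (p in seq_len(nrow(vals))) {
    x <- vals[p, ]
    if (fisher) x <- atanh(pmax(-1 + 1e-15, pmin(1 - 1e-15, x)))
    if (max(x) - min(x) == 0) {
      stop("degenerate series: edge (", es$pairs$i[p], ", ", es$pairs$j[p],
           ") is constant after the Fisher transform", call. = FALSE)
    }
    if (boxcox) {
      y <- x - min(x) + 1
      lambdas[p] <- boxcox_lambda(y, boxcox_grid)
      x <- boxcox_transform(y, lambdas[p])
    }
    vals[p, ] <- (x - mean(x)) / stats::sd(x)
  }
  out <- es
  out$values <- vals
  out$stage <- "zscored"
  out$lambda <- if (boxcox) lambdas else NULL
  out
}

#' Binarize standardized edge series into t-graphlets
#'
#' An edge is switched on at time `t` when its standardized connectivity
#' strictly exceeds `threshold_sd` standard deviations — one-sided,
#' positive tail, so only unusually strong positive connectivity
#' survives. For Gaussian series the expected activation fraction at the
#' default threshold of 2 is the upper normal tail, about 0.023.
#'
#' @param es an `edge_series_set` at stage `"zscored"`.
#' @param threshold_sd threshold in standard deviations (default 2).
#' @return A binary [temporal_network()].
#' @export
binarize <- function(es, threshold_sd = 2) {
  stopifnot(inherits(es, "edge_series_set"))
  if (!identical(es$stage, "zscored")) {
    stop("`es` must be at stage \"zscored\"; run postprocess_edge_series() first",
         call. = FALSE)
  }
  N <- es$N; TT <- ncol(es$values)
  A <- array(0, c(N, N, TT))
  on <- es$values > threshold_sd
  for (t in seq_len(TT)) {
    hit <- which(on[, t])
    if (length(hit)) {
      A[cbind(es$pairs$i[hit], es$pairs$j[hit], t)] <- 1
      A[cbind(es$pairs$j[hit], es$pairs$i[hit], t)] <- 1
    }
  }
  temporal_network(A)
}

#' Full derivation pipeline: time series to binary temporal network
#'
#' Convenience wrapper chaining [standardize_series()],
#' [temporal_weight_matrix()], [derive_edge_series()],
#' [postprocess_edge_series()] and [binarize()]. Deterministic: identical
#' input and parameters give bit-identical output.
#'
#' @param Y nodes-x-time numeric matrix.
#' @param threshold_sd binarization threshold (default 2).
#' @param fisher,boxcox,boxcox_grid passed to [postprocess_edge_series()].
#' @return List with `network` (binary [temporal_network()]), `edge_series`
#'   (stage `"zscored"`), `raw_series` (stage `"raw_r"`), and `W`.
#' @export
derive_temporal_network <- function(Y, threshold_sd = 2, fisher = TRUE,
                                    boxcox = TRUE,
                                    boxcox_grid = seq(-5, 5, by = 0.1)) {
  Z <- standardize_series(Y)
  W <- temporal_weight_matrix(Z)
  raw <- derive_edge_series(Z, W)
  post <- postprocess_edge_series(raw, fisher = fisher, boxcox = boxcox,
                                  boxcox_grid = boxcox_grid)
  list(network = binarize(post, threshold_sd = threshold_sd),
       edge_series = post, raw_series = raw, W = W)
}
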