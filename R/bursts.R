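# Burstiness of intercontact times, per edge, per node, and pooled across
# subjects.

#' Burstiness coefficient of an intercontact-time list
#'
#' `B = (sigma(tau) - mu(tau)) / (sigma(tau) + mu(tau))` with the
#' population standard deviation, so perfectly regular activation
#' (identical intercontact times) gives exactly `B = -1`, a memoryless
#' (geometric) process gives `B` near 0, and heavy-tailed intervals give
#' `B > 0`. With fewer than two intercontact times the coefficient is
#' undefined: too few intervals give too poor an estimate of `sigma`, so an
#' `NA` marker is returned rather than a value.
#'
#' @param taus vector of positive integer intercontact times.
#' @return A list of class `burstiness_result`: `B` (or `NA` when
#'   undefined), `n_icts`, `mu`, `sigma`.
#' @export
#' @examples
#' burstiness_coefficient(c(3, 3, 3))$B     # -1: perfectly periodic
#' burstiness_coefficient(c(1, 1, 1, 9))$B  # > 0: one long gap
burstiness_coefficient <- function(taus) {
  taus <- as.numeric(taus)
  if (anyNA(taus) || any(taus <= 0)) {
    stop("intercontact times must be positive", call. = FALSE)
  }
  n <- length(taus)
  if (n < 2L) {
    return(structure(list(B = NA_real_, n_icts = n,
                          mu = if (n) mean(taus) else NA_real_,
                          sigma = NA_real_),
                     class = "burstiness_result"))
  }
  mu <- mean(taus)
  sigma <- sqrt(mean((taus - mu)^2))  # population SD: B = -1 iff sigma = 0
  structure(list(B = (sigma - mu) / (sigma + mu), n_icts = n,
                 mu = mu, sigma = sigma),
            class = "burstiness_result")
}

#' @export
print.burstiness_result <- function(x, ...) {
  if (is.na(x$B)) {
    cat(sprintf("<burstiness> undefined (%d intercontact time%s)\n",
                x$n_icts, if (x$n_icts == 1) "" else "s"))
  } else {
    cat(sprintf("<burstiness> B = %.4f (n = %d, mu = %.3f, sigma = %.3f)\n",
                x$B, x$n_icts, x$mu, x$sigma))
  }
  invisible(x)
}

#' Edge-wise and pooled burstiness
#'
#' `edge_burstiness()` applies [burstiness_coefficient()] independently to
#' every unordered node pair. `pooled_burstiness()` concatenates each
#' pair's raw intercontact times across subjects in subject order before
#' computing `B` — the remedy for short recordings where single-subject
#' intercontact lists are too short for a stable estimate.
#'
#' @param ict an `intercontact_table` from [intercontact_times()].
#' @return Data frame with columns `i`, `j`, `n_icts`, `mu`, `sigma`, `B`
#'   (`NA` where undefined).
#' @export
edge_burstiness <- function(ict) {
  stopifnot(inherits(ict, "intercontact_table"))
  burst_table(ict$pairs$i, ict$pairs$j, ict$taus)
}

#' @rdname edge_burstiness
#' @param tables list of `intercontact_table`s, one per subject, sharing `N`.
#' @export
pooled_burstiness <- function(tables) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "intercontact_table")))
  Ns <- vapply(tables, function(x) x$N, numeric(1))
  if (length(unique(Ns)) != 1L) {
    stop("all subjects must share the same node count N", call. = FALSE)
  }
  pooled <- lapply(seq_along(tables[[1]]$taus), function(p) {
    unlist(lapply(tables, function(tb) tb$taus[[p]]), use.names = FALSE)
  })
  burst_table(tables[[1]]$pairs$i, tables[[1]]$pairs$j, pooled)
}

burst_table <- function(i, j, taus) {
  res <- lapply(taus, burstiness_coefficient)
  data.frame(i = i, j = j,
             n_icts = vapply(res, `[[`, numeric(1), "n_icts"),
             mu = vapply(res, `[[`, numeric(1), "mu"),
             sigma = vapply(res, `[[`, numeric(1), "sigma"),
             B = vapply(res, `[[`, numeric(1), "B"))
}

#' Nodal burstiness
#'
#' Two nodal summaries of edge burstiness: `mode = "sum"` sums the defined
#' edge coefficients `B_ij` over all pairs incident to each node (undefined
#' edges are skipped; a node with no defined edge scores 0);
#' `mode = "pooled"` concatenates the intercontact times of all incident
#' pairs and computes one coefficient from the pooled list (`NA` when the
#' pooled list has fewer than two values).
#'
#' @param ict an `intercontact_table`.
#' @param mode `"sum"` or `"pooled"`.
#' @return Numeric vector of length `N`.
#' @export
nodal_burstiness <- function(ict, mode = c("sum", "pooled")) {
  stopifnot(inherits(ict, "intercontact_table"))
  mode <- match.arg(mode)
  N <- ict$N
  out <- numeric(N)
  for (v in seq_len(N)) {
    inc <- which(ict$pairs$i == v | ict$pairs$j == v)
    if (mode == "sum") {
      B <- burst_table(ict$pairs$i[inc], ict$pairs$j[inc], ict$taus[inc])$B
      out[v] <- sum(B[!is.na(B)])
    } else {
      out[v] <- burstiness_coefficient(
        unlist(ict$taus[inc], use.names = FALSE))$B
    }
  }
  out
}

#' Pairwise burstiness as a symmetric matrix
#'
#' Convenience layout of [edge_burstiness()] output for export: `N x N`
#' symmetric matrix with `NA` on undefined pairs and the diagonal.
#'
#' @param ict an `intercontact_table`.
#' @return `N x N` numeric matrix.
#' @export
burstiness_matrix <- function(ict) {
  tb <- edge_burstiness(ict)
  M <- matrix(NA_real_, ict$N, ict$N)
  M[cbind(tb$i, tb$j)] <- tb$B
  M[cbind(tb$j, tb$i)] <- tb$B
  M
}
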