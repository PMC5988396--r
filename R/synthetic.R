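# Seeded synthetic generators: multistate community time series for the
# derivation pipeline, renewal edge processes for burstiness, and small
# deterministic fixture networks for the global measures.

#' Multistate community time series
#'
#' Emulates multivariate node signals with community structure and state
#' switching, the statistical structure the weighted-correlation estimator
#' assumes. A latent state sequence follows a Markov chain whose stay
#' probability gives geometric dwell times with the requested mean. In
#' state `s`, the nodes of one "coherent" community (states cycle through
#' the communities) share a common Gaussian factor giving within-community
#' correlation `within_cor[s]`; all other nodes are independent. Each
#' state additionally carries a fixed node-wise mean activation pattern
#' (drawn once per state with standard deviation `state_mean_sd`), so that
#' states are distinguishable by their global spatial pattern — the
#' feature the per-time-point distance weighting keys on. Independent
#' Gaussian noise with standard deviation `noise_sd` is added throughout.
#'
#' @param N number of nodes (default 20).
#' @param T number of time points (default 200).
#' @param communities integer community id per node (default: two equal
#'   communities).
#' @param n_states number of latent states (default 2).
#' @param dwell_mean mean state dwell time in time steps (default 20;
#'   geometric dwell distribution, `dwell_mean = Inf` gives a single
#'   uninterrupted state).
#' @param within_cor within-community correlation per state, each in
#'   `[0, 1)`; recycled to `n_states` (default 0.8).
#' @param noise_sd additive noise standard deviation (default 0.5).
#' @param state_mean_sd standard deviation of the state-specific node mean
#'   patterns (default 1; set 0 for zero-mean states).
#' @param seed integer seed; output is a pure function of parameters and
#'   seed.
#' @return List: `Y` (nodes x time matrix), `states` (length-`T` integer
#'   vector), `coherent_community` (community coherent in each state),
#'   `state_means` (`N x n_states`), and `params`.
#' @export
gen_multistate_timeseries <- function(N = 20L, T = 200L,
                                      communities = rep(1:2, length.out = N),
                                      n_states = 2L, dwell_mean = 20,
                                      within_cor = 0.8, noise_sd = 0.5,
                                      state_mean_sd = 1, seed = 1L) {
  N <- as.integer(N); T <- as.integer(T); n_states <- as.integer(n_states)
  stopifnot(N >= 2L, T >= 1L, n_states >= 1L, length(communities) == N)
  within_cor <- rep_len(within_cor, n_states)
  if (any(within_cor < 0 | within_cor >= 1)) {
    stop("`within_cor` values must lie in [0, 1)", call. = FALSE)
  }
  if (dwell_mean < 1) stop("`dwell_mean` must be >= 1", call. = FALSE)
  comm_ids <- sort(unique(communities))
  coherent <- comm_ids[((seq_len(n_states) - 1L) %% length(comm_ids)) + 1L]
  withr::with_seed(seed, {
    state_means <- matrix(stats::rnorm(N * n_states, sd = state_mean_sd),
                          N, n_states)
    # latent Markov chain with geometric dwell times
    states <- integer(T)
    states[1] <- sample.int(n_states, 1L)
    p_switch <- if (is.finite(dwell_mean)) 1 / dwell_mean else 0
    if (T > 1L) {
      for (t in 2:T) {
        if (n_states > 1L && stats::runif(1) < p_switch) {
          others <- setdiff(seq_len(n_states), states[t - 1L])
          states[t] <- others[sample.int(length(others), 1L)]
        } else {
          states[t] <- states[t - 1L]
        }
      }
    }
    Y <- matrix(stats::rnorm(N * T), N, T)  # idiosyncratic unit variance
    shared <- stats::rnorm(T)               # community factor per time point
    for (t in seq_len(T)) {
      s <- states[t]
      rho <- within_cor[s]
      members <- communities == coherent[s]
      Y[members, t] <- sqrt(rho) * shared[t] + sqrt(1 - rho) * Y[members, t]
      Y[, t] <- Y[, t] + state_means[, s]
    }
    Y <- Y + matrix(stats::rnorm(N * T, sd = noise_sd), N, T)
    list(Y = Y, states = states, coherent_community = coherent,
         state_means = state_means,
         params = list(N = N, T = T, communities = communities,
                       n_states = n_states, dwell_mean = dwell_mean,
                       within_cor = within_cor, noise_sd = noise_sd,
                       state_mean_sd = state_mean_sd, seed = seed))
  })
}

#' Renewal edge processes
#'
#' Generates a single edge's binary activation series from a renewal
#' process with the named intercontact-time distribution, truncated to
#' `T` time points. The first activation is at time 1.
#' \describe{
#'   \item{`periodic`}{intervals all equal to `period`; downstream
#'     burstiness is exactly -1.}
#'   \item{`geometric`}{memoryless intervals, `1 + Geometric(rate)` so the
#'     minimum interval is 1; downstream burstiness is near 0.}
#'   \item{`powerlaw`}{heavy-tailed intervals from a discrete inverse
#'     transform with minimum interval 1 (`ceiling(U^(-1/(exponent - 1)))`);
#'     downstream burstiness is positive.}
#' }
#'
#' @param kind `"periodic"`, `"geometric"`, or `"powerlaw"`.
#' @param T number of time points.
#' @param period integer period for `kind = "periodic"`.
#' @param rate success probability in `(0, 1]` for `kind = "geometric"`.
#' @param exponent power-law exponent `> 1` for `kind = "powerlaw"`.
#' @param seed integer seed.
#' @return List: `series` (binary length-`T` vector), `times` (activation
#'   time points), `intervals` (`diff(times)`).
#' @export
gen_edge_process <- function(kind = c("periodic", "geometric", "powerlaw"),
                             T = 100L, period = NULL, rate = NULL,
                             exponent = NULL, seed = 1L) {
  kind <- match.arg(kind)
  T <- as.integer(T)
  stopifnot(T >= 1L)
  times <- switch(kind,
    periodic = {
      period <- as.integer(period)
      if (is.na(period) || period < 1L) {
        stop("`period` must be an integer >= 1", call. = FALSE)
      }
      seq.int(1L, T, by = period)
    },
    geometric = {
      if (is.null(rate) || rate <= 0 || rate > 1) {
        stop("`rate` must be in (0, 1]", call. = FALSE)
      }
      withr::with_seed(seed, {
        n_guess <- ceiling(T * rate * 1.5) + 50L
        gaps <- integer(0)
        while (sum(gaps) < T) {
          gaps <- c(gaps, stats::rgeom(n_guess, rate) + 1L)
        }
        cumsum(c(1L, gaps))
      })
    },
    powerlaw = {
      if (is.null(exponent) || exponent <= 1) {
        stop("`exponent` must be > 1", call. = FALSE)
      }
      withr::with_seed(seed, {
        gaps <- integer(0)
        while (sum(gaps) < T) {
          u <- stats::runif(ceiling(T / 2) + 50L)
          gaps <- c(gaps, ceiling(u^(-1 / (exponent - 1))))
        }
        cumsum(c(1L, gaps))
      })
    })
  times <- times[times <= T]
  series <- integer(T)
  series[times] <- 1L
  list(series = series, times = times, intervals = diff(times))
}

#' Deterministic fixture networks
#'
#' Small 4-node constructions with analytically known measure values,
#' useful as worked examples and regression anchors:
#' \describe{
#'   \item{`fig3a_like`}{12 time points; pairs (1,2) and (3,4) active at
#'     t = 1..6, pairs (1,2) and (2,3) at t = 7..12. 24 contacts but only
#'     three distinct pairs: fluctuability 3/24 = 0.125, and few
#'     transitions, so volatility is low.}
#'   \item{`fig3bc_like`}{12 time points; two pairs active per time point,
#'     cycling through all six pairs so each is active exactly 4 times:
#'     fluctuability 6/24 = 0.25, with maximal switching between
#'     consecutive graphlets.}
#'   \item{`unique_edges`}{each of the six pairs active exactly once at a
#'     distinct time point: fluctuability exactly 1.}
#'   \item{`two_component`}{two node groups never connected to each other
#'     (pairs (1,2) and (3,4) active at every of 4 time points): full
#'     reachability is impossible from every start.}
#' }
#'
#' @param name fixture name.
#' @return A binary [temporal_network()].
#' @export
fixture_network <- function(name = c("fig3a_like", "fig3bc_like",
                                     "unique_edges", "two_component")) {
  name <- match.arg(name)
  cs <- switch(name,
    fig3a_like = {
      i <- c(rep(c(1, 3), 6), rep(c(1, 2), 6))
      j <- c(rep(c(2, 4), 6), rep(c(2, 3), 6))
      t <- c(rep(1:6, each = 2), rep(7:12, each = 2))
      contact_sequence(i, j, t, N = 4, T = 12)
    },
    fig3bc_like = {
      pairs <- cbind(i = c(1, 3, 1, 2, 1, 2),
                     j = c(2, 4, 3, 4, 4, 3))
      sched <- lapply(1:12, function(t) {
        sel <- ((2 * (t - 1)) %% 6) + 1:2
        cbind(pairs[sel, , drop = FALSE], t = t)
      })
      m <- do.call(rbind, sched)
      contact_sequence(m[, 1], m[, 2], m[, 3], N = 4, T = 12)
    },
    unique_edges = {
      ut <- which(upper.tri(matrix(0, 4, 4)), arr.ind = TRUE)
      contact_sequence(ut[, 1], ut[, 2], seq_len(nrow(ut)), N = 4, T = 6)
    },
    two_component = {
      contact_sequence(rep(c(1, 3), 4), rep(c(2, 4), 4),
                       rep(1:4, each = 2), N = 4, T = 4)
    })
  contacts_to_graphlets(cs)
}
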