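test_that("fluctuability counts distinct pairs against total activations", {
  expect_equal(fluctuability(fixture_network("fig3a_like")), 0.125)
  expect_equal(fluctuability(fixture_network("fig3bc_like")), 0.25)
  expect_equal(fluctuability(fixture_network("unique_edges")), 1)
  tn <- tn_from_contacts(c(1, 1, 2), c(2, 2, 3), c(1, 2, 3), N = 3, T = 3)
  expect_equal(fluctuability(tn), 2 / 3)
  empty <- contacts_to_graphlets(
    contact_sequence(integer(), integer(), integer(), N = 3, T = 2))
  expect_error(fluctuability(empty), "undefined")
})

test_that("nodal fluctuability is partner diversity per activation", {
  tn <- tn_from_contacts(c(1, 1), c(2, 2), c(1, 2), N = 3, T = 2)
  nf <- nodal_fluctuability(tn)
  expect_equal(nf[1], 1 / 2)  # one partner, two activations
  expect_equal(nf[3], 0)      # isolated node
  distinct <- fixture_network("unique_edges")
  expect_true(all(nodal_fluctuability(distinct) == 1))
})

test_that("volatility is the mean Hamming distance between graphlets", {
  A <- array(0, c(3, 3, 4))
  A[1, 2, ] <- A[2, 1, ] <- 1
  expect_equal(volatility(temporal_network(A)), 0)

  tn <- tn_from_contacts(c(1, 2, 2), c(2, 3, 3), c(1, 2, 3), N = 3, T = 3)
  expect_equal(volatility(tn), 1)  # transitions cost 2 then 0

  single <- tn_from_contacts(1, 2, 1, N = 3, T = 1)
  expect_error(volatility(single), "undefined")
  expect_error(volatility(tn, distance = "euclidean"), "Hamming")
})

test_that("edge volatility decomposes global volatility and yields centrality", {
  withr::local_seed(31)
  tn <- random_tn(5, 6)
  ev <- edge_volatility(tn)
  expect_equal(sum(ev$edges$value), volatility(tn))
  expect_length(ev$nodes, 5)

  always_on <- tn_from_contacts(rep(1, 4), rep(2, 4), 1:4, N = 3, T = 4)
  expect_equal(edge_volatility(always_on)$edges$value[1], 0)
  flicker <- tn_from_contacts(c(1, 1), c(2, 2), c(2, 4), N = 2, T = 4)
  expect_equal(edge_volatility(flicker)$edges$value[1], 1)  # 0,1,0,1
})

test_that("reachability latency selects the r-quantile travel time", {
  A <- array(1, c(4, 4, 3))
  for (t in 1:3) diag(A[, , t]) <- 0
  pt <- shortest_temporal_paths(temporal_network(A))
  expect_equal(reachability_latency(pt, r = 1), 1)

  split <- fixture_network("two_component")
  pt2 <- shortest_temporal_paths(split)
  expect_true(is.na(reachability_latency(pt2, r = 1)))
  # reaching half the nodes is instant inside each component
  expect_equal(reachability_latency(pt2, r = 0.5), 1)
  expect_error(reachability_latency(pt, r = 0), "\\(0, 1\\]")
  expect_error(reachability_latency(pt, r = 1.2), "\\(0, 1\\]")
})

test_that("reachability and efficiency match brute-force evaluation", {
  withr::local_seed(55)
  for (rep in 1:10) {
    N <- sample(3:6, 1); T <- sample(2:6, 1)
    tn <- random_tn(N, T, density = 0.5)
    pt <- shortest_temporal_paths(tn)
    # brute force directly over the duration array
    acc <- c(); n_def <- 0
    effsum <- 0
    for (i in seq_len(N)) for (t in seq_len(T)) {
      v <- sort(pt$d[i, , t])[floor(1 * N + 0.5)]
      if (is.finite(v)) { acc <- c(acc, v); n_def <- n_def + 1 }
      for (j in seq_len(N)) if (j != i && is.finite(pt$d[i, j, t])) {
        effsum <- effsum + 1 / pt$d[i, j, t]
      }
    }
    want_T <- if (n_def) sum(acc) / (T * N) else NA_real_
    want_Ts <- if (n_def) mean(acc) else NA_real_
    expect_equal(reachability_latency(pt, 1, "T"), want_T)
    expect_equal(reachability_latency(pt, 1, "Tstar"), want_Ts)
    expect_equal(temporal_efficiency(pt), effsum / (T * (N^2 - N)))
  }
})

test_that("temporal efficiency spans its analytic limits", {
  A <- array(1, c(3, 3, 2))
  for (t in 1:2) diag(A[, , t]) <- 0
  expect_equal(temporal_efficiency(shortest_temporal_paths(temporal_network(A))), 1)
  none <- contacts_to_graphlets(
    contact_sequence(integer(), integer(), integer(), N = 3, T = 2))
  expect_equal(temporal_efficiency(shortest_temporal_paths(none)), 0)
})

test_that("order dependence splits the measures as expected", {
  withr::local_seed(66)
  tn <- fixture_network("fig3a_like")
  perm <- sample(n_times(tn))
  tnp <- temporal_network(unclass(tn)[, , perm])
  expect_equal(fluctuability(tnp), fluctuability(tn))
  expect_equal(temporal_degree_centrality(tnp), temporal_degree_centrality(tn))
  # volatility is order sensitive but time-reversal invariant
  expect_false(isTRUE(all.equal(volatility(tnp), volatility(tn))))
  rev <- temporal_network(unclass(tn)[, , n_times(tn):1])
  expect_equal(volatility(rev), volatility(tn))
  # efficiency depends on order too (swapping the first two steps of a
  # temporal chain breaks the relay)
  chain <- tn_from_contacts(c(1, 2, 3), c(2, 3, 4), c(1, 2, 3), N = 4, T = 3)
  swapped <- temporal_network(unclass(chain)[, , c(2, 1, 3)])
  eff <- function(x) temporal_efficiency(shortest_temporal_paths(x))
  expect_false(isTRUE(all.equal(eff(chain), eff(swapped))))
})

test_that("the three canonical regimes order F and V as described", {
  a <- fixture_network("fig3a_like")      # few repeated edges
  b <- fixture_network("fig3bc_like")     # all pairs, maximal switching
  # blockwise analogue: all six pairs, changed every four time points
  pairs <- cbind(c(1, 3, 1, 2, 1, 2), c(2, 4, 3, 4, 4, 3))
  blocks <- do.call(rbind, lapply(1:12, function(t) {
    sel <- (((t - 1) %/% 4) * 2) %% 6 + 1:2
    cbind(pairs[sel, , drop = FALSE], t)
  }))
  cc <- contacts_to_graphlets(
    contact_sequence(blocks[, 1], blocks[, 2], blocks[, 3], N = 4, T = 12))
  expect_lt(fluctuability(a), fluctuability(b))
  expect_equal(fluctuability(b), fluctuability(cc))
  expect_lt(volatility(a), volatility(cc))
  expect_lt(volatility(cc), volatility(b))
})

test_that("adding contacts never decreases temporal efficiency", {
  withr::local_seed(95)
  for (rep in 1:8) {
    tn <- random_tn(sample(3:5, 1), sample(2:5, 1), density = 0.3)
    e0 <- temporal_efficiency(shortest_temporal_paths(tn))
    absent <- which(tn == 0 & upper_tri_idx(dim(tn)[1], dim(tn)[3]),
                    arr.ind = TRUE)
    if (!nrow(absent)) next
    pick <- absent[sample(nrow(absent), 1), ]
    A2 <- unclass(tn)
    A2[pick[1], pick[2], pick[3]] <- A2[pick[2], pick[1], pick[3]] <- 1
    e1 <- temporal_efficiency(shortest_temporal_paths(temporal_network(A2)))
    expect_gte(e1, e0)
  }
})
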