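test_that("standardization is exact, idempotent, and rejects flat series", {
  Y <- rbind(1:3, c(2, 5, 8))
  Z <- standardize_series(Y)
  expect_equal(rowMeans(Z), c(0, 0), tolerance = 1e-12)
  expect_equal(apply(Z, 1, sd), c(1, 1), tolerance = 1e-12)
  expect_equal(standardize_series(Z), Z, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(standardize_series(rbind(1:3, c(4, 4, 4))), "node 2")
})

test_that("temporal weights invert distances, scale jointly, and pin the diagonal", {
  Y <- rbind(c(0, 3, 6), c(0, 4, 8))  # column distances 5, 10, 5
  W <- temporal_weight_matrix(Y)
  expect_equal(W, rbind(c(1, 1, 0), c(1, 1, 1), c(0, 1, 1)))
  expect_equal(W, t(W))

  # exactly equidistant columns: all off-diagonal weights collapse to 1
  Wc <- temporal_weight_matrix(diag(3))
  expect_true(all(Wc == 1))

  # duplicated columns: capped at the maximum finite weight, with warning
  Yd <- rbind(c(0, 0, 3, 9), c(0, 0, 4, 12))
  expect_warning(Wd <- temporal_weight_matrix(Yd), "identical")
  expect_equal(Wd[1, 2], 1)
  expect_equal(diag(Wd), rep(1, 4))
  expect_error(temporal_weight_matrix(Y[, 1:2]), "3 time points")
})

test_that("weighted Pearson reduces to ordinary Pearson under equal weights", {
  withr::local_seed(12)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    w0 <- runif(1, 0.1, 5)
    expect_equal(weighted_pearson(x, y, rep(w0, n)), cor(x, y),
                 tolerance = 1e-12)
  }
  expect_equal(weighted_pearson(c(0, 1, 2), c(0, 1, 0), c(1, 1, 1)), 0)
  expect_equal(weighted_pearson(c(0, 1, 2), c(0, 1, 0), c(1, 1, 2)),
               -0.0625 / sqrt(0.6875 * 0.1875))
  expect_error(weighted_pearson(1:3, 1:3, c(-1, 1, 1)), "non-negative")
  expect_error(weighted_pearson(1:3, c(2, 2, 2), c(1, 1, 1)), "degenerate")
})

test_that("edge series match per-time-point weighted correlations", {
  withr::local_seed(23)
  Y <- matrix(rnorm(3 * 12), 3, 12)
  Y[2, 1:6] <- Y[1, 1:6] + rnorm(6, sd = 0.1)  # state switch for pair (1,2)
  Z <- standardize_series(Y)
  W <- temporal_weight_matrix(Z)
  es <- derive_edge_series(Z, W)
  expect_equal(es$stage, "raw_r")
  for (t in c(1, 5, 12)) {
    for (p in seq_len(nrow(es$pairs))) {
      expect_equal(es$values[p, t],
                   weighted_pearson(Z[es$pairs$i[p], ], Z[es$pairs$j[p], ],
                                    W[t, ]))
    }
  }
  expect_true(all(es$values >= -1 & es$values <= 1))

  # a perfectly correlated pair stays at 1 under any weighting
  Y2 <- rbind(rnorm(10), 0)
  Y2[2, ] <- Y2[1, ]
  W2 <- matrix(runif(100, 0.1, 1), 10, 10); diag(W2) <- 1
  es2 <- derive_edge_series(Y2, W2)
  expect_equal(es2$values[1, ], rep(1, 10), tolerance = 1e-12)

  # uniform weights reproduce the static Pearson at every time point
  esu <- derive_edge_series(Z, matrix(1, 12, 12))
  stat <- cor(t(Z))
  expect_equal(esu$values, matrix(stat[cbind(es$pairs$i, es$pairs$j)],
                                  nrow(es$pairs), 12),
               tolerance = 1e-12)
})

test_that("Box-Cox grid search recovers the generating transform", {
  withr::local_seed(90)
  ln <- exp(rnorm(1e4))                      # lognormal: lambda near 0
  expect_lt(abs(boxcox_lambda(ln)), 0.2)
  ga <- rnorm(1e4, 10); ga <- ga - min(ga) + 1  # Gaussian: lambda near 1
  expect_lt(abs(boxcox_lambda(ga) - 1), 0.3)
  # independent profile-likelihood oracle over the same grid
  mb <- MASS::boxcox(ln ~ 1, lambda = seq(-5, 5, 0.1), plotit = FALSE)
  expect_equal(boxcox_lambda(ln), mb$x[which.max(mb$y)])
  mb2 <- MASS::boxcox(ga ~ 1, lambda = seq(-5, 5, 0.1), plotit = FALSE)
  expect_equal(boxcox_lambda(ga), mb2$x[which.max(mb2$y)])
})

test_that("post-processing standardizes every edge series and is deterministic", {
  withr::local_seed(34)
  Z <- standardize_series(matrix(rnorm(5 * 40), 5, 40))
  es <- derive_edge_series(Z, temporal_weight_matrix(Z))
  post <- postprocess_edge_series(es)
  expect_equal(post$stage, "zscored")
  expect_equal(rowMeans(post$values), rep(0, nrow(post$values)),
               tolerance = 1e-10)
  expect_equal(apply(post$values, 1, sd), rep(1, nrow(post$values)),
               tolerance = 1e-10)
  expect_true(all(post$lambda >= -5 & post$lambda <= 5))
  expect_error(postprocess_edge_series(post), "raw_r")

  flat <- es
  flat$values[1, ] <- 0.3
  expect_error(postprocess_edge_series(flat), "constant")
})

test_that("the full pipeline is a pure function of its input", {
  withr::local_seed(56)
  Y <- matrix(rnorm(4 * 30), 4, 30)
  r1 <- derive_temporal_network(Y)
  r2 <- derive_temporal_network(Y)
  expect_identical(r1$edge_series$values, r2$edge_series$values)
  expect_identical(unclass(r1$network), unclass(r2$network))
})

test_that("binarization keeps the strict positive tail", {
  es <- list(values = rbind(c(0.5, 2.5, -1.0, 2.1)),
             pairs = data.frame(i = 1, j = 2), N = 2, stage = "zscored")
  class(es) <- "edge_series_set"
  tn <- binarize(es, threshold_sd = 2)
  expect_equal(tn[1, 2, ], c(0, 1, 0, 1))
  tn0 <- binarize(es, threshold_sd = 0)
  expect_equal(tn0[1, 2, ], c(1, 1, 0, 1))
  expect_error(binarize(structure(list(stage = "raw_r"),
                                  class = "edge_series_set")), "zscored")

  # Gaussian series activate at about the upper-tail rate
  withr::local_seed(67)
  es2 <- list(values = matrix(rnorm(1e5), 1), pairs = data.frame(i = 1, j = 2),
              N = 2, stage = "zscored")
  class(es2) <- "edge_series_set"
  frac <- mean(binarize(es2, 2)[1, 2, ])
  expect_lt(abs(frac - pnorm(2, lower.tail = FALSE)), 0.005)
})
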