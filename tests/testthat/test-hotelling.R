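test_that("pooled covariance is the df-weighted average of group covariances", {
  X <- matrix(c(0, 1, 2, 5, 1, 3), ncol = 2)
  expect_equal(pooled_covariance(X, X), cov(X))

  # n1 = n2: constructed samples with S1 = I, S2 = 3I -> S = 2I
  X1 <- matrix(c(-1, 1, -1, 1, -1, -1, 1, 1), ncol = 2) / sqrt(4 / 3)
  X2 <- sqrt(3) * X1
  expect_equal(cov(X1), diag(2), tolerance = 1e-12)
  expect_equal(pooled_covariance(X1, X2), 2 * diag(2), tolerance = 1e-12)

  # constant columns give zero rows/cols
  C1 <- cbind(rep(1, 4), rnorm(4)); C2 <- cbind(rep(1, 3), rnorm(3))
  S <- pooled_covariance(C1, C2)
  expect_equal(S[1, ], c(0, 0))
})

test_that("T2 on identical groups is 0 and the p=1 case is the pooled t^2", {
  X <- matrix(rnorm(40), ncol = 4)
  h0 <- hotelling_t2(X, X)
  expect_equal(h0$t2, 0)
  expect_equal(h0$p_value, 1)

  h <- hotelling_t2(matrix(0:2), matrix(3:5))
  expect_equal(h$t2, 13.5)
  expect_equal(h$df1, 1)
  expect_equal(h$df2, 4)
  tt <- t.test(0:2, 3:5, var.equal = TRUE)
  expect_equal(h$t2, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(h$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("T2 reduces to the squared pooled t on random univariate data", {
  set.seed(101)
  for (i in 1:100) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    h <- hotelling_t2(matrix(x), matrix(y))
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(h$t2, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(h$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("T2 matches a brute-force eigen-inverse oracle and is affine invariant", {
  set.seed(202)
  for (i in 1:20) {
    p <- 3
    X1 <- matrix(rnorm(10 * p), ncol = p)
    X2 <- matrix(rnorm(12 * p, 0.3), ncol = p)
    h <- hotelling_t2(X1, X2)
    expect_equal(h$t2, t2_brute(X1, X2), tolerance = 1e-10)
    # affine invariance under a random invertible map plus offset
    repeat { A <- matrix(rnorm(p * p), p); if (abs(det(A)) > 0.1) break }
    b <- rnorm(p)
    ht <- hotelling_t2(sweep(X1 %*% A, 2, b, "+"), sweep(X2 %*% A, 2, b, "+"))
    expect_equal(ht$t2, h$t2, tolerance = 1e-8)
    # exchangeability of the two groups
    hs <- hotelling_t2(X2, X1)
    expect_equal(hs$t2, h$t2, tolerance = 1e-12)
    expect_equal(hs$p_value, h$p_value, tolerance = 1e-12)
  }
})

test_that("degenerate inputs raise the documented errors", {
  X1 <- matrix(rnorm(8), ncol = 4)
  X2 <- matrix(rnorm(8), ncol = 4)
  expect_error(hotelling_t2(X1, X2), class = "vmr_dimension_error")
  C <- cbind(rep(1, 5), rnorm(5))
  expect_error(hotelling_t2(C, cbind(rep(1, 5), rnorm(5))),
               class = "vmr_singular_covariance")
  # ridge opt-in makes the singular case computable
  h <- hotelling_t2(C, cbind(rep(1, 5), rnorm(5)), ridge = 1e-6)
  expect_true(is.finite(h$t2))
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.37), 0.37)
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), class = "vmr_validation_error")
  # monotone non-decreasing in p-value rank, never below raw
  set.seed(9); p <- runif(50)
  q <- fdr_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("pairwise battery enumerates pairs and adjusts one family", {
  w <- tiny_windows(seed = 13)
  b <- suppressWarnings(pairwise_battery(w, "strain",
                                         window_tags = list("pre", "post"),
                                         filter = list(stimulus = "on")))
  expect_equal(nrow(b), 6L)  # 3 pairs x 2 windows
  expect_equal(b$p_adj, fdr_adjust(b$p_raw))
  expect_true(all(b$p_adj >= b$p_raw))
  # sub-interval 1-2 s: p_dim = 2, df2 = n1 + n2 - 3
  b2 <- suppressWarnings(pairwise_battery(w, "strain", window_tags = list(c(1, 2)),
                                          filter = list(stimulus = "on")))
  expect_true(all(b2$p_dim == 2))
  expect_true(all(b2$df2 == b2$n1 + b2$n2 - 3))
  expect_equal(unique(b2$window), "1:2")
})

test_that("pooling several trials triggers the pseudoreplication warning", {
  w <- tiny_windows(seed = 13)
  expect_warning(pairwise_battery(w, "strain", window_tags = list("post"),
                                  filter = list(stimulus = "on")),
                 class = "vmr_pseudoreplication_warning")
  expect_silent(pairwise_battery(w, "strain", window_tags = list("post"),
                                 filter = list(stimulus = "on", trial_index = 1)))
})

test_that("an injected post-onset jump is detected before-vs-after", {
  # large stimulus effect: same-group pre-vs-post must be significant in
  # nearly every simulated dataset
  hits <- 0L
  for (r in 1:50) {
    sim <- generate_plate_experiment(
      tiny_config(rows = 4, cols = 6, stages = 6, stage_mult = c(`6` = 1),
                  stage_resp = c(`6` = 1), n_trials = 1,
                  kernel_on = list(peak = 0.4, decay = 0.2, sustained = 0.15)),
      seed = 6000 + r)
    w <- extract_windows(sim$activity, sim$schedule)
    b <- prepost_battery(w, "strain", filter = list(stimulus = "on"))
    hits <- hits + all(b$p_adj < 0.05)
  }
  expect_gte(hits / 50, 0.95)
})
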