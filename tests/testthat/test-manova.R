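test_that("design construction codes treatment contrasts in term order", {
  md <- data.frame(g = rep(c("a", "b", "c"), each = 3))
  d <- build_design(md, "g")
  expect_equal(ncol(d$X), 3L)  # intercept + 2 dummies
  expect_equal(d$assign, c(0L, 1L, 1L))

  md2 <- expand.grid(strain = paste0("s", 1:3), stage_dpf = 3:9)
  d2 <- build_design(md2, c("strain", "stage_dpf", "strain:stage_dpf"))
  expect_equal(sum(d2$assign == 3), (3 - 1) * (7 - 1))  # 12 interaction cols

  expect_error(build_design(md2, c("strain", "strain:stage_dpf")),
               class = "vmr_validation_error")
  expect_error(build_design(data.frame(g = rep("a", 5)), "g"),
               class = "vmr_degenerate_factor")
})

test_that("the full VMR term list yields 12 testable terms in order", {
  w <- tiny_windows(seed = 17)
  fit <- manova_windows(w, response = "full")
  expect_equal(nrow(fit$table), 12L)
  expect_equal(fit$table$term[1:6],
               c("well", "bio_rep", "strain", "stage_dpf", "trial_index",
                 "stimulus"))
  expect_equal(fit$table$order_index, 1:12)
  expect_true(all(fit$table$pillai >= 0 &
                    fit$table$pillai <= pmin(fit$p_dim, fit$table$q)))
})

test_that("Pillai trace matches an independent eigenvalue oracle", {
  set.seed(33)
  for (i in 1:10) {
    A <- matrix(rnorm(9), 3); B <- matrix(rnorm(9), 3)
    H <- crossprod(A); E <- crossprod(B) + diag(1e-3, 3)
    expect_equal(pillai_trace(H, E), pillai_eigen_oracle(H, E), tolerance = 1e-10)
  }
  expect_equal(pillai_trace(matrix(2), matrix(2)), 0.5)
  f0 <- pillai_approx_f(0, p = 4, q = 2, v = 30)
  expect_equal(f0$f, 0)
  expect_equal(f0$p_value, 1)
})

test_that("p=1 single factor reduces to one-way ANOVA", {
  set.seed(44)
  g <- factor(rep(c("a", "b", "c"), times = c(7, 9, 8)))
  y <- rnorm(24, mean = as.integer(g) * 0.5)
  fit <- manova_fit(matrix(y), build_design(data.frame(g = g), "g"))
  av <- anova(aov(y ~ g))
  expect_equal(fit$table$approx_f, av$`F value`[1], tolerance = 1e-8)
  expect_equal(fit$table$p_value, av$`Pr(>F)`[1], tolerance = 1e-8)
  oracle <- ss_oneway_oracle(y, g)
  expect_equal(fit$table$pillai, oracle$between / oracle$total, tolerance = 1e-10)
})

test_that("multi-factor p=1 fits reproduce sequential univariate ANOVA", {
  w <- tiny_windows(seed = 21)
  keep <- w$meta$stimulus == "on"
  md <- w$meta[keep, ]
  y <- w$values[keep, "5"]
  terms <- c("well", "bio_rep", "strain", "stage_dpf", "strain:stage_dpf")
  fit <- manova_fit(matrix(y), build_design(md, terms))
  md_f <- md; for (v in c("well", "bio_rep", "strain", "stage_dpf")) {
    md_f[[v]] <- factor(md_f[[v]])
  }
  av <- anova(lm(y ~ well + bio_rep + strain + stage_dpf + strain:stage_dpf,
                 data = md_f))
  expect_equal(fit$table$approx_f, av$`F value`[1:5], tolerance = 1e-8)
  expect_equal(fit$table$p_value, av$`Pr(>F)`[1:5], tolerance = 1e-8)
})

test_that("sequential SSCP decomposition partitions the total exactly", {
  w <- tiny_windows(seed = 19)
  fit <- manova_windows(w, response = "full")
  recon <- Reduce(`+`, fit$H) + fit$E
  expect_equal(recon, fit$total_sscp, tolerance = 1e-8)
  # pre/post responses fit separately partition as well
  for (resp in c("pre", "post")) {
    f2 <- manova_windows(w, terms = default_vmr_terms(FALSE), response = resp,
                         filter = list(stimulus = "on"))
    expect_equal(Reduce(`+`, f2$H) + f2$E, f2$total_sscp, tolerance = 1e-8)
  }
})

test_that("permuting response columns leaves every V, F and p unchanged", {
  w <- tiny_windows(seed = 23)
  keep <- w$meta$stimulus == "off"
  md <- w$meta[keep, ]
  Y <- window_matrix(w, "post")[keep, ]
  terms <- c("well", "strain", "stage_dpf")
  f1 <- manova_fit(Y, build_design(md, terms))
  perm <- sample(ncol(Y))
  f2 <- manova_fit(Y[, perm], build_design(md, terms))
  expect_equal(f2$table$pillai, f1$table$pillai, tolerance = 1e-10)
  expect_equal(f2$table$approx_f, f1$table$approx_f, tolerance = 1e-10)
  expect_equal(f2$table$p_value, f1$table$p_value, tolerance = 1e-10)
  expect_equal(f2$E, f1$E[perm, perm], tolerance = 1e-10)
})

test_that("the fit agrees with the reference MANOVA implementation", {
  w <- tiny_windows(seed = 29)
  keep <- w$meta$stimulus == "on" & w$meta$trial_index == 1
  md <- w$meta[keep, ]
  Y <- window_matrix(w, c(1, 5))[keep, ]
  terms <- c("strain", "stage_dpf", "strain:stage_dpf")
  fit <- manova_fit(Y, build_design(md, terms))
  md_f <- data.frame(strain = factor(md$strain), stage = factor(md$stage_dpf))
  ref <- summary(manova(Y ~ strain * stage, data = md_f), test = "Pillai")$stats
  expect_equal(fit$table$pillai, unname(ref[1:3, "Pillai"]), tolerance = 1e-8)
  expect_equal(fit$table$approx_f, unname(ref[1:3, "approx F"]), tolerance = 1e-8)
  expect_equal(fit$table$p_value, unname(ref[1:3, "Pr(>F)"]), tolerance = 1e-8)
})

test_that("zero-signal responses give V near 0 and error df guards hold", {
  md <- data.frame(g = rep(c("a", "b"), each = 4))
  set.seed(55)
  Y0 <- matrix(rnorm(8), ncol = 2)
  fit <- manova_fit(rbind(Y0, Y0), build_design(md, "g"))  # equal group means
  expect_equal(fit$table$pillai, 0, tolerance = 1e-12)
  expect_equal(fit$table$p_value, 1)
  # response dimension above error df is refused
  expect_error(manova_fit(matrix(rnorm(8 * 7), nrow = 8),
                          build_design(md, "g")),
               class = "vmr_response_dimension_error")
})
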