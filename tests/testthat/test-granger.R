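test_that("within demeaning centers each group exactly and is idempotent", {
  expect_equal(within_demean(c(1, 2, 3), rep("a", 3)), c(-1, 0, 1))
  v <- c(1, 2, 3, 10, 20, 30)
  g <- rep(c("a", "b"), each = 3)
  d <- within_demean(v, g)
  expect_equal(as.vector(tapply(d, g, mean)), c(0, 0))
  expect_equal(within_demean(d, g), d)
  expect_error(within_demean(numeric(0), character(0)), "empty")
})

test_that("pooled within OLS identifies noiseless dynamics exactly", {
  withr::local_seed(12)
  N <- 8; T_ <- 12
  X <- matrix(rnorm(N * T_), N)
  Y <- matrix(0, N, T_)
  a <- rnorm(N, sd = 3)
  for (t in 2:T_) Y[, t] <- a + 0.5 * Y[, t - 1] + 0.3 * X[, t - 1]
  fit <- pooled_within_ols(Y, X, p = 1)
  expect_equal(unname(fit$theta), c(0.5, 0.3), tolerance = 1e-8)
  # identically-zero cause is a singular design, named in the error
  expect_error(pooled_within_ols(Y, matrix(0, N, T_), p = 1,
                                 cause = "xvar", effect = "yvar"),
               "singular.*xvar")
})

test_that("pooled within OLS equals the per-subject-dummy regression oracle", {
  withr::local_seed(13)
  for (rep_ in 1:5) {
    N <- 6; T_ <- 9
    Y <- matrix(rnorm(N * T_), N) + rnorm(N, sd = 2)
    X <- matrix(rnorm(N * T_), N) + rnorm(N, sd = 2)
    fit <- pooled_within_ols(Y, X, p = 1)
    # oracle: explicit dummy-variable least squares on the stacked raw data
    df <- data.frame(
      y = as.vector(t(Y[, 2:T_])),
      ylag = as.vector(t(Y[, 1:(T_ - 1)])),
      xlag = as.vector(t(X[, 1:(T_ - 1)])),
      subj = factor(rep(1:N, each = T_ - 1)))
    dummy <- coef(lm(y ~ 0 + subj + ylag + xlag, data = df))
    expect_equal(unname(fit$theta), unname(dummy[c("ylag", "xlag")]),
                 tolerance = 1e-10)
  }
})

test_that("half-panel jackknife combination is the stated arithmetic", {
  expect_equal(hpj_estimate(c(1, 2), c(1, 2), c(1, 2)), c(1, 2))
  expect_equal(hpj_estimate(1.0, 0.8, 0.6), 1.3)
  expect_error(hpj_estimate(1:2, 1:3, 1:2), "equal length")
})

test_that("granger_test validates inputs and returns a coherent result", {
  withr::local_seed(14)
  p <- null_pair(10, 9)
  expect_error(granger_test(p, "x", "x"), "must differ")
  expect_error(granger_test(p, "nope", "y"), "unknown variable")
  r <- granger_test(p, "x", "y")
  expect_s3_class(r, "granger_pair")
  expect_gte(r$wald, 0)
  expect_equal(r$df, 1L)
  expect_true(r$p_value >= 0 && r$p_value <= 1)
  expect_length(r$theta_hpj, 2L)
  expect_equal(r$n_effective, 10L * 8L)
  arr <- array(rnorm(6 * 4 * 2), dim = c(6, 4, 2),
               dimnames = list(NULL, NULL, c("y", "x")))
  tiny <- panel_dataset(long_from_array(arr))
  expect_error(granger_test(tiny, "x", "y"), "too small|too short")
})

test_that("Wald statistics and p-values are scale equivariant", {
  withr::local_seed(15)
  p <- edge_pair(12, 9, beta = 0.5)
  r1 <- granger_test(p, "x", "y")
  d <- p$data
  d$value[d$variable == "x"] <- 37.5 * d$value[d$variable == "x"]
  d$value[d$variable == "y"] <- 0.004 * d$value[d$variable == "y"]
  r2 <- granger_test(panel_dataset(d), "x", "y")
  expect_equal(r1$wald, r2$wald, tolerance = 1e-9)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-9)
})

test_that("bootstrap mode is seed-deterministic and tracks the clustered test", {
  withr::local_seed(16)
  p <- edge_pair(20, 9, beta = 0.6)
  b1 <- granger_test(p, "x", "y", variance = "bootstrap", n_boot = 99, seed = 5)
  b2 <- granger_test(p, "x", "y", variance = "bootstrap", n_boot = 99, seed = 5)
  expect_identical(b1$p_value, b2$p_value)
  # under the null the two variance modes agree on the 5% decision almost always
  agree <- replicate(30, {
    pn <- null_pair(50, 9)
    pc <- granger_test(pn, "x", "y")$p_value < 0.05
    pb <- granger_test(pn, "x", "y", variance = "bootstrap",
                       n_boot = 99, seed = 1)$p_value < 0.05
    pc == pb
  })
  expect_gte(mean(agree), 0.9)
})

test_that("pairwise sweep covers all ordered pairs and is order-invariant", {
  withr::local_seed(17)
  spec <- sparse_var_spec(V = 4, n_edges = 3, coef = 0.5, N = 12, T_ = 9, seed = 30)
  p <- simulate_panel_var(spec)$panel
  gs <- pairwise_granger(p)
  expect_length(gs$results, 4 * 3)
  expect_equal(length(gs$errors), 0L)
  df <- as.data.frame(gs)
  expect_equal(nrow(df), 12L)
  # permuting the variable list permutes but does not change the triples
  gs2 <- pairwise_granger(p, variables = rev(p$variables))
  key <- function(d) d[order(d$cause, d$effect), c("cause", "effect", "p_value")]
  d1 <- key(as.data.frame(gs))
  d2 <- key(as.data.frame(gs2))
  rownames(d1) <- rownames(d2) <- NULL
  expect_equal(d1, d2)
  # 2 variables -> 2 results
  expect_length(pairwise_granger(p, variables = p$variables[1:2])$results, 2L)
})

test_that("per-pair failures are collected, not fatal", {
  withr::local_seed(18)
  N <- 8; T_ <- 9
  arr <- array(rnorm(N * T_ * 3), dim = c(N, T_, 3),
               dimnames = list(NULL, NULL, c("a", "b", "flat")))
  arr[, , "flat"] <- matrix(rep(rnorm(N), T_), N)  # constant within subject
  p <- panel_dataset(long_from_array(arr))
  gs <- pairwise_granger(p)
  expect_length(gs$results, 6L)
  expect_gt(length(gs$errors), 0L)
  expect_match(gs$errors[1], "singular|constant")
  ok <- !vapply(gs$results, function(r) is.null(r$theta_within), logical(1))
  expect_true(any(ok))
})
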