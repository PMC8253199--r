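test_that("ADF orthogonalization reduces to scaled identities with no controls", {
  withr::local_seed(2)
  y <- cumsum(rnorm(12))
  comp <- adf_components(y, lags = 0, deterministic = "none")
  # with no lags and no deterministic terms the residuals are the raw
  # series scaled by the ADF residual SD
  expect_equal(comp$e * comp$sigma, diff(y))
  expect_equal(comp$v * comp$sigma, y[-length(y)])
  expect_error(adf_components(rep(1, 10)), "constant")
  expect_error(adf_components(rnorm(4), lags = 2), "too few")
})

test_that("white noise yields a slope near -1 in the ADF regression", {
  withr::local_seed(3)
  slopes <- replicate(200, {
    comp <- adf_components(rnorm(40), lags = 0, deterministic = "none")
    sum(comp$v * comp$e) / sum(comp$v^2)
  })
  expect_equal(mean(slopes), -1, tolerance = 0.05)
})

test_that("t* is invariant to rescaling a subject's series", {
  p <- simulate_unit_root_panel(6, 20, seed = 4)
  r1 <- llc_test(p, "y", nrep = 400, seed = 9)
  d <- p$data
  d$value[d$subject == "S01"] <- 1000 * d$value[d$subject == "S01"]
  p2 <- panel_dataset(d)
  r2 <- llc_test(p2, "y", nrep = 400, seed = 9)
  expect_equal(r1$t_star, r2$t_star, tolerance = 1e-10)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-10)
})

test_that("llc results are deterministic given the seed and monotone in t*", {
  p <- simulate_unit_root_panel(8, 15, seed = 5)
  r1 <- llc_test(p, "y", nrep = 400, seed = 21)
  r2 <- llc_test(p, "y", nrep = 400, seed = 21)
  expect_identical(r1$t_star, r2$t_star)
  expect_identical(r1$p_value, r2$p_value)
  expect_equal(r1$p_value, pnorm(r1$t_star))  # left-tail one-sided
  expect_true(r1$sigma_star > 0)
  expect_true(r1$p_value >= 0 && r1$p_value <= 1)
})

test_that("a constant subject series fails with the subject named", {
  arr <- array(rnorm(3 * 10), dim = c(3, 10, 1), dimnames = list(NULL, NULL, "y"))
  arr[2, , 1] <- 7
  p <- panel_dataset(long_from_array(arr))
  expect_error(llc_test(p, "y", nrep = 100), "S02.*constant|constant.*S02")
})

test_that("llc has power against clearly stationary panels", {
  withr::local_seed(6)
  # AR(1) levels need no ADF augmentation, so power is measured at the
  # correct lag order 0 (augmentation lags cost power; see the vignette)
  rej <- replicate(40, {
    N <- 20; T_ <- 50
    Y <- matrix(0, N, T_ + 20)
    for (t in 2:(T_ + 20)) Y[, t] <- 0.3 * Y[, t - 1] + rnorm(N)
    arr <- array(Y[, 21:(T_ + 20)] + rnorm(N), dim = c(N, T_, 1),
                 dimnames = list(NULL, NULL, "y"))
    p <- panel_dataset(long_from_array(arr))
    llc_test(p, "y", lags = 0, nrep = 400, seed = 13)$reject_unit_root
  })
  expect_gt(mean(rej), 0.9)
})

test_that("tabulated moments are close to matched simulated moments", {
  tab <- llc_moment_table()
  expect_true(all(tab$sigma_star > 0))
  expect_setequal(unique(tab$deterministic), c("none", "intercept", "trend"))
  p <- simulate_unit_root_panel(20, 26, seed = 31)
  rs <- llc_test(p, "y", lags = 0, nrep = 2000, seed = 17, moments = "simulated")
  rt <- llc_test(p, "y", lags = 0, moments = "tabulated")
  expect_lt(abs(rs$t_star - rt$t_star), 0.2)
})

test_that("ensure_stationary differences integrated variables and logs it", {
  # stationary panel: nothing differenced
  spec <- synthetic_spec(N = 20, T_ = 20, A = diag(c(0.3, 0.3)), seed = 8)
  p <- simulate_panel_var(spec)$panel
  out <- ensure_stationary(p, lags = 0, nrep = 400, seed = 3)
  expect_equal(out$log$diff_order, c(0L, 0L))
  expect_identical(out$panel$data, p$data)

  # a pure random-walk variable (white-noise base series, so lag order 0 is
  # correctly specified) gets differenced exactly once in most replicates;
  # the expected miss rate is the test size alpha plus a little type II
  hits <- vapply(1:100, function(s) {
    spec <- synthetic_spec(N = 30, T_ = 40, A = diag(c(0.4, 0, 0.4)),
                           unit_root_flags = c(FALSE, TRUE, FALSE), seed = s)
    p <- simulate_panel_var(spec)$panel
    out <- suppressWarnings(ensure_stationary(p, lags = 0, nrep = 400, seed = 7))
    identical(out$log$diff_order, c(0L, 1L, 0L))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("max_diff = 0 flags a nonstationary variable untransformed", {
  p <- simulate_unit_root_panel(20, 30, seed = 9)
  expect_warning(out <- ensure_stationary(p, max_diff = 0, nrep = 400, seed = 5),
                 "nonstationary")
  expect_false(out$log$stationary)
  expect_identical(out$panel$data, p$data)
  expect_error(ensure_stationary(p, max_diff = 0, on_fail = "error",
                                 nrep = 400, seed = 5),
               "nonstationary")
})

test_that("differencing keeps the panel balanced across variables", {
  spec <- synthetic_spec(N = 10, T_ = 20, A = diag(c(0.3, 0.3, 0.3)),
                         unit_root_flags = c(TRUE, TRUE, FALSE), seed = 10)
  p <- simulate_panel_var(spec)$panel
  out <- suppressWarnings(ensure_stationary(p, lags = 0, nrep = 300, seed = 11))
  expect_s3_class(out$panel, "panel_dataset")
  dmax <- max(out$log$diff_order)
  expect_equal(unname(out$panel$n_times), 20L - dmax)
  # untouched variable equals the truncated original
  keep <- (dmax + 1L):20L
  expect_equal(panel_array(out$panel)[, , "v3"], panel_array(p)[, , "v3"][, keep])
})
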