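#' Per-panel ADF orthogonalization for the pooled unit-root test
#'
#' First stage of the Levin-Lin-Chu procedure for one subject's series:
#' the first difference `dy_t` and the lagged level `y_{t-1}` are each
#' regressed on the lagged differences `dy_{t-1}..dy_{t-lags}` plus the
#' deterministic terms, and the residual series are both normalized by the
#' residual standard error of the full ADF regression (which additionally
#' includes the lagged level). With `lags = 0` and no deterministic terms
#' the orthogonalization is the identity up to the scale factor.
#'
#' @param series numeric vector, one subject's `T` values.
#' @param lags number of lagged-difference (ADF augmentation) terms.
#' @param deterministic `"none"`, `"intercept"` or `"trend"` (intercept
#'   plus linear trend).
#' @return list with `e` (normalized difference residuals), `v`
#'   (normalized lagged-level residuals, aligned with `e`), `sigma`
#'   (the ADF residual standard error used for normalization), and
#'   `s_ratio` (Bartlett long-run to innovation SD ratio, used by
#'   [llc_test()]).
#' @export
adf_components <- function(series, lags = 0L,
                           deterministic = c("intercept", "none", "trend")) {
  deterministic <- match.arg(deterministic)
  T_ <- length(series)
  lags <- as.integer(lags)
  if (any(!is.finite(series))) stop_("series contains non-finite values")
  if (stats::sd(series) == 0) stop_("zero variance: series is constant")
  n_det <- switch(deterministic, none = 0L, intercept = 1L, trend = 2L)
  n_obs <- T_ - lags - 1L
  if (n_obs < 3L) stop_("too few observations: T - lags - 1 = %d < 3", n_obs)
  if (n_obs - n_det - lags - 1L < 1L) {
    stop_("too few observations for ADF regression with %d lag(s) and '%s' terms",
          lags, deterministic)
  }
  dy <- diff(series)
  t_idx <- (lags + 2L):T_              # rows of the ADF regression
  y_resp <- dy[t_idx - 1L]             # dy_t
  y_lag <- series[t_idx - 1L]          # y_{t-1}
  X <- NULL
  if (lags > 0L) {
    X <- vapply(seq_len(lags), function(l) dy[t_idx - 1L - l], numeric(n_obs))
  }
  D <- switch(deterministic,
              none = NULL,
              intercept = matrix(1, n_obs, 1L),
              trend = cbind(1, seq_len(n_obs)))
  Z <- cbind(X, D)
  e <- resid_on(y_resp, Z)
  v <- resid_on(y_lag, Z)
  if (sum(v^2) < 1e-12 * n_obs) stop_("degenerate lagged-level residuals")
  delta_i <- sum(v * e) / sum(v^2)
  rss <- sum((e - delta_i * v)^2)
  dof <- n_obs - lags - n_det - 1L
  sigma <- sqrt(rss / dof)
  if (sigma <= 0) stop_("zero variance: ADF residuals are degenerate")
  # Bartlett long-run variance of dy (centered per deterministic spec)
  dyc <- switch(deterministic,
                none = dy,
                intercept = dy - mean(dy),
                trend = resid_on(dy, cbind(1, seq_along(dy))))
  K <- min(ceiling(3.21 * T_^(1/3)), T_ - 3L)
  nK <- length(dyc)
  s2 <- sum(dyc^2) / nK
  for (l in seq_len(max(K, 0L))) {
    if (l >= nK) break
    w <- 1 - l / (K + 1)
    s2 <- s2 + 2 * w * sum(dyc[(l + 1L):nK] * dyc[seq_len(nK - l)]) / nK
  }
  s2 <- max(s2, 1e-12)
  list(e = e / sigma, v = v / sigma, sigma = sigma,
       s_ratio = sqrt(s2) / sigma)
}

# Raw pooled LLC regression on a subjects-by-time matrix Y (N x T): returns
# t_delta and the components of the moment-adjustment factor. The
# calibration loop and llc_test() share this kernel.
llc_kernel <- function(Y, lags, deterministic) {
  N <- nrow(Y)
  comps <- vector("list", N)
  for (i in seq_len(N)) {
    comps[[i]] <- tryCatch(
      adf_components(Y[i, ], lags = lags, deterministic = deterministic),
      error = function(err) stop_("subject %s: %s", rownames(Y)[i] %||% i,
                                  conditionMessage(err)))
  }
  e <- unlist(lapply(comps, `[[`, "e"))
  v <- unlist(lapply(comps, `[[`, "v"))
  delta <- sum(v * e) / sum(v^2)
  n_tot <- length(e)
  rss <- sum((e - delta * v)^2)
  sigma2_e <- rss / (n_tot - 1L)
  se_delta <- sqrt(sigma2_e / sum(v^2))
  t_delta <- delta / se_delta
  T_tilde <- ncol(Y) - lags - 1L
  S_N <- mean(vapply(comps, `[[`, 0, "s_ratio"))
  adj <- N * T_tilde * S_N * se_delta / sigma2_e
  list(delta = delta, t_delta = t_delta, se_delta = se_delta,
       sigma2_e = sigma2_e, S_N = S_N, T_tilde = T_tilde, adj = adj)
}

.llc_moments_cache <- new.env(parent = emptyenv())

#' Monte-Carlo calibration of the LLC adjustment moments
#'
#' Estimates the mean and scale adjustment constants of the pooled panel
#' unit-root t-statistic under the unit-root null, at the exact panel
#' dimensions in hand: `nrep` panels of `N` driftless Gaussian random walks
#' of length `T` are generated, the pooled statistic `t_delta` and its
#' replicate-specific adjustment factor `a = N * T_tilde * S_N *
#' SE(delta) / sigma2_e` are computed with the same kernel as the test
#' itself, and the moments are the solution of the location-scale match:
#' `mu_star = mean(t_delta) / mean(a)`, `sigma_star = sd(t_delta - a *
#' mu_star)`. Results are cached per (N, T, lags, deterministic, nrep,
#' seed) within the session.
#'
#' @param N,T_ panel dimensions to match.
#' @param lags ADF augmentation lags.
#' @param deterministic deterministic specification.
#' @param nrep Monte-Carlo replicates (>= 2000 recommended).
#' @param seed integer seed; calibration is deterministic given the seed.
#' @return list with `mu_star`, `sigma_star`, `nrep`.
#' @export
calibrate_llc_moments <- function(N, T_, lags = 0L,
                                  deterministic = "intercept",
                                  nrep = 2000L, seed = 1L) {
  key <- paste(N, T_, lags, deterministic, nrep, seed, sep = "|")
  hit <- .llc_moments_cache[[key]]
  if (!is.null(hit)) return(hit)
  tstats <- numeric(nrep)
  adjs <- numeric(nrep)
  withr::with_seed(seed, {
    for (r in seq_len(nrep)) {
      Y <- t(vapply(seq_len(N), function(i) cumsum(stats::rnorm(T_)),
                    numeric(T_)))
      k <- llc_kernel(Y, lags, deterministic)
      tstats[r] <- k$t_delta
      adjs[r] <- k$adj
    }
  })
  mu_star <- mean(tstats) / mean(adjs)
  sigma_star <- stats::sd(tstats - adjs * mu_star)
  out <- list(mu_star = mu_star, sigma_star = sigma_star, nrep = nrep)
  .llc_moments_cache[[key]] <- out
  out
}

#' Levin-Lin-Chu panel unit-root test
#'
#' Pooled panel test of a common unit root: each subject's series is
#' orthogonalized by [adf_components()], the normalized residual pairs are
#' pooled into a single no-intercept regression of `e` on `v` giving the
#' common autoregressive deviation `delta` and its t-statistic, and the
#' t-statistic is centered and scaled with adjustment moments `mu_star`,
#' `sigma_star` to obtain `t_star`, referred to the left tail of the
#' standard normal. Small `t_star` (large negative) rejects the unit root,
#' i.e. supports stationarity.
#'
#' Adjustment moments come either from a runtime Monte-Carlo calibration at
#' the matched panel dimensions (`moments = "simulated"`, the default —
#' appropriate for the very short panels this package targets) or from a
#' precomputed lookup over effective lengths (`moments = "tabulated"`,
#' interpolated; see [llc_moment_table()]).
#'
#' @param panel a [panel_dataset()] (single condition, or pass `condition`).
#' @param variable variable name to test.
#' @param deterministic `"intercept"` (default), `"none"` or `"trend"`.
#' @param lags `"auto"` (0 when `T < 15`, else `floor(T^(1/3))`) or an
#'   integer.
#' @param alpha significance level for the reject decision.
#' @param moments `"simulated"` or `"tabulated"`.
#' @param nrep calibration replicates for simulated moments.
#' @param seed seed for the moment calibration.
#' @param condition condition to test when the panel has several.
#' @return object of class `unit_root_result`: list with fields `variable`,
#'   `deterministic`, `lags`, `delta`, `t_delta`, `t_star`, `mu_star`,
#'   `sigma_star`, `p_value`, `alpha`, `reject_unit_root`, `moments_mode`,
#'   `N`, `T_tilde`, `S_N`.
#' @export
llc_test <- function(panel, variable, deterministic = c("intercept", "none", "trend"),
                     lags = "auto", alpha = 0.05,
                     moments = c("simulated", "tabulated"),
                     nrep = 2000L, seed = 1L, condition = NULL) {
  stopifnot(inherits(panel, "panel_dataset"))
  deterministic <- match.arg(deterministic)
  moments <- match.arg(moments)
  if (!variable %in% panel$variables) stop_("unknown variable '%s'", variable)
  if (is.null(condition)) {
    if (length(panel$conditions) != 1L) {
      stop_("panel has multiple conditions; specify `condition`")
    }
    condition <- panel$conditions
  }
  arr <- panel_array(panel, condition)
  Y <- arr[, , variable, drop = TRUE]
  T_ <- ncol(Y)
  if (identical(lags, "auto")) {
    lags <- if (T_ < 15L) 0L else as.integer(floor(T_^(1/3)))
  }
  lags <- as.integer(lags)
  if (T_ - lags - 1L < 3L) stop_("lags = %d too large for T = %d", lags, T_)
  k <- llc_kernel(Y, lags, deterministic)
  if (moments == "simulated") {
    mom <- calibrate_llc_moments(nrow(Y), T_, lags, deterministic,
                                 nrep = nrep, seed = seed)
  } else {
    mom <- lookup_llc_moments(k$T_tilde, deterministic)
  }
  t_star <- (k$t_delta - k$adj * mom$mu_star) / mom$sigma_star
  p <- stats::pnorm(t_star)
  structure(list(
    variable = variable, deterministic = deterministic, lags = lags,
    delta = k$delta, t_delta = k$t_delta, t_star = t_star,
    mu_star = mom$mu_star, sigma_star = mom$sigma_star,
    p_value = p, alpha = alpha, reject_unit_root = p < alpha,
    moments_mode = moments, N = nrow(Y), T_tilde = k$T_tilde, S_N = k$S_N
  ), class = "unit_root_result")
}

#' @export
print.unit_root_result <- function(x, ...) {
  cat(sprintf("LLC panel unit-root test: %s (det: %s, lags: %d, moments: %s)\n",
              x$variable, x$deterministic, x$lags, x$moments_mode))
  cat(sprintf("  delta = %.4f, t_delta = %.3f, t* = %.3f, p = %.4g -> %s unit root at alpha = %g\n",
              x$delta, x$t_delta, x$t_star, x$p_value,
              if (x$reject_unit_root) "REJECT" else "cannot reject", x$alpha))
  invisible(x)
}

#' Precomputed LLC adjustment-moment table
#'
#' Adjustment moments `(mu_star, sigma_star)` per deterministic
#' specification over a grid of effective panel lengths, precomputed with
#' [calibrate_llc_moments()] at high replication (20000 replicates,
#' N = 50). Used by `moments = "tabulated"` in [llc_test()] with linear
#' interpolation in the effective length; effective lengths outside the
#' grid use the nearest endpoint.
#'
#' @return data.frame with columns `deterministic`, `T_tilde`, `mu_star`,
#'   `sigma_star`.
#' @export
llc_moment_table <- function() .llc_moment_grid

lookup_llc_moments <- function(T_tilde, deterministic) {
  tab <- .llc_moment_grid[.llc_moment_grid$deterministic == deterministic, ]
  x <- tab$T_tilde
  mu <- stats::approx(x, tab$mu_star, xout = T_tilde, rule = 2)$y
  sg <- stats::approx(x, tab$sigma_star, xout = T_tilde, rule = 2)$y
  list(mu_star = mu, sigma_star = sg, nrep = NA_integer_)
}

#' Difference panel variables until the panel unit-root test rejects
#'
#' Runs [llc_test()] on each requested variable; whenever the unit root is
#' not rejected the variable is first-differenced (within subject) and
#' retested, up to `max_diff` times. The returned panel is globally
#' truncated so all variables stay balanced on a common time grid, and the
#' log records the differencing order applied per variable, with variables
#' still nonstationary after `max_diff` rounds flagged (a warning by
#' default, an error when `on_fail = "error"`).
#'
#' @param panel a [panel_dataset()] with a single condition.
#' @param variables variables to screen (default all).
#' @param alpha significance level of each test.
#' @param max_diff maximum differencing rounds per variable.
#' @param on_fail `"warn"` (default) or `"error"` when a variable remains
#'   nonstationary.
#' @param ... further arguments passed to [llc_test()]
#'   (`deterministic`, `lags`, `moments`, `nrep`, `seed`).
#' @return list with `panel` (transformed, balanced) and `log` (data.frame:
#'   `variable`, `diff_order`, `p_value_final`, `stationary`).
#' @export
ensure_stationary <- function(panel, variables = NULL, alpha = 0.05,
                              max_diff = 2L, on_fail = c("warn", "error"), ...) {
  stopifnot(inherits(panel, "panel_dataset"))
  on_fail <- match.arg(on_fail)
  if (length(panel$conditions) != 1L) {
    stop_("ensure_stationary() works on a single condition; use filter_condition()")
  }
  variables <- variables %||% panel$variables
  diff_order <- stats::setNames(integer(length(variables)), variables)
  p_final <- stats::setNames(rep(NA_real_, length(variables)), variables)
  stationary <- stats::setNames(logical(length(variables)), variables)
  for (v in variables) {
    probe <- panel
    d <- 0L
    repeat {
      res <- llc_test(probe, v, alpha = alpha, ...)
      p_final[v] <- res$p_value
      if (res$reject_unit_root) { stationary[v] <- TRUE; break }
      if (d >= max_diff) { stationary[v] <- FALSE; break }
      probe <- difference(probe, v, 1L)
      d <- d + 1L
    }
    diff_order[v] <- d
  }
  flagged <- names(stationary)[!stationary]
  if (length(flagged)) {
    msg <- sprintf("variable(s) still nonstationary after %d difference(s): %s",
                   max_diff, paste(flagged, collapse = ", "))
    if (on_fail == "error") stop_(msg) else warning(msg, call. = FALSE)
  }
  dmax <- max(diff_order, 0L)
  out <- panel
  if (dmax > 0L) {
    # apply each variable's differencing, then align all variables on the
    # common truncated grid (drop the first dmax time points)
    arr <- panel_array(out)
    T_ <- dim(arr)[2]; Tn <- T_ - dmax
    N <- dim(arr)[1]
    res <- arr[, (dmax + 1L):T_, , drop = FALSE]
    for (v in panel$variables) {
      d <- if (v %in% names(diff_order)) diff_order[[v]] else 0L
      if (d > 0L) {
        dv <- apply(arr[, , v, drop = TRUE], 1L,
                    function(s) diff(s, differences = d))
        dv <- t(matrix(dv, ncol = N))          # N x (T - d)
        res[, , v] <- dv[, (dmax - d + 1L):(T_ - d), drop = FALSE]
      }
    }
    V <- dim(res)[3]
    long <- data.frame(
      subject = rep(panel$subjects, times = Tn * V),
      condition = panel$conditions,
      time = rep(rep(seq_len(Tn) - 1L, each = N), times = V),
      variable = rep(panel$variables, each = N * Tn),
      value = as.vector(res),
      stringsAsFactors = FALSE)
    meta <- panel$meta[setdiff(names(panel$meta), "time_labels")]
    meta$transformations <- c(meta$transformations,
                              sprintf("ensure_stationary: %s",
                                      paste(sprintf("%s^%d", names(diff_order), diff_order),
                                            collapse = " ")))
    out <- panel_dataset(long, units = panel$units, meta = meta)
  }
  list(panel = out,
       log = data.frame(variable = variables,
                        diff_order = as.integer(diff_order),
                        p_value_final = as.numeric(p_final),
                        stationary = as.logical(stationary),
                        row.names = NULL, stringsAsFactors = FALSE))
}
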