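#' Within (fixed-effects) demeaning
#'
#' Subtracts each group's mean from its values, absorbing subject fixed
#' effects before pooled estimation. Idempotent; grouping is preserved.
#'
#' @param values numeric vector.
#' @param group group (subject) labels, same length as `values`.
#' @return numeric vector of demeaned values.
#' @export
within_demean <- function(values, group) {
  if (length(values) != length(group)) stop_("`values` and `group` lengths differ")
  if (!length(values)) stop_("empty input")
  g <- as.factor(group)
  if (any(tabulate(g) == 0L)) stop_("empty group")
  values - ave(values, g)
}

# Build the stacked within-demeaned Granger design for effect matrix Y and
# cause matrix X (both N x T), lag order p, over regressand times tset
# (subset of (p+1):T). Each column (regressand and regressors) is demeaned
# within subject over the window. Returns the stacked pieces plus
# per-subject row indexing for clustered variance.
granger_design <- function(Y, X, p, tset, cause, effect) {
  N <- nrow(Y); h <- length(tset)
  demean <- function(M) M - rowMeans(M)
  yd <- demean(Y[, tset, drop = FALSE])
  cols <- vector("list", 2L * p)
  for (l in seq_len(p)) {
    cols[[l]] <- demean(Y[, tset - l, drop = FALSE])
    cols[[p + l]] <- demean(X[, tset - l, drop = FALSE])
  }
  # stack subject-major: rows 1..h are subject 1, etc.
  yv <- as.vector(t(yd))
  Z <- vapply(cols, function(M) as.vector(t(M)), numeric(N * h))
  colnames(Z) <- c(paste0("rho", seq_len(p)), paste0("beta", seq_len(p)))
  # singularity guard with a named error
  scales <- sqrt(colSums(Z^2))
  if (any(scales < 1e-10)) {
    bad <- colnames(Z)[which.min(scales)]
    who <- if (grepl("^beta", bad)) cause else effect
    stop_("singular design: regressor %s (variable '%s') is constant after demeaning",
          bad, who)
  }
  XtX <- crossprod(Z)
  if (rcond(XtX) < 1e-12) {
    stop_("singular design for pair %s -> %s (collinear lags)", cause, effect)
  }
  list(y = yv, Z = Z, XtX = XtX, N = N, h = h,
       subject = rep(seq_len(N), each = h))
}

#' Pooled within-estimator OLS for the panel Granger regression
#'
#' Stacks, over subjects, the within-demeaned effect series and its `p` own
#' lags plus the cause's `p` lags (restricted to an optional time window),
#' and solves the pooled ordinary least squares problem. The coefficient
#' order is `(rho_1..rho_p, beta_1..beta_p)`: own lags first, cross lags
#' second. Also returns the cross-product matrix needed for sandwich
#' variance estimation.
#'
#' @param Y,X numeric `N x T` matrices (subjects in rows): effect and cause.
#' @param p lag order.
#' @param window optional integer vector of regressand time indices (1-based
#'   columns of `Y`, all `> p`); default the full effective range
#'   `(p+1):T`.
#' @param cause,effect variable names used in error messages.
#' @return list with `theta` (named coefficient vector), `XtX`, `residuals`,
#'   `n_obs`, `subject` (cluster index per stacked row), `Z`, `y`.
#' @export
pooled_within_ols <- function(Y, X, p = 1L, window = NULL,
                              cause = "x", effect = "y") {
  stopifnot(is.matrix(Y), is.matrix(X), dim(Y) == dim(X))
  p <- as.integer(p)
  T_ <- ncol(Y)
  window <- window %||% ((p + 1L):T_)
  if (any(window <= p) || any(window > T_)) stop_("window out of range")
  if (length(window) < p + 2L) {
    stop_("effective window too short: %d observation(s) per subject for lag order %d",
          length(window), p)
  }
  d <- granger_design(Y, X, p, window, cause, effect)
  theta <- drop(solve(d$XtX, crossprod(d$Z, d$y)))
  names(theta) <- colnames(d$Z)
  res <- d$y - drop(d$Z %*% theta)
  list(theta = theta, XtX = d$XtX, residuals = res, n_obs = length(d$y),
       subject = d$subject, Z = d$Z, y = d$y)
}

#' Half-panel jackknife bias correction
#'
#' Combines the full-window estimate with estimates from the first and
#' second halves of the time range: `2 * theta_full - (theta_first +
#' theta_second) / 2`, removing the leading `O(1/T)` (Nickell) bias of the
#' pooled within estimator in dynamic panels.
#'
#' @param theta_full,theta_first_half,theta_second_half equal-length
#'   coefficient vectors.
#' @return bias-corrected coefficient vector.
#' @export
hpj_estimate <- function(theta_full, theta_first_half, theta_second_half) {
  if (length(theta_full) != length(theta_first_half) ||
      length(theta_full) != length(theta_second_half)) {
    stop_("coefficient vectors must have equal length")
  }
  2 * theta_full - (theta_first_half + theta_second_half) / 2
}

# Delete-one-subject jackknife variance of the half-panel-jackknife
# estimator. Because the within transformation is per subject, removing a
# subject leaves the other subjects' demeaned rows unchanged, so each
# delete-one estimate is exact via a rank downdate of the normal equations
# in each of the three window regressions; the deleted-subject estimates of
# the full jackknife combination then give a CR3-type clustered variance
# with factor (N-1)/N. A plain sandwich built from influence scores
# understates the combination's dispersion in short panels and
# over-rejects, which is why the jackknife form is used.
hpj_jackknife_vcov <- function(fits) {
  N <- max(fits$full$subject)
  k <- ncol(fits$full$Z)
  pieces <- lapply(fits[c("full", "first", "second")], function(f) {
    list(XtX = f$XtX, Xty = crossprod(f$Z, f$y), Z = f$Z, y = f$y,
         subject = f$subject)
  })
  th_del <- matrix(0, N, k)
  for (i in seq_len(N)) {
    ths <- lapply(pieces, function(pc) {
      rows <- pc$subject == i
      Zi <- pc$Z[rows, , drop = FALSE]
      solve(pc$XtX - crossprod(Zi), pc$Xty - crossprod(Zi, pc$y[rows]))
    })
    th_del[i, ] <- 2 * ths[[1]] - 0.5 * (ths[[2]] + ths[[3]])
  }
  ctr <- colMeans(th_del)
  crossprod(sweep(th_del, 2L, ctr)) * (N - 1) / N
}

granger_fit_hpj <- function(Y, X, p, cause, effect) {
  T_ <- ncol(Y)
  tset <- (p + 1L):T_
  h <- length(tset) %/% 2L
  if (h < p + 2L) {
    stop_("T = %d too small for half-panel jackknife with lag order %d", T_, p)
  }
  full <- pooled_within_ols(Y, X, p, tset, cause, effect)
  first <- pooled_within_ols(Y, X, p, tset[seq_len(h)], cause, effect)
  second <- pooled_within_ols(Y, X, p, tset[(length(tset) - h + 1L):length(tset)],
                              cause, effect)
  theta_hpj <- hpj_estimate(full$theta, first$theta, second$theta)
  list(full = full, first = first, second = second,
       theta_within = full$theta, theta_hpj = theta_hpj)
}

wald_beta <- function(fits, theta_eval, p) {
  V <- hpj_jackknife_vcov(fits)
  bidx <- p + seq_len(p)
  b <- theta_eval[bidx]
  drop(t(b) %*% solve(V[bidx, bidx, drop = FALSE], b))
}

#' Pairwise panel Granger non-causality test
#'
#' Tests whether `cause` Granger-causes `effect` in a balanced panel: the
#' within-demeaned effect series is regressed on its own `p` lags and the
#' cause's `p` lags pooled over subjects, the coefficient vector is
#' bias-corrected with the half-panel jackknife ([hpj_estimate()]; each
#' half re-estimates its own within transformation, and with an odd
#' effective length the middle period is dropped so the halves are balanced
#' and disjoint), and the cross-lag coefficients are tested jointly with a
#' Wald statistic. The test is bivariate: no conditioning beyond the
#' effect's own lags.
#'
#' Variance: `"clustered"` (default) uses a delete-one-subject jackknife
#' (CR3-type cluster-robust) variance of the bias-corrected estimator —
#' each subject's deletion re-solves all three window regressions exactly
#' via rank downdates, and the dispersion of the deleted-subject estimates
#' (factor `(N-1)/N`) estimates the variance of the combination — referred
#' to chi-square with `p` degrees of freedom. A plain one-window sandwich
#' understates the half-panel-jackknife estimator's dispersion when `T` is
#' small and over-rejects; the cluster jackknife is calibrated at nominal
#' size in panels as short as the study design. `"bootstrap"` resamples subjects with replacement `n_boot`
#' times and compares the observed Wald statistic to recentered bootstrap
#' Wald statistics (percentile-t cluster bootstrap), which is more robust
#' when the number of subjects is very small.
#'
#' @param panel a [panel_dataset()].
#' @param cause,effect distinct variable names.
#' @param p lag order (default 1; short panels cannot support much more).
#' @param variance `"clustered"` or `"bootstrap"`.
#' @param n_boot bootstrap draws (bootstrap mode).
#' @param seed seed for the bootstrap (deterministic given the seed).
#' @param condition condition to use when the panel has several.
#' @return object of class `granger_pair`: list with fields `cause`,
#'   `effect`, `lag_order`, `theta_within`, `theta_hpj`, `wald`, `df`,
#'   `p_value`, `n_effective`, `variance_mode`.
#' @export
granger_test <- function(panel, cause, effect, p = 1L,
                         variance = c("clustered", "bootstrap"),
                         n_boot = 199L, seed = 1L, condition = NULL) {
  stopifnot(inherits(panel, "panel_dataset"))
  variance <- match.arg(variance)
  if (identical(cause, effect)) stop_("`cause` and `effect` must differ")
  for (v in c(cause, effect)) {
    if (!v %in% panel$variables) stop_("unknown variable '%s'", v)
  }
  if (is.null(condition)) {
    if (length(panel$conditions) != 1L) stop_("panel has multiple conditions; specify `condition`")
    condition <- panel$conditions
  }
  arr <- panel_array(panel, condition)
  Y <- arr[, , effect, drop = TRUE]
  X <- arr[, , cause, drop = TRUE]
  p <- as.integer(p)
  if (ncol(Y) - p < 4L) stop_("T - p = %d < 4: panel too short", ncol(Y) - p)
  est <- granger_fit_hpj(Y, X, p, cause, effect)
  W <- wald_beta(est, est$theta_hpj, p)
  if (variance == "clustered") {
    p_value <- stats::pchisq(W, df = p, lower.tail = FALSE)
  } else {
    N <- nrow(Y)
    bidx <- p + seq_len(p)
    b_hat <- est$theta_hpj[bidx]
    wstar <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(bi) {
        idx <- sample.int(N, N, replace = TRUE)
        tryCatch({
          eb <- granger_fit_hpj(Y[idx, , drop = FALSE], X[idx, , drop = FALSE],
                                p, cause, effect)
          V <- hpj_jackknife_vcov(eb)
          db <- eb$theta_hpj[bidx] - b_hat
          drop(t(db) %*% solve(V[bidx, bidx, drop = FALSE], db))
        }, error = function(e) NA_real_)
      }, numeric(1))
    })
    wstar <- wstar[is.finite(wstar)]
    p_value <- (1 + sum(wstar >= W)) / (length(wstar) + 1)
  }
  structure(list(
    cause = cause, effect = effect, lag_order = p,
    theta_within = est$theta_within, theta_hpj = est$theta_hpj,
    wald = W, df = p, p_value = p_value,
    n_effective = est$full$n_obs, variance_mode = variance
  ), class = "granger_pair")
}

#' @export
print.granger_pair <- function(x, ...) {
  cat(sprintf("Panel Granger test: %s -> %s (p = %d, %s variance)\n",
              x$cause, x$effect, x$lag_order, x$variance_mode))
  cat(sprintf("  beta_hpj = %s, Wald = %.3f (df = %d), p = %.4g\n",
              paste(sprintf("%.4f", x$theta_hpj[x$lag_order + seq_len(x$lag_order)]),
                    collapse = ", "),
              x$wald, x$df, x$p_value))
  invisible(x)
}

#' All ordered-pair panel Granger tests
#'
#' Runs [granger_test()] for every ordered pair of the given variables
#' (row-major in the variable list: for each cause, every effect), so `V`
#' variables give `V * (V - 1)` results. Per-pair errors are captured as
#' result entries with `NA` statistics and collected in the `errors` field
#' rather than aborting the sweep.
#'
#' @param panel a [panel_dataset()].
#' @param variables variable subset (default all, in panel order).
#' @param p lag order.
#' @param ... passed to [granger_test()] (`variance`, `n_boot`, `seed`,
#'   `condition`).
#' @return object of class `granger_set`: list with `results` (list of
#'   `granger_pair`), `variables`, `lag_order`, `errors` (named character
#'   vector, possibly empty).
#' @export
pairwise_granger <- function(panel, variables = NULL, p = 1L, ...) {
  stopifnot(inherits(panel, "panel_dataset"))
  variables <- variables %||% panel$variables
  if (length(variables) < 2L) stop_("need at least 2 variables")
  results <- list()
  errors <- character(0)
  for (cause in variables) {
    for (effect in variables) {
      if (cause == effect) next
      key <- paste0(cause, "->", effect)
      r <- tryCatch(granger_test(panel, cause, effect, p = p, ...),
                    error = function(e) {
                      structure(list(cause = cause, effect = effect,
                                     lag_order = p, theta_within = NULL,
                                     theta_hpj = rep(NA_real_, 2L * p),
                                     wald = NA_real_, df = p,
                                     p_value = NA_real_, n_effective = NA_integer_,
                                     variance_mode = NA_character_,
                                     error = conditionMessage(e)),
                                class = "granger_pair")
                    })
      if (!is.null(r$error)) errors[key] <- r$error
      results[[key]] <- r
    }
  }
  structure(list(results = results, variables = variables, lag_order = p,
                 errors = errors),
            class = "granger_set")
}

#' @export
as.data.frame.granger_set <- function(x, ...) {
  do.call(rbind, lapply(x$results, function(r) {
    p <- r$lag_order
    beta <- r$theta_hpj[p + seq_len(p)]
    out <- data.frame(cause = r$cause, effect = r$effect, lag = p,
                      wald = r$wald, df = r$df, p_value = r$p_value,
                      stringsAsFactors = FALSE)
    for (l in seq_len(p)) out[[paste0("beta_hpj", l)]] <- beta[l]
    out$error <- r$error %||% NA_character_
    out
  })) -> df
  rownames(df) <- NULL
  df
}

#' @export
print.granger_set <- function(x, ...) {
  cat(sprintf("<granger_set> %d ordered pair(s) over %d variables (lag order %d)\n",
              length(x$results), length(x$variables), x$lag_order))
  if (length(x$errors)) {
    cat(sprintf("  %d pair(s) errored: %s\n", length(x$errors),
                paste(names(x$errors), collapse = ", ")))
  }
  invisible(x)
}
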