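# Shared fixture builders. Everything is generated in code; no stored data.

# Long data.frame for a panel with the given subjects x times x variables
# array (dim N x T x V, dimnames optional).
long_from_array <- function(arr, condition = "all") {
  dn <- dimnames(arr)
  N <- dim(arr)[1]; T_ <- dim(arr)[2]; V <- dim(arr)[3]
  subjects <- dn[[1]] %||% sprintf("S%02d", seq_len(N))
  vars <- dn[[3]] %||% paste0("v", seq_len(V))
  data.frame(
    subject = rep(subjects, times = T_ * V),
    condition = condition,
    time = rep(rep(seq_len(T_) - 1L, each = N), times = V),
    variable = rep(vars, each = N * T_),
    value = as.vector(arr),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-variable panel from effect matrix Y and cause matrix X (both N x T).
two_var_panel <- function(Y, X, names = c("y", "x")) {
  arr <- array(c(Y, X), dim = c(nrow(Y), ncol(Y), 2L),
               dimnames = list(NULL, NULL, names))
  panel_dataset(long_from_array(arr))
}

# Independent white-noise panel pair with subject fixed effects.
null_pair <- function(N, T_) {
  two_var_panel(matrix(rnorm(N * T_), N) + rnorm(N),
                matrix(rnorm(N * T_), N) + rnorm(N))
}

# x -> y panel with cross-lag coefficient beta and own-lag rho, after burn-in.
edge_pair <- function(N, T_, beta, rho = 0.3, burn = 30L) {
  Ttot <- T_ + burn
  X <- matrix(rnorm(N * Ttot), N)
  Y <- matrix(0, N, Ttot)
  a <- rnorm(N)
  for (t in 2:Ttot) Y[, t] <- a + rho * Y[, t - 1] + beta * X[, t - 1] + rnorm(N)
  keep <- (burn + 1L):Ttot
  two_var_panel(Y[, keep], X[, keep])
}

# Random sparse synthetic VAR spec on V variables with n_edges cross edges
# of magnitude coef (alternating signs) and own-lag 0.2, drawn reproducibly
# from `seed`. Edges run from a source block to a sink block, so the truth
# contains no directed 2-paths: bivariate pairwise Granger testing detects
# indirect (mediated) influence as readily as direct edges, and a chain-free
# truth keeps the edge-recovery measurement about direct-edge detection
# rather than about that intrinsic conflation (which is documented as a
# limitation of the pairwise design).
sparse_var_spec <- function(V, n_edges, coef, N, T_, seed) {
  src <- seq_len(floor(V / 2)); snk <- setdiff(seq_len(V), src)
  A <- withr::with_seed(seed * 7919L, {
    pairs <- as.matrix(expand.grid(src, snk))
    pick <- pairs[sample.int(nrow(pairs), n_edges), , drop = FALSE]
    A <- matrix(0, V, V)
    A[pick] <- coef * ifelse(seq_len(n_edges) %% 2 == 0, -1, 1)
    diag(A) <- 0.2
    A
  })
  synthetic_spec(N = N, T_ = T_, A = A, seed = seed)
}

# Independent betweenness oracle by shortest-walk counting with matrix
# powers: walks of minimal length are exactly the shortest simple paths, so
# sigma_st = (B^d(s,t))[s,t] and the paths through v split multiplicatively.
oracle_betweenness <- function(B, normalized = TRUE) {
  n <- nrow(B)
  P <- vector("list", n)
  P[[1]] <- B
  for (L in 2:n) P[[L]] <- P[[L - 1]] %*% B
  D <- matrix(Inf, n, n)
  for (L in n:1) D[P[[L]] > 0] <- L
  diag(D) <- 0
  btw <- numeric(n)
  for (v in 1:n) {
    for (s in 1:n) {
      for (t_ in 1:n) {
        if (s == t_ || s == v || t_ == v || !is.finite(D[s, t_])) next
        d1 <- D[s, v]; d2 <- D[v, t_]
        if (is.finite(d1) && is.finite(d2) && d1 + d2 == D[s, t_]) {
          btw[v] <- btw[v] + P[[d1]][s, v] * P[[d2]][v, t_] / P[[D[s, t_]]][s, t_]
        }
      }
    }
  }
  if (normalized) btw / ((n - 1) * (n - 2)) else btw
}
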