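#!/usr/bin/env Rscript
# Step 5 — quick Monte-Carlo validation of the statistical machinery.
#
# A reduced-replicate version of the operating-characteristic experiments
# that the test suite runs in full: empirical size and power of the
# half-panel-jackknife Granger test on short panels, size of the panel
# unit-root screen on random walks, and end-to-end edge recovery on sparse
# synthetic truth. Writes results/method_validation.tsv. Full-replicate
# versions (500/200/500/50 replicates) live in tests/testthat/test-acceptance.R.

library(phosnet)

seed <- as.integer(Sys.getenv("PHOSNET_SEED", "1"))
n_small <- 150L

size_rej <- vapply(seq_len(n_small), function(s) {
  spec <- synthetic_spec(N = 50, T_ = 9, A = diag(c(0.3, 0.3)),
                         variable_names = c("y", "x"), seed = seed * 100000L + s)
  granger_test(simulate_panel_var(spec)$panel, "x", "y")$p_value < 0.05
}, logical(1))
cat(sprintf("Granger size (null VAR, N=50 T=9, %d reps): %.3f (nominal 0.05)\n",
            n_small, mean(size_rej)))

A <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
A["x", "y"] <- 0.8
pow_rej <- vapply(seq_len(n_small), function(s) {
  spec <- synthetic_spec(N = 50, T_ = 9, A = A, variable_names = c("x", "y"),
                         seed = seed * 200000L + s)
  granger_test(simulate_panel_var(spec)$panel, "x", "y")$p_value < 0.05
}, logical(1))
cat(sprintf("Granger power (beta = 0.8, N=50 T=9, %d reps): %.3f\n",
            n_small, mean(pow_rej)))

llc_rej <- vapply(seq_len(n_small), function(s) {
  p <- simulate_unit_root_panel(20, 50, seed = seed * 300000L + s)
  llc_test(p, "y", nrep = 2000, seed = 77)$reject_unit_root
}, logical(1))
cat(sprintf("Unit-root test size (random walks, N=20 T=50, %d reps): %.3f (nominal 0.05)\n",
            n_small, mean(llc_rej)))

f1s <- vapply(1:15, function(s) {
  src <- 1:4; snk <- 5:8
  Af <- withr::with_seed(seed * 7919L + s, {
    pairs <- as.matrix(expand.grid(src, snk))
    pick <- pairs[sample.int(nrow(pairs), 8L), , drop = FALSE]
    Af <- matrix(0, 8, 8)
    Af[pick] <- 0.6 * ifelse(seq_len(8) %% 2 == 0, -1, 1)
    diag(Af) <- 0.2
    Af
  })
  spec <- synthetic_spec(N = 30, T_ = 9, A = Af, seed = seed * 400000L + s)
  sim <- simulate_panel_var(spec)
  st <- suppressWarnings(ensure_stationary(sim$panel, nrep = 1000, seed = 1))
  net <- suppressWarnings(build_adjacency(pairwise_granger(st$panel),
                                          alpha = 0.05,
                                          nodes = st$panel$variables))
  unname(edge_f1(net, sim$truth)["f1"])
}, numeric(1))
cat(sprintf("Edge-recovery F1 (sparse truth, N=30 T=9, 15 seeds): mean %.3f\n",
            mean(f1s)))

dir.create("results", showWarnings = FALSE)
write.table(
  data.frame(metric = c("granger_size", "granger_power", "llc_size", "edge_f1"),
             value = c(mean(size_rej), mean(pow_rej), mean(llc_rej), mean(f1s)),
             replicates = c(n_small, n_small, n_small, 15L)),
  "results/method_validation.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/method_validation.tsv\n")
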