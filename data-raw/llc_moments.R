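# Regenerates R/llc_moments_data.R: adjustment moments for the pooled panel
# unit-root statistic under the null, per deterministic spec over a grid of
# effective lengths T_tilde (= T - 1 at lag order 0). N = 50 subjects,
# 8000 replicates per cell. Run from the repository root:
#   Rscript data-raw/llc_moments.R
library(phosnet)

grid_T <- c(4, 5, 6, 8, 10, 15, 25, 35, 50)
dets <- c("none", "intercept", "trend")
rows <- list()
i <- 0L
for (det in dets) {
  for (Tt in grid_T) {
    i <- i + 1L
    mom <- calibrate_llc_moments(N = 50, T_ = Tt + 1L, lags = 0L,
                                 deterministic = det, nrep = 8000L,
                                 seed = 1000L + i)
    rows[[i]] <- data.frame(deterministic = det, T_tilde = Tt,
                            mu_star = mom$mu_star, sigma_star = mom$sigma_star)
    message(sprintf("%s T_tilde=%d: mu*=%.4f sigma*=%.4f", det, Tt,
                    mom$mu_star, mom$sigma_star))
  }
}
tab <- do.call(rbind, rows)

out <- file("R/llc_moments_data.R", "w")
writeLines(c(
  "# Adjustment-moment constants for llc_test(moments = \"tabulated\"), keyed by",
  "# deterministic specification and effective panel length T_tilde.",
  "# Precomputed with calibrate_llc_moments() (N = 50, 8000 replicates per",
  "# cell) by data-raw/llc_moments.R; regenerate with that script if the",
  "# pooled test kernel changes.",
  ".llc_moment_grid <- data.frame(",
  sprintf("  deterministic = c(%s),", paste(sprintf('"%s"', tab$deterministic), collapse = ", ")),
  sprintf("  T_tilde = c(%s),", paste(tab$T_tilde, collapse = ", ")),
  sprintf("  mu_star = c(%s),", paste(sprintf("%.6f", tab$mu_star), collapse = ", ")),
  sprintf("  sigma_star = c(%s),", paste(sprintf("%.6f", tab$sigma_star), collapse = ", ")),
  "  stringsAsFactors = FALSE",
  ")"
), out)
close(out)
message("wrote R/llc_moments_data.R")
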