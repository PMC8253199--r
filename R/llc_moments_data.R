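# Adjustment-moment constants for llc_test(moments = "tabulated"), keyed by
# deterministic specification and effective panel length T_tilde.
# Precomputed with calibrate_llc_moments() (N = 50, 8000 replicates per
# cell) by data-raw/llc_moments.R; regenerate with that script if the
# pooled test kernel changes.
.llc_moment_grid <- data.frame(
  deterministic = c("none", "none", "none", "none", "none", "none", "none", "none", "none", "intercept", "intercept", "intercept", "intercept", "intercept", "intercept", "intercept", "intercept", "intercept", "trend", "trend", "trend", "trend", "trend", "trend", "trend", "trend", "trend"),
  T_tilde = c(4, 5, 6, 8, 10, 15, 25, 35, 50, 4, 5, 6, 8, 10, 15, 25, 35, 50, 4, 5, 6, 8, 10, 15, 25, 35, 50),
  mu_star = c(0.082246, 0.047286, 0.032095, 0.015533, 0.007839, -0.000220, -0.001972, -0.003042, -0.004774, -2.078312, -1.265609, -1.110581, -1.008765, -0.977463, -0.818539, -0.691990, -0.643936, -0.604481, -45.742018, -2.830502, -1.848301, -1.555752, -1.491210, -1.176825, -0.891589, -0.782293, -0.699525),
  sigma_star = c(2.953770, 1.831230, 1.514863, 1.254797, 1.171846, 1.087054, 1.067728, 1.029804, 1.015836, 39.284286, 4.080354, 2.604308, 1.369021, 1.169262, 0.999219, 0.905317, 0.874113, 0.828491, 2184.661164, 20.821107, 5.964129, 1.975749, 1.374165, 1.014607, 0.943239, 0.881416, 0.817179),
  stringsAsFactors = FALSE
)
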