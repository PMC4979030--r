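# shared fixtures: small canonical models and replicate-averaging utilities

unit_square <- cc_window(1)

ns_families <- c("gaussian", "disk", "cauchy", "vargamma")

test_model <- function(family, r_t = 0.03, kappa = 50, mu = 40, ...) {
  cluster_model(family, r_t = r_t, kappa = kappa, mu = mu, ...)
}

# replicate-averaged empirical curve plus the spread of the replicate curves
average_curve <- function(model, reps, seed, statistic = "K",
                          config = estimator_config(n_bins = 128),
                          window = unit_square, beta = 1) {
  est <- switch(statistic, K = estimate_K, L_minus_r = estimate_L_minus_r,
                pcf = estimate_pcf)
  vals <- NULL
  for (i in seq_len(reps)) {
    pp <- simulate_neyman_scott(model, window, seed = seed + i)
    if (beta < 1) pp <- superimpose_csr(pp, beta, seed = seed + 10000 + i)
    cv <- est(pp, config)
    if (is.null(vals)) { r <- cv$r; vals <- matrix(NA_real_, reps, length(r)) }
    vals[i, ] <- cv$value
  }
  list(r = r, mean = colMeans(vals), se = apply(vals, 2, stats::sd) / sqrt(reps))
}
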