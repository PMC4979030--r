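#' Simulation study: recovery of the radius of maximal aggregation
#'
#' For every `(kappa, r_t)` cell, simulates `replicates` clustered patterns,
#' extracts the empirical radius of maximal aggregation from each
#' \eqn{\hat L(r) - r} curve, and compares against the theoretical
#' [solve_ra()] prediction. Reported per cell: the theoretical `p`, the mean
#' empirical `p_hat`, the root-mean-squared error of \eqn{\hat r_a}
#' normalized by the theoretical value, the number of replicates whose
#' maximum sat on the grid boundary (excluded from the averages), and the
#' seed. Fully deterministic given the root seed.
#'
#' @param family `"gaussian"` or `"disk"`.
#' @param kappa,r_t Parameter grids (crossed).
#' @param mu Mean points per cluster.
#' @param replicates Replicates per cell.
#' @param window Observation window (unit square by default, matching the
#'   simulation conventions of the validation study).
#' @param config An [estimator_config()].
#' @param seed Root seed; per-replicate seeds are derived deterministically.
#' @return A data frame with one row per cell.
#' @export
study_ra_recovery <- function(family, kappa, r_t, mu = 40, replicates = 100,
                              window = cc_window(1),
                              config = estimator_config(), seed = 1) {
  grid <- expand.grid(kappa = kappa, r_t = r_t, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    kap <- grid$kappa[i]; rt <- grid$r_t[i]
    model <- cluster_model(family, r_t = rt, kappa = kap, mu = mu)
    theo <- solve_ra(model, q = NULL)
    ra_hat <- rep(NA_real_, replicates)
    boundary <- 0L
    for (j in seq_len(replicates)) {
      pp <- simulate_neyman_scott(model, window,
                                  seed = child_seed(seed, (i - 1) * replicates + j))
      est <- empirical_ra(estimate_L_minus_r(pp, config))
      if (est$boundary) boundary <- boundary + 1L else ra_hat[j] <- est$r_a
    }
    ok <- !is.na(ra_hat)
    data.frame(family = family, kappa = kap, r_t = rt, kappa_rt2 = kap * rt^2,
               p_theory = theo$p, p_hat_mean = mean(ra_hat[ok]) / rt,
               nrmse = sqrt(mean((ra_hat[ok] - theo$r_a)^2)) / theo$r_a,
               replicates = replicates, boundary = boundary, seed = seed,
               flag = if (all(!ok)) "no-maximum" else "ok")
  })
  do.call(rbind, rows)
}

#' Simulation study: occupancy recovery by two PCF fitting routes
#'
#' Simulates Thomas (Gaussian) cluster patterns for each mean occupancy in
#' `mu_values`, estimates the PCF of every replicate, and fits it with (1)
#' the family's own theoretical PCF by minimum contrast (occupancy
#' \eqn{\hat N = \hat\rho/\hat\kappa}) and (2) the exponential approximation
#' (occupancy \eqn{\hat N_a = 2\pi a d^2 \hat\rho}). The exponential route
#' overestimates by the scaling factor `l` (about 1.48 for Gaussian
#' clusters); the model route is asymptotically unbiased.
#'
#' @param mu_values Mean points per cluster to sweep.
#' @param kappa,sigma Thomas parameters.
#' @param replicates Replicates per `mu`.
#' @param window Observation window.
#' @param config An [estimator_config()].
#' @param r_m Upper fitting limit passed to both fits.
#' @param seed Root seed.
#' @return A data frame with one row per `mu`: means and standard deviations
#'   of \eqn{\hat N/\mu} for both routes, plus counts of failed fits
#'   (excluded from the averages).
#' @export
study_cluster_count_recovery <- function(mu_values = c(20, 50, 100), kappa = 25,
                                         sigma = 0.02, replicates = 20,
                                         window = cc_window(1),
                                         config = estimator_config(n_bins = 256),
                                         r_m = NULL, seed = 1) {
  rows <- lapply(seq_along(mu_values), function(i) {
    mu <- mu_values[i]
    model <- cluster_model("gaussian", r_t = sigma, kappa = kappa, mu = mu)
    n_exp <- rep(NA_real_, replicates)
    n_mod <- rep(NA_real_, replicates)
    failed <- 0L
    for (j in seq_len(replicates)) {
      pp <- simulate_neyman_scott(model, window,
                                  seed = child_seed(seed, (i - 1) * replicates + j))
      rho <- pattern_intensity(pp)
      pcf <- estimate_pcf(pp, config)
      ef <- tryCatch(fit_exponential_lse(pcf, r_m = r_m), error = function(e) NULL)
      mf <- tryCatch(fit_model_pcf(pcf, "gaussian", r_m = r_m),
                     error = function(e) NULL)
      if (is.null(ef) || is.null(mf) || !mf$converged) { failed <- failed + 1L; next }
      n_exp[j] <- n_per_cluster(ef, rho)
      n_mod[j] <- rho / mf$kappa
    }
    ok <- !is.na(n_exp)
    data.frame(mu = mu, kappa = kappa, sigma = sigma,
               ratio_exp_mean = mean(n_exp[ok]) / mu,
               ratio_exp_sd = stats::sd(n_exp[ok]) / mu,
               ratio_model_mean = mean(n_mod[ok]) / mu,
               ratio_model_sd = stats::sd(n_mod[ok]) / mu,
               replicates = replicates, failed = failed, seed = seed)
  })
  do.call(rbind, rows)
}

#' Deterministic bias-map and normalized-K sweep studies
#'
#' `study_bias_map` evaluates [bias_map()] for several families on shared
#' grids; `study_normalized_k` sweeps [normalized_ra()] over window ratios
#' and point counts. Both are deterministic.
#'
#' @param families Model families.
#' @param kappa,r_t,window_ratios,n_points Grids.
#' @param family A single family for the sweep.
#' @param q Quantile for `p_q`.
#' @return A data frame.
#' @export
study_bias_map <- function(families = c("gaussian", "disk"), kappa, r_t,
                           q = 0.95) {
  do.call(rbind, lapply(families, bias_map, kappa_grid = kappa,
                        rt_grid = r_t, q = q))
}

#' @rdname study_bias_map
#' @export
study_normalized_k <- function(family = "disk", r_t = 1,
                               window_ratios = c(50, 500),
                               n_points = c(100, 1000, 10000)) {
  grid <- expand.grid(window_ratio = window_ratios, n = n_points,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    res <- normalized_ra(family, r_t, grid$n[i], grid$window_ratio[i])
    data.frame(family = family, r_t = r_t, window_ratio = grid$window_ratio[i],
               n = grid$n[i], r_tilde_a = res$r_tilde_a, ratio = res$ratio,
               boundary = res$boundary)
  })
  do.call(rbind, rows)
}

#' Write a study table to CSV
#'
#' @param table A study data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
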