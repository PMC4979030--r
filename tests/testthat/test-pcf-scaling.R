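test_that("an exactly exponential input is recovered to high precision", {
  # tabulated curve path
  r <- seq(0.001, 12, length.out = 6000)
  a0 <- 2.3; d0 <- 0.8
  curve <- correlation_curve(r, 1 + a0 * exp(-r / d0), "pcf")
  fit <- fit_exponential_lse(curve)
  expect_equal(fit$a, a0, tolerance = 1e-6)
  expect_equal(fit$d, d0, tolerance = 1e-6)
  expect_lt(fit$E, 1e-10)
  # model path: the vargamma PCF is exponential, so the fit is exact
  m <- cluster_model("vargamma", 0.7, kappa = 3)
  fit2 <- fit_exponential_lse(m)
  expect_equal(fit2$d, 0.7, tolerance = 1e-8)
  expect_equal(fit2$a, model_pcf_amplitude(m), tolerance = 1e-8)
  laws <- scaling_laws("vargamma")
  expect_equal(c(laws$m, laws$n, laws$l), c(1, 1, 1), tolerance = 1e-7)
})

test_that("fitted stationarity holds: the profiled optimum is a minimum of E", {
  m <- cluster_model("gaussian", 1, kappa = 1 / (4 * pi))
  fit <- fit_exponential_lse(m)
  E_at <- function(a, d) {
    integrate(function(r) (1 + a * exp(-r / d) - pcf_theoretical(m, r))^2,
              0, fit$r_m, rel.tol = 1e-10)$value
  }
  E0 <- E_at(fit$a, fit$d)
  expect_equal(E0, fit$E, tolerance = 1e-6)
  for (eps in c(-1e-3, 1e-3)) {
    expect_gte(E_at(fit$a * (1 + eps), fit$d), E0 - 1e-12)
    expect_gte(E_at(fit$a, fit$d * (1 + eps)), E0 - 1e-12)
  }
})

test_that("scaling laws are pure ratios, invariant to kappa and r_t", {
  ref <- list(gaussian = NULL, disk = NULL, cauchy = NULL)
  for (fam in c("gaussian", "disk", "cauchy")) {
    vals <- lapply(list(c(1, 1), c(0.02, 25), c(5, 0.003)), function(pr) {
      m <- cluster_model(fam, r_t = pr[1], kappa = pr[2])
      fit <- fit_exponential_lse(m)
      c(m = fit$d / pr[1], n = fit$a / model_pcf_amplitude(m))
    })
    expect_equal(vals[[2]], vals[[1]], tolerance = 1e-6)
    expect_equal(vals[[3]], vals[[1]], tolerance = 1e-6)
  }
})

test_that("internal identities tie l to n m^2 across amplitude conventions", {
  g <- scaling_laws("gaussian")
  expect_equal(g$l, g$n * g$m^2 / 2, tolerance = 1e-6)
  cau <- scaling_laws("cauchy")
  expect_equal(cau$l, cau$n * cau$m^2 / 4, tolerance = 1e-6)
})

test_that("enlarging r_m beyond the per-family minimum leaves the laws stable", {
  # the laws converge with r_m: the step from the per-family default to twice
  # that is at most ~1%, and beyond twice the default they are constant
  for (fam in c("gaussian", "disk", "ising")) {
    lim <- switch(fam, gaussian = 6, disk = 3, ising = 4)
    base <- scaling_laws(fam)
    x2 <- scaling_laws(fam, r_m = 2 * lim)
    x4 <- scaling_laws(fam, r_m = 4 * lim)
    x8 <- scaling_laws(fam, r_m = 8 * lim)
    expect_equal(x2$m / base$m, 1, tolerance = 0.015)
    expect_equal(x2$l / base$l, 1, tolerance = 0.015)
    expect_equal(x4$m / x2$m, 1, tolerance = 1e-3)
    expect_equal(x8$m / x2$m, 1, tolerance = 1e-3)
    expect_equal(x8$l / x2$l, 1, tolerance = 1e-3)
  }
})

test_that("ising fit matches the closed-form maximizer at r_m = Inf", {
  # profiled objective for v = r^{-1/4} e^{-r} is proportional to
  # d^{1/2}/(1+d)^{3/2}, maximized exactly at d = 1/2
  m <- cluster_model("ising", 1, a_I = 1)
  fit <- fit_exponential_lse(m, r_m = Inf)
  expect_equal(fit$d, 0.5, tolerance = 1e-6)
  # quarter-power amplitude law: xi ratio 16 gives amplitude ratio 2
  n1 <- ising_amplitude_ratio(2)
  n2 <- ising_amplitude_ratio(32)
  expect_equal(n1 / n2, 2, tolerance = 1e-6)
  expect_true(all(diff(ising_amplitude_ratio(c(5, 50, 500))) < 0))
})

test_that("degenerate (non-clustered) inputs are rejected with a clear error", {
  r <- seq(0.01, 1, length.out = 200)
  expect_error(fit_exponential_lse(correlation_curve(r, rep(1, 200), "pcf")),
               "degenerate")
  expect_error(fit_exponential_lse(correlation_curve(r, 1 - 0.1 * exp(-r), "pcf")),
               "degenerate")
})

test_that("minimum contrast on a theoretical curve recovers its parameters", {
  m <- cluster_model("gaussian", 0.02, kappa = 25)
  r <- seq(5e-4, 0.25, length.out = 800)
  fit <- fit_model_pcf(theory_curve(m, "pcf", r), "gaussian")
  expect_true(fit$converged)
  expect_equal(fit$kappa, 25, tolerance = 1e-5)
  expect_equal(fit$r_t, 0.02, tolerance = 1e-5)
  # self-consistency for a second family
  m2 <- cluster_model("cauchy", 0.03, kappa = 40)
  fit2 <- fit_model_pcf(theory_curve(m2, "pcf", r), "cauchy")
  expect_equal(fit2$kappa, 40, tolerance = 1e-4)
  expect_equal(fit2$r_t, 0.03, tolerance = 1e-4)
})

test_that("cluster reports correct by the assumed family and surface failures", {
  m <- cluster_model("vargamma", 0.02, kappa = 25, mu = 60)
  pp <- simulate_neyman_scott(m, unit_square, seed = 13, dilation = 0.3)
  rep1 <- estimate_cluster_report(pp, estimator_config(n_bins = 128),
                                  family = "vargamma")
  # the vargamma identity row: correction leaves the estimates unchanged
  expect_equal(rep1$corrected$N, rep1$N_a, tolerance = 1e-6)
  expect_equal(rep1$corrected$r_t, rep1$fit$d, tolerance = 1e-6)
  csr <- simulate_csr(800, unit_square, seed = 14)
  rep2 <- estimate_cluster_report(csr, estimator_config(n_bins = 128))
  expect_false(is.null(rep2$error))
  expect_match(rep2$error, "degenerate|few")
})
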