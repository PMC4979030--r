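test_that("pair-distance distributions are valid CDFs with matching densities", {
  for (fam in ns_families) {
    m <- test_model(fam, r_t = 1, kappa = 1)
    hi <- if (fam == "disk") 2 else 60
    # the Cauchy pair distance is heavy tailed (1 - H ~ 2/r): go far out
    lim <- if (fam == "cauchy") 2e6 else hi
    r <- seq(0, hi, length.out = 200)
    H <- pair_distance_cdf(m, r)
    expect_equal(H[1], 0)
    expect_true(all(diff(H) >= -1e-12))
    expect_true(all(H >= 0 & H <= 1))
    expect_equal(pair_distance_cdf(m, lim), 1, tolerance = 1e-5)
    # density integrates to one and differentiates the CDF
    quad <- integrate(function(x) pair_distance_pdf(m, x), 0,
                      if (fam == "disk") 2 else Inf, rel.tol = 1e-10)$value
    expect_equal(quad, 1, tolerance = 1e-8)
    mid <- r[r > 0.05 & r < hi * 0.95]
    dH <- (pair_distance_cdf(m, mid + 1e-6) - pair_distance_cdf(m, mid - 1e-6)) / 2e-6
    expect_equal(dH, pair_distance_pdf(m, mid), tolerance = 1e-4)
  }
})

test_that("gaussian pair distance matches Monte-Carlo sampled offspring pairs", {
  # two N(0, sigma^2 I) offspring differ by a Rayleigh(sqrt(2) sigma) distance
  sigma <- 0.7
  m <- cluster_model("gaussian", sigma, kappa = 1)
  set.seed(42)
  nmc <- 2e5
  d <- sqrt((rnorm(nmc, sd = sigma) - rnorm(nmc, sd = sigma))^2 +
            (rnorm(nmc, sd = sigma) - rnorm(nmc, sd = sigma))^2)
  for (r in c(0.5, 1.4, 2.8)) {
    mc <- mean(d <= r)
    se <- sqrt(mc * (1 - mc) / nmc)
    expect_lt(abs(pair_distance_cdf(m, r) - mc), 4 * se + 1e-4)
  }
  expect_equal(pair_distance_cdf(cluster_model("gaussian", 1, kappa = 1), 2),
               1 - exp(-1), tolerance = 1e-12)
})

test_that("pair-distance endpoints behave (disk support, zero at origin)", {
  expect_equal(pair_distance_cdf(cluster_model("disk", 1, kappa = 1), 2), 1)
  expect_equal(pair_distance_cdf(cluster_model("cauchy", 1, kappa = 1), 0), 0)
  expect_error(pair_distance_cdf(cluster_model("ising", 1, a_I = 1), 1),
               "Ising")
})

test_that("K has the canonical Neyman-Scott decomposition", {
  r <- seq(0, 0.3, length.out = 60)
  for (fam in ns_families) {
    m <- test_model(fam)
    expect_equal(K_theoretical(m, r) - pi * r^2,
                 pair_distance_cdf(m, r) / m$kappa, tolerance = 1e-10)
    expect_equal(K_theoretical(m, 0), 0)
    expect_true(all(diff(K_theoretical(m, r)) > 0))
  }
  # frozen arithmetic from the closed form
  m <- cluster_model("gaussian", 0.03, kappa = 50)
  expect_equal(K_theoretical(m, 0.1),
               pi * 0.01 + (1 - exp(-0.01 / 0.0036)) / 50, tolerance = 1e-12)
  expect_equal(K_theoretical(m, 0.1), 0.0501724, tolerance = 1e-6)
  expect_equal(L_minus_r_theoretical(m, 0.1), sqrt(0.0501724 / pi) - 0.1,
               tolerance = 1e-6)
  # CSR limit: cluster term vanishes as kappa grows
  dense <- cluster_model("gaussian", 0.03, kappa = 1e9)
  expect_equal(K_theoretical(dense, 0.1) / (pi * 0.01), 1, tolerance = 1e-6)
  # geometric counts double the cluster term
  geo <- cluster_model("gaussian", 0.03, kappa = 50, count_dist = "geometric")
  expect_equal(K_theoretical(geo, 0.1) - pi * 0.01,
               2 * (K_theoretical(m, 0.1) - pi * 0.01), tolerance = 1e-12)
})

test_that("pcf is the derivative of K over 2 pi r, for every family", {
  for (fam in c(ns_families, "ising")) {
    m <- if (fam == "ising") cluster_model("ising", 0.05, a_I = 2)
         else test_model(fam)
    r <- seq(0.01, 0.25, length.out = 80)
    eps <- 1e-6
    Kp <- (K_theoretical(m, r + eps) - K_theoretical(m, r - eps)) / (2 * eps)
    expect_equal(Kp / (2 * pi * r), pcf_theoretical(m, r), tolerance = 1e-6)
  }
})

test_that("pcf limits and sentinels at the origin", {
  expect_equal(pcf_theoretical(cluster_model("vargamma", 1, kappa = 1), 2),
               1 + exp(-2) / (2 * pi), tolerance = 1e-12)
  # amplitude 1/(4 pi kappa sigma^2) = 1 at kappa = 1/(4 pi), sigma = 1
  m <- cluster_model("gaussian", 1, kappa = 1 / (4 * pi))
  expect_equal(pcf_theoretical(m, 0), 2)
  expect_equal(pcf_theoretical(cluster_model("disk", 1, kappa = 1), 2), 1)
  expect_warning(v0 <- pcf_theoretical(cluster_model("ising", 1, a_I = 1), 0),
                 "diverges")
  expect_identical(v0, Inf)
  # attractive models: g >= 1, g -> 1
  for (fam in ns_families) {
    m2 <- test_model(fam)
    g <- pcf_theoretical(m2, seq(0.001, 1, length.out = 50))
    expect_true(all(g >= 1))
    expect_equal(pcf_theoretical(m2, 5), 1, tolerance = 1e-3)
  }
})

test_that("background attenuates the PCF amplitude quadratically", {
  expect_equal(apply_background(2, 1), 2)
  expect_equal(apply_background(2, 0.5), 0.5)
  expect_equal(apply_background(7, 0), 0)
  m1 <- test_model("gaussian")
  m2 <- test_model("gaussian", beta = 0.5)
  r <- seq(0.005, 0.2, length.out = 50)
  expect_equal(pcf_theoretical(m2, r) - 1, (pcf_theoretical(m1, r) - 1) * 0.25,
               tolerance = 1e-12)
  # L - r vanishes identically when the cluster term does
  m0 <- test_model("gaussian", beta = 0)
  expect_equal(L_minus_r_theoretical(m0, r), rep(0, length(r)), tolerance = 1e-12)
})

test_that("offspring radial quantiles invert the kernel CDFs", {
  g <- cluster_model("gaussian", 1, kappa = 1)
  expect_equal(offspring_radial_quantile(g, 0.95), sqrt(2 * log(20)),
               tolerance = 1e-9)
  d <- cluster_model("disk", 1, kappa = 1)
  expect_equal(offspring_radial_quantile(d, 0.95), sqrt(0.95), tolerance = 1e-9)
  expect_equal(offspring_radial_quantile(d, 1 - 1e-9), 1, tolerance = 1e-4)
  expect_true(all(diff(offspring_radial_quantile(g, c(0.5, 0.8, 0.95))) > 0))
  # vargamma: cross-check the numeric inversion against an independent
  # trapezoidal CDF of the Whittle-Matern(-1/4) radial density
  u95 <- offspring_radial_quantile(cluster_model("vargamma", 1, kappa = 1), 0.95)
  x <- seq(1e-6, 40, length.out = 40000)
  dens <- x^(3 / 4) * besselK(x, 1 / 4)
  cdf <- cumsum((dens[-1] + dens[-length(x)]) / 2 * diff(x))
  cdf <- cdf / cdf[length(cdf)]
  u95_trap <- x[which(cdf >= 0.95)[1]]
  expect_equal(u95, u95_trap, tolerance = 1e-3)
  expect_error(offspring_radial_quantile(cluster_model("ising", 1, a_I = 1), 0.5),
               "Ising")
})

test_that("occupancy integral recovers mu and the analytic exponential form", {
  fit1 <- structure(list(a = 1, d = 1, E = 0, r_m = Inf),
                    class = "exponential_fit")
  expect_equal(n_per_cluster(fit1, 1), 2 * pi)
  # flat pcf: zero occupancy
  flat <- correlation_curve(seq(0.01, 1, length.out = 100),
                            rep(1, 100), "pcf")
  expect_equal(n_per_cluster(flat, 10), 0)
  # theoretical curves: N = rho / kappa = mu for Poisson counts, beta = 1
  for (fam in ns_families) {
    m <- test_model(fam, r_t = 0.02, kappa = 50, mu = 100)
    expect_equal(n_per_cluster(m), 100, tolerance = 1e-6)
    # grid reach set by the family's tail: the truncation error of the
    # occupancy integral is 1 - H_d(hi), heavy for the Cauchy model, which
    # also needs a log-spaced grid to resolve its peak and its long tail
    hi <- switch(fam, gaussian = 0.3, disk = 0.3, vargamma = 3, cauchy = 60)
    r <- if (fam == "cauchy") exp(seq(log(1e-4), log(hi), length.out = 20000))
         else seq(hi / 20000, hi, length.out = 20000)
    curve <- theory_curve(m, "pcf", r)
    expect_equal(n_per_cluster(curve, rho = 5000), 100, tolerance = 2e-3)
  }
  # quadratic background effect on the occupancy integral
  mb <- test_model("gaussian", r_t = 0.02, kappa = 50, mu = 100, beta = 0.5)
  expect_equal(n_per_cluster(mb, rho = 5000), 100 * 0.25, tolerance = 1e-6)
  # non-decaying tail is rejected
  heavy <- correlation_curve(seq(0.01, 1, length.out = 100),
                             1 + 1 / seq(0.01, 1, length.out = 100), "pcf")
  expect_error(n_per_cluster(heavy, 1), "converge")
})

test_that("theory curves round-trip through CSV", {
  m <- test_model("gaussian")
  cv <- theory_curve(m, "L_minus_r", seq(0.001, 0.2, length.out = 50))
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(cv, path)
  back <- read_curve_csv(path)
  expect_equal(back$r, cv$r)
  expect_equal(back$value, cv$value)
  expect_equal(back$statistic, "L_minus_r")
})

test_that("window exposes area and perimeter and rejects degenerate sides", {
  w <- cc_window(2, 0.5)
  expect_equal(window_area(w), 1)
  expect_equal(window_perimeter(w), 5)
  expect_error(cc_window(-1, 1))
  expect_error(cc_window(0))
})
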