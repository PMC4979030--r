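test_that("simulation is reproducible per seed and seeds differ", {
  m <- test_model("gaussian", r_t = 0.02, kappa = 25, mu = 40)
  a <- simulate_neyman_scott(m, unit_square, seed = 5)
  b <- simulate_neyman_scott(m, unit_square, seed = 5)
  c <- simulate_neyman_scott(m, unit_square, seed = 6)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_false(identical(a$x, c$x))
})

test_that("realized intensity matches mu * kappa over replicates", {
  m <- test_model("gaussian", r_t = 0.02, kappa = 25, mu = 40)
  counts <- vapply(1:200, function(s)
    npoints(simulate_neyman_scott(m, unit_square, seed = 300 + s)), numeric(1))
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 1000), 3 * se)
})

test_that("disk offspring stay within R of their parent", {
  m <- test_model("disk", r_t = 0.05, kappa = 25, mu = 30)
  pp <- simulate_neyman_scott(m, unit_square, seed = 9)
  prov <- pp$provenance
  d <- sqrt((pp$x - prov$parents[prov$parent_index, "x"])^2 +
            (pp$y - prov$parents[prov$parent_index, "y"])^2)
  expect_true(all(d <= 0.05 + 1e-12))
})

test_that("vargamma offspring radii follow the Whittle-Matern radial CDF", {
  m <- test_model("vargamma", r_t = 0.05, kappa = 10, mu = 50)
  pp <- simulate_neyman_scott(m, unit_square, seed = 21, dilation = 1)
  prov <- pp$provenance
  d <- sqrt((pp$x - prov$parents[prov$parent_index, "x"])^2 +
            (pp$y - prov$parents[prov$parent_index, "y"])^2)
  # median displacement should match the kernel median (KS-style spot check)
  med <- offspring_radial_quantile(m, 0.5) * 0.05
  frac <- mean(d <= med)
  expect_lt(abs(frac - 0.5), 4 / sqrt(length(d)) + 0.02)
})

test_that("replicate-averaged empirical K matches the theoretical K", {
  m <- test_model("gaussian", r_t = 0.02, kappa = 25, mu = 40)
  avg <- average_curve(m, reps = 60, seed = 500, statistic = "K",
                       config = estimator_config(n_bins = 64, r_max = 0.125))
  theo <- K_theoretical(m, avg$r)
  inside <- abs(avg$mean - theo) <= 3.5 * avg$se
  expect_gt(mean(inside), 0.9)
})

test_that("superimposing monomers preserves the pattern and the beta arithmetic", {
  m <- test_model("gaussian", r_t = 0.02, kappa = 25, mu = 40)
  pp <- simulate_neyman_scott(m, unit_square, seed = 31)
  expect_identical(superimpose_csr(pp, 1, seed = 1), pp)
  added <- vapply(1:100, function(s)
    npoints(superimpose_csr(pp, 0.5, seed = s)) - npoints(pp), numeric(1))
  se <- stats::sd(added) / sqrt(length(added))
  expect_lt(abs(mean(added) - npoints(pp)), 3 * se)
  expect_error(superimpose_csr(pp, 0, seed = 1), "beta")
})

test_that("monomer background attenuates the empirical pcf amplitude by beta^2", {
  m <- test_model("gaussian", r_t = 0.02, kappa = 25, mu = 40)
  cfg <- estimator_config(n_bins = 64, r_max = 0.125, bandwidth = 0.005)
  pure <- average_curve(m, reps = 40, seed = 700, statistic = "pcf", config = cfg)
  half <- average_curve(m, reps = 40, seed = 700, statistic = "pcf", config = cfg,
                        beta = 0.5)
  band <- pure$r > 0.01 & pure$r < 0.05
  ratio <- mean(half$mean[band] - 1) / mean(pure$mean[band] - 1)
  expect_lt(abs(ratio - 0.25), 0.06)
})

test_that("patterns round-trip through CSV with their window", {
  pp <- simulate_neyman_scott(test_model("disk", 0.03, kappa = 30, mu = 20),
                              cc_window(2, 1), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pattern_csv(pp, path)
  back <- read_pattern_csv(path)
  expect_equal(back$x, pp$x)
  expect_equal(back$y, pp$y)
  expect_equal(back$window$width, 2)
  expect_equal(back$window$height, 1)
})

test_that("fixture suites are deterministic and fully manifested", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  man1 <- generate_fixture_suite(dir1, "gaussian", kappa = c(20, 40),
                                 r_t = c(0.02, 0.04), mu = 10,
                                 replicates = 2, seed = 77)
  man2 <- generate_fixture_suite(dir2, "gaussian", kappa = c(20, 40),
                                 r_t = c(0.02, 0.04), mu = 10,
                                 replicates = 2, seed = 77)
  expect_equal(nrow(man1), 8)
  expect_setequal(list.files(dir1), c(man1$file, "manifest.csv"))
  for (f in man1$file) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
  }
  # manifest parameters round-trip the configuration
  expect_setequal(unique(man1$kappa), c(20, 40))
  expect_setequal(unique(man1$r_t), c(0.02, 0.04))
  expect_true(all(man1$mu == 10))
})

test_that("resource guard and unsupported families are refused", {
  big <- cluster_model("gaussian", 0.01, kappa = 1e4, mu = 1e4)
  expect_error(simulate_neyman_scott(big, unit_square, seed = 1), "guard")
  expect_error(simulate_neyman_scott(cluster_model("ising", 1, a_I = 1),
                                     unit_square, seed = 1), "Ising")
})
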