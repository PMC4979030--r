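#' Planar point patterns
#'
#' A `point_pattern` holds planar coordinates inside a rectangular
#' [cc_window()], with optional provenance (generating model, seed, parents).
#'
#' @param x,y Coordinates.
#' @param window A [cc_window()].
#' @param provenance Optional list recording how the pattern was generated.
#' @return An object of class `"point_pattern"`.
#' @export
point_pattern <- function(x, y, window, provenance = NULL) {
  stopifnot(inherits(window, "cc_window"), length(x) == length(y))
  if (length(x) > 0) {
    stopifnot(all(x >= 0), all(x <= window$width),
              all(y >= 0), all(y <= window$height))
  }
  structure(list(x = as.numeric(x), y = as.numeric(y), window = window,
                 provenance = provenance),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point pattern: %d points in [0, %g] x [0, %g] (intensity %.4g)\n",
              length(x$x), x$window$width, x$window$height, pattern_intensity(x)))
  invisible(x)
}

#' @rdname point_pattern
#' @param pattern A `point_pattern`.
#' @export
npoints <- function(pattern) length(pattern$x)

#' @rdname point_pattern
#' @export
pattern_intensity <- function(pattern) npoints(pattern) / window_area(pattern$window)

#' Simulate a Neyman-Scott clustered point pattern
#'
#' Parents follow a homogeneous Poisson process with intensity `kappa`; each
#' parent receives a random number of offspring (Poisson or geometric with
#' mean `mu`) displaced by the family's kernel, and the offspring form the
#' pattern. Parents are generated in the window dilated by a guard margin
#' (default `4 * r_t` for unbounded kernels, exactly `r_t` for the disk) so
#' that offspring intensity is stationary inside the window and the empirical
#' K is not biased by cluster truncation at the borders; offspring are then
#' clipped to the window.
#'
#' @param model A Neyman-Scott [cluster_model()] with `kappa` and `mu` set.
#' @param window A [cc_window()].
#' @param seed Integer seed (mandatory: every simulation is reproducible).
#' @param dilation Guard margin; `NULL` for the family default.
#' @return A [point_pattern()] whose provenance records the model, seed,
#'   parents and the parent index of every retained offspring.
#' @examples
#' pp <- simulate_neyman_scott(cluster_model("gaussian", 0.02, kappa = 25, mu = 40),
#'                             cc_window(1), seed = 1)
#' npoints(pp)
#' @export
simulate_neyman_scott <- function(model, window, seed, dilation = NULL) {
  stopifnot(inherits(model, "cluster_model"), inherits(window, "cc_window"))
  if (!is_neyman_scott(model))
    stop("the Ising model is not a Neyman-Scott process and cannot be simulated here")
  if (is.null(model$mu)) stop("simulation requires 'mu'")
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (is.null(dilation)) {
    dilation <- if (model$family == "disk") model$r_t else 4 * model$r_t
  }
  wext <- window$width + 2 * dilation
  hext <- window$height + 2 * dilation
  expected <- model$kappa * wext * hext * model$mu
  if (expected > 1e7)
    stop("expected point count ", format(expected), " exceeds the 1e7 resource guard")

  set.seed(as.integer(seed))
  n_parents <- rpois(1, model$kappa * wext * hext)
  px <- runif(n_parents, -dilation, window$width + dilation)
  py <- runif(n_parents, -dilation, window$height + dilation)
  s <- switch(model$count_dist,
              poisson = rpois(n_parents, model$mu),
              geometric = rgeom(n_parents, prob = 1 / (1 + model$mu)))
  idx <- rep.int(seq_len(n_parents), s)
  ntot <- length(idx)
  rad <- offspring_sample_radius(model$family, runif(ntot), model$r_t)
  ang <- runif(ntot, 0, 2 * pi)
  ox <- px[idx] + rad * cos(ang)
  oy <- py[idx] + rad * sin(ang)
  keep <- ox >= 0 & ox <= window$width & oy >= 0 & oy <= window$height
  point_pattern(ox[keep], oy[keep], window,
                provenance = list(model = model, seed = as.integer(seed),
                                  dilation = dilation,
                                  parents = cbind(x = px, y = py),
                                  parent_index = idx[keep],
                                  counts = s))
}

#' Simulate complete spatial randomness
#'
#' @param intensity Expected points per unit area.
#' @inheritParams simulate_neyman_scott
#' @return A [point_pattern()].
#' @export
simulate_csr <- function(intensity, window, seed) {
  stopifnot(intensity > 0, inherits(window, "cc_window"))
  set.seed(as.integer(seed))
  n <- rpois(1, intensity * window_area(window))
  point_pattern(runif(n, 0, window$width), runif(n, 0, window$height), window,
                provenance = list(model = "csr", intensity = intensity,
                                  seed = as.integer(seed)))
}

#' Superimpose a CSR monomer background on a clustered pattern
#'
#' Adds Poisson monomers with intensity `rho_c (1 - beta)/beta`, where
#' `rho_c` is the realized intensity of the clustered pattern, so that the
#' expected clustered fraction of the result is `beta`. The PCF amplitude of
#' the superposition is attenuated by `beta^2` (see [apply_background()]).
#'
#' @param pattern A clustered [point_pattern()].
#' @param beta Clustered fraction in (0, 1]; `beta = 1` returns the pattern
#'   unchanged (pure CSR must be generated directly with [simulate_csr()]).
#' @param seed Integer seed.
#' @return A [point_pattern()].
#' @export
superimpose_csr <- function(pattern, beta, seed) {
  stopifnot(inherits(pattern, "point_pattern"),
            is.numeric(beta), length(beta) == 1)
  if (beta <= 0 || beta > 1)
    stop("beta must lie in (0, 1]; generate pure CSR directly for beta = 0")
  if (beta == 1) return(pattern)
  w <- pattern$window
  set.seed(as.integer(seed))
  lambda <- pattern_intensity(pattern) * (1 - beta) / beta
  n <- rpois(1, lambda * window_area(w))
  point_pattern(c(pattern$x, runif(n, 0, w$width)),
                c(pattern$y, runif(n, 0, w$height)), w,
                provenance = list(clustered = pattern$provenance, beta = beta,
                                  monomers = n, seed = as.integer(seed)))
}

# deterministic per-replicate child seed from a root seed (kept < 2^31 - 1)
child_seed <- function(root, i) {
  as.integer((as.numeric(root) * 48271 + as.numeric(i) * 16807) %% 2147483587 + 1)
}

#' Read and write point patterns as CSV
#'
#' Plain `x,y` tables with the window recorded in `# key=value` comment lines,
#' so a pattern file round-trips without a sidecar.
#'
#' @param pattern A [point_pattern()].
#' @param path File path.
#' @return `write_pattern_csv` returns `path` invisibly; `read_pattern_csv`
#'   returns a [point_pattern()].
#' @export
write_pattern_csv <- function(pattern, path) {
  stopifnot(inherits(pattern, "point_pattern"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# window_width=%.15g", pattern$window$width), con)
  writeLines(sprintf("# window_height=%.15g", pattern$window$height), con)
  writeLines("x,y", con)
  if (npoints(pattern) > 0)
    writeLines(sprintf("%.15g,%.15g", pattern$x, pattern$y), con)
  invisible(path)
}

#' @rdname write_pattern_csv
#' @param window Optional [cc_window()] overriding the one stored in the file.
#' @export
read_pattern_csv <- function(path, window = NULL) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    ln <- grep(paste0("^#\\s*", key, "="), meta, value = TRUE)
    if (length(ln) == 0) return(NULL)
    as.numeric(sub(".*=", "", ln[1]))
  }
  if (is.null(window)) {
    w <- get_meta("window_width"); h <- get_meta("window_height")
    if (is.null(w) || is.null(h))
      stop("no window stored in file; pass 'window' explicitly")
    window <- cc_window(w, h)
  }
  tab <- read.csv(textConnection(lines[!grepl("^#", lines)]))
  point_pattern(tab$x, tab$y, window)
}

#' Generate a deterministic suite of simulated fixture patterns
#'
#' Simulates every combination of the supplied parameter grids for a number
#' of replicates, writes each pattern as CSV and a manifest recording the
#' ground-truth parameters and per-file seed. Re-running with the same root
#' seed reproduces the files byte for byte.
#'
#' @param dir Output directory (created if needed).
#' @param family Neyman-Scott family name.
#' @param kappa,r_t Parameter grids.
#' @param mu Mean points per cluster.
#' @param beta Clustered fraction (monomers added when `beta < 1`).
#' @param replicates Replicates per grid cell.
#' @param window A [cc_window()].
#' @param seed Root seed; per-file seeds are derived deterministically.
#' @return The manifest as a data frame (also written to `manifest.csv`),
#'   invisibly.
#' @export
generate_fixture_suite <- function(dir, family, kappa, r_t, mu = 40, beta = 1,
                                   replicates = 1, window = cc_window(1),
                                   seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- expand.grid(kappa = kappa, r_t = r_t, rep = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    s <- child_seed(seed, i)
    model <- cluster_model(family, r_t = g$r_t, kappa = g$kappa, mu = mu)
    pp <- simulate_neyman_scott(model, window, seed = s)
    if (beta < 1) pp <- superimpose_csr(pp, beta, seed = child_seed(s, 1))
    fname <- sprintf("%s_k%g_rt%g_rep%d.csv", family, g$kappa, g$r_t, g$rep)
    write_pattern_csv(pp, file.path(dir, fname))
    rows[[i]] <- data.frame(file = fname, family = family, kappa = g$kappa,
                            r_t = g$r_t, mu = mu, beta = beta, seed = s,
                            n_points = npoints(pp))
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
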