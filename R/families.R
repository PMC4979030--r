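# Internal per-family closed forms.
#
# For a Neyman-Scott process the distance between two offspring of the same
# parent has density h_d and CDF H_d; all second-order summaries follow from
# them. Shapes below are for the kernels named in cluster_model():
#   gaussian : offspring N(0, sigma^2 I); pair distance Rayleigh(sqrt(2) sigma)
#   disk     : offspring uniform in a disk of radius R ("disk line picking")
#   cauchy   : offspring bivariate Cauchy(eta); pair distance bivariate
#              Cauchy(2 eta) by stability
#   vargamma : offspring Whittle-Matern(nu = -1/4, eta); pair distance density
#              r e^{-r/eta}/eta^2 (Matern smoothness doubles under convolution:
#              nu_pair = 2 nu + 1 = 1/2, and x^{1/2} K_{1/2}(x) is exponential)
# The Ising model is defined directly through its Ornstein-Zernike PCF
# 1 + a_I r^{-1/4} e^{-r/xi} (r in nanometers) and has no offspring kernel.

pair_support <- function(family, r_t) {
  if (family == "disk") 2 * r_t else Inf
}

# pair-distance CDF, unit-free: argument r, size r_t
pair_cdf_raw <- function(family, r, r_t) {
  switch(family,
    gaussian = 1 - exp(-r^2 / (4 * r_t^2)),
    disk = {
      z <- pmin(pmax(r / (2 * r_t), 0), 1)
      out <- 2 + (1 / pi) * ((8 * z^2 - 4) * acos(z) - 2 * asin(z) +
                             4 * z * sqrt((1 - z^2)^3) - 6 * z * sqrt(1 - z^2))
      ifelse(r >= 2 * r_t, 1, out)
    },
    cauchy = 1 - (1 + r^2 / (4 * r_t^2))^(-1 / 2),
    vargamma = 1 - (1 + r / r_t) * exp(-r / r_t),
    stop("no pair-distance CDF for family '", family, "'")
  )
}

pair_pdf_raw <- function(family, r, r_t) {
  switch(family,
    gaussian = (r / (2 * r_t^2)) * exp(-r^2 / (4 * r_t^2)),
    disk = {
      z <- pmin(pmax(r / (2 * r_t), 0), 1)
      out <- (2 * r / r_t^2) * ((2 / pi) * acos(z) - (z / pi) * 2 * sqrt(1 - z^2))
      # equivalently (4r / pi R^2) acos(z) - (4 r z / pi R^2) sqrt(1 - z^2)
      ifelse(r >= 2 * r_t, 0, out)
    },
    cauchy = (r / (4 * r_t^2)) * (1 + r^2 / (4 * r_t^2))^(-3 / 2),
    vargamma = (r / r_t^2) * exp(-r / r_t),
    stop("no pair-distance density for family '", family, "'")
  )
}

# PCF shape v with v scaled so that g = 1 + amp * v; conventions chosen so the
# amplitude a_t below matches h_d/(2 pi r kappa) = a_t v exactly.
pcf_shape <- function(family, r, r_t) {
  switch(family,
    gaussian = exp(-r^2 / (4 * r_t^2)),
    disk = {
      z <- pmin(pmax(r / (2 * r_t), 0), 1)
      ifelse(r >= 2 * r_t, 0, acos(z) - z * sqrt(1 - z^2))
    },
    cauchy = (1 + r^2 / (4 * r_t^2))^(-3 / 2),
    vargamma = exp(-r / r_t),
    ising = r^(-1 / 4) * exp(-r / r_t),
    stop("unknown family '", family, "'")
  )
}

# true PCF amplitude a_t for a unit clustered fraction and Poisson counts
amp_true <- function(family, r_t, kappa = NULL, a_I = NULL) {
  switch(family,
    gaussian = 1 / (4 * pi * kappa * r_t^2),
    disk = 2 / (pi^2 * kappa * r_t^2),
    cauchy = 1 / (8 * pi * kappa * r_t^2),
    vargamma = 1 / (2 * pi * kappa * r_t^2),
    ising = a_I,
    stop("unknown family '", family, "'")
  )
}

# integral of v(r) 2 pi r dr over the full support; N_t = rho * amp * this
pcf_shape_integral <- function(family, r_t) {
  switch(family,
    gaussian = 4 * pi * r_t^2,
    disk = pi^2 * r_t^2 / 2,          # 8 pi R^2 int_0^1 z (acos z - z sqrt(1-z^2)) dz
    cauchy = 8 * pi * r_t^2,
    vargamma = 2 * pi * r_t^2,
    ising = 2 * pi * gamma(7 / 4) * r_t^(7 / 4),
    stop("unknown family '", family, "'")
  )
}

# default upper fitting limit for the exponential LSE fit (in units of r_t);
# beyond these the fitted (m, n, l) are stable to < 0.5%
default_fit_limit <- function(family) {
  switch(family,
    gaussian = 6, disk = 3, ising = 4, cauchy = Inf, vargamma = Inf)
}

# offspring radial CDF P(|X| <= x) for a single offspring displacement
offspring_cdf <- function(family, x, r_t) {
  switch(family,
    gaussian = 1 - exp(-x^2 / (2 * r_t^2)),
    disk = pmin(pmax(x / r_t, 0), 1)^2,
    cauchy = 1 - (1 + x^2 / r_t^2)^(-1 / 2),
    vargamma = vargamma_radial_cdf(x, r_t),
    stop("no offspring kernel for family '", family, "'")
  )
}

# Whittle-Matern(nu = -1/4) radial density ~ x^{3/4} K_{1/4}(x/eta);
# normalization int_0^inf u^{3/4} K_{1/4}(u) du = 2^{-1/4} Gamma(3/4)
vargamma_radial_density <- function(x, r_t) {
  u <- x / r_t
  ifelse(u <= 0, 0, u^(3 / 4) * besselK(u, 1 / 4) / (2^(-1 / 4) * gamma(3 / 4) * r_t))
}

vargamma_radial_cdf <- function(x, r_t) {
  vapply(x, function(xi) {
    if (xi <= 0) return(0)
    v <- integrate(vargamma_radial_density, 0, xi, r_t = r_t,
                   rel.tol = 1e-10, abs.tol = 1e-12)$value
    min(v, 1)
  }, numeric(1))
}

# sample one radial offspring displacement distance per entry of u ~ U(0,1)
offspring_sample_radius <- function(family, u, r_t) {
  switch(family,
    gaussian = r_t * sqrt(-2 * log(1 - u)),
    disk = r_t * sqrt(u),
    cauchy = r_t * sqrt((1 - u)^(-2) - 1),
    vargamma = vargamma_radial_quantile(u, r_t),
    stop("no offspring kernel for family '", family, "'")
  )
}

# inverse radial CDF by monotone interpolation on a fixed grid (tail by
# root-finding); adequate for simulation, exact enough for the u ranges used
vargamma_radial_quantile <- function(u, r_t) {
  grid <- r_t * exp(seq(log(1e-4), log(40), length.out = 400))
  cdf <- vargamma_radial_cdf(grid, r_t)
  keep <- !duplicated(cdf)
  q <- approx(c(0, cdf[keep]), c(0, grid[keep]), xout = u, rule = 2)$y
  q
}
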