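#' Intra-cluster pair-distance distribution
#'
#' For a Neyman-Scott model, the distance between two offspring of the same
#' parent has CDF \eqn{H_d} and density \eqn{h_d}; every second-order summary
#' of the process is a functional of them. Closed forms: Gaussian
#' \eqn{H_d(r) = 1 - e^{-r^2/4\sigma^2}} (the difference of two
#' \eqn{N(0,\sigma^2 I)} points is Rayleigh with scale \eqn{\sqrt 2 \sigma});
#' disk: the "disk line picking" distribution on \eqn{[0, 2R]}; Cauchy
#' \eqn{H_d(r) = 1 - (1 + r^2/4\eta^2)^{-1/2}}; variance-Gamma
#' \eqn{h_d(r) = r e^{-r/\eta}/\eta^2}.
#'
#' @param model A Neyman-Scott [cluster_model()] (the Ising model has no
#'   offspring kernel and is rejected).
#' @param r Nonnegative distances.
#' @return `pair_distance_cdf`: probabilities in \[0, 1\];
#'   `pair_distance_pdf`: the density.
#' @examples
#' m <- cluster_model("disk", r_t = 1, kappa = 1)
#' pair_distance_cdf(m, 2)   # 1: no intra-disk distance exceeds 2R
#' @export
pair_distance_cdf <- function(model, r) {
  stopifnot(inherits(model, "cluster_model"), all(r >= 0))
  if (!is_neyman_scott(model))
    stop("the Ising model has no intra-cluster pair-distance distribution")
  pair_cdf_raw(model$family, r, model$r_t)
}

#' @rdname pair_distance_cdf
#' @export
pair_distance_pdf <- function(model, r) {
  stopifnot(inherits(model, "cluster_model"), all(r >= 0))
  if (!is_neyman_scott(model))
    stop("the Ising model has no intra-cluster pair-distance distribution")
  pair_pdf_raw(model$family, r, model$r_t)
}

#' Theoretical second-order summaries of a cluster model
#'
#' For Neyman-Scott processes with Poisson offspring counts,
#' \deqn{K(r) = \pi r^2 + \beta^2 H_d(r)/\kappa,}
#' independent of the mean points per cluster `mu`; geometric counts double the
#' cluster term. The pair correlation function is
#' \eqn{g(r) = K'(r)/(2\pi r) = 1 + \beta^2 c_S h_d(r)/(2\pi r \kappa)}, and
#' \eqn{L(r) - r = \sqrt{K(r)/\pi} - r}. For the Ising model the PCF is the
#' Ornstein-Zernike form \eqn{1 + a_I r^{-1/4} e^{-r/\xi}} (`r` in nm) and K
#' follows by exact integration via the lower incomplete gamma function.
#'
#' @param model A [cluster_model()].
#' @param r Nonnegative distances (`pcf_theoretical` requires the Ising model
#'   to be evaluated at `r > 0`; its PCF diverges at the origin, where an
#'   `Inf` sentinel is returned with a warning; the other families return
#'   their finite limits).
#' @return Numeric vector: an area for `K_theoretical`, a length for
#'   `L_minus_r_theoretical`, dimensionless for `pcf_theoretical`.
#' @examples
#' m <- cluster_model("gaussian", r_t = 0.03, kappa = 50)
#' K_theoretical(m, 0.1)          # pi 0.01 + (1 - exp(-0.01/0.0036))/50
#' L_minus_r_theoretical(m, 0.1)
#' @export
K_theoretical <- function(model, r) {
  stopifnot(inherits(model, "cluster_model"), all(r >= 0))
  base <- pi * r^2
  b2 <- model$beta^2
  if (is_neyman_scott(model)) {
    cs <- count_factor(model$count_dist)
    base + b2 * cs * pair_cdf_raw(model$family, r, model$r_t) / model$kappa
  } else {
    # int_0^r a_I s^{-1/4} e^{-s/xi} 2 pi s ds = 2 pi a_I xi^{7/4} gamma(7/4, r/xi)
    xi <- model$r_t
    base + b2 * model$a_I * 2 * pi * xi^(7 / 4) * gamma(7 / 4) *
      stats::pgamma(r / xi, shape = 7 / 4)
  }
}

# analytic dK/dr, used by the radius-of-maximal-aggregation solver
K_prime_theoretical <- function(model, r) {
  b2 <- model$beta^2
  if (is_neyman_scott(model)) {
    cs <- count_factor(model$count_dist)
    2 * pi * r + b2 * cs * pair_pdf_raw(model$family, r, model$r_t) / model$kappa
  } else {
    2 * pi * r + b2 * model$a_I * 2 * pi * r^(3 / 4) * exp(-r / model$r_t)
  }
}

#' @rdname K_theoretical
#' @export
L_minus_r_theoretical <- function(model, r) {
  sqrt(K_theoretical(model, r) / pi) - r
}

#' @rdname K_theoretical
#' @export
pcf_theoretical <- function(model, r) {
  stopifnot(inherits(model, "cluster_model"), all(r >= 0))
  amp <- model_pcf_amplitude(model)
  if (model$family == "ising" && any(r == 0)) {
    warning("the Ising PCF diverges at r = 0; returning Inf there")
    out <- rep(Inf, length(r))
    out[r > 0] <- 1 + amp * pcf_shape(model$family, r[r > 0], model$r_t)
    return(out)
  }
  v <- numeric(length(r))
  pos <- r > 0
  v[pos] <- pcf_shape(model$family, r[pos], model$r_t)
  if (any(!pos)) {
    v[!pos] <- switch(model$family,  # finite r -> 0 limits
                      gaussian = 1, cauchy = 1, vargamma = 1, disk = pi / 2)
  }
  1 + amp * v
}

#' Effective PCF amplitude of a model (including background and count law)
#'
#' The PCF of a model is `1 + B * v(r)` with shape `v` fixed by the family;
#' `B` collects the true amplitude `a_t`, the count-distribution factor and
#' the quadratic background attenuation `beta^2`.
#'
#' @param model A [cluster_model()].
#' @return The dimensionless amplitude `B`.
#' @export
model_pcf_amplitude <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  at <- amp_true(model$family, model$r_t, kappa = model$kappa, a_I = model$a_I)
  cs <- if (is_neyman_scott(model)) count_factor(model$count_dist) else 1
  apply_background(cs * at, model$beta)
}

#' Quadratic effect of a monomer background on the PCF amplitude
#'
#' Superimposing a CSR monomer pattern so that the clustered fraction of
#' points is `beta` leaves the shape of `g - 1` unchanged and multiplies its
#' amplitude by `beta^2`: \eqn{B_e = B \beta^2}.
#'
#' @param B Nonnegative PCF amplitude of the purely clustered process.
#' @param beta Clustered fraction in \[0, 1\].
#' @return The attenuated amplitude `B * beta^2`.
#' @examples
#' apply_background(2, 0.5)  # 0.5
#' @export
apply_background <- function(B, beta) {
  stopifnot(all(B >= 0), all(beta >= 0), all(beta <= 1))
  B * beta^2
}

#' Radial quantile of the offspring kernel
#'
#' Returns the ratio \eqn{u_q} such that a fraction `q` of a cluster's points
#' lie within distance \eqn{u_q r_t} of the cluster center. This converts the
#' model-bound size parameter into the model-free radius \eqn{r_q = u_q r_t}
#' (conceptually akin to a FWHM). Gaussian: \eqn{\sqrt{2\ln(1/(1-q))}}
#' (Rayleigh radial CDF); disk: \eqn{\sqrt q}; Cauchy:
#' \eqn{\sqrt{(1-q)^{-2} - 1}}; variance-Gamma: numeric inversion of the
#' Whittle-Matern(-1/4) radial CDF.
#'
#' @param model A Neyman-Scott [cluster_model()].
#' @param q Fraction in (0, 1).
#' @return The dimensionless ratio \eqn{u_q}.
#' @examples
#' m <- cluster_model("gaussian", 1, kappa = 1)
#' offspring_radial_quantile(m, 0.95)  # sqrt(2 log 20) ~ 2.4477
#' @export
offspring_radial_quantile <- function(model, q) {
  stopifnot(inherits(model, "cluster_model"),
            is.numeric(q), all(q > 0), all(q < 1))
  if (!is_neyman_scott(model))
    stop("the Ising model has no offspring kernel")
  fam <- model$family
  vapply(q, function(qi) {
    if (fam == "vargamma") {
      f <- function(x) vargamma_radial_cdf(x, 1) - qi
      uniroot(f, c(1e-8, 60), tol = 1e-12)$root
    } else {
      f <- function(x) offspring_cdf(fam, x, 1) - qi
      upper <- if (fam == "disk") 1 else 1e6
      uniroot(f, c(1e-12, upper), tol = 1e-12)$root
    }
  }, numeric(1))
}

#' Average number of points per cluster implied by a PCF
#'
#' From the pair correlation function, \eqn{N = \rho \int_0^\infty (g(r) - 1)
#' \, 2\pi r \, dr}. For the exponential approximation
#' \eqn{g_a = 1 + a e^{-r/d}} this is \eqn{N_a = 2\pi a d^2 \rho} (analytic
#' path); for the theoretical PCF of a Neyman-Scott model with Poisson counts
#' and no background it equals \eqn{\rho/\kappa}.
#'
#' @param x A [correlation_curve()] with statistic `"pcf"`, a
#'   [cluster_model()], or an `"exponential_fit"` from
#'   [fit_exponential_lse()].
#' @param rho Point intensity (points per unit area). Defaults to the model
#'   intensity when `x` is a model with `mu` set.
#' @param ... Unused.
#' @return The occupancy `N` (a count).
#' @export
n_per_cluster <- function(x, rho, ...) UseMethod("n_per_cluster")

#' @rdname n_per_cluster
#' @export
n_per_cluster.cluster_model <- function(x, rho = model_intensity(x), ...) {
  amp <- model_pcf_amplitude(x)
  rho * amp * pcf_shape_integral(x$family, x$r_t)
}

#' @rdname n_per_cluster
#' @export
n_per_cluster.exponential_fit <- function(x, rho, ...) {
  2 * pi * x$a * x$d^2 * rho
}

#' @rdname n_per_cluster
#' @export
n_per_cluster.correlation_curve <- function(x, rho, ...) {
  if (x$statistic != "pcf") stop("n_per_cluster needs a PCF curve")
  r <- x$r
  integrand <- (x$value - 1) * 2 * pi * r
  # convergence guard: the tail of (g-1) r must have decayed
  ntail <- max(3L, ceiling(length(r) / 10))
  tail_mean <- mean(abs(integrand[(length(r) - ntail + 1):length(r)]))
  if (tail_mean > 0.01 * max(abs(integrand)))
    stop("PCF tail has not decayed to 1; the occupancy integral does not converge")
  rho * trapz(r, integrand)
}

# trapezoidal rule
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
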