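#' Cluster process models
#'
#' A `cluster_model` names a cluster-generating point process together with its
#' parameters. Four Neyman-Scott (Poisson cluster) families are supported --
#' Poisson parents of intensity `kappa`, each with a random number of offspring
#' (mean `mu`) displaced by a radially symmetric kernel -- plus an Ising form
#' specified directly through its Ornstein-Zernike pair correlation function.
#'
#' The size parameter `r_t` means, per family:
#' \describe{
#'   \item{`gaussian`}{Thomas process; `r_t` is the kernel standard deviation
#'     \eqn{\sigma}.}
#'   \item{`disk`}{Matern cluster process; `r_t` is the disk radius \eqn{R}
#'     (offspring uniform in a disk of radius R).}
#'   \item{`cauchy`}{Bivariate-Cauchy kernel with scale \eqn{\eta}.}
#'   \item{`vargamma`}{Variance-Gamma (Whittle-Matern) kernel with scale
#'     \eqn{\eta} and smoothness -1/4, the unique member of that family whose
#'     cluster PCF is exactly exponential, \eqn{g(r) = 1 + a_t e^{-r/\eta}}.}
#'   \item{`ising`}{Correlation length \eqn{\xi}; the PCF is
#'     \eqn{1 + a_I r^{-1/4} e^{-r/\xi}} with `r` in nanometers (the amplitude
#'     convention is unit-bound, see [ising_amplitude_ratio()]). Not a
#'     Neyman-Scott process: it has no offspring kernel and cannot be
#'     simulated here.}
#' }
#'
#' A monomer (completely spatially random) background can be described by a
#' clustered fraction `beta < 1`; it leaves the shapes of K, L - r and g
#' unchanged and scales the cluster term by `beta^2` (see
#' [apply_background()]).
#'
#' @param family One of `"gaussian"`, `"disk"`, `"cauchy"`, `"vargamma"`,
#'   `"ising"`.
#' @param r_t Positive cluster size parameter (sigma, R, eta or xi).
#' @param kappa Clusters (parents) per unit area; required for Neyman-Scott
#'   families.
#' @param mu Mean number of points per cluster; required for simulation and
#'   intensity bookkeeping, not by the second-order theory (K is independent
#'   of `mu` for Poisson counts).
#' @param count_dist Offspring count distribution, `"poisson"` or
#'   `"geometric"` (geometric on \{0, 1, 2, ...\} with mean `mu`).
#' @param beta Clustered fraction in (0, 1]; 1 means no monomer background.
#' @param a_I Dimensionless Ising amplitude (Ising family only).
#' @return An object of class `"cluster_model"`.
#' @examples
#' thomas <- cluster_model("gaussian", r_t = 0.02, kappa = 25, mu = 40)
#' pcf_theoretical(thomas, c(0.01, 0.05))
#' @export
cluster_model <- function(family = c("gaussian", "disk", "cauchy", "vargamma", "ising"),
                          r_t, kappa = NULL, mu = NULL,
                          count_dist = c("poisson", "geometric"),
                          beta = 1, a_I = NULL) {
  family <- match.arg(family)
  count_dist <- match.arg(count_dist)
  stopifnot(is.numeric(r_t), length(r_t) == 1, is.finite(r_t), r_t > 0)
  stopifnot(is.numeric(beta), length(beta) == 1, beta >= 0, beta <= 1)
  if (family == "ising") {
    if (is.null(a_I)) stop("ising models require the amplitude 'a_I'")
    stopifnot(is.numeric(a_I), a_I > 0)
  } else {
    if (is.null(kappa)) stop("Neyman-Scott models require 'kappa'")
    stopifnot(is.numeric(kappa), kappa > 0)
  }
  if (!is.null(mu)) stopifnot(is.numeric(mu), mu > 0)
  structure(list(family = family, r_t = as.numeric(r_t),
                 kappa = if (is.null(kappa)) NULL else as.numeric(kappa),
                 mu = if (is.null(mu)) NULL else as.numeric(mu),
                 count_dist = count_dist, beta = as.numeric(beta),
                 a_I = if (is.null(a_I)) NULL else as.numeric(a_I)),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster model: %s (r_t = %g", x$family, x$r_t))
  if (!is.null(x$kappa)) cat(sprintf(", kappa = %g", x$kappa))
  if (!is.null(x$a_I)) cat(sprintf(", a_I = %g", x$a_I))
  if (!is.null(x$mu)) cat(sprintf(", mu = %g [%s]", x$mu, x$count_dist))
  if (x$beta < 1) cat(sprintf(", beta = %g", x$beta))
  cat(")\n")
  invisible(x)
}

is_neyman_scott <- function(model) model$family != "ising"

#' Total intensity of a cluster model
#'
#' For a Neyman-Scott model with clustered fraction `beta`, the intensity of
#' the superposed (clustered + monomer) process is `mu * kappa / beta`
#' (`mu * kappa` when `beta = 1`).
#'
#' @param model A [cluster_model()] with `mu` set.
#' @return Points per unit area.
#' @export
model_intensity <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  if (!is_neyman_scott(model)) stop("intensity is not defined by the Ising parameters")
  if (is.null(model$mu)) stop("model has no 'mu'")
  if (model$beta <= 0) stop("beta must be positive to define a total intensity")
  model$mu * model$kappa / model$beta
}

# E[S(S-1)]/mu^2 for the offspring count distribution. The geometric value 2
# follows from E[S(S-1)] = 2 mu^2 for the geometric law on {0,1,2,...}; this
# convention is isolated here.
count_factor <- function(count_dist) {
  switch(count_dist, poisson = 1, geometric = 2,
         stop("unknown count distribution: ", count_dist))
}
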