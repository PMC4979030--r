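#' Radius of maximal aggregation: theory
#'
#' The radius of maximal aggregation \eqn{r_a} is the location of the maximum
#' of \eqn{L(r) - r}. For K-functions of the canonical form
#' \eqn{K(r) = \pi r^2 + H(r)/A}, the stationarity condition
#' \eqn{L'(r_a) - 1 = 0} is equivalent to \eqn{K'(r_a)^2 = 4\pi K(r_a)},
#' which rearranges to
#' \deqn{A = \frac{h(r_a)^2}{4\pi\,(H(r_a) - r_a h(r_a))}.}
#' Hence \eqn{r_a} depends on the cluster density (through `A`) as well as on
#' the size parameter: the ratio \eqn{p = r_a / r_t} is a nonlinear function
#' of the dimensionless product \eqn{\kappa r_t^2} alone, and the singularity
#' of the right-hand side at \eqn{H(r_a) = r_a h(r_a)} yields a model-specific
#' lower bound on `p` (see [p_lower_bound()]).
#'
#' `solve_ra` locates the first interior maximum of `L(r) - r` by scanning
#' the sign of \eqn{K'(r) - 2\sqrt{\pi K(r)}} on a log-spaced grid over
#' `[1e-3, 50] * r_t` and refining with [uniroot()] (tolerance
#' `1e-12 * r_t`).
#'
#' @param model A [cluster_model()].
#' @param q Quantile for the model-free ratio \eqn{p_q = p / u_q}; `NULL` to
#'   skip (and for families without an offspring kernel).
#' @return An object of class `"bias_result"`: list with `family`, `r_a`,
#'   `p`, `p_q`, `q`, `lower_bound_p`, `upper_bound_p` and the model.
#' @examples
#' solve_ra(cluster_model("disk", r_t = 0.02, kappa = 25))
#' @export
solve_ra <- function(model, q = 0.95) {
  stopifnot(inherits(model, "cluster_model"))
  rt <- model$r_t
  phi <- function(r) K_prime_theoretical(model, r) -
    2 * sqrt(pi * K_theoretical(model, r))
  grid <- rt * exp(seq(log(1e-3), log(50), length.out = 600))
  s <- sign(phi(grid))
  flip <- which(s[-1] < 0 & s[-length(s)] > 0)
  if (length(flip) == 0)
    stop("no interior maximum of L(r) - r in the search bracket")
  i <- flip[1]  # first (smallest-r) interior maximum
  r_a <- uniroot(phi, c(grid[i], grid[i + 1]), tol = 1e-12 * rt)$root
  lb <- p_lower_bound(model$family)
  ub <- p_upper_bound(model$family)
  p <- r_a / rt
  p_q <- NULL
  if (!is.null(q) && is_neyman_scott(model))
    p_q <- p / offspring_radial_quantile(model, q)
  structure(list(family = model$family, model = model, r_a = r_a, p = p,
                 q = q, p_q = p_q, lower_bound_p = lb, upper_bound_p = ub),
            class = "bias_result")
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf("radius of maximal aggregation: r_a = %g, p = r_a/r_t = %.6g (bounds %.6g .. %s)\n",
              x$r_a, x$p, x$lower_bound_p,
              if (is.finite(x$upper_bound_p)) format(x$upper_bound_p) else "Inf"))
  if (!is.null(x$p_q))
    cat(sprintf("  p_%g = %.6g\n", x$q, x$p_q))
  invisible(x)
}

#' Model-specific lower bound on p = r_a / r_t
#'
#' The singularity of the stationarity identity at
#' \eqn{H(r) - r h(r) = 0} bounds the radius of maximal aggregation from
#' below, independently of the cluster density: `p_lower_bound` root-finds
#' \eqn{H_d(r) = r h_d(r)} on the pair-distance support (in units of `r_t`,
#' so the result is a pure ratio). For the Gaussian model the equation
#' reduces in closed form to \eqn{e^t = 1 + 2t} with \eqn{t = (r/2\sigma)^2},
#' giving 2.24181...; for the disk model the root is 1.29564....
#'
#' @param family A model family name.
#' @return The dimensionless lower bound for `p`.
#' @examples
#' p_lower_bound("disk")      # 1.29564
#' p_lower_bound("gaussian")  # 2.24181
#' @export
p_lower_bound <- function(family) {
  model <- unit_model(family)
  cf <- canonical_K_form(model)
  f <- function(r) cf$H(r) - r * cf$h(r)
  upper <- if (family == "disk") 2 - 1e-9 else 80
  # f < 0 near 0 (H lags r h while h is increasing), > 0 in the tail; scan for
  # the sign change first -- the closed forms cancel to roundoff near r = 0
  grid <- exp(seq(log(1e-3), log(upper), length.out = 400))
  s <- sign(f(grid))
  flip <- which(s[-1] > 0 & s[-length(s)] < 0)
  if (length(flip) == 0) stop("no singularity root found for family '", family,
                              "'; the lower-bound assumptions fail")
  i <- flip[1]
  uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-12)$root
}

#' @rdname p_lower_bound
#' @export
p_upper_bound <- function(family) {
  # the disk pair distance has bounded support, capping r_a at 2R;
  # the other families are unbounded above
  if (family == "disk") 2 else Inf
}

unit_model <- function(family) {
  if (family == "ising") cluster_model("ising", r_t = 1, a_I = 1)
  else cluster_model(family, r_t = 1, kappa = 1)
}

#' Convert p to the model-free ratio p_q
#'
#' \eqn{p_q = p / u_q}, where \eqn{u_q} is the offspring radial quantile
#' ratio ([offspring_radial_quantile()]): the radius of maximal aggregation
#' expressed relative to the radius containing a fraction `q` of the
#' cluster's points rather than to the model-bound size parameter.
#'
#' @param result A `"bias_result"` from [solve_ra()], or a bare `p` value.
#' @param q Fraction in (0, 1).
#' @param model Required when `result` is a bare number.
#' @return The dimensionless ratio \eqn{p_q}.
#' @export
p_to_pq <- function(result, q, model = NULL) {
  if (inherits(result, "bias_result")) {
    model <- result$model
    p <- result$p
  } else {
    stopifnot(is.numeric(result), !is.null(model))
    p <- result
  }
  p / offspring_radial_quantile(model, q)
}

#' Map the bias ratio p over a parameter grid
#'
#' Evaluates [solve_ra()] over the cross of `kappa_grid` and `rt_grid`. `p`
#' depends on `(kappa, r_t)` only through the dimensionless product
#' `kappa * r_t^2`, which is reported alongside.
#'
#' @param family A Neyman-Scott family name (or `"ising"`, in which case
#'   `kappa_grid` is interpreted as the amplitude `a_I`).
#' @param kappa_grid,rt_grid Positive parameter grids.
#' @param q Quantile for `p_q` (`NULL` to skip).
#' @return A data frame with one row per grid cell: parameters,
#'   `kappa_rt2`, `r_a`, `p`, `p_q`, bounds and a `flag` column
#'   (`"ok"` or `"no-maximum"`).
#' @export
bias_map <- function(family, kappa_grid, rt_grid, q = 0.95) {
  grid <- expand.grid(kappa = kappa_grid, r_t = rt_grid, KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0) {
    return(data.frame(family = character(), kappa = numeric(), r_t = numeric(),
                      kappa_rt2 = numeric(), r_a = numeric(), p = numeric(),
                      p_q = numeric(), lower_bound_p = numeric(),
                      upper_bound_p = numeric(), flag = character()))
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    kap <- grid$kappa[i]; rt <- grid$r_t[i]
    model <- if (family == "ising")
      cluster_model("ising", r_t = rt, a_I = kap)
    else cluster_model(family, r_t = rt, kappa = kap)
    res <- tryCatch(solve_ra(model, q = if (is_neyman_scott(model)) q else NULL),
                    error = function(e) NULL)
    if (is.null(res)) {
      data.frame(family = family, kappa = kap, r_t = rt, kappa_rt2 = kap * rt^2,
                 r_a = NA_real_, p = NA_real_, p_q = NA_real_,
                 lower_bound_p = p_lower_bound(family),
                 upper_bound_p = p_upper_bound(family), flag = "no-maximum")
    } else {
      data.frame(family = family, kappa = kap, r_t = rt, kappa_rt2 = kap * rt^2,
                 r_a = res$r_a, p = res$p,
                 p_q = if (is.null(res$p_q)) NA_real_ else res$p_q,
                 lower_bound_p = res$lower_bound_p,
                 upper_bound_p = res$upper_bound_p, flag = "ok")
    }
  })
  do.call(rbind, rows)
}

#' Radius of maximal aggregation of the normalized-K statistic
#'
#' Builds the theoretical K of the family on a dense grid, normalizes it by
#' the CSR standard deviation for `n_points` points in a square window of
#' side `window_ratio * r_t`, and locates the maximum. As the window grows,
#' the normalizer tends to a multiple of `r`, so the maximizer converges to
#' the maximizer of `H_d(r)/r` -- which is exactly the root of
#' `H_d(r) = r h_d(r)`, i.e. the L-based lower bound of `p` ([p_lower_bound()]).
#' At moderate window ratios the location depends on `n_points` (but never on
#' `kappa` or `beta`, which scale the statistic without moving its maximum).
#'
#' @param family Model family.
#' @param r_t True size parameter.
#' @param n_points Number of points entering the normalizer.
#' @param window_ratio Side of the square window divided by `r_t`.
#' @param n_grid Grid resolution.
#' @return A list with `r_tilde_a`, `ratio` (`r_tilde_a / r_t`) and
#'   `boundary` flag.
#' @export
normalized_ra <- function(family, r_t, n_points, window_ratio, n_grid = 4000) {
  stopifnot(window_ratio > 0, n_points >= 2)
  model <- if (family == "ising") cluster_model("ising", r_t = r_t, a_I = 1)
           else cluster_model(family, r_t = r_t, kappa = 1 / r_t^2)
  side <- window_ratio * r_t
  window <- cc_window(side)
  r_hi <- min(side / 2, 8 * r_t)
  r <- seq(r_hi / n_grid, r_hi, length.out = n_grid)
  K <- correlation_curve(r, K_theoretical(model, r), "K")
  res <- normalized_K(K, window, n_points, r_t = r_t)
  list(r_tilde_a = res$r_tilde_a, ratio = res$r_tilde_a / r_t,
       boundary = res$boundary)
}
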