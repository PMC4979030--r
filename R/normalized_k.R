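#' CSR standard deviation of the K estimator
#'
#' Approximation to the standard deviation of the translation-corrected
#' Ripley K estimator under complete spatial randomness with `n` points in a
#' rectangular window of area `A` and perimeter `P`:
#' \deqn{\mathrm{Var}\,\hat K(r) = \frac{2 A^2 \beta_r}{n^2}
#'   \left(1 + 0.305\gamma_r + \beta_r(-1 + 0.0415\, n \gamma_r)\right),}
#' with \eqn{\beta_r = \pi r^2 / A} and \eqn{\gamma_r = P r / A}. This is the
#' normalizer used by the variance-normalized K statistic; it is isolated
#' here as the single place the approximation enters.
#'
#' @param r Distances (`r > 0`; the normalizer vanishes at 0).
#' @param n Number of points.
#' @param area,perimeter Window area and perimeter.
#' @return Standard deviations, same length as `r`.
#' @export
csr_k_sd <- function(r, n, area, perimeter) {
  stopifnot(n >= 2, area > 0, perimeter > 0, all(r >= 0))
  beta_r <- pi * r^2 / area
  gamma_r <- perimeter * r / area
  v <- (2 * area^2 * beta_r / n^2) *
    (1 + 0.305 * gamma_r + beta_r * (-1 + 0.0415 * n * gamma_r))
  sqrt(pmax(v, 0))
}

#' Variance-normalized K statistic
#'
#' Normalizes a K curve (empirical or theoretical) by the CSR standard
#' deviation of the K estimator: \eqn{(K(r) - \pi r^2) / c(r, n, A, P)}.
#' Unlike \eqn{L(r) - r}, the location of the maximum of this statistic
#' depends on the number of points `n` and on the window size, but not on the
#' cluster density `kappa` or the clustered fraction `beta` (both only scale
#' the curve).
#'
#' @param K A [correlation_curve()] with statistic `"K"`, evaluated on a grid
#'   starting at `r > 0` (the normalizer vanishes at the origin).
#' @param window The observation window ([cc_window()]).
#' @param n_points Number of points entering the normalizer.
#' @param r_t Optional true size parameter; when given, the window ratio
#'   (shorter side / `r_t`) and `r_tilde_a / r_t` are reported.
#' @return An object of class `"normalized_k_result"`: list with the
#'   normalized `curve`, the refined argmax `r_tilde_a`, its `boundary` flag,
#'   `n_points`, and `window_ratio` (`NULL` without `r_t`).
#' @export
normalized_K <- function(K, window, n_points, r_t = NULL) {
  stopifnot(inherits(K, "correlation_curve"), K$statistic == "K",
            inherits(window, "cc_window"), n_points >= 2)
  r <- K$r
  pos <- r > 0
  r <- r[pos]
  sd <- csr_k_sd(r, n_points, window_area(window), window_perimeter(window))
  value <- (K$value[pos] - pi * r^2) / sd
  curve <- correlation_curve(r, value, "normalized_K",
                             meta = c(K$meta, list(n_points = n_points)))
  peak <- empirical_ra(curve)
  structure(list(curve = curve, r_tilde_a = peak$r_a, boundary = peak$boundary,
                 n_points = n_points,
                 window_ratio = if (is.null(r_t)) NULL else
                   min(window$width, window$height) / r_t),
            class = "normalized_k_result")
}

#' @export
print.normalized_k_result <- function(x, ...) {
  cat(sprintf("normalized-K: r_tilde_a = %g (n = %d%s)%s\n",
              x$r_tilde_a, x$n_points,
              if (is.null(x$window_ratio)) "" else
                sprintf(", window ratio %g", x$window_ratio),
              if (x$boundary) " [boundary maximum]" else ""))
  invisible(x)
}
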