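#' Configuration for the empirical summary estimators
#'
#' @param r_max Largest evaluated distance; defaults to a quarter of the
#'   shorter window side (maxima of interest sit well inside the window) and
#'   must not exceed half of it.
#' @param n_bins Number of grid bins (at least 16; default 512).
#' @param edge_correction `"translation"` (default; exactly computable for
#'   rectangles) or `"none"`.
#' @param bandwidth Kernel bandwidth for the pair-correlation estimator;
#'   `NULL` applies the Stoyan-type rule of thumb `0.15 / sqrt(rho_hat)`.
#' @return An object of class `"estimator_config"`.
#' @export
estimator_config <- function(r_max = NULL, n_bins = 512,
                             edge_correction = c("translation", "none"),
                             bandwidth = NULL) {
  edge_correction <- match.arg(edge_correction)
  stopifnot(n_bins >= 16)
  if (!is.null(r_max)) stopifnot(is.numeric(r_max), r_max > 0)
  if (!is.null(bandwidth)) stopifnot(is.numeric(bandwidth), bandwidth > 0)
  structure(list(r_max = r_max, n_bins = as.integer(n_bins),
                 edge_correction = edge_correction, bandwidth = bandwidth),
            class = "estimator_config")
}

resolve_rmax <- function(config, window) {
  short <- min(window$width, window$height)
  r_max <- config$r_max %||% (short / 4)
  if (r_max > short / 2 + 1e-12)
    stop("r_max must not exceed half the shorter window side")
  r_max
}

# unordered pair distances and translation-correction weights 1/T(dx, dy),
# where T is the overlap area of the window with its shifted copy
pair_data <- function(pattern, edge_correction = "translation", r_max = Inf) {
  xy <- cbind(pattern$x, pattern$y)
  d <- as.numeric(dist(xy))
  if (edge_correction == "translation") {
    dx <- as.numeric(dist(pattern$x))
    dy <- as.numeric(dist(pattern$y))
    w <- 1 / ((pattern$window$width - dx) * (pattern$window$height - dy))
  } else {
    w <- rep(1 / window_area(pattern$window), length(d))
  }
  keep <- d <= r_max
  list(d = d[keep], w = w[keep])
}

#' Empirical Ripley K, Besag L(r) - r and pair correlation function
#'
#' The K estimator is the translation-corrected
#' \deqn{\hat K(r) = \frac{A^2}{n(n-1)} \sum_{i \ne j}
#'   \frac{1(d_{ij} \le r)}{T(x_i - x_j)},}
#' where `T(v) = (width - |v_x|)(height - |v_y|)` is the area of the overlap
#' of the window with its copy shifted by the pair difference `v`; with this
#' normalization \eqn{E \hat K(r) = \pi r^2} under CSR.
#' \eqn{\hat L(r) - r = \sqrt{\hat K(r)/\pi} - r}. The pair correlation
#' estimator smooths the same weighted pair counts with an Epanechnikov
#' kernel:
#' \deqn{\hat g(r) = \frac{A^2}{2\pi r \, n(n-1)} \sum_{i \ne j}
#'   \frac{k_h(r - d_{ij})}{T(x_i - x_j)}.}
#'
#' @param pattern A [point_pattern()] with at least two points.
#' @param config An [estimator_config()].
#' @return A [correlation_curve()] of the corresponding statistic, evaluated
#'   on `n_bins` equal-width bins up to `r_max`.
#' @examples
#' pp <- simulate_csr(500, cc_window(1), seed = 7)
#' K <- estimate_K(pp, estimator_config(n_bins = 64))
#' @export
estimate_K <- function(pattern, config = estimator_config()) {
  stopifnot(inherits(pattern, "point_pattern"), inherits(config, "estimator_config"))
  n <- npoints(pattern)
  if (n < 2) stop("at least two points are required")
  r_max <- resolve_rmax(config, pattern$window)
  breaks <- seq(0, r_max, length.out = config$n_bins + 1)
  pd <- pair_data(pattern, config$edge_correction, r_max)
  bin <- findInterval(pd$d, breaks, rightmost.closed = TRUE, left.open = TRUE)
  bin[bin < 1] <- 1  # coincident points fall in the first bin
  wsum <- vapply(seq_len(config$n_bins),
                 function(b) 0, numeric(1))
  if (length(pd$d) > 0) {
    agg <- rowsum(pd$w, group = bin)
    wsum[as.integer(rownames(agg))] <- agg[, 1]
  }
  A <- window_area(pattern$window)
  K <- 2 * A^2 * cumsum(wsum) / (n * (n - 1))
  correlation_curve(breaks[-1], K, "K",
                    meta = list(n_points = n, edge = config$edge_correction,
                                source = "empirical"))
}

#' @rdname estimate_K
#' @export
estimate_L_minus_r <- function(pattern, config = estimator_config()) {
  K <- estimate_K(pattern, config)
  correlation_curve(K$r, sqrt(K$value / pi) - K$r, "L_minus_r", meta = K$meta)
}

#' @rdname estimate_K
#' @export
estimate_pcf <- function(pattern, config = estimator_config()) {
  stopifnot(inherits(pattern, "point_pattern"), inherits(config, "estimator_config"))
  n <- npoints(pattern)
  if (n < 2) stop("at least two points are required")
  r_max <- resolve_rmax(config, pattern$window)
  h <- config$bandwidth %||% (0.15 / sqrt(pattern_intensity(pattern)))
  if (h <= 0) stop("bandwidth must be positive")
  r_grid <- seq(r_max / config$n_bins, r_max, length.out = config$n_bins)
  pd <- pair_data(pattern, config$edge_correction, r_max + h)
  ord <- order(pd$d)
  ds <- pd$d[ord]
  ws <- pd$w[ord]
  A <- window_area(pattern$window)
  const <- 2 * A^2 / (n * (n - 1) * 2 * pi)
  g <- vapply(r_grid, function(r) {
    lo <- findInterval(r - h, ds) + 1
    hi <- findInterval(r + h, ds)
    if (hi < lo) return(0)
    u <- (r - ds[lo:hi]) / h
    kern <- 0.75 * (1 - u^2) / h  # Epanechnikov
    const * sum(ws[lo:hi] * kern) / r
  }, numeric(1))
  correlation_curve(r_grid, pmax(g, 0), "pcf",
                    meta = list(n_points = n, bandwidth = h,
                                edge = config$edge_correction,
                                source = "empirical"))
}

#' Radius of maximal aggregation of a tabulated curve
#'
#' Returns the location of the maximum of an `L_minus_r` (or `normalized_K`)
#' curve, refined by fitting a quadratic through the maximal bin and its two
#' neighbors. Ties break toward smaller `r`; a maximum attained at either end
#' of the grid is flagged as a boundary maximum (no interior peak).
#'
#' @param curve A [correlation_curve()] of statistic `"L_minus_r"` or
#'   `"normalized_K"`.
#' @return A list with elements `r_a` (the refined argmax), `value` (the
#'   curve maximum) and `boundary` (logical flag).
#' @export
empirical_ra <- function(curve) {
  stopifnot(inherits(curve, "correlation_curve"))
  if (!curve$statistic %in% c("L_minus_r", "normalized_K"))
    stop("the radius of maximal aggregation is defined on L(r) - r or normalized-K curves")
  r <- curve$r; v <- curve$value
  i <- which.max(v)
  if (i == 1L || i == length(v)) {
    return(list(r_a = r[i], value = v[i], boundary = TRUE))
  }
  # quadratic through (r[i-1], r[i], r[i+1])
  d1 <- r[i] - r[i - 1]; d2 <- r[i] - r[i + 1]
  n1 <- d1^2 * (v[i] - v[i + 1]) - d2^2 * (v[i] - v[i - 1])
  n2 <- d1 * (v[i] - v[i + 1]) - d2 * (v[i] - v[i - 1])
  r_star <- if (abs(n2) < .Machine$double.eps) r[i] else r[i] - 0.5 * n1 / n2
  list(r_a = r_star, value = v[i], boundary = FALSE)
}
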