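#' Tabulated correlation curves
#'
#' A `correlation_curve` is a tabulated function of inter-point distance:
#' Ripley's K, Besag's L(r) - r, the pair correlation function g, or the
#' variance-normalized K statistic.
#'
#' @param r Strictly increasing nonnegative distances.
#' @param value Function values at `r`.
#' @param statistic One of `"K"`, `"L_minus_r"`, `"pcf"`, `"normalized_K"`.
#' @param meta Optional named list of provenance (family, parameters, ...).
#' @return An object of class `"correlation_curve"`.
#' @export
correlation_curve <- function(r, value,
                              statistic = c("K", "L_minus_r", "pcf", "normalized_K"),
                              meta = list()) {
  statistic <- match.arg(statistic)
  stopifnot(is.numeric(r), is.numeric(value), length(r) == length(value),
            length(r) >= 2, all(is.finite(r)), all(r >= 0), all(diff(r) > 0))
  if (statistic == "K") {
    if (any(value < -1e-12)) stop("K values must be nonnegative")
    if (any(diff(value) < -1e-8 * max(abs(value))))
      stop("K values must be nondecreasing")
  }
  if (statistic == "pcf" && any(value < 0)) stop("pcf values must be nonnegative")
  structure(list(r = as.numeric(r), value = as.numeric(value),
                 statistic = statistic, meta = meta),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("correlation curve: %s on r in [%g, %g] (%d points)\n",
              x$statistic, min(x$r), max(x$r), length(x$r)))
  invisible(x)
}

#' @export
plot.correlation_curve <- function(x, ...) {
  ylab <- switch(x$statistic, K = "K(r)", L_minus_r = "L(r) - r",
                 pcf = "g(r)", normalized_K = "normalized K")
  plot(x$r, x$value, type = "l", xlab = "r", ylab = ylab, ...)
  invisible(x)
}

#' Tabulate a theoretical summary curve for a cluster model
#'
#' @param model A [cluster_model()].
#' @param statistic `"K"`, `"L_minus_r"` or `"pcf"`.
#' @param r Evaluation grid (strictly increasing, nonnegative; the Ising pcf
#'   needs `r > 0`).
#' @return A [correlation_curve()].
#' @export
theory_curve <- function(model, statistic = c("K", "L_minus_r", "pcf"), r) {
  statistic <- match.arg(statistic)
  value <- switch(statistic,
                  K = K_theoretical(model, r),
                  L_minus_r = L_minus_r_theoretical(model, r),
                  pcf = pcf_theoretical(model, r))
  correlation_curve(r, value, statistic,
                    meta = list(family = model$family, r_t = model$r_t,
                                kappa = model$kappa, a_I = model$a_I,
                                beta = model$beta, source = "theory"))
}

#' Canonical K-function decomposition
#'
#' Every model handled here has \eqn{K(r) = \pi r^2 + H(r)/A} with `H`
#' nondecreasing, `H(0) = 0`, `h = H'` and `A > 0` (`A` is the cluster
#' density `kappa` for Neyman-Scott families, and `1/a_I` for the Ising
#' form). The radius-of-maximal-aggregation theory ([solve_ra()],
#' [p_lower_bound()]) works on this decomposition.
#'
#' @param model A [cluster_model()].
#' @return A list with functions `H(r)`, `h(r)` and the scale factor `A`.
#' @export
canonical_K_form <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  b2 <- model$beta^2
  if (is_neyman_scott(model)) {
    cs <- count_factor(model$count_dist)
    fam <- model$family; rt <- model$r_t
    list(H = function(r) b2 * cs * pair_cdf_raw(fam, r, rt),
         h = function(r) b2 * cs * pair_pdf_raw(fam, r, rt),
         A = model$kappa)
  } else {
    xi <- model$r_t
    list(H = function(r) b2 * 2 * pi * xi^(7 / 4) * gamma(7 / 4) *
           stats::pgamma(r / xi, shape = 7 / 4),
         h = function(r) b2 * 2 * pi * r^(3 / 4) * exp(-r / xi),
         A = 1 / model$a_I)
  }
}

#' Read and write correlation curves as two-column CSV
#'
#' The file holds comment lines (`# key=value`) naming the statistic and any
#' provenance, then a `r,value` table.
#'
#' @param curve A [correlation_curve()].
#' @param path File path.
#' @return `write_curve_csv` returns `path` invisibly; `read_curve_csv`
#'   returns a [correlation_curve()].
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# statistic=%s", curve$statistic), con)
  for (nm in names(curve$meta)) {
    val <- curve$meta[[nm]]
    if (!is.null(val) && length(val) == 1 && !is.na(val))
      writeLines(sprintf("# %s=%s", nm, format(val, digits = 15)), con)
  }
  writeLines("r,value", con)
  writeLines(sprintf("%.15g,%.15g", curve$r, curve$value), con)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in hdr) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  statistic <- meta$statistic %||% "K"
  meta$statistic <- NULL
  tab <- read.csv(textConnection(lines[!grepl("^#", lines)]))
  correlation_curve(tab$r, tab$value, statistic, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
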