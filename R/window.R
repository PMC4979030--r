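#' Rectangular observation window
#'
#' Observation windows are axis-aligned rectangles `[0, width] x [0, height]`.
#' The area and perimeter enter the CSR variance normalizer of the
#' normalized-K statistic (see [csr_k_sd()]).
#'
#' @param width,height Positive side lengths, in the coordinate unit of the
#'   point pattern (the package is unit-agnostic except for the Ising
#'   amplitude convention, which is tied to nanometers).
#' @return An object of class `"cc_window"` with fields `width` and `height`.
#' @examples
#' w <- cc_window(1, 1)
#' window_area(w)
#' window_perimeter(w)
#' @export
cc_window <- function(width, height = width) {
  stopifnot(is.numeric(width), is.numeric(height),
            length(width) == 1, length(height) == 1,
            is.finite(width), is.finite(height),
            width > 0, height > 0)
  structure(list(width = as.numeric(width), height = as.numeric(height)),
            class = "cc_window")
}

#' @rdname cc_window
#' @param window A `"cc_window"` object.
#' @export
window_area <- function(window) {
  stopifnot(inherits(window, "cc_window"))
  window$width * window$height
}

#' @rdname cc_window
#' @export
window_perimeter <- function(window) {
  stopifnot(inherits(window, "cc_window"))
  2 * (window$width + window$height)
}

#' @export
print.cc_window <- function(x, ...) {
  cat(sprintf("window: [0, %g] x [0, %g] (area %g, perimeter %g)\n",
              x$width, x$height, window_area(x), window_perimeter(x)))
  invisible(x)
}
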