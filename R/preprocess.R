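#' Autolevels brightness normalization
#'
#' Percentile-clipped linear contrast stretch: pixels at or below the
#' `low` percentile map to the bottom of `output_range`, pixels at or above
#' the `high` percentile map to its top, linear in between. Applied per frame
#' before classification so that positive affine changes of illumination
#' (gain and offset) produce identical normalized images — the property the
#' downstream texture classifier relies on.
#'
#' A constant (degenerate) frame is returned as a constant mid-range frame
#' rather than raising an error.
#'
#' @param image numeric matrix (any intensity scale).
#' @param low,high clipping percentiles, `0 <= low < high <= 100`
#'   (defaults 1 and 99).
#' @param output_range length-2 numeric output bounds (default full 16-bit).
#' @return numeric matrix of the same dimension, integer-valued on
#'   `output_range`.
#' @export
autolevels <- function(image, low = 1, high = 99,
                       output_range = c(0, 65535)) {
  stopifnot(is.matrix(image), length(image) > 0,
            low >= 0, high <= 100, low < high,
            length(output_range) == 2, output_range[1] < output_range[2])
  q <- stats::quantile(image, c(low, high) / 100, names = FALSE)
  lo <- output_range[1]; hi <- output_range[2]
  if (q[2] <= q[1]) {
    out <- image
    out[] <- round((lo + hi) / 2)
    return(out)
  }
  out <- (image - q[1]) / (q[2] - q[1]) * (hi - lo) + lo
  out[] <- pmin(pmax(round(out), lo), hi)
  out
}
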