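#' @importFrom EBImage bwlabel fillHull erode dilate makeBrush otsu
#' @importFrom Matrix bandSparse rowSums
NULL

INTENSITY_MAX <- 65535

#' Label connected components of a binary mask (8-connectivity)
#'
#' Diagonal-touching foreground pixels belong to the same component, matching
#' the connectivity used throughout the detection stage. Labels are positive
#' integers ordered by first (column-major) occurrence.
#'
#' @param mask logical or 0/1 numeric matrix.
#' @return integer matrix of the same dimension; 0 is background.
#' @export
label_components <- function(mask) {
  m <- (as.matrix(mask) > 0) * 1
  if (!any(m > 0)) return(matrix(0L, nrow(m), ncol(m)))
  lab <- bwlabel(m)  # 4-connected first pass
  n <- max(lab)
  if (n > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    # diagonal adjacencies between distinct 4-connected labels
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
    a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]
    keep1 <- a1 > 0 & b1 > 0 & a1 != b1
    keep2 <- a2 > 0 & b2 > 0 & a2 != b2
    pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    if (nrow(pairs)) {
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
    root <- vapply(seq_len(n), find, integer(1))
    lab[] <- c(0L, root)[lab + 1L]
  }
  # relabel consecutively in order of first occurrence
  u <- unique(as.vector(lab)); u <- u[u > 0]
  new_id <- integer(max(lab)); new_id[u] <- seq_along(u)
  out <- lab
  out[] <- ifelse(lab > 0, new_id[pmax(lab, 1)], 0L)
  storage.mode(out) <- "integer"
  out
}

#' Separable Gaussian blur of a matrix
#'
#' Edge weights are renormalized at the borders (replicate-style boundary),
#' so a constant matrix stays constant. Kernel radius is clipped to the image
#' size, which keeps the operation defined on small masks.
#'
#' @param x numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return numeric matrix of the same dimension.
#' @export
blur_gaussian <- function(x, sigma) {
  stopifnot(is.matrix(x), sigma >= 0)
  if (sigma == 0) return(x)
  band <- function(n) {
    r <- min(ceiling(3 * sigma), n - 1L)
    k <- stats::dnorm(seq(-r, r), sd = sigma)
    B <- bandSparse(n, n, -r:r,
                    diagonals = lapply(-r:r, function(d) rep(k[d + r + 1], n - abs(d))))
    B / Matrix::rowSums(B)
  }
  Br <- band(nrow(x)); Bc <- band(ncol(x))
  as.matrix(Br %*% x %*% Matrix::t(Bc))
}

disc_brush <- function(radius) {
  if (radius < 1) return(matrix(1, 1, 1))
  makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

erode_mask <- function(mask, radius) {
  if (radius < 1) return(mask > 0)
  erode((mask > 0) * 1, disc_brush(radius)) > 0
}

dilate_mask <- function(mask, radius) {
  if (radius < 1) return(mask > 0)
  dilate((mask > 0) * 1, disc_brush(radius)) > 0
}

#' Summed-area table window sums
#'
#' Returns the matrix of sums of all `h x w` windows of `x` at every top-left
#' position, computed via an integral image.
#' @noRd
window_sums <- function(x, h, w) {
  nr <- nrow(x); nc <- ncol(x)
  stopifnot(h <= nr, w <= nc)
  S <- apply(apply(x, 2, cumsum), 1, cumsum)  # transposed integral image
  S <- t(S)
  Sp <- matrix(0, nr + 1, nc + 1)
  Sp[-1, -1] <- S
  i <- seq_len(nr - h + 1); j <- seq_len(nc - w + 1)
  Sp[i + h, j + w, drop = FALSE] - Sp[i, j + w, drop = FALSE] -
    Sp[i + h, j, drop = FALSE] + Sp[i, j, drop = FALSE]
}

clamp16 <- function(x) pmin(pmax(round(x), 0), INTENSITY_MAX)
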