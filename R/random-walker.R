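#' Semi-supervised random-walker segmentation
#'
#' Assigns every unlabeled pixel the probability that a random walk started
#' there, on the 4-connected pixel lattice with edge weights
#' `w = exp(-beta * (dI)^2)` (intensities normalized to [0, 1]), reaches each
#' seed label first. This is the combinatorial Dirichlet problem: the
#' probabilities solve `L_UU x = -L_US m` for each label indicator `m`, where
#' `L` is the graph Laplacian split over unlabeled (U) and seeded (S) pixels.
#' Each pixel's label is the argmax probability; seeds keep their labels.
#'
#' @param image numeric intensity matrix.
#' @param seeds integer matrix, same dimension; 0 = unlabeled, positive
#'   integers are seed labels. At least two distinct labels required.
#' @param beta edge-weight sharpness (default 130).
#' @param tol maximum acceptable residual of the linear solve (default 1e-6).
#' @param roi optional logical matrix restricting the graph; pixels outside
#'   are ignored (treated as absent) and returned as label 0.
#' @return list with `labels` (integer matrix), `prob` (named list of
#'   per-label probability matrices; rows of probabilities over labels sum to
#'   1 on in-graph pixels) and `labels_set`.
#' @export
random_walker <- function(image, seeds, beta = 130, tol = 1e-6, roi = NULL) {
  stopifnot(is.matrix(image), all(dim(image) == dim(seeds)), beta > 0)
  h <- nrow(image); w <- ncol(image)
  seeds <- matrix(as.integer(seeds), h, w)
  if (is.null(roi)) roi <- matrix(TRUE, h, w)
  stopifnot(all(dim(roi) == dim(image)))
  labs <- sort(unique(seeds[seeds > 0 & roi]))
  if (length(labs) < 2)
    stop("random_walker needs at least 2 distinct seed labels")

  rng <- range(image)
  img <- if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1]) else image * 0

  idx <- matrix(0L, h, w)
  idx[roi] <- seq_len(sum(roi))
  n <- sum(roi)

  edge_list <- function(di, dj) {
    i1 <- seq_len(h - di); j1 <- seq_len(w - dj)
    a <- idx[i1, j1, drop = FALSE]; b <- idx[i1 + di, j1 + dj, drop = FALSE]
    keep <- a > 0 & b > 0
    wgt <- exp(-beta * (img[i1, j1, drop = FALSE] -
                        img[i1 + di, j1 + dj, drop = FALSE])^2) + 1e-10
    cbind(a[keep], b[keep], wgt[keep])
  }
  E <- rbind(edge_list(1L, 0L), edge_list(0L, 1L))

  W <- Matrix::sparseMatrix(i = c(E[, 1], E[, 2]), j = c(E[, 2], E[, 1]),
                            x = c(E[, 3], E[, 3]), dims = c(n, n))
  d <- Matrix::rowSums(W)
  L <- Matrix::Diagonal(n, d) - W

  seeded <- seeds > 0 & roi
  s_idx <- idx[seeded]
  u_idx <- setdiff(seq_len(n), s_idx)
  s_lab <- seeds[seeded]

  prob <- lapply(labs, function(l) matrix(NA_real_, h, w))
  names(prob) <- as.character(labs)

  if (length(u_idx) > 0) {
    Luu <- L[u_idx, u_idx, drop = FALSE]
    Lus <- L[u_idx, s_idx, drop = FALSE]
    M <- vapply(labs[-length(labs)], function(l) as.numeric(s_lab == l),
                numeric(length(s_lab)))
    B <- -Lus %*% M
    X <- as.matrix(Matrix::solve(Luu, B))
    resid <- max(abs(Luu %*% X - B))
    if (is.finite(resid) && resid > tol)
      stop("random_walker linear solve residual ", format(resid),
           " exceeds tolerance ", format(tol))
    X <- cbind(X, 1 - rowSums(X))
  } else {
    X <- matrix(numeric(0), 0, length(labs))
  }

  roi_pos <- which(roi)
  for (k in seq_along(labs)) {
    pm <- matrix(NA_real_, h, w)
    v <- numeric(n)
    v[u_idx] <- X[, k]
    v[s_idx] <- as.numeric(s_lab == labs[k])
    pm[roi_pos] <- v
    prob[[k]] <- pm
  }

  lab_map <- matrix(0L, h, w)
  P <- vapply(prob, function(m) m[roi_pos], numeric(length(roi_pos)))
  if (length(roi_pos) == 1L) P <- matrix(P, nrow = 1)
  lab_map[roi_pos] <- labs[max.col(P, ties.method = "first")]
  lab_map[seeded] <- seeds[seeded]

  list(labels = lab_map, prob = prob, labels_set = labs)
}
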