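#' Sliding-window scan of a frame
#'
#' Slides the fixed detection window from the top-left corner across the frame
#' at the given stride and scores every position with the patch classifier,
#' producing a grid of P(iPSC) values. The right/bottom remainder smaller than
#' one window is not scored (no padding); the grid has
#' `floor((H - window)/stride) + 1` rows and the analogous number of columns.
#'
#' @param model a `patch_classifier`.
#' @param frame numeric matrix, already brightness-normalized (see
#'   [autolevels()]); must be at least `window` in both dimensions.
#' @param window window side (default 96).
#' @param stride step in pixels (default 96, non-overlapping tiling).
#' @return object of class `score_map`: list with `scores` (grid matrix),
#'   `window`, `stride`, `frame_dim`.
#' @export
scan_frame <- function(model, frame, window = 96L, stride = 96L) {
  stopifnot(is.matrix(frame))
  window <- as.integer(window); stride <- as.integer(stride)
  if (nrow(frame) < window || ncol(frame) < window)
    stop("frame smaller than the detection window")
  ys <- seq(1L, nrow(frame) - window + 1L, by = stride)
  xs <- seq(1L, ncol(frame) - window + 1L, by = stride)
  feats <- matrix(0, length(ys) * length(xs), 10)
  k <- 0L
  for (xj in xs) for (yi in ys) {
    k <- k + 1L
    feats[k, ] <- patch_features(frame[yi:(yi + window - 1L),
                                       xj:(xj + window - 1L)], window)
  }
  p <- predict_features(model, feats)
  structure(list(scores = matrix(p, length(ys), length(xs)),
                 window = window, stride = stride,
                 frame_dim = dim(frame)),
            class = "score_map")
}

#' Binarize a score map to pixel resolution
#'
#' A pixel is set when any window covering it scores at or above the
#' threshold (union rule). With stride equal to the window size the windows
#' tile the scored area and each pixel is decided by exactly one window.
#'
#' @param smap a `score_map`.
#' @param threshold probability cutoff (default 0.5).
#' @return logical matrix with the source frame's dimensions.
#' @export
binarize <- function(smap, threshold = 0.5) {
  stopifnot(inherits(smap, "score_map"))
  out <- matrix(FALSE, smap$frame_dim[1], smap$frame_dim[2])
  pass <- which(smap$scores >= threshold, arr.ind = TRUE)
  w <- smap$window; s <- smap$stride
  for (k in seq_len(nrow(pass))) {
    y0 <- (pass[k, 1] - 1L) * s + 1L
    x0 <- (pass[k, 2] - 1L) * s + 1L
    out[y0:(y0 + w - 1L), x0:(x0 + w - 1L)] <- TRUE
  }
  out
}

#' Post-process a binary detection map
#'
#' Fixed order: fill enclosed holes, Gaussian-blur the 0/1 mask, re-binarize
#' at `rebin_threshold`, then discard 8-connected components smaller than
#' `min_area_px` (the sparse residuals counted as noise). Defaults: sigma half
#' a window, re-binarization at 0.5, minimum area one window.
#'
#' @param bmap logical matrix from [binarize()].
#' @param sigma Gaussian standard deviation in px (default 48).
#' @param rebin_threshold threshold on the blurred mask (default 0.5).
#' @param min_area_px minimum component area kept (default 96^2).
#' @return logical matrix.
#' @export
postprocess_map <- function(bmap, sigma = 48, rebin_threshold = 0.5,
                            min_area_px = 96^2) {
  m <- (as.matrix(bmap) > 0) * 1
  if (!any(m > 0)) return(m > 0)
  m <- fillHull(m)
  if (sigma > 0) m <- (blur_gaussian(m, sigma) >= rebin_threshold) * 1
  lab <- label_components(m)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < min_area_px)
    if (length(drop)) m[lab %in% drop] <- 0
  }
  m > 0
}

#' Extract colony regions from a post-processed binary map
#'
#' 8-connected components with their area, centroid, bounding box and boundary
#' contour (pixels of the region not interior under 4-connectivity).
#'
#' @param bmap logical matrix.
#' @param day,well metadata carried into the output.
#' @return tibble with `region_id`, `well`, `day`, `area_px`, `centroid_x`,
#'   `centroid_y`, `bbox_x0`, `bbox_y0`, `bbox_x1`, `bbox_y1`, and a `contour`
#'   list-column of (x, y) coordinate matrices.
#' @export
extract_regions <- function(bmap, day = NA_integer_, well = NA_integer_) {
  lab <- label_components(bmap)
  n <- max(lab)
  if (n == 0)
    return(tibble::tibble(region_id = integer(), well = integer(),
                          day = integer(), area_px = numeric(),
                          centroid_x = numeric(), centroid_y = numeric(),
                          bbox_x0 = integer(), bbox_y0 = integer(),
                          bbox_x1 = integer(), bbox_y1 = integer(),
                          contour = list()))
  interior <- erode_mask(lab > 0, 1)
  purrr::map_dfr(seq_len(n), function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    edge <- idx[!interior[idx], , drop = FALSE]
    tibble::tibble(region_id = i, well = well, day = day,
                   area_px = nrow(idx),
                   centroid_x = mean(idx[, 2]), centroid_y = mean(idx[, 1]),
                   bbox_x0 = min(idx[, 2]), bbox_y0 = min(idx[, 1]),
                   bbox_x1 = max(idx[, 2]), bbox_y1 = max(idx[, 1]),
                   contour = list(cbind(x = edge[, 2], y = edge[, 1])))
  })
}

#' Detect colonies in one frame
#'
#' Convenience wrapper chaining [autolevels()], [scan_frame()], [binarize()]
#' and [postprocess_map()].
#'
#' @param model a `patch_classifier`.
#' @param frame raw intensity matrix.
#' @param window,stride scan geometry.
#' @param threshold score cutoff.
#' @param sigma,rebin_threshold,min_area_px post-processing parameters.
#' @param normalize apply [autolevels()] first (default TRUE).
#' @return logical binary map.
#' @export
detect_frame <- function(model, frame, window = 96L, stride = 96L,
                         threshold = NULL, sigma = 48, rebin_threshold = 0.5,
                         min_area_px = 96^2, normalize = TRUE) {
  if (is.null(threshold)) threshold <- model$threshold
  f <- if (normalize) autolevels(frame) else frame
  smap <- scan_frame(model, f, window = window, stride = stride)
  postprocess_map(binarize(smap, threshold), sigma = sigma,
                  rebin_threshold = rebin_threshold,
                  min_area_px = min_area_px)
}
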