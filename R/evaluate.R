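#' Pearson correlation of a detection mask against a reporter image
#'
#' The validation statistic used with a pluripotency reporter channel: the
#' reporter is binarized (Otsu threshold by default) and the Pearson
#' correlation of the two 0/1 pixel fields is computed over the whole frame.
#' A constant field makes r undefined; this is reported, not raised.
#'
#' @param detection logical/0-1 matrix.
#' @param reporter fluorescence intensity matrix, same dimensions.
#' @param reporter_threshold fixed binarization threshold; `NULL` (default)
#'   uses Otsu's method on the reporter.
#' @param mode `"binary"` (default, r between the two binary fields) or
#'   `"intensity"` (r between raw reporter intensity and the binary mask).
#' @return one-row tibble `pearson_r`, `n_pixels`, `reporter_threshold`,
#'   `reason` (NA unless r is undefined).
#' @export
pearson_overlap <- function(detection, reporter, reporter_threshold = NULL,
                            mode = c("binary", "intensity")) {
  mode <- match.arg(mode)
  stopifnot(all(dim(detection) == dim(reporter)))
  det <- as.numeric(as.matrix(detection) > 0)
  rep_m <- as.matrix(reporter)
  if (is.null(reporter_threshold)) {
    rng <- range(rep_m)
    reporter_threshold <- if (rng[2] > rng[1])
      as.numeric(otsu(Image((rep_m - rng[1]) / (rng[2] - rng[1])))) *
        (rng[2] - rng[1]) + rng[1]
    else rng[1]
  }
  rep_v <- if (mode == "binary") as.numeric(rep_m >= reporter_threshold)
           else as.numeric(rep_m)
  if (stats::sd(det) == 0 || stats::sd(rep_v) == 0) {
    return(tibble::tibble(pearson_r = NA_real_, n_pixels = length(det),
                          reporter_threshold = reporter_threshold,
                          reason = "constant field: correlation undefined"))
  }
  tibble::tibble(pearson_r = stats::cor(det, rep_v), n_pixels = length(det),
                 reporter_threshold = reporter_threshold,
                 reason = NA_character_)
}

#' Mask agreement metrics
#'
#' Per-colony intersection-over-union (each truth colony matched to the
#' best-overlapping predicted component) plus global pixel precision and
#' recall.
#'
#' @param pred logical/0-1 predicted mask.
#' @param truth integer truth label mask, same dimensions.
#' @return list with `per_colony` (tibble `colony_id`, `truth_area`, `iou`)
#'   and `pixel` (one-row tibble `precision`, `recall`, `f1`; precision is NA
#'   with a reason when nothing is predicted).
#' @export
mask_metrics <- function(pred, truth) {
  stopifnot(all(dim(pred) == dim(truth)))
  p <- as.matrix(pred) > 0
  t_lab <- as.matrix(truth)
  pred_lab <- label_components(p)
  ids <- sort(unique(t_lab[t_lab > 0]))
  per <- purrr::map_dfr(ids, function(i) {
    reg <- t_lab == i
    inter_labels <- pred_lab[reg]
    inter_labels <- inter_labels[inter_labels > 0]
    if (!length(inter_labels)) {
      return(tibble::tibble(colony_id = i, truth_area = sum(reg), iou = 0))
    }
    best <- as.integer(names(which.max(table(inter_labels))))
    comp <- pred_lab == best
    tibble::tibble(colony_id = i, truth_area = sum(reg),
                   iou = sum(reg & comp) / sum(reg | comp))
  })
  tp <- sum(p & t_lab > 0)
  precision <- if (sum(p) > 0) tp / sum(p) else NA_real_
  recall <- if (sum(t_lab > 0) > 0) tp / sum(t_lab > 0) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(per_colony = per,
       pixel = tibble::tibble(precision = precision, recall = recall, f1 = f1,
                              reason = if (is.na(precision))
                                "empty prediction: precision undefined"
                              else NA_character_))
}

#' Picking-day accuracy
#'
#' Fraction of tracks whose predicted trigger day is within `k` days of the
#' expert day; missing predictions count as incorrect.
#'
#' @param decisions tibble `track_id`, `trigger_day` from
#'   [picking_decision()].
#' @param truth tibble `track_id`, `picking_day`.
#' @param k day tolerance (default 1).
#' @return one-row tibble `n`, `n_correct`, `accuracy`, `mean_abs_error`
#'   (over non-missing predictions).
#' @export
picking_accuracy <- function(decisions, truth, k = 1) {
  j <- dplyr::inner_join(decisions, truth, by = "track_id")
  stopifnot(nrow(j) > 0)
  ok <- !is.na(j$trigger_day) & abs(j$trigger_day - j$picking_day) <= k
  tibble::tibble(n = nrow(j), n_correct = sum(ok), accuracy = mean(ok),
                 mean_abs_error = mean(abs(j$trigger_day - j$picking_day),
                                       na.rm = TRUE))
}
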