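#' Segment one frame into labelled colonies
#'
#' Before (and on) the seed day, colonies are simply the 8-connected
#' components of the binary detection map. After the seed day — the mature
#' cases where tiled detection under-resolves boundaries — the prior day's
#' labels are propagated: each prior label, eroded, seeds the foreground; the
#' complement of a dilation of the detection map seeds the background; and the
#' random walker refines the boundary on the intensity image, restricted to a
#' dilated envelope of the detection map.
#'
#' @param bmap logical binary detection map for the frame.
#' @param frame intensity matrix (used only for refinement after seed day).
#' @param day frame day index.
#' @param seed_day protocol seed frame day (default 12).
#' @param prior_labels labelled matrix from the previous processed day;
#'   required when `day > seed_day`.
#' @param erode_px foreground seed erosion radius (default 5).
#' @param bg_dilate_px background seeds sit outside this dilation of the
#'   detection support (default 5, symmetric with `erode_px` so the walker's
#'   midpoint boundary is unbiased on pure texture).
#' @param dilate_px outer envelope: refined labels may not extend further
#'   than this dilation of the detection map (default 15).
#' @param beta random-walker edge sharpness (default 130).
#' @return integer label matrix (0 = background). A prior label with no
#'   support in the current map yields no pixels (colony lost, no error).
#' @export
segment_frame <- function(bmap, frame, day, seed_day = 12L,
                          prior_labels = NULL, erode_px = 5L,
                          bg_dilate_px = 5L, dilate_px = 15L, beta = 130) {
  bmap <- as.matrix(bmap) > 0
  if (day <= seed_day) return(label_components(bmap))
  if (is.null(prior_labels))
    stop("segmenting day ", day, " (> seed day ", seed_day,
         ") requires prior_labels")
  if (!any(bmap)) return(matrix(0L, nrow(bmap), ncol(bmap)))

  prior_ids <- sort(unique(prior_labels[prior_labels > 0]))
  seeds <- matrix(0L, nrow(bmap), ncol(bmap))
  for (l in prior_ids) {
    reg <- prior_labels == l
    er <- erode_mask(reg, erode_px)
    if (!any(er)) er <- reg & bmap        # tiny colony: use raw prior support
    seeds[er] <- l
  }
  # interior of the current detection also seeds foreground, labelled by the
  # unique prior colony it overlaps; keeps the boundary current when colonies
  # grow quickly between frames
  det_core <- label_components(erode_mask(bmap, erode_px))
  for (cc in seq_len(max(det_core))) {
    sel <- det_core == cc
    owners <- unique(prior_labels[sel & prior_labels > 0])
    if (length(owners) == 1) seeds[sel & seeds == 0L] <- owners
  }
  support <- bmap | (prior_labels > 0)
  fg_any <- dilate_mask(support, bg_dilate_px)
  bg_id <- max(prior_ids, 0L) + 1L
  seeds[!fg_any] <- bg_id
  roi <- dilate_mask(fg_any, 1L)

  present <- sort(unique(seeds[seeds > 0]))
  if (length(present) < 2 || !any(seeds > 0 & seeds != bg_id)) {
    # no foreground seeds survived: fall back to plain components
    return(label_components(bmap))
  }
  rw <- random_walker(frame, seeds, beta = beta, roi = roi)
  out <- rw$labels
  out[out == bg_id] <- 0L
  out[is.na(out)] <- 0L
  # restrict labels to the detection envelope
  out[!dilate_mask(bmap, min(bg_dilate_px, dilate_px))] <- 0L
  out
}

#' Link per-day label maps into colony tracks
#'
#' Backward tracking: starting from the final frame (and optionally the seed
#' frame), each region on day `d` is linked to the region on the previous
#' processed day with maximal pixel overlap, accepted when
#' `overlap / min(area)` is at least `min_overlap`. Ties are broken toward
#' the larger candidate region, then the lower region id. Regions that never
#' appear in the final frame (or the seed frame when `seed_day` is given)
#' start no track.
#'
#' @param label_maps tibble with columns `day` and `labels` (list of integer
#'   matrices), at least two days.
#' @param min_overlap acceptance threshold on `overlap / min(area)`
#'   (default 0.3).
#' @param seed_day optional day whose regions also start tracks (traced
#'   backward from there) even if absent from the final frame.
#' @return tibble with `track_id`, `day`, `region_id`, `area_px`, and
#'   `first_positive_day` (earliest linked day, repeated along the track).
#' @export
link_tracks <- function(label_maps, min_overlap = 0.3, seed_day = NULL) {
  stopifnot(is.data.frame(label_maps), nrow(label_maps) >= 2)
  lm <- label_maps[order(label_maps$day), ]
  days <- lm$day
  maps <- lm$labels

  region_ids <- lapply(maps, function(m) sort(unique(m[m > 0])))
  areas <- lapply(maps, function(m) {
    if (max(m) == 0) numeric(0) else tabulate(m[m > 0])
  })

  best_match <- function(cur_map, cur_id, prev_map, prev_areas) {
    sel <- prev_map[cur_map == cur_id]
    sel <- sel[sel > 0]
    if (!length(sel)) return(NA_integer_)
    ov <- table(sel)
    cand <- as.integer(names(ov))
    ovn <- as.numeric(ov)
    cur_area <- sum(cur_map == cur_id)
    frac <- ovn / pmin(cur_area, prev_areas[cand])
    ok <- frac >= 0.0  # filtered below against min_overlap
    score <- ovn
    # order: max overlap, then larger candidate area, then lower id
    ord <- order(-score, -prev_areas[cand], cand)
    pick <- cand[ord[1]]
    if (frac[ord[1]] >= min_overlap) pick else NA_integer_
  }

  trace_back <- function(start_di, start_region) {
    rows <- list()
    cur <- start_region
    for (di in seq(start_di, 1)) {
      rows[[length(rows) + 1]] <-
        tibble::tibble(day = days[di], region_id = cur,
                       area_px = areas[[di]][cur])
      if (di == 1) break
      nxt <- best_match(maps[[di]], cur, maps[[di - 1]], areas[[di - 1]])
      if (is.na(nxt)) break
      cur <- nxt
    }
    dplyr::bind_rows(rev(rows))
  }

  nd <- length(days)
  tracks <- list()
  used_seed_regions <- integer(0)
  seed_di <- if (!is.null(seed_day)) match(seed_day, days) else NA_integer_

  for (r in region_ids[[nd]]) {
    tr <- trace_back(nd, r)
    tracks[[length(tracks) + 1]] <- tr
    if (!is.na(seed_di)) {
      on_seed <- tr$region_id[tr$day == days[seed_di]]
      used_seed_regions <- c(used_seed_regions, on_seed)
    }
  }
  if (!is.na(seed_di)) {
    for (r in setdiff(region_ids[[seed_di]], used_seed_regions)) {
      tracks[[length(tracks) + 1]] <- trace_back(seed_di, r)
    }
  }
  if (!length(tracks))
    return(tibble::tibble(track_id = integer(), day = integer(),
                          region_id = integer(), area_px = numeric(),
                          first_positive_day = integer()))
  out <- dplyr::bind_rows(
    purrr::imap(tracks, function(tr, i) dplyr::mutate(tr, track_id = i)))
  out |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(first_positive_day = min(.data$day)) |>
    dplyr::ungroup() |>
    dplyr::select("track_id", "day", "region_id", "area_px",
                  "first_positive_day")
}

#' Growth curve of tracked colonies
#'
#' Area per tracked day in px^2; days where a track has no region are simply
#' absent (no interpolation).
#'
#' @param tracks tibble from [link_tracks()].
#' @return tibble `track_id`, `day`, `area_px`.
#' @export
growth_curve <- function(tracks) {
  stopifnot(is.data.frame(tracks), nrow(tracks) > 0)
  tracks |>
    dplyr::filter(!is.na(.data$area_px), .data$area_px > 0) |>
    dplyr::arrange(.data$track_id, .data$day) |>
    dplyr::select("track_id", "day", "area_px")
}

#' Segment and track a whole time-lapse series
#'
#' Runs [segment_frame()] over the days in order (labels propagate forward
#' from the seed day) and links the per-day label maps with [link_tracks()].
#'
#' @param bmaps tibble with `day` and `bmap` (list of logical matrices).
#' @param frames tibble with `day` and `frame` (list of intensity matrices).
#' @param seed_day seed frame day (default 12).
#' @param ... passed to [segment_frame()] and [link_tracks()].
#' @param min_overlap linking threshold (default 0.3).
#' @return list with `labels` (tibble `day`, `labels`) and `tracks`.
#' @export
segment_and_track <- function(bmaps, frames, seed_day = 12L,
                              min_overlap = 0.3, ...) {
  ord <- order(bmaps$day)
  bmaps <- bmaps[ord, ]
  days <- bmaps$day
  labs <- vector("list", length(days))
  prior <- NULL
  for (i in seq_along(days)) {
    d <- days[i]
    fr <- frames$frame[[match(d, frames$day)]]
    labs[[i]] <- segment_frame(bmaps$bmap[[i]], fr, d, seed_day = seed_day,
                               prior_labels = prior, ...)
    if (d >= seed_day || i == length(days)) prior <- labs[[i]]
    if (d < seed_day) prior <- labs[[i]]  # always propagate most recent
  }
  label_tbl <- tibble::tibble(day = days, labels = labs)
  tracks <- link_tracks(label_tbl, min_overlap = min_overlap,
                        seed_day = if (seed_day %in% days) seed_day else NULL)
  list(labels = label_tbl, tracks = tracks)
}
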