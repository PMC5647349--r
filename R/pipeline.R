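#' Build and validate a run manifest
#'
#' A manifest lists the frames of a run: one row per well and day with the
#' file path. `build_manifest()` scans a directory for the canonical
#' `well{W}_day{D}.tif` naming; `validate_manifest()` checks every referenced
#' file exists before any compute happens.
#'
#' @param dir directory of frames.
#' @return tibble `well`, `day`, `path`.
#' @export
build_manifest <- function(dir) {
  files <- list.files(dir, pattern = "^well\\d+_day\\d+\\.tif$")
  if (!length(files)) stop("no well{W}_day{D}.tif frames found in ", dir)
  m <- regmatches(files, regexec("^well(\\d+)_day(\\d+)\\.tif$", files))
  tibble::tibble(well = as.integer(vapply(m, `[`, "", 2)),
                 day = as.integer(vapply(m, `[`, "", 3)),
                 path = file.path(dir, files)) |>
    dplyr::arrange(.data$well, .data$day)
}

#' @rdname build_manifest
#' @param manifest tibble `well`, `day`, `path`.
#' @export
validate_manifest <- function(manifest) {
  stopifnot(is.data.frame(manifest),
            all(c("well", "day", "path") %in% names(manifest)))
  missing <- manifest$path[!file.exists(manifest$path)]
  if (length(missing))
    stop("manifest references missing frame(s): ",
         paste(missing, collapse = ", "))
  invisible(manifest)
}

#' Pipeline configuration
#'
#' Collects the tunable parameters of every stage with the pipeline's
#' defaults; the snapshot travels with the run outputs for provenance.
#'
#' @param window,stride scan geometry (defaults 96/96).
#' @param score_threshold window score cutoff (default 0.5).
#' @param sigma,rebin_threshold,min_area_px post-processing (defaults 48,
#'   0.5, one window).
#' @param seed_day segmentation seed frame day (default 12).
#' @param erode_px,bg_dilate_px,dilate_px random-walker seed and envelope
#'   radii (defaults 5, 5, 15).
#' @param beta random-walker edge sharpness (default 130).
#' @param min_overlap track linking threshold (default 0.3).
#' @param picking_threshold mature-posterior trigger (default 0.3).
#' @param n_states,n_restarts phase model size and restarts.
#' @param seed RNG seed for model fitting.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(window = 96L, stride = 96L, score_threshold = 0.5,
                            sigma = 48, rebin_threshold = 0.5,
                            min_area_px = 96^2, seed_day = 12L,
                            erode_px = 5L, bg_dilate_px = 5L,
                            dilate_px = 15L, beta = 130,
                            min_overlap = 0.3, picking_threshold = 0.3,
                            n_states = 4L, n_restarts = 20L, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the end-to-end pipeline on a time-lapse series
#'
#' Composes the stages in the protocol's order for a single well: brightness
#' normalization, sliding-window detection and post-processing per day,
#' seeded segmentation and backward tracking, growth-curve and feature
#' extraction, phase decoding with a supplied (or freshly fitted) HMM, and
#' the picking decision. Rerunning with identical inputs and seeds reproduces
#' identical outputs.
#'
#' @param frames tibble `well`, `day`, `frame` (list of matrices), or a
#'   manifest tibble with `path` instead of `frame` (frames are then read
#'   from disk after validation).
#' @param classifier a trained `patch_classifier`.
#' @param hmm optional fitted `phase_hmm`; if `NULL` and `expert_labels` is
#'   given, a model is fitted on this run's curves.
#' @param expert_labels optional tibble `track_id`, `picking_day` used to fit
#'   the HMM when `hmm` is `NULL`.
#' @param config a [pipeline_config()].
#' @return list with `binary_maps`, `labels`, `tracks`, `curves`, `features`,
#'   `hmm`, `posterior`, `decisions`, and the `config` snapshot.
#' @export
run_pipeline <- function(frames, classifier, hmm = NULL,
                         expert_labels = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(classifier, "patch_classifier"),
            inherits(config, "pipeline_config"))
  if (!"frame" %in% names(frames)) {
    validate_manifest(frames)
    frames <- frames |>
      dplyr::mutate(frame = purrr::map(.data$path, read_frame))
  }
  frames <- frames |> dplyr::arrange(.data$day)

  bmaps <- frames |>
    dplyr::mutate(bmap = purrr::map(.data$frame, function(f)
      detect_frame(classifier, f, window = config$window,
                   stride = config$stride, threshold = config$score_threshold,
                   sigma = config$sigma,
                   rebin_threshold = config$rebin_threshold,
                   min_area_px = config$min_area_px))) |>
    dplyr::select("day", "bmap")

  st <- segment_and_track(bmaps, frames, seed_day = config$seed_day,
                          min_overlap = config$min_overlap,
                          erode_px = config$erode_px,
                          bg_dilate_px = config$bg_dilate_px,
                          dilate_px = config$dilate_px, beta = config$beta)
  if (nrow(st$tracks) == 0)
    return(list(binary_maps = bmaps, labels = st$labels, tracks = st$tracks,
                curves = NULL, features = NULL, hmm = hmm, posterior = NULL,
                decisions = NULL, config = config))
  curves <- growth_curve(st$tracks)
  fp <- st$tracks |>
    dplyr::distinct(.data$track_id, .data$first_positive_day)
  features <- curves |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_split() |>
    purrr::map_dfr(function(df)
      extract_features(df, first_positive_day =
                         fp$first_positive_day[fp$track_id == df$track_id[1]]))

  if (is.null(hmm)) {
    if (is.null(expert_labels))
      stop("run_pipeline needs either a fitted `hmm` or `expert_labels`")
    labels <- purrr::map_dfr(unique(curves$track_id), function(id) {
      pk <- expert_labels$picking_day[expert_labels$track_id == id]
      if (!length(pk)) return(NULL)
      cv <- curves[curves$track_id == id, ]
      dplyr::mutate(
        make_stage_labels(cv, pk,
                          fp$first_positive_day[fp$track_id == id]),
        track_id = id)
    })
    hmm <- fit_phase_hmm(features, labels, n_states = config$n_states,
                         n_restarts = config$n_restarts, seed = config$seed)
  }
  posterior <- mature_posterior(hmm, features)
  decisions <- picking_decision(posterior,
                                threshold = config$picking_threshold)
  list(binary_maps = bmaps, labels = st$labels, tracks = st$tracks,
       curves = curves, features = features, hmm = hmm,
       posterior = posterior, decisions = decisions, config = config)
}
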