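# Shared fixtures, built once per test run and memoized. Sizes are chosen so
# the whole suite runs in minutes on one CPU; the vignette documents the
# problem sizes as the package's validation choices.

.fx <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# validation-scale scene: colonies large relative to the 96 px window, as for
# mature colonies in real wells
fixture_scene <- function() memo("scene", function() {
  generate_scene(scene_config(
    image_size = c(1600, 1600), n_colonies = 3,
    growth = list(carrying_capacity = c(250000, 220000, 260000),
                  rate = 0.55, onset_day = c(8, 9, 10),
                  initial_area = 1200),
    seed = 7))
})

fixture_norm_frames <- function() memo("norm_frames", function() {
  sc <- fixture_scene()
  fr <- sc$frames
  fr$frame <- lapply(fr$frame, autolevels)
  fr
})

fixture_classifier <- function() memo("classifier", function() {
  sc <- fixture_scene()
  pd <- generate_patch_dataset(fixture_norm_frames(), sc$masks, 500, seed = 2)
  train_patch_classifier(pd, seed = 3)
})

# small staggered-onset scene for segmentation/tracking tests
fixture_small_scene <- function() memo("small_scene", function() {
  generate_scene(scene_config(
    image_size = c(512, 512), n_colonies = 3,
    growth = list(carrying_capacity = c(20000, 15000, 24000),
                  rate = 0.55, onset_day = c(8, 9, 10),
                  initial_area = 1200),
    seed = 13))
})

# tabular growth cohort with stage labels and a fitted phase model
fixture_cohort_fit <- function() memo("cohort_fit", function() {
  coh <- simulate_growth_cohort(n_normal = 60, seed = 11)
  curves <- coh$curves; info <- coh$info
  featl <- purrr::map_dfr(split(curves, curves$track_id), function(df)
    extract_features(df, first_positive_day =
      info$first_positive_day[info$track_id == df$track_id[1]]))
  labs <- purrr::map_dfr(seq_len(nrow(info)), function(i) {
    cv <- curves[curves$track_id == info$track_id[i], ]
    dplyr::mutate(make_stage_labels(cv, info$picking_day[i],
                                    info$first_positive_day[i]),
                  track_id = info$track_id[i])
  })
  fit <- fit_phase_hmm(featl, labs, n_states = 4, n_restarts = 10, seed = 5)
  list(fit = fit, features = featl, labels = labs, info = info,
       curves = curves)
})

cohort_features <- function(coh) {
  purrr::map_dfr(split(coh$curves, coh$curves$track_id), function(df)
    extract_features(df, first_positive_day =
      coh$info$first_positive_day[coh$info$track_id == df$track_id[1]]))
}

# deterministic stub classifier scoring 0.5 everywhere (geometry tests)
stub_classifier <- function(p = 0.5) {
  nm <- names(patch_features(matrix(0, 96, 96)))
  center <- rep(0, 10); names(center) <- nm
  scl <- rep(1, 10); names(scl) <- nm
  wts <- rep(0, (10 + 1) * 1 + 2)
  wts[(10 + 1) * 1 + 1] <- log(p / (1 - p))  # output bias; hidden weight 0
  structure(list(wts = wts, n_in = 10L, size = 1L, center = center,
                 scale = scl, threshold = 0.5, patch_size = 96L,
                 train_x = matrix(0, 2, 10, dimnames = list(NULL, nm)),
                 train_y = c(0, 1),
                 meta = list(seed = 1L, decay = 0, maxit = 0L, n_class0 = 1,
                             n_class1 = 1, holdout_accuracy = NA,
                             n_holdout = 0, rounds = 0L)),
            class = "patch_classifier")
}

# score_map builder for binarization-contract tests
make_score_map <- function(scores, window, stride, frame_dim) {
  structure(list(scores = scores, window = as.integer(window),
                 stride = as.integer(stride), frame_dim = frame_dim),
            class = "score_map")
}
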