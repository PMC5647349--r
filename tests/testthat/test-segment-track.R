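# disk mask helper for constructed tracking scenarios
disk_mask <- function(h, w, cy, cx, r, id = 1L) {
  yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  m <- matrix(0L, h, w)
  m[(yy - cy)^2 + (xx - cx)^2 <= r^2] <- id
  m
}

test_that("before the seed day, labels are the connected components of the map", {
  m <- matrix(FALSE, 200, 200)
  m[11:60, 11:60] <- TRUE
  m[101:160, 101:160] <- TRUE
  lab <- segment_frame(m, matrix(0, 200, 200), day = 10, seed_day = 12)
  expect_setequal(unique(lab[lab > 0]), c(1L, 2L))
  expect_equal(sum(lab == 1), 2500)
  expect_equal(sum(lab == 2), 3600)
})

test_that("after the seed day, missing priors raise and lost colonies vanish quietly", {
  m <- matrix(FALSE, 200, 200)
  m[51:120, 51:120] <- TRUE
  expect_error(segment_frame(m, matrix(0, 200, 200), day = 13, seed_day = 12),
               "prior_labels")
  # a prior colony with no support in the current map emits no pixels
  prior <- disk_mask(200, 200, 60, 60, 20, 1L)
  prior[prior == 0] <- disk_mask(200, 200, 160, 160, 15, 2L)[prior == 0]
  bmap <- disk_mask(200, 200, 60, 60, 24) > 0   # colony 2 gone
  set.seed(1)
  frame <- matrix(rnorm(200 * 200, 30000, 1500), 200, 200)
  lab <- segment_frame(bmap, frame, day = 13, seed_day = 12,
                       prior_labels = prior)
  expect_true(any(lab == 1))
  expect_equal(sum(lab == 2), 0)
})

test_that("random-walker refinement recovers a grown colony boundary", {
  sc <- fixture_small_scene()
  masks <- sc$masks
  frames <- sc$frames
  bmaps <- tibble::tibble(day = masks$day,
                          bmap = lapply(masks$mask, function(m) m > 0))
  st <- segment_and_track(bmaps, frames, seed_day = 12)
  cu <- growth_curve(st$tracks)
  # every colony tracked with per-day areas within 10% of the truth table
  expect_equal(length(unique(cu$track_id)), 3)
  for (t in unique(cu$track_id)) {
    fp <- min(cu$day[cu$track_id == t])
    cid <- sc$colonies$colony_id[sc$colonies$first_positive_day == fp]
    j <- dplyr::inner_join(cu[cu$track_id == t, ],
                           sc$areas[sc$areas$colony_id == cid, ], by = "day")
    expect_true(all(abs(j$area_px.x - j$area_px.y) / j$area_px.y <= 0.10))
  }
})

test_that("random-walker refinement of a detected map improves on the raw components", {
  clf <- fixture_classifier()
  sc <- fixture_scene()
  frames_n <- fixture_norm_frames()
  mk20 <- sc$masks$mask[[match(20, sc$masks$day)]]
  bm19 <- detect_frame(clf, frames_n$frame[[match(19, frames_n$day)]],
                       normalize = FALSE)
  bm20 <- detect_frame(clf, frames_n$frame[[match(20, frames_n$day)]],
                       normalize = FALSE)
  prior <- label_components(bm19)
  refined <- segment_frame(bm20, frames_n$frame[[match(20, frames_n$day)]],
                           day = 20, seed_day = 12, prior_labels = prior)
  iou_of <- function(lab) {
    vapply(1:3, function(i) {
      truth_i <- mk20 == i
      ov <- table(lab[truth_i & lab > 0])
      if (!length(ov)) return(0)
      best <- as.integer(names(which.max(ov)))
      sum(truth_i & lab == best) / sum(truth_i | lab == best)
    }, numeric(1))
  }
  iou_plain <- iou_of(label_components(bm20))
  iou_ref <- iou_of(refined)
  expect_true(all(iou_ref >= iou_plain - 1e-9))
  expect_gte(mean(iou_ref), mean(iou_plain))
})

test_that("nested growing footprints give one track with the right first-positive day", {
  days <- 8:22
  maps <- tibble::tibble(day = days, labels = lapply(seq_along(days), function(i)
    disk_mask(300, 300, 150, 150, 20 + 4 * i)))
  tr <- link_tracks(maps)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 15)
  expect_equal(unique(tr$first_positive_day), 8)
})

test_that("disjoint colonies are never merged and late-only regions start no track", {
  days <- 10:14
  maps <- tibble::tibble(day = days, labels = lapply(seq_along(days), function(i) {
    m <- disk_mask(300, 300, 80, 80, 15 + 3 * i, 1L)
    m2 <- disk_mask(300, 300, 220, 220, 12 + 3 * i, 1L)
    m[m2 > 0] <- 2L
    m
  }))
  tr <- link_tracks(maps)
  expect_equal(length(unique(tr$track_id)), 2)
  # regions on each track stay on one colony (centroid side never flips)
  expect_true(all(table(tr$track_id) == 5))

  # a region appearing only on an intermediate day, gone by the final frame,
  # starts no track
  maps2 <- maps
  extra <- maps2$labels[[2]]
  extra[disk_mask(300, 300, 80, 250, 10) > 0] <- 3L
  maps2$labels[[2]] <- extra
  tr2 <- link_tracks(maps2)
  expect_equal(length(unique(tr2$track_id)), 2)
  # ... but a seed-day region does start a track when seed_day is given
  tr3 <- link_tracks(maps2, seed_day = 11)
  expect_equal(length(unique(tr3$track_id)), 3)
})

test_that("five-colony scene: tracks recover identity and first-positive day", {
  cfg <- scene_config(image_size = c(800, 800), n_colonies = 5,
                      growth = list(carrying_capacity = c(20000, 15000, 24000,
                                                          18000, 21000),
                                    rate = 0.55,
                                    onset_day = c(8, 9, 10, 8, 11),
                                    initial_area = 1200),
                      seed = 17)
  sc <- generate_scene(cfg)
  bmaps <- tibble::tibble(day = sc$masks$day,
                          bmap = lapply(sc$masks$mask, function(m) m > 0))
  st <- segment_and_track(bmaps, sc$frames, seed_day = 12)
  tr <- st$tracks
  expect_gte(length(unique(tr$track_id)), 4)
  # match each track to a truth colony by final-frame overlap and compare
  # first-positive days
  lab_fin <- st$labels$labels[[nrow(st$labels)]]
  mk_fin <- sc$masks$mask[[nrow(sc$masks)]]
  n_good <- 0
  for (t in unique(tr$track_id)) {
    reg <- tr$region_id[tr$track_id == t & tr$day == max(tr$day)]
    if (!length(reg)) next
    ov <- table(mk_fin[lab_fin == reg & mk_fin > 0])
    if (!length(ov)) next
    cid <- as.integer(names(which.max(ov)))
    fp_truth <- sc$colonies$first_positive_day[sc$colonies$colony_id == cid]
    fp_track <- unique(tr$first_positive_day[tr$track_id == t])
    if (abs(fp_track - fp_truth) <= 1) n_good <- n_good + 1
  }
  expect_gte(n_good, 4)
})

test_that("growth curves report tracked areas and omit missing days", {
  tr <- tibble::tibble(track_id = c(1, 1, 1), day = c(8, 9, 11),
                       region_id = 1L, area_px = c(100, 150, NA),
                       first_positive_day = 8)
  cu <- growth_curve(tr)
  expect_equal(cu$day, c(8, 9))
  expect_equal(cu$area_px, c(100, 150))
})

test_that("tracking is deterministic and independent of label enumeration order", {
  days <- 10:13
  maps <- tibble::tibble(day = days, labels = lapply(seq_along(days), function(i) {
    m <- disk_mask(200, 200, 60, 60, 12 + 3 * i, 1L)
    m2 <- disk_mask(200, 200, 150, 150, 10 + 3 * i, 1L)
    m[m2 > 0] <- 2L
    m
  }))
  # relabel day maps with swapped ids
  maps_swapped <- maps
  maps_swapped$labels <- lapply(maps$labels, function(m) {
    out <- m
    out[m == 1L] <- 2L; out[m == 2L] <- 1L
    out
  })
  tr <- link_tracks(maps)
  tr_sw <- link_tracks(maps_swapped)
  a <- dplyr::arrange(dplyr::select(tr, "day", "area_px"), day, area_px)
  b <- dplyr::arrange(dplyr::select(tr_sw, "day", "area_px"), day, area_px)
  expect_equal(a, b)
})
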