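test_that("empty scene yields background-only frames and empty truth", {
  sc <- generate_scene(scene_config(image_size = c(288, 288), n_colonies = 0,
                                    day_range = 8:10, seed = 1))
  expect_equal(nrow(sc$frames), 3)
  expect_true(all(vapply(sc$masks$mask, function(m) all(m == 0), logical(1))))
  expect_equal(nrow(sc$areas), 0)
  expect_equal(nrow(sc$colonies), 0)
})

test_that("scene generation is bit-identical under a fixed seed", {
  cfg <- scene_config(image_size = c(288, 288), n_colonies = 1,
                      growth = list(carrying_capacity = 8000, rate = 0.55,
                                    onset_day = 8, initial_area = 1200),
                      day_range = 8:12, seed = 42)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$frames$frame, b$frames$frame)
  expect_identical(a$masks$mask, b$masks$mask)
})

test_that("truth area table matches the closed-form logistic law", {
  K <- 20000; r <- 0.55; on <- 8; a0 <- 1200
  cfg <- scene_config(image_size = c(512, 512), n_colonies = 1,
                      growth = list(carrying_capacity = K, rate = r,
                                    onset_day = on, initial_area = a0),
                      seed = 3)
  sc <- generate_scene(cfg)
  expected <- logistic_area(sc$areas$day, K, r, on, a0)
  expect_equal(sc$areas$area_px, expected)
  # rasterized mask area within perimeter-order error of the table
  for (i in seq_len(nrow(sc$masks))) {
    a_tab <- sc$areas$area_px[sc$areas$day == sc$masks$day[i]]
    a_mask <- sum(sc$masks$mask[[i]] > 0)
    if (a_tab > 0) {
      perim <- 2 * pi * sqrt(a_tab / pi)
      expect_lt(abs(a_mask - a_tab), perim + 4)
    } else expect_equal(a_mask, 0)
  }
})

test_that("truth areas are non-decreasing and frames are 16-bit", {
  sc <- fixture_small_scene()
  by_col <- split(sc$areas, sc$areas$colony_id)
  for (df in by_col) {
    df <- df[order(df$day), ]
    expect_true(all(diff(df$area_px) >= 0))
  }
  f <- sc$frames$frame[[1]]
  expect_true(all(f >= 0 & f <= 65535))
  expect_true(is.integer(f))
})

test_that("picking day is the first day at the maturity fraction and never precedes first-positive day", {
  sc <- fixture_small_scene()
  for (i in seq_len(nrow(sc$colonies))) {
    ci <- sc$colonies[i, ]
    a <- sc$areas[sc$areas$colony_id == ci$colony_id, ]
    reached <- a$day[a$area_px >= 0.6 * ci$carrying_capacity]
    expect_equal(ci$picking_day, min(reached))
    expect_gte(ci$picking_day, ci$first_positive_day)
  }
})

test_that("colony placement failure raises an explicit error", {
  cfg <- scene_config(image_size = c(300, 300), n_colonies = 8,
                      growth = list(carrying_capacity = 20000, rate = 0.55,
                                    onset_day = 8, initial_area = 1200),
                      seed = 1)
  expect_error(generate_scene(cfg), "disjoint")
})

test_that("reporter support matches the mask exactly at full coverage and infinite SNR", {
  sc <- fixture_small_scene()
  mk <- sc$masks$mask[[nrow(sc$masks)]]
  rep_img <- generate_reporter(mk, reporter_snr = Inf, coverage_fraction = 1,
                               seed = 1)
  expect_identical(rep_img > 25000, mk > 0)
})

test_that("reporter covers the configured fraction of colony pixels", {
  sc <- fixture_small_scene()
  mk <- sc$masks$mask[[nrow(sc$masks)]]
  rep_img <- generate_reporter(mk, reporter_snr = 20, coverage_fraction = 0.9,
                               seed = 5)
  thr <- 1000 + 10 * 400  # halfway to the signal level
  frac <- mean(rep_img[mk > 0] > thr)
  expect_gt(frac, 0.85)
  expect_lt(frac, 0.95)
})

test_that("empty truth mask yields a pure-noise reporter", {
  rep_img <- generate_reporter(matrix(0L, 64, 64), reporter_snr = 10,
                               coverage_fraction = 0.9, seed = 2)
  expect_lt(max(rep_img), 1000 + 6 * 400)
})

test_that("patch dataset honours counts, shape and label convention", {
  sc <- fixture_small_scene()
  pd <- generate_patch_dataset(sc$frames, sc$masks, 30, seed = 9)
  expect_equal(nrow(pd), 60)
  expect_equal(sum(pd$label == 0), 30)
  expect_equal(sum(pd$label == 1), 30)
  expect_true(all(vapply(pd$patch, function(p) all(dim(p) == c(96, 96)),
                         logical(1))))
  # label 0 patches lie fully inside colonies; label 1 fully outside
  for (i in seq_len(nrow(pd))) {
    mk <- sc$masks$mask[[match(pd$day[i], sc$masks$day)]]
    sub <- mk[pd$y[i]:(pd$y[i] + 95), pd$x[i]:(pd$x[i] + 95)]
    if (pd$label[i] == 0) expect_true(all(sub > 0)) else expect_true(all(sub == 0))
  }
})

test_that("patch sampling is reproducible and errors when colony area is insufficient", {
  sc <- fixture_small_scene()
  a <- generate_patch_dataset(sc$frames, sc$masks, 20, seed = 4)
  b <- generate_patch_dataset(sc$frames, sc$masks, 20, seed = 4)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_error(generate_patch_dataset(sc$frames, sc$masks, 1e6, seed = 1),
               "insufficient")
})

test_that("growth cohort: curves follow the logistic with bounded noise and labels are consistent", {
  coh <- simulate_growth_cohort(n_normal = 20, noise_cv = 0.05, seed = 3)
  expect_equal(length(unique(coh$curves$track_id)), 20)
  for (i in c(1, 10, 20)) {
    inf <- coh$info[coh$info$track_id == i, ]
    cv <- coh$curves[coh$curves$track_id == i, ]
    truth <- logistic_area(cv$day, inf$carrying_capacity, inf$rate,
                           inf$onset_day, 1200)
    expect_true(all(abs(log(cv$area_px / truth)) < 5 * 0.05))
    expect_gte(inf$picking_day, inf$first_positive_day)
  }
})

test_that("scene round-trips through the on-disk dialect", {
  dir <- withr::local_tempdir()
  sc <- generate_scene(scene_config(image_size = c(288, 288), n_colonies = 1,
                                    growth = list(carrying_capacity = 6000,
                                                  rate = 0.55, onset_day = 8,
                                                  initial_area = 1200),
                                    day_range = 8:10, seed = 2))
  write_scene(sc, dir)
  man <- build_manifest(dir)
  expect_equal(nrow(man), 3)
  fr <- read_frame(man$path[1])
  expect_identical(fr, sc$frames$frame[[1]])
  cfg2 <- read_scene_config(file.path(dir, "scene_config.txt"))
  expect_equal(cfg2$growth$carrying_capacity, 6000)
  expect_equal(cfg2$image_size, c(288L, 288L))
})
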