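test_that("feature extraction follows the difference definitions", {
  cv <- tibble::tibble(day = 8:10, area_px = c(100, 150, 225))
  f <- extract_features(cv, first_positive_day = 8)
  expect_equal(f$d_area, c(0, 50, 75))
  expect_equal(f$dd_area, c(0, 50, 25))
  expect_equal(f$area, c(100, 150, 225))
  expect_equal(f$age, c(0, 1, 2))

  single <- extract_features(tibble::tibble(day = 9, area_px = 500))
  expect_equal(single$d_area, 0)
  expect_equal(single$dd_area, 0)
  expect_equal(single$age, 0)

  lin <- extract_features(tibble::tibble(day = 1:6, area_px = 10 * (1:6)))
  expect_true(all(lin$dd_area[-(1:2)] == 0))
})

test_that("stage labels encode the first and mature blocks", {
  cv <- tibble::tibble(day = 7:22)
  lab <- make_stage_labels(cv, picking_day = 14, first_positive_day = 7)
  expect_equal(lab$stage[lab$day %in% 7:9], rep("first", 3))
  expect_equal(lab$stage[lab$day %in% 10:12], rep("unknown", 3))
  expect_equal(lab$stage[lab$day %in% 13:22], rep("mature", 10))

  lab2 <- make_stage_labels(cv, picking_day = 22, first_positive_day = 7)
  expect_equal(sum(lab2$stage == "mature"), 2)

  expect_error(make_stage_labels(cv, picking_day = 10, first_positive_day = 7),
               "overlap")
})

test_that("abnormality statistic is the windowed mean first-order difference", {
  cv <- tibble::tibble(track_id = 1, day = 10:12, area_px = c(100, 200, 300))
  cohort <- dplyr::bind_rows(cv,
    tibble::tibble(track_id = 2:11, day = 10, area_px = 1) |>
      tidyr::expand_grid(extra_day = 0:2) |>
      dplyr::mutate(day = day + extra_day,
                    area_px = 50 * (1 + extra_day)) |>
      dplyr::select(track_id, day, area_px))
  fa <- filter_abnormal(cohort, bounds = c(-1e9, 1e9))
  expect_equal(fa$stats$stat[fa$stats$track_id == 1], 100)

  flat <- tibble::tibble(track_id = 1:6, day = 10) |>
    tidyr::expand_grid(extra = 0:5) |>
    dplyr::mutate(day = day + extra, area_px = 777) |>
    dplyr::select(track_id, day, area_px)
  fa2 <- filter_abnormal(flat, bounds = c(-1, 1))
  expect_true(all(fa2$stats$stat == 0))

  # a curve not covering the window is rejected with the documented reason
  short <- dplyr::bind_rows(flat,
    tibble::tibble(track_id = 99, day = c(7, 8), area_px = c(10, 20)))
  fa3 <- filter_abnormal(short, bounds = c(-1, 1))
  expect_equal(fa3$rejected$reason[fa3$rejected$track_id == 99],
               "insufficient window coverage")
})

test_that("planted overgrowers are rejected by the default bounds", {
  coh <- simulate_growth_cohort(n_normal = 90, n_abnormal = 10, seed = 21)
  fa <- filter_abnormal(coh$curves)
  over <- coh$info$track_id[coh$info$status == "overgrown"]
  expect_gte(sum(over %in% fa$rejected$track_id), 8)
})

test_that("single-state fit recovers the closed-form Gaussian MLE", {
  set.seed(1)
  feats <- tibble::tibble(track_id = rep(1:3, each = 5), day = rep(1:5, 3),
                          d_area = rnorm(15), dd_area = rnorm(15),
                          area = rnorm(15, 10), age = rep(0:4, 3))
  m1 <- fit_phase_hmm(feats, n_states = 1, n_restarts = 1, seed = 1)
  X <- as.matrix(feats[, m1$feature_cols])
  Xs <- sweep(sweep(X, 2, m1$center), 2, m1$scale, "/")
  expect_equal(as.vector(m1$means[1, ]), as.vector(colMeans(Xs)),
               tolerance = 1e-10)
  expect_equal(as.vector(m1$vars[1, ]),
               as.vector(apply(Xs, 2, function(v) mean((v - mean(v))^2))),
               tolerance = 1e-8)
  # K = 1 decodes the all-ones path
  expect_true(all(viterbi_phases(m1, feats)$state == 1))
})

test_that("EM log-likelihood is non-decreasing and stochastic-matrix invariants hold", {
  cf <- fixture_cohort_fit()
  expect_true(all(diff(cf$fit$ll_history) > -1e-8))
  expect_equal(sum(cf$fit$pi), 1, tolerance = 1e-12)
  expect_equal(rowSums(cf$fit$A), rep(1, 4), tolerance = 1e-12)
  expect_true(all(cf$fit$A[lower.tri(cf$fit$A)] == 0))
  expect_true(all(cf$fit$vars > 0))
})

test_that("forward likelihood and posteriors match exhaustive enumeration", {
  set.seed(23)
  for (rep in 1:20) {
    K <- sample(2:4, 1); T_ <- sample(3:7, 1)
    inst <- random_hmm_instance(K, T_)
    model <- as_phase_hmm(inst)
    feats <- obs_to_features(inst$obs)
    ll <- phase_loglik(model, feats)$loglik
    expect_equal(ll, enum_loglik(inst$pi, inst$A, inst$obs, inst$means,
                                 inst$vars), tolerance = 1e-10)
    post <- mature_posterior(model, feats)
    g <- as.matrix(post[, paste0("p", seq_len(K))])
    expect_equal(unname(g), enum_posterior(inst$pi, inst$A, inst$obs,
                                           inst$means, inst$vars),
                 tolerance = 1e-10)
    expect_equal(rowSums(g), rep(1, T_), tolerance = 1e-12)
  }
})

test_that("Viterbi equals the enumerated argmax path and toy two-state decoding works", {
  # two-state toy: state means 0 and 10 on one feature, A = [[.8,.2],[0,1]]
  inst <- list(pi = c(1, 0), A = matrix(c(0.8, 0.2, 0, 1), 2, 2, byrow = TRUE),
               means = matrix(c(0, 10), 2, 1), vars = matrix(1, 2, 1),
               obs = matrix(c(0.1, 9.8), 2, 1))
  model <- as_phase_hmm(inst)
  path <- viterbi_phases(model, obs_to_features(inst$obs))$state
  expect_equal(path, c(1L, 2L))
  expect_equal(path, enum_viterbi(inst$pi, inst$A, inst$obs, inst$means,
                                  inst$vars))

  set.seed(29)
  for (rep in 1:20) {
    K <- sample(2:4, 1); T_ <- sample(3:7, 1)
    inst <- random_hmm_instance(K, T_)
    model <- as_phase_hmm(inst)
    path <- viterbi_phases(model, obs_to_features(inst$obs))$state
    expect_equal(path, enum_viterbi(inst$pi, inst$A, inst$obs, inst$means,
                                    inst$vars))
    expect_true(all(diff(path) >= 0))  # left-to-right monotonicity
  }
})

test_that("decoded training paths respect the stage-label clamps", {
  cf <- fixture_cohort_fit()
  vp <- viterbi_phases(cf$fit, cf$features)
  j <- dplyr::inner_join(vp, cf$labels, by = c("track_id", "day"))
  expect_gte(mean(j$state[j$stage == "first"] == 1), 0.9)
  expect_gte(mean(j$state[j$stage == "mature"] == 4), 0.9)
})

test_that("mature posterior trends from 0 to 1 with a single 0.5 crossing for most tracks", {
  cf <- fixture_cohort_fit()
  post <- mature_posterior(cf$fit, cf$features)
  by_track <- split(post, post$track_id)
  early_late_ok <- vapply(by_track, function(df) {
    df <- df[order(df$day), ]
    df$p_mature[1] < 0.2 && df$p_mature[nrow(df)] > 0.8
  }, logical(1))
  single_cross <- vapply(by_track, function(df) {
    df <- df[order(df$day), ]
    sum(diff(df$p_mature >= 0.5) != 0) == 1
  }, logical(1))
  expect_gte(mean(early_late_ok), 0.9)
  expect_gte(mean(single_cross), 0.9)
})

test_that("picking decision implements first-crossing, overgrowth flag and the closest rule", {
  post <- tibble::tibble(track_id = 1, day = 11:14,
                         p_mature = c(0, 0.1, 0.35, 0.9))
  expect_equal(picking_decision(post, 0.3)$trigger_day, 13)
  expect_equal(picking_decision(post, 0.3, rule = "closest")$trigger_day, 13)

  none <- tibble::tibble(track_id = 1, day = 11:14, p_mature = rep(0, 4))
  expect_true(is.na(picking_decision(none, 0.3)$trigger_day))

  hot <- tibble::tibble(track_id = 1, day = 11:14,
                        p_mature = c(0, 0.4, 0.995, 1))
  dec <- picking_decision(hot, 0.3)
  expect_true(dec$overgrowth_risk)
})

test_that("picking-day prediction matches expert labels on a held-out cohort", {
  cf <- fixture_cohort_fit()
  post <- mature_posterior(cf$fit, cf$features)
  dec <- picking_decision(post, 0.3)
  acc <- picking_accuracy(dec, cf$info, k = 1)
  expect_gte(acc$accuracy, 0.8)

  held <- simulate_growth_cohort(n_normal = 40, seed = 99)
  feats_h <- cohort_features(held)
  dec_h <- picking_decision(mature_posterior(cf$fit, feats_h), 0.3)
  expect_gte(picking_accuracy(dec_h, held$info, k = 1)$accuracy, 0.8)
})

test_that("threshold calibration recovers the generating threshold", {
  # constructed consistency: every track crosses exactly at 0.3 on the expert day
  days <- 7:16
  posts <- purrr::map_dfr(1:8, function(i) {
    cross_at <- 9 + (i %% 4)
    p <- ifelse(days < cross_at, 0.29, ifelse(days == cross_at, 0.3, 0.9))
    tibble::tibble(track_id = i, day = days, p_mature = p)
  })
  expert <- posts |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(picking_day = day[which(p_mature >= 0.3)[1]])
  cal <- calibrate_threshold(posts, expert, grid = seq(0.05, 0.95, by = 0.05))
  expect_equal(as.numeric(cal), 0.3, tolerance = 1e-9)

  # recovery: sigmoid scores, pre-crossing values just below 0.3
  set.seed(9)
  posts2 <- purrr::map_dfr(1:20, function(i) {
    mid <- runif(1, 11, 15)
    p <- plogis(1.6 * (days - mid))
    tibble::tibble(track_id = i, day = days, p_mature = p)
  })
  expert2 <- posts2 |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(picking_day = day[which(p_mature >= 0.3)[1]])
  cal2 <- calibrate_threshold(posts2, expert2)
  expect_lt(abs(as.numeric(cal2) - 0.3), 0.05)
})

test_that("phase model serialization round-trips decoding exactly", {
  cf <- fixture_cohort_fit()
  f <- withr::local_tempfile(fileext = ".json")
  write_phase_hmm(cf$fit, f)
  m2 <- read_phase_hmm(f)
  expect_identical(mature_posterior(cf$fit, cf$features),
                   mature_posterior(m2, cf$features))
  expect_identical(viterbi_phases(cf$fit, cf$features),
                   viterbi_phases(m2, cf$features))
})

test_that("tidiers summarize the fitted model", {
  cf <- fixture_cohort_fit()
  td <- tidy(cf$fit)
  expect_equal(nrow(td), 16)
  expect_setequal(unique(td$feature), c("d_area", "dd_area", "area", "age"))
  gl <- glance(cf$fit)
  expect_equal(gl$n_states, 4)
  expect_equal(gl$n_seq, 60)
})
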