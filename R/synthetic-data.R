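#' Scene configuration for the synthetic bright-field generator
#'
#' Describes a simulated reprogramming well: frame geometry, number of
#' colonies, texture statistics of background and colony regions, per-colony
#' logistic growth parameters, the imaging day range and the reporter
#' signal-to-noise ratio. The generator emulates the statistical structure the
#' detection pipeline relies on — textured colony regions distinct from the
#' background, sigmoid area growth, a fluorescence reporter co-located with
#' true colonies — not the optics of phase imaging.
#'
#' @param image_size integer (H, W) in pixels; each dimension must be at least
#'   three detection windows (288 px).
#' @param n_colonies number of colonies to place.
#' @param day_range inclusive day indices imaged once per day.
#' @param texture list with background/colony texture descriptors: mean
#'   intensity (16-bit scale), noise standard deviation, and spatial
#'   correlation length in pixels.
#' @param growth list with per-colony logistic parameters, recycled to
#'   `n_colonies`: `carrying_capacity` (plateau area, px^2), `rate` (/day),
#'   `onset_day` (first day the colony is visible; must be >= first day),
#'   `initial_area` (area at onset, px^2).
#' @param reporter_snr fluorescence signal-to-noise ratio used by
#'   [generate_reporter()].
#' @param maturity_fraction fraction of carrying capacity defining the
#'   ground-truth picking day (first day the noiseless curve reaches it).
#' @param seed integer RNG seed; everything downstream is deterministic in it.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(image_size = c(512L, 512L),
                         n_colonies = 3,
                         day_range = 7:22,
                         texture = list(
                           background = list(mean = 30000, sd = 1500, corr_len = 1.5),
                           colony     = list(mean = 26000, sd = 4500, corr_len = 5)
                         ),
                         growth = list(
                           carrying_capacity = 22000,
                           rate = 0.55,
                           onset_day = 8,
                           initial_area = 1200
                         ),
                         reporter_snr = 10,
                         maturity_fraction = 0.6,
                         seed = 1L) {
  image_size <- as.integer(image_size)
  stopifnot(length(image_size) == 2, all(image_size >= 3L * 96L),
            n_colonies >= 0, length(day_range) >= 1,
            reporter_snr > 0, maturity_fraction > 0, maturity_fraction <= 1)
  day_range <- sort(as.integer(day_range))
  g <- lapply(growth, function(v) rep_len(v, max(n_colonies, 1)))
  if (n_colonies > 0 && any(g$onset_day < min(day_range)))
    stop("colony onset_day must be >= the first imaging day")
  structure(list(image_size = image_size, n_colonies = as.integer(n_colonies),
                 day_range = day_range, texture = texture, growth = g,
                 reporter_snr = reporter_snr,
                 maturity_fraction = maturity_fraction, seed = as.integer(seed)),
            class = "scene_config")
}

#' Closed-form logistic colony area
#'
#' Area of a colony on day `d`: 0 before onset, then
#' `K / (1 + exp(-r (d - t50)))` where `t50` is positioned so the curve passes
#' through `initial_area` at the onset day.
#'
#' @param day numeric vector of days.
#' @param carrying_capacity plateau area K in px^2.
#' @param rate logistic rate r per day.
#' @param onset_day day the colony first appears.
#' @param initial_area area at onset (px^2), strictly inside (0, K).
#' @return numeric vector of areas (px^2).
#' @export
logistic_area <- function(day, carrying_capacity, rate, onset_day, initial_area) {
  stopifnot(initial_area > 0, initial_area < carrying_capacity)
  t50 <- onset_day + log((carrying_capacity - initial_area) / initial_area) / rate
  a <- carrying_capacity / (1 + exp(-rate * (day - t50)))
  a[day < onset_day] <- 0
  a
}

correlated_noise <- function(h, w, sd, corr_len) {
  z <- matrix(stats::rnorm(h * w), h, w)
  if (corr_len > 0.5) {
    z <- blur_gaussian(z, corr_len)
    z <- z / stats::sd(as.vector(z))
  }
  z * sd
}

place_colonies <- function(cfg) {
  h <- cfg$image_size[1]; w <- cfg$image_size[2]
  n <- cfg$n_colonies
  rmax <- sqrt(cfg$growth$carrying_capacity / pi)
  centers <- matrix(NA_real_, n, 2)
  margin <- 8
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(400)) {
      cy <- stats::runif(1, rmax[i] + margin, h - rmax[i] - margin)
      cx <- stats::runif(1, rmax[i] + margin, w - rmax[i] - margin)
      if (i == 1) { ok <- TRUE }
      else {
        d <- sqrt((centers[seq_len(i - 1), 1] - cy)^2 +
                  (centers[seq_len(i - 1), 2] - cx)^2)
        ok <- all(d > rmax[i] + rmax[seq_len(i - 1)] + 2 * margin)
      }
      if (ok) { centers[i, ] <- c(cy, cx); break }
    }
    if (!ok) stop("could not place ", n, " disjoint colonies in a ",
                  h, "x", w, " frame; reduce n_colonies or carrying capacity")
  }
  centers
}

#' Generate a synthetic time-lapse scene with ground truth
#'
#' Produces one 16-bit bright-field-like frame per day together with the
#' ground truth every downstream stage is scored against: per-day colony label
#' masks, the closed-form area table, per-colony picking day (first day the
#' noiseless logistic curve reaches `maturity_fraction` of carrying capacity)
#' and first-positive day. Colonies are rasterized as disks whose area tracks
#' the logistic law; colony and background pixels carry band-limited Gaussian
#' textures with different mean, variance and correlation length.
#'
#' @param config a [scene_config()].
#' @return list with `frames` (tibble: `well`, `day`, `frame` list-column of
#'   H x W integer matrices), `masks` (tibble: `day`, `mask` list-column of
#'   integer label matrices), `areas` (tibble: `colony_id`, `day`, `area_px`),
#'   `colonies` (tibble: `colony_id`, `picking_day`, `first_positive_day`,
#'   growth parameters and center), and `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  cfg <- config
  h <- cfg$image_size[1]; w <- cfg$image_size[2]
  set.seed(cfg$seed)
  n <- cfg$n_colonies
  centers <- if (n > 0) place_colonies(cfg) else matrix(numeric(0), 0, 2)

  days <- cfg$day_range
  g <- cfg$growth
  area_tbl <- if (n > 0) {
    tidyr::expand_grid(colony_id = seq_len(n), day = days) |>
      dplyr::mutate(area_px = logistic_area(.data$day,
                                            g$carrying_capacity[.data$colony_id],
                                            g$rate[.data$colony_id],
                                            g$onset_day[.data$colony_id],
                                            g$initial_area[.data$colony_id]))
  } else tibble::tibble(colony_id = integer(), day = integer(), area_px = numeric())

  colonies <- if (n > 0) {
    purrr::map_dfr(seq_len(n), function(i) {
      a <- logistic_area(days, g$carrying_capacity[i], g$rate[i],
                         g$onset_day[i], g$initial_area[i])
      pick <- days[which(a >= cfg$maturity_fraction * g$carrying_capacity[i])[1]]
      tibble::tibble(colony_id = i,
                     first_positive_day = g$onset_day[i],
                     picking_day = pick,
                     carrying_capacity = g$carrying_capacity[i],
                     rate = g$rate[i], onset_day = g$onset_day[i],
                     center_y = centers[i, 1], center_x = centers[i, 2])
    })
  } else tibble::tibble(colony_id = integer(), first_positive_day = integer(),
                        picking_day = integer(), carrying_capacity = numeric(),
                        rate = numeric(), onset_day = numeric(),
                        center_y = numeric(), center_x = numeric())

  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  tb <- cfg$texture$background; tc <- cfg$texture$colony

  frames <- vector("list", length(days))
  masks <- vector("list", length(days))
  for (di in seq_along(days)) {
    d <- days[di]
    mask <- matrix(0L, h, w)
    if (n > 0) {
      for (i in seq_len(n)) {
        a <- area_tbl$area_px[area_tbl$colony_id == i & area_tbl$day == d]
        if (a > 0) {
          r <- sqrt(a / pi)
          inside <- (yy - centers[i, 1])^2 + (xx - centers[i, 2])^2 <= r^2
          mask[inside] <- i
        }
      }
    }
    img <- tb$mean + correlated_noise(h, w, tb$sd, tb$corr_len)
    if (any(mask > 0)) {
      ctex <- tc$mean + correlated_noise(h, w, tc$sd, tc$corr_len)
      img[mask > 0] <- ctex[mask > 0]
    }
    img <- clamp16(img)
    storage.mode(img) <- "integer"
    frames[[di]] <- img
    masks[[di]] <- mask
  }

  list(frames = tibble::tibble(well = 1L, day = days, frame = frames),
       masks = tibble::tibble(day = days, mask = masks),
       areas = area_tbl,
       colonies = colonies,
       config = cfg)
}

#' Generate a fluorescence reporter image for a truth mask
#'
#' Emulates a pluripotency reporter channel: bright signal over a
#' `coverage_fraction` subset of the true colony area (reporter-negative
#' subregions are spatially coherent, mimicking the observed ~10% of cells not
#' expressing the reporter) on top of background noise. Signal level is
#' `reporter_snr` times the background noise standard deviation.
#'
#' @param truth_mask integer label matrix (0 = background).
#' @param reporter_snr signal-to-noise ratio; `Inf` gives a noise-free image.
#' @param coverage_fraction fraction of colony pixels carrying signal, in (0, 1].
#' @param seed RNG seed.
#' @param background_mean,background_sd background intensity model (16-bit).
#' @return numeric matrix, 16-bit range.
#' @export
generate_reporter <- function(truth_mask, reporter_snr = 10,
                              coverage_fraction = 0.9, seed = 1L,
                              background_mean = 1000, background_sd = 400) {
  stopifnot(coverage_fraction > 0, coverage_fraction <= 1)
  m <- as.matrix(truth_mask)
  set.seed(seed)
  h <- nrow(m); w <- ncol(m)
  noise_sd <- if (is.infinite(reporter_snr)) 0 else background_sd
  img <- background_mean + matrix(stats::rnorm(h * w, sd = noise_sd), h, w)
  fg <- m > 0
  if (any(fg)) {
    signal <- fg
    if (coverage_fraction < 1) {
      field <- blur_gaussian(matrix(stats::rnorm(h * w), h, w), 6)
      thr <- stats::quantile(field[fg], 1 - coverage_fraction)
      signal <- fg & (field >= thr)
    }
    level <- if (is.infinite(reporter_snr)) 50000 else reporter_snr * background_sd
    img[signal] <- img[signal] + level
  }
  clamp16(img)
}

#' Sample a labelled 96x96 patch dataset from a scene
#'
#' Draws `n_per_class` patches fully inside colony regions (label 0, the iPSC
#' class) and `n_per_class` fully in the background (label 1), following the
#' label convention that 0 marks the iPSC texture. Placement is uniform over
#' all valid top-left positions across the provided frames.
#'
#' @param frames tibble with `well`, `day`, `frame` as from [generate_scene()].
#' @param masks tibble with `day`, `mask` truth label matrices.
#' @param n_per_class patches per class.
#' @param seed RNG seed.
#' @param window patch side length (default 96).
#' @return tibble with `patch` (list of window x window matrices), `label`
#'   (0 = iPSC, 1 = non-iPSC), `well`, `day`, `x`, `y` (top-left, 1-based).
#' @export
generate_patch_dataset <- function(frames, masks, n_per_class, seed = 1L,
                                   window = 96L) {
  set.seed(seed)
  window <- as.integer(window)
  pos_pool <- list(); neg_pool <- list()
  for (k in seq_len(nrow(frames))) {
    d <- frames$day[k]
    mk <- masks$mask[[which(masks$day == d)[1]]]
    ws <- window_sums((mk > 0) * 1, window, window)
    full <- which(ws == window * window, arr.ind = TRUE)
    empty <- which(ws == 0, arr.ind = TRUE)
    if (nrow(full)) pos_pool[[length(pos_pool) + 1]] <-
      cbind(k, full[, 1, drop = FALSE], full[, 2, drop = FALSE])
    if (nrow(empty)) neg_pool[[length(neg_pool) + 1]] <-
      cbind(k, empty[, 1, drop = FALSE], empty[, 2, drop = FALSE])
  }
  pos <- do.call(rbind, pos_pool); neg <- do.call(rbind, neg_pool)
  if (is.null(pos) || nrow(pos) < n_per_class)
    stop("insufficient colony area to draw ", n_per_class,
         " fully-interior iPSC patches")
  if (is.null(neg) || nrow(neg) < n_per_class)
    stop("insufficient background area to draw ", n_per_class, " patches")
  take <- function(pool, n, label) {
    idx <- sample(nrow(pool), n)
    purrr::map_dfr(idx, function(j) {
      k <- pool[j, 1]; y <- pool[j, 2]; x <- pool[j, 3]
      tibble::tibble(
        patch = list(frames$frame[[k]][y:(y + window - 1), x:(x + window - 1)]),
        label = label, well = frames$well[k], day = frames$day[k],
        x = x, y = y)
    })
  }
  dplyr::bind_rows(take(pos, n_per_class, 0L), take(neg, n_per_class, 1L))
}

#' Simulate a cohort of colony growth curves (no imaging)
#'
#' Fast tabular counterpart of [generate_scene()] for the growth-phase model:
#' logistic area trajectories with multiplicative observation noise, expert
#' picking-day labels (first day the noiseless curve reaches
#' `maturity_fraction` of carrying capacity), and optionally planted abnormal
#' overgrowers with scaled rate and carrying capacity.
#'
#' @param n_normal,n_abnormal cohort composition.
#' @param day_range imaging days.
#' @param carrying_capacity,rate,onset_day,initial_area normal-growth
#'   parameter ranges; capacity and rate are drawn uniformly from the given
#'   2-vectors (scalars are fixed values), onset uniformly from its integer
#'   range.
#' @param abnormal_mult multiplier applied to both rate and carrying capacity
#'   of abnormal colonies (default 3).
#' @param noise_cv coefficient of variation of multiplicative area noise.
#' @param maturity_fraction picking-day definition.
#' @param seed RNG seed.
#' @return list with `curves` (tibble `track_id`, `day`, `area_px`) and
#'   `info` (tibble `track_id`, `status`, `picking_day`, `first_positive_day`,
#'   parameters).
#' @export
simulate_growth_cohort <- function(n_normal = 90, n_abnormal = 0,
                                   day_range = 7:22,
                                   carrying_capacity = c(15000, 30000),
                                   rate = c(0.45, 0.65),
                                   onset_day = c(7, 10),
                                   initial_area = 1200,
                                   abnormal_mult = 3,
                                   noise_cv = 0.05,
                                   maturity_fraction = 0.6,
                                   seed = 1L) {
  set.seed(seed)
  n <- n_normal + n_abnormal
  days <- sort(as.integer(day_range))
  draw <- function(rng, n) if (length(rng) == 2) stats::runif(n, rng[1], rng[2]) else rep(rng, n)
  K <- draw(carrying_capacity, n)
  r <- draw(rate, n)
  on <- round(draw(onset_day, n))
  status <- rep(c("normal", "overgrown"), c(n_normal, n_abnormal))
  K[status == "overgrown"] <- K[status == "overgrown"] * abnormal_mult
  r[status == "overgrown"] <- r[status == "overgrown"] * abnormal_mult

  curves <- purrr::map_dfr(seq_len(n), function(i) {
    a <- logistic_area(days, K[i], r[i], on[i], initial_area)
    keep <- a > 0
    obs <- a[keep] * exp(stats::rnorm(sum(keep), 0, noise_cv))
    tibble::tibble(track_id = i, day = days[keep], area_px = obs)
  })
  info <- purrr::map_dfr(seq_len(n), function(i) {
    a <- logistic_area(days, K[i], r[i], on[i], initial_area)
    pick <- days[which(a >= maturity_fraction * K[i])[1]]
    tibble::tibble(track_id = i, status = status[i], picking_day = pick,
                   first_positive_day = on[i], carrying_capacity = K[i],
                   rate = r[i], onset_day = on[i])
  })
  list(curves = curves, info = info)
}
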