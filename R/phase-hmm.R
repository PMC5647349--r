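#' Growth features of a colony curve
#'
#' The four per-day features the phase model observes: first-order area
#' difference, second-order area difference, area itself, and days since the
#' colony first appeared. Differences undefined at the start of the track are
#' set to 0 (dropping those days instead is available via `boundary`).
#'
#' @param curve tibble with `day`, `area_px` for one track (or `track_id`
#'   present for many; then `first_positive_day` is taken per track from the
#'   earliest day unless supplied in the data).
#' @param first_positive_day earliest day the colony was detected; defaults
#'   to the first day of the curve.
#' @param rate_type `"absolute"` (area differences, default) or `"relative"`
#'   (differences divided by current area).
#' @param boundary `"zero"` (default) or `"drop"` for the undefined leading
#'   differences.
#' @return tibble `track_id`, `day`, `d_area`, `dd_area`, `area`, `age`.
#' @export
extract_features <- function(curve, first_positive_day = NULL,
                             rate_type = c("absolute", "relative"),
                             boundary = c("zero", "drop")) {
  rate_type <- match.arg(rate_type)
  boundary <- match.arg(boundary)
  stopifnot(is.data.frame(curve), nrow(curve) > 0)
  if (!"track_id" %in% names(curve)) curve$track_id <- 1L
  one <- function(df) {
    df <- df[order(df$day), ]
    a <- df$area_px
    d1 <- c(0, diff(a))
    if (rate_type == "relative") d1 <- c(0, diff(a) / a[-length(a)])
    d2 <- c(0, diff(d1))
    fp <- if (is.null(first_positive_day)) min(df$day) else first_positive_day
    out <- tibble::tibble(track_id = df$track_id[1], day = df$day,
                          d_area = d1, dd_area = d2, area = a,
                          age = df$day - fp)
    if (boundary == "drop" && nrow(out) > 2) out <- out[-c(1, 2), ]
    out
  }
  curve |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_split() |>
    purrr::map_dfr(one)
}

#' Partial stage labels from expert picking days
#'
#' Encodes the two labelled stages used to anchor the phase model: the first
#' stage runs from the start of the track to two days after the colony first
#' shows, and the mature stage from one day ahead of the expert picking day to
#' the end. Everything between is unknown. The blocks must not overlap.
#'
#' @param curve tibble with `day` (one track).
#' @param picking_day expert picking day, within the curve's day range.
#' @param first_positive_day first day the colony shows (default: first day).
#' @return tibble `day`, `stage` with stage in `first`, `unknown`, `mature`.
#' @export
make_stage_labels <- function(curve, picking_day, first_positive_day = NULL) {
  stopifnot(is.data.frame(curve), nrow(curve) > 0)
  days <- sort(curve$day)
  fp <- if (is.null(first_positive_day)) min(days) else first_positive_day
  if (!(picking_day %in% days) && (picking_day < min(days) || picking_day > max(days)))
    stop("picking_day outside the curve's day range")
  first_end <- fp + 2
  mature_start <- picking_day - 1
  if (mature_start <= first_end)
    stop("degenerate colony: first-stage block (through day ", first_end,
         ") overlaps mature block (from day ", mature_start, ")")
  tibble::tibble(day = days,
                 stage = dplyr::case_when(days <= first_end ~ "first",
                                          days >= mature_start ~ "mature",
                                          TRUE ~ "unknown"))
}

#' Abnormal growth-curve filter
#'
#' Discriminates over/undergrown colonies by the mean first-order difference
#' of the growth curve between `day_lo` and `day_hi` (per-day rate over
#' consecutive observed days). Curves whose statistic falls outside `bounds`
#' are rejected. Default bounds are robust estimates of the cohort's 5th and
#' 95th percentiles (median +/- z[0.95] * MAD), so that gross outliers cannot
#' mask themselves when estimating the bounds. Curves with fewer than two
#' points in the window are rejected with reason
#' `"insufficient window coverage"`.
#'
#' @param curves tibble `track_id`, `day`, `area_px`.
#' @param day_lo,day_hi window (defaults 10 and 20).
#' @param bounds optional numeric `c(lo, hi)` overriding the defaults.
#' @return list with `normal` (curves subset), `rejected` (tibble `track_id`,
#'   `stat`, `reason`), `stats` (per-track statistic) and `bounds`.
#' @export
filter_abnormal <- function(curves, day_lo = 10, day_hi = 20, bounds = NULL) {
  stopifnot(is.data.frame(curves), nrow(curves) > 0)
  stats_tbl <- curves |>
    dplyr::filter(.data$day >= day_lo, .data$day <= day_hi) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::summarise(n_window = dplyr::n(),
                     stat = if (dplyr::n() >= 2)
                       mean(diff(.data$area_px) / diff(.data$day)) else NA_real_,
                     .groups = "drop")
  missing <- curves |>
    dplyr::distinct(.data$track_id) |>
    dplyr::anti_join(stats_tbl, by = "track_id") |>
    dplyr::mutate(n_window = 0L, stat = NA_real_)
  stats_tbl <- dplyr::bind_rows(stats_tbl, missing)

  s <- stats_tbl$stat[!is.na(stats_tbl$stat)]
  if (is.null(bounds)) {
    m <- stats::median(s); dev <- stats::mad(s)
    bounds <- c(m - stats::qnorm(0.95) * dev, m + stats::qnorm(0.95) * dev)
  }
  stats_tbl <- stats_tbl |>
    dplyr::mutate(reason = dplyr::case_when(
      is.na(.data$stat) ~ "insufficient window coverage",
      .data$stat < bounds[1] ~ "rate below lower bound",
      .data$stat > bounds[2] ~ "rate above upper bound",
      TRUE ~ NA_character_))
  rejected <- stats_tbl |>
    dplyr::filter(!is.na(.data$reason)) |>
    dplyr::select("track_id", "stat", "reason")
  normal <- curves |>
    dplyr::anti_join(rejected, by = "track_id")
  list(normal = normal, rejected = rejected,
       stats = dplyr::select(stats_tbl, "track_id", "stat"), bounds = bounds)
}

## ---- HMM internals ------------------------------------------------------

# emission log-density matrix T x K for standardized obs, with -Inf on
# clamped-out states
log_emissions <- function(obs, means, vars, mask) {
  T_ <- nrow(obs); K <- nrow(means)
  logB <- matrix(0, T_, K)
  for (k in seq_len(K)) {
    logB[, k] <- rowSums(stats::dnorm(obs, mean = matrix(means[k, ], T_,
                                                         ncol(obs), byrow = TRUE),
                                      sd = matrix(sqrt(vars[k, ]), T_,
                                                  ncol(obs), byrow = TRUE),
                                      log = TRUE))
  }
  logB[!mask] <- -Inf
  logB
}

# scaled forward-backward; returns loglik, gamma (T x K), xi_sum (K x K)
forward_backward <- function(pi, A, logB) {
  T_ <- nrow(logB); K <- ncol(logB)
  m <- apply(logB, 1, max)
  if (any(!is.finite(m))) return(NULL)
  B <- exp(logB - m)
  alpha <- matrix(0, T_, K); cc <- numeric(T_)
  a <- pi * B[1, ]
  cc[1] <- sum(a)
  if (cc[1] <= 0 || !is.finite(cc[1])) return(NULL)
  alpha[1, ] <- a / cc[1]
  if (T_ > 1) for (t in 2:T_) {
    a <- as.vector(alpha[t - 1, ] %*% A) * B[t, ]
    cc[t] <- sum(a)
    if (cc[t] <= 0 || !is.finite(cc[t])) return(NULL)
    alpha[t, ] <- a / cc[t]
  }
  beta <- matrix(0, T_, K)
  beta[T_, ] <- 1
  xi_sum <- matrix(0, K, K)
  if (T_ > 1) for (t in (T_ - 1):1) {
    bb <- B[t + 1, ] * beta[t + 1, ]
    beta[t, ] <- as.vector(A %*% bb) / cc[t + 1]
    xi <- (alpha[t, ] %o% bb) * A / cc[t + 1]
    xi_sum <- xi_sum + xi
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(loglik = sum(log(cc)) + sum(m), gamma = gamma, xi_sum = xi_sum)
}

lr_transition_init <- function(K, dwell) {
  A <- matrix(0, K, K)
  for (j in seq_len(K)) {
    if (j == K) { A[j, j] <- 1 } else {
      A[j, j] <- dwell
      A[j, (j + 1):K] <- (1 - dwell) / (K - j)
    }
  }
  A
}

# contiguous block assignment honoring first/mature clamps; middle split into
# equal-length periods over states 2..K-1
segmented_states <- function(T_, mask, K) {
  first_end <- 0L; mature_start <- T_ + 1L
  only <- function(t) { w <- which(mask[t, ]); if (length(w) == 1) w else 0L }
  for (t in seq_len(T_)) { if (only(t) == 1L) first_end <- t else break }
  for (t in T_:1) { if (only(t) == K) mature_start <- t else break }
  st <- integer(T_)
  if (first_end > 0) st[1:first_end] <- 1L
  if (mature_start <= T_) st[mature_start:T_] <- K
  mid <- which(st == 0L)
  if (length(mid)) {
    n_mid_states <- max(K - 2L, 1L)
    cuts <- ceiling(seq_along(mid) / (length(mid) / n_mid_states))
    cuts <- pmin(cuts, n_mid_states)
    st[mid] <- if (K > 2) 1L + cuts else pmin(cuts, K)
  }
  as.integer(pmin(pmax(st, 1L), K))
}

#' Fit the growth-phase hidden Markov model
#'
#' Multi-restart Baum-Welch estimation of a left-to-right Gaussian-emission
#' HMM over the four growth features, with partial stage labels clamping the
#' first and mature states during the E-step. Features are z-scored over the
#' training set and the transform is stored in the model. Each restart
#' initializes by segmenting every sequence — labelled first days to state 1,
#' labelled mature days to the last state, and the unlabelled middle split
#' into contiguous periods of similar length — then jitters the resulting
#' moments; EM iterates until the log-likelihood gain falls below `tol` or
#' `max_iter` iterations. The best-likelihood restart is returned.
#'
#' @param features long tibble `track_id`, `day` plus the feature columns.
#' @param labels optional tibble `track_id`, `day`, `stage`
#'   (`first`/`unknown`/`mature`); missing days are unknown.
#' @param n_states number of hidden states (default 4).
#' @param n_restarts Baum-Welch initializations (default 2000; tests and the
#'   pipeline use fewer).
#' @param seed RNG seed; restart seeds derive from it deterministically.
#' @param max_iter,tol EM stopping rule (defaults 500 and 1e-6).
#' @param var_floor emission variance floor on the standardized scale.
#' @param feature_cols observation columns (default the four growth features).
#' @param topology `"left_to_right"` (upper-triangular transitions, default)
#'   or `"full"`.
#' @return object of class `phase_hmm`.
#' @export
fit_phase_hmm <- function(features, labels = NULL, n_states = 4L,
                          n_restarts = 2000L, seed = 1L, max_iter = 500L,
                          tol = 1e-6, var_floor = 1e-6,
                          feature_cols = c("d_area", "dd_area", "area", "age"),
                          topology = c("left_to_right", "full")) {
  topology <- match.arg(topology)
  stopifnot(is.data.frame(features), nrow(features) > 0,
            all(feature_cols %in% names(features)), n_states >= 1)
  K <- as.integer(n_states)

  feats <- features |> dplyr::arrange(.data$track_id, .data$day)
  if (!is.null(labels)) {
    feats <- feats |>
      dplyr::left_join(dplyr::select(labels, "track_id", "day", "stage"),
                       by = c("track_id", "day"))
    feats$stage[is.na(feats$stage)] <- "unknown"
  } else feats$stage <- "unknown"

  X <- as.matrix(feats[, feature_cols])
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd); scale[scale == 0 | is.na(scale)] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")

  ids <- unique(feats$track_id)
  seqs <- lapply(ids, function(id) {
    rows <- which(feats$track_id == id)
    mask <- matrix(TRUE, length(rows), K)
    st <- feats$stage[rows]
    mask[st == "first", ] <- FALSE;  mask[st == "first", 1] <- TRUE
    mask[st == "mature", ] <- FALSE; mask[st == "mature", K] <- TRUE
    list(obs = Xs[rows, , drop = FALSE], mask = mask)
  })
  n_obs <- nrow(Xs)
  F_ <- length(feature_cols)

  run_em <- function(pi, A, means, vars) {
    ll_hist <- numeric(0)
    ll_prev <- -Inf
    for (it in seq_len(max_iter)) {
      g1 <- numeric(K); xi_tot <- matrix(0, K, K)
      wsum <- numeric(K)
      msum <- matrix(0, K, F_); vsum <- matrix(0, K, F_)
      ll <- 0
      for (s in seqs) {
        logB <- log_emissions(s$obs, means, vars, s$mask)
        fb <- forward_backward(pi, A, logB)
        if (is.null(fb)) return(NULL)
        ll <- ll + fb$loglik
        g <- fb$gamma
        g1 <- g1 + g[1, ]
        xi_tot <- xi_tot + fb$xi_sum
        wsum <- wsum + colSums(g)
        msum <- msum + t(g) %*% s$obs
        vsum <- vsum + t(g) %*% (s$obs^2)
      }
      ll_hist <- c(ll_hist, ll)
      if (is.finite(ll_prev) && ll - ll_prev < tol) break
      ll_prev <- ll
      # M-step
      pi <- g1 / sum(g1)
      rs <- rowSums(xi_tot)
      A_new <- A
      for (j in seq_len(K)) {
        if (rs[j] > 0) A_new[j, ] <- xi_tot[j, ] / rs[j]
      }
      if (topology == "left_to_right") {
        A_new[lower.tri(A_new)] <- 0
        A_new <- A_new / pmax(rowSums(A_new), .Machine$double.eps)
        A_new[K, ] <- 0; A_new[K, K] <- 1
      }
      A <- A_new
      ok <- wsum > .Machine$double.eps
      mu <- means; va <- vars
      mu[ok, ] <- msum[ok, , drop = FALSE] / wsum[ok]
      va[ok, ] <- vsum[ok, , drop = FALSE] / wsum[ok] - mu[ok, , drop = FALSE]^2
      va <- pmax(va, var_floor)
      means <- mu; vars <- va
    }
    list(pi = pi, A = A, means = means, vars = vars,
         loglik = ll_hist[length(ll_hist)], ll_history = ll_hist,
         n_iter = length(ll_hist))
  }

  # moments of the segmented initialization (shared across restarts)
  assign0 <- unlist(lapply(seqs, function(s) segmented_states(nrow(s$obs), s$mask, K)))
  base_means <- matrix(0, K, F_); base_vars <- matrix(1, K, F_)
  for (k in seq_len(K)) {
    rows <- assign0 == k
    if (any(rows)) {
      base_means[k, ] <- colMeans(Xs[rows, , drop = FALSE])
      v <- apply(Xs[rows, , drop = FALSE], 2, stats::var)
      v[is.na(v)] <- 1
      base_vars[k, ] <- pmax(v, var_floor)
    }
  }
  pi0 <- tabulate(vapply(seqs, function(s) segmented_states(nrow(s$obs), s$mask, K)[1],
                         integer(1)), K) + 0.5
  pi0 <- pi0 / sum(pi0)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    if (r == 1L) {
      means <- base_means; vars <- base_vars
      A <- lr_transition_init(K, 0.8)
      pi <- pi0
    } else {
      means <- base_means + matrix(stats::rnorm(K * F_, 0, 0.35), K, F_)
      vars <- pmax(base_vars * exp(matrix(stats::runif(K * F_, -0.5, 0.5), K, F_)),
                   var_floor)
      A <- lr_transition_init(K, stats::runif(1, 0.55, 0.95))
      pi <- pi0
    }
    if (topology == "full") {
      A <- matrix(1 / K, K, K) + matrix(stats::runif(K * K, 0, 0.1), K, K)
      A <- A / rowSums(A)
    }
    fit <- run_em(pi, A, means, vars)
    if (!is.null(fit) && is.finite(fit$loglik) &&
        (is.null(best) || fit$loglik > best$loglik)) {
      best <- fit
      best$restart <- r
    }
  }
  if (is.null(best)) stop("all Baum-Welch restarts degenerate")

  structure(list(n_states = K, feature_cols = feature_cols,
                 center = center, scale = scale,
                 pi = best$pi, A = best$A,
                 means = best$means, vars = best$vars,
                 loglik = best$loglik, ll_history = best$ll_history,
                 n_iter = best$n_iter, restart = best$restart,
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed),
                 topology = topology,
                 n_seq = length(seqs), n_obs = n_obs),
            class = "phase_hmm")
}

model_sequences <- function(model, features) {
  stopifnot(all(c("track_id", "day", model$feature_cols) %in% names(features)))
  feats <- features |> dplyr::arrange(.data$track_id, .data$day)
  X <- as.matrix(feats[, model$feature_cols])
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  ids <- unique(feats$track_id)
  list(feats = feats, ids = ids,
       rows = lapply(ids, function(id) which(feats$track_id == id)),
       Xs = Xs)
}

#' Decode growth phases with the Viterbi algorithm
#'
#' Maximum a posteriori state path per track; under the left-to-right
#' topology paths are monotone non-decreasing. Ties break toward the lower
#' state index.
#'
#' @param model a fitted `phase_hmm`.
#' @param features long feature tibble as used in fitting.
#' @return tibble `track_id`, `day`, `state`.
#' @export
viterbi_phases <- function(model, features) {
  ms <- model_sequences(model, features)
  K <- model$n_states
  logA <- log(model$A)
  logpi <- log(model$pi)
  mask_all <- matrix(TRUE, 1, K)
  out <- purrr::map_dfr(seq_along(ms$ids), function(i) {
    rows <- ms$rows[[i]]
    obs <- ms$Xs[rows, , drop = FALSE]
    T_ <- nrow(obs)
    logB <- log_emissions(obs, model$means, model$vars,
                          matrix(TRUE, T_, K))
    delta <- matrix(-Inf, T_, K)
    psi <- matrix(0L, T_, K)
    delta[1, ] <- logpi + logB[1, ]
    if (T_ > 1) for (t in 2:T_) {
      for (k in seq_len(K)) {
        v <- delta[t - 1, ] + logA[, k]
        j <- which.max(v)   # first max -> lower state on ties
        psi[t, k] <- j
        delta[t, k] <- v[j] + logB[t, k]
      }
    }
    path <- integer(T_)
    path[T_] <- which.max(delta[T_, ])
    if (T_ > 1) for (t in (T_ - 1):1) path[t] <- psi[t + 1, path[t + 1]]
    tibble::tibble(track_id = ms$ids[i], day = ms$feats$day[rows],
                   state = path)
  })
  out
}

#' Mature-phase posterior probabilities
#'
#' Forward-backward smoothing of the fitted model over each track; per-day
#' state posteriors sum to one, and the mature score is the posterior of the
#' final state.
#'
#' @inheritParams viterbi_phases
#' @return tibble `track_id`, `day`, `p1` ... `pK`, `p_mature`.
#' @export
mature_posterior <- function(model, features) {
  ms <- model_sequences(model, features)
  K <- model$n_states
  purrr::map_dfr(seq_along(ms$ids), function(i) {
    rows <- ms$rows[[i]]
    obs <- ms$Xs[rows, , drop = FALSE]
    logB <- log_emissions(obs, model$means, model$vars,
                          matrix(TRUE, nrow(obs), K))
    fb <- forward_backward(model$pi, model$A, logB)
    if (is.null(fb)) stop("forward-backward degenerate for track ", ms$ids[i])
    g <- fb$gamma
    colnames(g) <- paste0("p", seq_len(K))
    dplyr::bind_cols(tibble::tibble(track_id = ms$ids[i],
                                    day = ms$feats$day[rows]),
                     tibble::as_tibble(g),
                     tibble::tibble(p_mature = g[, K]))
  })
}

#' Sequence log-likelihood under the model
#'
#' @inheritParams viterbi_phases
#' @return tibble `track_id`, `loglik`.
#' @export
phase_loglik <- function(model, features) {
  ms <- model_sequences(model, features)
  K <- model$n_states
  purrr::map_dfr(seq_along(ms$ids), function(i) {
    rows <- ms$rows[[i]]
    obs <- ms$Xs[rows, , drop = FALSE]
    logB <- log_emissions(obs, model$means, model$vars,
                          matrix(TRUE, nrow(obs), K))
    fb <- forward_backward(model$pi, model$A, logB)
    tibble::tibble(track_id = ms$ids[i],
                   loglik = if (is.null(fb)) -Inf else fb$loglik)
  })
}

#' Picking decision from the mature-phase posterior
#'
#' Default rule: trigger on the first day the mature score reaches the
#' threshold (0.3); `rule = "closest"` instead picks the day whose score is
#' closest to the threshold. A score reaching `overgrowth_level` flags
#' overgrowth risk (random differentiation).
#'
#' @param posterior tibble `track_id`, `day`, `p_mature` from
#'   [mature_posterior()].
#' @param threshold picking threshold (default 0.3).
#' @param rule `"first_crossing"` (default) or `"closest"`.
#' @param overgrowth_level score treated as "reached 1" (default 0.99).
#' @return tibble `track_id`, `trigger_day` (NA when never reached),
#'   `overgrowth_risk`, `max_score`.
#' @export
picking_decision <- function(posterior, threshold = 0.3,
                             rule = c("first_crossing", "closest"),
                             overgrowth_level = 0.99) {
  rule <- match.arg(rule)
  stopifnot(all(c("track_id", "day", "p_mature") %in% names(posterior)),
            all(posterior$p_mature >= 0 & posterior$p_mature <= 1))
  posterior |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::summarise(
      trigger_day = if (rule == "first_crossing") {
        w <- which(.data$p_mature >= threshold)
        if (length(w)) .data$day[w[1]] else NA_integer_
      } else .data$day[which.min(abs(.data$p_mature - threshold))],
      overgrowth_risk = any(.data$p_mature >= overgrowth_level),
      max_score = max(.data$p_mature),
      .groups = "drop")
}

#' Calibrate the picking threshold against expert picking days
#'
#' Grid search for the threshold minimizing the mean absolute difference
#' between the triggered day and the expert day over labelled tracks; a
#' missing trigger costs the cohort's day span. Ties resolve to the smaller
#' threshold.
#'
#' @param posterior tibble from [mature_posterior()].
#' @param expert tibble `track_id`, `picking_day` (at least 5 tracks).
#' @param grid candidate thresholds in (0, 1).
#' @param rule decision rule passed to [picking_decision()].
#' @return the calibrated threshold (numeric scalar) with attribute `costs`,
#'   a tibble of the grid and its mean absolute day errors.
#' @export
calibrate_threshold <- function(posterior, expert,
                                grid = seq(0.01, 0.99, by = 0.01),
                                rule = "first_crossing") {
  stopifnot(is.data.frame(expert), nrow(expert) >= 5)
  span <- diff(range(posterior$day)) + 1
  costs <- vapply(grid, function(th) {
    dec <- picking_decision(posterior, threshold = th, rule = rule)
    j <- dplyr::inner_join(dec, expert, by = "track_id")
    mean(ifelse(is.na(j$trigger_day), span,
                abs(j$trigger_day - j$picking_day)))
  }, numeric(1))
  best <- grid[which.min(costs)]  # which.min takes the first -> smallest
  attr(best, "costs") <- tibble::tibble(threshold = grid, cost = costs)
  best
}

#' Sample feature sequences from a phase HMM
#'
#' Generates hidden state paths and Gaussian observations from explicit
#' parameters (or a fitted `phase_hmm`), on the raw feature scale if the
#' model carries a standardization transform.
#'
#' @param model list or `phase_hmm` with `pi`, `A`, `means`, `vars` (and
#'   optionally `center`, `scale`, `feature_cols`).
#' @param n_seq number of sequences.
#' @param len sequence length (scalar or vector recycled over sequences).
#' @param seed RNG seed.
#' @param first_day starting day index (default 7).
#' @return list with `features` (long tibble) and `states`
#'   (tibble `track_id`, `day`, `state`).
#' @export
sample_phase_hmm <- function(model, n_seq, len, seed = 1L, first_day = 7L) {
  set.seed(seed)
  K <- nrow(model$A)
  F_ <- ncol(model$means)
  fc <- model$feature_cols %||% paste0("f", seq_len(F_))
  center <- model$center %||% rep(0, F_)
  scale <- model$scale %||% rep(1, F_)
  len <- rep_len(len, n_seq)
  feats <- list(); states <- list()
  for (i in seq_len(n_seq)) {
    T_ <- len[i]
    st <- integer(T_)
    st[1] <- sample.int(K, 1, prob = model$pi)
    if (T_ > 1) for (t in 2:T_)
      st[t] <- sample.int(K, 1, prob = model$A[st[t - 1], ])
    obs <- matrix(stats::rnorm(T_ * F_,
                               mean = model$means[st, , drop = FALSE],
                               sd = sqrt(model$vars[st, , drop = FALSE])),
                  T_, F_)
    obs <- sweep(sweep(obs, 2, scale, "*"), 2, center, "+")
    colnames(obs) <- fc
    day <- first_day + seq_len(T_) - 1L
    feats[[i]] <- dplyr::bind_cols(tibble::tibble(track_id = i, day = day),
                                   tibble::as_tibble(obs))
    states[[i]] <- tibble::tibble(track_id = i, day = day, state = st)
  }
  list(features = dplyr::bind_rows(feats), states = dplyr::bind_rows(states))
}

#' Serialize / restore a phase HMM as JSON
#'
#' @param model a `phase_hmm`.
#' @param path file path.
#' @export
write_phase_hmm <- function(model, path) {
  stopifnot(inherits(model, "phase_hmm"))
  obj <- unclass(model)
  obj$format <- "colonyscope-phase-hmm"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_phase_hmm
#' @export
read_phase_hmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "colonyscope-phase-hmm"))
    stop("not a colonyscope phase HMM file")
  obj$format <- NULL
  obj$A <- as.matrix(obj$A)
  obj$means <- as.matrix(obj$means)
  obj$vars <- as.matrix(obj$vars)
  colnames(obj$means) <- colnames(obj$vars) <- obj$feature_cols
  structure(obj, class = "phase_hmm")
}

#' @export
print.phase_hmm <- function(x, ...) {
  cat("<phase_hmm> ", x$n_states, " states (left-to-right), features: ",
      paste(x$feature_cols, collapse = ", "), "\n", sep = "")
  cat("  loglik ", format(x$loglik), " after ", x$n_iter,
      " EM iterations (best of ", x$n_restarts, " restarts)\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
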