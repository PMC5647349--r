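# Independent oracles: exhaustive enumeration for HMM quantities and the
# absorbing-Markov-chain fundamental matrix for random-walker probabilities.
# These never call the package's forward/backward/Viterbi/solver code paths.

# all K^T state paths as a matrix (rows = paths)
all_paths <- function(K, T_) {
  as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
}

# emission density matrix T x K for diagonal-Gaussian emissions
oracle_emissions <- function(obs, means, vars) {
  T_ <- nrow(obs); K <- nrow(means)
  em <- matrix(0, T_, K)
  for (k in seq_len(K))
    em[, k] <- exp(rowSums(dnorm(obs,
                                 mean = matrix(means[k, ], T_, ncol(obs), byrow = TRUE),
                                 sd = matrix(sqrt(vars[k, ]), T_, ncol(obs), byrow = TRUE),
                                 log = TRUE)))
  em
}

# total likelihood by summing over every path
enum_loglik <- function(pi, A, obs, means, vars) {
  T_ <- nrow(obs); K <- length(pi)
  em <- oracle_emissions(obs, means, vars)
  P <- all_paths(K, T_)
  pr <- pi[P[, 1]] * em[cbind(1L, P[, 1])]
  if (T_ > 1) for (t in 2:T_)
    pr <- pr * A[cbind(P[, t - 1], P[, t])] * em[cbind(t, P[, t])]
  log(sum(pr))
}

# most probable path by enumeration; ties resolve to the lexicographically
# smallest path (lower state indices first), matching the decoder contract
enum_viterbi <- function(pi, A, obs, means, vars) {
  T_ <- nrow(obs); K <- length(pi)
  em <- oracle_emissions(obs, means, vars)
  P <- all_paths(K, T_)
  lp <- log(pi[P[, 1]]) + log(em[cbind(1L, P[, 1])])
  if (T_ > 1) for (t in 2:T_)
    lp <- lp + log(A[cbind(P[, t - 1], P[, t])]) + log(em[cbind(t, P[, t])])
  best <- which(lp == max(lp))
  if (length(best) > 1) {
    ord <- do.call(order, as.data.frame(P[best, , drop = FALSE]))
    best <- best[ord[1]]
  }
  as.integer(P[best, ])
}

# per-day state posteriors by enumeration
enum_posterior <- function(pi, A, obs, means, vars) {
  T_ <- nrow(obs); K <- length(pi)
  em <- oracle_emissions(obs, means, vars)
  P <- all_paths(K, T_)
  pr <- pi[P[, 1]] * em[cbind(1L, P[, 1])]
  if (T_ > 1) for (t in 2:T_)
    pr <- pr * A[cbind(P[, t - 1], P[, t])] * em[cbind(t, P[, t])]
  g <- matrix(0, T_, K)
  for (t in seq_len(T_)) for (k in seq_len(K))
    g[t, k] <- sum(pr[P[, t] == k])
  g / sum(pr)
}

# random LR-HMM instance generator for property tests
random_hmm_instance <- function(K, T_, F_ = 2, left_to_right = TRUE) {
  pi <- runif(K) + 0.1; pi <- pi / sum(pi)
  A <- matrix(runif(K * K) + 0.1, K, K)
  if (left_to_right) A[lower.tri(A)] <- 0
  A <- A / rowSums(A)
  means <- matrix(rnorm(K * F_, sd = 2), K, F_)
  vars <- matrix(runif(K * F_, 0.3, 2), K, F_)
  obs <- matrix(rnorm(T_ * F_, sd = 2), T_, F_)
  list(pi = pi, A = A, means = means, vars = vars, obs = obs)
}

# wrap explicit parameters as a phase_hmm with identity standardization
as_phase_hmm <- function(inst, feature_cols = NULL) {
  F_ <- ncol(inst$means)
  fc <- feature_cols %||% paste0("f", seq_len(F_))
  center <- rep(0, F_); names(center) <- fc
  scl <- rep(1, F_); names(scl) <- fc
  structure(list(n_states = length(inst$pi), feature_cols = fc,
                 center = center, scale = scl,
                 pi = inst$pi, A = inst$A,
                 means = inst$means, vars = inst$vars),
            class = "phase_hmm")
}

obs_to_features <- function(obs, feature_cols = NULL) {
  fc <- feature_cols %||% paste0("f", seq_len(ncol(obs)))
  colnames(obs) <- fc
  dplyr::bind_cols(tibble::tibble(track_id = 1L, day = seq_len(nrow(obs))),
                   tibble::as_tibble(obs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# absorbing-chain oracle for random-walker probabilities: transition matrix
# P = D^-1 W over all pixels, seeds absorbing; absorption probabilities from
# the fundamental matrix N = (I - Q)^-1, B = N R. Mirrors the edge-weight
# definition (range normalization, 4-connectivity, +1e-10 regularizer).
rw_oracle <- function(image, seeds, beta) {
  h <- nrow(image); w <- ncol(image); n <- h * w
  rng <- range(image)
  img <- if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1]) else image * 0
  id <- matrix(seq_len(n), h, w)
  W <- matrix(0, n, n)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (i < h) {
      wt <- exp(-beta * (img[i, j] - img[i + 1, j])^2) + 1e-10
      W[id[i, j], id[i + 1, j]] <- wt; W[id[i + 1, j], id[i, j]] <- wt
    }
    if (j < w) {
      wt <- exp(-beta * (img[i, j] - img[i, j + 1])^2) + 1e-10
      W[id[i, j], id[i, j + 1]] <- wt; W[id[i, j + 1], id[i, j]] <- wt
    }
  }
  P <- W / rowSums(W)
  s_idx <- which(as.vector(seeds) > 0)
  u_idx <- setdiff(seq_len(n), s_idx)
  labs <- sort(unique(seeds[seeds > 0]))
  out <- lapply(labs, function(l) {
    v <- numeric(n); v[s_idx] <- as.numeric(seeds[s_idx] == l); v
  })
  if (length(u_idx)) {
    Q <- P[u_idx, u_idx, drop = FALSE]
    R <- P[u_idx, s_idx, drop = FALSE]
    B <- solve(diag(length(u_idx)) - Q, R)
    for (k in seq_along(labs)) {
      out[[k]][u_idx] <- B %*% as.numeric(seeds[s_idx] == labs[k])
    }
  }
  names(out) <- as.character(labs)
  lapply(out, function(v) matrix(v, h, w))
}
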