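#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted phase HMM
#'
#' One row per state and feature with the emission mean and standard
#' deviation, on both the standardized and the raw feature scale.
#'
#' @param x a `phase_hmm`.
#' @param ... unused.
#' @return tibble `state`, `feature`, `mean`, `sd`, `mean_raw`, `sd_raw`,
#'   `dwell` (self-transition probability of the state).
#' @method tidy phase_hmm
#' @export
tidy.phase_hmm <- function(x, ...) {
  K <- x$n_states
  purrr::map_dfr(seq_len(K), function(k) {
    tibble::tibble(state = k, feature = x$feature_cols,
                   mean = x$means[k, ], sd = sqrt(x$vars[k, ]),
                   mean_raw = x$means[k, ] * x$scale + x$center,
                   sd_raw = sqrt(x$vars[k, ]) * x$scale,
                   dwell = x$A[k, k])
  })
}

#' Model-level summary of a fitted phase HMM
#'
#' @param x a `phase_hmm`.
#' @param ... unused.
#' @return one-row tibble `n_states`, `n_seq`, `n_obs`, `loglik`, `n_iter`,
#'   `n_restarts`, `restart`.
#' @method glance phase_hmm
#' @export
glance.phase_hmm <- function(x, ...) {
  tibble::tibble(n_states = x$n_states, n_seq = x$n_seq, n_obs = x$n_obs,
                 loglik = x$loglik, n_iter = x$n_iter,
                 n_restarts = x$n_restarts, restart = x$restart)
}

#' Summary of a trained patch classifier
#'
#' @param x a `patch_classifier`.
#' @param ... unused.
#' @return one-row tibble with training sizes, holdout accuracy, threshold
#'   and fine-tuning rounds.
#' @method glance patch_classifier
#' @export
glance.patch_classifier <- function(x, ...) {
  tibble::tibble(n_class0 = x$meta$n_class0, n_class1 = x$meta$n_class1,
                 hidden = x$size, holdout_accuracy = x$meta$holdout_accuracy,
                 threshold = x$threshold, rounds = x$meta$rounds)
}
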