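#' Sort per-epoch classifier outputs across channels
#'
#' For each epoch the per-channel SVM outputs are sorted in ascending order;
#' rank k over time then forms the k-th sorted output time series (column k of
#' the result), which is what the Kalman filter smooths.
#'
#' @param raw epochs x channels matrix of decision values.
#' @return matrix of the same shape, rows sorted ascending.
#' @export
sort_outputs <- function(raw) {
  raw <- as.matrix(raw)
  if (ncol(raw) == 1) return(raw)
  t(apply(raw, 1, sort))
}

#' Causal scalar Kalman filter (random-walk state, noisy observation)
#'
#' State model `x_k = x_{k-1} + w_k`, `w ~ N(0, q)`; observation
#' `z_k = x_k + v_k`, `v ~ N(0, r)`; standard predict/update recursion. With
#' `q = 0` and a diffuse initial variance the output converges to the running
#' mean; with large `q` the filter approaches the identity.
#'
#' @param z numeric series to filter.
#' @param q process variance (>= 0).
#' @param r measurement variance (> 0).
#' @param initial_state prior mean; defaults to the first observation.
#' @param initial_variance prior variance; defaults to `r`.
#' @return filtered series, same length as `z`.
#' @export
kalman_filter <- function(z, q = 0.01, r = 1,
                          initial_state = NULL, initial_variance = NULL) {
  stopifnot(q >= 0, r > 0)
  n <- length(z)
  if (n == 0) return(numeric(0))
  x <- initial_state %||% z[1]
  P <- initial_variance %||% r
  out <- numeric(n)
  for (k in seq_len(n)) {
    Pp <- P + q
    K <- Pp / (Pp + r)
    x <- x + K * (z[k] - x)
    # P = (1 - K) * Pp algebraically, but that form cancels catastrophically
    # for diffuse priors (K ~ 1); the product form is stable
    P <- Pp * r / (Pp + r)
    out[k] <- x
  }
  out
}

#' Steady-state Kalman gain for the random-walk model
#'
#' Solves the scalar Riccati fixed point for [kalman_filter()]'s model; the
#' steady-state output/input variance ratio for white-noise input is
#' `K / (2 - K)`.
#'
#' @param q process variance.
#' @param r measurement variance.
#' @return the steady-state gain K in (0, 1].
#' @export
kalman_steady_state_gain <- function(q, r) {
  P <- (-q + sqrt(q^2 + 4 * q * r)) / 2
  (P + q) / (P + q + r)
}

#' Full classifier-output post-processing
#'
#' Sorts the per-epoch channel outputs, Kalman-filters the sorted rank series
#' over time, and reduces to a per-epoch multi-channel score by taking the
#' maximum over ranks (equivalent to requiring detection in at least one
#' channel).
#'
#' @param raw epochs x channels matrix of decision values.
#' @param q,r Kalman parameters (see [kalman_filter()]).
#' @param filter_ranks `"all"` filters every rank series, `"max"` only the
#'   top-rank series, `"none"` disables filtering.
#' @return list with `sorted`, `filtered` (matrices) and `score` (per-epoch
#'   multi-channel score vector).
#' @export
postprocess_outputs <- function(raw, q = 0.01, r = 1,
                                filter_ranks = c("all", "max", "none")) {
  filter_ranks <- match.arg(filter_ranks)
  sorted <- sort_outputs(raw)
  filtered <- sorted
  if (filter_ranks == "all") {
    for (k in seq_len(ncol(sorted))) {
      filtered[, k] <- kalman_filter(sorted[, k], q = q, r = r)
    }
  } else if (filter_ranks == "max") {
    k <- ncol(sorted)
    filtered[, k] <- kalman_filter(sorted[, k], q = q, r = r)
  }
  list(sorted = sorted, filtered = filtered,
       score = apply(filtered, 1, max))
}

#' Threshold scores into binary epoch decisions
#'
#' @param scores per-epoch scores.
#' @param threshold detection threshold; decision 1 iff `score >= threshold`.
#' @return integer 0/1 vector.
#' @export
decide <- function(scores, threshold) {
  as.integer(scores >= threshold)
}
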