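#' Derive a child RNG seed from a master seed and a stream index
#'
#' Deterministic 31-bit mixing (multiplicative congruential rounds) so that
#' every stochastic stage of the pipeline (Monte Carlo run, training-set draw,
#' patient, recording) gets its own reproducible seed from one master seed.
#'
#' @param master integer master seed.
#' @param stream integer stream index (>= 0).
#' @return a single integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(master, stream) {
  m <- 2147483647
  x <- as.numeric(master) %% m
  s <- as.numeric(stream) %% m
  # two LCG rounds keep all products < 2^53 (exact in doubles)
  x <- (x * 69069 + s + 1) %% m
  x <- (x * 48271 + 7) %% m
  as.integer(x)
}

# Run code under a temporary RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# merge possibly-overlapping [start, end) intervals; returns sorted data.frame
merge_intervals <- function(ann) {
  if (is.null(ann) || nrow(ann) == 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  ann <- ann[order(ann$start_s), , drop = FALSE]
  out_s <- ann$start_s[1]
  out_e <- ann$end_s[1]
  if (nrow(ann) > 1) {
    for (i in 2:nrow(ann)) {
      if (ann$start_s[i] <= out_e[length(out_e)]) {
        out_e[length(out_e)] <- max(out_e[length(out_e)], ann$end_s[i])
      } else {
        out_s <- c(out_s, ann$start_s[i])
        out_e <- c(out_e, ann$end_s[i])
      }
    }
  }
  data.frame(start_s = out_s, end_s = out_e)
}

# overlap (seconds) of [a0,a1) with the union of merged intervals
interval_overlap <- function(a0, a1, intervals) {
  if (nrow(intervals) == 0) return(0)
  sum(pmax(0, pmin(a1, intervals$end_s) - pmax(a0, intervals$start_s)))
}
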