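#' Weighted isotonic regression along a given condition order
#'
#' Finds the weighted least-squares projection of \code{values} onto the cone
#' of vectors that are weakly nondecreasing along \code{order}, using the
#' pool-adjacent-violators algorithm. This is the one-variable building block
#' of conjoint monotonic regression: the best-fitting monotonic approximation
#' of one dependent variable under a candidate ordering of the conditions.
#'
#' @param values Numeric vector of observed condition values.
#' @param weights Strictly positive numeric vector of the same length
#'   (precision weights; unit weights give ordinary isotonic regression).
#' @param order Integer permutation of \code{seq_along(values)} giving the
#'   sequence along which the fit must be weakly nondecreasing. Defaults to the
#'   identity.
#' @return A list with components \code{fitted} (numeric vector, in the
#'   original condition indexing, weakly nondecreasing when listed in
#'   \code{order}) and \code{sse} (the minimised weighted sum of squared
#'   deviations).
#' @export
#' @examples
#' isotonic_fit(c(1, 0), c(1, 1))          # pools to (0.5, 0.5), sse 0.5
#' isotonic_fit(c(1, 2, 3), c(1, 1, 1))    # already monotone, sse 0
isotonic_fit <- function(values, weights = rep(1, length(values)),
                         order = seq_along(values)) {
  values <- as.numeric(values)
  weights <- as.numeric(weights)
  n <- length(values)
  if (length(weights) != n)
    stop("'values' and 'weights' must have the same length", call. = FALSE)
  if (anyNA(values) || anyNA(weights))
    stop("'values' and 'weights' must not contain missing values", call. = FALSE)
  if (any(weights <= 0))
    stop("all weights must be strictly positive", call. = FALSE)
  order <- as.integer(order)
  if (length(order) != n || !setequal(order, seq_len(n)))
    stop("'order' must be a permutation of seq_along(values)", call. = FALSE)
  res <- cpp_pava(values[order], weights[order])
  fitted <- numeric(n)
  fitted[order] <- res$fitted
  list(fitted = fitted, sse = res$sse)
}

# starting orders for the permutation search: a few deterministic rank-based
# starts plus random restarts drawn from the current RNG stream.
.cmr_starts <- function(x, y, n_random = 8L) {
  n <- length(x)
  rx <- rank(x, ties.method = "first")
  ry <- rank(y, ties.method = "first")
  det <- rbind(order(rx), order(ry), order(rx + ry), seq_len(n))
  if (n_random > 0L) {
    rnd <- t(vapply(seq_len(n_random), function(i) sample.int(n),
                    integer(n)))
    det <- rbind(det, rnd)
  }
  # 0-based for the C++ side
  det - 1L
}
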