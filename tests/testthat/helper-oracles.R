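# Independent reference implementations used to check the package's C++
# search paths. Deliberately naive: plain-R PAVA, full permutation
# enumeration, and (where available) a quadratic-programming solve of the
# order-constrained least-squares problem.

# all permutations of 1..n (n small)
perms_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms_of(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

# O(n^2) weighted PAVA, written independently of the package internals
pava_ref <- function(v, w) {
  n <- length(v)
  val <- as.numeric(v); wt <- as.numeric(w); len <- rep(1L, n)
  m <- n
  repeat {
    viol <- which(diff(val[seq_len(m)]) < 0)
    if (length(viol) == 0) break
    i <- viol[1]
    nv <- (val[i] * wt[i] + val[i + 1] * wt[i + 1]) / (wt[i] + wt[i + 1])
    val[i] <- nv; wt[i] <- wt[i] + wt[i + 1]; len[i] <- len[i] + len[i + 1]
    if (i + 2 <= m) {
      val[(i + 1):(m - 1)] <- val[(i + 2):m]
      wt[(i + 1):(m - 1)] <- wt[(i + 2):m]
      len[(i + 1):(m - 1)] <- len[(i + 2):m]
    }
    m <- m - 1L
  }
  fitted <- rep(val[seq_len(m)], times = len[seq_len(m)])
  list(fitted = fitted, sse = sum(w * (v - fitted)^2))
}

# brute-force conjoint monotonic regression: minimum over every total order
cmr_ref <- function(x, wx, y, wy) {
  n <- length(x)
  best <- Inf; best_ord <- seq_len(n)
  for (ord in perms_of(n)) {
    s <- pava_ref(x[ord], wx[ord])$sse + pava_ref(y[ord], wy[ord])$sse
    if (s < best) { best <- s; best_ord <- ord }
  }
  list(sse = best, order = best_ord)
}

# order-constrained least squares via quadratic programming (pracma):
# minimise sum w (v - f)^2 subject to f_1 <= f_2 <= ... <= f_n
iso_qp_ref <- function(v, w) {
  n <- length(v)
  C <- 2 * diag(w, n)
  d <- -2 * w * v
  A <- matrix(0, n - 1, n)
  for (i in seq_len(n - 1)) { A[i, i] <- 1; A[i, i + 1] <- -1 }
  sol <- pracma::quadprog(C, d, A = A, b = rep(0, n - 1))
  fitted <- sol$xmin
  list(fitted = fitted, sse = sum(w * (v - fitted)^2))
}

# build a scored state-trace dataset from a synthetic config
synth_state_trace <- function(cfg, dv_pair = c("think", "feel")) {
  d <- sample_dataset(cfg)
  tab <- endorsement_proportions(screen_dont_know(d$responses)$kept)
  g <- median_split(d$ep_scores)
  build_state_trace(tab, g, dv_pair)
}
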