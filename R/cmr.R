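#' Conjoint monotonic regression
#'
#' Fits the one-latent-dimension null model to a state-trace dataset: finds
#' the total order of conditions minimising the combined weighted sum of
#' squared deviations of the two dependent variables from values that are each
#' weakly nondecreasing along that common order. The minimised misfit
#' (\code{fit_stat}) is zero exactly when some ordering renders both mean
#' vectors jointly monotone, i.e. when the data are consistent with a single
#' latent variable under monotone measurement mappings (jointly decreasing
#' relations are covered automatically, by reversal of the order).
#'
#' @param data A \code{\link{state_trace}} object.
#' @param method Search strategy over total orders. \code{"exhaustive"}
#'   enumerates all permutations (allowed for up to 8 conditions);
#'   \code{"branch_and_bound"} is exact, pruning with the prefix isotonic-fit
#'   lower bound (practical to ~14 conditions); \code{"multistart"} is a
#'   heuristic local search with an insertion neighbourhood, used for larger
#'   designs and flagged \code{exact = FALSE}. \code{"auto"} (default) picks
#'   exhaustive for <= 8, branch-and-bound for <= 14, multistart above.
#' @param n_random_starts Number of random restarts added to the deterministic
#'   rank-based starting orders of the heuristic (also used to seed the
#'   branch-and-bound incumbent). Drawn from the current RNG stream.
#' @return An object of class \code{"cmr"}: a list with \code{order} (the
#'   optimal permutation of condition indices), \code{x_fitted} and
#'   \code{y_fitted} (monotone fitted values, original indexing),
#'   \code{fit_stat}, \code{exact}, \code{method} and the \code{data}.
#' @seealso \code{\link{cmr_test}} for the bootstrap test of the null.
#' @export
#' @examples
#' st <- state_trace(c(.2, .5, .9), c(.1, .4, .8))
#' cmr(st)                      # jointly monotone: fit_stat 0
#' st2 <- state_trace(c(0, 1), c(1, 0))
#' cmr(st2)$fit_stat            # forced pooling: 0.5
cmr <- function(data,
                method = c("auto", "exhaustive", "branch_and_bound", "multistart"),
                n_random_starts = 8L) {
  stopifnot(inherits(data, "state_trace"))
  method <- match.arg(method)
  n <- length(data$x_means)
  if (method == "auto")
    method <- if (n <= 8) "exhaustive" else if (n <= 14) "branch_and_bound" else "multistart"
  if (method == "exhaustive" && n > 8)
    stop("exhaustive search is limited to 8 conditions (", n,
         " requested); use method = \"branch_and_bound\" (exact, <= ~14) ",
         "or \"multistart\" (heuristic)", call. = FALSE)

  res <- .cmr_search(data$x_means, data$x_weights, data$y_means, data$y_weights,
                     method, n_random_starts)
  ord <- res$order
  fx <- isotonic_fit(data$x_means, data$x_weights, ord)
  fy <- isotonic_fit(data$y_means, data$y_weights, ord)

  structure(list(order = ord,
                 x_fitted = fx$fitted, y_fitted = fy$fitted,
                 fit_stat = res$sse,
                 exact = method %in% c("exhaustive", "branch_and_bound"),
                 method = method,
                 data = data,
                 call = match.call()),
            class = "cmr")
}

# shared permutation-search kernel working on raw vectors (also used by the
# bootstrap loop, which must avoid rebuilding state_trace objects)
.cmr_search <- function(x, wx, y, wy, method, n_random_starts = 8L) {
  n <- length(x)
  res <- switch(method,
    exhaustive = cpp_cmr_exhaustive(x, wx, y, wy),
    branch_and_bound = cpp_cmr_branch_bound(x, wx, y, wy,
                                            .cmr_starts(x, y, n_random_starts)),
    multistart = cpp_cmr_multistart(x, wx, y, wy,
                                    .cmr_starts(x, y, n_random_starts)))
  # Jointly monotone data must yield an exact zero, but the block-sum
  # arithmetic of the isotonic fit can leave O(eps) residue when the fit
  # interpolates the data.  Snap below a scale-relative threshold.
  scale <- sum(wx * x^2) + sum(wy * y^2)
  sse <- max(res$sse, 0)
  if (sse <= 1e-10 * max(scale, 1)) sse <- 0
  list(order = res$order + 1L, sse = sse)
}

#' @export
print.cmr <- function(x, digits = 4, ...) {
  cat("Conjoint monotonic regression (", length(x$order), " conditions)\n", sep = "")
  cat("  method: ", x$method, if (x$exact) " (exact)" else " (heuristic)",
      "\n", sep = "")
  cat("  fit_stat (combined weighted SSE): ",
      format(x$fit_stat, digits = digits), "\n", sep = "")
  if (x$fit_stat <= 1e-9)
    cat("  data are jointly monotone: consistent with one latent dimension\n")
  invisible(x)
}

#' @export
summary.cmr <- function(object, ...) {
  d <- object$data
  tab <- data.frame(condition = .label_strings(d$condition_labels),
                    x_mean = d$x_means, x_fitted = object$x_fitted,
                    y_mean = d$y_means, y_fitted = object$y_fitted)
  tab <- tab[object$order, , drop = FALSE]
  structure(list(fit = object, table = tab), class = "summary.cmr")
}

#' @export
print.summary.cmr <- function(x, digits = 4, ...) {
  print(x$fit)
  cat("\nConditions in the fitted common order:\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.cmr <- function(object, ...) {
  m <- cbind(x_fitted = object$x_fitted, y_fitted = object$y_fitted)
  colnames(m) <- paste0(object$data$dv_names, "_fitted")
  rownames(m) <- .label_strings(object$data$condition_labels)
  m
}

#' @export
fitted.cmr <- function(object, ...) coef(object)

#' @export
residuals.cmr <- function(object, ...) {
  m <- cbind(object$data$x_means - object$x_fitted,
             object$data$y_means - object$y_fitted)
  colnames(m) <- object$data$dv_names
  rownames(m) <- .label_strings(object$data$condition_labels)
  m
}
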