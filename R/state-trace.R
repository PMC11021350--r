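#' Construct a state-trace dataset
#'
#' Bundles the condition means of two dependent variables (and their precision
#' weights, and optionally the per-participant values backing each mean) into
#' the object consumed by \code{\link{cmr}} and \code{\link{cmr_test}}.
#'
#' Weights are precisions: with across-participant standard deviation
#' \eqn{s_c} and \eqn{n_c} contributing participants in condition \eqn{c}, the
#' default weight is \eqn{n_c / s_c^2}, so that \eqn{1/\sqrt{w_c}} is the
#' standard error of the condition mean. If backing matrices are supplied and
#' weights are not, weights are computed this way; otherwise unit weights are
#' used.
#'
#' @param x_means,y_means Numeric vectors of condition means (one per
#'   condition, same length, length >= 2).
#' @param x_weights,y_weights Optional strictly positive precision weights.
#' @param backing_x,backing_y Optional participant-by-condition matrices of the
#'   per-participant values behind each mean (NAs allowed for cells a
#'   participant cannot contribute to). Column means must reproduce the
#'   supplied means.
#' @param condition_labels Optional character vector or data frame labelling
#'   the conditions.
#' @param dv_names Length-2 character vector naming the two dependent
#'   variables.
#' @return An object of class \code{"state_trace"}.
#' @export
#' @examples
#' st <- state_trace(c(.2, .5, .9), c(.1, .4, .8), dv_names = c("think", "feel"))
#' st
state_trace <- function(x_means, y_means,
                        x_weights = NULL, y_weights = NULL,
                        backing_x = NULL, backing_y = NULL,
                        condition_labels = NULL,
                        dv_names = c("x", "y")) {
  x_means <- as.numeric(x_means)
  y_means <- as.numeric(y_means)
  n <- length(x_means)
  if (n < 2)
    stop("a state-trace dataset needs at least 2 conditions", call. = FALSE)
  if (length(y_means) != n)
    stop("'x_means' and 'y_means' must have the same length", call. = FALSE)
  if (anyNA(x_means) || anyNA(y_means))
    stop("condition means must not be missing", call. = FALSE)

  w_from_backing <- function(b, means, lab) {
    b <- as.matrix(b)
    if (ncol(b) != n)
      stop(sprintf("'backing_%s' must have one column per condition", lab),
           call. = FALSE)
    cm <- colMeans(b, na.rm = TRUE)
    if (max(abs(cm - means)) > 1e-8)
      stop(sprintf("column means of 'backing_%s' do not reproduce the supplied means", lab),
           call. = FALSE)
    nc <- colSums(!is.na(b))
    if (any(nc < 2))
      stop(sprintf("every condition needs >= 2 contributing participants in 'backing_%s'", lab),
           call. = FALSE)
    v <- apply(b, 2, var, na.rm = TRUE)
    v <- pmax(v, 1e-4)  # variance floor keeps precisions finite for degenerate cells
    nc / v
  }

  if (!is.null(backing_x)) backing_x <- as.matrix(backing_x)
  if (!is.null(backing_y)) backing_y <- as.matrix(backing_y)
  if (is.null(x_weights))
    x_weights <- if (is.null(backing_x)) rep(1, n) else w_from_backing(backing_x, x_means, "x")
  if (is.null(y_weights))
    y_weights <- if (is.null(backing_y)) rep(1, n) else w_from_backing(backing_y, y_means, "y")
  x_weights <- as.numeric(x_weights)
  y_weights <- as.numeric(y_weights)
  if (length(x_weights) != n || length(y_weights) != n)
    stop("weights must have one entry per condition", call. = FALSE)
  if (any(x_weights <= 0) || any(y_weights <= 0))
    stop("weights must be strictly positive", call. = FALSE)
  if (!is.null(backing_x) && !is.null(backing_y) &&
      nrow(backing_x) != nrow(backing_y))
    stop("backing matrices must have the same participants (rows)", call. = FALSE)
  if (is.null(condition_labels))
    condition_labels <- paste0("C", seq_len(n))
  if (length(dv_names) != 2)
    stop("'dv_names' must have length 2", call. = FALSE)

  structure(list(condition_labels = condition_labels,
                 x_means = x_means, y_means = y_means,
                 x_weights = x_weights, y_weights = y_weights,
                 backing_x = backing_x, backing_y = backing_y,
                 dv_names = as.character(dv_names)),
            class = "state_trace")
}

#' @export
print.state_trace <- function(x, ...) {
  cat("State-trace dataset:", length(x$x_means), "conditions;",
      "DVs:", paste(x$dv_names, collapse = " vs "), "\n")
  cat("  backing data:",
      if (is.null(x$backing_x)) "none (means + weights only)"
      else paste0(nrow(x$backing_x), " participants"), "\n")
  df <- data.frame(condition = .label_strings(x$condition_labels),
                   x_mean = round(x$x_means, 4), y_mean = round(x$y_means, 4),
                   x_se = round(1 / sqrt(x$x_weights), 4),
                   y_se = round(1 / sqrt(x$y_weights), 4))
  names(df)[2:5] <- c(paste0(x$dv_names[1], "_mean"), paste0(x$dv_names[2], "_mean"),
                      paste0(x$dv_names[1], "_se"), paste0(x$dv_names[2], "_se"))
  print(df, row.names = FALSE)
  invisible(x)
}

.label_strings <- function(labels) {
  if (is.data.frame(labels)) {
    if ("condition" %in% names(labels)) return(as.character(labels$condition))
    return(do.call(paste, c(lapply(labels, as.character), sep = ".")))
  }
  as.character(labels)
}
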