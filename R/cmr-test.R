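#' Bootstrap test of the one-latent-dimension null
#'
#' Tests whether the observed departure from joint monotonicity (the CMR
#' \code{fit_stat}) is larger than expected if the monotonic model were true.
#' Bootstrap datasets are generated under the fitted monotonic null and the
#' CMR statistic is recomputed for each; the p-value is the add-one proportion
#' of bootstrap statistics at least as large as the observed one,
#' \eqn{(1 + \#\{T^*_b \ge T\}) / (B + 1)}.
#'
#' Two resampling modes are available. \code{"participant_resample"} (needs
#' backing matrices) resamples participants with replacement, recomputes the
#' condition means, and recentres each resampled mean vector on the fitted
#' monotone values (a mean shift, so the null holds exactly in the resampling
#' world while the dependence structure of the data is preserved). The
#' precision weights are held fixed at their observed values in both modes:
#' they are constants of the weighted least-squares statistic, not
#' re-estimated nuisance parameters. \code{"parametric_normal"} draws each
#' condition mean independently from a normal distribution centred on the
#' fitted monotone value with standard deviation \eqn{1/\sqrt{w_c}} (the
#' standard error implied by the precision weight), which is the procedure for
#' summary-statistics input.
#'
#' @param data A \code{\link{state_trace}} object.
#' @param n_boot Number of bootstrap samples (>= 1). 10,000 is a sensible
#'   default for analyses; 199–999 for simulation studies.
#' @param seed Integer master seed; every random draw (including the heuristic
#'   search restarts) derives from it, so results are bit-for-bit reproducible
#'   given \code{(seed, n_boot, mode)}. If \code{NULL} a seed is drawn and
#'   recorded.
#' @param mode Resampling scheme, see Details.
#' @param method Order-search strategy passed to \code{\link{cmr}}; the same
#'   strategy is used for the observed and the bootstrap statistics.
#' @param m Multiplicity for the Bonferroni-adjusted p-value
#'   (\code{p_adjusted = min(1, m * p_value)}); 1 leaves p unadjusted.
#' @param n_random_starts Random restarts for the heuristic search.
#' @return An object of class \code{"cmr_test"}: the fitted \code{model}
#'   (class \code{"cmr"}), \code{observed_stat}, \code{boot_stats},
#'   \code{p_value}, \code{p_adjusted}, \code{n_boot}, \code{seed},
#'   \code{mode}.
#' @export
#' @examples
#' st <- state_trace(c(.2, .5, .9), c(.1, .4, .8))
#' cmr_test(st, n_boot = 99, seed = 1, mode = "parametric_normal")$p_value  # 1
cmr_test <- function(data, n_boot = 10000L, seed = NULL,
                     mode = c("participant_resample", "parametric_normal"),
                     method = c("auto", "exhaustive", "branch_and_bound", "multistart"),
                     m = 1L, n_random_starts = 8L) {
  stopifnot(inherits(data, "state_trace"))
  mode <- match.arg(mode)
  method <- match.arg(method)
  n_boot <- as.integer(n_boot)
  if (is.na(n_boot) || n_boot < 1)
    stop("'n_boot' must be a positive integer", call. = FALSE)
  if (mode == "participant_resample" &&
      (is.null(data$backing_x) || is.null(data$backing_y)))
    stop("mode \"participant_resample\" requires backing matrices; ",
         "use mode = \"parametric_normal\" for means + dispersions only",
         call. = FALSE)
  if (is.null(seed))
    seed <- sample.int(.Machine$integer.max, 1L)
  seed <- as.integer(seed)
  set.seed(seed)

  fit <- cmr(data, method = method, n_random_starts = n_random_starts)
  obs <- fit$fit_stat
  n <- length(data$x_means)
  search_method <- fit$method  # resolved from "auto"

  boot_stats <- numeric(n_boot)
  if (mode == "parametric_normal") {
    se_x <- 1 / sqrt(data$x_weights)
    se_y <- 1 / sqrt(data$y_weights)
    for (b in seq_len(n_boot)) {
      xb <- rnorm(n, fit$x_fitted, se_x)
      yb <- rnorm(n, fit$y_fitted, se_y)
      boot_stats[b] <- .cmr_search(xb, data$x_weights, yb, data$y_weights,
                                   search_method, n_random_starts)$sse
    }
  } else {
    bx <- data$backing_x
    by <- data$backing_y
    np <- nrow(bx)
    shift_x <- fit$x_fitted - data$x_means
    shift_y <- fit$y_fitted - data$y_means
    # weights are treated as fixed constants of the statistic (standard
    # weighted-least-squares bootstrap): only the condition means are
    # recomputed from each resample
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(np, np, replace = TRUE)
        sx <- .col_stats(bx[idx, , drop = FALSE])
        sy <- .col_stats(by[idx, , drop = FALSE])
        if (all(sx$n >= 2) && all(sy$n >= 2)) break
      }
      xb <- sx$mean + shift_x
      yb <- sy$mean + shift_y
      boot_stats[b] <- .cmr_search(xb, data$x_weights, yb, data$y_weights,
                                   search_method, n_random_starts)$sse
    }
  }

  p <- (1 + sum(boot_stats >= obs)) / (n_boot + 1)
  structure(list(model = fit,
                 observed_stat = obs,
                 boot_stats = boot_stats,
                 p_value = p,
                 p_adjusted = adjust_pvalues(p, m),
                 n_boot = n_boot, seed = seed, mode = mode,
                 m = as.integer(m)),
            class = "cmr_test")
}

# column means / variances / counts of a participant x condition matrix with NAs
# (colSums arithmetic; apply(var) is too slow for the bootstrap inner loop)
.col_stats <- function(b) {
  ok <- !is.na(b)
  n <- colSums(ok)
  b0 <- b
  b0[!ok] <- 0
  s1 <- colSums(b0)
  s2 <- colSums(b0 * b0)
  mu <- s1 / n
  v <- ifelse(n > 1, pmax(s2 - s1^2 / n, 0) / (n - 1), 0)
  list(mean = mu, var = v, n = n)
}

#' CMR test from published summary statistics
#'
#' Runs the conjoint-monotonic-regression bootstrap test from a table of
#' group-level summary statistics (mean, SD, N per condition and dependent
#' variable), the mode used when reanalysing published results where raw data
#' are unavailable. SDs are used to estimate the variability of the data,
#' assuming normally distributed observations: condition weights are the
#' precisions \eqn{n/\mathrm{sd}^2} and the parametric bootstrap draws each
#' condition mean from \eqn{N(\mathrm{fitted}, \mathrm{sd}/\sqrt{n})}.
#'
#' @param input Data frame with columns \code{condition}, \code{dv},
#'   \code{mean}, \code{sd}, \code{n}: exactly two dependent variables, both
#'   present for every condition, \code{sd > 0}, \code{n >= 2}. See
#'   \code{\link{read_summary_stats}} for the file dialect.
#' @inheritParams cmr_test
#' @return A \code{"cmr_test"} object (mode \code{"parametric_normal"}).
#' @export
cmr_from_summary <- function(input, n_boot = 10000L, seed = NULL,
                             method = c("auto", "exhaustive", "branch_and_bound",
                                        "multistart"),
                             m = 1L, n_random_starts = 8L) {
  input <- as.data.frame(input)
  need <- c("condition", "dv", "mean", "sd", "n")
  if (!all(need %in% names(input)))
    stop("summary input must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  input$sd <- as.numeric(input$sd)
  input$n <- as.numeric(input$n)
  input$mean <- as.numeric(input$mean)
  if (any(!is.finite(input$sd)) || any(input$sd <= 0))
    stop("all SDs must be strictly positive", call. = FALSE)
  if (any(!is.finite(input$n)) || any(input$n < 2))
    stop("all Ns must be >= 2", call. = FALSE)
  dvs <- unique(input$dv)
  if (length(dvs) != 2)
    stop("summary input must contain exactly two dependent variables, got ",
         length(dvs), call. = FALSE)
  conds <- unique(input$condition)
  a <- input[input$dv == dvs[1], ]
  b <- input[input$dv == dvs[2], ]
  a <- a[match(conds, a$condition), ]
  b <- b[match(conds, b$condition), ]
  if (anyNA(a$mean) || anyNA(b$mean))
    stop("both dependent variables must be present for every condition",
         call. = FALSE)
  st <- state_trace(a$mean, b$mean,
                    x_weights = a$n / a$sd^2, y_weights = b$n / b$sd^2,
                    condition_labels = as.character(conds),
                    dv_names = as.character(dvs))
  cmr_test(st, n_boot = n_boot, seed = seed, mode = "parametric_normal",
           method = method, m = m, n_random_starts = n_random_starts)
}

#' Read a summary-statistics table
#'
#' Reads the delimited dialect \code{condition,dv,mean,sd,n} (comma or tab,
#' autodetected) used by \code{\link{cmr_from_summary}}.
#'
#' @param path Path to the file.
#' @return A data frame.
#' @export
read_summary_stats <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .detect_sep(path)
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("condition", "dv", "mean", "sd", "n")
  if (!all(need %in% names(df)))
    stop("expected header ", paste(need, collapse = ","), call. = FALSE)
  df
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the number of tests in the family and caps at 1.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param m Number of tests in the family (>= 1).
#' @return Adjusted p-values, \code{pmin(1, m * p)}.
#' @export
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.03), m = 3)
adjust_pvalues <- function(p_values, m) {
  p_values <- as.numeric(p_values)
  m <- as.integer(m)
  if (is.na(m) || m < 1) stop("'m' must be a positive integer", call. = FALSE)
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  pmin(1, m * p_values)
}

#' @export
print.cmr_test <- function(x, digits = 4, ...) {
  cat("CMR bootstrap test of the one-latent-dimension null\n")
  cat("  DVs: ", paste(x$model$data$dv_names, collapse = " vs "),
      "  (", length(x$model$order), " conditions)\n", sep = "")
  cat("  observed fit_stat: ", format(x$observed_stat, digits = digits),
      "   [search: ", x$model$method,
      if (x$model$exact) ", exact]" else ", heuristic]", "\n", sep = "")
  cat("  bootstrap: ", x$mode, ", B = ", x$n_boot, ", seed = ", x$seed,
      "\n", sep = "")
  cat("  p = ", format(x$p_value, digits = digits), sep = "")
  if (x$m > 1)
    cat(";  Bonferroni (m = ", x$m, ") adjusted p = ",
        format(x$p_adjusted, digits = digits), sep = "")
  cat("\n")
  concl <- if (x$p_adjusted < 0.05)
    "reject the single-latent-dimension null (p < .05)"
  else "no significant departure from a single monotone curve"
  cat("  ", concl, "\n", sep = "")
  invisible(x)
}

#' @export
summary.cmr_test <- function(object, ...) {
  print(object)
  invisible(summary(object$model))
}

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}
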