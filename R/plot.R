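.exchange_palette <- c(sincere = "#1b9e77", simple_sarcasm = "#d95f02",
                       paradoxical_sarcasm = "#7570b3", sarcasm = "#e7298a",
                       lying = "#66a61e")

# marker by item type, fill by EP group (filled = high)
.pch_for <- function(item_type, group) {
  ifelse(item_type == "target",
         ifelse(group == "high", 19, 1),
         ifelse(group == "high", 17, 2))
}

#' State-trace plot
#'
#' Scatter of the condition means of one dependent variable against the other,
#' optionally with standard-error bars and the best-fitting monotonic curve
#' (dashed line through the fitted values in the model's common order). When
#' the conditions carry the full design labels, colour encodes exchange type
#' and marker shape/fill encode item type and emotion-perception group.
#'
#' @param x A \code{\link{state_trace}} object.
#' @param model Optional \code{\link{cmr}} fit whose monotone curve to draw.
#' @param error_bars \code{"se"} (default; bars of length \eqn{1/\sqrt{w}} per
#'   axis) or \code{"none"}.
#' @param main Plot title.
#' @param show_legend Draw the design legend when design labels are present.
#' @param ... Further arguments passed to \code{plot}.
#' @return Invisibly, \code{x}.
#' @export
plot.state_trace <- function(x, model = NULL,
                             error_bars = c("se", "none"),
                             main = NULL, show_legend = TRUE, ...) {
  error_bars <- match.arg(error_bars)
  labs <- x$condition_labels
  designed <- is.data.frame(labs) &&
    all(c("exchange_type", "item_type", "group") %in% names(labs))
  col <- if (designed) .exchange_palette[labs$exchange_type] else "black"
  pch <- if (designed) .pch_for(labs$item_type, labs$group) else 19

  se_x <- 1 / sqrt(x$x_weights)
  se_y <- 1 / sqrt(x$y_weights)
  xl <- range(c(x$x_means - se_x, x$x_means + se_x))
  yl <- range(c(x$y_means - se_y, x$y_means + se_y))
  plot(x$x_means, x$y_means, col = col, pch = pch,
       xlab = paste(x$dv_names[1], "endorsement rate"),
       ylab = paste(x$dv_names[2], "endorsement rate"),
       xlim = xl, ylim = yl,
       main = if (is.null(main)) paste(x$dv_names[1], "vs", x$dv_names[2]) else main,
       ...)
  if (error_bars == "se") {
    suppressWarnings({  # zero-length arrows on tiny SEs
      arrows(x$x_means - se_x, x$y_means, x$x_means + se_x, x$y_means,
             angle = 90, code = 3, length = 0.02, col = "grey50")
      arrows(x$x_means, x$y_means - se_y, x$x_means, x$y_means + se_y,
             angle = 90, code = 3, length = 0.02, col = "grey50")
    })
  }
  if (!is.null(model)) {
    stopifnot(inherits(model, "cmr"))
    lines(model$x_fitted[model$order], model$y_fitted[model$order],
          lty = 2, lwd = 1.5)
    points(x$x_means, x$y_means, col = col, pch = pch)
  }
  if (designed && show_legend) {
    legend("topleft",
           legend = c(names(.exchange_palette),
                      "target/high", "target/low", "lure/high", "lure/low"),
           col = c(.exchange_palette, rep("grey30", 4)),
           pch = c(rep(15, 5), 19, 1, 17, 2),
           cex = 0.7, bty = "n", ncol = 2)
  }
  invisible(x)
}

#' @export
plot.cmr <- function(x, ...) {
  plot.state_trace(x$data, model = x, ...)
  invisible(x)
}

#' @export
plot.cmr_test <- function(x, which = c("trace", "bootstrap"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    plot.state_trace(x$model$data, model = x$model, ...)
  } else {
    hist(x$boot_stats, breaks = 30,
         main = "Bootstrap null distribution of the CMR statistic",
         xlab = "fit_stat", ...)
    abline(v = x$observed_stat, lty = 2, lwd = 2)
  }
  invisible(x)
}

#' Render a state-trace plot to a file
#'
#' Writes the state-trace plot (points, SE bars, dashed best-fitting monotonic
#' curve) to a PDF or PNG, chosen by file extension.
#'
#' @param data A \code{\link{state_trace}} object.
#' @param model Optional \code{\link{cmr}} fit.
#' @param file Output path ending in \code{.pdf} or \code{.png}.
#' @param width,height Device size in inches.
#' @param ... Passed to \code{\link{plot.state_trace}}.
#' @return The path, invisibly.
#' @export
render_state_trace <- function(data, model = NULL, file,
                               width = 7, height = 5.5, ...) {
  ext <- tolower(tools::file_ext(file))
  dir <- dirname(file)
  if (!dir.exists(dir))
    stop("output directory does not exist: ", dir, call. = FALSE)
  switch(ext,
         pdf = pdf(file, width = width, height = height),
         png = png(file, width = width * 100, height = height * 100, res = 100,
                   type = "cairo"),
         stop("unsupported image format: .", ext, " (use .pdf or .png)",
              call. = FALSE))
  on.exit(dev.off())
  plot.state_trace(data, model = model, ...)
  invisible(file)
}
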