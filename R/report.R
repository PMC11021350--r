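#' Write analysis reports
#'
#' Serialises a CMR test (or the bundle of three pairwise analyses) as a
#' structured text report and/or a machine-readable JSON file containing the
#' common order, fitted values, misfit statistic, p-values, and everything
#' needed to reproduce the run exactly (seed, n_boot, mode, software
#' version). Output is deterministic: identical inputs and seed give
#' byte-identical files.
#'
#' @param x A \code{"cmr_test"} or \code{"cmr_analyses"} object.
#' @param json,txt Output paths (either may be \code{NULL} to skip).
#' @return Invisibly, the list that was serialised.
#' @export
write_report <- function(x, json = NULL, txt = NULL) UseMethod("write_report")

.report_list <- function(x) {
  stopifnot(inherits(x, "cmr_test"))
  d <- x$model$data
  list(dv_names = d$dv_names,
       condition_labels = .label_strings(d$condition_labels),
       order = x$model$order,
       x_means = d$x_means, y_means = d$y_means,
       x_fitted = x$model$x_fitted, y_fitted = x$model$y_fitted,
       fit_stat = x$observed_stat,
       p_value = x$p_value,
       p_adjusted = x$p_adjusted,
       m = x$m,
       n_boot = x$n_boot, seed = x$seed, mode = x$mode,
       search_method = x$model$method, exact = x$model$exact,
       package_version = as.character(packageVersion("statrace")))
}

.report_text <- function(x) {
  l <- .report_list(x)
  c(sprintf("CMR state-trace analysis: %s vs %s",
            l$dv_names[1], l$dv_names[2]),
    sprintf("conditions: %d", length(l$order)),
    sprintf("search: %s (%s)", l$search_method,
            if (l$exact) "exact" else "heuristic"),
    sprintf("fit_stat: %.10g", l$fit_stat),
    sprintf("bootstrap: mode=%s B=%d seed=%d", l$mode, l$n_boot, l$seed),
    sprintf("p_value: %.10g", l$p_value),
    sprintf("p_adjusted (m=%d): %.10g", l$m, l$p_adjusted),
    sprintf("package_version: %s", l$package_version),
    "",
    "conditions in fitted order (condition, x_mean, x_fitted, y_mean, y_fitted):",
    sprintf("  %s %.6f %.6f %.6f %.6f",
            formatC(l$condition_labels[l$order], width = max(nchar(l$condition_labels))),
            l$x_means[l$order], l$x_fitted[l$order],
            l$y_means[l$order], l$y_fitted[l$order]))
}

#' @export
write_report.cmr_test <- function(x, json = NULL, txt = NULL) {
  l <- .report_list(x)
  if (!is.null(json))
    jsonlite::write_json(l, json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(txt))
    writeLines(.report_text(x), txt)
  invisible(l)
}

#' @export
write_report.cmr_analyses <- function(x, json = NULL, txt = NULL) {
  l <- lapply(x$results, .report_list)
  l$master_seed <- x$seed
  if (!is.null(json))
    jsonlite::write_json(l, json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(txt)) {
    lines <- unlist(lapply(names(x$results), function(nm)
      c(paste0("== ", nm, " =="), .report_text(x$results[[nm]]), "")))
    writeLines(lines, txt)
  }
  invisible(l)
}
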