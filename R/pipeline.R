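#' Read item-level yes/no/don't-know responses
#'
#' Reads the delimited item-response dialect with header
#' \code{participant_id,part,scene_id,exchange_type,question_type,item_type,response}
#' (comma or tab autodetected, UTF-8). Tokens are normalised
#' case-insensitively; \code{"don't know"} / \code{"don't_know"} /
#' \code{"dontknow"} are accepted for \code{dont_know}. One record per row;
#' nothing is dropped at this stage.
#'
#' Part/exchange consistency is enforced: Part Two scenes carry only sincere,
#' simple-sarcasm and paradoxical-sarcasm exchanges; Part Three only sarcasm
#' (enriched) and lying.
#'
#' @param path Path to the file.
#' @return A data frame of item responses, one row per original row.
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .detect_sep(path)
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE, strip.white = TRUE,
                 colClasses = "character", fileEncoding = "UTF-8")
  need <- c("participant_id", "part", "scene_id", "exchange_type",
            "question_type", "item_type", "response")
  if (!all(need %in% names(df)))
    stop("expected header ", paste(need, collapse = ","), "; got ",
         paste(names(df), collapse = ","), call. = FALSE)
  df <- df[need]
  validate_responses(df)
}

#' Validate (and normalise) a table of item responses
#'
#' @param df Data frame with the columns of \code{\link{read_responses}}.
#' @return The normalised data frame, invisibly usable downstream.
#' @export
validate_responses <- function(df) {
  norm <- function(x) tolower(trimws(as.character(x)))
  df$part <- norm(df$part)
  df$exchange_type <- norm(df$exchange_type)
  df$question_type <- norm(df$question_type)
  df$item_type <- norm(df$item_type)
  r <- norm(df$response)
  r[r %in% c("don't know", "don't_know", "dontknow", "dk", "dont know")] <- "dont_know"
  df$response <- r

  bad_row <- function(ok, what, allowed) {
    if (!all(ok))
      stop("row ", which(!ok)[1], ": unknown ", what, " token '",
           df[[what]][which(!ok)[1]], "' (allowed: ",
           paste(allowed, collapse = ", "), ")", call. = FALSE)
  }
  bad_row(df$part %in% c("two", "three"), "part", c("two", "three"))
  bad_row(df$exchange_type %in% .exchange_levels, "exchange_type", .exchange_levels)
  bad_row(df$question_type %in% .question_levels, "question_type", .question_levels)
  bad_row(df$item_type %in% .item_levels, "item_type", .item_levels)
  bad_row(df$response %in% c("yes", "no", "dont_know"), "response",
          c("yes", "no", "dont_know"))

  mismatch <- .part_of_exchange[df$exchange_type] != df$part
  if (any(mismatch))
    stop("row ", which(mismatch)[1], ": exchange type '",
         df$exchange_type[which(mismatch)[1]],
         "' is not a Part ", df$part[which(mismatch)[1]], " exchange",
         call. = FALSE)
  df
}

#' Remove "don't know" responses
#'
#' Don't-know responses are treated as missing data and removed before any
#' scoring; they contribute to neither the numerator nor the denominator of
#' endorsement proportions. The removal rate is reported against ALL input
#' rows (including "say" control rows, if present).
#'
#' @param responses Data frame from \code{\link{read_responses}}.
#' @return A list with \code{kept} (the screened data frame) and \code{report}
#'   (\code{n_dont_know}, \code{pct} = percentage of input rows removed).
#' @export
screen_dont_know <- function(responses) {
  n_total <- nrow(responses)
  is_dk <- responses$response == "dont_know"
  kept <- responses[!is_dk, , drop = FALSE]
  rownames(kept) <- NULL
  report <- list(n_dont_know = sum(is_dk),
                 pct = if (n_total > 0) 100 * sum(is_dk) / n_total else 0)
  list(kept = kept, report = report)
}

#' Per-participant endorsement proportions
#'
#' Scores screened responses as the proportion of "yes" decisions per
#' participant within each cell of the social exchange type x probe question
#' (think/do/feel) x item type (target/lure) crossing — the endorsement-rate
#' dependent measure of the signal-detection framing, computed separately for
#' target items (correct answer yes) and lure items (correct answer no).
#' "Say" control questions are parsed upstream but excluded here. Cells with
#' no contributing items are reported missing (\code{n_items = 0}).
#'
#' @param responses Screened data frame (no dont_know rows; any remaining are
#'   dropped defensively).
#' @return A data frame (one row per participant x exchange x question x item
#'   type, full crossing) with \code{proportion} and \code{n_items}.
#' @export
endorsement_proportions <- function(responses) {
  df <- responses[responses$question_type %in% .analysis_questions &
                    responses$response != "dont_know", , drop = FALSE]
  parts <- sort(unique(responses$participant_id))
  grid <- expand.grid(participant_id = parts,
                      exchange_type = .exchange_levels,
                      question_type = .analysis_questions,
                      item_type = .item_levels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    key <- interaction(df$participant_id, df$exchange_type, df$question_type,
                       df$item_type, drop = FALSE)
    yes <- tapply(df$response == "yes", key, sum)
    tot <- tapply(rep(1L, nrow(df)), key, sum)
    gkey <- paste(grid$participant_id, grid$exchange_type, grid$question_type,
                  grid$item_type, sep = ".")
    grid$n_items <- as.integer(tot[gkey])
    grid$n_items[is.na(grid$n_items)] <- 0L
    grid$proportion <- as.numeric(yes[gkey]) / grid$n_items
    grid$proportion[grid$n_items == 0L] <- NA_real_
  } else {
    grid$n_items <- 0L
    grid$proportion <- NA_real_
  }
  grid <- grid[order(grid$participant_id, match(grid$exchange_type, .exchange_levels),
                     match(grid$question_type, .analysis_questions),
                     match(grid$item_type, .item_levels)), ]
  rownames(grid) <- NULL
  class(grid) <- c("endorsement_table", "data.frame")
  grid
}

#' Median split on emotion-perception scores
#'
#' Dichotomises Emotion Evaluation Test totals (0–28) into high / low
#' emotion-perceptual-ability groups at the sample median. Scores strictly
#' above the median go to \code{"high"}; scores at or below the median
#' (including ties at the median) go to \code{"low"}.
#'
#' @param ep_scores Named numeric vector, participant id -> score in 0–28.
#' @return An object of class \code{"ep_grouping"}: \code{group} (named
#'   character vector, \code{"high"}/\code{"low"}), \code{ep_score},
#'   \code{median_value}.
#' @export
#' @examples
#' median_split(c(a = 20, b = 21, c = 24, d = 25))
median_split <- function(ep_scores) {
  if (length(ep_scores) == 0) stop("no scores supplied", call. = FALSE)
  if (is.null(names(ep_scores)) || any(!nzchar(names(ep_scores))))
    stop("'ep_scores' must be named by participant id", call. = FALSE)
  s <- as.numeric(ep_scores)
  if (anyNA(s) || any(s < 0 | s > 28))
    stop("scores must lie in 0-28", call. = FALSE)
  med <- median(s)
  group <- ifelse(s > med, "high", "low")
  names(group) <- names(ep_scores)
  structure(list(group = group, ep_score = ep_scores, median_value = med),
            class = "ep_grouping")
}

#' @export
print.ep_grouping <- function(x, ...) {
  cat("Emotion-perception median split (median = ", x$median_value, ")\n",
      sep = "")
  for (g in c("high", "low")) {
    sc <- as.numeric(x$ep_score[x$group == g])
    cat(sprintf("  %-4s n = %3d  M = %.2f  SD = %.2f\n", g, length(sc),
                mean(sc), sd(sc)))
  }
  invisible(x)
}

#' Build a state-trace dataset for one pair of dependent variables
#'
#' Assembles the 20-condition state-trace dataset (5 exchange types x 2 item
#' types x 2 emotion-perception groups) for a pair of probe-question dependent
#' variables. Condition means are across-participant means of per-participant
#' endorsement proportions; precision weights come from the across-participant
#' variance and count; the per-participant matrices are retained for
#' participant resampling.
#'
#' Participants missing more than \code{max_missing} of their cells (on either
#' variable) are excluded wholesale; otherwise a participant is simply absent
#' from the cells they cannot contribute to.
#'
#' @param table Endorsement table from \code{\link{endorsement_proportions}}.
#' @param grouping \code{\link{median_split}} result covering the scored
#'   participants.
#' @param dv_pair Two distinct question types among think/do/feel; first is x.
#' @param max_missing Maximum tolerated fraction of missing cells per
#'   participant before wholesale exclusion (default 0.2).
#' @return A \code{\link{state_trace}} object with 20 conditions labelled by
#'   \code{\link{condition_grid}}.
#' @export
build_state_trace <- function(table, grouping, dv_pair, max_missing = 0.2) {
  dv_pair <- as.character(dv_pair)
  if (length(dv_pair) != 2 || !all(dv_pair %in% .analysis_questions) ||
      dv_pair[1] == dv_pair[2])
    stop("'dv_pair' must be two distinct question types among ",
         paste(.analysis_questions, collapse = ", "), call. = FALSE)
  stopifnot(inherits(grouping, "ep_grouping"))
  parts <- sort(unique(table$participant_id))
  missing_group <- setdiff(parts, names(grouping$group))
  if (length(missing_group) > 0)
    stop("no emotion-perception group for participant(s): ",
         paste(utils::head(missing_group, 5), collapse = ", "), call. = FALSE)
  grid <- condition_grid()

  dv_matrix <- function(dv) {
    sub <- table[table$question_type == dv, , drop = FALSE]
    m <- matrix(NA_real_, nrow = length(parts), ncol = nrow(grid),
                dimnames = list(parts, grid$condition))
    pg <- grouping$group[sub$participant_id]
    cond <- paste(sub$exchange_type, sub$item_type, pg, sep = ".")
    idx <- cbind(match(sub$participant_id, parts), match(cond, grid$condition))
    m[idx] <- sub$proportion
    m
  }
  mx <- dv_matrix(dv_pair[1])
  my <- dv_matrix(dv_pair[2])

  # wholesale exclusion: fraction of a participant's OWN 10 x-cells (their
  # group's columns) that are missing
  frac_missing <- function(m) {
    per_group_cols <- split(seq_len(nrow(grid)), grid$group)
    vapply(seq_along(parts), function(i) {
      cols <- per_group_cols[[grouping$group[parts[i]]]]
      mean(is.na(m[i, cols]))
    }, numeric(1))
  }
  drop <- frac_missing(mx) > max_missing | frac_missing(my) > max_missing
  if (any(drop)) {
    mx <- mx[!drop, , drop = FALSE]
    my <- my[!drop, , drop = FALSE]
  }
  nx <- colSums(!is.na(mx))
  ny <- colSums(!is.na(my))
  if (any(nx < 2) || any(ny < 2))
    stop("condition(s) with fewer than 2 contributing participants: ",
         paste(grid$condition[nx < 2 | ny < 2], collapse = ", "), call. = FALSE)

  state_trace(colMeans(mx, na.rm = TRUE), colMeans(my, na.rm = TRUE),
              backing_x = mx, backing_y = my,
              condition_labels = grid, dv_names = dv_pair)
}

#' Run the three pairwise state-trace analyses
#'
#' Runs the CMR bootstrap test for the three dependent-variable pairings that
#' probe theory-of-mind dimensionality: think vs feel (first-order cognitive
#' vs affective), do vs feel (second-order cognitive vs affective) and think
#' vs do (first- vs second-order cognitive), Bonferroni-adjusting each p-value
#' for the family of three tests.
#'
#' @param table Endorsement table from \code{\link{endorsement_proportions}}.
#' @param grouping \code{\link{median_split}} result.
#' @param n_boot Bootstrap samples per analysis.
#' @param seed Master seed; analysis i uses \code{seed + i - 1}.
#' @param mode,method,n_random_starts Passed to \code{\link{cmr_test}}.
#' @return An object of class \code{"cmr_analyses"}: a named list of three
#'   \code{"cmr_test"} results (\code{think_feel}, \code{do_feel},
#'   \code{think_do}).
#' @export
run_three_analyses <- function(table, grouping, n_boot = 10000L, seed = 1L,
                               mode = "participant_resample",
                               method = "auto", n_random_starts = 8L) {
  pairs <- list(think_feel = c("think", "feel"),
                do_feel = c("do", "feel"),
                think_do = c("think", "do"))
  seed <- as.integer(seed)
  res <- vector("list", length(pairs))
  names(res) <- names(pairs)
  for (i in seq_along(pairs)) {
    st <- build_state_trace(table, grouping, pairs[[i]])
    res[[i]] <- cmr_test(st, n_boot = n_boot, seed = seed + i - 1L,
                         mode = mode, method = method, m = 3L,
                         n_random_starts = n_random_starts)
  }
  structure(list(results = res, seed = seed, n_boot = as.integer(n_boot),
                 mode = mode), class = "cmr_analyses")
}

#' @export
print.cmr_analyses <- function(x, digits = 4, ...) {
  cat("Three pairwise state-trace analyses (CMR bootstrap, Bonferroni m = 3)\n")
  cat("  mode = ", x$mode, ", B = ", x$n_boot, ", master seed = ", x$seed,
      "\n", sep = "")
  tab <- data.frame(
    analysis = names(x$results),
    fit_stat = vapply(x$results, function(r) r$observed_stat, numeric(1)),
    p = vapply(x$results, function(r) r$p_value, numeric(1)),
    p_bonferroni = vapply(x$results, function(r) r$p_adjusted, numeric(1)))
  tab[-1] <- lapply(tab[-1], signif, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Export an endorsement table
#'
#' @param table Endorsement table.
#' @param path Output path (comma-delimited).
#' @return The path, invisibly.
#' @export
write_endorsement_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
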