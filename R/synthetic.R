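#' Configuration for the synthetic response generator
#'
#' Defines a generative model with known latent dimensionality over the full
#' 20-condition design (5 exchange types x 2 item types x 2 emotion-perception
#' groups) and three dependent variables (think/do/feel).
#'
#' Under \code{"one_latent"} each condition has a single latent value
#' \eqn{\theta_c} and every dependent variable maps it through its own
#' monotone logistic link, \eqn{p_{dv}(c) = \mathrm{logit}^{-1}(a_{dv}
#' \theta_c + b_{dv})}, so the population cell probabilities of any two DVs
#' are jointly monotone (zero CMR misfit). Under \code{"two_latent"} a second
#' latent pushes the DVs apart: condition \eqn{c} receives a perturbation
#' \eqn{\delta s_c} on the latent scale with sign \eqn{s_c} alternating along
#' the \eqn{\theta} ranking and DV loadings (think 0, do -1, feel +1), which
#' guarantees a crossing — no common order exists at population level — for
#' every DV pair as soon as \eqn{\delta > 0}.
#'
#' The \code{delta} presets \code{"small"}, \code{"medium"} and \code{"large"}
#' are 0.25, 0.5 and 1.0 on the latent (logit) scale.
#'
#' @param model \code{"one_latent"} or \code{"two_latent"}.
#' @param n_participants Number of simulated participants (>= 4; half per
#'   emotion-perception group). Default 114, a typical healthy-older-adult
#'   sample size for this design.
#' @param items_per_cell Items per condition x DV cell in the \code{"grid"}
#'   layout (default 4).
#' @param theta Vector of 20 latent condition values in the
#'   \code{\link{condition_grid}} ordering. The default spreads exchange-type
#'   effects (-0.5 to 0.5), separates targets from lures (+/-1.6, so targets
#'   sit at high and lures at low endorsement rates) and gives the high EP
#'   group a +0.5 latent advantage over the low group.
#' @param delta Departure magnitude (nonnegative; \code{two_latent} only), a
#'   number or one of the presets. \code{delta = 0} reduces \code{two_latent}
#'   to \code{one_latent} exactly.
#' @param link_params Data frame \code{dv, slope, intercept} for the three
#'   logistic links (slopes must be positive).
#' @param participant_sd SD of the participant random intercept on the latent
#'   scale (default 0.3; set 0 for idealised data).
#' @param dont_know_rate Probability that a scored response is replaced by
#'   "don't know" (default 0.004, i.e. the under-1\% regime).
#' @param include_say Emit "say" control rows as well (default TRUE).
#' @param seed Integer seed; all sampling derives from it.
#' @return An object of class \code{"synth_config"}.
#' @export
synth_config <- function(model = c("one_latent", "two_latent"),
                         n_participants = 114L,
                         items_per_cell = 4L,
                         theta = NULL,
                         delta = 0,
                         link_params = NULL,
                         participant_sd = 0.3,
                         dont_know_rate = 0.004,
                         include_say = TRUE,
                         seed = 1L) {
  model <- match.arg(model)
  n_participants <- as.integer(n_participants)
  items_per_cell <- as.integer(items_per_cell)
  if (is.na(n_participants) || n_participants < 4)
    stop("'n_participants' must be >= 4 (>= 2 per group)", call. = FALSE)
  if (is.na(items_per_cell) || items_per_cell < 1)
    stop("'items_per_cell' must be >= 1", call. = FALSE)
  grid <- condition_grid()
  if (is.null(theta)) {
    ex_eff <- setNames(seq(-0.5, 0.5, length.out = 5), .exchange_levels)
    theta <- ex_eff[grid$exchange_type] +
      ifelse(grid$item_type == "target", 1.6, -1.6) +
      ifelse(grid$group == "high", 0.25, -0.25)
    theta <- unname(theta)
  }
  theta <- as.numeric(theta)
  if (length(theta) != nrow(grid) || anyNA(theta))
    stop("'theta' must be a complete vector of ", nrow(grid),
         " latent condition values", call. = FALSE)
  if (is.character(delta)) {
    presets <- c(small = 0.25, medium = 0.5, large = 1.0)
    if (!delta %in% names(presets))
      stop("unknown delta preset '", delta, "'", call. = FALSE)
    delta <- presets[[delta]]
  }
  delta <- as.numeric(delta)
  if (is.na(delta) || delta < 0)
    stop("'delta' must be nonnegative", call. = FALSE)
  if (model == "one_latent") delta <- 0
  if (is.null(link_params))
    link_params <- data.frame(dv = c("think", "do", "feel"),
                              slope = c(1.0, 0.9, 1.1),
                              intercept = c(0.0, -0.1, 0.1),
                              stringsAsFactors = FALSE)
  if (!all(c("dv", "slope", "intercept") %in% names(link_params)) ||
      !setequal(link_params$dv, .analysis_questions))
    stop("'link_params' needs rows for think, do, feel with slope and intercept",
         call. = FALSE)
  if (any(link_params$slope <= 0))
    stop("link slopes must be positive (monotone increasing links)", call. = FALSE)
  if (participant_sd < 0) stop("'participant_sd' must be >= 0", call. = FALSE)
  if (dont_know_rate < 0 || dont_know_rate >= 1)
    stop("'dont_know_rate' must be in [0, 1)", call. = FALSE)
  structure(list(model = model, n_participants = n_participants,
                 items_per_cell = items_per_cell, theta = theta,
                 delta = delta, link_params = link_params,
                 participant_sd = participant_sd,
                 dont_know_rate = dont_know_rate,
                 include_say = isTRUE(include_say),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# per-DV latent values after the second-latent perturbation (20 x 3 matrix)
.effective_theta <- function(config) {
  grid <- condition_grid()
  th <- config$theta
  loading <- c(think = 0, do = -1, feel = 1)
  s <- ifelse(rank(th, ties.method = "first") %% 2 == 0, 1, -1)
  out <- sapply(.analysis_questions, function(dv) th + config$delta * s * loading[dv])
  rownames(out) <- grid$condition
  out
}

#' Population cell probabilities implied by a synthetic configuration
#'
#' The probability of a "yes" response in every condition x DV cell for the
#' average participant (random intercept at 0).
#'
#' @param config A \code{\link{synth_config}}.
#' @return A data frame: condition labels, \code{dv}, \code{theta} (effective
#'   latent value for that DV) and \code{probability}.
#' @export
cell_probabilities <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  grid <- condition_grid()
  te <- .effective_theta(config)
  lp <- config$link_params
  out <- do.call(rbind, lapply(.analysis_questions, function(dv) {
    a <- lp$slope[lp$dv == dv]
    b <- lp$intercept[lp$dv == dv]
    data.frame(grid, dv = dv, theta = te[, dv],
               probability = plogis(a * te[, dv] + b),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Population state trace for a DV pair
#'
#' The population cell probabilities of two dependent variables as a
#' \code{\link{state_trace}} (unit weights). Under \code{one_latent} its CMR
#' misfit is exactly zero; under \code{two_latent} with \code{delta > 0} it is
#' strictly positive.
#'
#' @param config A \code{\link{synth_config}}.
#' @param dv_pair Two distinct DVs among think/do/feel.
#' @return A \code{\link{state_trace}}.
#' @export
population_state_trace <- function(config, dv_pair = c("think", "feel")) {
  p <- cell_probabilities(config)
  grid <- condition_grid()
  px <- p$probability[p$dv == dv_pair[1]]
  py <- p$probability[p$dv == dv_pair[2]]
  state_trace(px, py, condition_labels = grid, dv_names = dv_pair)
}

# scene table for the "tasit" layout: 31 scenes (Part Two: 5 sincere, 5
# simple-sarcasm, 5 paradoxical-sarcasm; Part Three: 8 enriched-sarcasm, 8
# lying), 4 probe questions each, item type fixed per scene x question in an
# alternating pattern so every (exchange, question, target/lure) cell is
# populated. This is a synthetic stand-in for the commercial instrument's
# structure (counts per cell are not those of the real test form).
.tasit_layout <- function() {
  n_scenes <- c(sincere = 5L, simple_sarcasm = 5L, paradoxical_sarcasm = 5L,
                sarcasm = 8L, lying = 8L)
  rows <- list()
  sc <- 0L
  for (ex in .exchange_levels) {
    for (j in seq_len(n_scenes[[ex]])) {
      sc <- sc + 1L
      for (qi in seq_along(.question_levels)) {
        rows[[length(rows) + 1L]] <- data.frame(
          part = .part_of_exchange[[ex]],
          scene_id = sprintf("S%02d", sc),
          exchange_type = ex,
          question_type = .question_levels[qi],
          item_type = if ((j + qi) %% 2 == 0) "target" else "lure",
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# pseudo-scene table for the "grid" layout: items_per_cell scenes per
# (exchange, item type), each carrying all four questions with that item type
.grid_layout <- function(items_per_cell, include_say) {
  qs <- if (include_say) .question_levels else .analysis_questions
  g <- expand.grid(k = seq_len(items_per_cell),
                   question_type = qs,
                   item_type = .item_levels,
                   exchange_type = .exchange_levels,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(part = unname(.part_of_exchange[g$exchange_type]),
             scene_id = sprintf("%s_%s_%02d",
                                toupper(substr(g$exchange_type, 1, 3)),
                                substr(g$item_type, 1, 1), g$k),
             exchange_type = g$exchange_type,
             question_type = g$question_type,
             item_type = g$item_type,
             stringsAsFactors = FALSE)
}

#' Simulate an item-level response dataset
#'
#' Draws a full dataset in the item-response dialect from a synthetic
#' configuration. Emotion-perception scores are drawn per group (high: M
#' 24.92, SD 0.96; low: M 20.90, SD 2.50, rounded and clipped to 0–28, the
#' profile of a healthy-older-adult sample) and the generating groups are then
#' defined by the generator's own median split of those scores, so the
#' pipeline's \code{\link{median_split}} recovers them exactly. Each
#' participant receives a normal random intercept on the latent scale;
#' responses are Bernoulli draws at the logistic cell probability. A small
#' fraction of scored (non-"say") responses is replaced by "don't know".
#'
#' @param config A \code{\link{synth_config}}.
#' @param layout \code{"grid"}: \code{items_per_cell} items per condition x DV
#'   cell (rows per participant = 5 x 2 x 3 x items_per_cell, plus say rows if
#'   enabled). \code{"tasit"}: the 31-scene two-part structure (93 scored + 31
#'   say responses per participant).
#' @param n_dont_know Exact number of don't-know responses to inject
#'   (overrides the rate; useful for fixtures).
#' @return An object of class \code{"synth_dataset"}: \code{responses} (data
#'   frame in the pipeline dialect), \code{ep_scores} (named integer vector),
#'   \code{config}, \code{layout}.
#' @export
sample_dataset <- function(config, layout = c("grid", "tasit"),
                           n_dont_know = NULL) {
  stopifnot(inherits(config, "synth_config"))
  layout <- match.arg(layout)
  set.seed(config$seed)
  n <- config$n_participants
  ids <- sprintf("P%03d", seq_len(n))
  n_hi <- n %/% 2L
  raw <- c(rnorm(n_hi, 24.92, 0.96), rnorm(n - n_hi, 20.90, 2.50))
  ep <- as.integer(pmin(28, pmax(0, round(raw))))
  names(ep) <- ids
  grouping <- median_split(ep)
  if (length(unique(grouping$group)) < 2)
    stop("degenerate emotion-perception scores: one group is empty; ",
         "increase n_participants", call. = FALSE)
  u <- rnorm(n, 0, config$participant_sd)

  scenes <- if (layout == "tasit") .tasit_layout()
            else .grid_layout(config$items_per_cell, config$include_say)
  if (!config$include_say)
    scenes <- scenes[scenes$question_type != "say", , drop = FALSE]

  per <- scenes[rep(seq_len(nrow(scenes)), times = n), , drop = FALSE]
  per$participant_id <- rep(ids, each = nrow(scenes))
  per <- per[c("participant_id", "part", "scene_id", "exchange_type",
               "question_type", "item_type")]
  rownames(per) <- NULL

  te <- .effective_theta(config)   # 20 x 3
  lp <- config$link_params
  grid <- condition_grid()
  cond <- paste(per$exchange_type, per$item_type,
                grouping$group[per$participant_id], sep = ".")
  ci <- match(cond, grid$condition)
  ui <- u[match(per$participant_id, ids)]
  p <- numeric(nrow(per))
  is_say <- per$question_type == "say"
  p[is_say] <- ifelse(per$item_type[is_say] == "target", 0.9, 0.1)
  for (dv in .analysis_questions) {
    rows <- per$question_type == dv
    a <- lp$slope[lp$dv == dv]
    b <- lp$intercept[lp$dv == dv]
    p[rows] <- plogis(a * (te[ci[rows], dv] + ui[rows]) + b)
  }
  per$response <- ifelse(runif(nrow(per)) < p, "yes", "no")

  scored_idx <- which(!is_say)
  n_dk <- if (!is.null(n_dont_know)) as.integer(n_dont_know)
          else rbinom(1, length(scored_idx), config$dont_know_rate)
  if (n_dk > 0) {
    dk <- sample(scored_idx, min(n_dk, length(scored_idx)))
    per$response[dk] <- "dont_know"
  }

  structure(list(responses = per, ep_scores = ep, config = config,
                 layout = layout),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat("Synthetic item-response dataset (", x$config$model,
      if (x$config$delta > 0) paste0(", delta = ", x$config$delta), ")\n",
      sep = "")
  cat("  layout: ", x$layout, "; ", x$config$n_participants,
      " participants; ", nrow(x$responses), " rows (",
      sum(x$responses$question_type != "say"), " scored, ",
      sum(x$responses$response == "dont_know"), " don't-know)\n", sep = "")
  invisible(x)
}

#' Write simulated responses / EP scores to disk
#'
#' \code{write_responses} emits the pipeline input dialect;
#' \code{write_ep_scores} emits \code{participant_id,ep_score}. Output is
#' deterministic (fixed row order, no quoting), so identical configurations
#' produce byte-identical files.
#'
#' @param x A \code{synth_dataset} (or, for \code{write_responses}, a response
#'   data frame).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_responses <- function(x, path) {
  df <- if (inherits(x, "synth_dataset")) x$responses else as.data.frame(x)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
write_ep_scores <- function(x, path) {
  stopifnot(inherits(x, "synth_dataset"))
  df <- data.frame(participant_id = names(x$ep_scores),
                   ep_score = as.integer(x$ep_scores))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read emotion-perception scores
#'
#' Reads the \code{participant_id,ep_score} dialect written by
#' \code{\link{write_ep_scores}}.
#'
#' @param path Path to the file.
#' @return Named integer vector of scores.
#' @export
read_ep_scores <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE,
                 sep = .detect_sep(path))
  if (!all(c("participant_id", "ep_score") %in% names(df)))
    stop("expected header participant_id,ep_score", call. = FALSE)
  setNames(as.integer(df$ep_score), df$participant_id)
}

#' Simulate a summary-statistics dataset
#'
#' Emulates the structure of reanalysing published group-level results:
#' \code{n_groups} groups with a latent value each (equally spaced on
#' [-1, 1]), two dependent variables mapped through the think and feel
#' logistic links, and normal within-group noise around the cell probability.
#' Under \code{two_latent} the second DV receives the alternating-sign
#' perturbation \code{delta * s_g}, producing a population crossing.
#'
#' @param config A \code{\link{synth_config}} (uses \code{model},
#'   \code{delta}, \code{link_params}, \code{seed}).
#' @param n_groups Number of groups (>= 2).
#' @param n_per_group Observations per group.
#' @param sd_within Within-group SD of individual scores (default 0.15).
#' @return A data frame in the \code{condition,dv,mean,sd,n} dialect.
#' @export
sample_summary_dataset <- function(config, n_groups = 5L, n_per_group = 20L,
                                   sd_within = 0.15) {
  stopifnot(inherits(config, "synth_config"))
  n_groups <- as.integer(n_groups)
  if (is.na(n_groups) || n_groups < 2)
    stop("'n_groups' must be >= 2", call. = FALSE)
  set.seed(config$seed)
  tau <- seq(-1, 1, length.out = n_groups)
  s <- rep_len(c(1, -1), n_groups)
  lp <- config$link_params
  links <- lp[match(c("think", "feel"), lp$dv), ]
  loading <- c(0, 1)
  out <- list()
  for (g in seq_len(n_groups)) {
    for (d in 1:2) {
      mu <- plogis(links$slope[d] * (tau[g] + config$delta * s[g] * loading[d]) +
                     links$intercept[d])
      obs <- rnorm(n_per_group, mu, sd_within)
      out[[length(out) + 1L]] <- data.frame(
        condition = sprintf("G%d", g), dv = c("dv1", "dv2")[d],
        mean = mean(obs), sd = sd(obs), n = n_per_group,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
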