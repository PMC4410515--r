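#' Configuration for the synthetic participant generator
#'
#' Collects everything needed to generate synthetic credence data with the
#' statistical structure assumed by the urn-study regression analysis: per
#' participant, a trial of draws without replacement is simulated, the
#' objective posterior O and the explanatory-power scores of the two urn
#' hypotheses are computed at every step, and the reported credence is a
#' linear function of these plus Gaussian noise.
#'
#' The default coefficients (0.33, 0.40, 0.24, -0.13) are the reported
#' estimates of the best-fitting explanationist regression model of the
#' original study (intercept, O, A-score, B-score under the \eqn{L_2}
#' rescaling of Good's measure); the default design is 26 participants by
#' 10 draws. The default noise level `noise_sd = 0.08` puts the generating
#' model's \eqn{R^2} in the mid-0.8 range reported there.
#'
#' @param n_participants Number of simulated participants (default 26).
#' @param n_draws Draws per trial (default 10).
#' @param coefficients Numeric vector `(intercept, b_O, b_A, b_B)`.
#' @param noise_sd Standard deviation of the additive credence noise.
#' @param measure Explanatory-power measure for the computed scores;
#'   default `"G3"` (\eqn{L_2}).
#' @param judgment_noise_sd Standard deviation of the noise separating
#'   judged from computed scores (default 0.1); see [add_judgment_noise()].
#' @param participant_sd Standard deviation of an optional participant-level
#'   random intercept (default 0: observations are pooled, as the original
#'   models assume).
#' @param urn An [urn_spec()]; defaults to the standard two-urn design.
#' @param seed Optional integer seed.
#' @return An object of class `"generator_config"`.
#' @examples
#' generator_config(seed = 1)
#' @export
generator_config <- function(n_participants = 26L, n_draws = 10L,
                             coefficients = c(0.33, 0.40, 0.24, -0.13),
                             noise_sd = 0.08, measure = "G3",
                             judgment_noise_sd = 0.1,
                             participant_sd = 0, urn = urn_spec(),
                             seed = NULL) {
  if (n_participants < 1L) stop("need at least one participant", call. = FALSE)
  if (!is.numeric(coefficients) || length(coefficients) != 4L) {
    stop("'coefficients' must be (intercept, b_O, b_A, b_B)", call. = FALSE)
  }
  for (nm in c("noise_sd", "judgment_noise_sd", "participant_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("'", nm, "' must be a nonnegative number", call. = FALSE)
    }
  }
  structure(list(n_participants = as.integer(n_participants),
                 n_draws = as.integer(n_draws),
                 coefficients = stats::setNames(coefficients,
                                                c("intercept", "O", "A", "B")),
                 noise_sd = noise_sd,
                 measure = as_measure_spec(measure),
                 judgment_noise_sd = judgment_noise_sd,
                 participant_sd = participant_sd,
                 urn = urn, seed = seed),
            class = "generator_config")
}

#' Read a generator configuration from YAML or JSON
#'
#' Files carry any subset of the [generator_config()] fields (urn
#' composition as `urn: {black: [...], white: [...], priors: [...]}`;
#' measure as an id/preset string or `{id: ..., alpha: ...}`); missing
#' fields take the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file with an explicit
#'   `seed` field.
#' @return A `"generator_config"`.
#' @export
generator_config_from_file <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  for (nm in c("n_participants", "n_draws", "coefficients", "noise_sd",
               "judgment_noise_sd", "participant_sd", "seed")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  }
  if (!is.null(raw$measure)) {
    args$measure <- if (is.list(raw$measure)) {
      measure_spec(raw$measure$id, raw$measure$alpha)
    } else as_measure_spec(raw$measure)
  }
  if (!is.null(raw$urn)) {
    args$urn <- urn_spec(black = raw$urn$black, white = raw$urn$white,
                         priors = raw$urn$priors)
  }
  do.call(generator_config, args)
}

# Score lookup by (step, cumulative black count): O and both urn-hypothesis
# scores depend on the draws only through these counts, so precomputing the
# (n_draws + 1) x n_draws table makes dataset generation cheap.
score_table <- function(spec, n_draws, measure) {
  measure <- as_measure_spec(measure)
  space <- hypothesis_space(spec$labels, spec$priors)
  out <- vector("list", n_draws)
  for (k in seq_len(n_draws)) {
    rows <- lapply(0:k, function(b) {
      draws <- c(rep("B", b), rep("W", k - b))
      lik <- urn_likelihoods(spec, draws)
      z <- sum(spec$priors * lik)
      if (z <= 0) return(c(O = NA_real_, A = NA_real_, B = NA_real_))
      ev <- evidence_model(lik)
      c(O = spec$priors[[1L]] * lik[[1L]] / z,
        A = power_from_model(measure, space, ev, spec$labels[1L]),
        B = power_from_model(measure, space, ev, spec$labels[2L]))
    })
    out[[k]] <- do.call(rbind, rows)
  }
  out
}

#' Generate a synthetic participant dataset
#'
#' Simulates the urn experiment for each participant and builds the trial
#' table of the regression analysis: per draw, the objective posterior `O`
#' of urn A, the computed explanatory-power scores `score_A` and `score_B`
#' of the two urn hypotheses against the draws so far, noisy judged
#' counterparts `judged_A` and `judged_B`, and the credence
#' \deqn{S = \beta_0 + \beta_O O + \beta_A \cdot \text{score}_A +
#'       \beta_B \cdot \text{score}_B + \varepsilon,
#'       \quad \varepsilon \sim N(0, \sigma^2),}
#' truncated to \eqn{[0, 1]} by resampling the noise (so no point mass
#' accumulates at the boundaries). The fraction of rows that needed
#' resampling is recorded in the `"truncation_rate"` attribute and a warning
#' is issued if it exceeds 5%.
#'
#' @param config A [generator_config()].
#' @return A data frame (one row per participant x draw) with columns
#'   `participant`, `step`, `color`, `urn` (the truly selected urn), `O`,
#'   `score_A`, `score_B`, `judged_A`, `judged_B`, `S`; the configuration is
#'   echoed in the `"config"` attribute.
#' @examples
#' head(generate_dataset(generator_config(n_participants = 2, seed = 1)))
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "generator_config")) {
    stop("'config' must be a generator_config", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  spec <- config$urn
  n <- config$n_draws
  tab <- score_table(spec, n, config$measure)
  parts <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    trial <- simulate_trial(spec, n)
    blacks <- cumsum(trial$draws == "B")
    sc <- t(vapply(seq_len(n), function(k) tab[[k]][blacks[k] + 1L, ],
                   numeric(3)))
    parts[[p]] <- data.frame(participant_id = p, step = seq_len(n),
                             color = trial$draws, urn = trial$urn,
                             O = sc[, "O"], score_A = sc[, "A"],
                             score_B = sc[, "B"])
  }
  out <- do.call(rbind, parts)
  beta <- config$coefficients
  mu <- beta[["intercept"]] + beta[["O"]] * out$O +
    beta[["A"]] * out$score_A + beta[["B"]] * out$score_B
  if (config$participant_sd > 0) {
    re <- stats::rnorm(config$n_participants, 0, config$participant_sd)
    mu <- mu + re[out$participant_id]
  }
  S <- mu + stats::rnorm(nrow(out), 0, config$noise_sd)
  resampled <- 0L
  bad <- which(S < 0 | S > 1)
  while (length(bad) > 0L) {
    resampled <- resampled + length(bad)
    S[bad] <- mu[bad] + stats::rnorm(length(bad), 0, config$noise_sd)
    bad <- bad[S[bad] < 0 | S[bad] > 1]
  }
  out$S <- S
  out <- add_judgment_noise(out, config$judgment_noise_sd,
                            measure = config$measure)
  rate <- resampled / nrow(out)
  if (rate > 0.05) {
    warning(sprintf("truncation resampling affected %.1f%% of rows",
                    100 * rate), call. = FALSE)
  }
  attr(out, "config") <- config
  attr(out, "truncation_rate") <- rate
  rownames(out) <- NULL
  out
}

measure_bounds <- function(measure) {
  measure <- as_measure_spec(measure)
  if (measure$id == "good") c(-Inf, Inf) else c(-1, 1)
}

#' Add judged-score columns to a trial table
#'
#' Emulates human judgments of explanatory goodness as noisy reflections of
#' the computed scores: `judged_A`/`judged_B` are the computed scores plus
#' independent Gaussian noise, clipped to the measure's range. With
#' `sd = 0` the judged columns equal the computed ones.
#'
#' @param table A trial table with `score_A` and `score_B` columns.
#' @param sd Nonnegative noise standard deviation.
#' @param seed Optional integer seed.
#' @param measure Measure whose range bounds the clipping; defaults to the
#'   table's `"config"` attribute or, failing that, a bounded measure.
#' @return The table with `judged_A` and `judged_B` columns replaced.
#' @export
add_judgment_noise <- function(table, sd, seed = NULL, measure = NULL) {
  if (!all(c("score_A", "score_B") %in% names(table))) {
    stop("'table' must contain score_A and score_B columns", call. = FALSE)
  }
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0) {
    stop("'sd' must be a nonnegative number", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(measure)) {
    cfg <- attr(table, "config")
    measure <- if (!is.null(cfg)) cfg$measure else "popper"
  }
  bounds <- measure_bounds(measure)
  clip <- function(x) pmin(pmax(x, bounds[1L]), bounds[2L])
  n <- nrow(table)
  table$judged_A <- clip(table$score_A + stats::rnorm(n, 0, sd))
  table$judged_B <- clip(table$score_B + stats::rnorm(n, 0, sd))
  table
}

#' Write / read a trial table as CSV
#'
#' Plain RFC-4180 CSV with UTF-8 encoding and `.` decimal separator. The
#' measure used for the computed scores is recorded in a leading `#` comment
#' line, which [read_trial_table()] skips.
#'
#' @param table A trial table (see [generate_dataset()]).
#' @param path File path.
#' @return `write_trial_table()`: the path, invisibly.
#'   `read_trial_table()`: the trial table data frame.
#' @export
write_trial_table <- function(table, path) {
  cfg <- attr(table, "config")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(cfg)) {
    m <- cfg$measure
    writeLines(sprintf("# measure: %s%s", m$id,
                       if (!is.null(m$alpha)) sprintf(" alpha=%g", m$alpha)
                       else ""), con)
  }
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  utils::read.csv(path, comment.char = "#", fileEncoding = "UTF-8")
}
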