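#' Two-urn experimental design
#'
#' Describes the urn-drawing design: two (or more) urns with known black and
#' white ball counts, one of which is selected with known prior probability
#' (a fair coin toss by default), after which balls are drawn from it without
#' replacement. The default composition is the one used in the interview
#' study this package models: urn A with 30 black and 10 white balls, urn B
#' with 15 black and 25 white.
#'
#' @param black Integer vector of black-ball counts, one per urn.
#' @param white Integer vector of white-ball counts, one per urn.
#' @param priors Urn selection probabilities; default uniform.
#' @param labels Urn labels; default `"H_A"`, `"H_B"`, ...
#' @return An object of class `"urn_spec"`.
#' @examples
#' urn_spec()  # the standard design
#' @export
urn_spec <- function(black = c(30, 15), white = c(10, 25), priors = NULL,
                     labels = NULL) {
  if (length(black) != length(white) || length(black) < 2L) {
    stop("need matching black/white counts for at least two urns",
         call. = FALSE)
  }
  if (any(black < 0) || any(white < 0) ||
      any(black != round(black)) || any(white != round(white))) {
    stop("ball counts must be nonnegative integers", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- paste0("H_", LETTERS[seq_along(black)])
  }
  if (is.null(priors)) priors <- rep(1 / length(black), length(black))
  priors <- check_distribution(priors, length(black), "priors")
  structure(list(black = as.integer(black), white = as.integer(white),
                 priors = priors, labels = as.character(labels)),
            class = "urn_spec")
}

#' @export
print.urn_spec <- function(x, ...) {
  cat("<urn_spec>\n")
  print(data.frame(urn = x$labels, black = x$black, white = x$white,
                   prior = x$priors))
  invisible(x)
}

check_draws <- function(draws) {
  if (length(draws) == 0L) return(character(0))
  draws <- toupper(as.character(draws))
  if (!all(draws %in% c("B", "W"))) {
    stop("draws must be 'B' (black) or 'W' (white)", call. = FALSE)
  }
  draws
}

#' Likelihood of an ordered draw sequence from one urn
#'
#' Probability of drawing the given ordered color sequence from an urn with
#' the stated composition, sampling without replacement: the product over
#' steps of (remaining balls of the drawn color) / (remaining balls).
#' Sequences that exhaust a color's stock have probability 0.
#'
#' @param black,white Ball counts of the urn.
#' @param draws Character vector of `"B"`/`"W"` draws (empty allowed).
#' @return The sequence probability.
#' @examples
#' sequence_likelihood(30, 10, "B")             # 0.75
#' sequence_likelihood(30, 10, c("B", "B"))     # (30/40)(29/39)
#' @export
sequence_likelihood <- function(black, white, draws) {
  draws <- check_draws(draws)
  if (length(draws) == 0L) return(1)
  b <- black; w <- white; p <- 1
  for (d in draws) {
    total <- b + w
    if (total == 0L) return(0)
    if (d == "B") {
      if (b == 0L) return(0)
      p <- p * b / total
      b <- b - 1L
    } else {
      if (w == 0L) return(0)
      p <- p * w / total
      w <- w - 1L
    }
  }
  p
}

# Per-urn likelihoods of a draw sequence, as a named vector over urn labels.
urn_likelihoods <- function(spec, draws) {
  stats::setNames(
    vapply(seq_along(spec$black), function(i) {
      sequence_likelihood(spec$black[i], spec$white[i], draws)
    }, numeric(1)),
    spec$labels)
}

#' Objective posterior trajectory of the first urn
#'
#' The probability that the first urn (urn A) was selected, given the first
#' k draws, for k = 0, 1, ..., n: the objective conditional probabilities a
#' Bayesian updater's credences should track over the course of a trial.
#'
#' @param spec An [urn_spec()].
#' @param draws Character vector of `"B"`/`"W"` draws.
#' @return Numeric vector of length `length(draws) + 1`; element k + 1 is
#'   \eqn{\Pr(H_A \mid \text{first } k \text{ draws})}, so the first element
#'   is the selection prior.
#' @examples
#' posterior_trajectory(urn_spec(), c("B", "B"))  # 0.5, 2/3, 870/1080
#' @export
posterior_trajectory <- function(spec, draws) {
  draws <- check_draws(draws)
  out <- numeric(length(draws) + 1L)
  out[1L] <- spec$priors[1L]
  for (k in seq_along(draws)) {
    lik <- urn_likelihoods(spec, draws[seq_len(k)])
    z <- sum(spec$priors * lik)
    if (z <= 0) {
      stop("draw sequence impossible under every urn", call. = FALSE)
    }
    out[k + 1L] <- spec$priors[1L] * lik[1L] / z
  }
  out
}

#' Per-draw objective posteriors and explanatory-power scores
#'
#' For each step k of a draw sequence, computes the objective posterior O of
#' the first urn and the explanatory-power score of each urn hypothesis
#' against the cumulative evidence (the first k draws), under the given
#' measure. This is the quantitative backbone of the interview trials: O is
#' what credence in urn A should be, and the scores formalize how well each
#' urn hypothesis explains the draws so far.
#'
#' @param spec An [urn_spec()] (two urns).
#' @param draws Character vector of `"B"`/`"W"` draws.
#' @param measure A [measure_spec()] or preset string; default `"G3"`
#'   (the \eqn{L_2} rescaling of Good's measure).
#' @param evidence_unit `"cumulative"` scores each hypothesis against all
#'   draws so far (the default, matching the trial instructions);
#'   `"latest"` scores against the most recent draw only.
#' @return A data frame with one row per step: `step`, `color`, `O`,
#'   `score_A`, `score_B`.
#' @examples
#' trial_scores(urn_spec(), c("B", "W"), "schupbach_sprenger")
#' @export
trial_scores <- function(spec, draws, measure = "G3",
                         evidence_unit = c("cumulative", "latest")) {
  evidence_unit <- match.arg(evidence_unit)
  measure <- as_measure_spec(measure)
  draws <- check_draws(draws)
  if (length(spec$black) != 2L) {
    stop("trial scoring assumes a two-urn design", call. = FALSE)
  }
  n <- length(draws)
  O <- posterior_trajectory(spec, draws)[-1L]
  space <- hypothesis_space(spec$labels, spec$priors)
  score_A <- score_B <- numeric(n)
  for (k in seq_len(n)) {
    ev_draws <- if (evidence_unit == "cumulative") draws[seq_len(k)]
                else draws[k]
    ev <- evidence_model(urn_likelihoods(spec, ev_draws))
    score_A[k] <- power_from_model(measure, space, ev, spec$labels[1L])
    score_B[k] <- power_from_model(measure, space, ev, spec$labels[2L])
  }
  data.frame(step = seq_len(n), color = draws, O = O,
             score_A = score_A, score_B = score_B)
}

#' Simulate one trial of the urn experiment
#'
#' Selects an urn according to the selection priors, then draws `n_draws`
#' balls from it without replacement.
#'
#' @param spec An [urn_spec()].
#' @param n_draws Number of draws; default 10, must not exceed the smallest
#'   urn's total ball count.
#' @param seed Optional integer seed for reproducibility.
#' @return A list with `urn` (selected label) and `draws` (character vector
#'   of `"B"`/`"W"`).
#' @examples
#' simulate_trial(urn_spec(), 10, seed = 1)
#' @export
simulate_trial <- function(spec, n_draws = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  totals <- spec$black + spec$white
  if (n_draws < 0L || n_draws > min(totals)) {
    stop("'n_draws' must be between 0 and the smallest urn size",
         call. = FALSE)
  }
  i <- sample.int(length(spec$labels), 1L, prob = spec$priors)
  pool <- c(rep("B", spec$black[i]), rep("W", spec$white[i]))
  draws <- if (n_draws == 0L) character(0) else sample(pool, n_draws)
  list(urn = spec$labels[i], draws = draws)
}

#' Enumerate all draw sequences with their joint probabilities
#'
#' Exhaustively lists the color sequences of length `n` together with their
#' marginal probabilities \eqn{\sum_i \Pr(\text{urn } i)\Pr(\text{sequence}
#' \mid \text{urn } i)}. A brute-force oracle for the sampling machinery;
#' probabilities sum to 1.
#'
#' @param spec An [urn_spec()].
#' @param n Sequence length (kept small; at most 12).
#' @return A data frame with columns `sequence` (string of `"B"`/`"W"`) and
#'   `probability`.
#' @examples
#' enumerate_sequences(urn_spec(), 1)  # B: 0.5625, W: 0.4375
#' @export
enumerate_sequences <- function(spec, n) {
  if (n < 0L || n > 12L) stop("'n' must be between 0 and 12", call. = FALSE)
  if (n == 0L) return(data.frame(sequence = "", probability = 1))
  grid <- expand.grid(rep(list(c("B", "W")), n), stringsAsFactors = FALSE)
  seqs <- apply(as.matrix(grid), 1L, paste0, collapse = "")
  probs <- vapply(seq_len(nrow(grid)), function(r) {
    draws <- as.character(grid[r, ])
    sum(spec$priors * urn_likelihoods(spec, draws))
  }, numeric(1))
  data.frame(sequence = seqs, probability = probs)
}
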