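#' Configuration of the coin-bias convergence simulation
#'
#' Describes the normative testbed on which update rules are compared: a
#' coin of unknown bias, a finite grid of candidate bias hypotheses with a
#' prior over them, and repeated toss sequences generated from the true
#' bias. Each rule updates toss by toss; recorded are the first toss at
#' which the credence in the true bias hypothesis strictly exceeds the
#' threshold, and the Brier-score inaccuracy trajectory.
#'
#' @param grid Candidate bias values in \eqn{[0, 1]}; default
#'   \eqn{\{0, 0.1, \ldots, 1\}}.
#' @param true_bias True heads probability; must lie on the grid.
#' @param priors Prior over the grid; default uniform.
#' @param bonus A [bonus_policy()] for the abductive rule; default `c = 0.1`.
#' @param threshold Convergence threshold \eqn{\theta \in (0.5, 1)}, default
#'   0.9 (crossings are strict).
#' @param max_tosses Tosses per replication (default 500); runs that never
#'   cross the threshold are censored.
#' @param replications Number of replicated toss sequences (default 1000).
#' @param bonus_evidence What the best explainer is judged against:
#'   `"cumulative"` (default) scores each bias hypothesis against the whole
#'   toss record so far, so the bonus tracks the empirically best-supported
#'   hypothesis; `"latest"` scores against the most recent toss only, which
#'   always crowns an extreme bias hypothesis.
#' @param seed Optional integer seed.
#' @return An object of class `"coin_sim_config"`.
#' @examples
#' coin_sim_config(replications = 50, max_tosses = 200, seed = 1)
#' @export
coin_sim_config <- function(grid = seq(0, 1, by = 0.1), true_bias = 0.7,
                            priors = NULL, bonus = bonus_policy(0.1),
                            threshold = 0.9, max_tosses = 500L,
                            replications = 1000L,
                            bonus_evidence = c("cumulative", "latest"),
                            seed = NULL) {
  bonus_evidence <- match.arg(bonus_evidence)
  if (any(grid < 0 | grid > 1) || length(grid) < 2L) {
    stop("'grid' must hold at least two bias values in [0, 1]",
         call. = FALSE)
  }
  idx <- which(abs(grid - true_bias) < 1e-9)
  if (length(idx) != 1L) {
    stop("'true_bias' must be a member of the bias grid", call. = FALSE)
  }
  if (threshold <= 0.5 || threshold >= 1) {
    stop("'threshold' must lie in (0.5, 1)", call. = FALSE)
  }
  if (replications < 1L || max_tosses < 1L) {
    stop("'replications' and 'max_tosses' must be at least 1", call. = FALSE)
  }
  if (is.null(priors)) priors <- rep(1 / length(grid), length(grid))
  priors <- check_distribution(priors, length(grid), "priors")
  structure(list(grid = grid, true_bias = grid[idx], true_index = idx,
                 priors = priors, bonus = bonus, threshold = threshold,
                 max_tosses = as.integer(max_tosses),
                 replications = as.integer(replications),
                 bonus_evidence = bonus_evidence, seed = seed),
            class = "coin_sim_config")
}

#' First crossing of a credence threshold
#'
#' First (1-based) position of a probability trajectory strictly above the
#' threshold, or `NA` (censored) if it never crosses.
#'
#' @param trajectory Numeric vector of probabilities.
#' @param threshold Threshold \eqn{\theta}.
#' @return Integer index or `NA_integer_`.
#' @examples
#' time_to_threshold(c(0.5, 0.95, 0.99), 0.9)  # 2
#' @export
time_to_threshold <- function(trajectory, threshold) {
  if (length(trajectory) == 0L) stop("empty trajectory", call. = FALSE)
  hit <- which(trajectory > threshold)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Brier-score inaccuracy of a sequence of credence states
#'
#' Per state, the squared distance \eqn{\sum_i (\Pr(H_i) -
#' \mathbf{1}\{H_i = H_{true}\})^2} between the credence distribution and
#' the truth indicator; ranges from 0 (point mass on the truth) to 2 (point
#' mass on a falsehood).
#'
#' @param states A [credence_state()], a named probability vector, or a list
#'   of either.
#' @param true_label Label of the true hypothesis.
#' @return Numeric vector of one score per state.
#' @examples
#' brier_trajectory(credence_state(c(a = 0.5, b = 0.5)), "a")  # 0.5
#' @export
brier_trajectory <- function(states, true_label) {
  if (inherits(states, "credence_state") || is.numeric(states)) {
    states <- list(states)
  }
  vapply(states, function(s) {
    v <- as_credences(s)
    if (!true_label %in% names(v)) {
      stop("true hypothesis '", true_label, "' not in the credence state",
           call. = FALSE)
    }
    sum((v - as.numeric(names(v) == true_label))^2)
  }, numeric(1))
}

# One update rule pushed through all replications at once. posterior: R x K
# matrix; tosses: R x T 0/1 matrix. Returns trajectories of the credence in
# the true hypothesis and of the Brier score (both R x T).
run_rule_matrix <- function(config, tosses, rule) {
  grid <- config$grid
  K <- length(grid)
  R <- nrow(tosses)
  nt <- ncol(tosses)
  P <- matrix(config$priors, nrow = R, ncol = K, byrow = TRUE)
  truth <- as.numeric(seq_len(K) == config$true_index)
  traj <- brier <- matrix(NA_real_, R, nt)
  heads <- integer(R)
  cvec <- config$bonus$c
  for (t in seq_len(nt)) {
    x <- tosses[, t]
    heads <- heads + x
    lik <- x %o% grid + (1 - x) %o% (1 - grid)
    num <- P * lik
    if (rule == "abduction") {
      sc <- if (config$bonus_evidence == "cumulative") {
        vapply(grid, function(p) stats::dbinom(heads, t, p, log = TRUE),
               numeric(R))
      } else {
        log(lik)
      }
      sc <- matrix(sc, nrow = R)  # vapply drops to a vector when R = 1
      top <- sc[cbind(seq_len(R), max.col(sc, ties.method = "first"))]
      unique_best <- rowSums(sc >= top - 1e-9) == 1L
      bump <- which(unique_best)
      if (length(bump)) {
        best <- max.col(sc, ties.method = "first")[bump]
        num[cbind(bump, best)] <- num[cbind(bump, best)] + cvec
      }
    }
    P <- num / rowSums(num)
    traj[, t] <- P[, config$true_index]
    brier[, t] <- rowSums(sweep(P, 2L, truth)^2)
  }
  list(trajectory_true = traj, brier = brier)
}

#' Run the coin-bias simulation for both update rules
#'
#' Samples `replications` toss sequences from the true bias, updates a
#' Bayesian and an abductive agent toss by toss on each (the evidence unit
#' of a single update is the latest toss; where the explanatory bonus lands
#' is governed by `bonus_evidence`, see [coin_sim_config()]), and summarizes
#' convergence. Both rules see identical toss sequences, so with bonus
#' `c = 0` their trajectories are bit-identical.
#'
#' @param config A [coin_sim_config()].
#' @return An object of class `"coin_sim_summary"`: per rule (`bayes`,
#'   `abduction`) a list with `times` (per-replication first crossing of the
#'   threshold by the credence in the true hypothesis; `NA` = censored),
#'   `mean_time`/`median_time` over uncensored runs, `censored` count,
#'   `mean_brier` (mean Brier trajectory across replications, one value per
#'   toss), and `mean_final_posterior` (mean credence in the true hypothesis
#'   at the last toss); plus the `config`.
#' @examples
#' run_coin_sim(coin_sim_config(replications = 20, max_tosses = 100,
#'                              seed = 1))
#' @export
run_coin_sim <- function(config) {
  if (!inherits(config, "coin_sim_config")) {
    stop("'config' must be a coin_sim_config", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  R <- config$replications
  nt <- config$max_tosses
  tosses <- matrix(stats::rbinom(R * nt, 1L, config$true_bias), R, nt)
  rules <- list(bayes = run_rule_matrix(config, tosses, "bayes"),
                abduction = run_rule_matrix(config, tosses, "abduction"))
  out <- lapply(rules, function(res) {
    times <- apply(res$trajectory_true > config$threshold, 1L,
                   function(z) if (any(z)) which(z)[1L] else NA_integer_)
    list(times = times,
         mean_time = mean(times, na.rm = TRUE),
         median_time = stats::median(times, na.rm = TRUE),
         censored = sum(is.na(times)),
         mean_brier = colMeans(res$brier),
         mean_final_posterior = mean(res$trajectory_true[, nt]),
         trajectory_true = res$trajectory_true)
  })
  structure(c(out, list(config = config)), class = "coin_sim_summary")
}

#' @export
print.coin_sim_summary <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<coin_sim_summary> true bias %.2f, threshold %.2f, c = %g, %d reps x %d tosses\n",
    cfg$true_bias, cfg$threshold, cfg$bonus$c, cfg$replications,
    cfg$max_tosses))
  for (rule in c("bayes", "abduction")) {
    r <- x[[rule]]
    cat(sprintf(
      "  %-9s mean time %.1f, median %s, censored %d, final Brier %.4f\n",
      rule, r$mean_time, format(r$median_time), r$censored,
      r$mean_brier[length(r$mean_brier)]))
  }
  invisible(x)
}

#' Sweep the bonus magnitude and tabulate convergence
#'
#' Reruns the coin-bias simulation for each bonus magnitude in `c_values`
#' (reusing the configured seed, so all sweeps see the same toss sequences)
#' and tabulates per rule and bonus the mean and median time to threshold,
#' censored count, and final mean Brier score. The Bayesian rule is
#' unaffected by the bonus and is reported once per sweep for reference.
#'
#' @param config A [coin_sim_config()].
#' @param c_values Numeric vector of bonus magnitudes.
#' @return A data frame with columns `rule`, `c`, `mean_time`,
#'   `median_time`, `censored`, `brier_final`, `mean_final_posterior`.
#' @examples
#' compare_rules(coin_sim_config(replications = 20, max_tosses = 100,
#'                               seed = 1), c_values = c(0, 0.1))
#' @export
compare_rules <- function(config, c_values = c(0, 0.05, 0.1)) {
  rows <- list()
  for (cv in c_values) {
    cfg <- config
    cfg$bonus <- bonus_policy(cv, selector = config$bonus$selector)
    sim <- run_coin_sim(cfg)
    for (rule in c("bayes", "abduction")) {
      r <- sim[[rule]]
      rows[[length(rows) + 1L]] <- data.frame(
        rule = rule, c = cv, mean_time = r$mean_time,
        median_time = r$median_time, censored = r$censored,
        brier_final = r$mean_brier[length(r$mean_brier)],
        mean_final_posterior = r$mean_final_posterior)
    }
  }
  do.call(rbind, rows)
}
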