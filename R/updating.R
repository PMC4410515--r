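#' Finite hypothesis partition with priors
#'
#' A set of mutually exclusive, jointly exhaustive hypotheses together with a
#' prior credence for each. All updating machinery in the package operates on
#' such finite partitions.
#'
#' @param labels Character vector of unique hypothesis labels (length >= 2).
#' @param priors Probability vector over the labels; defaults to uniform.
#'   Must be nonnegative and sum to 1 (absolute tolerance 1e-9).
#' @return An object of class `"hypothesis_space"` with elements `labels`
#'   and `priors` (named).
#' @examples
#' hypothesis_space(c("H_A", "H_B"))
#' hypothesis_space(c("fair", "biased"), priors = c(0.8, 0.2))
#' @export
hypothesis_space <- function(labels, priors = NULL) {
  labels <- as.character(labels)
  if (length(labels) < 2L || anyDuplicated(labels)) {
    stop("need at least two distinct hypothesis labels", call. = FALSE)
  }
  if (is.null(priors)) priors <- rep(1 / length(labels), length(labels))
  priors <- check_distribution(priors, length(labels), "priors")
  names(priors) <- labels
  structure(list(labels = labels, priors = priors),
            class = "hypothesis_space")
}

check_distribution <- function(p, n, name, tol = 1e-9) {
  if (!is.numeric(p) || length(p) != n || anyNA(p)) {
    stop("'", name, "' must be a numeric vector of length ", n, call. = FALSE)
  }
  if (any(p < 0) || abs(sum(p) - 1) > tol) {
    stop("'", name, "' must be nonnegative and sum to 1", call. = FALSE)
  }
  p
}

as_hypothesis_space <- function(x) {
  if (inherits(x, "hypothesis_space")) return(x)
  stop("expected a 'hypothesis_space' object", call. = FALSE)
}

hypothesis_index <- function(space, h) {
  if (is.numeric(h)) {
    h <- as.integer(h)
    if (h < 1L || h > length(space$labels)) {
      stop("hypothesis index out of range", call. = FALSE)
    }
    return(h)
  }
  i <- match(as.character(h), space$labels)
  if (is.na(i)) stop("unknown hypothesis label: ", h, call. = FALSE)
  i
}

#' @export
print.hypothesis_space <- function(x, ...) {
  cat("<hypothesis_space> ", length(x$labels), " hypotheses\n", sep = "")
  print(x$priors)
  invisible(x)
}

#' Credence state over a hypothesis partition
#'
#' A probability distribution representing an agent's degrees of belief, with
#' a stage tag distinguishing pre-update (`"t1"`) from post-update (`"t2"`)
#' states.
#'
#' @param values Named probability vector (one credence per hypothesis);
#'   nonnegative, summing to 1 within 1e-9.
#' @param stage `"t1"` (prior) or `"t2"` (posterior).
#' @return An object of class `"credence_state"`.
#' @examples
#' credence_state(c(H_A = 0.5, H_B = 0.5))
#' @export
credence_state <- function(values, stage = c("t1", "t2")) {
  stage <- match.arg(stage)
  values <- check_distribution(values, length(values), "values")
  if (is.null(names(values))) {
    stop("credence values must be named by hypothesis", call. = FALSE)
  }
  structure(list(values = values, stage = stage), class = "credence_state")
}

#' @export
print.credence_state <- function(x, ...) {
  cat("<credence_state> stage ", x$stage, "\n", sep = "")
  print(x$values)
  invisible(x)
}

as_credences <- function(x) {
  if (inherits(x, "credence_state")) return(x$values)
  if (inherits(x, "hypothesis_space")) return(x$priors)
  if (is.numeric(x) && !is.null(names(x))) {
    return(check_distribution(x, length(x), "credences"))
  }
  stop("expected a credence_state, hypothesis_space, or named probability ",
       "vector", call. = FALSE)
}

#' Evidence model: per-hypothesis likelihoods
#'
#' Records \eqn{\Pr(E \mid H_i)} for each hypothesis of a partition. The
#' marginal \eqn{\Pr(E)} is derived against whichever credence vector an
#' update is performed from.
#'
#' @param likelihoods Named numeric vector of likelihoods in \eqn{[0, 1]}.
#' @return An object of class `"evidence_model"`.
#' @examples
#' evidence_model(c(H_A = 0.75, H_B = 0.375))  # one black draw
#' @export
evidence_model <- function(likelihoods) {
  if (!is.numeric(likelihoods) || anyNA(likelihoods) ||
      any(likelihoods < 0) || any(likelihoods > 1)) {
    stop("likelihoods must be probabilities in [0, 1]", call. = FALSE)
  }
  if (is.null(names(likelihoods))) {
    stop("likelihoods must be named by hypothesis", call. = FALSE)
  }
  structure(list(likelihoods = likelihoods), class = "evidence_model")
}

evidence_likelihoods <- function(evidence, labels) {
  lik <- if (inherits(evidence, "evidence_model")) evidence$likelihoods
         else evidence
  if (!is.numeric(lik)) stop("expected an evidence model", call. = FALSE)
  if (!is.null(names(lik)) && !is.null(labels)) {
    if (!setequal(names(lik), labels)) {
      stop("evidence likelihoods do not cover the hypothesis labels",
           call. = FALSE)
    }
    lik <- lik[labels]
  } else if (length(lik) != length(labels)) {
    stop("likelihood vector length does not match the partition",
         call. = FALSE)
  }
  unname(lik)
}

#' Bonus policy for abductive updating
#'
#' Specifies the explanatory bonus of the abductive update rule: a flat
#' amount `c` added to the numerator of the unique best-explaining
#' hypothesis, nothing to the others, and nothing to anyone on a tie.
#' `c = 0` makes abductive updating coincide with Bayesian conditioning.
#'
#' @param c Nonnegative bonus magnitude. Default 0.1.
#' @param selector How the best explainer is picked: `"likelihood"` (the
#'   hypothesis conferring the highest probability on the evidence; with
#'   equal priors every implemented power measure induces this ordering) or
#'   a [measure_spec()]/preset string naming an explanatory-power measure.
#' @return An object of class `"bonus_policy"`.
#' @examples
#' bonus_policy(0.1)
#' bonus_policy(0.05, selector = "schupbach_sprenger")
#' @export
bonus_policy <- function(c = 0.1, selector = "likelihood") {
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c < 0) {
    stop("bonus magnitude 'c' must be a nonnegative number", call. = FALSE)
  }
  if (!(is.character(selector) && length(selector) == 1L &&
        selector == "likelihood")) {
    selector <- as_measure_spec(selector)
  }
  structure(list(c = c, selector = selector), class = "bonus_policy")
}

#' Bayesian conditioning on a finite partition
#'
#' Standard Bayes's-Rule updating: the posterior credence in each hypothesis
#' is its prior credence times the likelihood of the evidence under it,
#' renormalized.
#'
#' @param credences A [credence_state()], [hypothesis_space()], or named
#'   probability vector giving the pre-update credences.
#' @param evidence An [evidence_model()] (or named likelihood vector).
#' @return A [credence_state()] at stage `"t2"`.
#' @examples
#' sp <- hypothesis_space(c("H_A", "H_B"))
#' bayes_update(sp, evidence_model(c(H_A = 0.75, H_B = 0.375)))  # (2/3, 1/3)
#' @export
bayes_update <- function(credences, evidence) {
  prior <- as_credences(credences)
  lik <- evidence_likelihoods(evidence, names(prior))
  num <- prior * lik
  z <- sum(num)
  if (z <= 0) {
    stop("cannot condition on evidence with zero prior probability",
         call. = FALSE)
  }
  credence_state(num / z, stage = "t2")
}

#' Abductive (explanationist) updating
#'
#' Probabilistic abduction: like Bayesian conditioning, except that the
#' hypothesis that best explains the evidence receives an additive bonus in
#' its numerator before renormalization,
#' \deqn{\Pr_{t_2}(H_i) = \frac{\Pr_{t_1}(H_i)\Pr_{t_1}(E \mid H_i) +
#'       \mathcal{E}_i}{\sum_j \Pr_{t_1}(H_j)\Pr_{t_1}(E \mid H_j) +
#'       \mathcal{E}_j},}
#' where \eqn{\mathcal{E}_i = c} for the unique best explainer and 0
#' otherwise. With `c = 0` (or on a tie for best) the rule reduces exactly to
#' [bayes_update()].
#'
#' @inheritParams bayes_update
#' @param bonus A [bonus_policy()].
#' @return A [credence_state()] at stage `"t2"`.
#' @examples
#' sp <- hypothesis_space(c("H_A", "H_B"))
#' ev <- evidence_model(c(H_A = 0.75, H_B = 0.375))
#' abductive_update(sp, ev, bonus_policy(0.1))
#' @export
abductive_update <- function(credences, evidence, bonus = bonus_policy()) {
  prior <- as_credences(credences)
  lik <- evidence_likelihoods(evidence, names(prior))
  if (!inherits(bonus, "bonus_policy")) {
    stop("'bonus' must be a bonus_policy object", call. = FALSE)
  }
  if (sum(prior * lik) <= 0) {
    stop("cannot condition on evidence with zero prior probability",
         call. = FALSE)
  }
  num <- prior * lik
  best <- best_explainer(hypothesis_space(names(prior), unname(prior)),
                         evidence_model(stats::setNames(lik, names(prior))),
                         selector = bonus$selector)
  if (!is.na(best)) {
    i <- match(best, names(prior))
    num[i] <- num[i] + bonus$c
  }
  if (any(num < 0)) stop("negative update numerator", call. = FALSE)
  credence_state(num / sum(num), stage = "t2")
}

#' Identify the best-explaining hypothesis
#'
#' Scores every hypothesis of a partition against the evidence with the
#' selected criterion and returns the label of the unique maximizer, or `NA`
#' when the top score is tied (within absolute tolerance 1e-12).
#'
#' @param space A [hypothesis_space()] (its priors are used where the
#'   selector measure needs them).
#' @param evidence An [evidence_model()].
#' @param selector `"likelihood"` or a [measure_spec()]; see [bonus_policy()].
#' @return A hypothesis label, or `NA_character_` on a tie.
#' @examples
#' sp <- hypothesis_space(c("H_A", "H_B"))
#' best_explainer(sp, evidence_model(c(H_A = 0.75, H_B = 0.375)))  # "H_A"
#' @export
best_explainer <- function(space, evidence, selector = "likelihood") {
  space <- as_hypothesis_space(space)
  lik <- evidence_likelihoods(evidence, space$labels)
  if (is.character(selector) && length(selector) == 1L &&
      selector == "likelihood") {
    scores <- lik
  } else {
    measure <- as_measure_spec(selector)
    ev <- evidence_model(stats::setNames(lik, space$labels))
    scores <- vapply(space$labels, function(h) {
      power_from_model(measure, space, ev, h)
    }, numeric(1))
  }
  top <- max(scores)
  ties <- which(scores >= top - 1e-12)
  if (length(ties) != 1L) return(NA_character_)
  space$labels[ties]
}
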