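#' Specify a measure of explanatory power
#'
#' Constructs the specification of a probabilistic measure of explanatory
#' power, i.e. of the degree to which a hypothesis H accounts for evidence E.
#' Five measures are supported:
#'
#' * `"simple"`: the difference \eqn{\Pr(E \mid H) - \Pr(E)};
#' * `"popper"`: the normalized ratio
#'   \eqn{(\Pr(E \mid H) - \Pr(E)) / (\Pr(E \mid H) + \Pr(E))};
#' * `"good"`: the log-likelihood ratio \eqn{\ln(\Pr(E \mid H)/\Pr(E))},
#'   unbounded;
#' * `"good_rescaled"`: Good's measure pushed through the bounded rescaling
#'   \eqn{L_\alpha} (see [rescale_good()]), with shape parameter `alpha`;
#' * `"schupbach_sprenger"`: the posterior contrast
#'   \eqn{(\Pr(H \mid E) - \Pr(H \mid \neg E)) /
#'        (\Pr(H \mid E) + \Pr(H \mid \neg E))}.
#'
#' All measures take the value 0 when H and E are probabilistically
#' independent (the neutral point). All except `"good"` are bounded in
#' \eqn{[-1, 1]}.
#'
#' The preset names `"G1"`, `"G2"`, `"G3"` expand to the rescalings
#' \eqn{L_{0.5}}, \eqn{L_1}, \eqn{L_2} of Good's measure, i.e.
#' `measure_spec("good_rescaled", alpha = 0.5)` and so on.
#'
#' @param id One of `"simple"`, `"popper"`, `"good"`, `"good_rescaled"`,
#'   `"schupbach_sprenger"`, or a preset name `"G1"`, `"G2"`, `"G3"`.
#' @param alpha Positive shape parameter; required iff `id = "good_rescaled"`.
#' @return An object of class `"measure_spec"` with elements `id` and
#'   (when applicable) `alpha`.
#' @seealso [power_from_conditionals()], [power_from_model()]
#' @examples
#' measure_spec("popper")
#' measure_spec("G3")  # same as measure_spec("good_rescaled", alpha = 2)
#' @export
measure_spec <- function(id, alpha = NULL) {
  presets <- list(G1 = 0.5, G2 = 1, G3 = 2)
  if (id %in% names(presets)) {
    alpha <- presets[[id]]
    id <- "good_rescaled"
  }
  ids <- c("simple", "popper", "good", "good_rescaled", "schupbach_sprenger")
  if (!is.character(id) || length(id) != 1L || !id %in% ids) {
    stop("unknown measure id: ", deparse(id), call. = FALSE)
  }
  if (id == "good_rescaled") {
    if (is.null(alpha) || !is.numeric(alpha) || length(alpha) != 1L ||
        is.na(alpha) || alpha <= 0) {
      stop("'good_rescaled' requires a positive 'alpha'", call. = FALSE)
    }
  } else if (!is.null(alpha)) {
    stop("'alpha' is only meaningful for id = 'good_rescaled'", call. = FALSE)
  }
  structure(list(id = id, alpha = alpha), class = "measure_spec")
}

#' @export
print.measure_spec <- function(x, ...) {
  cat("<measure_spec> ", x$id,
      if (!is.null(x$alpha)) sprintf(" (alpha = %g)", x$alpha), "\n", sep = "")
  invisible(x)
}

# Accept a measure_spec, a bare id string, or a preset name.
as_measure_spec <- function(x) {
  if (inherits(x, "measure_spec")) return(x)
  if (is.character(x) && length(x) == 1L) return(measure_spec(x))
  if (is.list(x) && !is.null(x$id)) return(measure_spec(x$id, x$alpha))
  stop("cannot interpret ", deparse(x), " as a measure specification",
       call. = FALSE)
}

check_prob <- function(x, name, open = FALSE) {
  if (is.null(x) || !is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop("'", name, "' must be a single probability", call. = FALSE)
  }
  if (open) {
    if (x <= 0 || x >= 1) {
      stop("'", name, "' must lie strictly inside (0, 1); got ", x,
           call. = FALSE)
    }
  } else if (x < 0 || x > 1) {
    stop("'", name, "' must lie in [0, 1]; got ", x, call. = FALSE)
  }
  invisible(x)
}

#' Explanatory power from conditional probabilities
#'
#' Evaluates a measure of explanatory power directly from the probabilities it
#' needs. The likelihood-based measures (`simple`, `popper`, `good`,
#' `good_rescaled`) require `p_e_given_h` and `p_e`; the Schupbach-Sprenger
#' measure requires `p_h_given_e` and `p_h_given_not_e` and is dispatched to
#' [power_ss()].
#'
#' Good's measure is undefined at \eqn{\Pr(E \mid H) = 0}. By default
#' (`good_zero = "sentinel"`) it returns `-Inf`, which [rescale_good()] maps
#' to -1 so the bounded rescalings stay total; `good_zero = "error"` raises
#' instead.
#'
#' @param measure A [measure_spec()] (or an id/preset string).
#' @param p_e_given_h \eqn{\Pr(E \mid H)}, in \eqn{[0, 1]}.
#' @param p_e \eqn{\Pr(E)}, strictly inside \eqn{(0, 1)}.
#' @param p_h_given_e,p_h_given_not_e Posterior probabilities of H given E and
#'   given not-E; only used by `schupbach_sprenger`.
#' @param good_zero `"sentinel"` or `"error"`; behavior of Good's measure at
#'   `p_e_given_h = 0`.
#' @return The numeric score. In \eqn{[-1, 1]} for all measures except
#'   `good`, whose range is the whole extended real line.
#' @examples
#' power_from_conditionals("popper", p_e_given_h = 0.75, p_e = 0.5625)
#' power_from_conditionals("good", p_e_given_h = 0.4, p_e = 0.2)  # ln 2
#' power_from_conditionals("G3", p_e_given_h = 0.75, p_e = 0.5625)
#' @export
power_from_conditionals <- function(measure, p_e_given_h = NULL, p_e = NULL,
                                    p_h_given_e = NULL,
                                    p_h_given_not_e = NULL,
                                    good_zero = c("sentinel", "error")) {
  measure <- as_measure_spec(measure)
  good_zero <- match.arg(good_zero)
  if (measure$id == "schupbach_sprenger") {
    return(power_ss(p_h_given_e, p_h_given_not_e))
  }
  check_prob(p_e_given_h, "p_e_given_h")
  check_prob(p_e, "p_e", open = TRUE)
  switch(measure$id,
    simple = p_e_given_h - p_e,
    popper = (p_e_given_h - p_e) / (p_e_given_h + p_e),
    good = good_score(p_e_given_h, p_e, good_zero),
    good_rescaled = rescale_good(good_score(p_e_given_h, p_e, good_zero),
                                 measure$alpha)
  )
}

good_score <- function(p_e_given_h, p_e, good_zero) {
  if (p_e_given_h == 0) {
    if (good_zero == "error") {
      stop("Good's measure is undefined at Pr(E|H) = 0", call. = FALSE)
    }
    return(-Inf)
  }
  log(p_e_given_h / p_e)
}

#' Bounded rescaling of Good's measure
#'
#' The map
#' \deqn{L_\alpha(x) = \mathrm{sign}(x)\,
#'       \left(1 - e^{-x^2 / (2\alpha^2)}\right)}
#' compresses an unbounded log-ratio score into \eqn{[-1, 1]}. It is odd,
#' strictly increasing, fixes 0, and sends \eqn{\pm\infty} to \eqn{\pm 1}.
#' Smaller `alpha` makes the compression saturate faster. The presets
#' `"G1"`, `"G2"`, `"G3"` of [measure_spec()] correspond to
#' \eqn{\alpha = 0.5, 1, 2}.
#'
#' @param x Score(s) to rescale; finite or infinite. Vectorized.
#' @param alpha Positive shape parameter.
#' @return Value(s) in \eqn{[-1, 1]}.
#' @examples
#' rescale_good(1, alpha = 1)    # 1 - exp(-1/2)
#' rescale_good(1, alpha = 0.5)  # 1 - exp(-2)
#' @export
rescale_good <- function(x, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0) {
    stop("'alpha' must be a positive number", call. = FALSE)
  }
  if (!is.numeric(x)) stop("'x' must be numeric", call. = FALSE)
  out <- sign(x) * (1 - exp(-x^2 / (2 * alpha^2)))
  # sign(x) * (1 - e^{-Inf}) would be NaN via Inf^2 * 0; patch the limits
  out[is.infinite(x)] <- sign(x[is.infinite(x)])
  out
}

#' Schupbach-Sprenger explanatory power
#'
#' The posterior-contrast measure
#' \deqn{\frac{\Pr(H \mid E) - \Pr(H \mid \neg E)}
#'            {\Pr(H \mid E) + \Pr(H \mid \neg E)},}
#' bounded in \eqn{[-1, 1]}, equal to 0 when E is irrelevant to H, 1 when E
#' entails H, and -1 when E refutes H.
#'
#' @param p_h_given_e \eqn{\Pr(H \mid E)}, in \eqn{[0, 1]}.
#' @param p_h_given_not_e \eqn{\Pr(H \mid \neg E)}, in \eqn{[0, 1]}.
#' @return The score, in \eqn{[-1, 1]}.
#' @examples
#' power_ss(2 / 3, 2 / 7)  # 0.4: one black draw in the two-urn setup
#' @export
power_ss <- function(p_h_given_e, p_h_given_not_e) {
  check_prob(p_h_given_e, "p_h_given_e")
  check_prob(p_h_given_not_e, "p_h_given_not_e")
  s <- p_h_given_e + p_h_given_not_e
  if (s == 0) {
    stop("Schupbach-Sprenger score undefined: both conditionals are zero",
         call. = FALSE)
  }
  (p_h_given_e - p_h_given_not_e) / s
}

#' Explanatory power of a hypothesis within a full model
#'
#' Assembles the probabilities a measure needs from a hypothesis partition
#' with priors and an evidence model with per-hypothesis likelihoods, then
#' evaluates the measure for hypothesis `h`:
#' \eqn{\Pr(E) = \sum_i \Pr(H_i)\Pr(E \mid H_i)},
#' \eqn{\Pr(H \mid E)} by Bayes's theorem, and
#' \eqn{\Pr(H \mid \neg E) = \Pr(H)(1 - \Pr(E \mid H))/(1 - \Pr(E))}.
#'
#' @param measure A [measure_spec()] (or id/preset string).
#' @param space A [hypothesis_space()].
#' @param evidence An [evidence_model()] over the same hypotheses.
#' @param h Hypothesis label (or index) to score.
#' @param good_zero Passed to [power_from_conditionals()].
#' @return The numeric score of `h` against the evidence.
#' @examples
#' sp <- hypothesis_space(c("H_A", "H_B"))  # equal priors
#' ev <- evidence_model(c(H_A = 0.75, H_B = 0.375))
#' power_from_model("schupbach_sprenger", sp, ev, "H_A")  # 0.4
#' power_from_model("good", sp, ev, "H_A")                # ln(4/3)
#' @export
power_from_model <- function(measure, space, evidence, h,
                             good_zero = c("sentinel", "error")) {
  measure <- as_measure_spec(measure)
  good_zero <- match.arg(good_zero)
  space <- as_hypothesis_space(space)
  lik <- evidence_likelihoods(evidence, space$labels)
  i <- hypothesis_index(space, h)
  p_e <- sum(space$priors * lik)
  if (p_e <= 0) {
    stop("evidence has zero marginal probability under the model",
         call. = FALSE)
  }
  if (measure$id == "schupbach_sprenger") {
    if (p_e >= 1) {
      stop("Pr(H | not-E) undefined: evidence has marginal probability 1",
           call. = FALSE)
    }
    p_h_e <- unname(space$priors[[i]]) * lik[i] / p_e
    p_h_ne <- unname(space$priors[[i]]) * (1 - lik[i]) / (1 - p_e)
    return(power_ss(p_h_e, p_h_ne))
  }
  if (p_e >= 1) {
    stop("degenerate evidence: marginal probability must lie in (0, 1)",
         call. = FALSE)
  }
  power_from_conditionals(measure, p_e_given_h = lik[i], p_e = p_e,
                          good_zero = good_zero)
}
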