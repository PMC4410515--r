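#' Fit a Gaussian linear credence model by maximum likelihood
#'
#' Ordinary least squares (equivalently, Gaussian maximum likelihood) fit of
#' the credence `S` on a set of predictor columns, with the bookkeeping the
#' model-comparison machinery needs: the maximized log-likelihood is
#' evaluated at the ML variance estimate \eqn{\hat\sigma^2 = RSS/n}, the
#' parameter count `k` is the number of regression coefficients (including
#' the intercept) plus one for the noise variance, and `AIC = 2k - 2LL`.
#' Pointwise per-observation log-likelihoods are retained for the non-nested
#' tests ([vuong_test()], [clarke_test()]).
#'
#' Standardized coefficients (`beta`) are reported alongside the raw ones:
#' the estimate rescaled by the predictor and response standard deviations.
#'
#' @param table Data frame containing `response` and the predictors.
#' @param predictors Character vector of predictor column names (possibly
#'   empty: intercept-only model).
#' @param response Response column name; default `"S"`.
#' @param name Model label; defaults to `"M" + predictor initials`.
#' @return An object of class `"credence_fit"`: list with `name`,
#'   `predictors`, `coefficients` (data frame with `B`, `SE_B`, `beta`, `t`,
#'   `p`), `n`, `k`, `LL`, `AIC`, `R2`, `pointwise_ll`, and the underlying
#'   `lm` object.
#' @examples
#' d <- generate_dataset(generator_config(seed = 1))
#' fit_credence_model(d, c("O", "score_A", "score_B"))
#' @export
fit_credence_model <- function(table, predictors, response = "S",
                               name = NULL) {
  missing_cols <- setdiff(c(response, predictors), names(table))
  if (length(missing_cols) > 0L) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  rhs <- if (length(predictors) == 0L) "1" else paste(predictors,
                                                      collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(fml, data = table)
  if (any(is.na(stats::coef(fit)))) {
    stop("singular design: predictors are collinear", call. = FALSE)
  }
  n <- length(stats::residuals(fit))
  res <- stats::residuals(fit)
  rss <- sum(res^2)
  if (rss <= 0) stop("degenerate fit: zero residual variance", call. = FALSE)
  sigma2 <- rss / n
  pointwise <- stats::dnorm(res, mean = 0, sd = sqrt(sigma2), log = TRUE)
  ll <- sum(pointwise)
  k <- length(stats::coef(fit)) + 1L
  sm <- summary(fit)
  ct <- sm$coefficients
  sd_y <- stats::sd(table[[response]])
  beta_std <- vapply(rownames(ct), function(v) {
    if (v == "(Intercept)") NA_real_
    else ct[v, 1L] * stats::sd(table[[v]]) / sd_y
  }, numeric(1))
  coefs <- data.frame(term = rownames(ct), B = ct[, 1L], SE_B = ct[, 2L],
                      beta = beta_std, t = ct[, 3L], p = ct[, 4L],
                      row.names = NULL)
  if (is.null(name)) {
    name <- paste0("M", paste(substr(predictors, 1L, 1L), collapse = ""))
  }
  structure(list(name = name, predictors = predictors,
                 response = response, coefficients = coefs,
                 n = n, k = k, LL = ll, AIC = 2 * k - 2 * ll,
                 R2 = sm$r.squared, pointwise_ll = pointwise, lm = fit),
            class = "credence_fit")
}

#' @export
print.credence_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<credence_fit> %s: %s ~ %s\n", x$name, x$response,
              if (length(x$predictors)) paste(x$predictors, collapse = " + ")
              else "1"))
  cat(sprintf("  n = %d, k = %d, LL = %.2f, AIC = %.2f, R2 = %.3f\n",
              x$n, x$k, x$LL, x$AIC, x$R2))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Likelihood-ratio test of nested Gaussian linear models
#'
#' Statistic \eqn{2(LL_{full} - LL_{nested})} referred to a chi-squared
#' distribution with df equal to the difference in parameter counts.
#'
#' @param nested,full `"credence_fit"` objects on the same rows, with the
#'   nested model's predictors a subset of the full model's.
#' @return A list with `statistic`, `df`, `p`.
#' @examples
#' d <- generate_dataset(generator_config(seed = 1))
#' m0 <- fit_credence_model(d, "O", name = "MO")
#' m1 <- fit_credence_model(d, c("O", "score_A", "score_B"), name = "MOAB")
#' lr_test(m0, m1)
#' @export
lr_test <- function(nested, full) {
  if (!inherits(nested, "credence_fit") || !inherits(full, "credence_fit")) {
    stop("expected credence_fit objects", call. = FALSE)
  }
  if (nested$n != full$n) {
    stop("models were fitted on different numbers of rows", call. = FALSE)
  }
  if (!all(nested$predictors %in% full$predictors) ||
      length(nested$predictors) >= length(full$predictors)) {
    stop("'nested' must be strictly nested within 'full'", call. = FALSE)
  }
  lr_from_loglik(nested$LL, full$LL, full$k - nested$k)
}

#' Likelihood-ratio arithmetic from log-likelihoods
#'
#' The pure arithmetic of the likelihood-ratio test, usable directly on
#' published log-likelihood values: statistic \eqn{2(LL_1 - LL_0)}, upper
#' chi-squared tail with `df` degrees of freedom.
#'
#' @param ll_nested,ll_full Maximized log-likelihoods.
#' @param df Degrees of freedom (difference in parameter counts).
#' @return A list with `statistic`, `df`, `p`.
#' @examples
#' lr_from_loglik(202.39, 222.64, df = 2)  # chi2 = 40.50
#' @export
lr_from_loglik <- function(ll_nested, ll_full, df) {
  stat <- 2 * (ll_full - ll_nested)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Vuong's test for non-nested models
#'
#' Normal-reference test on the pointwise log-likelihood differences
#' \eqn{d_i = \ell_i^{(A)} - \ell_i^{(B)}}: the statistic is
#' \eqn{\sum_i d_i / (\sqrt{n}\, \mathrm{sd}(d))} with a two-sided normal
#' p value. A positive significant statistic prefers model A, a negative
#' one model B. The basic (uncorrected) statistic is the default; the
#' Schwarz correction subtracting \eqn{(k_A - k_B)\ln(n)/2} from
#' \eqn{\sum_i d_i} is available for models of unequal size.
#'
#' @param fitA,fitB `"credence_fit"` objects on the same rows.
#' @param alpha Significance level deciding the `preferred` field.
#' @param correction `"none"` (default) or `"bic"` (Schwarz-corrected).
#' @return A list with `test = "vuong"`, `statistic`, `p`, `preferred`
#'   (model name or `NA`), and `degenerate` (`TRUE` when the pointwise
#'   differences have zero variance).
#' @export
vuong_test <- function(fitA, fitB, alpha = 0.05,
                       correction = c("none", "bic")) {
  correction <- match.arg(correction)
  d <- pointwise_diffs(fitA, fitB)
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) {
    return(list(test = "vuong", statistic = NA_real_, p = NA_real_,
                preferred = NA_character_, degenerate = TRUE))
  }
  num <- sum(d)
  if (correction == "bic") num <- num - (fitA$k - fitB$k) * log(n) / 2
  z <- num / (sqrt(n) * s)
  p <- 2 * stats::pnorm(-abs(z))
  preferred <- if (p < alpha) {
    if (z > 0) fitA$name else fitB$name
  } else NA_character_
  list(test = "vuong", statistic = z, p = p, preferred = preferred,
       degenerate = FALSE)
}

#' Clarke's distribution-free test for non-nested models
#'
#' Sign test on the pointwise log-likelihood differences: after dropping
#' exact zeros, `B` counts the observations favoring model A and is referred
#' to an exact two-sided Binomial(n', 1/2) distribution. A significant
#' majority prefers the corresponding model.
#'
#' @inheritParams vuong_test
#' @return A list with `test = "clarke"`, `statistic` (the count B), `n_used`
#'   (nonzero differences), `p`, `preferred`, `degenerate`.
#' @export
clarke_test <- function(fitA, fitB, alpha = 0.05) {
  d <- pointwise_diffs(fitA, fitB)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(test = "clarke", statistic = NA_real_, n_used = 0L,
                p = NA_real_, preferred = NA_character_, degenerate = TRUE))
  }
  b <- sum(d > 0)
  p <- stats::binom.test(b, n, p = 0.5)$p.value
  preferred <- if (p < alpha) {
    if (b > n / 2) fitA$name else fitB$name
  } else NA_character_
  list(test = "clarke", statistic = b, n_used = n, p = p,
       preferred = preferred, degenerate = FALSE)
}

pointwise_diffs <- function(fitA, fitB) {
  if (!inherits(fitA, "credence_fit") || !inherits(fitB, "credence_fit")) {
    stop("expected credence_fit objects", call. = FALSE)
  }
  if (fitA$n != fitB$n) {
    stop("models were fitted on different numbers of rows", call. = FALSE)
  }
  fitA$pointwise_ll - fitB$pointwise_ll
}

#' Fit and compare a family of credence models
#'
#' Fits every model of a named predictor-set list on the same trial table
#' and assembles the comparison report: per model `k`, `LL`, `AIC`, `dAIC`
#' against the best (lowest) AIC, a likelihood-ratio test against the
#' declared baseline model (which must be nested in every other model), and
#' `R2`; plus all pairwise Vuong and Clarke tests among non-nested model
#' pairs.
#'
#' @param table Trial table with the predictor columns.
#' @param models Named list mapping model name to character vector of
#'   predictor columns.
#' @param baseline Name of the baseline model (nested in all others).
#' @param response Response column; default `"S"`.
#' @return An object of class `"comparison_report"`: list with `table` (data
#'   frame: model, k, LL, AIC, dAIC, chi2, df, p, R2), `fits`, and
#'   `pairwise` (data frame of non-nested test results).
#' @examples
#' d <- generate_dataset(generator_config(seed = 1))
#' compare_models(d, list(MO = "O", MOAB = c("O", "score_A", "score_B")),
#'                baseline = "MO")
#' @export
compare_models <- function(table, models, baseline, response = "S") {
  if (is.null(names(models)) || anyDuplicated(names(models))) {
    stop("'models' must be a uniquely named list of predictor sets",
         call. = FALSE)
  }
  if (!baseline %in% names(models)) {
    stop("baseline model not in 'models'", call. = FALSE)
  }
  fits <- lapply(names(models), function(nm) {
    fit_credence_model(table, models[[nm]], response = response, name = nm)
  })
  names(fits) <- names(models)
  base_pred <- models[[baseline]]
  for (nm in setdiff(names(models), baseline)) {
    if (!all(base_pred %in% models[[nm]])) {
      stop("baseline is not nested in model ", nm, call. = FALSE)
    }
  }
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  best <- names(which(aic == min(aic)))
  if (length(best) > 1L) {
    warning("AIC tie between ", paste(best, collapse = ", "),
            "; breaking by name order", call. = FALSE)
    best <- sort(best)[1L]
  }
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (nm == baseline) {
      chi2 <- df <- p <- NA_real_
    } else {
      lr <- lr_test(fits[[baseline]], f)
      chi2 <- lr$statistic; df <- lr$df; p <- lr$p
    }
    data.frame(model = nm, k = f$k, LL = f$LL, AIC = f$AIC,
               dAIC = f$AIC - min(aic), chi2 = chi2, df = df, p = p,
               R2 = f$R2)
  })
  tab <- do.call(rbind, rows)
  nms <- names(fits)
  pairs <- list()
  for (i in seq_along(nms)) {
    for (j in seq_along(nms)) {
      if (j <= i) next
      pi <- models[[nms[i]]]; pj <- models[[nms[j]]]
      if (all(pi %in% pj) || all(pj %in% pi)) next
      v <- vuong_test(fits[[nms[i]]], fits[[nms[j]]])
      cl <- clarke_test(fits[[nms[i]]], fits[[nms[j]]])
      pairs[[length(pairs) + 1L]] <- data.frame(
        model_A = nms[i], model_B = nms[j],
        vuong_z = v$statistic, vuong_p = v$p,
        vuong_preferred = if (is.na(v$preferred)) NA_character_
                          else v$preferred,
        clarke_B = cl$statistic, clarke_n = cl$n_used, clarke_p = cl$p,
        clarke_preferred = if (is.na(cl$preferred)) NA_character_
                           else cl$preferred)
    }
  }
  pairwise <- if (length(pairs)) do.call(rbind, pairs) else NULL
  structure(list(table = tab, fits = fits, pairwise = pairwise,
                 baseline = baseline, best = best),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, digits = 2, ...) {
  cat("<comparison_report> baseline =", x$baseline, "; best AIC =", x$best,
      "\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat("\nNon-nested pairwise tests:\n")
    pw <- x$pairwise
    pw$vuong_z <- round(pw$vuong_z, digits)
    pw$vuong_p <- signif(pw$vuong_p, 3)
    pw$clarke_p <- signif(pw$clarke_p, 3)
    print(pw, row.names = FALSE)
  }
  invisible(x)
}

#' Comparison arithmetic from published model summaries
#'
#' Recomputes the derived columns of a model-comparison table from reported
#' `k` and `LL` values alone: `AIC = 2k - 2LL`, `dAIC` against the best
#' (lowest) AIC, and the likelihood-ratio chi-squared of each model against
#' a declared nested baseline (df from the difference in `k`). Useful for
#' checking the internal arithmetic consistency of published comparison
#' tables, where the underlying data are unavailable.
#'
#' @param summaries Data frame with columns `model`, `k`, `LL`.
#' @param baseline Baseline model name (nested within the others).
#' @return Data frame with columns `model`, `k`, `LL`, `AIC`, `dAIC`,
#'   `chi2`, `df`, `p`.
#' @examples
#' comparison_from_summaries(urn_study_models()[1:2, c("model", "k", "LL")],
#'                           baseline = "MO")
#' @export
comparison_from_summaries <- function(summaries, baseline) {
  need <- c("model", "k", "LL")
  if (!all(need %in% names(summaries))) {
    stop("'summaries' needs columns model, k, LL", call. = FALSE)
  }
  if (!baseline %in% summaries$model) {
    stop("baseline not among the models", call. = FALSE)
  }
  aic <- 2 * summaries$k - 2 * summaries$LL
  base <- summaries[summaries$model == baseline, ]
  chi2 <- df <- p <- rep(NA_real_, nrow(summaries))
  other <- summaries$model != baseline
  chi2[other] <- 2 * (summaries$LL[other] - base$LL)
  df[other] <- summaries$k[other] - base$k
  p[other] <- stats::pchisq(chi2[other], df[other], lower.tail = FALSE)
  data.frame(model = summaries$model, k = summaries$k, LL = summaries$LL,
             AIC = aic, dAIC = aic - min(aic), chi2 = chi2, df = df, p = p)
}
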