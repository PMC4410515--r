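# Shared fixture builders for the test suite. Everything is generated in
# code; no stored data files.

# A random finite partition with strictly positive priors and likelihoods
# bounded away from 0 so that every update is well-defined.
random_partition <- function(n_max = 6L) {
  n <- sample(2:n_max, 1L)
  labels <- paste0("H", seq_len(n))
  priors <- stats::runif(n, 0.05, 1)
  priors <- priors / sum(priors)
  lik <- stats::runif(n, 0.05, 0.95)
  list(space = hypothesis_space(labels, priors),
       evidence = evidence_model(stats::setNames(lik, labels)))
}

# The standard two-urn design and its first-draw likelihoods.
standard_urn <- function() urn_spec()

first_black_evidence <- function() {
  evidence_model(c(H_A = 0.75, H_B = 0.375))
}

# All draw sequences of a given length as a list of character vectors.
all_sequences <- function(n) {
  if (n == 0L) return(list(character(0)))
  grid <- expand.grid(rep(list(c("B", "W")), n), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(r) as.character(grid[r, ]))
}

# Forge a minimal credence_fit carrying a given pointwise log-likelihood
# vector, for exercising the non-nested tests on constructed inputs.
fake_fit <- function(pointwise, name = "F", k = 3L) {
  structure(list(name = name, predictors = character(0), response = "S",
                 n = length(pointwise), k = k, LL = sum(pointwise),
                 AIC = 2 * k - 2 * sum(pointwise), R2 = NA_real_,
                 pointwise_ll = pointwise),
            class = "credence_fit")
}
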