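test_that("draw-sequence likelihoods follow without-replacement counting", {
  expect_equal(sequence_likelihood(30, 10, "B"), 0.75)
  expect_equal(sequence_likelihood(30, 10, c("B", "B")), (30 / 40) * (29 / 39))
  expect_identical(sequence_likelihood(30, 10, rep("W", 11)), 0)
  expect_identical(sequence_likelihood(30, 10, character(0)), 1)
  # order of draws never changes the sequence probability
  expect_equal(sequence_likelihood(15, 25, c("B", "W", "B")),
               sequence_likelihood(15, 25, c("W", "B", "B")))
})

test_that("objective posterior trajectory matches hand arithmetic", {
  spec <- standard_urn()
  expect_equal(posterior_trajectory(spec, character(0)), 0.5)
  expect_equal(posterior_trajectory(spec, "B"), c(0.5, 2 / 3))
  expect_equal(posterior_trajectory(spec, c("B", "B")),
               c(0.5, 2 / 3, 870 / 1080))
})

test_that("sequential updating equals joint conditioning on the sequence", {
  spec <- standard_urn()
  sp <- hypothesis_space(spec$labels, spec$priors)
  for (n in 1:4) {
    for (draws in all_sequences(n)) {
      # sequential: one Bayes step per draw with single-draw likelihoods
      # conditioned on the history under each urn
      cred <- sp$priors
      hist <- character(0)
      for (d in draws) {
        lik <- vapply(seq_along(spec$black), function(i) {
          num <- sequence_likelihood(spec$black[i], spec$white[i],
                                     c(hist, d))
          den <- sequence_likelihood(spec$black[i], spec$white[i], hist)
          num / den
        }, numeric(1))
        cred <- bayes_update(
          credence_state(cred),
          evidence_model(stats::setNames(lik, spec$labels)))$values
        hist <- c(hist, d)
      }
      joint <- posterior_trajectory(spec, draws)
      expect_equal(cred[["H_A"]], joint[length(joint)], tolerance = 1e-12)
    }
  }
})

test_that("posteriors depend only on draw counts, not order", {
  spec <- standard_urn()
  set.seed(5)
  for (i in 1:20) {
    draws <- sample(c("B", "W"), 6, replace = TRUE)
    perm <- sample(draws)
    a <- posterior_trajectory(spec, draws)
    b <- posterior_trajectory(spec, perm)
    expect_equal(a[7], b[7], tolerance = 1e-12)
  }
})

test_that("trial scores reproduce the first-draw worked case", {
  row <- trial_scores(standard_urn(), "B", "schupbach_sprenger")
  expect_equal(row$O, 2 / 3)
  expect_equal(row$score_A, 0.4)
  expect_equal(row$score_B, -4 / 11)
  expect_identical(nrow(trial_scores(standard_urn(), character(0))), 0L)
})

test_that("indistinguishable urns pin O at the prior with zero scores", {
  same <- urn_spec(black = c(30, 30), white = c(10, 10))
  tab <- trial_scores(same, c("B", "W", "B"), "popper")
  expect_equal(tab$O, rep(0.5, 3))
  expect_equal(tab$score_A, rep(0, 3))
  expect_equal(tab$score_B, rep(0, 3))
})

test_that("score ordering tracks the cumulative likelihood ordering", {
  spec <- standard_urn()
  set.seed(9)
  for (m in c("popper", "G3", "schupbach_sprenger")) {
    draws <- sample(c("B", "W"), 8, replace = TRUE)
    tab <- trial_scores(spec, draws, m)
    for (k in seq_along(draws)) {
      lA <- sequence_likelihood(30, 10, draws[seq_len(k)])
      lB <- sequence_likelihood(15, 25, draws[seq_len(k)])
      expect_identical(tab$score_A[k] > tab$score_B[k], lA > lB)
    }
  }
})

test_that("sequence enumeration is exhaustive and sums to one", {
  spec <- standard_urn()
  e1 <- enumerate_sequences(spec, 1)
  expect_equal(e1$probability[e1$sequence == "B"], 0.5625)
  expect_equal(e1$probability[e1$sequence == "W"], 0.4375)
  expect_identical(nrow(enumerate_sequences(spec, 2)), 4L)
  for (n in 1:6) {
    expect_equal(sum(enumerate_sequences(spec, n)$probability), 1,
                 tolerance = 1e-12)
  }
})

test_that("simulated trials are reproducible and respect the design", {
  spec <- standard_urn()
  t1 <- simulate_trial(spec, 10, seed = 42)
  t2 <- simulate_trial(spec, 10, seed = 42)
  expect_identical(t1, t2)
  expect_length(t1$draws, 10)

  forced <- urn_spec(black = c(40, 0), white = c(0, 40), priors = c(1, 0))
  allb <- simulate_trial(forced, 10, seed = 1)
  expect_identical(allb$urn, "H_A")
  expect_true(all(allb$draws == "B"))

  expect_error(simulate_trial(spec, 41), "n_draws")

  set.seed(77)
  urns <- replicate(1e4, simulate_trial(spec, 0)$urn)
  expect_lt(abs(mean(urns == "H_A") - 0.5), 0.015)
})

test_that("Monte-Carlo draw frequencies match the enumeration", {
  spec <- standard_urn()
  n <- 3
  set.seed(123)
  sims <- replicate(1e5, paste0(simulate_trial(spec, n)$draws,
                                collapse = ""))
  ref <- enumerate_sequences(spec, n)
  counts <- table(factor(sims, levels = ref$sequence))
  gof <- stats::chisq.test(as.vector(counts), p = ref$probability)
  expect_gt(gof$p.value, 0.001)
})
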