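test_that("worked values of the power measures are reproduced", {
  # neutral point: evidence probabilistically independent of the hypothesis
  for (m in c("simple", "popper", "good")) {
    expect_identical(power_from_conditionals(m, 0.4, 0.4), 0)
  }
  expect_equal(power_from_conditionals("popper", 0.75, 0.5625),
               0.1875 / 1.3125)
  expect_equal(power_from_conditionals("good", 0.4, 0.2), log(2))
  expect_identical(power_from_conditionals("popper", 0, 0.5), -1)
  expect_identical(power_ss(0.3, 0.3), 0)
  expect_identical(power_ss(1, 0), 1)
  expect_equal(power_ss(2 / 3, 2 / 7), 0.4)
})

test_that("L_alpha rescaling matches its closed form and limits", {
  expect_identical(rescale_good(0, 1), 0)
  expect_identical(rescale_good(0, 17), 0)
  expect_equal(rescale_good(1, 1), 1 - exp(-1 / 2))
  expect_equal(rescale_good(-1, 1), -(1 - exp(-1 / 2)))
  expect_equal(rescale_good(1, 0.5), 1 - exp(-2))
  expect_identical(rescale_good(Inf, 2), 1)
  expect_identical(rescale_good(-Inf, 2), -1)
  expect_error(rescale_good(1, 0), "alpha")
  expect_error(rescale_good(1, -2), "alpha")
})

test_that("L_alpha is odd, strictly increasing, and saturates at +/-1", {
  set.seed(11)
  for (alpha in c(0.5, 1, 2, 5)) {
    x <- sort(stats::runif(200, -20, 20))
    y <- rescale_good(x, alpha)
    expect_equal(rescale_good(-x, alpha), -y)
    expect_true(all(diff(y) >= 0))
    expect_true(all(y >= -1 & y <= 1))
    # strictness where the exponential has not saturated to +/-1
    xs <- sort(stats::runif(200, -2 * alpha, 2 * alpha))
    expect_true(all(diff(rescale_good(xs, alpha)) > 0))
    expect_gt(rescale_good(1e6, alpha), 1 - 1e-12)
  }
})

test_that("preset names expand to the Good rescalings", {
  expect_equal(measure_spec("G1"), measure_spec("good_rescaled", 0.5))
  expect_equal(measure_spec("G2"), measure_spec("good_rescaled", 1))
  expect_equal(measure_spec("G3"), measure_spec("good_rescaled", 2))
  x <- log(4 / 3)
  expect_equal(power_from_conditionals("G3", 0.75, 0.5625),
               rescale_good(x, 2))
})

test_that("bounded measures stay in [-1, 1] and vanish at independence", {
  set.seed(7)
  n <- 1e4
  pe <- stats::runif(n, 0.01, 0.99)
  peh <- stats::runif(n)
  for (m in c("popper", "G1", "G2", "G3")) {
    v <- vapply(seq_len(n),
                function(i) power_from_conditionals(m, peh[i], pe[i]),
                numeric(1))
    expect_true(all(v >= -1 & v <= 1))
    expect_identical(power_from_conditionals(m, pe[1], pe[1]), 0)
  }
  p1 <- stats::runif(n)
  p2 <- stats::runif(n)
  keep <- p1 + p2 > 0
  vss <- vapply(which(keep), function(i) power_ss(p1[i], p2[i]), numeric(1))
  expect_true(all(vss >= -1 & vss <= 1))
})

test_that("every measure is non-decreasing in Pr(E|H) at fixed Pr(E)", {
  peh <- seq(0.01, 0.99, by = 0.01)
  for (pe in c(0.2, 0.5, 0.8)) {
    for (m in c("simple", "popper", "good", "G1", "G3")) {
      v <- vapply(peh, function(l) power_from_conditionals(m, l, pe),
                  numeric(1))
      expect_true(all(diff(v) >= 0), info = paste(m, pe))
    }
  }
})

test_that("Good's measure at Pr(E|H) = 0 follows the configured mode", {
  expect_identical(power_from_conditionals("good", 0, 0.5), -Inf)
  expect_identical(power_from_conditionals("G2", 0, 0.5), -1)
  expect_error(power_from_conditionals("good", 0, 0.5, good_zero = "error"),
               "undefined")
})

test_that("degenerate inputs raise the documented errors", {
  expect_error(power_from_conditionals("popper", 0.5, 0), "p_e")
  expect_error(power_from_conditionals("popper", 0.5, 1), "p_e")
  expect_error(power_ss(0, 0), "undefined")
  expect_error(measure_spec("nonsense"), "unknown measure")
  expect_error(measure_spec("good_rescaled"), "alpha")
  expect_error(measure_spec("popper", alpha = 1), "alpha")
})

test_that("model-based scores equal hand-assembled conditional inputs", {
  # exhaustive two-hypothesis grid; the oracle assembles Pr(E), Pr(H|E),
  # Pr(H|not-E) by direct arithmetic and calls the formula layer itself
  priors_A <- seq(0.1, 0.9, by = 0.2)
  liks <- seq(0.05, 0.95, by = 0.15)
  measures <- list("simple", "popper", "good", "G1", "G3",
                   "schupbach_sprenger")
  for (pa in priors_A) {
    sp <- hypothesis_space(c("H_A", "H_B"), c(pa, 1 - pa))
    for (la in liks) for (lb in liks) {
      ev <- evidence_model(c(H_A = la, H_B = lb))
      pe <- pa * la + (1 - pa) * lb
      if (pe <= 0 || pe >= 1) next
      for (m in measures) {
        got <- power_from_model(m, sp, ev, "H_A")
        want <- if (identical(m, "schupbach_sprenger")) {
          power_ss(pa * la / pe, pa * (1 - la) / (1 - pe))
        } else {
          power_from_conditionals(m, p_e_given_h = la, p_e = pe)
        }
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
})

test_that("equal likelihoods give score 0 for every measure", {
  sp <- hypothesis_space(c("a", "b", "c"), c(0.2, 0.3, 0.5))
  ev <- evidence_model(c(a = 0.4, b = 0.4, c = 0.4))
  for (m in c("simple", "popper", "good", "G2", "schupbach_sprenger")) {
    expect_equal(power_from_model(m, sp, ev, "b"), 0, tolerance = 1e-15)
  }
})
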