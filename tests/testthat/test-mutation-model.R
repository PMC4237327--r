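test_that("oncogenic hit probability is the per-gene rate scaled by the oncogene count", {
  expect_equal(oncogenic_hit_probability(mutation_params(u = 1e-7, n_min = 5)),
               2.9e-6)
  expect_equal(oncogenic_hit_probability(mutation_params(u = 0, n_min = 1)), 0)
  # the packaged constants are mutually consistent
  p <- mutation_params(u = 1e-7, n_min = 5, n_onco = 29, G = 18440)
  expect_equal(p$n_onco, nrow(load_oncogene_set()))
})

test_that("parameter validation rejects out-of-range inputs", {
  expect_error(mutation_params(u = 1e-2, n_min = 5), "1e-3")
  expect_error(mutation_params(u = NA, n_min = 5), "finite")
  expect_error(mutation_params(u = 1e-7, n_min = 30), "n_onco")
  expect_error(mutation_params(u = 1e-7, n_min = 0), "n_min")
  expect_error(mutation_params(u = 1e-7, n_min = 5, S = -1), "positive")
  expect_error(mutation_params(u = 1e-7, n_min = 5, n_onco = 30000), "G")
})

test_that("log-space binomial pmf matches a direct implementation and normalises", {
  # dual route: our lchoose/log1p assembly vs stats::dbinom
  for (case in list(c(d = 1e3, u = 1e-6), c(d = 5e4, u = 2.9e-6),
                    c(d = 50, u = 0.01))) {
    x <- 0:min(case[["d"]], 40)
    expect_equal(prob_x_hits_binomial(x, case[["d"]], case[["u"]]),
                 dbinom(x, case[["d"]], case[["u"]]), tolerance = 1e-12)
  }
  expect_equal(sum(prob_x_hits_binomial(0:50, 50, 0.01)), 1, tolerance = 1e-12)
  expect_equal(prob_x_hits_binomial(0, 1000, 1e-6), (1 - 1e-6)^1000)
  expect_equal(prob_x_hits_binomial(5, 3, 0.1), 0)   # x > d is impossible
  expect_error(prob_x_hits_binomial(2, 100, 1.5), "u_o")
  # frozen arbitrary-precision value (20000 choose 2) u^2 (1-u)^19998
  expect_equal(prob_x_hits_binomial(2, 20000, 2.9e-6),
               0.0015871489225998049391, tolerance = 1e-12)
})

test_that("Poisson pmf has its closed form and approximates the binomial", {
  expect_equal(prob_x_hits_poisson(0, 0), 1)
  expect_equal(prob_x_hits_poisson(1, 0.01), 0.01 * exp(-0.01))
  expect_equal(sum(prob_x_hits_poisson(0:200, 0.5)), 1, tolerance = 1e-12)
  expect_error(prob_x_hits_poisson(1, -0.1), "lambda")

  # spec'd example: d = 25000 divisions at u_o = 2.9e-6, x up to 8
  d <- 25000; u_o <- 2.9e-6
  x <- 0:8
  pois <- prob_x_hits_poisson(x, u_o * d)
  bino <- prob_x_hits_binomial(x, d, u_o)
  expect_lt(max(abs(pois - bino) / bino), 0.01)
  # frozen value: Poisson(2; 0.058) agrees with the exact binomial to 0.5%
  expect_equal(prob_x_hits_poisson(2, 2.9e-6 * 20000),
               0.0015872192115886951013, tolerance = 1e-12)
  expect_lt(abs(prob_x_hits_poisson(2, 0.058) /
                  prob_x_hits_binomial(2, 20000, 2.9e-6) - 1), 0.005)
})

test_that("Poisson-binomial agreement holds across the rare-mutation regime", {
  # property sweep: all pmf values above 1e-12 agree within 1% once a cell
  # has accumulated the division counts relevant to the model (>= 1e4)
  for (u_o in c(1e-6, 1e-5, 1e-4)) {
    for (d in c(1e4, 1e5)) {
      x <- 0:40
      bino <- prob_x_hits_binomial(x, d, u_o)
      pois <- prob_x_hits_poisson(x, u_o * d)
      keep <- bino >= 1e-12
      expect_lt(max(abs(pois[keep] - bino[keep]) / bino[keep]), 0.01,
                label = sprintf("u_o=%g d=%g disagreement", u_o, d))
    }
  }
  # at smaller division counts the approximation error follows the
  # classical x^2 / (2 d) envelope rather than a flat 1%
  d <- 1e3; u_o <- 1e-4
  x <- 0:7
  bino <- prob_x_hits_binomial(x, d, u_o)
  pois <- prob_x_hits_poisson(x, u_o * d)
  rel <- abs(pois - bino) / bino
  expect_true(all(rel <= pmax(x^2 / (2 * d), 1e-4)))
})

test_that("ordering-weighted hit probability reduces, caps and scales as it should", {
  lam <- 0.05
  # S = x! means every temporal ordering transforms: plain Poisson term
  expect_equal(prob_x_transforming(4, lam, S = factorial(4)),
               prob_x_hits_poisson(4, lam))
  expect_equal(prob_x_transforming(1, lam, S = 1),
               prob_x_hits_poisson(1, lam))
  # linear (hence strictly increasing) in S
  ps <- sapply(c(1, 5, 20, 100), function(S)
    prob_x_transforming(5, lam, S = S))
  expect_true(all(diff(ps) > 0))
  expect_equal(ps[4] / ps[1], 100)
  # the ordering fraction caps at 1
  expect_error(prob_x_transforming(3, lam, S = 7), "x!")
  expect_error(prob_x_transforming(2, lam, S = 1e9, ordering = "permutation"),
               "cap")
  # "all" ignores the multiplicity and "permutation" divides by falling factorial
  expect_equal(prob_x_transforming(3, lam, S = 2, ordering = "all"),
               prob_x_hits_poisson(3, lam))
  expect_equal(prob_x_transforming(2, lam, S = 1, ordering = "permutation"),
               prob_x_hits_poisson(2, lam) / (29 * 28))
})

test_that("per-cell transformation probability sums the transforming hit counts", {
  p <- default_mut(n_min = 5, S = 30)
  expect_equal(per_cell_transformation_prob(0, p), 0)
  # truncating the series at n_onco = 29 loses < 1e-12 relative to x -> 200
  p1 <- mutation_params(u = 1e-7, n_min = 1, S = 1)
  for (lam in c(0.05, 0.2, 0.49)) {
    full <- sum(1 / factorial(1:200) * dpois(1:200, lam))
    expect_equal(per_cell_transformation_prob(lam, p1), full,
                 tolerance = 1e-12)
  }
  # monotone nondecreasing in lambda over a dense scan
  lam <- seq(0, 0.3, length.out = 1000)
  p50 <- mutation_params(u = 1e-7, n_min = 5, S = 50)
  expect_true(all(diff(per_cell_transformation_prob(lam, p50)) >= 0))
  # monotone in S and in n_min
  lam0 <- 0.1
  pS <- sapply(c(1, 10, 100), function(S)
    per_cell_transformation_prob(lam0, mutation_params(u = 1e-7, n_min = 5,
                                                       S = S)))
  expect_true(all(diff(pS) > 0))
  pn <- sapply(1:8, function(n)
    per_cell_transformation_prob(lam0, mutation_params(u = 1e-7, n_min = n,
                                                       S = 1)))
  expect_true(all(diff(pn) < 0))
})

test_that("small-lambda limit follows the leading-order closed form", {
  # P1 ~ S lambda^n_min e^(-lambda) / (n_min!)^2 as lambda -> 0
  lam <- 1e-4
  for (n_min in c(2, 5)) {
    S <- min(30, factorial(n_min))
    p <- mutation_params(u = 1e-7, n_min = n_min, S = S)
    leading <- S * lam^n_min * exp(-lam) / factorial(n_min)^2
    expect_equal(per_cell_transformation_prob(lam, p) / leading, 1,
                 tolerance = 1e-4)
  }
})

test_that("a hit requirement above the oncogene count yields zero with a warning", {
  p <- default_mut()
  p$n_min <- 35L  # bypass the constructor to probe the operational guard
  expect_warning(out <- per_cell_transformation_prob(0.1, p), "n_onco")
  expect_equal(out, 0)
})
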