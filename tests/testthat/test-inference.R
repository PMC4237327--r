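test_that("noiseless self-generated tables are recovered almost exactly", {
  g <- fast_grid()
  tab <- make_table(k = 0.07, S = 30, n_min = 5, grid = g)
  fit <- quiet_fit(tab, n_min = 5, u = 1e-7, N0 = 1e5, grid = g)
  expect_lt(abs(fit$k_hat - 0.07) / 0.07, 0.05)
  expect_lt(abs(fit$S_hat - 30) / 30, 0.10)
  expect_lt(fit$objective, 1e-10)

  # round-trip self-consistency: refitting the fitted curve's own binned
  # rates lands on the same optimum
  tab2 <- incidence_table(
    data.frame(age_lo = fit$residuals$age_lo,
               age_hi = fit$residuals$age_hi,
               rate_per_100k_py = fit$residuals$fitted))
  fit2 <- quiet_fit(tab2, n_min = 5, u = 1e-7, N0 = 1e5, grid = g)
  expect_equal(fit2$k_hat, fit$k_hat, tolerance = 1e-3)
  expect_equal(fit2$objective, 0, tolerance = 1e-10)
})

test_that("fitting is robust to multiplicative observation noise", {
  g <- fast_grid()
  errs <- purrr::map_dbl(1:20, function(s) {
    tab <- make_table(k = 0.07, S = 30, n_min = 5, noise = "lognormal",
                      sigma = 0.1, seed = s, grid = g)
    fit <- quiet_fit(tab, n_min = 5, u = 1e-7, N0 = 1e5, grid = g)
    abs(fit$k_hat - 0.07) / 0.07
  })
  expect_lt(median(errs), 0.10)
})

test_that("the objective is a local minimum at the generating parameters", {
  g <- fast_grid()
  tab <- make_table(k = 0.05, S = 20, n_min = 4, grid = g)
  obs <- tab$rate_per_100k_py
  w <- 1 / pmax(obs, 1)^2
  obj <- function(k, S) {
    curves <- run_model(mutation_params(u = 1e-7, n_min = 4, S = S),
                        population_params(N0 = 1e5, k = k), grid = g)
    m <- pmax(bin_average_incidence(tab, curves)$model_rate, 0)
    sum(w * (m - obs)^2)
  }
  centre <- obj(0.05, 20)
  for (dk in c(0.8, 1, 1.2)) {
    for (dS in c(0.8, 1, 1.2)) {
      if (dk == 1 && dS == 1) next
      expect_gt(obj(0.05 * dk, 20 * dS), centre)
    }
  }
})

test_that("profiled multiplicity reduces to a rate ratio for a one-bin table", {
  g <- fast_grid()
  unit <- run_model(mutation_params(u = 1e-7, n_min = 5, S = 1),
                    population_params(N0 = 1e5, k = 0.05), grid = g)
  one <- incidence_table(data.frame(age_lo = 40, age_hi = 60,
                                    rate_per_100k_py = 1e-4))
  m <- bin_average_incidence(one, unit)$model_rate
  fit <- quiet_fit(one, n_min = 5, u = 1e-7, N0 = 1e5, grid = g,
                   k_bounds = c(0.0499, 0.0501))
  expect_equal(fit$S_hat, 1e-4 / m, tolerance = 1e-2)
})

test_that("the n_min sweep identifies the generating hit requirement", {
  g <- fast_grid()
  tab <- make_table(k = 0.07, S = 30, n_min = 5, grid = g)
  sweep <- suppressMessages(suppressWarnings(
    sweep_n_min(tab, 2:6, u = 1e-7, N0 = 1e5, grid = g)))
  expect_equal(sweep$n_min[1], 5)   # report is objective-ordered
  obj <- function(n) sweep$objective[sweep$n_min == n]
  expect_gt(obj(2), obj(5))

  empty <- sweep_n_min(tab, integer(0), u = 1e-7, N0 = 1e5, grid = g)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("n_min", "objective", "feasible") %in% names(empty)))
})

test_that("feasibility is monotone in the tolerance", {
  g <- fast_grid()
  tab <- make_table(grid = g)
  loose <- quiet_fit(tab, n_min = 5, u = 1e-7, N0 = 1e5, grid = g,
                     tolerance = 10, peak_window = c(0, 100))
  tight <- quiet_fit(tab, n_min = 5, u = 1e-7, N0 = 1e5, grid = g,
                     tolerance = 1e-30, peak_window = c(0, 100))
  expect_true(loose$feasible)
  expect_false(tight$feasible)
  # the estimates themselves do not depend on the tolerance
  expect_equal(loose$k_hat, tight$k_hat)
})

test_that("degenerate tables are rejected and the identifiability note is emitted", {
  g <- fast_grid()
  zero <- incidence_table(data.frame(age_lo = 0, age_hi = 50,
                                     rate_per_100k_py = 0))
  expect_error(suppressMessages(
    fit_incidence_model(zero, n_min = 5, u = 1e-7, N0 = 1e5, grid = g)),
    "zero")
  tab <- make_table(grid = g)
  expect_message(fit_incidence_model(tab, n_min = 5, u = 1e-7, N0 = 1e5,
                                     grid = g),
                 class = "nscglioma_identifiability")
})

test_that("tidy and glance expose the calibration in broom conventions", {
  g <- fast_grid()
  fit <- quiet_fit(make_table(grid = g), n_min = 5, u = 1e-7, N0 = 1e5,
                   grid = g)
  td <- tidy(fit)
  expect_equal(td$term, c("k", "S"))
  expect_equal(td$estimate, c(fit$k_hat, fit$S_hat))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("objective", "peak_age_hat", "feasible") %in% names(gl)))
  expect_true(fit$S_hat <= factorial(5))

  path <- withr::local_tempfile(fileext = ".csv")
  write_calibration_report(fit, path)
  expect_equal(nrow(readr::read_csv(path, show_col_types = FALSE)), 1)
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_calibration_report(fit, path2, format = "keyvalue")
  expect_true(any(grepl("^n_min5\\.k_hat = ", readLines(path2))))
})
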