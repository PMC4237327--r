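test_that("division rate interpolates the rodent anchors and clamps outside", {
  sched <- division_schedule()
  expect_equal(division_rate(0, sched), 251)
  expect_equal(division_rate(85, sched), 318)
  expect_equal(division_rate(42.5, sched), (251 + 318) / 2)
  expect_equal(division_rate(100, sched), 318)   # clamped past t_end
  expect_equal(division_rate(c(0, 50, 99), division_schedule("constant")),
               rep(251, 3))
  expect_error(division_rate(-1, sched), "non-negative")
  # custom anchors shift the ramp
  late <- division_schedule(t_start = 20, t_end = 85)
  expect_equal(division_rate(10, late), 251)
})

test_that("cumulative divisions follow the closed-form piecewise-linear integral", {
  sched <- division_schedule()
  expect_equal(cumulative_divisions(0, sched), 0)
  expect_equal(cumulative_divisions(2, division_schedule("constant")), 502)
  expect_equal(cumulative_divisions(85, sched), (251 + 318) / 2 * 85)
  # past the ramp the rate is flat at r_aged
  expect_equal(cumulative_divisions(100, sched),
               (251 + 318) / 2 * 85 + 318 * 15)

  # trapezoidal quadrature on a fine grid agrees to 1e-9 relative
  for (sch in list(sched, division_schedule(t_start = 18, t_end = 75))) {
    t <- seq(0, 100, by = 0.001)
    r <- division_rate(t, sch)
    quad <- cumsum(c(0, diff(t) * (head(r, -1) + tail(r, -1)) / 2))
    idx <- which(t %in% c(10, 50, 85, 100))
    expect_equal(cumulative_divisions(t[idx], sch), quad[idx],
                 tolerance = 1e-9)
  }

  # D is strictly increasing and below the linear schedule when rates rise
  t <- seq(0.5, 100, by = 0.5)
  expect_true(all(diff(cumulative_divisions(t, sched)) > 0))
  expect_true(all(cumulative_divisions(t, division_schedule("constant")) <=
                    cumulative_divisions(t, sched)))
})

test_that("NSC pool decays exponentially and memorylessly", {
  pop <- population_params(N0 = 3e5, k = log(2))
  expect_equal(population_size(0, pop), 3e5)
  expect_equal(population_size(1, pop), 1.5e5)   # half-life of one year
  expect_equal(population_size(10, population_params(N0 = 42, k = 0)), 42)
  # N(t2)/N(t1) depends only on the elapsed time
  pop2 <- population_params(N0 = 1e5, k = 0.07)
  t1 <- c(1, 5, 20); t2 <- t1 + 13
  expect_equal(population_size(t2, pop2) / population_size(t1, pop2),
               rep(exp(-0.07 * 13), 3))
  expect_error(population_params(N0 = 0, k = 0.1), "positive")
  expect_error(population_params(N0 = 1e5, k = -1), "k")
})

test_that("48-hour division counts annualise to the published integer rates", {
  expect_equal(annual_rate_from_48h(1.37), 251)
  expect_equal(annual_rate_from_48h(1.74), 318)
  expect_equal(annual_rate_from_48h(0), 0)
  expect_error(annual_rate_from_48h(-0.5), "non-negative")
  # with 182.5 periods the young-adult rate would round down to 250
  expect_equal(annual_rate_from_48h(1.37, derivation_constants(182.5)), 250)
})

test_that("section counts scale to cells per millimetre consistently across section thicknesses", {
  expect_equal(cells_per_mm_from_section(144, 200), 720)
  expect_equal(cells_per_mm_from_section(22, 30), 733 + 1 / 3)
  # the two independent histology protocols agree within 2%
  expect_lt(abs(cells_per_mm_from_section(22, 30) / 720 - 1), 0.02)
  expect_equal(cells_per_mm_from_section(0, 200), 0)
  expect_error(cells_per_mm_from_section(144, 0), "positive")
})
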