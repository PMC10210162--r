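test_that("uts constructor enforces its invariants", {
  expect_s3_class(uts(1:10, 0.1), "uts")
  expect_error(uts(1, 0.1), "2 samples")
  expect_error(uts(c(1, NA), 0.1), "finite")
  expect_error(uts(1:10, -0.1), "dt")
  expect_error(uts(1:10, 0.1, period = 0.35), "integer multiple")
})

test_that("resampling reproduces affine signals exactly and honours the grid", {
  times <- sort(c(0, 0.86, runif(30, 0.01, 0.85)))
  s <- resample_uniform(times, 2 * times, 0.001)
  expect_lt(max(abs(s$values - 2 * time_axis(s))), 1e-12)
  # 20 acquired frames closing the cycle at T = 0.86 s -> 860 samples at 1 ms
  tf <- seq(0, 0.86, length.out = 21)
  vf <- sin(pi * pmin(tf, 0.3) / 0.3)^2
  sf <- resample_uniform(tf, vf, 0.001)
  expect_equal(length(sf$values), 860L)
  expect_equal(sf$period, 0.86)
  # interpolant passes exactly through the input knots
  on_grid <- round(tf[-21] / 0.001) + 1
  expect_lt(max(abs(sf$values[on_grid] - vf[-21])), 1e-12)
})

test_that("shape-preserving interpolation of a nonnegative pulse never undershoots", {
  # piecewise-linear oracle: between nonnegative knots every interpolated
  # value must stay within the knot range, hence nonnegative
  tk <- c(0, 0.05, 0.1, 0.15, 0.2, 0.45, 0.9)
  vk <- c(0, 0.2, 1.0, 0.4, 0, 0, 0)
  s <- resample_uniform(tk, vk, 0.001)
  expect_gte(min(s$values), -1e-14)
  # small overshoot above the peak knot is tolerated (monotonicity is only
  # guaranteed on monotone knot runs); undershoot below zero is not
  expect_lte(max(s$values), max(vk) + 0.01 * diff(range(vk)))
})

test_that("tiling repeats the cycle bit-identically and round-trips by slicing", {
  s <- synth_inlet_flow(synth_waveform_spec(seed = 3L))
  expect_identical(tile_cycles(s, 1)$values, s$values)
  t5 <- tile_cycles(s, 5)
  expect_equal(length(t5$values), 5L * length(s$values))
  for (k in c(1L, 3L, 5L)) {
    expect_identical(slice_cycle(t5, k)$values, s$values)
  }
  expect_error(tile_cycles(t5, 2), "one whole cycle")
})

test_that("cycle periodicity change is zero iff the last two cycles agree", {
  s <- synth_inlet_flow(synth_waveform_spec(seed = 1L))
  expect_identical(cycle_periodicity_change(tile_cycles(s, 2)), 0)
  grown <- uts(c(s$values, 1.01 * s$values), s$dt, s$period)
  expect_equal(cycle_periodicity_change(grown), 0.01, tolerance = 1e-12)
  expect_lt(cycle_periodicity_change(grown), 0.015)  # judged periodic
  expect_error(cycle_periodicity_change(s), "two whole cycles")
})

test_that("transient decay toward a limit cycle gives monotonically shrinking cycle change", {
  s <- synth_inlet_flow(synth_waveform_spec(seed = 2L))
  r <- 0.4  # per-cycle decay factor of the transient
  n <- length(s$values)
  cycles <- lapply(1:8, function(k) s$values * (1 + r^k))
  full <- uts(unlist(cycles), s$dt, s$period)
  changes <- vapply(3:8, function(k) {
    sub <- uts(unlist(cycles[1:k]), s$dt, s$period)
    cycle_periodicity_change(sub)
  }, 0)
  expect_true(all(diff(changes) < 0))
  # closed form: change_k = r^(k-1) (1-r) / (1 + r^(k-1)), so the ratio of
  # consecutive changes approaches r from above
  ratios <- changes[-1] / changes[-length(changes)]
  expected <- r * (1 + r^(3:7 - 1)) / (1 + r^(3:7))
  expect_equal(ratios, expected, tolerance = 1e-9)
})

test_that("plane averaging returns pointwise mean and n-1 standard deviation", {
  s <- synth_inlet_flow(synth_waveform_spec(seed = 4L))
  same <- plane_average(list(s, s, s, s, s))
  expect_identical(same$mean$values, s$values)
  expect_identical(max(abs(same$spread$values)), 0)
  const <- lapply(1:3, function(v) uts(rep(v, 100), 0.01))
  pa <- plane_average(const)
  expect_equal(unique(pa$mean$values), 2)
  expect_equal(unique(pa$spread$values), 1)  # sample convention
  bad <- uts(s$values, s$dt * 2, s$period * 2)
  expect_error(plane_average(list(s, bad)), "share dt")
})

test_that("plane-average mean converges to the clean pulse as noise shrinks", {
  s <- synth_inlet_flow(synth_waveform_spec(seed = 5L))
  set.seed(11)
  err <- vapply(c(1e-5, 1e-6, 1e-7), function(sig) {
    planes <- lapply(1:5, function(i) {
      uts(s$values + stats::rnorm(length(s$values), 0, sig), s$dt, s$period)
    })
    max(abs(plane_average(planes)$mean$values - s$values))
  }, 0)
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 1e-6)
})

test_that("cycle-mean value matches closed forms", {
  expect_equal(mean_value(uts(rep(5e-5, 100), 0.01)), 5e-5)
  t <- (0:999) * 0.001
  sine <- uts(sin(2 * pi * t), 0.001, 0.5)  # two whole cycles
  expect_lt(abs(mean_value(sine)), 1e-12)
  # half-sine pulse of width w: mean = A * (2/pi) * (w/T)
  A <- 4e-4; w <- 0.3; T <- 0.86
  tt <- (0:859) * 0.001
  pulse <- uts(ifelse(tt < w, A * sin(pi * tt / w), 0), 0.001, T)
  expect_equal(mean_value(pulse), A * 2 / pi * w / T, tolerance = 1e-5)
})

test_that("perfusion fractions sum to one and flag negative branches", {
  f <- perfusion_fractions(c(1, 1, 2))
  expect_equal(as.numeric(f), c(0.25, 0.25, 0.5))
  expect_equal(sum(perfusion_fractions(runif(7))), 1, tolerance = 1e-12)
  expect_equal(as.numeric(perfusion_fractions(3)), 1)
  g <- perfusion_fractions(c(2, -0.5, 1))
  expect_equal(sum(g), 1, tolerance = 1e-12)
  expect_identical(attr(g, "negative"), c(FALSE, TRUE, FALSE))
  expect_error(perfusion_fractions(c(1, -2)), "positive")
})

test_that("flow converts to area-mean velocity and back", {
  q <- uts(rep(5e-5, 100), 0.01)
  v <- flow_to_mean_velocity(q, 1e-4)
  expect_equal(unique(v$values), 0.5)
  back <- uts(v$values * 1e-4, v$dt, v$period)
  expect_rel_equal(back$values, q$values, 1e-15)
  expect_error(flow_to_mean_velocity(q, 0), "positive")
})

test_that("waveform CSV writer/reader round-trips dt, period, and values", {
  s <- synth_inlet_flow(synth_waveform_spec(seed = 6L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(s, path, "flow_m3s")
  r <- read_waveform_csv(path)
  expect_equal(r$dt, s$dt)
  expect_equal(r$period, s$period)
  expect_equal(r$values, s$values, tolerance = 1e-10)
})

test_that("periodic time shift is exact on grid multiples and wraps around", {
  s <- synth_inlet_flow(synth_waveform_spec(seed = 7L))
  sh <- time_shift(s, 10 * s$dt)
  expect_equal(sh$values[11:length(s$values)],
               s$values[1:(length(s$values) - 10)], tolerance = 1e-9)
  expect_equal(time_shift(s, 0)$values, s$values, tolerance = 1e-12)
  expect_equal(time_shift(s, s$period)$values, s$values, tolerance = 1e-9)
})
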