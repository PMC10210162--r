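test_that("TAWSS matches closed-form averages", {
  n <- 1000; dt <- 0.001
  const <- wss_series(cbind(rep(2, n), 0, 0), dt)
  expect_equal(tawss(const), 2)
  t <- (0:(n - 1)) * dt
  sine <- wss_series(cbind(sin(2 * pi * t), 0, 0), dt)
  expect_equal(tawss(sine), 2 / pi, tolerance = 1e-4)
  expect_equal(tawss(wss_series(matrix(0, n, 3), dt)), 0)
})

test_that("OSI hits its limits and matches a quadrature oracle", {
  expect_equal(osi(synth_wss_series("unidirectional")), 0)
  expect_equal(osi(synth_wss_series("reversing")), 0.5, tolerance = 1e-6)
  n <- 1000; dt <- 0.001
  t <- (0:(n - 1)) * dt
  # nonnegative single-axis shear is unidirectional regardless of shape
  expect_equal(osi(wss_series(cbind(1 + cos(2 * pi * t), 0, 0), dt)), 0,
               tolerance = 1e-12)
  # DC offset of half the amplitude: compare against direct quadrature
  tau <- 0.5 + cos(2 * pi * t)
  oracle <- 0.5 * (1 - abs(mean(tau)) / mean(abs(tau)))
  expect_equal(osi(wss_series(cbind(tau, 0, 0), dt)), oracle)
  expect_error(osi(wss_series(matrix(0, n, 3), dt)), "undefined")
})

test_that("OSI stays in [0, 0.5] and TAWSS bounds the mean vector for random shear", {
  set.seed(42)
  for (i in 1:25) {
    n <- 500
    comp <- matrix(stats::rnorm(3 * n), n, 3) +
      matrix(rep(stats::rnorm(3), each = n), n, 3)
    s <- wss_series(comp, 0.001, 0.5)
    o <- osi(s)
    expect_gte(o, 0); expect_lte(o, 0.5)
    mean_mag <- sqrt(sum(colMeans(wss_series(comp, 0.001, 0.5)$components)^2))
    expect_gte(tawss(s) + 1e-12, mean_mag)
  }
  # equality iff the direction is constant (OSI exactly 0)
  uni <- synth_wss_series("unidirectional")
  expect_equal(tawss(uni), sqrt(sum(colMeans(uni$components)^2)),
               tolerance = 1e-12)
})

test_that("pressure summaries report systolic/diastolic/pulse/mean in mmHg", {
  n <- 860
  t <- (0:(n - 1)) / n
  p <- uts((100 + 20 * sin(2 * pi * t)) * MMHG_PA, 0.001, 0.86)
  s <- pressure_summary(p)
  expect_equal(unname(s["systolic"]), 120, tolerance = 1e-4)
  expect_equal(unname(s["diastolic"]), 80, tolerance = 1e-4)
  expect_equal(unname(s["pulse"]), 40, tolerance = 1e-3)
  expect_equal(unname(s["mean"]), 100, tolerance = 1e-6)
  const <- pressure_summary(uts(rep(90, 100), 0.01), unit = "mmhg")
  expect_equal(unname(const["pulse"]), 0)
  expect_equal(unname(const["mean"]), 90)
})

test_that("the time-average pressure is not the one-third-rule MAP in general", {
  # the 1/3 rule weights diastole 2:1; a waveform spending only half the
  # cycle in diastole has a higher time-average than the rule predicts
  n <- 1000
  p <- uts(c(rep(120, n / 2), rep(80, n / 2)), 0.001, 1, "pressure_mmhg")
  s <- pressure_summary(p, unit = "mmhg")
  rule <- mean_arterial_pressure(pressure_targets(120, 80))
  expect_equal(unname(s["mean"]), 100)
  expect_gt(abs(s[["mean"]] - rule), 5)
})

test_that("foot detection finds ramp onsets and is translation-equivariant", {
  n <- 1000; dt <- 0.001
  t <- (0:(n - 1)) * dt
  t0 <- 0.3
  ramp <- uts(pmax(0, pmin(t - t0, 0.2)), dt, 1)
  expect_equal(arrival_time_foot(ramp), t0, tolerance = dt)
  base <- time_shift(synth_inlet_flow(synth_waveform_spec(seed = 1L)), 0.2)
  delta <- 0.0137
  expect_equal(arrival_time_foot(time_shift(base, delta)),
               arrival_time_foot(base) + delta, tolerance = dt / 2)
  expect_error(arrival_time_foot(uts(rep(1, 100), 0.01)), "flat")
})

test_that("foot detection tolerates measurement noise", {
  base <- time_shift(synth_inlet_flow(synth_waveform_spec(seed = 2L)), 0.2)
  clean <- arrival_time_foot(base, smooth_window = 9L)
  peak <- max(base$values)
  set.seed(7)
  hits <- 0L
  for (i in 1:200) {
    noisy <- uts(base$values + stats::rnorm(length(base$values), 0, 0.02 * peak),
                 base$dt, base$period)
    foot <- tryCatch(arrival_time_foot(noisy, smooth_window = 9L),
                     error = function(e) NA_real_)
    if (is.finite(foot) && abs(foot - clean) <= 2 * base$dt) hits <- hits + 1L
  }
  expect_gte(hits, 190L)  # >= 95% of seeded trials
})

test_that("PWV is recovered from shifted copies by both arrival estimators", {
  base <- time_shift(synth_inlet_flow(synth_waveform_spec(period = 0.86,
                                                          seed = 3L)), 0.15)
  d12 <- seq(0, 0.3, length.out = 12)
  for (speed in c(7.85, 4.38)) {
    planes <- synth_plane_delays(base, d12, speed)
    expect_equal(pwv_from_planes(planes)$pwv, speed, tolerance = 0.05 / speed)
    expect_equal(pwv_from_planes(planes, method = "xcorr")$pwv, speed,
                 tolerance = 0.05 / speed)
  }
  # two planes, exact grid shift
  two <- synth_plane_delays(base, c(0, 0.2), 0.2 / (20 * base$dt))
  expect_equal(pwv_from_planes(two)$pwv, 10, tolerance = 0.01)
  # reversed ordering is non-physical
  rev_planes <- plane_arrival_set(d12, rev(synth_plane_delays(base, d12,
                                                              7.85)$waveforms))
  expect_error(pwv_from_planes(rev_planes), "not strictly increasing")
})

test_that("jittered arrival delays leave the regression slope unbiased", {
  base <- time_shift(synth_inlet_flow(synth_waveform_spec(seed = 4L)), 0.15)
  d12 <- seq(0, 0.3, length.out = 12)
  speed <- 6
  set.seed(99)
  est <- replicate(100, {
    delays <- d12 / speed + stats::rnorm(12, 0, 5e-4)
    delays[1] <- 0
    planes <- plane_arrival_set(d12, lapply(delays, function(dd) {
      time_shift(base, dd)
    }))
    pwv_from_planes(planes, method = "xcorr")$pwv
  })
  expect_equal(mean(est), speed, tolerance = 0.01)
})

test_that("WSS CSV reader accepts the component layout", {
  n <- 500; dt <- 0.001
  t <- (0:(n - 1)) * dt
  df <- data.frame(time_s = t, tau_x_pa = sin(2 * pi * t / 0.5),
                   tau_y_pa = 0, tau_z_pa = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  s <- read_wss_csv(path)
  expect_equal(osi(s), 0.5, tolerance = 1e-6)
})
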