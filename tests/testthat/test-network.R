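k_diss <- estimation_constants(c_pwv = 4.38)

test_that("segment RLC values follow the closed-form conversions", {
  g <- segment_geometry("seg", 0.1, 1e-4)
  rlc <- segment_rlc_from_geometry(g, estimation_constants(c_pwv = 4.38))
  expect_equal(rlc$r_seg, 8 * pi * 0.004 * 0.1 / 1e-8)
  expect_equal(signif(rlc$r_seg, 4), 1.005e6)
  expect_equal(rlc$l_seg, 1060 * 0.1 / 1e-4)
  expect_equal(signif(rlc$l_seg, 3), 1.06e6)
  # segment compliance coincides with the geometric segment compliance C0
  expect_equal(rlc$c_seg,
               geometric_compliance(estimation_constants(c_pwv = 4.38), g)$C0)
})

test_that("topology validation rejects malformed trees", {
  inlet <- uts(rep(5e-5, 860), 0.001, 0.86)
  seg2 <- data.frame(name = c("A", "B"), parent = c("", "A"),
                     length_m = 0.1, area_m2 = 1e-4)
  wk <- list(B = wk_params(1e7, 1e8, 1e-9))
  expect_s3_class(arterial_network(seg2, wk, inlet, k_diss),
                  "arterial_network")
  noroot <- data.frame(name = c("A", "B"), parent = c("B", "A"),
                       length_m = 0.1, area_m2 = 1e-4)
  expect_error(arterial_network(noroot, wk, inlet, k_diss), "exactly one root")
  orphan <- data.frame(name = c("A", "B"), parent = c("", "Z"),
                       length_m = 0.1, area_m2 = 1e-4)
  expect_error(arterial_network(orphan, wk, inlet, k_diss), "unknown parent")
  expect_error(arterial_network(seg2, list(), inlet, k_diss),
               "terminal Windkessel")
})

test_that("a single segment with terminal Windkessel reaches the resistive steady state", {
  segs <- data.frame(name = "A", parent = "", length_m = 0.1, area_m2 = 1e-4)
  inlet <- uts(rep(5e-5, 860), 0.001, 0.86)
  net <- arterial_network(segs, list(A = wk_params(1e7, 1e8, 1e-9)),
                          inlet, k_diss)
  sol <- simulate_network(net, n_cycles = 60, init_pressure_pa = 0,
                          periodic_tol = 1e-9)
  rlc <- segment_rlc_from_geometry(segment_geometry("A", 0.1, 1e-4), k_diss)
  expect_equal(tail(sol$inlet_pressure$values, 1),
               5e-5 * (rlc$r_seg + 1e7 + 1e8), tolerance = 1e-3)
})

test_that("a symmetric bifurcation splits flow exactly in half", {
  segs <- data.frame(name = c("P", "L", "R"), parent = c("", "P", "P"),
                     length_m = c(0.05, 0.1, 0.1),
                     area_m2 = c(4e-4, 1e-4, 1e-4))
  wk <- wk_params(5e7, 1e9, 5e-10)
  inlet <- synth_inlet_flow(synth_waveform_spec(seed = 1L))
  net <- arterial_network(segs, list(L = wk, R = wk), inlet, k_diss)
  sol <- simulate_network(net)
  expect_rel_equal(sol$flow[["L"]]$values, sol$flow[["R"]]$values, 1e-9)
})

test_that("paper-scale trees reach periodicity within 20 cycles and conserve mass", {
  for (case in c("dissected", "healthy")) {
    geo <- aorta_geometry(case)
    inlet <- synth_inlet_flow(synth_waveform_spec(seed = 2L))
    est <- estimate_windkessel(geo, k_diss, pressure_targets(189, 101),
                               mean_value(inlet))
    wk <- stats::setNames(lapply(seq_len(nrow(est)), function(i) {
      wk_params(est$Z[i], est$R[i], est$C[i])
    }), est$branch)
    net <- arterial_network(aorta_network_segments(case), wk, inlet, k_diss)
    sol <- simulate_network(net, n_cycles = 20L)
    expect_true(sol$periodic)
    expect_lte(sol$cycles_run, 20L)
    # at a converged limit cycle the compliances store no net volume
    tight <- simulate_network(net, n_cycles = 30L, periodic_tol = 1e-6)
    term_means <- vapply(geo$branch,
                         function(b) mean_value(tight$flow[[b]]), 0)
    expect_equal(sum(term_means), mean_value(inlet),
                 tolerance = 5e-3)
  }
})

test_that("discrete mass balance holds at every junction at every step", {
  geo <- aorta_geometry("healthy")
  inlet <- synth_inlet_flow(synth_waveform_spec(seed = 3L))
  est <- estimate_windkessel(geo, k_diss, pressure_targets(120, 80),
                             mean_value(inlet))
  wk <- stats::setNames(lapply(seq_len(nrow(est)), function(i) {
    wk_params(est$Z[i], est$R[i], est$C[i])
  }), est$branch)
  net <- arterial_network(aorta_network_segments("healthy"), wk, inlet, k_diss)
  sol <- simulate_network(net, n_cycles = 5L, periodic_tol = 0,
                          init_pressure_pa = 80 * MMHG_PA)
  nm <- net$name
  N <- ncol(sol$p_hist); dt <- sol$dt
  u <- rep(inlet$values, length.out = N)
  peak <- max(abs(inlet$values))
  for (i in seq_along(nm)) {
    c_i <- net$rlc[[i]]$c_seg
    inflow <- if (i == net$root) u else sol$q_hist[nm[i], ]
    kids <- which(net$parent_idx == i)
    out <- rep(0, N)
    for (kk in kids) out <- out + sol$q_hist[nm[kk], ]
    if (i %in% net$leaves) {
      wkp <- net$terminals[[nm[i]]]
      out <- out + (sol$p_hist[i, ] - sol$pc_hist[nm[i], ]) / wkp$Z
    }
    dp <- c(sol$p_hist[i, 1] - 80 * MMHG_PA, diff(sol$p_hist[i, ]))
    resid <- c_i * dp / dt - (inflow - out)
    expect_lt(max(abs(resid)) / peak, 1e-9)
  }
})

test_that("the zero-compliance, zero-inertance limit matches the resistor-tree solution", {
  segs <- data.frame(name = c("P", "L", "R"), parent = c("", "P", "P"),
                     length_m = c(0.05, 0.1, 0.12),
                     area_m2 = c(4e-4, 1e-4, 1.5e-4),
                     r_seg = c(2e6, 5e6, 3e6), l_seg = 0, c_seg = 0)
  wkL <- wk_params(1e7, 2e8, 1e-9)
  wkR <- wk_params(2e7, 1e8, 1e-9)
  Q <- 5e-5
  inlet <- uts(rep(Q, 860), 0.001, 0.86)
  net <- arterial_network(segs, list(L = wkL, R = wkR), inlet,
                          estimation_constants(c_pwv = 4.38))
  sol <- simulate_network(net, n_cycles = 60, periodic_tol = 1e-10)
  # independent oracle: two-branch resistive divider at the junction
  RL <- 5e6 + 1e7 + 2e8
  RR <- 3e6 + 2e7 + 1e8
  pP <- Q * (RL * RR) / (RL + RR)
  qL <- pP / RL
  expect_equal(tail(sol$pressure[["P"]]$values, 1), pP, tolerance = 1e-6)
  expect_equal(tail(sol$flow[["L"]]$values, 1), qL, tolerance = 1e-6)
  expect_equal(tail(sol$inlet_pressure$values, 1), pP + 2e6 * Q,
               tolerance = 1e-6)
})

test_that("network solutions serialise to per-branch waveform CSVs", {
  segs <- data.frame(name = "A", parent = "", length_m = 0.1, area_m2 = 1e-4)
  inlet <- uts(rep(5e-5, 860), 0.001, 0.86)
  net <- arterial_network(segs, list(A = wk_params(1e7, 1e8, 1e-9)),
                          inlet, k_diss)
  sol <- simulate_network(net, n_cycles = 5)
  dir <- withr::local_tempdir()
  write_network_solution(sol, dir)
  back <- read_waveform_csv(file.path(dir, "A_pressure.csv"))
  expect_equal(back$values, sol$pressure[["A"]]$values, tolerance = 1e-9)
})
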