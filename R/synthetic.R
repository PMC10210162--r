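#' Specification of a synthetic cardiac flow waveform
#'
#' Parametric family emulating aortic inlet and branch flow waveforms: a
#' half-sine systolic pulse of width `systolic_fraction * period`, an
#' optional brief negative post-systolic lobe (end-systolic reversal) sized
#' by `regurgitant_fraction`, a constant diastolic baseline, and optional
#' small seeded harmonic perturbations (zero-mean, so the cycle mean is
#' unchanged) that make per-branch waveforms distinct.
#'
#' @param period cardiac-cycle duration, s (default 0.86).
#' @param peak_flow systolic peak flow, m^3/s (default 4e-4, aortic scale;
#'   branch waveforms use 0.05-0.8 x 1e-4).
#' @param systolic_fraction fraction of the cycle occupied by the systolic
#'   pulse, in (0, 1) (default 0.35).
#' @param diastolic_offset constant baseline flow, m^3/s (default 0).
#' @param regurgitant_fraction depth of the reversal lobe relative to the
#'   peak, in [0, 1) (default 0).
#' @param harmonics number of harmonic components; 1 means the pure pulse
#'   shape, larger values add seeded low-amplitude harmonics (default 1).
#' @param seed integer seed controlling the harmonic perturbations.
#' @export
synth_waveform_spec <- function(period = 0.86, peak_flow = 4e-4,
                                systolic_fraction = 0.35,
                                diastolic_offset = 0,
                                regurgitant_fraction = 0,
                                harmonics = 1L, seed = 1L) {
  stopifnot(period > 0, peak_flow > 0,
            systolic_fraction > 0, systolic_fraction < 1, harmonics >= 1)
  if (regurgitant_fraction >= 1 || regurgitant_fraction < 0) {
    stop("regurgitant_fraction must lie in [0, 1)")
  }
  structure(list(period = period, peak_flow = peak_flow,
                 systolic_fraction = systolic_fraction,
                 diastolic_offset = diastolic_offset,
                 regurgitant_fraction = regurgitant_fraction,
                 harmonics = as.integer(harmonics), seed = as.integer(seed)),
            class = "synth_waveform_spec")
}

#' Generate a synthetic cardiac-cycle flow waveform
#'
#' Deterministic given the spec (including its seed). With no reversal
#' lobe, no offset and `harmonics = 1` the waveform is nonnegative with
#' cycle mean `peak_flow * (2/pi) * systolic_fraction` (the half-sine
#' integral).
#'
#' @param spec a [synth_waveform_spec].
#' @param dt sample interval, s (default 0.001).
#' @return single-cycle flow [uts].
#' @export
synth_inlet_flow <- function(spec, dt = 0.001) {
  stopifnot(inherits(spec, "synth_waveform_spec"))
  n <- round(spec$period / dt)
  t <- (0:(n - 1)) * dt
  w <- spec$systolic_fraction * spec$period
  v <- ifelse(t < w, spec$peak_flow * sin(pi * t / w), 0)
  if (spec$regurgitant_fraction > 0) {
    wr <- 0.5 * w  # reversal lobe spans half the systolic width
    s <- t - w
    lobe <- ifelse(s >= 0 & s < wr,
                   -spec$regurgitant_fraction * spec$peak_flow * sin(pi * s / wr),
                   0)
    v <- v + lobe
  }
  v <- v + spec$diastolic_offset
  if (spec$harmonics > 1L) {
    rng <- local_rng(spec$seed)
    for (k in 2:spec$harmonics) {
      amp <- 0.02 * spec$peak_flow * rng()
      phase <- 2 * pi * rng()
      v <- v + amp * sin(2 * pi * k * t / spec$period + phase)
    }
  }
  uts(v, dt, n * dt, "flow_m3s")
}

# small deterministic uniform(0,1) stream independent of the global RNG state
local_rng <- function(seed) {
  state <- as.double(seed %% 2147483647)
  if (state == 0) state <- 1
  function() {
    state <<- (state * 16807) %% 2147483647
    state / 2147483647
  }
}

#' Ground-truth Windkessel pressure/flow pair for recovery experiments
#'
#' Builds a periodic branch pressure waveform by driving the truth
#' Windkessel with a synthetic flow pulse (pressure-out causality to a
#' periodic state), then computes the exactly corresponding periodic
#' Windkessel flow cycle under the same truth parameters. Feeding the pair
#' into [calibrate_branch] with a perturbed start is the standard
#' parameter-recovery oracle.
#'
#' @param truth a [wk_params], the generating parameters.
#' @param pressure_source optional pressure [uts]; when `NULL` it is
#'   generated from `flow_spec`.
#' @param flow_spec a [synth_waveform_spec] for the driving flow.
#' @param dt sample interval, s.
#' @param n_cycles cycles used to reach periodicity (default 20).
#' @param p_init initial pressure, Pa (default 101 mmHg).
#' @return list with `pressure` (one periodic cycle, [uts]), `flow` (the
#'   matching periodic Windkessel flow cycle), and `truth`.
#' @export
synth_wk_truth_pair <- function(truth, pressure_source = NULL,
                                flow_spec = synth_waveform_spec(),
                                dt = 0.001, n_cycles = 20L,
                                p_init = 101 * MMHG_PA) {
  stopifnot(inherits(truth, "wk_params"))
  if (is.null(pressure_source)) {
    q_drive <- synth_inlet_flow(flow_spec, dt)
    p_full <- simulate_pressure_from_flow(truth, q_drive, p_init, n_cycles)
    pressure_source <- slice_cycle(p_full)
  }
  flow <- periodic_wk_flow(truth, pressure_source,
                           calibration_config(max_cycles_per_eval = n_cycles))
  list(pressure = pressure_source, flow = flow, truth = truth)
}

#' Multi-plane waveform set with a known wave speed
#'
#' Shifts a base waveform by `distance / wave_speed` per plane (periodic
#' interpolated shift), producing the synthetic input with which the PWV
#' estimator can be validated.
#'
#' @param base single-cycle [uts].
#' @param distances plane distances from the first plane, m (increasing,
#'   first typically 0).
#' @param wave_speed propagation speed, m/s (> 0).
#' @return a [plane_arrival_set].
#' @export
synth_plane_delays <- function(base, distances, wave_speed) {
  if (!is.finite(wave_speed) || wave_speed <= 0) stop("wave_speed must be positive")
  waves <- lapply(distances, function(d) time_shift(base, d / wave_speed))
  plane_arrival_set(distances, waves)
}

#' Synthetic wall shear stress vector series
#'
#' Three canonical shear regimes for exercising TAWSS/OSI:
#' `unidirectional` (fixed direction, nonnegative half-sine magnitude, so
#' OSI = 0), `reversing` (zero-mean single-axis sinusoid, OSI = 0.5), and
#' `mixed` (a seeded random direction walk with a prescribed ratio of mean
#' vector magnitude to TAWSS via `mean_ratio`, so OSI = 0.5 (1 -
#' mean_ratio) for the single-axis construction used).
#'
#' @param mode one of `"unidirectional"`, `"reversing"`, `"mixed"`.
#' @param amplitude shear amplitude, Pa (> 0).
#' @param period cycle duration, s.
#' @param dt sample interval, s.
#' @param seed integer seed (used by `mixed`).
#' @param mean_ratio for `mixed`: target |mean| / TAWSS in [0, 1]
#'   (default 0.5).
#' @return a [wss_series].
#' @export
synth_wss_series <- function(mode = c("unidirectional", "reversing", "mixed"),
                             amplitude = 1, period = 1, dt = 0.001,
                             seed = 1L, mean_ratio = 0.5) {
  mode <- match.arg(mode)
  stopifnot(amplitude > 0)
  n <- round(period / dt)
  t <- (0:(n - 1)) * dt
  comp <- matrix(0, n, 3)
  if (mode == "unidirectional") {
    mag <- amplitude * abs(sin(pi * t / period))
    dir <- c(1, 2, 2) / 3  # arbitrary fixed unit direction
    comp <- outer(mag, dir)
  } else if (mode == "reversing") {
    comp[, 1] <- amplitude * sin(2 * pi * t / period)
  } else {
    # single-axis magnitude that spends (1+mean_ratio)/2 of the cycle
    # positive: |mean|/mean|.| = mean_ratio exactly for a square profile
    rng <- local_rng(seed)
    axis <- c(rng(), rng(), rng())
    axis <- axis / sqrt(sum(axis^2))
    sgn <- ifelse(t < (1 + mean_ratio) / 2 * period, 1, -1)
    comp <- outer(amplitude * sgn, axis)
  }
  wss_series(comp, dt, period)
}

#' Bundled 1D branch geometry of a dissected and a healthy thoracic aorta
#'
#' Centerline lengths and mean cross-sectional areas of the terminal
#' branches of two reference thoracic aortae (a type-B aortic dissection
#' patient and a healthy volunteer), as reduced from 3D reconstructions to
#' 1D segments: right subclavian (RSA), right and left common carotid
#' (RCCA, LCCA), left subclavian (LSA), and the descending aorta — split
#' into true and false lumen (DAoTL, DAoFL) for the dissection, a single
#' channel for the healthy aorta.
#'
#' @param case `"dissected"` (6 branches) or `"healthy"` (5 branches).
#' @return data.frame with columns `branch`, `length_m`, `area_m2`.
#' @export
aorta_geometry <- function(case = c("dissected", "healthy")) {
  case <- match.arg(case)
  if (case == "dissected") {
    data.frame(
      branch = c("RSA", "RCCA", "LCCA", "LSA", "DAoTL", "DAoFL"),
      length_m = c(1.10, 0.46, 0.80, 1.48, 1.87, 1.85) * 1e-1,
      area_m2 = c(4.04, 1.34, 3.35, 3.05, 12.50, 25.70) * 1e-5)
  } else {
    data.frame(
      branch = c("RSA", "RCCA", "LCCA", "LSA", "DAoTL"),
      length_m = c(0.25, 0.34, 0.66, 1.35, 2.61) * 1e-1,
      area_m2 = c(7.03, 3.91, 3.46, 6.75, 43.50) * 1e-5)
  }
}

#' Reference-scale arterial tree fixtures
#'
#' Builds an [arterial_network] segment table for the two reference cases:
#' the dissected aorta is partitioned into 22 segments (ascending aorta and
#' arch trunk, separate true- and false-lumen descending channels, and the
#' four supra-aortic branches), the healthy aorta into 9 (5 trunk segments
#' plus 4 branches). Trunk dimensions are plausible adult thoracic-aorta
#' values; terminal branch segments carry the [aorta_geometry] dimensions.
#'
#' @param case `"dissected"` or `"healthy"`.
#' @return data.frame of segments (`name`, `parent`, `length_m`, `area_m2`)
#'   whose leaves are the [aorta_geometry] branch names.
#' @export
aorta_network_segments <- function(case = c("dissected", "healthy")) {
  case <- match.arg(case)
  geo <- aorta_geometry(case)
  row <- function(name, parent, l, a) {
    data.frame(name = name, parent = parent, length_m = l, area_m2 = a)
  }
  gbranch <- function(name, parent) {
    g <- geo[geo$branch == name, ]
    row(name, parent, g$length_m, g$area_m2)
  }
  if (case == "healthy") {
    segs <- rbind(
      row("AscAo", "", 0.07, 6.5e-4),
      row("Arch1", "AscAo", 0.025, 5.8e-4),
      row("Arch2", "Arch1", 0.02, 5.4e-4),
      row("Arch3", "Arch2", 0.02, 5.0e-4),
      gbranch("RSA", "AscAo"),   # brachiocephalic territory
      gbranch("RCCA", "Arch1"),
      gbranch("LCCA", "Arch2"),
      gbranch("LSA", "Arch3"),
      gbranch("DAoTL", "Arch3"))
    stopifnot(nrow(segs) == 9L)
  } else {
    # trunk: 3 ascending + 4 arch segments; descending TL and FL each split
    # into chains so wave travel is resolved; 4 supra-aortic branches
    tl <- geo[geo$branch == "DAoTL", ]
    fl <- geo[geo$branch == "DAoFL", ]
    tl_chain <- do.call(rbind, lapply(1:4, function(i) {
      row(paste0("DAoTLs", i), if (i == 1) "Arch4" else paste0("DAoTLs", i - 1),
          tl$length_m / 5, tl$area_m2)
    }))
    fl_chain <- do.call(rbind, lapply(1:4, function(i) {
      row(paste0("DAoFLs", i), if (i == 1) "Arch4" else paste0("DAoFLs", i - 1),
          fl$length_m / 5, fl$area_m2)
    }))
    segs <- rbind(
      row("AscAo1", "", 0.0225, 6.2e-4),
      row("AscAo2", "AscAo1", 0.0225, 6.0e-4),
      row("AscAo3", "AscAo2", 0.0225, 5.9e-4),
      row("AscAo4", "AscAo3", 0.0225, 5.8e-4),
      row("Arch1", "AscAo4", 0.02, 5.2e-4),
      row("Arch2", "Arch1", 0.02, 4.8e-4),
      row("Arch3", "Arch2", 0.02, 4.4e-4),
      row("Arch4", "Arch3", 0.02, 4.0e-4),
      gbranch("RSA", "AscAo4"),
      gbranch("RCCA", "Arch1"),
      gbranch("LCCA", "Arch2"),
      gbranch("LSA", "Arch3"),
      tl_chain,
      row("DAoTL", "DAoTLs4", tl$length_m / 5, tl$area_m2),
      fl_chain,
      row("DAoFL", "DAoFLs4", fl$length_m / 5, fl$area_m2))
    stopifnot(nrow(segs) == 22L)
  }
  segs
}
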