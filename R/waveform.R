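#' Uniformly sampled physical time series
#'
#' The canonical signal container used throughout the package: an evenly
#' sampled physical signal (flow in m^3/s, pressure in Pa, velocity in m/s,
#' or shear magnitude in Pa) together with its sample interval `dt` and the
#' cardiac-cycle duration `period`. Samples are stored for `t = 0, dt, ...`
#' starting at the cycle origin (the ECG R-wave for in vivo data); the sample
#' at `t = period` is *not* stored — it duplicates the cycle start for a
#' periodic signal.
#'
#' @param values numeric vector of samples (>= 2, all finite).
#' @param dt sample interval in seconds (> 0).
#' @param period cardiac-cycle duration in seconds; must be an integer
#'   multiple of `dt` (within 1e-9 s). Defaults to the grid span
#'   `length(values) * dt`, i.e. a single cycle.
#' @param label free-text tag describing the signal kind (e.g. `"flow_m3s"`).
#' @return An object of class `uts`.
#' @export
uts <- function(values, dt, period = length(values) * dt, label = "signal") {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("a time series needs at least 2 samples")
  if (!all(is.finite(values))) stop("all values must be finite")
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  if (!is.finite(period) || period <= 0) stop("period must be positive")
  k <- period / dt
  if (abs(k - round(k)) * dt > 1e-9) {
    stop("period must be an integer multiple of dt (within 1e-9 s)")
  }
  structure(list(values = values, dt = dt, period = period, label = label),
            class = "uts")
}

#' @export
print.uts <- function(x, ...) {
  cat(sprintf("<uts '%s'> %d samples, dt = %g s, period = %g s (%.3g cycles)\n",
              x$label, length(x$values), x$dt, x$period, n_cycles(x)))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.uts <- function(x) length(x$values)

#' Samples per cardiac cycle
#' @param series a [uts] object.
#' @return integer count of samples in one cycle.
#' @export
samples_per_cycle <- function(series) as.integer(round(series$period / series$dt))

#' Number of (possibly fractional) cycles stored
#' @param series a [uts] object.
#' @export
n_cycles <- function(series) length(series$values) / samples_per_cycle(series)

#' Time axis of a series
#' @param series a [uts] object.
#' @return numeric vector of sample times, starting at 0.
#' @export
time_axis <- function(series) (seq_along(series$values) - 1) * series$dt

#' Extract one whole cycle from a multi-cycle series
#'
#' @param series a [uts] object holding whole cycles.
#' @param k cycle index (1-based); defaults to the last cycle.
#' @return a single-cycle [uts].
#' @export
slice_cycle <- function(series, k = NULL) {
  spc <- samples_per_cycle(series)
  nc <- length(series$values) %/% spc
  if (nc < 1L) stop("series holds less than one whole cycle")
  if (is.null(k)) k <- nc
  if (k < 1L || k > nc) stop("cycle index out of range")
  idx <- ((k - 1L) * spc + 1L):(k * spc)
  uts(series$values[idx], series$dt, series$period, series$label)
}

#' Resample an (irregular) time/value series onto a uniform grid
#'
#' Interpolates measured samples onto a uniform grid with step `target_dt`
#' using monotone (shape-preserving) piecewise-cubic Hermite interpolation,
#' so a nonnegative flow pulse never develops negative overshoot between
#' nonnegative knots. The interpolant passes exactly through the input
#' points, and reproduces affine signals exactly. The output grid spans
#' `[times[1], times[n])`: the closing sample is dropped because it
#' duplicates the cycle start of a periodic signal, and the grid span
#' becomes the cycle `period`.
#'
#' @param times sample times in seconds, strictly increasing, >= 2 points.
#' @param values physical samples at `times`.
#' @param target_dt uniform step in seconds (typically 0.001 s).
#' @param label signal tag for the result.
#' @return a [uts] covering one cycle of duration `times[n] - times[1]`.
#' @export
resample_uniform <- function(times, values, target_dt, label = "signal") {
  if (length(times) < 2L || length(times) != length(values)) {
    stop("times and values must have equal length >= 2")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.finite(target_dt) || target_dt <= 0) stop("target_dt must be positive")
  span <- times[length(times)] - times[1]
  n <- round(span / target_dt)
  if (n < 2) stop("target_dt is too large for the input span")
  f <- stats::splinefun(times, values, method = "monoH.FC")
  grid <- times[1] + (0:(n - 1)) * target_dt
  uts(f(grid), dt = target_dt, period = n * target_dt, label = label)
}

#' Repeat a single-cycle waveform over several cardiac cycles
#'
#' @param series a [uts] holding exactly one whole cycle.
#' @param n_cycles number of cycles in the output (>= 1).
#' @return a [uts] of `n_cycles` bit-identical copies of the input cycle.
#' @export
tile_cycles <- function(series, n_cycles) {
  stopifnot(inherits(series, "uts"))
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  spc <- samples_per_cycle(series)
  if (length(series$values) != spc) {
    stop("tile_cycles expects a series holding exactly one whole cycle")
  }
  uts(rep(series$values, n_cycles), series$dt, series$period, series$label)
}

#' Relative change between the last two cardiac cycles
#'
#' Periodicity diagnostic: the maximum over samples of the absolute
#' difference between the final cycle and the one before it, normalised by
#' the maximum absolute value of the previous cycle. Simulations are judged
#' time-periodic when this falls below a tolerance (default 1.5%).
#'
#' @param series a [uts] holding at least two whole cycles.
#' @return dimensionless relative change (0 iff the two cycles are identical).
#' @export
cycle_periodicity_change <- function(series) {
  spc <- samples_per_cycle(series)
  nc <- length(series$values) %/% spc
  if (nc < 2L) stop("periodicity needs at least two whole cycles")
  last <- slice_cycle(series, nc)$values
  prev <- slice_cycle(series, nc - 1L)$values
  ref <- max(abs(prev))
  if (ref == 0) return(if (max(abs(last)) == 0) 0 else Inf)
  max(abs(last - prev)) / ref
}

#' Average waveforms measured at parallel planes of one branch
#'
#' Branch flow waveforms are typically measured at several analysis planes
#' placed perpendicular to the vessel axis (five planes in routine 4D
#' Flow-MRI processing) and averaged pointwise.
#'
#' @param group a list of [uts] objects sharing `dt` and `period`.
#' @return list with components `mean` and `spread` (pointwise sample
#'   standard deviation, n-1 convention), both [uts].
#' @export
plane_average <- function(group) {
  if (length(group) < 1L) stop("plane group must be non-empty")
  ref <- group[[1]]
  for (s in group) {
    stopifnot(inherits(s, "uts"))
    if (abs(s$dt - ref$dt) > 1e-12 || abs(s$period - ref$period) > 1e-12 ||
        length(s$values) != length(ref$values)) {
      stop("all planes must share dt, period, and length")
    }
  }
  m <- do.call(cbind, lapply(group, function(s) s$values))
  mu <- rowMeans(m)
  sd_ <- if (ncol(m) > 1L) apply(m, 1, stats::sd) else rep(0, nrow(m))
  list(mean = uts(mu, ref$dt, ref$period, ref$label),
       spread = uts(sd_, ref$dt, ref$period, paste0(ref$label, "_sd")))
}

#' Cycle-averaged value of a periodic signal
#'
#' Time average over whole cardiac cycles by the trapezoidal rule with
#' periodic closure (the sample at `t = period` equals the cycle start), for
#' which the trapezoidal average reduces to the arithmetic mean of the
#' stored samples.
#'
#' @param series a [uts] holding at least one whole cycle.
#' @return scalar time-average in the units of the series.
#' @export
mean_value <- function(series) {
  spc <- samples_per_cycle(series)
  nc <- length(series$values) %/% spc
  if (nc < 1L) stop("mean_value needs at least one whole cycle")
  mean(series$values[1:(nc * spc)])
}

#' Perfusion fractions from per-branch mean flows
#'
#' Splits the net (cycle-mean) inlet flow across outlet branches. A negative
#' branch mean (net retrograde flow) is permitted and yields a negative
#' fraction, flagged in the result; the total must be positive.
#'
#' @param branch_means named or unnamed numeric vector of cycle-mean branch
#'   flows, m^3/s.
#' @return numeric vector of fractions summing to 1, with attribute
#'   `negative` marking branches with negative means.
#' @export
perfusion_fractions <- function(branch_means) {
  branch_means <- unlist(branch_means)
  if (!all(is.finite(branch_means))) stop("branch means must be finite")
  total <- sum(branch_means)
  if (total <= 0) stop("total mean flow must be positive")
  f <- branch_means / total
  attr(f, "negative") <- branch_means < 0
  f
}

#' Convert a flow waveform to area-mean velocity
#'
#' @param series a flow [uts] in m^3/s.
#' @param area vessel cross-sectional area in m^2 (> 0).
#' @return velocity [uts] in m/s.
#' @export
flow_to_mean_velocity <- function(series, area) {
  if (!is.finite(area) || area <= 0) stop("area must be positive")
  uts(series$values / area, series$dt, series$period, "velocity_ms")
}

#' Read a waveform CSV
#'
#' Format: optional comment lines starting with `#` (the writer records
#' `# dt_s=` and `# period_s=`), then a header `time_s,<quantity>_<unit>`
#' and one sample per row.
#'
#' @param path file path.
#' @return a [uts]; `dt`/`period` come from the comments when present,
#'   otherwise from the time column (period = grid span + dt).
#' @export
read_waveform_csv <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "="), meta, value = TRUE)
    if (length(hit)) as.numeric(sub(paste0("^#\\s*", key, "="), "", hit[1])) else NA_real_
  }
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  if (ncol(df) < 2L) stop("waveform CSV needs time and value columns")
  dt <- get_meta("dt_s")
  period <- get_meta("period_s")
  if (is.na(dt)) dt <- stats::median(diff(df[[1]]))
  if (is.na(period)) period <- nrow(df) * dt
  uts(df[[2]], dt = dt, period = period, label = names(df)[2])
}

#' Write a waveform CSV
#'
#' @param series a [uts].
#' @param path output path.
#' @param quantity value-column name, `<quantity>_<unit>` (defaults to the
#'   series label).
#' @export
write_waveform_csv <- function(series, path, quantity = series$label) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt_s=%.12g", series$dt), con)
  writeLines(sprintf("# period_s=%.12g", series$period), con)
  writeLines(paste0("time_s,", quantity), con)
  utils::write.table(
    data.frame(t = sprintf("%.12g", time_axis(series)),
               v = sprintf("%.12g", series$values)),
    con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a multi-plane waveform CSV (wide layout)
#'
#' Wide layout `time_s,plane1,...,planeK`, one column per analysis plane.
#'
#' @param path file path.
#' @return list of [uts], one per plane column.
#' @export
read_plane_group_csv <- function(path) {
  lines <- readLines(path)
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  dt <- stats::median(diff(df[[1]]))
  lapply(seq_len(ncol(df) - 1L), function(i) {
    uts(df[[i + 1L]], dt = dt, period = nrow(df) * dt, label = names(df)[i + 1L])
  })
}

#' Periodic time shift of a single-cycle waveform
#'
#' Shifts a periodic waveform by `delay` seconds (positive delay moves
#' features later in the cycle), evaluating the shifted signal by periodic
#' spline interpolation. Used to construct multi-plane waveform sets with a
#' known wave speed.
#'
#' @param series a single-cycle [uts].
#' @param delay shift in seconds (any real; wrapped modulo the period).
#' @return shifted [uts] on the same grid.
#' @export
time_shift <- function(series, delay) {
  spc <- samples_per_cycle(series)
  if (length(series$values) != spc) stop("time_shift expects one whole cycle")
  t <- time_axis(series)
  f <- stats::splinefun(c(t, series$period), c(series$values, series$values[1]),
                        method = "periodic")
  uts(f((t - delay) %% series$period), series$dt, series$period, series$label)
}
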