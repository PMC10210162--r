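#' Wall shear stress vector time series
#'
#' The instantaneous wall shear stress vector at one surface location,
#' sampled uniformly over at least one cardiac cycle.
#'
#' @param components numeric matrix (n x 3) of shear components, Pa.
#' @param dt sample interval, s.
#' @param period cardiac-cycle duration, s.
#' @return object of class `wss_series`.
#' @export
wss_series <- function(components, dt, period = nrow(components) * dt) {
  components <- as.matrix(components)
  if (ncol(components) != 3L) stop("shear components must be an n x 3 matrix")
  if (!all(is.finite(components))) stop("shear components must be finite")
  if (dt <= 0 || period <= 0) stop("dt and period must be positive")
  spc <- round(period / dt)
  if (nrow(components) < spc) stop("series must cover at least one whole cycle")
  structure(list(components = components, dt = dt, period = period),
            class = "wss_series")
}

# first whole cycle of the component matrix
wss_cycle <- function(series) {
  spc <- as.integer(round(series$period / series$dt))
  series$components[seq_len(spc), , drop = FALSE]
}

# periodic trapezoidal cycle-average of sampled values (= arithmetic mean)
cycle_average <- function(v) mean(v)

#' Time-averaged wall shear stress (TAWSS)
#'
#' Cycle average of the shear vector magnitude,
#' `TAWSS = (1/T) integral_0^T |tau(t)| dt`, by the trapezoidal rule with
#' periodic closure.
#'
#' @param series a [wss_series].
#' @return TAWSS in Pa.
#' @export
tawss <- function(series) {
  m <- wss_cycle(series)
  cycle_average(sqrt(rowSums(m^2)))
}

#' Oscillatory shear index (OSI)
#'
#' `OSI = 0.5 * (1 - |integral tau dt| / integral |tau| dt)` over one
#' cardiac cycle: 0 for purely unidirectional shear, 0.5 for fully
#' reversing shear with zero mean direction. Identically zero shear makes
#' the ratio 0/0 and is an error rather than a value.
#'
#' @param series a [wss_series].
#' @return dimensionless OSI in [0, 0.5] (clipped only against round-off).
#' @export
osi <- function(series) {
  m <- wss_cycle(series)
  num <- sqrt(sum(colMeans(m)^2))        # |cycle-average vector|
  den <- cycle_average(sqrt(rowSums(m^2)))  # cycle-average magnitude
  if (den == 0) stop("OSI is undefined for identically zero shear (0/0)")
  val <- 0.5 * (1 - num / den)
  min(max(val, 0), 0.5)
}

#' Systolic/diastolic/pulse/mean pressure summary of one cardiac cycle
#'
#' Operates on the final whole cycle of the series and reports in mmHg.
#'
#' @param series a pressure [uts].
#' @param unit unit of the stored samples: `"pa"` (default) or `"mmhg"`.
#' @return named numeric vector `systolic`, `diastolic`, `pulse`, `mean`
#'   in mmHg (mean is the trapezoidal time-average).
#' @export
pressure_summary <- function(series, unit = c("pa", "mmhg")) {
  unit <- match.arg(unit)
  cyc <- slice_cycle(series)$values
  if (unit == "pa") cyc <- cyc / MMHG_PA
  c(systolic = max(cyc), diastolic = min(cyc),
    pulse = max(cyc) - min(cyc), mean = mean(cyc))
}

#' Arrival time of the systolic wavefront by intersecting tangents
#'
#' The "foot" of the waveform: the intersection of the pre-upstroke
#' baseline (the minimum level before the systolic peak) with the upstroke
#' tangent. The tangent is fitted by least squares over the rising edge
#' between 20% and 80% of the pulse height, which gives sub-sample
#' resolution and is robust to measurement noise; this regression variant
#' of the foot-to-foot technique is standard in multi-plane PWV analysis.
#'
#' @param series a single-cycle (or longer; the first cycle is used) [uts]
#'   with a detectable systolic upstroke inside the cycle.
#' @param smooth_window odd moving-average window (samples) applied
#'   circularly before analysis; 1 (default) means no smoothing.
#' @return foot arrival time in seconds from the cycle start.
#' @export
arrival_time_foot <- function(series, smooth_window = 1L) {
  v <- slice_cycle(series, 1L)$values
  dt <- series$dt
  if (smooth_window > 1L) {
    w <- as.integer(smooth_window)
    if (w %% 2L == 0L) w <- w + 1L
    kern <- rep(1 / w, w)
    h <- (w - 1L) %/% 2L
    v <- as.numeric(stats::filter(c(utils::tail(v, h), v, utils::head(v, h)),
                                  kern, sides = 2))[(h + 1L):(h + length(v))]
  }
  ipk <- which.max(v)
  pre <- v[seq_len(ipk)]
  base0 <- min(pre)
  height <- v[ipk] - base0
  if (height <= 0) {
    stop("no upstroke detected: waveform is flat or non-increasing")
  }
  # robust baseline: median of the pre-peak samples in the lowest 20% band
  # (a plain minimum is biased low under measurement noise, a mean is
  # dragged up by the start of the upstroke)
  baseline <- stats::median(pre[pre <= base0 + 0.2 * height])
  lo <- baseline + 0.2 * (v[ipk] - baseline)
  hi <- baseline + 0.8 * (v[ipk] - baseline)
  below <- which(pre <= lo)
  if (length(below) == 0L) stop("no upstroke detected: no pre-upstroke baseline")
  i0 <- max(below)
  above <- which(v[i0:ipk] >= hi)
  i1 <- if (length(above)) i0 + above[1] - 1L else ipk
  if (i1 - i0 < 1L) i1 <- min(i0 + 1L, ipk)
  seg <- i0:i1
  t_seg <- (seg - 1) * dt
  fit <- stats::lm.fit(cbind(1, t_seg), v[seg])
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  if (!is.finite(b) || b <= 0) stop("no upstroke detected: tangent slope is not positive")
  unname((baseline - a) / b)
}

#' Multi-plane waveform set for pulse wave velocity estimation
#'
#' @param distances centerline distance of each analysis plane from the
#'   first, m; strictly increasing, >= 2 planes (12 equally spaced planes
#'   along the aorta is typical 4D Flow-MRI practice).
#' @param waveforms list of [uts], one per plane, sharing grid and period.
#' @return object of class `plane_arrival_set`.
#' @export
plane_arrival_set <- function(distances, waveforms) {
  if (length(distances) < 2L) stop("PWV needs at least two planes")
  if (any(diff(distances) <= 0)) stop("distances must be strictly increasing")
  if (length(waveforms) != length(distances)) {
    stop("one waveform per distance required")
  }
  structure(list(distances = distances, waveforms = waveforms),
            class = "plane_arrival_set")
}

#' Pulse wave velocity from multi-plane waveforms
#'
#' Estimates each plane's wavefront arrival time — by the intersecting-
#' tangents foot ([arrival_time_foot], default) or by cross-correlation
#' against the first plane — then fits distance against arrival time by
#' least squares. The regression slope is the PWV.
#'
#' @param planes a [plane_arrival_set].
#' @param method `"tangents"` (default) or `"xcorr"`.
#' @return object of class `pwv_estimate`: `pwv` (m/s), per-plane `feet`
#'   (s), and the `fit` (an `lm` of distance on arrival time).
#' @export
pwv_from_planes <- function(planes, method = c("tangents", "xcorr")) {
  method <- match.arg(method)
  if (method == "tangents") {
    feet <- vapply(planes$waveforms, arrival_time_foot, 0)
  } else {
    base <- planes$waveforms[[1]]
    feet <- vapply(planes$waveforms, function(w) xcorr_delay(base, w), 0)
  }
  if (any(diff(feet) <= 0)) {
    stop("arrival times are not strictly increasing with distance (non-physical ordering)")
  }
  fit <- stats::lm(planes$distances ~ feet)
  structure(list(pwv = unname(stats::coef(fit)[2]), feet = feet, fit = fit),
            class = "pwv_estimate")
}

#' @export
print.pwv_estimate <- function(x, ...) {
  cat(sprintf("<pwv_estimate> PWV = %.3f m/s from %d planes (R^2 = %.4f)\n",
              x$pwv, length(x$feet), summary(x$fit)$r.squared))
  invisible(x)
}

# circular cross-correlation delay of w relative to base, with parabolic
# sub-sample refinement
xcorr_delay <- function(base, w) {
  a <- slice_cycle(base, 1L)$values - mean(slice_cycle(base, 1L)$values)
  b <- slice_cycle(w, 1L)$values - mean(slice_cycle(w, 1L)$values)
  n <- length(a)
  cc <- vapply(0:(n - 1), function(k) sum(a * b[((0:(n - 1)) + k) %% n + 1]), 0)
  i <- which.max(cc)
  cm <- cc[if (i == 1) n else i - 1]; cp <- cc[if (i == n) 1 else i + 1]
  denom <- cm - 2 * cc[i] + cp
  delta <- if (denom < 0) 0.5 * (cm - cp) / denom else 0
  lag <- (i - 1 + delta)
  if (lag > n / 2) lag <- lag - n  # wrap to signed delay
  lag * base$dt
}

#' Per-branch hemodynamic metrics report as JSON
#'
#' @param metrics named list (e.g. per-branch lists of TAWSS, OSI,
#'   pressure summaries) serialisable by jsonlite.
#' @param path output path.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a wall-shear CSV (`time_s,tau_x_pa,tau_y_pa,tau_z_pa`)
#' @param path file path.
#' @return a [wss_series].
#' @export
read_wss_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (ncol(df) < 4L) stop("WSS CSV needs time and three component columns")
  dt <- stats::median(diff(df[[1]]))
  wss_series(as.matrix(df[, 2:4]), dt = dt, period = nrow(df) * dt)
}
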