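#' Branch segment geometry
#'
#' One row of the 1D vessel geometry table: the centerline length and mean
#' cross-sectional area of a branch, as extracted from centerlines of a
#' reconstructed 3D surface.
#'
#' @param name branch identifier (e.g. `"RSA"`, `"DAoTL"`).
#' @param length_l centerline length, m (> 0).
#' @param area_A0 mean cross-sectional area, m^2 (> 0).
#' @export
segment_geometry <- function(name, length_l, area_A0) {
  if (!is.finite(length_l) || length_l <= 0) stop("length_l must be positive")
  if (!is.finite(area_A0) || area_A0 <= 0) stop("area_A0 must be positive")
  structure(list(name = as.character(name), length_l = length_l,
                 area_A0 = area_A0), class = "segment_geometry")
}

#' Physical constants for Windkessel parameter estimation
#'
#' @param rho blood density, kg m^-3 (default 1060).
#' @param c_pwv arterial pulse wave velocity, m/s (no universal default:
#'   e.g. 7.85 m/s for a healthy thoracic aorta, 4.38 m/s for a dissected
#'   one as measured by multi-plane 4D Flow-MRI).
#' @param lambda_scale,phi_scale dimensionless geometric scaling factors of
#'   the distal branching tree (defaults 0.68 and 0.6), both in (0, 1).
#' @param mu dynamic blood viscosity, Pa s (default 0.004).
#' @export
estimation_constants <- function(c_pwv, rho = 1060, lambda_scale = 0.68,
                                 phi_scale = 0.6, mu = 0.004) {
  vals <- c(rho = rho, c_pwv = c_pwv, lambda_scale = lambda_scale,
            phi_scale = phi_scale, mu = mu)
  if (!all(is.finite(vals)) || any(vals <= 0)) stop("constants must be positive")
  if (lambda_scale >= 1 || phi_scale >= 1) {
    stop("scaling factors must lie in (0, 1)")
  }
  structure(as.list(vals), class = "estimation_constants")
}

#' Target systolic/diastolic brachial pressures
#'
#' @param p_sys systolic pressure, mmHg.
#' @param p_dia diastolic pressure, mmHg (0 < p_dia < p_sys).
#' @export
pressure_targets <- function(p_sys, p_dia) {
  if (!(p_sys > p_dia && p_dia > 0)) stop("need p_sys > p_dia > 0")
  structure(list(p_sys = p_sys, p_dia = p_dia), class = "pressure_targets")
}

#' Characteristic impedance from geometry and pulse wave velocity
#'
#' Water-hammer estimate `Z = rho * c_pwv / A0`: the ratio of oscillatory
#' pressure to oscillatory flow at the outlet of a vessel with mean
#' cross-sectional area A0 carrying waves at speed c_pwv.
#'
#' @param constants an [estimation_constants].
#' @param geometry a [segment_geometry].
#' @return Z in Pa s m^-3.
#' @export
characteristic_impedance <- function(constants, geometry) {
  constants$rho * constants$c_pwv / geometry$area_A0
}

#' Geometric estimate of peripheral resistance
#'
#' Scales the characteristic impedance by the branching factors of the
#' distal tree: `R = Z * lambda / (2 * phi^(4 - lambda))`.
#'
#' @param Z characteristic impedance, Pa s m^-3.
#' @param constants an [estimation_constants].
#' @return raw geometric resistance estimate, Pa s m^-3.
#' @export
geometric_resistance <- function(Z, constants) {
  Z * constants$lambda_scale /
    (2 * constants$phi_scale^(4 - constants$lambda_scale))
}

#' Geometric estimate of distal compliance
#'
#' The vessel's own volumetric compliance is `C0 = A0 * l / (rho * c^2)`
#' (inverse stiffness of a tube of area A0 and length l carrying waves at
#' speed c); the distal-tree compliance scales it by the branching factors:
#' `C = C0 * x / (1 - x)` with `x = 2 * lambda * phi^3`, which requires
#' `x < 1`.
#'
#' @param constants an [estimation_constants].
#' @param geometry a [segment_geometry].
#' @return list with `C0` (segment compliance) and `C_raw` (scaled distal
#'   estimate), both m^3 Pa^-1.
#' @export
geometric_compliance <- function(constants, geometry) {
  C0 <- geometry$area_A0 * geometry$length_l /
    (constants$rho * constants$c_pwv^2)
  x <- 2 * constants$lambda_scale * constants$phi_scale^3
  if (x >= 1) stop("non-physical scaling factors: 2*lambda*phi^3 must be < 1")
  list(C0 = C0, C_raw = C0 * x / (1 - x))
}

#' Mean arterial pressure by the one-third rule
#'
#' `P_mean = P_dia + (P_sys - P_dia) / 3`.
#'
#' @param targets a [pressure_targets].
#' @return mean arterial pressure, mmHg.
#' @export
mean_arterial_pressure <- function(targets) {
  targets$p_dia + (targets$p_sys - targets$p_dia) / 3
}

#' Net peripheral resistance from target mean pressure and inlet flow
#'
#' `R_T = P_mean / Q_in_mean`, with the pressure converted to Pa.
#'
#' @param P_mean mean arterial pressure, mmHg.
#' @param Q_in_mean cycle-mean inlet flow, m^3/s (> 0).
#' @return total peripheral resistance, Pa s m^-3.
#' @export
total_peripheral_resistance <- function(P_mean, Q_in_mean) {
  if (!is.finite(Q_in_mean) || Q_in_mean <= 0) {
    stop("mean inlet flow must be positive")
  }
  P_mean * MMHG_PA / Q_in_mean
}

#' Distribute the net resistance across branches in proportion to impedance
#'
#' Chooses per-branch resistances `R_j = k * Z_j` with
#' `k = R_T * sum(1/Z_j) - 1`, the unique proportional solution of the
#' parallel-sum constraint `1/R_T = sum_j 1/(Z_j + R_j)` (the aortic-root
#' inlet is excluded from the sum; pass only terminal branches). The
#' resulting R/Z ratio is identical across branches.
#'
#' @param Z_list numeric vector of per-branch characteristic impedances.
#' @param R_T net peripheral resistance, Pa s m^-3; must exceed the parallel
#'   combination of the impedances alone, otherwise no positive resistances
#'   exist under the proportional scheme.
#' @return numeric vector of per-branch resistances, Pa s m^-3.
#' @export
rescale_resistances_to_total <- function(Z_list, R_T) {
  Z_list <- unlist(Z_list)
  if (any(Z_list <= 0)) stop("impedances must be positive")
  k <- R_T * sum(1 / Z_list) - 1
  if (k <= 0) {
    stop(sprintf(paste0(
      "R_T = %.4g is not attainable: it must exceed the parallel impedance ",
      "sum %.4g for positive branch resistances"), R_T, 1 / sum(1 / Z_list)))
  }
  k * Z_list
}

#' Residual of the parallel-sum consistency check
#'
#' @param Z_list,R_list per-branch impedances and resistances, Pa s m^-3.
#' @param R_T net peripheral resistance, Pa s m^-3.
#' @return dimensionless relative residual
#'   `|sum(1/(Z+R)) - 1/R_T| * R_T`.
#' @export
verify_parallel_sum <- function(Z_list, R_list, R_T) {
  Z_list <- unlist(Z_list); R_list <- unlist(R_list)
  if (length(Z_list) != length(R_list)) stop("Z and R lists differ in length")
  abs(sum(1 / (Z_list + R_list)) - 1 / R_T) * R_T
}

#' Estimate 3-element Windkessel parameters for every terminal branch
#'
#' The default path computes Z from geometry and pulse wave velocity,
#' resistances by distributing the pressure-target-derived net resistance
#' across branches ([rescale_resistances_to_total]), and compliances from
#' the geometric estimate with an optional global multiplier. A purely
#' geometric resistance path ([geometric_resistance]) is available via
#' `r_mode = "geometric"` (used when no inlet flow measurement exists).
#'
#' @param geometry data.frame with columns `branch`, `length_m`, `area_m2`
#'   (terminal branches only; the aortic-root inlet must not be listed).
#' @param constants an [estimation_constants].
#' @param targets a [pressure_targets] (required for `r_mode = "rescale"`).
#' @param q_in_mean cycle-mean inlet flow, m^3/s (required for rescale mode).
#' @param r_mode `"rescale"` (default) or `"geometric"`.
#' @param c_multiplier global multiplier applied to the geometric compliance
#'   estimate (default 1); compliance is refined downstream by calibration.
#' @return data.frame with columns `branch`, `Z`, `R`, `C` (SI units) and
#'   attribute `R_T` when applicable.
#' @export
estimate_windkessel <- function(geometry, constants, targets = NULL,
                                q_in_mean = NULL,
                                r_mode = c("rescale", "geometric"),
                                c_multiplier = 1) {
  r_mode <- match.arg(r_mode)
  geoms <- lapply(seq_len(nrow(geometry)), function(i) {
    segment_geometry(geometry$branch[i], geometry$length_m[i],
                     geometry$area_m2[i])
  })
  Z <- vapply(geoms, function(g) characteristic_impedance(constants, g), 0)
  C <- vapply(geoms, function(g) {
    geometric_compliance(constants, g)$C_raw
  }, 0) * c_multiplier
  R_T <- NULL
  if (r_mode == "rescale") {
    if (is.null(targets) || is.null(q_in_mean)) {
      stop("rescale mode needs pressure targets and a mean inlet flow")
    }
    R_T <- total_peripheral_resistance(mean_arterial_pressure(targets),
                                       q_in_mean)
    R <- rescale_resistances_to_total(Z, R_T)
  } else {
    R <- vapply(Z, geometric_resistance, 0, constants = constants)
  }
  out <- data.frame(branch = geometry$branch, Z = Z, R = R, C = C)
  attr(out, "R_T") <- R_T
  out
}

#' Format a parameter table in reporting units
#'
#' Scales to the conventional reporting multipliers (Z in 1e7, R in 1e9
#' Pa s m^-3, C in 1e-10 m^3 Pa^-1) rounded to 3 significant figures.
#'
#' @param params data.frame from [estimate_windkessel] (columns `branch`,
#'   `Z`, `R`, `C` in SI units).
#' @return data.frame with scaled, rounded columns.
#' @export
format_parameter_table <- function(params) {
  data.frame(branch = params$branch,
             Z_1e7 = signif(params$Z / 1e7, 3),
             R_1e9 = signif(params$R / 1e9, 3),
             C_1e10 = signif(params$C / 1e-10, 3))
}

#' Read a branch geometry CSV (`branch,length_m,area_m2`)
#' @param path file path.
#' @return data.frame with columns `branch`, `length_m`, `area_m2`.
#' @export
read_geometry_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("branch", "length_m", "area_m2")
  if (!all(need %in% names(df))) {
    stop("geometry CSV needs columns: ", paste(need, collapse = ", "))
  }
  df[need]
}

#' Write a branch geometry CSV
#' @param geometry data.frame with columns `branch`, `length_m`, `area_m2`.
#' @param path output path.
#' @export
write_geometry_csv <- function(geometry, path) {
  out <- data.frame(branch = geometry$branch,
                    length_m = sprintf("%.17g", geometry$length_m),
                    area_m2 = sprintf("%.17g", geometry$area_m2))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write per-branch Windkessel parameters as YAML or JSON
#'
#' Layout: `{branch: {Z: ..., R: ..., C: ...}}`, SI units. The format is
#' chosen by file extension (`.yaml`/`.yml` vs `.json`).
#'
#' @param path file path.
#' @return named list of [wk_params].
#' @export
read_wk_params <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  lapply(raw, function(p) wk_params(p$Z, p$R, p$C))
}

#' @rdname read_wk_params
#' @param params named list of [wk_params] (or a parameter data.frame from
#'   [estimate_windkessel]).
#' @export
write_wk_params <- function(params, path) {
  if (is.data.frame(params)) {
    params <- stats::setNames(
      lapply(seq_len(nrow(params)), function(i) {
        wk_params(params$Z[i], params$R[i], params$C[i])
      }), params$branch)
  }
  raw <- lapply(params, function(p) list(Z = p$Z, R = p$R, C = p$C))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(raw, path)
  } else {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
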