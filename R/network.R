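#' Lumped RLC properties of one arterial segment
#'
#' Electrical-analogue constants of a straight vessel segment of length `l`
#' and mean cross-sectional area `A0`:
#' viscous (Poiseuille) resistance `r = 8 pi mu l / A0^2`,
#' blood inertance `L = rho l / A0`, and
#' volumetric wall compliance `c = A0 l / (rho c_pwv^2)`.
#'
#' @param geometry a [segment_geometry].
#' @param constants an [estimation_constants].
#' @return list with `r_seg` (Pa s m^-3), `l_seg` (Pa s^2 m^-3), `c_seg`
#'   (m^3 Pa^-1).
#' @export
segment_rlc_from_geometry <- function(geometry, constants) {
  list(r_seg = 8 * pi * constants$mu * geometry$length_l / geometry$area_A0^2,
       l_seg = constants$rho * geometry$length_l / geometry$area_A0,
       c_seg = geometry$area_A0 * geometry$length_l /
         (constants$rho * constants$c_pwv^2))
}

#' Arterial tree specification for branch pressure-waveform generation
#'
#' Describes a rooted tree of vessel segments, each lumped into one RLC
#' element (computed from its geometry unless overridden), with a 3-element
#' Windkessel attached at every leaf and a prescribed flow waveform at the
#' root. Solving this network yields a plausible periodic pressure waveform
#' at each branch, against which terminal Windkessel parameters are
#' calibrated.
#'
#' @param segments data.frame with columns `name`, `parent` (`NA` or `""`
#'   for the root segment), `length_m`, `area_m2`; optional columns
#'   `r_seg`, `l_seg`, `c_seg` override the geometric RLC values.
#' @param terminals named list of [wk_params], one entry per leaf segment.
#' @param inlet inlet flow [uts] (one cardiac cycle), m^3/s.
#' @param constants an [estimation_constants] used for the RLC conversion.
#' @return object of class `arterial_network`.
#' @export
arterial_network <- function(segments, terminals, inlet, constants) {
  stopifnot(is.data.frame(segments), inherits(inlet, "uts"))
  segments$parent[is.na(segments$parent)] <- ""
  name <- as.character(segments$name)
  if (anyDuplicated(name)) stop("segment names must be unique")
  root <- which(segments$parent == "")
  if (length(root) != 1L) stop("the tree must have exactly one root segment")
  parent_idx <- match(segments$parent, name)
  bad <- which(segments$parent != "" & is.na(parent_idx))
  if (length(bad)) stop("unknown parent for segment: ", name[bad[1]])
  # acyclicity: walking parent pointers must reach the root
  for (i in seq_along(name)) {
    j <- i; seen <- 0L
    while (!is.na(parent_idx[j])) {
      j <- parent_idx[j]; seen <- seen + 1L
      if (seen > length(name)) stop("segment topology contains a cycle")
    }
    if (j != root) stop("tree is not connected: segment ", name[i])
  }
  leaves <- setdiff(seq_along(name), parent_idx[!is.na(parent_idx)])
  miss <- setdiff(name[leaves], names(terminals))
  if (length(miss)) {
    stop("every leaf needs a terminal Windkessel; missing: ",
         paste(miss, collapse = ", "))
  }
  rlc <- lapply(seq_along(name), function(i) {
    g <- segment_geometry(name[i], segments$length_m[i], segments$area_m2[i])
    v <- segment_rlc_from_geometry(g, constants)
    for (f in c("r_seg", "l_seg", "c_seg")) {
      if (f %in% names(segments) && is.finite(segments[[f]][i])) {
        v[[f]] <- segments[[f]][i]
      }
    }
    v
  })
  structure(list(segments = segments, name = name, parent_idx = parent_idx,
                 root = root, leaves = leaves, rlc = rlc,
                 terminals = terminals[name[leaves]], inlet = inlet,
                 constants = constants),
            class = "arterial_network")
}

#' @export
print.arterial_network <- function(x, ...) {
  cat(sprintf("<arterial_network> %d segments, %d terminal Windkessels, root '%s'\n",
              length(x$name), length(x$leaves), x$name[x$root]))
  invisible(x)
}

#' Simulate the lumped arterial network to a periodic state
#'
#' Integrates the linear network ODE system — per-segment momentum balance
#' with resistance and inertance, per-node mass balance into the segment
#' compliance, and the terminal Windkessel relations at the leaves — by
#' backward Euler (unconditionally stable at dt = 1e-3 s, and the same
#' discretisation used for the stand-alone Windkessel). The prescribed
#' inlet flow enters the root node; the reported inlet pressure adds the
#' root segment's own resistive and inertial drop.
#'
#' The run stops early once every monitored pressure and flow changes by
#' less than `periodic_tol` between consecutive cycles.
#'
#' @param network an [arterial_network].
#' @param n_cycles maximum number of cardiac cycles (default 20).
#' @param init_pressure_pa initial pressure of all nodes, Pa (default
#'   101 mmHg, a dissection-type diastolic value; use 80 mmHg for
#'   normotensive configurations).
#' @param periodic_tol cycle-to-cycle relative change defining
#'   time-periodicity (default 0.015).
#' @return object of class `network_solution`: named lists `pressure` and
#'   `flow` of single-cycle [uts] per segment (the last cycle run),
#'   `inlet_pressure`, flags `periodic`/`cycles_run`, and the full state
#'   history (`p_hist`, `q_hist`, `pc_hist`) for diagnostics.
#' @export
simulate_network <- function(network, n_cycles = 20L,
                             init_pressure_pa = 101 * MMHG_PA,
                             periodic_tol = 0.015) {
  stopifnot(inherits(network, "arterial_network"))
  S <- length(network$name)
  leaves <- network$leaves
  L <- length(leaves)
  inlet <- network$inlet
  spc <- samples_per_cycle(inlet)
  if (length(inlet$values) != spc) stop("inlet must hold exactly one cycle")
  dt <- inlet$dt
  # state x = [p_1..p_S, q_(non-root), pc_1..pc_L]
  nonroot <- setdiff(seq_len(S), network$root)
  iq <- stats::setNames(seq_along(nonroot) + S, network$name[nonroot])
  ipc <- stats::setNames(seq_along(leaves) + S + length(nonroot),
                         network$name[leaves])
  nx <- S + length(nonroot) + L
  Mdiag <- numeric(nx)
  A <- matrix(0, nx, nx)
  b <- numeric(nx)
  for (i in seq_len(S)) {
    Mdiag[i] <- network$rlc[[i]]$c_seg
    if (i == network$root) b[i] <- 1 else A[i, iq[network$name[i]]] <- 1
  }
  for (k in nonroot) {
    row <- iq[network$name[k]]
    Mdiag[row] <- network$rlc[[k]]$l_seg
    pm <- network$parent_idx[k]
    A[row, pm] <- 1
    A[row, k] <- -1
    A[row, row] <- -network$rlc[[k]]$r_seg
    A[pm, row] <- A[pm, row] - 1  # outflow from parent node
  }
  for (j in seq_along(leaves)) {
    i <- leaves[j]
    wk <- network$terminals[[network$name[i]]]
    row <- ipc[network$name[i]]
    Mdiag[row] <- wk$C
    A[row, i] <- 1 / wk$Z
    A[row, row] <- -(1 / wk$Z + 1 / wk$R)
    A[i, i] <- A[i, i] - 1 / wk$Z   # terminal outflow from node i
    A[i, row] <- A[i, row] + 1 / wk$Z
  }
  # equilibrate before factoring: pressures (~1e4 Pa), flows (~1e-4 m^3/s)
  # and compliance/inertance rows span ~14 orders of magnitude
  K <- diag(Mdiag, nx) - dt * A
  col_scale <- c(rep(1e4, S), rep(1e-4, length(nonroot)), rep(1e4, L))
  K <- sweep(K, 2, col_scale, `*`)
  row_scale <- apply(abs(K), 1, max)
  G <- sweep(solve(K / row_scale), 1, col_scale, `*`)
  N <- n_cycles * spc
  u <- rep(inlet$values, n_cycles)
  x <- numeric(nx)
  x[1:S] <- init_pressure_pa
  x[ipc] <- init_pressure_pa
  # terminal flows consistent with the initial pressures (zero drop across Z)
  hist <- matrix(NA_real_, nx, N)
  cycles_run <- n_cycles
  periodic <- FALSE
  for (n in seq_len(N)) {
    x <- G %*% ((Mdiag * x + dt * b * u[n]) / row_scale)
    if (!all(is.finite(x))) {
      stop(sprintf("network solve diverged at step %d (t = %.4g s)", n, n * dt))
    }
    hist[, n] <- x
    if (n %% spc == 0L && n >= 2L * spc) {
      prev <- hist[, (n - 2L * spc + 1L):(n - spc), drop = FALSE]
      cur <- hist[, (n - spc + 1L):n, drop = FALSE]
      ref <- apply(abs(prev), 1, max)
      chg <- apply(abs(cur - prev), 1, max) / pmax(ref, 1e-300)
      if (max(chg[ref > 0]) < periodic_tol) {
        periodic <- TRUE
        cycles_run <- n %/% spc
        N <- n
        break
      }
    }
  }
  hist <- hist[, seq_len(N), drop = FALSE]
  last <- (N - spc + 1L):N
  mk <- function(vals, lab) uts(vals, dt, inlet$period, lab)
  pressure <- stats::setNames(
    lapply(seq_len(S), function(i) mk(hist[i, last], "pressure_pa")),
    network$name)
  flow <- stats::setNames(lapply(seq_len(S), function(i) {
    if (i == network$root) mk(inlet$values, "flow_m3s")
    else mk(hist[iq[network$name[i]], last], "flow_m3s")
  }), network$name)
  # inlet pressure = root node pressure + root segment resistive/inertial drop
  r0 <- network$rlc[[network$root]]
  dqdt <- (inlet$values - inlet$values[c(spc, 1:(spc - 1))]) / dt
  inlet_p <- mk(hist[network$root, last] + r0$r_seg * inlet$values +
                  r0$l_seg * dqdt, "pressure_pa")
  structure(list(pressure = pressure, flow = flow, inlet_pressure = inlet_p,
                 cycles_run = cycles_run, periodic = periodic,
                 dt = dt, period = inlet$period, spc = spc,
                 p_hist = `rownames<-`(hist[1:S, , drop = FALSE], network$name),
                 q_hist = `rownames<-`(hist[iq, , drop = FALSE], names(iq)),
                 pc_hist = `rownames<-`(hist[ipc, , drop = FALSE], names(ipc)),
                 leaf_names = network$name[leaves]),
            class = "network_solution")
}

#' @export
print.network_solution <- function(x, ...) {
  cat(sprintf("<network_solution> %d segments, %d cycles run, periodic: %s\n",
              length(x$pressure), x$cycles_run, x$periodic))
  invisible(x)
}

#' Write a network solution as one waveform CSV per branch
#'
#' @param solution a `network_solution`.
#' @param dir output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
write_network_solution <- function(solution, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(solution$pressure)) {
    p1 <- file.path(dir, paste0(nm, "_pressure.csv"))
    p2 <- file.path(dir, paste0(nm, "_flow.csv"))
    write_waveform_csv(solution$pressure[[nm]], p1, "pressure_pa")
    write_waveform_csv(solution$flow[[nm]], p2, "flow_m3s")
    paths <- c(paths, p1, p2)
  }
  invisible(paths)
}
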