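#' Build the physical-to-lattice configuration for the flow solver
#'
#' Maps the culture-medium properties onto two-relaxation-time D3Q19 lattice
#' parameters. The time step keeps intrinsic compressibility negligible,
#' `dt = 0.06 dx / vmax`; the even (viscous) relaxation rate follows
#' `s1 = (3 nu dt / dx^2 + 1/2)^-1` with lattice sound speed `cs^2 = 1/3`,
#' and the odd rate obeys the magic-number relation
#' `s2 = 8 (2 - s1) / (8 - s1)`, which places bounce-back walls halfway
#' between fluid and solid nodes.
#'
#' @param rho fluid density (kg m^-3); default 993 (culture medium at 37 C)
#' @param mu dynamic viscosity (Pa s); default 1e-3
#' @param dx lattice spacing (m); default 8e-6
#' @param vmax target maximal fluid velocity (m s^-1); default 10e-3, the
#'   Poiseuille centreline estimate in the circular channel
#' @param tol windowed relative-L2 convergence tolerance on the velocity
#' @param max_steps step cap (the full-scale configuration needs about 1e6
#'   steps; desk-scale lattices converge far earlier on the windowed
#'   criterion)
#' @return an object of class `flow_config`
#' @export
build_flow_config <- function(rho = 993, mu = 1e-3, dx = 8e-6,
                              vmax = 10e-3, tol = 1e-6,
                              max_steps = 1000000L) {
  stopifnot(rho > 0, mu > 0, dx > 0, vmax > 0)
  nu <- mu / rho
  dt <- 0.06 * dx / vmax
  s1 <- 1 / (3 * nu * dt / dx^2 + 0.5)
  if (s1 <= 0 || s1 >= 2)
    stop(sprintf("s1 = %.4f outside (0, 2) at dx = %.3g m, dt = %.3g s", s1, dx, dt))
  s2 <- 8 * (2 - s1) / (8 - s1)
  structure(list(rho = rho, mu = mu, nu = nu, dx = dx, dt = dt,
                 cs2 = 1 / 3, s1 = s1, s2 = s2, vmax = vmax,
                 tol = tol, max_steps = as.integer(max_steps)),
            class = "flow_config")
}

#' @export
print.flow_config <- function(x, ...) {
  cat(sprintf("flow_config: dx = %.3g m, dt = %.3g s, s1 = %.4f, s2 = %.4f\n",
              x$dx, x$dt, x$s1, x$s2))
  cat(sprintf("  nu = %.4g m2/s, vmax = %.3g m/s, magic = %.5f\n",
              x$nu, x$vmax, (1 / x$s1 - 0.5) * (1 / x$s2 - 0.5)))
  invisible(x)
}

# face codes for the solver: 0 periodic, 1 no-slip, 2 symmetry
.face_codes <- function(bc) {
  codes <- c(periodic = 0L, noslip = 1L, symmetry = 2L)
  out <- integer(6)
  nm <- c("x", "y", "z")
  for (a in 1:3) {
    v <- bc[[nm[a]]]
    if (length(v) == 1L) v <- c(v, v)
    out[2 * a - 1] <- codes[[v[1]]]
    out[2 * a] <- codes[[v[2]]]
  }
  if (any(xor(out[c(1, 3, 5)] == 0, out[c(2, 4, 6)] == 0)))
    stop("periodic boundaries must pair up on both faces of an axis")
  out
}

#' Run the steady perfusion flow simulation
#'
#' D3Q19 two-relaxation-time lattice Boltzmann solve of the Stokes-regime
#' perfusion flow. Hydrogel and spheroid voxels are impermeable solids
#' (halfway bounce-back); the default boundary plan mirrors the bioreactor
#' segment: symmetry plane at X = 0, no-slip at X = X_max, periodic in Y and
#' Z. Flow is driven by a constant body force along `force_axis`; when
#' `match_vmax` is TRUE the force is tuned (secant iteration on the linear
#' Stokes response, warm-started) until the mean fluid speed on the symmetry
#' plane matches `config$vmax`, the Poiseuille centreline estimate along the
#' bioreactor axis.
#'
#' @param volume a [labeled_volume()]
#' @param config a [build_flow_config()]
#' @param body_force physical body-force density (N m^-3); the starting
#'   guess when `match_vmax` is TRUE
#' @param force_axis axis of the driving force, default "z" (bioreactor axis)
#' @param bc boundary plan: list with entries x, y, z, each a single code or
#'   a pair (`"periodic"`, `"noslip"`, `"symmetry"`)
#' @param match_vmax tune the body force to the symmetry-plane target?
#' @param max_outer cap on force-tuning iterations
#' @param window convergence-check window (steps)
#' @return an object of class `flow_field` with physical velocities (m/s)
#' @export
run_flow <- function(volume, config, body_force = NULL, force_axis = "z",
                     bc = list(x = c("symmetry", "noslip"),
                               y = "periodic", z = "periodic"),
                     match_vmax = TRUE, max_outer = 5L, window = 1000L) {
  stopifnot(inherits(volume, "labeled_volume"), inherits(config, "flow_config"))
  if (abs(volume$spacing * 1e-6 - config$dx) > 1e-12)
    stop("volume spacing and config dx disagree")
  dims <- dim(volume$labels)
  faces <- .face_codes(bc)
  axis_id <- match(force_axis, c("x", "y", "z"))

  if (is.null(body_force)) {
    # plane-Poiseuille guess for the inner half-channel of width w
    w <- max(volume$bands[1], 2L) * config$dx
    body_force <- 2 * config$mu * config$vmax / w^2
  }
  to_lattice <- function(f_phys) f_phys * config$dt^2 / (config$dx * config$rho)
  u_phys <- function(res) cbind(res$ux, res$uy, res$uz) * (config$dx / config$dt)

  lab <- as.integer(volume$labels)
  f_init <- NULL
  f_now <- body_force
  # initialize from the 1-D two-channel Poiseuille profile (slab treated as
  # solid): cuts the slow cross-section momentum-diffusion transient
  if (force_axis == "z" && any(volume$bands > 0)) {
    n_in <- volume$bands[1]; n_out <- volume$bands[2]
    nx <- dims[1]
    f_lat0 <- body_force * config$dt^2 / (config$dx * config$rho)
    nu_lat <- config$cs2 * (1 / config$s1 - 0.5)
    xs <- ((which(lab == 0L) - 1L) %% nx)          # 0-based x of fluid nodes
    w <- numeric(length(xs))
    if (n_in > 0) {
      sel <- xs < n_in
      xi <- xs[sel] + 0.5
      w[sel] <- f_lat0 / (2 * nu_lat) * (n_in^2 - xi^2)
    }
    if (n_out > 0) {
      sel <- xs >= nx - n_out
      eta <- xs[sel] - (nx - n_out) + 0.5
      w[sel] <- f_lat0 / (2 * nu_lat) * eta * (n_out - eta)
    }
    w19 <- c(1/3, rep(1/18, 6), rep(1/36, 12))
    cz19 <- c(0, 0, 0, 0, 0, 1, -1, 0, 0, 0, 0, 1, 1, -1, -1, 1, 1, -1, -1)
    fmat <- vapply(1:19, function(q) {
      cu <- cz19[q] * w
      w19[q] * (1 + 3 * cu + 4.5 * cu^2 - 1.5 * w^2)
    }, numeric(length(w)))
    f_init <- as.numeric(fmat)
  }
  res <- NULL
  history <- numeric(0)
  for (it in seq_len(max(1L, if (match_vmax) max_outer else 1L))) {
    fvec <- c(0, 0, 0)
    fvec[axis_id] <- to_lattice(f_now)
    res <- run_flow_cpp(lab, dims, config$s1, config$s2, fvec, faces,
                        config$tol, config$max_steps, as.integer(window),
                        f_init)
    if (!match_vmax) break
    u <- u_phys(res)
    plane <- res$fluid_index - 1L
    on_plane <- (plane %% dims[1]) == 0L
    if (!any(on_plane)) stop("no fluid nodes on the symmetry plane X = 0")
    v_meas <- mean(sqrt(rowSums(u[on_plane, , drop = FALSE]^2)))
    history <- c(history, v_meas)
    if (abs(v_meas - config$vmax) <= 0.01 * config$vmax) break
    if (v_meas <= 0) stop("flow tuning failed: zero measured plane velocity")
    scale <- config$vmax / v_meas
    f_now <- f_now * scale
    # warm start: rescale the velocity-carrying part of the populations
    w19 <- c(1/3, rep(1/18, 6), rep(1/36, 12))
    fmat <- matrix(res$f, ncol = 19)
    fmat <- sweep(sweep(fmat, 2, w19, "-") * scale, 2, w19, "+")
    f_init <- as.numeric(fmat)
  }
  u <- u_phys(res)
  nfluid <- length(res$fluid_index)
  mach <- max(sqrt(res$ux^2 + res$uy^2 + res$uz^2)) / sqrt(1 / 3)
  structure(list(velocity = u, rho_lat = res$rho, f = res$f,
                 fluid_index = res$fluid_index, dims = dims,
                 steps = res$steps, converged = res$converged,
                 delta = res$delta, mass_trace = res$mass_trace,
                 body_force = f_now, force_axis = force_axis,
                 faces = faces, config = config, n_fluid = nfluid,
                 lattice_mach = mach, vmax_history = history),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("flow_field: %d fluid nodes, %d steps (%s), max |u| = %.3g m/s\n",
              x$n_fluid, x$steps,
              if (x$converged) "converged" else "step cap reached",
              max(sqrt(rowSums(x$velocity^2)))))
  cat(sprintf("  body force %.4g N/m3 along %s, lattice Mach %.3g\n",
              x$body_force, x$force_axis, x$lattice_mach))
  invisible(x)
}

#' Velocity field on the full voxel grid
#'
#' Expands the per-fluid-node velocities of a [run_flow()] result onto the
#' full grid (zero in solid phases), e.g. for export or for the oxygen
#' solver.
#' @param flow a `flow_field`
#' @return a `n_voxel x 3` matrix of physical velocities (m/s)
#' @export
flow_velocity_grid <- function(flow, dims = flow$dims) {
  u <- matrix(0, nrow = prod(dims), ncol = 3)
  u[flow$fluid_index, ] <- flow$velocity
  u
}
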