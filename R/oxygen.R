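#' Michaelis-Menten kinetics of oxygen consumption in spheroids
#'
#' Default values are the experimentally estimated cell densities and
#' per-cell kinetic constants of the two co-cultured cell types:
#' `rho = 3.54e14 m^-3` each, `Vmax_MSC = 5.4e-17 mol cell^-1 s^-1`,
#' `K_M_MSC = 3.8e-3 mol m^-3`, `Vmax_HUVEC = 2.4e-17`,
#' `K_M_HUVEC = 5e-4`.
#'
#' @param rho_msc,rho_huvec cell densities inside spheroids (m^-3)
#' @param vmax_msc,vmax_huvec maximal per-cell consumption (mol cell^-1 s^-1)
#' @param km_msc,km_huvec half-saturation concentrations (mol m^-3)
#' @return an object of class `kinetics_params`
#' @export
kinetics_params <- function(rho_msc = 3.54e14, rho_huvec = 3.54e14,
                            vmax_msc = 5.4e-17, vmax_huvec = 2.4e-17,
                            km_msc = 3.8e-3, km_huvec = 5e-4) {
  stopifnot(rho_msc > 0, rho_huvec > 0, vmax_msc > 0, vmax_huvec > 0,
            km_msc > 0, km_huvec > 0)
  structure(list(rho_msc = rho_msc, rho_huvec = rho_huvec,
                 vmax_msc = vmax_msc, vmax_huvec = vmax_huvec,
                 km_msc = km_msc, km_huvec = km_huvec),
            class = "kinetics_params")
}

#' Volumetric oxygen consumption rate
#'
#' Michaelis-Menten-like sink of the spheroid phase (negative = consumption):
#' `r_O2 = -rho_MSC Vmax_MSC c/(c + K_M_MSC) - rho_HUVEC Vmax_HUVEC c/(c + K_M_HUVEC)`.
#' @param c dissolved oxygen concentration(s), mol m^-3
#' @param kinetics a [kinetics_params()]
#' @return consumption rate (mol m^-3 s^-1), same length as `c`
#' @export
michaelis_menten_rate <- function(c, kinetics = kinetics_params()) {
  if (any(c < 0)) stop("negative concentration")
  -(kinetics$rho_msc * kinetics$vmax_msc * c / (c + kinetics$km_msc) +
      kinetics$rho_huvec * kinetics$vmax_huvec * c / (c + kinetics$km_huvec))
}

#' Thiele modulus of a spheroid
#'
#' Dimensionless competition between oxygen consumption kinetics and
#' diffusive supply for a spheroid of radius `r_sph` bathed at `c0`:
#' `phi = sqrt((rho_MSC Vmax_MSC + rho_HUVEC Vmax_HUVEC) r_sph^2 / (D_sph c0))`.
#' `phi << 1` is the reaction-controlled regime, `phi >> 1`
#' diffusion-controlled; the default parameters at `r_sph = 50 um` give
#' `phi` close to 1.
#' @param kinetics a [kinetics_params()]
#' @param r_sph spheroid radius (m)
#' @param d_sph oxygen diffusivity in the spheroid (m^2 s^-1)
#' @param c0 ambient dissolved-oxygen concentration (mol m^-3)
#' @return the Thiele modulus (dimensionless)
#' @export
thiele_modulus <- function(kinetics = kinetics_params(), r_sph = 50e-6,
                           d_sph = 3e-10, c0 = 0.21) {
  stopifnot(r_sph >= 0, d_sph > 0, c0 > 0)
  vr <- kinetics$rho_msc * kinetics$vmax_msc +
    kinetics$rho_huvec * kinetics$vmax_huvec
  sqrt(vr * r_sph^2 / (d_sph * c0))
}

#' Build the D3Q7 oxygen transport configuration
#'
#' Per-phase antisymmetric relaxation rates follow
#' `s- = (D dt / (ce dx^2) + 1/2)^-1` with scale parameter `ce = 1/4` and
#' `s+ = 2 - s-`. The time step obeys the advective stability bound
#' `dt <= dx / (2 vmax)`; when the advective bound is slack (static culture,
#' or slow pore flow), dt is additionally capped so the largest lattice
#' diffusivity `D dt / dx^2` stays at or below `d_lat_max` for accuracy.
#'
#' @param d_fluid,d_hydrogel,d_spheroid diffusion coefficients (m^2 s^-1);
#'   defaults 3.3e-9 (medium as water at 37 C), 1.6e-9 (measured in the
#'   gel), 3e-10 (spheroid tissue)
#' @param c0 boundary dissolved-oxygen concentration (mol m^-3), default
#'   0.21 (equilibrium with air at 1 atm, 37 C)
#' @param dx lattice spacing (m)
#' @param vmax maximal fluid velocity in the oxygen domain (m s^-1); use the
#'   bioreactor estimate 10e-3 when pore velocities are not known
#' @param ce lattice scale parameter (default 1/4)
#' @param d_lat_max accuracy cap on the lattice diffusivity
#' @param dt optional explicit time step (s), overriding the rules
#' @param tol windowed relative-change convergence tolerance
#' @param max_steps step cap (about 7e5 at full scale)
#' @return an object of class `oxygen_config`
#' @export
build_oxygen_config <- function(d_fluid = 3.3e-9, d_hydrogel = 1.6e-9,
                                d_spheroid = 3e-10, c0 = 0.21, dx = 8e-6,
                                vmax = 10e-3, ce = 0.25, d_lat_max = 0.2,
                                dt = NULL, tol = 1e-7,
                                max_steps = 700000L) {
  stopifnot(d_fluid > 0, d_hydrogel > 0, d_spheroid > 0, c0 > 0, dx > 0,
            vmax > 0, ce > 0, ce < 1 / 3)
  if (is.null(dt)) {
    dt_adv <- dx / (2 * vmax)
    dt_acc <- d_lat_max * dx^2 / max(d_fluid, d_hydrogel, d_spheroid)
    dt <- min(dt_adv, dt_acc)
  }
  s_minus <- vapply(c(d_fluid, d_hydrogel, d_spheroid), function(D)
    1 / (D * dt / (ce * dx^2) + 0.5), numeric(1))
  if (any(s_minus <= 0 | s_minus >= 2))
    stop(sprintf("relaxation rate outside (0, 2): s- = %s",
                 paste(signif(s_minus, 4), collapse = ", ")))
  structure(list(d_fluid = d_fluid, d_hydrogel = d_hydrogel,
                 d_spheroid = d_spheroid, c0 = c0, dx = dx, dt = dt,
                 ce = ce, s_minus = s_minus, s_plus = 2 - s_minus,
                 tol = tol, max_steps = as.integer(max_steps)),
            class = "oxygen_config")
}

#' @export
print.oxygen_config <- function(x, ...) {
  cat(sprintf("oxygen_config: dx = %.3g m, dt = %.3g s, ce = %.3g, c0 = %.3g mol/m3\n",
              x$dx, x$dt, x$ce, x$c0))
  cat(sprintf("  s- (fluid, hydrogel, spheroid) = %.4f, %.4f, %.4f\n",
              x$s_minus[1], x$s_minus[2], x$s_minus[3]))
  invisible(x)
}

#' Solve steady oxygen transport with Michaelis-Menten consumption
#'
#' D3Q7 two-relaxation-time solve of the convection-diffusion-reaction
#' equation across fluid, hydrogel and spheroid phases (concentration
#' continuity at interfaces, partition coefficients 1). Dirichlet
#' concentration `c0` is imposed by anti-bounce-back on both X faces of the
#' (slab) domain; Y and Z are periodic by default. The sink acts in
#' spheroid voxels only, evaluated explicitly from the previous step's
#' concentration. With `flow = NULL` the run is the static-culture mode
#' (pure diffusion); with a flow field, pore velocities advect the
#' equilibrium populations.
#'
#' @param volume a [labeled_volume()], typically the [crop_slab()] of a
#'   seeded segment
#' @param config a [build_oxygen_config()]
#' @param kinetics a [kinetics_params()]
#' @param flow optional velocity matrix (`n_voxel x 3`, m/s, zero outside
#'   pores) congruent with `volume`, e.g. from [flow_velocity_grid()]
#' @param dirichlet_all_faces impose `c0` on all six faces (validation
#'   geometries) instead of the two X faces
#' @param window convergence-check window (steps)
#' @return an object of class `oxygen_field`
#' @export
run_oxygen <- function(volume, config = build_oxygen_config(),
                       kinetics = kinetics_params(), flow = NULL,
                       dirichlet_all_faces = FALSE, window = 500L) {
  stopifnot(inherits(volume, "labeled_volume"), inherits(config, "oxygen_config"))
  dims <- dim(volume$labels)
  faces <- if (dirichlet_all_faces) rep(1L, 6L) else c(1L, 1L, 0L, 0L, 0L, 0L)
  u <- NULL
  if (!is.null(flow)) {
    stopifnot(nrow(flow) == prod(dims))
    u <- flow * (config$dt / config$dx)     # lattice units
    umax <- max(abs(u))
    if (umax > config$ce)
      stop(sprintf("lattice velocity %.3g exceeds the stable range (ce = %g); reduce dt",
                   umax, config$ce))
  }
  res <- run_oxygen_cpp(as.integer(volume$labels), dims, config$s_minus,
                        config$ce, config$c0, u,
                        kinetics$rho_msc * kinetics$vmax_msc * config$dt,
                        kinetics$km_msc,
                        kinetics$rho_huvec * kinetics$vmax_huvec * config$dt,
                        kinetics$km_huvec, faces, config$tol,
                        config$max_steps, as.integer(window), config$c0)
  conc <- array(res$c, dim = dims)
  vox_m3 <- (config$dx)^3
  structure(list(c = conc,
                 sink = array(res$sink / config$dt, dim = dims),
                 steps = res$steps, converged = res$converged,
                 delta = res$delta,
                 influx_mol_s = res$influx_per_step * vox_m3 / config$dt,
                 consumption_mol_s = res$consumption_per_step * vox_m3 / config$dt,
                 config = config, kinetics = kinetics,
                 advective = !is.null(flow)),
            class = "oxygen_field")
}

#' @export
print.oxygen_field <- function(x, ...) {
  cat(sprintf("oxygen_field: %s, %d steps (%s)\n",
              if (x$advective) "advective" else "diffusion only",
              x$steps, if (x$converged) "converged" else "step cap reached"))
  cat(sprintf("  c in [%.4g, %.4g] mol/m3; influx %.3g mol/s vs consumption %.3g mol/s\n",
              min(x$c), max(x$c), x$influx_mol_s, x$consumption_mol_s))
  invisible(x)
}

#' Hypoxic cell fraction
#'
#' Percentage of spheroid voxels whose steady concentration is below the
#' hypoxia threshold (default: the MSC half-saturation constant
#' `K_M = 3.8e-3 mol m^-3`). Cells are assumed uniformly dense within
#' spheroids, so the voxel fraction equals the cell fraction.
#' @param field an `oxygen_field`
#' @param volume the matching [labeled_volume()]
#' @param threshold hypoxia threshold (mol m^-3)
#' @return hypoxic fraction in percent
#' @export
hypoxic_fraction <- function(field, volume, threshold = 3.8e-3) {
  stopifnot(inherits(field, "oxygen_field"))
  sph <- volume$labels == 2L
  if (!any(sph)) stop("no spheroid phase in the volume")
  100 * mean(field$c[sph] < threshold)
}

#' Periphery-to-centre oxygen partition metrics
#'
#' Two observables of the scaffold-scale oxygen landscape: the ratio of the
#' mean concentration in the outer 20 % X-bands of the slab to the mean in
#' the central 20 % band, and the largest intra-spheroid relative drop
#' `1 - min(c)/max(c)` over all spheroids (in percent).
#' @param field an `oxygen_field`
#' @param volume the matching [labeled_volume()] (slab domain)
#' @return list with `periphery_center_ratio`, `max_spheroid_drop_pct` and
#'   the per-spheroid drop table
#' @export
oxygen_partition_metrics <- function(field, volume) {
  stopifnot(inherits(field, "oxygen_field"))
  dims <- dim(volume$labels)
  nx <- dims[1]
  xi <- slice.index(volume$labels, 1)
  wband <- max(1L, round(0.2 * nx))
  outer_band <- xi <= wband | xi > nx - wband
  c_lo <- floor((nx - wband) / 2) + 1L
  central <- xi >= c_lo & xi < c_lo + wband
  ratio <- mean(field$c[outer_band]) / mean(field$c[central])
  drops <- data.frame()
  if (any(volume$labels == 2L)) {
    cc <- label_components_cpp(as.logical(volume$labels == 2L), dims, 26L)
    nlab <- attr(cc, "n_labels")
    drops <- do.call(rbind, lapply(seq_len(nlab), function(l) {
      cs <- field$c[cc == l]
      data.frame(id = l, min_c = min(cs), max_c = max(cs),
                 drop_pct = 100 * (1 - min(cs) / max(cs)))
    }))
  }
  list(periphery_center_ratio = ratio,
       max_spheroid_drop_pct = if (nrow(drops)) max(drops$drop_pct) else 0,
       spheroid_drops = drops)
}
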