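#' Superficial velocity in the empty bioreactor tube
#'
#' Volumetric flow rate divided by the empty tube cross-section:
#' `vs = q / (pi d^2 / 4)`. At the operating point q = 10 mL/min through a
#' 12 mm inner-diameter tube this gives 1.47 mm/s.
#' @param q_ml_min volumetric flow rate (mL min^-1)
#' @param tube_diameter_mm tube inner diameter (mm)
#' @return superficial velocity (mm s^-1)
#' @export
superficial_velocity <- function(q_ml_min = 10, tube_diameter_mm = 12) {
  stopifnot(q_ml_min > 0, tube_diameter_mm > 0)
  q_m3_s <- q_ml_min * 1e-6 / 60
  area_m2 <- pi * (tube_diameter_mm * 1e-3)^2 / 4
  (q_m3_s / area_m2) * 1e3
}

#' Pipeline configuration
#'
#' Bundles the per-stage specifications and toggles for a full
#' generate-simulate-measure run.
#' @param scaffold a [scaffold_spec()]
#' @param seeding a [seeding_spec()]
#' @param flow_cfg a [build_flow_config()]
#' @param oxygen_cfg a [build_oxygen_config()]
#' @param kinetics a [kinetics_params()]
#' @param q_ml_min,tube_diameter_mm bioreactor operating point
#' @param stages character subset of
#'   `c("flow", "oxygen", "morphometry", "spatial")`
#' @param master_seed one seed; stage seeds are derived from it by hashing
#'   stage names
#' @param output_dir optional directory for report/CSV/VTK outputs
#' @return an object of class `pipeline_config`
#' @export
pipeline_config <- function(scaffold = scaffold_spec(),
                            seeding = seeding_spec("CSD4"),
                            flow_cfg = build_flow_config(),
                            oxygen_cfg = build_oxygen_config(),
                            kinetics = kinetics_params(),
                            q_ml_min = 10, tube_diameter_mm = 12,
                            stages = c("flow", "oxygen", "morphometry",
                                       "spatial"),
                            master_seed = 1L, output_dir = NULL) {
  stopifnot(q_ml_min > 0, tube_diameter_mm > 0,
            all(stages %in% c("flow", "oxygen", "morphometry", "spatial")))
  structure(list(scaffold = scaffold, seeding = seeding,
                 flow_cfg = flow_cfg, oxygen_cfg = oxygen_cfg,
                 kinetics = kinetics, q_ml_min = q_ml_min,
                 tube_diameter_mm = tube_diameter_mm, stages = stages,
                 master_seed = as.integer(master_seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full generate - simulate - measure pipeline
#'
#' Executes the enabled stages in dependency order: geometry generation and
#' spheroid seeding always run; then morphometry on the seeded volume, flow
#' plus wall shear stress, oxygen transport on the slab (reusing pore
#' velocities when the flow stage ran), and the spatial point-pattern
#' analysis on synthetic day-1 / day-7 cell patterns. Fully reproducible
#' from the configuration and the master seed.
#'
#' @param config a [pipeline_config()]
#' @param verbose print stage progress
#' @return an object of class `run_report` (a nested list; every stage key
#'   is present, disabled stages hold `NULL`)
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  stage_time <- list()
  tic <- function() proc.time()[["elapsed"]]

  config$scaffold$rng_seed <- derive_seed(config$master_seed, "scaffold")
  config$seeding$rng_seed <- derive_seed(config$master_seed, "seeding")

  say("generating scaffold segment ...")
  t <- tic()
  vol0 <- generate_scaffold_segment(config$scaffold)
  seeded <- seed_spheroids(vol0, config$seeding)
  vol <- seeded$volume
  stage_time$generate <- tic() - t

  report <- list(
    provenance = list(master_seed = config$master_seed,
                      stages = config$stages,
                      package_version = as.character(utils::packageVersion("perfuscaff"))),
    operating_point = list(
      q_ml_min = config$q_ml_min,
      tube_diameter_mm = config$tube_diameter_mm,
      superficial_velocity_mm_s = superficial_velocity(config$q_ml_min,
                                                       config$tube_diameter_mm)),
    geometry = list(
      dims = dim(vol$labels),
      measured_porosity = attr(vol0, "measured_porosity"),
      measured_mean_pore_size_um = attr(vol0, "measured_mean_pore_size"),
      n_spheroids = nrow(seeded$table),
      mean_spheroid_volume_um3 = if (nrow(seeded$table)) mean(seeded$table$volume_um3) else NA),
    morphometry = NULL, flow = NULL, wss = NULL, oxygen = NULL,
    spatial = NULL)

  if ("morphometry" %in% config$stages) {
    say("morphometry ...")
    t <- tic()
    sm <- spheroid_morphometry(vol)
    report$morphometry <- list(
      porosity = porosity(vol),
      spheroid_count = sm$summary$count,
      spheroid_mean_volume_um3 = sm$summary$mean_volume_um3,
      spheroid_mean_equiv_diameter_um = sm$summary$mean_equiv_diameter_um)
    stage_time$morphometry <- tic() - t
  }

  flow <- NULL
  if ("flow" %in% config$stages) {
    say("flow simulation ...")
    t <- tic()
    flow <- run_flow(vol, config$flow_cfg)
    wss <- compute_wss(flow, vol)
    report$flow <- list(steps = flow$steps, converged = flow$converged,
                        body_force_n_m3 = flow$body_force,
                        lattice_mach = flow$lattice_mach)
    smry <- region_mean_wss(wss)
    report$wss <- list(summary = smry,
                       pore_wall_mean_mpa = 1e3 * smry$mean_tau_pa[smry$region == "pore_wall"])
    stage_time$flow <- tic() - t
  }

  if ("oxygen" %in% config$stages) {
    say("oxygen transport ...")
    t <- tic()
    slab <- crop_slab(vol)
    uslab <- NULL
    if (!is.null(flow)) {
      ugrid <- flow_velocity_grid(flow)
      r <- slab_range(vol)
      keepx <- rep(seq_len(dim(vol$labels)[1]) %in% r[1]:r[2],
                   times = prod(dim(vol$labels)[2:3]))
      uslab <- ugrid[keepx, , drop = FALSE]
    }
    oxy <- run_oxygen(slab, config$oxygen_cfg, config$kinetics, flow = uslab)
    metrics <- oxygen_partition_metrics(oxy, slab)
    hyp <- if (any(slab$labels == 2L)) hypoxic_fraction(oxy, slab) else NA_real_
    report$oxygen <- list(
      mode = if (is.null(uslab)) "diffusive" else "advective",
      steps = oxy$steps, converged = oxy$converged,
      hypoxic_fraction_pct = hyp,
      periphery_center_ratio = metrics$periphery_center_ratio,
      max_spheroid_drop_pct = metrics$max_spheroid_drop_pct,
      thiele_modulus_r50um = thiele_modulus(config$kinetics, 50e-6,
                                            config$oxygen_cfg$d_spheroid,
                                            config$oxygen_cfg$c0))
    stage_time$oxygen <- tic() - t
  }

  if ("spatial" %in% config$stages) {
    say("spatial statistics ...")
    t <- tic()
    seed_sp <- derive_seed(config$master_seed, "spatial")
    analyse <- function(mode) {
      pat <- generate_cell_pattern(50, 150, 150, mode = mode, seed = seed_sp)
      r <- seq(0, 25, length.out = 26)
      vapply(c("MSC", "HUVEC"), function(ty) {
        k <- ripley_k3(pat, type = ty, r = r)
        as.character(classify_vs_poisson(k, r = 20, seed = seed_sp))
      }, character(1))
    }
    report$spatial <- list(day1 = analyse("mixed_uniform"),
                           day7 = analyse("huvec_core"))
    stage_time$spatial <- tic() - t
  }

  report$timing_s <- stage_time
  report$total_s <- tic() - t0
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, file.path(config$output_dir, "report.json"))
  }
  structure(report, class = "run_report")
}

#' Write / read a pipeline report as JSON
#'
#' Timings are excluded from the serialized form so that identical
#' configurations and seeds give byte-identical reports.
#' @param report a `run_report`
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$timing_s <- NULL
  out$total_s <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
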