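test_that("oxygen lattice configuration follows the stability and relaxation rules", {
  cfg <- build_oxygen_config(dt = 4e-4)
  expect_equal(cfg$s_minus[2], 1.8519, tolerance = 1e-4)   # hydrogel phase
  expect_equal(cfg$s_plus + cfg$s_minus, rep(2, 3), tolerance = 1e-14)
  # advective bound dt <= dx / (2 vmax) binds at the bioreactor operating point
  cfg2 <- build_oxygen_config(vmax = 10e-3)
  expect_equal(cfg2$dt, 8e-6 / (2 * 10e-3))
  # vanishing diffusivity pushes s- to the stability boundary 2
  s <- 1 / (1e-15 * cfg$dt / (0.25 * (8e-6)^2) + 0.5)
  expect_equal(s, 2, tolerance = 1e-6)
  expect_error(build_oxygen_config(ce = 0.5), "ce")
})

test_that("the Michaelis-Menten sink reproduces its closed-form values", {
  kin <- kinetics_params()
  expect_identical(michaelis_menten_rate(0, kin), 0)
  # half-saturation: with the HUVEC term zeroed, rate at K_M is half-maximal
  kin_msc <- kinetics_params(rho_huvec = 1e-30)
  expect_equal(michaelis_menten_rate(kin_msc$km_msc, kin_msc),
               -0.5 * kin_msc$rho_msc * kin_msc$vmax_msc,
               tolerance = 1e-10)
  # plug-in at c0 with printed defaults
  expect_equal(michaelis_menten_rate(0.21, kin), -2.725e-2, tolerance = 1e-3)
  expect_error(michaelis_menten_rate(-0.1, kin), "negative")
})

test_that("the Thiele modulus behaves as its definition demands", {
  expect_equal(thiele_modulus(r_sph = 50e-6), 1.047, tolerance = 1e-3)
  expect_equal(round(thiele_modulus(r_sph = 50e-6)), 1)
  expect_equal(thiele_modulus(r_sph = 0), 0)
  expect_equal(thiele_modulus(r_sph = 100e-6),
               2 * thiele_modulus(r_sph = 50e-6), tolerance = 1e-12)
})

test_that("without a sink the field settles at the boundary concentration", {
  vol <- labeled_volume(array(1L, dim = c(20, 6, 6)), 8)
  cfg <- build_oxygen_config(tol = 1e-10, max_steps = 50000L)
  ox <- run_oxygen(vol, cfg)
  expect_equal(range(ox$c), c(0.21, 0.21), tolerance = 1e-12)
})

test_that("a uniform zeroth-order sink recovers the slab parabola", {
  # c >> K_M everywhere, so the sink is effectively constant
  kin <- kinetics_params(km_msc = 1e-9, km_huvec = 1e-9,
                         rho_msc = 1e13, rho_huvec = 1e13)
  vol <- labeled_volume(array(2L, dim = c(40, 6, 6)), 8)
  D <- 3e-10
  cfg <- build_oxygen_config(d_fluid = D, d_hydrogel = D, d_spheroid = D,
                             vmax = 1e-6, tol = 1e-10, max_steps = 100000L)
  ox <- run_oxygen(vol, cfg, kin)
  expect_true(ox$converged)
  R <- 1e13 * (5.4e-17 + 2.4e-17)
  prof <- tapply(ox$c, slice.index(vol$labels, 1), mean)
  x <- (as.numeric(names(prof)) - 0.5) * cfg$dx
  L <- 40 * cfg$dx
  ana <- cfg$c0 - R * x * (L - x) / (2 * D)
  expect_lt(max(abs(prof - ana)) / (cfg$c0 - min(ana)), 0.02)
  # steady-state flux balance: influx equals consumption
  expect_lt(abs(ox$influx_mol_s / ox$consumption_mol_s - 1), 0.02)
  # maximum principle (to numerical zero)
  expect_gte(min(ox$c), -1e-8 * cfg$c0)
  expect_lte(max(ox$c), cfg$c0 * (1 + 1e-12))
})

test_that("a single spheroid matches the independent radial BVP oracle", {
  n <- 48; r_sph <- 10; sp_um <- 4
  vol <- spheroid_in_box(n = n, r_sph_vox = r_sph, spacing = sp_um)
  dx <- sp_um * 1e-6
  cfg <- build_oxygen_config(dx = dx, vmax = 1e-6, tol = 1e-9,
                             max_steps = 200000L)
  kin <- kinetics_params()
  ox <- run_oxygen(vol, cfg, kin, dirichlet_all_faces = TRUE)
  expect_true(ox$converged)
  # radial profile of the simulation
  ax <- seq_len(n) - (n + 1) / 2
  rr <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+")) * dx
  r_out <- (n / 2 - 2) * dx
  shell <- abs(rr - r_out) < dx / 2
  c_out <- mean(ox$c[shell])
  oracle <- radial_bvp_oracle(r_sph * dx, r_out, c_out,
                              cfg$d_spheroid, cfg$d_hydrogel, kin)
  inside <- rr <= r_sph * dx
  rel_err <- abs(ox$c[inside] - oracle(rr[inside])) / cfg$c0
  expect_lt(max(rel_err), 0.05)
  # the Thiele-consistent central dip exists but is moderate at phi ~ 1
  expect_lt(min(ox$c[inside]), c_out)
  expect_gt(min(ox$c[inside]), 0)
})

test_that("hypoxic fraction obeys its limits and grows with radius and density", {
  fix <- small_segment()
  slab <- crop_slab(fix$volume)
  cfg <- build_oxygen_config(vmax = 1e-6, tol = 1e-8, max_steps = 200000L)
  ox <- cached("slab_oxygen", run_oxygen(slab, cfg))
  # no-sink field has no hypoxia; threshold c0 catches every spheroid voxel
  novol <- labeled_volume(array(c(2L, rep(1L, 999)), dim = c(10, 10, 10)), 8)
  nox <- run_oxygen(novol, build_oxygen_config(vmax = 1e-6, tol = 1e-9,
                                               max_steps = 50000L),
                    kinetics_params(rho_msc = 1e-30, rho_huvec = 1e-30))
  expect_equal(hypoxic_fraction(nox, novol), 0)
  expect_equal(hypoxic_fraction(ox, slab, threshold = cfg$c0 * (1 + 1e-9)), 100)
  expect_error(hypoxic_fraction(ox, labeled_volume(array(0L, c(4, 4, 4)), 8)),
               "no spheroid")
  # monotone in spheroid radius and in cell density
  frac_of <- function(r_vox, dens_scale) {
    vol <- spheroid_in_box(n = 44, r_sph_vox = r_vox, spacing = 8)
    kin <- kinetics_params(rho_msc = 3.54e14 * dens_scale,
                           rho_huvec = 3.54e14 * dens_scale)
    cfg <- build_oxygen_config(vmax = 1e-6, tol = 1e-8, max_steps = 200000L)
    oxs <- run_oxygen(vol, cfg, kin, dirichlet_all_faces = TRUE)
    hypoxic_fraction(oxs, vol)
  }
  by_radius <- c(frac_of(8, 1), frac_of(13, 1), frac_of(18, 1))
  expect_true(all(diff(by_radius) >= 0))
  expect_gt(by_radius[3], by_radius[1])
  by_density <- c(frac_of(13, 1), frac_of(13, 4))
  expect_true(all(diff(by_density) >= 0))
  expect_gt(by_density[2], by_density[1])
})

test_that("oxygen partition metrics read the concentration landscape", {
  # uniform field: ratio 1, zero drops
  vol <- labeled_volume(array(rep(c(2L, 1L), c(8, 992)), dim = c(10, 10, 10)), 8)
  field <- structure(list(c = array(0.2, dim = c(10, 10, 10)),
                          advective = FALSE),
                     class = "oxygen_field")
  m <- oxygen_partition_metrics(field, vol)
  expect_equal(m$periphery_center_ratio, 1.0)
  expect_equal(m$max_spheroid_drop_pct, 0)
  # linear profile: band means are computable in closed form
  nx <- 50
  lin <- structure(list(c = array(rep(seq_len(nx) / nx, 16), dim = c(nx, 4, 4)),
                        advective = FALSE),
                   class = "oxygen_field")
  lvol <- labeled_volume(array(1L, dim = c(nx, 4, 4)), 8)
  m2 <- oxygen_partition_metrics(lin, lvol)
  wb <- round(0.2 * nx)
  outer_mean <- mean(c(seq_len(wb), (nx - wb + 1):nx)) / nx
  c_lo <- floor((nx - wb) / 2) + 1
  central_mean <- mean(c_lo:(c_lo + wb - 1)) / nx
  expect_equal(m2$periphery_center_ratio, outer_mean / central_mean,
               tolerance = 1e-12)
  # seeded synthetic segment: periphery better oxygenated than the centre
  fix <- small_segment()
  slab <- crop_slab(fix$volume)
  ox <- cached("slab_oxygen", stop("fixture must exist"))
  m3 <- oxygen_partition_metrics(ox, slab)
  expect_gt(m3$periphery_center_ratio, 1)
  expect_gt(m3$max_spheroid_drop_pct, 0)
})

test_that("perfusion does not worsen pore oxygenation on matched geometry", {
  fix <- small_segment()
  slab <- crop_slab(fix$volume)
  cfg <- build_oxygen_config(vmax = 1e-6, tol = 1e-8, max_steps = 200000L)
  # purpose-built geometry: hydrogel block with straight X-channels (so a
  # uniform channel velocity is divergence-free) and an embedded spheroid
  dims <- c(48, 20, 20)
  lab <- array(1L, dim = dims)
  lab[, 3:6, 3:6] <- 0L; lab[, 13:16, 3:6] <- 0L
  lab[, 3:6, 13:16] <- 0L; lab[, 13:16, 13:16] <- 0L
  ax <- seq_len(48) - 24.5; ay <- seq_len(20) - 10.5
  d2 <- outer(outer(ax^2, ay^2, "+"), ay^2, "+")
  lab[d2 <= 6^2] <- 2L
  vol <- labeled_volume(lab, 8)
  cfg <- build_oxygen_config(vmax = 1e-6, tol = 1e-9, max_steps = 300000L)
  static <- run_oxygen(vol, cfg)
  u <- matrix(0, nrow = length(lab), ncol = 3)
  u[lab == 0L, 1] <- 2e-5
  cfg_adv <- build_oxygen_config(vmax = 2e-4, tol = 1e-9, max_steps = 300000L)
  adv <- run_oxygen(vol, cfg_adv, flow = u)
  # perfusion improves oxygenation on average; pointwise the advected
  # depression shifts downstream and may dip a few percent below the static
  # field, so only gross pointwise worsening would flag a defect
  expect_gte(mean(adv$c), mean(static$c))
  expect_gte(min(adv$c - static$c), -0.05 * cfg$c0)
})
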