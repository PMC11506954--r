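test_that("lattice mapping reproduces the operating-point parameters", {
  cfg <- build_flow_config(rho = 993, mu = 1e-3, dx = 8e-6, vmax = 10e-3)
  expect_equal(cfg$dt, 4.8e-5, tolerance = 1e-12)
  expect_equal(cfg$s1, 0.36156, tolerance = 1e-4)
  expect_equal(cfg$s2, 1.71607, tolerance = 1e-4)
  # magic combination is an exact algebraic identity of the s2 relation
  expect_equal((1 / cfg$s1 - 0.5) * (1 / cfg$s2 - 0.5), 3 / 16,
               tolerance = 1e-14)
  for (s1 in c(0.1, 0.7, 1.3, 1.9)) {
    s2 <- 8 * (2 - s1) / (8 - s1)
    expect_equal((1 / s1 - 0.5) * (1 / s2 - 0.5), 3 / 16, tolerance = 1e-14)
  }
  # halving dx at fixed vmax halves dt
  cfg2 <- build_flow_config(dx = 4e-6)
  expect_equal(cfg2$dt, cfg$dt / 2)
})

test_that("plane Poiseuille flow matches the closed form", {
  nx <- 22
  vol <- channel_volume(nx = nx)
  cfg <- build_flow_config(tol = 1e-9, max_steps = 100000L)
  f_phys <- 1000
  fl <- run_flow(vol, cfg, body_force = f_phys, force_axis = "z",
                 bc = periodic_bc, match_vmax = FALSE, window = 200L)
  expect_true(fl$converged)
  x <- (fl$fluid_index - 1L) %% nx
  prof <- tapply(fl$velocity[, 3], x, mean)
  xp <- (as.numeric(names(prof)) - 0.5) * cfg$dx
  H <- (nx - 2) * cfg$dx
  ana <- f_phys * xp * (H - xp) / (2 * cfg$mu)
  expect_lt(max(abs(prof - ana)) / max(ana), 0.02)
  # solid nodes excluded by construction; transverse velocity negligible
  expect_lt(max(abs(fl$velocity[, 1:2])), 1e-9 * max(ana))
  expect_lt(fl$lattice_mach, 0.1)
})

test_that("zero body force leaves the fluid quiescent", {
  vol <- channel_volume(nx = 12)
  cfg <- build_flow_config(tol = 1e-9, max_steps = 5000L)
  fl <- run_flow(vol, cfg, body_force = 0, bc = periodic_bc,
                 match_vmax = FALSE, window = 200L)
  expect_lt(max(abs(fl$velocity)), 1e-15)
})

test_that("mass is conserved to 1e-10 relative over 1e4 steps", {
  vol <- channel_volume(nx = 16, ny = 6, nz = 6)
  cfg <- build_flow_config(tol = 0, max_steps = 10000L)  # force full run
  fl <- run_flow(vol, cfg, body_force = 500, bc = periodic_bc,
                 match_vmax = FALSE, window = 1000L)
  drift <- diff(range(fl$mass_trace)) / fl$mass_trace[1]
  expect_lt(drift, 1e-10)
})

test_that("duct flow is identical when the geometry is rotated", {
  # walls on X faces; drive along y, then along z: profiles must match
  vol <- channel_volume(nx = 18, ny = 5, nz = 5)
  cfg <- build_flow_config(tol = 1e-9, max_steps = 50000L)
  fy <- run_flow(vol, cfg, body_force = 800, force_axis = "y",
                 bc = periodic_bc, match_vmax = FALSE, window = 200L)
  fz <- run_flow(vol, cfg, body_force = 800, force_axis = "z",
                 bc = periodic_bc, match_vmax = FALSE, window = 200L)
  expect_equal(fy$velocity[, 2], fz$velocity[, 3], tolerance = 1e-12)
  expect_equal(fy$velocity[, 3], fz$velocity[, 2], tolerance = 1e-12)
})

test_that("the symmetry plane mirrors a half-channel onto the full solution", {
  # half channel: symmetry at X-, wall (solid layer) at X+; compare with the
  # centre half of a full channel of doubled width
  nxh <- 11
  labh <- array(0L, dim = c(nxh, 4, 4))
  labh[nxh, , ] <- 1L
  volh <- labeled_volume(labh, 8, bands = c(0L, 0L))
  cfg <- build_flow_config(tol = 1e-9, max_steps = 50000L)
  fh <- run_flow(volh, cfg, body_force = 1000, force_axis = "z",
                 bc = list(x = c("symmetry", "noslip"), y = "periodic",
                           z = "periodic"),
                 match_vmax = FALSE, window = 200L)
  nxf <- 2 * nxh
  labf <- array(0L, dim = c(nxf, 4, 4))
  labf[1, , ] <- 1L; labf[nxf, , ] <- 1L
  volf <- labeled_volume(labf, 8, bands = c(0L, 0L))
  ff <- run_flow(volf, cfg, body_force = 1000, force_axis = "z",
                 bc = periodic_bc, match_vmax = FALSE, window = 200L)
  xh <- (fh$fluid_index - 1L) %% nxh
  profh <- tapply(fh$velocity[, 3], xh, mean)
  xf <- (ff$fluid_index - 1L) %% nxf
  proff <- tapply(ff$velocity[, 3], xf, mean)
  # half-channel node at x maps to full-channel node nxh + x (mirror plane
  # halfway outside the first node); compare against the upper half
  expect_equal(as.numeric(profh),
               as.numeric(proff[as.character(as.numeric(names(profh)) + nxh)]),
               tolerance = 0.02)
})

test_that("stationarity: extra steps after convergence change nothing", {
  vol <- channel_volume(nx = 14)
  cfg <- build_flow_config(tol = 1e-8, max_steps = 50000L)
  fl <- run_flow(vol, cfg, body_force = 500, bc = periodic_bc,
                 match_vmax = FALSE, window = 500L)
  expect_true(fl$converged)
  fl2 <- run_flow(vol, cfg, body_force = 500, bc = periodic_bc,
                  match_vmax = FALSE, window = 500L)
  expect_equal(fl$velocity, fl2$velocity, tolerance = 1e-12)
})

test_that("body-force tuning matches the symmetry-plane velocity target", {
  fix <- small_segment()
  cfg <- build_flow_config(tol = 3e-5, max_steps = 200000L)
  fl <- run_flow(fix$volume, cfg)
  u <- fl$velocity
  on_plane <- ((fl$fluid_index - 1L) %% fl$dims[1]) == 0L
  v_plane <- mean(sqrt(rowSums(u[on_plane, , drop = FALSE]^2)))
  expect_lt(abs(v_plane - cfg$vmax) / cfg$vmax, 0.02)
  expect_true(fl$converged)
  assign("segment_flow", fl, envir = .fixture_cache)
})
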