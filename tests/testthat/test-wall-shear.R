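test_that("boundary regions are tagged by their anatomy", {
  fix <- small_segment()
  reg <- classify_boundary_regions(fix$volume)
  nx <- dim(fix$volume$labels)[1]
  x <- ((reg$index - 1) %% nx) + 1
  r <- slab_range(fix$volume)
  expect_true(all(reg$region[x == nx] == "bioreactor_wall"))
  expect_true(all(reg$region[x > r[1] & x < r[2]] == "pore_wall"))
  expect_true(all(reg$region[x < r[1]] == "inner_periphery"))
  expect_true(all(reg$region[x > r[2] & x < nx] == "outer_periphery"))
  # all-fluid volume: only the forced X_max wall plane remains
  open <- labeled_volume(array(0L, dim = c(8, 4, 4)), 8, bands = c(0L, 0L))
  reg2 <- classify_boundary_regions(open)
  expect_true(all(((reg2$index - 1) %% 8) + 1 == 8))
})

test_that("wall normals recover flat, spherical and corner geometry", {
  # flat axis-aligned wall: exact axis normal (checked in the channel)
  vol <- channel_volume(nx = 12)
  reg <- classify_boundary_regions(vol)
  sel <- ((reg$index - 1) %% 12) == 1     # fluid nodes next to the x- wall
  n <- estimate_wall_normals(vol, reg$index[sel],
                             faces = rep(0L, 6L))
  expect_true(all(abs(n[, 1] - 1) < 1e-12))
  # discretized sphere: median angular error below 10 degrees
  lab <- array(0L, dim = c(34, 34, 34))
  ctr <- 17.5
  ax <- seq_len(34) - ctr
  d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  lab[d2 <= 12^2] <- 1L
  svol <- labeled_volume(lab, 8)
  regs <- classify_boundary_regions(svol)
  sel <- regs$region == "pore_wall"
  nodes <- regs$index[sel]
  nrm <- estimate_wall_normals(svol, nodes, faces = rep(0L, 6L))
  pos <- nodes - 1
  px <- pos %% 34 + 1 - ctr
  py <- (pos %/% 34) %% 34 + 1 - ctr
  pz <- pos %/% (34 * 34) + 1 - ctr
  rad <- cbind(px, py, pz) / sqrt(px^2 + py^2 + pz^2)
  cosang <- rowSums(nrm * rad)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  expect_lt(median(ang), 10)
  # 90-degree inner corner: diagonal normal
  lab2 <- array(0L, dim = c(12, 12, 12))
  lab2[1:2, , ] <- 1L
  lab2[, 1:2, ] <- 1L
  cvol <- labeled_volume(lab2, 8)
  corner <- which(lab2 == 0L &
                    slice.index(lab2, 1) == 3 & slice.index(lab2, 2) == 3 &
                    slice.index(lab2, 3) == 6)
  ncorner <- estimate_wall_normals(cvol, corner, faces = rep(0L, 6L))
  expect_equal(abs(ncorner[1, 1]), abs(ncorner[1, 2]), tolerance = 1e-12)
  expect_equal(ncorner[1, 3], 0, tolerance = 1e-12)
})

test_that("Poiseuille wall shear stress matches the momentum balance", {
  nx <- 42
  vol <- channel_volume(nx = nx)
  cfg <- build_flow_config(tol = 1e-9, max_steps = 100000L)
  f_phys <- 1000
  fl <- run_flow(vol, cfg, body_force = f_phys, force_axis = "z",
                 bc = periodic_bc, match_vmax = FALSE, window = 200L)
  w <- compute_wss(fl, vol)
  H <- (nx - 2) * cfg$dx
  xr <- ((w$index - 1) %% nx) + 1
  wall_tau <- w$tau_pa[xr %in% c(2, nx - 1)]
  expect_lt(max(abs(wall_tau - f_phys * H / 2)) / (f_phys * H / 2), 0.05)
  # global momentum budget: wall traction balances the body-force input
  A_wall <- 2 * prod(dim(vol$labels)[2:3]) * cfg$dx^2
  V_fluid <- fl$n_fluid * cfg$dx^3
  expect_lt(abs(mean(wall_tau) * A_wall - f_phys * V_fluid) /
              (f_phys * V_fluid), 0.05)
})

test_that("WSS vanishes for quiescent fluid and purely normal traction", {
  vol <- channel_volume(nx = 16)
  cfg <- build_flow_config(tol = 1e-9, max_steps = 5000L)
  fl <- run_flow(vol, cfg, body_force = 0, bc = periodic_bc,
                 match_vmax = FALSE, window = 200L)
  w <- compute_wss(fl, vol)
  expect_lt(max(w$tau_pa), 1e-12)
  # purely normal traction projects to zero tangential stress
  n <- c(1, 0, 0)
  sigma <- diag(c(-5, -5, -5))                     # isotropic pressure
  tr <- sigma %*% n
  tang <- tr - sum(tr * n) * n
  expect_equal(sqrt(sum(tang^2)), 0)
})

test_that("WSS scales linearly with the body force in the Stokes regime", {
  vol <- channel_volume(nx = 22, ny = 6, nz = 6)
  cfg <- build_flow_config(tol = 1e-9, max_steps = 100000L)
  f1 <- run_flow(vol, cfg, body_force = 400, bc = periodic_bc,
                 match_vmax = FALSE, window = 200L)
  f2 <- run_flow(vol, cfg, body_force = 800, bc = periodic_bc,
                 match_vmax = FALSE, window = 200L)
  w1 <- compute_wss(f1, vol)
  w2 <- compute_wss(f2, vol)
  expect_lt(max(abs(w2$tau_pa - 2 * w1$tau_pa) / pmax(w2$tau_pa, 1e-15)),
            0.01)
})

test_that("tau is invariant under 90-degree rotation of geometry and flow", {
  vol <- channel_volume(nx = 18, ny = 5, nz = 5)
  cfg <- build_flow_config(tol = 1e-9, max_steps = 50000L)
  fy <- run_flow(vol, cfg, body_force = 600, force_axis = "y",
                 bc = periodic_bc, match_vmax = FALSE, window = 200L)
  fz <- run_flow(vol, cfg, body_force = 600, force_axis = "z",
                 bc = periodic_bc, match_vmax = FALSE, window = 200L)
  wy <- compute_wss(fy, vol)
  wz <- compute_wss(fz, vol)
  expect_equal(sort(wy$tau_pa), sort(wz$tau_pa), tolerance = 1e-10)
})

test_that("region means aggregate the stress modulus correctly", {
  f <- structure(data.frame(index = 1:4,
                            region = factor(rep("pore_wall", 4),
                                            levels = c("pore_wall",
                                                       "inner_periphery",
                                                       "outer_periphery",
                                                       "bioreactor_wall")),
                            nx = 1, ny = 0, nz = 0,
                            tau_pa = c(1e-3, 3e-3, 2e-3, 2e-3)),
                 class = c("wss_field", "data.frame"))
  out <- region_mean_wss(f, "pore_wall")
  expect_equal(out$mean_tau_pa, 2e-3)
  expect_equal(out$max_tau_pa, 3e-3)
  expect_identical(out$n_nodes, 4L)
  expect_error(region_mean_wss(f, "outer_periphery"), "no boundary nodes")
})
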