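# Shared fixtures. Everything is generated in code; heavier objects are
# cached per test run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# plane channel: solid walls on the two X faces, open elsewhere
channel_volume <- function(nx = 42, ny = 4, nz = 4, spacing = 8) {
  lab <- array(0L, dim = c(nx, ny, nz))
  lab[1, , ] <- 1L
  lab[nx, , ] <- 1L
  labeled_volume(lab, spacing, bands = c(0L, 0L))
}

periodic_bc <- list(x = "periodic", y = "periodic", z = "periodic")

# small synthetic seeded segment shared by flow / oxygen / morphometry tests
small_segment <- function() {
  cached("small_segment", {
    spec <- scaffold_spec(segment_length_x = 0.96, width_y = 0.4,
                          height_z = 0.2, channel_inner_width = 0.24,
                          channel_outer_width = 0.24, rng_seed = 11)
    vol <- generate_scaffold_segment(spec)
    seeded <- seed_spheroids(vol, seeding_spec("CSD4", rng_seed = 11),
                             count = 4L)
    list(spec = spec, bare = vol, volume = seeded$volume,
         table = seeded$table)
  })
}

# independent 1-D spherically symmetric two-region reaction-diffusion oracle:
# finite differences + Picard iteration on the Michaelis-Menten sink.
# Returns a function c(r) by linear interpolation.
radial_bvp_oracle <- function(r_sph, r_out, c_out, d_sph, d_med, kinetics,
                              n_grid = 1500L) {
  r <- seq(0, r_out, length.out = n_grid)
  h <- r[2] - r[1]
  Dm <- ifelse(utils::head(r, -1) + h / 2 < r_sph, d_sph, d_med)  # at midpoints
  rm <- utils::head(r, -1) + h / 2
  cvec <- rep(c_out, n_grid)
  rate <- function(c) {
    c <- pmax(c, 0)
    kinetics$rho_msc * kinetics$vmax_msc * c / (c + kinetics$km_msc) +
      kinetics$rho_huvec * kinetics$vmax_huvec * c / (c + kinetics$km_huvec)
  }
  for (iter in 1:200) {
    # tridiagonal system for d/dr(r^2 D dc/dr)/r^2 = q(r), q = rate inside
    q <- ifelse(r < r_sph, rate(cvec), 0)
    lower <- numeric(n_grid); diagv <- numeric(n_grid); upper <- numeric(n_grid)
    rhs <- numeric(n_grid)
    for (i in 2:(n_grid - 1)) {
      wL <- rm[i - 1]^2 * Dm[i - 1] / h^2
      wR <- rm[i]^2 * Dm[i] / h^2
      lower[i] <- wL; upper[i] <- wR; diagv[i] <- -(wL + wR)
      rhs[i] <- q[i] * r[i]^2
    }
    diagv[1] <- -1; upper[1] <- 1; rhs[1] <- 0          # symmetry c'(0)=0
    diagv[n_grid] <- 1; lower[n_grid] <- 0; rhs[n_grid] <- c_out
    # Thomas algorithm
    cp <- numeric(n_grid); dp <- numeric(n_grid)
    cp[1] <- upper[1] / diagv[1]; dp[1] <- rhs[1] / diagv[1]
    for (i in 2:n_grid) {
      m <- diagv[i] - lower[i] * cp[i - 1]
      cp[i] <- upper[i] / m
      dp[i] <- (rhs[i] - lower[i] * dp[i - 1]) / m
    }
    cnew <- numeric(n_grid)
    cnew[n_grid] <- dp[n_grid]
    for (i in (n_grid - 1):1) cnew[i] <- dp[i] - cp[i] * cnew[i + 1]
    if (max(abs(cnew - cvec)) < 1e-10) { cvec <- cnew; break }
    cvec <- 0.5 * cvec + 0.5 * cnew
  }
  stats::approxfun(r, pmax(cvec, 0), rule = 2)
}

# single spheroid of radius `r_sph_vox` voxels centred in a cubic box of
# side n voxels, hydrogel medium elsewhere
spheroid_in_box <- function(n = 48, r_sph_vox = 10, spacing = 8,
                            medium = 1L) {
  ax <- seq_len(n) - (n + 1) / 2
  d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  lab <- array(medium, dim = c(n, n, n))
  lab[d2 <= r_sph_vox^2] <- 2L
  labeled_volume(lab, spacing)
}
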