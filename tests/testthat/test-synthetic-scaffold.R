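test_that("generated segments hit the porosity target, conserve phases and are reproducible", {
  fix <- small_segment()
  vol <- fix$bare
  expect_equal(attr(vol, "measured_porosity"), fix$spec$target_porosity,
               tolerance = 0.03 / fix$spec$target_porosity)
  expect_lt(abs(attr(vol, "measured_mean_pore_size") -
                  fix$spec$target_mean_pore_size), 15)
  # phase-label conservation
  counts <- tabulate(vol$labels + 1L, nbins = 3L)
  expect_identical(sum(counts), length(vol$labels))
  # channel bands are pure fluid
  expect_true(all(vol$labels[seq_len(vol$bands[1]), , ] == 0L))
  nx <- dim(vol$labels)[1]
  expect_true(all(vol$labels[(nx - vol$bands[2] + 1):nx, , ] == 0L))
  # determinism: same spec, same seed, voxel-identical
  vol2 <- generate_scaffold_segment(fix$spec)
  expect_identical(vol$labels, vol2$labels)
})

test_that("pore space percolates in X through the slab", {
  vol <- small_segment()$bare
  r <- slab_range(vol)
  slab <- vol$labels[r[1]:r[2], , , drop = FALSE] == 0L
  comp <- label_components_cpp(as.logical(slab), dim(slab), 6L)
  dim(comp) <- dim(slab)
  spanning <- intersect(unique(as.vector(comp[1, , ])),
                        unique(as.vector(comp[dim(slab)[1], , ])))
  expect_true(any(spanning > 0))
})

test_that("the all-fluid porosity limit degenerates cleanly", {
  spec <- scaffold_spec(segment_length_x = 0.4, width_y = 0.16,
                        height_z = 0.16, channel_inner_width = 0.08,
                        channel_outer_width = 0.08,
                        target_porosity = 0.9999)
  vol <- generate_scaffold_segment(spec)
  expect_true(all(vol$labels == 0L))
  expect_equal(attr(vol, "measured_porosity"), 1.0)
})

test_that("spheroid seeding respects pore space and matches target volumes", {
  fix <- small_segment()
  tab <- fix$table
  expect_gt(nrow(tab), 0)
  # molding never overwrites hydrogel and stays inside the slab
  expect_identical(sum(fix$bare$labels == 1L), sum(fix$volume$labels == 1L))
  sph <- which(fix$volume$labels == 2L)
  expect_true(all(fix$bare$labels[sph] == 0L))
  # table rows correspond one-to-one to labelled spheroids
  sm <- spheroid_morphometry(fix$volume)
  expect_identical(sm$summary$count, nrow(tab))
  # equivalent diameter closed form
  expect_equal(tab$equiv_diameter_um, (6 * tab$volume_um3 / pi)^(1 / 3))
})

test_that("a 6.0e5 um^3 spheroid has equivalent diameter 104.6 um", {
  expect_equal((6 * 6.0e5 / pi)^(1 / 3), 104.6, tolerance = 5e-4)
})

test_that("realized mean spheroid volumes match the per-CSD targets", {
  # all-pore box: molding is then unconstrained and the sample is large
  # enough (n = 50) for the 20 % band to be a real check, not noise
  vol <- labeled_volume(array(0L, dim = c(80, 80, 80)), 8, bands = c(0L, 0L))
  for (csd in c("CSD1", "CSD4")) {
    target <- seeding_spec(csd)$mean_spheroid_volume
    seeded <- seed_spheroids(vol, seeding_spec(csd, rng_seed = 3), count = 50L)
    expect_gte(nrow(seeded$table), 45)
    mv <- mean(seeded$table$volume_um3)
    expect_lt(abs(mv - target) / target, 0.20)
  }
  # sanity band on the constrained segment (only ~4 spheroids fit, so the
  # sample mean carries ~35 % standard error; the law itself is checked
  # above at n = 50)
  fix <- small_segment()
  expect_lt(abs(mean(fix$table$volume_um3) - 10.9e5) / 10.9e5, 0.5)
})

test_that("zero-count seeding is a no-op", {
  fix <- small_segment()
  out <- seed_spheroids(fix$bare, seeding_spec("CSD1"), count = 0L)
  expect_identical(out$volume$labels, fix$bare$labels)
  expect_identical(nrow(out$table), 0L)
})

test_that("spheroid centres distribute uniformly across octants", {
  # all-pore box: placement is then uniform over the whole slab
  lab <- array(0L, dim = c(64, 64, 64))
  vol <- labeled_volume(lab, 8, bands = c(0L, 0L))
  seeding <- seeding_spec("custom", cells_per_scaffold = 1e5,
                          mean_spheroid_volume = 6e4,
                          spheroid_count_full_scaffold = 100, rng_seed = 5)
  out <- seed_spheroids(vol, seeding, count = 250L)
  tab <- out$table
  expect_gte(nrow(tab), 200)
  mid <- 64 * 8 / 2
  code <- 1L + (tab$x_um > mid) + 2L * (tab$y_um > mid) + 4L * (tab$z_um > mid)
  counts <- tabulate(code, nbins = 8L)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("synthetic cell patterns follow the declared radial laws", {
  # uniform-in-ball: r^3 is uniform on [0, R^3]
  pat <- generate_cell_pattern(50, 200, 200, mode = "mixed_uniform", seed = 2)
  r3 <- rowSums(pat$points^2)^(3 / 2)
  for (ty in c("MSC", "HUVEC")) {
    ks <- stats::ks.test(r3[pat$type == ty], "punif", 0, 50^3)
    expect_gt(ks$p.value, 0.01)
  }
  # huvec_core: HUVEC count inside the core exceeds the uniform n/8 share
  pat7 <- generate_cell_pattern(50, 200, 200, mode = "huvec_core",
                                core_fraction = 0.5, seed = 2)
  rh <- sqrt(rowSums(pat7$points[pat7$type == "HUVEC", ]^2))
  n_core <- sum(rh <= 25)
  # binomial oracle: under uniformity P(X > qbinom(0.999, 200, 1/8)) < 1e-3
  expect_gt(n_core, qbinom(0.999, 200, 1 / 8))
  # MSCs stay uniform in the huvec_core mode
  rm3 <- rowSums(pat7$points[pat7$type == "MSC", ]^2)^(3 / 2)
  expect_gt(stats::ks.test(rm3, "punif", 0, 50^3)$p.value, 0.01)
  # typed edge cases
  only_h <- generate_cell_pattern(50, 0, 30, seed = 1)
  expect_true(all(only_h$type == "HUVEC"))
  expect_error(generate_cell_pattern(50, -1, 10), "n_msc")
})
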