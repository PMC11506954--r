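test_that("isotropic resampling preserves extent, identity and constants", {
  # OCT-like anisotropic stack (8 x 8 x 1.45 um) resampled to 8 um cubes
  set.seed(1)
  g <- gray_volume(array(runif(32 * 32 * 110), dim = c(32, 32, 110)),
                   c(8, 8, 1.45))
  out <- resample_isotropic(g, 8)
  expect_equal(out$spacing, rep(8, 3))
  expect_lt(abs(dim(out$intensities)[3] * 8 - 110 * 1.45), 8)
  expect_gte(min(out$intensities), min(g$intensities))
  expect_lte(max(out$intensities), max(g$intensities))
  # already isotropic at target: identity
  iso <- gray_volume(array(runif(10^3), dim = c(10, 10, 10)), rep(8, 3))
  expect_identical(resample_isotropic(iso, 8)$intensities, iso$intensities)
  # constant volume stays constant
  const <- gray_volume(array(0.7, dim = c(12, 12, 30)), c(4, 4, 2))
  expect_true(all(abs(resample_isotropic(const, 4)$intensities - 0.7) < 1e-12))
  expect_error(resample_isotropic(iso, -1), "positive")
})

test_that("pore segmentation recovers constructed cavity topology", {
  # one cubic cavity in solid: exactly one pore label
  a <- array(1, dim = c(24, 24, 24))
  a[8:16, 8:16, 8:16] <- 0
  g <- gray_volume(a, rep(8, 3))
  labs <- segment_pores(g, sigma = 0, threshold = 0.5)
  expect_identical(attr(labs, "n_labels"), 1L)

  # two cavities joined by a thin neck: watershed separates them
  b <- array(1, dim = c(44, 24, 24))
  ax <- function(c0, r) {
    for (x in (c0[1] - r):(c0[1] + r)) for (y in (c0[2] - r):(c0[2] + r))
      for (z in (c0[3] - r):(c0[3] + r))
        if ((x - c0[1])^2 + (y - c0[2])^2 + (z - c0[3])^2 <= r^2)
          b[x, y, z] <<- 0
  }
  ax(c(12, 12, 12), 7)
  ax(c(32, 12, 12), 7)
  b[18:26, 11:13, 11:13] <- 0              # neck narrower than the lobes
  gb <- gray_volume(b, rep(8, 3))
  labs2 <- segment_pores(gb, sigma = 0, threshold = 0.5)
  expect_identical(attr(labs2, "n_labels"), 2L)

  # salt-and-pepper noise is removed by despeckle: label count unchanged
  set.seed(42)
  noisy <- b
  flip <- sample(length(noisy), round(0.05 * length(noisy)))
  noisy[flip] <- 1 - noisy[flip]
  labs3 <- segment_pores(gray_volume(noisy, rep(8, 3)), sigma = 1,
                         threshold = 0.5)
  expect_identical(attr(labs3, "n_labels"), attr(labs2, "n_labels"))

  # empty pore phase fails loudly
  solid <- gray_volume(array(1, dim = c(8, 8, 8)), rep(8, 3))
  expect_error(segment_pores(solid, sigma = 0, threshold = 0.5), "empty pore")
})

test_that("segmentation is idempotent on binary noise-free input", {
  a <- array(1, dim = c(24, 24, 24))
  a[6:12, 6:12, 6:12] <- 0
  a[15:20, 15:20, 15:20] <- 0
  l1 <- segment_pores(gray_volume(a, rep(8, 3)), sigma = 0, threshold = 0.5)
  binary_again <- array(as.numeric(l1 == 0), dim = dim(l1))
  l2 <- segment_pores(gray_volume(binary_again, rep(8, 3)), sigma = 0,
                      threshold = 0.5)
  expect_identical(attr(l1, "n_labels"), attr(l2, "n_labels"))
  expect_identical(l1 > 0, l2 > 0)
})

test_that("porosity is the pore voxel fraction of the region", {
  lab <- array(0L, dim = c(10, 10, 10))
  lab[1:5, , ] <- 1L
  vol <- labeled_volume(lab, 8, bands = c(0L, 0L))
  expect_equal(porosity(vol), 0.5)
  solid <- labeled_volume(array(1L, dim = c(6, 6, 6)), 8)
  expect_equal(porosity(solid), 0.0)
  expect_error(porosity(vol, region = array(FALSE, dim = c(10, 10, 10))),
               "empty region")
  # generated scaffold matches its porosity target
  fix <- small_segment()
  expect_lt(abs(porosity(fix$bare) - fix$spec$target_porosity), 0.03)
})

test_that("pore size is the cube root of pore volume and scales with spacing", {
  # single cubic pore of side 80 um (10 voxels at 8 um)
  lab <- array(0L, dim = c(20, 20, 20))
  lab[5:14, 5:14, 5:14] <- 1L
  pst <- pore_size_table(array(as.integer(lab), dim = dim(lab)), 8)
  expect_equal(pst$table$size_um, 80)
  # doubling the spacing doubles sizes
  pst2 <- pore_size_table(array(as.integer(lab), dim = dim(lab)), 16)
  expect_equal(pst2$table$size_um, 160)
  # micropore/macropore split by the 100 um classification
  lab2 <- array(0L, dim = c(40, 26, 26))
  lab2[2:8, 2:8, 2:8] <- 1L                       # 7 vox = 56 um
  lab2[15:33, 4:22, 4:22] <- 2L                   # 19 vox = 152 um
  pst3 <- pore_size_table(array(as.integer(lab2), dim = dim(lab2)), 8)
  expect_equal(pst3$micropore_fraction, 0.5)
  expect_equal(pst3$macropore_fraction, 0.5)
})

test_that("pore volumes sum to porosity times region volume on labelled input", {
  fix <- small_segment()
  vol <- fix$bare
  r <- slab_range(vol)
  slab <- vol$labels[r[1]:r[2], , , drop = FALSE]
  labs <- .separate_pores(array(slab == 0L, dim = dim(slab)))
  pst <- pore_size_table(array(as.integer(labs), dim = dim(slab)), vol$spacing)
  region_vol <- prod(dim(slab)) * vol$spacing^3
  expect_equal(sum(pst$table$volume_um3),
               porosity(vol, count_spheroid_as_pore = FALSE) * region_vol)
})

test_that("spheroid morphometry counts disjoint balls and their volumes", {
  lab <- array(0L, dim = c(48, 20, 20))
  ball <- function(lab, c0, r) {
    ax <- seq_len(dim(lab)[1]); ay <- seq_len(dim(lab)[2]); az <- seq_len(dim(lab)[3])
    d2 <- outer(outer((ax - c0[1])^2, (ay - c0[2])^2, "+"), (az - c0[3])^2, "+")
    lab[d2 <= r^2] <- 2L
    lab
  }
  for (cx in c(8, 24, 40)) lab <- ball(lab, c(cx, 10, 10), 5)
  vol <- labeled_volume(lab, 8)
  sm <- spheroid_morphometry(vol)
  expect_identical(sm$summary$count, 3L)
  expect_equal(sd(sm$table$volume_um3), 0)
  # single ball of radius 50 um at fine spacing: equivalent diameter ~100 um
  lab2 <- array(0L, dim = c(36, 36, 36))
  lab2 <- ball(lab2, c(18, 18, 18), 12.5)          # 12.5 voxels at 4 um = 50 um radius
  sm2 <- spheroid_morphometry(labeled_volume(lab2, 4))
  expect_lt(abs(sm2$summary$mean_equiv_diameter_um - 100), 4)
  expect_error(spheroid_morphometry(labeled_volume(array(0L, c(4, 4, 4)), 8)),
               "no spheroid")
})

test_that("morphometry summaries are invariant under axis permutation", {
  fix <- small_segment()
  vol <- fix$volume
  sm <- spheroid_morphometry(vol)
  perm <- labeled_volume(aperm(vol$labels, c(3, 1, 2)), vol$spacing)
  smp <- spheroid_morphometry(perm)
  expect_identical(sm$summary$count, smp$summary$count)
  expect_equal(sort(sm$table$volume_um3), sort(smp$table$volume_um3))
})
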