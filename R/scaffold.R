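#' Scaffold segment specification
#'
#' Describes the synthetic bioreactor segment: a macroporous hydrogel slab
#' flanked in X by two pure-fluid bypass channels (the circular inner and
#' annular outer channel of the stacked-disc bioreactor, straightened to
#' bands). Targets are the hydrated-state statistics measured on OCT
#' reconstructions: porosity about 25 % and mean pore size (cube root of
#' pore volume) about 108 um.
#'
#' @param segment_length_x,width_y,height_z domain dimensions (mm); defaults
#'   are the 6.4 x 1.2 x 0.64 mm simulation segment
#' @param channel_inner_width,channel_outer_width fluid band widths (mm) at
#'   low/high X; defaults 1.75 / 1.5 mm leave a slab of about 2.6 mm
#' @param target_porosity hydrated pore volume fraction of the slab
#' @param target_mean_pore_size mean cube-root pore volume (um)
#' @param anisotropy_x correlation-length ratio of the pore network along
#'   X versus the transverse axes; freeze-drying grows lamellar ice crystals
#'   along the radial thermal gradient, leaving elongated, X-connected
#'   pores, and values well above 1 also guarantee slab-spanning pore
#'   percolation at 25 % porosity
#' @param voxel_spacing isotropic lattice spacing (um)
#' @param rng_seed integer seed; geometry, placement and size draws use
#'   named substreams derived from it
#' @return an object of class `scaffold_spec`
#' @export
scaffold_spec <- function(segment_length_x = 6.4, width_y = 1.2,
                          height_z = 0.64, channel_inner_width = 1.75,
                          channel_outer_width = 1.5,
                          target_porosity = 0.25,
                          target_mean_pore_size = 108,
                          anisotropy_x = 5, voxel_spacing = 8,
                          rng_seed = 1L) {
  stopifnot(target_porosity > 0, target_porosity < 1,
            voxel_spacing > 0, segment_length_x > 0, width_y > 0,
            height_z > 0, channel_inner_width >= 0, channel_outer_width >= 0,
            target_mean_pore_size > 0, anisotropy_x >= 1)
  if (channel_inner_width + channel_outer_width >= segment_length_x)
    stop("channel widths leave no room for the scaffold slab")
  structure(list(segment_length_x = segment_length_x, width_y = width_y,
                 height_z = height_z,
                 channel_inner_width = channel_inner_width,
                 channel_outer_width = channel_outer_width,
                 target_porosity = target_porosity,
                 target_mean_pore_size = target_mean_pore_size,
                 anisotropy_x = anisotropy_x,
                 voxel_spacing = voxel_spacing,
                 rng_seed = as.integer(rng_seed)),
            class = "scaffold_spec")
}

#' Spheroid seeding specification
#'
#' Seeding condition of a full scaffold, following the measured relation
#' between initial cell seeding density (CSD) and the spheroids formed 24 h
#' post-seeding: CSD1 (400k cells) to CSD4 (1M cells), with the measured
#' mean spheroid volumes (x 1e5 um^3: 6.0, 7.6, 6.3, 10.9) and total counts
#' (773, 805, 2384, 1368).
#'
#' @param csd_label one of "CSD1".."CSD4" (fills defaults), or "custom"
#' @param cells_per_scaffold initial cells seeded per scaffold
#' @param mean_spheroid_volume target mean spheroid volume (um^3)
#' @param spheroid_count_full_scaffold spheroid count for the whole scaffold
#' @param rng_seed integer seed
#' @return an object of class `seeding_spec`
#' @export
seeding_spec <- function(csd_label = "CSD4", cells_per_scaffold = NULL,
                         mean_spheroid_volume = NULL,
                         spheroid_count_full_scaffold = NULL,
                         rng_seed = 1L) {
  presets <- list(
    CSD1 = list(cells = 4e5, vol = 6.0e5, count = 773),
    CSD2 = list(cells = 6e5, vol = 7.6e5, count = 805),
    CSD3 = list(cells = 8e5, vol = 6.3e5, count = 2384),
    CSD4 = list(cells = 1e6, vol = 10.9e5, count = 1368))
  if (csd_label %in% names(presets)) {
    p <- presets[[csd_label]]
    if (is.null(cells_per_scaffold)) cells_per_scaffold <- p$cells
    if (is.null(mean_spheroid_volume)) mean_spheroid_volume <- p$vol
    if (is.null(spheroid_count_full_scaffold)) spheroid_count_full_scaffold <- p$count
  }
  stopifnot(cells_per_scaffold > 0, mean_spheroid_volume > 0,
            spheroid_count_full_scaffold >= 0)
  d_mean <- (6 * mean_spheroid_volume / pi)^(1 / 3)
  structure(list(csd_label = csd_label,
                 cells_per_scaffold = cells_per_scaffold,
                 mean_spheroid_volume = mean_spheroid_volume,
                 spheroid_count_full_scaffold = spheroid_count_full_scaffold,
                 spheroid_diameter_mean = d_mean,
                 rng_seed = as.integer(rng_seed)),
            class = "seeding_spec")
}

# internal: mean pore size (um) of a binary pore mask via the EDT/h-maxima
# watershed separation used by segment_pores()
.measure_mean_pore_size <- function(pore, spacing, h = 2) {
  dims <- dim(pore)
  labs <- .separate_pores(pore, h = h)
  nlab <- attr(labs, "n_labels")
  if (is.null(nlab) || nlab == 0) return(NA_real_)
  counts <- tabulate(labs[labs > 0], nbins = nlab)
  mean((counts * spacing^3)^(1 / 3))
}

# internal: EDT -> h-maxima markers -> watershed separation of a pore mask
.separate_pores <- function(pore, h = 2) {
  dims <- dim(pore)
  d2 <- edt_squared_cpp(as.logical(pore), dims)
  dist <- sqrt(d2)
  markers <- hmaxima_markers_cpp(dist, as.logical(pore), dims, h)
  labs <- watershed_cpp(dist, markers, as.logical(pore), dims)
  attr(labs, "n_labels") <- attr(markers, "n_labels")
  labs
}

#' Generate a synthetic scaffold segment
#'
#' Builds the three-part voxel geometry (inner fluid channel band, porous
#' hydrogel slab, outer fluid channel band). The pore network is synthesised
#' by thresholding a smoothed Gaussian random field at the quantile matching
#' the target porosity; the field's correlation length is tuned by bisection
#' until the measured mean pore size (via the same watershed morphometry the
#' measurement module uses) matches the target. Pore space is required to
#' percolate in X; non-percolating draws are retried on fresh substreams.
#'
#' @param spec a [scaffold_spec()]
#' @param size_tol acceptable deviation of the measured mean pore size (um)
#' @param max_iter bisection iteration cap
#' @return a [labeled_volume()]; attributes `measured_porosity` and
#'   `measured_mean_pore_size` record the achieved statistics
#' @export
generate_scaffold_segment <- function(spec, size_tol = 5, max_iter = 12) {
  stopifnot(inherits(spec, "scaffold_spec"))
  sp <- spec$voxel_spacing
  nx <- max(1L, round(spec$segment_length_x * 1000 / sp))
  ny <- max(1L, round(spec$width_y * 1000 / sp))
  nz <- max(1L, round(spec$height_z * 1000 / sp))
  n_in <- round(spec$channel_inner_width * 1000 / sp)
  n_out <- round(spec$channel_outer_width * 1000 / sp)
  nxs <- nx - n_in - n_out
  if (nxs < 4) stop("slab thinner than 4 voxels; enlarge the domain or shrink the channels")
  sdims <- c(nxs, ny, nz)

  # degenerate limit: (almost) no solid requested
  if (spec$target_porosity > 0.999) {
    lab <- array(0L, dim = c(nx, ny, nz))
    vol <- labeled_volume(lab, sp, bands = c(n_in, n_out))
    attr(vol, "measured_porosity") <- 1.0
    attr(vol, "measured_mean_pore_size") <- NA_real_
    return(vol)
  }

  target_vox <- spec$target_mean_pore_size / sp
  for (attempt in 1:10) {
    noise <- with_seed(derive_seed(spec$rng_seed, paste0("geometry", attempt)),
                       array(rnorm(prod(sdims)), dim = sdims))
    make_pore <- function(sigma) {
      g <- gaussian_blur_cpp(noise, sdims,
                             c(spec$anisotropy_x * sigma, sigma, sigma))
      thr <- quantile(g, spec$target_porosity)
      array(g < thr, dim = sdims)
    }
    lo <- 0.6; hi <- 8
    size_lo <- .measure_mean_pore_size(make_pore(lo), sp)
    size_hi <- .measure_mean_pore_size(make_pore(hi), sp)
    if (is.na(size_lo) || is.na(size_hi) ||
        size_lo > spec$target_mean_pore_size ||
        size_hi < spec$target_mean_pore_size)
      stop(sprintf(paste0("target mean pore size %.0f um unreachable: ",
                          "achievable range [%.0f, %.0f] um at porosity %.2f"),
                   spec$target_mean_pore_size, size_lo, size_hi,
                   spec$target_porosity))
    sigma <- NA; size_mid <- NA; pore <- NULL
    for (it in seq_len(max_iter)) {
      sigma <- sqrt(lo * hi)
      pore <- make_pore(sigma)
      size_mid <- .measure_mean_pore_size(pore, sp)
      if (abs(size_mid - spec$target_mean_pore_size) <= size_tol) break
      if (size_mid < spec$target_mean_pore_size) lo <- sigma else hi <- sigma
    }
    if (abs(size_mid - spec$target_mean_pore_size) > 3 * size_tol)
      stop(sprintf("pore-size tuning failed: achieved %.0f um vs target %.0f um",
                   size_mid, spec$target_mean_pore_size))

    # percolation in X: one pore component must span the slab
    comp <- label_components_cpp(as.logical(pore), sdims, 6L)
    dim(comp) <- sdims
    spanning <- intersect(unique(as.vector(comp[1, , ])),
                          unique(as.vector(comp[nxs, , ])))
    spanning <- spanning[spanning > 0]
    if (length(spanning) > 0) {
      lab <- array(0L, dim = c(nx, ny, nz))
      slab <- array(1L, dim = sdims)
      slab[pore] <- 0L
      lab[(n_in + 1):(n_in + nxs), , ] <- slab
      vol <- labeled_volume(lab, sp, bands = c(n_in, n_out))
      attr(vol, "measured_porosity") <- mean(pore)
      attr(vol, "measured_mean_pore_size") <- size_mid
      attr(vol, "grf_sigma_vox") <- sigma
      return(vol)
    }
  }
  stop("pore network failed to percolate in X after 10 attempts")
}

# internal: lognormal diameter sampler (CV 0.25, truncated to [40, 200] um)
# rescaled so that the expected sphere volume matches `target_volume`
.sample_diameters <- function(n, target_volume, cv = 0.25,
                              lim = c(40, 200)) {
  sdlog <- sqrt(log(1 + cv^2))
  mean_vol_at <- function(mu) {
    # E[(pi/6) d^3] under truncated lognormal, by quadrature
    d <- seq(lim[1], lim[2], length.out = 2048)
    f <- stats::dlnorm(d, mu, sdlog)
    w <- f / sum(f)
    sum(w * (pi / 6) * d^3)
  }
  mu <- uniroot(function(m) mean_vol_at(m) - target_volume,
                lower = log(lim[1]) - 4, upper = log(lim[2]) + 1,
                tol = 1e-8)$root
  # truncated draw by inverse CDF (robust even when the truncation window
  # sits far in a tail)
  plo <- stats::plnorm(lim[1], mu, sdlog)
  phi <- stats::plnorm(lim[2], mu, sdlog)
  stats::qlnorm(plo + (phi - plo) * runif(n), mu, sdlog)
}

#' Seed spheroids into the pore space of a scaffold segment
#'
#' Spheroid centres are drawn uniformly over pore voxels (matching the
#' measured strongly uniform distribution along all three axes); diameters
#' follow a truncated lognormal law rescaled so the expected volume matches
#' the seeding target. Each spheroid is molded to its hosting pore: it
#' acquires nearest pore voxels (never hydrogel) until its nominal volume is
#' reached, up to 2.2x its nominal radius - emulating aggregates conforming
#' to pore contours at conserved cell volume.
#'
#' @param volume a [labeled_volume()] with pore space
#' @param seeding a [seeding_spec()]
#' @param count optional explicit spheroid count for this segment; default
#'   scales the full-scaffold count by the segment/full scaffold volume ratio
#' @param full_scaffold_volume full-scaffold gel volume (mm^3); default is an
#'   annular disc 8.4 mm outer / 3.5 mm inner diameter whose thickness is
#'   twice the segment height (the segment spans a half-thickness)
#' @return list with `volume` (spheroids painted as phase 2) and `table`
#'   (data frame: id, volume_um3, equiv_diameter_um, centroid x/y/z in um)
#' @export
seed_spheroids <- function(volume, seeding, count = NULL,
                           full_scaffold_volume = NULL) {
  stopifnot(inherits(volume, "labeled_volume"), inherits(seeding, "seeding_spec"))
  sp <- volume$spacing
  dims <- dim(volume$labels)
  r <- slab_range(volume)
  if (is.null(full_scaffold_volume)) {
    thickness_mm <- 2 * dims[3] * sp / 1000
    full_scaffold_volume <- pi / 4 * (8.4^2 - 3.5^2) * thickness_mm
  }
  if (is.null(count)) {
    seg_vol_mm3 <- (r[2] - r[1] + 1) * dims[2] * dims[3] * (sp / 1000)^3
    count <- round(seeding$spheroid_count_full_scaffold *
                     seg_vol_mm3 / full_scaffold_volume)
  }
  empty_tab <- data.frame(id = integer(0), volume_um3 = numeric(0),
                          equiv_diameter_um = numeric(0),
                          x_um = numeric(0), y_um = numeric(0), z_um = numeric(0))
  if (count == 0) return(list(volume = volume, table = empty_tab))

  lab <- volume$labels
  pore_idx <- which(lab == 0L & slice.index(lab, 1) >= r[1] &
                      slice.index(lab, 1) <= r[2])
  if (length(pore_idx) == 0) stop("no pore space to seed")

  diams <- with_seed(derive_seed(seeding$rng_seed, "sizes"),
                     .sample_diameters(count, seeding$mean_spheroid_volume))
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  rows <- vector("list", count)
  placed <- 0L
  lab <- with_seed(derive_seed(seeding$rng_seed, "placement"), {
    for (i in seq_len(count)) {
      r_nom <- diams[i] / 2 / sp                     # voxels
      v_nom <- max(1L, round((pi / 6) * (diams[i] / sp)^3))  # voxels
      r_cap <- 2.2 * r_nom
      w <- as.integer(ceiling(r_cap))
      for (attempt in 1:40) {
        ctr <- sample(pore_idx, 1L)
        if (lab[ctr] != 0L) next                     # centre got occupied
        c0 <- ctr - 1L
        cx <- c0 %% nx; cy <- (c0 %/% nx) %% ny; cz <- c0 %/% (nx * ny)
        xs <- max(r[1] - 1L, cx - w):min(r[2] - 1L, cx + w)  # stay in slab X
        ys <- max(0L, cy - w):min(ny - 1L, cy + w)
        zs <- max(0L, cz - w):min(nz - 1L, cz + w)
        gx <- rep(xs, times = length(ys) * length(zs))
        gy <- rep(rep(ys, each = length(xs)), times = length(zs))
        gz <- rep(zs, each = length(xs) * length(ys))
        d2 <- (gx - cx)^2 + (gy - cy)^2 + (gz - cz)^2
        keep <- d2 <= r_cap^2
        idx <- 1L + gx[keep] + nx * (gy[keep] + ny * gz[keep])
        d2 <- d2[keep]
        free <- lab[idx] == 0L
        # clearance: reject a candidate whose molding region would touch an
        # already placed spheroid (keep aggregates individually resolvable)
        touching <- any(lab[idx[d2 <= (r_nom + 1.8)^2]] == 2L)
        idx <- idx[free]; d2 <- d2[free]
        if (touching || length(idx) < max(8L, v_nom %/% 2L)) next
        ord <- order(d2)
        take <- idx[ord[seq_len(min(v_nom, length(idx)))]]
        lab[take] <- 2L
        placed <- placed + 1L
        vol_um3 <- length(take) * sp^3
        pos <- take - 1L
        rows[[i]] <- data.frame(
          id = placed, volume_um3 = vol_um3,
          equiv_diameter_um = (6 * vol_um3 / pi)^(1 / 3),
          x_um = mean(pos %% nx + 0.5) * sp,
          y_um = mean((pos %/% nx) %% ny + 0.5) * sp,
          z_um = mean(pos %/% (nx * ny) + 0.5) * sp)
        break
      }
    }
    lab
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- empty_tab
  if (placed < count)
    warning(sprintf("requested %d spheroids, placed %d (pore space exhausted)",
                    count, placed))
  out <- labeled_volume(lab, sp, origin = volume$origin, bands = volume$bands)
  list(volume = out, table = tab)
}

#' Generate a synthetic cell-position pattern inside a spheroid
#'
#' Emulates the observed spatial organisation of the two cell types:
#' `mixed_uniform` draws MSCs and HUVECs uniformly in the spheroid ball
#' (day-1, freshly aggregated state); `huvec_core` concentrates HUVECs in a
#' central sub-ball (day-7 state after inward endothelial migration) while
#' MSCs stay uniform.
#'
#' @param spheroid_radius ball radius (um)
#' @param n_msc,n_huvec point counts per type
#' @param mode `"mixed_uniform"` or `"huvec_core"`
#' @param core_fraction core sub-ball radius as a fraction of the spheroid
#'   radius (huvec_core mode)
#' @param core_prob probability that a HUVEC falls in the core sub-ball
#'   (huvec_core mode)
#' @param seed integer seed
#' @return a `point_pattern3d`: data frame of points (um) with `type`, plus
#'   the ball window
#' @export
generate_cell_pattern <- function(spheroid_radius, n_msc, n_huvec,
                                  mode = c("mixed_uniform", "huvec_core"),
                                  core_fraction = 0.5, core_prob = 0.8,
                                  seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_msc >= 0, n_huvec >= 0, spheroid_radius > 0)
  if (mode == "huvec_core")
    stopifnot(core_fraction > 0, core_fraction < 1)
  runif_ball <- function(n, R) {
    if (n == 0) return(matrix(numeric(0), ncol = 3))
    r <- R * runif(n)^(1 / 3)
    z <- runif(n, -1, 1)
    phi <- runif(n, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    cbind(r * s * cos(phi), r * s * sin(phi), r * z)
  }
  pts <- with_seed(seed, {
    msc <- runif_ball(n_msc, spheroid_radius)
    if (mode == "mixed_uniform") {
      huv <- runif_ball(n_huvec, spheroid_radius)
    } else {
      in_core <- runif(n_huvec) < core_prob
      huv <- matrix(0, nrow = n_huvec, ncol = 3)
      if (any(in_core))
        huv[in_core, ] <- runif_ball(sum(in_core),
                                     core_fraction * spheroid_radius)
      if (any(!in_core))
        huv[!in_core, ] <- runif_ball(sum(!in_core), spheroid_radius)
    }
    rbind(msc, huv)
  })
  type <- factor(c(rep("MSC", n_msc), rep("HUVEC", n_huvec)),
                 levels = c("MSC", "HUVEC"))
  point_pattern3d(pts, type,
                  window = list(type = "ball", center = c(0, 0, 0),
                                radius = spheroid_radius))
}
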