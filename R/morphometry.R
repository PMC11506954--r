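#' Grayscale voxel volume
#'
#' Simple container for (possibly anisotropic) grayscale stacks prior to
#' isotropic resampling.
#' @param intensities 3-D numeric array
#' @param spacing per-axis voxel spacing (um), length 3
#' @return an object of class `gray_volume`
#' @export
gray_volume <- function(intensities, spacing) {
  stopifnot(length(dim(intensities)) == 3L, length(spacing) == 3L,
            all(spacing > 0), all(is.finite(intensities)))
  structure(list(intensities = intensities, spacing = as.numeric(spacing)),
            class = "gray_volume")
}

#' Resample a grayscale volume to an isotropic grid
#'
#' Trilinear interpolation onto cubic voxels of `target_spacing`, preserving
#' the physical extent of the stack within one voxel (mirrors the resampling
#' of OCT stacks to cubic 8 um voxels before analysis).
#' @param volume a [gray_volume()]
#' @param target_spacing isotropic spacing (um)
#' @return a [gray_volume()] with isotropic spacing
#' @export
resample_isotropic <- function(volume, target_spacing) {
  stopifnot(inherits(volume, "gray_volume"))
  if (target_spacing <= 0) stop("target_spacing must be positive")
  d <- dim(volume$intensities)
  if (all(volume$spacing == target_spacing)) return(volume)
  extent <- d * volume$spacing
  new_dims <- pmax(1L, as.integer(round(extent / target_spacing)))
  out <- resample_trilinear_cpp(volume$intensities, d, volume$spacing,
                                new_dims, rep(target_spacing, 3))
  gray_volume(array(out, dim = new_dims), rep(target_spacing, 3))
}

# internal: Otsu threshold from a histogram of intensities
.otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- hist(x, breaks = seq(rng[1], rng[2], length.out = nbins + 1L),
            plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Segment the pore network of a grayscale volume
#'
#' Executes the analysis chain used on OCT/microCT reconstructions:
#' Gaussian smoothing, global thresholding, despeckling (removal of
#' sub-resolution components), object separation by marker-based watershed
#' on the Euclidean distance transform, and connected-component labeling.
#'
#' @param volume a [gray_volume()] with isotropic spacing
#' @param sigma Gaussian smoothing width (voxels)
#' @param threshold global threshold; `NULL` selects it by Otsu's method on
#'   the smoothed histogram
#' @param pore_side `"dark"` if pores are darker than the gel (OCT
#'   convention) or `"bright"`
#' @param min_voxels despeckle limit: pore components smaller than this are
#'   removed (default 27 = 3^3, sub-resolution at 8 um spacing)
#' @param h h-maxima depth (voxels) for the watershed markers
#' @return integer label array (0 = solid); attribute `n_labels` gives the
#'   number of pores
#' @export
segment_pores <- function(volume, sigma = 1, threshold = NULL,
                          pore_side = c("dark", "bright"),
                          min_voxels = 27L, h = 2) {
  stopifnot(inherits(volume, "gray_volume"))
  pore_side <- match.arg(pore_side)
  if (length(unique(volume$spacing)) != 1L)
    stop("segment_pores expects an isotropic volume; run resample_isotropic first")
  dims <- dim(volume$intensities)
  sm <- if (sigma > 0)
    gaussian_blur_cpp(volume$intensities, dims, rep(sigma, 3))
  else volume$intensities
  if (is.null(threshold)) threshold <- .otsu_threshold(sm)
  pore <- if (pore_side == "dark") sm < threshold else sm > threshold
  dim(pore) <- dims
  if (!any(pore)) stop("empty pore phase after thresholding")
  # despeckle: drop connected pore components below the size limit
  cc <- label_components_cpp(as.logical(pore), dims, 26L)
  nlab <- attr(cc, "n_labels")
  if (nlab > 0) {
    sizes <- tabulate(cc[cc > 0], nbins = nlab)
    small <- which(sizes < min_voxels)
    if (length(small)) pore[array(cc %in% small, dim = dims)] <- FALSE
  }
  if (!any(pore)) stop("empty pore phase after despeckling")
  labs <- .separate_pores(array(pore, dim = dims), h = h)
  dim(labs) <- dims
  labs
}

#' Porosity of a labelled volume
#'
#' Pore (fluid) voxel fraction of the selected region. The default region is
#' the scaffold slab, excluding the bypass channel bands.
#' @param volume a [labeled_volume()]
#' @param region optional logical array selecting the region
#' @param count_spheroid_as_pore logical; spheroids occupy former pore
#'   space, so for hydrated-porosity accounting they count as pore volume
#'   (default TRUE)
#' @return porosity fraction in `[0, 1]`
#' @export
porosity <- function(volume, region = NULL, count_spheroid_as_pore = TRUE) {
  stopifnot(inherits(volume, "labeled_volume"))
  lab <- volume$labels
  if (is.null(region)) {
    r <- slab_range(volume)
    region <- slice.index(lab, 1) >= r[1] & slice.index(lab, 1) <= r[2]
  }
  if (!any(region)) stop("empty region")
  sel <- lab[region]
  if (count_spheroid_as_pore) mean(sel != 1L) else mean(sel == 0L)
}

#' Pore size table
#'
#' Per-pore volume and size; pore size is defined as the cube root of the
#' 3-D pore volume. Also reports the micropore (< 100 um) and macropore
#' (> 100 um) count fractions of the standard classification.
#'
#' @param labels integer pore-label array (0 = solid), e.g. from
#'   [segment_pores()]
#' @param spacing isotropic voxel spacing (um)
#' @return a list with `table` (data frame: id, volume_um3, size_um,
#'   centroid x/y/z um), `mean_pore_size_um`, `micropore_fraction`,
#'   `macropore_fraction`
#' @export
pore_size_table <- function(labels, spacing) {
  dims <- dim(labels)
  nlab <- max(0L, max(labels))
  if (nlab == 0L)
    return(list(table = data.frame(), mean_pore_size_um = NA_real_,
                micropore_fraction = NA_real_, macropore_fraction = NA_real_))
  st <- label_stats_cpp(as.integer(labels), dims, nlab)
  keep <- st$count > 0
  vol <- st$count[keep] * spacing^3
  size <- vol^(1 / 3)
  tab <- data.frame(id = which(keep), volume_um3 = vol, size_um = size,
                    x_um = (st$cx[keep] + 0.5) * spacing,
                    y_um = (st$cy[keep] + 0.5) * spacing,
                    z_um = (st$cz[keep] + 0.5) * spacing)
  list(table = tab,
       mean_pore_size_um = mean(size),
       micropore_fraction = mean(size < 100),
       macropore_fraction = mean(size > 100))
}

#' Spheroid morphometry
#'
#' Labels the spheroid phase by 26-connected components and summarises
#' count, mean volume and mean equivalent diameter, as reported for
#' spheroids formed 24 h post-seeding.
#' @param volume a [labeled_volume()] containing spheroid voxels (phase 2)
#' @return list with `table` (id, volume_um3, equiv_diameter_um, centroid)
#'   and `summary` (count, mean_volume_um3, mean_equiv_diameter_um)
#' @export
spheroid_morphometry <- function(volume) {
  stopifnot(inherits(volume, "labeled_volume"))
  dims <- dim(volume$labels)
  mask <- volume$labels == 2L
  if (!any(mask)) stop("no spheroid phase present")
  cc <- label_components_cpp(as.logical(mask), dims, 26L)
  nlab <- attr(cc, "n_labels")
  st <- label_stats_cpp(cc, dims, nlab)
  sp <- volume$spacing
  vol <- st$count * sp^3
  tab <- data.frame(id = seq_len(nlab), volume_um3 = vol,
                    equiv_diameter_um = (6 * vol / pi)^(1 / 3),
                    x_um = (st$cx + 0.5) * sp,
                    y_um = (st$cy + 0.5) * sp,
                    z_um = (st$cz + 0.5) * sp)
  list(table = tab,
       summary = list(count = nlab,
                      mean_volume_um3 = mean(vol),
                      mean_equiv_diameter_um = mean(tab$equiv_diameter_um)))
}
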