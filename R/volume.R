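#' Labeled voxel volume
#'
#' The shared geometry substrate of the package: a 3-D integer array of phase
#' labels (0 = fluid, 1 = hydrogel, 2 = spheroid) on an isotropic grid.
#' Axis convention: X is the radial perfusion-chamber direction (symmetry
#' plane at low X, bioreactor wall at high X), Z the bioreactor axis along
#' which the flow is driven. Y and Z are treated as periodic by the solvers.
#'
#' @param labels integer 3-D array with values in \{0, 1, 2\}
#' @param spacing isotropic voxel spacing in micrometres
#' @param origin physical coordinates (um) of the corner of voxel (1,1,1)
#' @param bands optional integer vector `c(inner, outer)`: the number of
#'   voxel layers at low/high X that form the pure-fluid bypass channels
#' @return an object of class `labeled_volume`
#' @export
labeled_volume <- function(labels, spacing, origin = c(0, 0, 0),
                           bands = c(0L, 0L)) {
  stopifnot(length(dim(labels)) == 3L, spacing > 0)
  labels <- array(as.integer(labels), dim = dim(labels))
  if (!all(labels %in% 0:2)) stop("labels must be 0 (fluid), 1 (hydrogel) or 2 (spheroid)")
  structure(
    list(labels = labels, spacing = spacing, origin = origin,
         bands = as.integer(bands)),
    class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  counts <- tabulate(x$labels + 1L, nbins = 3L)
  cat(sprintf("labeled_volume: %d x %d x %d voxels at %.3g um\n", d[1], d[2], d[3], x$spacing))
  cat(sprintf("  fluid %d | hydrogel %d | spheroid %d voxels\n",
              counts[1], counts[2], counts[3]))
  if (any(x$bands > 0))
    cat(sprintf("  channel bands: %d (inner) / %d (outer) voxel layers in X\n",
                x$bands[1], x$bands[2]))
  invisible(x)
}

#' Indices of the scaffold slab along X
#'
#' The X-range of the hydrogel slab, i.e. the volume without the fluid
#' channel bands.
#' @param volume a [labeled_volume()]
#' @return integer vector `c(first, last)` of slab X indices
#' @export
slab_range <- function(volume) {
  nx <- dim(volume$labels)[1]
  c(volume$bands[1] + 1L, nx - volume$bands[2])
}

#' Crop a volume to its scaffold slab
#'
#' Removes the bypass channel bands, returning the reduced domain used for
#' oxygen transport (Dirichlet boundary concentration is imposed on the two
#' exposed X faces).
#' @param volume a [labeled_volume()]
#' @return a [labeled_volume()] without channel bands
#' @export
crop_slab <- function(volume) {
  r <- slab_range(volume)
  lab <- volume$labels[r[1]:r[2], , , drop = FALSE]
  labeled_volume(lab, volume$spacing,
                 origin = volume$origin + c((r[1] - 1L) * volume$spacing, 0, 0))
}

#' Write / read a labeled volume as a multi-page TIFF stack
#'
#' One 8-bit page per Z slice; grid metadata travels in a JSON sidecar next
#' to the TIFF (same path with extension `.json`).
#' @param volume a [labeled_volume()]
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
write_labeled_tiff <- function(volume, path) {
  d <- dim(volume$labels)
  pages <- lapply(seq_len(d[3]), function(z) {
    # tiff expects [row, col] images in [0, 1]; store label/255
    t(volume$labels[, , z]) / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  meta <- list(spacing_um = volume$spacing, origin_um = volume$origin,
               dim = d, bands = volume$bands,
               axis_convention = "X radial, Z bioreactor axis")
  jsonlite::write_json(meta, sub("\\.tiff?$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_labeled_tiff
#' @export
read_labeled_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(sub("\\.tiff?$", ".json", path),
                              simplifyVector = TRUE)
  d <- as.integer(meta$dim)
  lab <- array(0L, dim = d)
  for (z in seq_len(d[3])) lab[, , z] <- as.integer(round(t(pages[[z]]) * 255))
  labeled_volume(lab, as.numeric(meta$spacing_um),
                 origin = as.numeric(meta$origin_um),
                 bands = as.integer(meta$bands))
}

#' Export scalar or label fields as legacy VTK structured points
#'
#' ASCII legacy VTK, suitable for ParaView. Fields are written as point data
#' on the voxel grid.
#' @param fields named list of 3-D arrays (all the same dimension)
#' @param spacing voxel spacing (um)
#' @param path output `.vtk` path
#' @param origin grid origin (um)
#' @return `path`, invisibly
#' @export
write_vtk_points <- function(fields, spacing, path, origin = c(0, 0, 0)) {
  stopifnot(length(fields) >= 1, !is.null(names(fields)))
  d <- dim(fields[[1]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "perfuscaff field export", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %g %g %g", origin[1], origin[2], origin[3]),
               sprintf("SPACING %g %g %g", spacing, spacing, spacing),
               sprintf("POINT_DATA %d", prod(d))), con)
  for (nm in names(fields)) {
    stopifnot(identical(dim(fields[[nm]]), d))
    writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(format(as.vector(fields[[nm]]), trim = TRUE, digits = 7), con)
  }
  invisible(path)
}
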