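#' Classify solid-adjacent fluid nodes into anatomical wall regions
#'
#' Every fluid node with a solid voxel among its D3Q19 link neighbours is a
#' boundary node. Nodes adjacent to the no-slip X_max plane are tagged
#' `bioreactor_wall`; nodes inside the inner/outer channel bands facing the
#' scaffold are `inner_periphery` / `outer_periphery`; solid adjacency
#' within the slab is `pore_wall`.
#'
#' @param volume a [labeled_volume()]
#' @return data frame: `index` (1-based voxel index), `region` factor
#' @export
classify_boundary_regions <- function(volume) {
  stopifnot(inherits(volume, "labeled_volume"))
  lab <- volume$labels
  dims <- dim(lab)
  nx <- dims[1]
  solid <- lab != 0L
  # D3Q19 link neighbours = 18-neighbourhood
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) %in% c(1, 2), ]
  near_solid <- array(FALSE, dim = dims)
  for (k in seq_len(nrow(offs))) {
    sh <- .shift_array(solid, c(offs$dx[k], offs$dy[k], offs$dz[k]))
    near_solid <- near_solid | sh
  }
  at_wall <- slice.index(lab, 1) == nx                      # X_max plane
  fluid <- lab == 0L
  boundary <- fluid & (near_solid | at_wall)
  idx <- which(boundary)
  x <- ((idx - 1L) %% nx) + 1L
  r <- slab_range(volume)
  region <- rep("pore_wall", length(idx))
  region[x < r[1]] <- "inner_periphery"
  region[x > r[2]] <- "outer_periphery"
  region[x == nx] <- "bioreactor_wall"
  data.frame(index = idx,
             region = factor(region,
                             levels = c("pore_wall", "inner_periphery",
                                        "outer_periphery", "bioreactor_wall")))
}

# internal: shift a logical array by (dx, dy, dz), padding with FALSE
.shift_array <- function(a, d) {
  dims <- dim(a)
  out <- array(FALSE, dim = dims)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    n <- dims[ax]
    if (d[ax] >= 0) {
      src[[ax]] <- seq_len(n - d[ax])
      dst[[ax]] <- seq_len(n - d[ax]) + d[ax]
    } else {
      src[[ax]] <- seq_len(n + d[ax]) - d[ax]
      dst[[ax]] <- seq_len(n + d[ax])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Estimate local wall normals at boundary nodes
#'
#' Staircase-robust local detection: the normal at a solid-adjacent fluid
#' node is the normalised negative sum of offset vectors to all solid voxels
#' within a cubic window of radius `r_n`, pointing into the fluid. A zero
#' resultant (pathological symmetric cavity) falls back to the nearest solid
#' link direction.
#'
#' @param volume a [labeled_volume()]
#' @param nodes 1-based voxel indices of boundary-adjacent fluid nodes
#' @param r_n window radius in voxels (default 3)
#' @param faces face boundary codes as used by the flow solver (default:
#'   symmetry at X-, no-slip wall at X+, periodic Y/Z)
#' @return matrix of unit normals (one row per node)
#' @export
estimate_wall_normals <- function(volume, nodes, r_n = 3L,
                                  faces = c(2L, 1L, 0L, 0L, 0L, 0L)) {
  stopifnot(inherits(volume, "labeled_volume"))
  wall_normals_cpp(as.integer(volume$labels), dim(volume$labels),
                   as.integer(nodes), as.integer(r_n), as.integer(faces))
}

#' Compute the wall-shear-stress field
#'
#' Evaluates the deviatoric viscous stress tensor at every boundary-adjacent
#' fluid node from the second moment of the non-equilibrium populations of
#' the converged flow, converts it to physical units
#' (`sigma_phys = sigma_lat * rho * dx^2 / dt^2`), and takes the WSS modulus
#' as the magnitude of the tangential projection of the traction:
#' `tau = | sigma.n - (n . sigma.n) n |`.
#'
#' @param flow a converged `flow_field` from [run_flow()]
#' @param volume the [labeled_volume()] the flow was run on
#' @param regions optional result of [classify_boundary_regions()]
#' @param r_n wall-normal window radius (voxels)
#' @return an object of class `wss_field`: data frame with node index,
#'   region, normal components and `tau_pa`
#' @export
compute_wss <- function(flow, volume, regions = NULL, r_n = 3L) {
  stopifnot(inherits(flow, "flow_field"))
  if (!flow$converged)
    stop("flow field did not meet its convergence criterion; rerun with more steps")
  if (is.null(regions)) regions <- classify_boundary_regions(volume)
  cfg <- flow$config
  fvec <- c(0, 0, 0)
  fvec[match(flow$force_axis, c("x", "y", "z"))] <-
    flow$body_force * cfg$dt^2 / (cfg$dx * cfg$rho)
  sig <- stress_from_populations_cpp(flow$f, flow$n_fluid, fvec, cfg$s1, cfg$s2)
  scale <- cfg$rho * cfg$dx^2 / cfg$dt^2
  # map boundary voxel indices onto fluid-node rows
  row_of <- integer(prod(flow$dims))
  row_of[flow$fluid_index] <- seq_len(flow$n_fluid)
  rows <- row_of[regions$index]
  keep <- rows > 0
  regions <- regions[keep, , drop = FALSE]
  rows <- rows[keep]
  nrm <- estimate_wall_normals(volume, regions$index, r_n = r_n,
                               faces = flow$faces)
  s <- sig[rows, , drop = FALSE] * scale
  # traction t = sigma . n (symmetric tensor stored xx,yy,zz,xy,xz,yz)
  tx <- s[, 1] * nrm[, 1] + s[, 4] * nrm[, 2] + s[, 5] * nrm[, 3]
  ty <- s[, 4] * nrm[, 1] + s[, 2] * nrm[, 2] + s[, 6] * nrm[, 3]
  tz <- s[, 5] * nrm[, 1] + s[, 6] * nrm[, 2] + s[, 3] * nrm[, 3]
  tn <- tx * nrm[, 1] + ty * nrm[, 2] + tz * nrm[, 3]
  tau <- sqrt(pmax(0, (tx - tn * nrm[, 1])^2 + (ty - tn * nrm[, 2])^2 +
                     (tz - tn * nrm[, 3])^2))
  structure(data.frame(index = regions$index, region = regions$region,
                       nx = nrm[, 1], ny = nrm[, 2], nz = nrm[, 3],
                       tau_pa = tau),
            class = c("wss_field", "data.frame"))
}

#' Region-wise WSS summary
#'
#' Unweighted arithmetic mean (plus max and node count) of the WSS modulus
#' over the nodes of one region, or of all regions at once.
#' @param field a `wss_field` from [compute_wss()]
#' @param region region name, or `NULL` for a summary of every region
#' @return data frame: region, mean_tau_pa, max_tau_pa, n_nodes
#' @export
region_mean_wss <- function(field, region = NULL) {
  stopifnot(inherits(field, "wss_field"))
  if (!is.null(region)) {
    sel <- field$region == region
    if (!any(sel)) stop(sprintf("region '%s' has no boundary nodes", region))
    return(data.frame(region = region,
                      mean_tau_pa = mean(field$tau_pa[sel]),
                      max_tau_pa = max(field$tau_pa[sel]),
                      n_nodes = sum(sel)))
  }
  do.call(rbind, lapply(levels(field$region), function(rg) {
    sel <- field$region == rg
    if (!any(sel))
      return(data.frame(region = rg, mean_tau_pa = NA_real_,
                        max_tau_pa = NA_real_, n_nodes = 0L))
    data.frame(region = rg, mean_tau_pa = mean(field$tau_pa[sel]),
               max_tau_pa = max(field$tau_pa[sel]), n_nodes = sum(sel))
  }))
}
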