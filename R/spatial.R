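#' Typed 3-D point pattern
#'
#' @param points matrix or data frame with 3 columns (x, y, z in um)
#' @param type factor (or character) of cell types per point, levels
#'   `MSC`/`HUVEC`
#' @param window observation window: `list(type = "box", L = c(Lx, Ly, Lz),
#'   origin = c(0,0,0))` or `list(type = "ball", center, radius)`
#' @return an object of class `point_pattern3d`
#' @export
point_pattern3d <- function(points, type, window) {
  pts <- as.matrix(points)
  if (length(pts) == 0) pts <- matrix(numeric(0), ncol = 3)
  stopifnot(ncol(pts) == 3, window$type %in% c("box", "ball"))
  type <- factor(type, levels = union(c("MSC", "HUVEC"), unique(as.character(type))))
  stopifnot(length(type) == nrow(pts))
  if (nrow(pts) > 0) {
    if (window$type == "box") {
      org <- if (is.null(window$origin)) c(0, 0, 0) else window$origin
      ok <- all(pts >= matrix(org, nrow(pts), 3, byrow = TRUE) - 1e-9) &&
        all(pts <= matrix(org + window$L, nrow(pts), 3, byrow = TRUE) + 1e-9)
    } else {
      d <- sqrt(rowSums(sweep(pts, 2, window$center)^2))
      ok <- all(d <= window$radius + 1e-9)
    }
    if (!ok) stop("points outside the declared window")
  }
  structure(list(points = pts, type = type, window = window),
            class = "point_pattern3d")
}

#' @export
print.point_pattern3d <- function(x, ...) {
  cat(sprintf("point_pattern3d: %d points (%s) in a %s window\n",
              nrow(x$points),
              paste(sprintf("%s: %d", levels(x$type), table(x$type)),
                    collapse = ", "),
              x$window$type))
  invisible(x)
}

.window_volume <- function(window) {
  if (window$type == "box") prod(window$L)
  else 4 / 3 * pi * window$radius^3
}

#' Detect fluorescent-cluster maxima in a single-channel stack
#'
#' Moves from pixel- to object-oriented analysis: 3-D local maxima above an
#' intensity floor mark cell-representing fluorescent clusters. Maxima are
#' greedily suppressed (brightest kept, ties broken by lexicographic voxel
#' order) so that no two retained points lie closer than `min_separation` -
#' by default the rendered cell size of the channel's type (15 um MSC,
#' 7 um HUVEC).
#'
#' @param volume a [gray_volume()] (single channel, calibrated spacing)
#' @param type cell type of the channel (`"MSC"` red / `"HUVEC"` green)
#' @param min_separation minimal distance between retained maxima (um);
#'   default = cell size of `type`
#' @param intensity_floor minimum intensity of a retained maximum
#' @return a [point_pattern3d()] with the stack extent as box window
#' @export
detect_maxima_3d <- function(volume, type = c("MSC", "HUVEC"),
                             min_separation = NULL, intensity_floor = 0) {
  stopifnot(inherits(volume, "gray_volume"))
  type <- match.arg(type)
  if (is.null(min_separation))
    min_separation <- cell_size_convention()[[type]]
  dims <- dim(volume$intensities)
  idx <- local_maxima_cpp(volume$intensities, dims, intensity_floor)
  window <- list(type = "box", L = dims * volume$spacing, origin = c(0, 0, 0))
  if (length(idx) == 0)
    return(point_pattern3d(matrix(numeric(0), ncol = 3),
                           factor(character(0), levels = c("MSC", "HUVEC")),
                           window))
  vals <- volume$intensities[idx + 1L]
  ord <- order(-vals, idx)            # brightest first, lex tie-break
  idx <- idx[ord]
  x <- (idx %% dims[1] + 0.5) * volume$spacing[1]
  y <- ((idx %/% dims[1]) %% dims[2] + 0.5) * volume$spacing[2]
  z <- (idx %/% (dims[1] * dims[2]) + 0.5) * volume$spacing[3]
  pts <- cbind(x, y, z)
  keep <- logical(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- colSums((t(pts[keep, , drop = FALSE]) - pts[i, ])^2)
    if (min(d2) >= min_separation^2) keep[i] <- TRUE
  }
  pts <- pts[keep, , drop = FALSE]
  point_pattern3d(pts, factor(rep(type, nrow(pts)), levels = c("MSC", "HUVEC")),
                  window)
}

#' Rendered cell sizes per type
#'
#' Convention used to render detected maxima as objects of realistic cell
#' size: 15 um MSCs, 7 um HUVECs.
#' @return named list of sizes (um)
#' @export
cell_size_convention <- function() list(MSC = 15, HUVEC = 7)

#' Ripley's K function for a 3-D point pattern
#'
#' `K(r) = (1/lambda) E[number of further same-type points within distance
#' r of a typical point]`, estimated with `lambda = n / V` and an edge
#' correction: translation correction for box windows, exact isotropic
#' (spherical-cap) correction for ball windows. Under complete spatial
#' randomness `K(r) = 4 pi r^3 / 3`.
#'
#' @param pattern a [point_pattern3d()]
#' @param type which type to analyse (types are analysed independently);
#'   `NULL` uses all points
#' @param r distance grid (um); `r_max` must not exceed half the shortest
#'   window side (box) or the window radius (ball)
#' @return an object of class `k_estimate`: data frame `r`, `k`, `k_pois`
#'   with metadata attributes
#' @export
ripley_k3 <- function(pattern, type = NULL, r = NULL) {
  stopifnot(inherits(pattern, "point_pattern3d"))
  pts <- pattern$points
  if (!is.null(type)) pts <- pts[pattern$type == type, , drop = FALSE]
  n <- nrow(pts)
  if (n < 2) stop("need at least 2 points of the requested type")
  win <- pattern$window
  rmax_bound <- if (win$type == "box") min(win$L) / 2 else win$radius
  if (is.null(r)) r <- seq(0, rmax_bound / 2, length.out = 64L)
  if (max(r) > rmax_bound + 1e-9)
    stop(sprintf("r_max = %.3g exceeds the window bound %.3g", max(r), rmax_bound))
  V <- .window_volume(win)
  counts <- if (win$type == "box") {
    org <- if (is.null(win$origin)) c(0, 0, 0) else win$origin
    k3_box_counts_cpp(sweep(pts, 2, org), as.numeric(r), as.numeric(win$L))
  } else {
    k3_ball_counts_cpp(pts, as.numeric(r), as.numeric(win$center), win$radius)
  }
  lambda <- n / V
  k <- counts / (lambda * n)
  out <- data.frame(r = r, k = k, k_pois = 4 / 3 * pi * r^3)
  structure(out, class = c("k_estimate", "data.frame"),
            n = n, volume = V, lambda = lambda,
            correction = if (win$type == "box") "translation" else "isotropic",
            type = if (is.null(type)) "all" else as.character(type),
            window = win)
}

#' Pool K estimates across replicates
#'
#' Replicated point patterns (multiple spheroids per condition) are pooled
#' by the standard weighted average with weights proportional to the
#' squared point counts.
#' @param estimates list of `k_estimate` objects on a common r grid and type
#' @return the pooled `k_estimate`
#' @export
pool_k <- function(estimates) {
  stopifnot(length(estimates) >= 1,
            all(vapply(estimates, inherits, logical(1), "k_estimate")))
  r0 <- estimates[[1]]$r
  for (e in estimates)
    if (!isTRUE(all.equal(e$r, r0))) stop("replicates must share the r grid")
  tys <- vapply(estimates, attr, character(1), "type")
  if (length(unique(tys)) != 1) stop("replicates must share the type label")
  ns <- vapply(estimates, function(e) as.numeric(attr(e, "n")), numeric(1))
  w <- ns^2 / sum(ns^2)
  k <- Reduce(`+`, Map(function(e, wi) wi * e$k, estimates, w))
  out <- data.frame(r = r0, k = k, k_pois = estimates[[1]]$k_pois)
  structure(out, class = c("k_estimate", "data.frame"),
            n = sum(ns), replicate_ns = ns,
            volume = attr(estimates[[1]], "volume"),
            lambda = NA_real_, correction = attr(estimates[[1]], "correction"),
            type = tys[1], window = attr(estimates[[1]], "window"),
            n_replicates = length(estimates))
}

#' Monte-Carlo envelope of K under complete spatial randomness
#'
#' Simulates `nsim` binomial (CSR) patterns at matched point count and
#' window and returns the rank-based pointwise envelope: the `rank`-th
#' smallest and largest simulated K at each r, giving exact two-sided
#' non-coverage `2 rank / (nsim + 1)` for a CSR pattern.
#' @param n point count, or a vector of replicate point counts: each
#'   simulation then draws that many CSR patterns and pools their K
#'   estimates exactly as [pool_k()] does, so pooled estimates are compared
#'   against an envelope with the pooled sampling distribution
#' @param window observation window (as in [point_pattern3d()])
#' @param r distance grid
#' @param nsim number of CSR simulations (default 99)
#' @param rank envelope rank (default 2: ~96 % envelope at nsim = 99;
#'   use nsim = 199, rank = 5 for an exact 95 % envelope)
#' @param seed RNG seed
#' @return data frame `r`, `lo`, `hi`, `k_pois`
#' @export
csr_envelope <- function(n, window, r, nsim = 99L, rank = 2L, seed = 1L) {
  stopifnot(all(n >= 2), nsim >= 2 * rank)
  one_k <- function(nn) {
    pts <- .runif_window(nn, window)
    pat <- point_pattern3d(pts, factor(rep("MSC", nn),
                                       levels = c("MSC", "HUVEC")), window)
    ripley_k3(pat, type = NULL, r = r)
  }
  sims <- with_seed(seed, {
    vapply(seq_len(nsim), function(s) {
      if (length(n) == 1L) one_k(n)$k
      else pool_k(lapply(n, one_k))$k
    }, numeric(length(r)))
  })
  lo <- apply(sims, 1, function(v) sort(v)[rank])
  hi <- apply(sims, 1, function(v) sort(v, decreasing = TRUE)[rank])
  data.frame(r = r, lo = lo, hi = hi, k_pois = 4 / 3 * pi * r^3)
}

# internal: uniform points in a window
.runif_window <- function(n, window) {
  if (window$type == "box") {
    org <- if (is.null(window$origin)) c(0, 0, 0) else window$origin
    cbind(runif(n, org[1], org[1] + window$L[1]),
          runif(n, org[2], org[2] + window$L[2]),
          runif(n, org[3], org[3] + window$L[3]))
  } else {
    R <- window$radius * runif(n)^(1 / 3)
    z <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi); s <- sqrt(1 - z^2)
    sweep(cbind(R * s * cos(phi), R * s * sin(phi), R * z), 2,
          window$center, "+")
  }
}

#' Classify a K estimate against the Poisson reference
#'
#' Compares the observed K at distance `r` with the CSR value
#' `4 pi r^3 / 3` through a Monte-Carlo envelope at matched point count and
#' window: above the envelope = clustered, below = dispersed, inside = CSR.
#' @param estimate a `k_estimate`
#' @param r the distance at which to classify (must be on the grid)
#' @param nsim,rank envelope parameters (see [csr_envelope()])
#' @param seed RNG seed for the envelope
#' @return factor level among `clustered`, `dispersed`, `CSR`
#' @export
classify_vs_poisson <- function(estimate, r, nsim = 99L, rank = 2L,
                                seed = 1L) {
  stopifnot(inherits(estimate, "k_estimate"))
  i <- which(abs(estimate$r - r) < 1e-9)
  if (length(i) != 1) stop("r is not on the estimate's grid")
  n_env <- attr(estimate, "replicate_ns")
  if (is.null(n_env)) n_env <- attr(estimate, "n")
  env <- csr_envelope(n_env, attr(estimate, "window"),
                      estimate$r, nsim = nsim, rank = rank, seed = seed)
  k <- estimate$k[i]
  out <- if (k > env$hi[i]) "clustered" else if (k < env$lo[i]) "dispersed" else "CSR"
  factor(out, levels = c("clustered", "dispersed", "CSR"))
}
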