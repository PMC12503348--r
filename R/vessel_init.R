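# Initial capillary network: synthetic plexus masks, distance-transform /
# skeleton radius estimation, and reconstruction of the phase field from a
# binary 2D segmentation (in 2D directly, in 3D as a union of balls of the
# local radius centered on the skeleton at a chosen depth).

#' Binary vessel mask
#'
#' @param pixels Binary matrix (1 = vessel), indexed `[ix, iy]` with x along
#'   rows, y along columns.
#' @param pixel_size Pixel size in micrometres.
#' @param provenance Free-text tag (e.g. "synthetic").
#' @return An object of class `rh_mask`.
#' @export
vessel_mask <- function(pixels, pixel_size, provenance = "unspecified") {
  stopifnot(is.matrix(pixels), pixel_size > 0)
  pixels <- (pixels != 0) + 0
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 provenance = provenance), class = "rh_mask")
}

#' @export
print.rh_mask <- function(x, ...) {
  cat(sprintf("<rh_mask> %d x %d px @ %g um/px, vessel fraction %.3f (%s)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              mean(x$pixels), x$provenance))
  invisible(x)
}

# 1D squared-distance transform (Felzenszwalb & Huttenlocher lower envelope)
dt1d <- function(f) {
  n <- length(f)
  d <- numeric(n)
  v <- integer(n); z <- numeric(n + 1)
  k <- 1L
  v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
      if (s <= z[k]) { k <- k - 1L } else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Euclidean distance transform of a binary mask
#'
#' Exact distance (in pixels) from each vessel pixel to the nearest
#' background pixel; 0 on the background.
#'
#' @param pixels Binary matrix (1 = vessel).
#' @return Matrix of distances in pixel units.
#' @export
distance_transform <- function(pixels) {
  big <- 1e12
  f <- ifelse(pixels != 0, big, 0)
  if (all(f == 0)) return(f)
  if (all(pixels != 0)) {
    warning("distance_transform: mask has no background pixel")
    return(matrix(sqrt(big), nrow(pixels), ncol(pixels)))
  }
  g <- apply(f, 2, dt1d)              # along x (rows)
  g <- t(apply(g, 1, dt1d))           # along y (columns)
  sqrt(g)
}

# 3x3 neighbour extraction via zero-padded shifts; returns a list of 8
# matrices P2..P9 ordered clockwise starting north (row-1 direction).
.shift <- function(m, di, dj) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(0, n1, n2)
  si <- max(1, 1 + di):min(n1, n1 + di)
  sj <- max(1, 1 + dj):min(n2, n2 + dj)
  out[si, sj] <- m[si - di, sj - dj]
  out
}

#' Morphological skeleton (Zhang-Suen thinning)
#'
#' Iterative thinning of the vessel region to a 1-pixel-wide medial curve.
#'
#' @param pixels Binary matrix (1 = vessel).
#' @return Binary matrix of skeleton pixels.
#' @export
skeletonize <- function(pixels) {
  img <- (pixels != 0) + 0
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      P <- lapply(offs, function(o) .shift(img, o[1], o[2]))
      B <- Reduce(`+`, P)
      seqP <- c(P, P[1])
      A <- 0
      for (k in 1:8) A <- A + (seqP[[k]] == 0 & seqP[[k + 1]] == 1)
      if (pass == 1) {
        cond <- P[[1]] * P[[3]] * P[[5]] == 0 & P[[3]] * P[[5]] * P[[7]] == 0
      } else {
        cond <- P[[1]] * P[[3]] * P[[7]] == 0 & P[[1]] * P[[5]] * P[[7]] == 0
      }
      del <- img == 1 & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) {
        img[del] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}

#' Local vessel radius map
#'
#' Euclidean distance transform of the vessel region restricted to the
#' medial-axis skeleton (zero off-skeleton), in micrometres: each skeleton
#' pixel carries the local half-width of the vessel it belongs to.
#'
#' @param mask An `rh_mask`.
#' @return Matrix of radii in micrometres.
#' @export
local_radius <- function(mask) {
  stopifnot(inherits(mask, "rh_mask"))
  edt <- distance_transform(mask$pixels)
  skel <- skeletonize(mask$pixels)
  edt * skel * mask$pixel_size
}

# node index (1-based) of the pixel containing position `pos_um`, ties on a
# pixel border broken toward the lower index
.pos_to_pixel <- function(pos_um, pixel_size, npx) {
  px <- floor(pos_um / pixel_size - 1e-9) + 1
  pmin(pmax(px, 1), npx)
}

#' Reconstruct a 2D phase field from a mask
#'
#' Maps the binary raster onto the grid: `c = +1` at nodes whose position
#' falls in a vessel pixel, `-1` elsewhere.
#'
#' @param mask An `rh_mask`.
#' @param domain A 2D `rh_domain`.
#' @param units [unit_system()] used to convert node coordinates (sau) to
#'   micrometres.
#' @return Field array with values in \{-1, +1\}.
#' @export
reconstruct_field_2d <- function(mask, domain, units = unit_system()) {
  stopifnot(inherits(mask, "rh_mask"), domain$dim == 2)
  npx <- dim(mask$pixels)
  cover_um <- npx * mask$pixel_size
  extent_um <- domain$extent * units$sau
  if (any(extent_um > cover_um * (1 + 1e-6))) {
    stop(sprintf(
      "mask (%g x %g um) does not cover the domain (%g x %g um)",
      cover_um[1], cover_um[2], extent_um[1], extent_um[2]), call. = FALSE)
  }
  ax <- grid_axes(domain)
  ix <- .pos_to_pixel((ax[[1]] - domain$origin[1]) * units$sau,
                      mask$pixel_size, npx[1])
  iy <- .pos_to_pixel((ax[[2]] - domain$origin[2]) * units$sau,
                      mask$pixel_size, npx[2])
  2 * mask$pixels[ix, iy, drop = FALSE] - 1
}

#' Reconstruct a 3D phase field from a 2D mask
#'
#' Places the skeleton of the mask at depth `z0` and sets `c = +1` at every
#' node within the local radius of a skeleton point (union of balls carried
#' along the skeleton), `-1` elsewhere.  Projected onto the `z0` plane this
#' recovers the 2D vessel region to within a grid cell.
#'
#' @param mask An `rh_mask`.
#' @param domain A 3D `rh_domain`.
#' @param z0 Axial placement of the vessel plane, sau (default mid-depth).
#' @param units [unit_system()].
#' @return Field array with values in \{-1, +1\}.
#' @export
reconstruct_field_3d <- function(mask, domain, z0 = NULL,
                                 units = unit_system()) {
  stopifnot(inherits(mask, "rh_mask"), domain$dim == 3)
  if (is.null(z0)) z0 <- domain$origin[3] + domain$extent[3] / 2
  if (z0 < domain$origin[3] || z0 > domain$origin[3] + domain$extent[3]) {
    stop("z0 outside the domain axial extent", call. = FALSE)
  }
  rad_um <- local_radius(mask)
  skel_idx <- which(rad_um > 0, arr.ind = TRUE)
  cf <- empty_field(domain, fill = -1)
  if (nrow(skel_idx) == 0) return(cf)
  h_um <- domain$h * units$sau
  n <- domain$n
  origin_um <- domain$origin * units$sau
  z0_um <- z0 * units$sau
  # skeleton point centers in um (pixel centers)
  px <- mask$pixel_size
  centers <- cbind((skel_idx[, 1] - 0.5) * px,
                   (skel_idx[, 2] - 0.5) * px,
                   z0_um)
  radii <- rad_um[skel_idx]
  stride <- cumprod(c(1, n[-3]))
  for (i in seq_len(nrow(centers))) {
    ctr <- centers[i, ]
    r <- radii[i]
    lo <- pmax(floor((ctr - r - origin_um) / h_um) + 1, 1)
    hi <- pmin(ceiling((ctr + r - origin_um) / h_um) + 1, n)
    if (any(lo > hi)) next
    idx <- lapply(1:3, function(k) lo[k]:hi[k])
    sub <- as.matrix(do.call(expand.grid, idx))
    posn <- sweep((sub - 1) * h_um, 2, origin_um, `+`)
    inside <- rowSums((posn - matrix(ctr, nrow(sub), 3, byrow = TRUE))^2) <=
      r^2
    if (!any(inside)) next
    lin <- as.vector((sub[inside, , drop = FALSE] - 1) %*% stride) + 1
    cf[lin] <- 1
  }
  cf
}

#' Generate a synthetic planar capillary plexus
#'
#' Produces a reproducible binary mask of smooth, non-overlapping vessel
#' paths of prescribed widths that avoid an avascular disk (the future
#' tumor site).  Paths are gently curved lines (sinusoidal perturbation of
#' a chord) kept outside the disk by construction; a bounded retry loop
#' rejects paths that overlap previously placed vessels.
#'
#' @param n_vessels Number of vessels.
#' @param width_range Vessel width range in micrometres, `c(min, max)`.
#' @param size_px Mask side lengths in pixels, `c(nx, ny)` (scalar
#'   recycled).
#' @param pixel_size Pixel size, micrometres.
#' @param avascular_center Disk center in micrometres (default mask
#'   center).
#' @param avascular_radius Disk radius in micrometres.
#' @param seed RNG seed; identical seeds give bitwise-identical masks.
#' @param max_retries Retries per vessel before declaring the spec
#'   infeasible.
#' @return An `rh_mask` with provenance `"synthetic"`.
#' @export
synth_plexus <- function(n_vessels = 4, width_range = c(8, 16),
                         size_px = 256, pixel_size = 2,
                         avascular_center = NULL, avascular_radius = 100,
                         seed = 1L, max_retries = 50) {
  stopifnot(all(width_range > 0), n_vessels >= 1)
  size_px <- rep(as.integer(size_px), length.out = 2)
  ext <- size_px * pixel_size
  if (is.null(avascular_center)) avascular_center <- ext / 2
  with_seed(seed, {
    pixels <- matrix(0, size_px[1], size_px[2])
    widths <- seq(width_range[1], width_range[2],
                  length.out = n_vessels)
    paths <- list()
    diag_len <- sqrt(sum(ext^2))
    for (v in seq_len(n_vessels)) {
      w <- widths[v]
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        theta <- stats::runif(1, 0, 2 * pi)
        # signed offset of the chord from the disk center
        margin <- avascular_radius + w / 2 + 2 * pixel_size
        d_off <- stats::runif(1, margin, margin + 0.35 * diag_len)
        side <- sample(c(-1, 1), 1)
        nrm <- c(cos(theta), sin(theta))
        tang <- c(-sin(theta), cos(theta))
        amp <- stats::runif(1, 0, 0.5 * (d_off - margin))
        freq <- stats::runif(1, 1, 3)
        phase <- stats::runif(1, 0, 2 * pi)
        s <- seq(-diag_len, diag_len, by = pixel_size / 2)
        wob <- amp * sin(2 * pi * freq * s / diag_len + phase)
        pts <- cbind(
          avascular_center[1] + side * nrm[1] * (d_off + wob) + tang[1] * s,
          avascular_center[2] + side * nrm[2] * (d_off + wob) + tang[2] * s)
        keep <- pts[, 1] > -w & pts[, 1] < ext[1] + w &
          pts[, 2] > -w & pts[, 2] < ext[2] + w
        pts <- pts[keep, , drop = FALSE]
        if (nrow(pts) < 4) next
        # reject paths that would merge with an existing vessel
        clear <- TRUE
        for (j in seq_along(paths)) {
          dmin <- min_path_dist(pts, paths[[j]]$pts)
          if (dmin < (w + paths[[j]]$w) / 2 + 2 * pixel_size) {
            clear <- FALSE
            break
          }
        }
        if (!clear) next
        pixels <- stamp_path(pixels, pts, w / 2, pixel_size)
        paths[[length(paths) + 1]] <- list(pts = pts, w = w)
        placed <- TRUE
        break
      }
      if (!placed) {
        stop(sprintf(paste("synth_plexus: could not place vessel %d after",
                           "%d retries; spec may be infeasible"),
                     v, max_retries), call. = FALSE)
      }
    }
    vessel_mask(pixels, pixel_size, provenance = "synthetic")
  })
}

# min distance between two sampled polylines (coarse but adequate: samples
# every pixel_size/2)
min_path_dist <- function(a, b) {
  # subsample for speed
  ai <- a[seq(1, nrow(a), by = 4), , drop = FALSE]
  bi <- b[seq(1, nrow(b), by = 4), , drop = FALSE]
  min(sqrt(outer(ai[, 1], bi[, 1], `-`)^2 + outer(ai[, 2], bi[, 2], `-`)^2))
}

# stamp disks of radius r (um) at each path sample onto the pixel matrix
stamp_path <- function(pixels, pts, r, pixel_size) {
  n1 <- nrow(pixels); n2 <- ncol(pixels)
  rp <- r / pixel_size
  rint <- ceiling(rp)
  offs <- as.matrix(expand.grid(-rint:rint, -rint:rint))
  offs <- offs[rowSums(offs^2) <= rp^2, , drop = FALSE]
  ctr <- cbind(ceiling(pts[, 1] / pixel_size - 0.5),
               ceiling(pts[, 2] / pixel_size - 0.5))
  ctr <- pmax(pmin(ctr, matrix(c(n1, n2), nrow(ctr), 2, byrow = TRUE)),
              1)
  for (i in seq_len(nrow(ctr))) {
    ii <- ctr[i, 1] + offs[, 1]
    jj <- ctr[i, 2] + offs[, 2]
    ok <- ii >= 1 & ii <= n1 & jj >= 1 & jj <= n2
    pixels[cbind(ii[ok], jj[ok])] <- 1
  }
  pixels
}
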