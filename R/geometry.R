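#' Construct a simulation domain
#'
#' Axis-aligned box with a uniform node-centered grid.  Following the mesh
#' convention of the model, the lateral sides are twice the lesion bounding
#' box and the axial side equals the retinal depth; extents are rounded up
#' to an integer multiple of the spacing `h`.  The x,y plane is parallel to
#' the retinal layers, z points toward the inner eye.
#'
#' @param lesion_bbox Lateral side length(s) of the lesion bounding box, sau
#'   (length 1 recycled, or one per lateral axis).
#' @param retinal_depth Axial extent, sau; `NULL` for a 2D (or 1D) domain.
#' @param h Grid spacing, sau.  Must not exceed the tip-cell radius so a
#'   tip-cell imprint always covers at least one node.
#' @param dim Spatial dimension (1, 2 or 3); defaults to the number of
#'   lateral axes plus one if `retinal_depth` is given.
#' @param R_c Tip-cell radius used for the `h <= R_c` check, sau.
#' @param strict If `TRUE`, `h > R_c` is an error instead of a warning.
#' @param origin Lower-corner coordinates, sau (default all zero).
#' @return An object of class `rh_domain` with fields `dim`, `extent`, `h`,
#'   `origin`, `n` (nodes per axis).
#' @examples
#' d <- make_domain(lesion_bbox = 666.5 / 800, retinal_depth = 1031 / 800,
#'                  h = 7 / 800)
#' round(d$extent * 800)  # 1337 1337 1036 (1333x1333x1031 rounded up to h)
#' @export
make_domain <- function(lesion_bbox, retinal_depth = NULL, h, dim = NULL,
                        R_c = 0.0125, strict = FALSE, origin = NULL) {
  stopifnot(h > 0, all(lesion_bbox > 0))
  if (is.null(dim)) dim <- if (is.null(retinal_depth)) 2 else 3
  lateral <- rep(2 * lesion_bbox, length.out = dim - !is.null(retinal_depth))
  extent <- c(lateral, retinal_depth)
  sim_domain(extent = extent, h = h, dim = dim, R_c = R_c, strict = strict,
             origin = origin)
}

#' Construct a domain directly from its extent
#'
#' @param extent Side lengths per axis, sau.
#' @inheritParams make_domain
#' @return An `rh_domain`.
#' @export
sim_domain <- function(extent, h, dim = length(extent), R_c = 0.0125,
                       strict = FALSE, origin = NULL) {
  stopifnot(h > 0, all(extent > 0), dim %in% 1:3, length(extent) == dim)
  if (h > R_c) {
    msg <- sprintf("grid spacing h = %g exceeds the tip-cell radius R_c = %g",
                   h, R_c)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  n_cells <- ceiling(extent / h - 1e-9)
  extent <- n_cells * h
  if (is.null(origin)) origin <- rep(0, dim)
  stopifnot(length(origin) == dim)
  structure(list(dim = dim, extent = extent, h = h, origin = origin,
                 n = as.integer(n_cells + 1)),
            class = "rh_domain")
}

#' @export
print.rh_domain <- function(x, ...) {
  cat(sprintf("<rh_domain> %dD, extent (%s) sau, h = %g sau, %s nodes\n",
              x$dim, paste(signif(x$extent, 6), collapse = " x "), x$h,
              paste(x$n, collapse = " x ")))
  invisible(x)
}

#' Grid node coordinates along each axis
#'
#' @param domain An `rh_domain`.
#' @return List of numeric vectors, one per axis.
#' @export
grid_axes <- function(domain) {
  lapply(seq_len(domain$dim), function(k) {
    domain$origin[k] + domain$h * (seq_len(domain$n[k]) - 1)
  })
}

# n-dim array of zeros shaped like the grid
empty_field <- function(domain, fill = 0) {
  array(fill, dim = domain$n)
}

# Node positions as an (N x dim) matrix in linear index order (x fastest).
node_positions <- function(domain) {
  ax <- grid_axes(domain)
  as.matrix(do.call(expand.grid, ax))
}

#' Prescribed tumor ellipsoid
#'
#' The tumor is a growing ellipsoid with equal lateral semiaxes; its volume
#' multiplies by `tgr` per tau, so each semiaxis carries an exponent t/3.
#'
#' @param center Center position, sau (length = domain dim where used).
#' @param d_p Initial lateral diameter, sau.
#' @param d_a Initial axial diameter, sau (ignored in 2D).
#' @param tgr Per-tau multiplicative volume growth factor (>= 1 for growth);
#'   defaults to the 35%-per-year rate.
#' @return An object of class `rh_tumor`.
#' @export
tumor_ellipsoid <- function(center, d_p, d_a = d_p,
                            tgr = default_parameters()$tgr) {
  stopifnot(d_p > 0, d_a > 0, tgr > 0)
  structure(list(center = center, d_p = d_p, d_a = d_a, tgr = tgr),
            class = "rh_tumor")
}

#' Tumor semiaxes at a given time
#'
#' `s_x = s_y = (d_p/2) tgr^(t/3)`, `s_z = (d_a/2) tgr^(t/3)` with `tgr`
#' the per-tau volume factor, so volume(t)/volume(0) = tgr^t.
#'
#' @param tumor An `rh_tumor`.
#' @param t Time, tau (>= 0).
#' @return Named vector `c(s_x, s_y, s_z)`, sau.
#' @export
semiaxes_at <- function(tumor, t) {
  stopifnot(inherits(tumor, "rh_tumor"))
  if (any(t < 0)) stop("semiaxes_at: negative time", call. = FALSE)
  f <- tumor$tgr^(t / 3)
  c(s_x = tumor$d_p / 2 * f, s_y = tumor$d_p / 2 * f, s_z = tumor$d_a / 2 * f)
}

#' Tumor indicator field
#'
#' phi = 1 where sum_i (x_i - c_i)^2 / s_i^2 <= 1, else 0.  Boundary points
#' are inside (<=).  Applied to a whole grid it returns a nodal field; given
#' a position matrix it returns a vector.
#'
#' @param tumor An `rh_tumor`.
#' @param t Time, tau.
#' @param domain An `rh_domain`, or `x` a position matrix (rows = points).
#' @param x Optional positions (n x dim matrix or a single vector), sau.
#' @return Array over the grid, or numeric vector for explicit positions.
#' @export
tumor_indicator <- function(tumor, t, domain = NULL, x = NULL) {
  s <- semiaxes_at(tumor, t)
  if (!is.null(x)) {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    d <- ncol(x)
    q <- rep(0, nrow(x))
    for (k in seq_len(d)) {
      q <- q + (x[, k] - tumor$center[k])^2 / s[k]^2
    }
    return(as.numeric(q <= 1))
  }
  stopifnot(inherits(domain, "rh_domain"))
  ax <- grid_axes(domain)
  d <- domain$dim
  # separable quadratic form, built by broadcasting per axis
  q <- empty_field(domain)
  for (k in seq_len(d)) {
    contrib <- (ax[[k]] - tumor$center[k])^2 / s[k]^2
    q <- q + array(rep(contrib, each = prod(domain$n[seq_len(k - 1)])),
                   dim = domain$n)
  }
  array(as.numeric(q <= 1), dim = domain$n)
}

#' Discrete tumor volume
#'
#' Voxel sum of the indicator times h^dim; converges to the analytic
#' ellipsoid volume as h -> 0.
#'
#' @inheritParams tumor_indicator
#' @return Volume in sau^dim.
#' @export
tumor_volume <- function(tumor, t, domain) {
  sum(tumor_indicator(tumor, t, domain)) * domain$h^domain$dim
}

#' Analytic ellipsoid volume (or area in 2D)
#'
#' @inheritParams tumor_indicator
#' @param dim Spatial dimension.
#' @return 4/3 pi s_x s_y s_z in 3D; pi s_x s_y in 2D.
#' @export
tumor_volume_analytic <- function(tumor, t, dim = 3) {
  s <- semiaxes_at(tumor, t)
  if (dim == 3) 4 / 3 * pi * s[["s_x"]] * s[["s_y"]] * s[["s_z"]]
  else if (dim == 2) pi * s[["s_x"]] * s[["s_y"]]
  else 2 * s[["s_x"]]
}
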