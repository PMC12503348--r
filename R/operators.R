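# Sparse finite-difference operators on the uniform grid.
#
# The Laplacian uses the ghost-node zero-flux (homogeneous Neumann) closure:
# the 1D second-difference matrix has rows [-1 1]/h^2 at the ends.  It is
# symmetric with zero row (and column) sums, which is what makes the
# Cahn-Hilliard step exactly mass conservative.

# 1D Neumann second-difference matrix, scaled by 1/h^2
neumann_d2 <- function(n, h) {
  if (n == 1) return(Matrix::Matrix(0, 1, 1, sparse = TRUE))
  d <- c(-1, rep(-2, n - 2), -1)
  Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                     diagonals = list(rep(1, n - 1), d, rep(1, n - 1))) / h^2
}

#' Sparse grid operators for a domain
#'
#' Builds the Neumann (zero-flux) Laplacian `L` on the node-centered grid
#' and, optionally, its square `LL` (used by the implicit Cahn-Hilliard
#' Jacobian).  Fields are stored in linear index order with x fastest.
#'
#' @param domain An `rh_domain`.
#' @param squared Also compute `LL = L %*% L`.
#' @return List with `L`, optionally `LL`, and `N` (node count).
#' @export
grid_operators <- function(domain, squared = TRUE) {
  n <- domain$n
  h <- domain$h
  d <- domain$dim
  eye <- lapply(n, function(m) Matrix::Diagonal(m))
  L <- NULL
  for (k in seq_len(d)) {
    facs <- eye
    facs[[k]] <- neumann_d2(n[k], h)
    term <- facs[[d]]
    if (d > 1) for (j in (d - 1):1) term <- term %x% facs[[j]]
    L <- if (is.null(L)) term else L + term
  }
  L <- methods::as(L, "CsparseMatrix")
  out <- list(L = L, N = prod(n), domain = domain)
  if (squared) out$LL <- methods::as(L %*% L, "CsparseMatrix")
  out
}

#' Nodal gradient of a field
#'
#' Central differences in the interior, one-sided at the boundaries.
#'
#' @param f Field array shaped like the grid.
#' @param domain An `rh_domain`.
#' @return List of arrays, one gradient component per axis.
#' @export
gradient_field <- function(f, domain) {
  n <- domain$n
  h <- domain$h
  d <- domain$dim
  f <- array(f, dim = n)
  out <- vector("list", d)
  for (k in seq_len(d)) {
    g <- array(0, dim = n)
    nk <- n[k]
    idx <- function(i) {
      args <- rep(list(quote(expr = )), d)
      args[[k]] <- i
      do.call(`[`, c(list(f), args, list(drop = FALSE)))
    }
    if (nk >= 3) {
      asg <- slice_assign(g, k, 2:(nk - 1),
                          (idx(3:nk) - idx(1:(nk - 2))) / (2 * h))
      g <- asg
    }
    if (nk >= 2) {
      g <- slice_assign(g, k, 1, (idx(2) - idx(1)) / h)
      g <- slice_assign(g, k, nk, (idx(nk) - idx(nk - 1)) / h)
    }
    out[[k]] <- g
  }
  out
}

# assign values into array a along axis k at indices i
slice_assign <- function(a, k, i, value) {
  d <- length(dim(a))
  args <- rep(list(quote(expr = )), d)
  args[[k]] <- i
  do.call(`[<-`, c(list(a), args, list(value = value)))
}

#' Euclidean norm of a nodal gradient
#'
#' @param grad List of component arrays from [gradient_field()].
#' @return Array of per-node norms.
#' @export
gradient_norm <- function(grad) {
  s <- 0
  for (g in grad) s <- s + g^2
  sqrt(s)
}

# Multilinear interpolation of one or more fields at continuous positions.
# fields: list of arrays; pts: (m x dim) matrix in physical coordinates.
# Returns a matrix (m x length(fields)).
interp_fields <- function(fields, domain, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  d <- domain$dim
  n <- domain$n
  h <- domain$h
  m <- nrow(pts)
  # fractional index coordinates, clamped to the grid
  fi <- matrix(0, m, d)
  for (k in seq_len(d)) {
    fi[, k] <- pmin(pmax((pts[, k] - domain$origin[k]) / h, 0), n[k] - 1)
  }
  i0 <- pmin(floor(fi), matrix(rep(n - 2, each = m), m, d))
  i0[i0 < 0] <- 0
  w <- fi - i0
  nf <- length(fields)
  out <- matrix(0, m, nf)
  corners <- as.matrix(do.call(expand.grid,
                               rep(list(c(0, 1)), d)))
  stride <- cumprod(c(1, n[-d]))
  for (cc in seq_len(nrow(corners))) {
    off <- corners[cc, ]
    wt <- rep(1, m)
    for (k in seq_len(d)) {
      wt <- wt * if (off[k] == 1) w[, k] else 1 - w[, k]
    }
    lin <- rep(1, m)
    for (k in seq_len(d)) lin <- lin + (i0[, k] + off[k]) * stride[k]
    for (jf in seq_len(nf)) {
      out[, jf] <- out[, jf] + wt * fields[[jf]][lin]
    }
  }
  out
}
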