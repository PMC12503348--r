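#' Heaviside step with the intravascular convention
#'
#' `H(c) = 1` for `c > 0`, else 0.  `H(0) = 0`, so the diffuse interface's
#' midpoint belongs to tissue; the production mask `(1 - H(c))` then
#' suppresses AF production strictly inside vessels only.
#'
#' @param c Numeric (scalar, vector or array).
#' @return Same shape, values in \{0, 1\}.
#' @export
heaviside <- function(c) {
  (c > 0) + 0
}

#' Solve the quasi-steady angiogenic-factor field
#'
#' Solves `D_af lap(af) + V_pT phi (1 - H(c)) - V_uc af H(c) - V_d af = 0`
#' with zero-flux boundaries.  The AF equilibrates much faster than growth
#' or sprouting, so the field is re-solved to steady state each step.
#'
#' @param phi Tumor indicator field (0/1 array on the grid).
#' @param c Capillary phase field array.
#' @param p An `rh_params`.
#' @param domain An `rh_domain`.
#' @param ops Optional [grid_operators()] (reused across calls).
#' @param rtol Relative residual tolerance for the linear solve check.
#' @return An object of class `rh_af`: fields `af` (array, afau),
#'   `grad` (list of component arrays), `G` (gradient-norm array).
#' @export
solve_af_steady <- function(phi, c, p, domain, ops = NULL, rtol = 1e-8) {
  if (is.null(ops)) ops <- grid_operators(domain, squared = FALSE)
  H <- heaviside(as.vector(c))
  react <- p$V_uc * H + p$V_d
  if (all(react == 0)) {
    stop(paste("singular AF system: V_d = 0 and no vessel uptake anywhere;",
               "the pure-Neumann problem has no unique solution"),
         call. = FALSE)
  }
  A <- -p$D_af * ops$L + Matrix::Diagonal(ops$N, react)
  b <- p$V_pT * as.vector(phi) * (1 - H)
  af <- as.numeric(Matrix::solve(A, b))
  res <- sqrt(sum((as.numeric(A %*% af) - b)^2))
  scale <- max(sqrt(sum(b^2)), 1e-30)
  if (res / scale > rtol && res > 1e-12) {
    stop(sprintf("AF solve did not converge: relative residual %.3e",
                 res / scale), call. = FALSE)
  }
  af <- array(af, dim = domain$n)
  grad <- gradient_field(af, domain)
  structure(list(af = af, grad = grad, G = gradient_norm(grad)),
            class = "rh_af")
}

#' Gradient of an AF field
#'
#' Recomputes (or returns the cached) nodal gradient: central differences in
#' the interior, one-sided at boundaries.
#'
#' @param aff An `rh_af` (or a bare array).
#' @param domain An `rh_domain`.
#' @return List of gradient component arrays.
#' @export
af_gradient <- function(aff, domain) {
  if (inherits(aff, "rh_af")) {
    if (!is.null(aff$grad)) return(aff$grad)
    aff <- aff$af
  }
  gradient_field(aff, domain)
}

#' @export
print.rh_af <- function(x, ...) {
  cat(sprintf("<rh_af> mean %.4g, range [%.4g, %.4g] afau\n",
              mean(x$af), min(x$af), max(x$af)))
  invisible(x)
}
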