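#' Capillary phase-field state
#'
#' The phase field `c` is about +1 in the intravascular space and -1 in
#' tissue, with a diffuse interface.  `mu` is the auxiliary chemical
#' potential of the split fourth-order system.
#'
#' @param c Phase field array on the grid.
#' @param mu Optional chemical potential array (computed on demand).
#' @return An object of class `rh_capillaries`.
#' @export
capillary_state <- function(c, mu = NULL) {
  structure(list(c = c, mu = mu), class = "rh_capillaries")
}

#' @export
print.rh_capillaries <- function(x, ...) {
  cat(sprintf("<rh_capillaries> c in [%.3f, %.3f], vessel fraction %.3f\n",
              min(x$c), max(x$c), mean(x$c > 0)))
  invisible(x)
}

#' AF-dependent proliferation rate
#'
#' Piecewise-linear saturating law: 0 for `af <= 0`, `alpha * af` up to
#' `af_p`, then constant `alpha * af_p`.
#'
#' @param af AF concentration, afau (vectorised).
#' @param alpha Proliferation rate, 1/(afau tau).
#' @param af_p Saturation concentration, afau.
#' @return Proliferation rate(s), 1/tau.
#' @export
B_p <- function(af, alpha, af_p) {
  alpha * pmin(pmax(af, 0), af_p)
}

# chemical potential mu = c^3 - c - eps * lap(c) with Neumann closure
chemical_potential <- function(cvec, p, ops) {
  cvec^3 - cvec - p$eps * as.numeric(ops$L %*% cvec)
}

#' One implicit step of the capillary phase field
#'
#' Backward-Euler step of
#' `dc/dt = M lap(mu) + B_p(af) c H(c)`, `mu = -c + c^3 - eps lap(c)`
#' with zero-flux boundaries on both `c` and `mu`, solved by Newton on the
#' mu-eliminated system.  With the default `alpha_p = 0` the bulk source is
#' identically zero and all vessel growth comes from tip-cell imprints.
#'
#' @param state An `rh_capillaries`.
#' @param af An `rh_af` (or array), used by the proliferation source.
#' @param dt Time step, tau.
#' @param p An `rh_params`.
#' @param domain An `rh_domain`.
#' @param ops [grid_operators()] with `LL` (built if missing).
#' @param tol Absolute nonlinear residual tolerance (max norm).
#' @param max_iter Newton iteration cap.
#' @return Updated `rh_capillaries` with fresh `mu`.
#' @export
step_capillaries <- function(state, af, dt, p, domain, ops = NULL,
                             tol = 1e-8, max_iter = 30) {
  stopifnot(dt > 0)
  if (is.null(ops) || is.null(ops$LL)) ops <- grid_operators(domain)
  cn <- as.vector(state$c)
  afv <- if (inherits(af, "rh_af")) as.vector(af$af) else as.vector(af)
  bp <- B_p(afv, p$alpha_p, p$af_p)
  N <- ops$N
  Ident <- Matrix::Diagonal(N)
  cv <- cn
  ok <- FALSE
  residual <- function(v) {
    v - cn - dt * p$M * as.numeric(ops$L %*% chemical_potential(v, p, ops)) -
      dt * bp * v * heaviside(v)
  }
  Fres <- residual(cv)
  for (it in seq_len(max_iter)) {
    if (max(abs(Fres)) < tol) { ok <- TRUE; break }
    D <- Matrix::Diagonal(N, 3 * cv^2 - 1)
    J <- Ident - dt * p$M * (ops$L %*% D - p$eps * ops$LL) -
      Matrix::Diagonal(N, dt * bp * heaviside(cv))
    delta <- as.numeric(Matrix::solve(J, Fres))
    # backtracking line search on the residual max-norm
    fcur <- max(abs(Fres))
    alpha <- 1
    for (ls in 1:6) {
      Ftrial <- residual(cv - alpha * delta)
      if (all(is.finite(Ftrial)) && max(abs(Ftrial)) < fcur) break
      alpha <- alpha / 2
    }
    cv <- cv - alpha * delta
    Fres <- residual(cv)
    if (!all(is.finite(cv))) break
  }
  if (!ok && (!all(is.finite(Fres)) || max(abs(Fres)) >= tol)) {
    stop(sprintf(paste("capillary step rejected: Newton residual %.3e",
                       "after %d iterations (dt = %g); caller may halve dt"),
                 if (all(is.finite(Fres))) max(abs(Fres)) else Inf,
                 max_iter, dt), call. = FALSE)
  }
  mu <- chemical_potential(cv, p, ops)
  capillary_state(array(cv, dim = domain$n), array(mu, dim = domain$n))
}

#' Ginzburg-Landau energy of the phase field
#'
#' `sum [ (c^2-1)^2/4 + (eps/2) |grad c|^2 ] h^dim`, with the gradient term
#' evaluated as the quadratic form `(eps/2) c' (-L) c h^dim` — the discrete
#' energy whose H^-1 gradient flow the implicit stepper dissipates.
#'
#' @param state An `rh_capillaries` (or bare array).
#' @param p An `rh_params`.
#' @param domain An `rh_domain`.
#' @param ops Optional [grid_operators()].
#' @return Scalar energy.
#' @export
ginzburg_landau_energy <- function(state, p, domain, ops = NULL) {
  if (is.null(ops)) ops <- grid_operators(domain, squared = FALSE)
  cv <- if (inherits(state, "rh_capillaries")) as.vector(state$c)
        else as.vector(state)
  well <- sum((cv^2 - 1)^2) / 4
  gradsq <- -sum(cv * as.numeric(ops$L %*% cv))
  (well + p$eps / 2 * gradsq) * domain$h^domain$dim
}

#' Total phase-field mass
#'
#' `sum(c) h^dim`; conserved by the Neumann Cahn-Hilliard step when
#' `alpha_p = 0` and no tip cells imprint.
#'
#' @inheritParams ginzburg_landau_energy
#' @return Scalar.
#' @export
field_mass <- function(state, domain) {
  cv <- if (inherits(state, "rh_capillaries")) state$c else state
  sum(cv) * domain$h^domain$dim
}
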