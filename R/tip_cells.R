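# Discrete tip-cell agents.  Tips are stored in a data.frame with one row
# per agent: position columns x1..xd, velocity columns v1..vd, `active`,
# `born_at`.  The per-step sweep order is: deactivate -> activate ->
# velocities -> imprint -> move, so the imprint uses the velocity of the
# current step.

#' Empty tip-cell table
#'
#' @param dim Spatial dimension.
#' @return Zero-row data.frame with the tip-cell columns.
#' @export
empty_tips <- function(dim) {
  cols <- c(paste0("x", seq_len(dim)), paste0("v", seq_len(dim)))
  out <- as.data.frame(matrix(numeric(0), 0, 2 * dim))
  names(out) <- cols
  out$active <- logical(0)
  out$born_at <- numeric(0)
  out
}

tip_positions <- function(tips, dim) {
  as.matrix(tips[, paste0("x", seq_len(dim)), drop = FALSE])
}

# pairwise min distance from each row of `pts` to rows of `ref`
min_dist_to <- function(pts, ref) {
  if (nrow(ref) == 0) return(rep(Inf, nrow(pts)))
  apply(pts, 1, function(q) {
    sqrt(min(colSums((t(ref) - q)^2)))
  })
}

#' Activate tip cells
#'
#' Places a new tip cell at every grid node inside the vascular network
#' (`c >= 1 - c_tol`) where both the AF concentration (`af >= T_c`) and its
#' gradient norm (`G >= G_m`) exceed their thresholds, subject to the
#' Delta-Notch exclusion: no two active tips (old or new) closer than
#' `delta4`.  Exclusion is greedy in node (linear-index) order, which is
#' deterministic; `order = "random"` uses a seeded random sweep instead.
#'
#' @param cfield Capillary field array (or `rh_capillaries`).
#' @param aff An `rh_af`.
#' @param tips Current tip table.
#' @param p An `rh_params`.
#' @param domain An `rh_domain`.
#' @param t Current time (recorded as `born_at`).
#' @param order `"lexicographic"` (default) or `"random"`.
#' @param seed Seed for the random sweep order.
#' @return Updated tip table.
#' @export
activate_tips <- function(cfield, aff, tips, p, domain, t = 0,
                          order = c("lexicographic", "random"), seed = 1L) {
  order <- match.arg(order)
  cv <- if (inherits(cfield, "rh_capillaries")) as.vector(cfield$c)
        else as.vector(cfield)
  eligible <- which(cv >= 1 - p$c_tol &
                      as.vector(aff$af) >= p$T_c &
                      as.vector(aff$G) >= p$G_m)
  if (length(eligible) == 0) return(tips)
  if (order == "random") {
    eligible <- with_seed(seed, sample(eligible))
  }
  d <- domain$dim
  pos <- node_positions(domain)[eligible, , drop = FALSE]
  act <- tip_positions(tips[tips$active, , drop = FALSE], d)
  new_rows <- list()
  for (i in seq_len(nrow(pos))) {
    q <- pos[i, ]
    if (nrow(act) > 0 &&
        min(colSums((t(act) - q)^2)) < p$delta4^2) next
    act <- rbind(act, q)
    row <- as.list(c(q, rep(0, d)))
    names(row) <- c(paste0("x", seq_len(d)), paste0("v", seq_len(d)))
    row$active <- TRUE
    row$born_at <- t
    new_rows[[length(new_rows) + 1]] <- as.data.frame(row)
  }
  if (length(new_rows)) tips <- rbind(tips, do.call(rbind, new_rows))
  tips
}

#' Deactivate tip cells
#'
#' A tip cell becomes inactive when its local conditions no longer meet the
#' activation thresholds: interpolated `af < T_c` or interpolated gradient
#' norm `G < G_m`.
#'
#' @inheritParams activate_tips
#' @return Updated tip table.
#' @export
deactivate_tips <- function(tips, aff, p, domain) {
  act <- which(tips$active)
  if (length(act) == 0) return(tips)
  d <- domain$dim
  pts <- tip_positions(tips[act, , drop = FALSE], d)
  vals <- interp_fields(c(list(aff$af), aff$grad), domain, pts)
  afv <- vals[, 1]
  G <- sqrt(rowSums(vals[, -1, drop = FALSE]^2))
  off <- afv < p$T_c | G < p$G_m
  tips$active[act[off]] <- FALSE
  tips
}

#' Tip-cell velocity law
#'
#' `v = chi * grad(af)` for `G_m <= G < G_M`, and `v = chi * grad(af) * G_M
#' / G` for `G >= G_M`: the speed is `chi * G` below the cap and saturates
#' at `chi * G_M`, always parallel to the AF gradient.
#'
#' @param gradient AF gradient vector at the tip, afau/sau.
#' @param p An `rh_params`.
#' @return Velocity vector, sau/tau.
#' @export
tip_velocity <- function(gradient, p) {
  G <- sqrt(sum(gradient^2))
  if (G < p$G_m) {
    stop(sprintf(paste("tip_velocity called with G = %.4g < G_m = %.4g;",
                       "the tip should have been deactivated first"),
                 G, p$G_m), call. = FALSE)
  }
  if (G >= p$G_M) p$chi * gradient * p$G_M / G else p$chi * gradient
}

# assign this step's velocities to all active tips; tips whose interpolated
# gradient fell below G_m since deactivation are switched off defensively
assign_velocities <- function(tips, aff, p, domain) {
  act <- which(tips$active)
  if (length(act) == 0) return(tips)
  d <- domain$dim
  pts <- tip_positions(tips[act, , drop = FALSE], d)
  gv <- interp_fields(aff$grad, domain, pts)
  G <- sqrt(rowSums(gv^2))
  drop <- G < p$G_m
  tips$active[act[drop]] <- FALSE
  keep <- act[!drop]
  if (length(keep)) {
    Gk <- G[!drop]
    fac <- ifelse(Gk >= p$G_M, p$chi * p$G_M / Gk, p$chi)
    for (k in seq_len(d)) {
      tips[[paste0("v", k)]][keep] <- fac * gv[!drop, k]
    }
  }
  tips
}

#' Imprint tip cells onto the phase field
#'
#' Every node within `R_c` of an active tip is overwritten with
#' `c_c = S_p(af) * pi * R_c^2 / |v|`, where `S_p` is the stalk-cell
#' proliferation law (the [B_p()] shape with `alpha_pSC`) evaluated at the
#' tip's local AF, and `|v|` is the tip speed of this step, floored at
#' `v_min` to guard the division.  This carries the tip-cell mass and the
#' stalk-cell proliferation into the continuum field.
#'
#' @param state An `rh_capillaries`.
#' @param tips Tip table with velocities assigned this step.
#' @param aff An `rh_af`.
#' @param p An `rh_params`.
#' @param domain An `rh_domain`.
#' @return Updated `rh_capillaries` (mu invalidated).
#' @export
imprint_tips <- function(state, tips, aff, p, domain) {
  act <- which(tips$active)
  if (length(act) == 0) return(state)
  d <- domain$dim
  cf <- state$c
  n <- domain$n
  h <- domain$h
  pts <- tip_positions(tips[act, , drop = FALSE], d)
  vmat <- as.matrix(tips[act, paste0("v", seq_len(d)), drop = FALSE])
  af_at <- interp_fields(list(aff$af), domain, pts)[, 1]
  sp <- B_p(af_at, p$alpha_pSC, p$af_p)
  speed <- pmax(sqrt(rowSums(vmat^2)), p$v_min)
  cc <- sp * pi * p$R_c^2 / speed
  rng_nodes <- ceiling(p$R_c / h)
  for (i in seq_along(act)) {
    q <- pts[i, ]
    lo <- pmax(floor((q - domain$origin) / h) - rng_nodes + 1, 1)
    hi <- pmin(floor((q - domain$origin) / h) + rng_nodes + 2, n)
    idx <- lapply(seq_len(d), function(k) lo[k]:hi[k])
    sub <- as.matrix(do.call(expand.grid, idx))
    posn <- sweep((sub - 1) * h, 2, domain$origin, `+`)
    inside <- rowSums((posn - matrix(q, nrow(sub), d, byrow = TRUE))^2) <=
      p$R_c^2
    if (!any(inside)) next
    lin <- as.vector((sub[inside, , drop = FALSE] - 1) %*%
                       cumprod(c(1, n[-d]))) + 1
    cf[lin] <- cc[i]
  }
  capillary_state(cf, mu = NULL)
}

#' Move tip cells
#'
#' `position <- position + v * dt`, clamped to the domain box (zero-flux
#' world).
#'
#' @param tips Tip table with velocities assigned.
#' @param dt Time step, tau.
#' @param domain An `rh_domain`.
#' @return Updated tip table.
#' @export
move_tips <- function(tips, dt, domain) {
  act <- which(tips$active)
  if (length(act) == 0 || dt == 0) return(tips)
  d <- domain$dim
  for (k in seq_len(d)) {
    xk <- tips[[paste0("x", k)]][act] + tips[[paste0("v", k)]][act] * dt
    lo <- domain$origin[k]
    hi <- domain$origin[k] + domain$extent[k]
    tips[[paste0("x", k)]][act] <- pmin(pmax(xk, lo), hi)
  }
  tips
}

# run `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
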