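# Orchestration of the coupled time loop: prescribed tumor growth,
# quasi-steady AF solve, agent sweep, implicit capillary step, adaptive
# time stepping (only while no tip cell is active) and the bisection
# estimators for activation times and the minimal angiogenic tumor size.

#' Initialise a simulation state
#'
#' @param c0 Initial capillary field array (values in \{-1, +1\} from a
#'   reconstruction, or any phase-field-like array).
#' @param tumor An `rh_tumor`.
#' @param p An `rh_params`.
#' @param domain An `rh_domain`.
#' @param seed RNG seed recorded with the run.
#' @param ops Optional precomputed [grid_operators()].
#' @return An object of class `rh_state`.
#' @export
init_state <- function(c0, tumor, p, domain, seed = 1L, ops = NULL) {
  if (is.null(ops)) ops <- grid_operators(domain)
  structure(list(
    t = 0, step_index = 0L,
    capillaries = capillary_state(array(c0, dim = domain$n)),
    af = NULL, tumor = tumor, tips = empty_tips(domain$dim),
    p = p, domain = domain, ops = ops, seed = as.integer(seed),
    history = empty_history(), events = empty_events(domain$dim)
  ), class = "rh_state")
}

empty_history <- function() {
  data.frame(step = integer(0), t_tau = numeric(0), dt = numeric(0),
             n_active_tips = integer(0), af_mean = numeric(0),
             af_max = numeric(0), af_min = numeric(0),
             tumor_volume = numeric(0), vessel_volume_fraction = numeric(0),
             energy = numeric(0))
}

empty_events <- function(dim) {
  out <- data.frame(step = integer(0), t_tau = numeric(0),
                    event = character(0))
  for (k in seq_len(dim)) out[[paste0("x", k)]] <- numeric(0)
  out
}

#' @export
print.rh_state <- function(x, ...) {
  cat(sprintf(
    "<rh_state> t = %.2f tau (%.2f d), step %d, %d active tips\n",
    x$t, x$t * x$p$units$tau / 1440, x$step_index, sum(x$tips$active)))
  invisible(x)
}

#' Adaptive time step
#'
#' `dt = max(dt_min, dt_max / (1 + alpha |E'|^2))` with
#' `E' = -||grad mu||^2`, the domain L2 norm of the chemical-potential
#' gradient (configurable to the max norm).  Used only while no tip cell is
#' active, when the model is purely PDE-based.
#'
#' @param mu Chemical potential field array.
#' @param p An `rh_params`.
#' @param domain An `rh_domain`.
#' @param norm `"l2"` (default) or `"linf"`.
#' @return Time step in tau, clamped to `[dt_min, dt_max]`.
#' @export
adaptive_dt <- function(mu, p, domain, norm = c("l2", "linf")) {
  norm <- match.arg(norm)
  g <- gradient_norm(gradient_field(mu, domain))
  gn2 <- if (norm == "l2") sum(g^2) * domain$h^domain$dim else max(g)^2
  Eprime <- -gn2
  max(p$dt_min, p$dt_max / (1 + p$alpha_dt * Eprime^2))
}

# activation predicate: does any node satisfy all three activation
# thresholds (ignoring Notch exclusion, which cannot veto the first tip)?
any_activation <- function(cfield, aff, p) {
  cv <- if (inherits(cfield, "rh_capillaries")) as.vector(cfield$c)
        else as.vector(cfield)
  any(cv >= 1 - p$c_tol & as.vector(aff$af) >= p$T_c &
        as.vector(aff$G) >= p$G_m)
}

#' Bisection of the earliest activation time within a large step
#'
#' When the adaptive scheme proposes `dt_candidate > dt_min` with no active
#' tips, a naive large step could skip an activation inside the span.  This
#' probes trial advances (tumor at `t + dt`, one capillary step of size
#' `dt`, AF re-solve, activation predicates) and bisects down to the
#' earliest activating step size, to within `dt_min`.
#'
#' @param state An `rh_state` with no active tips.
#' @param dt_candidate Proposed step, > dt_min.
#' @param p An `rh_params`.
#' @return Effective dt: the smallest activating dt in
#'   `[dt_min, dt_candidate]` (within dt_min), or `dt_candidate` if no
#'   activation occurs anywhere in the span.
#' @export
bisect_activation_time <- function(state, dt_candidate, p = state$p) {
  trial <- function(dt) {
    phi <- tumor_indicator(state$tumor, state$t + dt, state$domain)
    cap <- tryCatch(
      step_capillaries(state$capillaries, state$af, dt, p,
                       state$domain, state$ops),
      error = function(e) NULL)
    # an unsolvable trial step counts as "activating": the bisection then
    # shrinks dt, which is conservative (no activation is ever skipped)
    if (is.null(cap)) return(TRUE)
    aff <- solve_af_steady(phi, cap$c, p, state$domain, state$ops)
    any_activation(cap, aff, p)
  }
  if (!trial(dt_candidate)) return(dt_candidate)
  if (trial(p$dt_min)) return(p$dt_min)
  lo <- p$dt_min          # known non-activating
  hi <- dt_candidate      # known activating
  while (hi - lo > p$dt_min) {
    mid <- (lo + hi) / 2
    if (trial(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Advance the simulation by one step
#'
#' One loop iteration: update the tumor at the current time, solve the AF
#' field, run the agent sweep (deactivate, activate, velocities, imprint),
#' choose dt (dt_min while tips are active, otherwise the adaptive rule
#' plus activation-time bisection), take the implicit capillary step, move
#' the tips, advance time and append the history row.
#'
#' @param state An `rh_state`.
#' @param p Parameters (defaults to those stored in the state).
#' @param max_retries Halved-dt retries when the capillary step fails.
#' @return Updated `rh_state`.
#' @export
step <- function(state, p = state$p, max_retries = 4) {
  domain <- state$domain
  ops <- state$ops
  phi <- tumor_indicator(state$tumor, state$t, domain)
  state$af <- solve_af_steady(phi, state$capillaries$c, p, domain, ops)

  prev_active <- which(state$tips$active)
  n_tips_before_act <- nrow(state$tips)
  state$tips <- deactivate_tips(state$tips, state$af, p, domain)
  state$tips <- activate_tips(state$capillaries, state$af, state$tips, p,
                              domain, t = state$t)
  state$tips <- assign_velocities(state$tips, state$af, p, domain)
  has_tips <- any(state$tips$active)
  if (has_tips) {
    state$capillaries <- imprint_tips(state$capillaries, state$tips,
                                      state$af, p, domain)
    dt <- p$dt_min
  } else {
    mu <- state$capillaries$mu
    if (is.null(mu)) {
      mu <- array(chemical_potential(as.vector(state$capillaries$c), p, ops),
                  dim = domain$n)
    }
    dt <- adaptive_dt(mu, p, domain)
    if (dt > p$dt_min) dt <- bisect_activation_time(state, dt, p)
  }
  # log agent events
  state$events <- log_events(state$events, state, prev_active,
                             n_tips_before_act)

  cap <- NULL
  for (r in 0:max_retries) {
    cap <- tryCatch(step_capillaries(state$capillaries, state$af, dt, p,
                                     domain, ops),
                    error = function(e) e)
    if (!inherits(cap, "error")) break
    if (dt <= p$dt_min || r == max_retries) {
      stop("capillary step failed at dt = ", dt, ": ",
           conditionMessage(cap), call. = FALSE)
    }
    dt <- max(dt / 2, p$dt_min)
  }
  state$capillaries <- cap
  state$tips <- move_tips(state$tips, dt, domain)
  state$t <- state$t + dt
  state$step_index <- state$step_index + 1L
  state$history <- rbind(state$history, history_row(state, phi, dt))
  rownames(state$history) <- NULL
  state
}

# One activation row per tip born this step (even if it is dropped again
# within the same sweep, which then also logs a deactivation) and one
# deactivation row per tip switched off, so per step:
# n_active = n_active_prev - deactivations + activations.
log_events <- function(events, state, prev_active, n_tips_before_act) {
  d <- state$domain$dim
  newly <- seq_len(nrow(state$tips))
  newly <- newly[newly > n_tips_before_act]
  add <- function(ev, rows) {
    if (length(rows) == 0) return(NULL)
    # the sweep belongs to the step being taken (step_index + 1)
    out <- data.frame(step = rep(state$step_index + 1L, length(rows)),
                      t_tau = rep(state$t, length(rows)),
                      event = rep(ev, length(rows)))
    for (k in seq_len(d)) out[[paste0("x", k)]] <-
        state$tips[[paste0("x", k)]][rows]
    out
  }
  dropped <- c(prev_active[!state$tips$active[prev_active]],
               newly[!state$tips$active[newly]])
  do.call(rbind, Filter(Negate(is.null),
                        list(events, add("deactivation", dropped),
                             add("activation", newly))))
}

history_row <- function(state, phi, dt) {
  domain <- state$domain
  p <- state$p
  data.frame(
    step = state$step_index,
    t_tau = state$t,
    dt = dt,
    n_active_tips = sum(state$tips$active),
    af_mean = mean(state$af$af),
    af_max = max(state$af$af),
    af_min = min(state$af$af),
    tumor_volume = sum(phi) * domain$h^domain$dim,
    vessel_volume_fraction = mean(state$capillaries$c > 0),
    energy = ginzburg_landau_energy(state$capillaries, p, domain, state$ops)
  )
}

#' Run a simulation for a fixed duration
#'
#' @param state An `rh_state` from [init_state()] (or
#'   [scenario_initial_state()]).
#' @param t_end End time, tau.
#' @param max_steps Safety cap on the number of steps.
#' @param progress Print a line every `progress` steps (0 = silent).
#' @return Final `rh_state` with the full history.
#' @export
simulate_run <- function(state, t_end, max_steps = 100000L, progress = 0) {
  while (state$t < t_end - 1e-9 && state$step_index < max_steps) {
    state <- step(state)
    if (progress > 0 && state$step_index %% progress == 0) {
      message(sprintf("step %d  t = %.1f tau  tips = %d",
                      state$step_index, state$t, sum(state$tips$active)))
    }
  }
  state
}

#' Number of base (dt_min) steps in a time span
#'
#' @param duration_min Span in minutes.
#' @param p An `rh_params`.
#' @return `ceiling(duration / dt_min)`; e.g. 30 days at dt_min = 26 min
#'   gives 1662.
#' @export
n_base_steps <- function(duration_min, p = default_parameters()) {
  dt_min_minutes <- p$dt_min * p$units$tau
  as.integer(ceiling(duration_min / dt_min_minutes - 1e-9))
}

#' Estimate the minimal tumor size capable of triggering sprouting
#'
#' The model is deterministic, so capability is probed with a single-step
#' activation test: solve the AF field on the initial state with the tumor
#' at a trial volume fraction and check whether any node satisfies the
#' activation thresholds.  At fraction 1 (the clinically observed volume) a
#' negative test flags the condition as incapable; otherwise the volume
#' fraction is bisected, with probes realised by scaling both diameters by
#' `fraction^(1/3)`, until the bracket is narrower than `tol_fraction` of
#' the maximal volume.
#'
#' @param activates Either a function `fraction -> logical` (the activation
#'   predicate) or `NULL` to build the predicate from `c0`/`tumor`/...
#' @param c0 Initial capillary field (used when `activates` is NULL).
#' @param tumor `rh_tumor` at the maximal (observed) size.
#' @param p An `rh_params`.
#' @param domain An `rh_domain`.
#' @param ops Optional [grid_operators()].
#' @param tol_fraction Stopping bracket width as a fraction of the maximal
#'   volume (default 0.05).
#' @return An `rh_minsize` list: `capable`, `min_volume_fraction`,
#'   `min_diameter_fraction`, `iterations`, `bracket`.
#' @export
estimate_minimal_size <- function(activates = NULL, c0 = NULL, tumor = NULL,
                                  p = NULL, domain = NULL, ops = NULL,
                                  tol_fraction = 0.05) {
  if (is.null(activates)) {
    stopifnot(!is.null(c0), !is.null(tumor), !is.null(p), !is.null(domain))
    if (is.null(ops)) ops <- grid_operators(domain, squared = FALSE)
    c0 <- array(c0, dim = domain$n)
    activates <- function(fraction) {
      sc <- fraction^(1 / 3)
      tum <- tumor_ellipsoid(tumor$center, tumor$d_p * sc, tumor$d_a * sc,
                             tumor$tgr)
      phi <- tumor_indicator(tum, 0, domain)
      aff <- solve_af_steady(phi, c0, p, domain, ops)
      any_activation(c0, aff, p)
    }
  }
  iterations <- 1L
  if (!isTRUE(activates(1))) {
    return(structure(list(capable = FALSE, min_volume_fraction = NA_real_,
                          min_diameter_fraction = NA_real_,
                          iterations = iterations, bracket = NA_real_),
                     class = "rh_minsize"))
  }
  lo <- 0   # largest known non-activating fraction
  hi <- 1   # smallest known activating fraction
  while (hi - lo >= tol_fraction) {
    mid <- (lo + hi) / 2
    iterations <- iterations + 1L
    if (isTRUE(activates(mid))) hi <- mid else lo <- mid
  }
  structure(list(capable = TRUE, min_volume_fraction = hi,
                 min_diameter_fraction = hi^(1 / 3),
                 iterations = iterations, bracket = hi - lo),
            class = "rh_minsize")
}

#' @export
print.rh_minsize <- function(x, ...) {
  if (!x$capable) {
    cat("<rh_minsize> incapable of inducing angiogenesis at maximal size\n")
  } else {
    cat(sprintf(
      "<rh_minsize> min volume %.1f%% (diameter %.1f%%) of maximum, %d probes\n",
      100 * x$min_volume_fraction, 100 * x$min_diameter_fraction,
      x$iterations))
  }
  invisible(x)
}
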