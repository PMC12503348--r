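#' Simulation unit system
#'
#' The model is nondimensionalised with three base units: a space unit
#' (`sau`, in micrometres), a time unit (`tau`, in minutes) and an
#' angiogenic-factor concentration unit (`afau`, in pg/mL).  All internal
#' computation happens in simulation units; physical units appear only at
#' I/O boundaries.
#'
#' @param sau Length unit in micrometres (default 800).
#' @param tau Time unit in minutes (default 26).
#' @param afau AF concentration unit in pg/mL (default 6000).
#' @return An object of class `rh_units`.
#' @examples
#' u <- unit_system()
#' to_sim_units(14, "ng mL^-1 mm^-1", u)  # G_m -> 1.866667 afau/sau
#' @export
unit_system <- function(sau = 800, tau = 26, afau = 6000) {
  if (!(is.numeric(sau) && is.numeric(tau) && is.numeric(afau)) ||
      any(c(sau, tau, afau) <= 0) || anyNA(c(sau, tau, afau))) {
    stop("unit_system: sau, tau and afau must be strictly positive numbers",
         call. = FALSE)
  }
  structure(list(sau = sau, tau = tau, afau = afau), class = "rh_units")
}

#' @export
print.rh_units <- function(x, ...) {
  cat(sprintf("<rh_units> sau = %g um, tau = %g min, afau = %g pg/mL\n",
              x$sau, x$tau, x$afau))
  invisible(x)
}

# Minutes per year used for rate conversions (365-day year).
.MIN_PER_YEAR <- 365 * 24 * 60

# Base units: length in um, time in min, mass in pg, volume in mL.
# Each entry: scale to the base unit of its dimension.
.UNIT_TABLE <- list(
  um  = list(dim = "L", scale = 1),
  mm  = list(dim = "L", scale = 1e3),
  cm  = list(dim = "L", scale = 1e4),
  m   = list(dim = "L", scale = 1e6),
  s   = list(dim = "T", scale = 1 / 60),
  sec = list(dim = "T", scale = 1 / 60),
  min = list(dim = "T", scale = 1),
  hr  = list(dim = "T", scale = 60),
  h   = list(dim = "T", scale = 60),
  day = list(dim = "T", scale = 1440),
  y   = list(dim = "T", scale = .MIN_PER_YEAR),
  yr  = list(dim = "T", scale = .MIN_PER_YEAR),
  pg  = list(dim = "M", scale = 1),
  ng  = list(dim = "M", scale = 1e3),
  ug  = list(dim = "M", scale = 1e6),
  mg  = list(dim = "M", scale = 1e9),
  g   = list(dim = "M", scale = 1e12),
  mL  = list(dim = "V", scale = 1),
  uL  = list(dim = "V", scale = 1e-3),
  L   = list(dim = "V", scale = 1e3)
)

# Parse a unit string like "um^2 mL min^-1 ng^-1" or "pg/mL" or "sau^2/tau".
# Returns list(scale, dims = c(L, T, C)) where scale converts a value in the
# given unit to base units (um, min, pg/mL) raised to dims; the simulation
# units sau/tau/afau are handled relative to `units`.
parse_unit <- function(unit, units = unit_system()) {
  if (length(unit) != 1 || !is.character(unit)) {
    stop("unit must be a single character string", call. = FALSE)
  }
  s <- gsub("·", " ", unit)      # middle dot
  s <- gsub("μm", "um", s)       # Greek mu
  s <- gsub("µm", "um", s)       # micro sign
  s <- gsub("\\*", " ", s)
  # slashes flip the sign of every following token
  parts <- strsplit(s, "/", fixed = TRUE)[[1]]
  if (length(parts) == 0) parts <- ""
  dims <- c(L = 0, T = 0, M = 0, V = 0)
  log_scale <- 0
  sim_table <- list(
    sau  = list(dim = "L", scale = units$sau),
    tau  = list(dim = "T", scale = units$tau),
    afau = list(dim = "C", scale = units$afau)
  )
  for (k in seq_along(parts)) {
    sgn <- if (k == 1) 1 else -1
    toks <- strsplit(trimws(parts[k]), "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    for (tok in toks) {
      if (tok == "1") next
      m <- regmatches(tok, regexec("^([A-Za-z]+)(\\^?(-?[0-9]+))?$", tok))[[1]]
      if (length(m) == 0 || !nzchar(m[2])) {
        stop(sprintf("unknown unit token '%s' in '%s'", tok, unit),
             call. = FALSE)
      }
      name <- m[2]
      expo <- if (nzchar(m[4])) as.numeric(m[4]) else 1
      expo <- sgn * expo
      entry <- sim_table[[name]]
      if (is.null(entry)) entry <- .UNIT_TABLE[[name]]
      if (is.null(entry)) {
        stop(sprintf("unknown unit '%s' in '%s'", name, unit), call. = FALSE)
      }
      if (entry$dim == "C") {
        # simulation concentration unit: counts as mass/volume pair
        dims["M"] <- dims["M"] + expo
        dims["V"] <- dims["V"] - expo
      } else {
        dims[entry$dim] <- dims[entry$dim] + expo
      }
      log_scale <- log_scale + expo * log(entry$scale)
    }
  }
  if (dims["M"] != -dims["V"]) {
    stop(sprintf(paste0("unit '%s' has mass/volume signature that is not a ",
                        "pure concentration; not expressible in sau/tau/afau"),
                 unit), call. = FALSE)
  }
  list(scale = exp(log_scale),
       dims = c(L = unname(dims["L"]), T = unname(dims["T"]),
                C = unname(dims["M"])))
}

#' Convert a physical quantity to simulation units
#'
#' The unit string is a product of powers of length, time and concentration
#' units separated by spaces, `*` or `/` (e.g. `"um^2 mL min^-1 ng^-1"`,
#' `"ng mL^-1 mm^-1"`, `"mm^2/s"`).  The simulation units `sau`, `tau`,
#' `afau` are themselves valid tokens, so `to_sim_units(1, "sau", u) == 1`.
#'
#' @param value Numeric value(s) in the given physical unit.
#' @param unit Unit string.
#' @param units An [unit_system()].
#' @return Dimensionless value(s) in simulation units.
#' @export
to_sim_units <- function(value, unit, units = unit_system()) {
  pu <- parse_unit(unit, units)
  base <- value * pu$scale
  unname(base / (units$sau^pu$dims[["L"]] * units$tau^pu$dims[["T"]] *
                   units$afau^pu$dims[["C"]]))
}

#' Convert a simulation-unit value back to a physical unit
#'
#' Inverse of [to_sim_units()]; round-trips to within 1e-12 relative.
#'
#' @inheritParams to_sim_units
#' @export
from_sim_units <- function(value, unit, units = unit_system()) {
  pu <- parse_unit(unit, units)
  base <- value * (units$sau^pu$dims[["L"]] * units$tau^pu$dims[["T"]] *
                     units$afau^pu$dims[["C"]])
  unname(base / pu$scale)
}

# Physical parameter values with their unit strings (headline runs for the
# ranged parameters M, V_pT, V_uc).
physical_parameter_table <- function() {
  data.frame(
    symbol = c("M", "eps", "alpha_p", "alpha_pSC", "af_p", "G_m", "G_M",
               "chi", "R_c", "T_c", "delta4", "D_af", "V_pT", "V_uc",
               "V_d", "tgr_per_year", "dt_min", "dt_max"),
    value = c(1e-9, 1.5625, 0, 0.000538889, 1800, 14, 42,
              8.33333, 10, 3000, 40, 4.24e-5, 47.3, 2.3e-4,
              0.92, 1.35, 26, 1300),
    unit = c("mm^2/s", "um^2", "mL hr^-1 pg^-1", "mL hr^-1 pg^-1",
             "pg mL^-1", "ng mL^-1 mm^-1", "ng mL^-1 mm^-1",
             "um^2 mL min^-1 ng^-1", "um", "pg mL^-1", "um", "mm^2/s",
             "pg mL^-1 s^-1", "s^-1", "hr^-1", "1", "min", "min"),
    stringsAsFactors = FALSE
  )
}

#' Default model parameters in simulation units
#'
#' Converts the full physical parameter set (chemotactic sensitivity,
#' activation thresholds, AF kinetics, Cahn-Hilliard mobility and interface
#' width, tip-cell geometry, time-step bounds) to simulation units.  Ranged
#' parameters default to the headline values M = 1e-9 mm^2/s,
#' V_pT = 47.3 pg mL^-1 s^-1, V_uc = 2.3e-4 s^-1.
#'
#' The tumor growth rate is stored as `tgr`, the per-tau multiplicative
#' volume factor derived from the 35%-per-year volumetric rate.  Two printed
#' nondimensional values in the source table (V_d, M) do not agree exactly
#' with their physical values; the physical values are authoritative here
#' and any entry can be overridden via `...`.
#'
#' @param units An [unit_system()].
#' @param ... Named overrides, already in simulation units
#'   (e.g. `V_uc = 1.0`).
#' @return An object of class `rh_params` (a named list), validated.
#' @examples
#' p <- default_parameters()
#' p$T_c    # 0.5 afau
#' p$chi    # 0.002031 sau^2/(afau tau)
#' @export
default_parameters <- function(units = unit_system(), ...) {
  tab <- physical_parameter_table()
  p <- list()
  for (i in seq_len(nrow(tab))) {
    sym <- tab$symbol[i]
    if (sym == "tgr_per_year") next
    p[[sym]] <- to_sim_units(tab$value[i], tab$unit[i], units)
  }
  # volumetric growth factor per tau: 1.35^ (tau / one year)
  tgr_y <- tab$value[tab$symbol == "tgr_per_year"]
  p$tgr <- tgr_y^(units$tau / .MIN_PER_YEAR)
  p$alpha_dt <- 100        # adaptive-step weight, dimensionless
  p$c_tol <- 1e-3          # activation threshold slack on c >= 1
  p$v_min <- 1e-6          # tip-speed floor for the imprint division, sau/tau
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), c(names(p), "tgr"))
    if (length(bad)) {
      stop("unknown parameter override(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    p[names(ov)] <- ov
  }
  p$units <- units
  class(p) <- "rh_params"
  validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Checks the structural invariants: `G_m < G_M`, nonnegative rates, lengths
#' and diffusivities, `dt_min <= dt_max`, `af_p > 0`, `R_c > 0`,
#' `delta4 > 0`.
#'
#' @param p An `rh_params` object.
#' @return `p`, invisibly; errors if an invariant is violated.
#' @export
validate_parameters <- function(p) {
  stopifnot(inherits(p, "rh_params"))
  chk <- function(cond, msg) if (!isTRUE(cond)) stop("invalid parameters: ",
                                                    msg, call. = FALSE)
  chk(p$G_m < p$G_M, "G_m must be < G_M")
  nonneg <- c("M", "eps", "alpha_p", "alpha_pSC", "D_af", "V_pT", "V_uc",
              "V_d", "chi")
  for (s in nonneg) chk(p[[s]] >= 0, paste(s, "must be nonnegative"))
  chk(p$dt_min <= p$dt_max, "dt_min must be <= dt_max")
  chk(p$dt_min > 0, "dt_min must be positive")
  chk(p$af_p > 0, "af_p must be positive")
  chk(p$R_c > 0, "R_c must be positive")
  chk(p$delta4 > 0, "delta4 must be positive")
  chk(p$T_c >= 0, "T_c must be nonnegative")
  chk(p$tgr > 0, "tgr must be positive")
  invisible(p)
}

#' @export
print.rh_params <- function(x, ...) {
  cat("<rh_params> (simulation units)\n")
  nm <- setdiff(names(x), "units")
  for (s in nm) cat(sprintf("  %-9s %g\n", s, x[[s]]))
  invisible(x)
}

#' Load parameters from a config file
#'
#' Reads a JSON (or YAML, if the `yaml` package is installed) file whose
#' `parameters` entries are objects `{"value": v, "unit": "..."}`; converts
#' each to simulation units on top of [default_parameters()].
#'
#' @param path Path to the config file.
#' @param units Optional [unit_system()]; a `units` block in the file
#'   (fields `sau`, `tau`, `afau`) takes precedence.
#' @param quiet Suppress the per-parameter conversion log.
#' @return An `rh_params` object.
#' @export
load_parameters <- function(path, units = NULL, quiet = FALSE) {
  cfg <- read_config(path)
  if (is.null(units)) {
    ub <- cfg$units
    units <- if (is.null(ub)) unit_system() else
      unit_system(sau = ub$sau %||% 800, tau = ub$tau %||% 26,
                  afau = ub$afau %||% 6000)
  }
  p <- default_parameters(units)
  for (nm in names(cfg$parameters)) {
    ent <- cfg$parameters[[nm]]
    val <- if (is.list(ent)) to_sim_units(ent$value, ent$unit %||% "1", units)
           else as.numeric(ent)
    if (!quiet && is.list(ent)) {
      message(sprintf("parameter %s: %g [%s] -> %g [sim units]",
                      nm, ent$value, ent$unit %||% "1", val))
    }
    p[[nm]] <- val
  }
  validate_parameters(p)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
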