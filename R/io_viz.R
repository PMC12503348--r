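# Readers/writers for run artifacts: legacy-VTK structured-points fields,
# history CSV, portable-bitmap masks with a JSON sidecar, config files and
# run metadata.  Display convention (recorded in the field metadata): the
# capillaries are the c = 0 isosurface, the tumor the phi = 0.5 isosurface.

#' Write simulation fields to a VTK file
#'
#' Writes `c`, `mu`, `af` and `phi` as point data on the structured grid in
#' legacy VTK ASCII (STRUCTURED_POINTS), readable by standard viewers.
#' Values are printed with full double precision so a read-back is
#' bitwise-equal.
#'
#' @param state An `rh_state` (or a named list of field arrays plus a
#'   `domain` argument).
#' @param path Output file path.
#' @param fields Optional named list of arrays overriding the state fields.
#' @param domain Domain (defaults to `state$domain`).
#' @return `path`, invisibly.
#' @export
write_fields <- function(state, path, fields = NULL, domain = NULL) {
  if (is.null(fields)) {
    stopifnot(inherits(state, "rh_state"))
    domain <- state$domain
    phi <- tumor_indicator(state$tumor, state$t, domain)
    mu <- state$capillaries$mu
    if (is.null(mu)) {
      mu <- array(chemical_potential(as.vector(state$capillaries$c),
                                     state$p, state$ops), dim = domain$n)
    }
    fields <- list(c = state$capillaries$c, mu = mu,
                   af = if (is.null(state$af)) empty_field(domain)
                        else state$af$af,
                   phi = phi)
  }
  stopifnot(!is.null(domain))
  n3 <- c(domain$n, rep(1L, 3 - domain$dim))
  o3 <- c(domain$origin, rep(0, 3 - domain$dim))
  con <- tryCatch(suppressWarnings(file(path, "w")),
                  error = function(e) stop("unwritable path '", path, "': ",
                                           conditionMessage(e),
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "rhangio fields (display: capillaries isosurface c=0, tumor phi=0.5; units sau/tau/afau)",
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d %d", n3[1], n3[2], n3[3]),
    sprintf("ORIGIN %.17g %.17g %.17g", o3[1], o3[2], o3[3]),
    sprintf("SPACING %.17g %.17g %.17g", domain$h, domain$h, domain$h),
    sprintf("POINT_DATA %d", prod(n3))), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.17g", as.vector(fields[[nm]])), con)
  }
  invisible(path)
}

#' Read fields written by [write_fields()]
#'
#' @param path VTK file path.
#' @return List with `dims`, `origin`, `spacing` and `fields` (named list
#'   of arrays).
#' @export
read_fields <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(grep("^DIMENSIONS", lines, value = TRUE),
                              " ")[[1]][-1])
  origin <- as.numeric(strsplit(grep("^ORIGIN", lines, value = TRUE),
                                " ")[[1]][-1])
  spacing <- as.numeric(strsplit(grep("^SPACING", lines, value = TRUE),
                                 " ")[[1]][-1])
  npts <- prod(dims)
  starts <- grep("^SCALARS", lines)
  fields <- list()
  for (s in starts) {
    nm <- strsplit(lines[s], " ")[[1]][2]
    vals <- as.numeric(lines[(s + 2):(s + 1 + npts)])
    fields[[nm]] <- array(vals, dim = dims[dims > 1])
  }
  list(dims = dims, origin = origin, spacing = spacing, fields = fields)
}

#' Export the per-step history table as CSV
#'
#' Columns: step, t_tau, t_days, dt, n_active_tips, af_mean, af_max,
#' af_min, tumor_volume, vessel_volume_fraction, energy.  `t_days`
#' converts tau to days through the time unit (26 min by default).
#'
#' @param state An `rh_state` (or a bare history data.frame plus `tau_min`).
#' @param path Output CSV path.
#' @param tau_min Minutes per tau (taken from the state when available).
#' @return The exported data.frame, invisibly.
#' @export
export_history <- function(state, path, tau_min = NULL) {
  if (inherits(state, "rh_state")) {
    hist <- state$history
    tau_min <- state$p$units$tau
  } else {
    hist <- state
    if (is.null(tau_min)) tau_min <- 26
  }
  out <- data.frame(step = hist$step, t_tau = hist$t_tau,
                    t_days = hist$t_tau * tau_min / 1440,
                    dt = hist$dt, n_active_tips = hist$n_active_tips,
                    af_mean = hist$af_mean, af_max = hist$af_max,
                    af_min = hist$af_min, tumor_volume = hist$tumor_volume,
                    vessel_volume_fraction = hist$vessel_volume_fraction,
                    energy = hist$energy)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Export the tip-cell event log as CSV
#'
#' @param state An `rh_state`.
#' @param path Output CSV path.
#' @return The event data.frame, invisibly.
#' @export
export_events <- function(state, path) {
  utils::write.csv(state$events, path, row.names = FALSE)
  invisible(state$events)
}

#' Write run metadata as JSON
#'
#' Records the seed, package version, parameter set (simulation units) and
#' a parameter hash for reproducibility audits.
#'
#' @param state An `rh_state`.
#' @param path Output JSON path.
#' @return The metadata list, invisibly.
#' @export
write_run_metadata <- function(state, path) {
  pnum <- state$p[vapply(state$p, is.numeric, TRUE)]
  meta <- list(
    package = "rhangio",
    version = as.character(utils::packageVersion("rhangio")),
    seed = state$seed,
    steps = state$step_index,
    t_tau = state$t,
    units = unclass(state$p$units),
    parameters = pnum,
    parameter_hash = param_hash(pnum),
    display = list(capillaries_isosurface = 0, tumor_isosurface = 0.5)
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(meta)
}

param_hash <- function(p) {
  s <- paste(names(p), vapply(p, function(v) sprintf("%.17g", v), ""),
             collapse = ";")
  # small rolling hash; avoids a digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Write a mask as ASCII portable bitmap (P1) with a JSON sidecar
#'
#' The sidecar `<path>.json` stores `pixel_size_um` and `provenance`.
#'
#' @param mask An `rh_mask`.
#' @param path Output `.pbm` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "rh_mask"))
  px <- mask$pixels
  # PBM raster is row-major top-to-bottom; store y as rows, x as columns
  img <- t(px)[ncol(px):1, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P1", sprintf("%d %d", ncol(img), nrow(img))), con)
  utils::write.table(img, con, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(pixel_size_um = mask$pixel_size,
                            provenance = mask$provenance),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a mask written by [write_mask()]
#'
#' @param path `.pbm` path (expects the `.json` sidecar alongside).
#' @param pixel_size Override for the pixel size when no sidecar exists.
#' @return An `rh_mask`.
#' @export
read_mask <- function(path, pixel_size = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  stopifnot(lines[1] == "P1")
  dims <- as.integer(strsplit(trimws(lines[2]), "[[:space:]]+")[[1]])
  vals <- as.integer(unlist(strsplit(trimws(lines[-(1:2)]),
                                     "[[:space:]]+")))
  img <- matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
  px <- t(img[nrow(img):1, , drop = FALSE])
  sidecar <- paste0(path, ".json")
  prov <- "file"
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    pixel_size <- pixel_size %||% meta$pixel_size_um
    prov <- meta$provenance %||% "file"
  }
  if (is.null(pixel_size)) stop("pixel_size not given and no sidecar found",
                                call. = FALSE)
  vessel_mask(px, pixel_size, provenance = prov)
}

# read a JSON (or YAML) config file into a list
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config requires the 'yaml' package; use JSON instead",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Number of snapshot files for a cadence
#'
#' Writing every `k`-th step of an `n`-step run produces `ceiling(n / k)`
#' files.
#'
#' @param n_steps Steps executed.
#' @param cadence Snapshot interval `k`.
#' @return Integer file count.
#' @export
snapshot_count <- function(n_steps, cadence) {
  as.integer(ceiling(n_steps / cadence))
}
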