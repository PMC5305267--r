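# Configuration files, trace serialization and run manifests.  Parameters
# live in a single human-editable YAML file; traces are CSV; field
# snapshots are written as plain CSV matrices with a JSON index.

config_sections <- c("params", "solver", "stimulus", "experiment")

#' Load a configuration file
#'
#' Reads a YAML configuration with optional sections `params`, `solver`,
#' `stimulus` and `experiment`.  Every key of [polar_params()],
#' [solver_config()] and [stimulus_protocol()] is accepted under its
#' section; unknown sections or keys are rejected, missing ones take the
#' documented defaults, and the assembled objects are validated.
#'
#' @param path Path to a YAML file; an empty or absent-section file yields
#'   the full default set.
#' @return A list with `params` (`polar_params`), `solver`
#'   (`solver_config`), `stimulus` (`polar_protocol`) and `experiment`
#'   (plain list, passed through).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), config_sections)
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  get_sec <- function(nm) if (is.null(raw[[nm]])) list() else raw[[nm]]
  par_raw <- get_sec("params")
  # YAML 1.1 parses a bare `N:` key as a boolean; the only boolean-like key
  # in the schema is the grid size, so map it back
  names(par_raw)[names(par_raw) %in% c("FALSE", "F")] <- "N"
  params <- do.call(polar_params, par_raw)
  solver <- do.call(solver_config, get_sec("solver"))
  stim <- get_sec("stimulus")
  if (!is.null(stim$schedule)) stim$schedule <- tibble::as_tibble(stim$schedule)
  stimulus <- do.call(stimulus_protocol, stim)
  list(params = params, solver = solver, stimulus = stimulus,
       experiment = get_sec("experiment"))
}

#' Write a configuration file
#'
#' Serializes a parameter set, solver configuration and stimulus protocol
#' to YAML so that [load_config()] round-trips them.
#'
#' @param path Output path.
#' @param params A `polar_params`.
#' @param solver A `solver_config`.
#' @param stimulus A `polar_protocol`.
#' @param experiment Optional plain list of experiment options.
#' @return `path`, invisibly.
#' @export
write_config <- function(path, params = polar_params(),
                         solver = solver_config(),
                         stimulus = stimulus_protocol("none"),
                         experiment = NULL) {
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, is.null, logical(1))]
  }
  st <- strip(stimulus)
  if (!is.null(st$schedule)) st$schedule <- as.list(st$schedule)
  out <- list(params = strip(params), solver = strip(solver), stimulus = st)
  if (!is.null(experiment)) out$experiment <- experiment
  yaml::write_yaml(out, path)
  invisible(path)
}

trace_columns <- c("t", "max_u", "total_u", "total_f", "mt",
                   "polarity_angle_deg", "polarized_flag", "mass_u",
                   "mass_v", "clipped")

#' Write / read a simulation trace
#'
#' `write_trace()` stores the scalar metric series of a trace as CSV
#' (units: t in s, concentrations in um^-2, tension in pN/um, angles in
#' degrees in `[0, 360)`); `read_trace()` reads it back into a metrics
#' tibble, checking the column schema.
#'
#' @param trace A `polar_trace`.
#' @param path CSV file path.
#' @return `write_trace()`: the path, invisibly. `read_trace()`: a tibble
#'   with the trace metric columns.
#' @export
write_trace <- function(trace, path) {
  m <- trace$metrics
  uH <- tryCatch(u_high(trace$params), error = function(e) NA_real_)
  m$polarized_flag <- !is.na(uH) & m$max_u >= 0.95 * uH
  m <- m[, intersect(trace_columns, names(m))]
  write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  m <- read.csv(path)
  missing_cols <- setdiff(setdiff(trace_columns, c("polarized_flag", "clipped")),
                          names(m))
  if (length(missing_cols))
    stop("trace file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  tibble::as_tibble(m)
}

#' Write field snapshots
#'
#' Stores the full-field snapshots of a trace (if any were recorded) as
#' one CSV matrix per field and time, plus a JSON index with the grid
#' metadata.
#'
#' @param trace A `polar_trace` run with `field_snapshot_every > 0`.
#' @param dir Output directory (created if needed).
#' @return The index file path, invisibly.
#' @export
write_fields <- function(trace, dir) {
  if (!length(trace$snapshots)) stop("trace has no field snapshots")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- list(N = trace$geometry$N, L = trace$geometry$L,
              h = trace$geometry$h, times = numeric(0), files = list())
  for (i in seq_along(trace$snapshots)) {
    sn <- trace$snapshots[[i]]
    fu <- file.path(dir, sprintf("u_%04d.csv", i))
    ff <- file.path(dir, sprintf("f_%04d.csv", i))
    utils::write.table(sn$u, fu, sep = ",", row.names = FALSE, col.names = FALSE)
    utils::write.table(sn$f, ff, sep = ",", row.names = FALSE, col.names = FALSE)
    idx$times <- c(idx$times, sn$t)
    idx$files[[i]] <- list(t = sn$t, u = basename(fu), f = basename(ff))
  }
  index_path <- file.path(dir, "index.json")
  jsonlite::write_json(idx, index_path, auto_unbox = TRUE, digits = NA)
  invisible(index_path)
}

#' Run manifest
#'
#' Writes a JSON manifest that pins down a run: the full configuration,
#' seeds, package version, timestamp, output inventory and solver
#' diagnostics (negative-concentration clips, Rac mass drift per second).
#' Re-running the same package build from a manifest's configuration and
#' seed reproduces the trace exactly.
#'
#' @param trace A `polar_trace`.
#' @param path Output JSON path.
#' @param seed The seed(s) used by the run, if any.
#' @param outputs Character vector of files written for this run.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(trace, path, seed = NULL, outputs = character()) {
  m <- trace$metrics
  mass <- m$mass_u + m$mass_v
  drift <- if (nrow(m) > 1)
    max(abs(diff(mass))) / diff(m$t)[1] else 0
  man <- list(
    package = "polartension",
    version = as.character(utils::packageVersion("polartension")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    params = unclass(trace$params),
    solver = unclass(trace$config),
    protocol = if (!is.null(trace$protocol)) {
      pr <- unclass(trace$protocol)
      pr$schedule <- if (!is.null(pr$schedule)) as.list(pr$schedule)
      pr[!vapply(pr, is.null, logical(1))]
    },
    diagnostics = list(negative_clips = trace$clipped,
                       max_mass_drift_per_s = drift),
    outputs = as.list(outputs))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
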