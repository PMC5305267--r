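# Time integration of the phase-field model.  The heavy loop lives in
# compiled code (src/stepper.cpp); R drives it segment-by-segment over the
# piecewise-constant stimulus schedule and assembles tidy traces.

#' Solver configuration
#'
#' @param t_end Simulation horizon (s).
#' @param dt Time step (s); defaults to the `dt` of the parameter set at
#'   run time when `NULL`.
#' @param snapshot_every Interval between recorded trace rows (s).
#' @param delta_phi Relative floor applied to the phase-field weights when
#'   recovering concentrations from the weighted state; in (0, 0.1].
#' @param stabilization_coeff Multiplier (>= 1) on the implicit spectral
#'   diffusion operator; 1 integrates constant-coefficient diffusion
#'   exactly per Fourier mode.
#' @param matched_measure When `TRUE` (default), the cytosol-side membrane
#'   exchange uses the same interface weight `B(phi)` as the membrane
#'   side, so the total Rac mass (membrane + cytosol) is conserved exactly
#'   and the cytosolic pool stays at its resting level, as the model
#'   intends (tension, not Rac-GDP depletion, is the global inhibitor).
#'   `FALSE` uses an `|grad phi|` weight on the cytosol side instead; the
#'   mismatch of the two interface measures then feeds a spurious net Rac
#'   source (kept for diagnostics of that formulation).
#' @param field_snapshot_every Interval between stored full-field snapshots
#'   (s); 0 stores none.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(t_end = 100, dt = NULL, snapshot_every = 1,
                          delta_phi = 0.01, stabilization_coeff = 1,
                          matched_measure = TRUE,
                          field_snapshot_every = 0) {
  stopifnot(t_end > 0, is.null(dt) || dt > 0,
            snapshot_every > 0, field_snapshot_every >= 0)
  if (delta_phi <= 0 || delta_phi > 0.1)
    stop("delta_phi must lie in (0, 0.1]")
  if (stabilization_coeff < 1)
    stop("stabilization_coeff must be >= 1 (the maximum phase-field mobility ratio)")
  structure(list(t_end = t_end, dt = dt, snapshot_every = snapshot_every,
                 delta_phi = delta_phi,
                 stabilization_coeff = stabilization_coeff,
                 matched_measure = matched_measure,
                 field_snapshot_every = field_snapshot_every),
            class = "solver_config")
}

floored_weights <- function(geometry, delta_phi) {
  list(Bt = pmax(geometry$mem_w, delta_phi * max(geometry$mem_w)),
       phit = pmax(geometry$phi, delta_phi))
}

#' Initial cell state
#'
#' Homogeneous resting state `u0`, `v0`, `f0` on the cell support, with
#' optional independent zero-mean Gaussian noise added to `u` and `v`
#' inside the cell (concentrations are clipped at zero).
#'
#' @param geometry A `polar_geometry`.
#' @param params A `polar_params`.
#' @param noise_var Variance of the Gaussian perturbation (um^-4 units of
#'   concentration squared); 0 gives the exactly homogeneous state.
#' @param seed Integer seed for the noise draw (required if `noise_var > 0`).
#' @return A list of class `polar_state` with concentration fields `u`,
#'   `v`, `f`, time `t` and tension `mt`.
#' @export
initial_state <- function(geometry, params, noise_var = 0, seed = NULL) {
  N <- geometry$N
  inside <- geometry$phi > 0.5
  mk <- function(base) {
    z <- matrix(base, N, N)
    z
  }
  u <- mk(params$u0); v <- mk(params$v0); f <- mk(params$f0)
  if (noise_var > 0) {
    if (is.null(seed)) stop("a seed is required when noise_var > 0")
    sd0 <- sqrt(noise_var)
    noise <- with_seed(seed, function() {
      list(nu = matrix(rnorm(N^2, 0, sd0), N, N),
           nv = matrix(rnorm(N^2, 0, sd0), N, N))
    })
    u <- pmax(u + noise$nu * inside, 0)
    v <- pmax(v + noise$nv * inside, 0)
  }
  state <- list(u = u, v = v, f = f, t = 0,
                mt = NA_real_)
  state$mt <- membrane_tension(f, geometry, params)
  class(state) <- "polar_state"
  state
}

#' @export
print.polar_state <- function(x, ...) {
  cat(sprintf("<polar_state> t=%.2f s  mt=%.4g pN/um  max u=%.4g  max f=%.4g\n",
              x$t, x$mt, max(x$u), max(x$f)))
  invisible(x)
}

# polarity angle from the B(phi)-weighted first moment of u; NA when the
# normalized moment is below the noise floor
moment_angle <- function(Mx, My, mass_u, geometry, floor_frac = 0.02) {
  rc <- sqrt(geometry$area / pi)
  len <- sqrt(Mx^2 + My^2) / pmax(mass_u, .Machine$double.eps)
  ang <- (atan2(My, Mx) * 180 / pi) %% 360
  ang[len < floor_frac * rc] <- NA_real_
  ang
}

metrics_to_tibble <- function(m, geometry) {
  colnames(m) <- c("t", "max_u", "total_u", "total_f", "mt", "Mx", "My",
                   "mass_u", "mass_v", "clipped")
  tb <- tibble::as_tibble(m)
  tb$polarity_angle_deg <- moment_angle(tb$Mx, tb$My, tb$mass_u, geometry)
  tb
}

# Run the phase-field integrator over a table of segments
# (t0, t1, field [list of k_s matrices or NULL], mt_override [NA = dynamic]).
run_pf <- function(state, geometry, params, config, segments) {
  dt <- if (is.null(config$dt)) params$dt else config$dt
  fw <- floored_weights(geometry, config$delta_phi)
  Wu <- geometry$mem_w * state$u
  Wv <- geometry$phi * state$v
  Wf <- geometry$phi * state$f
  rec_every <- max(1L, as.integer(round(config$snapshot_every / dt)))
  snap_every <- if (config$field_snapshot_every > 0)
    max(1L, as.integer(round(config$field_snapshot_every / dt))) else 0L
  zero <- matrix(0, geometry$N, geometry$N)
  if (!("mt_override" %in% names(segments)))
    segments$mt_override <- NA_real_

  all_metrics <- list()
  snaps <- list()
  t_base <- state$t
  for (i in seq_len(nrow(segments))) {
    nsteps <- as.integer(round((segments$t1[i] - segments$t0[i]) / dt))
    if (nsteps <= 0) next
    ks <- segments$field[[i]]
    if (is.null(ks)) ks <- zero
    mt_ov <- segments$mt_override[i]
    out <- .pf_run_cpp(Wu, Wv, Wf,
                       geometry$mem_w, geometry$phi, geometry$grad_phi_mag,
                       fw$Bt, fw$phit, ks, geometry$xc, geometry$yc,
                       unclass(params), dt, nsteps, geometry$h, geometry$dA,
                       rec_every, if (is.na(mt_ov)) -1 else mt_ov,
                       isTRUE(config$matched_measure), snap_every,
                       config$stabilization_coeff)
    m <- out$metrics
    m[, 1] <- m[, 1] + t_base + segments$t0[i]
    all_metrics[[length(all_metrics) + 1]] <- m
    if (snap_every > 0) {
      st <- out$snap_t + t_base + segments$t0[i]
      for (k in seq_along(st)) {
        snaps[[length(snaps) + 1]] <-
          list(t = st[k], u = out$snap_u[, , k], f = out$snap_f[, , k])
      }
    }
    Wu <- out$Wu; Wv <- out$Wv; Wf <- out$Wf
  }
  m <- do.call(rbind, all_metrics)
  m <- m[!duplicated(round(m[, 1], 9)), , drop = FALSE]
  final <- list(u = Wu / fw$Bt, v = Wv / fw$phit, f = Wf / fw$phit,
                t = t_base + segments$t1[nrow(segments)],
                mt = m[nrow(m), 5])
  class(final) <- "polar_state"
  list(metrics = metrics_to_tibble(m, geometry), final = final,
       snapshots = snaps, clipped = m[nrow(m), 10])
}

#' Rested cell state
#'
#' Integrates the unstimulated model until the initial homogeneous pool
#' has converted and the cell sits in its resting low-Rac-GTP state; the
#' natural starting point for stimulus-threshold measurements.
#'
#' @param geometry A `polar_geometry`.
#' @param params A `polar_params`.
#' @param t_rest Relaxation time (s).
#' @param config Optional `solver_config`.
#' @return A `polar_state` with `t` reset to 0.
#' @export
rested_state <- function(geometry, params, t_rest = 80, config = NULL) {
  cfg <- if (is.null(config)) solver_config(t_end = t_rest) else config
  cfg$t_end <- t_rest
  s0 <- initial_state(geometry, params)
  segs <- tibble::tibble(t0 = 0, t1 = t_rest, field = list(NULL),
                         mt_override = NA_real_)
  out <- run_pf(s0, geometry, params, cfg, segs)
  st <- out$final
  st$t <- 0
  st
}

#' Advance the model by one time step
#'
#' Single step of the stabilized exponential Fourier-spectral scheme for
#' the three weighted fields, with the stimulus field held fixed and
#' membrane tension recomputed from the current F-actin total (mechanical
#' equilibrium is treated as instantaneous).
#'
#' @param state A `polar_state`.
#' @param geometry A `polar_geometry`.
#' @param params A `polar_params`.
#' @param k_s_field Stimulus rate matrix (1/s); defaults to zero.
#' @param config A [solver_config()].
#' @return The advanced `polar_state` (time moved by one `dt`).
#' @export
step <- function(state, geometry, params, k_s_field = NULL,
                 config = solver_config()) {
  if (is.null(k_s_field)) k_s_field <- matrix(0, geometry$N, geometry$N)
  if (any(k_s_field < 0)) stop("k_s_field must be non-negative")
  dt <- if (is.null(config$dt)) params$dt else config$dt
  segs <- tibble::tibble(t0 = 0, t1 = dt, field = list(k_s_field),
                         mt_override = NA_real_)
  cfg <- config
  cfg$snapshot_every <- dt
  out <- run_pf(state, geometry, params, cfg, segs)
  out$final
}

new_polar_trace <- function(metrics, events, final, geometry, params,
                            protocol, config, snapshots, clipped) {
  structure(list(metrics = metrics, events = events, final_state = final,
                 geometry = geometry, params = params, protocol = protocol,
                 config = config, snapshots = snapshots, clipped = clipped),
            class = "polar_trace")
}

#' @export
print.polar_trace <- function(x, ...) {
  n <- nrow(x$metrics)
  cat(sprintf("<polar_trace> %d rows over t = [%g, %g] s\n",
              n, x$metrics$t[1], x$metrics$t[n]))
  cat(sprintf("  final: max_u=%.4g  total_u=%.4g  mt=%.4g  angle=%s\n",
              x$metrics$max_u[n], x$metrics$total_u[n], x$metrics$mt[n],
              ifelse(is.na(x$metrics$polarity_angle_deg[n]), "undef",
                     sprintf("%.1f deg", x$metrics$polarity_angle_deg[n]))))
  if (x$clipped > 0)
    cat(sprintf("  note: %d negative-concentration clips during the run\n",
                as.integer(x$clipped)))
  invisible(x)
}

#' Simulate the phase-field polarity model
#'
#' Integrates the coupled Rac-GTP / Rac-GDP / F-actin equations under a
#' stimulus protocol and records polarity metrics (maximum membrane
#' Rac-GTP, totals, membrane tension, polarity angle) at regular
#' intervals.  Deterministic given the protocol seed.
#'
#' @param initial A `polar_state` from [initial_state()].
#' @param geometry A `polar_geometry`.
#' @param params A `polar_params`.
#' @param protocol A [stimulus_protocol()].
#' @param config A [solver_config()].
#' @return A `polar_trace`; its `$metrics` tibble has columns `t`, `max_u`,
#'   `total_u`, `total_f`, `mt`, `polarity_angle_deg`, `mass_u`, `mass_v`.
#' @examples
#' \donttest{
#' p <- polar_params(N = 64)
#' g <- make_disk(p)
#' tr <- simulate(initial_state(g, p), g, p,
#'                stimulus_protocol("graded", ks_amp = 0.01, ks_dur = 20),
#'                solver_config(t_end = 40))
#' tail(tr$metrics)
#' }
#' @export
simulate <- function(initial, geometry, params,
                     protocol = stimulus_protocol("none"),
                     config = solver_config()) {
  segs <- protocol_segments(protocol, geometry, params, config$t_end)
  out <- run_pf(initial, geometry, params, config, segs)
  new_polar_trace(out$metrics, attr(segs, "events"), out$final, geometry,
                  params, protocol, config, out$snapshots, out$clipped)
}
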