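# Alternative formulation: the flat ("traditional") 2D polarity model in
# which the membrane overlaps the cytosol on a hard disk mask, and membrane
# tension throttles actin polymerization through a Brownian-ratchet load
# factor instead of a Hill-type brake.

#' Brownian-ratchet load factor
#'
#' The probability factor `exp(-mt * delta / kBT)` by which a load (here
#' membrane tension acting over the monomer step `delta`) slows actin
#' polymerization in the elastic Brownian-ratchet picture.
#'
#' @param mt Membrane tension (pN/um), non-negative; scalar or vector.
#' @param params A `polar_params` (uses `delta`, `kBT`).
#' @return Multiplier in `(0, 1]`; 1 at zero load, strictly decreasing.
#' @examples
#' p <- polar_params()
#' ratchet_factor(0, p)                         # 1
#' ratchet_factor(log(2) * p$kBT / p$delta, p)  # 0.5
#' @export
ratchet_factor <- function(mt, params) {
  if (any(mt < 0)) stop("mt must be non-negative")
  exp(-mt * params$delta / params$kBT)
}

#' Disk mask geometry for the flat 2D model
#'
#' Binary indicator of a disk of radius `R` centered in the domain, on the
#' same grid conventions as the phase-field geometries.  Diffusion on the
#' mask uses a conservative zero-flux finite-difference Laplacian.
#'
#' @param params A [polar_params()].
#' @return A `polar_geometry` of kind `"disk_mask"` whose `phi` is the
#'   binary mask.
#' @export
make_disk_mask <- function(params) {
  N <- params$N
  h <- params$L / N
  xs <- (seq_len(N) - 1) * h - params$L / 2
  rho <- sqrt(outer(xs^2, xs^2, "+"))
  phi <- (rho <= params$R) * 1.0
  new_polar_geometry(phi, params, kind = "disk_mask")
}

# driver analogous to run_pf for the masked explicit integrator
run_trad <- function(state, geometry, params, config, segments) {
  dt <- if (is.null(config$dt)) params$dt else config$dt
  rec_every <- max(1L, as.integer(round(config$snapshot_every / dt)))
  snap_every <- if (config$field_snapshot_every > 0)
    max(1L, as.integer(round(config$field_snapshot_every / dt))) else 0L
  zero <- matrix(0, geometry$N, geometry$N)
  if (!("mt_override" %in% names(segments)))
    segments$mt_override <- NA_real_
  u <- state$u * geometry$phi
  v <- state$v * geometry$phi
  f <- state$f * geometry$phi
  all_metrics <- list()
  snaps <- list()
  t_base <- state$t
  for (i in seq_len(nrow(segments))) {
    nsteps <- as.integer(round((segments$t1[i] - segments$t0[i]) / dt))
    if (nsteps <= 0) next
    ks <- segments$field[[i]]
    if (is.null(ks)) ks <- zero
    mt_ov <- segments$mt_override[i]
    out <- .trad_run_cpp(u, v, f, geometry$phi, ks,
                         geometry$xc - geometry$center[["x"]],
                         geometry$yc - geometry$center[["y"]],
                         unclass(params), dt, nsteps, geometry$h,
                         geometry$dA, rec_every,
                         if (is.na(mt_ov)) -1 else mt_ov, snap_every)
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
    u <- out$u; v <- out$v; f <- out$f
  }
  m <- do.call(rbind, all_metrics)
  m <- m[!duplicated(round(m[, 1], 9)), , drop = FALSE]
  final <- list(u = u, v = v, f = f,
                t = t_base + segments$t1[nrow(segments)], mt = m[nrow(m), 5])
  class(final) <- "polar_state"
  list(metrics = metrics_to_tibble(m, geometry), final = final,
       snapshots = snaps, clipped = m[nrow(m), 10])
}

#' Simulate the flat 2D (traditional) polarity model
#'
#' Evolves the local kinetics with ordinary diffusion on a hard disk mask
#' (zero-flux boundary), with the F-actin production throttled by the
#' Brownian-ratchet factor [ratchet_factor()] instead of the saturating
#' tension brake.  Supports the same stimulus protocols as [simulate()].
#'
#' @param initial A `polar_state` (see [initial_state()], built on the
#'   mask geometry).
#' @param geometry A geometry from [make_disk_mask()].
#' @param params A `polar_params` (uses `delta`, `kBT` for the ratchet).
#' @param protocol A [stimulus_protocol()].
#' @param config A [solver_config()].
#' @return A `polar_trace`.
#' @export
simulate_traditional <- function(initial, geometry, params,
                                 protocol = stimulus_protocol("none"),
                                 config = solver_config()) {
  segs <- protocol_segments(protocol, geometry, params, config$t_end)
  out <- run_trad(initial, geometry, params, config, segs)
  new_polar_trace(out$metrics, attr(segs, "events"), out$final, geometry,
                  params, protocol, config, out$snapshots, out$clipped)
}

#' Aspiration-release experiment in the flat 2D model
#'
#' Same protocol as [aspiration_release()], run with the traditional
#' masked model: polarize, instantly multiply the tension, hold, release.
#'
#' @inheritParams aspiration_release
#' @return A `polar_trace` with an `aspiration` attribute.
#' @export
aspiration_release_traditional <- function(params, tension_multiplier = 25,
                                           t_aspirate = 100, t_release = 132,
                                           t_end = 450,
                                           warmup_amp = 0.004, warmup_dur = 20,
                                           geometry = NULL, config = NULL) {
  if (t_release <= t_aspirate) stop("t_release must exceed t_aspirate")
  if (is.null(geometry)) geometry <- make_disk_mask(params)
  cfg <- if (is.null(config)) solver_config(t_end = t_end) else config
  cfg$t_end <- t_end
  s0 <- initial_state(geometry, params)
  ks <- graded_matrix(geometry, warmup_amp, 0, params$R)
  run1 <- run_trad(s0, geometry, params, cfg,
                   tibble::tibble(t0 = c(0, warmup_dur),
                                  t1 = c(warmup_dur, t_aspirate),
                                  field = list(ks, NULL),
                                  mt_override = NA_real_))
  mt_hold <- params$mt0 *
    (1 + params$lam * sum(geometry$phi * run1$final$f) * geometry$dA) *
    tension_multiplier
  run2 <- run_trad(run1$final, geometry, params, cfg,
                   tibble::tibble(t0 = 0, t1 = t_release - t_aspirate,
                                  field = list(NULL), mt_override = mt_hold))
  run3 <- run_trad(run2$final, geometry, params, cfg,
                   tibble::tibble(t0 = 0, t1 = t_end - t_release,
                                  field = list(NULL), mt_override = NA_real_))
  metrics <- dplyr::bind_rows(run1$metrics, run2$metrics[-1, ],
                              run3$metrics[-1, ])
  tr <- new_polar_trace(metrics,
                        tibble::tibble(onset = c(0, t_aspirate),
                                       offset = c(warmup_dur, t_release)),
                        run3$final, geometry, params, protocol = NULL,
                        config = cfg, snapshots = NULL,
                        clipped = run3$clipped)
  attr(tr, "aspiration") <- list(t_aspirate = t_aspirate,
                                 t_release = t_release, mt_hold = mt_hold,
                                 tension_multiplier = tension_multiplier)
  tr
}
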