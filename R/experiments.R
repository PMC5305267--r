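# In-silico experiments and polarity analytics built on the solver and the
# stimulus protocols.

ang_diff <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

circ_mean_deg <- function(a) {
  a <- a[!is.na(a)]
  if (!length(a)) return(NA_real_)
  (atan2(mean(sin(a * pi / 180)), mean(cos(a * pi / 180))) * 180 / pi) %% 360
}

#' Detect polarization in a trace
#'
#' A run counts as polarized when the maximum membrane Rac-GTP reaches
#' within `tol_frac` of the high well-mixed state `u_H` and stays there to
#' the end of the trace; the polarization time is measured from stimulus
#' onset to the first crossing.
#'
#' @param trace A `polar_trace` (or any object with `$metrics`).
#' @param u_H High stable Rac-GTP state; computed from the trace's
#'   parameters when omitted.
#' @param tol_frac Relative tolerance below `u_H` that still counts as
#'   reached; in (0, 0.2].
#' @param onset Stimulus onset time (s); taken from the trace's recorded
#'   events when omitted.
#' @return A list with `polarized` (flag) and `polarization_time`
#'   (s; `NA` when not polarized).
#' @export
detect_polarization <- function(trace, u_H = NULL, tol_frac = 0.05,
                                onset = NULL) {
  if (tol_frac <= 0 || tol_frac > 0.2) stop("tol_frac must lie in (0, 0.2]")
  m <- trace$metrics
  if (is.null(u_H)) u_H <- u_high(trace$params)
  if (is.null(onset)) {
    ev <- trace$events
    onset <- if (!is.null(ev) && nrow(ev)) min(ev$onset) else 0
  }
  if (max(m$t) <= onset) stop("trace ends before the stimulus onset")
  thr <- (1 - tol_frac) * u_H
  sel <- m$t >= onset
  mu <- m$max_u[sel]
  tt <- m$t[sel]
  above <- mu >= thr
  if (!any(above)) return(list(polarized = FALSE, polarization_time = NA_real_))
  # first upward crossing (the decay of a supra-threshold initial pool is
  # not a polarization event)
  up <- which(above & !c(FALSE, above[-length(above)]))
  first <- if (length(up)) up[length(up)] else 1L
  stays <- all(mu[first:length(mu)] >= thr)
  if (!stays && any(above)) {
    first <- which(above)[1]
    stays <- all(mu[first:length(mu)] >= thr)
  }
  list(polarized = stays,
       polarization_time = if (stays) tt[first] - onset else NA_real_)
}

#' Polarity angle of a Rac-GTP field
#'
#' Direction (degrees, 0 = +x, counterclockwise) of the membrane-weighted
#' first moment of `u` about the cell center; `NA` when the normalized
#' moment is below the noise floor (e.g. for a uniform field).
#'
#' @param u_field Rac-GTP concentration matrix.
#' @param geometry A `polar_geometry`.
#' @param floor_frac Noise floor as a fraction of the effective cell
#'   radius.
#' @return Angle in `[0, 360)` degrees, or `NA`.
#' @export
polarity_angle <- function(u_field, geometry, floor_frac = 0.02) {
  if (any(u_field < 0)) stop("u_field must be non-negative")
  B <- geometry$mem_w
  Mx <- sum(B * u_field * (geometry$xc - geometry$center[["x"]])) * geometry$dA
  My <- sum(B * u_field * (geometry$yc - geometry$center[["y"]])) * geometry$dA
  mass <- sum(B * u_field) * geometry$dA
  moment_angle(Mx, My, mass, geometry, floor_frac)
}

#' Membrane profile of a field
#'
#' Bins the membrane-weighted values of a field by polar angle about the
#' cell center, giving the quasi-1D profile along the membrane ring.
#'
#' @param u_field Concentration matrix.
#' @param geometry A `polar_geometry`.
#' @param nbins Number of angular bins.
#' @return A tibble with `angle` (bin center, degrees) and `value`
#'   (membrane-weighted mean).
#' @export
membrane_profile <- function(u_field, geometry, nbins = 120) {
  B <- geometry$mem_w
  sel <- B > 1e-3 * max(B)
  ang <- (atan2(geometry$yc - geometry$center[["y"]],
                geometry$xc - geometry$center[["x"]]) * 180 / pi) %% 360
  bin <- pmin(floor(ang[sel] / (360 / nbins)) + 1, nbins)
  w <- B[sel]
  val <- u_field[sel]
  num <- tapply(w * val, bin, sum)
  den <- tapply(w, bin, sum)
  out <- tibble::tibble(angle = (as.numeric(names(num)) - 0.5) * 360 / nbins,
                        value = as.numeric(num / den))
  out[order(out$angle), ]
}

# number of connected arcs of the membrane ring above a threshold
count_fronts <- function(u_field, geometry, threshold, nbins = 120) {
  prof <- membrane_profile(u_field, geometry, nbins)
  hi <- prof$value > threshold
  if (!any(hi)) return(0L)
  if (all(hi)) return(1L)
  runs <- sum(diff(c(hi, hi[1])) == 1)
  max(runs, 1L)
}

# fraction of the membrane ring above a threshold
front_arc_fraction <- function(u_field, geometry, threshold, nbins = 120) {
  prof <- membrane_profile(u_field, geometry, nbins)
  mean(prof$value > threshold)
}

#' Polarization threshold by bisection
#'
#' Finds the stimulus strength at which a graded stimulus of fixed
#' duration (or fixed amplitude) just polarizes the resting cell, by
#' bisection on the amplitude (or duration) with [detect_polarization()]
#' as the oracle.
#'
#' @param params A `polar_params` (its `mt0` sets the tension condition).
#' @param ks_dur Stimulus duration (s) when bisecting the amplitude, or
#'   the fixed amplitude when `vary = "dur"`.
#' @param vary `"amp"` (default) or `"dur"`.
#' @param bracket Lower/upper bracket for the bisected quantity; the lower
#'   end must fail to polarize and the upper end must polarize.
#' @param tol_rel Relative tolerance of the bisection (default 2%).
#' @param settle Extra relaxation time after the stimulus (s) used to
#'   check that the polarized state persists.
#' @param geometry Optional prebuilt disk geometry (rebuilt from `params`
#'   when omitted).
#' @param config Optional `solver_config` template.
#' @return A list of class `polar_threshold_fit`: `threshold`, `vary`,
#'   `mt0`, and a `probes` tibble of the bisection history.
#' @export
threshold_search <- function(params, ks_dur = 20, vary = c("amp", "dur"),
                             bracket = c(5e-4, 0.05), tol_rel = 0.02,
                             settle = 120, geometry = NULL, config = NULL) {
  vary <- match.arg(vary)
  if (is.null(geometry)) geometry <- make_disk(params)
  uH <- u_high(params)
  s0 <- rested_state(geometry, params)
  probe <- function(x) {
    amp <- if (vary == "amp") x else ks_dur
    dur <- if (vary == "amp") ks_dur else x
    cfg <- if (is.null(config)) solver_config(t_end = dur + settle)
           else { config$t_end <- dur + settle; config }
    pr <- stimulus_protocol("graded", ks_amp = amp, ks_dur = dur, direction = 0)
    tr <- simulate(s0, geometry, params, pr, cfg)
    detect_polarization(tr, u_H = uH)$polarized
  }
  lo <- bracket[1]; hi <- bracket[2]
  p_lo <- probe(lo); p_hi <- probe(hi)
  probes <- tibble::tibble(x = c(lo, hi), polarized = c(p_lo, p_hi))
  if (p_lo || !p_hi)
    stop("bracket does not straddle the threshold: lower endpoint polarized = ",
         p_lo, ", upper endpoint polarized = ", p_hi)
  while (hi / lo - 1 > tol_rel) {
    mid <- sqrt(lo * hi)
    p_mid <- probe(mid)
    probes <- rbind(probes, tibble::tibble(x = mid, polarized = p_mid))
    if (p_mid) hi <- mid else lo <- mid
  }
  structure(list(threshold = sqrt(lo * hi), vary = vary, mt0 = params$mt0,
                 ks_dur = if (vary == "amp") ks_dur else NA_real_,
                 ks_amp = if (vary == "dur") ks_dur else NA_real_,
                 tol_rel = tol_rel, probes = probes[order(probes$x), ]),
            class = "polar_threshold_fit")
}

#' @export
print.polar_threshold_fit <- function(x, ...) {
  cat(sprintf("<polar_threshold_fit> mt0=%.3g: threshold ks_%s = %.5g (tol %.1f%%, %d probes)\n",
              x$mt0, x$vary, x$threshold, 100 * x$tol_rel, nrow(x$probes)))
  invisible(x)
}

#' Amplitude-duration threshold curve
#'
#' Traces the polarization-threshold relationship between stimulus
#' amplitude and duration at a fixed basal membrane tension, by repeating
#' [threshold_search()] over a set of durations.  The curve is
#' hyperbola-like: larger amplitudes pair with shorter durations.
#'
#' @param params A `polar_params` (its `mt0` sets the tension).
#' @param ks_durs Durations (s) at which to find the amplitude threshold.
#' @param ... Passed to [threshold_search()].
#' @return A list of class `polar_threshold_curve` with a `points` tibble
#'   (`ks_dur`, `ks_amp`, `product`) and `mt0`.
#' @export
threshold_curve <- function(params, ks_durs = c(5, 10, 20, 40), ...) {
  pts <- purrr::map_dfr(ks_durs, function(d) {
    fit <- threshold_search(params, ks_dur = d, ...)
    tibble::tibble(ks_dur = d, ks_amp = fit$threshold,
                   product = d * fit$threshold)
  })
  structure(list(points = pts, mt0 = params$mt0),
            class = "polar_threshold_curve")
}

#' Fold change of the threshold stimulus product across tensions
#'
#' Computes the threshold amplitude at two basal tensions (same duration)
#' and returns the ratio of the stimulus-strength products
#' `ks_amp* x ks_dur`, the effective barrier fold change between the two
#' tension conditions.
#'
#' @param params A `polar_params` template.
#' @param mt0_low,mt0_high The two basal tensions (pN/um).
#' @param ks_dur Common stimulus duration (s).
#' @param ... Passed to [threshold_search()].
#' @return A list with `ratio`, `threshold_low`, `threshold_high`.
#' @export
threshold_product_ratio <- function(params, mt0_low = 0.2, mt0_high = 1.0,
                                    ks_dur = 20, ...) {
  fit_lo <- threshold_search(modify_params(params, mt0 = mt0_low),
                             ks_dur = ks_dur, ...)
  fit_hi <- threshold_search(modify_params(params, mt0 = mt0_high),
                             ks_dur = ks_dur, ...)
  list(ratio = fit_hi$threshold / fit_lo$threshold,
       threshold_low = fit_lo$threshold, threshold_high = fit_hi$threshold,
       ks_dur = ks_dur)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced and the
#' invariants re-validated.
#'
#' @param params A `polar_params`.
#' @param ... name = value replacements.
#' @return A `polar_params`.
#' @export
modify_params <- function(params, ...) {
  do.call(polar_params, modifyList(unclass(params), list(...)))
}

#' Perturbation-stability experiment
#'
#' Polarizes a cell, then applies a schedule of graded stimuli with random
#' amplitudes, durations and axis directions, and scores how often the
#' polarity follows a stimulus redirection.  `n_s` counts stimulus events
#' whose direction differs from the previous one (the first event is
#' compared to the pre-schedule polarity axis); `n_p` counts those events
#' after which the polarity angle (averaged over the last 10% of the
#' inter-event interval) settles within 45 degrees of the new stimulus
#' direction having started away from it.
#'
#' @param params A `polar_params`; its `mt0` sets the tension condition.
#' @param seed Integer seed for the schedule draw.
#' @param n_events Number of stimulus events.
#' @param amp_range,dur_range,gap Schedule parameters, see
#'   [switching_schedule()].
#' @param warmup_amp,warmup_dur Graded stimulus used to pre-polarize the
#'   cell along direction 0.
#' @param warmup_relax Relaxation time between the warm-up stimulus and
#'   the schedule (s).
#' @param geometry,config Optional prebuilt geometry / solver settings.
#' @return A list of class `polar_stability` with counts `n_s`, `n_p`,
#'   `ratio`, the per-event tibble `events`, and the full `trace`.
#' @export
stability_experiment <- function(params, seed = 1L, n_events = 10,
                                 amp_range = c(0.00025, 0.0024),
                                 dur_range = c(6, 16), gap = 25,
                                 warmup_amp = 0.002, warmup_dur = 30,
                                 warmup_relax = 20,
                                 geometry = NULL, config = NULL) {
  if (is.null(geometry)) geometry <- make_disk(params)
  uH <- u_high(params)
  s0 <- initial_state(geometry, params)
  cfg0 <- if (is.null(config)) solver_config(t_end = 1) else config
  # warm-up: polarize along direction 0
  cfg0$t_end <- warmup_dur + warmup_relax
  warm <- simulate(s0, geometry, params,
                   stimulus_protocol("graded", ks_amp = warmup_amp,
                                     ks_dur = warmup_dur, direction = 0),
                   cfg0)
  if (!detect_polarization(warm, u_H = uH)$polarized)
    stop("cell failed to polarize during the warm-up stimulus")
  sch <- switching_schedule(seed, n_events, amp_range, dur_range,
                            gap = gap, t_start = 0)
  cfg <- cfg0
  cfg$t_end <- max(sch$onset + sch$ks_dur) + gap
  tr <- simulate(warm$final_state, geometry, params,
                 stimulus_protocol("switching_sequence", schedule = sch,
                                   seed = seed),
                 cfg)
  m <- tr$metrics
  # polarity reading per event: circular mean of the defined angles in the
  # response window (stimulus onset to 15 s past its end, clipped at the
  # next onset) -- the asymmetric response develops during the stimulus and
  # relaxes afterwards, so this window captures where the polarity settled
  t_off <- warm$final_state$t   # trace clock continues from the warm-up
  bounds <- c(sch$onset, cfg$t_end)
  settled <- vapply(seq_len(n_events), function(i) {
    t0 <- bounds[i] + t_off
    t1 <- min(bounds[i + 1], sch$onset[i] + sch$ks_dur[i] + 15) + t_off
    sel <- m$t >= t0 & m$t <= t1
    circ_mean_deg(m$polarity_angle_deg[sel])
  }, numeric(1))
  pre <- c(circ_mean_deg(utils::tail(warm$metrics$polarity_angle_deg, 3)),
           settled[-n_events])
  prev_dir <- c(NA, sch$direction[-n_events])
  # first event: a redirection iff it points away from the current polarity
  # (or the polarity axis is unreadable, in which case it counts)
  first_red <- is.na(pre[1]) || ang_diff(sch$direction[1], pre[1]) > 45
  is_redirect <- c(first_red, sch$direction[-1] != prev_dir[-1])
  away <- is.na(pre) | ang_diff(pre, sch$direction) > 45
  followed <- !is.na(settled) & ang_diff(settled, sch$direction) <= 45 & away
  events <- tibble::tibble(event = sch$event, onset = sch$onset,
                           direction = sch$direction, ks_amp = sch$ks_amp,
                           ks_dur = sch$ks_dur, pre_angle = pre,
                           settled_angle = settled,
                           stimulus_redirect = is_redirect,
                           polarity_redirect = is_redirect & followed)
  n_s <- sum(events$stimulus_redirect)
  n_p <- sum(events$polarity_redirect)
  structure(list(n_s = n_s, n_p = n_p,
                 ratio = if (n_s > 0) n_p / n_s else NA_real_,
                 seed = seed, mt0 = params$mt0, events = events, trace = tr),
            class = "polar_stability")
}

#' @export
print.polar_stability <- function(x, ...) {
  cat(sprintf("<polar_stability> mt0=%.3g seed=%d: n_p/n_s = %d/%d = %.3g\n",
              x$mt0, x$seed, x$n_p, x$n_s, x$ratio))
  invisible(x)
}

#' Stability ensemble over seeds
#'
#' Repeats [stability_experiment()] over an ensemble of schedule seeds and
#' aggregates the redirection ratio.
#'
#' @inheritParams stability_experiment
#' @param seeds Integer vector of schedule seeds.
#' @param ... Passed to [stability_experiment()].
#' @return A list with per-seed tibble `runs`, and `mean_ratio`,
#'   `sd_ratio` of the pooled per-seed ratios.
#' @export
stability_ensemble <- function(params, seeds = 1:10, ...) {
  runs <- purrr::map_dfr(seeds, function(s) {
    st <- stability_experiment(params, seed = s, ...)
    tibble::tibble(seed = s, n_s = st$n_s, n_p = st$n_p, ratio = st$ratio)
  })
  ok <- !is.na(runs$ratio)
  list(runs = runs,
       mean_ratio = mean(runs$ratio[ok]),
       sd_ratio = sd(runs$ratio[ok]),
       n_s_total = sum(runs$n_s), n_p_total = sum(runs$n_p),
       pooled_ratio = sum(runs$n_p) / sum(runs$n_s))
}

#' Micropipette aspiration-release experiment
#'
#' Polarizes a cell, then at `t_aspirate` instantly elevates membrane
#' tension to `tension_multiplier` times its current value (decoupling it
#' from F-actin, as during micropipette aspiration), and at `t_release`
#' restores the tension-F-actin relationship.  The trace records the
#' collapse of the Rac-GTP peak during aspiration and its recovery after
#' release.
#'
#' @param params A `polar_params`.
#' @param tension_multiplier Factor applied to `mt(f)` at the aspiration
#'   instant (held fixed while aspirated).
#' @param t_aspirate,t_release Aspiration window (s), measured on the
#'   simulation clock; the cell is polarized with a graded stimulus
#'   beforehand and must be polarized at `t_aspirate`.
#' @param t_end End of the simulation (s).
#' @param warmup_amp,warmup_dur Polarizing stimulus.
#' @param geometry,config Optional geometry / solver settings.
#' @return A `polar_trace` with an `aspiration` attribute holding the
#'   window and the tension applied.
#' @export
aspiration_release <- function(params, tension_multiplier = 25,
                               t_aspirate = 100, t_release = 156,
                               t_end = 450,
                               warmup_amp = 0.004, warmup_dur = 20,
                               geometry = NULL, config = NULL) {
  if (t_release <= t_aspirate) stop("t_release must exceed t_aspirate")
  if (t_aspirate <= warmup_dur) stop("aspiration must start after the stimulus")
  if (is.null(geometry)) geometry <- make_disk(params)
  cfg <- if (is.null(config)) solver_config(t_end = t_end) else config
  cfg$t_end <- t_end
  s0 <- initial_state(geometry, params)
  uH <- u_high(params)
  ks <- graded_matrix(geometry, warmup_amp, 0, params$R)
  # phase 1: stimulate and relax up to the aspiration instant
  segs1 <- tibble::tibble(t0 = c(0, warmup_dur), t1 = c(warmup_dur, t_aspirate),
                          field = list(ks, NULL), mt_override = NA_real_)
  run1 <- run_pf(s0, geometry, params, cfg, segs1)
  if (utils::tail(run1$metrics$max_u, 1) < 0.95 * uH)
    stop("cell is not polarized at t_aspirate; increase warmup_amp or t_aspirate")
  mt_hold <- membrane_tension(run1$final$f, geometry, params) * tension_multiplier
  run2 <- run_pf(run1$final, geometry, params, cfg,
                 tibble::tibble(t0 = 0, t1 = t_release - t_aspirate,
                                field = list(NULL), mt_override = mt_hold))
  run3 <- run_pf(run2$final, geometry, params, cfg,
                 tibble::tibble(t0 = 0, t1 = t_end - t_release,
                                field = list(NULL), mt_override = NA_real_))
  # run_pf continues each segment on the absolute simulation clock
  metrics <- dplyr::bind_rows(run1$metrics, run2$metrics[-1, ],
                              run3$metrics[-1, ])
  events <- tibble::tibble(onset = c(0, t_aspirate), offset = c(warmup_dur, t_release))
  tr <- new_polar_trace(metrics, events, run3$final, geometry, params,
                        protocol = NULL, config = cfg, snapshots = NULL,
                        clipped = run3$clipped)
  attr(tr, "aspiration") <- list(t_aspirate = t_aspirate,
                                 t_release = t_release, mt_hold = mt_hold,
                                 tension_multiplier = tension_multiplier)
  tr
}

#' Decay and recovery times of an aspiration-release trace
#'
#' The decay time is measured from the aspiration instant until the
#' Rac-GTP peak has fallen halfway to the low state; the recovery time
#' from the release instant until the peak is back within `tol_frac` of
#' its pre-aspiration value.
#'
#' @param trace A trace from [aspiration_release()].
#' @param tol_frac Recovery tolerance relative to the pre-aspiration peak.
#' @return A list with `decay_time` and `recovery_time` (s; `NA` when the
#'   corresponding transition is not observed).
#' @export
aspiration_times <- function(trace, tol_frac = 0.05) {
  asp <- attr(trace, "aspiration")
  if (is.null(asp)) stop("trace does not carry an aspiration attribute")
  m <- trace$metrics
  uL <- u_low(trace$params)
  pre <- m$max_u[max(which(m$t <= asp$t_aspirate))]
  low_thr <- (uL + pre) / 2        # half-collapse of the Rac-GTP peak
  dur <- m$t > asp$t_aspirate
  dec <- which(dur & m$max_u <= low_thr)
  rec_thr <- (1 - tol_frac) * pre
  rec <- which(m$t > asp$t_release & m$max_u >= rec_thr)
  list(decay_time = if (length(dec)) m$t[dec[1]] - asp$t_aspirate else NA_real_,
       recovery_time = if (length(rec)) m$t[rec[1]] - asp$t_release else NA_real_)
}

#' Severing experiment on a tethered cell
#'
#' Polarizes the pseudopod of a pseudopod-neck-body cell, keeps a
#' sustained sub-threshold random stimulus on throughout, then severs the
#' neck.  When `release_tension` is `TRUE` the separated body recomputes
#' its membrane tension from its own (low) F-actin content, which drops
#' the tension and lets the noise nucleate a new polarity; when `FALSE`
#' the body keeps the elevated pre-cut tension and stays unpolarized.
#'
#' @param params A `polar_params`.
#' @param release_tension Whether the body's tension relaxes after the cut.
#' @param noise_amp Amplitude of the sustained random stimulus (1/s).
#' @param seed Integer seed for the noise draws.
#' @param t_cut Severing time (s); chosen while the pseudopod front has
#'   not yet crossed the neck.
#' @param t_after Post-cut observation time (s).
#' @param noise_redraw Redraw interval of the frozen random field (s).
#' @param warmup_amp,warmup_dur Stimulus patch polarizing the pseudopod tip.
#' @param v_start Initial cytosolic Rac-GDP level of the rested tethered
#'   cell (um^-2); sets the body's ignition reserve.
#' @param cut_frac Cut position along the open neck (0 = body end).
#' @param body_radius,neck_length,neck_halfwidth,pseudopod_radius Shape
#'   parameters, see [make_tethered()].
#' @param config Optional solver settings.
#' @return A list of class `polar_severing`: `front_trace`, `body_trace`,
#'   `pre_trace`, `body_polarized`, `body_f_cv_precut`, `mt_precut`.
#' @export
severing_experiment <- function(params, release_tension = TRUE,
                                noise_amp = 0.044, seed = 1L,
                                t_cut = 40, t_after = 240,
                                noise_redraw = 10,
                                warmup_amp = 0.003, warmup_dur = 40,
                                v_start = 7.0, cut_frac = 0.15,
                                body_radius = 6, neck_length = 12,
                                neck_halfwidth = 1.5, pseudopod_radius = 4.5,
                                config = NULL) {
  geo <- make_tethered(params, body_radius = body_radius,
                       neck_length = neck_length,
                       neck_halfwidth = neck_halfwidth,
                       pseudopod_radius = pseudopod_radius)
  cfg <- if (is.null(config)) solver_config(t_end = t_cut) else config
  uH <- u_high(params)

  noise_segments <- function(geometry, t_len, seed0, extra_field = NULL,
                             extra_until = 0, noise_from = 0) {
    onsets <- seq(0, t_len, by = noise_redraw)
    onsets <- onsets[onsets < t_len]
    tibble::tibble(
      t0 = onsets,
      t1 = pmin(onsets + noise_redraw, t_len),
      field = lapply(seq_along(onsets), function(i) {
        f <- local_random_matrix(geometry, noise_amp, 0, params$R,
                                 Inf, seed0 + i)
        if (onsets[i] < noise_from) f <- f * 0
        if (!is.null(extra_field) && onsets[i] < extra_until)
          f <- f + extra_field
        f
      }),
      mt_override = NA_real_)
  }

  # phase 1: ignite the pseudopod tip under sustained noise.  Start from
  # the rested tethered cell (membrane pool at u_L, cytosolic pool at
  # `v_start`, comparable to the rested disk's level) so the body carries
  # an ignition reserve; the polarizing stimulus covers only the outer
  # half of the pseudopod, and the cut is made while the resulting front
  # is still confined to the pseudopod-neck region.
  uL <- u_low(params)
  s0 <- initial_state(geo, params)
  s0$u <- matrix(uL, geo$N, geo$N)
  s0$v <- matrix(v_start, geo$N, geo$N)
  ks_warm <- warmup_amp * 2 * params$R *
    (geo$xc > geo$pseudopod_center[["x"]]) * (geo$phi > 1e-3)
  cfg$t_end <- t_cut
  # the sustained noise is switched on once the pseudopod front (and the
  # tension it generates) is established; it is sub-threshold for the
  # tension-elevated cell but supra-threshold at basal tension
  segs <- noise_segments(geo, t_cut, seed0 = seed * 1000L,
                         extra_field = ks_warm, extra_until = warmup_dur,
                         noise_from = warmup_dur)
  pre <- run_pf(s0, geo, params, cfg, segs)

  # cut near the body end of the neck; the pre-cut body must be
  # unpolarized with low, even F-actin
  ni <- geo$neck_interval
  pieces <- sever(geo, cut_x = ni[1] + cut_frac * (ni[2] - ni[1]),
                  params = params)
  body_sel <- pieces$body$phi > 0.5
  f_body <- pre$final$f[body_sel]
  u_body <- pre$final$u
  body_f_cv <- sd(f_body) / max(mean(f_body), .Machine$double.eps)
  mt_precut <- membrane_tension(pre$final$f, geo, params)
  body_max_u <- max(u_body[pieces$body$mem_w > 1e-3 * max(pieces$body$mem_w)])
  if (body_max_u >= 0.95 * uH)
    stop("body is polarized before the cut; fixture invalid")

  restrict <- function(piece) {
    st <- pre$final
    st$t <- 0
    st
  }

  run_piece <- function(piece, dynamic_mt, seed0) {
    cfgp <- cfg
    cfgp$t_end <- t_after
    segs <- noise_segments(piece, t_after, seed0 = seed0)
    if (!dynamic_mt) segs$mt_override <- mt_precut
    out <- run_pf(restrict(piece), piece, params, cfgp, segs)
    new_polar_trace(out$metrics, NULL, out$final, piece, params,
                    protocol = NULL, config = cfgp, snapshots = NULL,
                    clipped = out$clipped)
  }
  front_trace <- run_piece(pieces$front, dynamic_mt = TRUE,
                           seed0 = seed * 2000L)
  body_trace <- run_piece(pieces$body, dynamic_mt = release_tension,
                          seed0 = seed * 3000L)
  body_pol <- detect_polarization(body_trace, u_H = uH, onset = 0)
  structure(list(front_trace = front_trace, body_trace = body_trace,
                 pre_metrics = pre$metrics,
                 body_polarized = body_pol$polarized,
                 body_polarization_time = body_pol$polarization_time,
                 body_f_cv_precut = body_f_cv, mt_precut = mt_precut,
                 release_tension = release_tension, seed = seed),
            class = "polar_severing")
}

#' @export
print.polar_severing <- function(x, ...) {
  cat(sprintf("<polar_severing> tension %s: body %s after the cut (pre-cut body F-actin CV %.3g)\n",
              if (x$release_tension) "released" else "held",
              if (x$body_polarized) "polarized" else "stayed unpolarized",
              x$body_f_cv_precut))
  invisible(x)
}

#' One-at-a-time parameter sensitivity of the polarized state
#'
#' Perturbs each kinetic/tension parameter by +/- `perturbation_frac`, re-runs
#' the standard polarization protocol, and reports the worse (larger) of
#' the two relative changes in the steady maximum Rac-GTP concentration.
#'
#' @param params Baseline `polar_params`.
#' @param perturbation_frac Relative perturbation (default 0.30).
#' @param param_names Parameters to perturb.
#' @param stim_amp,stim_dur Polarizing stimulus.
#' @param t_end Run horizon (s); the steady value is the final `max_u`.
#' @param geometry,config Optional geometry / solver settings.
#' @return A tibble with `parameter`, `rel_change` (max over the two
#'   signs of `|delta max_u| / max_u`), the two signed changes, and a
#'   `failed` flag for runs that did not complete.
#' @export
sensitivity_analysis <- function(params, perturbation_frac = 0.30,
                                 param_names = c("b", "r", "c1", "c2", "c3",
                                                 "K1", "K2", "K3", "d_f",
                                                 "mt0", "lam", "K_F",
                                                 "D_u", "D_v", "D_f"),
                                 stim_amp = 0.02, stim_dur = 20,
                                 t_end = 150, geometry = NULL,
                                 config = NULL) {
  if (perturbation_frac < 0) stop("perturbation_frac must be non-negative")
  if (is.null(geometry)) geometry <- make_disk(params)
  cfg <- if (is.null(config)) solver_config(t_end = t_end) else config
  cfg$t_end <- t_end
  pr <- stimulus_protocol("graded", ks_amp = stim_amp, ks_dur = stim_dur,
                          direction = 0)
  run_max_u <- function(p) {
    tr <- simulate(initial_state(geometry, p), geometry, p, pr, cfg)
    utils::tail(tr$metrics$max_u, 1)
  }
  base <- run_max_u(params)
  purrr::map_dfr(param_names, function(nm) {
    ch <- vapply(c(1 - perturbation_frac, 1 + perturbation_frac), function(fac) {
      tryCatch({
        p2 <- do.call(modify_params,
                      c(list(params), stats::setNames(list(params[[nm]] * fac), nm)))
        (run_max_u(p2) - base) / base
      }, error = function(e) NA_real_)
    }, numeric(1))
    tibble::tibble(parameter = nm, rel_change = max(abs(ch), na.rm = FALSE),
                   change_minus = ch[1], change_plus = ch[2],
                   failed = anyNA(ch))
  })
}

#' Steady-state statistics under noisy initial conditions
#'
#' Repeats the standard polarization run from initial states perturbed by
#' independent Gaussian noise on `u` and `v`, and reports the ensemble
#' mean and standard deviation of the steady maximum and total Rac-GTP.
#'
#' @param params A `polar_params`.
#' @param noise_var Variance of the initial Gaussian perturbation.
#' @param n_replicates Number of replicates.
#' @param seed Base seed; replicate k uses `seed + k`.
#' @param stim_amp,stim_dur Polarizing stimulus.
#' @param t_end Run horizon (s).
#' @param geometry,config Optional geometry / solver settings.
#' @return A list with the per-replicate tibble `runs`, ensemble
#'   `mean_max_u`, `sd_max_u`, `mean_total_u`, `sd_total_u`, and the
#'   number of replicates that failed to polarize.
#' @export
initial_condition_study <- function(params, noise_var = 0.01,
                                    n_replicates = 5, seed = 1L,
                                    stim_amp = 0.02, stim_dur = 20,
                                    t_end = 200, geometry = NULL,
                                    config = NULL) {
  if (is.null(geometry)) geometry <- make_disk(params)
  cfg <- if (is.null(config)) solver_config(t_end = t_end) else config
  cfg$t_end <- t_end
  uH <- u_high(params)
  pr <- stimulus_protocol("graded", ks_amp = stim_amp, ks_dur = stim_dur,
                          direction = 0)
  runs <- purrr::map_dfr(seq_len(n_replicates), function(k) {
    s0 <- initial_state(geometry, params, noise_var = noise_var,
                        seed = seed + k)
    tr <- simulate(s0, geometry, params, pr, cfg)
    pol <- detect_polarization(tr, u_H = uH)
    tibble::tibble(replicate = k,
                   max_u = utils::tail(tr$metrics$max_u, 1),
                   total_u = utils::tail(tr$metrics$total_u, 1),
                   polarized = pol$polarized)
  })
  ok <- runs$polarized
  list(runs = runs,
       mean_max_u = mean(runs$max_u[ok]), sd_max_u = sd(runs$max_u[ok]),
       mean_total_u = mean(runs$total_u[ok]), sd_total_u = sd(runs$total_u[ok]),
       n_failed = sum(!ok))
}

#' Competition between two simultaneous stimuli
#'
#' Applies two opposing graded stimuli of different amplitudes and tracks
#' the number of high-Rac membrane fronts over time.  Two fronts form
#' when both stimuli are supra-threshold; the front triggered by the
#' stronger stimulus eventually absorbs the other.
#'
#' @param params A `polar_params`.
#' @param amp1,amp2 Amplitudes of the stronger (direction 0) and weaker
#'   (direction 180) stimulus; `amp1 > amp2`.
#' @param ks_dur Stimulus duration (s).
#' @param t_end Run horizon (s).
#' @param snapshot_every Field snapshot cadence used for front counting (s).
#' @param geometry,config Optional geometry / solver settings.
#' @return A list with the trace, a `fronts` tibble (`t`, `n_fronts`),
#'   and the final front angle `final_angle`.
#' @export
dual_stimulus_competition <- function(params, amp1 = 0.02, amp2 = 0.012,
                                      ks_dur = 20, t_end = 200,
                                      snapshot_every = 5,
                                      geometry = NULL, config = NULL) {
  if (amp1 <= amp2) stop("amp1 must exceed amp2")
  if (is.null(geometry)) geometry <- make_disk(params)
  cfg <- if (is.null(config)) solver_config(t_end = t_end) else config
  cfg$t_end <- t_end
  cfg$field_snapshot_every <- snapshot_every
  pr <- stimulus_protocol("dual_gradient", ks_amp = amp1, ks_amp2 = amp2,
                          ks_dur = ks_dur, direction = 0)
  s0 <- rested_state(geometry, params)
  tr <- simulate(s0, geometry, params, pr, cfg)
  thr <- (u_low(params) + u_high(params)) / 2
  fronts <- purrr::map_dfr(tr$snapshots, function(sn) {
    tibble::tibble(t = sn$t,
                   n_fronts = count_fronts(sn$u, geometry, thr))
  })
  # direction of the surviving front right after the weaker one is absorbed
  twin <- NA_real_
  had2 <- which(fronts$n_fronts >= 2)
  if (length(had2)) {
    after <- which(fronts$n_fronts == 1 & fronts$t > fronts$t[had2[1]])
    if (length(after)) twin <- fronts$t[after[1]]
  }
  winner <- NA_real_
  if (!is.na(twin)) {
    snw <- tr$snapshots[[which(vapply(tr$snapshots, `[[`, 0, "t") == twin)[1]]]
    prof <- membrane_profile(snw$u, geometry)
    winner <- prof$angle[which.max(prof$value)]
  }
  list(trace = tr, fronts = fronts, absorbed_at = twin,
       winner_angle = winner,
       final_angle = polarity_angle(tr$final_state$u, geometry))
}
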