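# Stimulus protocols: spatial fields of the extra activation rate k_s(x,y,t)
# that multiplies Rac-GDP in the activation term.  All protocols are
# piecewise-constant in time (fields are frozen during an event), which the
# solver exploits by integrating segment-by-segment.

# run fn with a temporary RNG state seeded by `seed`
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

axis_directions <- c(0, 90, 180, 270)

#' Stimulus protocol
#'
#' Declarative description of the stimulus field `k_s(x, y, t)`.
#'
#' @param kind One of `"graded"` (linear gradient across the cell),
#'   `"local_random"` (uniform random noise on a band of the cell),
#'   `"switching_sequence"` (a schedule of graded events in random
#'   directions), `"dual_gradient"` (two simultaneous opposing gradients)
#'   or `"none"`.
#' @param ks_amp Amplitude; for graded stimuli the field is
#'   `ks_amp * (R + s xi)` so it spans `[0, 2 R ks_amp]` (1/s) across the
#'   cell.
#' @param ks_dur Duration of the stimulus (s).
#' @param direction Axis direction in degrees, one of 0, 90, 180, 270
#'   (0 is +x).
#' @param onset Stimulus onset time (s).
#' @param region_fraction Band scale for local stimuli: the band spans
#'   `[0, region_fraction * R]` along the chosen axis.
#' @param seed Integer seed for the random draws of `local_random` and
#'   `switching_sequence` protocols.
#' @param ks_amp2,direction2 Amplitude and direction of the second gradient
#'   of a `dual_gradient` protocol.
#' @param schedule For `switching_sequence`: a tibble as returned by
#'   [switching_schedule()].
#' @return A list of class `polar_protocol`.
#' @export
stimulus_protocol <- function(kind = c("graded", "local_random",
                                       "switching_sequence", "dual_gradient",
                                       "none"),
                              ks_amp = 0.005, ks_dur = 20, direction = 0,
                              onset = 0, region_fraction = 0.25, seed = 1L,
                              ks_amp2 = NULL, direction2 = NULL,
                              schedule = NULL) {
  kind <- match.arg(kind)
  if (ks_amp < 0) stop("ks_amp must be non-negative")
  if (ks_dur <= 0) stop("ks_dur must be positive")
  if (!direction %in% axis_directions)
    stop("direction must be one of 0, 90, 180, 270")
  if (kind == "dual_gradient") {
    if (is.null(ks_amp2)) stop("dual_gradient needs ks_amp2")
    if (is.null(direction2)) direction2 <- (direction + 180) %% 360
  }
  if (kind == "switching_sequence" && is.null(schedule))
    stop("switching_sequence needs a schedule (see switching_schedule())")
  structure(list(kind = kind, ks_amp = ks_amp, ks_dur = ks_dur,
                 direction = direction, onset = onset,
                 region_fraction = region_fraction, seed = as.integer(seed),
                 ks_amp2 = ks_amp2, direction2 = direction2,
                 schedule = schedule),
            class = "polar_protocol")
}

# signed coordinate along a stimulus axis
axis_coord <- function(geometry, direction) {
  switch(as.character(direction),
         "0" = geometry$xc - geometry$center[["x"]],
         "90" = geometry$yc - geometry$center[["y"]],
         "180" = -(geometry$xc - geometry$center[["x"]]),
         "270" = -(geometry$yc - geometry$center[["y"]]),
         stop("direction must be one of 0, 90, 180, 270"))
}

graded_matrix <- function(geometry, ks_amp, direction, R) {
  xi <- axis_coord(geometry, direction)
  ks_amp * pmin(pmax(R + xi, 0), 2 * R) * (geometry$phi > 1e-3)
}

# constant patch on the rim sector facing `direction` (outer band of width
# `width_frac * R` along the axis); amplitude matches the pole value of a
# graded field of the same ks_amp
rim_patch_matrix <- function(geometry, ks_amp, direction, R,
                             width_frac = 0.5) {
  xi <- axis_coord(geometry, direction)
  ks_amp * 2 * R * (xi > (1 - width_frac) * R) * (geometry$phi > 1e-3)
}

#' Graded stimulus field
#'
#' Linear activation gradient across the cell: `ks_amp * (R + xi)` with
#' `xi` the cell-centered coordinate along the chosen axis, clamped to
#' `[0, 2R]`, restricted to the cell support, and zero after the stimulus
#' has expired.
#'
#' @param protocol A `polar_protocol` of kind `"graded"`.
#' @param geometry A `polar_geometry`.
#' @param params A `polar_params` (for the cell radius `R`).
#' @param t Time (s) at which to evaluate the field.
#' @return Matrix of activation rates (1/s).
#' @export
graded_field <- function(protocol, geometry, params, t) {
  if (protocol$kind != "graded") stop("protocol kind must be 'graded'")
  active <- t > protocol$onset && t <= protocol$onset + protocol$ks_dur
  if (!active) return(matrix(0, geometry$N, geometry$N))
  graded_matrix(geometry, protocol$ks_amp, protocol$direction, params$R)
}

local_random_matrix <- function(geometry, ks_amp, direction, R,
                                region_fraction, seed) {
  xi <- axis_coord(geometry, direction)
  # non-finite region_fraction: noise over the whole cell support
  band <- if (!is.finite(region_fraction)) geometry$phi > 0.5
          else xi >= 0 & xi <= region_fraction * R & geometry$phi > 0.5
  R0 <- with_seed(seed, function() {
    matrix(runif(geometry$N^2), geometry$N, geometry$N)
  })
  ks_amp * R0 * band
}

#' Local random stimulus field
#'
#' Spatially uncorrelated uniform noise `ks_amp * R0`, `R0 ~ U(0, 1)` drawn
#' once per grid point at onset (frozen during the event), on a band of the
#' cell spanning `[0, region_fraction * R]` along the chosen axis from the
#' cell center; zero elsewhere and after expiry.  Reproducible under the
#' protocol seed.
#'
#' @inheritParams graded_field
#' @return Matrix of activation rates (1/s).
#' @export
local_random_field <- function(protocol, geometry, params, t) {
  if (protocol$kind != "local_random") stop("protocol kind must be 'local_random'")
  active <- t > protocol$onset && t <= protocol$onset + protocol$ks_dur
  if (!active) return(matrix(0, geometry$N, geometry$N))
  local_random_matrix(geometry, protocol$ks_amp, protocol$direction,
                      params$R, protocol$region_fraction, protocol$seed)
}

#' Random switching-stimulus schedule
#'
#' Draws a sequence of graded-stimulus events with directions uniform on
#' {0, 90, 180, 270} and amplitudes/durations uniform on the given ranges;
#' events are laid out sequentially with a fixed relaxation gap after each.
#'
#' @param seed Integer seed.
#' @param n_events Number of events (>= 1).
#' @param amp_range,dur_range Ranges (min, max) for the event amplitude and
#'   duration.
#' @param gap Time between the end of one event and the next onset (s).
#' @param t_start Onset of the first event (s).
#' @return A tibble with columns `event`, `onset`, `ks_amp`, `ks_dur`,
#'   `direction`.
#' @export
switching_schedule <- function(seed, n_events,
                               amp_range = c(0.002, 0.010),
                               dur_range = c(8, 20),
                               gap = 40, t_start = 0) {
  stopifnot(n_events >= 1, all(amp_range > 0), all(dur_range > 0),
            amp_range[2] >= amp_range[1], dur_range[2] >= dur_range[1],
            gap >= 0)
  with_seed(seed, function() {
    dirs <- sample(axis_directions, n_events, replace = TRUE)
    amps <- runif(n_events, amp_range[1], amp_range[2])
    durs <- runif(n_events, dur_range[1], dur_range[2])
    onsets <- t_start + cumsum(c(0, (durs + gap)[-n_events]))
    tibble::tibble(event = seq_len(n_events), onset = onsets,
                   ks_amp = amps, ks_dur = durs, direction = dirs)
  })
}

# Compile a protocol into piecewise-constant segments covering [0, t_end]:
# a tibble with t0, t1 and a list-column of k_s matrices (NULL = zero).
protocol_segments <- function(protocol, geometry, params, t_end) {
  zero <- NULL
  events <- switch(protocol$kind,
    none = tibble::tibble(onset = numeric(), offset = numeric(),
                          field = list()),
    graded = tibble::tibble(
      onset = protocol$onset, offset = protocol$onset + protocol$ks_dur,
      field = list(graded_matrix(geometry, protocol$ks_amp,
                                 protocol$direction, params$R))),
    local_random = tibble::tibble(
      onset = protocol$onset, offset = protocol$onset + protocol$ks_dur,
      field = list(local_random_matrix(geometry, protocol$ks_amp,
                                       protocol$direction, params$R,
                                       protocol$region_fraction,
                                       protocol$seed))),
    dual_gradient = tibble::tibble(
      onset = protocol$onset, offset = protocol$onset + protocol$ks_dur,
      # two rim patches on opposite sides: opposing graded ramps would sum
      # to a nearly uniform drive, which cannot seed two separate fronts
      field = list(rim_patch_matrix(geometry, protocol$ks_amp,
                                    protocol$direction, params$R) +
                   rim_patch_matrix(geometry, protocol$ks_amp2,
                                    protocol$direction2, params$R))),
    switching_sequence = {
      sch <- protocol$schedule
      if (any(diff(sch$onset) < sch$ks_dur[-nrow(sch)]))
        stop("overlapping events in switching schedule")
      tibble::tibble(
        onset = sch$onset, offset = sch$onset + sch$ks_dur,
        field = lapply(seq_len(nrow(sch)), function(i) {
          graded_matrix(geometry, sch$ks_amp[i], sch$direction[i], params$R)
        }))
    })
  events <- events[events$onset < t_end, , drop = FALSE]
  # breakpoints -> segments
  brk <- sort(unique(c(0, t_end, events$onset, pmin(events$offset, t_end))))
  brk <- brk[brk >= 0 & brk <= t_end]
  segs <- tibble::tibble(t0 = brk[-length(brk)], t1 = brk[-1])
  segs$field <- lapply(seq_len(nrow(segs)), function(i) {
    mid <- (segs$t0[i] + segs$t1[i]) / 2
    hit <- which(events$onset <= mid & events$offset > mid)
    if (!length(hit)) zero else Reduce(`+`, events$field[hit])
  })
  attr(segs, "events") <- events[, c("onset", "offset")]
  segs
}
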