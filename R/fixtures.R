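# Self-contained synthetic fixtures with analytic or constructed expected
# outcomes, so every part of the simulator is testable without external
# data.

#' Single-mode diffusion fixture
#'
#' A pure Fourier mode `cos(2 pi m x / L)` diffusing with constant
#' coefficient on the periodic domain; its amplitude decays exactly as
#' `exp(-D (2 pi m / L)^2 t)`.
#'
#' @param D Diffusion coefficient (um^2/s).
#' @param mode_index Integer mode number `m` along x; must be resolvable
#'   (`m < N/2`).
#' @param L Domain edge (um).
#' @param N Grid points per axis.
#' @return A list of class `polar_fixture` with the initial `field`, the
#'   wavenumber `k`, the decay `rate`, and `amplitude_at(t)`.
#' @export
make_diffusion_fixture <- function(D = 1, mode_index = 1, L = 40, N = 64) {
  if (mode_index >= N / 2) stop("aliased mode: need mode_index < N/2")
  if (D < 0) stop("D must be non-negative")
  h <- L / N
  xs <- (seq_len(N) - 1) * h
  field <- matrix(cos(2 * pi * mode_index * xs / L), N, N)
  k <- 2 * pi * mode_index / L
  structure(list(field = field, D = D, mode_index = mode_index, L = L,
                 N = as.integer(N), k = k, rate = D * k^2,
                 amplitude_at = function(t) exp(-D * k^2 * t)),
            class = "polar_fixture")
}

#' Run a diffusion fixture through the spectral integrator
#'
#' Advances the fixture field with the production solver path (unit
#' weights, all reactions off) and returns the measured amplitude ratio
#' of the seeded mode, to be compared with `amplitude_at(t_end)`.
#'
#' @param fixture From [make_diffusion_fixture()].
#' @param t_end Integration time (s).
#' @param dt Time step (s).
#' @return Measured amplitude ratio (scalar).
#' @export
run_diffusion_fixture <- function(fixture, t_end = 1, dt = 0.01) {
  N <- fixture$N
  ones <- matrix(1, N, N)
  zero <- matrix(0, N, N)
  par <- list(D_u = fixture$D, D_v = fixture$D, D_f = fixture$D,
              b = 0, r = 0, c1 = 0, c2 = 0, c3 = 0,
              K1 = 1, K2 = 1, K3 = 1, d_f = 0, mt0 = 1, lam = 0, K_F = 1)
  h <- fixture$L / N
  nsteps <- as.integer(round(t_end / dt))
  out <- .pf_run_cpp(fixture$field, fixture$field, fixture$field,
                     ones, ones, zero, ones, ones, zero,
                     zero, zero, par, dt, nsteps, h, h^2,
                     nsteps, -1, FALSE, 0L, 1)
  # amplitude via projection on the seeded mode
  proj <- function(z) sum(z * fixture$field) / sum(fixture$field^2)
  proj(out$Wu)
}

#' Polarization fixture at a known threshold
#'
#' Builds a graded-stimulus setup at a chosen multiple of the polarization
#' threshold, with the expected outcome recorded: supra-threshold
#' (`factor > 1`) runs polarize, sub-threshold runs transiently rise and
#' fall back.
#'
#' @param params A `polar_params`.
#' @param supra Logical; `TRUE` for a supra-threshold fixture.
#' @param threshold Known amplitude threshold (from [threshold_search()]);
#'   computed on the fly when omitted (slow).
#' @param factor Multiple of the threshold to use (defaults 1.2 for supra,
#'   0.8 for sub).
#' @param ks_dur Stimulus duration (s).
#' @return A list of class `polar_fixture` with the `protocol` and the
#'   `expect_polarized` flag.
#' @export
make_polarization_fixture <- function(params, supra = TRUE, threshold = NULL,
                                      factor = if (supra) 1.2 else 0.8,
                                      ks_dur = 20) {
  if (is.null(threshold))
    threshold <- threshold_search(params, ks_dur = ks_dur)$threshold
  structure(list(protocol = stimulus_protocol("graded",
                                              ks_amp = factor * threshold,
                                              ks_dur = ks_dur, direction = 0),
                 threshold = threshold, factor = factor,
                 expect_polarized = supra),
            class = "polar_fixture")
}

#' Noisy initial state fixture
#'
#' Homogeneous resting state with independent Gaussian perturbations on
#' the Rac pools inside the cell (see [initial_state()]); a thin wrapper
#' fixing the construction used by the initial-condition analysis.
#'
#' @param seed Integer seed.
#' @param noise_var Perturbation variance.
#' @param params A `polar_params`.
#' @param geometry A `polar_geometry`.
#' @return A `polar_state`.
#' @export
make_noise_initial_state <- function(seed, noise_var, params, geometry) {
  initial_state(geometry, params, noise_var = noise_var, seed = seed)
}
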