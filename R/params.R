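#' Model parameters for the mechano-chemical polarity model
#'
#' Constructs the full parameter set of the coupled Rac-GTP / Rac-GDP /
#' F-actin / membrane-tension model.  Defaults were calibrated so that the
#' well-mixed kinetics are bistable at the reference cytosolic Rac-GDP level
#' (`v0 = 6` per square micron), the homogeneous resting state is
#' `u0 = 2`, `v0 = 6`, `f0 = 0`, and the simulated cell reproduces the
#' reference steady polarized state (see the methods vignette for the
#' calibration protocol).
#'
#' Units: lengths in micrometres, times in seconds, concentrations in
#' molecules per square micron, tensions in pN per micron.
#'
#' @param D_u,D_v,D_f Diffusion coefficients of membrane Rac-GTP, cytosolic
#'   Rac-GDP and F-actin (um^2/s).  Must satisfy `D_u < D_f` and
#'   `D_f` much smaller than `D_v`: the active form is slow, the inactive
#'   cytosolic form communicates quickly across the cell.
#' @param b Basal GDP-to-GTP activation rate (1/s).
#' @param r GTP-to-GDP deactivation rate (1/s).
#' @param c1,c2,c3 Maximum rates of Rac self-activation, of F-actin-mediated
#'   Rac activation, and of Rac-driven F-actin polymerization.
#' @param K1,K2,K3 Microscopic dissociation constants of the three Hill
#'   terms (um^-2).
#' @param d_f F-actin depolymerization rate (1/s).
#' @param mt0 Basal membrane tension of the resting cell (pN/um).
#' @param lam Coupling of membrane tension to the total F-actin amount
#'   (the tension is `mt0 * (1 + lam * F_tot)`; `lam * F_tot` is treated as
#'   dimensionless).
#' @param K_F Tension scale of the polymerization brake
#'   `K_F / (K_F + mt)` (pN/um).
#' @param R Cell radius (um).
#' @param eps Phase-field interface half-width (um).
#' @param L Edge length of the periodic computational domain (um).
#' @param N Grid points per axis.
#' @param dt Time step (s).
#' @param u0,v0,f0 Initial homogeneous concentrations (um^-2).
#' @param delta,kBT Brownian-ratchet step size (um) and thermal energy
#'   (pN um); used only by the flat-2D (traditional) model variant.
#' @param c3_flat Maximum F-actin polymerization rate of the flat-2D
#'   variant, where F-actin is areal rather than produced at the diffuse
#'   membrane (so its working scale differs from `c3`).
#' @param ... Overrides for any of the above, as name = value.
#'
#' @return A list of class `polar_params`.
#' @examples
#' p <- polar_params()
#' p$mt0
#' polar_params(mt0 = 1.0)$mt0
#' @export
polar_params <- function(D_u = 0.5, D_v = 50, D_f = 1,
                         b = 0.008, r = 2,
                         c1 = 0.0736, c2 = 0.106, c3 = 1,
                         K1 = 0.4, K2 = 0.65, K3 = 0.8,
                         d_f = 0.03,
                         mt0 = 0.2, lam = 0.004, K_F = 3.3,
                         R = 10, eps = 1, L = 40, N = 128L, dt = 0.01,
                         u0 = 2, v0 = 6, f0 = 0, delta = 0.005,
                         kBT = 4.1e-3, c3_flat = 0.25, ...) {
  p <- list(D_u = D_u, D_v = D_v, D_f = D_f, b = b, r = r,
            c1 = c1, c2 = c2, c3 = c3, K1 = K1, K2 = K2, K3 = K3,
            d_f = d_f, mt0 = mt0, lam = lam, K_F = K_F,
            R = R, eps = eps, L = L, N = as.integer(N), dt = dt,
            u0 = u0, v0 = v0, f0 = f0, delta = delta, kBT = kBT,
            c3_flat = c3_flat)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  class(p) <- "polar_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks positivity of rates and scales, the diffusion ordering
#' `D_u < D_f << D_v`, and that the cell fits inside the periodic domain.
#'
#' @param p A `polar_params` object.
#' @return `p`, invisibly; errors name the offending key.
#' @export
validate_params <- function(p) {
  pos <- c("D_u", "D_v", "D_f", "b", "r", "c1", "c3", "K1", "K2", "K3",
           "d_f", "mt0", "K_F", "R", "eps", "L", "dt", "v0", "delta", "kBT")
  for (k in pos) {
    if (!is.numeric(p[[k]]) || length(p[[k]]) != 1L || p[[k]] <= 0)
      stop("parameter '", k, "' must be a single positive number")
  }
  for (k in c("c2", "lam", "u0", "f0", "c3_flat")) {
    if (!is.numeric(p[[k]]) || length(p[[k]]) != 1L || p[[k]] < 0)
      stop("parameter '", k, "' must be a single non-negative number")
  }
  if (!(p$D_u < p$D_f)) stop("invariant violated: need D_u < D_f")
  if (!(p$D_f < p$D_v)) stop("invariant violated: need D_f << D_v")
  if (!(p$R < p$L / 2)) stop("invariant violated: need R < L/2 (cell must fit in the domain)")
  if (p$N < 16L) stop("parameter 'N' must be at least 16")
  invisible(p)
}

#' @export
print.polar_params <- function(x, ...) {
  cat("<polar_params>\n")
  cat(sprintf("  kinetics : b=%.4g r=%.4g c=(%.4g, %.4g, %.4g) K=(%.4g, %.4g, %.4g) d_f=%.4g\n",
              x$b, x$r, x$c1, x$c2, x$c3, x$K1, x$K2, x$K3, x$d_f))
  cat(sprintf("  diffusion: D_u=%.3g D_f=%.3g D_v=%.3g um^2/s\n", x$D_u, x$D_f, x$D_v))
  cat(sprintf("  tension  : mt0=%.3g pN/um  lam=%.3g  K_F=%.3g\n", x$mt0, x$lam, x$K_F))
  cat(sprintf("  geometry : R=%.3g um  eps=%.3g um  L=%.3g um  N=%d  dt=%.3g s\n",
              x$R, x$eps, x$L, x$N, x$dt))
  cat(sprintf("  initial  : u0=%.3g v0=%.3g f0=%.3g um^-2\n", x$u0, x$v0, x$f0))
  invisible(x)
}

#' Hill activation rate
#'
#' The saturating activation `c * x^2 / (x^2 + K^2)` used for Rac
#' self-activation, F-actin-mediated Rac activation and Rac-driven actin
#' polymerization.
#'
#' @param x Concentration (um^-2); scalar, vector or matrix, non-negative.
#' @param c Maximum rate at saturation.
#' @param K Half-saturation (dissociation) constant (um^-2), positive.
#' @return Rate(s) in `[0, c)`, same shape as `x`.
#' @examples
#' hill(1, c = 1, K = 1)   # half-saturation
#' @export
hill <- function(x, c, K) {
  if (!is.numeric(K) || K <= 0) stop("K must be positive")
  if (any(x < 0)) stop("x must be non-negative")
  x2 <- x^2
  c * x2 / (x2 + K^2)
}

#' Effective membrane tension from the F-actin field
#'
#' Membrane tension is treated as spatially homogeneous and slaved to the
#' total cytosolic F-actin amount: `mt = mt0 * (1 + lam * F_tot)` with
#' `F_tot` the phase-field-weighted integral of `f` over the domain.
#'
#' @param f F-actin field (matrix on the geometry grid) or a `polar_state`.
#' @param geometry A `polar_geometry`.
#' @param params A `polar_params`.
#' @return A single tension value (pN/um), `>= mt0`.
#' @export
membrane_tension <- function(f, geometry, params) {
  if (inherits(f, "polar_state")) f <- f$f
  if (!all(dim(f) == dim(geometry$phi)))
    stop("shape mismatch: f is ", paste(dim(f), collapse = "x"),
         " but the geometry grid is ", paste(dim(geometry$phi), collapse = "x"))
  ftot <- sum(geometry$phi * f) * geometry$dA
  params$mt0 * (1 + params$lam * ftot)
}

#' Local (non-diffusive) reaction rates
#'
#' Evaluates the pointwise kinetics of the three species at fixed membrane
#' tension: activation of Rac-GTP from Rac-GDP (basal + self-activation +
#' F-actin feedback + stimulus, all multiplying `v`), first-order
#' deactivation, and tension-throttled F-actin polymerization with
#' first-order depolymerization.
#'
#' @param u,v,f Concentrations (um^-2); scalars or matrices of equal shape.
#' @param mt Membrane tension (pN/um), positive.
#' @param k_s Stimulus activation rate (1/s); scalar or matrix.
#' @param params A `polar_params`.
#' @return A list with components `R_u`, `R_v`, `R_f`;
#'   `R_u + R_v == 0` identically (local Rac conservation).
#' @export
reaction_rates <- function(u, v, f, mt, k_s = 0, params) {
  if (any(mt <= 0)) stop("mt must be positive")
  p <- params
  act <- p$b + hill(u, p$c1, p$K1) + hill(f, p$c2, p$K2) + k_s
  R_u <- act * v - p$r * u
  R_f <- hill(u, p$c3, p$K3) * p$K_F / (p$K_F + mt) - p$d_f * f
  list(R_u = R_u, R_v = -R_u, R_f = R_f)
}

#' Well-mixed fixed points of the Rac-GTP kinetics
#'
#' Finds all non-negative roots of `R_u(u) = 0` with Rac-GDP clamped at
#' `v0` and F-actin at `f_level`, i.e. the spatially uniform steady states
#' of the activation/deactivation balance.  In the bistable regime there
#' are three roots: the low state `u_L`, an unstable middle state, and the
#' high (polarized-front) state `u_H`.
#'
#' @param params A `polar_params`.
#' @param v0 Clamped Rac-GDP concentration; defaults to `params$v0`.
#' @param f_level Clamped F-actin concentration.  The default `NULL`
#'   slaves F-actin to its quasi-steady value at the local Rac-GTP level
#'   and the basal tension,
#'   `f_qss(u) = c3 hill(u) K_F / ((K_F + mt0) d_f)`, which is the level
#'   the slow F-actin pool relaxes to behind a front; a numeric value
#'   clamps it instead (0 recovers the actin-free kinetics, which are
#'   monostable at the default parameters).
#' @param u_max Upper end of the root search bracket.
#' @return A tibble with columns `u` (ascending) and `stable` (logical;
#'   outer roots of a bistable triplet are stable).
#' @examples
#' well_mixed_fixed_points(polar_params())
#' @export
well_mixed_fixed_points <- function(params, v0 = params$v0,
                                    f_level = NULL,
                                    u_max = 10 * max(params$u0, 1)) {
  if (v0 <= 0) stop("v0 must be positive")
  f_at <- if (is.null(f_level)) {
    function(u) hill(u, params$c3, params$K3) * params$K_F /
      ((params$K_F + params$mt0) * params$d_f)
  } else {
    function(u) f_level
  }
  g <- function(u) {
    (params$b + hill(u, params$c1, params$K1) +
       hill(f_at(u), params$c2, params$K2)) * v0 - params$r * u
  }
  us <- seq(0, u_max, length.out = 4001L)
  gs <- vapply(us, g, numeric(1))
  flips <- which(gs[-1] * gs[-length(gs)] <= 0 & gs[-length(gs)] != 0)
  roots <- vapply(flips, function(i) {
    uniroot(g, c(us[i], us[i + 1]), tol = 1e-12)$root
  }, numeric(1))
  roots <- sort(unique(round(roots, 10)))
  if (!length(roots))
    stop("no fixed point found in [0, ", u_max, "]; widen the bracket")
  # a root is stable when g crosses from positive to negative
  stable <- vapply(roots, function(x) g(x - 1e-7) > 0 && g(x + 1e-7) < 0, logical(1))
  tibble::tibble(u = roots, stable = stable)
}

#' Convenience accessors for the bistable states
#'
#' `u_high()` and `u_low()` return the high and low stable fixed points of
#' the well-mixed Rac-GTP kinetics at the reference Rac-GDP level.
#'
#' `u_high()` falls back to the zero-tension quasi-steady F-actin level
#' when the basal-tension kinetics have lost the high state (possible at
#' strongly elevated `mt0`, where the polarized state survives only
#' through the global Rac-GDP rise).
#'
#' @inheritParams well_mixed_fixed_points
#' @return A single concentration (um^-2).
#' @export
u_high <- function(params, v0 = params$v0, f_level = NULL) {
  fp <- well_mixed_fixed_points(params, v0 = v0, f_level = f_level)
  if (is.null(f_level) && nrow(fp) == 1) {
    p0 <- params
    p0$mt0 <- 1e-9
    fp <- well_mixed_fixed_points(p0, v0 = v0, f_level = NULL)
  }
  if (nrow(fp) == 1)
    stop("kinetics are monostable: no high fixed point")
  max(fp$u[fp$stable])
}

#' @rdname u_high
#' @export
u_low <- function(params, v0 = params$v0, f_level = NULL) {
  fp <- well_mixed_fixed_points(params, v0 = v0, f_level = f_level)
  min(fp$u[fp$stable])
}
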