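# Phase-field geometry: smooth indicator fields for cell shapes on a
# periodic grid.  Coordinates are cell-centered: x = y = 0 at the domain
# center, element [i, j] sits at (xs[i], ys[j]).

fft2 <- function(z) stats::fft(z)
ifft2 <- function(z) stats::fft(z, inverse = TRUE) / length(z)

# periodic wavenumbers in FFT ordering
fft_wavenumbers <- function(N, L) {
  idx <- c(0:(N %/% 2), -((N - (N %/% 2 + 1)):1))
  2 * pi * idx / L
}

# spectral gradient components of a periodic real field
spectral_grad <- function(z, L) {
  N <- nrow(z)
  k <- fft_wavenumbers(N, L)
  Z <- fft2(z)
  gx <- Re(ifft2((1i * k) * Z))        # recycles k down rows (x-direction)
  gy <- Re(ifft2(t(t(Z) * (1i * k))))  # along columns (y-direction)
  list(gx = gx, gy = gy)
}

new_polar_geometry <- function(phi, params, kind, extra = list()) {
  N <- nrow(phi)
  L <- params$L
  h <- L / N
  g <- spectral_grad(phi, L)
  gphi <- sqrt(g$gx^2 + g$gy^2)
  Bphi <- phi^2 * (1 - phi)^2
  # membrane state weight for u: areal (phi) within the diffuse layer,
  # smoothly zero outside it; carries the ring's areal measure so the
  # membrane pool can deplete the cytosolic pool (wave pinning)
  mem_w <- phi * Bphi / (Bphi + 1.25e-5 * max(Bphi))
  xs <- (seq_len(N) - 1) * h - L / 2
  xc <- matrix(xs, N, N, byrow = FALSE)
  yc <- matrix(xs, N, N, byrow = TRUE)
  dA <- h^2
  area <- sum(phi) * dA
  # centroid of the support (used as the polarity-moment origin)
  cx <- sum(phi * xc) / sum(phi)
  cy <- sum(phi * yc) / sum(phi)
  out <- c(list(phi = phi, Bphi = Bphi, grad_phi_mag = gphi, mem_w = mem_w,
                xc = xc, yc = yc, xs = xs, h = h, dA = dA, L = L, N = N,
                eps = params$eps, area = area, center = c(x = cx, y = cy),
                kind = kind),
           extra)
  class(out) <- "polar_geometry"
  out
}

#' @export
print.polar_geometry <- function(x, ...) {
  cat(sprintf("<polar_geometry: %s>  N=%d  L=%g um  h=%.4g um  area=%.1f um^2\n",
              x$kind, x$N, x$L, x$h, x$area))
  invisible(x)
}

#' Phase-field disk geometry
#'
#' Builds the smooth indicator of a disk of radius `R` centered in the
#' periodic domain: `phi = (tanh((R - rho)/eps) + 1) / 2` with `rho` the
#' distance from the domain center.  The diffuse `phi = 0.5` layer of
#' width ~`eps` represents the cell membrane; the membrane weight
#' `B(phi) = phi^2 (1-phi)^2` and the spectral gradient magnitude
#' `|grad phi|` are precomputed.
#'
#' @param params A [polar_params()]; uses `R`, `eps`, `L`, `N`.
#' @return A `polar_geometry` with fields `phi`, `Bphi`, `grad_phi_mag`,
#'   cell-centered coordinate matrices `xc`, `yc`, spacing `h`, cell area
#'   `area` and `center`.
#' @examples
#' g <- make_disk(polar_params(N = 64))
#' g$area / (pi * 10^2)   # ~1
#' @export
make_disk <- function(params) {
  # the tanh layer has full width ~2*eps; require it to cover >= 2 spacings
  if (2 * params$eps < 2 * params$L / params$N)
    stop("interface unresolved: the interface layer (~2*eps) must span at ",
         "least 2 grid spacings (eps = ", params$eps, ", h = ",
         params$L / params$N, ")")
  if (params$R + 3 * params$eps >= params$L / 2)
    stop("cell does not fit: need R + several eps < L/2")
  N <- params$N
  h <- params$L / N
  xs <- (seq_len(N) - 1) * h - params$L / 2
  rho <- sqrt(outer(xs^2, xs^2, "+"))
  phi <- 0.5 * (tanh((params$R - rho) / params$eps) + 1)
  new_polar_geometry(phi, params, kind = "disk")
}

#' Membrane weights of a phase field
#'
#' Returns the interface-localized measures used to place membrane-bound
#' quantities: `B(phi) = phi^2 (1 - phi)^2` and the spectral gradient
#' magnitude `|grad phi|`.  Both vanish away from the diffuse interface.
#'
#' @param phi Phase-field matrix with values in `[0, 1]`.
#' @param L Domain edge length (um) for the spectral derivative.
#' @return A list with `Bphi` and `grad_phi_mag`.
#' @export
membrane_measures <- function(phi, L) {
  if (any(phi < -1e-6) || any(phi > 1 + 1e-6))
    stop("phi must lie in [0, 1]")
  g <- spectral_grad(phi, L)
  list(Bphi = phi^2 * (1 - phi)^2, grad_phi_mag = sqrt(g$gx^2 + g$gy^2))
}

# signed distance to a disk (negative inside)
sdf_disk <- function(xc, yc, cx, cy, R) sqrt((xc - cx)^2 + (yc - cy)^2) - R

# signed distance to an axis-aligned box centered at (cx, cy)
sdf_box <- function(xc, yc, cx, cy, hx, hy) {
  qx <- abs(xc - cx) - hx
  qy <- abs(yc - cy) - hy
  outside <- sqrt(pmax(qx, 0)^2 + pmax(qy, 0)^2)
  inside <- pmin(pmax(qx, qy), 0)
  outside + inside
}

#' Tethered pseudopod-neck-body geometry
#'
#' Builds the smooth indicator of a cell shaped like a large body disk
#' joined to a small pseudopod disk by a thin rectangular neck along the
#' x axis (pseudopod on the +x side).  The neck is long and thin so that
#' diffusion between pseudopod and body is severely restricted without
#' being cut off.  The shape is the tanh-smoothed signed-distance
#' indicator of the union, centered in the domain.
#'
#' @param params A [polar_params()].
#' @param body_radius,pseudopod_radius Disk radii (um).
#' @param neck_length Gap between the two disk rims bridged by the neck (um).
#' @param neck_halfwidth Half-width of the neck (um); must exceed two grid
#'   spacings so the neck stays diffusively connected.
#' @return A `polar_geometry` (kind `"tethered"`) with extra fields
#'   `body_center`, `pseudopod_center` and `neck_interval` (x-range of the
#'   open neck, used to validate severing cuts).
#' @export
make_tethered <- function(params, body_radius = 6, neck_length = 8,
                          neck_halfwidth = 1.5, pseudopod_radius = 3.5) {
  h <- params$L / params$N
  if (neck_halfwidth < 2 * h)
    stop("neck unresolved: neck_halfwidth must be at least 2 grid spacings")
  stopifnot(body_radius > 0, neck_length >= 0, pseudopod_radius > 0)
  extent <- 2 * body_radius + neck_length + 2 * pseudopod_radius
  if (extent + 4 * params$eps >= params$L)
    stop("tethered shape does not fit in the domain")
  bx <- -extent / 2 + body_radius
  px <- extent / 2 - pseudopod_radius
  N <- params$N
  xs <- (seq_len(N) - 1) * h - params$L / 2
  xc <- matrix(xs, N, N, byrow = FALSE)
  yc <- matrix(xs, N, N, byrow = TRUE)
  d <- pmin(sdf_disk(xc, yc, bx, 0, body_radius),
            sdf_disk(xc, yc, px, 0, pseudopod_radius),
            sdf_box(xc, yc, (bx + px) / 2, 0, (px - bx) / 2, neck_halfwidth))
  phi <- 0.5 * (tanh(-d / params$eps) + 1)
  new_polar_geometry(phi, params, kind = "tethered",
                     extra = list(body_center = c(x = bx, y = 0),
                                  pseudopod_center = c(x = px, y = 0),
                                  neck_interval = c(bx + body_radius,
                                                    px - pseudopod_radius)))
}

#' Sever a geometry along a vertical cut
#'
#' Splits a phase field into a front (x > `cut_x`) and a body
#' (x < `cut_x`) piece by multiplying `phi` with complementary
#' tanh-smoothed half-space indicators, so the two pieces partition the
#' original support exactly (`phi_front + phi_body = phi`).
#'
#' @param geometry A `polar_geometry`; for tethered shapes the cut must
#'   cross the open neck.
#' @param cut_x Cut position (cell-centered x, um).  Defaults to the neck
#'   midpoint for tethered shapes and 0 otherwise.
#' @param params The `polar_params` used to build the geometry.
#' @return A list with `front` and `body` geometries.
#' @export
sever <- function(geometry, cut_x = NULL, params) {
  if (is.null(cut_x)) {
    cut_x <- if (!is.null(geometry$neck_interval)) mean(geometry$neck_interval) else 0
  }
  if (!is.null(geometry$neck_interval)) {
    ni <- geometry$neck_interval
    if (cut_x <= ni[1] || cut_x >= ni[2])
      stop("cut_x = ", cut_x, " lies outside the neck interval [",
           ni[1], ", ", ni[2], "]")
  }
  Hf <- 0.5 * (tanh((geometry$xc - cut_x) / geometry$eps) + 1)
  front <- new_polar_geometry(geometry$phi * Hf, params, kind = "severed_front")
  body <- new_polar_geometry(geometry$phi * (1 - Hf), params, kind = "severed_body")
  list(front = front, body = body)
}
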