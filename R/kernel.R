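# Forward model of the four-pulse DEER dipolar evolution signal.

#' Point-dipole coupling constant
#'
#' Dipolar coupling constant for two free-electron point dipoles,
#' in MHz nm^3. The Cu(II) g-values deviate from g_e by a few percent;
#' orientation selection is deliberately ignored (the coordination-plane
#' normals of interacting Cu centres are broadly distributed), so the
#' free-electron constant is used throughout.
#' @export
DIPOLAR_NU0 <- 52.04

#' Dipolar coupling frequency between two electron spins
#'
#' Frequency of the secular dipole-dipole coupling for an interspin vector
#' of length `r` at angle `theta` to the external field,
#' \deqn{\nu(r,\theta) = \nu_0 r^{-3} (1 - 3\cos^2\theta),}
#' with \eqn{\nu_0 = 52.04} MHz nm^3 for two free electrons.
#'
#' @param r interspin distance in nm (positive).
#' @param theta angle between interspin vector and field, radians.
#' @return frequency in MHz (vectorized over `r` and `theta`).
#' @examples
#' dipolar_frequency(2, pi / 2)        # 52.04 / 8 MHz
#' dipolar_frequency(3, acos(1 / sqrt(3)))  # magic angle: 0
#' @export
dipolar_frequency <- function(r, theta) {
  if (any(!is.finite(r)) || any(r <= 0)) stop("`r` must be positive and finite")
  DIPOLAR_NU0 / r^3 * (1 - 3 * cos(theta)^2)
}

# Fresnel-integral closed form of the orientation average
#   K(t, r) = int_0^1 cos(2 pi nu0/r^3 (1 - 3 x^2) t) dx,  x = cos(theta).
# With a = 2 pi nu_perp t (dimensionless phase) and z = sqrt(6 a / pi):
#   K = sqrt(pi/(6a)) [cos(a) C(z) + sin(a) S(z)].
kernel_fresnel <- function(t_ns, r_nm) {
  a <- outer(abs(t_ns) * 1e-3, 2 * pi * DIPOLAR_NU0 / r_nm^3)
  out <- a
  zero <- a == 0
  if (any(!zero)) {
    aa <- a[!zero]
    z <- sqrt(6 * aa / pi)
    out[!zero] <- sqrt(pi / (6 * aa)) *
      (cos(aa) * pracma::fresnelC(z) + sin(aa) * pracma::fresnelS(z))
  }
  out[zero] <- 1
  out
}

# Orientation average by fixed-order Gauss-Legendre quadrature in cos(theta).
# Order fixed at 1001 nodes for reproducibility.
kernel_quadrature_nodes <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- pracma::gaussLegendre(1001, 0, 1)
    cache
  }
})

kernel_quadrature <- function(t_ns, r_nm) {
  gl <- kernel_quadrature_nodes()
  out <- matrix(NA_real_, length(t_ns), length(r_nm))
  for (j in seq_along(r_nm)) {
    nu <- DIPOLAR_NU0 / r_nm[j]^3 * (1 - 3 * gl$x^2)  # MHz at each node
    # phase = 2 pi nu[MHz] t[ns] 1e-3
    out[, j] <- as.vector(cos(outer(t_ns * 1e-3, 2 * pi * nu)) %*% gl$w)
  }
  out
}

#' Powder-averaged DEER kernel
#'
#' Orientation average of the dipolar oscillation over an isotropic
#' ("powder") distribution of interspin vectors,
#' \deqn{K(t, r) = \int_0^{\pi/2} \cos(2\pi\,\nu(r,\theta)\,t)\,
#'   \sin\theta\, d\theta,}
#' so that \eqn{K(0, r) = 1} for every distance. Evaluated either through
#' the Fresnel-integral closed form (default, exact to machine precision)
#' or by 1001-node Gauss-Legendre quadrature in \eqn{\cos\theta}.
#'
#' @param t evolution times in ns.
#' @param r interspin distances in nm (positive).
#' @param method `"fresnel"` (closed form) or `"quadrature"`.
#' @return a `length(t)` x `length(r)` matrix of kernel values; dropped to a
#'   vector if either argument has length one.
#' @examples
#' powder_kernel(0, c(2, 3, 5))              # all 1
#' powder_kernel(seq(0, 1000, 100), 2.25)
#' @export
powder_kernel <- function(t, r, method = c("fresnel", "quadrature")) {
  method <- match.arg(method)
  if (any(!is.finite(r)) || any(r <= 0)) stop("`r` must be positive and finite")
  if (any(!is.finite(t))) stop("`t` must be finite")
  out <- switch(method,
    fresnel = kernel_fresnel(t, r),
    quadrature = kernel_quadrature(t, r)
  )
  if (length(t) == 1L || length(r) == 1L) drop(out) else out
}

#' Dipolar form factor of a distance distribution
#'
#' Distance average of the powder kernel,
#' \eqn{F(t) = \int p(r) K(t, r)\, dr} (trapezoid rule on the grid of `p`),
#' i.e. the noise- and background-free dipolar evolution signal of an
#' ensemble with interspin distance density `p`.
#'
#' @param p a [distance_distribution] object (or list with fields `r`, `p`).
#' @param t evolution times in ns.
#' @param lambda modulation depth; `form_factor` returns the full modulation
#'   function \eqn{1 - \lambda + \lambda F(t)} when `lambda < 1`.
#' @return numeric vector of signal values, `F(0) = 1` for normalized `p`.
#' @export
form_factor <- function(p, t, lambda = 1) {
  p <- as_distance_distribution(p)
  if (length(p$r) < 2L) stop("distance grid is empty or degenerate")
  w <- trapz_weights(p$r)
  f <- as.vector(kernel_fresnel(t, p$r) %*% (w * p$p))
  1 - lambda + lambda * f
}

#' Intermolecular background decay
#'
#' Echo decay caused by pumped spins distributed homogeneously in three
#' dimensions, which gives a stretched exponential with exponent linear in
#' time: \eqn{B(t) = \exp(-k t)}.
#'
#' @param t evolution times in ns.
#' @param k background decay rate per ns (non-negative).
#' @return numeric vector of background values.
#' @export
deer_background <- function(t, k) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0)
    stop("`k` must be a single non-negative rate per ns")
  exp(-k * t)
}

# Trapezoid-weighted kernel matrix mapping a density on `r` to F on `t`:
# F = (K * w) %*% p. Used by both the forward simulator and the inversion.
deer_kernel_matrix <- function(t, r) {
  kernel_fresnel(t, r) * rep(trapz_weights(r), each = length(t))
}
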