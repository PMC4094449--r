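# Biot-Savart computation of the z-component of the magnetic flux density
# generated by the in-plane current density, evaluated at pixel centers of
# the mid-slice. The conducting object is modelled as a slab of thickness L
# (z-invariant J), so each source pixel is a column of height L; the
# z-integral of the volume kernel has the closed form
#   Bz(r) = mu0/(4 pi) * sum_{r'} [(y-y') Jx - (x-x') Jy] * A
#                         * L / (rho^2 sqrt(rho^2 + L^2/4)),
# with A the pixel area and rho = |r - r'| in-plane. For rho >> L this tends
# to the point-volume kernel L*A/rho^3; for L >> rho it reaches the 2-D limit
# 2A/rho^2, under which mu0 J = perp-grad(Bz) - the regime the transversal
# J-substitution reconstruction relies on. The singular self-pixel term is
# set to zero: the integrand is odd over a symmetric pixel.

#' Magnetic flux density from a current density distribution
#'
#' @param j A `current_density_map` (see [current_density()]).
#' @param thickness Conducting thickness L of the slab in meters: the
#'   z-extent over which the current density flows (default 0.080 m, the
#'   height of typical boundary electrodes). Source pixels are columns of
#'   this height; the field is evaluated at the mid-slice.
#' @param method `"fft"` (default; two cross-correlations evaluated by zero-
#'   padded FFTs, exact up to floating rounding) or `"direct"` (brute-force
#'   double sum, O(N^2), kept as the independent reference path).
#' @param injection,tc_s Metadata forwarded to the returned image.
#' @return A [flux_density_image()] in tesla.
#' @export
bz_from_current <- function(j, thickness = 0.080,
                            method = c("fft", "direct"),
                            injection = 1L, tc_s = NA_real_) {
  method <- match.arg(method)
  stopifnot(inherits(j, "current_density_map"), thickness > 0)
  grid <- j$grid
  px <- grid$pixel_size
  n <- grid$n_rows
  m <- grid$n_cols
  cst <- 1e-7 * px^2  # mu0 / (4 pi) * pixel area
  l2 <- (thickness / 2)^2

  jx <- j$Jx
  jy <- j$Jy
  jx[!j$support] <- 0
  jy[!j$support] <- 0

  # column kernel: thickness / (rho^2 sqrt(rho^2 + (L/2)^2))
  col_kernel <- function(rho2) {
    out <- thickness / (rho2 * sqrt(rho2 + l2))
    out[rho2 == 0] <- 0
    out
  }

  if (method == "direct") {
    co <- pixel_coords(grid)
    bz <- matrix(0, n, m)
    src <- which(jx != 0 | jy != 0, arr.ind = TRUE)
    for (ii in seq_len(n)) {
      for (jj in seq_len(m)) {
        dx <- co$x[jj] - co$x[src[, 2]]
        dy <- co$y[ii] - co$y[src[, 1]]
        rho2 <- dx^2 + dy^2
        kern <- col_kernel(rho2)
        vals <- (dy * jx[src] - dx * jy[src]) * kern
        bz[ii, jj] <- cst * sum(vals)
      }
    }
  } else {
    # Kernel K(di, dj) for offset r - r' = (dj*px, di*px):
    #   K1 acts on Jx (factor +dy), K2 on Jy (factor -dx).
    p2 <- 2L * n
    q2 <- 2L * m
    di <- c(0:(n - 1L), rep(0L, p2 - 2L * n + 1L), -( (n - 1L):1L))
    dj <- c(0:(m - 1L), rep(0L, q2 - 2L * m + 1L), -( (m - 1L):1L))
    dym <- matrix(di * px, p2, q2)
    dxm <- matrix(dj * px, p2, q2, byrow = TRUE)
    kern <- col_kernel(dxm^2 + dym^2)
    k1 <- dym * kern
    k2 <- -dxm * kern

    pad <- function(a) {
      out <- matrix(0, p2, q2)
      out[seq_len(n), seq_len(m)] <- a
      out
    }
    conv <- function(k, a) {
      Re(stats::fft(stats::fft(k) * stats::fft(pad(a)), inverse = TRUE)) /
        (p2 * q2)
    }
    bz <- cst * (conv(k1, jx)[seq_len(n), seq_len(m)] +
                 conv(k2, jy)[seq_len(n), seq_len(m)])
  }

  flux_density_image(bz, grid, injection = injection, tc_s = tc_s)
}
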