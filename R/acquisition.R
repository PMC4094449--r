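# Noisy MR acquisition model and phase-difference Bz extraction. The complex
# image pair for the positive/negative current injections is
#   S± = M exp(i delta) exp(± i gamma Bz Tc) + noise,
# simulated directly in the image domain (under ideal full sampling this is
# equivalent to adding the noise in k-space, and it avoids modelling gradient
# encoding). `noise_std` is the magnitude of the complex perturbation: each
# quadrature receives i.i.d. N(0, noise_std/sqrt(2)), which makes the
# extracted-Bz noise match the standard model sd(Bz) = 1/(2 gamma Tc SNR)
# with SNR = M / noise_std.

#' Simulate the complex MR image pair for a +/- current injection
#'
#' @param m A [magnitude_image()]; its `noise_std` sets the complex noise
#'   level.
#' @param bz A [flux_density_image()] on the same grid (tesla).
#' @param tc_s Current injection time in seconds.
#' @param seed Integer seed; the simulation is bit-reproducible given the
#'   seed and leaves the caller's RNG state untouched.
#' @param delta Systematic phase artifact field in radians (matrix or scalar;
#'   default 0). It cancels in the phase difference of the pair.
#' @return Object of class `complex_image_pair` with fields `s_plus`,
#'   `s_minus` (complex matrices), `tc_s`, `gamma`, `noise_std`, `seed`.
#' @export
simulate_acquisition <- function(m, bz, tc_s, seed, delta = 0) {
  stopifnot(inherits(m, "magnitude_image"),
            inherits(bz, "flux_density_image"))
  stop_if_grid_mismatch(m, bz, "magnitude and flux density")
  if (!is.numeric(tc_s) || tc_s <= 0) {
    stop("tc_s must be positive (seconds)", call. = FALSE)
  }
  phase <- GAMMA_PROTON * bz$values * tc_s
  wrap <- max(abs(phase))
  if (wrap >= pi / 2) {
    stop(sprintf(
      "phase |gamma Bz Tc| reaches %.3g rad (>= pi/2): the phase-difference extraction would wrap; reduce Tc or the current amplitude",
      wrap), call. = FALSE)
  }
  if (length(delta) == 1L) {
    delta <- matrix(delta, m$grid$n_rows, m$grid$n_cols)
  }
  base <- m$values * exp(1i * delta)
  n_px <- length(base)
  sd_q <- m$noise_std / sqrt(2)
  noise <- with_seed(seed, {
    matrix(complex(real = stats::rnorm(2 * n_px, sd = sd_q),
                   imaginary = stats::rnorm(2 * n_px, sd = sd_q)),
           nrow = n_px, ncol = 2)
  })
  s_plus <- base * exp(1i * phase) +
    matrix(noise[, 1], m$grid$n_rows, m$grid$n_cols)
  s_minus <- base * exp(-1i * phase) +
    matrix(noise[, 2], m$grid$n_rows, m$grid$n_cols)
  structure(list(s_plus = s_plus, s_minus = s_minus, grid = m$grid,
                 tc_s = tc_s, gamma = GAMMA_PROTON, noise_std = m$noise_std,
                 support = m$support, injection = bz$injection, seed = seed),
            class = "complex_image_pair")
}

#' Extract the magnetic flux density from a complex image pair
#'
#' Bz = arg(S+ conj(S-)) / (2 gamma Tc), the principal-value phase of the
#' conjugate product, in which any systematic phase artifact cancels.
#' Zero-magnitude pixels (undefined phase) get Bz = 0 and are flagged.
#'
#' @param pair A `complex_image_pair` from [simulate_acquisition()] (or built
#'   from measured data).
#' @return A [flux_density_image()]; attribute `flagged` is a logical matrix
#'   marking zero-magnitude pixels.
#' @export
extract_bz <- function(pair) {
  stopifnot(inherits(pair, "complex_image_pair"))
  if (!is.numeric(pair$tc_s) || pair$tc_s <= 0) {
    stop("pair must carry a positive tc_s", call. = FALSE)
  }
  prod <- pair$s_plus * Conj(pair$s_minus)
  flagged <- Mod(pair$s_plus) == 0 | Mod(pair$s_minus) == 0
  bz <- Arg(prod) / (2 * pair$gamma * pair$tc_s)
  bz[flagged] <- 0
  out <- flux_density_image(bz, pair$grid, injection = pair$injection,
                            tc_s = pair$tc_s, support = pair$support)
  attr(out, "flagged") <- flagged
  out
}

#' Per-pixel noise level of the measured flux density
#'
#' Implements the noise model sd(Bz) = 1 / (2 gamma Tc SNR) with
#' SNR = M / noise_std, valid above a low-SNR threshold. Below the threshold
#' the model underestimates badly, so the value is clamped at the threshold
#' SNR and the pixel is flagged in `low_snr_mask`.
#'
#' @param m A [magnitude_image()].
#' @param tc_s Current injection time in seconds (> 0).
#' @param snr_threshold Validity bound of the model (default 2.8).
#' @return Object of class `noise_std_map` with fields `values` (tesla),
#'   `low_snr_mask`, `snr` and the grid/support.
#' @export
noise_std_map <- function(m, tc_s, snr_threshold = 2.8) {
  stopifnot(inherits(m, "magnitude_image"))
  if (!is.numeric(tc_s) || length(tc_s) != 1L || tc_s <= 0) {
    stop("tc_s must be a positive scalar (seconds)", call. = FALSE)
  }
  snr <- m$values / m$noise_std
  low <- m$support & snr <= snr_threshold
  snr_eff <- pmax(snr, snr_threshold)
  vals <- 1 / (2 * GAMMA_PROTON * tc_s * snr_eff)
  vals[!m$support] <- 0
  new_field(vals, m$grid, m$support, "noise_std_map",
            list(low_snr_mask = low, snr = snr, tc_s = tc_s,
                 snr_threshold = snr_threshold,
                 mag_noise_std = m$noise_std))
}
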