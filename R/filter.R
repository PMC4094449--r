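# The adaptively weighted spatial averaging filter: the enhancement method at
# the heart of this package. For each pixel r a disc-shaped neighborhood of
# radius eta(r) is averaged with weights
#   w_r(s) = exp(-|M(r) - M(s)| / h(r)) / zeta(r),   zeta normalizing to 1,
# where M is the MR magnitude image. Both the distance denominator h(r) and
# the radius eta(r) grow with the local noise level of the measured flux
# density, so strong averaging happens exactly where the reconstructed
# conductivity cannot be trusted, while large magnitude contrasts (|M(r)-M(s)|
# >> h) suppress mixing across tissue boundaries.

#' Noise-adaptive filter parameter maps
#'
#' Maps the per-pixel flux-density noise level to the filter's distance
#' denominator `h` (magnitude units) and neighborhood radius `eta` (pixels),
#' both proportional to sd(Bz):
#' `h = max(h_floor, c_h * noise_std * sd/sd_ref)` and
#' `eta = min(eta_max, round(c_eta * sd/sd_ref))` (round half up), where
#' `sd_ref` is the noise level at a reference magnitude SNR `snr_ref` and the
#' magnitude noise std converts the dimensionless ratio into magnitude units.
#' The anchoring is absolute, so a uniformly clean acquisition (magnitude SNR
#' above about `2 c_eta * snr_ref`) drives `eta` to zero and the filter to
#' the identity - the do-no-harm limit - while pixels near or below the
#' reference SNR get windows growing up to `eta_max`.
#'
#' @param noise A `noise_std_map` from [noise_std_map()].
#' @param c_h,c_eta Dimensionless proportionality constants (> 0).
#' @param eta_max Cap on the neighborhood radius in pixels.
#' @param h_floor Lower bound on `h` in magnitude units. Default: 5% of the
#'   magnitude image's dynamic range over the support when `m` is supplied,
#'   otherwise 0 (no floor).
#' @param m Optional [magnitude_image()] used only for the `h_floor` default.
#' @param snr_ref Reference magnitude SNR defining `sd_ref` (default 5, just
#'   above the noise model's validity bound of about 3: averaging should be
#'   fully engaged where the flux-density data approach unreliability).
#' @return Object of class `filter_params` with matrices `h`, `eta` and the
#'   constants used.
#' @export
filter_params <- function(noise, c_h = 1, c_eta = 4, eta_max = 6L,
                          h_floor = NULL, m = NULL, snr_ref = 5) {
  stopifnot(inherits(noise, "noise_std_map"))
  if (!is.numeric(c_h) || c_h <= 0 || !is.numeric(c_eta) || c_eta <= 0) {
    stop("c_h and c_eta must be positive", call. = FALSE)
  }
  stopifnot(is.numeric(snr_ref), snr_ref > 0)
  s <- noise$support
  if (!any(s)) stop("noise map has empty support", call. = FALSE)
  if (is.null(h_floor)) {
    h_floor <- if (is.null(m)) 0 else {
      0.05 * diff(range(m$values[m$support]))
    }
  }
  sd_ref <- 1 / (2 * GAMMA_PROTON * noise$tc_s * snr_ref)
  ratio <- noise$values / sd_ref
  h <- matrix(pmax(c_h * noise$mag_noise_std * ratio, h_floor),
              nrow(ratio), ncol(ratio))
  h[h <= 0] <- max(h_floor, .Machine$double.eps)  # h must stay positive
  eta <- matrix(pmin(round_half_up(c_eta * ratio), eta_max),
                nrow(ratio), ncol(ratio))
  eta[!s] <- 0
  eta <- matrix(as.integer(eta), nrow(ratio), ncol(ratio))
  structure(list(h = h, eta = eta, c_h = c_h, c_eta = c_eta,
                 eta_max = as.integer(eta_max), h_floor = h_floor,
                 sd_ref = sd_ref, snr_ref = snr_ref, grid = noise$grid,
                 support = s),
            class = "filter_params")
}

# Offsets (di, dj) with di^2 + dj^2 <= r^2, as an integer matrix.
#' @keywords internal
#' @noRd
disc_offsets <- function(r) {
  r <- as.integer(r)
  d <- expand.grid(di = -r:r, dj = -r:r)
  d <- d[d$di^2 + d$dj^2 <= r^2, , drop = FALSE]
  as.matrix(d)
}

#' Weight kernel of the adaptive filter at one pixel
#'
#' Returns the neighborhood offsets and normalized weights the filter uses at
#' pixel `r`. The neighborhood is the Euclidean disc of radius `eta(r)`
#' clipped to the support; the center pixel is included (distance 0, maximal
#' unnormalized weight 1).
#'
#' @param m A [magnitude_image()].
#' @param r Integer pair `(row, col)` (1-based) inside the support.
#' @param params A [filter_params()] on the same grid.
#' @return List with `offsets` (k x 2 integer matrix of (di, dj)), `weights`
#'   (summing to 1), `zeta` (the normalizer) and `center` (index of the
#'   center entry).
#' @export
weight_kernel <- function(m, r, params) {
  stopifnot(inherits(m, "magnitude_image"), inherits(params, "filter_params"))
  i <- as.integer(r[1]); j <- as.integer(r[2])
  s <- m$support
  if (!s[i, j]) stop("pixel r lies outside the support", call. = FALSE)
  eta_r <- params$eta[i, j]
  off <- disc_offsets(eta_r)
  ii <- i + off[, 1]
  jj <- j + off[, 2]
  ok <- ii >= 1L & ii <= nrow(s) & jj >= 1L & jj <= ncol(s)
  ok[ok] <- s[cbind(ii[ok], jj[ok])]
  off <- off[ok, , drop = FALSE]
  d <- abs(m$values[i, j] - m$values[cbind(i + off[, 1], j + off[, 2])]) /
    params$h[i, j]
  w <- exp(-d)
  zeta <- sum(w)
  list(offsets = off, weights = w / zeta, zeta = zeta,
       center = which(off[, 1] == 0L & off[, 2] == 0L))
}

# Core engine: filter an arbitrary field with the magnitude-driven kernel.
# Vectorized over pixels by looping over neighborhood offsets; an offset
# contributes at pixel r iff |offset| <= eta(r) and both endpoints are in the
# support. Pixels with eta = 0 pass through bit-exactly (single unit weight).
#' @keywords internal
#' @noRd
filter_field <- function(x, m_values, params) {
  s <- params$support
  eta <- params$eta
  h <- params$h
  eta_sq <- matrix(as.numeric(eta)^2, nrow(eta), ncol(eta))
  num <- matrix(0, nrow(x), ncol(x))
  zeta <- matrix(0, nrow(x), ncol(x))
  off <- disc_offsets(max(eta))
  for (k in seq_len(nrow(off))) {
    di <- off[k, 1]; dj <- off[k, 2]
    r2 <- di^2 + dj^2
    ok <- s & (eta_sq >= r2) & (shift_mat(s, di, dj) > 0)
    if (!any(ok)) next
    w <- matrix(0, nrow(x), ncol(x))
    w[ok] <- exp(-abs(m_values[ok] - shift_mat(m_values, di, dj)[ok]) / h[ok])
    num <- num + w * shift_mat(x, di, dj)
    zeta <- zeta + w
  }
  out <- x
  out[s] <- num[s] / zeta[s]
  out
}

#' Apply the adaptively weighted spatial averaging filter
#'
#' Replaces each conductivity value by the weighted average of its
#' noise-adapted neighborhood (see [filter_params()] and [weight_kernel()]).
#'
#' @param sigma A [conductivity_image()] to enhance (typically a noisy
#'   reconstruction).
#' @param m The [magnitude_image()] driving the weights (used as acquired; no
#'   pre-smoothing).
#' @param params A [filter_params()] on the same grid.
#' @return The filtered [conductivity_image()] (`check = FALSE`).
#' @export
apply_filter <- function(sigma, m, params) {
  stopifnot(inherits(sigma, "conductivity_image"),
            inherits(m, "magnitude_image"),
            inherits(params, "filter_params"))
  stop_if_grid_mismatch(sigma, m, "conductivity and magnitude")
  stop_if_grid_mismatch(sigma, params, "conductivity and filter params")
  vals <- filter_field(sigma$values, m$values, params)
  if (!all(is.finite(vals[sigma$support]))) {
    stop("filtered image contains non-finite values", call. = FALSE)
  }
  out <- conductivity_image(vals, sigma$grid, support = sigma$support,
                            check = FALSE)
  out
}

#' Error decomposition of the filtered image (synthetic mode)
#'
#' For known truth `sigma_t` and additive noise `N`, the filtered image
#' satisfies `|sigma_w - sigma_t| <= E1 + E2` pointwise, where
#' `E1 = |sum_s w(s) (sigma_t(s) - sigma_t(r))|` is the blurring error (zero
#' on regions the kernel does not straddle) and `E2 = |sum_s w(s) N(s)|` is
#' the averaged-noise error.
#'
#' @param sigma_true The noiseless [conductivity_image()].
#' @param noise Numeric matrix of additive conductivity noise (same shape).
#' @param m The [magnitude_image()] driving the kernel.
#' @param params A [filter_params()].
#' @return List with matrices `e1`, `e2`, the filtered image `sigma_w` (of
#'   `sigma_true + noise`), and `bound_gap = (E1 + E2) - |sigma_w - sigma_t|`
#'   (nonnegative up to floating rounding).
#' @export
error_decomposition <- function(sigma_true, noise, m, params) {
  stopifnot(inherits(sigma_true, "conductivity_image"),
            inherits(m, "magnitude_image"),
            inherits(params, "filter_params"))
  stop_if_grid_mismatch(sigma_true, m, "truth and magnitude")
  s <- params$support
  st <- sigma_true$values
  f_st <- filter_field(st, m$values, params)
  f_n <- filter_field(noise, m$values, params)
  e1 <- abs(f_st - st)
  e2 <- abs(f_n)
  e1[!s] <- 0
  e2[!s] <- 0
  sigma_w <- conductivity_image(filter_field(st + noise, m$values, params),
                                sigma_true$grid, support = sigma_true$support,
                                check = FALSE)
  gap <- (e1 + e2) - abs(sigma_w$values - st)
  gap[!s] <- 0
  list(e1 = e1, e2 = e2, sigma_w = sigma_w, bound_gap = gap)
}
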