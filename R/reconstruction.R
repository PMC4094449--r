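# Transversal J-substitution reconstruction: a single-pass conductivity
# update from the mismatch between measured and homogeneous-model flux
# density under two orthogonal injections,
#   sigma = sigma_H - (1/mu0) * sum_n perp_grad(Bz_n - Bz_n^H) . grad(u_n^H)
#                       / sum_n |grad(u_n^H)|^2 .
# The update differentiates the noisy Bz only once and acts pixel-locally, so
# noise in one region does not propagate into others.

#' Forward solution for a homogeneous reference conductivity
#'
#' Solves the voltage problem with a uniform conductivity `sigma_h` on the
#' given support for each electrode configuration, and computes the
#' corresponding current density and flux density.
#'
#' @param sigma_h Homogeneous reference conductivity in S/m (> 0).
#' @param grid An [mreit_grid()].
#' @param electrodes List of [make_electrodes()] configurations, one per
#'   injection (typically horizontal then vertical).
#' @param support Logical support mask (default: whole grid).
#' @return Object of class `homogeneous_reference` with `sigma_h`, `u_h`,
#'   `j_h`, `bz_h` (lists over injections), `grid`, `support`.
#' @export
homogeneous_reference <- function(sigma_h, grid, electrodes, support = NULL) {
  stopifnot(is.numeric(sigma_h), length(sigma_h) == 1L, sigma_h > 0,
            inherits(grid, "mreit_grid"), is.list(electrodes))
  if (is.null(support)) support <- matrix(TRUE, grid$n_rows, grid$n_cols)
  vals <- matrix(0, grid$n_rows, grid$n_cols)
  vals[support] <- sigma_h
  sig <- conductivity_image(vals, grid, support = support)
  u_h <- list(); j_h <- list(); bz_h <- list()
  for (k in seq_along(electrodes)) {
    u <- solve_voltage(sig, electrodes[[k]])
    j <- current_density(sig, u)
    u_h[[k]] <- u
    j_h[[k]] <- j
    bz_h[[k]] <- bz_from_current(j, thickness = electrodes[[k]]$thickness,
                                 injection = k)
  }
  structure(list(sigma_h = sigma_h, u_h = u_h, j_h = j_h, bz_h = bz_h,
                 grid = grid, support = support, electrodes = electrodes),
            class = "homogeneous_reference")
}

#' Perpendicular (rotated) transverse gradient
#'
#' Computes the rotated gradient (df/dy, -df/dx) with the shared stencil.
#'
#' @param f Numeric matrix.
#' @param grid An [mreit_grid()].
#' @param support Logical support mask (default: whole grid).
#' @return List with components `px` (= df/dy) and `py` (= -df/dx).
#' @export
perp_gradient <- function(f, grid, support = NULL) {
  stopifnot(inherits(grid, "mreit_grid"))
  if (is.null(support)) support <- matrix(TRUE, nrow(f), ncol(f))
  g <- field_gradient(f, support, grid$pixel_size)
  list(px = g$gy, py = -g$gx)
}

#' Reconstruct conductivity by transversal J-substitution
#'
#' @param bz_list List of two measured [flux_density_image()]s for the two
#'   orthogonal injections, in the same order as the reference's electrode
#'   configurations.
#' @param ref A [homogeneous_reference()] computed on the identical grid,
#'   support and electrodes.
#' @param eps_denominator Relative floor for the |grad u_H|^2 denominator:
#'   pixels where it falls below `eps_denominator * max(denominator)` (e.g.
#'   in electrode shadows with almost no reference current) are floored and
#'   flagged.
#' @return A [conductivity_image()] (`check = FALSE`: noisy reconstructions
#'   may contain non-positive excursions) with attribute `flagged` marking
#'   floored pixels.
#' @export
transversal_j_substitution <- function(bz_list, ref, eps_denominator = 1e-6) {
  stopifnot(inherits(ref, "homogeneous_reference"),
            is.list(bz_list), length(bz_list) == length(ref$u_h))
  grid <- ref$grid
  s <- ref$support
  num <- matrix(0, grid$n_rows, grid$n_cols)
  den <- matrix(0, grid$n_rows, grid$n_cols)
  for (n in seq_along(bz_list)) {
    bz <- bz_list[[n]]
    stopifnot(inherits(bz, "flux_density_image"))
    stop_if_grid_mismatch(bz, ref, "measured Bz and reference")
    db <- bz$values - ref$bz_h[[n]]$values
    pg <- perp_gradient(db, grid, s)
    gu <- field_gradient(ref$u_h[[n]]$values, s, grid$pixel_size)
    num <- num + pg$px * gu$gx + pg$py * gu$gy
    den <- den + gu$gx^2 + gu$gy^2
  }
  den_max <- max(den[s])
  if (den_max == 0) {
    stop("reference voltage gradient vanishes everywhere: no current flows",
         call. = FALSE)
  }
  floor_val <- eps_denominator * den_max
  flagged <- s & den < floor_val
  den_f <- pmax(den, floor_val)
  sig <- matrix(0, grid$n_rows, grid$n_cols)
  sig[s] <- ref$sigma_h - num[s] / (MU0 * den_f[s])
  out <- conductivity_image(sig, grid, support = s, check = FALSE)
  attr(out, "flagged") <- flagged
  out
}
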