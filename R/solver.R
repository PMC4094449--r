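# Finite-volume solver for the current-injection Neumann problem
#   div(sigma grad u) = 0 in the support, -sigma du/dn = g on its boundary.
# Five-point stencil with harmonic averaging of sigma on faces; the pure
# Neumann rank deficiency is removed by a zero-mean Lagrange multiplier, which
# also fixes the gauge. The scheme is conservative, so discrete flux balance
# holds to solver tolerance.

#' Solve the voltage distribution for an injected current
#'
#' @param sigma A [conductivity_image()]; the solve runs on its support.
#' @param electrodes An [make_electrodes()] configuration on the same grid.
#' @return A `voltage_map` (volts, zero mean over the support).
#' @export
solve_voltage <- function(sigma, electrodes) {
  stopifnot(inherits(sigma, "conductivity_image"),
            inherits(electrodes, "electrode_config"))
  stop_if_grid_mismatch(sigma, list(grid = electrodes$grid),
                        "conductivity and electrodes")
  grid <- sigma$grid
  s <- sigma$support
  sv <- sigma$values
  th <- electrodes$thickness
  n_pix <- sum(s)
  idx <- matrix(0L, grid$n_rows, grid$n_cols)
  idx[s] <- seq_len(n_pix)

  # Interior face conductances (face length px / distance px cancel, leaving
  # harmonic-mean sigma times thickness, in siemens).
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add_faces <- function(di, dj) {
    nb_ok <- shift_mat(s, di, dj) > 0
    both <- s & nb_ok
    if (!any(both)) return(invisible(NULL))
    p <- idx[both]
    sig_p <- sv[both]
    sig_q <- shift_mat(sv, di, dj)[both]
    q <- shift_mat(idx, di, dj)[both]
    cond <- 2 * sig_p * sig_q / (sig_p + sig_q) * th
    ii <<- c(ii, p, p)
    jj <<- c(jj, p, q)
    xx <<- c(xx, cond, -cond)
    invisible(NULL)
  }
  # Each ordered neighbor pair appears once per direction, covering both
  # orientations of every face.
  add_faces(0L, 1L); add_faces(0L, -1L); add_faces(1L, 0L); add_faces(-1L, 0L)

  faces <- resolve_electrodes(electrodes, s)
  b <- numeric(n_pix)
  el <- faces[faces$current != 0, ]
  if (abs(sum(el$current)) > 1e-12 * sum(abs(el$current))) {
    stop("incompatible Neumann data: net injected current is nonzero",
         call. = FALSE)
  }
  for (k in seq_len(nrow(el))) {
    p <- idx[el$i[k], el$j[k]]
    b[p] <- b[p] + el$current[k]
  }

  # Zero-mean constraint via bordered system.
  a_mat <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                dims = c(n_pix, n_pix))
  ones <- rep(1, n_pix)
  aug <- rbind(cbind(a_mat, ones), c(ones, 0))
  sol <- tryCatch(
    Matrix::solve(aug, c(b, 0)),
    error = function(e) {
      stop(paste0("voltage system is singular (disconnected support or ",
                  "incompatible Neumann data): ", conditionMessage(e)),
           call. = FALSE)
    }
  )
  u <- matrix(0, grid$n_rows, grid$n_cols)
  u[s] <- as.numeric(sol)[seq_len(n_pix)]
  voltage_map(u, grid, s)
}

#' Current density from conductivity and voltage
#'
#' Computes J = -sigma grad(u) with the package's shared gradient stencil
#' (central differences in the support interior, one-sided at the support
#' boundary).
#'
#' @param sigma A [conductivity_image()].
#' @param u A `voltage_map` solved on the same grid.
#' @return A `current_density_map` with components `Jx`, `Jy` in A/m^2.
#' @export
current_density <- function(sigma, u) {
  stopifnot(inherits(sigma, "conductivity_image"),
            inherits(u, "voltage_map"))
  stop_if_grid_mismatch(sigma, u, "conductivity and voltage")
  s <- sigma$support & u$support
  g <- field_gradient(u$values, s, sigma$grid$pixel_size)
  current_density_map(-sigma$values * g$gx, -sigma$values * g$gy,
                      sigma$grid, s)
}

# Discrete divergence of a vector field with the shared stencil (diagnostic;
# used by the conservation tests).
#' @keywords internal
#' @noRd
divergence_field <- function(jx, jy, support, pixel_size) {
  gx <- field_gradient(jx, support, pixel_size)$gx
  gy <- field_gradient(jy, support, pixel_size)$gy
  gx + gy
}
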