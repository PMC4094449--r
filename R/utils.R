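# Internal numerical utilities shared by every module: one gradient stencil,
# one matrix-shift primitive, one seeded-RNG wrapper.

# Gyromagnetic ratio of the proton, rad/(T s).
GAMMA_PROTON <- 26.75e7

# Magnetic permeability of free space, T m / A.
MU0 <- 4e-7 * pi

#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# out[i, j] = f[i + di, j + dj]; zero fill outside.
#' @keywords internal
#' @noRd
shift_mat <- function(f, di, dj, fill = 0) {
  n <- nrow(f)
  m <- ncol(f)
  out <- matrix(fill, n, m)
  ri <- seq_len(n)
  rj <- seq_len(m)
  ok_i <- ri[ri + di >= 1L & ri + di <= n]
  ok_j <- rj[rj + dj >= 1L & rj + dj <= m]
  if (length(ok_i) && length(ok_j)) {
    out[ok_i, ok_j] <- f[ok_i + di, ok_j + dj]
  }
  out
}

# Shift with edge replication (used by the reaction-diffusion baseline).
#' @keywords internal
#' @noRd
shift_rep <- function(f, di, dj) {
  n <- nrow(f)
  m <- ncol(f)
  src_i <- pmin(pmax(seq_len(n) + di, 1L), n)
  src_j <- pmin(pmax(seq_len(m) + dj, 1L), m)
  f[src_i, src_j, drop = FALSE]
}

# The package-wide gradient stencil: central differences where both neighbors
# lie in the support, one-sided at the support boundary, zero where isolated.
# Returns list(gx, gy) with x increasing along columns and y along rows.
#' @keywords internal
#' @noRd
field_gradient <- function(f, support, pixel_size) {
  stopifnot(identical(dim(f), dim(support)))
  s <- support
  gE <- shift_mat(f, 0L, 1L); aE <- shift_mat(s, 0L, 1L) > 0
  gW <- shift_mat(f, 0L, -1L); aW <- shift_mat(s, 0L, -1L) > 0
  gN <- shift_mat(f, 1L, 0L); aN <- shift_mat(s, 1L, 0L) > 0
  gS <- shift_mat(f, -1L, 0L); aS <- shift_mat(s, -1L, 0L) > 0

  gx <- matrix(0, nrow(f), ncol(f))
  gy <- matrix(0, nrow(f), ncol(f))

  both <- aE & aW
  gx[both] <- (gE[both] - gW[both]) / (2 * pixel_size)
  fwd <- aE & !aW
  gx[fwd] <- (gE[fwd] - f[fwd]) / pixel_size
  bwd <- !aE & aW
  gx[bwd] <- (f[bwd] - gW[bwd]) / pixel_size

  both <- aN & aS
  gy[both] <- (gN[both] - gS[both]) / (2 * pixel_size)
  fwd <- aN & !aS
  gy[fwd] <- (gN[fwd] - f[fwd]) / pixel_size
  bwd <- !aN & aS
  gy[bwd] <- (f[bwd] - gS[bwd]) / pixel_size

  gx[!s] <- 0
  gy[!s] <- 0
  list(gx = gx, gy = gy)
}

# Round-half-up to integer (reproducible across platforms, unlike round()).
#' @keywords internal
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' @keywords internal
#' @noRd
stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  ga <- a$grid
  gb <- b$grid
  if (ga$n_rows != gb$n_rows || ga$n_cols != gb$n_cols ||
      abs(ga$pixel_size - gb$pixel_size) > 1e-15 * ga$pixel_size) {
    stop(sprintf("grid mismatch between %s: %dx%d (%.6g m) vs %dx%d (%.6g m)",
                 what, ga$n_rows, ga$n_cols, ga$pixel_size,
                 gb$n_rows, gb$n_cols, gb$pixel_size), call. = FALSE)
  }
  invisible(TRUE)
}
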