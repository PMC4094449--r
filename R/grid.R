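#' Pixel grid with physical spacing
#'
#' A rectangular pixel grid carrying the physical pixel size in meters. The
#' coordinate convention used throughout the package is pixel-centered and
#' 0-based: pixel (r, c) (row r, column c, both counted from 0) has its center
#' at physical position x = (c + 1/2) * pixel_size, y = (r + 1/2) * pixel_size,
#' so x increases with column index and y with row index. All geometry is in
#' meters. In R's 1-based indexing, element `[i, j]` of a field matrix is pixel
#' (i - 1, j - 1).
#'
#' @param n_rows,n_cols Matrix dimensions (at least 8 each).
#' @param fov Field of view along one axis in meters; exactly one of `fov` and
#'   `pixel_size` must be given. A non-square grid uses `fov / n_cols` as the
#'   (isotropic) pixel size.
#' @param pixel_size Pixel spacing in meters (isotropic).
#' @return An object of class `mreit_grid` with fields `n_rows`, `n_cols`,
#'   `pixel_size` (m).
#' @examples
#' g <- mreit_grid(128, fov = 0.24)
#' g$pixel_size   # 0.001875 m
#' @export
mreit_grid <- function(n_rows, n_cols = n_rows, fov = NULL, pixel_size = NULL) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (n_rows < 8L || n_cols < 8L) {
    stop("grid must be at least 8x8", call. = FALSE)
  }
  if (is.null(pixel_size) == is.null(fov)) {
    stop("give exactly one of 'fov' or 'pixel_size'", call. = FALSE)
  }
  if (is.null(pixel_size)) pixel_size <- fov / n_cols
  if (!is.finite(pixel_size) || pixel_size <= 0) {
    stop("pixel_size must be positive and finite", call. = FALSE)
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, pixel_size = pixel_size,
         origin = "pixel-centered, 0-based (row, col); x ~ col, y ~ row"),
    class = "mreit_grid"
  )
}

#' Physical coordinates of pixel centers
#'
#' @param grid An [mreit_grid()].
#' @return List with vectors `x` (length `n_cols`), `y` (length `n_rows`) and
#'   matrices `X`, `Y` of the same shape as a field on the grid, all in meters.
#' @export
pixel_coords <- function(grid) {
  stopifnot(inherits(grid, "mreit_grid"))
  x <- (seq_len(grid$n_cols) - 0.5) * grid$pixel_size
  y <- (seq_len(grid$n_rows) - 0.5) * grid$pixel_size
  list(x = x, y = y,
       X = matrix(x, grid$n_rows, grid$n_cols, byrow = TRUE),
       Y = matrix(y, grid$n_rows, grid$n_cols))
}

#' @export
print.mreit_grid <- function(x, ...) {
  cat(sprintf("<mreit_grid> %d x %d, pixel %.4g mm (FOV %.4g x %.4g mm)\n",
              x$n_rows, x$n_cols, 1e3 * x$pixel_size,
              1e3 * x$pixel_size * x$n_rows, 1e3 * x$pixel_size * x$n_cols))
  invisible(x)
}
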