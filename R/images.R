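# 2-D field containers. Each is a list(values, grid, ...) with a class tag;
# `values` is an n_rows x n_cols numeric matrix and `support` a logical matrix
# marking the pixels that belong to the imaged object. Values outside the
# support are stored as 0.

new_field <- function(values, grid, support, class, extra = list()) {
  stopifnot(inherits(grid, "mreit_grid"))
  values <- as.matrix(values)
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols) {
    stop(sprintf("field is %dx%d but grid is %dx%d",
                 nrow(values), ncol(values), grid$n_rows, grid$n_cols),
         call. = FALSE)
  }
  if (is.null(support)) {
    support <- matrix(TRUE, grid$n_rows, grid$n_cols)
  }
  support <- matrix(as.logical(support), grid$n_rows, grid$n_cols)
  structure(c(list(values = values, grid = grid, support = support), extra),
            class = c(class, "mreit_field"))
}

#' Conductivity image
#'
#' A 2-D conductivity field sigma in S/m on a pixel grid.
#'
#' @param values Numeric matrix, S/m.
#' @param grid An [mreit_grid()].
#' @param support Logical matrix marking object pixels; defaults to
#'   `values > 0`.
#' @param check If `TRUE`, enforce that values are finite everywhere and
#'   strictly positive on the support. Reconstructed images from noisy data may
#'   legitimately contain non-positive excursions; constructors on that path
#'   pass `check = FALSE`.
#' @return Object of class `conductivity_image`.
#' @export
conductivity_image <- function(values, grid, support = NULL, check = TRUE) {
  if (is.null(support)) support <- as.matrix(values) > 0
  img <- new_field(values, grid, support, "conductivity_image")
  if (check) {
    if (!all(is.finite(img$values))) {
      stop("conductivity must be finite everywhere", call. = FALSE)
    }
    if (any(img$values[img$support] <= 0)) {
      stop("conductivity must be positive on the support", call. = FALSE)
    }
  }
  img
}

#' MR magnitude image
#'
#' Nonnegative MR magnitude M (arbitrary units) with the standard deviation of
#' its complex acquisition noise. `noise_std` is the magnitude of the complex
#' noise perturbation (each quadrature receives `noise_std / sqrt(2)`), so the
#' per-pixel magnitude SNR entering the flux-density noise model is
#' `values / noise_std`.
#'
#' @param values Numeric matrix, >= 0, arbitrary units.
#' @param noise_std Scalar > 0, same units as `values`.
#' @param grid An [mreit_grid()].
#' @param support Optional logical support mask (default: `values > 0`).
#' @return Object of class `magnitude_image`.
#' @export
magnitude_image <- function(values, noise_std, grid, support = NULL) {
  if (is.null(support)) support <- as.matrix(values) > 0
  if (!is.numeric(noise_std) || length(noise_std) != 1L ||
      !is.finite(noise_std) || noise_std <= 0) {
    stop("noise_std must be a positive finite scalar", call. = FALSE)
  }
  img <- new_field(values, grid, support, "magnitude_image",
                   list(noise_std = noise_std))
  if (any(img$values < 0) || !all(is.finite(img$values))) {
    stop("magnitude must be finite and nonnegative", call. = FALSE)
  }
  img
}

#' Magnetic flux density image
#'
#' The z-component Bz of the current-induced magnetic flux density, in tesla,
#' for one injection.
#'
#' @param values Numeric matrix, tesla.
#' @param grid An [mreit_grid()].
#' @param injection Injection label (1 or 2).
#' @param tc_s Current injection time in seconds (carried as metadata).
#' @param support Optional logical support mask.
#' @return Object of class `flux_density_image`.
#' @export
flux_density_image <- function(values, grid, injection = 1L, tc_s = NA_real_,
                               support = NULL) {
  img <- new_field(values, grid, support, "flux_density_image",
                   list(injection = as.integer(injection), tc_s = tc_s))
  if (!all(is.finite(img$values))) {
    stop("flux density must be finite", call. = FALSE)
  }
  img
}

#' Region-of-interest mask
#'
#' @param label Short region name (e.g. "D1").
#' @param mask Logical matrix; must be nonempty.
#' @param grid An [mreit_grid()].
#' @return Object of class `roi_mask`.
#' @export
roi_mask <- function(label, mask, grid) {
  m <- new_field(mask * 1, grid, mask, "roi_mask", list(label = label))
  m$mask <- m$support
  if (!any(m$mask)) stop("ROI mask is empty", call. = FALSE)
  m
}

# Internal: voltage map with zero-mean gauge over the support.
voltage_map <- function(values, grid, support) {
  v <- new_field(values, grid, support, "voltage_map")
  v$values[v$support] <- v$values[v$support] - mean(v$values[v$support])
  v$values[!v$support] <- 0
  v
}

# Internal: current density with components Jx, Jy in A/m^2.
current_density_map <- function(jx, jy, grid, support) {
  j <- new_field(jx, grid, support, "current_density_map")
  j$Jx <- j$values
  j$Jy <- matrix(as.numeric(jy), grid$n_rows, grid$n_cols)
  j
}

#' @export
print.mreit_field <- function(x, ...) {
  v <- x$values[x$support]
  cat(sprintf("<%s> %d x %d, %d support px, range [%.4g, %.4g]\n",
              class(x)[1], x$grid$n_rows, x$grid$n_cols, sum(x$support),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}
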