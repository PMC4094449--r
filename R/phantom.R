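# Synthetic disc phantom emulating a saline MREIT test object: a background
# disc with cylindrical inclusions of contrasting conductivity and depressed
# MR magnitude (gel objects have short T2, so they appear dark and their Bz
# data are noisy).

#' Describe a cylindrical inclusion
#'
#' @param center Numeric length-2, physical (x, y) center in meters.
#' @param radius Core radius in meters.
#' @param conductivity Core conductivity in S/m.
#' @param magnitude_level MR magnitude level of the core (arbitrary units).
#' @param wrap_radius Outer radius of a wrapping annulus in meters, or `NULL`
#'   for a plain disc.
#' @param wrap_conductivity Annulus conductivity in S/m (required with
#'   `wrap_radius`).
#' @param wrap_magnitude_level Annulus magnitude level; defaults to
#'   `magnitude_level`.
#' @param label Region label used for the ROI masks (e.g. "D1").
#' @return Object of class `mreit_inclusion`.
#' @export
inclusion <- function(center, radius, conductivity, magnitude_level = 4,
                      wrap_radius = NULL, wrap_conductivity = NULL,
                      wrap_magnitude_level = NULL, label = "D") {
  stopifnot(length(center) == 2L, radius > 0, conductivity > 0)
  if (!is.null(wrap_radius)) {
    if (wrap_radius <= radius) {
      stop("wrap_radius must exceed the core radius", call. = FALSE)
    }
    if (is.null(wrap_conductivity) || wrap_conductivity <= 0) {
      stop("a wrapped inclusion needs a positive wrap_conductivity",
           call. = FALSE)
    }
    if (is.null(wrap_magnitude_level)) wrap_magnitude_level <- magnitude_level
  }
  structure(list(center = as.numeric(center), radius = radius,
                 conductivity = conductivity,
                 magnitude_level = magnitude_level,
                 wrap_radius = wrap_radius,
                 wrap_conductivity = wrap_conductivity,
                 wrap_magnitude_level = wrap_magnitude_level,
                 label = label),
            class = "mreit_inclusion")
}

#' Default three-inclusion phantom layout
#'
#' The layout emulates a cylindrical saline phantom (0.4 S/m) with three
#' objects: D1 a 1.5 S/m gel disc, D2 a 0.1 S/m gel disc, and D3 a 1.5 S/m
#' core wrapped in a 0.3 S/m annulus. Geometry scales with the field of view;
#' at the default 240 mm FOV the inclusions sit on a 50 mm orbit with radii
#' 16 mm (D1, D2) and 10/20 mm (D3 core/annulus). All objects share a low
#' magnitude level (default 4) against the saline background (default 30),
#' reproducing the low-SNR interior that makes their flux-density data noisy.
#'
#' @param fov Field of view in meters.
#' @param magnitude_inclusion Magnitude level inside the objects.
#' @return List of three [inclusion()] objects.
#' @export
default_inclusions <- function(fov = 0.24, magnitude_inclusion = 4) {
  ctr <- c(fov / 2, fov / 2)
  orbit <- 0.05 / 0.24 * fov
  at <- function(deg) ctr + orbit * c(cos(deg * pi / 180), sin(deg * pi / 180))
  list(
    inclusion(at(90), radius = 0.016 / 0.24 * fov, conductivity = 1.5,
              magnitude_level = magnitude_inclusion, label = "D1"),
    inclusion(at(210), radius = 0.016 / 0.24 * fov, conductivity = 0.1,
              magnitude_level = magnitude_inclusion, label = "D2"),
    inclusion(at(330), radius = 0.010 / 0.24 * fov, conductivity = 1.5,
              magnitude_level = magnitude_inclusion,
              wrap_radius = 0.020 / 0.24 * fov, wrap_conductivity = 0.3,
              wrap_magnitude_level = magnitude_inclusion, label = "D3")
  )
}

#' Generate a synthetic disc phantom
#'
#' Builds piecewise-constant conductivity and magnitude maps for a background
#' disc containing cylindrical inclusions, together with ROI masks for each
#' inclusion core, each annulus, and the background. A pixel takes the value
#' of the innermost region containing its center (no anti-aliasing), keeping
#' the ROI gradient-variance metric meaningful on piecewise-constant truth.
#'
#' @param grid An [mreit_grid()].
#' @param background_sigma Background conductivity in S/m.
#' @param inclusions List of [inclusion()] objects (may be empty).
#' @param disc_radius Background disc radius in meters (default 0.4 x FOV).
#' @param disc_center Physical (x, y) of the disc center (default FOV center).
#' @param magnitude_background Background MR magnitude level (arbitrary units).
#' @param magnitude_noise_std Complex acquisition noise std in magnitude units.
#' @param seed Accepted for interface symmetry and ignored: the phantom is
#'   purely geometric; all randomness enters later, in the simulated
#'   acquisition.
#' @return List with `sigma` ([conductivity_image()]), `magnitude`
#'   ([magnitude_image()]), `rois` (named list of [roi_mask()]: one per
#'   inclusion core, `<label>_annulus` for each wrap, and `background`),
#'   `support` (logical matrix) and the geometry actually used.
#' @examples
#' g <- mreit_grid(64, fov = 0.24)
#' ph <- make_disc_phantom(g)
#' sort(unique(ph$sigma$values[ph$support]))  # 0.1 0.3 0.4 1.5
#' @export
make_disc_phantom <- function(grid,
                              background_sigma = 0.4,
                              inclusions = default_inclusions(
                                grid$n_cols * grid$pixel_size),
                              disc_radius = 0.4 * grid$n_cols * grid$pixel_size,
                              disc_center = NULL,
                              magnitude_background = 30,
                              magnitude_noise_std = 1,
                              seed = NULL) {
  stopifnot(inherits(grid, "mreit_grid"), background_sigma > 0,
            disc_radius > 0)
  fov_x <- grid$n_cols * grid$pixel_size
  fov_y <- grid$n_rows * grid$pixel_size
  if (is.null(disc_center)) disc_center <- c(fov_x / 2, fov_y / 2)

  co <- pixel_coords(grid)
  d2 <- function(center) (co$X - center[1])^2 + (co$Y - center[2])^2
  support <- d2(disc_center) <= disc_radius^2
  if (!any(support)) stop("background disc contains no pixels", call. = FALSE)

  sig <- matrix(0, grid$n_rows, grid$n_cols)
  mag <- matrix(0, grid$n_rows, grid$n_cols)
  sig[support] <- background_sigma
  mag[support] <- magnitude_background

  rois <- list()
  covered <- matrix(FALSE, grid$n_rows, grid$n_cols)
  for (inc in inclusions) {
    stopifnot(inherits(inc, "mreit_inclusion"))
    outer_r <- if (is.null(inc$wrap_radius)) inc$radius else inc$wrap_radius
    if (sqrt(sum((inc$center - disc_center)^2)) + outer_r > disc_radius) {
      stop(sprintf(
        "inclusion '%s' (outer radius %.4g m at (%.4g, %.4g)) extends outside the background disc",
        inc$label, outer_r, inc$center[1], inc$center[2]), call. = FALSE)
    }
    core <- d2(inc$center) <= inc$radius^2
    if (!is.null(inc$wrap_radius)) {
      ann <- d2(inc$center) <= inc$wrap_radius^2 & !core
      sig[ann] <- inc$wrap_conductivity
      mag[ann] <- inc$wrap_magnitude_level
      rois[[paste0(inc$label, "_annulus")]] <-
        roi_mask(paste0(inc$label, "_annulus"), ann, grid)
      covered <- covered | ann
    }
    sig[core] <- inc$conductivity
    mag[core] <- inc$magnitude_level
    rois[[inc$label]] <- roi_mask(inc$label, core, grid)
    covered <- covered | core
  }
  rois[["background"]] <- roi_mask("background", support & !covered, grid)

  list(
    sigma = conductivity_image(sig, grid, support = support),
    magnitude = magnitude_image(mag, magnitude_noise_std, grid,
                                support = support),
    rois = rois,
    support = support,
    disc_radius = disc_radius,
    disc_center = disc_center,
    background_sigma = background_sigma,
    inclusions = inclusions
  )
}

#' Boundary electrode pair for current injection
#'
#' Describes two opposite boundary electrodes driving an injection current
#' through the object. The configuration is resolved against a concrete
#' support mask at solve time: boundary faces whose outward normal points
#' along the injection axis and whose centers lie within the electrode width
#' (measured transversally about the support centroid) receive a uniform
#' Neumann current flux; current I enters through one electrode and leaves
#' through the other, so the net injected flux is exactly zero (the
#' compatibility condition of the Neumann problem).
#'
#' @param grid An [mreit_grid()].
#' @param pair `"horizontal"` (current along x: enters at the +x electrode,
#'   exits at -x) or `"vertical"` (along y).
#' @param current Injection current in amperes (> 0).
#' @param width Electrode width in meters along the boundary; `Inf` selects
#'   the full opposing sides (useful for strip geometries).
#' @param thickness Conducting thickness of the 2-D model in meters: the
#'   z-extent over which the injected current flows, converting surface flux
#'   into amperes (default 0.080 m, the electrode height; the same thickness
#'   is used by the Biot-Savart kernel so the forward model stays coherent).
#' @return Object of class `electrode_config`.
#' @export
make_electrodes <- function(grid, pair = c("horizontal", "vertical"),
                            current = 0.010, width = 0.080,
                            thickness = 0.080) {
  pair <- match.arg(pair)
  stopifnot(inherits(grid, "mreit_grid"))
  if (!is.numeric(current) || current <= 0) {
    stop("current must be positive (amperes)", call. = FALSE)
  }
  if (width <= 0 || thickness <= 0) {
    stop("width and thickness must be positive (meters)", call. = FALSE)
  }
  structure(list(grid = grid, pair = pair, current = current,
                 width = width, thickness = thickness),
            class = "electrode_config")
}

# Resolve an electrode configuration against a support mask. Returns a data
# frame of boundary faces: pixel (i, j), face direction, and the signed
# Neumann current carried by the face (amperes into the domain; the per-face
# flux density g is current / (pixel_size * thickness)).
#' @keywords internal
#' @noRd
resolve_electrodes <- function(electrodes, support) {
  grid <- electrodes$grid
  px <- grid$pixel_size
  co <- pixel_coords(grid)
  s <- support

  face_dirs <- list(
    E = list(di = 0L, dj = 1L, nx = 1, ny = 0),
    W = list(di = 0L, dj = -1L, nx = -1, ny = 0),
    N = list(di = 1L, dj = 0L, nx = 0, ny = 1),
    S = list(di = -1L, dj = 0L, nx = 0, ny = -1)
  )

  xc <- mean(co$X[s])
  yc <- mean(co$Y[s])

  faces <- do.call(rbind, lapply(names(face_dirs), function(d) {
    fd <- face_dirs[[d]]
    is_face <- s & !(shift_mat(s, fd$di, fd$dj) > 0)
    idx <- which(is_face, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(i = idx[, 1], j = idx[, 2], dir = d,
               x = co$x[idx[, 2]] + fd$nx * px / 2,
               y = co$y[idx[, 1]] + fd$ny * px / 2)
  }))

  w2 <- electrodes$width / 2
  if (electrodes$pair == "horizontal") {
    extent <- diff(range(co$Y[s])) + px
    sel_in <- faces$dir == "E" & abs(faces$y - yc) <= w2
    sel_out <- faces$dir == "W" & abs(faces$y - yc) <= w2
  } else {
    extent <- diff(range(co$X[s])) + px
    sel_in <- faces$dir == "N" & abs(faces$x - xc) <= w2
    sel_out <- faces$dir == "S" & abs(faces$x - xc) <= w2
  }
  if (is.finite(electrodes$width) && electrodes$width > extent) {
    stop(sprintf(
      "electrode width %.4g m exceeds the support's transverse extent %.4g m",
      electrodes$width, extent), call. = FALSE)
  }
  if (!any(sel_in) || !any(sel_out)) {
    stop("electrode selects no boundary faces; widen it or check the support",
         call. = FALSE)
  }

  faces$current <- 0
  faces$current[sel_in] <- electrodes$current / sum(sel_in)
  faces$current[sel_out] <- -electrodes$current / sum(sel_out)
  faces$g <- faces$current / (px * electrodes$thickness)
  faces
}
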