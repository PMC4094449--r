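# Shared in-code fixtures: everything is generated programmatically.

GAMMA <- 26.75e7
MU0 <- 4e-7 * pi

# Uniform rectangular strip with full-edge electrodes: the geometry with an
# exact 1-D analytic voltage solution.
strip_fixture <- function(n_rows = 16, n_cols = 24, sigma = 2,
                          pixel_size = 0.005, current = 0.01,
                          thickness = 0.004) {
  g <- mreit_grid(n_rows, n_cols, pixel_size = pixel_size)
  sig <- conductivity_image(matrix(sigma, n_rows, n_cols), g)
  el <- make_electrodes(g, "horizontal", current = current, width = Inf,
                        thickness = thickness)
  list(grid = g, sigma = sig, electrodes = el, current = current,
       thickness = thickness,
       cross_section = n_rows * pixel_size * thickness)
}

# Small default phantom for fast end-to-end runs.
small_phantom <- function(n = 64, fov = 0.24, ...) {
  g <- mreit_grid(n, fov = fov)
  list(grid = g, phantom = make_disc_phantom(g, ...))
}

# Build a magnitude image + params pair with prescribed constant SNR level,
# handy for filter unit tests. tc chosen so sd(Bz) is in the model's range.
flat_params <- function(m_values, noise_std = 1, tc_s = 0.01, c_h = 1,
                        c_eta = 4, eta_max = 6, h_floor = 0, snr_ref = 5,
                        support = NULL) {
  g <- mreit_grid(nrow(m_values), ncol(m_values),
                  pixel_size = 0.24 / ncol(m_values))
  m <- magnitude_image(m_values, noise_std, g, support = support)
  nz <- noise_std_map(m, tc_s = tc_s)
  list(grid = g, m = m,
       params = filter_params(nz, c_h = c_h, c_eta = c_eta,
                              eta_max = eta_max, h_floor = h_floor,
                              snr_ref = snr_ref))
}

# Hand-made complex image pair (for extraction tests on synthetic phases).
raw_pair <- function(s_plus, s_minus, tc_s, grid, injection = 1L) {
  structure(list(s_plus = s_plus, s_minus = s_minus, grid = grid,
                 tc_s = tc_s, gamma = GAMMA, noise_std = 1,
                 support = matrix(TRUE, grid$n_rows, grid$n_cols),
                 injection = injection, seed = NA_integer_),
            class = "complex_image_pair")
}
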