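# Adaptive weighted spatial averaging filter.

test_that("filter parameter maps follow the prescribed arithmetic", {
  # SNR equal to the reference SNR makes sd = sd_ref: h = c_h, eta = c_eta
  fx <- flat_params(matrix(5, 16, 16), noise_std = 1, c_h = 1, c_eta = 2,
                    snr_ref = 5)
  expect_equal(unique(fx$params$h[fx$params$support]), 1)
  expect_equal(unique(fx$params$eta[fx$params$support]), 2L)
})

test_that("h and eta are monotone in the local noise level", {
  m_vals <- matrix(30, 16, 16)
  m_vals[, 9:16] <- 4  # right half noisier (lower SNR)
  fx <- flat_params(m_vals, noise_std = 1)
  left <- fx$params$support & col(m_vals) <= 8
  right <- fx$params$support & col(m_vals) > 8
  expect_gt(min(fx$params$h[right]), max(fx$params$h[left]))
  expect_gte(min(fx$params$eta[right]), max(fx$params$eta[left]))
})

test_that("low uniform noise collapses the filter to the identity", {
  fx <- flat_params(matrix(500, 16, 16), noise_std = 1)
  expect_true(all(fx$params$eta == 0L))
  g <- fx$grid
  sig <- conductivity_image(matrix(runif(256, 0.5, 1.5), 16, 16), g)
  out <- apply_filter(sig, fx$m, fx$params)
  expect_identical(out$values, sig$values)
})

test_that("weight kernels match hand-evaluated weights and normalize exactly", {
  # two-pixel support, M = (10, 12), h = 2: weights (1, e^-1)/(1 + e^-1)
  g <- mreit_grid(8, 8, pixel_size = 0.01)
  m_vals <- matrix(0, 8, 8)
  m_vals[4, 4] <- 10; m_vals[4, 5] <- 12
  m <- magnitude_image(m_vals, 1, g)  # support = the two pixels
  params <- structure(list(h = matrix(2, 8, 8), eta = matrix(2L, 8, 8),
                           grid = g, support = m$support),
                      class = "filter_params")
  k <- weight_kernel(m, c(4, 4), params)
  expect_equal(sum(k$weights), 1, tolerance = 1e-15)
  expect_equal(sort(k$weights, decreasing = TRUE),
               c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)

  # constant magnitude: uniform weights 1/k over the clipped disc
  m2 <- magnitude_image(matrix(7, 8, 8), 1, g)
  params2 <- structure(list(h = matrix(1, 8, 8), eta = matrix(2L, 8, 8),
                            grid = g, support = m2$support),
                       class = "filter_params")
  k2 <- weight_kernel(m2, c(4, 4), params2)
  expect_equal(length(k2$weights), 13L)  # |{(di,dj): di^2+dj^2 <= 4}|
  expect_equal(unique(round(k2$weights, 15)), 1 / 13)
})

test_that("weights sum to one for randomized kernels", {
  g <- mreit_grid(16, 16, pixel_size = 0.01)
  set.seed(99)
  for (case in 1:40) {
    m <- magnitude_image(matrix(runif(256, 1, 50), 16, 16), 1, g)
    params <- structure(
      list(h = matrix(runif(256, 0.05, 10), 16, 16),
           eta = matrix(sample(0:4, 256, replace = TRUE), 16, 16),
           grid = g, support = m$support),
      class = "filter_params")
    px <- sample(2:15, 2)
    k <- weight_kernel(m, px, params)
    expect_lt(abs(sum(k$weights) - 1), 1e-12)
    expect_true(all(k$weights >= 0))
  }
})

test_that("apply_filter agrees with per-pixel kernels and respects convexity", {
  g <- mreit_grid(16, 16, pixel_size = 0.01)
  set.seed(4)
  m <- magnitude_image(matrix(runif(256, 1, 40), 16, 16), 1, g)
  nz <- noise_std_map(m, tc_s = 0.01)
  params <- filter_params(nz, c_h = 1, c_eta = 3, eta_max = 4, h_floor = 0.5)
  sig <- conductivity_image(matrix(runif(256, 0.1, 2), 16, 16), g)
  out <- apply_filter(sig, m, params)
  for (rep in 1:30) {
    px <- sample(16, 2, replace = TRUE)
    k <- weight_kernel(m, px, params)
    vals <- sig$values[cbind(px[1] + k$offsets[, 1], px[2] + k$offsets[, 2])]
    expect_equal(out$values[px[1], px[2]], sum(k$weights * vals),
                 tolerance = 1e-12)
    expect_gte(out$values[px[1], px[2]], min(vals) - 1e-12)
    expect_lte(out$values[px[1], px[2]], max(vals) + 1e-12)
  }
})

test_that("constant conductivity is invariant under any magnitude image", {
  g <- mreit_grid(16, 16, pixel_size = 0.01)
  set.seed(8)
  m <- magnitude_image(matrix(runif(256, 1, 40), 16, 16), 1, g)
  params <- filter_params(noise_std_map(m, tc_s = 0.01), h_floor = 0.1)
  sig <- conductivity_image(matrix(0.7, 16, 16), g)
  out <- apply_filter(sig, m, params)
  expect_equal(out$values, sig$values, tolerance = 1e-14)
})

test_that("eta = 0 everywhere passes the image through bit-exactly", {
  g <- mreit_grid(12, 12, pixel_size = 0.01)
  m <- magnitude_image(matrix(10, 12, 12), 1, g)
  params <- structure(list(h = matrix(1, 12, 12), eta = matrix(0L, 12, 12),
                           grid = g, support = m$support),
                      class = "filter_params")
  set.seed(2)
  sig <- conductivity_image(matrix(runif(144, 0.1, 2), 12, 12), g)
  out <- apply_filter(sig, m, params)
  expect_identical(out$values, sig$values)
})

test_that("magnitude edges suppress cross-boundary mixing", {
  g <- mreit_grid(10, 10, pixel_size = 0.01)
  m_vals <- matrix(10, 10, 10)
  m_vals[, 6:10] <- 10 + 6  # |dM| / h = 6 > 5 across the edge
  m <- magnitude_image(m_vals, 1, g)
  params <- structure(list(h = matrix(1, 10, 10), eta = matrix(2L, 10, 10),
                           grid = g, support = m$support),
                      class = "filter_params")
  k <- weight_kernel(m, c(5, 5), params)
  across <- k$offsets[, 2] + 5 >= 6
  expect_true(all(k$weights[across] <= exp(-5) * k$weights[k$center]))
})

test_that("noise suppression matches a Monte-Carlo of the same box average", {
  # constant magnitude + eta = 2 makes the kernel a uniform 13-point disc;
  # compare the package's V reduction on one field with a Monte-Carlo of an
  # independently coded disc average over fresh noise fields
  n <- 40
  g <- mreit_grid(n, n, pixel_size = 0.002)
  m <- magnitude_image(matrix(10, n, n), 1, g)
  params <- structure(list(h = matrix(1, n, n), eta = matrix(2L, n, n),
                           grid = g, support = m$support),
                      class = "filter_params")
  roi <- roi_mask("all", matrix(TRUE, n, n), g)
  offs <- expand.grid(di = -2:2, dj = -2:2)
  offs <- offs[offs$di^2 + offs$dj^2 <= 4, ]
  box_avg <- function(x) {
    out <- matrix(0, n, n)
    cnt <- matrix(0, n, n)
    for (k in seq_len(nrow(offs))) {
      i <- pmin(pmax(seq_len(n) + offs$di[k], 1), n)
      sel_i <- seq_len(n) + offs$di[k] >= 1 & seq_len(n) + offs$di[k] <= n
      sel_j <- seq_len(n) + offs$dj[k] >= 1 & seq_len(n) + offs$dj[k] <= n
      shifted <- matrix(0, n, n); ok <- matrix(FALSE, n, n)
      shifted[sel_i, sel_j] <- x[which(sel_i) + offs$di[k],
                                 which(sel_j) + offs$dj[k]]
      ok[sel_i, sel_j] <- TRUE
      out <- out + shifted * ok
      cnt <- cnt + ok
    }
    out / cnt
  }
  set.seed(31)
  ratios <- replicate(15, {
    noise <- matrix(rnorm(n * n, sd = 0.2), n, n)
    img <- conductivity_image(1 + noise, g, support = m$support,
                              check = FALSE)
    smoothed <- conductivity_image(box_avg(1 + noise), g,
                                   support = m$support, check = FALSE)
    roi_variance(smoothed, roi) / roi_variance(img, roi)
  })
  noise <- matrix(rnorm(n * n, sd = 0.2), n, n)
  img <- conductivity_image(1 + noise, g, support = m$support, check = FALSE)
  filt <- apply_filter(img, m, params)
  got <- roi_variance(filt, roi) / roi_variance(img, roi)
  expect_equal(got, mean(ratios), tolerance = 0.2)
})

test_that("error decomposition bounds the filtering error pointwise", {
  g <- mreit_grid(16, 16, pixel_size = 0.01)
  set.seed(12)
  m <- magnitude_image(matrix(runif(256, 2, 40), 16, 16), 1, g)
  params <- filter_params(noise_std_map(m, tc_s = 0.01), h_floor = 0.2)
  sig_t <- conductivity_image(matrix(rep(c(0.5, 1.5), each = 128), 16, 16),
                              g)
  noise <- matrix(rnorm(256, sd = 0.3), 16, 16)
  dec <- error_decomposition(sig_t, noise, m, params)
  expect_true(all(dec$bound_gap >= -1e-12))
  # sigma_t constant: E1 vanishes identically
  dec_c <- error_decomposition(conductivity_image(matrix(1, 16, 16), g),
                               noise, m, params)
  expect_lt(max(dec_c$e1), 1e-14)
  # zero noise: E2 vanishes and E1 alone bounds the error
  dec_n <- error_decomposition(sig_t, matrix(0, 16, 16), m, params)
  expect_true(all(dec_n$e2 == 0))
  expect_true(all(abs(dec_n$sigma_w$values - sig_t$values) <=
                    dec_n$e1 + 1e-12))
})

test_that("E1 vanishes inside piecewise-constant regions with confined kernels", {
  g <- mreit_grid(20, 20, pixel_size = 0.01)
  sig_vals <- matrix(0.5, 20, 20); sig_vals[, 11:20] <- 1.5
  sig_t <- conductivity_image(sig_vals, g)
  m <- magnitude_image(matrix(10, 20, 20), 1, g)
  params <- structure(list(h = matrix(1, 20, 20), eta = matrix(2L, 20, 20),
                           grid = g, support = m$support),
                      class = "filter_params")
  dec <- error_decomposition(sig_t, matrix(0, 20, 20), m, params)
  # brute-force support test: pixels whose kernel cannot straddle the edge
  confined <- abs(col(sig_vals) - 10.5) > 2.5
  expect_lt(max(dec$e1[confined]), 1e-14)
  expect_gt(max(dec$e1[!confined]), 0)
})
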