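# Kernel convolution, detector response, profile extraction and penumbra.

small_kernel <- kernel_params(c(0.8, 0.15, 0.05), c(0.2, 0.6, 1.2))

test_that("FFT convolution equals direct summation on small grids", {
  set.seed(7)
  grid <- make_grid(c(-3.2, 3.1), c(-3.2, 3.1), 0.1)  # 64 x 64
  F <- matrix(runif(length(grid$x) * length(grid$y)),
              length(grid$x), length(grid$y))
  fl <- fluence_grid(F, grid)
  dd <- convolve_dose(fl, small_kernel, pad_sigmas = 3)
  # direct-summation oracle with the identical sampled kernel
  ks <- fffqa:::kernel_samples(small_kernel, 0.1, 3)
  K <- matrix(0, 2 * ks$R + 1, 2 * ks$R + 1)
  for (i in 1:3) K <- K + small_kernel$amplitudes[i] * tcrossprod(ks$G[, i])
  direct <- direct_conv2(F, K) * ks$scale
  direct <- direct[ks$R + seq_along(grid$x), ks$R + seq_along(grid$y)]
  expect_equal(dd$values, direct, tolerance = 1e-10)
})

test_that("convolution identities: impulse, uniform plateau, Gaussian widths", {
  m <- models$fff6
  grid <- make_grid(c(-4, 4), c(-4, 4), 0.1)
  nx <- length(grid$x); ny <- length(grid$y)
  i0 <- which.min(abs(grid$x)); j0 <- which.min(abs(grid$y))

  # unit impulse -> sampled kernel shape, maximum at the impulse
  F <- matrix(0, nx, ny); F[i0, j0] <- 1
  d <- convolve_dose(fluence_grid(F, grid), small_kernel)
  expect_equal(which.max(d$values), (j0 - 1L) * nx + i0)
  ratio <- d$values[i0 + 10, j0] / d$values[i0, j0]
  expect_equal(ratio,
               evaluate_kernel(small_kernel, 1, 0) /
                 evaluate_kernel(small_kernel, 0, 0), tolerance = 1e-3)

  # uniform fluence: plateau dose = fluence * sum(A) where the grid
  # covers the whole (renormalized) kernel support
  Fu <- matrix(2, nx, ny)
  du <- convolve_dose(fluence_grid(Fu, grid), small_kernel)
  expect_equal(du$values[i0, j0] /
                 (2 * sum(small_kernel$amplitudes)), 1, tolerance = 1e-4)

  # Gaussian in, Gaussian out with sigma = sqrt(sf^2 + s0^2)
  one <- kernel_params(c(1, 1e-8, 1e-8), c(0.3, 0.6, 1.0))
  sf <- 0.5
  Fg <- outer(dnorm(grid$x, 0, sf), dnorm(grid$y, 0, sf)) * 0.1^2
  dg <- convolve_dose(fluence_grid(Fg, grid), one)
  sexp <- sqrt(sf^2 + 0.3^2)
  expect_equal(dg$values[i0 + 10, j0] / dg$values[i0, j0],
               exp(-1^2 / (2 * sexp^2)), tolerance = 1e-4)
})

test_that("line-profile convolution matches the full 2D convolution", {
  m <- models$fff6
  seg <- two_row_segment()
  grid <- make_grid(c(-5, 5), c(-5, 5), 0.1)
  fl <- segment_fluence(m, seg, grid)
  full <- convolve_dose(fl, m$kernel)
  j0 <- which.min(abs(grid$y))
  line <- dose_profile_line(fl, m$kernel, axis = "x", fixed = 0)
  expect_equal(line$values, full$values[, j0], tolerance = 1e-9)
  i5 <- which.min(abs(grid$x - 0.5))
  liney <- dose_profile_line(fl, m$kernel, axis = "y", fixed = 0.5)
  expect_equal(liney$values, full$values[i5, ], tolerance = 1e-9)
})

test_that("convolution is translation-equivariant and mirror-consistent", {
  grid <- make_grid(c(-3, 3), c(-3, 3), 0.1)
  nx <- length(grid$x); ny <- length(grid$y)
  F <- matrix(0, nx, ny); F[25, 30] <- 1
  Fs <- matrix(0, nx, ny); Fs[35, 36] <- 1
  d1 <- convolve_dose(fluence_grid(F, grid), small_kernel)$values
  d2 <- convolve_dose(fluence_grid(Fs, grid), small_kernel)$values
  # interior translation: shifted impulse gives shifted response
  expect_equal(d2[20 + 1:20, 20 + 1:20], d1[10 + 1:20, 14 + 1:20],
               tolerance = 1e-12)
  set.seed(3)
  Fr <- matrix(runif(nx * ny), nx, ny)
  dm <- convolve_dose(fluence_grid(Fr[rev(1:nx), ], grid), small_kernel)$values
  dr <- convolve_dose(fluence_grid(Fr, grid), small_kernel)$values
  expect_equal(dm, dr[rev(1:nx), ], tolerance = 1e-12)
})

test_that("detector response: identity, erf step edge, mass conservation", {
  pos <- seq(-5, 5, 0.05)
  step <- beam_profile(pos, as.numeric(pos < 0), axis = "x")
  expect_identical(apply_detector_response(step, detector_response(0)), step)

  det <- detector_response(0.2)
  sm <- apply_detector_response(step, det)
  w <- penumbra_width(sm, "right")
  expect_lt(abs(w - 2 * 0.8416 * 0.2), 1e-3)

  # mass conservation for an interior-supported bump
  bump <- beam_profile(pos, dnorm(pos, 0, 0.8), axis = "x")
  sb <- apply_detector_response(bump, det)
  expect_equal(sum(sb$values), sum(bump$values), tolerance = 1e-6)

  expect_error(apply_detector_response(
    beam_profile(c(0, 1, 3), c(1, 1, 1), axis = "x"), det), "uniform")
})

test_that("profile extraction is symmetric and penumbra widens under VAE", {
  m <- models$fff6
  seg <- rect_field_segment(rect_field(6, 6), bank_y = c(-8, 8))
  grid <- make_grid(c(-6, 6), c(-6, 6), 0.1)
  dose <- convolve_dose(segment_fluence(m, seg, grid), m$kernel)
  pr <- extract_profile(dose, axis = "x", fixed = 0)
  expect_equal(approx(pr$positions, pr$values, 0)$y, 1.0, tolerance = 1e-12)
  expect_lt(abs(penumbra_width(pr, "left") - penumbra_width(pr, "right")),
            1e-6)
  conv <- apply_detector_response(pr, detector_response(0.2))
  expect_gt(penumbra_width(conv, "left"), penumbra_width(pr, "left"))

  # off-grid fixed coordinate interpolates between lines
  pr2 <- extract_profile(dose, axis = "x", fixed = 0.05, normalize = FALSE)
  j <- which.min(abs(grid$y - 0)); j2 <- which.min(abs(grid$y - 0.1))
  expect_equal(pr2$values, (dose$values[, j] + dose$values[, j2]) / 2,
               tolerance = 1e-12)
})

test_that("penumbra via dense-quadrature convolution oracle", {
  # step fluence convolved with the shipped kernel: compare the 20-80%
  # width against direct numerical convolution of the ideal edge
  m <- models$fff6
  pos <- seq(-4, 4, 0.1)
  grid <- make_grid(c(-4, 4), c(-4, 4), 0.1)
  F <- matrix(as.numeric(grid$x[row(matrix(0, length(grid$x), length(grid$y)))]
                         < 1), length(grid$x), length(grid$y))
  line <- dose_profile_line(fluence_grid(F, grid), m$kernel, axis = "x")
  v <- line$values / line$values[which.min(abs(pos + 2))]  # plateau-normalized
  prof <- beam_profile(pos, v, axis = "x")
  # oracle: edge response of the radially symmetric kernel is
  # sum_i A_i Phi((e - x)/sigma_i) (exact for an infinite straight edge)
  edge_resp <- function(x) {
    s <- 0
    for (i in 1:3) s <- s + m$kernel$amplitudes[i] *
        pnorm((1 - x) / m$kernel$sigmas[i])
    s
  }
  plateau <- edge_resp(-2)
  cross <- function(level) uniroot(function(x) edge_resp(x) - level * plateau,
                                   c(0, 3), tol = 1e-10)$root
  expect_lt(abs(penumbra_width(prof, "right") - (cross(0.2) - cross(0.8))),
            0.01)
})
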