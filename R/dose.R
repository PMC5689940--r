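#' 1D beam profile
#'
#' @param positions strictly increasing coordinates in cm.
#' @param values relative dose values.
#' @param axis `"x"` (cross-plane) or `"y"` (in-plane).
#' @param fixed the fixed coordinate of the scan line, cm.
#' @export
beam_profile <- function(positions, values, axis = c("x", "y"), fixed = 0) {
  axis <- match.arg(axis)
  stopifnot(length(positions) == length(values))
  if (any(diff(positions) <= 0))
    stop("profile positions must be strictly increasing")
  structure(list(positions = as.numeric(positions),
                 values = as.numeric(values),
                 axis = axis, fixed = fixed),
            class = "beam_profile")
}

#' Gaussian detector response
#'
#' Finite-size scanning chambers smooth measured profiles (the volume
#' averaging effect); this is emulated by convolving computed profiles
#' with a Gaussian response of width `sigma`.  The default 0.20 cm is an
#' assumption representative of a CC13-class chamber and is configurable.
#'
#' @param sigma response width in cm (>= 0; 0 disables the convolution).
#' @export
detector_response <- function(sigma = 0.20) {
  if (sigma < 0) stop("detector sigma must be >= 0")
  structure(list(sigma = sigma), class = "detector_response")
}

## sampled 1D kernels per component on a common +/-R offset lattice;
## the global scale c makes the discrete 2D kernel sum equal sum(A_i)
kernel_samples <- function(kernel, spacing, pad_sigmas = 4) {
  if (pad_sigmas < 3)
    stop(sprintf(
      "insufficient kernel padding: need pad_sigmas >= 3 (support 3*sigma_max = %.1f cm)",
      3 * max(kernel$sigmas)))
  R <- ceiling(pad_sigmas * max(kernel$sigmas) / spacing)
  offs <- (-R:R) * spacing
  G <- vapply(kernel$sigmas, function(s) dnorm(offs, 0, s) * spacing,
              numeric(length(offs)))
  si <- colSums(G)
  list(G = G, R = R,
       scale = sum(kernel$amplitudes) / sum(kernel$amplitudes * si^2))
}

## linear 2D convolution via zero-padded FFT on composite-friendly sizes
conv2_fft <- function(A, B) {
  m <- nrow(A) + nrow(B) - 1L
  n <- ncol(A) + ncol(B) - 1L
  M <- stats::nextn(m, c(2, 3, 5))
  N <- stats::nextn(n, c(2, 3, 5))
  PA <- matrix(0, M, N); PA[seq_len(nrow(A)), seq_len(ncol(A))] <- A
  PB <- matrix(0, M, N); PB[seq_len(nrow(B)), seq_len(ncol(B))] <- B
  C <- Re(stats::fft(stats::fft(PA) * stats::fft(PB), inverse = TRUE)) / (M * N)
  C[seq_len(m), seq_len(n)]
}

#' Convolve fluence with the dose deposition kernel
#'
#' Linear (zero-padded) 2D convolution of the fluence with the kernel
#' sampled at pixel centers on the fluence lattice and renormalized so
#' that its discrete sum equals the analytic `sum(A_i)` — this removes
#' discretization bias at 1 mm spacing.  The output is cropped to the
#' input extent; for fluence supported well inside the grid the plane sum
#' is conserved up to padding leakage.
#'
#' @param fluence [fluence_grid()].
#' @param kernel [kernel_params()].
#' @param pad_sigmas kernel sampling half-width in units of the broadest
#'   sigma; must be >= 3.
#' @return a [dose_grid()] on the same lattice.
#' @export
convolve_dose <- function(fluence, kernel, pad_sigmas = 4) {
  stopifnot(inherits(fluence, "fluence_grid"), inherits(kernel, "kernel_params"))
  if (fluence$spacing > 0.1 + 1e-12)
    stop("convolve_dose: grid spacing must be <= 1 mm")
  ks <- kernel_samples(kernel, fluence$spacing, pad_sigmas)
  K <- matrix(0, 2 * ks$R + 1, 2 * ks$R + 1)
  for (i in 1:3)
    K <- K + kernel$amplitudes[i] * tcrossprod(ks$G[, i])
  C <- conv2_fft(fluence$values, K) * ks$scale
  nx <- length(fluence$x); ny <- length(fluence$y)
  vals <- C[ks$R + seq_len(nx), ks$R + seq_len(ny)]
  vals[vals < 0] <- 0  # FFT roundoff
  dose_grid(vals, grid_of(fluence))
}

#' Dose profile along one grid line without the full 2D convolution
#'
#' Exploits the separability of each Gaussian kernel component to compute
#' the convolved dose exactly along a single line: a weighted collapse of
#' the fluence across the perpendicular axis followed by a 1D
#' convolution.  Identical (to FFT roundoff) to extracting the same line
#' from [convolve_dose()]; used heavily in commissioning fits.
#'
#' @param fluence [fluence_grid()].
#' @param kernel [kernel_params()].
#' @param axis scan axis, `"x"` or `"y"`.
#' @param fixed fixed coordinate of the line, cm.
#' @param pad_sigmas as in [convolve_dose()].
#' @return a [beam_profile()] of unnormalized dose on the grid positions.
#' @export
dose_profile_line <- function(fluence, kernel, axis = c("x", "y"),
                              fixed = 0, pad_sigmas = 4) {
  axis <- match.arg(axis)
  ks <- kernel_samples(kernel, fluence$spacing, pad_sigmas)
  F <- fluence$values
  if (axis == "x") { perp <- fluence$y; along <- fluence$x }
  else { perp <- fluence$x; along <- fluence$y; F <- t(F) }
  n <- length(along)
  out <- numeric(n)
  for (i in 1:3) {
    wperp <- dnorm(fixed - perp, 0, kernel$sigmas[i]) * fluence$spacing
    W <- as.vector(F %*% wperp)
    full <- convolve(W, rev(ks$G[, i]), type = "open")
    out <- out + kernel$amplitudes[i] * full[ks$R + seq_len(n)]
  }
  beam_profile(along, out * ks$scale, axis = axis, fixed = fixed)
}

#' Apply the detector volume-averaging response to a profile
#'
#' 1D convolution with a unit-mass Gaussian sampled on the (uniform)
#' profile lattice; the profile ends are replicate-padded so plateaus are
#' preserved.  `sigma = 0` is the identity.
#'
#' @param profile [beam_profile()] with uniform sampling.
#' @param det [detector_response()].
#' @export
apply_detector_response <- function(profile, det) {
  stopifnot(inherits(profile, "beam_profile"),
            inherits(det, "detector_response"))
  if (det$sigma == 0) return(profile)
  d <- diff(profile$positions)
  if (diff(range(d)) > 1e-9 * mean(d))
    stop("apply_detector_response requires uniform profile sampling")
  h <- mean(d)
  R <- ceiling(5 * det$sigma / h)
  g <- dnorm((-R:R) * h, 0, det$sigma)
  g <- g / sum(g)
  v <- profile$values
  vp <- c(rep(v[1], R), v, rep(v[length(v)], R))
  out <- convolve(vp, rev(g), type = "open")[2 * R + seq_along(v)]
  beam_profile(profile$positions, out, axis = profile$axis,
               fixed = profile$fixed)
}

#' Extract a profile from a dose plane
#'
#' Linear interpolation between the two grid lines adjacent to `fixed`;
#' values are normalized to the central axis when `normalize = TRUE`.
#'
#' @param dose a [dose_grid()] (or [fluence_grid()]).
#' @param axis scan axis, `"x"` or `"y"`.
#' @param fixed fixed coordinate of the line, cm (must lie on the grid
#'   extent).
#' @param normalize divide by the central-axis value.
#' @export
extract_profile <- function(dose, axis = c("x", "y"), fixed = 0,
                            normalize = TRUE) {
  axis <- match.arg(axis)
  V <- dose$values
  if (axis == "x") { perp <- dose$y; along <- dose$x } else {
    perp <- dose$x; along <- dose$y; V <- t(V)
  }
  if (fixed < perp[1] || fixed > perp[length(perp)])
    stop("fixed coordinate outside the grid")
  j <- min(max(findInterval(fixed, perp), 1L), length(perp) - 1L)
  w <- (fixed - perp[j]) / (perp[j + 1] - perp[j])
  vals <- V[, j] * (1 - w) + V[, j + 1] * w
  cax <- approx(along, vals, 0)$y
  if (normalize) {
    if (!is.finite(cax) || cax <= 0)
      stop("cannot normalize: central-axis value missing or non-positive")
    vals <- vals / cax
  }
  p <- beam_profile(along, vals, axis = axis, fixed = fixed)
  attr(p, "cax") <- cax
  p
}

## position where a monotone edge crosses `level`, by linear interpolation
edge_cross <- function(pos, val, level, from_left = TRUE) {
  idx <- if (from_left) seq_along(val) else rev(seq_along(val))
  below <- val[idx] < level
  k <- which(!below)[1]
  if (is.na(k) || k == 1) return(NA_real_)
  i1 <- idx[k - 1]; i2 <- idx[k]
  pos[i1] + (level - val[i1]) * (pos[i2] - pos[i1]) / (val[i2] - val[i1])
}

#' Penumbra width of a profile edge
#'
#' Distance between the 20% and 80% intensity points on one field edge,
#' with levels relative to the central-axis value and crossings found by
#' linear interpolation between samples.
#'
#' @param profile [beam_profile()] normalized to the central axis.
#' @param edge `"left"` or `"right"`.
#' @param levels the two fractional intensity levels (default 0.2, 0.8).
#' @return penumbra width in cm.
#' @export
penumbra_width <- function(profile, edge = c("left", "right"),
                           levels = c(0.2, 0.8)) {
  edge <- match.arg(edge)
  pos <- profile$positions; val <- profile$values
  from_left <- edge == "left"
  p20 <- edge_cross(pos, val, levels[1], from_left)
  p80 <- edge_cross(pos, val, levels[2], from_left)
  if (is.na(p20) || is.na(p80))
    stop(sprintf("no %g-%g%% crossing found on the %s edge",
                 100 * levels[1], 100 * levels[2], edge))
  abs(p80 - p20)
}
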