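# Shared fixtures: shipped models are loaded once per test session.
models <- list(
  ff6 = beam_model_library("6FF"),
  fff6 = beam_model_library("6FFF"),
  ff10 = beam_model_library("10FF"),
  fff10 = beam_model_library("10FFF"))

# a small aperture used in several places: two open rows of different width
two_row_segment <- function(mu = 1) {
  mlc_segment(data.frame(y_low = c(-1, 0), y_high = c(0, 1),
                         x_left = c(-2, -1), x_right = c(2, 3)),
              jaw_y = c(-1, 1), mu = mu)
}

# iterated QUADPACK quadrature over a rectangle: an adaptive-quadrature
# oracle independent of the closed-form error-function path
quad2 <- function(f, x1, x2, y1, y2, tol = 1e-12) {
  inner <- function(y) vapply(y, function(yy)
    integrate(function(x) f(x, yy), x1, x2,
              rel.tol = tol, abs.tol = 0)$value, numeric(1))
  integrate(inner, y1, y2, rel.tol = tol, abs.tol = 0)$value
}

# direct-summation 2D linear convolution (shift-and-accumulate definition),
# independent of the FFT implementation
direct_conv2 <- function(F, K) {
  nx <- nrow(F); ny <- ncol(F)
  out <- matrix(0, nx + nrow(K) - 1, ny + ncol(K) - 1)
  for (a in seq_len(nrow(K)))
    for (b in seq_len(ncol(K))) {
      if (K[a, b] == 0) next
      out[a + 0:(nx - 1), b + 0:(ny - 1)] <-
        out[a + 0:(nx - 1), b + 0:(ny - 1)] + K[a, b] * F
    }
  out
}

# brute-force 2D gamma oracle: exhaustive search with its own bilinear
# interpolation (pracma), independent of the package implementation
gamma_oracle <- function(reference, evaluated, crit) {
  pts <- expand.grid(ix = seq_along(reference$x), iy = seq_along(reference$y))
  pts$x <- reference$x[pts$ix]; pts$y <- reference$y[pts$iy]
  pts$ref <- reference$values[cbind(pts$ix, pts$iy)]
  pts <- pts[is.finite(pts$ref), ]
  dmax <- max(pts$ref)
  pts <- pts[pts$ref >= crit$threshold_pct / 100 * dmax, ]
  rad <- crit$search_radius_factor * crit$dta
  s <- seq(-rad, rad, by = crit$interp_step)
  vapply(seq_len(nrow(pts)), function(k) {
    best <- Inf
    delta <- crit$dose_pct / 100 *
      (if (crit$mode == "local") pts$ref[k] else dmax)
    for (dx in s) for (dy in s) {
      r2 <- dx^2 + dy^2
      if (r2 > rad^2 + 1e-12) next
      xq <- pts$x[k] + dx; yq <- pts$y[k] + dy
      if (xq < min(evaluated$x) || xq > max(evaluated$x) ||
          yq < min(evaluated$y) || yq > max(evaluated$y)) next
      de <- pracma::interp2(evaluated$y, evaluated$x, evaluated$values,
                            yq, xq)
      g2 <- ((de - pts$ref[k]) / delta)^2 + r2 / crit$dta^2
      if (g2 < best) best <- g2
    }
    sqrt(best)
  }, numeric(1))
}
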