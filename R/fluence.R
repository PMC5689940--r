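## extra-focal scatter fluence on the iso-plane lattice.
## Back-projection is affine in the point coordinate, so the erf integral
## separates into an x factor (per grid x) and a y factor (per grid y)
## for every open leaf row and source component; the map is assembled
## from outer products.
scatter_map <- function(source, segment, geometry, grid) {
  sad <- geometry$sad
  cm <- (sad - source$plane_z) / (sad - geometry$z_mlc)
  cj <- (sad - source$plane_z) / (sad - geometry$z_jaw)
  proj_m <- function(e, pv) pv * (1 - cm) + e * (geometry$z_mlc / sad) * cm
  proj_j <- function(e, pv) pv * (1 - cj) + e * (geometry$z_jaw / sad) * cj
  x <- grid$x; y <- grid$y
  S <- matrix(0, length(x), length(y))
  lp <- segment$leaf_pairs
  open <- which(lp$x_right - lp$x_left > 1e-12)
  if (!length(open)) return(S)
  jy1 <- proj_j(segment$jaw_y[1], y)
  jy2 <- proj_j(segment$jaw_y[2], y)
  for (r in open) {
    xs1 <- proj_m(lp$x_left[r], x)
    xs2 <- proj_m(lp$x_right[r], x)
    lo <- pmax(proj_m(lp$y_low[r], y), jy1)
    hi <- pmin(proj_m(lp$y_high[r], y), jy2)
    for (i in seq_len(source$n_components)) {
      sx <- source$sigma_x[i] * sqrt(2)
      sy <- source$sigma_y[i] * sqrt(2)
      gx <- erf(xs2 / sx) - erf(xs1 / sx)
      gy <- pmax(0, erf(hi / sy) - erf(lo / sy))
      S <- S + source$amplitudes[i] / 4 * outer(gx, gy)
    }
  }
  S
}

#' Energy fluence of one segment
#'
#' Per lattice point p: `[T(p) + scatter(p)] * R_norm(|p|)`, where T is
#' the primary transmission from [transmission_map()], the scatter term
#' integrates the extra-focal source over the rectangles visible from p
#' (closed-form error functions), and R_norm is the normalized off-axis
#' ratio (identically 1 for FF modes).
#'
#' @param model [beam_model()].
#' @param segment [mlc_segment()].
#' @param grid lattice from [make_grid()]; spacing must be <= 0.1 cm.
#' @param include_oar set `FALSE` to skip the off-axis-ratio modulation
#'   (used internally during commissioning).
#' @return a [fluence_grid()].
#' @export
segment_fluence <- function(model, segment, grid, include_oar = TRUE) {
  stopifnot(inherits(model, "beam_model"), inherits(segment, "mlc_segment"))
  if (!length(grid$x) || !length(grid$y)) stop("empty fluence grid")
  if (grid$spacing > 0.1 + 1e-12)
    stop("fluence grid spacing must be <= 0.1 cm")
  tm <- transmission_map(segment, model, grid)
  sm <- scatter_map(model$source, segment, model$geometry, grid)
  vals <- tm + sm
  if (include_oar && !is.null(model$oar)) {
    rr <- sqrt(outer(grid$x^2, grid$y^2, `+`))
    vals <- vals * evaluate_oar(model$oar, rr, normalize = TRUE)
  }
  fluence_grid(vals, grid)
}

#' Energy fluence of a full IMRT beam
#'
#' MU-weighted sum of the segment fluences.  With `normalize =
#' "relative"` the weights are `mu_s / total_mu` so the result is
#' invariant under uniform MU rescaling; with `"absolute"` the raw MU
#' weights are used.
#'
#' @param model [beam_model()].
#' @param beam [beam_delivery()].
#' @param grid lattice from [make_grid()].
#' @param normalize `"relative"` or `"absolute"`.
#' @return a [fluence_grid()].
#' @export
beam_fluence <- function(model, beam, grid,
                         normalize = c("relative", "absolute")) {
  stopifnot(inherits(beam, "beam_delivery"))
  normalize <- match.arg(normalize)
  if (beam$total_mu <= 0) stop("beam has zero total MU")
  vals <- matrix(0, length(grid$x), length(grid$y))
  for (s in beam$segments) {
    w <- if (normalize == "relative") s$mu / beam$total_mu else s$mu
    if (w == 0) next
    vals <- vals + w * segment_fluence(model, s, grid)$values
  }
  fluence_grid(vals, grid)
}
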