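#' Symmetric rectangular field
#'
#' A field named "A x B" has `x_open = A` (MLC-defined opening along the
#' cross-plane axis) and `y_open = B` (jaw-defined opening along the
#' in-plane axis), both in cm at the isocenter.
#'
#' @param x_open,y_open field openings in cm (> 0).
#' @export
rect_field <- function(x_open, y_open = x_open) {
  if (x_open <= 0 || y_open <= 0) stop("field openings must be > 0")
  structure(list(x_open = x_open, y_open = y_open), class = "rect_field")
}

#' Integrate the source over a rectangle via error functions
#'
#' Closed-form integral of the bivariate Gaussian source over an axis
#' aligned rectangle on the source plane:
#' sum_i (A_i/4) [erf(x2/sqrt(2)sx_i) - erf(x1/...)] [erf(y2/...) - erf(y1/...)].
#' Infinite bounds are allowed.
#'
#' @param source [source_params()].
#' @param x1,x2,y1,y2 rectangle bounds in cm on the source plane
#'   (vectorized, recycled); requires `x1 <= x2`, `y1 <= y2`
#'   (degenerate zero-width rectangles are allowed).
#' @return integral values in `[0, sum(A_i)]`.
#' @export
gaussian_rect_integral <- function(source, x1, x2, y1, y2) {
  stopifnot(inherits(source, "source_params"))
  n <- max(length(x1), length(x2), length(y1), length(y2))
  x1 <- rep_len(x1, n); x2 <- rep_len(x2, n)
  y1 <- rep_len(y1, n); y2 <- rep_len(y2, n)
  if (any(x1 > x2) || any(y1 > y2))
    stop("gaussian_rect_integral: inverted rectangle bounds")
  out <- numeric(n)
  for (i in seq_len(source$n_components)) {
    sx <- source$sigma_x[i] * sqrt(2)
    sy <- source$sigma_y[i] * sqrt(2)
    out <- out + source$amplitudes[i] / 4 *
      (erf(x2 / sx) - erf(x1 / sx)) * (erf(y2 / sy) - erf(y1 / sy))
  }
  out
}

#' Back-project a collimator edge onto the source plane
#'
#' A collimator edge specified at the isocenter (`e_iso`) sits physically
#' at lateral position `e_iso * z_level / sad` at its collimator level.
#' The ray from the calculation point through that physical edge is
#' intersected with the source plane.
#'
#' @param e_iso edge position in cm at the isocenter projection.
#' @param z_level collimator plane level, cm from target.
#' @param p lateral coordinate (cm) of the calculation point in the same
#'   direction as the edge.
#' @param z_p axial position of the calculation point, cm from target.
#' @param z_source source plane position, cm from target; requires
#'   `z_source < z_level < z_p`.
#' @param sad source-axis distance in cm.
#' @return lateral coordinate on the source plane, cm.
#' @export
backproject_edge <- function(e_iso, z_level, p, z_p, z_source, sad = 100) {
  if (!(z_source < z_level && z_level < z_p))
    stop("backproject_edge: requires z_source < z_level < z_p")
  p + (e_iso * z_level / sad - p) * (z_p - z_source) / (z_p - z_level)
}

## the rectangle on the source plane visible from point (px, py, z_p)
## through a rectangular field (x edges at the MLC level, y at the jaws)
visible_field_rect <- function(field, geometry, z_source,
                               px = 0, py = 0, z_p = geometry$sad) {
  hx <- field$x_open / 2; hy <- field$y_open / 2
  x1 <- backproject_edge(-hx, geometry$z_mlc, px, z_p, z_source, geometry$sad)
  x2 <- backproject_edge(hx, geometry$z_mlc, px, z_p, z_source, geometry$sad)
  y1 <- backproject_edge(-hy, geometry$z_jaw, py, z_p, z_source, geometry$sad)
  y2 <- backproject_edge(hy, geometry$z_jaw, py, z_p, z_source, geometry$sad)
  c(x1 = x1, x2 = x2, y1 = y1, y2 = y2)
}

## Sc from raw components: shared by compute_sc and the commissioning fit
sc_from_source <- function(source, geometry, field, reference = rect_field(10, 10),
                           px = 0, py = 0, z_p = geometry$sad) {
  num_rect <- visible_field_rect(field, geometry, source$plane_z, px, py, z_p)
  ref_rect <- visible_field_rect(reference, geometry, source$plane_z, px, py, z_p)
  empty <- num_rect["x1"] > num_rect["x2"] || num_rect["y1"] > num_rect["y2"]
  head <- if (empty) {
    warning("empty visible region: head-scatter term set to 0 (primary only)")
    0
  } else {
    gaussian_rect_integral(source, num_rect["x1"], num_rect["x2"],
                           num_rect["y1"], num_rect["y2"])
  }
  ref <- gaussian_rect_integral(source, ref_rect["x1"], ref_rect["x2"],
                                ref_rect["y1"], ref_rect["y2"])
  unname((1 + head) / (1 + ref))
}

#' In-air output factor of a rectangular field
#'
#' Sc is the ratio of primary-plus-head-scatter fluence of the field to
#' that of the 10 x 10 cm^2 reference, both computed by integrating the
#' extra-focal source over the rectangle visible from the calculation
#' point: x edges back-projected from the MLC level, y edges from the jaw
#' level.  Sc(10 x 10) = 1 exactly.
#'
#' @param model [beam_model()].
#' @param field [rect_field()].
#' @param point calculation point `c(px, py, z_p)` in cm; default the
#'   isocenter on the central axis.
#' @export
compute_sc <- function(model, field, point = c(0, 0, model$geometry$sad)) {
  stopifnot(inherits(model, "beam_model"), inherits(field, "rect_field"))
  if (point[3] <= model$geometry$z_jaw)
    stop("compute_sc: calculation point must lie below the jaws")
  sc_from_source(model$source, model$geometry, field,
                 px = point[1], py = point[2], z_p = point[3])
}

#' Collimator exchange metric
#'
#' Relative Sc difference between transposed rectangular fields,
#' `100 * |Sc(a x b) - Sc(b x a)| / Sc(b x a)`.  Nonzero values arise from
#' the different collimator heights and the x/y asymmetry of the source.
#'
#' @param model [beam_model()].
#' @param a,b field openings in cm (`a != b`).
#' @export
collimator_exchange <- function(model, a, b) {
  if (a == b) stop("collimator_exchange: requires a != b")
  s_ab <- compute_sc(model, rect_field(a, b))
  s_ba <- compute_sc(model, rect_field(b, a))
  100 * abs(s_ab - s_ba) / s_ba
}

#' In-air output factor dataset
#'
#' @param fields list of [rect_field()] (or a data frame with columns
#'   `field_x_cm`, `field_y_cm`).
#' @param sc measured/synthesized Sc values.
#' @param role `"fit"` or `"validate"` per record.
#' @return a data frame of class `sc_dataset` with columns `field_x_cm`,
#'   `field_y_cm`, `sc`, `role`.  Must contain the 10 x 10 reference with
#'   sc = 1 (normalization).
#' @export
sc_dataset <- function(fields, sc, role = "fit") {
  if (is.data.frame(fields)) {
    fx <- fields$field_x_cm; fy <- fields$field_y_cm
  } else {
    fx <- vapply(fields, `[[`, numeric(1), "x_open")
    fy <- vapply(fields, `[[`, numeric(1), "y_open")
  }
  stopifnot(length(fx) == length(sc))
  role <- rep_len(role, length(sc))
  if (!any(role %in% c("fit", "validate")))
    stop("role must be 'fit' or 'validate'")
  ref <- which(abs(fx - 10) < 1e-9 & abs(fy - 10) < 1e-9)
  if (!length(ref) || any(abs(sc[ref] - 1) > 1e-9))
    stop("sc_dataset must contain the 10x10 reference field with sc = 1")
  structure(data.frame(field_x_cm = fx, field_y_cm = fy,
                       sc = sc, role = role),
            class = c("sc_dataset", "data.frame"))
}
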