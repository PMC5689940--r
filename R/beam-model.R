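## error function via the normal CDF (exact, handles +/-Inf)
erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

#' Extra-focal source parameters
#'
#' The extra-focal (head-scatter) source is a sum of N bivariate Gaussian
#' intensity distributions on a plane perpendicular to the beam axis,
#' located below the target (at the bottom of the flattening filter for FF
#' beams, of the primary collimator for FFF beams).  Amplitudes are
#' relative to the primary point source, whose weight is fixed at 1.
#'
#' @param amplitudes numeric vector of relative intensities A_i (> 0).
#' @param sigma_x,sigma_y per-component standard deviations in cm along the
#'   cross-plane (x, leaf travel) and in-plane (y, jaw) directions.
#' @param plane_z distance in cm from the target to the source plane along
#'   the beam axis; must lie strictly between the target and the uppermost
#'   collimating device.
#' @return object of class `source_params`.
#' @export
source_params <- function(amplitudes, sigma_x, sigma_y, plane_z = 6) {
  n <- length(amplitudes)
  if (n < 1 || length(sigma_x) != n || length(sigma_y) != n)
    stop("amplitudes, sigma_x and sigma_y must have equal positive length")
  if (any(!is.finite(c(amplitudes, sigma_x, sigma_y, plane_z))))
    stop("source parameters must be finite")
  if (any(amplitudes <= 0)) stop("all amplitudes must be > 0")
  if (any(sigma_x <= 0) || any(sigma_y <= 0)) stop("all sigmas must be > 0")
  if (plane_z <= 0) stop("plane_z must be > 0 (cm from target)")
  structure(list(amplitudes = as.numeric(amplitudes),
                 sigma_x = as.numeric(sigma_x),
                 sigma_y = as.numeric(sigma_y),
                 n_components = n,
                 plane_z = plane_z),
            class = "source_params")
}

#' Off-axis-ratio polynomial (FFF beams)
#'
#' A fourth-degree polynomial R(r) in the radial distance r (cm, at the
#' isocenter-depth plane) models the cone-shaped lateral profile of
#' unflattened beams.  Its absolute scale is irrelevant because planes are
#' relatively normalized; use [evaluate_oar()] with `normalize = TRUE` for
#' the R(r)/R(0) form.
#'
#' @param coeffs exactly 5 coefficients a_0..a_4 (argument in cm).
#' @param valid_radius radius in cm beyond which the polynomial is held
#'   constant (default 22): outside the radial range covered by the
#'   commissioning profiles a fourth-degree polynomial extrapolates
#'   unphysically (it eventually turns negative).
#' @export
oar_poly <- function(coeffs, valid_radius = 22) {
  if (length(coeffs) != 5 || any(!is.finite(coeffs)))
    stop("oar_poly requires exactly 5 finite coefficients a_0..a_4")
  if (valid_radius <= 0) stop("valid_radius must be > 0")
  structure(list(coeffs = as.numeric(coeffs), valid_radius = valid_radius),
            class = "oar_poly")
}

#' Dose deposition kernel parameters
#'
#' The poly-energetic dose deposition kernel is the sum of three circularly
#' symmetric 2D Gaussians with weights A_i and widths sigma_i.
#'
#' @param amplitudes 3 weights (unitless, > 0).
#' @param sigmas 3 standard deviations in cm (> 0), conventionally ordered
#'   narrow to broad.
#' @export
kernel_params <- function(amplitudes, sigmas) {
  if (length(amplitudes) != 3 || length(sigmas) != 3)
    stop("kernel_params requires exactly 3 components")
  if (any(!is.finite(c(amplitudes, sigmas))) ||
      any(amplitudes <= 0) || any(sigmas <= 0))
    stop("kernel weights and sigmas must be finite and > 0")
  structure(list(amplitudes = as.numeric(amplitudes),
                 sigmas = as.numeric(sigmas)),
            class = "kernel_params")
}

#' Rounded-leaf-end transmission parameters
#'
#' Transmission through the first `soft_range` cm inside an MLC leaf tip
#' declines as L(d) = exp(-d^alpha / beta) with distance d into the leaf
#' measured from the tip (cm, at isocenter projection).
#'
#' @param alpha,beta shape parameters (> 0).  Fitted Versa HD values are
#'   0.70 and 0.24 for both 6 and 10 MV.
#' @param soft_range distance in cm over which the tip law applies
#'   (default 1.0); beyond it the bulk leaf transmission takes over.
#' @export
leaf_end_params <- function(alpha = 0.70, beta = 0.24, soft_range = 1.0) {
  if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0)
    stop("alpha and beta must be finite and > 0")
  if (soft_range <= 0) stop("soft_range must be > 0")
  structure(list(alpha = alpha, beta = beta, soft_range = soft_range),
            class = "leaf_end_params")
}

#' MLC transmission factors
#'
#' @param bulk transmission through the leaf body (fraction in (0, 1)).
#' @param interleaf additional transmission on the boundary strip between
#'   two closed neighbouring leaves (replaces `bulk` there).
#' @param tongue_and_groove multiplicative factor applied to the open-side
#'   fluence on the strip where an exposed leaf abuts a shielded one.
#' @param tg_width_iso projected tongue-and-groove strip width at the
#'   isocenter in cm (Versa HD: 0.026 cm).
#' @param interleaf_width_iso projected interleaf strip width in cm.
#' @param leaf_width_iso projected leaf width at isocenter in cm.
#' @export
mlc_transmission <- function(bulk = 0.01, interleaf = 0.01,
                             tongue_and_groove = 0.01,
                             tg_width_iso = 0.026,
                             interleaf_width_iso = 0.03,
                             leaf_width_iso = 0.5) {
  fr <- c(bulk, interleaf, tongue_and_groove)
  if (any(fr <= 0) || any(fr >= 1))
    stop("transmission fractions must lie in (0, 1)")
  if (tg_width_iso <= 0 || interleaf_width_iso <= 0 || leaf_width_iso <= 0)
    stop("strip and leaf widths must be > 0")
  structure(list(bulk = bulk, interleaf = interleaf,
                 tongue_and_groove = tongue_and_groove,
                 tg_width_iso = tg_width_iso,
                 interleaf_width_iso = interleaf_width_iso,
                 leaf_width_iso = leaf_width_iso),
            class = "mlc_transmission")
}

#' Treatment head geometry
#'
#' Axial positions are cm from the target along the beam axis.  On a Versa
#' HD the MLC sits above the single jaw pair: the MLC defines the x (cross
#' plane) field edges and the jaws the y (in plane) edges.  The defaults
#' are plausible Elekta-like values; every one is overridable and is
#' recorded in all file outputs.
#'
#' @param sad source-axis distance in cm (default 100).
#' @param z_mlc,z_jaw collimator plane levels in cm from the target.
#' @param source_plane_z_ff,source_plane_z_fff default extra-focal source
#'   plane positions for the two beam modes.
#' @export
machine_geometry <- function(sad = 100, z_mlc = 33.0, z_jaw = 43.0,
                             source_plane_z_ff = 12.5,
                             source_plane_z_fff = 6.0) {
  if (!(z_mlc < z_jaw && z_jaw < sad && z_mlc > 0))
    stop("geometry requires 0 < z_mlc < z_jaw < sad")
  if (source_plane_z_ff >= z_mlc || source_plane_z_fff >= z_mlc ||
      source_plane_z_ff <= 0 || source_plane_z_fff <= 0)
    stop("source planes must lie strictly between target and the MLC")
  structure(list(sad = sad, z_mlc = z_mlc, z_jaw = z_jaw,
                 source_plane_z_ff = source_plane_z_ff,
                 source_plane_z_fff = source_plane_z_fff),
            class = "machine_geometry")
}

#' Full beam model for one energy/mode
#'
#' Bundles every fitted model quantity for one of the four supported
#' energy/filtration modes.  FFF modes must carry an off-axis-ratio
#' polynomial; FF modes must not (their profiles are treated as flat).
#'
#' @param energy_mode one of `"6FF"`, `"6FFF"`, `"10FF"`, `"10FFF"`.
#' @param source [source_params()].
#' @param kernel [kernel_params()].
#' @param oar [oar_poly()] or `NULL` for FF modes.
#' @param leaf_end [leaf_end_params()].
#' @param mlc [mlc_transmission()].
#' @param geometry [machine_geometry()].
#' @param provenance free-text note on parameter origin, carried through
#'   file round trips.
#' @export
beam_model <- function(energy_mode, source, kernel, oar = NULL,
                       leaf_end = leaf_end_params(),
                       mlc = mlc_transmission(),
                       geometry = machine_geometry(),
                       provenance = "") {
  energy_mode <- match.arg(energy_mode, c("6FF", "6FFF", "10FF", "10FFF"))
  fff <- grepl("FFF$", energy_mode)
  if (fff && is.null(oar))
    stop("FFF beam models require an off-axis-ratio polynomial")
  if (!fff && !is.null(oar))
    stop("FF beam models must not carry an off-axis-ratio polynomial")
  stopifnot(inherits(source, "source_params"),
            inherits(kernel, "kernel_params"),
            inherits(leaf_end, "leaf_end_params"),
            inherits(mlc, "mlc_transmission"),
            inherits(geometry, "machine_geometry"))
  if (source$plane_z >= geometry$z_mlc)
    stop("source plane must lie above the MLC level")
  structure(list(energy_mode = energy_mode, source = source, oar = oar,
                 kernel = kernel, leaf_end = leaf_end, mlc = mlc,
                 geometry = geometry, provenance = provenance),
            class = "beam_model")
}

#' @export
print.beam_model <- function(x, ...) {
  cat(sprintf("<beam_model %s>\n", x$energy_mode))
  s <- x$source
  cat(sprintf("  source: %d bivariate Gaussian(s) at z = %.1f cm, sum(A) = %.4f\n",
              s$n_components, s$plane_z, sum(s$amplitudes)))
  for (i in seq_len(s$n_components))
    cat(sprintf("    A=%.4f sigma_x=%.4f sigma_y=%.4f cm\n",
                s$amplitudes[i], s$sigma_x[i], s$sigma_y[i]))
  cat(sprintf("  kernel: sum(A) = %.4f, sigmas = %s cm\n",
              sum(x$kernel$amplitudes),
              paste(format(x$kernel$sigmas, digits = 4), collapse = ", ")))
  if (!is.null(x$oar))
    cat(sprintf("  OAR poly: a0 = %.4g\n", x$oar$coeffs[1]))
  cat(sprintf("  leaf end: alpha=%.2f beta=%.2f; MLC bulk=%.3g\n",
              x$leaf_end$alpha, x$leaf_end$beta, x$mlc$bulk))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Evaluate the extra-focal source distribution
#'
#' Computes the intensity density (per cm^2) of the summed bivariate
#' Gaussian source at coordinates (x, y) on the source plane.
#'
#' @param source [source_params()].
#' @param x,y coordinates in cm (vectorized, recycled).
#' @return strictly positive intensity density values.
#' @export
evaluate_source <- function(source, x, y) {
  stopifnot(inherits(source, "source_params"))
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("evaluate_source: coordinates must be finite")
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  out <- numeric(n)
  for (i in seq_len(source$n_components)) {
    sx <- source$sigma_x[i]; sy <- source$sigma_y[i]
    out <- out + source$amplitudes[i] / (2 * pi * sx * sy) *
      exp(-x^2 / (2 * sx^2) - y^2 / (2 * sy^2))
  }
  out
}

#' Central intensity of the extra-focal source
#'
#' @param source [source_params()].
#' @return the source intensity density at the origin.
#' @export
central_intensity <- function(source) evaluate_source(source, 0, 0)

#' Axis-averaged half-maximum radius of the source
#'
#' Finds, by bracketed root finding, the distance along x and along y at
#' which the combined source distribution falls to half its central value,
#' and returns the mean of the two radii.  Note that for a sum of
#' Gaussians this half-maximum radius of the combined distribution is the
#' natural single-number width; it is not the FWHM of any individual
#' component.
#'
#' @param source [source_params()].
#' @return mean of the x and y half-maximum radii in cm, with the two
#'   per-axis radii attached as attribute `"radii"`.
#' @export
half_max_radius <- function(source) {
  target <- central_intensity(source) / 2
  find <- function(f) {
    if (f(50) - target >= 0)
      stop("no half-maximum root in (0, 50 cm): degenerate source parameters")
    uniroot(function(r) f(r) - target, c(0, 50), tol = 1e-8)$root
  }
  rx <- find(function(r) evaluate_source(source, r, 0))
  ry <- find(function(r) evaluate_source(source, 0, r))
  structure((rx + ry) / 2, radii = c(x = rx, y = ry))
}

#' Total extra-focal intensity relative to the primary source
#'
#' @param source [source_params()].
#' @return sum of the Gaussian amplitudes (unitless).
#' @export
total_extrafocal_intensity <- function(source) sum(source$amplitudes)

#' Relative head-scatter reduction between two source models
#'
#' @param ff,fff [source_params()] for the flattened and unflattened beams.
#' @return percent reduction `100 * (total_ff - total_fff) / total_ff`.
#' @export
head_scatter_reduction <- function(ff, fff) {
  tot_ff <- total_extrafocal_intensity(ff)
  tot_fff <- total_extrafocal_intensity(fff)
  if (tot_ff == 0) stop("FF total extra-focal intensity is zero")
  100 * (tot_ff - tot_fff) / tot_ff
}

#' Evaluate the off-axis-ratio polynomial
#'
#' @param oar [oar_poly()].
#' @param r radial distance in cm at the isocenter-depth plane
#'   (vectorized, must be >= 0: the model is rotationally symmetric).
#'   Radii beyond `valid_radius` evaluate at `valid_radius`.
#' @param normalize if `TRUE`, return R(r)/R(0).
#' @export
evaluate_oar <- function(oar, r, normalize = FALSE) {
  stopifnot(inherits(oar, "oar_poly"))
  if (any(r < 0)) stop("evaluate_oar: pass a radius (r >= 0)")
  r <- pmin(r, oar$valid_radius)
  a <- oar$coeffs
  val <- a[1] + r * (a[2] + r * (a[3] + r * (a[4] + r * a[5])))
  if (normalize) val / a[1] else val
}

#' Evaluate the dose deposition kernel
#'
#' Rotationally symmetric: the value depends only on x^2 + y^2, and the
#' integral over the plane equals the sum of the component weights.
#'
#' @param kernel [kernel_params()].
#' @param x,y coordinates in cm (vectorized, recycled).
#' @return dose density values (per cm^2).
#' @export
evaluate_kernel <- function(kernel, x, y) {
  stopifnot(inherits(kernel, "kernel_params"))
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("evaluate_kernel: coordinates must be finite")
  r2 <- x^2 + y^2
  out <- 0
  for (i in 1:3) {
    s <- kernel$sigmas[i]
    out <- out + kernel$amplitudes[i] / (2 * pi * s^2) * exp(-r2 / (2 * s^2))
  }
  out
}

#' Rounded-leaf-end transmission
#'
#' L(d) = exp(-d^alpha / beta) for distance d (cm) into the leaf measured
#' from the tip, within `soft_range`.  At and beyond `soft_range` the
#' standalone function returns `max(L(soft_range), bulk)` so that
#' transmission never increases with depth; inside a transmission map the
#' leaf body is handled by the bulk MLC factor instead (see
#' [transmission_map()]).
#'
#' @param p [leaf_end_params()].
#' @param d distance into the leaf from the tip, cm (vectorized, >= 0).
#' @param bulk bulk leaf transmission used in the deep-leaf clamp.
#' @return transmission fraction in (0, 1]; L(0) = 1.
#' @export
leaf_end_transmission <- function(p, d, bulk = 0.01) {
  stopifnot(inherits(p, "leaf_end_params"))
  if (any(d < 0)) stop("leaf_end_transmission: d must be >= 0")
  dd <- pmin(d, p$soft_range)
  val <- exp(-dd^p$alpha / p$beta)
  ifelse(d >= p$soft_range, pmax(val, bulk), val)
}

#' Load one of the shipped beam models
#'
#' Reads the packaged parameter set for the requested energy/mode from the
#' plain-text model files installed with the package.
#'
#' @param energy_mode `"6FF"`, `"6FFF"`, `"10FF"` or `"10FFF"`.
#' @return a [beam_model()].
#' @export
beam_model_library <- function(energy_mode = c("6FF", "6FFF", "10FF", "10FFF")) {
  energy_mode <- match.arg(energy_mode)
  path <- system.file("extdata",
                      paste0("beam_model_", tolower(energy_mode), ".json"),
                      package = "fffqa", mustWork = TRUE)
  read_beam_model(path)
}
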