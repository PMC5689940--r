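#' Synthetic fixture specification
#'
#' Bundles the knobs of the synthetic data generators.  Defaults mirror
#' realistic QA conditions: 0.1% relative repeatability on in-air output
#' factors, 0.5% on scanned profiles, a MapCHECK-like staggered diode
#' lattice with 1 cm pitch, and step-and-shoot plans obeying the
#' treatment-planning constraints (at most 70 segments, at least 4 cm^2
#' segment area).
#'
#' @param energy_mode beam mode for the generators.
#' @param noise_sc relative (1-sigma) multiplicative noise on Sc.
#' @param noise_profile relative noise on profile and plane values.
#' @param detector_spacing diode pitch in cm.
#' @param detector_pattern `"staggered"` (MapCHECK-like) or `"regular"`.
#' @param n_segments segments per beam (<= 70).
#' @param min_segment_area minimum open area per segment, cm^2.
#' @param seed integer seed.
#' @export
fixture_spec <- function(energy_mode = "6FFF", noise_sc = 0.001,
                         noise_profile = 0.005, detector_spacing = 1.0,
                         detector_pattern = c("staggered", "regular"),
                         n_segments = 10, min_segment_area = 4, seed = 1) {
  detector_pattern <- match.arg(detector_pattern)
  if (noise_sc < 0 || noise_profile < 0) stop("noise must be >= 0")
  if (n_segments < 1 || n_segments > 70)
    stop("n_segments must be between 1 and 70")
  if (min_segment_area <= 0) stop("min_segment_area must be > 0")
  structure(list(energy_mode = energy_mode, noise_sc = noise_sc,
                 noise_profile = noise_profile,
                 detector_spacing = detector_spacing,
                 detector_pattern = detector_pattern,
                 n_segments = n_segments,
                 min_segment_area = min_segment_area, seed = seed),
            class = "fixture_spec")
}

#' Standard commissioning field menu for Sc
#'
#' Square fields from 3 x 3 to 35 x 35 cm^2 plus rectangular families
#' with one side fixed at 10 cm (fit) and at 4 cm (validation).
#'
#' @return data frame with columns `field_x_cm`, `field_y_cm`, `role`.
#' @export
default_sc_fields <- function() {
  sq <- c(3, 5, 6, 8, 10, 12, 15, 20, 25, 30, 35)
  varied <- c(4, 6, 8, 12, 15, 20, 25, 30)
  rbind(
    data.frame(field_x_cm = sq, field_y_cm = sq, role = "fit"),
    data.frame(field_x_cm = 10, field_y_cm = varied, role = "fit"),
    data.frame(field_x_cm = varied, field_y_cm = 10, role = "fit"),
    data.frame(field_x_cm = 4, field_y_cm = varied, role = "validate"),
    data.frame(field_x_cm = setdiff(varied, 4), field_y_cm = 4,
               role = "validate"))
}

#' Generate a synthetic Sc dataset
#'
#' Computes Sc for the field menu from the model, applies multiplicative
#' Gaussian noise, and renormalizes to the (noisy) 10 x 10 reading so the
#' reference record is exactly 1, as in a real measurement session.
#'
#' @param model [beam_model()].
#' @param fields data frame as from [default_sc_fields()].
#' @param noise relative noise standard deviation.
#' @param seed integer seed.
#' @return an [sc_dataset()].
#' @export
make_sc_dataset <- function(model, fields = default_sc_fields(),
                            noise = 0.001, seed = 1) {
  sc <- vapply(seq_len(nrow(fields)), function(i)
    compute_sc(model, rect_field(fields$field_x_cm[i], fields$field_y_cm[i])),
    numeric(1))
  set.seed(seed)
  sc <- sc * (1 + noise * rnorm(length(sc)))
  ref <- which(fields$field_x_cm == 10 & fields$field_y_cm == 10)[1]
  sc <- sc / sc[ref]
  sc_dataset(data.frame(field_x_cm = fields$field_x_cm,
                        field_y_cm = fields$field_y_cm),
             sc, fields$role)
}

#' Generate synthetic scanned profiles
#'
#' Forward-computes VAE-convolved, central-axis-normalized profiles of
#' square fields (emulating water-tank scans at 10 cm depth, 90 cm SSD),
#' then applies multiplicative noise and renormalizes to the central
#' axis.
#'
#' @param model [beam_model()].
#' @param sizes square field sizes in cm.
#' @param axis `"x"` (cross-plane, leaf-tip edges) or `"y"` (in-plane,
#'   jaw edges).
#' @param det [detector_response()].
#' @param noise relative noise standard deviation.
#' @param seed integer seed.
#' @return a [profile_set()].
#' @export
make_profiles <- function(model, sizes, axis = "y",
                          det = detector_response(), noise = 0.005,
                          seed = 1) {
  set.seed(seed)
  entries <- lapply(sizes, function(s) {
    field <- rect_field(s, s)
    pr <- rect_field_profile(model, field, axis, det)
    v <- pr$values * (1 + noise * rnorm(length(pr$values)))
    v <- v / approx(pr$positions, v, 0)$y
    list(field = field, axis = axis, depth_cm = 10, ssd_cm = 90,
         profile = beam_profile(pr$positions, v, axis = axis))
  })
  profile_set(entries)
}

#' Generate a random step-and-shoot IMRT beam
#'
#' Segments are built from smooth random walks of per-row leaf openings
#' over a 0.5 cm leaf bank, with conformal jaws and the planning
#' constraints of the fixture spec enforced (redrawing a segment up to
#' 1000 times before giving up).
#'
#' @param spec [fixture_spec()].
#' @return a [beam_delivery()].
#' @export
make_imrt_plan <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  lw <- 0.5
  edges <- seq(-10, 10, by = lw)
  n_rows <- length(edges) - 1
  draw_segment <- function() {
    n_open <- sample(4:12, 1)
    first <- sample(seq_len(n_rows - n_open + 1), 1)
    open <- first:(first + n_open - 1)
    ctr <- runif(1, -2, 2); wid <- runif(1, 2, 6)
    xl <- rep(0, n_rows); xr <- rep(0, n_rows)
    for (r in open) {
      wid <- min(max(wid + rnorm(1, 0, 0.8), 0.5), 8)
      ctr <- min(max(ctr + rnorm(1, 0, 0.4), -4), 4)
      xl[r] <- ctr - wid / 2; xr[r] <- ctr + wid / 2
    }
    lp <- data.frame(y_low = edges[-length(edges)], y_high = edges[-1],
                     x_left = xl, x_right = xr)
    jaw <- c(edges[first], edges[first + n_open])
    area <- sum((xr - xl)[open]) * lw
    list(seg = mlc_segment(lp, jaw, mu = round(runif(1, 5, 30))),
         area = area)
  }
  segs <- vector("list", spec$n_segments)
  for (k in seq_len(spec$n_segments)) {
    for (try in 1:1000) {
      d <- draw_segment()
      if (d$area >= spec$min_segment_area) break
      if (try == 1000)
        stop(sprintf("segment area constraint unmet after 1000 draws (seed %d)",
                     spec$seed))
    }
    segs[[k]] <- d$seg
  }
  beam_delivery(segs, spec$energy_mode)
}

#' Calculate the planar dose of a beam
#'
#' Convenience wrapper: MU-weighted beam fluence on the grid, convolved
#' with the model kernel.
#'
#' @param model [beam_model()].
#' @param beam [beam_delivery()].
#' @param grid lattice from [make_grid()]; default covers the beam
#'   aperture with a 3 cm margin at 1 mm spacing.
#' @export
calc_dose_plane <- function(model, beam, grid = NULL) {
  if (is.null(grid)) grid <- beam_extent_grid(beam)
  convolve_dose(beam_fluence(model, beam, grid), model$kernel)
}

## symmetric 1 mm grid covering all apertures plus a margin
beam_extent_grid <- function(beam, margin = 3, spacing = 0.1) {
  lim <- 0
  for (s in beam$segments) {
    lp <- s$leaf_pairs
    open <- lp$x_right - lp$x_left > 1e-12
    if (any(open))
      lim <- max(lim, abs(lp$x_left[open]), abs(lp$x_right[open]))
    lim <- max(lim, abs(s$jaw_y))
  }
  L <- ceiling(lim + margin)
  make_grid(c(-L, L), c(-L, L), spacing)
}

#' Generate a pseudo-measured dose plane on a diode-array lattice
#'
#' Computes the planar dose of the beam, samples it at the detector
#' positions (a staggered or regular lattice), and applies multiplicative
#' Gaussian noise.  The result is a sparse [dose_grid()] on a lattice of
#' half the diode pitch with `NA` at non-detector positions, mimicking a
#' MapCHECK-like 2D array.
#'
#' @param model [beam_model()].
#' @param beam [beam_delivery()].
#' @param spec [fixture_spec()] supplying detector pattern and noise.
#' @param dose optional precomputed dense [dose_grid()] of the beam (to
#'   avoid recomputation when the caller also needs the calculation).
#' @param seed overrides `spec$seed` when given.
#' @export
make_measurement <- function(model, beam, spec = fixture_spec(),
                             dose = NULL, seed = NULL) {
  if (is.null(dose)) dose <- calc_dose_plane(model, beam)
  pitch <- spec$detector_spacing
  step <- if (spec$detector_pattern == "staggered") pitch / 2 else pitch
  L <- step * floor(max(dose$x) / step)
  dg <- make_grid(c(-L, L), c(-L, L), step)
  vals <- matrix(NA_real_, length(dg$x), length(dg$y))
  idx <- expand.grid(i = seq_along(dg$x), j = seq_along(dg$y))
  if (spec$detector_pattern == "staggered")
    idx <- idx[(idx$i + idx$j) %% 2 == 0, ]
  vals[cbind(idx$i, idx$j)] <-
    interp_bilinear(dose, dg$x[idx$i], dg$y[idx$j])
  set.seed(if (is.null(seed)) spec$seed else seed)
  noise <- matrix(rnorm(length(vals), 0, spec$noise_profile),
                  nrow(vals), ncol(vals))
  vals <- vals * (1 + noise)
  dose_grid(vals, dg)
}
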