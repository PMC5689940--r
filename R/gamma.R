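#' Gamma comparison criteria
#'
#' @param dose_pct dose-difference criterion in percent.
#' @param dta distance-to-agreement in cm.
#' @param threshold_pct low-dose threshold in percent of the reference
#'   plane maximum; reference points below it are excluded.
#' @param mode `"local"` (criterion scales with the local reference dose)
#'   or `"global"` (with the reference maximum).
#' @param search_radius_factor search disk radius in units of `dta`.
#' @param interp_step sub-grid search step in cm; must be <= dta / 5.
#' @export
gamma_criteria <- function(dose_pct = 2, dta = 0.2, threshold_pct = 10,
                           mode = c("local", "global"),
                           search_radius_factor = 3, interp_step = 0.01) {
  mode <- match.arg(mode)
  if (dose_pct <= 0 || dta <= 0 || threshold_pct <= 0 ||
      search_radius_factor <= 0 || interp_step <= 0)
    stop("gamma criteria must all be positive")
  if (interp_step > dta / 5 + 1e-12)
    stop("interp_step must be <= dta / 5")
  structure(list(dose_pct = dose_pct, dta = dta,
                 threshold_pct = threshold_pct, mode = mode,
                 search_radius_factor = search_radius_factor,
                 interp_step = interp_step),
            class = "gamma_criteria")
}

#' 2D gamma comparison of two dose planes
#'
#' For every reference point above the low-dose threshold, gamma is the
#' minimum over a search disk of
#' `sqrt((dose difference / criterion)^2 + (distance / dta)^2)`, with the
#' evaluated plane resampled by bilinear interpolation on an
#' `interp_step` lattice.  By the MapCHECK convention the reference is
#' the measurement and the evaluated plane the calculation.  Reference
#' planes may contain `NA` values (e.g. a sparse diode array embedded in
#' a grid); those points are simply not evaluated.
#'
#' @param reference [dose_grid()] (may be sparse via `NA`s).
#' @param evaluated dense [dose_grid()] overlapping the reference extent.
#' @param criteria [gamma_criteria()].
#' @return object of class `gamma_result`: `points` (data frame with
#'   x, y, ref_dose, gamma), `gamma_map` (matrix aligned with the
#'   reference lattice, `NA` where not evaluated), `passing_rate`
#'   (percent of evaluated points with gamma <= 1), `n_evaluated`,
#'   `n_below_threshold`, `n_zero_ref`, and the criteria.
#' @export
gamma_index <- function(reference, evaluated, criteria = gamma_criteria()) {
  stopifnot(inherits(reference, "dose_grid"),
            inherits(evaluated, "dose_grid"),
            inherits(criteria, "gamma_criteria"))
  if (max(reference$x) < min(evaluated$x) ||
      min(reference$x) > max(evaluated$x) ||
      max(reference$y) < min(evaluated$y) ||
      min(reference$y) > max(evaluated$y))
    stop("reference and evaluated planes have disjoint extents")
  if (anyNA(evaluated$values))
    stop("evaluated plane must be dense (no NA)")

  pts <- expand.grid(ix = seq_along(reference$x), iy = seq_along(reference$y))
  pts$x <- reference$x[pts$ix]; pts$y <- reference$y[pts$iy]
  pts$ref <- reference$values[cbind(pts$ix, pts$iy)]
  pts <- pts[is.finite(pts$ref), ]

  dmax <- max(pts$ref)
  thr <- criteria$threshold_pct / 100 * dmax
  n_below <- sum(pts$ref < thr)
  pts <- pts[pts$ref >= thr, ]
  n_zero <- 0L
  if (criteria$mode == "local") {
    n_zero <- sum(pts$ref == 0)
    pts <- pts[pts$ref > 0, ]
  }
  if (!nrow(pts)) stop("no reference points above the dose threshold")

  rad <- criteria$search_radius_factor * criteria$dta
  s <- seq(-rad, rad, by = criteria$interp_step)
  offs <- expand.grid(dx = s, dy = s)
  offs <- offs[offs$dx^2 + offs$dy^2 <= rad^2 + 1e-12, ]
  r2term <- (offs$dx^2 + offs$dy^2) / criteria$dta^2

  gam <- vapply(seq_len(nrow(pts)), function(k) {
    de <- interp_bilinear(evaluated, pts$x[k] + offs$dx, pts$y[k] + offs$dy)
    delta <- criteria$dose_pct / 100 *
      (if (criteria$mode == "local") pts$ref[k] else dmax)
    g2 <- ((de - pts$ref[k]) / delta)^2 + r2term
    sqrt(min(g2, na.rm = TRUE))
  }, numeric(1))

  gmap <- matrix(NA_real_, length(reference$x), length(reference$y))
  gmap[cbind(pts$ix, pts$iy)] <- gam
  structure(list(
    points = data.frame(x = pts$x, y = pts$y, ref_dose = pts$ref, gamma = gam),
    gamma_map = gmap,
    passing_rate = 100 * mean(gam <= 1 + 1e-9),
    n_evaluated = length(gam),
    n_below_threshold = n_below,
    n_zero_ref = n_zero,
    criteria = criteria),
    class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  c <- x$criteria
  cat(sprintf("<gamma_result> %g%%/%g mm (%s), %g%% threshold\n",
              c$dose_pct, 10 * c$dta, c$mode, c$threshold_pct))
  cat(sprintf("  passing rate: %.1f%% of %d evaluated points (%d below threshold)\n",
              x$passing_rate, x$n_evaluated, x$n_below_threshold))
  invisible(x)
}
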