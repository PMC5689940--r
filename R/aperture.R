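#' One MLC/jaw aperture of a step-and-shoot delivery
#'
#' Leaf rows must tile a contiguous y range without overlap; tips may
#' touch (closed row) but never cross.  All coordinates are cm projected
#' to the isocenter plane.
#'
#' @param leaf_pairs data frame with columns `y_low`, `y_high` (row edges)
#'   and `x_left`, `x_right` (tip positions).
#' @param jaw_y length-2 jaw opening `c(y1, y2)`.
#' @param mu monitor-unit weight (>= 0).
#' @export
mlc_segment <- function(leaf_pairs, jaw_y, mu = 1) {
  lp <- as.data.frame(leaf_pairs)
  need <- c("y_low", "y_high", "x_left", "x_right")
  if (!all(need %in% names(lp)))
    stop("leaf_pairs needs columns y_low, y_high, x_left, x_right")
  lp <- lp[order(lp$y_low), need]
  bad <- which(lp$x_left > lp$x_right + 1e-12)
  if (length(bad))
    stop(sprintf("leaf row %d: x_left > x_right", bad[1]))
  if (any(lp$y_high <= lp$y_low))
    stop("every leaf row needs y_low < y_high")
  if (nrow(lp) > 1 &&
      any(abs(lp$y_low[-1] - lp$y_high[-nrow(lp)]) > 1e-9))
    stop("leaf rows must tile a contiguous y-range without gaps or overlap")
  if (length(jaw_y) != 2 || jaw_y[1] >= jaw_y[2])
    stop("jaw_y must be c(y1, y2) with y1 < y2")
  if (mu < 0) stop("mu must be >= 0")
  structure(list(leaf_pairs = lp, jaw_y = as.numeric(jaw_y), mu = mu),
            class = "mlc_segment")
}

#' An ordered list of segments forming one IMRT beam
#'
#' @param segments list of [mlc_segment()].
#' @param energy_mode beam mode tag.
#' @export
beam_delivery <- function(segments, energy_mode = "6FFF") {
  if (!length(segments)) stop("beam_delivery needs at least one segment")
  if (!all(vapply(segments, inherits, logical(1), "mlc_segment")))
    stop("segments must all be mlc_segment objects")
  total_mu <- sum(vapply(segments, `[[`, numeric(1), "mu"))
  structure(list(segments = segments, energy_mode = energy_mode,
                 total_mu = total_mu),
            class = "beam_delivery")
}

#' Build the segment of a symmetric rectangular field
#'
#' All leaf rows across the bank carry the same tip positions so the MLC
#' defines the x edges; the jaws define the y edges.  The bank extends
#' well beyond the jaw opening, as on the real machine.
#'
#' @param field [rect_field()].
#' @param leaf_width_iso leaf width at isocenter, cm.
#' @param bank_y length-2 extent of the leaf bank in y, cm.
#' @param mu monitor units.
#' @export
rect_field_segment <- function(field, leaf_width_iso = 0.5,
                               bank_y = c(-20, 20), mu = 1) {
  edges <- seq(bank_y[1], bank_y[2], by = leaf_width_iso)
  n <- length(edges) - 1
  lp <- data.frame(y_low = edges[-length(edges)], y_high = edges[-1],
                   x_left = rep(-field$x_open / 2, n),
                   x_right = rep(field$x_open / 2, n))
  mlc_segment(lp, jaw_y = c(-field$y_open / 2, field$y_open / 2), mu = mu)
}

## per-row primary transmission along the grid x vector
row_transmission <- function(xl, xr, xvec, leaf_end, bulk) {
  open <- xvec > xl & xvec < xr
  d <- ifelse(xvec <= xl, xl - xvec, pmax(xvec - xr, 0))
  blocked <- ifelse(d <= leaf_end$soft_range,
                    pmax(exp(-d^leaf_end$alpha / leaf_end$beta), bulk),
                    bulk)
  ifelse(open, 1, blocked)
}

#' Primary transmission map of a segment
#'
#' For every lattice point (isocenter-plane coordinates) the map holds the
#' primary-photon transmission: 1 inside the open aperture, the rounded
#' leaf-end law within `soft_range` of a tip, the bulk factor under the
#' leaf body, the interleaf factor on boundary strips between two closed
#' leaves, and the tongue-and-groove factor on strips where an open row
#' abuts a closed one.  Strips narrower than a pixel are area-averaged
#' into the 1 mm lattice.  Points outside the jaw opening are multiplied
#' by the jaw transmission.
#'
#' @param segment [mlc_segment()].
#' @param model [beam_model()].
#' @param grid lattice from [make_grid()].
#' @param jaw_transmission transmission under the jaws; defaults to the
#'   MLC bulk factor.
#' @return an nx-by-ny matrix of fractions in (0, 1].
#' @export
transmission_map <- function(segment, model, grid,
                             jaw_transmission = model$mlc$bulk) {
  stopifnot(inherits(segment, "mlc_segment"), inherits(model, "beam_model"))
  mlc <- model$mlc; le <- model$leaf_end
  lp <- segment$leaf_pairs
  x <- grid$x; y <- grid$y; h <- grid$spacing
  nr <- nrow(lp)
  if (h > mlc$tg_width_iso * 10)
    warning("grid spacing much coarser than tongue-and-groove width; strips are area-averaged")

  ## per-row transmission and open indicator over x
  RT <- vapply(seq_len(nr), function(r)
    row_transmission(lp$x_left[r], lp$x_right[r], x, le, mlc$bulk),
    numeric(length(x)))
  OPEN <- vapply(seq_len(nr), function(r)
    x > lp$x_left[r] & x < lp$x_right[r], logical(length(x)))
  if (nr == 1) { RT <- matrix(RT, ncol = 1); OPEN <- matrix(OPEN, ncol = 1) }

  ## area-weighted base map: overlap of each y pixel with each row
  ylo <- y - h / 2; yhi <- y + h / 2
  OV <- pmax(outer(lp$y_high, yhi, pmin) - outer(lp$y_low, ylo, pmax), 0)
  w_out <- pmax(0, h - colSums(OV))
  tm <- RT %*% OV / h + outer(rep(mlc$bulk, length(x)), w_out / h)

  ## sub-pixel strips at interior row boundaries
  add_strip <- function(tm, b, width, sval, base, mask) {
    ov <- pmax(0, pmin(b + width / 2, yhi) - pmax(b - width / 2, ylo))
    jj <- which(ov > 0)
    for (j in jj)
      tm[mask, j] <- tm[mask, j] + ov[j] / h * (sval - base[mask])
    tm
  }
  if (nr > 1) {
    for (k in seq_len(nr - 1)) {
      b <- lp$y_high[k]
      o1 <- OPEN[, k]; o2 <- OPEN[, k + 1]
      base <- (RT[, k] + RT[, k + 1]) / 2
      m_tg <- xor(o1, o2)
      if (any(m_tg))
        tm <- add_strip(tm, b, mlc$tg_width_iso, mlc$tongue_and_groove,
                        base, m_tg)
      m_il <- !o1 & !o2
      if (any(m_il))
        tm <- add_strip(tm, b, mlc$interleaf_width_iso, mlc$interleaf,
                        base, m_il)
    }
  }

  ## jaw factor with sub-pixel edge weighting
  fi <- pmax(0, pmin(segment$jaw_y[2], yhi) - pmax(segment$jaw_y[1], ylo)) / h
  jf <- fi + (1 - fi) * jaw_transmission
  sweep(tm, 2, jf, `*`)
}

#' Visible source-plane rectangles of a segment
#'
#' One rectangle per open leaf row as seen from the calculation point:
#' x range given by the back-projected tip positions and y range by the
#' back-projected row edges (both from the MLC level) intersected with the
#' back-projected jaw edges (from the jaw level).  Empty intersections are
#' dropped.
#'
#' @param segment [mlc_segment()].
#' @param p calculation point `c(px, py)` (cm at the z_p plane) or
#'   `c(px, py, z_p)`; default on-axis at the isocenter.
#' @param geometry [machine_geometry()].
#' @param z_source source plane position, cm from target.
#' @return data frame with columns `x1`, `x2`, `y1`, `y2` (cm on the
#'   source plane); zero rows for a fully closed segment.
#' @export
visible_rects <- function(segment, p = c(0, 0), geometry = machine_geometry(),
                          z_source = geometry$source_plane_z_fff) {
  stopifnot(inherits(segment, "mlc_segment"))
  px <- p[1]; py <- p[2]
  z_p <- if (length(p) >= 3) p[3] else geometry$sad
  lp <- segment$leaf_pairs
  open <- lp$x_right - lp$x_left > 1e-12
  if (!any(open))
    return(data.frame(x1 = numeric(0), x2 = numeric(0),
                      y1 = numeric(0), y2 = numeric(0)))
  lp <- lp[open, ]
  bp <- function(e, z_l, pv) backproject_edge(e, z_l, pv, z_p, z_source,
                                              geometry$sad)
  x1 <- bp(lp$x_left, geometry$z_mlc, px)
  x2 <- bp(lp$x_right, geometry$z_mlc, px)
  y1 <- pmax(bp(lp$y_low, geometry$z_mlc, py),
             bp(segment$jaw_y[1], geometry$z_jaw, py))
  y2 <- pmin(bp(lp$y_high, geometry$z_mlc, py),
             bp(segment$jaw_y[2], geometry$z_jaw, py))
  keep <- x2 > x1 & y2 > y1
  data.frame(x1 = x1, x2 = x2, y1 = y1, y2 = y2)[keep, , drop = FALSE]
}
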