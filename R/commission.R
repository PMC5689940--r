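#' Commissioning profile collection
#'
#' @param entries list of entries, each a list with components `field`
#'   ([rect_field()]), `axis` (`"x"` cross-plane / leaf-tip edges, `"y"`
#'   in-plane / jaw edges), `depth_cm`, `ssd_cm` and `profile`
#'   ([beam_profile()] normalized to the central axis).
#' @export
profile_set <- function(entries) {
  ok <- vapply(entries, function(e)
    inherits(e$field, "rect_field") && e$axis %in% c("x", "y") &&
      inherits(e$profile, "beam_profile"), logical(1))
  if (!all(ok)) stop("malformed profile_set entry")
  structure(list(entries = entries), class = "profile_set")
}

#' Commissioning fit report
#'
#' Residuals are percent-of-signal differences on the observations used
#' for the fit; when the input carries a held-out validation block its
#' residuals are reported alongside.
#'
#' @param stage one of `"source"`, `"oar"`, `"kernel"`, `"leaf_end"`.
#' @param params the fitted parameter object.
#' @param residuals numeric vector of fit residuals, percent.
#' @param iterations optimizer iteration count.
#' @param converged logical convergence flag.
#' @param seed the seed that controlled the multistarts.
#' @param validation optional numeric vector of validation residuals.
#' @export
fit_report <- function(stage, params, residuals, iterations, converged,
                       seed, validation = NULL) {
  structure(list(stage = stage, params = params,
                 residual_max = max(abs(residuals)),
                 residual_rms = sqrt(mean(residuals^2)),
                 iterations = iterations, converged = converged,
                 seed = seed,
                 validation_max = if (length(validation))
                   max(abs(validation)) else NA_real_),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report %s> max resid %.4f%%, rms %.4f%%, %d iter, %s (seed %d)\n",
              x$stage, x$residual_max, x$residual_rms, x$iterations,
              if (x$converged) "converged" else "NOT converged", x$seed))
  if (is.finite(x$validation_max))
    cat(sprintf("  validation max resid %.4f%%\n", x$validation_max))
  invisible(x)
}

## Sc for many rectangular fields at the on-axis isocenter point
sc_calc_fields <- function(source, geometry, fx, fy) {
  zs <- source$plane_z; sad <- geometry$sad
  bp <- function(e, zl) backproject_edge(e, zl, 0, sad, zs, sad)
  x2 <- bp(fx / 2, geometry$z_mlc); y2 <- bp(fy / 2, geometry$z_jaw)
  head <- gaussian_rect_integral(source, -x2, x2, -y2, y2)
  rx <- bp(5, geometry$z_mlc); ry <- bp(5, geometry$z_jaw)
  ref <- gaussian_rect_integral(source, -rx, rx, -ry, ry)
  (1 + head) / (1 + ref)
}

## shared bounded Levenberg-Marquardt multistart driver
lm_multistart <- function(resid_fn, starts, lower, upper, maxiter = 300) {
  best <- NULL
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, lower), upper)
    fit <- try(minpack.lm::nls.lm(
      par = p0, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = maxiter, ftol = 1e-12, ptol = 1e-12)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  best
}

#' Stage 1: fit the extra-focal source from in-air output factors
#'
#' Bounded nonlinear least squares over the amplitudes and per-axis
#' sigmas of `n_components` bivariate Gaussians, minimizing the percent
#' difference between calculated and measured Sc over the `role == "fit"`
#' records.  Fields smaller than 3 x 3 cm^2 are rejected (source
#' occlusion makes them unusable for the fit).
#'
#' @param sc [sc_dataset()] with at least 8 fit fields.
#' @param geometry [machine_geometry()].
#' @param plane_z source plane position in cm.
#' @param n_components number of Gaussians (default 2).
#' @param seed integer controlling the multistart perturbations.
#' @param n_starts number of optimizer starts.
#' @return list with `params` ([source_params()]) and `report`
#'   ([fit_report()]).
#' @export
fit_source <- function(sc, geometry = machine_geometry(), plane_z = 6,
                       n_components = 2, seed = 1, n_starts = 5) {
  stopifnot(inherits(sc, "sc_dataset"))
  if (any(pmin(sc$field_x_cm, sc$field_y_cm) < 3))
    stop("fields smaller than 3x3 cm^2 must be excluded from the source fit")
  fit <- sc[sc$role == "fit", ]
  if (nrow(fit) < 8) stop("need at least 8 fit fields")
  N <- n_components
  mk <- function(p) source_params(p[1:N], p[N + 1:N], p[2 * N + 1:N], plane_z)
  resid_fn <- function(p)
    100 * (sc_calc_fields(mk(p), geometry, fit$field_x_cm, fit$field_y_cm) -
             fit$sc)
  lower <- c(rep(1e-8, N), rep(0.05, 2 * N))
  upper <- c(rep(0.5, N), rep(20, 2 * N))
  base <- c(rep(0.03, N),
            rep_len(c(3, 0.8), N), rep_len(c(3, 0.8), N))
  starts <- list(base)
  set.seed(seed)
  for (k in seq_len(n_starts - 1))
    starts[[k + 1]] <- base * exp(rnorm(3 * N, 0, 0.4))
  best <- lm_multistart(resid_fn, starts, lower, upper)
  params <- mk(best$par)
  val <- sc[sc$role == "validate", ]
  vres <- if (nrow(val))
    100 * (sc_calc_fields(params, geometry, val$field_x_cm, val$field_y_cm) -
             val$sc) else NULL
  list(params = params,
       report = fit_report("source", params, resid_fn(best$par),
                           best$niter, best$info %in% 1:4, seed, vres))
}

## grid used for every rectangular-field profile computation; shared by
## the synthetic generator and the fitting stages so forward models match
field_profile_grid <- function(field, margin = 5, spacing = 0.1) {
  hx <- field$x_open / 2 + margin
  hy <- field$y_open / 2 + margin
  make_grid(c(-hx, hx), c(-hy, hy), spacing)
}

## forward model: normalized VAE-convolved profile of a rectangular field
## on the grid positions of its scan axis
rect_field_profile <- function(model, field, axis, det,
                               include_oar = TRUE, fluence = NULL) {
  grid <- field_profile_grid(field)
  if (is.null(fluence)) {
    seg <- rect_field_segment(field, model$mlc$leaf_width_iso,
                              bank_y = c(-1, 1) * (field$y_open / 2 + 5))
    fluence <- segment_fluence(model, seg, grid, include_oar = include_oar)
  }
  raw <- dose_profile_line(fluence, model$kernel, axis = axis)
  conv <- apply_detector_response(raw, det)
  cax <- approx(conv$positions, conv$values, 0)$y
  beam_profile(conv$positions, conv$values / cax, axis = axis)
}

#' Stage 2: fit the off-axis-ratio polynomial from large-field profiles
#'
#' Dose is linear in the polynomial coefficients (the OAR multiplies the
#' fluence before the kernel convolution), so the degree-4 polynomial is
#' recovered by a linear least-squares fit through the full VAE-convolved
#' forward model: basis doses of `fluence * r^k` are computed once and
#' the coefficient vector is the null-space direction of the stacked
#' normalized-profile equations.  Only in-field samples at least 1 cm
#' inside the field edges enter the fit.
#'
#' @param profiles [profile_set()] of large square fields (30 x 30 and
#'   40 x 40 cm^2 in the standard menu).
#' @param model [beam_model()]-like list supplying the source, MLC,
#'   geometry and a provisional kernel; any `oar` component is ignored.
#' @param det [detector_response()].
#' @param seed recorded in the report (the fit itself is deterministic).
#' @return list with `params` ([oar_poly()], scaled to R(0) = 1) and
#'   `report`.
#' @export
fit_oar <- function(profiles, model, det = detector_response(), seed = 1) {
  stopifnot(inherits(profiles, "profile_set"))
  rows <- list(); meta <- list()
  for (e in profiles$entries) {
    grid <- field_profile_grid(e$field)
    seg <- rect_field_segment(e$field, model$mlc$leaf_width_iso,
                              bank_y = c(-1, 1) * (e$field$y_open / 2 + 5))
    base <- segment_fluence(model, seg, grid, include_oar = FALSE)
    # same held-constant radial argument as evaluate_oar, so the forward
    # model stays linear in the coefficients
    rr <- pmin(sqrt(outer(grid$x^2, grid$y^2, `+`)), 22)
    half <- if (e$axis == "x") e$field$x_open / 2 else e$field$y_open / 2
    sel <- abs(e$profile$positions) <= half - 1
    if (!any(sel)) stop("in-field mask empty for a fit_oar entry")
    pos <- e$profile$positions[sel]
    B <- matrix(0, length(pos), 5); B0 <- numeric(5)
    for (k in 0:4) {
      fk <- fluence_grid(base$values * rr^k, grid)
      pr <- apply_detector_response(
        dose_profile_line(fk, model$kernel, axis = e$axis), det)
      B[, k + 1] <- approx(pr$positions, pr$values, pos)$y
      B0[k + 1] <- approx(pr$positions, pr$values, 0)$y
    }
    M <- e$profile$values[sel]
    rows[[length(rows) + 1]] <- B - M %o% B0
    meta[[length(meta) + 1]] <- list(B = B, B0 = B0, M = M)
  }
  X <- do.call(rbind, rows)
  a <- svd(X)$v[, 5]
  if (a[1] < 0) a <- -a
  a <- a / a[1]                      # scale so R(0) = 1
  params <- oar_poly(a)
  resid <- unlist(lapply(meta, function(m)
    100 * (as.vector(m$B %*% a) / sum(m$B0 * a) - m$M)))
  list(params = params,
       report = fit_report("oar", params, resid, 1L, TRUE, seed))
}

#' Stage 3: fit the dose deposition kernel from in-plane profiles
#'
#' Bounded least squares over the three component weights and sigmas,
#' comparing VAE-convolved normalized profiles along the in-plane (jaw
#' defined) axis so that the rounded leaf end cannot influence the fit.
#' The sigma ordering `sigma_0 < sigma_1 < sigma_2` is enforced through
#' disjoint box constraints.  Fluences are computed once per field; each
#' optimizer step only redoes the (separable) line convolution.
#'
#' @param profiles [profile_set()] with `axis == "y"` entries
#'   (5, 10, 20 and 30 cm squares in the standard menu).
#' @param model [beam_model()] supplying source, OAR, MLC and geometry.
#' @param det [detector_response()].
#' @param seed multistart seed.
#' @param n_starts number of optimizer starts.
#' @return list with `params` ([kernel_params()]) and `report`.
#' @export
fit_kernel <- function(profiles, model, det = detector_response(),
                       seed = 1, n_starts = 3) {
  stopifnot(inherits(profiles, "profile_set"))
  if (!all(vapply(profiles$entries, function(e) e$axis == "y", logical(1))))
    stop("fit_kernel requires in-plane (axis 'y', jaw-defined) profiles only")
  pre <- lapply(profiles$entries, function(e) {
    grid <- field_profile_grid(e$field)
    seg <- rect_field_segment(e$field, model$mlc$leaf_width_iso,
                              bank_y = c(-1, 1) * (e$field$y_open / 2 + 5))
    list(fl = segment_fluence(model, seg, grid),
         pos = e$profile$positions, meas = e$profile$values)
  })
  resid_fn <- function(p) {
    kern <- kernel_params(p[1:3], p[4:6])
    unlist(lapply(pre, function(q) {
      pr <- apply_detector_response(
        dose_profile_line(q$fl, kern, axis = "y"), det)
      v <- approx(pr$positions, pr$values, q$pos)$y
      100 * (v / approx(pr$positions, pr$values, 0)$y - q$meas)
    }))
  }
  lower <- c(1e-4, 1e-4, 1e-4, 0.05, 0.60, 3.0)
  upper <- c(3, 3, 3, 0.60, 3.0, 15.0)
  base <- c(0.8, 0.05, 0.01, 0.30, 1.5, 6.0)
  starts <- list(base)
  set.seed(seed)
  for (k in seq_len(n_starts - 1))
    starts[[k + 1]] <- base * exp(rnorm(6, 0, 0.3))
  best <- lm_multistart(resid_fn, starts, lower, upper)
  params <- kernel_params(best$par[1:3], best$par[4:6])
  list(params = params,
       report = fit_report("kernel", params, resid_fn(best$par),
                           best$niter, best$info %in% 1:4, seed))
}

#' Stage 4: fit the rounded-leaf-end transmission from cross-plane profiles
#'
#' With the kernel fixed, alpha and beta of the leaf-tip transmission law
#' are fitted to VAE-convolved normalized profiles along the cross-plane
#' (leaf-tip defined) axis.  The extra-focal scatter map of each field is
#' cached: only the thin primary-transmission band near the tips changes
#' between optimizer steps.
#'
#' @param profiles [profile_set()] with `axis == "x"` entries.
#' @param model [beam_model()] carrying the fitted kernel.
#' @param det [detector_response()].
#' @param seed multistart seed.
#' @return list with `params` ([leaf_end_params()]) and `report`.
#' @export
fit_leaf_end <- function(profiles, model, det = detector_response(),
                         seed = 1) {
  stopifnot(inherits(profiles, "profile_set"))
  if (!all(vapply(profiles$entries, function(e) e$axis == "x", logical(1))))
    stop("fit_leaf_end requires cross-plane (axis 'x', leaf-tip) profiles only")
  pre <- lapply(profiles$entries, function(e) {
    grid <- field_profile_grid(e$field)
    seg <- rect_field_segment(e$field, model$mlc$leaf_width_iso,
                              bank_y = c(-1, 1) * (e$field$y_open / 2 + 5))
    sm <- scatter_map(model$source, seg, model$geometry, grid)
    rmap <- if (!is.null(model$oar))
      evaluate_oar(model$oar, sqrt(outer(grid$x^2, grid$y^2, `+`)),
                   normalize = TRUE) else 1
    list(grid = grid, seg = seg, sm = sm, rmap = rmap,
         pos = e$profile$positions, meas = e$profile$values)
  })
  resid_fn <- function(p) {
    m2 <- model; m2$leaf_end <- leaf_end_params(p[1], p[2])
    unlist(lapply(pre, function(q) {
      tm <- transmission_map(q$seg, m2, q$grid)
      fl <- fluence_grid((tm + q$sm) * q$rmap, q$grid)
      pr <- apply_detector_response(
        dose_profile_line(fl, model$kernel, axis = "x"), det)
      v <- approx(pr$positions, pr$values, q$pos)$y
      100 * (v / approx(pr$positions, pr$values, 0)$y - q$meas)
    }))
  }
  lower <- c(0.01, 0.01); upper <- c(5, 5)
  set.seed(seed)
  starts <- list(c(1, 0.5), c(0.5, 1), c(2, 0.2))
  best <- lm_multistart(resid_fn, starts, lower, upper)
  params <- leaf_end_params(best$par[1], best$par[2])
  list(params = params,
       report = fit_report("leaf_end", params, resid_fn(best$par),
                           best$niter, best$info %in% 1:4, seed))
}

#' Run the full four-stage commissioning pipeline
#'
#' Stage 1 fits the source from Sc; stage 2 the off-axis ratio from
#' large-field profiles (FFF only); stage 3 the kernel from in-plane
#' profiles; stage 4 the rounded leaf end from cross-plane profiles.
#' The provisional kernel used before stage 3 defaults to the shipped
#' same-energy kernel.
#'
#' @param sc [sc_dataset()].
#' @param oar_profiles [profile_set()] of large fields, or `NULL` for FF.
#' @param inplane_profiles [profile_set()] with `axis == "y"`.
#' @param crossplane_profiles [profile_set()] with `axis == "x"`.
#' @param energy_mode beam mode of the machine being commissioned.
#' @param geometry [machine_geometry()].
#' @param provisional_kernel [kernel_params()] used in stage 2; default
#'   the shipped kernel for `energy_mode`.
#' @param det [detector_response()].
#' @param seed integer seed for all stages.
#' @return list with `model` (the commissioned [beam_model()]) and
#'   `reports` (one [fit_report()] per stage).
#' @export
run_commissioning <- function(sc, oar_profiles, inplane_profiles,
                              crossplane_profiles, energy_mode = "6FFF",
                              geometry = machine_geometry(),
                              provisional_kernel = NULL,
                              det = detector_response(), seed = 1) {
  fff <- grepl("FFF$", energy_mode)
  plane_z <- if (fff) geometry$source_plane_z_fff else geometry$source_plane_z_ff
  if (is.null(provisional_kernel))
    provisional_kernel <- beam_model_library(energy_mode)$kernel
  reports <- list()

  s1 <- fit_source(sc, geometry, plane_z, seed = seed)
  reports$source <- s1$report

  work <- beam_model(energy_mode, s1$params, provisional_kernel,
                     oar = if (fff) oar_poly(c(1, 0, 0, 0, 0)) else NULL,
                     geometry = geometry)
  if (fff) {
    if (is.null(oar_profiles)) stop("FFF commissioning needs oar_profiles")
    s2 <- fit_oar(oar_profiles, work, det, seed = seed)
    reports$oar <- s2$report
    work$oar <- s2$params
  }

  s3 <- fit_kernel(inplane_profiles, work, det, seed = seed)
  reports$kernel <- s3$report
  work$kernel <- s3$params

  s4 <- fit_leaf_end(crossplane_profiles, work, det, seed = seed)
  reports$leaf_end <- s4$report
  work$leaf_end <- s4$params

  list(model = work, reports = reports)
}

#' Worst 1D gamma between a profile and a reference
#'
#' Agreement metric in the "1%/1 mm" sense: for every point of `profile`
#' the minimum over position offsets of
#' `sqrt((value difference / dose_tol)^2 + (offset / dist_tol)^2)`
#' against the linearly interpolated reference, and the maximum of that
#' over the profile.  A result <= 1 means the whole profile agrees with
#' the reference within the stated tolerances.
#'
#' @param profile,reference [beam_profile()]s on overlapping ranges
#'   (normalized the same way).
#' @param dose_tol absolute value tolerance (default 0.01, i.e. 1% of the
#'   central-axis value of a normalized profile).
#' @param dist_tol position tolerance in cm (default 0.1, i.e. 1 mm).
#' @return the maximum 1D gamma over the evaluable points.
#' @export
profile_max_gamma <- function(profile, reference, dose_tol = 0.01,
                              dist_tol = 0.1) {
  offs <- seq(-3 * dist_tol, 3 * dist_tol, by = dist_tol / 20)
  g <- vapply(seq_along(profile$positions), function(i) {
    p <- profile$positions[i]
    refv <- approx(reference$positions, reference$values, p + offs)$y
    g2 <- ((profile$values[i] - refv) / dose_tol)^2 + (offs / dist_tol)^2
    if (all(is.na(g2))) NA_real_ else sqrt(min(g2, na.rm = TRUE))
  }, numeric(1))
  max(g, na.rm = TRUE)
}
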