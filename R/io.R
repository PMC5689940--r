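## readLines tolerant of CRLF endings
read_text_lines <- function(path) {
  x <- readLines(path, warn = FALSE)
  sub("\r$", "", x)
}

num_fmt <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)

#' Write / read a beam model as structured text (JSON)
#'
#' The file carries one full parameter set (source, OAR, kernel, leaf
#' end, MLC factors, geometry) plus a free-text provenance note; numeric
#' round trips are exact to better than 1e-12.
#'
#' @param model [beam_model()].
#' @param path file path.
#' @export
write_beam_model <- function(model, path) {
  stopifnot(inherits(model, "beam_model"))
  obj <- list(
    format_version = 1L,
    energy_mode = model$energy_mode,
    provenance = model$provenance,
    source = list(amplitudes = model$source$amplitudes,
                  sigma_x = model$source$sigma_x,
                  sigma_y = model$source$sigma_y,
                  plane_z = model$source$plane_z),
    oar = if (!is.null(model$oar))
      list(coeffs = model$oar$coeffs,
           valid_radius = model$oar$valid_radius),
    kernel = list(amplitudes = model$kernel$amplitudes,
                  sigmas = model$kernel$sigmas),
    leaf_end = unclass(model$leaf_end),
    mlc = unclass(model$mlc),
    geometry = unclass(model$geometry))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_beam_model
#' @export
read_beam_model <- function(path) {
  obj <- jsonlite::fromJSON(paste(read_text_lines(path), collapse = "\n"),
                            simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != 1)
    stop("beam model file: unsupported or missing format_version (expected 1)")
  need <- c("energy_mode", "source", "kernel", "leaf_end", "mlc", "geometry")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("beam model file: missing field(s) ", paste(miss, collapse = ", "))
  g <- obj$geometry
  beam_model(
    energy_mode = obj$energy_mode,
    source = source_params(obj$source$amplitudes, obj$source$sigma_x,
                           obj$source$sigma_y, obj$source$plane_z),
    kernel = kernel_params(obj$kernel$amplitudes, obj$kernel$sigmas),
    oar = if (!is.null(obj$oar))
      oar_poly(obj$oar$coeffs,
               if (is.null(obj$oar$valid_radius)) 22
               else obj$oar$valid_radius),
    leaf_end = leaf_end_params(obj$leaf_end$alpha, obj$leaf_end$beta,
                               obj$leaf_end$soft_range),
    mlc = mlc_transmission(obj$mlc$bulk, obj$mlc$interleaf,
                           obj$mlc$tongue_and_groove, obj$mlc$tg_width_iso,
                           obj$mlc$interleaf_width_iso, obj$mlc$leaf_width_iso),
    geometry = machine_geometry(g$sad, g$z_mlc, g$z_jaw,
                                g$source_plane_z_ff, g$source_plane_z_fff),
    provenance = if (is.null(obj$provenance)) "" else obj$provenance)
}

#' Write / read an Sc dataset as CSV
#'
#' Columns `field_x_cm`, `field_y_cm`, `sc`, `role`; the 10 x 10
#' reference row (sc = 1) is mandatory.
#'
#' @param sc [sc_dataset()].
#' @param path file path.
#' @export
write_sc_dataset <- function(sc, path) {
  utils::write.csv(as.data.frame(sc), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sc_dataset
#' @export
read_sc_dataset <- function(path) {
  df <- utils::read.csv(text = paste(read_text_lines(path), collapse = "\n"))
  need <- c("field_x_cm", "field_y_cm", "sc", "role")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sc dataset file: missing column(s) ", paste(miss, collapse = ", "))
  sc_dataset(df[c("field_x_cm", "field_y_cm")], df$sc, df$role)
}

#' Write / read a profile set as long-format CSV
#'
#' Columns `field_x_cm`, `field_y_cm`, `axis`, `depth_cm`, `ssd_cm`,
#' `position_cm`, `value`.
#'
#' @param ps [profile_set()].
#' @param path file path.
#' @export
write_profile_set <- function(ps, path) {
  stopifnot(inherits(ps, "profile_set"))
  rows <- lapply(ps$entries, function(e)
    data.frame(field_x_cm = e$field$x_open, field_y_cm = e$field$y_open,
               axis = e$axis, depth_cm = e$depth_cm, ssd_cm = e$ssd_cm,
               position_cm = e$profile$positions,
               value = e$profile$values))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_profile_set
#' @export
read_profile_set <- function(path) {
  df <- utils::read.csv(text = paste(read_text_lines(path), collapse = "\n"))
  need <- c("field_x_cm", "field_y_cm", "axis", "depth_cm", "ssd_cm",
            "position_cm", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("profile set file: missing column(s) ", paste(miss, collapse = ", "))
  key <- interaction(df$field_x_cm, df$field_y_cm, df$axis,
                     df$depth_cm, df$ssd_cm, drop = TRUE)
  entries <- lapply(split(df, key), function(d) {
    d <- d[order(d$position_cm), ]
    list(field = rect_field(d$field_x_cm[1], d$field_y_cm[1]),
         axis = d$axis[1], depth_cm = d$depth_cm[1], ssd_cm = d$ssd_cm[1],
         profile = beam_profile(d$position_cm, d$value, axis = d$axis[1]))
  })
  profile_set(unname(entries))
}

#' Write / read a beam delivery in the documented JSON dialect
#'
#' Schema: `{energy_mode, segments: [{mu, jaw_y: [y1, y2],
#' leaves: [{y: [lo, hi], x: [left, right]}, ...]}, ...]}`.
#'
#' @param beam [beam_delivery()].
#' @param path file path.
#' @export
write_beam_json <- function(beam, path) {
  stopifnot(inherits(beam, "beam_delivery"))
  obj <- list(
    format_version = 1L,
    energy_mode = beam$energy_mode,
    segments = lapply(beam$segments, function(s) {
      lp <- s$leaf_pairs
      list(mu = s$mu, jaw_y = s$jaw_y,
           leaves = lapply(seq_len(nrow(lp)), function(r)
             list(y = c(lp$y_low[r], lp$y_high[r]),
                  x = c(lp$x_left[r], lp$x_right[r]))))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_beam_json
#' @export
read_beam_json <- function(path) {
  obj <- jsonlite::fromJSON(paste(read_text_lines(path), collapse = "\n"),
                            simplifyVector = FALSE)
  if (is.null(obj$format_version) || obj$format_version != 1)
    stop("beam file: unsupported or missing format_version (expected 1)")
  if (is.null(obj$segments) || !length(obj$segments))
    stop("beam file: no segments")
  segs <- lapply(obj$segments, function(s) {
    lp <- do.call(rbind, lapply(s$leaves, function(l)
      data.frame(y_low = l$y[[1]], y_high = l$y[[2]],
                 x_left = l$x[[1]], x_right = l$x[[2]])))
    mlc_segment(lp, unlist(s$jaw_y), mu = s$mu)
  })
  beam_delivery(segs, obj$energy_mode)
}

#' Write / read a dose or fluence plane in the ASCII grid format
#'
#' Header lines (`# key value ...`) record the grid origin, spacing,
#' normalization tag and energy mode, followed by whitespace-delimited
#' rows, one line per x lattice position with the values across y.  `NA`
#' marks unsampled points (sparse detector arrays).  The reader accepts
#' CRLF line endings; the writer output is bit-stable for fixed input.
#'
#' @param plane [dose_grid()] or [fluence_grid()].
#' @param path file path.
#' @param energy_mode tag recorded in the header.
#' @export
write_dose_plane <- function(plane, path, energy_mode = "") {
  stopifnot(inherits(plane, "dose_plane"))
  type <- if (inherits(plane, "fluence_grid")) "fluence" else "dose"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# fffqa-plane 1",
    paste("# type", type),
    paste("# origin_cm", num_fmt(plane$x[1]), num_fmt(plane$y[1])),
    paste("# spacing_cm", num_fmt(plane$spacing)),
    paste("# normalization", plane$normalization),
    paste("# energy_mode", energy_mode)), con)
  for (i in seq_along(plane$x))
    writeLines(paste(num_fmt(plane$values[i, ]), collapse = " "), con)
  invisible(path)
}

#' @rdname write_dose_plane
#' @export
read_dose_plane <- function(path) {
  lines <- read_text_lines(path)
  if (!grepl("^# fffqa-plane 1$", lines[1]))
    stop("plane file: unsupported or missing format header (expected 'fffqa-plane 1')")
  hdr <- grep("^#", lines)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, " "), lines, value = TRUE)
    if (!length(ln)) stop("plane file: missing header '", key, "'")
    strsplit(sub(paste0("^# ", key, " "), "", ln[1]), "\\s+")[[1]]
  }
  type <- get("type")
  origin <- as.numeric(get("origin_cm"))
  spacing <- as.numeric(get("spacing_cm"))
  norm <- get("normalization")
  body <- lines[-hdr]
  body <- body[nzchar(trimws(body))]
  vals <- do.call(rbind, lapply(body, function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    v <- rep(NA_real_, length(tok))
    num <- tok != "NA"
    v[num] <- as.numeric(tok[num])
    v
  }))
  grid <- list(x = origin[1] + spacing * (seq_len(nrow(vals)) - 1),
               y = origin[2] + spacing * (seq_len(ncol(vals)) - 1),
               spacing = spacing)
  if (type == "fluence") fluence_grid(vals, grid)
  else dose_grid(vals, grid, normalization = norm)
}

#' Read and validate a run configuration (JSON)
#'
#' Known keys: `model` (path), `geometry` (named overrides), `grid`
#' (`xlim`, `ylim`, `spacing`), `gamma` (`dose_pct`, `dta`,
#' `threshold_pct`, `mode`), `output` (path), `log_level`, `seed`.
#' Unknown keys are rejected before any computation.
#'
#' @param path file path.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(paste(read_text_lines(path), collapse = "\n"),
                            simplifyVector = TRUE)
  allowed <- c("model", "geometry", "grid", "gamma", "output",
               "log_level", "seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("run config: unknown key(s) ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$geometry)) {
    gk <- setdiff(names(cfg$geometry),
                  c("sad", "z_mlc", "z_jaw", "source_plane_z_ff",
                    "source_plane_z_fff"))
    if (length(gk))
      stop("run config: unknown geometry key(s) ", paste(gk, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}
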