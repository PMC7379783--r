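#' Construct a trial recording
#'
#' In-memory container for one running trial: synchronized marker and
#' force-plate streams plus metadata. Markers are stored in metres at
#' `marker_rate` Hz; forces in newtons (CoP in metres) at `force_rate` Hz.
#' Both streams share one clock; `t0` is the alignment offset applied at load.
#'
#' @param markers Named list of `n x 3` numeric matrices (columns X forward,
#'   Y left, Z up, metres), one per marker.
#' @param marker_time Numeric vector of marker timestamps, seconds.
#' @param forces Data frame with columns `time`, `Fx`, `Fy`, `Fz`, `CoPx`,
#'   `CoPy` (newtons / metres). CoP is meaningful only while `Fz` exceeds the
#'   contact threshold.
#' @param body_mass Body mass, kg.
#' @param shoe_mass Mass of one shoe, kg.
#' @param side Dominant-side label (`"right"` or `"left"`).
#' @param t0 Clock alignment offset, seconds (default 0).
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(markers, marker_time, forces, body_mass, shoe_mass,
                            side = "right", t0 = 0) {
  stopifnot(is.list(markers), length(markers) > 0, is.data.frame(forces))
  need <- c("time", "Fx", "Fy", "Fz", "CoPx", "CoPy")
  if (!all(need %in% names(forces)))
    stop("force stream needs columns ", paste(need, collapse = ", "))
  if (body_mass <= 0) stop("invalid mass")
  markers <- lapply(markers, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3) stop("markers must be n x 3 matrices")
    dimnames(m) <- list(NULL, c("X", "Y", "Z"))
    m
  })
  marker_rate <- .infer_rate(marker_time, "marker")
  force_rate <- .infer_rate(forces$time, "force")
  if (abs(force_rate / marker_rate - round(force_rate / marker_rate)) > 1e-6)
    stop("force rate must be an integer multiple of the marker rate")
  structure(
    list(markers = markers, marker_time = as.numeric(marker_time),
         forces = forces, marker_rate = marker_rate, force_rate = force_rate,
         body_mass = body_mass, shoe_mass = shoe_mass, side = side, t0 = t0),
    class = "trial_recording"
  )
}

#' @export
print.trial_recording <- function(x, ...) {
  cat("<trial_recording> ", length(x$markers), " markers @ ", round(x$marker_rate),
      " Hz, forces @ ", round(x$force_rate), " Hz, ",
      format(diff(range(x$marker_time)), digits = 3), " s, body ",
      x$body_mass, " kg, shoe ", x$shoe_mass, " kg\n", sep = "")
  invisible(x)
}

.infer_rate <- function(t, what, rel_tol = 1e-4) {
  if (length(t) < 2) stop("irregular sampling: ", what, " stream too short")
  dt <- diff(t)
  if (any(dt <= 0)) stop("irregular sampling: non-monotone ", what, " time base")
  if (max(abs(dt - stats::median(dt))) > rel_tol * stats::median(dt))
    stop("irregular sampling: non-uniform ", what, " time base")
  1 / stats::median(dt)
}

# Linear interpolation of interior NA runs of length <= max_gap; leading and
# trailing NAs and longer runs are load errors.
.fill_gaps <- function(x, max_gap = 10L, what = "series") {
  if (!anyNA(x)) return(x)
  idx <- which(is.na(x))
  r <- rle(is.na(x))
  if (any(r$values & r$lengths > max_gap)) stop("gap too long in ", what)
  if (is.na(x[1]) || is.na(x[length(x)])) stop("gap too long in ", what)
  x[idx] <- stats::approx(seq_along(x)[-idx], x[-idx], xout = idx)$y
  x
}

# ---- trial file I/O --------------------------------------------------------
# Marker TSV: "# units: mm" header, then frame, time, <marker>_X/_Y/_Z columns.
# Force TSV: "# units: N m" header, then time, Fx, Fy, Fz, CoPx, CoPy.
# Metadata TSV: key<TAB>value with body_mass_kg, shoe_mass_kg, side.

.read_tsv_with_units <- function(path, expected_units) {
  lines <- readLines(path, n = 1L, encoding = "UTF-8")
  if (!grepl("^#\\s*units:", lines))
    stop("unknown units: missing '# units:' header in ", path)
  units <- trimws(sub("^#\\s*units:", "", lines))
  if (units != expected_units)
    stop("unknown units: expected '", expected_units, "', found '", units,
         "' in ", path)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Load a trial from marker, force and metadata files
#'
#' Reads the package's documented TSV dialect, converts markers from
#' millimetres to metres, validates uniform sampling, fills marker gaps of at
#' most 10 samples by linear interpolation, and attaches the metadata.
#'
#' @param marker_path Marker TSV (mm; columns `frame`, `time`, then
#'   `<marker>_X`, `<marker>_Y`, `<marker>_Z` per marker).
#' @param force_path Force TSV (N, m; columns `time`, `Fx`, `Fy`, `Fz`,
#'   `CoPx`, `CoPy`).
#' @param meta_path Metadata TSV (`key<TAB>value`: `body_mass_kg`,
#'   `shoe_mass_kg`, `side`).
#' @return A [trial_recording()].
#' @export
load_trial <- function(marker_path, force_path, meta_path) {
  mk <- .read_tsv_with_units(marker_path, "mm")
  fo <- .read_tsv_with_units(force_path, "N m")
  meta_raw <- utils::read.delim(meta_path, header = FALSE, comment.char = "#",
                                stringsAsFactors = FALSE)
  meta <- stats::setNames(as.list(meta_raw[[2]]), meta_raw[[1]])
  if (is.null(meta$body_mass_kg) || is.null(meta$shoe_mass_kg))
    stop("metadata must provide body_mass_kg and shoe_mass_kg")

  coord_cols <- setdiff(names(mk), c("frame", "time"))
  stems <- unique(sub("_[XYZ]$", "", coord_cols))
  markers <- lapply(stems, function(s) {
    m <- cbind(X = mk[[paste0(s, "_X")]], Y = mk[[paste0(s, "_Y")]],
               Z = mk[[paste0(s, "_Z")]]) / 1000
    for (j in 1:3) m[, j] <- .fill_gaps(m[, j], what = paste0("marker ", s))
    m
  })
  names(markers) <- stems
  for (col in c("Fx", "Fy", "Fz"))
    fo[[col]] <- .fill_gaps(fo[[col]], what = paste0("force ", col))
  trial_recording(markers, mk$time, fo,
                  body_mass = as.numeric(meta$body_mass_kg),
                  shoe_mass = as.numeric(meta$shoe_mass_kg),
                  side = if (is.null(meta$side)) "right" else meta$side)
}

#' Write a trial to the TSV dialect read by [load_trial()]
#'
#' @param recording A [trial_recording()].
#' @param marker_path,force_path,meta_path Output file paths.
#' @return Invisibly, the three paths.
#' @export
write_trial <- function(recording, marker_path, force_path, meta_path) {
  mk <- data.frame(frame = seq_along(recording$marker_time),
                   time = recording$marker_time, check.names = FALSE)
  for (s in names(recording$markers)) {
    m <- recording$markers[[s]] * 1000
    mk[[paste0(s, "_X")]] <- m[, 1]
    mk[[paste0(s, "_Y")]] <- m[, 2]
    mk[[paste0(s, "_Z")]] <- m[, 3]
  }
  .write_tsv_with_units(mk, marker_path, "mm")
  .write_tsv_with_units(recording$forces, force_path, "N m")
  writeLines(c("# calfcontrib trial metadata",
               paste0("body_mass_kg\t", format(recording$body_mass, digits = 15)),
               paste0("shoe_mass_kg\t", format(recording$shoe_mass, digits = 15)),
               paste0("side\t", recording$side)),
             meta_path, useBytes = TRUE)
  invisible(c(marker_path, force_path, meta_path))
}

.write_tsv_with_units <- function(df, path, units) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# units: ", units), con)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
}

# ---- normalization ---------------------------------------------------------

#' Body-mass normalization of ground reaction forces
#'
#' Divides every force component by body mass (N/kg), the convention used to
#' make GRF magnitudes comparable across participants. Reporting only: the
#' dynamics consumes raw newtons.
#'
#' @param forces Numeric vector/matrix/data frame of forces, N.
#' @param body_mass Body mass, kg (> 0).
#' @return Forces divided by `body_mass`, N/kg, same shape as the input.
#' @export
normalize_grf <- function(forces, body_mass) {
  if (!is.numeric(body_mass) || length(body_mass) != 1L || body_mass <= 0)
    stop("invalid mass")
  if (is.data.frame(forces)) as.data.frame(lapply(forces, `/`, body_mass))
  else forces / body_mass
}

#' Gait-cycle time normalization
#'
#' Resamples a time series onto 101 points at 0, 1, ..., 100 percent of a
#' cycle by linear interpolation.
#'
#' @param time Timestamps of the series, seconds.
#' @param values Numeric vector (or matrix, resampled column-wise).
#' @param cycle_start,cycle_end Cycle boundaries, seconds
#'   (`cycle_end > cycle_start`); the series must cover the interval.
#' @return For vector input, a data frame with `percent` (0..100) and `value`;
#'   for matrix input, a list with `percent` and resampled `values` matrix.
#' @export
normalize_cycle <- function(time, values, cycle_start, cycle_end) {
  if (cycle_end <= cycle_start) stop("out of range: cycle_end <= cycle_start")
  if (cycle_start < min(time) - 1e-9 || cycle_end > max(time) + 1e-9)
    stop("out of range: cycle not covered by the series")
  tq <- cycle_start + (cycle_end - cycle_start) * seq(0, 100) / 100
  if (is.matrix(values)) {
    out <- apply(values, 2, function(v) stats::approx(time, v, xout = tq)$y)
    return(list(percent = seq(0, 100), values = out))
  }
  data.frame(percent = seq(0, 100),
             value = stats::approx(time, values, xout = tq)$y)
}
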