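# Reading and writing raw walkway exports, peak-pressure reduction, and
# assembly of per-pass recordings.
#
# A raw export has one row per sensor activation sample with eight columns:
# time (s), x/y grid index, pressure, and the device's own foot type, foot
# count, footfall and pass index annotations. The device-provided footfall
# labels are read but never used for segmentation (footfalls are re-derived
# by clustering); they are retained for validation only.

RAW_COLUMNS <- c("time", "x_index", "y_index", "pressure",
                 "foot_type", "foot_count", "footfall", "pass_index")
MANDATORY_RAW <- c("time", "x_index", "y_index", "pressure", "pass_index")

#' Column-alias dialect for raw walkway exports
#'
#' Maps the canonical eight raw columns to the header names used by a
#' particular export. `sep = NULL` autodetects comma vs tab from the
#' header line.
#'
#' @param aliases named list: canonical name -> character vector of
#'   acceptable header spellings (case-insensitive). Defaults cover common
#'   export spellings ("Time", "X", "Y", "Pressure", "Foot Type", ...).
#' @param sep field separator, or `NULL` to autodetect.
#' @export
walkway_dialect <- function(aliases = list(), sep = NULL) {
  default <- list(
    time = c("time", "t", "time_s"),
    x_index = c("x_index", "x", "x-coordinate", "xcoordinate"),
    y_index = c("y_index", "y", "y-coordinate", "ycoordinate"),
    pressure = c("pressure", "pressure_level", "pressure level", "p"),
    foot_type = c("foot_type", "foot type", "foottype", "side"),
    foot_count = c("foot_count", "foot count", "footcount"),
    footfall = c("footfall", "footfall_id"),
    pass_index = c("pass_index", "pass index", "passindex", "pass")
  )
  for (nm in names(aliases)) default[[nm]] <- unique(c(aliases[[nm]], default[[nm]]))
  structure(list(aliases = default, sep = sep), class = "walkway_dialect")
}

#' Read a raw walkway export
#'
#' Parses a delimited text export (CSV or TSV, autodetected) into one raw
#' sensor event per row. Header names are resolved through the dialect's
#' alias map; row order is preserved.
#'
#' @param path path to the export file.
#' @param dialect a [walkway_dialect()].
#' @param mat a [mat_spec()] used to validate grid indices.
#' @return data.frame with the eight canonical columns (optional ones `NA`
#'   when absent from the file).
#' @export
read_raw_export <- function(path, dialect = walkway_dialect(), mat = mat_spec()) {
  if (!file.exists(path)) gm_stop(sprintf("file not found: %s", path), "gaitmat_io_error")
  header_line <- readLines(path, n = 1L)
  sep <- dialect$sep %||% (if (grepl("\t", header_line)) "\t" else ",")
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  norm <- function(x) gsub("[ _.-]", "", tolower(trimws(x)))
  hdr <- norm(names(df))
  out <- data.frame(row.names = seq_len(nrow(df)))
  for (col in RAW_COLUMNS) {
    hit <- which(hdr %in% norm(dialect$aliases[[col]]))
    if (length(hit) == 0) {
      if (col %in% MANDATORY_RAW) {
        gm_stop(sprintf("raw export is missing mandatory column '%s'", col),
                "gaitmat_format_error")
      }
      out[[col]] <- NA
      next
    }
    out[[col]] <- df[[hit[1]]]
  }
  numeric_cols <- c("time", "x_index", "y_index", "pressure", "pass_index")
  for (col in numeric_cols) {
    v <- out[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad)) {
        gm_stop(sprintf("non-numeric value in column '%s' at data line %d: '%s'",
                        col, bad[1], v[bad[1]]), "gaitmat_parse_error")
      }
      out[[col]] <- vn
    }
  }
  if (any(out$time < 0, na.rm = TRUE)) gm_stop("negative times in export", "gaitmat_format_error")
  if (any(out$pressure < 0, na.rm = TRUE)) gm_stop("negative pressures in export", "gaitmat_format_error")
  if (any(out$x_index < 0 | out$x_index > mat$max_x_index, na.rm = TRUE) ||
      any(out$y_index < 0 | out$y_index > mat$max_y_index, na.rm = TRUE)) {
    gm_stop("grid indices outside mat bounds", "gaitmat_format_error")
  }
  rownames(out) <- NULL
  out
}

#' Write a raw walkway export
#'
#' Inverse of [read_raw_export()]: writes the canonical eight columns as CSV.
#' @param events data.frame of raw sensor events.
#' @param path output path.
#' @export
write_raw_export <- function(events, path) {
  stopifnot(all(MANDATORY_RAW %in% names(events)))
  for (col in setdiff(RAW_COLUMNS, names(events))) events[[col]] <- NA
  utils::write.csv(events[, RAW_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reduce per-sensor time series to peak-pressure points
#'
#' For every sensor cell and activation episode, keeps only the timestamp
#' at which the maximum pressure was observed. Ties on pressure break to
#' the earliest time. A cell re-activated after a gap longer than
#' `episode_gap` starts a new activation episode (one cell can be struck by
#' two different footfalls in the same pass). Grid indices convert to
#' centimetres via the mat pitch.
#'
#' @param events data.frame of raw sensor events (as from [read_raw_export()]).
#' @param mat a [mat_spec()].
#' @param episode_gap seconds of inactivity that separate two activation
#'   episodes of the same cell; default 0.2 s.
#' @return data.frame of sensor points: `pass_index`, `x_index`, `y_index`,
#'   `episode`, `x_cm`, `y_cm`, `t_peak`, `peak_pressure`, `device_footfall`.
#' @export
reduce_to_peak <- function(events, mat = mat_spec(), episode_gap = 0.2) {
  cols <- c("pass_index", "x_index", "y_index", "time", "pressure")
  if (nrow(events) == 0) {
    return(data.frame(pass_index = numeric(0), x_index = numeric(0),
                      y_index = numeric(0), episode = integer(0),
                      x_cm = numeric(0), y_cm = numeric(0), t_peak = numeric(0),
                      peak_pressure = numeric(0), device_footfall = numeric(0)))
  }
  stopifnot(all(cols %in% names(events)))
  dt <- data.table::as.data.table(events)
  if (!"footfall" %in% names(dt)) dt[, "footfall" := NA_real_]
  data.table::setorderv(dt, c("pass_index", "x_index", "y_index", "time"))
  time <- pressure <- x_index <- y_index <- pass_index <- episode <- footfall <- NULL # NSE
  dt[, episode := cumsum(c(0, diff(time) > episode_gap)) + 1L,
     by = c("pass_index", "x_index", "y_index")]
  pk <- dt[, {
    i <- which.max(pressure)      # first max: earliest-time tie-break
    list(t_peak = time[i], peak_pressure = pressure[i],
         device_footfall = as.numeric(footfall[i]))
  }, by = c("pass_index", "x_index", "y_index", "episode")]
  pk[, "x_cm" := x_index * mat$pitch_cm]
  pk[, "y_cm" := y_index * mat$pitch_cm]
  out <- as.data.frame(pk[, c("pass_index", "x_index", "y_index", "episode",
                              "x_cm", "y_cm", "t_peak", "peak_pressure",
                              "device_footfall")])
  out[order(out$pass_index, out$t_peak, out$x_index, out$y_index), , drop = FALSE] ->
    out
  rownames(out) <- NULL
  out
}

#' Split reduced sensor points into per-pass recordings
#'
#' @param points sensor points from [reduce_to_peak()].
#' @param metadata data.frame with one row per pass: `pass_index`,
#'   `subject_id`, `visit_id`, `class_label`, `height_cm`.
#' @return list of `pass_recording` objects (points sorted by `t_peak`).
#' @export
split_passes <- function(points, metadata) {
  stopifnot(all(c("pass_index", "subject_id", "visit_id", "class_label",
                  "height_cm") %in% names(metadata)))
  if (nrow(points) == 0) return(list())
  idx <- unique(points$pass_index)
  missing <- setdiff(idx, metadata$pass_index)
  if (length(missing)) {
    gm_stop(sprintf("pass_index %s not present in metadata",
                    paste(missing, collapse = ", ")), "gaitmat_linkage_error")
  }
  lapply(sort(idx), function(pi) {
    pts <- points[points$pass_index == pi, , drop = FALSE]
    pts <- pts[order(pts$t_peak, pts$x_index, pts$y_index), , drop = FALSE]
    rownames(pts) <- NULL
    md <- metadata[metadata$pass_index == pi, , drop = FALSE][1, ]
    structure(
      list(pass_index = pi, points = pts, subject_id = md$subject_id,
           visit_id = md$visit_id, class_label = md$class_label,
           height_cm = md$height_cm),
      class = "pass_recording"
    )
  })
}

#' @export
print.pass_recording <- function(x, ...) {
  cat(sprintf("<pass_recording> pass %s, subject %s (visit %s, %s), %d sensor points\n",
              x$pass_index, x$subject_id, x$visit_id, x$class_label, nrow(x$points)))
  invisible(x)
}
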