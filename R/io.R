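#' @name record_io
#' @title Delimited-text readers and writers for fNIRS records
#'
#' @description
#' Records travel as a plain CSV matrix (one header row naming the
#' columns, `hbo_ch<k>` / `hbr_ch<k>` for hemodynamic records and
#' `od_ch<k>_<lambda>nm` for optical-density records) plus a JSON sidecar
#' `<path>.json` carrying the sampling rate, channel layout and, for
#' optical density, the wavelengths.  On read, columns are normalized to
#' ascending channel id with the HbO block before the HbR block, whatever
#' the file order.
NULL

.sidecar_path <- function(path) paste0(path, ".json")

.write_sidecar <- function(path, fs_hz, layout, wavelengths_nm = NULL) {
  meta <- list(fs_hz = fs_hz,
               channel_ids = layout$channel_ids,
               hemisphere_of = as.list(layout$hemisphere_of),
               source_detector_distance_cm = layout$source_detector_distance_cm)
  if (!is.null(wavelengths_nm)) meta$wavelengths_nm <- wavelengths_nm
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
}

.read_sidecar <- function(path) {
  sc <- .sidecar_path(path)
  if (!file.exists(sc)) stop("missing sidecar file ", sc, call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  layout <- channel_layout(meta$channel_ids, unlist(meta$hemisphere_of),
                           meta$source_detector_distance_cm %||% 3.0)
  list(fs_hz = meta$fs_hz, layout = layout,
       wavelengths_nm = meta$wavelengths_nm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_numeric_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(df) < 1L || is.null(names(df)) || any(names(df) == "")) {
    stop("missing or malformed header row in ", path, call. = FALSE)
  }
  bad <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(bad)) {
    stop("non-numeric cells in column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  as.matrix(df)
}

#' Read a record from disk
#'
#' @param path CSV file written by [write_record()] (or compatible); a
#'   JSON sidecar `<path>.json` must accompany it.
#' @param kind `"hemodynamic"` or `"optical_density"`.
#' @return A [hemodynamic_record()] or [optical_density_record()].
#' @export
read_record <- function(path, kind = c("hemodynamic", "optical_density")) {
  kind <- match.arg(kind)
  meta <- .read_sidecar(path)
  mat <- .read_numeric_csv(path)
  ids <- meta$layout$channel_ids
  if (kind == "hemodynamic") {
    want <- c(paste0("hbo_ch", ids), paste0("hbr_ch", ids))
    miss <- setdiff(want, colnames(mat))
    if (length(miss)) stop("missing column(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    if (ncol(mat) != length(want)) {
      stop("file has ", ncol(mat), " columns but the layout implies ",
           length(want), call. = FALSE)
    }
    n <- length(ids)
    hemodynamic_record(hbo = mat[, want[seq_len(n)], drop = FALSE],
                       hbr = mat[, want[n + seq_len(n)], drop = FALSE],
                       fs_hz = meta$fs_hz, layout = meta$layout)
  } else {
    if (is.null(meta$wavelengths_nm)) {
      stop("sidecar lacks wavelengths_nm for an optical-density record",
           call. = FALSE)
    }
    wl <- meta$wavelengths_nm
    want <- as.vector(t(outer(ids, wl, function(ch, w)
      sprintf("od_ch%d_%gnm", ch, w))))
    miss <- setdiff(want, colnames(mat))
    if (length(miss)) stop("missing column(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    optical_density_record(od = mat[, want, drop = FALSE],
                           wavelengths_nm = wl, fs_hz = meta$fs_hz,
                           layout = meta$layout)
  }
}

#' Write a record to disk
#'
#' Writes the data matrix as CSV (HbO channels 1..N then HbR channels
#' 1..N, or channel-major wavelength columns for optical density) and the
#' metadata as a JSON sidecar.  Values are written with 15 significant
#' digits, enough for a 1e-12-relative round trip.
#'
#' @param record A [hemodynamic_record()] or [optical_density_record()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop("cannot write to ", path, ": directory does not exist",
                    call. = FALSE)
  if (inherits(record, "hemodynamic_record")) {
    mat <- cbind(record$hbo, record$hbr)
    .write_sidecar(path, record$fs_hz, record$layout)
  } else if (inherits(record, "optical_density_record")) {
    mat <- record$od
    .write_sidecar(path, record$fs_hz, record$layout,
                   record$wavelengths_nm)
  } else {
    stop("record must be a hemodynamic or optical-density record",
         call. = FALSE)
  }
  df <- as.data.frame(signif(mat, 15))
  names(df) <- colnames(mat)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read trial onsets and labels
#'
#' @param onsets_s Numeric onsets in seconds.
#' @param labels Parallel trial labels.
#' @param path Output CSV path.
#' @return `path` (write) or a list with `onsets_s`, `labels` (read).
#' @export
write_events <- function(onsets_s, labels, path) {
  utils::write.csv(data.frame(onset_s = onsets_s,
                              label = as.character(labels)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("onset_s", "label") %in% names(df))) {
    stop("events file needs columns onset_s and label", call. = FALSE)
  }
  list(onsets_s = df$onset_s,
       labels = factor(df$label, levels = task_levels()))
}
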