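# File interfaces: 16-bit multi-page TIFF video stacks with JSON sidecars,
# trace/series CSV export.  Camera counts are stored as integers in
# [0, 65535]; the TIFF round trip is bit-identical for such stacks.

#' Write a video stack as a 16-bit multi-page TIFF
#'
#' @param stack A [video_stack()] whose intensities are integers in
#'   `[0, 65535]` (as produced by [generate_video()]).
#' @param path Output TIFF path.
#' @param sidecar Optional list (e.g. ground truth and configuration) written
#'   as JSON next to the TIFF (same path, `.json` extension).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, sidecar = NULL) {
  stopifnot(inherits(stack, "video_stack"))
  fr <- stack$frames
  if (any(fr < 0 | fr > 65535) || any(fr != round(fr)))
    stop("frames must hold 16-bit integer counts in [0, 65535]")
  pages <- lapply(seq_len(dim(fr)[3]), function(i) fr[, , i] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  if (!is.null(sidecar)) {
    jsonlite::write_json(sidecar, sub("\\.tiff?$", ".json", path,
                                      ignore.case = TRUE),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a multi-page TIFF into a video stack
#'
#' @param path TIFF path.
#' @param frame_rate_hz Acquisition rate, frames/s (TIFF carries no timing).
#' @param pixel_size_mm Pixel pitch, mm/pixel, optional.
#' @param polarity Signal polarity, `"up"`, `"down"` or `"auto"` (default).
#' @return A [video_stack()] with intensities restored to integer counts.
#' @export
read_stack <- function(path, frame_rate_hz, pixel_size_mm = NULL,
                       polarity = "auto") {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("unreadable TIFF: ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1)
    stop("inconsistent page shapes in ", path)
  frames <- array(unlist(pages, use.names = FALSE),
                  dim = c(dims[[1]][1], dims[[1]][2], length(pages)))
  video_stack(round(frames * 65535), frame_rate_hz, pixel_size_mm, polarity)
}

#' Export a trace as CSV (time_s, dff)
#'
#' @param trace A [ca_trace] object (see [condition_trace()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$time_s, dff = trace$dff),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a perfusion series as CSV
#'
#' Columns `time_day, conc_mM, cells_per_ml` (header row required on read).
#'
#' @param series A [perfusion_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_perfusion_csv <- function(series, path) {
  utils::write.csv(data.frame(time_day = series$t_day, conc_mM = series$conc_mM,
                              cells_per_ml = series$cells_per_ml),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a perfusion series from CSV
#'
#' @param path CSV with header `time_day, conc_mM, cells_per_ml`.
#' @param cin_mM Feed (inlet) concentration, mM.
#' @param dilution_per_day Dilution rate, 1/day.
#' @return A [perfusion_series()].
#' @export
read_perfusion_csv <- function(path, cin_mM, dilution_per_day) {
  df <- utils::read.csv(path)
  need <- c("time_day", "conc_mM", "cells_per_ml")
  if (!all(need %in% names(df)))
    stop("perfusion CSV must have columns: ", paste(need, collapse = ", "))
  perfusion_series(df$time_day, df$conc_mM, df$cells_per_ml,
                   cin_mM = cin_mM, dilution_per_day = dilution_per_day)
}
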