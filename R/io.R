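#' Read and write confounds tables
#'
#' Tab-separated, columns `trans_x..rot_z` plus `framewise_displacement`
#' (first volume 0).
#'
#' @param scan a `scan_record` (or a list with `realignment_params` and
#'   `fd_series`).
#' @param path file path.
#' @return `read_confounds()` returns a list with `realignment_params`
#'   (matrix) and `fd_series`.
#' @export
write_confounds <- function(scan, path) {
  df <- as.data.frame(scan$realignment_params)
  df$framewise_displacement <- scan$fd_series
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_confounds
#' @export
read_confounds <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  rp_cols <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  assert_that(all(c(rp_cols, "framewise_displacement") %in% names(df)),
              "confounds file is missing required columns")
  list(realignment_params = as.matrix(df[, rp_cols]),
       fd_series = df$framewise_displacement)
}

#' Read and write ROI timeseries tables
#'
#' CSV, one row per volume, one column per ROI, header mandatory.
#' @param ts tibble/data.frame of ROI timeseries.
#' @param path file path.
#' @export
write_roi_timeseries <- function(ts, path) {
  readr::write_csv(tibble::as_tibble(ts), path)
  invisible(path)
}

#' @rdname write_roi_timeseries
#' @export
read_roi_timeseries <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  assert_that(ncol(out) >= 1, "empty ROI timeseries file")
  out
}
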