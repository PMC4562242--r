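#' Read and write event tables (BIDS-events dialect)
#'
#' Events are stored as tab-separated tables with columns `onset`, `duration`,
#' `trial_type`, `run`, `responded`, `correct`; in memory the condition column
#' is called `condition`.
#'
#' @param events Event tibble.
#' @param path File path.
#' @return `write_events_tsv` returns `path` invisibly; `read_events_tsv`
#'   returns the event tibble.
#' @export
write_events_tsv <- function(events, path) {
  out <- dplyr::rename(events, trial_type = "condition")
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  dplyr::rename(ev, condition = "trial_type")
}

#' Read and write motion parameters (6-column whitespace text)
#'
#' @param motion Volumes x 6 numeric matrix.
#' @param path File path.
#' @return `write_motion_par` returns `path` invisibly; `read_motion_par`
#'   returns the matrix.
#' @export
write_motion_par <- function(motion, path) {
  utils::write.table(motion, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_par
#' @export
read_motion_par <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- list(NULL, c("trans_x", "trans_y", "trans_z",
                              "rot_x", "rot_y", "rot_z"))
  m
}

#' Read and write volumes as NIfTI-1
#'
#' Thin wrappers around RNifti keeping the rest of the package array-based.
#'
#' @param vol 3D or 4D numeric array (or logical for masks).
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   plain array.
#' @export
write_volume <- function(vol, path) {
  RNifti::writeNifti(RNifti::asNifti(vol + 0), path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim = dim(img))
}
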