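#' Read a BIDS-style events TSV into a stimulus schedule
#'
#' Expects a tab-separated file with header columns `onset`, `duration`,
#' `trial_type` (seconds, `.` decimal). Onsets must be strictly
#' increasing, as schedules are ordered.
#'
#' @param path file path.
#' @param session_id,session_duration optional metadata to attach; the
#'   duration defaults to the last onset plus 6 s when absent.
#' @return a `stim_schedule` data frame.
#' @export
read_events_tsv <- function(path, session_id = NA,
                            session_duration = NULL) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stopf("%s: line 1: missing column(s) %s", path,
          paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) > 1 && any(diff(df$onset) <= 0)) {
    bad <- which(diff(df$onset) <= 0)[1] + 1
    stopf("%s: line %d: onsets must be strictly increasing", path,
          bad + 1) # +1 for the header line
  }
  df <- df[, need]
  attr(df, "session_id") <- session_id
  attr(df, "session_duration") <-
    session_duration %||% (df$onset[nrow(df)] + 6)
  class(df) <- c("stim_schedule", "data.frame")
  df
}

#' Write a stimulus schedule as a BIDS-style events TSV
#'
#' @param schedule a `stim_schedule` data frame.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_events_tsv <- function(schedule, path) {
  utils::write.table(
    schedule[, c("onset", "duration", "trial_type")], path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 4-D NIfTI-1 file as an fMRI volume series
#'
#' The TR is taken from the time-dimension pixdim; voxel sizes and the
#' spatial transform come from the header.
#'
#' @param path NIfTI file path.
#' @param subject_id,session_id optional metadata.
#' @return an [fmri_series()] object.
#' @export
read_fmri_nifti <- function(path, subject_id = NA, session_id = NA) {
  img <- RNifti::readNifti(path)
  a <- array(as.vector(img), dim = dim(img)) # plain array, no handles
  if (length(dim(a)) != 4) {
    stopf("%s: expected a 4-D volume series, got %d dimension(s)", path,
          length(dim(a)))
  }
  pd <- RNifti::pixdim(img)
  fmri_series(a, voxel_size = pd[1:3], TR = pd[4],
              affine = unclass(RNifti::xform(img)),
              subject_id = subject_id, session_id = session_id)
}

# build an RNifti image carrying voxel sizes, TR and affine
as_nifti_image <- function(data, voxel_size, TR = NULL, affine = NULL) {
  nd <- length(dim(data))
  pix <- c(voxel_size, if (nd >= 4) TR %||% 1)
  hdr <- RNifti::niftiHeader(list(
    dim = c(nd, dim(data), rep(1, 7 - nd)),
    pixdim = c(-1, pix, rep(0, 7 - length(pix)))))
  img <- RNifti::asNifti(data, reference = hdr)
  if (!is.null(affine)) {
    RNifti::sform(img) <- structure(affine, code = 2L)
  }
  img
}

#' Write an fMRI volume series or a 3-D map as NIfTI-1
#'
#' Volume series write their TR into the time-dimension pixdim; values are
#' stored as 64-bit floats so round trips are exact.
#'
#' @param x an [fmri_series()] object or a 3-D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size,affine geometry for bare arrays (ignored for
#'   `fmri_series` input).
#' @return the path, invisibly.
#' @export
write_fmri_nifti <- function(x, path, voxel_size = c(3, 3, 3),
                             affine = NULL) {
  if (inherits(x, "fmri_series")) {
    img <- as_nifti_image(x$data, x$voxel_size, x$TR, x$affine)
  } else {
    img <- as_nifti_image(x, voxel_size, affine = affine)
  }
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a 3-D NIfTI map
#'
#' @param path NIfTI file path.
#' @return list with `data` (3-D array), `voxel_size`, `affine`.
#' @export
read_map_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  a <- array(as.vector(img), dim = dim(img))
  if (length(dim(a)) != 3) {
    stopf("%s: expected a 3-D map, got %d dimension(s)", path,
          length(dim(a)))
  }
  list(data = a, voxel_size = RNifti::pixdim(img)[1:3],
       affine = unclass(RNifti::xform(img)))
}

#' Write an EEG recording as a flat binary array with a JSON sidecar
#'
#' Samples are stored as little-endian 64-bit floats, channel-major
#' (channel fastest), with shape, sampling rate and labels in
#' `<prefix>.json`.
#'
#' @param recording an [eeg_recording()] object.
#' @param prefix output path prefix (writes `<prefix>.dat` and
#'   `<prefix>.json`).
#' @return the prefix, invisibly.
#' @export
write_eeg_bin <- function(recording, prefix) {
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(recording$data), con, size = 8, endian = "little")
  meta <- list(fs = recording$fs,
               channel_labels = recording$channel_labels,
               n_channels = nrow(recording$data),
               n_samples = ncol(recording$data),
               subject_id = recording$subject_id,
               session_id = recording$session_id,
               dtype = "float64le", order = "channel-major")
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read an EEG recording written by [write_eeg_bin()]
#'
#' @param prefix path prefix used at write time.
#' @return an [eeg_recording()] object.
#' @export
read_eeg_bin <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  con <- file(paste0(prefix, ".dat"), "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = meta$n_channels * meta$n_samples,
               size = 8, endian = "little")
  eeg_recording(matrix(x, meta$n_channels, meta$n_samples),
                as.numeric(meta$fs), meta$channel_labels,
                meta$subject_id, meta$session_id)
}
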