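#' Flag low-motion frames from a framewise displacement trace
#'
#' A frame is retained iff its FD is strictly below the threshold (the
#' inclusion rule is "FD < threshold"; equality censors).
#'
#' @param fd Nonnegative numeric vector of per-frame FD in mm.
#' @param threshold FD threshold in mm.
#' @return Logical vector, TRUE = retain.
#' @export
flag_frames <- function(fd, threshold) {
  if (any(fd < 0)) stop("FD values must be nonnegative")
  if (threshold <= 0) stop("threshold must be positive")
  fd < threshold
}

#' Censor retained runs shorter than a contiguity minimum
#'
#' Any maximal run of retained frames shorter than `min_contig` is censored;
#' no frame is ever un-censored. Idempotent.
#'
#' @param retain Logical retain vector.
#' @param min_contig Minimum retained run length in frames.
#' @return Logical vector.
#' @export
enforce_contiguity <- function(retain, min_contig) {
  stopifnot(is.logical(retain), min_contig >= 1)
  r <- rle(retain)
  r$values[r$values & r$lengths < min_contig] <- FALSE
  inverse.rle(r)
}

#' Build a censor mask from an FD trace
#'
#' Applies [flag_frames()] then [enforce_contiguity()].
#'
#' @param fd FD trace in mm.
#' @param fd_threshold FD threshold in mm.
#' @param min_contig Minimum retained run length; 1 disables the rule.
#' @return Logical retain vector with attributes `fd_threshold`,
#'   `min_contig`.
#' @export
censor_mask <- function(fd, fd_threshold, min_contig = 1L) {
  retain <- enforce_contiguity(flag_frames(fd, fd_threshold), min_contig)
  attr(retain, "fd_threshold") <- fd_threshold
  attr(retain, "min_contig") <- min_contig
  retain
}

#' Does a subject meet the minimum retained-frame criterion?
#'
#' @param retain Logical retain vector (after contiguity enforcement).
#' @param min_retained Minimum number of retained frames for inclusion.
#' @return TRUE iff the retained frame count is >= `min_retained`.
#' @export
subject_included <- function(retain, min_retained) {
  sum(retain) >= min_retained
}

#' Denoising chain configuration
#'
#' Defaults mirror the processing rules applied to the real acquisitions: a
#' 0.3 mm FD mask drives interpolation and regression, the final analysis
#' mask censors at 0.2 mm with a 5-contiguous-frame rule, subjects need
#' 600 retained frames, and the pass-band is 0.008-0.10 Hz.
#'
#' @param process_fd_threshold FD threshold (mm) for the processing mask.
#' @param final_fd_threshold FD threshold (mm) for the final analysis mask.
#' @param min_contig Contiguity minimum (frames), applied at the final mask.
#' @param min_retained Minimum retained frames for subject inclusion.
#' @param band Pass-band in Hz, `c(low, high)`.
#' @return A `denoise_config` list.
#' @export
denoise_config <- function(process_fd_threshold = 0.3,
                           final_fd_threshold = 0.2,
                           min_contig = 5L,
                           min_retained = 600L,
                           band = c(0.008, 0.10)) {
  stopifnot(process_fd_threshold > 0, final_fd_threshold > 0,
            min_contig >= 1, length(band) == 2,
            band[1] > 0, band[1] < band[2])
  structure(
    list(process_fd_threshold = process_fd_threshold,
         final_fd_threshold = final_fd_threshold,
         min_contig = as.integer(min_contig),
         min_retained = as.integer(min_retained),
         band = band),
    class = "denoise_config"
  )
}
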