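# Preprocessing: onset alignment, fixed-length cropping, dataset-global
# normalization. Recordings are cropped to 120 samples (4 s at 30 Hz) and the
# whole dataset is scaled by its single maximum force value so that profiles
# from different subjects share one normalized amplitude scale.

#' Align a raw recording to its force onset and crop to fixed length
#'
#' The onset is the first sample exceeding `onset_fraction` times the
#' recording's own maximum; the output is `target_len` samples starting at the
#' onset, copied bit-exactly (no resampling or filtering). The default length,
#' 120 samples at 30 Hz, is the 4 s analysis window used throughout.
#'
#' @param r A [force_profile()] (raw recording, any length).
#' @param target_len Number of samples to keep (default 120).
#' @param onset_fraction Onset threshold as a fraction of the per-recording
#'   maximum (default 0.10).
#' @return A [force_profile()] of exactly `target_len` samples.
#' @examples
#' rec <- force_profile(c(rep(0, 30), rep(1, 170)))
#' length(align_and_crop(rec)$samples)
#' @export
align_and_crop <- function(r, target_len = 120, onset_fraction = 0.10) {
  stopifnot(inherits(r, "force_profile"))
  if (!is.numeric(target_len) || length(target_len) != 1 || target_len < 1) {
    stop("target_len must be a positive count")
  }
  if (onset_fraction < 0 || onset_fraction > 1) {
    stop("onset_fraction must lie in [0, 1]")
  }
  peak <- max(r$samples)
  if (peak <= 0) stop("recording has no positive samples: onset undefined")
  onset <- which(r$samples > onset_fraction * peak)[1]
  avail <- length(r$samples) - onset + 1
  if (avail < target_len) {
    stop(sprintf(
      "recording too short after onset at sample %d: %d samples available, %d required (deficit %d)",
      onset, avail, target_len, target_len - avail))
  }
  force_profile(r$samples[onset:(onset + target_len - 1)], rate = r$rate,
                normalized = r$normalized, label = r$label)
}

#' Normalize a set of force profiles to the dataset-global maximum
#'
#' Every sample in every profile is divided by the single largest force value
#' across the whole dataset, so the global maximum maps to exactly 1 and every
#' per-profile maximum is at most 1. The scaling constant is returned so that
#' quantities derived from normalized data (e.g. fitted velocity levels) can
#' be mapped back to the original scale, and so that simulated and measured
#' data can share a scale.
#'
#' @param profiles A list of [force_profile()] objects (at least one), with at
#'   least one strictly positive sample among them.
#' @return A list with elements `profiles` (the normalized profiles, flagged
#'   `normalized = TRUE`) and `constant` (the global maximum that was divided
#'   out). Normalizing an already-normalized output again is the identity
#'   (constant 1).
#' @examples
#' ps <- list(force_profile(c(0, 2)), force_profile(c(1, 4)))
#' nd <- normalize_dataset(ps)
#' nd$constant                      # 4
#' sapply(nd$profiles, function(p) max(p$samples))
#' @export
normalize_dataset <- function(profiles) {
  if (inherits(profiles, "force_profile")) profiles <- list(profiles)
  if (!is.list(profiles) || length(profiles) == 0 ||
      !all(vapply(profiles, inherits, logical(1), "force_profile"))) {
    stop("profiles must be a non-empty list of force_profile objects")
  }
  const <- max(vapply(profiles, function(p) max(p$samples), numeric(1)))
  if (const <= 0) stop("dataset-global maximum is not positive: cannot normalize")
  out <- lapply(profiles, function(p) {
    force_profile(p$samples / const, rate = p$rate, normalized = TRUE,
                  label = p$label)
  })
  list(profiles = out, constant = const)
}
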