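#' Channel layout
#'
#' Describes the probe montage: which measurement channels sit over the
#' right (C4) and left (C3) motor cortex.  The default 34-channel montage
#' places channels 1-17 over C4 and 18-34 over C3, so right-hand movement
#' (contralateral C3) activates channels 18-34 and left-hand movement
#' activates channels 1-17.
#'
#' @param channel_ids Integer channel identifiers (unique).
#' @param hemisphere_of Character vector (values "C3"/"C4") named by
#'   channel id, one entry per channel.
#' @param source_detector_distance_cm Optode separation in cm; default 3.
#' @return A `channel_layout`.
#' @export
channel_layout <- function(channel_ids,
                           hemisphere_of,
                           source_detector_distance_cm = 3.0) {
  channel_ids <- as.integer(channel_ids)
  if (anyDuplicated(channel_ids)) stop("channel ids must be unique",
                                       call. = FALSE)
  if (length(channel_ids) < 1L) stop("at least one channel is required",
                                     call. = FALSE)
  hemisphere_of <- unlist(hemisphere_of)
  if (!setequal(names(hemisphere_of), as.character(channel_ids)) ||
      length(hemisphere_of) != length(channel_ids)) {
    stop("hemisphere_of must map every channel id to exactly one hemisphere",
         call. = FALSE)
  }
  if (!all(hemisphere_of %in% c("C3", "C4"))) {
    stop("hemispheres must be 'C3' or 'C4'", call. = FALSE)
  }
  if (source_detector_distance_cm <= 0) {
    stop("source_detector_distance_cm must be positive", call. = FALSE)
  }
  structure(list(channel_ids = sort(channel_ids),
                 hemisphere_of = hemisphere_of[as.character(sort(channel_ids))],
                 source_detector_distance_cm = source_detector_distance_cm),
            class = "channel_layout")
}

#' Default motor-cortex montage
#'
#' @param n_channels Number of channels (default 34).  The first half
#'   (channels 1-17 for 34) is assigned to C4, the rest to C3.
#' @param source_detector_distance_cm Optode separation in cm.
#' @return A [channel_layout()].
#' @export
default_layout <- function(n_channels = 34L,
                           source_detector_distance_cm = 3.0) {
  n_channels <- as.integer(n_channels)
  ids <- seq_len(n_channels)
  half <- ceiling(n_channels / 2)
  hemi <- stats::setNames(ifelse(ids <= half, "C4", "C3"), ids)
  channel_layout(ids, hemi, source_detector_distance_cm)
}

#' Channels over a hemisphere
#'
#' @param layout A [channel_layout()].
#' @param hemisphere "C3" or "C4".
#' @return Integer channel ids.
#' @export
channels_over <- function(layout, hemisphere) {
  stopifnot(inherits(layout, "channel_layout"),
            hemisphere %in% c("C3", "C4"))
  layout$channel_ids[layout$hemisphere_of == hemisphere]
}
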