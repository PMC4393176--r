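#' Per-segment radial displacement field
#'
#' Container for the speckle-tracking-style output the dyskinesia
#' analysis consumes: an M x N matrix of mean radial endocardial
#' displacement (mm, inward positive) for M angular segments over N
#' time points, together with the frame times (fraction of cycle) and
#' the reference frame relative to which displacement is measured.
#' The reference column is identically zero by construction.
#'
#' @param d numeric M x N matrix of displacements, mm, inward positive.
#' @param frame_times strictly increasing times in \[0, 1), length N.
#' @param reference_frame column index of the reference (typically
#'   end-diastolic) frame.
#' @return object of class `displacement_field`.
#' @seealso [efficiency_series()], [dyskinesia_index()],
#'   [segment_radial_displacements()]
#' @export
displacement_field <- function(d, frame_times = NULL, reference_frame = 1L) {
  stop_if(!is.matrix(d) || !is.numeric(d), "d must be a numeric matrix")
  stop_if(nrow(d) < 2, "need at least 2 segments, got %d", nrow(d))
  stop_if(ncol(d) < 2, "need at least 2 frames, got %d", ncol(d))
  stop_if(any(!is.finite(d)), "displacements must be finite everywhere")
  if (is.null(frame_times)) frame_times <- seq(0, ncol(d) - 1) / ncol(d)
  stop_if(length(frame_times) != ncol(d),
          "frame_times length (%d) must match frame count (%d)",
          length(frame_times), ncol(d))
  stop_if(any(diff(frame_times) <= 0) || frame_times[1] < 0 ||
            frame_times[length(frame_times)] >= 1,
          "frame_times must be strictly increasing within [0, 1)")
  stop_if(!is_count(reference_frame, 1) || reference_frame > ncol(d),
          "reference_frame out of range")
  stop_if(any(d[, reference_frame] != 0),
          "reference-frame column must be identically zero")
  structure(
    list(d = unname(d),
         n_segments = nrow(d),
         frame_times = as.numeric(frame_times),
         reference_frame = as.integer(reference_frame)),
    class = "displacement_field"
  )
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf(
    "Radial displacement field: %d segments x %d frames (reference frame %d)\n",
    x$n_segments, ncol(x$d), x$reference_frame))
  rng <- range(x$d)
  cat(sprintf("  displacement range [%.3f, %.3f] mm (inward positive)\n",
              rng[1], rng[2]))
  invisible(x)
}
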