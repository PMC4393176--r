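# Geometric replacement for the proprietary speckle tracker: mean
# radial endocardial displacement per angular segment, sampled by ray
# casting from a fixed end-diastolic centroid.

#' Per-segment radial displacements from a contour cine
#'
#' Computes the displacement table a speckle tracker would export, from
#' the traced endocardial contours of one short-axis slice:
#'
#' 1. the centroid of the reference (end-diastolic) frame is fixed as
#'    the origin for all frames — a per-frame centroid would absorb the
#'    translation of a bulging wall and mask dyskinesia;
#' 2. each frame's radius is sampled along `rays_per_segment` rays per
#'    angular segment (equal angular bins, CCW from +x, segment 1
#'    starting at angle 0);
#' 3. a segment's radius is the mean over its rays;
#' 4. displacement `d[i, t] = r_ref[i] - r_t[i]`, so inward motion is
#'    positive.
#'
#' Contours must be star-shaped about the reference centroid (true for
#' LV short-axis anatomy); a violation is an error naming the frame,
#' not a silent repair.
#'
#' @param slice_frames list of endocardial contours (n x 2 vertex
#'   matrices), one per frame, or one slice of a `cine_stack`.
#' @param n_segments number of angular segments (>= 2; 96 matches the
#'   instrument convention).
#' @param reference_frame index of the reference frame; default is the
#'   end-diastolic frame, detected as the frame of maximal area.
#' @param rays_per_segment radius samples per segment (>= 4).
#' @param frame_times optional frame times in \[0, 1).
#' @return a [displacement_field()].
#' @examples
#' stack <- simulate_cine_stack(motion_params(n_slices = 2))
#' f <- segment_radial_displacements(stack$slices[[1]])
#' dim(f$d)  # 96 x 35
#' @export
segment_radial_displacements <- function(slice_frames, n_segments = 96,
                                         reference_frame = NULL,
                                         rays_per_segment = 4,
                                         frame_times = NULL) {
  frames <- extract_endo_frames(slice_frames)
  stop_if(length(frames) < 2, "need at least 2 frames")
  stop_if(!is_count(n_segments, 2), "n_segments must be an integer >= 2")
  stop_if(!is_count(rays_per_segment, 4),
          "rays_per_segment must be an integer >= 4")
  frames <- lapply(frames, as_polygon)
  if (is.null(reference_frame)) {
    areas <- vapply(frames, contour_area, numeric(1))
    reference_frame <- which.max(areas)
  }
  stop_if(!is_count(reference_frame, 1) ||
            reference_frame > length(frames), "reference_frame out of range")
  center <- contour_centroid(frames[[reference_frame]])
  K <- rays_per_segment
  # rays at segment-interior angles, K per segment, segment 1 from 0
  angles <- (seq_len(n_segments * K) - 0.5) * 2 * pi / (n_segments * K)
  seg <- rep(seq_len(n_segments), each = K)
  radii <- vapply(seq_along(frames), function(t) {
    r <- polygon_radii(frames[[t]], angles, center,
                       what = sprintf("frame %d", t))
    as.numeric(tapply(r, seg, mean))
  }, numeric(n_segments))
  d <- radii[, reference_frame] - radii
  d[, reference_frame] <- 0  # exact zero, not r - r round-off
  displacement_field(d, frame_times = frame_times,
                     reference_frame = reference_frame)
}

# Accept either a bare list of contours or one slice of a cine_stack
# (frames as list(endo =, epi =)).
extract_endo_frames <- function(slice_frames) {
  stop_if(!is.list(slice_frames), "slice_frames must be a list of contours")
  lapply(slice_frames, function(f) {
    if (is.list(f) && !is.null(f$endo)) f$endo else f
  })
}
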