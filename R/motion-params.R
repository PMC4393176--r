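#' Generative parameters for the synthetic LV motion phantom
#'
#' Bundles and validates the parameters that define a synthetic mouse
#' left-ventricular short-axis phantom: chamber geometry, per-segment
#' systolic excursion, stack layout, measurement noise and the random
#' seed. Defaults emulate a murine acquisition: 96 angular segments,
#' 35 frames per cardiac cycle, 6 short-axis slices at 1.0 mm spacing,
#' a 1.5 mm end-diastolic endocardial radius and a 1.0 mm end-diastolic
#' wall.
#'
#' Sign convention (used everywhere in the package): positive amplitude
#' and positive radial displacement mean *inward* (contractile) motion;
#' negative amplitude is outward, dyskinetic bulging.
#'
#' @param n_segments number of angular segments (>= 2).
#' @param n_frames frames per cardiac cycle (>= 3).
#' @param amplitudes per-segment peak radial excursion in mm, signed
#'   (inward positive). A scalar is recycled to all segments.
#' @param base_radius end-diastolic endocardial radius of the basal
#'   slice, mm.
#' @param wall_thickness_ed end-diastolic wall thickness, mm.
#' @param n_slices number of short-axis slices, apex to base.
#' @param slice_spacing inter-slice distance, mm.
#' @param apex_taper fractional reduction of `base_radius` per slice
#'   toward the apex (linear in slice index).
#' @param noise_sd standard deviation of additive radial measurement
#'   noise, mm (0 = noiseless).
#' @param seed integer seed for the phantom's noise stream, or `NULL`.
#' @param es_fraction fraction of the cycle at which end-systole occurs
#'   (peak of the systolic waveform).
#' @param verts_per_segment endocardial vertices sampled per angular
#'   segment (>= 4 gives faithful sector-mean radii).
#' @param thin_factor multiplier applied to `wall_thickness_ed` over
#'   segments with negative (dyskinetic) amplitude; 1 = no thinning.
#' @param with_epi if `TRUE`, simulated cine stacks carry a matching
#'   epicardial contour per frame.
#'
#' @return An object of class `motion_params` (a validated list).
#' @seealso [simulate_displacement_field()], [simulate_cine_stack()],
#'   [analytic_di()]
#' @examples
#' p <- motion_params(amplitudes = dyskinetic_amplitudes(96, 14))
#' analytic_di(p)
#' @export
motion_params <- function(n_segments = 96, n_frames = 35,
                          amplitudes = 0.4, base_radius = 1.5,
                          wall_thickness_ed = 1.0, n_slices = 6,
                          slice_spacing = 1.0, apex_taper = 0.08,
                          noise_sd = 0, seed = NULL,
                          es_fraction = 0.4, verts_per_segment = 4,
                          thin_factor = 1, with_epi = TRUE) {
  stop_if(!is_count(n_segments, 2), "n_segments must be an integer >= 2")
  stop_if(!is_count(n_frames, 3), "n_frames must be an integer >= 3")
  stop_if(!is_number(base_radius) || base_radius <= 0,
          "base_radius must be > 0")
  stop_if(!is_number(wall_thickness_ed) || wall_thickness_ed <= 0,
          "wall_thickness_ed must be > 0")
  stop_if(!is_count(n_slices, 1), "n_slices must be an integer >= 1")
  stop_if(!is_number(slice_spacing) || slice_spacing <= 0,
          "slice_spacing must be > 0")
  stop_if(!is_number(apex_taper) || apex_taper < 0 ||
            apex_taper * (n_slices - 1) >= 1,
          "apex_taper must be in [0, 1/(n_slices-1))")
  stop_if(!is_number(noise_sd) || noise_sd < 0, "noise_sd must be >= 0")
  stop_if(!is_number(es_fraction) || es_fraction <= 0 || es_fraction >= 1,
          "es_fraction must be in (0, 1)")
  stop_if(!is_count(verts_per_segment, 4),
          "verts_per_segment must be an integer >= 4")
  stop_if(!is_number(thin_factor) || thin_factor <= 0,
          "thin_factor must be > 0")
  stop_if(!is.numeric(amplitudes) || anyNA(amplitudes),
          "amplitudes must be numeric and finite")
  if (length(amplitudes) == 1L) amplitudes <- rep(amplitudes, n_segments)
  stop_if(length(amplitudes) != n_segments,
          "amplitudes must have length 1 or n_segments (%d), got %d",
          n_segments, length(amplitudes))
  stop_if(any(abs(amplitudes) >= base_radius),
          "|amplitudes| must be < base_radius (%.3f mm): contour would self-invert",
          base_radius)
  if (!is.null(seed)) {
    stop_if(!is_count(seed, 0), "seed must be a non-negative integer")
  }
  structure(
    list(n_segments = as.integer(n_segments),
         n_frames = as.integer(n_frames),
         amplitudes = as.numeric(amplitudes),
         base_radius = base_radius,
         wall_thickness_ed = wall_thickness_ed,
         n_slices = as.integer(n_slices),
         slice_spacing = slice_spacing,
         apex_taper = apex_taper,
         noise_sd = noise_sd,
         seed = seed,
         es_fraction = es_fraction,
         verts_per_segment = as.integer(verts_per_segment),
         thin_factor = thin_factor,
         with_epi = isTRUE(with_epi)),
    class = "motion_params"
  )
}

#' @export
print.motion_params <- function(x, ...) {
  n_dys <- sum(x$amplitudes < 0)
  cat(sprintf(
    "LV motion phantom parameters\n  %d segments x %d frames, %d slices @ %.2f mm\n",
    x$n_segments, x$n_frames, x$n_slices, x$slice_spacing))
  cat(sprintf("  ED radius %.2f mm (apex taper %.2f/slice), wall %.2f mm\n",
              x$base_radius, x$apex_taper, x$wall_thickness_ed))
  cat(sprintf("  amplitudes: %d inward, %d dyskinetic; noise SD %.3f mm\n",
              x$n_segments - n_dys, n_dys, x$noise_sd))
  invisible(x)
}

#' Build an amplitude vector with a contiguous dyskinetic sector
#'
#' Convenience constructor for the common phantom configuration: inward
#' contraction everywhere except a contiguous angular sector that bulges
#' outward during systole (the infarct-zone pattern).
#'
#' @param n_segments total segments.
#' @param n_dyskinetic number of contiguous dyskinetic segments
#'   (starting at segment 1).
#' @param inward inward amplitude, mm, for healthy segments (positive).
#' @param outward outward excursion, mm, for dyskinetic segments
#'   (stored as a negative amplitude).
#' @return numeric vector of signed amplitudes, length `n_segments`.
#' @examples
#' a <- dyskinetic_amplitudes(96, 24, inward = 0.4, outward = 0.3)
#' sum(a < 0)
#' @export
dyskinetic_amplitudes <- function(n_segments = 96, n_dyskinetic = 0,
                                  inward = 0.4, outward = inward) {
  stop_if(!is_count(n_segments, 2), "n_segments must be an integer >= 2")
  stop_if(!is_count(n_dyskinetic, 0) || n_dyskinetic > n_segments,
          "n_dyskinetic must be in 0..n_segments")
  stop_if(inward <= 0 || outward <= 0,
          "inward and outward are magnitudes and must be > 0")
  amp <- rep(inward, n_segments)
  if (n_dyskinetic > 0) amp[seq_len(n_dyskinetic)] <- -outward
  amp
}

#' Systolic excursion waveform
#'
#' Raised-cosine contraction profile over one cardiac cycle: 0 at
#' end-diastole (t = 0), rising smoothly to 1 at end-systole
#' (`es_fraction` of the cycle) and relaxing back to 0 at t = 1.
#' Frame-to-frame smoothness avoids spurious discretization artifacts
#' in displacement tracks; any shared waveform cancels out of the
#' dyskinesia index in the noiseless case, so the shape does not bias
#' oracle comparisons.
#'
#' @param t time as fraction of cycle, in \[0, 1\].
#' @param es_fraction end-systolic time fraction, in (0, 1).
#' @return waveform value(s) in \[0, 1\].
#' @export
systolic_waveform <- function(t, es_fraction = 0.4) {
  stop_if(!is_number(es_fraction) || es_fraction <= 0 || es_fraction >= 1,
          "es_fraction must be in (0, 1)")
  stop_if(any(t < 0 | t > 1), "t must lie in [0, 1]")
  up <- t <= es_fraction
  s <- numeric(length(t))
  s[up] <- 0.5 * (1 - cos(pi * t[up] / es_fraction))
  s[!up] <- 0.5 * (1 - cos(pi * (1 - t[!up]) / (1 - es_fraction)))
  s
}
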