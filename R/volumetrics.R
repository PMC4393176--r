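# 3D LV volumetrics by short-axis disc summation, with per-slice
# end-diastole/end-systole detection.

#' End-diastolic and end-systolic frames of one slice
#'
#' ED is the frame of maximal endocardial cross-sectional area, ES the
#' frame of minimal area, each detected on the slice's own cine (ties
#' broken toward the earliest frame).
#'
#' @param slice_frames list of endocardial contours (or one slice of a
#'   `cine_stack`), >= 2 frames.
#' @return integer vector `c(ed = ..., es = ...)` of frame indices.
#' @export
ed_es_frames <- function(slice_frames) {
  frames <- extract_endo_frames(slice_frames)
  stop_if(length(frames) < 2, "need at least 2 frames")
  areas <- vapply(frames, contour_area, numeric(1))
  c(ed = which.max(areas), es = which.min(areas))
}

#' LV volumes by disc summation over a short-axis stack
#'
#' Chamber volume is the sum of slice cross-sectional areas times the
#' slice spacing (a stack of discs), with each slice's area taken at
#' that slice's own ED (respectively ES) frame. Per-slice phase
#' detection is the default because infarcted ventricles contract
#' dyssynchronously; `global_frames = TRUE` instead fixes one ED/ES
#' frame pair for the whole stack (the frames extremizing total area).
#'
#' @param stack a `cine_stack` (see [simulate_cine_stack()] /
#'   [read_cine_stack()]).
#' @param global_frames use a single ED/ES frame pair for all slices.
#' @return object of class `volumetrics_result`: `per_slice`
#'   data.frame (slice, ed_frame, es_frame, area_ed, area_es in mm^2),
#'   `lvedv`, `lvesv`, `sv` in mm^3 (= uL), `ef` in percent, and
#'   `slice_spacing`.
#' @examples
#' v <- lv_volumes(simulate_cine_stack(motion_params()))
#' v$ef
#' @export
lv_volumes <- function(stack, global_frames = FALSE) {
  stop_if(!inherits(stack, "cine_stack"), "stack must be a cine_stack")
  stop_if(length(stack$slices) < 1, "stack has no slices")
  areas <- lapply(stack$slices, function(sl) {
    vapply(extract_endo_frames(sl), contour_area, numeric(1))
  })
  if (global_frames) {
    total <- Reduce(`+`, areas)
    ed <- rep(which.max(total), length(areas))
    es <- rep(which.min(total), length(areas))
  } else {
    ed <- vapply(areas, which.max, integer(1))
    es <- vapply(areas, which.min, integer(1))
  }
  per_slice <- data.frame(
    slice = seq_along(areas),
    ed_frame = ed,
    es_frame = es,
    area_ed = mapply(function(a, k) a[k], areas, ed),
    area_es = mapply(function(a, k) a[k], areas, es))
  lvedv <- sum(per_slice$area_ed) * stack$slice_spacing
  lvesv <- sum(per_slice$area_es) * stack$slice_spacing
  structure(c(list(per_slice = per_slice, lvedv = lvedv, lvesv = lvesv,
                   slice_spacing = stack$slice_spacing),
              ef_sv(lvedv, lvesv)),
            class = "volumetrics_result")
}

#' @export
print.volumetrics_result <- function(x, ...) {
  cat(sprintf("LV volumetrics (%d slices @ %.2f mm):\n",
              nrow(x$per_slice), x$slice_spacing))
  cat(sprintf("  LVEDV %.2f uL   LVESV %.2f uL   SV %.2f uL   EF %.1f%%\n",
              x$lvedv, x$lvesv, x$sv, x$ef))
  invisible(x)
}

#' Ejection fraction and stroke volume from chamber volumes
#'
#' `sv = lvedv - lvesv`; `ef = 100 * sv / lvedv` (percent). An
#' end-systolic volume exceeding the end-diastolic volume signals an
#' upstream ED/ES mis-detection and is an error.
#'
#' @param lvedv end-diastolic volume, mm^3 (> 0).
#' @param lvesv end-systolic volume, mm^3, in \[0, lvedv\].
#' @return list with `ef` (percent) and `sv` (mm^3).
#' @examples
#' ef_sv(60, 40)  # ef 33.3, sv 20
#' @export
ef_sv <- function(lvedv, lvesv) {
  stop_if(!is_number(lvedv) || lvedv <= 0, "lvedv must be > 0")
  stop_if(!is_number(lvesv) || lvesv < 0, "lvesv must be >= 0")
  stop_if(lvesv > lvedv,
          "lvesv (%.3f) > lvedv (%.3f): check ED/ES frame detection",
          lvesv, lvedv)
  sv <- lvedv - lvesv
  list(ef = 100 * sv / lvedv, sv = sv)
}

#' Fold change of a longitudinal series relative to baseline
#'
#' Expresses each value of one animal's series as a multiple of that
#' animal's baseline value (baseline maps to 1). Used for volume
#' metrics when groups differ at baseline; fractions like EF are
#' reported absolute instead — which metrics are normalized is a
#' pipeline configuration choice, not hard-wired.
#'
#' @param values numeric series (one animal, one metric over time).
#' @param baseline that animal's baseline value (> 0).
#' @return `values / baseline`.
#' @examples
#' relative_change(c(30, 45, 60), 30)  # 1.0 1.5 2.0
#' @export
relative_change <- function(values, baseline) {
  stop_if(!is_number(baseline) || baseline <= 0, "baseline must be > 0")
  stop_if(!is.numeric(values) || anyNA(values), "values must be numeric")
  values / baseline
}
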