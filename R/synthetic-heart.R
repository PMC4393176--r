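# Synthetic LV motion phantom: displacement-field and contour-cine
# generators with closed-form ground truth. The phantom stands in for
# the speckle-tracker export and the traced B-mode cines, so every
# downstream stage can be validated against known answers.

# End-diastolic endocardial radius of slice j (1 = apex .. n_slices = base).
slice_radii_ed <- function(params) {
  j <- seq_len(params$n_slices)
  params$base_radius * (1 - params$apex_taper * (params$n_slices - j))
}

#' Simulate a per-segment radial displacement field
#'
#' Emulates the displacement table a speckle tracker exports for one
#' short-axis slice: segment i moves as `amplitudes[i] * s(t)` where
#' `s` is the shared raised-cosine systolic waveform
#' ([systolic_waveform()]), plus independent Gaussian radial noise of
#' SD `noise_sd` on every non-reference frame. Frame 1 (t = 0,
#' end-diastole) is the reference and is identically zero.
#'
#' @param params a [motion_params()] object.
#' @return a [displacement_field()] with `n_segments` rows and
#'   `n_frames` columns.
#' @examples
#' f <- simulate_displacement_field(motion_params(amplitudes = 0.4))
#' dyskinesia_index(f)$di  # 1: fully coherent inward motion
#' @export
simulate_displacement_field <- function(params) {
  stop_if(!inherits(params, "motion_params"),
          "params must be a motion_params object")
  tt <- seq(0, params$n_frames - 1) / params$n_frames
  s <- systolic_waveform(tt, params$es_fraction)
  d <- outer(params$amplitudes, s)
  if (params$noise_sd > 0) {
    eps <- with_seed(params$seed,
                     matrix(stats::rnorm(length(d), 0, params$noise_sd),
                            nrow = nrow(d)))
    eps[, 1] <- 0  # displacement is measured relative to the reference frame
    d <- d + eps
  }
  displacement_field(d, frame_times = tt, reference_frame = 1L)
}

#' Simulate a short-axis contour cine stack
#'
#' Generates the geometric phantom: for each slice (apex to base) and
#' frame, an endocardial polygon with radius
#' `r(theta, t) = R_slice - A(theta) * s(t) + noise`, where `A` is
#' piecewise constant over the angular segments (inward positive) and
#' `R_slice` tapers linearly toward the apex. When `params$with_epi`
#' is set, a matching epicardial contour is offset outward by the
#' end-diastolic wall thickness, scaled by `thin_factor` over
#' dyskinetic (negative-amplitude) segments.
#'
#' @param params a [motion_params()] object.
#' @return a `cine_stack`: list with `slices` (list over slices of
#'   lists over frames, each `list(endo, epi)` of n x 2 vertex
#'   matrices, CCW), `slice_spacing`, and `frame_times`.
#' @examples
#' stack <- simulate_cine_stack(motion_params(n_slices = 3))
#' lv_volumes(stack)
#' @export
simulate_cine_stack <- function(params) {
  stop_if(!inherits(params, "motion_params"),
          "params must be a motion_params object")
  M <- params$n_segments
  nv <- M * params$verts_per_segment
  theta <- (seq_len(nv) - 0.5) * 2 * pi / nv       # CCW from +x
  sector <- floor((seq_len(nv) - 1) / params$verts_per_segment) + 1L
  amp_v <- params$amplitudes[sector]
  tt <- seq(0, params$n_frames - 1) / params$n_frames
  s <- systolic_waveform(tt, params$es_fraction)
  radii_ed <- slice_radii_ed(params)
  thick_v <- params$wall_thickness_ed *
    ifelse(amp_v < 0, params$thin_factor, 1)
  noise <- if (params$noise_sd > 0) {
    with_seed(params$seed,
              array(stats::rnorm(params$n_slices * nv * params$n_frames,
                                 0, params$noise_sd),
                    dim = c(nv, params$n_frames, params$n_slices)))
  } else {
    NULL
  }
  ct <- cos(theta); st <- sin(theta)
  slices <- vector("list", params$n_slices)
  for (j in seq_len(params$n_slices)) {
    frames <- vector("list", params$n_frames)
    for (k in seq_len(params$n_frames)) {
      r <- radii_ed[j] - amp_v * s[k]
      if (!is.null(noise)) r <- r + noise[, k, j]
      stop_if(any(r <= 0),
              "slice %d frame %d: endocardial radius would be <= 0", j, k)
      endo <- cbind(r * ct, r * st)
      epi <- if (params$with_epi) {
        cbind((r + thick_v) * ct, (r + thick_v) * st)
      } else {
        NULL
      }
      frames[[k]] <- list(endo = endo, epi = epi)
    }
    slices[[j]] <- frames
  }
  structure(list(slices = slices,
                 slice_spacing = params$slice_spacing,
                 frame_times = tt),
            class = "cine_stack")
}

#' @export
print.cine_stack <- function(x, ...) {
  nf <- length(x$slices[[1]])
  nv <- nrow(x$slices[[1]][[1]]$endo)
  has_epi <- !is.null(x$slices[[1]][[1]]$epi)
  cat(sprintf(
    "Short-axis contour cine: %d slices x %d frames @ %.2f mm spacing\n",
    length(x$slices), nf, x$slice_spacing))
  cat(sprintf("  %d endocardial vertices per contour%s\n", nv,
              if (has_epi) ", with epicardium" else ""))
  invisible(x)
}

#' Closed-form dyskinesia index of a noiseless shared-waveform phantom
#'
#' When every segment follows the same waveform `s(t)` with amplitude
#' `A[i]` and there is no noise, the efficiency at every included frame
#' is `|sum(A)| / sum(|A|)` — the waveform cancels — so the dyskinesia
#' index equals that ratio exactly. This closed form is the oracle the
#' numerical pipeline is validated against.
#'
#' @param params a [motion_params()] object with `noise_sd = 0`.
#' @return the exact dyskinesia index, in \[0, 1\].
#' @examples
#' analytic_di(motion_params(amplitudes = dyskinetic_amplitudes(96, 24,
#'                                                              inward = 1)))
#' # (72 - 24) / 96 = 0.5
#' @export
analytic_di <- function(params) {
  stop_if(!inherits(params, "motion_params"),
          "params must be a motion_params object")
  stop_if(params$noise_sd != 0,
          "the closed-form oracle is defined only for noise_sd = 0")
  denom <- sum(abs(params$amplitudes))
  stop_if(denom == 0, "DI undefined: all amplitudes are zero (no motion)")
  abs(sum(params$amplitudes)) / denom
}

#' Closed-form disc-summation volumes of a noiseless phantom
#'
#' End-diastolic and end-systolic chamber volumes of the continuous
#' phantom geometry, by summing exact slice areas times slice spacing.
#' Each slice's ES area is evaluated at the frame where the systolic
#' waveform is largest over the simulated frame grid (matching per-slice
#' ES detection on the discrete cine), with
#' `area(t) = 1/2 * sum_sectors (2*pi/M) * (R_slice - A_i * s(t))^2`.
#'
#' @param params a [motion_params()] object with `noise_sd = 0`.
#' @return list with `lvedv`, `lvesv`, `ef`, `sv` (volumes in mm^3 =
#'   uL, `ef` in percent).
#' @export
analytic_volumes <- function(params) {
  stop_if(!inherits(params, "motion_params"),
          "params must be a motion_params object")
  stop_if(params$noise_sd != 0,
          "the closed-form oracle is defined only for noise_sd = 0")
  tt <- seq(0, params$n_frames - 1) / params$n_frames
  s_max <- max(systolic_waveform(tt, params$es_fraction))
  w <- 2 * pi / params$n_segments
  radii <- slice_radii_ed(params)
  area_at <- function(R, s) 0.5 * w * sum((R - params$amplitudes * s)^2)
  area_ed <- vapply(radii, area_at, numeric(1), s = 0)
  area_es <- vapply(radii, area_at, numeric(1), s = s_max)
  # the phantom's chamber shrinks monotonically in s only if net motion
  # is inward; ED/ES frames are still area extrema per slice
  lvedv <- sum(pmax(area_ed, area_es)) * params$slice_spacing
  lvesv <- sum(pmin(area_ed, area_es)) * params$slice_spacing
  c(list(lvedv = lvedv, lvesv = lvesv), ef_sv(lvedv, lvesv))
}

#' Simulate a labelled cohort of phantom hearts
#'
#' Draws `n_per_group` animals per group from group-specific phantom
#' templates with between-animal variability: each animal's per-segment
#' amplitudes are the template's plus independent Gaussian jitter of SD
#' `jitter_sd` (mm). Per-animal parameters are returned alongside the
#' simulated data so recovered quantities can be compared with ground
#' truth. Fully deterministic given `seed`.
#'
#' @param group_specs named list; each element a list with `params`
#'   (a [motion_params()] template) and `jitter_sd` (mm, >= 0).
#' @param n_per_group integer vector (recycled) of animals per group,
#'   each >= 2.
#' @param seed integer seed controlling all draws.
#' @param output `"stack"` for full contour cines, `"field"` for
#'   displacement fields only (the speckle-tracker-equivalent route).
#' @return list of animals, each
#'   `list(id, group, params, stack-or-field)`.
#' @examples
#' specs <- list(
#'   control = list(params = motion_params(
#'     amplitudes = dyskinetic_amplitudes(96, 14), noise_sd = 0.05),
#'     jitter_sd = 0.08),
#'   treated = list(params = motion_params(
#'     amplitudes = dyskinetic_amplitudes(96, 4), noise_sd = 0.05),
#'     jitter_sd = 0.08))
#' cohort <- simulate_cohort(specs, n_per_group = c(3, 3), seed = 1,
#'                           output = "field")
#' sapply(cohort, function(a) dyskinesia_index(a$data)$di)
#' @export
simulate_cohort <- function(group_specs, n_per_group, seed,
                            output = c("stack", "field")) {
  output <- match.arg(output)
  stop_if(is.null(names(group_specs)) || any(names(group_specs) == ""),
          "group_specs must be a named list")
  n_per_group <- rep_len(as.integer(n_per_group), length(group_specs))
  stop_if(any(n_per_group < 2),
          "n_per_group must be >= 2 (group statistics undefined below that)")
  stop_if(!is_count(seed, 0), "seed must be a non-negative integer")
  n_total <- sum(n_per_group)
  seeds <- derive_seeds(seed, 2L * n_total)
  animals <- vector("list", n_total)
  idx <- 0L
  for (g in seq_along(group_specs)) {
    spec <- group_specs[[g]]
    stop_if(!inherits(spec$params, "motion_params"),
            "group '%s': spec$params must be a motion_params object",
            names(group_specs)[g])
    jit <- spec$jitter_sd %||% 0
    stop_if(!is_number(jit) || jit < 0, "jitter_sd must be >= 0")
    for (a in seq_len(n_per_group[g])) {
      idx <- idx + 1L
      tmpl <- spec$params
      amp <- tmpl$amplitudes
      if (jit > 0) {
        amp <- amp + with_seed(seeds[2L * idx - 1L],
                               stats::rnorm(length(amp), 0, jit))
      }
      p <- motion_params(
        n_segments = tmpl$n_segments, n_frames = tmpl$n_frames,
        amplitudes = amp, base_radius = tmpl$base_radius,
        wall_thickness_ed = tmpl$wall_thickness_ed,
        n_slices = tmpl$n_slices, slice_spacing = tmpl$slice_spacing,
        apex_taper = tmpl$apex_taper, noise_sd = tmpl$noise_sd,
        seed = seeds[2L * idx], es_fraction = tmpl$es_fraction,
        verts_per_segment = tmpl$verts_per_segment,
        thin_factor = tmpl$thin_factor, with_epi = tmpl$with_epi)
      data <- switch(output,
                     stack = simulate_cine_stack(p),
                     field = simulate_displacement_field(p))
      animals[[idx]] <- list(
        id = sprintf("%s_%02d", names(group_specs)[g], a),
        group = names(group_specs)[g],
        params = p,
        data = data)
    }
  }
  animals
}

`%||%` <- function(a, b) if (is.null(a)) b else a
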