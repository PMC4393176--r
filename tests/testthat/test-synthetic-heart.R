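test_that("motion parameter validation rejects degenerate phantoms", {
  expect_error(motion_params(n_segments = 1), "n_segments")
  expect_error(motion_params(n_frames = 2), "n_frames")
  expect_error(motion_params(base_radius = 0), "base_radius")
  expect_error(motion_params(amplitudes = 1.6), "self-invert")
  expect_error(motion_params(amplitudes = rep(0.4, 10)), "length")
  expect_error(motion_params(noise_sd = -0.1), "noise_sd")
})

test_that("systolic waveform is anchored at ED and peaks at end-systole", {
  t <- seq(0, 1, by = 0.01)
  s <- systolic_waveform(t, es_fraction = 0.4)
  expect_equal(s[1], 0)
  expect_equal(s[length(s)], 0)
  expect_equal(s[t == 0.4], 1)
  expect_true(all(s >= 0 & s <= 1))
  expect_true(all(diff(s[t <= 0.4]) > 0))   # monotone contraction
  expect_true(all(diff(s[t >= 0.4]) < 0))   # monotone relaxation
})

test_that("noiseless displacement fields are the amplitude-waveform product", {
  p <- motion_params(amplitudes = 0.4, noise_sd = 0)
  f <- simulate_displacement_field(p)
  expect_equal(dim(f$d), c(96, 35))
  s <- systolic_waveform(f$frame_times, p$es_fraction)
  expect_equal(f$d, outer(rep(0.4, 96), s))
  # every column a non-negative multiple of the shared waveform
  expect_true(all(f$d >= 0))
  expect_identical(dyskinesia_index(f)$di, 1)
})

test_that("72 inward / 24 outward shared-waveform field has DI 0.5", {
  p <- motion_params(amplitudes = dyskinetic_amplitudes(96, 24, inward = 1))
  expect_equal(analytic_di(p), 0.5)
  f <- simulate_displacement_field(p)
  expect_equal(dyskinesia_index(f)$di, 0.5, tolerance = 1e-14)
})

test_that("simulation is reproducible from the seed", {
  p <- motion_params(noise_sd = 0.05, seed = 42)
  expect_identical(simulate_displacement_field(p)$d,
                   simulate_displacement_field(p)$d)
  s1 <- simulate_cine_stack(p)
  s2 <- simulate_cine_stack(p)
  expect_identical(s1, s2)
  p2 <- motion_params(noise_sd = 0.05, seed = 43)
  expect_false(identical(simulate_displacement_field(p2)$d,
                         simulate_displacement_field(p)$d))
})

test_that("cine stack honours the structural contract", {
  p <- motion_params(n_slices = 6, n_frames = 35, noise_sd = 0.02, seed = 1)
  stack <- simulate_cine_stack(p)
  expect_length(stack$slices, 6)
  expect_true(all(vapply(stack$slices, length, integer(1)) == 35))
  poly <- stack$slices[[3]][[10]]$endo
  expect_gte(nrow(poly), 8)
  expect_gt(dyskindex:::polygon_signed_area(poly), 0)  # CCW
  expect_true(dyskindex:::polygon_is_simple(poly))
})

test_that("uniform contraction shrinks the slice to the analytic circle", {
  p <- motion_params(amplitudes = 0.4, base_radius = 1.5, noise_sd = 0,
                     apex_taper = 0, n_slices = 1)
  stack <- simulate_cine_stack(p)
  areas <- vapply(stack$slices[[1]], function(f) contour_area(f$endo),
                  numeric(1))
  s <- systolic_waveform(stack$frame_times, p$es_fraction)
  # frame times hit s = 1 exactly at 35 frames with es_fraction 0.4
  expect_equal(min(areas), pi * 1.1^2, tolerance = 1e-4)
  expect_equal(which.min(areas), which.max(s))
  expect_equal(max(areas), pi * 1.5^2, tolerance = 1e-4)
})

test_that("a dyskinetic sector bulges outward at peak systole", {
  p <- motion_params(amplitudes = dyskinetic_amplitudes(96, 24, inward = 0.4,
                                                        outward = 0.3),
                     noise_sd = 0, apex_taper = 0, n_slices = 1)
  stack <- simulate_cine_stack(p)
  es <- which.max(systolic_waveform(stack$frame_times, p$es_fraction))
  poly <- stack$slices[[1]][[es]]$endo
  r <- sqrt(rowSums(poly^2))
  nv_per_seg <- nrow(poly) / 96
  dys <- seq_len(24 * nv_per_seg)
  expect_equal(unique(round(r[dys], 10)), 1.8)       # 1.5 + 0.3 outward
  expect_equal(unique(round(r[-dys], 10)), 1.1)      # 1.5 - 0.4 inward
})

test_that("the cine generator rejects radii collapsing through zero", {
  p <- motion_params(amplitudes = 0.85, base_radius = 1.0, apex_taper = 0.08)
  expect_error(simulate_cine_stack(p), "radius")
})

test_that("analytic DI matches its closed form and rejects zero motion", {
  expect_equal(analytic_di(motion_params(amplitudes = 0.3)), 1)
  half <- c(rep(0.2, 48), rep(-0.2, 48))
  expect_equal(analytic_di(motion_params(amplitudes = half)), 0)
  expect_error(analytic_di(motion_params(amplitudes = 0, noise_sd = 0)),
               "undefined")
  expect_error(analytic_di(motion_params(noise_sd = 0.1)), "noise")
})

test_that("noiseless simulated DI equals analytic DI across random phantoms", {
  set.seed(11)
  for (k in 1:25) {
    amps <- runif(96, -0.8, 1.2)
    if (sum(abs(amps)) == 0) next
    p <- motion_params(amplitudes = amps, noise_sd = 0)
    f <- simulate_displacement_field(p)
    expect_equal(dyskinesia_index(f)$di, analytic_di(p), tolerance = 1e-12)
  }
})

test_that("DI estimate converges to the oracle at low noise", {
  set.seed(5)
  amps <- dyskinetic_amplitudes(96, 24, inward = 1)
  truth <- analytic_di(motion_params(amplitudes = amps))
  err <- vapply(1:20, function(r) {
    p <- motion_params(amplitudes = amps, n_frames = 200,
                       noise_sd = 0.01, seed = 1000 + r)
    abs(dyskinesia_index(simulate_displacement_field(p))$di - truth)
  }, numeric(1))
  expect_lt(mean(err), 0.02)
})

test_that("cohort simulation is labelled, seeded, and jitter-controlled", {
  specs <- list(
    control = list(params = motion_params(
      amplitudes = dyskinetic_amplitudes(96, 14)), jitter_sd = 0.08),
    treated = list(params = motion_params(
      amplitudes = dyskinetic_amplitudes(96, 4)), jitter_sd = 0.08))
  cohort <- simulate_cohort(specs, n_per_group = c(3, 2), seed = 9,
                            output = "field")
  expect_length(cohort, 5)
  expect_equal(vapply(cohort, `[[`, "", "group"),
               c(rep("control", 3), rep("treated", 2)))
  again <- simulate_cohort(specs, n_per_group = c(3, 2), seed = 9,
                           output = "field")
  expect_identical(cohort, again)
  # zero jitter, zero noise: all animals in a group identical
  specs0 <- lapply(specs, function(s) list(params = s$params, jitter_sd = 0))
  c0 <- simulate_cohort(specs0, n_per_group = c(2, 2), seed = 1,
                        output = "field")
  expect_identical(c0[[1]]$data$d, c0[[2]]$data$d)
  expect_error(simulate_cohort(specs, n_per_group = 1, seed = 1),
               "n_per_group")
})
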