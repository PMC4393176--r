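test_that("cine stacks survive a write/read round trip", {
  p <- motion_params(n_slices = 3, n_frames = 8, noise_sd = 0.02, seed = 4,
                     verts_per_segment = 4, n_segments = 12)
  stack <- simulate_cine_stack(p)
  path <- withr::local_tempfile(fileext = ".json")
  write_cine_stack(stack, path)
  back <- read_cine_stack(path)
  expect_equal(back$slice_spacing, stack$slice_spacing)
  expect_equal(back$frame_times, stack$frame_times)
  for (j in seq_along(stack$slices)) {
    for (k in seq_along(stack$slices[[j]])) {
      expect_equal(back$slices[[j]][[k]]$endo, stack$slices[[j]][[k]]$endo,
                   tolerance = 1e-12)
      expect_equal(back$slices[[j]][[k]]$epi, stack$slices[[j]][[k]]$epi,
                   tolerance = 1e-12)
    }
  }
})

test_that("clockwise contours are normalized to CCW with area preserved", {
  p <- motion_params(n_slices = 1, n_frames = 3, n_segments = 8,
                     noise_sd = 0)
  stack <- simulate_cine_stack(p)
  cw <- stack$slices[[1]][[1]]$endo
  stack$slices[[1]][[1]]$endo <- cw[rev(seq_len(nrow(cw))), ]
  path <- withr::local_tempfile(fileext = ".json")
  write_cine_stack(stack, path)
  back <- read_cine_stack(path)
  loaded <- back$slices[[1]][[1]]$endo
  expect_gt(dyskindex:::polygon_signed_area(loaded), 0)
  expect_equal(contour_area(loaded), contour_area(cw))
})

test_that("structural violations are rejected with located messages", {
  p <- motion_params(n_slices = 2, n_frames = 4, n_segments = 8,
                     noise_sd = 0)
  stack <- simulate_cine_stack(p)
  path <- withr::local_tempfile(fileext = ".json")

  broken <- stack
  broken$slices[[2]] <- broken$slices[[2]][1:3]  # 4 vs 3 frames
  write_cine_stack(broken, path)
  expect_error(read_cine_stack(path), "frame counts")

  bowtie <- stack
  poly <- bowtie$slices[[1]][[2]]$endo
  poly[c(1, 2), ] <- poly[c(2, 1), ]             # swap to self-intersect
  bowtie$slices[[1]][[2]]$endo <- poly
  write_cine_stack(bowtie, path)
  expect_error(read_cine_stack(path), "slice 1 frame 2")

  tiny <- stack
  tiny$slices[[1]][[1]]$endo <- circle_poly(1, n = 6)
  write_cine_stack(tiny, path)
  expect_error(read_cine_stack(path), ">= 8")
})

test_that("displacement tables round-trip losslessly", {
  p <- motion_params(noise_sd = 0.05, seed = 12)
  f <- simulate_displacement_field(p)
  path <- withr::local_tempfile(fileext = ".csv")
  write_displacement_table(f, path)
  back <- read_displacement_table(path)
  expect_equal(back$d, f$d, tolerance = 1e-12)
  expect_equal(back$frame_times, f$frame_times, tolerance = 1e-12)
  expect_equal(back$reference_frame, f$reference_frame)
  expect_equal(dim(back$d), c(96, 35))
})

test_that("grid holes, duplicates and unit variants are handled", {
  f <- simulate_displacement_field(motion_params(n_segments = 4,
                                                 n_frames = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_displacement_table(f, path)
  tab <- utils::read.csv(path)

  hole <- tab[!(tab$segment_id == 3 & tab$frame_index == 2), ]
  utils::write.csv(hole, path, row.names = FALSE)
  expect_error(read_displacement_table(path), "segment 3, frame 2")

  dup <- rbind(tab, tab[7, ])
  utils::write.csv(dup, path, row.names = FALSE)
  expect_error(read_displacement_table(path), "duplicate")

  um <- tab
  names(um)[names(um) == "displacement_mm"] <- "displacement_um"
  um$displacement_um <- um$displacement_um * 1000
  utils::write.csv(um, path, row.names = FALSE)
  expect_equal(read_displacement_table(path)$d, f$d, tolerance = 1e-12)
})

test_that("study reports serialize deterministically", {
  cfg <- demo_config(seed = 3, n_per_group = c(2, 2))
  cfg$timepoints <- c("baseline", "d2", "d7")
  rep1 <- run_study(cfg)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_report(rep1, dir1)
  write_report(run_study(cfg), dir2)
  files <- c("per_animal_metrics.csv", "group_summaries.csv",
             "statistics.json", "manifest.json")
  expect_setequal(list.files(dir1), files)
  for (f in files) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
})
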