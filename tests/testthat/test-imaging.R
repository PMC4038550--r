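# Synthetic field rendering: placement, camera model, binning, ground truth.

test_that("placement honours counts, margins and the minimum gap", {
  spec <- small_spec()
  expect_equal(nrow(place_cells(spec, 0, seed = 1)), 0)
  g <- place_cells(spec, 10, seed = 2)
  expect_equal(nrow(g), 10)
  # brute-force pairwise boundary-gap oracle
  for (i in seq_len(nrow(g) - 1)) {
    for (j in seq((i + 1), nrow(g))) {
      expect_gte(brute_gap(g[i, ], g[j, ]), spec$min_gap_px - 1e-6)
    }
  }
  # identical seeds give identical placements
  expect_identical(g, place_cells(spec, 10, seed = 2))
})

test_that("impossible packings saturate with a warning, not an error", {
  tiny <- field_spec(width_px = 100, height_px = 100, n_cells_target = 500)
  expect_warning(g <- place_cells(tiny, 500, seed = 1, max_attempts = 3000),
                 "saturated")
  expect_lt(nrow(g), 500)
  expect_gt(nrow(g), 0)
})

test_that("noise-free rendering is exact over the truth mask", {
  spec <- small_spec(psf_sigma_px = 0)
  cam <- quiet_camera()
  # empty field: uniform background
  f0 <- render_field(numeric(0), place_cells(spec, 0, seed = 1), spec, cam)
  expect_true(all(f0$fluorescence ==
                    cam$offset + cam$gain * spec$fluor_bg_level))
  # one cell at a known AU value, unbinned sensor: in-mask mean exact
  cam1 <- quiet_camera(binning = 1)
  g <- place_cells(spec, 1, seed = 3)
  v <- 123.4
  fi <- render_field(v, g, spec, cam1, seed = 4)
  inmask <- fi$fluorescence[fi$truth_mask == 1]
  expect_equal(mean(inmask),
               cam1$offset + cam1$gain * (spec$fluor_bg_level + v),
               tolerance = 1e-12)
  # and the quantify stage recovers the AU value to machine precision
  rec <- measure_cells(fi$truth_mask, fi$fluorescence,
                       background = cam1$offset +
                         cam1$gain * spec$fluor_bg_level,
                       gain = cam1$gain)
  expect_equal(rec$corrected_mean, v, tolerance = 1e-12)
  expect_equal(fi$cell_truths$optical_mean_au, v, tolerance = 1e-12)
  # with 2x2 binning, majority-rule mask edges mix in background; the
  # recorded optical ground truth accounts for this exactly
  fi2 <- render_field(v, g, spec, cam, seed = 4)
  rec2 <- measure_cells(fi2$truth_mask, fi2$fluorescence,
                        background = cam$offset +
                          cam$gain * spec$fluor_bg_level,
                        gain = cam$gain)
  expect_equal(rec2$corrected_mean, fi2$cell_truths$optical_mean_au,
               tolerance = 1e-12)
  expect_lt(fi2$cell_truths$optical_mean_au, v)
})

test_that("value/geometry length mismatches are rejected", {
  spec <- small_spec()
  g <- place_cells(spec, 3, seed = 1)
  expect_error(render_field(c(1, 2), g, spec, quiet_camera()), "one AU value")
})

test_that("camera noise has the Poisson + Gaussian variance", {
  spec <- field_spec(width_px = 320, height_px = 320, n_cells_target = 0,
                     psf_sigma_px = 0, fluor_bg_level = 80)
  cam <- camera_model(offset = 50, read_noise_sd = 4, gain = 2,
                      shot_noise = TRUE, binning = 1)
  fi <- render_field(numeric(0), place_cells(spec, 0, seed = 1), spec, cam,
                     seed = 9)
  v_expect <- cam$gain^2 * spec$fluor_bg_level + cam$read_noise_sd^2
  expect_equal(stats::var(as.numeric(fi$fluorescence)), v_expect,
               tolerance = 0.05)
  expect_equal(mean(fi$fluorescence),
               cam$offset + cam$gain * spec$fluor_bg_level,
               tolerance = 0.005)
})

test_that("2x2 binning averages and halves the dimensions", {
  spec <- small_spec(psf_sigma_px = 0)
  g <- place_cells(spec, 4, seed = 5)
  v <- rep(100, 4)
  f1 <- render_field(v, g, spec, camera_model(binning = 1, shot_noise = FALSE,
                                              read_noise_sd = 0), seed = 1)
  f2 <- render_field(v, g, spec, camera_model(binning = 2, shot_noise = FALSE,
                                              read_noise_sd = 0), seed = 1)
  expect_equal(dim(f2$fluorescence), dim(f1$fluorescence) / 2)
  # mean binning: AU scale is unchanged (same total average signal)
  expect_equal(mean(f2$fluorescence), mean(f1$fluorescence),
               tolerance = 1e-12)
  # truth labels survive binning for every placed cell
  expect_setequal(unique(as.vector(f2$truth_mask)), c(0L, 1L, 2L, 3L, 4L))
})

test_that("saturation is monitored and reported", {
  spec <- small_spec(psf_sigma_px = 0, fluor_bg_level = 10)
  cam <- camera_model(offset = 0, gain = 100, shot_noise = FALSE,
                      read_noise_sd = 0, bit_depth = 8, binning = 1)
  g <- place_cells(spec, 2, seed = 1)
  fi <- render_field(c(1e4, 1e4), g, spec, cam, seed = 1)
  expect_gt(fi$saturated_fraction, 0)
  expect_lte(max(fi$fluorescence), 2^8 - 1)
  # default acceptance-scale rendering does not clip
  spec2 <- small_spec()
  g2 <- place_cells(spec2, 5, seed = 2)
  fi2 <- render_field(rep(300, 5), g2, spec2, camera_model(), seed = 2)
  expect_equal(fi2$saturated_fraction, 0)
})

test_that("fields round-trip to 16-bit TIFF and CSV on disk", {
  spec <- small_spec()
  g <- place_cells(spec, 3, seed = 6)
  fi <- render_field(rep(120, 3), g, spec, camera_model(), seed = 6)
  dir <- withr::local_tempdir()
  paths <- write_field_image(fi, file.path(dir, "cond", "r1", "field001"))
  expect_true(all(file.exists(paths)))
  bf <- read_tiff16(paths[1])
  expect_equal(bf, round(fi$brightfield), tolerance = 1e-9)
  mask <- read_tiff16(paths[3])
  expect_identical(matrix(as.integer(mask), nrow(mask)), fi$truth_mask)
  truth <- read.csv(paths[4])
  expect_equal(truth$au_true, rep(120, 3))
})
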