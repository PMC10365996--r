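test_that("scenes are bit-identical under a fixed seed and differ across seeds", {
  cfg <- function(s) scene_config(crop_side = 64L, object_pixel_size = 3.5,
                                  n_frames = 6L, frame_interval = 10,
                                  profile = secretion_profile("constant", rate = 1),
                                  seed = s)
  a <- simulate_scene(cfg(3)); b <- simulate_scene(cfg(3))
  expect_identical(a$sensing$stack$frames, b$sensing$stack$frames)
  expect_identical(a$reference$stack$frames, b$reference$stack$frames)
  expect_identical(a$truth$centroids, b$truth$centroids)
  c <- simulate_scene(cfg(4))
  expect_false(identical(a$sensing$stack$frames, c$sensing$stack$frames))
  # simulation must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_scene(cfg(5))); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("a well larger than the crop is a configuration error", {
  expect_error(scene_config(crop_side = 96L, object_pixel_size = 0.65),
               "does not fit")
})

test_that("deposited mass is conserved and saturates under Langmuir binding", {
  # b << b_max: total bound mass equals rate * time within 1%
  cfg <- scene_config(crop_side = 96L, object_pixel_size = 2.6,
                      n_frames = 13L, frame_interval = 10,
                      profile = secretion_profile("constant", rate = 2),
                      binding = list(b_max = 1e9), noise = list(read_sd = 0),
                      motion_msd_target = 0, seed = 1)
  field <- secretion_field(cfg, t = 120)
  expect_equal(sum(field), 2 * 120, tolerance = 0.01)
  expect_true(all(field >= 0))
  # r = 0 gives a zero field
  cfg0 <- scene_config(crop_side = 64L, object_pixel_size = 3.5,
                       profile = secretion_profile("none"), seed = 1)
  expect_equal(max(secretion_field(cfg0, t = 100)), 0)
  # small b_max: the field saturates and per-pixel bound mass never exceeds it
  cfgS <- scene_config(crop_side = 96L, object_pixel_size = 2.6,
                       n_frames = 25L, frame_interval = 20,
                       profile = secretion_profile("constant", rate = 5),
                       binding = list(b_max = 0.05),
                       noise = list(read_sd = 0), motion_msd_target = 0,
                       seed = 2, keep_truth_maps = TRUE)
  sc <- simulate_scene(cfgS)
  last <- sc$truth$bound[[25]]
  expect_lte(max(last), 0.05 + 1e-9)
  added <- vapply(2:25, function(t) sum(sc$truth$bound[[t]]) -
                    sum(sc$truth$bound[[t - 1]]), numeric(1))
  expect_lt(added[24], added[2])  # uptake slows as the surface fills
  # per-pixel bound mass is non-decreasing (irreversible binding)
  for (t in 2:25)
    expect_true(all(sc$truth$bound[[t]] >= sc$truth$bound[[t - 1]] - 1e-12))
})

test_that("optical transduction is linear for small shifts and departs at large ones", {
  opt <- optics_config()
  base <- transduce(matrix(0, 4, 4), opt, b_max = 1, baseline = 1000)
  expect_equal(base, matrix(1000, 4, 4), tolerance = 1e-9)
  # shift << FWHM on the flank: response proportional to the shift within 5%
  shifts <- c(0.2, 0.4, 0.8)
  resp <- vapply(shifts, function(s) {
    o <- optics_config(dlambda_max = s)
    1000 - transduce(matrix(1, 1, 1), o, baseline = 1000)[1, 1]
  }, numeric(1))
  expect_lt(abs(resp[2] / resp[1] - 2) / 2, 0.05)
  expect_lt(abs(resp[3] / resp[1] - 4) / 4, 0.05)
  # nonlinearity factor grows with shift and is material at a full FWHM
  nl <- transduction_nonlinearity(opt, c(0.5, 5, 22.6))
  expect_true(all(diff(nl) > 0))
  expect_lt(nl[1], 0.05)
  expect_gt(nl[3], 0.2)
  # linear approximation mode agrees with the full integral for tiny shifts
  o_lin <- optics_config(linear = TRUE)
  b <- matrix(0.01, 3, 3)
  expect_equal(transduce(b, o_lin, baseline = 1000),
               transduce(b, optics_config(), baseline = 1000),
               tolerance = 2e-3)
})

test_that("reference wells share drift statistics but carry no signal", {
  sc <- small_scene(profile_for("I"), seed = 41, n_frames = 15L)
  ref <- sc$reference$stack$frames
  # no cell disc: reference intensities stay near baseline everywhere
  inside <- disc <- secretomap:::disc_mask(96, c(47.5, 47.5),
                                           sc$truth$well_radius_px - 2)
  for (t in c(1, 8, 15))
    expect_gt(min(ref[[t]][inside]), 900)
  # sensing well carries the darker cell
  sens1 <- sc$sensing$stack$frames[[1]]
  expect_lt(min(sens1[sc$truth$cell_masks[[1]]]), 800)
})

test_that("burst release dumps its mass within the configured spread", {
  cfg <- scene_config(crop_side = 96L, object_pixel_size = 2.6,
                      n_frames = 60L, frame_interval = 2,
                      profile = secretion_profile("burst", t_burst = 40,
                                                  mass = 300, spread_min = 10),
                      seed = 5)
  sc <- simulate_scene(cfg)
  an <- analyze_scene(sc)
  area <- area_curve(an$maps, pixel_area = 2.6^2)
  # release area reaches 80% of its maximum within 6 frames of t_burst
  i_burst <- which(sc$sensing$stack$times >= 40)[1]
  i80 <- which(area$value >= 0.8 * max(area$value))[1]
  expect_lte(i80 - i_burst, 6)
  # before the burst only the residual noise-leak area remains
  expect_lt(mean(area$value[1:(i_burst - 1)]), 0.15 * max(area$value))
})

test_that("mitosis renders an elongating mother that splits into two daughters", {
  cfg <- scene_config(crop_side = 96L, object_pixel_size = 2.6,
                      n_frames = 12L, frame_interval = 20, cell_radius = 10,
                      profile = secretion_profile("none"),
                      division = list(t_div = 120), seed = 6)
  sc <- simulate_scene(cfg)
  ncomp <- vapply(sc$truth$cell_masks, function(m)
    max(EBImage::bwlabel(m + 0)), numeric(1))
  expect_equal(ncomp[1], 1)
  expect_equal(ncomp[12], 2)
  expect_true(length(sc$truth$division_frames) >= 1)
  # area roughly doubles after the split
  a1 <- sum(sc$truth$cell_masks[[1]])
  a12 <- sum(sc$truth$cell_masks[[12]])
  expect_gt(a12 / a1, 1.5)
})

test_that("scene export writes stacks, truth and config", {
  sc <- small_scene(profile_for("I"), seed = 42, n_frames = 4L)
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  expect_true(all(file.exists(file.path(dir,
    c("sensing.tif", "reference.tif", "truth_cell_masks.tif",
      "ground_truth.json", "scene_config.yaml")))))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$label, "I")
  meta <- acquisition_meta(frame_interval = 20)
  back <- read_timelapse(file.path(dir, "sensing.tif"), meta)
  expect_equal(back$frames, sc$sensing$stack$frames)
})
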