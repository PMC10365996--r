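mk_stack <- function(frames, dt = 10)
  image_stack(frames, times = (seq_along(frames) - 1) * dt)

test_that("difference stacks follow |I(t) - I(1)| with optional smoothing", {
  const <- mk_stack(replicate(4, matrix(5, 16, 16), simplify = FALSE))
  d <- difference_stack(const, sigma = 0)
  for (f in d$frames) expect_equal(max(abs(f)), 0)
  two <- mk_stack(list(matrix(5, 8, 8), matrix(7, 8, 8)))
  d2 <- difference_stack(two, sigma = 0)
  expect_equal(d2$frames[[2]], matrix(2, 8, 8))
  expect_equal(d2$frames[[1]], matrix(0, 8, 8))
  # single-pixel step smoothed at sigma 1.5 equals the dense kernel oracle
  a <- matrix(100, 33, 33); b <- a; b[17, 17] <- 110
  d3 <- difference_stack(mk_stack(list(a, b)), sigma = 1.5)
  delta <- matrix(0, 33, 33); delta[17, 17] <- 10
  k <- outer(gauss_kernel(1.5, 0), gauss_kernel(1.5, 0))
  expect_equal(d3$frames[[2]], dense_filter_oracle(delta, k), tolerance = 1e-9)
  expect_error(difference_stack(mk_stack(list(a))), "2 frames")
})

test_that("reference levels are mean + 3 sd over the ROI and track shared drift", {
  ones <- structure(list(frames = replicate(3, matrix(1, 20, 20), simplify = FALSE),
                         times = c(0, 10, 20), sigma = 0), class = "diff_stack")
  lv <- reference_level(ones, roi = c(5, 5, 8, 8))
  expect_equal(lv$level, rep(1, 3))
  # half 0.5 / half 1.5: mean 1, sd 0.5 (n-1 denominator), level 2.5
  f <- matrix(rep(c(0.5, 1.5), each = 32), 8, 8)
  st <- structure(list(frames = list(f), times = 0, sigma = 0),
                  class = "diff_stack")
  expect_equal(reference_level(st, roi = c(0, 0, 8, 8))$level,
               1 + 3 * stats::sd(as.numeric(f)))
  expect_error(reference_level(ones, roi = c(15, 15, 10, 10)), "bounds")
  expect_error(reference_level(ones, roi = c(0, 0, 1, 2)), "4 pixels")

  # linear drift d(t) = 0.02 t shared by both wells is tracked within noise
  set.seed(6)
  times <- (0:10) * 10
  base <- matrix(800, 40, 40)
  mkwell <- function() mk_stack(lapply(times / 10 + 1, function(i)
    pmax(base * (1 + 0.002 * times[i]) + matrix(rnorm(1600, 0, 1), 40, 40), 0)))
  refd <- difference_stack(mkwell(), sigma = 1.5)
  lv2 <- reference_level(refd, roi = c(8, 8, 24, 24))
  drift_truth <- 800 * 0.002 * times
  expect_lt(max(abs(lv2$level - drift_truth)[-1] / pmax(drift_truth[-1], 1)), 0.25)
  expect_gt(stats::cor(lv2$level[-1], drift_truth[-1]), 0.99)
})

test_that("background subtraction clamps at zero and gates noise-only wells", {
  d <- structure(list(frames = list(matrix(0, 6, 6), matrix(3, 6, 6)),
                      times = c(0, 10), sigma = 0), class = "diff_stack")
  lv <- structure(list(level = c(0, 2.5), times = c(0, 10), roi = c(0, 0, 2, 2)),
                  class = "background_levels")
  out <- subtract_background(d, lv)
  expect_equal(out$frames[[2]], matrix(0.5, 6, 6))
  lv$level <- c(0, 4)
  expect_equal(subtract_background(d, lv)$frames[[2]], matrix(0, 6, 6))
  lv$level <- c(0, 1, 2)
  lv$times <- c(0, 10, 20)
  expect_error(subtract_background(d, lv), "mismatch")

  # pure-noise sensing well: >= 99% of pixels are zero after correction,
  # and the non-zero fraction stays under the one-sided 3 sigma bound (1.5%)
  set.seed(7)
  noisy <- function() mk_stack(replicate(6, {
    matrix(800 + rnorm(48^2, 0, 2), 48, 48)
  }, simplify = FALSE))
  sens <- difference_stack(noisy(), sigma = 1.5)
  ref <- difference_stack(noisy(), sigma = 1.5)
  corr <- subtract_background(sens, reference_level(ref))
  frac <- vapply(corr$frames[-1], function(f) mean(f > 0), numeric(1))
  expect_lt(max(frac), 0.015)
  expect_gt(min(vapply(corr$frames[-1], function(f) mean(f == 0), numeric(1))),
            0.99)
})

test_that("cluster pruning removes small distant blobs and never adds intensity", {
  f <- matrix(0, 120, 120)
  f[55:65, 55:65] <- 5                      # halo at the cell
  f[10:11, 108:109] <- 3                    # 4-px blob far away
  out <- prune_clusters(f, k = 4, min_size = 20, max_dist = 40,
                        cell_centroid = c(59, 59))
  expect_equal(sum(out[10:11, 108:109]), 0)
  expect_equal(out[55:65, 55:65], f[55:65, 55:65])
  # all clusters large: no-op
  g <- matrix(0, 60, 60); g[5:20, 5:20] <- 2; g[40:55, 40:55] <- 2
  expect_identical(prune_clusters(g, k = 2, min_size = 10, max_dist = 5,
                                  cell_centroid = c(30, 30)), g)
  # random speckle: pruning is monotone in total intensity
  set.seed(8)
  sp <- matrix(0, 80, 80)
  sp[sample(6400, 60)] <- runif(60, 0, 3)
  pr <- prune_clusters(sp, k = 4, min_size = 20, max_dist = 20,
                       cell_centroid = c(40, 40))
  expect_lte(sum(pr), sum(sp))
  expect_identical(prune_clusters(matrix(0, 10, 10), 4, 20, 5, c(5, 5)),
                   matrix(0, 10, 10))
})

test_that("secretion maps have zero support on the cell path, outside the well, and at frame 0", {
  sc <- small_scene(profile_for("I"), seed = 31, n_frames = 25L)
  an <- analyze_scene(sc)
  maps <- an$maps
  expect_equal(max(abs(maps$frames[[1]])), 0)
  outside <- !circle_mask(maps$circle, dim(maps$frames[[1]]))
  cum <- maps$cumulative_masks
  for (t in seq_along(maps$frames)) {
    expect_equal(max(maps$frames[[t]][outside]), 0)
    expect_equal(max(maps$frames[[t]][cum[[t]]]), 0)
    expect_true(all(maps$frames[[t]] >= 0))
  }
  # the non-zero support overlaps the true halo (IoU >= 0.6 at high SNR)
  truth_halo <- sc$truth$bound[[25]] > 0.01 * max(sc$truth$bound[[25]])
  truth_halo <- truth_halo & maps$roi
  support <- maps$frames[[25]] > 0 & maps$roi
  expect_gte(sum(support & truth_halo) / sum(support | truth_halo), 0.6)
})

test_that("no-secretion scenes produce (near-)empty maps", {
  sc <- small_scene(profile_for("NS"), seed = 32, n_frames = 15L)
  an <- analyze_scene(sc)
  nz <- vapply(an$maps$frames, function(f) mean(f > 0), numeric(1))
  expect_lt(max(nz), 0.015)
  expect_equal(an$record$secretion_type, "NS")
})

test_that("the mapping pipeline is translation-equivariant", {
  set.seed(9)
  n <- 80
  mkframes <- function(dr, dc) {
    halo <- matrix(0, n, n)
    halo[(30:40) + dr, (30:40) + dc] <- 40
    base <- matrix(800, n, n)
    list(base, base + halo)
  }
  circ0 <- structure(list(center = c(35, 35), radius = 30, score = 1),
                     class = "well_circle")
  circ1 <- structure(list(center = c(40, 42), radius = 30, score = 1),
                     class = "well_circle")
  mask0 <- matrix(FALSE, n, n); mask0[33:37, 33:37] <- TRUE
  mask1 <- matrix(FALSE, n, n); mask1[38:42, 40:44] <- TRUE
  ref <- mk_stack(list(matrix(800, n, n), matrix(800, n, n)))
  wrap <- function(st, id, role) structure(
    list(stack = st, well_id = id, role = role, crop_origin = c(0L, 0L)),
    class = "well_stack")
  run <- function(dr, dc, circ, mask) build_secretion_maps(
    list(sensing = wrap(mk_stack(mkframes(dr, dc)), "S", "sensing"),
         reference = wrap(ref, "R", "reference")),
    masks = list(mask, mask), circle = circ, sigma = 0)
  m0 <- run(0, 0, circ0, mask0)
  m1 <- run(5, 7, circ1, mask1)
  s0 <- which(m0$frames[[2]] > 0, arr.ind = TRUE)
  s1 <- which(m1$frames[[2]] > 0, arr.ind = TRUE)
  expect_identical(s1[, 1] - 5L, s0[, 1])
  expect_identical(s1[, 2] - 7L, s0[, 2])
})

test_that("secretion maps export to float TIFF with a provenance sidecar", {
  sc <- small_scene(profile_for("I"), seed = 33, n_frames = 8L)
  an <- analyze_scene(sc)
  tf <- withr::local_tempfile(fileext = ".tif")
  write_secretion_maps(an$maps, tf)
  expect_true(file.exists(tf) && file.exists(paste0(tf, ".json")))
  side <- jsonlite::read_json(paste0(tf, ".json"))
  expect_equal(side$sigma, 1.5)
  pages <- tiff::readTIFF(tf, all = TRUE)
  expect_length(pages, 8)
  back <- pages[[8]] * side$intensity_scale
  expect_equal(max(abs(back - an$maps$frames[[8]])), 0, tolerance = 1e-4)
})
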