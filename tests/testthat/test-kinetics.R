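mk_curve <- function(values, dt = 10)
  secretomap:::secretion_curve((seq_along(values) - 1) * dt, values, "tic")

test_that("TIC and area reductions match brute-force pixel loops", {
  maps <- list(frames = list(matrix(c(0, 2, 0, 1, 0, 3, 0, 0, 0), 3, 3)),
               times = 0)
  expect_equal(tic_curve(maps)$value, 6)
  zero <- list(frames = replicate(3, matrix(0, 5, 5), simplify = FALSE),
               times = c(0, 10, 20))
  expect_equal(tic_curve(zero)$value, c(0, 0, 0))
  set.seed(12)
  rnd <- list(frames = replicate(6, matrix(pmax(rnorm(64, 1, 2), 0), 8, 8),
                                 simplify = FALSE), times = (0:5) * 10)
  loop <- vapply(rnd$frames, function(f) {
    s <- 0
    for (i in 1:8) for (j in 1:8) if (f[i, j] != 0) s <- s + f[i, j]
    s
  }, numeric(1))
  expect_equal(tic_curve(rnd)$value, loop, tolerance = 1e-12)
  # permutation invariance of both reductions
  perm <- lapply(rnd$frames, function(f) matrix(sample(f), 8, 8))
  set.seed(13)
  expect_equal(tic_curve(list(frames = perm, times = rnd$times))$value, loop)

  # area: count of non-zero pixels times physical pixel area
  f100 <- matrix(0, 20, 20); f100[1:100] <- 2
  am <- list(frames = list(f100), times = 0)
  expect_equal(area_curve(am, pixel_area = 0.04515625)$value, 4.515625)
  expect_equal(area_curve(zero, 1)$value, c(0, 0, 0))
  full <- list(frames = list(matrix(1, 350, 350)), times = 0)
  expect_equal(area_curve(full, 1)$value, 122500)
})

test_that("onset detection honours the persistence contract", {
  expect_equal(detect_onset(mk_curve(c(0, 0, 1.2, 3.4))), 20)
  expect_true(is.na(detect_onset(mk_curve(rep(0, 6)))))
  blip <- mk_curve(c(0, 5, 0, 0))
  expect_equal(detect_onset(blip, persistence = 1), 10)
  expect_true(is.na(detect_onset(blip, persistence = 2)))
})

test_that("plateau detection bounds ramp-flat(-ramp) curves correctly", {
  # type II shape: plateau starts at the first flat triple, runs to the end
  p2 <- detect_plateau(mk_curve(c(0, 1, 2, 3, 3, 3, 3)), epsilon = 0)
  expect_equal(p2$start, 30)
  expect_equal(p2$end, 60)
  expect_true(p2$at_curve_end)
  expect_equal(p2$plateau_mean, 3)
  # pure ramp has no plateau
  expect_null(detect_plateau(mk_curve(0:10), epsilon = 0))
  # 12-point ramp-flat-ramp, hand-enumerated bounds
  v <- c(0, 1, 2, 3, 4, 4, 4, 4, 5, 6, 7, 8)
  p3 <- detect_plateau(mk_curve(v), epsilon = 0)
  expect_equal(p3$start, 40)   # first flat triple begins at value index 5
  expect_equal(p3$end, 70)     # rise of three successive steps starts there
  expect_false(p3$at_curve_end)
  expect_equal(p3$plateau_mean, 4)
  # the shallow ramp right after onset is not a plateau (min_level guard)
  soft <- c(0, 0.01, 0.02, 0.03, 0.04, 1, 3, 6, 9, 12, 15, 18)
  expect_null(detect_plateau(mk_curve(soft)))
})

test_that("segment fits report per-hour slopes and R squared", {
  t_min <- (0:12) * 10
  exact <- secretomap:::secretion_curve(t_min, 100 * t_min / 60, "tic")
  f <- fit_segment(exact, c(0, 120))
  expect_equal(f$slope, 100)
  expect_equal(f$r_squared, 1)
  expect_false(f$degenerate)
  # 1%-of-range noise keeps R^2 above 0.9
  set.seed(14)
  for (i in 1:5) {
    noisy <- secretomap:::secretion_curve(
      t_min, pmax(100 * t_min / 60 + rnorm(13, 0, 0.01 * 200), 0), "tic")
    expect_gt(fit_segment(noisy, c(0, 120))$r_squared, 0.9)
  }
  const <- mk_curve(rep(5, 8))
  fc <- fit_segment(const, c(0, 70))
  expect_true(fc$degenerate)
  expect_equal(fc$slope, 0)
  expect_equal(fc$r_squared, 0)
  expect_error(fit_segment(exact, c(0, 10)), "fewer than 3")
})

test_that("secretion typing follows the plateau-based decision tree", {
  # noiseless linear curve: type I, one fit over onset..80% max
  lin <- mk_curve(c(0, 1:12) * 10)
  r1 <- classify_and_fit(lin)
  expect_equal(r1$secretion_type, "I")
  expect_length(r1$fits, 1)
  expect_gte(r1$fits[[1]]$r_squared, 0.99)
  # saturating curve: type II
  sat <- mk_curve(c(0, 10, 30, 60, 80, 92, 98, 100, 100, 100, 100, 100))
  r2 <- classify_and_fit(sat)
  expect_equal(r2$secretion_type, "II")
  # ramp-plateau-ramp: type III with two fits; duration sums both intervals
  v3 <- c(0, 10, 20, 30, 40, 40, 40, 40, 40, 55, 70, 85, 100, 115, 130)
  r3 <- classify_and_fit(mk_curve(v3))
  expect_equal(r3$secretion_type, "III")
  expect_length(r3$fits, 2)
  expect_equal(r3$duration_min,
               diff(r3$fits[[1]]$interval) + diff(r3$fits[[2]]$interval))
  # plateau interval itself is never part of the duration
  expect_lte(r3$fits[[1]]$interval[2], r3$plateau$start + 10)
  expect_gte(r3$fits[[2]]$interval[1], r3$plateau$end)
  # all-zero and sub-floor curves are NS
  expect_equal(classify_and_fit(mk_curve(rep(0, 10)))$secretion_type, "NS")
  weak <- mk_curve(c(0, 2, 0, 0, 3, 0, 0, 0, 2, 0))
  expect_equal(classify_and_fit(weak, noise_floor = 1)$secretion_type, "NS")
  expect_equal(coef(r1), r1$fits[[1]]$slope)
})

test_that("population summaries reproduce printed worked examples", {
  mkrec <- function(type, max_tic = 10, dur = 100) {
    structure(list(cell_id = "c", secretion_type = type, onset_min = 0,
                   duration_min = dur, fits = list(), area_fits = list(),
                   max_tic = max_tic, max_area = 1, plateau = NULL,
                   noise_floor = 0, apoptosis_onset = NULL),
              class = "kinetics_record")
  }
  # 111 sorted ASCs with 6 / 4 / 1 of types I / II / III
  recs <- c(lapply(1:6, function(i) mkrec("I")),
            lapply(1:4, function(i) mkrec("II")),
            list(mkrec("III")),
            lapply(1:100, function(i) mkrec("NS")))
  ps <- population_summary(recs)
  expect_equal(round(ps$secreting_fraction, 1), 9.9)
  expect_equal(round(unname(ps$percent[c("I", "II", "III")]), 1),
               c(5.4, 3.6, 0.9))
  expect_equal(sum(ps$counts), 111)
  # all NS
  expect_equal(population_summary(lapply(1:5, function(i)
    mkrec("NS")))$secreting_fraction, 0)
  # sample sd uses the n - 1 denominator
  two <- list(mkrec("I", max_tic = 10), mkrec("I", max_tic = 20))
  ps2 <- population_summary(two)
  expect_equal(ps2$max_tic["mean", "I"], 15)
  expect_equal(ps2$max_tic["sd", "I"], sqrt(50), tolerance = 1e-12)
})

test_that("curves and records export to CSV round-trippably", {
  tic <- mk_curve(c(0, 5, 12, 20))
  rec <- classify_and_fit(tic)
  dir <- withr::local_tempdir()
  export_kinetics(curves = list(tic = tic), records = list(rec), dir = dir)
  back <- utils::read.csv(file.path(dir, "tic_curve.csv"))
  expect_equal(back$tic_au, tic$value)
  recs <- utils::read.csv(file.path(dir, "kinetics_records.csv"))
  expect_equal(recs$secretion_type, "I")
})
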