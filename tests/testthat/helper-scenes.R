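# Shared fixtures: desk-scale synthetic scenes (96 px crop at 2.6 um/px so
# the 200 um well fits a small image) and the standard analysis shorthand.

small_scene <- function(profile, seed, n_frames = 37L, frame_interval = 20,
                        ...) {
  simulate_scene(scene_config(
    crop_side = 96L, object_pixel_size = 2.6, n_frames = n_frames,
    frame_interval = frame_interval, profile = profile, seed = seed, ...))
}

profile_for <- function(label, rate = 1) {
  switch(label,
    NS = secretion_profile("none"),
    I = secretion_profile("constant", rate = rate),
    II = secretion_profile("saturating", rate = rate, t_plateau = 300),
    III = secretion_profile("two_phase", rate = rate, t_plateau = 240,
                            t_resume = 480, rate2 = 1.5 * rate))
}

# Maps + kinetics with ground-truth masks (isolates mapping/kinetics from
# the classifier); returns record, curves and the reference-derived floor.
analyze_scene <- function(scene, prune = FALSE) {
  pair <- list(sensing = scene$sensing, reference = scene$reference)
  maps <- build_secretion_maps(pair, scene$truth$cell_masks, prune = prune)
  tic <- tic_curve(maps)
  empty <- lapply(maps$frames, function(f) matrix(FALSE, nrow(f), ncol(f)))
  ref_pair <- list(sensing = scene$reference, reference = scene$reference)
  floor_tic <- noise_floor_tic(
    build_secretion_maps(ref_pair, empty, circle = maps$circle))
  rec <- classify_and_fit(tic, noise_floor = floor_tic)
  list(maps = maps, tic = tic, record = rec, floor = floor_tic)
}

# Between-class variance of splitting the pixel values of x at `thr`.
otsu_between_var <- function(x, thr) {
  lo <- x[x < thr]; hi <- x[x >= thr]
  if (!length(lo) || !length(hi)) return(0)
  length(lo) * length(hi) * (mean(lo) - mean(hi))^2 / length(x)^2
}

# Brute-force Otsu: exhaustive search over all 8-bit thresholds for the
# maximizer of the between-class variance, computed directly on the data.
otsu_bruteforce <- function(x) {
  cand <- seq(1 / 256, 255 / 256, by = 1 / 256)
  v <- vapply(cand, function(t) otsu_between_var(x, t), numeric(1))
  list(threshold = cand[which.max(v)], var = max(v))
}

# Dense 2D correlation oracle (direct loops, zero-order reflect padding) for
# validating the separable filtering path.
dense_filter_oracle <- function(image, kern2d) {
  r <- (nrow(kern2d) - 1L) %/% 2L
  n <- nrow(image); m <- ncol(image)
  ri <- c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))
  ci <- c(rev(seq_len(r)), seq_len(m), m + 1 - seq_len(r))
  p <- image[ri, ci]
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m))
    out[i, j] <- sum(p[i:(i + 2L * r), j:(j + 2L * r)] * kern2d)
  out
}
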