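# Synthetic plasmonic microwell scenes with ground truth.
#
# A scene is a pair of cropped well stacks (sensing + empty reference) plus
# the simulator-side truth: per-frame bound-mass maps, cell masks, centroids,
# event times and the true secretion-type label. The optical chain is
# modelled physically: secreted mass binds near the cell (Langmuir-limited,
# diffusion-widened halo), bound mass redshifts the local
# extraordinary-optical-transmission resonance, and a narrowband LED probing
# the flank of the Lorentzian line converts the shift into a transmitted-
# intensity change.

#' Secretion time profile
#'
#' @param type one of `"none"`, `"constant"`, `"saturating"`, `"two_phase"`,
#'   `"burst"`, `"burst_plus_gradual"`.
#' @param rate secretion rate, mass units per minute (first phase).
#' @param t_onset secretion start, minutes.
#' @param t_plateau end of the first phase (types `saturating`/`two_phase`).
#' @param t_resume start of the second phase (`two_phase`).
#' @param rate2 second-phase rate (`two_phase`; default `rate`).
#' @param t_burst burst time, minutes (`burst*` types).
#' @param mass total burst mass (`burst*` types).
#' @param spread_min burst duration, minutes (default 10).
#' @return classed list used by [simulate_scene()].
#' @export
secretion_profile <- function(type = c("none", "constant", "saturating",
                                       "two_phase", "burst",
                                       "burst_plus_gradual"),
                              rate = 1, t_onset = 0, t_plateau = NULL,
                              t_resume = NULL, rate2 = NULL, t_burst = NULL,
                              mass = NULL, spread_min = 10) {
  type <- match.arg(type)
  if (type %in% c("saturating", "two_phase") && is.null(t_plateau))
    stop("t_plateau required for type ", type)
  if (type == "two_phase" && is.null(t_resume))
    stop("t_resume required for two_phase")
  if (grepl("^burst", type) && (is.null(t_burst) || is.null(mass)))
    stop("t_burst and mass required for burst profiles")
  structure(list(type = type, rate = rate, t_onset = t_onset,
                 t_plateau = t_plateau, t_resume = t_resume,
                 rate2 = if (is.null(rate2)) rate else rate2,
                 t_burst = t_burst, mass = mass, spread_min = spread_min),
            class = "secretion_profile")
}

#' Instantaneous secretion rate
#'
#' @param profile a [secretion_profile()].
#' @param t time in minutes (vectorized).
#' @return rate in mass units per minute.
#' @export
secretion_rate <- function(profile, t) {
  r <- numeric(length(t))
  p <- profile
  r <- switch(p$type,
    none = r,
    constant = ifelse(t >= p$t_onset, p$rate, 0),
    saturating = ifelse(t >= p$t_onset & t < p$t_plateau, p$rate, 0),
    two_phase = ifelse(t >= p$t_onset & t < p$t_plateau, p$rate,
                       ifelse(t >= p$t_resume, p$rate2, 0)),
    burst = ifelse(t >= p$t_burst & t < p$t_burst + p$spread_min,
                   p$mass / p$spread_min, 0),
    burst_plus_gradual = ifelse(t >= p$t_burst & t < p$t_burst + p$spread_min,
                                p$mass / p$spread_min, 0) +
                         ifelse(t >= p$t_burst + p$spread_min, p$rate, 0))
  r
}

profile_truth <- function(profile, t_end) {
  p <- profile
  switch(p$type,
    none = list(label = "NS", onset = NA_real_),
    constant = list(label = "I", onset = p$t_onset),
    saturating = list(label = "II", onset = p$t_onset,
                      plateau_start = p$t_plateau, plateau_end = t_end),
    two_phase = list(label = "III", onset = p$t_onset,
                     plateau_start = p$t_plateau, plateau_end = p$t_resume),
    burst = list(label = "burst", onset = p$t_burst),
    burst_plus_gradual = list(label = "burst_gradual", onset = p$t_burst))
}

#' Optical transduction parameters
#'
#' The sensor's transmission resonance is modelled as a Lorentzian line
#' centred at `lambda0` with the given FWHM; binding shifts it red by
#' `dlambda_max * b / b_max`. A Gaussian narrowband LED parked on the blue
#' flank converts shifts into transmitted-intensity changes.
#'
#' @param lambda0 resonance wavelength in water, nm (default 860.7).
#' @param fwhm resonance full width at half maximum, nm (default 22.6).
#' @param led_center LED centre wavelength, nm (default: half an FWHM blue
#'   of the resonance, the steepest-slope operating point).
#' @param led_fwhm LED bandwidth FWHM, nm.
#' @param dlambda_max resonance shift at full surface coverage, nm.
#' @param linear use the documented first-order (small-shift) approximation
#'   instead of the full band integral.
#' @return classed list.
#' @export
optics_config <- function(lambda0 = 860.7, fwhm = 22.6,
                          led_center = lambda0 - fwhm / 2, led_fwhm = 10,
                          dlambda_max = 15, linear = FALSE) {
  structure(list(lambda0 = lambda0, fwhm = fwhm, led_center = led_center,
                 led_fwhm = led_fwhm, dlambda_max = dlambda_max,
                 linear = linear),
            class = "optics_config")
}

# Band-integrated relative transmission T(shift)/T(0) on a shift grid.
transmission_curve <- function(optics, shifts) {
  led_sd <- optics$led_fwhm / (2 * sqrt(2 * log(2)))
  lam <- seq(optics$led_center - 5 * led_sd, optics$led_center + 5 * led_sd,
             length.out = 801L)
  led <- exp(-(lam - optics$led_center)^2 / (2 * led_sd^2))
  led <- led / sum(led)
  lorentz <- function(delta) 1 / (1 + (2 * delta / optics$fwhm)^2)
  vapply(shifts, function(s) sum(led * lorentz(lam - (optics$lambda0 + s))),
         numeric(1L))
}

#' Transduce a bound-density map into a transmitted-intensity image
#'
#' @param bound_density matrix of bound mass density (same units as `b_max`).
#' @param optics an [optics_config()].
#' @param b_max surface capacity; local shift is
#'   `dlambda_max * min(bound / b_max, 1)`.
#' @param baseline baseline intensity (scalar or matrix).
#' @return intensity image `baseline * T(shift) / T(0)`.
#' @export
transduce <- function(bound_density, optics, b_max = 1, baseline = 1) {
  shift <- optics$dlambda_max * pmin(bound_density / b_max, 1)
  if (optics$linear) {
    t0 <- transmission_curve(optics, 0)
    slope <- (transmission_curve(optics, 1e-3) - t0) / 1e-3
    rel <- 1 + (slope / t0) * shift
  } else {
    grid <- seq(0, optics$dlambda_max, length.out = 257L)
    tc <- transmission_curve(optics, grid)
    rel <- matrix(stats::approx(grid, tc / tc[1L], xout = as.numeric(shift))$y,
                  nrow(shift), ncol(shift))
  }
  baseline * rel
}

#' Transduction nonlinearity factor
#'
#' Relative departure of the full band-integrated response from the
#' first-order (linear) approximation at a given resonance shift.
#'
#' @param optics an [optics_config()].
#' @param shift resonance shift in nm (vectorized).
#' @return `|full - linear| / |full response|` at each shift.
#' @export
transduction_nonlinearity <- function(optics, shift) {
  t0 <- transmission_curve(optics, 0)
  slope <- (transmission_curve(optics, 1e-3) - t0) / 1e-3
  full <- transmission_curve(optics, shift) / t0 - 1
  lin <- (slope / t0) * shift
  ifelse(abs(full) < .Machine$double.eps, 0, abs(full - lin) / abs(full))
}

#' Synthetic scene configuration
#'
#' Defaults reproduce the study conditions: a 200 um x 50 um microwell
#' imaged in a 350 px square crop at 0.65 um/px, 73 frames at 10 min
#' (12 h), a ~15 um hybridoma-like cell 30% darker than the background with
#' ~1.3 um^2 mean squared displacement over the run, and additive read noise
#' with slow multiplicative drift shared between paired wells.
#'
#' @param well_diameter,well_height microwell geometry, um.
#' @param object_pixel_size pixel size at the sample plane, um/px.
#' @param crop_side crop side, px.
#' @param frame_interval frame spacing, minutes.
#' @param n_frames number of frames.
#' @param cell_radius cell disc radius, um.
#' @param cell_contrast fractional darkening of the cell vs background.
#' @param motion_msd_target target mean squared displacement over the run,
#'   um^2.
#' @param profile a [secretion_profile()].
#' @param halo list: `sigma0` initial puff sd (um; default `cell_radius`),
#'   `D` effective diffusion coefficient (um^2/min), `anisotropy` optional
#'   vector of angular weights (recycled around the circle; `NULL` =
#'   isotropic).
#' @param binding list: `b_max` surface capacity (density units per pixel),
#'   `capture_eff` capture efficiency in `[0, 1]`.
#' @param optics an [optics_config()].
#' @param noise list: `read_sd` additive Gaussian sd (grey levels), `shot`
#'   logical Poisson shot noise, `drift_amp` relative amplitude of the
#'   shared sinusoidal drift, `drift_period` minutes.
#' @param baseline_intensity background grey level inside the well.
#' @param division `NULL` or `list(t_div = minutes)`: the mother disc
#'   elongates over the two frames before `t_div`, then splits into two
#'   daughters.
#' @param seed RNG seed; identical config + seed gives bit-identical stacks.
#' @param keep_truth_maps store per-frame true bound-mass maps (memory!).
#' @return classed `scene_config` list.
#' @export
scene_config <- function(well_diameter = 200, well_height = 50,
                         object_pixel_size = 0.65, crop_side = 350L,
                         frame_interval = 10, n_frames = 73L,
                         cell_radius = 7.5, cell_contrast = 0.3,
                         motion_msd_target = 1.3,
                         profile = secretion_profile("constant", rate = 1),
                         halo = list(), binding = list(), optics = optics_config(),
                         noise = list(), baseline_intensity = 1000,
                         division = NULL, seed = 0L, keep_truth_maps = TRUE) {
  halo <- utils::modifyList(list(sigma0 = cell_radius, D = 0.5, anisotropy = NULL),
                            halo)
  binding <- utils::modifyList(list(b_max = 1, capture_eff = 1), binding)
  noise <- utils::modifyList(list(read_sd = 2, shot = FALSE, drift_amp = 0.001,
                                  drift_period = 600), noise)
  stopifnot(well_diameter > 0, well_height > 0, object_pixel_size > 0,
            crop_side >= 16L, frame_interval > 0, n_frames >= 1L,
            cell_radius > 0, cell_contrast >= 0, cell_contrast < 1,
            halo$sigma0 > 0, halo$D >= 0, binding$b_max > 0,
            binding$capture_eff > 0, binding$capture_eff <= 1,
            noise$read_sd >= 0, baseline_intensity > 0)
  if (well_diameter / object_pixel_size > crop_side)
    stop("well (", well_diameter, " um) does not fit the ", crop_side,
         " px crop at ", object_pixel_size, " um/px")
  structure(list(well_diameter = well_diameter, well_height = well_height,
                 object_pixel_size = object_pixel_size,
                 crop_side = as.integer(crop_side),
                 frame_interval = frame_interval, n_frames = as.integer(n_frames),
                 cell_radius = cell_radius, cell_contrast = cell_contrast,
                 motion_msd_target = motion_msd_target, profile = profile,
                 halo = halo, binding = binding, optics = optics,
                 noise = noise, baseline_intensity = baseline_intensity,
                 division = division, seed = as.integer(seed),
                 keep_truth_maps = keep_truth_maps),
            class = "scene_config")
}

disc_mask <- function(n, center, radius_px) {
  outer((seq_len(n) - 1 - center[1L])^2, (seq_len(n) - 1 - center[2L])^2, "+") <=
    radius_px^2
}

# Angularly weighted Gaussian deposition kernel, normalized over `support`.
deposition_kernel <- function(n, center, sigma_px, anisotropy, support) {
  dr <- outer(seq_len(n) - 1 - center[1L], rep(1, n))
  dc <- outer(rep(1, n), seq_len(n) - 1 - center[2L])
  w <- exp(-(dr^2 + dc^2) / (2 * sigma_px^2))
  if (!is.null(anisotropy)) {
    k <- length(anisotropy)
    th <- atan2(dc, dr)  # (-pi, pi]
    idx <- pmin(k, 1L + floor((th + pi) / (2 * pi) * k))
    w <- w * matrix(anisotropy[idx], n, n)
  }
  w[!support] <- 0
  s <- sum(w)
  if (s > 0) w / s else w
}

#' Bound-density field of a secretion profile at time t
#'
#' Accumulates the deposition of the configured profile from the start of
#' the run to `t`: each step's released mass lands as an angularly weighted
#' Gaussian puff centred at the cell, whose width grows diffusively with the
#' age of the secretion, scaled by the Langmuir factor `1 - b / b_max`.
#' Binding is irreversible, so the field is non-decreasing per pixel.
#'
#' @param config a [scene_config()].
#' @param t evaluation time, minutes.
#' @param positions optional `n_steps x 2` matrix of 0-based cell positions
#'   (px) per frame; default: the well centre (static cell).
#' @return bound-density matrix (`crop_side` square).
#' @export
secretion_field <- function(config, t, positions = NULL) {
  n <- config$crop_side
  h <- config$object_pixel_size
  center <- c((n - 1) / 2, (n - 1) / 2)
  well <- disc_mask(n, center, (config$well_diameter / 2) / h)
  times <- seq(0, t, by = config$frame_interval)
  if (is.null(positions))
    positions <- matrix(rep(center, each = length(times)), ncol = 2L)
  acc <- accumulate_bound(config, times, positions, well)
  acc$bound[[length(acc$bound)]]
}

# Stepwise bound-mass accumulation over `times`; returns per-step maps.
accumulate_bound <- function(config, times, positions, well) {
  n <- config$crop_side
  h <- config$object_pixel_size
  b <- matrix(0, n, n)
  out <- vector("list", length(times))
  out[[1L]] <- b
  p <- config$profile
  for (i in seq_along(times)[-1L]) {
    dt <- times[i] - times[i - 1L]
    tm <- (times[i] + times[i - 1L]) / 2
    m <- secretion_rate(p, tm) * dt
    if (m > 0) {
      onset <- profile_truth(p, times[length(times)])$onset
      age <- max(tm - onset, 0)
      sigma_px <- sqrt(config$halo$sigma0^2 + 4 * config$halo$D * age) / h
      ctr <- positions[min(i, nrow(positions)), ]
      w <- deposition_kernel(n, ctr, sigma_px, config$halo$anisotropy, well)
      b_max <- config$binding$b_max
      add <- m * w * config$binding$capture_eff * pmax(1 - b / b_max, 0)
      b <- b + pmin(add, b_max - b)  # a step can never overfill a site
    }
    out[[i]] <- b
  }
  list(bound = out)
}

#' Simulate a sensing/reference microwell scene
#'
#' Renders a cropped sensing well (bright nanohole-array background, darker
#' microwell wall outside the circle, a dark motile cell disc, and the
#' transduced secretion halo) and a matching empty reference well sharing
#' the global drift and noise statistics, together with full ground truth.
#'
#' @param config a [scene_config()].
#' @return object of class `scene`: `sensing` and `reference` `well_stack`s
#'   and `truth` (per-frame `bound` maps if kept, `cell_masks`, `centroids`
#'   px, `total_secreted` mass, `events`, `label`, `snr`, `peak_signal`,
#'   `division_frames`).
#' @export
simulate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_local_seed(config$seed, simulate_scene_impl(config))
}

simulate_scene_impl <- function(config) {
  n <- config$crop_side
  h <- config$object_pixel_size
  nf <- config$n_frames
  times <- (seq_len(nf) - 1L) * config$frame_interval
  center <- c((n - 1) / 2, (n - 1) / 2)
  rw_px <- (config$well_diameter / 2) / h
  well <- disc_mask(n, center, rw_px)
  baseline <- matrix(0.55 * config$baseline_intensity, n, n)
  baseline[well] <- config$baseline_intensity

  # seeded random walk rescaled to hit the MSD target exactly
  steps <- matrix(stats::rnorm(2L * nf, sd = 1), ncol = 2L)
  steps[1L, ] <- 0
  path <- apply(steps, 2L, cumsum)
  emp <- if (nf > 1L) mean(rowSums(path[-1L, , drop = FALSE]^2)) else 0
  if (emp > 0 && config$motion_msd_target > 0)
    path <- path * sqrt(config$motion_msd_target / emp)
  else path[] <- 0
  pos_um <- path                      # um displacement from well centre
  pos_px <- sweep(pos_um / h, 2L, center, "+")
  max_off <- 0.6 * rw_px
  pos_px <- pmin(pmax(pos_px, center[1L] - max_off), center[1L] + max_off)

  r_cell_px <- config$cell_radius / h
  div <- config$division
  div_axis <- if (!is.null(div)) stats::runif(1, 0, pi) else NA_real_
  cell_masks <- vector("list", nf)
  division_frames <- integer(0)
  for (t in seq_len(nf)) {
    if (!is.null(div) && times[t] >= div$t_div) {
      sep <- min(2.2 * r_cell_px, 1.2 * r_cell_px +
                   0.5 * r_cell_px * (times[t] - div$t_div) / config$frame_interval)
      off <- sep / 2 * c(cos(div_axis), sin(div_axis))
      cell_masks[[t]] <- disc_mask(n, pos_px[t, ] + off, r_cell_px) |
        disc_mask(n, pos_px[t, ] - off, r_cell_px)
    } else if (!is.null(div) && times[t] >= div$t_div - 2 * config$frame_interval) {
      # elongating mother just before the split
      off <- 0.5 * r_cell_px * c(cos(div_axis), sin(div_axis))
      cell_masks[[t]] <- disc_mask(n, pos_px[t, ] + off, r_cell_px) |
        disc_mask(n, pos_px[t, ] - off, r_cell_px)
      division_frames <- c(division_frames, t)
    } else {
      cell_masks[[t]] <- disc_mask(n, pos_px[t, ], r_cell_px)
    }
    if (!is.null(div) && times[t] >= div$t_div)
      division_frames <- c(division_frames, t)
  }

  acc <- accumulate_bound(config, times, pos_px, well)
  bound <- acc$bound

  drift <- 1 + config$noise$drift_amp *
    sin(2 * pi * times / config$noise$drift_period)
  render <- function(t, with_cell) {
    img <- transduce(bound[[t]], config$optics, config$binding$b_max, baseline)
    img[!well] <- baseline[!well]
    if (with_cell) img[cell_masks[[t]]] <- img[cell_masks[[t]]] * (1 - config$cell_contrast)
    img
  }
  clean_first <- render(1L, TRUE)
  peak_signal <- max(abs(render(nf, FALSE) - transduce(bound[[1L]], config$optics,
                                                      config$binding$b_max,
                                                      baseline)))
  frames_s <- vector("list", nf)
  frames_r <- vector("list", nf)
  for (t in seq_len(nf)) {
    s <- render(t, TRUE) * drift[t]
    r <- baseline * drift[t]
    s <- s + stats::rnorm(n * n, sd = config$noise$read_sd)
    r <- r + stats::rnorm(n * n, sd = config$noise$read_sd)
    if (isTRUE(config$noise$shot)) {
      s <- stats::rpois(n * n, pmax(s, 0))
      r <- stats::rpois(n * n, pmax(r, 0))
    }
    frames_s[[t]] <- matrix(round(pmax(s, 0)), n, n)
    frames_r[[t]] <- matrix(round(pmax(r, 0)), n, n)
  }

  tr <- profile_truth(config$profile, times[nf])
  truth <- list(
    bound = if (config$keep_truth_maps) bound else NULL,
    total_secreted = sum(bound[[nf]]),
    cell_masks = cell_masks,
    centroids = pos_px,
    events = tr[setdiff(names(tr), "label")],
    label = tr$label,
    division_frames = unique(division_frames),
    peak_signal = peak_signal,
    snr = if (config$noise$read_sd > 0) peak_signal / config$noise$read_sd
          else Inf,
    well_center = center, well_radius_px = rw_px)

  mkstack <- function(frames, id, role)
    structure(list(stack = image_stack(frames, times), well_id = id,
                   role = role, crop_origin = c(0L, 0L)),
              class = "well_stack")
  structure(list(sensing = mkstack(frames_s, "S1", "sensing"),
                 reference = mkstack(frames_r, "R1", "reference"),
                 truth = truth, config = config),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("Synthetic scene: %d frames, label '%s', SNR %.1f\n",
              n_frames(x$sensing$stack), x$truth$label, x$truth$snr))
  invisible(x)
}

#' Write a simulated scene to disk
#'
#' Writes sensing/reference TIFF stacks, per-frame truth mask TIFFs, a
#' ground-truth JSON and the resolved configuration.
#'
#' @param scene a [simulate_scene()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_timelapse(scene$sensing, file.path(dir, "sensing.tif"))
  write_timelapse(scene$reference, file.path(dir, "reference.tif"))
  masks <- image_stack(lapply(scene$truth$cell_masks, function(m) m + 0),
                       scene$sensing$stack$times)
  write_timelapse(masks, file.path(dir, "truth_cell_masks.tif"), bits = 8L)
  tr <- scene$truth
  jsonlite::write_json(
    list(label = tr$label, events = tr$events,
         total_secreted = tr$total_secreted,
         centroids = tr$centroids, peak_signal = tr$peak_signal,
         snr = tr$snr, division_frames = tr$division_frames),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  cfg <- scene$config
  cfg$profile <- unclass(cfg$profile)
  cfg$optics <- unclass(cfg$optics)
  yaml::write_yaml(unclass(cfg), file.path(dir, "scene_config.yaml"))
  invisible(dir)
}
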