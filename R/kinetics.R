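# Reduction of secretion map stacks to TIC / secretion-area curves, onset and
# plateau detection, linear segment fitting, secretion typing, and population
# summaries.

#' Total intensity change (TIC) curve
#'
#' Per-frame sum of the non-zero pixels of each secretion map frame. With the
#' nonnegativity clamp this equals the full-frame sum.
#'
#' @param maps a `secretion_maps` object (or list with `frames`, `times`).
#' @return object of class `secretion_curve` (data frame `time_min`,
#'   `value`; attribute `kind = "tic"`, arbitrary grey-level units).
#' @export
tic_curve <- function(maps) {
  v <- vapply(maps$frames, function(f) sum(f[f > 0]), numeric(1L))
  secretion_curve(maps$times, v, "tic")
}

#' Secretion area curve
#'
#' Number of non-zero secretion-map pixels times the physical pixel area.
#'
#' @param maps a `secretion_maps` object.
#' @param pixel_area area of one pixel at the sample plane, um^2 (square of
#'   [object_pixel_size()]).
#' @return `secretion_curve` (um^2; attribute `kind = "area"`).
#' @export
area_curve <- function(maps, pixel_area) {
  stopifnot(pixel_area > 0)
  v <- vapply(maps$frames, function(f) sum(f > 0) * pixel_area, numeric(1L))
  secretion_curve(maps$times, v, "area")
}

secretion_curve <- function(times, values, kind) {
  stopifnot(length(times) == length(values), all(values >= 0))
  structure(data.frame(time_min = as.numeric(times), value = as.numeric(values)),
            kind = kind, class = c("secretion_curve", "data.frame"))
}

#' @export
print.secretion_curve <- function(x, ...) {
  cat(sprintf("%s curve: %d frames, t = %g..%g min, max %.4g\n",
              toupper(attr(x, "kind")), nrow(x), x$time_min[1L],
              x$time_min[nrow(x)], max(x$value)))
  invisible(x)
}

#' @export
plot.secretion_curve <- function(x, ...) {
  kind <- attr(x, "kind")
  ylab <- if (identical(kind, "area")) expression(Secretion~area~(mu * m^2))
          else "TIC (a.u.)"
  graphics::plot(x$time_min / 60, x$value, type = "o", pch = 16, cex = 0.6,
                 xlab = "Time (h)", ylab = ylab, ...)
  invisible(x)
}

#' Detect the onset of secretion
#'
#' Earliest time with curve value > 0 sustained for `persistence` consecutive
#' frames (default 1: the first strictly positive frame).
#'
#' @param curve a `secretion_curve`.
#' @param persistence required consecutive positive frames (>= 1).
#' @return onset time in minutes, or `NA` if never reached.
#' @export
detect_onset <- function(curve, persistence = 1L) {
  stopifnot(persistence >= 1L)
  pos <- curve$value > 0
  n <- length(pos)
  for (i in seq_len(n - persistence + 1L))
    if (all(pos[i:(i + persistence - 1L)])) return(curve$time_min[i])
  NA_real_
}

#' Detect a secretion plateau
#'
#' The plateau starts at the first time after onset from which the curve does
#' not increase for three successive frames (each step at most
#' `epsilon * max(value)`), and ends at the first later time from which the
#' curve rises again for three successive frames, or at the end of the curve.
#'
#' @param curve a `secretion_curve`.
#' @param epsilon relative step tolerance (fraction of the curve maximum;
#'   default 0.01, `epsilon = 0` reproduces the strict rule).
#' @param onset onset time (minutes); computed via [detect_onset()] when
#'   missing.
#' @param min_level minimum curve level (fraction of the maximum) at which a
#'   plateau may start (default 0.2). Guards against the shallow ramp just
#'   after onset, whose steps are below `epsilon * max` simply because the
#'   signal is still small, being read as a plateau.
#' @return list (`start`, `end` in minutes, `plateau_mean`, `at_curve_end`)
#'   or `NULL` when no plateau exists. Requires at least six frames from
#'   onset (a flat triple cannot be bounded on fewer).
#' @export
detect_plateau <- function(curve, epsilon = 0.01, onset = NULL,
                           min_level = 0.2) {
  if (is.null(onset)) onset <- detect_onset(curve)
  if (is.na(onset)) return(NULL)
  i0 <- match(onset, curve$time_min)
  n <- nrow(curve)
  if (n - i0 < 5L) return(NULL)
  mx <- max(curve$value)
  tol <- epsilon * mx
  steps <- diff(curve$value)  # steps[i] = value[i+1] - value[i]
  flat3 <- function(i) i + 2L <= length(steps) && all(steps[i:(i + 2L)] <= tol) &&
    curve$value[i] >= min_level * mx
  rise3 <- function(i) i + 2L <= length(steps) && all(steps[i:(i + 2L)] > tol)
  p <- NA_integer_
  for (i in i0:(n - 3L)) if (flat3(i)) { p <- i; break }
  if (is.na(p)) return(NULL)
  q <- NA_integer_
  if (p + 1L <= n - 3L)
    for (i in (p + 1L):(n - 3L)) if (rise3(i)) { q <- i; break }
  at_end <- is.na(q)
  if (at_end) q <- n
  idx <- p:q
  list(start = curve$time_min[p], end = curve$time_min[q],
       plateau_mean = mean(curve$value[idx]), at_curve_end = at_end)
}

#' Least-squares linear fit over a time interval
#'
#' @param curve a `secretion_curve`.
#' @param interval `c(t0, t1)` in minutes (inclusive); needs >= 3 samples.
#' @return object of class `linear_fit`: `slope` (per hour), `intercept`,
#'   `r_squared`, `interval`, `n`, `degenerate` (TRUE when the segment is
#'   constant, reported with slope 0 and R^2 0).
#' @export
fit_segment <- function(curve, interval) {
  stopifnot(length(interval) == 2L, interval[1L] <= interval[2L])
  sel <- curve$time_min >= interval[1L] & curve$time_min <= interval[2L]
  if (sum(sel) < 3L) stop("fit interval contains fewer than 3 samples")
  t_h <- curve$time_min[sel] / 60
  y <- curve$value[sel]
  if (stats::var(y) < .Machine$double.eps) {
    fit <- list(slope = 0, intercept = y[1L], r_squared = 0, degenerate = TRUE)
  } else {
    m <- stats::lm(y ~ t_h)
    r2 <- 1 - sum(stats::residuals(m)^2) / sum((y - mean(y))^2)
    fit <- list(slope = unname(stats::coef(m)[2L]),
                intercept = unname(stats::coef(m)[1L]),
                r_squared = min(max(r2, 0), 1),
                degenerate = FALSE)
  }
  structure(c(fit, list(interval = as.numeric(interval), n = sum(sel))),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear fit over %g-%g min: slope %.4g /h, R^2 %.3f (n = %d)%s\n",
              x$interval[1L], x$interval[2L], x$slope, x$r_squared, x$n,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# First time at/after `from` where the curve reaches `target`, pushed right so
# the fit window holds >= 3 samples.
reach_time <- function(curve, from, target) {
  i0 <- which(curve$time_min >= from)[1L]
  hit <- which(curve$value >= target & curve$time_min >= from)
  j <- if (length(hit)) hit[1L] else nrow(curve)
  j <- min(max(j, i0 + 2L), nrow(curve))
  curve$time_min[j]
}

#' Classify a secretion profile and fit its kinetic segments
#'
#' Applies the full kinetics workflow to a TIC curve: onset detection, noise
#' floor gating, plateau detection, secretion typing, and per-segment linear
#' fits. Types: non-secreting (NS); I, linear over the run (fit from onset
#' until the curve reaches 80% of its maximum); II, rise then plateau to the
#' end of the run (same fit interval); III, rise-plateau-rise (two fits: from
#' onset to 80% of the plateau mean, and from the end of the plateau to 80%
#' of the maximum). Duration is the fitted-interval length (the sum of both
#' for type III), never including the plateau.
#'
#' @param curve TIC `secretion_curve`.
#' @param area optional matching area `secretion_curve`; supplies `max_area`
#'   and an adsorption-rate fit over the same interval(s).
#' @param noise_floor minimum TIC to count as secreting (same a.u. as the
#'   curve; typically a multiple of the reference-well residual TIC sd, see
#'   [noise_floor_tic()]).
#' @param floor_persistence consecutive frames the curve must stay above
#'   `noise_floor` to count as secreting (default 3). Residual noise
#'   exceedances are isolated single-frame events, whereas genuinely bound
#'   mass persists, so a sustained exceedance separates the two far more
#'   reliably than the maximum alone.
#' @param epsilon plateau step tolerance (see [detect_plateau()]).
#' @param persistence onset persistence in frames (see [detect_onset()]).
#' @param cell_id identifier carried into the record.
#' @param apoptosis_onset optional externally annotated apoptosis onset
#'   (minutes); stored, never computed.
#' @return object of class `kinetics_record` with fields `cell_id`,
#'   `secretion_type` (`"NS"`, `"I"`, `"II"`, `"III"`), `onset_min`,
#'   `duration_min`, `fits` (list of [fit_segment()] results; empty for NS,
#'   two for type III), `area_fits`, `max_tic`, `max_area`, `plateau`,
#'   `apoptosis_onset`.
#' @export
classify_and_fit <- function(curve, area = NULL, noise_floor = 0,
                             floor_persistence = 3L, epsilon = 0.01,
                             persistence = 1L, cell_id = "cell",
                             apoptosis_onset = NULL) {
  max_tic <- max(curve$value)
  max_area <- if (!is.null(area)) max(area$value) else NA_real_
  onset <- detect_onset(curve, persistence = persistence)
  rec <- function(type, fits = list(), area_fits = list(), plateau = NULL) {
    duration <- if (length(fits))
      sum(vapply(fits, function(f) diff(f$interval), numeric(1L))) else NA_real_
    structure(list(cell_id = cell_id, secretion_type = type,
                   onset_min = onset, duration_min = duration, fits = fits,
                   area_fits = area_fits, max_tic = max_tic,
                   max_area = max_area, plateau = plateau,
                   noise_floor = noise_floor,
                   apoptosis_onset = apoptosis_onset),
              class = "kinetics_record")
  }
  above <- curve$value > noise_floor
  k <- min(floor_persistence, max(1L, length(above) - 1L))
  sustained <- any(vapply(seq_len(length(above) - k + 1L),
                          function(i) all(above[i:(i + k - 1L)]), logical(1L)))
  if (is.na(onset) || !sustained) {
    onset <- NA_real_
    return(rec("NS"))
  }
  plateau <- detect_plateau(curve, epsilon = epsilon, onset = onset)
  fit_pair <- function(iv) {
    f <- fit_segment(curve, iv)
    af <- if (!is.null(area)) list(fit_segment(area, iv)) else list()
    list(fit = f, area = af)
  }
  if (is.null(plateau) || plateau$at_curve_end) {
    iv <- c(onset, reach_time(curve, onset, 0.8 * max_tic))
    fp <- fit_pair(iv)
    type <- if (is.null(plateau)) "I" else "II"
    return(rec(type, list(fp$fit), fp$area, plateau))
  }
  iv1 <- c(onset, reach_time(curve, onset, 0.8 * plateau$plateau_mean))
  iv2 <- c(plateau$end, reach_time(curve, plateau$end, 0.8 * max_tic))
  fp1 <- fit_pair(iv1); fp2 <- fit_pair(iv2)
  rec("III", list(fp1$fit, fp2$fit), c(fp1$area, fp2$area), plateau)
}

#' @export
print.kinetics_record <- function(x, ...) {
  cat(sprintf("Kinetics record '%s': type %s\n", x$cell_id, x$secretion_type))
  if (x$secretion_type != "NS") {
    cat(sprintf("  onset %g min, duration %g min, max TIC %.4g a.u.\n",
                x$onset_min, x$duration_min, x$max_tic))
    for (f in x$fits) { cat("  "); print(f) }
  } else {
    cat(sprintf("  max TIC %.4g a.u. (noise floor %.4g)\n", x$max_tic,
                x$noise_floor))
  }
  invisible(x)
}

#' @export
summary.kinetics_record <- function(object, ...) print(object)

#' @export
coef.kinetics_record <- function(object, ...) {
  if (!length(object$fits)) return(numeric(0))
  vapply(object$fits, function(f) f$slope, numeric(1L))
}

#' Noise floor from a reference well's residual TIC
#'
#' Processes a reference well as if it were a sensing well (against a second
#' reference) and returns a multiple of the sd of the resulting residual TIC,
#' for use as the NS/secreting gate in [classify_and_fit()].
#'
#' @param ref_maps `secretion_maps` built from a reference-reference pair.
#' @param multiple multiplier on the residual TIC sd (default 5).
#' @return noise floor in TIC a.u.
#' @export
noise_floor_tic <- function(ref_maps, multiple = 5) {
  multiple * stats::sd(tic_curve(ref_maps)$value)
}

#' Population summary of kinetics records
#'
#' @param records list of `kinetics_record` objects.
#' @return object of class `population_stats`: total `n`, per-type counts
#'   and percentages (of the whole population), the secreting fraction in
#'   percent, and per-type mean/sd (n - 1 denominator) of max TIC, max area,
#'   secretion rate (first-segment slope) and duration.
#' @export
population_summary <- function(records) {
  stopifnot(length(records) >= 1L)
  types <- factor(vapply(records, function(r) r$secretion_type, character(1L)),
                  levels = c("NS", "I", "II", "III"))
  n <- length(records)
  counts <- table(types)
  pct <- 100 * as.numeric(counts) / n
  names(pct) <- names(counts)
  stat <- function(get) {
    sapply(c("I", "II", "III"), function(ty) {
      v <- unlist(lapply(records[types == ty], get))
      v <- v[is.finite(v)]
      c(mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
        n = length(v))
    })
  }
  structure(
    list(n = n, counts = c(counts), percent = pct,
         secreting_fraction = 100 * sum(counts[c("I", "II", "III")]) / n,
         max_tic = stat(function(r) r$max_tic),
         max_area = stat(function(r) r$max_area),
         rate = stat(function(r) if (length(r$fits)) r$fits[[1L]]$slope else NA_real_),
         duration = stat(function(r) r$duration_min)),
    class = "population_stats")
}

#' @export
print.population_stats <- function(x, ...) {
  cat(sprintf("Population of %d cells: %.1f%% secreting\n", x$n,
              x$secreting_fraction))
  for (ty in c("I", "II", "III"))
    cat(sprintf("  type %-3s: %3d cells (%.1f%%)\n", ty, x$counts[[ty]],
                x$percent[[ty]]))
  cat(sprintf("  NS      : %3d cells (%.1f%%)\n", x$counts[["NS"]],
              x$percent[["NS"]]))
  invisible(x)
}

#' Export curves and records as CSV/JSON
#'
#' @param curves named list of `secretion_curve` objects.
#' @param records list of `kinetics_record` objects.
#' @param dir output directory (created if needed).
#' @return paths written, invisibly.
#' @export
export_kinetics <- function(curves = list(), records = list(), dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(curves)) {
    p <- file.path(dir, paste0(nm, "_curve.csv"))
    cu <- curves[[nm]]
    df <- data.frame(time_min = cu$time_min)
    df[[if (identical(attr(cu, "kind"), "area")) "area_um2" else "tic_au"]] <- cu$value
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (length(records)) {
    df <- do.call(rbind, lapply(records, function(r) data.frame(
      cell_id = r$cell_id, secretion_type = r$secretion_type,
      onset_min = r$onset_min, duration_min = r$duration_min,
      max_tic = r$max_tic, max_area = r$max_area,
      rate_au_per_h = if (length(r$fits)) r$fits[[1L]]$slope else NA_real_,
      r_squared = if (length(r$fits)) r$fits[[1L]]$r_squared else NA_real_)))
    p <- file.path(dir, "kinetics_records.csv")
    utils::write.csv(df, p, row.names = FALSE)
    jsonlite::write_json(lapply(records, unclass),
                         file.path(dir, "kinetics_records.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    paths <- c(paths, p, file.path(dir, "kinetics_records.json"))
  }
  invisible(paths)
}
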