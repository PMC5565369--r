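#' Compute the extent time series of a filopodium
#'
#' The extent at each frame is the Euclidean distance between the tracked
#' tip and base points,
#' `E = sqrt((x_tip - x_base)^2 + (y_tip - y_base)^2)`,
#' so it is invariant under rigid motion of the whole tissue (base and tip
#' translated/rotated together).
#'
#' @param pairs Paired frames from [pair_frames()].
#' @param track The [filopodium_track()] the pairs came from (supplies the
#'   frame interval and window bounds).
#' @return An object of class `extent_series`: list with `times` (min),
#'   `extents` (um), `frame_interval`, and flags `touches_window_start` /
#'   `touches_window_end` set when the first/last paired frame coincides
#'   with the window boundary (the filopodium was already present at the
#'   start, or still present at the end, of the recording).
#' @export
compute_extent_series <- function(pairs, track) {
  if (nrow(pairs) < 2) stop("need at least 2 paired frames")
  e <- sqrt((pairs$x_tip - pairs$x_base)^2 + (pairs$y_tip - pairs$y_base)^2)
  structure(
    list(times = pairs$t, extents = e,
         frame_interval = track$frame_interval,
         touches_window_start = pairs$frame[1] == track$window_start_frame,
         touches_window_end =
           pairs$frame[nrow(pairs)] == track$window_end_frame),
    class = "extent_series")
}

#' Build an extent series directly from times and extents
#'
#' Convenience constructor used by the model-fitting layer and by tests.
#'
#' @param times Strictly increasing times in minutes.
#' @param extents Non-negative extents in um, one per time.
#' @param frame_interval Minutes per frame; time spacings must be integer
#'   multiples of it.
#' @param touches_window_start,touches_window_end Truncation flags.
#' @return An `extent_series` object.
#' @export
extent_series <- function(times, extents, frame_interval = 2,
                          touches_window_start = FALSE,
                          touches_window_end = FALSE) {
  if (length(times) != length(extents))
    stop("times and extents must have equal length")
  if (length(times) < 1) stop("empty series")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(extents < 0)) stop("extents must be >= 0")
  mult <- diff(times) / frame_interval
  if (any(abs(mult - round(mult)) > 1e-9))
    stop("time spacing must be an integer multiple of frame_interval")
  structure(
    list(times = as.numeric(times), extents = as.numeric(extents),
         frame_interval = frame_interval,
         touches_window_start = isTRUE(touches_window_start),
         touches_window_end = isTRUE(touches_window_end)),
    class = "extent_series")
}

# Origin/end convention shared by both models: the filopodium origin (end)
# is taken one frame before (after) the recorded data, at extent zero.
series_anchors <- function(series) {
  if (all(series$extents <= 0)) stop("no extension: all extents are zero")
  dt <- series$frame_interval
  list(t_origin = series$times[1] - dt,
       t_end = series$times[length(series$times)] + dt)
}

#' Fit the two-phase "triangle" dynamic model
#'
#' The triangle model describes a filopodium that elongates and immediately
#' retracts.  Its base is the lifetime; its apex is the maximum extent.
#' The origin (end) is placed one frame before (after) the recorded data at
#' extent zero.  The elongation velocity Ve is the slope of the segment
#' from the origin to the first frame attaining the maximum extent Emax;
#' the retraction velocity Vr is minus the slope from the last frame
#' attaining Emax to the end.  Both are reported as positive magnitudes in
#' um/min.  A run of frames tied at Emax gives the model a flat apex.
#'
#' @param series An `extent_series`.
#' @return Object of class `triangle_model`: `t_origin`, `t_peak_first`,
#'   `t_peak_last`, `t_end`, `Emax`, `Ve`, `Vr`, `lifetime`.
#' @export
fit_triangle <- function(series) {
  a <- series_anchors(series)
  Emax <- max(series$extents)
  at_max <- which(series$extents >= Emax - 1e-12 * max(1, Emax))
  t_pk1 <- series$times[at_max[1]]
  t_pk2 <- series$times[at_max[length(at_max)]]
  structure(
    list(t_origin = a$t_origin, t_peak_first = t_pk1, t_peak_last = t_pk2,
         t_end = a$t_end, Emax = Emax,
         Ve = Emax / (t_pk1 - a$t_origin),
         Vr = Emax / (a$t_end - t_pk2),
         lifetime = a$t_end - a$t_origin),
    class = c("triangle_model", "filopodium_model"))
}

#' Fit the three-phase "trapezoid" dynamic model
#'
#' The trapezoid model adds a stationary phase between elongation and
#' retraction.  The stationary phase is characterised by Es, the extent at
#' the half lifetime (linearly interpolated between the two bracketing
#' frames when the half-lifetime falls between frames), and Vs, the mean
#' of the consecutive frame-to-frame velocities within the stationary
#' span.  The stationary span runs from the first to the last experimental
#' point with extent greater than or equal to Es; the stationary segment is
#' the line of slope Vs anchored at (t_half, Es).  The left (elongation)
#' side connects the origin to the stationary line at the span start; the
#' right (retraction) side connects the stationary line at the span end to
#' the end.  With a single stationary point the model degenerates to the
#' triangle construction (Vs = 0).
#'
#' @param series An `extent_series`.
#' @return Object of class `trapezoid_model`: `t_origin`, `t_s_start`,
#'   `t_s_end`, `t_end`, `t_half`, `Es`, `Vs`, `Ve`, `Vr`, `lifetime`.
#' @export
fit_trapezoid <- function(series) {
  a <- series_anchors(series)
  t_h <- (a$t_origin + a$t_end) / 2
  Es <- if (length(series$times) == 1) series$extents[1] else
    stats::approx(series$times, series$extents, xout = t_h, rule = 2)$y
  in_stat <- which(series$extents >= Es - 1e-12 * max(1, Es))
  i1 <- in_stat[1]; i2 <- in_stat[length(in_stat)]
  t_s1 <- series$times[i1]; t_s2 <- series$times[i2]
  if (i2 > i1) {
    dE <- diff(series$extents[i1:i2])
    dtv <- diff(series$times[i1:i2])
    Vs <- mean(dE / dtv)
  } else {
    Vs <- 0
  }
  stat_line <- function(t) Es + Vs * (t - t_h)
  Ve <- (stat_line(t_s1) - 0) / (t_s1 - a$t_origin)
  Vr <- (stat_line(t_s2) - 0) / (a$t_end - t_s2)
  structure(
    list(t_origin = a$t_origin, t_s_start = t_s1, t_s_end = t_s2,
         t_end = a$t_end, t_half = t_h, Es = Es, Vs = Vs,
         Ve = Ve, Vr = Vr, lifetime = a$t_end - a$t_origin),
    class = c("trapezoid_model", "filopodium_model"))
}

#' Evaluate a fitted dynamic model curve
#'
#' Piecewise-linear evaluation through the model vertices; zero outside
#' `[t_origin, t_end]` and continuous everywhere.
#'
#' @param model A `triangle_model` or `trapezoid_model`.
#' @param times Times (minutes) at which to evaluate.
#' @return Extents in um.
#' @export
model_curve <- function(model, times) {
  v <- model_vertices(model)
  out <- stats::approx(v$t, v$E, xout = times, rule = 2,
                       ties = "ordered")$y
  out[times < model$t_origin | times > model$t_end] <- 0
  out
}

model_vertices <- function(model) UseMethod("model_vertices")

#' @export
model_vertices.triangle_model <- function(model) {
  # Single apex at the intersection of the two side lines.  With a unique
  # peak frame the apex is (t_peak, Emax); with frames tied at Emax the
  # sides pass through the first/last tied frame and meet above the
  # plateau, so a genuine plateau is penalised relative to the trapezoid.
  t_apex <- (model$Ve * model$t_origin + model$Vr * model$t_end) /
    (model$Ve + model$Vr)
  list(t = c(model$t_origin, t_apex, model$t_end),
       E = c(0, model$Ve * (t_apex - model$t_origin), 0))
}

#' @export
model_vertices.trapezoid_model <- function(model) {
  line <- function(t) model$Es + model$Vs * (t - model$t_half)
  t <- c(model$t_origin, model$t_s_start, model$t_s_end, model$t_end)
  E <- c(0, line(model$t_s_start), line(model$t_s_end), 0)
  keep <- !duplicated(t)
  list(t = t[keep], E = E[keep])
}

#' Classify filopodium dynamics as triangle or trapezoid
#'
#' Both models are fitted and evaluated at the observed frame times; the
#' label is the model with the smaller root-mean-square error against the
#' observed extents.  Ties go to `triangle`, the simpler two-phase model,
#' with one exception: when the fits tie but two or more frames are tied
#' at the maximum extent, the series shows a stationary plateau that the
#' single-apex triangle merely happens to pass through (its sides straddle
#' the apex), and the label is `trapezoid`.  Degenerate trapezoids
#' (single-point stationary span on a unique peak, identical to the
#' triangle construction) are labelled `triangle`.
#'
#' @param series An `extent_series`.
#' @return List with `model_label` (`"triangle"` or `"trapezoid"`),
#'   `rmse_triangle`, `rmse_trapezoid`, and the two fitted models
#'   (`triangle`, `trapezoid`).
#' @export
classify_dynamics <- function(series) {
  tri <- fit_triangle(series)
  trap <- fit_trapezoid(series)
  rmse <- function(m) {
    r <- model_curve(m, series$times) - series$extents
    sqrt(mean(r^2))
  }
  r_tri <- rmse(tri)
  r_trap <- rmse(trap)
  tol <- 1e-9 * max(1, r_tri, r_trap)
  label <- if (r_trap < r_tri - tol) "trapezoid"
  else if (abs(r_trap - r_tri) <= tol && tri$t_peak_first < tri$t_peak_last)
    "trapezoid"               # tied fits, but the maximum is a plateau
  else "triangle"
  list(model_label = label, rmse_triangle = r_tri, rmse_trapezoid = r_trap,
       triangle = tri, trapezoid = trap)
}

#' Summarise one filopodium track
#'
#' Runs the full per-filopodium analysis: pair frames, compute the extent
#' series, fit and classify both dynamic models, and extract Emax,
#' lifetime, Ve and Vr.  A filopodium already present at the window start
#' (or born fully extended, with its first observed extent at Emax) has no
#' observable elongation phase, so Ve is not reported; one still present at
#' the window end has no observable retraction phase, so Vr is not
#' reported.  Emax and lifetime are always reported (lifetime is the
#' observed-window lifetime for truncated tracks).
#'
#' @param track A [filopodium_track()].
#' @return Object of class `filopodium_summary`: one-row data frame with
#'   columns `filopodium_id`, `group_label`, `Emax_um`, `lifetime_min`,
#'   `model_label`, `Ve_um_per_min`, `Vr_um_per_min` (NA when the phase is
#'   absent), `has_elongation`, `has_retraction`, `rmse_triangle`,
#'   `rmse_trapezoid`.
#' @export
summarize_filopodium <- function(track) {
  pairs <- pair_frames(track)
  series <- compute_extent_series(pairs, track)
  cls <- classify_dynamics(series)
  win <- cls[[cls$model_label]]
  Emax <- max(series$extents)
  has_elong <- !series$touches_window_start &&
    series$extents[1] < Emax - 1e-12 * max(1, Emax)
  has_retr <- !series$touches_window_end
  out <- data.frame(
    filopodium_id = track$filopodium_id,
    group_label = track$group_label,
    Emax_um = Emax,
    lifetime_min = win$lifetime,
    model_label = cls$model_label,
    Ve_um_per_min = if (has_elong) win$Ve else NA_real_,
    Vr_um_per_min = if (has_retr) win$Vr else NA_real_,
    has_elongation = has_elong,
    has_retraction = has_retr,
    rmse_triangle = cls$rmse_triangle,
    rmse_trapezoid = cls$rmse_trapezoid,
    stringsAsFactors = FALSE)
  class(out) <- c("filopodium_summary", class(out))
  out
}

#' Summarise a cohort of filopodium tracks
#'
#' @param tracks List of [filopodium_track()] objects.
#' @return Data frame with one [summarize_filopodium()] row per track.
#' @export
summarize_cohort <- function(tracks) {
  rows <- lapply(tracks, function(tr) {
    s <- summarize_filopodium(tr)
    class(s) <- "data.frame"
    s
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
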