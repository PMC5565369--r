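#' Configuration for the synthetic track generator
#'
#' The generator emits cohorts of base/tip tracks whose extent-over-time
#' follows known triangle or trapezoid kinetics, with additive Gaussian
#' localisation noise on the tip coordinates, a common straight-line tissue
#' drift on the base, and truncation by the recording window.  Defaults
#' mirror the imaging protocol the analysis is designed for: 2 min frame
#' interval, 30 min window, 49 x 76 um region.  Model parameter ranges are
#' uniform stand-ins chosen to span the scale of histoblast filopodia
#' (a few um maximum extent, lifetimes well inside the window).
#'
#' @param n_tracks Number of filopodia to generate.
#' @param p_trapezoid Probability that a track follows trapezoid dynamics.
#' @param Emax_range Uniform range of maximum extent, um.
#' @param lifetime_range Uniform range of lifetime, minutes (snapped to the
#'   frame grid; at least one frame each of elongation and retraction).
#' @param plateau_fraction_range Uniform range of the fraction of the
#'   lifetime spent stationary (trapezoid only).
#' @param Vs_range Uniform range of the stationary-phase slope, um/min.
#'   Default `c(0, 0)`: a flat plateau, the canonical stationary phase.
#' @param noise_sigma_um Std. dev. of Gaussian noise added to each tip
#'   coordinate, um.  When `noise_relative = TRUE` it is instead read as a
#'   fraction of each track's Emax (e.g. 0.02 for 2 percent).
#' @param noise_relative Interpret `noise_sigma_um` relative to Emax.
#' @param frame_interval_min,window_min,region_width_um,region_height_um
#'   Acquisition parameters, as in [acquisition_meta()].
#' @param base_drift_um_per_min Speed of the common tissue drift applied to
#'   the base path (direction drawn per track).
#' @param allow_truncation When `TRUE` (default) filopodium births are
#'   spread so that some tracks are clipped by the recording window, as in
#'   real movies.  When `FALSE` every track lies fully inside the window
#'   (requires `lifetime_range[2] <= window_min`), which makes every label
#'   and parameter identifiable — the regime used for exact-recovery and
#'   classification-accuracy checks.
#' @param seed Integer seed; identical seeds give identical cohorts.
#'
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_tracks = 100,
                             p_trapezoid = 0.5,
                             Emax_range = c(2, 8),
                             lifetime_range = c(8, 24),
                             plateau_fraction_range = c(0.3, 0.6),
                             Vs_range = c(0, 0),
                             noise_sigma_um = 0,
                             noise_relative = FALSE,
                             frame_interval_min = 2,
                             window_min = 30,
                             region_width_um = 49,
                             region_height_um = 76,
                             base_drift_um_per_min = 0.1,
                             allow_truncation = TRUE,
                             seed = 1L) {
  stopifnot(n_tracks >= 0,
            p_trapezoid >= 0, p_trapezoid <= 1,
            length(Emax_range) == 2, Emax_range[1] <= Emax_range[2],
            Emax_range[1] > 0,
            length(lifetime_range) == 2,
            lifetime_range[1] <= lifetime_range[2],
            length(plateau_fraction_range) == 2,
            plateau_fraction_range[1] <= plateau_fraction_range[2],
            plateau_fraction_range[1] >= 0, plateau_fraction_range[2] < 1,
            length(Vs_range) == 2, Vs_range[1] <= Vs_range[2],
            noise_sigma_um >= 0,
            frame_interval_min > 0, window_min > 0,
            base_drift_um_per_min >= 0)
  structure(as.list(environment()), class = "generator_config")
}

meta_from_config <- function(config) {
  acquisition_meta(frame_interval_min = config$frame_interval_min,
                   window_min = config$window_min,
                   region_width_um = config$region_width_um,
                   region_height_um = config$region_height_um)
}

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so generation never perturbs user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

# Build the ground-truth model object for a parameter set.  Vertex times
# lie on the frame grid so that noiseless sampling is lossless.
truth_model <- function(label, params) {
  if (label == "triangle") {
    structure(
      list(t_origin = params$t_origin,
           t_peak_first = params$t_origin + params$elong_min,
           t_peak_last = params$t_origin + params$elong_min,
           t_end = params$t_origin + params$elong_min + params$retract_min,
           Emax = params$Emax,
           Ve = params$Emax / params$elong_min,
           Vr = params$Emax / params$retract_min,
           lifetime = params$elong_min + params$retract_min),
      class = c("triangle_model", "filopodium_model"))
  } else {
    t_s1 <- params$t_origin + params$elong_min
    t_s2 <- t_s1 + params$plateau_min
    t_end <- t_s2 + params$retract_min
    t_h <- (params$t_origin + t_end) / 2
    line <- function(t) params$Emax + params$Vs * (t - t_h)
    structure(
      list(t_origin = params$t_origin, t_s_start = t_s1, t_s_end = t_s2,
           t_end = t_end, t_half = t_h, Es = params$Emax, Vs = params$Vs,
           Ve = line(t_s1) / (t_s1 - params$t_origin),
           Vr = line(t_s2) / (t_end - t_s2),
           lifetime = t_end - params$t_origin),
      class = c("trapezoid_model", "filopodium_model"))
  }
}

#' Generate one synthetic filopodium track
#'
#' The base follows a straight drift path; the tip sits at
#' `base + u * E(t)` for a fixed unit direction `u` and the model extent
#' curve `E(t)`, plus Gaussian noise on the tip coordinates.  Only window
#' frames at which the model extent is positive are emitted (the
#' origin/end frames at extent zero are, by convention, not part of the
#' recorded data).
#'
#' @param label `"triangle"` or `"trapezoid"`.
#' @param params List: `t_origin` (min, on the frame grid), `Emax` (um),
#'   `elong_min`, `retract_min` (phase durations, min, positive multiples
#'   of the frame interval), and for trapezoids `plateau_min` and `Vs`.
#' @param config A [generator_config()].
#' @param filopodium_id Id to stamp on the track.
#' @param group_label Cohort label.
#'
#' @return List with `track` (a [filopodium_track()]) and `truth` (one-row
#'   data frame: `filopodium_id`, `true_label`, `true_Ve`, `true_Vr`,
#'   `true_Emax`, `true_lifetime`, `truncated_start`, `truncated_end`,
#'   `ve_eligible`, `vr_eligible`).
#'   Errors with "unobservable track" when fewer than two positive-extent
#'   frames fall inside the window.
#' @export
gen_track <- function(label, params, config, filopodium_id = 1L,
                      group_label = "synthetic") {
  label <- match.arg(label, c("triangle", "trapezoid"))
  model <- truth_model(label, params)
  dt <- config$frame_interval_min
  frames <- seq_len(as.integer(round(config$window_min / dt)) + 1L)
  tt <- (frames - 1) * dt
  ext <- model_curve(model, tt)
  keep <- ext > 1e-12
  if (sum(keep) < 2)
    stop("unobservable track: model yields fewer than 2 frames in window")
  frames <- frames[keep]; tt <- tt[keep]; ext <- ext[keep]

  p0 <- c(stats::runif(1, 0, config$region_width_um),
          stats::runif(1, 0, config$region_height_um))
  th_d <- stats::runif(1, 0, 2 * pi)
  drift <- config$base_drift_um_per_min * c(cos(th_d), sin(th_d))
  th_u <- stats::runif(1, 0, 2 * pi)
  u <- c(cos(th_u), sin(th_u))
  sigma <- if (config$noise_relative)
    config$noise_sigma_um * params$Emax else config$noise_sigma_um

  bx <- p0[1] + drift[1] * tt
  by <- p0[2] + drift[2] * tt
  tx <- bx + u[1] * ext + stats::rnorm(length(tt), 0, sigma)
  ty <- by + u[2] * ext + stats::rnorm(length(tt), 0, sigma)

  track <- filopodium_track(
    filopodium_id,
    base = data.frame(frame = frames, x = bx, y = by),
    tip = data.frame(frame = frames, x = tx, y = ty),
    frame_interval = dt,
    window_start_frame = 1L,
    window_end_frame = as.integer(round(config$window_min / dt)) + 1L,
    group_label = group_label)
  truncated_start <- frames[1] == 1L
  truncated_end <- frames[length(frames)] == track$window_end_frame
  truth <- data.frame(
    filopodium_id = as.integer(filopodium_id),
    true_label = label,
    true_Ve = model$Ve, true_Vr = model$Vr,
    true_Emax = params$Emax,
    true_lifetime = model$lifetime,
    truncated_start = truncated_start,
    truncated_end = truncated_end,
    # phase observability, from the noiseless extents: the elongation
    # phase is observable unless the track starts at the window or its
    # first recorded extent is already the maximum
    ve_eligible = !truncated_start &&
      ext[1] < max(ext) - 1e-12 * max(1, max(ext)),
    vr_eligible = !truncated_end,
    stringsAsFactors = FALSE)
  list(track = track, truth = truth)
}

# Draw one parameter set on the frame grid.  Phase durations are whole
# numbers of frames; for trapezoids the plateau is long enough that the
# half-lifetime falls inside it, so Es equals the plateau level and the
# stationary span is identifiable.
sample_params <- function(label, config) {
  dt <- config$frame_interval_min
  L_frames <- max(2L, as.integer(round(
    stats::runif(1, config$lifetime_range[1], config$lifetime_range[2]) / dt)))
  Emax <- stats::runif(1, config$Emax_range[1], config$Emax_range[2])
  if (label == "triangle") {
    k_e <- max(1L, min(L_frames - 1L,
                       as.integer(round(stats::runif(1, 0.35, 0.65) * L_frames))))
    k_r <- L_frames - k_e
    params <- list(Emax = Emax, elong_min = k_e * dt, retract_min = k_r * dt)
  } else {
    pf <- stats::runif(1, config$plateau_fraction_range[1],
                       config$plateau_fraction_range[2])
    k_p <- max(1L, as.integer(round(pf * L_frames)))
    rem <- max(2L, L_frames - k_p)
    k_e <- max(1L, min(rem - 1L,
                       as.integer(round(stats::runif(1, 0.35, 0.65) * rem))))
    k_r <- rem - k_e
    if (abs(k_e - k_r) > k_p) {        # keep the half-lifetime on the plateau
      k_e <- rem %/% 2L
      k_r <- rem - k_e
    }
    params <- list(Emax = Emax, elong_min = k_e * dt,
                   retract_min = k_r * dt, plateau_min = k_p * dt,
                   Vs = stats::runif(1, config$Vs_range[1],
                                     config$Vs_range[2]))
  }
  L_min <- (params$elong_min + params$retract_min +
            if (label == "trapezoid") params$plateau_min else 0)
  if (config$allow_truncation) {
    lo <- -4
    hi <- max(lo, config$window_min - L_min + 4)
  } else {
    if (L_min > config$window_min)
      stop("lifetime exceeds window; cannot place untruncated track")
    lo <- 0
    hi <- config$window_min - L_min
  }
  grid <- seq(lo, hi, by = dt)
  params$t_origin <- grid[sample.int(length(grid), 1)]
  params
}

#' Generate a synthetic cohort of filopodium tracks
#'
#' Labels are drawn Bernoulli(`p_trapezoid`), parameters uniformly over the
#' configured ranges, and the output is fully reproducible from
#' `config$seed`.  Filopodium births are spread uniformly on the frame grid
#' from shortly before the window start to shortly before the window end,
#' so some tracks are naturally truncated by the window (their flags are
#' recorded).
#'
#' @param config A [generator_config()].
#' @param group_label Cohort label stamped on every track.
#' @return List with `tracks` (list of [filopodium_track()]) and `truth`
#'   (data frame of ground-truth records, one row per track).
#' @export
gen_cohort <- function(config, group_label = "synthetic") {
  with_seed(config$seed, {
    tracks <- vector("list", config$n_tracks)
    truths <- vector("list", config$n_tracks)
    i <- 0L
    while (i < config$n_tracks) {
      label <- if (stats::runif(1) < config$p_trapezoid)
        "trapezoid" else "triangle"
      params <- sample_params(label, config)
      res <- tryCatch(
        gen_track(label, params, config, filopodium_id = i + 1L,
                  group_label = group_label),
        error = function(e) NULL)  # unobservable draw: redraw
      if (is.null(res)) next
      i <- i + 1L
      tracks[[i]] <- res$track
      truths[[i]] <- res$truth
    }
    truth <- if (config$n_tracks > 0) do.call(rbind, truths) else
      data.frame(filopodium_id = integer(), true_label = character(),
                 true_Ve = numeric(), true_Vr = numeric(),
                 true_Emax = numeric(), true_lifetime = numeric(),
                 truncated_start = logical(), truncated_end = logical(),
                 ve_eligible = logical(), vr_eligible = logical())
    list(tracks = tracks, truth = truth)
  })
}

#' Generate a synthetic morphogen-gradient intensity profile
#'
#' Emulates a 1D fluorescence profile along the A/P axis: a uniform
#' background, a plateau of amplitude `amplitude` over `[0, plateau_len]`,
#' then an exponential decay with length constant `decay_len`, plus
#' additive Gaussian noise.  For a threshold at fraction `f` of the
#' above-background peak, the true domain width is
#' `plateau_len + decay_len * log(1/f)` (0 when `amplitude` is 0),
#' available via [true_domain_width()].
#'
#' @param plateau_len,decay_len Plateau length and decay length constant, um.
#' @param amplitude Peak intensity above background, a.u.
#' @param background Background intensity, a.u.
#' @param noise_sigma Std. dev. of additive Gaussian noise, a.u.
#' @param spacing_um Sample spacing along the axis, um.
#' @param total_len_um Profile length; default reaches 8 decay lengths past
#'   the plateau so the distal 10 percent is essentially pure background.
#' @param channel_label Channel name (e.g. `"Ptc"`, `"Ci"`).
#' @param seed Optional seed for the noise.
#' @return An [intensity_profile()].
#' @export
gen_intensity_profile <- function(plateau_len, decay_len,
                                  amplitude = 100, background = 10,
                                  noise_sigma = 0, spacing_um = 0.5,
                                  total_len_um = NULL,
                                  channel_label = "synthetic",
                                  seed = NULL) {
  stopifnot(plateau_len > 0, decay_len > 0, amplitude >= 0,
            background >= 0, noise_sigma >= 0, spacing_um > 0)
  if (is.null(total_len_um)) total_len_um <- plateau_len + 8 * decay_len
  pos <- seq(0, total_len_um, by = spacing_um)
  clean <- background + amplitude *
    ifelse(pos <= plateau_len, 1, exp(-(pos - plateau_len) / decay_len))
  noisy <- if (noise_sigma > 0) {
    gen <- function() clean + stats::rnorm(length(pos), 0, noise_sigma)
    if (is.null(seed)) gen() else with_seed(seed, gen())
  } else clean
  intensity_profile(pos, pmax(noisy, 0), channel_label = channel_label)
}

#' Closed-form domain width of a synthetic plateau + exponential profile
#'
#' @param plateau_len,decay_len As in [gen_intensity_profile()].
#' @param amplitude Peak amplitude above background.
#' @param threshold_fraction Fraction of the above-background peak.
#' @return Width in um: `plateau_len + decay_len * log(1/threshold_fraction)`,
#'   or 0 when `amplitude` is 0.
#' @export
true_domain_width <- function(plateau_len, decay_len, amplitude = 100,
                              threshold_fraction = 0.5) {
  if (amplitude <= 0) return(0)
  plateau_len + decay_len * log(1 / threshold_fraction)
}

#' Write a generated cohort as track + ground-truth CSV files
#'
#' @param cohort Output of [gen_cohort()].
#' @param tracks_path,truth_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort_csv <- function(cohort, tracks_path, truth_path) {
  write_csv_tracks(cohort$tracks, tracks_path)
  write_table_csv(cohort$truth, truth_path)
  invisible(c(tracks_path, truth_path))
}
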