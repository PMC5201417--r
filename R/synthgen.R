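# Synthetic-data generators with known ground truth for the three data
# classes the pipeline consumes: steady-state ATPase curves, wound-recoil
# displacement traces / kymographs, and coupled myosin-pulse / apical-area
# cell traces. Every generator is seeded and bit-reproducible.

# -- parameter containers -----------------------------------------------------

#' Michaelis-Menten parameter set
#'
#' Parameters of the actin-activated steady-state ATPase model
#' `rate = k_basal + k_cat * [A] / (K_app + [A])`.
#'
#' @param k_basal basal ATP hydrolysis rate without actin (s^-1), >= 0.
#' @param k_cat maximal actin-activated rate above basal (s^-1), >= 0.
#' @param K_app apparent actin affinity: actin concentration at half-maximal
#'   activation (uM), > 0.
#' @return an object of class `mm_params`.
#' @export
mm_params <- function(k_basal, k_cat, K_app) {
  if (any(!is.finite(c(k_basal, k_cat, K_app)))) {
    stop_invalid("Michaelis-Menten parameters must be finite")
  }
  if (k_basal < 0 || k_cat < 0) stop_invalid("k_basal and k_cat must be >= 0")
  if (K_app <= 0) stop_invalid("K_app must be > 0")
  structure(list(k_basal = k_basal, k_cat = k_cat, K_app = K_app),
            class = "mm_params")
}

#' Michaelis-Menten rate at given actin concentrations
#'
#' @param params an [mm_params()] object.
#' @param actin actin concentrations (uM), >= 0.
#' @return hydrolysis rates (s^-1).
#' @export
mm_rate <- function(params, actin) {
  stopifnot(inherits(params, "mm_params"))
  if (any(actin < 0)) stop_invalid("actin concentrations must be >= 0")
  params$k_basal + params$k_cat * actin / (params$K_app + actin)
}

#' Kelvin-Voigt parameter set
#'
#' Spring (stiffness `zeta`) and dashpot (viscosity `eta`) in parallel under
#' tension `tension`. Only the ratios are identifiable from displacement:
#' amplitude `A = tension/zeta` (um), relaxation time `tau = eta/zeta` (s) and
#' initial recoil velocity `v0 = tension/eta = A/tau` (um/s).
#'
#' @param tension tensile force in the tissue before the cut (arbitrary
#'   consistent force units), > 0.
#' @param zeta spring stiffness, > 0.
#' @param eta dashpot viscosity coefficient, > 0.
#' @return an object of class `kv_params` with derived `amplitude`, `tau`
#'   and `v0` fields.
#' @export
kv_params <- function(tension, zeta, eta) {
  if (any(!is.finite(c(tension, zeta, eta))) || tension <= 0 || zeta <= 0 || eta <= 0) {
    stop_invalid("Kelvin-Voigt parameters must all be finite and > 0")
  }
  structure(list(tension = tension, zeta = zeta, eta = eta,
                 amplitude = tension / zeta, tau = eta / zeta,
                 v0 = tension / eta),
            class = "kv_params")
}

# -- ATPase datasets ----------------------------------------------------------

#' Construct an ATPase dataset
#'
#' Tidy container of replicated (actin, rate) observations for one myosin
#' variant and phosphorylation state.
#'
#' @param actin_uM actin concentrations (uM), >= 0.
#' @param rate_per_s steady-state ATP hydrolysis rates (s^-1), finite.
#' @param replicate replicate identifiers (recycled).
#' @param variant variant label, e.g. `"RLC-TS"`.
#' @param mlck_treated logical; `TRUE` for MLCK-phosphorylated RLC.
#' @return a `data.frame` of class `atpase_dataset` with columns
#'   `variant`, `mlck_treated`, `actin_uM`, `rate_per_s`, `replicate`.
#' @export
atpase_dataset <- function(actin_uM, rate_per_s, replicate = 1L,
                           variant = "synthetic", mlck_treated = TRUE) {
  if (length(actin_uM) == 0) stop_invalid("empty actin concentration vector")
  if (any(actin_uM < 0)) stop_invalid("actin concentrations must be >= 0")
  if (any(!is.finite(rate_per_s))) stop_invalid("rates must be finite")
  if (length(rate_per_s) != length(actin_uM)) {
    stop_invalid("actin_uM and rate_per_s must have equal length")
  }
  df <- data.frame(variant = variant, mlck_treated = mlck_treated,
                   actin_uM = actin_uM, rate_per_s = rate_per_s,
                   replicate = rep_len(replicate, length(actin_uM)),
                   stringsAsFactors = FALSE)
  class(df) <- c("atpase_dataset", "data.frame")
  df
}

#' Generate a synthetic steady-state ATPase dataset
#'
#' Draws replicated hydrolysis rates from the Michaelis-Menten curve plus
#' additive Gaussian noise, truncated at zero to keep rates physical.
#'
#' @param params generating truth, an [mm_params()] object.
#' @param actin_concs actin concentrations assayed (uM).
#' @param noise_sd Gaussian noise standard deviation (s^-1), >= 0.
#' @param n_replicates replicates per concentration, >= 1.
#' @param seed integer seed; identical seed and arguments give bit-identical
#'   datasets.
#' @param variant,mlck_treated labels stored in the dataset.
#' @return an [atpase_dataset()].
#' @export
gen_atpase_dataset <- function(params, actin_concs, noise_sd = 0.02,
                               n_replicates = 4L, seed = 1L,
                               variant = "synthetic", mlck_treated = TRUE) {
  stopifnot(inherits(params, "mm_params"))
  if (length(actin_concs) == 0) stop_invalid("actin_concs must be non-empty")
  if (any(actin_concs < 0)) stop_invalid("actin_concs must be >= 0")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (n_replicates < 1) stop_invalid("n_replicates must be >= 1")
  set.seed(as.integer(seed))
  actin <- rep(actin_concs, times = n_replicates)
  replicate <- rep(seq_len(n_replicates), each = length(actin_concs))
  truth <- mm_rate(params, actin)
  rates <- pmax(0, truth + rnorm(length(actin), 0, noise_sd))
  atpase_dataset(actin, rates, replicate, variant, mlck_treated)
}

# -- displacement traces and kymographs ---------------------------------------

#' Construct a wound-edge displacement trace
#'
#' @param times time points (s), strictly increasing, with `t = 0` at the
#'   first post-cut frame.
#' @param displacement wound-edge displacement (um); `NA` marks frames where
#'   no wound was detectable; non-missing values must be >= 0.
#' @param embryo_id,genotype optional metadata labels.
#' @return an object of class `displacement_trace`.
#' @export
displacement_trace <- function(times, displacement, embryo_id = NA_character_,
                               genotype = NA_character_) {
  if (length(times) != length(displacement)) {
    stop_invalid("times and displacement must have equal length")
  }
  if (length(times) && any(diff(times) <= 0)) {
    stop_invalid("times must be strictly increasing")
  }
  ok <- !is.na(displacement)
  if (any(displacement[ok] < 0)) stop_invalid("displacement must be >= 0")
  structure(list(times = as.numeric(times),
                 displacement = as.numeric(displacement),
                 embryo_id = embryo_id, genotype = genotype),
            class = "displacement_trace")
}

#' Generate a synthetic Kelvin-Voigt recoil trace
#'
#' Samples `x(t) = A (1 - exp(-t/tau))` on a regular time grid and adds
#' Gaussian noise truncated at zero (displacement is physically non-negative).
#'
#' @param params either a [kv_params()] object or a list with `amplitude`
#'   (um) and `tau` (s) entries.
#' @param dt frame interval (s), > 0.
#' @param duration total trace duration (s), >= `dt`.
#' @param noise_sd Gaussian noise standard deviation (um), >= 0.
#' @param seed integer seed.
#' @param embryo_id,genotype metadata labels.
#' @return a [displacement_trace()].
#' @export
gen_displacement_trace <- function(params, dt, duration, noise_sd = 0,
                                   seed = 1L, embryo_id = NA_character_,
                                   genotype = NA_character_) {
  if (inherits(params, "kv_params")) {
    amplitude <- params$amplitude
    tau <- params$tau
  } else {
    amplitude <- params$amplitude
    tau <- params$tau
    if (is.null(amplitude) || is.null(tau)) {
      stop_invalid("params must be kv_params or a list with amplitude and tau")
    }
  }
  if (!is.finite(amplitude) || !is.finite(tau) || amplitude <= 0 || tau <= 0) {
    stop_invalid("amplitude and tau must be finite and > 0")
  }
  if (dt <= 0) stop_invalid("dt must be > 0")
  if (duration < dt) stop_invalid("duration must be >= dt")
  times <- seq(0, duration, by = dt)
  x <- amplitude * (1 - exp(-times / tau))
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    x <- pmax(0, x + rnorm(length(x), 0, noise_sd))
  }
  displacement_trace(times, x, embryo_id, genotype)
}

#' Construct a kymograph
#'
#' Space-by-time image of a laser ablation with physical calibration. Rows are
#' time frames, columns are positions along the spatial axis.
#'
#' @param image numeric matrix, rows = time frames, columns = space.
#' @param pixel_size spatial calibration (um per pixel), > 0.
#' @param frame_interval time between rows (s), > 0.
#' @param cut_position center of the incision along the spatial axis (um).
#' @param region_width width of the analysis band along the incision (um);
#'   the default matches taking kymographs along the center 4.25 um of an
#'   8.5 um cut.
#' @return an object of class `kymograph`.
#' @export
kymograph <- function(image, pixel_size, frame_interval, cut_position,
                      region_width = 4.25) {
  if (!is.matrix(image)) stop_invalid("image must be a matrix")
  if (pixel_size <= 0) stop_invalid("pixel_size must be > 0")
  if (frame_interval <= 0) stop_invalid("frame_interval must be > 0")
  structure(list(image = image, pixel_size = pixel_size,
                 frame_interval = frame_interval, cut_position = cut_position,
                 region_width = region_width),
            class = "kymograph")
}

#' Render a displacement trace as a synthetic kymograph
#'
#' Draws, for each time frame, bright tissue flanking a dark wound of width
#' `2 * displacement` centered at `gap_center`, plus Gaussian pixel noise.
#' A pixel belongs to the wound when its center lies strictly inside the
#' wound interval.
#'
#' @param trace a [displacement_trace()] (missing frames are rendered as
#'   uncut tissue).
#' @param pixel_size um per pixel, > 0.
#' @param gap_center wound center along the spatial axis (um).
#' @param width total spatial extent of the image (um); default
#'   `2 * gap_center`.
#' @param intensity_fg tissue (foreground) intensity, must exceed
#'   `intensity_bg`.
#' @param intensity_bg wound (background) intensity.
#' @param noise_sd Gaussian pixel noise sd (a.u.).
#' @param seed integer seed.
#' @return a [kymograph()].
#' @export
gen_kymograph <- function(trace, pixel_size, gap_center, width = 2 * gap_center,
                          intensity_fg = 1, intensity_bg = 0, noise_sd = 0,
                          seed = 1L) {
  stopifnot(inherits(trace, "displacement_trace"))
  if (pixel_size <= 0) stop_invalid("pixel_size must be > 0")
  if (intensity_fg <= intensity_bg) {
    stop_invalid("intensity_fg must exceed intensity_bg")
  }
  half_width <- min(gap_center, width - gap_center)
  disp <- trace$displacement
  if (any(disp[!is.na(disp)] > half_width)) {
    stop_invalid("displacement exceeds image half-width")
  }
  n_px <- round(width / pixel_size)
  centers <- (seq_len(n_px) - 0.5) * pixel_size
  img <- matrix(intensity_fg, nrow = length(trace$times), ncol = n_px)
  for (i in seq_along(disp)) {
    if (!is.na(disp[i]) && disp[i] > 0) {
      wound <- abs(centers - gap_center) < disp[i]
      img[i, wound] <- intensity_bg
    }
  }
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    img <- img + matrix(rnorm(length(img), 0, noise_sd), nrow = nrow(img))
  }
  dt <- if (length(trace$times) > 1) diff(trace$times)[1] else 1
  kymograph(img, pixel_size, dt, cut_position = gap_center)
}

# -- embryo datasets ----------------------------------------------------------

#' Configuration for synthetic embryo generation
#'
#' Defines the study conditions emulated by [gen_embryo()]: per-cell myosin
#' pulse statistics, the motor-activity coupling between myosin accumulation
#' and apical-area loss, noise levels, and acquisition timing.
#'
#' The coupling rule is: instantaneous area-loss rate =
#' `motor_activity_factor * area_gain * max(d myosin / dt, 0)`, floored at
#' `area_floor`. Lower motor-activity factors therefore reproduce slower
#' constriction at matched myosin accumulation.
#'
#' @param n_cells number of cells, >= 1.
#' @param frame_interval acquisition interval (s), > 0.
#' @param duration movie length (s). The default, 600 s, is sized for
#'   event-conditioned rate comparisons (cells stay off the area floor);
#'   half-time analyses use 1080 s so the slowest genotype crosses 50% of its
#'   initial area.
#' @param myosin_pulse_rate Poisson rate of accumulation pulses
#'   (events per min per cell).
#' @param myosin_pulse_amplitude_dist `c(mean, sd)` of the pulse rise slope
#'   (a.u. per s), truncated at 0.
#' @param motor_activity_factor dimensionless scalar in (0, 1] converting
#'   myosin accumulation rate into area-loss rate.
#' @param area_noise_sd additive Gaussian noise on area (um^2).
#' @param intensity_noise_sd additive Gaussian noise on intensity (a.u.).
#' @param seed integer dataset seed; per-cell substreams are derived from it,
#'   so regenerating any one cell is stable.
#' @param baseline_intensity resting apical myosin intensity (a.u.).
#' @param pulse_rise_s,pulse_decay_s pulse ramp durations (s).
#' @param area_start initial apical area (um^2).
#' @param area_floor minimal apical area (um^2); traces never go below it.
#' @param area_gain um^2 of area lost per a.u. of accumulated myosin at
#'   motor-activity factor 1.
#' @param onset_delay_s quiescent interval before pulses may start (s),
#'   providing pre-constriction coverage for initial-area estimation.
#' @return an object of class `synth_embryo_config`.
#' @export
synth_embryo_config <- function(n_cells = 100L, frame_interval = 5,
                                duration = 600, myosin_pulse_rate = 1.5,
                                myosin_pulse_amplitude_dist = c(1.0, 0.3),
                                motor_activity_factor = 1.0,
                                area_noise_sd = 0.5, intensity_noise_sd = 0.5,
                                seed = 1L, baseline_intensity = 10,
                                pulse_rise_s = 10, pulse_decay_s = 20,
                                area_start = 40, area_floor = 4,
                                area_gain = 0.2, onset_delay_s = 120) {
  if (n_cells < 1) stop_invalid("n_cells must be >= 1")
  if (frame_interval <= 0) stop_invalid("frame_interval must be > 0")
  if (duration < frame_interval) stop_invalid("duration must cover >= 1 frame")
  if (motor_activity_factor < 0 || motor_activity_factor > 1) {
    stop_invalid("motor_activity_factor must be in [0, 1]")
  }
  if (myosin_pulse_rate < 0) stop_invalid("myosin_pulse_rate must be >= 0")
  if (area_floor <= 0 || area_start <= area_floor) {
    stop_invalid("need area_start > area_floor > 0")
  }
  structure(list(n_cells = as.integer(n_cells), frame_interval = frame_interval,
                 duration = duration, myosin_pulse_rate = myosin_pulse_rate,
                 myosin_pulse_amplitude_dist = myosin_pulse_amplitude_dist,
                 motor_activity_factor = motor_activity_factor,
                 area_noise_sd = area_noise_sd,
                 intensity_noise_sd = intensity_noise_sd,
                 seed = as.integer(seed),
                 baseline_intensity = baseline_intensity,
                 pulse_rise_s = pulse_rise_s, pulse_decay_s = pulse_decay_s,
                 area_start = area_start, area_floor = area_floor,
                 area_gain = area_gain, onset_delay_s = onset_delay_s),
            class = "synth_embryo_config")
}

#' Construct an embryo dataset
#'
#' @param cells `data.frame` with columns `cell_id`, `time_min`, `area_um2`,
#'   `myosin_au`; times strictly increasing and areas > 0 within each cell.
#' @param embryo_id,genotype labels.
#' @param frame_interval acquisition interval (s).
#' @return an object of class `embryo_dataset` with `alignment_offset`
#'   initialized to `NA` (set by [align_embryos()]).
#' @export
embryo_dataset <- function(cells, embryo_id = "embryo1", genotype = "control",
                           frame_interval) {
  req <- c("cell_id", "time_min", "area_um2", "myosin_au")
  if (!all(req %in% names(cells))) {
    stop_invalid("cells must have columns ", paste(req, collapse = ", "))
  }
  if (nrow(cells) == 0) stop_invalid("embryo must contain at least one cell")
  if (any(cells$area_um2 <= 0)) stop_invalid("areas must be > 0")
  structure(list(embryo_id = embryo_id, genotype = genotype, cells = cells,
                 frame_interval = frame_interval, alignment_offset = NA_real_,
                 alignable = NA),
            class = "embryo_dataset")
}

# piecewise-linear pulse: rise at unit slope for rise_s, linear decay over
# decay_s back to zero; returns the intensity contribution at times t after
# pulse onset for a pulse of rise slope `slope`
pulse_shape <- function(t, slope, rise_s, decay_s) {
  peak <- slope * rise_s
  out <- numeric(length(t))
  rising <- t >= 0 & t < rise_s
  falling <- t >= rise_s & t < rise_s + decay_s
  out[rising] <- slope * t[rising]
  out[falling] <- peak * (1 - (t[falling] - rise_s) / decay_s)
  out
}

#' Generate a synthetic embryo with coupled myosin and area dynamics
#'
#' Per cell: apical myosin intensity is a baseline plus Poisson-timed
#' piecewise-linear ramp pulses (rise then decay); apical area starts at
#' `area_start` and loses area in proportion to the instantaneous myosin
#' accumulation rate scaled by the motor-activity factor, floored at
#' `area_floor`. Both channels then receive additive Gaussian noise (intensity
#' truncated at 0, area clamped at the floor).
#'
#' Pulse times, amplitudes and noise draws depend only on the dataset seed and
#' the cell index, never on `motor_activity_factor`, so genotypes generated
#' with the same seed have matched pulse statistics.
#'
#' @param config a [synth_embryo_config()].
#' @param embryo_id,genotype labels stored on the dataset.
#' @return an [embryo_dataset()].
#' @export
gen_embryo <- function(config, embryo_id = "synthetic", genotype = "synthetic") {
  stopifnot(inherits(config, "synth_embryo_config"))
  t_s <- seq(0, config$duration, by = config$frame_interval)
  n_t <- length(t_s)
  amp_mean <- config$myosin_pulse_amplitude_dist[1]
  amp_sd <- config$myosin_pulse_amplitude_dist[2]
  window_min <- (config$duration - config$onset_delay_s) / 60
  cells <- vector("list", config$n_cells)
  for (cell in seq_len(config$n_cells)) {
    set.seed(derive_seed(config$seed, cell))
    n_pulses <- if (config$myosin_pulse_rate > 0 && window_min > 0) {
      rpois(1, config$myosin_pulse_rate * window_min)
    } else 0L
    myosin_clean <- rep(config$baseline_intensity, n_t)
    if (n_pulses > 0) {
      onsets <- runif(n_pulses, config$onset_delay_s, config$duration)
      slopes <- pmax(0, rnorm(n_pulses, amp_mean, amp_sd))
      for (p in seq_len(n_pulses)) {
        myosin_clean <- myosin_clean +
          pulse_shape(t_s - onsets[p], slopes[p],
                      config$pulse_rise_s, config$pulse_decay_s)
      }
    }
    # couple area loss to the positive part of the myosin accumulation rate
    accum <- pmax(0, diff(myosin_clean))
    area_clean <- numeric(n_t)
    area_clean[1] <- config$area_start
    loss <- config$motor_activity_factor * config$area_gain * accum
    area_clean[-1] <- pmax(config$area_floor, config$area_start - cumsum(loss))
    myosin_obs <- pmax(0, myosin_clean +
                         rnorm(n_t, 0, config$intensity_noise_sd))
    area_obs <- pmax(config$area_floor, area_clean +
                       rnorm(n_t, 0, config$area_noise_sd))
    cells[[cell]] <- data.frame(cell_id = cell, time_min = t_s / 60,
                                area_um2 = area_obs, myosin_au = myosin_obs)
  }
  embryo_dataset(do.call(rbind, cells), embryo_id, genotype,
                 config$frame_interval)
}

# -- motility tracks ----------------------------------------------------------

#' Construct a motility track set
#'
#' @param tracks list of `data.frame`s with columns `time_s`, `x_nm`, `y_nm`;
#'   times strictly increasing within each track.
#' @param frame_interval time between positions (s).
#' @return an object of class `track_set`.
#' @export
track_set <- function(tracks, frame_interval) {
  if (length(tracks) == 0) stop_invalid("track set must be non-empty")
  for (tr in tracks) {
    if (!all(c("time_s", "x_nm", "y_nm") %in% names(tr))) {
      stop_invalid("each track needs columns time_s, x_nm, y_nm")
    }
    if (nrow(tr) >= 2 && any(diff(tr$time_s) <= 0)) {
      stop_invalid("track times must be strictly increasing")
    }
  }
  structure(list(tracks = tracks, frame_interval = frame_interval),
            class = "track_set")
}

#' Generate synthetic in vitro motility tracks
#'
#' Each track is a constant-speed 2D walk with a fresh uniform heading per
#' step, plus a common linear stage drift and additive positional noise.
#'
#' @param true_speed filament gliding speed (nm/s), >= 0.
#' @param drift_velocity `c(vx, vy)` stage drift (nm/s) shared by all tracks.
#' @param n_tracks number of tracks, >= 1.
#' @param duration track duration (s).
#' @param frame_interval time between positions (s).
#' @param noise_sd positional noise sd (nm).
#' @param seed integer seed.
#' @return a [track_set()].
#' @export
gen_motility_tracks <- function(true_speed, drift_velocity = c(0, 0),
                                n_tracks = 50L, duration = 30,
                                frame_interval = 1, noise_sd = 0, seed = 1L) {
  if (n_tracks < 1) stop_invalid("n_tracks must be >= 1")
  if (true_speed < 0) stop_invalid("true_speed must be >= 0")
  times <- seq(0, duration, by = frame_interval)
  n_steps <- length(times) - 1L
  step_len <- true_speed * frame_interval
  drift_step <- drift_velocity * frame_interval
  tracks <- vector("list", n_tracks)
  for (k in seq_len(n_tracks)) {
    set.seed(derive_seed(seed, k))
    theta <- runif(n_steps, 0, 2 * pi)
    dx <- step_len * cos(theta) + drift_step[1]
    dy <- step_len * sin(theta) + drift_step[2]
    x <- cumsum(c(0, dx))
    y <- cumsum(c(0, dy))
    if (noise_sd > 0) {
      x <- x + rnorm(length(x), 0, noise_sd)
      y <- y + rnorm(length(y), 0, noise_sd)
    }
    tracks[[k]] <- data.frame(time_s = times, x_nm = x, y_nm = y)
  }
  track_set(tracks, frame_interval)
}
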