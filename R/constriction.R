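# Constriction-rate analysis: myosin stack preprocessing (2.5 SD cytoplasmic
# rule), trace smoothing, instantaneous rates, detection of rapid
# myosin-accumulation instances against control statistics (1-2 SD window),
# event-conditioned constriction rates, embryo alignment and time-to-50%-A0,
# and the side-by-side myosin intensity profile comparison.

#' Instantaneous area and myosin rates of a cell trace
#'
#' Central differences at interior points, one-sided differences at the ends.
#' The constriction rate is reported as `-d(area)/dt`, so positive values
#' mean the apex is constricting. Input traces are expected to be smoothed
#' (see [smooth_trace()]).
#'
#' @param tr `data.frame` with columns `time_min`, `area_um2`, `myosin_au`.
#' @return `data.frame` with columns `time_min`, `area_rate` (um^2/min,
#'   positive = constricting) and `myosin_rate` (a.u./min).
#' @export
instantaneous_rates <- function(tr) {
  req <- c("time_min", "area_um2", "myosin_au")
  if (!all(req %in% names(tr))) {
    stop_invalid("trace needs columns ", paste(req, collapse = ", "))
  }
  t <- tr$time_min
  n <- length(t)
  if (n < 2) stop_invalid("need >= 2 time points")
  deriv <- function(x) {
    d <- numeric(n)
    if (n > 2) {
      d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
    }
    d[1] <- (x[2] - x[1]) / (t[2] - t[1])
    d[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
    d
  }
  data.frame(time_min = t,
             area_rate = -deriv(tr$area_um2),
             myosin_rate = deriv(tr$myosin_au))
}

#' Smoothed per-cell rate table for an embryo
#'
#' Smooths each cell's area and myosin traces with a Gaussian kernel and
#' computes instantaneous rates, the common preprocessing for control-rate
#' statistics and event detection.
#'
#' @param embryo an [embryo_dataset()].
#' @param smooth_sigma Gaussian kernel sd in frames (default 2).
#' @return `data.frame` with columns `cell_id`, `time_index`, `time_min`,
#'   `area_rate`, `myosin_rate`.
#' @export
cell_rates <- function(embryo, smooth_sigma = 2) {
  stopifnot(inherits(embryo, "embryo_dataset"))
  per_cell <- split(embryo$cells, embryo$cells$cell_id)
  out <- lapply(per_cell, function(cc) {
    sm <- data.frame(time_min = cc$time_min,
                     area_um2 = smooth_trace(cc$area_um2, smooth_sigma),
                     myosin_au = smooth_trace(cc$myosin_au, smooth_sigma))
    rates <- instantaneous_rates(sm)
    data.frame(cell_id = cc$cell_id[1], time_index = seq_len(nrow(cc)),
               time_min = rates$time_min, area_rate = rates$area_rate,
               myosin_rate = rates$myosin_rate)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Control-cohort myosin accumulation rate statistics
#'
#' Mean and standard deviation of the myosin accumulation rate pooled over
#' all time points of all cells of the control embryos. These statistics
#' define the normalization against which accumulation events are detected
#' in every genotype.
#'
#' @param controls list of control [embryo_dataset()]s (or a single one).
#' @param smooth_sigma trace smoothing sd in frames.
#' @return object of class `control_rate_stats`: `mean_rate`, `sd_rate`
#'   (a.u./min), `n_points`, `genotype`.
#' @export
control_rate_stats <- function(controls, smooth_sigma = 2) {
  if (inherits(controls, "embryo_dataset")) controls <- list(controls)
  if (length(controls) == 0) stop_invalid("need >= 1 control embryo")
  rates <- unlist(lapply(controls, function(e) {
    cell_rates(e, smooth_sigma)$myosin_rate
  }))
  if (length(rates) == 0) stop_invalid("empty control rate pool")
  structure(list(mean_rate = mean(rates), sd_rate = sd(rates),
                 n_points = length(rates),
                 genotype = controls[[1]]$genotype),
            class = "control_rate_stats")
}

#' Detect rapid myosin-accumulation instances
#'
#' Flags every (cell, time point) whose myosin accumulation rate lies in the
#' closed window `[mean + lo*sd, mean + hi*sd]` of the control statistics:
#' between one and two standard deviations above the control mean by default.
#' Events are per-time-point instances, not merged runs.
#'
#' @param rates a rate table from [cell_rates()] (columns `cell_id`,
#'   `time_index`, `myosin_rate`), or a plain numeric vector of rates.
#' @param stats a [control_rate_stats()] with `sd_rate > 0`.
#' @param lo,hi window bounds in SD units (`lo < hi`).
#' @param merge_runs when `TRUE`, consecutive flagged time points of a cell
#'   are collapsed to a single instance (the run's first time point); off by
#'   default, matching per-instance bookkeeping.
#' @return object of class `event_set`: `data.frame` `instances` with
#'   columns `cell_id`, `time_index`, `myosin_rate`, plus the window used.
#' @export
detect_accumulation_events <- function(rates, stats, lo = 1, hi = 2,
                                       merge_runs = FALSE) {
  stopifnot(inherits(stats, "control_rate_stats"))
  if (!is.finite(stats$sd_rate) || stats$sd_rate <= 0) {
    stop_invalid("control sd_rate must be > 0")
  }
  if (lo >= hi) stop_invalid("need lo < hi")
  if (is.numeric(rates)) {
    rates <- data.frame(cell_id = 1L, time_index = seq_along(rates),
                        myosin_rate = rates)
  }
  lo_rate <- stats$mean_rate + lo * stats$sd_rate
  hi_rate <- stats$mean_rate + hi * stats$sd_rate
  keep <- rates$myosin_rate >= lo_rate & rates$myosin_rate <= hi_rate
  inst <- rates[keep, c("cell_id", "time_index", "myosin_rate")]
  if (merge_runs && nrow(inst) > 1) {
    inst <- inst[order(inst$cell_id, inst$time_index), ]
    run_start <- c(TRUE, diff(inst$time_index) != 1 |
                     inst$cell_id[-1] != inst$cell_id[-nrow(inst)])
    inst <- inst[run_start, ]
  }
  rownames(inst) <- NULL
  structure(list(instances = inst,
                 lo = lo, hi = hi,
                 lo_rate = lo_rate, hi_rate = hi_rate,
                 n_rates = nrow(rates)),
            class = "event_set")
}

#' Constriction rates at detected accumulation events
#'
#' Looks up the constriction rate (`area_rate`) at every flagged instance.
#'
#' @param rates a rate table from [cell_rates()].
#' @param ev an [detect_accumulation_events()] result.
#' @return numeric vector of constriction rates (um^2/min) at the events;
#'   empty with a warning when the event set is empty.
#' @export
constriction_rates_at_events <- function(rates, ev) {
  stopifnot(inherits(ev, "event_set"))
  inst <- ev$instances
  if (nrow(inst) == 0) {
    warning("empty event set")
    return(numeric(0))
  }
  key_rates <- paste(rates$cell_id, rates$time_index)
  key_ev <- paste(inst$cell_id, inst$time_index)
  idx <- match(key_ev, key_rates)
  if (anyNA(idx)) stop_invalid("event references unknown (cell, time) instance")
  rates$area_rate[idx]
}

#' Mean apical area series of an embryo
#'
#' @param embryo an [embryo_dataset()].
#' @return list with `times` (min) and `area` (um^2), the mean over cells at
#'   each time point.
#' @export
mean_area_series <- function(embryo) {
  stopifnot(inherits(embryo, "embryo_dataset"))
  agg <- tapply(embryo$cells$area_um2, embryo$cells$time_min, mean)
  times <- as.numeric(names(agg))
  o <- order(times)
  list(times = times[o], area = as.numeric(agg)[o])
}

detect_onset <- function(times, area, onset_slope_threshold, sustain_frames,
                         smooth_sigma) {
  sm <- smooth_trace(area, smooth_sigma)
  rate <- instantaneous_rates(data.frame(time_min = times, area_um2 = sm,
                                         myosin_au = sm))$area_rate
  below <- rate >= onset_slope_threshold  # area_rate is -dA/dt
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= sustain_frames)
  if (length(hit) == 0) return(NA_real_)
  times[starts[hit[1]]]
}

#' Align embryos at constriction onset
#'
#' Onset is the first time the smoothed mean-area derivative drops below
#' `-onset_slope_threshold` and stays there for `sustain_frames` consecutive
#' frames. Each embryo's `alignment_offset` is set to its onset time, so
#' subtracting it puts all onsets at time 0. Embryos with no detectable
#' onset are flagged unalignable.
#'
#' @param embryos list of [embryo_dataset()]s.
#' @param onset_slope_threshold slope threshold (um^2/min), > 0.
#' @param sustain_frames consecutive frames the slope must be sustained.
#' @param smooth_sigma smoothing sd (frames) for the mean-area series.
#' @return the list of embryos with `alignment_offset` (min) and `alignable`
#'   set.
#' @export
align_embryos <- function(embryos, onset_slope_threshold = 1,
                          sustain_frames = 3, smooth_sigma = 2) {
  if (inherits(embryos, "embryo_dataset")) embryos <- list(embryos)
  lapply(embryos, function(e) {
    ms <- mean_area_series(e)
    onset <- detect_onset(ms$times, ms$area, onset_slope_threshold,
                          sustain_frames, smooth_sigma)
    e$alignment_offset <- onset
    e$alignable <- !is.na(onset)
    e
  })
}

#' Time for the mean apical area to halve
#'
#' The initial apical area `A0` is the mean area 2 min before constriction
#' onset (clamped to the start of coverage when the series begins later).
#' Returns the linearly interpolated first crossing of `0.5 * A0`, measured
#' from onset. A series that never reaches half its initial area yields a
#' censored result, not an error.
#'
#' @param mean_area mean apical area series (um^2).
#' @param times time points (min).
#' @param onset_time constriction onset (min); defaults to the series start.
#' @return object of class `half_time`: `t_half` (min from onset, `NA` when
#'   censored), `a0` (um^2), `censored`.
#' @export
time_to_half_area <- function(mean_area, times, onset_time = times[1]) {
  if (length(mean_area) != length(times)) {
    stop_invalid("mean_area and times must have equal length")
  }
  if (is.na(onset_time)) stop_invalid("onset_time is NA (unalignable embryo)")
  a0 <- approx(times, mean_area, xout = max(onset_time - 2, times[1]),
               rule = 2)$y
  target <- 0.5 * a0
  post <- which(times >= onset_time)
  below <- post[mean_area[post] <= target]
  if (length(below) == 0) {
    return(structure(list(t_half = NA_real_, a0 = a0, censored = TRUE),
                     class = "half_time"))
  }
  i <- below[1]
  if (i == 1 || mean_area[i] == target) {
    t_cross <- times[i]
  } else {
    # linear interpolation between the bracketing frames
    t_cross <- times[i - 1] + (times[i] - times[i - 1]) *
      (mean_area[i - 1] - target) / (mean_area[i - 1] - mean_area[i])
  }
  structure(list(t_half = t_cross - onset_time, a0 = a0, censored = FALSE),
            class = "half_time")
}

# -- myosin stack preprocessing ----------------------------------------------

#' Construct a myosin z-stack
#'
#' @param arr 3D numeric array indexed `[z, y, x]` with >= 2 z-slices.
#' @param cyto_mean,cyto_sd cytoplasmic reference statistics; when missing,
#'   they are estimated from `background_region`.
#' @param background_region list with integer vectors `y` and `x` designating
#'   a cytoplasmic background window (used over all z-slices).
#' @return object of class `myosin_stack`.
#' @export
myosin_stack <- function(arr, cyto_mean = NULL, cyto_sd = NULL,
                         background_region = NULL) {
  if (length(dim(arr)) != 3 || dim(arr)[1] < 2) {
    stop_invalid("need a 3D array [z, y, x] with >= 2 z-slices")
  }
  if (is.null(cyto_mean) || is.null(cyto_sd)) {
    if (is.null(background_region)) {
      stop_invalid("provide cytoplasmic stats or a background region")
    }
    vals <- arr[, background_region$y, background_region$x]
    cyto_mean <- mean(vals)
    cyto_sd <- sd(vals)
  }
  structure(list(arr = arr, cyto_mean = cyto_mean, cyto_sd = cyto_sd),
            class = "myosin_stack")
}

#' Remove cytoplasmic myosin and project a z-stack
#'
#' Per pixel, only the two highest z-values are considered; of those, values
#' greater than `mean_cyto + 2.5 * sd_cyto` are kept and the projection is
#' their maximum (0 where none qualifies). The projection is then smoothed
#' with a Gaussian kernel (`sigma = 0.5` px).
#'
#' @param s a [myosin_stack()].
#' @param sd_cutoff threshold in cytoplasmic SD units (default 2.5).
#' @param smoothing_sigma Gaussian sd in pixels applied after projection.
#' @return 2D matrix `[y, x]`; the unsmoothed projection is attached as
#'   attribute `"unsmoothed"`.
#' @export
preprocess_myosin_stack <- function(s, sd_cutoff = 2.5, smoothing_sigma = 0.5) {
  stopifnot(inherits(s, "myosin_stack"))
  thr <- s$cyto_mean + sd_cutoff * s$cyto_sd
  proj <- apply(s$arr, c(2, 3), function(z) {
    top2 <- sort(z, decreasing = TRUE)[1:2]
    keep <- top2[top2 > thr]
    if (length(keep)) max(keep) else 0
  })
  out <- gauss_smooth2d(proj, smoothing_sigma)
  attr(out, "unsmoothed") <- proj
  out
}

# -- side-by-side intensity profiles ------------------------------------------

blur_project_frame <- function(frame, sigma) {
  if (length(dim(frame)) == 3) {
    slices <- lapply(seq_len(dim(frame)[1]), function(z) {
      gauss_smooth2d(frame[z, , ], sigma)
    })
    Reduce(pmax, slices)
  } else {
    gauss_smooth2d(frame, sigma)
  }
}

#' Side-by-side myosin intensity profiles of two embryos
#'
#' For each embryo's image series: Gaussian-smooth every frame (and z-slice),
#' maximum-project over z, and average the intensity across the image height
#' to obtain a profile along a window of `line_length_um` (centered along the
#' furrow axis). The reported profile is taken at each embryo's
#' peak-mean-intensity time.
#'
#' @param imgA,imgB lists of frames; each frame a 2D matrix `[y, x]` or a 3D
#'   array `[z, y, x]`. Both series must share the pixel calibration.
#' @param pixel_size um per pixel of `imgA`.
#' @param pixel_size_b um per pixel of `imgB`; must equal `pixel_size`.
#' @param line_length_um profile window length (um), default 33.
#' @param smoothing_sigma Gaussian sd in pixels (default 1).
#' @return object of class `intensity_profile_pair`: `positions_um`,
#'   `profile_a`, `profile_b`, `peak_frame_a`, `peak_frame_b`.
#' @export
intensity_profile_pair <- function(imgA, imgB, pixel_size,
                                   pixel_size_b = pixel_size,
                                   line_length_um = 33, smoothing_sigma = 1) {
  if (!isTRUE(all.equal(pixel_size, pixel_size_b))) {
    stop_invalid("calibration mismatch between the paired images")
  }
  if (!is.list(imgA)) imgA <- list(imgA)
  if (!is.list(imgB)) imgB <- list(imgB)
  profile_series <- function(frames) {
    lapply(frames, function(f) {
      proj <- blur_project_frame(f, smoothing_sigma)
      n_win <- min(ncol(proj), max(1L, round(line_length_um / pixel_size)))
      start <- floor((ncol(proj) - n_win) / 2) + 1L
      colMeans(proj[, start:(start + n_win - 1L), drop = FALSE])
    })
  }
  prof_a <- profile_series(imgA)
  prof_b <- profile_series(imgB)
  peak_a <- which.max(vapply(prof_a, mean, numeric(1)))
  peak_b <- which.max(vapply(prof_b, mean, numeric(1)))
  pa <- prof_a[[peak_a]]
  structure(list(positions_um = (seq_along(pa) - 0.5) * pixel_size,
                 profile_a = pa, profile_b = prof_b[[peak_b]],
                 peak_frame_a = peak_a, peak_frame_b = peak_b),
            class = "intensity_profile_pair")
}
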