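# Laser-ablation recoil analysis: wound-edge extraction from kymographs,
# Kelvin-Voigt and power-law viscoelastic fits, the R^2 > 0.5 acceptance
# filter, and per-genotype cohort summaries.

# flip foreground/background runs shorter than min_px in a logical vector
# (1D stand-in for morphological speck removal along a kymograph row)
remove_small_runs <- function(bin, min_px) {
  if (min_px <= 1 || length(bin) == 0) return(bin)
  r <- rle(bin)
  # never flip runs at the row ends: they border the image, not a speck
  interior <- seq_along(r$lengths) > 1 & seq_along(r$lengths) < length(r$lengths)
  flip <- r$lengths < min_px & interior
  r$values[flip] <- !r$values[flip]
  inverse.rle(r)
}

#' Extract a wound-edge displacement trace from a kymograph
#'
#' Per time row: binarize the kymograph (Otsu by default), remove connected
#' foreground/background runs smaller than `min_object_px`, locate the wound
#' (the background run at the cut position, or nearest to it), and record
#' half the distance between the two wound edges as the displacement.
#'
#' Frames in which no wound is detectable are recorded as missing (`NA`),
#' not as zero.
#'
#' @param k a [kymograph()].
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param threshold intensity threshold when `threshold_method = "fixed"`.
#' @param min_object_px minimum run length (pixels) kept during speck
#'   removal.
#' @return a [displacement_trace()]; warns when no wound is found in any
#'   frame.
#' @export
extract_edges <- function(k, threshold_method = c("otsu", "fixed"),
                          threshold = NULL, min_object_px = 3L) {
  stopifnot(inherits(k, "kymograph"))
  threshold_method <- match.arg(threshold_method)
  img <- k$image
  if (threshold_method == "otsu") {
    rng <- range(img)
    if (diff(rng) == 0) {
      thr <- rng[1]  # flat image: nothing below threshold, no wound anywhere
      bin <- matrix(TRUE, nrow(img), ncol(img))
    } else {
      norm <- (img - rng[1]) / diff(rng)
      thr_norm <- EBImage::otsu(norm, range = c(0, 1))
      bin <- norm > thr_norm
    }
  } else {
    if (is.null(threshold)) stop_invalid("fixed thresholding needs 'threshold'")
    bin <- img > threshold
  }
  n_t <- nrow(img)
  cut_px <- k$cut_position / k$pixel_size + 0.5  # fractional pixel index
  disp <- rep(NA_real_, n_t)
  for (i in seq_len(n_t)) {
    row <- remove_small_runs(bin[i, ], min_object_px)
    if (all(row)) next  # no wound pixels this frame
    r <- rle(row)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    bg <- which(!r$values)
    # wound = background run containing the cut position, else the nearest one
    mid <- (starts[bg] + ends[bg]) / 2
    containing <- bg[cut_px >= starts[bg] - 0.5 & cut_px <= ends[bg] + 0.5]
    j <- if (length(containing)) containing[1] else bg[which.min(abs(mid - cut_px))]
    width_px <- r$lengths[j]
    disp[i] <- width_px * k$pixel_size / 2
  }
  if (all(is.na(disp))) warning("no wound detected in any frame")
  displacement_trace(seq(0, by = k$frame_interval, length.out = n_t), disp)
}

# shared R^2 about the mean of the fitted points
r_squared_about_mean <- function(obs, pred) {
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / ss_tot
}

#' Fit the Kelvin-Voigt recoil model to a displacement trace
#'
#' Least-squares fit of `x(t) = A (1 - exp(-t / tau))`, the displacement of a
#' spring-dashpot element (stiffness `zeta`, viscosity `eta`) released under
#' tension `T`: `A = T/zeta` and `tau = eta/zeta`. Only these two ratios are
#' identifiable from displacement, so `T`, `zeta` and `eta` are never
#' reported individually; the derived initial recoil velocity is
#' `v0 = A/tau = T/eta`.
#'
#' Fits with `R^2 <= r2_min` (default 0.5) are retained but flagged
#' `accepted = FALSE` and excluded from downstream velocity statistics.
#'
#' @param tr a [displacement_trace()] with >= 5 non-missing points including
#'   `t = 0`.
#' @param r2_min acceptance threshold on R^2.
#' @return an object of class `kelvin_voigt_fit`: `amplitude` (um), `tau`
#'   (s), `v0` (um/s), `r_squared`, `accepted`, `converged`, `n_points`.
#' @export
fit_kelvin_voigt <- function(tr, r2_min = 0.5) {
  stopifnot(inherits(tr, "displacement_trace"))
  ok <- !is.na(tr$displacement)
  if (!any(ok)) stop_invalid("all displacements missing")
  if (sum(ok) < 5) stop_invalid("need >= 5 non-missing points")
  if (min(tr$times) > 0) stop_invalid("time base must include t = 0")
  t <- tr$times[ok]
  x <- tr$displacement[ok]
  A0 <- max(x)
  if (A0 <= 0) A0 <- 1e-6
  target <- (1 - exp(-1)) * A0
  tau0 <- t[which.min(abs(x - target))]
  if (tau0 <= 0) tau0 <- max(diff(t)[1], 1e-3)
  fit <- tryCatch(
    nlsLM(x ~ A * (1 - exp(-t / tau)), data = data.frame(t = t, x = x),
          start = list(A = A0, tau = tau0), lower = c(1e-12, 1e-12),
          control = nls.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(amplitude = NA_real_, tau = NA_real_, v0 = NA_real_,
                          r_squared = NA_real_, accepted = FALSE,
                          converged = FALSE, n_points = sum(ok)),
                     class = "kelvin_voigt_fit"))
  }
  est <- coef(fit)
  A <- unname(est["A"]); tau <- unname(est["tau"])
  r2 <- r_squared_about_mean(x, A * (1 - exp(-t / tau)))
  structure(list(amplitude = A, tau = tau, v0 = A / tau,
                 r_squared = r2,
                 accepted = is.finite(r2) && r2 > r2_min,
                 converged = TRUE, n_points = sum(ok)),
            class = "kelvin_voigt_fit")
}

#' Initial recoil velocity of an accepted Kelvin-Voigt fit
#'
#' The derivative of the fitted displacement at `t = 0`: `v0 = A/tau`, equal
#' to tension over the dashpot viscosity (`T/eta`). At constant viscosity it
#' is the standard proxy for the tissue tension just before the cut.
#'
#' @param f an accepted [fit_kelvin_voigt()] result.
#' @return `v0` in um/s.
#' @export
initial_recoil_velocity <- function(f) {
  stopifnot(inherits(f, "kelvin_voigt_fit"))
  if (!isTRUE(f$accepted)) {
    stop_invalid("fit not accepted (R^2 = ",
                 formatC(f$r_squared, digits = 3, format = "fg"),
                 " <= threshold); refusing to report v0")
  }
  f$amplitude / f$tau
}

#' Time decay constant of an accepted Kelvin-Voigt fit
#'
#' The relaxation timescale `tau = eta/zeta` (dashpot viscosity over spring
#' stiffness), a tension-independent descriptor of tissue viscoelasticity.
#'
#' @param f an accepted [fit_kelvin_voigt()] result.
#' @return `tau` in s.
#' @export
time_decay_constant <- function(f) {
  stopifnot(inherits(f, "kelvin_voigt_fit"))
  if (!isTRUE(f$accepted)) {
    stop_invalid("fit not accepted (R^2 = ",
                 formatC(f$r_squared, digits = 3, format = "fg"),
                 " <= threshold); refusing to report tau")
  }
  f$tau
}

#' Fit a power law to a displacement trace
#'
#' Nonlinear least squares of `x = beta * t^alpha` on the points with
#' `t > 0` (the model is singular at `t = 0`). Fitting is performed in linear
#' displacement space, matching least squares on the displacement itself.
#' The exponent `alpha` is a descriptor of tissue viscoelasticity. The same
#' `R^2 > r2_min` acceptance rule as for the Kelvin-Voigt fit applies.
#'
#' @param tr a [displacement_trace()] with >= 5 non-missing points at
#'   `t > 0`.
#' @param r2_min acceptance threshold on R^2.
#' @return an object of class `power_law_fit`: `beta` (um s^-alpha),
#'   `alpha`, `r_squared`, `accepted`, `converged`, `n_points`.
#' @export
fit_power_law <- function(tr, r2_min = 0.5) {
  stopifnot(inherits(tr, "displacement_trace"))
  keep <- !is.na(tr$displacement) & tr$times > 0
  if (sum(keep) < 5) stop_invalid("need >= 5 non-missing points with t > 0")
  t <- tr$times[keep]
  x <- tr$displacement[keep]
  alpha0 <- 0.5
  beta0 <- max(x[length(x)], 1e-6) / t[length(t)]^alpha0
  fit <- tryCatch(
    nlsLM(x ~ beta * t^alpha, data = data.frame(t = t, x = x),
          start = list(beta = beta0, alpha = alpha0),
          lower = c(1e-12, 1e-6), upper = c(Inf, 5),
          control = nls.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(beta = NA_real_, alpha = NA_real_,
                          r_squared = NA_real_, accepted = FALSE,
                          converged = FALSE, n_points = sum(keep)),
                     class = "power_law_fit"))
  }
  est <- coef(fit)
  beta <- unname(est["beta"]); alpha <- unname(est["alpha"])
  r2 <- r_squared_about_mean(x, beta * t^alpha)
  structure(list(beta = beta, alpha = alpha, r_squared = r2,
                 accepted = is.finite(r2) && r2 > r2_min,
                 converged = TRUE, n_points = sum(keep)),
            class = "power_law_fit")
}

#' Fit both recoil models to one ablation
#'
#' Convenience wrapper returning the Kelvin-Voigt and power-law fits for a
#' trace together with the trace itself, the unit consumed by
#' [recoil_cohort_summary()].
#'
#' @param tr a [displacement_trace()].
#' @param r2_min acceptance threshold on R^2 for both fits.
#' @return list with elements `trace`, `kv`, `power`.
#' @export
analyze_ablation <- function(tr, r2_min = 0.5) {
  list(trace = tr,
       kv = fit_kelvin_voigt(tr, r2_min = r2_min),
       power = fit_power_law(tr, r2_min = r2_min))
}

box_quartiles <- function(x) {
  qs <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(q25 = qs[1], median = qs[2], q75 = qs[3], min = min(x), max = max(x))
}

#' Per-genotype summary of a recoil cohort
#'
#' Summarizes accepted fits per genotype with box-plot statistics (median,
#' quartiles, min/max) for the initial recoil velocity `v0`, the time decay
#' constant `tau` and the power-law exponent `alpha`, counts excluded
#' fits (R^2 below threshold), and computes the mean displacement curve
#' (+/- sd) across the cohort's traces.
#'
#' @param ablations list of [analyze_ablation()] results.
#' @param genotypes genotype label per ablation.
#' @return list of class `recoil_summary`: `stats` (one row per genotype)
#'   and `mean_displacement` (per genotype: `times`, `mean`, `sd`, `n`).
#' @export
recoil_cohort_summary <- function(ablations, genotypes) {
  if (length(ablations) == 0) stop_invalid("no ablations supplied")
  if (length(genotypes) != length(ablations)) {
    stop_invalid("genotypes must match ablations in length")
  }
  groups <- split(seq_along(ablations), genotypes)
  rows <- list(); curves <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    kv <- lapply(ablations[idx], `[[`, "kv")
    pl <- lapply(ablations[idx], `[[`, "power")
    kv_ok <- vapply(kv, function(f) isTRUE(f$accepted), logical(1))
    pl_ok <- vapply(pl, function(f) isTRUE(f$accepted), logical(1))
    if (!any(kv_ok)) stop_invalid("no accepted Kelvin-Voigt fit for genotype ", g)
    v0 <- vapply(kv[kv_ok], `[[`, numeric(1), "v0")
    tau <- vapply(kv[kv_ok], `[[`, numeric(1), "tau")
    alpha <- if (any(pl_ok)) vapply(pl[pl_ok], `[[`, numeric(1), "alpha") else NA_real_
    bq_v0 <- box_quartiles(v0); bq_tau <- box_quartiles(tau)
    bq_al <- if (any(pl_ok)) box_quartiles(alpha) else
      c(q25 = NA_real_, median = NA_real_, q75 = NA_real_,
        min = NA_real_, max = NA_real_)
    rows[[g]] <- data.frame(
      genotype = g, n = length(idx),
      n_accepted_kv = sum(kv_ok), n_excluded_kv = sum(!kv_ok),
      n_accepted_power = sum(pl_ok), n_excluded_power = sum(!pl_ok),
      v0_median = bq_v0["median"], v0_q25 = bq_v0["q25"], v0_q75 = bq_v0["q75"],
      v0_min = bq_v0["min"], v0_max = bq_v0["max"], v0_mean = mean(v0),
      tau_median = bq_tau["median"], tau_q25 = bq_tau["q25"],
      tau_q75 = bq_tau["q75"],
      alpha_median = bq_al["median"], alpha_q25 = bq_al["q25"],
      alpha_q75 = bq_al["q75"], alpha_mean = mean(alpha, na.rm = TRUE),
      row.names = NULL)
    # mean displacement over the common time span of the genotype's traces
    traces <- lapply(ablations[idx], `[[`, "trace")
    n_min <- min(vapply(traces, function(tr) length(tr$times), integer(1)))
    mat <- vapply(traces, function(tr) tr$displacement[seq_len(n_min)],
                  numeric(n_min))
    mat <- matrix(mat, nrow = n_min)
    curves[[g]] <- list(times = traces[[1]]$times[seq_len(n_min)],
                        mean = rowMeans(mat, na.rm = TRUE),
                        sd = apply(mat, 1, sd, na.rm = TRUE),
                        n = length(idx))
  }
  structure(list(stats = do.call(rbind, rows), mean_displacement = curves),
            class = "recoil_summary")
}
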