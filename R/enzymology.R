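# Steady-state ATPase analysis: Michaelis-Menten fitting of the allelic
# series, k_100 summary statistics, fold-activation / percent-of-reference
# ratios, and in vitro motility track speeds with stage-drift correction.

#' Fit the Michaelis-Menten model to a steady-state ATPase dataset
#'
#' Unweighted nonlinear least squares (Levenberg-Marquardt) of
#' `rate = k_basal + k_cat * [A] / (K_app + [A])` over all observations.
#' With at least three distinct actin concentrations all three parameters are
#' fitted; with exactly two distinct concentrations including 0 uM, `k_basal`
#' is fixed to the 0 uM mean and the remaining two parameters are fitted.
#'
#' The fit is flagged non-identifiable when the fitted `K_app` exceeds the
#' maximum assayed actin concentration: in that near-linear regime `k_cat`
#' and `K_app` are not experimentally accessible and only `k_100`-style
#' endpoint statistics are meaningful.
#'
#' @param ds an [atpase_dataset()].
#' @return an object of class `mm_fit`: `params` ([mm_params()] estimates),
#'   `std_errors`, `r_squared`, `identifiable`, `n_points`, `converged`.
#'   Non-convergence is reported via `converged = FALSE`, not an error.
#' @export
fit_michaelis_menten <- function(ds) {
  stopifnot(inherits(ds, "atpase_dataset"))
  actin <- ds$actin_uM
  rate <- ds$rate_per_s
  concs <- sort(unique(actin))
  fix_basal <- FALSE
  if (length(concs) < 3) {
    if (length(concs) == 2 && 0 %in% concs) {
      fix_basal <- TRUE
    } else {
      stop_invalid("need >= 3 distinct actin concentrations ",
                   "(or 2 including 0 uM) to fit")
    }
  }
  means <- tapply(rate, actin, mean)
  kb0 <- unname(means[as.character(min(concs))])
  kc0 <- max(max(means) - kb0, 1e-6)
  half <- kb0 + kc0 / 2
  Ka0 <- concs[which.min(abs(means[as.character(concs)] - half))]
  Ka0 <- max(Ka0, min(concs[concs > 0], na.rm = TRUE) / 2, 1e-3)
  df <- data.frame(a = actin, r = rate)
  fit <- if (fix_basal) {
    kb_fixed <- unname(means["0"])
    tryCatch(
      nlsLM(r ~ kb_fixed + kc * a / (Ka + a), data = df,
            start = list(kc = kc0, Ka = Ka0),
            lower = c(0, 1e-9),
            control = nls.control(maxiter = 200)),
      error = function(e) NULL)
  } else {
    tryCatch(
      nlsLM(r ~ kb + kc * a / (Ka + a), data = df,
            start = list(kb = max(kb0, 0), kc = kc0, Ka = Ka0),
            lower = c(0, 0, 1e-9),
            control = nls.control(maxiter = 200)),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    return(structure(list(params = NULL, std_errors = NULL,
                          r_squared = NA_real_, identifiable = FALSE,
                          n_points = length(rate), converged = FALSE),
                     class = "mm_fit"))
  }
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, length(est)))
  if (fix_basal) {
    params <- mm_params(unname(means["0"]), unname(est["kc"]), unname(est["Ka"]))
    std_errors <- c(k_basal = 0, k_cat = unname(se[1]), K_app = unname(se[2]))
  } else {
    params <- mm_params(unname(est["kb"]), unname(est["kc"]), unname(est["Ka"]))
    std_errors <- c(k_basal = unname(se[1]), k_cat = unname(se[2]),
                    K_app = unname(se[3]))
  }
  ss_res <- sum((rate - mm_rate(params, actin))^2)
  ss_tot <- sum((rate - mean(rate))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(params = params, std_errors = std_errors, r_squared = r2,
                 identifiable = params$K_app <= max(actin),
                 n_points = length(rate), converged = TRUE),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Michaelis-Menten fit: did not converge\n")
    return(invisible(x))
  }
  p <- x$params
  cat(sprintf("Michaelis-Menten fit (n = %d, R^2 = %.4f%s)\n", x$n_points,
              x$r_squared,
              if (x$identifiable) "" else ", K_app not identifiable"))
  cat(sprintf("  k_basal = %.4g +/- %.2g s^-1\n", p$k_basal, x$std_errors[1]))
  cat(sprintf("  k_cat   = %.4g +/- %.2g s^-1\n", p$k_cat, x$std_errors[2]))
  cat(sprintf("  K_app   = %.4g +/- %.2g uM\n", p$K_app, x$std_errors[3]))
  invisible(x)
}

#' Endpoint ATPase summary (k_basal and k_100)
#'
#' Means and standard deviations of the raw replicate rates at exactly 0 uM
#' (basal) and 100 uM actin (`k_100`), the highest concentration assayed.
#' These endpoint statistics remain meaningful when the Michaelis-Menten
#' parameters are not identifiable, and are computed from observations, not
#' from a fitted curve.
#'
#' @param ds an [atpase_dataset()] containing observations at 0 and 100 uM.
#' @return an object of class `k100_summary` with fields `variant`,
#'   `mlck_treated`, `k_basal`, `k_basal_sd`, `k_100`, `k_100_sd`,
#'   `n_basal`, `n_100`. Single-replicate standard deviations are reported
#'   as 0 with a warning.
#' @export
k100_summary <- function(ds) {
  stopifnot(inherits(ds, "atpase_dataset"))
  at0 <- ds$rate_per_s[ds$actin_uM == 0]
  at100 <- ds$rate_per_s[ds$actin_uM == 100]
  if (length(at0) == 0 || length(at100) == 0) {
    stop_invalid("dataset must contain observations at 0 uM and 100 uM actin")
  }
  sd_or_zero <- function(x, label) {
    if (length(x) < 2) {
      warning("single replicate at ", label, " uM; sd reported as 0")
      0
    } else sd(x)
  }
  structure(list(variant = ds$variant[1], mlck_treated = ds$mlck_treated[1],
                 k_basal = mean(at0), k_basal_sd = sd_or_zero(at0, 0),
                 k_100 = mean(at100), k_100_sd = sd_or_zero(at100, 100),
                 n_basal = length(at0), n_100 = length(at100)),
            class = "k100_summary")
}

#' Fold activation by RLC phosphorylation
#'
#' Ratio of the phosphorylated to unphosphorylated `k_100` for a variant,
#' quantifying how strongly MLCK phosphorylation activates the motor.
#'
#' @param k100_phos `k_100` of the MLCK-treated sample (s^-1).
#' @param k100_unphos `k_100` of the untreated sample (s^-1), > 0.
#' @return the ratio `k100_phos / k100_unphos`.
#' @export
fold_activation <- function(k100_phos, k100_unphos) {
  if (!is.finite(k100_unphos) || k100_unphos <= 0) {
    stop_invalid("k100_unphos must be finite and > 0")
  }
  k100_phos / k100_unphos
}

#' Motor activity as percent of a reference variant
#'
#' @param k100_variant `k_100` of the variant of interest (s^-1).
#' @param k100_reference `k_100` of the reference (typically phosphorylated
#'   wild type), > 0.
#' @return `100 * k100_variant / k100_reference` (percent).
#' @export
percent_of_reference <- function(k100_variant, k100_reference) {
  if (!is.finite(k100_reference) || k100_reference <= 0) {
    stop_invalid("k100_reference must be finite and > 0")
  }
  100 * k100_variant / k100_reference
}

#' Per-track filament gliding speeds with optional stage-drift correction
#'
#' Speed is the mean frame-to-frame step length divided by the frame
#' interval. With `drift_correct = TRUE` the global mean step vector over all
#' steps of all tracks (the stage drift estimate) is subtracted from every
#' step first.
#'
#' @param ts a [track_set()]; every track needs >= 2 points.
#' @param drift_correct logical.
#' @return numeric vector of per-track mean speeds (nm/s), with the
#'   estimated drift velocity (nm/s) as attribute `drift_velocity` when
#'   corrected.
#' @export
track_speeds <- function(ts, drift_correct = TRUE) {
  stopifnot(inherits(ts, "track_set"))
  if (length(ts$tracks) == 0) stop_invalid("empty track set")
  steps <- lapply(ts$tracks, function(tr) {
    if (nrow(tr) < 2) stop_invalid("each track needs >= 2 points")
    cbind(dx = diff(tr$x_nm), dy = diff(tr$y_nm), dt = diff(tr$time_s))
  })
  all_steps <- do.call(rbind, steps)
  drift <- c(0, 0)
  if (drift_correct) {
    drift <- c(mean(all_steps[, "dx"]), mean(all_steps[, "dy"]))
  }
  speeds <- vapply(steps, function(s) {
    len <- sqrt((s[, "dx"] - drift[1])^2 + (s[, "dy"] - drift[2])^2)
    mean(len / s[, "dt"])
  }, numeric(1))
  if (drift_correct) {
    attr(speeds, "drift_velocity") <- drift / ts$frame_interval
  }
  speeds
}
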