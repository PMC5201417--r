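# shared fixtures: generating truths and small builders used across tests

# phosphorylated wild-type generating truth (steady-state ATPase)
wt_truth <- function() mm_params(k_basal = 0.01, k_cat = 1.23, K_app = 38.9)

assay_concs <- function() c(0, 2, 5, 10, 20, 40, 70, 100)

# noiseless dataset carrying only the 0 and 100 uM endpoint observations of
# a printed summary row (k_basal, k_100), n replicates each
endpoint_dataset <- function(k_basal, k_100, n = 2, variant = "synthetic",
                             mlck_treated = TRUE) {
  atpase_dataset(actin_uM = rep(c(0, 100), each = n),
                 rate_per_s = rep(c(k_basal, k_100), each = n),
                 replicate = rep(seq_len(n), times = 2),
                 variant = variant, mlck_treated = mlck_treated)
}

# control-rate statistics with prescribed moments (for calibration tests)
fixed_rate_stats <- function(mean_rate, sd_rate) {
  structure(list(mean_rate = mean_rate, sd_rate = sd_rate,
                 n_points = NA_integer_, genotype = "control"),
            class = "control_rate_stats")
}

# synthetic allelic series sharing one seed (matched pulse statistics)
allelic_series <- function(factors, seed, duration, n_cells = 100) {
  lapply(factors, function(f) {
    gen_embryo(synth_embryo_config(n_cells = n_cells,
                                   motor_activity_factor = f,
                                   seed = seed, duration = duration),
               genotype = sprintf("factor_%.2f", f))
  })
}

# mean event-conditioned constriction rate per genotype against control stats
event_rate_means <- function(embryos, control_index = 1, smooth_sigma = 2) {
  stats <- control_rate_stats(embryos[[control_index]], smooth_sigma)
  vapply(embryos, function(e) {
    r <- cell_rates(e, smooth_sigma)
    ev <- detect_accumulation_events(r, stats)
    mean(constriction_rates_at_events(r, ev))
  }, numeric(1))
}
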