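#' Simulation specification for two-state EEG-like signals
#'
#' Describes a cohort of subjects, each recorded for
#' `2 * seconds_per_state` seconds over `n_channels` channels: the first
#' block in the alert (non-fatigue) state, the second in the fatigue state.
#' The two states differ in signal *irregularity*, the property sample
#' entropy measures: alert epochs are broadband-noise dominated (high
#' entropy), fatigue epochs are dominated by a narrowband alpha-range
#' oscillation with reduced noise (low entropy). Amplitude gain is jittered
#' per subject and channel; gain does not move sample entropy (the
#' tolerance scales with the epoch SD), so the state contrast is carried by
#' the oscillation-to-noise ratio alone, governed by `contrast`:
#' 1 = full recipe difference, 0 = identical recipes (no class signal).
#'
#' @param n_subjects number of subjects, default 10 (giving the canonical
#'   600 x 30 feature matrix at 1 s epochs; 15 gives 900 x 30).
#' @param seconds_per_state seconds per state per subject, default 30.
#' @param n_channels channels (electrodes), default 30.
#' @param rate sampling rate in Hz, default 1000.
#' @param contrast oscillation-to-noise contrast dial in [0, 1], default 1.
#' @param noise_sd broadband noise SD in the alert state, default 1.
#' @param osc_amp fatigue-state oscillation amplitude (in noise-SD units),
#'   default 2.
#' @param osc_freq center of the alpha band in Hz, default 10 (jittered
#'   per subject within 9-11 Hz).
#' @param gain_jitter_sd SD of the per-subject-and-channel log-normal
#'   amplitude jitter, default 0.2.
#' @param seed RNG seed for reproducibility, default 42.
#' @return a list of class `sim_spec`.
#' @export
sim_spec <- function(n_subjects = 10L, seconds_per_state = 30L,
                     n_channels = 30L, rate = 1000, contrast = 1,
                     noise_sd = 1, osc_amp = 2, osc_freq = 10,
                     gain_jitter_sd = 0.2, seed = 42L) {
  stopifnot(n_subjects >= 1, seconds_per_state >= 1, n_channels >= 1,
            rate > 0, contrast >= 0, contrast <= 1, noise_sd > 0,
            osc_amp >= 0, osc_freq > 0, gain_jitter_sd >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 seconds_per_state = as.integer(seconds_per_state),
                 n_channels = as.integer(n_channels), rate = rate,
                 contrast = contrast, noise_sd = noise_sd,
                 osc_amp = osc_amp, osc_freq = osc_freq,
                 gain_jitter_sd = gain_jitter_sd, seed = as.integer(seed)),
            class = "sim_spec")
}

# run expr under a local RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate two-state multichannel signals
#'
#' Deterministic given `spec$seed`. Subjects are stacked in time: each
#' contributes `seconds_per_state` alert seconds followed by the same
#' number of fatigue seconds, so per-epoch labels are exactly balanced.
#'
#' @param spec a [sim_spec()].
#' @return a list of class `sim_data`: `signals` (samples x channels),
#'   `rate`, per-1-second-epoch `labels` (0 alert / 1 fatigue), `subject`
#'   (epoch-wise subject index), and the `spec`.
#' @export
simulate_eeg <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  .with_seed(spec$seed, {
    spe <- as.integer(round(spec$rate))          # 1 s of samples
    sec_total <- 2L * spec$seconds_per_state
    n_sub_samp <- sec_total * spe
    tt <- seq_len(n_sub_samp) / spec$rate
    sig <- matrix(0, n_sub_samp * spec$n_subjects, spec$n_channels)
    for (s in seq_len(spec$n_subjects)) {
      f <- spec$osc_freq + runif(1, -1, 1)       # subject alpha peak
      # oscillation share per sample: 0 in the alert block, `contrast` in
      # the fatigue block
      share <- rep(c(0, spec$contrast),
                   each = spec$seconds_per_state * spe)
      for (q in seq_len(spec$n_channels)) {
        gain <- exp(rnorm(1, 0, spec$gain_jitter_sd))
        phase <- runif(1, 0, 2 * pi)
        osc <- spec$osc_amp * spec$noise_sd * sin(2 * pi * f * tt + phase)
        noise <- rnorm(n_sub_samp, 0, spec$noise_sd)
        x <- gain * (share * osc + (1 - 0.7 * share) * noise)
        sig[((s - 1L) * n_sub_samp + 1L):(s * n_sub_samp), q] <- x
      }
    }
    labels <- rep(rep(c(0L, 1L), each = spec$seconds_per_state),
                  times = spec$n_subjects)
    structure(list(signals = sig, rate = spec$rate, labels = labels,
                   subject = rep(seq_len(spec$n_subjects), each = sec_total),
                   spec = spec),
              class = "sim_data")
  })
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf("<sim_data> %d subject(s), %d channel(s), %d samples @ %g Hz, %d epochs\n",
              x$spec$n_subjects, ncol(x$signals), nrow(x$signals), x$rate,
              length(x$labels)))
  invisible(x)
}

#' Entropy features from a simulated recording
#'
#' Convenience wrapper: [simulate_eeg()] then [epoch_feature_matrix()] with
#' 1 s epochs, yielding the `n_subjects * 2 * seconds_per_state` x
#' `n_channels` labeled matrix (600 x 30 at the defaults).
#'
#' @param spec a [sim_spec()].
#' @param estimator entropy estimator, default `"sample"`.
#' @param m,r_factor entropy parameters.
#' @return a labeled `feature_matrix`.
#' @export
simulate_features <- function(spec = sim_spec(), estimator = "sample",
                              m = 2L, r_factor = 0.25) {
  sim <- simulate_eeg(spec)
  epoch_feature_matrix(sim$signals, rate = sim$rate, epoch_len = 1,
                       estimator = estimator, m = m, r_factor = r_factor,
                       labels = sim$labels)
}
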