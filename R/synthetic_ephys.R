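# Ground-truthed synthetic electrophysiology: mEPSC trains on a noisy
# baseline and evoked I/V sweep families under a tunable outward-block
# (rectification) model.

#' Synthetic miniature-EPSC trace
#'
#' Generates a voltage-clamp current trace containing Poisson-timed,
#' negative-going (inward) synaptic events shaped as differences of
#' exponentials, with lognormal amplitudes, on a Gaussian-noise baseline.
#' Each noiseless event's most negative point equals its ground-truth
#' amplitude to within one sample.
#'
#' @param duration_s Trace length in seconds.
#' @param rate_hz Mean event rate (Poisson), >= 0.
#' @param amp_median_pA Median event amplitude in pA (lognormal).
#' @param amp_sigma Lognormal sdlog of amplitudes (default 0.25).
#' @param rise_tau_ms,decay_tau_ms Event time constants in ms; `decay_tau_ms`
#'   must exceed `rise_tau_ms`.
#' @param noise_sd_pA Gaussian baseline noise SD in pA.
#' @param fs Sampling rate in Hz (default 20000, the standard acquisition
#'   rate).
#' @param onset_times Optional explicit event times in seconds, overriding
#'   the Poisson draw (useful for fully determined fixtures).
#' @param seed Integer seed.
#' @return A list with `trace` (an [ephys_trace()], inward currents
#'   negative) and `events` (ground-truth onset times, amplitudes and taus;
#'   onsets strictly increasing).
#' @export
gen_mepsc_trace <- function(duration_s, rate_hz, amp_median_pA = 20,
                            amp_sigma = 0.25, rise_tau_ms = 0.5,
                            decay_tau_ms = 5, noise_sd_pA = 2,
                            fs = 20000, onset_times = NULL, seed = NULL) {
  if (rate_hz < 0) stop("rate_hz must be >= 0", call. = FALSE)
  if (decay_tau_ms <= rise_tau_ms)
    stop("decay_tau_ms must exceed rise_tau_ms", call. = FALSE)
  if (fs <= 2000 / rise_tau_ms)
    stop("fs too low to resolve the rise time", call. = FALSE)
  n <- round(duration_s * fs)
  with_seed(seed, {
    if (is.null(onset_times)) {
      n_ev <- rpois(1, rate_hz * duration_s)
      onsets <- sort(unique(runif(n_ev, 0, max(duration_s - 0.05, 0))))
    } else {
      onsets <- sort(unique(as.numeric(onset_times)))
      if (length(onsets) > 0 && (min(onsets) < 0 || max(onsets) >= duration_s))
        stop("onset_times must lie inside the trace", call. = FALSE)
    }
    n_ev <- length(onsets)
    amps <- stats::rlnorm(n_ev, meanlog = log(amp_median_pA),
                          sdlog = amp_sigma)
    samples <- numeric(n)
    win <- round(min(10 * decay_tau_ms / 1000, duration_s) * fs)
    tker <- (seq_len(win) - 1) / fs
    for (i in seq_len(n_ev)) {
      i0 <- floor(onsets[i] * fs) + 1
      idx <- i0:min(i0 + win - 1, n)
      tt <- (idx - i0) / fs
      samples[idx] <- samples[idx] -
        amps[i] * biexp_template(tt, rise_tau_ms / 1000, decay_tau_ms / 1000)
    }
    if (noise_sd_pA > 0) samples <- samples + rnorm(n, 0, noise_sd_pA)
    list(trace = ephys_trace(samples, fs),
         events = data.frame(onset_s = onsets, amplitude_pA = amps,
                             rise_tau_ms = rep_len(rise_tau_ms, n_ev),
                             decay_tau_ms = rep_len(decay_tau_ms, n_ev)))
  })
}

#' Rectification model for evoked AMPA-receptor currents
#'
#' A voltage-dependent conductance with a sigmoidal outward block, the
#' phenomenological signature of polyamine block of GluA2-lacking AMPA
#' receptors at depolarized potentials:
#' `g(V) = g0 * (1 - block_depth / (1 + exp(-(V - v_half) / k_block)))`,
#' with peak current `I(V) = g(V) * (V - v_rev)`.
#'
#' @param g0 Baseline conductance in nS.
#' @param v_rev Reversal potential in mV (about +3 mV under typical recording
#'   conditions).
#' @param v_half Midpoint of the outward block in mV.
#' @param k_block Slope of the block in mV, > 0.
#' @param block_depth Fraction of conductance removed at depolarized
#'   potentials, in `[0, 1]`; 0 gives an ohmic (linear) I/V.
#' @return A `rectification_model` object.
#' @export
rectification_model <- function(g0 = 1, v_rev = 3, v_half = 20,
                                k_block = 10, block_depth = 0.8) {
  if (k_block <= 0) stop("k_block must be > 0", call. = FALSE)
  if (block_depth < 0 || block_depth > 1)
    stop("block_depth must be in [0, 1]", call. = FALSE)
  structure(list(g0 = g0, v_rev = v_rev, v_half = v_half,
                 k_block = k_block, block_depth = block_depth),
            class = "rectification_model")
}

model_conductance <- function(model, v) {
  model$g0 * (1 - model$block_depth /
                (1 + exp(-(v - model$v_half) / model$k_block)))
}

#' Peak current and true rectification index of a rectification model
#'
#' Closed-form peak currents `I(V) = g(V) (V - v_rev)` and the analytic
#' rectification index: the ratio of the least-squares I/V slope over
#' potentials below the reversal to the slope over potentials above it,
#' computed on the noiseless model values.
#'
#' @param model A [rectification_model()].
#' @param potentials Holding potentials in mV, spanning both sides of
#'   `v_rev`.
#' @return A list with `iv` (data frame of V and peak I in pA), `slope_neg`,
#'   `slope_pos` (nS) and `RI`.
#' @export
model_true_iv <- function(model, potentials) {
  stopifnot(inherits(model, "rectification_model"))
  i_pk <- model_conductance(model, potentials) * (potentials - model$v_rev)
  neg <- potentials < model$v_rev
  pos <- potentials > model$v_rev
  if (sum(neg) < 2 || sum(pos) < 2)
    stop("potentials must include at least two points on each side of v_rev",
         call. = FALSE)
  s_neg <- ols_slope(potentials[neg], i_pk[neg])
  s_pos <- ols_slope(potentials[pos], i_pk[pos])
  list(iv = data.frame(potential_mV = potentials, peak_pA = i_pk),
       slope_neg = s_neg, slope_pos = s_pos, RI = s_neg / s_pos)
}

ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Synthetic evoked-EPSC sweep family across holding potentials
#'
#' One sweep per holding potential: a stimulus-locked EPSC shaped as a
#' difference of exponentials whose peak equals the model current
#' `g(V) * (V - v_rev)`, plus Gaussian noise. The true rectification index is
#' the analytic slope ratio from [model_true_iv()].
#'
#' @param model A [rectification_model()].
#' @param potentials Holding potentials in mV (already junction-corrected);
#'   must span both sides of `v_rev`.
#' @param rise_tau_ms,decay_tau_ms EPSC template time constants.
#' @param latency_ms Synaptic delay between the stimulus and the EPSC onset
#'   (default 2.5 ms, placing the peak inside the conventional 3-6 ms
#'   post-stimulus measurement band).
#' @param noise_sd_pA Gaussian noise SD per sweep.
#' @param fs Sampling rate (default 20000).
#' @param stim_time_s Stimulus time within each sweep (default 0.01).
#' @param sweep_duration_s Sweep length (default 0.06).
#' @param seed Integer seed.
#' @return A list with `sweeps` (list of [ephys_trace()] with holding
#'   potentials and stimulus time), `true_iv`, `true_RI` and the model.
#' @export
gen_iv_sweeps <- function(model, potentials = seq(-60, 60, by = 20),
                          rise_tau_ms = 0.5, decay_tau_ms = 3,
                          latency_ms = 2.5, noise_sd_pA = 0, fs = 20000,
                          stim_time_s = 0.01, sweep_duration_s = 0.06,
                          seed = NULL) {
  truth <- model_true_iv(model, potentials)
  n <- round(sweep_duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  template <- biexp_template(t - stim_time_s - latency_ms / 1000,
                             rise_tau_ms / 1000, decay_tau_ms / 1000)
  with_seed(seed, {
    sweeps <- lapply(seq_along(potentials), function(i) {
      s <- template * truth$iv$peak_pA[i]
      if (noise_sd_pA > 0) s <- s + rnorm(n, 0, noise_sd_pA)
      ephys_trace(s, fs, holding_potential = potentials[i],
                  stim_time_s = stim_time_s)
    })
    list(sweeps = sweeps, true_iv = truth$iv, true_RI = truth$RI,
         slope_neg = truth$slope_neg, slope_pos = truth$slope_pos,
         model = model)
  })
}
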