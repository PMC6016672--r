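# Stimulation protocols: holding-current search, calibrated somatic test
# pulses, single and train trials with a 15-ms IPSP lead, and the A-type
# density sweep.

TRIAL_TYPES <- c("bAP", "IPSP-bAP", "IPSP",
                 "train-bAP", "train-IPSP-bAP", "train-IPSP", "train")

#' Count somatic spikes in a voltage series
#'
#' A spike is an upward crossing of the 0 mV detection threshold.
#'
#' @param v Voltage series (mV).
#' @param threshold Detection threshold (mV); default 0.
#' @return Integer spike count.
#' @export
count_spikes <- function(v, threshold = 0) {
  sum(head(v, -1) < threshold & tail(v, -1) >= threshold)
}

#' Iterative holding-current search
#'
#' Finds the constant somatic current injection that holds the somatic
#' resting potential at `v_target` to within `tol` (default 0.001 mV,
#' the criterion used for every condition). A secant iteration on the
#' steady-state somatic voltage is followed by a verification run: with
#' the candidate current, the settled state must remain within the
#' tolerance over a further 500-ms unstimulated run (stationarity of
#' the held state).
#'
#' @param graph A [compartment_graph()].
#' @param v_target Target somatic potential (mV); default -64.
#' @param tol Tolerance (mV); default 0.001.
#' @param settle Settling time for the verification run (ms).
#' @param dt Solver step (ms).
#' @param max_iter Maximum secant iterations.
#' @param kinetics Kinetic constants, see [default_kinetics()].
#' @return List of class `holding_result`: `current` (nA), `residual`
#'   (max |V - v_target| over the final 100 ms of the verification run),
#'   `state` (the settled state, for warm starts), `iterations`.
#' @export
find_holding_current <- function(graph, v_target = -64, tol = 1e-3,
                                 settle = 500, dt = 0.005,
                                 max_iter = 60,
                                 kinetics = default_kinetics()) {
  cfg_long <- solver_config(settle, dt = dt, record_v = graph$comps$label[1],
                            record_ica = character(),
                            sample_every = 40L)
  cfg_short <- solver_config(300, dt = dt, record_v = graph$comps$label[1],
                             record_ica = character(),
                             sample_every = 40L)
  run <- function(I, cfg, init = NULL) {
    simulate(graph, cfg,
             stimuli = list(stim_pulse(0, cfg$duration, I)), init = init,
             kinetics = kinetics)
  }
  # bracketless secant; the steady-state soma voltage is nearly affine
  # in the injected current
  I0 <- 0
  tr <- run(I0, cfg_long)
  v0 <- tail(tr$v[[1]], 1)
  # initial slope guess from total resting input conductance (nA/mV)
  g_in <- sum((graph$comps$g_leak) * graph$area) * 1e3  # mS -> nA/mV
  I1 <- I0 + (v_target - v0) * g_in
  if (I1 == I0) I1 <- I0 + 0.01
  tr <- run(I1, cfg_short, init = tr$final_state)
  v1 <- tail(tr$v[[1]], 1)
  iter <- 0
  residual <- Inf
  ver <- NULL
  slope <- 1 / g_in  # dV/dI estimate (mV/nA)
  repeat {
    while (abs(v1 - v_target) > tol / 20 && iter < max_iter) {
      if (I1 != I0 && v1 != v0) slope <- (v1 - v0) / (I1 - I0)
      I2 <- I1 + (v_target - v1) / slope
      tr <- run(I2, cfg_short, init = tr$final_state)
      I0 <- I1; v0 <- v1
      I1 <- I2; v1 <- tail(tr$v[[1]], 1)
      iter <- iter + 1
    }
    # verification: with the candidate current, the settled state must
    # stay within tolerance over a full further 500-ms unstimulated run
    ver <- run(I1, cfg_long, init = tr$final_state)
    vv <- ver$v[[1]]
    residual <- max(abs(vv - v_target))
    if (residual <= tol || iter >= max_iter) break
    # fold the fully settled endpoint back into the iteration, stepping
    # with the current slope estimate
    I0 <- I1; v0 <- tail(vv, 1)
    I1 <- I1 + (v_target - v0) / slope
    tr <- run(I1, cfg_short, init = ver$final_state)
    v1 <- tail(tr$v[[1]], 1)
    iter <- iter + 1
  }
  if (residual > tol)
    stop(sprintf(
      "holding-current search did not converge: residual %.3g mV", residual))
  structure(list(current = I1, residual = residual,
                 state = ver$final_state, iterations = iter),
            class = "holding_result")
}

#' Calibrate the somatic test-pulse amplitude
#'
#' Finds, by bisection to 0.01 nA, the smallest amplitude for which a
#' 0.5-ms somatic current pulse elicits exactly one somatic spike
#' (upward crossing of 0 mV). The search bracket is initialised to
#' 1.5-2.5 nA and expanded if needed. A condition whose threshold pulse
#' produces more than one spike (a burst) is rejected, mirroring the
#' exclusion of bursting cells.
#'
#' @param graph A [compartment_graph()].
#' @param holding A `holding_result` from [find_holding_current()].
#' @param pulse_width Pulse width (ms); default 0.5.
#' @param bracket Initial amplitude bracket (nA); default `c(1.5, 2.5)`.
#' @param tol Bisection tolerance (nA); default 0.01.
#' @param dt Solver step (ms).
#' @param kinetics Kinetic constants, see [default_kinetics()].
#' @return List of class `stim_calibration`: `amplitude` (nA), `spikes`
#'   at that amplitude.
#' @export
calibrate_spike_stimulus <- function(graph, holding, pulse_width = 0.5,
                                     bracket = c(1.5, 2.5), tol = 0.01,
                                     dt = 0.005,
                                     kinetics = default_kinetics()) {
  stopifnot(inherits(holding, "holding_result"))
  soma <- graph$comps$label[1]
  t_on <- 10; dur <- 50
  cfg <- solver_config(dur, dt = dt, record_v = soma,
                       record_ica = character(), sample_every = 4L)
  spikes_at <- function(amp) {
    tr <- simulate(graph, cfg,
                   stimuli = list(stim_pulse(0, dur, holding$current),
                                  stim_pulse(t_on, pulse_width, amp,
                                             target = soma)),
                   init = holding$state, kinetics = kinetics)
    count_spikes(tr$v[[1]])
  }
  lo <- bracket[1]; hi <- bracket[2]
  it <- 0
  while (spikes_at(hi) < 1 && hi < 40 && it < 12) { hi <- hi * 1.5; it <- it + 1 }
  if (spikes_at(hi) < 1)
    stop("no spiking amplitude found in the search bracket")
  it <- 0
  while (spikes_at(lo) >= 1 && lo > 0.05 && it < 12) { lo <- lo / 2; it <- it + 1 }
  if (spikes_at(lo) >= 1)
    stop("search bracket has no subthreshold lower bound")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (spikes_at(mid) >= 1) hi <- mid else lo <- mid
  }
  n_sp <- spikes_at(hi)
  if (n_sp != 1L)
    stop(sprintf(
      "burst at threshold (%d spikes): condition rejected", n_sp))
  structure(list(amplitude = hi, spikes = n_sp), class = "stim_calibration")
}

#' Protocol specification
#'
#' @param trial_type One of `"bAP"`, `"IPSP-bAP"`, `"IPSP"`,
#'   `"train-bAP"`, `"train-IPSP-bAP"`, `"train-IPSP"`, `"train"`.
#' @param gka_distal A-type density in the distal trunk segment
#'   (mS/cm2).
#' @param train_freq Train frequency (Hz), 50 or 100 by default usage.
#' @param train_n Spikes per train; default 5.
#' @param ipsp_lead IPSP lead before the test pulse (ms); default 15.
#' @param train_gap Gap between the end of the last train pulse and the
#'   test pulse (ms); default 20.
#' @param pulse_width Somatic pulse width (ms); default 0.5.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(trial_type, gka_distal = 70, train_freq = 100,
                          train_n = 5, ipsp_lead = 15, train_gap = 20,
                          pulse_width = 0.5) {
  trial_type <- match.arg(trial_type, TRIAL_TYPES)
  stopifnot(train_freq > 0, train_n >= 1, ipsp_lead > 0, train_gap >= 0)
  structure(list(trial_type = trial_type, gka_distal = gka_distal,
                 train_freq = train_freq, train_n = train_n,
                 ipsp_lead = ipsp_lead, train_gap = train_gap,
                 pulse_width = pulse_width),
            class = "protocol_spec")
}

has_train <- function(spec) startsWith(spec$trial_type, "train")
has_test <- function(spec)
  spec$trial_type %in% c("bAP", "IPSP-bAP", "train-bAP", "train-IPSP-bAP")
has_ipsp <- function(spec) grepl("IPSP", spec$trial_type)

# event times of a protocol relative to trial start (held state at t=0)
protocol_times <- function(spec, t_start = 20) {
  train_onsets <- numeric()
  if (has_train(spec)) {
    isi <- 1000 / spec$train_freq
    train_onsets <- t_start + (0:(spec$train_n - 1)) * isi
    t_test <- train_onsets[spec$train_n] + spec$pulse_width +
      spec$train_gap
  } else {
    t_test <- t_start + spec$ipsp_lead
  }
  list(train_onsets = train_onsets, t_test = t_test,
       t_ipsp = t_test - spec$ipsp_lead)
}

#' Prepare a simulated condition
#'
#' Builds the model for one A-type density, runs the holding-current
#' search and calibrates the single-spike test pulse.
#'
#' @param gka_distal Distal A-type density (mS/cm2).
#' @param dt Solver step (ms).
#' @param kinetics Kinetic constants, see [default_kinetics()].
#' @param ... Passed to [build_model()].
#' @return List of class `dendka_condition`: `graph`, `holding`,
#'   `stimulus`, `gka_distal`, `dt`.
#' @export
setup_condition <- function(gka_distal = 70, dt = 0.005,
                            kinetics = default_kinetics(), ...) {
  graph <- build_model(gka_distal = gka_distal, ...)
  holding <- find_holding_current(graph, dt = dt, kinetics = kinetics)
  stimulus <- calibrate_spike_stimulus(graph, holding, dt = dt,
                                       kinetics = kinetics)
  structure(list(graph = graph, holding = holding, stimulus = stimulus,
                 gka_distal = gka_distal, dt = dt, kinetics = kinetics),
            class = "dendka_condition")
}

#' Run one protocol trial
#'
#' Simulates a single trial of the given type from the held steady
#' state: optional 5-pulse train, optional GABAergic IPSP leading the
#' test pulse by 15 ms, and the calibrated 0.5-ms somatic test pulse.
#' The trace covers at least 100 ms after the test-pulse onset.
#'
#' @param spec A [protocol_spec()]; its `gka_distal` must match `cond`.
#' @param cond A prepared [setup_condition()].
#' @param post Time simulated after the test-pulse onset (ms);
#'   default 110.
#' @param sample_every Store every k-th solver step; default 4
#'   (0.02-ms sampling).
#' @param stim_margin Factor applied to the calibrated threshold
#'   amplitude for the pulses actually delivered (default 1.1): trials
#'   use clearly suprathreshold pulses, as in the recordings, so that
#'   every pulse of a train remains reliably single-spike.
#' @return List of class `trial_result`: `spec`, `trace`, `t_test`,
#'   `t_ipsp`, `train_onsets`, `holding` (nA), `amplitude` (nA),
#'   `train_ok` (every train pulse elicited exactly one spike),
#'   `n_spikes_test`.
#' @export
run_trial <- function(spec, cond, post = 110, sample_every = 4L,
                      stim_margin = 1.1) {
  stopifnot(inherits(spec, "protocol_spec"),
            inherits(cond, "dendka_condition"))
  if (!isTRUE(all.equal(spec$gka_distal, cond$gka_distal)))
    stop("protocol gka_distal does not match the prepared condition")
  graph <- cond$graph
  tm <- protocol_times(spec)
  duration <- tm$t_test + post
  soma <- graph$comps$label[1]
  syn_label <- graph$comps$label[graph$synapse_comp]

  stimuli <- list(stim_pulse(0, duration, cond$holding$current))
  amp <- cond$stimulus$amplitude * stim_margin
  for (on in tm$train_onsets)
    stimuli[[length(stimuli) + 1L]] <-
      stim_pulse(on, spec$pulse_width, amp, target = soma)
  if (has_test(spec))
    stimuli[[length(stimuli) + 1L]] <-
      stim_pulse(tm$t_test, spec$pulse_width, amp, target = soma)

  synapse <- if (has_ipsp(spec))
    synapse_spec(onset_times = tm$t_ipsp) else NULL

  cfg <- solver_config(duration, dt = cond$dt,
                       record_v = c(soma, syn_label, "spine_head"),
                       record_gates = syn_label,
                       sample_every = as.integer(sample_every))
  tr <- simulate(graph, cfg, stimuli = stimuli, synapse = synapse,
                 init = cond$holding$state, kinetics = cond$kinetics)

  vsoma <- tr$v[[soma]]
  train_ok <- TRUE
  if (has_train(spec)) {
    bounds <- c(tm$train_onsets,
                if (has_test(spec)) tm$t_test else duration)
    for (k in seq_along(tm$train_onsets)) {
      seg <- tr$time >= bounds[k] & tr$time < bounds[k + 1]
      if (count_spikes(vsoma[seg]) != 1L) train_ok <- FALSE
    }
  }
  n_spikes_test <- if (has_test(spec))
    count_spikes(vsoma[tr$time >= tm$t_test]) else 0L

  vol <- function(lab) {
    i <- comp_index(graph, lab)
    pi * graph$comps$diam[i]^2 / 4 * graph$comps$length[i]  # um3
  }

  structure(list(spec = spec, trace = tr, t_test = tm$t_test,
                 t_ipsp = if (has_ipsp(spec)) tm$t_ipsp else NA_real_,
                 train_onsets = tm$train_onsets,
                 holding = cond$holding$current, amplitude = amp,
                 train_ok = train_ok, n_spikes_test = n_spikes_test,
                 sites = list(soma = soma, synapse = syn_label,
                              spine = "spine_head", shaft = syn_label),
                 site_volumes = c(spine = vol("spine_head"),
                                  shaft = vol(syn_label))),
            class = "trial_result")
}

#' Run a train trial
#'
#' Convenience wrapper around [run_trial()] that requires a train
#' protocol and flags trials in which any train pulse failed to elicit
#' exactly one spike.
#'
#' @inheritParams run_trial
#' @return A `trial_result`; see [run_trial()].
#' @export
run_train_trial <- function(spec, cond, post = 110, sample_every = 4L,
                            stim_margin = 1.1) {
  if (!has_train(spec)) stop("protocol has no train component")
  run_trial(spec, cond, post = post, sample_every = sample_every,
            stim_margin = stim_margin)
}

# flux of the test-pulse calcium response at one site, with the
# train/IPSP baseline trial subtracted when provided
trial_flux <- function(trial, site, baseline_trial = NULL,
                       window = 100) {
  x <- ca_flux_integral(trial$trace, trial$t_test, window,
                        series = paste0("ica.", site), site = site)
  if (!is.null(baseline_trial)) {
    b <- ca_flux_integral(baseline_trial$trace, baseline_trial$t_test,
                          window, series = paste0("ica.", site),
                          site = site)
    x$integral <- x$integral - b$integral
  }
  x
}

#' Per-condition trial metrics for paired control/inhibited trials
#'
#' Computes, at the spine and shaft, the test-pulse AP metrics and
#' 100-ms calcium flux for a control/inhibited trial pair (subtracting
#' train-alone / train-IPSP baselines for train protocols) and the
#' resulting inhibition fraction.
#'
#' @param ctl,inh `trial_result`s for the control and inhibited trial.
#' @param ctl_base,inh_base Optional baseline `trial_result`s
#'   (train-alone and train-IPSP) whose flux is subtracted.
#' @return `data.frame` with one row per site.
#' @export
trial_pair_metrics <- function(ctl, inh, ctl_base = NULL,
                               inh_base = NULL) {
  syn <- ctl$sites$synapse
  comps <- list(spine = "spine_head", shaft = syn)
  rows <- Map(function(site_name, site) {
    f_ctl <- trial_flux(ctl, site, ctl_base)
    f_inh <- trial_flux(inh, site, inh_base)
    m_ctl <- ap_metrics(ctl$trace, series = paste0("v.", site),
                        ica_series = paste0("ica.", site),
                        t_range = c(ctl$t_test, ctl$t_test + 30))
    m_inh <- ap_metrics(inh$trace, series = paste0("v.", site),
                        ica_series = paste0("ica.", site),
                        t_range = c(inh$t_test, inh$t_test + 30))
    data.frame(
      site = site_name,
      ap_peak_ctl = m_ctl$peak, ap_peak_inh = m_inh$peak,
      dpeak = m_ctl$peak - m_inh$peak,
      half_width_ctl = m_ctl$half_width,
      half_width_inh = m_inh$half_width,
      peak_ica_ctl = abs(m_ctl$peak_ica),
      peak_ica_inh = abs(m_inh$peak_ica),
      flux_ctl = f_ctl$integral, flux_inh = f_inh$integral,
      inhibition_fraction = inhibition_fraction(f_ctl$integral,
                                                f_inh$integral))
  }, names(comps), comps)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sweep the distal A-type density
#'
#' For each density: re-runs the holding-current search, recalibrates
#' the test pulse, runs bAP, IPSP-bAP and IPSP trials, and summarises AP
#' peak and half-width at the synapse site, peak calcium current, 100-ms
#' calcium flux and the inhibition fraction at the spine and shaft. A
#' calibration failure marks the condition but does not abort the
#' sweep.
#'
#' @param g_values Distal densities (mS/cm2); default the 7-point grid
#'   10-70.
#' @param dt Solver step (ms).
#' @param kinetics Kinetic constants, see [default_kinetics()].
#' @param ... Passed to [build_model()].
#' @return `data.frame` of class `sweep_result`, one row per condition
#'   and site; failed conditions carry `NA` metrics and `ok = FALSE`.
#' @export
run_gka_sweep <- function(g_values = seq(10, 70, by = 10), dt = 0.005,
                          kinetics = default_kinetics(), ...) {
  stopifnot(length(g_values) >= 2)
  rows <- lapply(g_values, function(g) {
    res <- tryCatch({
      cond <- setup_condition(gka_distal = g, dt = dt,
                              kinetics = kinetics, ...)
      ctl <- run_trial(protocol_spec("bAP", gka_distal = g), cond)
      inh <- run_trial(protocol_spec("IPSP-bAP", gka_distal = g), cond)
      ipsp <- run_trial(protocol_spec("IPSP", gka_distal = g), cond)
      m <- trial_pair_metrics(ctl, inh, inh_base = ipsp)
      m$holding <- cond$holding$current
      m$amplitude <- cond$stimulus$amplitude
      m$ok <- TRUE
      m
    }, error = function(e) {
      data.frame(site = c("spine", "shaft"), ap_peak_ctl = NA_real_,
                 ap_peak_inh = NA_real_, dpeak = NA_real_,
                 half_width_ctl = NA_real_, half_width_inh = NA_real_,
                 peak_ica_ctl = NA_real_, peak_ica_inh = NA_real_,
                 flux_ctl = NA_real_, flux_inh = NA_real_,
                 inhibition_fraction = NA_real_, holding = NA_real_,
                 amplitude = NA_real_, ok = FALSE,
                 error = conditionMessage(e))
    })
    res$gka_distal <- g
    if (is.null(res$error)) res$error <- NA_character_
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}
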