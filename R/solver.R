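# Implicit (backward) Euler integration of the branched cable model.
#
# simulate() drives the compiled solver; solver_step() is the R-level
# reference of the same scheme (gate advance at the step's voltage, then
# one tree-structured linear solve), used for verification on small
# models.

# global reversal potentials of the standard mechanism set (mV)
E_NA <- 50
E_K <- -77
E_CA <- 120

# gate specs of the standard mechanism set (kinetics only; densities
# live on the graph)
gate_specs <- function(kinetics = default_kinetics()) {
  na <- mech_na(); kdr <- mech_kdr()
  ka <- mech_ka(kinetics = kinetics); ca <- mech_ca(kinetics = kinetics)
  list(m = na$gates$m, h = na$gates$h, n = kdr$gates$n,
       a = ka$gates$a, b = ka$gates$b, c = ca$gates$c)
}

#' Solver configuration
#'
#' @param duration Simulation length (ms), non-negative.
#' @param dt Fixed time step (ms); default 0.005 ms.
#' @param record_v Labels of compartments whose voltage is recorded.
#' @param record_ica Labels of compartments whose calcium current is
#'   recorded (those carrying the reporter channel).
#' @param record_gates Label of one compartment whose A-type gates
#'   (activation `a`, inactivation `b`) are recorded, or `NULL`.
#' @param sample_every Store every k-th step (1 = full resolution).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(duration, dt = 0.005,
                          record_v = NULL, record_ica = NULL,
                          record_gates = NULL, sample_every = 1L) {
  stopifnot(dt > 0, duration >= 0, sample_every >= 1L)
  structure(list(duration = duration, dt = dt, record_v = record_v,
                 record_ica = record_ica, record_gates = record_gates,
                 sample_every = as.integer(sample_every)),
            class = "solver_config")
}

#' Rectangular current pulse
#'
#' @param onset Start time (ms).
#' @param width Duration (ms), positive.
#' @param amplitude Amplitude (nA).
#' @param target Compartment label or index; default the soma (root).
#' @return An object of class `stim_pulse`.
#' @export
stim_pulse <- function(onset, width, amplitude, target = 1L) {
  stopifnot(width > 0, is.finite(amplitude))
  structure(list(onset = onset, width = width, amplitude = amplitude,
                 target = target), class = "stim_pulse")
}

#' Initial state at a uniform holding potential
#'
#' All compartments at `v`, every gate at its steady state for `v`, the
#' synapse at rest.
#'
#' @param graph A [compartment_graph()].
#' @param v Initial membrane potential (mV).
#' @param kinetics Kinetic constants, see [default_kinetics()].
#' @return A state list (`v`, `gates` matrix, `syn`, `t`).
#' @export
init_state <- function(graph, v = -64, kinetics = default_kinetics()) {
  gs <- gate_specs(kinetics)
  gates <- vapply(gs, function(g) rep(gate_steady_state(v, g), graph$n),
                  numeric(graph$n))
  if (is.null(dim(gates))) gates <- matrix(gates, nrow = graph$n)
  colnames(gates) <- names(gs)
  list(v = rep(v, graph$n), gates = gates, syn = c(A = 0, B = 0), t = 0)
}

resolve_rec <- function(graph, labels, default) {
  if (is.null(labels)) labels <- default
  if (is.null(labels) || !length(labels)) return(integer())
  comp_index(graph, labels)
}

#' Simulate the compartmental model
#'
#' Advances the full model with fixed-step backward Euler and returns the
#' recorded traces. Identical inputs give bit-identical output.
#'
#' @param graph A [compartment_graph()].
#' @param cfg A [solver_config()].
#' @param stimuli List of [stim_pulse()] objects (somatic holding current
#'   is just a long pulse).
#' @param synapse A [synapse_spec()] with `onset_times`, or `NULL`.
#' @param init Initial state from [init_state()] or a previous trace's
#'   `final_state`; defaults to all compartments held at -64 mV.
#' @param rate_tables Use voltage-indexed lookup tables (0.005 mV
#'   resolution, linearly interpolated) for gate steady states and decay
#'   factors. `FALSE` evaluates the rate functions exactly at every
#'   step, matching [solver_step()] bit for bit; used for verification.
#' @param kinetics Kinetic constants of the A-type and reporter-calcium
#'   gates, see [default_kinetics()].
#' @return An object of class `dendka_trace`: `time` (ms), named voltage
#'   series `v` (mV), calcium currents `ica` (nA, negative = inward),
#'   A-type gate series `gates`, synaptic conductance `syn_g` (nS), the
#'   `final_state` for warm restarts, and `min_v_all`/`max_v_all`, the
#'   extreme voltages reached in any compartment at any step.
#' @export
simulate <- function(graph, cfg, stimuli = list(), synapse = NULL,
                     init = NULL, rate_tables = TRUE,
                     kinetics = default_kinetics()) {
  stopifnot(inherits(graph, "compartment_graph"),
            inherits(cfg, "solver_config"),
            length(kinetics) == 12)
  if (inherits(stimuli, "stim_pulse")) stimuli <- list(stimuli)
  n <- graph$n
  if (is.null(init)) init <- init_state(graph, kinetics = kinetics)
  stopifnot(length(init$v) == n, nrow(init$gates) == n)

  dt <- cfg$dt
  n_steps <- round(cfg$duration / dt)
  comps <- graph$comps
  area <- graph$area
  parent0 <- ifelse(is.na(comps$parent), -1L, comps$parent - 1L)
  g_ax <- ifelse(is.na(graph$g_axial), 0, graph$g_axial)

  pulses <- matrix(0, nrow = length(stimuli), ncol = 4)
  for (i in seq_along(stimuli)) {
    p <- stimuli[[i]]
    stopifnot(inherits(p, "stim_pulse"))
    pulses[i, ] <- c(comp_index(graph, p$target) - 1L,
                     round(p$onset / dt),
                     round((p$onset + p$width) / dt),
                     p$amplitude * 1e-3)  # nA -> uA
  }

  has_syn <- !is.null(synapse)
  syn_comp0 <- 0L; syn_gmax <- 0; st1 <- 1; st2 <- 2; snorm <- 1; esyn <- 0
  syn_steps <- numeric()
  if (has_syn) {
    stopifnot(inherits(synapse, "synapse_spec"))
    if (is.na(graph$synapse_comp))
      stop("graph has no synapse compartment")
    syn_comp0 <- graph$synapse_comp - 1L
    syn_gmax <- synapse$g_max * 1e-6  # nS -> mS
    st1 <- synapse$tau_rise; st2 <- synapse$tau_decay
    snorm <- biexp_norm(st1, st2)
    esyn <- synapse$reversal
    syn_steps <- sort(round(synapse$onset_times / dt))
  }

  rec_v <- resolve_rec(graph, cfg$record_v, comps$label[1L])
  rec_ica <- resolve_rec(graph, cfg$record_ica,
                         comps$label[comps$g_ca > 0])
  rec_g <- if (is.null(cfg$record_gates)) -1L else
    comp_index(graph, cfg$record_gates) - 1L

  res <- cable_simulate_cpp(
    parent0, comps$cm * area, g_ax,
    comps$g_leak * area, comps$e_leak,
    comps$g_na * area, comps$g_kdr * area, comps$g_ka * area,
    comps$g_ca * area,
    E_NA, E_K, E_CA,
    dt, n_steps, cfg$sample_every, pulses,
    has_syn, syn_comp0, syn_gmax, st1, st2, snorm, esyn, syn_steps,
    rec_v - 1L, rec_ica - 1L, rec_g,
    init$v, init$gates, init$syn, isTRUE(rate_tables),
    as.numeric(kinetics))

  v <- lapply(seq_along(rec_v), function(j) res$v[, j])
  names(v) <- comps$label[rec_v]
  ica <- lapply(seq_along(rec_ica), function(j) res$ica[, j])
  names(ica) <- comps$label[rec_ica]
  gates <- if (rec_g >= 0)
    list(a = res$gates[, 1], b = res$gates[, 2]) else list()

  fg <- res$final_gates
  colnames(fg) <- c("m", "h", "n", "a", "b", "c")
  structure(
    list(time = res$time, v = v, ica = ica, gates = gates,
         syn_g = res$syn_g, dt = dt * cfg$sample_every,
         min_v_all = res$min_v_all, max_v_all = res$max_v_all,
         final_state = list(v = res$final_v, gates = fg,
                            syn = setNames(res$final_syn, c("A", "B")),
                            t = n_steps * dt)),
    class = "dendka_trace")
}

#' @export
print.dendka_trace <- function(x, ...) {
  cat("<dendka_trace> ", length(x$time), " samples, dt = ", x$dt,
      " ms, span ", format(max(x$time), digits = 6), " ms\n", sep = "")
  cat("  voltage sites: ", paste(names(x$v), collapse = ", "), "\n",
      sep = "")
  if (length(x$ica))
    cat("  calcium sites: ", paste(names(x$ica), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.dendka_trace <- function(x, ...) {
  out <- data.frame(time = x$time)
  for (s in names(x$v)) out[[paste0("v.", s)]] <- x$v[[s]]
  for (s in names(x$ica)) out[[paste0("ica.", s)]] <- x$ica[[s]]
  for (s in names(x$gates)) out[[paste0("gate_", s)]] <- x$gates[[s]]
  if (length(x$syn_g) == nrow(out) && any(x$syn_g != 0))
    out$syn_g <- x$syn_g
  out
}

#' Extract a named series from a trace
#'
#' @param trace A `dendka_trace`.
#' @param name Series name: `"v.<site>"`, `"ica.<site>"`, `"gate_a"`,
#'   `"gate_b"`, or `"syn_g"`.
#' @return Numeric vector aligned with `trace$time`.
#' @export
trace_series <- function(trace, name) {
  stopifnot(inherits(trace, "dendka_trace"))
  if (startsWith(name, "v.")) return(trace$v[[substring(name, 3)]])
  if (startsWith(name, "ica.")) return(trace$ica[[substring(name, 5)]])
  if (name == "gate_a") return(trace$gates$a)
  if (name == "gate_b") return(trace$gates$b)
  if (name == "syn_g") return(trace$syn_g)
  stop("unknown series: ", name)
}

#' Advance the model state by one backward-Euler step (R reference)
#'
#' Reference implementation of the scheme used by [simulate()]: gates are
#' advanced by the exact exponential update at the step's starting
#' voltage, then the linear voltage system is solved exactly by
#' tree-structured elimination. Intended for verification on small
#' models; [simulate()] runs the same scheme in compiled code.
#'
#' @param state State list as from [init_state()].
#' @param graph A [compartment_graph()].
#' @param dt Time step (ms), positive.
#' @param i_inj Injected currents (nA): named by compartment label or a
#'   full-length vector.
#' @param synapse A [synapse_spec()] or `NULL`; events are taken from
#'   `synapse$onset_times` snapped to the nearest step.
#' @param kinetics Kinetic constants, see [default_kinetics()].
#' @return The advanced state.
#' @export
solver_step <- function(state, graph, dt, i_inj = NULL, synapse = NULL,
                        kinetics = default_kinetics()) {
  stopifnot(inherits(graph, "compartment_graph"), dt > 0)
  n <- graph$n
  comps <- graph$comps
  area <- graph$area
  gs <- gate_specs(kinetics)
  v <- state$v
  gates <- state$gates
  for (g in names(gs))
    gates[, g] <- gate_step(gates[, g], v, dt, gs[[g]])

  inj <- numeric(n)  # uA
  if (!is.null(i_inj)) {
    if (!is.null(names(i_inj))) {
      idx <- comp_index(graph, names(i_inj))
      inj[idx] <- i_inj * 1e-3
    } else {
      stopifnot(length(i_inj) == n)
      inj <- i_inj * 1e-3
    }
  }

  syn <- state$syn
  g_syn <- 0
  if (!is.null(synapse)) {
    syn["A"] <- syn["A"] * exp(-dt / synapse$tau_rise)
    syn["B"] <- syn["B"] * exp(-dt / synapse$tau_decay)
    step_new <- round((state$t + dt) / dt)
    hits <- sum(round(synapse$onset_times / dt) == step_new)
    if (hits > 0) syn <- syn + hits
    g_syn <- synapse$g_max * 1e-6 *
      biexp_norm(synapse$tau_rise, synapse$tau_decay) *
      max(syn["B"] - syn["A"], 0)
  }

  cm_uF <- comps$cm * area
  g_na <- comps$g_na * area * gates[, "m"]^3 * gates[, "h"]
  g_k <- comps$g_kdr * area * gates[, "n"]^4
  g_ka <- comps$g_ka * area * gates[, "a"] * gates[, "b"]
  g_ca <- comps$g_ca * area * gates[, "c"]^2
  g_l <- comps$g_leak * area

  diag <- cm_uF / dt + g_l + g_na + g_k + g_ka + g_ca
  rhs <- cm_uF / dt * v + g_l * comps$e_leak + g_na * E_NA +
    (g_k + g_ka) * E_K + g_ca * E_CA + inj
  if (!is.null(synapse) && !is.na(graph$synapse_comp)) {
    sc <- graph$synapse_comp
    diag[sc] <- diag[sc] + g_syn
    rhs[sc] <- rhs[sc] + g_syn * synapse$reversal
  }
  g_ax <- ifelse(is.na(graph$g_axial), 0, graph$g_axial)
  if (n > 1L) {
    for (i in 2:n) {
      p <- comps$parent[i]
      diag[i] <- diag[i] + g_ax[i]
      diag[p] <- diag[p] + g_ax[i]
    }
    for (i in n:2) {
      p <- comps$parent[i]
      f <- g_ax[i] / diag[i]
      diag[p] <- diag[p] - g_ax[i] * f
      rhs[p] <- rhs[p] + rhs[i] * f
    }
  }
  if (!is.finite(diag[1]) || diag[1] == 0)
    stop("solver failure: singular system")
  v_new <- numeric(n)
  v_new[1] <- rhs[1] / diag[1]
  if (n > 1L) {
    for (i in 2:n)
      v_new[i] <- (rhs[i] + g_ax[i] * v_new[comps$parent[i]]) / diag[i]
  }
  list(v = v_new, gates = gates, syn = syn, t = state$t + dt)
}
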