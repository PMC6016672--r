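# Voltage-gated channel kinetics, leak, and the biexponential GABA-A synapse.
#
# All gates are expressed in steady-state / time-constant form,
#   dm/dt = (m_inf(V) - m) / tau(V),
# advanced by the exact exponential update at frozen voltage (gate_step).

#' Gate specification
#'
#' A single Hodgkin-Huxley gating variable, described by its steady-state
#' activation curve and voltage-dependent time constant.
#'
#' @param name Gate label (e.g. `"m"`).
#' @param steady_state Function of membrane potential (mV) returning the
#'   steady-state activation in `[0, 1]`.
#' @param time_constant Function of membrane potential (mV) returning the
#'   time constant in ms (strictly positive).
#' @param exponent Small positive integer power applied in the conductance
#'   product (e.g. 3 for the classic sodium `m` gate).
#' @return An object of class `gate_spec`.
#' @seealso [boltzmann_gate()], [gate_step()]
#' @export
gate_spec <- function(name, steady_state, time_constant, exponent = 1L) {
  stopifnot(is.character(name), length(name) == 1L,
            is.function(steady_state), is.function(time_constant),
            is.numeric(exponent), length(exponent) == 1L, exponent >= 1)
  structure(
    list(name = name, steady_state = steady_state,
         time_constant = time_constant, exponent = as.integer(exponent)),
    class = "gate_spec")
}

#' Single-Boltzmann gate
#'
#' Convenience constructor for a gate with sigmoidal steady state
#' `1 / (1 + exp(-(V - v_half)/k))` and a (possibly voltage-dependent)
#' time constant. A negative slope factor `k` gives an inactivation gate.
#'
#' @param name Gate label.
#' @param v_half Half-activation voltage (mV).
#' @param k Slope factor (mV); sign sets activation vs inactivation.
#' @param tau Time constant: a positive scalar (ms) or a function of V.
#' @param exponent Power in the conductance product.
#' @return A [gate_spec()].
#' @export
boltzmann_gate <- function(name, v_half, k, tau, exponent = 1L) {
  stopifnot(is.numeric(v_half), is.numeric(k), k != 0)
  tau_fun <- if (is.function(tau)) tau else {
    stopifnot(tau > 0)
    function(V) rep_len(tau, length(V))
  }
  gate_spec(name,
            steady_state = function(V) 1 / (1 + exp(-(V - v_half) / k)),
            time_constant = tau_fun,
            exponent = exponent)
}

# alpha/beta form helper; m_inf = a/(a+b), tau = 1/(a+b), floored for
# numerical safety near rate singularities.
rate_gate <- function(name, alpha, beta, exponent = 1L, tau_min = 0.02) {
  gate_spec(name,
            steady_state = function(V) {
              a <- alpha(V); b <- beta(V)
              a / (a + b)
            },
            time_constant = function(V) {
              pmax(1 / (alpha(V) + beta(V)), tau_min)
            },
            exponent = exponent)
}

# x/(exp(x/y) - 1) with the removable singularity at x = 0 handled.
vtrap <- function(x, y) {
  ifelse(abs(x / y) < 1e-6, y * (1 - x / y / 2), x / (exp(x / y) - 1))
}

#' Steady-state activation of a gate
#'
#' @param V Membrane potential (mV), finite.
#' @param gate A [gate_spec()].
#' @return Activation value(s) in `[0, 1]`.
#' @export
gate_steady_state <- function(V, gate) {
  stopifnot(inherits(gate, "gate_spec"), all(is.finite(V)))
  pmin(pmax(gate$steady_state(V), 0), 1)
}

#' Voltage-dependent time constant of a gate
#'
#' @inheritParams gate_steady_state
#' @return Time constant(s) in ms, strictly positive.
#' @export
gate_time_constant <- function(V, gate) {
  stopifnot(inherits(gate, "gate_spec"), all(is.finite(V)))
  tau <- gate$time_constant(V)
  stopifnot(all(tau > 0))
  tau
}

#' Advance a gating variable one time step
#'
#' Exact exponential update of the first-order gating ODE at frozen
#' voltage: `m' = m_inf + (m - m_inf) * exp(-dt / tau)`.
#'
#' @param m Current activation in `[0, 1]`.
#' @param V Membrane potential (mV) held over the step.
#' @param dt Step (ms), strictly positive.
#' @param gate A [gate_spec()].
#' @return Updated activation, guaranteed to stay in `[0, 1]`.
#' @export
gate_step <- function(m, V, dt, gate) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a single positive number")
  stopifnot(all(m >= 0), all(m <= 1))
  minf <- gate_steady_state(V, gate)
  tau <- gate_time_constant(V, gate)
  minf + (m - minf) * exp(-dt / tau)
}

#' Channel specification
#'
#' @param name Channel label.
#' @param gates List of [gate_spec()] objects.
#' @param max_density Maximal conductance density (mS/cm2), non-negative.
#' @param reversal Reversal potential (mV), finite.
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(name, gates, max_density, reversal) {
  stopifnot(is.character(name),
            is.list(gates), all(vapply(gates, inherits, TRUE, "gate_spec")),
            is.numeric(max_density), max_density >= 0,
            is.numeric(reversal), is.finite(reversal))
  names(gates) <- vapply(gates, `[[`, "", "name")
  structure(list(name = name, gates = gates,
                 max_density = max_density, reversal = reversal),
            class = "channel_spec")
}

#' Ohmic channel current density
#'
#' `I = g_bar * prod(gate^exponent) * (V - E)`; positive is outward.
#'
#' @param density Maximal conductance density (mS/cm2), non-negative.
#' @param gate_values Numeric vector of instantaneous gate values.
#' @param V Membrane potential (mV).
#' @param reversal Reversal potential (mV).
#' @param exponents Integer powers, one per gate (default all 1).
#' @return Current density in uA/cm2.
#' @export
channel_current <- function(density, gate_values, V, reversal,
                            exponents = NULL) {
  stopifnot(density >= 0)
  if (is.null(exponents)) exponents <- rep(1L, length(gate_values))
  stopifnot(length(exponents) == length(gate_values))
  open <- prod(gate_values ^ exponents)
  density * open * (V - reversal)
}

#' A-type conductance density along the apical trunk
#'
#' The A-type density is zero at the soma and over the most proximal
#' trunk segment and increases linearly, segment by segment, reaching
#' `g_distal` in the most distal segment. With the default discretisation
#' (100 segments of 5 um) the density of segment `k` (0-based) is
#' `g_distal * k / 99`, so the segment containing the synapse
#' (centre 122.5 um, k = 24) carries `g_distal * 24/99`: 17.0 mS/cm2
#' when `g_distal = 70` and 2.4 mS/cm2 when `g_distal = 10`.
#'
#' @param x Path distance from the soma (um), within `[0, trunk_length]`.
#' @param g_distal Density in the most distal segment (mS/cm2).
#' @param trunk_length Trunk length (um), default 500.
#' @param seg_length Segment length (um), default 5.
#' @return Conductance density (mS/cm2).
#' @export
ka_density_at <- function(x, g_distal, trunk_length = 500, seg_length = 5) {
  stopifnot(g_distal >= 0, trunk_length > 0, seg_length > 0)
  if (any(x < 0 | x > trunk_length))
    stop("'x' outside the trunk [0, trunk_length]")
  nseg <- round(trunk_length / seg_length)
  k <- pmin(floor(x / seg_length), nseg - 1)
  g_distal * k / (nseg - 1)
}

#' GABA-A synapse specification
#'
#' Peak-normalised biexponential conductance (difference of exponentials,
#' scaled so its maximum equals `g_max`), the conventional two-exponential
#' synapse mechanism.
#'
#' @param g_max Peak conductance (nS), positive. Default 2 nS.
#' @param tau_rise Rise time constant (ms). Default 5 ms.
#' @param tau_decay Decay time constant (ms), must exceed `tau_rise`.
#'   Default 74 ms.
#' @param reversal Reversal potential (mV); chloride, default -70 mV.
#' @param onset_times Activation times (ms).
#' @return An object of class `synapse_spec`.
#' @export
synapse_spec <- function(g_max = 2, tau_rise = 5, tau_decay = 74,
                         reversal = -70, onset_times = numeric()) {
  if (!(tau_decay > tau_rise && tau_rise > 0))
    stop("invalid kinetics: need tau_decay > tau_rise > 0")
  stopifnot(g_max > 0, is.finite(reversal))
  structure(list(g_max = g_max, tau_rise = tau_rise, tau_decay = tau_decay,
                 reversal = reversal, onset_times = as.numeric(onset_times)),
            class = "synapse_spec")
}

#' Time of peak of the biexponential conductance
#'
#' Closed form `t_peak = tau1*tau2/(tau2 - tau1) * log(tau2/tau1)`.
#'
#' @param syn A [synapse_spec()].
#' @return Time of peak after onset (ms).
#' @export
biexp_peak_time <- function(syn) {
  stopifnot(inherits(syn, "synapse_spec"))
  t1 <- syn$tau_rise; t2 <- syn$tau_decay
  (t1 * t2 / (t2 - t1)) * log(t2 / t1)
}

# normalisation so the peak of exp(-t/tau2) - exp(-t/tau1) equals 1
biexp_norm <- function(tau_rise, tau_decay) {
  tp <- (tau_rise * tau_decay / (tau_decay - tau_rise)) *
    log(tau_decay / tau_rise)
  1 / (exp(-tp / tau_decay) - exp(-tp / tau_rise))
}

#' Biexponential synaptic conductance
#'
#' `g(t) = g_max * N * (exp(-t/tau_decay) - exp(-t/tau_rise))` with `N`
#' chosen so the peak equals `g_max`; zero for `t <= 0`.
#'
#' @param t Time since synapse onset (ms); values before onset give 0.
#' @param syn A [synapse_spec()].
#' @return Conductance (nS), non-negative.
#' @export
biexp_conductance <- function(t, syn) {
  stopifnot(inherits(syn, "synapse_spec"))
  N <- biexp_norm(syn$tau_rise, syn$tau_decay)
  g <- syn$g_max * N * (exp(-t / syn$tau_decay) - exp(-t / syn$tau_rise))
  ifelse(t <= 0, 0, pmax(g, 0))
}

# ---------------------------------------------------------------------------
# Standard mechanism library.
#
# Sodium and delayed-rectifier kinetics are classic Hodgkin-Huxley rate
# forms (resting potential near -65 mV, spike threshold near -50 mV). The
# A-type channel follows the distal-dendrite phenotype: fast activation
# with a relatively depolarised midpoint, voltage-dependent inactivation
# with a midpoint near rest, rapid entry into inactivation during
# depolarisation and slow recovery at rest. The calcium channel is a
# medium-threshold two-gate activation channel used as a pure reporter
# (density 1e-7 mS/cm2) so that its current does not perturb the voltage.

#' Sodium channel (classic HH kinetics), default 4 mS/cm2, E = +50 mV
#' @param density Maximal density (mS/cm2).
#' @return A [channel_spec()].
#' @export
mech_na <- function(density = 4) {
  m <- rate_gate("m",
    alpha = function(V) 0.1 * vtrap(-(V + 40), 10),
    beta  = function(V) 4 * exp(-(V + 65) / 18),
    exponent = 3L)
  h <- rate_gate("h",
    alpha = function(V) 0.07 * exp(-(V + 65) / 20),
    beta  = function(V) 1 / (1 + exp(-(V + 35) / 10)),
    exponent = 1L)
  channel_spec("na", list(m, h), density, reversal = 50)
}

#' Delayed-rectifier potassium channel (classic HH n^4), default 0.1 mS/cm2
#' @param density Maximal density (mS/cm2).
#' @return A [channel_spec()].
#' @export
mech_kdr <- function(density = 0.1) {
  n <- rate_gate("n",
    alpha = function(V) 0.01 * vtrap(-(V + 55), 10),
    beta  = function(V) 0.125 * exp(-(V + 65) / 80),
    exponent = 4L)
  channel_spec("kdr", list(n), density, reversal = -77)
}

#' Default kinetic constants of the A-type and reporter-calcium gates
#'
#' The A-type activation gate `a` is a Boltzmann with midpoint
#' `ka_a_vhalf` and slope `ka_a_k` (fixed time constant `ka_a_tau`);
#' the inactivation gate `b` has midpoint `ka_b_vhalf`, slope `ka_b_k`
#' (descending), and a sigmoidal time constant
#' `ka_b_tau_min + ka_b_tau_amp / (1 + exp((V - ka_b_tau_vhalf)/ka_b_tau_k))`
#' giving slow recovery at rest and faster entry into inactivation when
#' depolarised. The reporter-calcium activation gate `c` (squared in the
#' conductance) is a Boltzmann with midpoint `ca_vhalf`, slope `ca_k`
#' and fixed time constant `ca_tau`. All voltages in mV, times in ms.
#'
#' @return Named numeric vector of the 12 constants.
#' @export
default_kinetics <- function() {
  c(ka_a_vhalf = -25, ka_a_k = 6, ka_a_tau = 1,
    ka_b_vhalf = -56, ka_b_k = 8,
    ka_b_tau_min = 8, ka_b_tau_amp = 50,
    ka_b_tau_vhalf = -50, ka_b_tau_k = 10,
    ca_vhalf = -12, ca_k = 3.5, ca_tau = 1.5)
}

#' A-type potassium channel (distal-dendrite phenotype)
#'
#' Activation gate `a`: Boltzmann midpoint -25 mV, slope 6 mV, tau 1 ms,
#' so the channel is essentially silent at the -64 mV holding potential
#' but strongly recruited over the voltage range visited by
#' back-propagated spikes in the proximal apical dendrite.
#' Inactivation gate `b`: midpoint -56 mV, slope -8 mV; time constant
#' `8 + 50 / (1 + exp((V + 50)/10))` ms, i.e. ~48 ms recovery at rest
#' and ~8 ms entry into inactivation when depolarised, so inactivation
#' accumulates more strongly over a 100-Hz spike train (10-ms
#' inter-spike interval) than a 50-Hz one, and persists across the
#' 20-ms gap before a test pulse. 4-AP block is modelled
#' exclusively as a reduction of `density`.
#'
#' @param density Maximal density (mS/cm2).
#' @param kinetics Kinetic constants, see [default_kinetics()].
#' @return A [channel_spec()].
#' @export
mech_ka <- function(density = 70, kinetics = default_kinetics()) {
  kk <- kinetics
  a <- boltzmann_gate("a", v_half = kk[["ka_a_vhalf"]],
                      k = kk[["ka_a_k"]], tau = kk[["ka_a_tau"]])
  b <- boltzmann_gate("b", v_half = kk[["ka_b_vhalf"]],
                      k = -kk[["ka_b_k"]],
                      tau = function(V) kk[["ka_b_tau_min"]] +
                        kk[["ka_b_tau_amp"]] /
                        (1 + exp((V - kk[["ka_b_tau_vhalf"]]) /
                                   kk[["ka_b_tau_k"]])))
  channel_spec("ka", list(a, b), density, reversal = -77)
}

#' Reporter calcium channel (medium-threshold, two-gate activation)
#'
#' Two identical activation gates with Boltzmann midpoint -12 mV, slope
#' 3.5 mV, tau 1.5 ms; no inactivation; ohmic driving force with
#' E_Ca = +120 mV. The default density of 1e-7 mS/cm2 makes the channel a
#' pure calcium reporter with negligible effect on membrane potential.
#'
#' @param density Maximal density (mS/cm2).
#' @param kinetics Kinetic constants, see [default_kinetics()].
#' @return A [channel_spec()].
#' @export
mech_ca <- function(density = 1e-7, kinetics = default_kinetics()) {
  c1 <- boltzmann_gate("c", v_half = kinetics[["ca_vhalf"]],
                       k = kinetics[["ca_k"]],
                       tau = kinetics[["ca_tau"]], exponent = 2L)
  channel_spec("ca", list(c1), density, reversal = 120)
}
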