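# Channel gating, the A-type density gradient, and the biexponential
# GABA-A conductance.

test_that("Boltzmann gate steady state: midpoint, closed form, saturation", {
  g <- boltzmann_gate("m", v_half = -30, k = 10, tau = 2)
  expect_equal(gate_steady_state(-30, g), 0.5)
  expect_equal(gate_steady_state(-20, g), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  expect_lt(gate_steady_state(-200, g), 1e-7)
  expect_true(all(diff(gate_steady_state(seq(-120, 60, 1), g)) > 0))
})

test_that("gate_step is the exact exponential update", {
  g <- boltzmann_gate("m", v_half = -30, k = 10, tau = 5)
  # fixed point
  minf <- gate_steady_state(-10, g)
  expect_equal(gate_step(minf, -10, 1, g), minf, tolerance = 1e-14)
  # closed form: m=0 toward m_inf at tau = dt gives 1 - 1/e of the gap
  g1 <- boltzmann_gate("m", v_half = 0, k = 1e-6, tau = 5)  # m_inf ~ 1 at V>0
  m1 <- gate_step(0, 50, 5, g1)
  expect_equal(m1, 1 - exp(-1), tolerance = 1e-9)
  # continuity for tiny dt
  expect_lt(abs(gate_step(0.3, -10, 1e-6, g) - 0.3), 1e-6)
  expect_error(gate_step(0.3, -10, 0, g), "dt")
  expect_error(gate_step(0.3, -10, -1, g), "dt")
})

test_that("channel_current follows the ohmic HH form", {
  # zero at reversal
  expect_equal(channel_current(4, c(0.5, 1), 50, 50,
                               exponents = c(3, 1)), 0)
  # g = 4, m^3 h with m = 0.5, h = 1, driving force 10 mV -> 5 uA/cm2
  expect_equal(channel_current(4, c(0.5, 1), 10, 0,
                               exponents = c(3, 1)), 5)
  # any closed gate shuts the channel
  expect_equal(channel_current(10, c(0, 0.9), -20, -77,
                               exponents = c(1, 1)), 0)
  expect_error(channel_current(-1, 1, 0, 0))
})

test_that("A-type density gradient reproduces the printed synapse-site values", {
  expect_equal(ka_density_at(122.5, 70), 17.0, tolerance = 0.05)
  expect_equal(ka_density_at(122.5, 10), 2.4, tolerance = 0.05)
  expect_equal(ka_density_at(0, 70), 0)
  # zero over the proximal segment, maximal in the distal segment
  expect_equal(ka_density_at(4.9, 70), 0)
  expect_equal(ka_density_at(499, 70), 70)
  expect_true(all(diff(ka_density_at(seq(2.5, 497.5, 5), 70)) >= 0))
  expect_error(ka_density_at(600, 70), "outside")
  expect_error(ka_density_at(-1, 70), "outside")
})

test_that("biexponential synapse is peak-normalised with the printed peak", {
  syn <- synapse_spec()  # 2 nS, tau 5/74 ms
  expect_equal(biexp_conductance(0, syn), 0)
  # numeric maximisation oracle: peak conductance and peak time
  opt <- optimize(function(t) biexp_conductance(t, syn),
                  c(0, 200), maximum = TRUE)
  expect_equal(opt$objective, 2, tolerance = 1e-7)
  t1 <- syn$tau_rise; t2 <- syn$tau_decay
  expect_equal(opt$maximum, t1 * t2 / (t2 - t1) * log(t2 / t1),
               tolerance = 1e-4)
  expect_equal(biexp_peak_time(syn), 14.4495, tolerance = 1e-4)
  expect_error(synapse_spec(tau_rise = 74, tau_decay = 5),
               "invalid kinetics")
})

test_that("biexponential integral matches the analytic value to 0.1%", {
  syn <- synapse_spec()
  num <- integrate(function(t) biexp_conductance(t, syn), 0, 3000,
                   rel.tol = 1e-9)$value
  N <- 1 / (exp(-biexp_peak_time(syn) / syn$tau_decay) -
              exp(-biexp_peak_time(syn) / syn$tau_rise))
  ana <- syn$g_max * N * (syn$tau_decay - syn$tau_rise)
  expect_equal(num, ana, tolerance = 1e-3)
})

test_that("gates stay in [0,1] under random piecewise-constant voltage", {
  set.seed(7)
  chans <- list(mech_na(), mech_kdr(), mech_ka(), mech_ca())
  gates <- unlist(lapply(chans, `[[`, "gates"), recursive = FALSE)
  for (rep in 1:5) {
    vs <- runif(30, -120, 60)
    for (g in gates) {
      m <- runif(1)
      for (v in vs) {
        m <- gate_step(m, v, runif(1, 0.001, 2), g)
        expect_gte(m, 0)
        expect_lte(m, 1)
      }
    }
  }
})

test_that("gates converge to steady state under voltage clamp", {
  chans <- list(mech_na(), mech_kdr(), mech_ka(), mech_ca())
  gates <- unlist(lapply(chans, `[[`, "gates"), recursive = FALSE)
  for (v in c(-80, -50, 0)) {
    for (g in gates) {
      tau <- gate_time_constant(v, g)
      m <- 0.9
      # 40 steps of tau/2 span 20 tau
      for (i in 1:40) m <- gate_step(m, v, tau / 2, g)
      expect_lt(abs(m - gate_steady_state(v, g)), 1e-6)
    }
  }
})

test_that("A-type inactivation is voltage dependent with recovery at rest", {
  b <- mech_ka()$gates$b
  clamp <- function(v, dur) {
    m <- gate_steady_state(-64, b)
    for (i in seq_len(dur / 0.5)) m <- gate_step(m, v, 0.5, b)
    m
  }
  expect_lt(clamp(0, 50), clamp(-64, 50))
  # recovery: after inactivation at 0 mV, a rest period restores b
  m0 <- clamp(0, 50)
  m_rec <- m0
  for (i in 1:400) m_rec <- gate_step(m_rec, -64, 0.5, b)
  expect_gt(m_rec, m0 + 0.2)
})
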