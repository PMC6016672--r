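# Synthetic line-scan generation and the experimental analysis chain.

mk_template <- function(amp_spine = 1, amp_shaft = 0.6, dur = 220,
                        rate = 500, t_test = 35, light = TRUE,
                        rest = 0.05, tau = 50) {
  tt <- seq(0, dur, by = 1000 / rate)
  transient <- function(a)
    rest + a * ifelse(tt >= t_test, exp(-(tt - t_test) / tau), 0)
  structure(list(time = tt,
                 ca = list(spine = transient(amp_spine),
                           shaft = transient(amp_shaft)),
                 t_test = t_test,
                 t_ipsp = if (light) t_test - 15 else NA_real_,
                 light = light),
            class = "imaging_template")
}

test_that("Hill fluorescence: baseline, saturation, midpoint", {
  cfg <- imaging_config()
  expect_equal(fluorescence_from_ca(0, cfg), cfg$g0)
  expect_equal(fluorescence_from_ca(1e9, cfg), cfg$g_sat,
               tolerance = 1e-6)
  expect_equal(fluorescence_from_ca(cfg$kd, cfg),
               cfg$g0 + (cfg$g_sat - cfg$g0) / 2)
  expect_true(all(diff(fluorescence_from_ca(seq(0, 50, 0.1), cfg)) > 0))
})

test_that("line-scan generation is deterministic and noiseless without noise", {
  tpl <- mk_template()
  cfg <- imaging_config()
  a <- simulate_linescan(tpl, cfg, seed = 11)
  b <- simulate_linescan(tpl, cfg, seed = 11)
  expect_identical(a, b)
  c2 <- simulate_linescan(tpl, cfg, seed = 12)
  expect_false(identical(a$spine$green, c2$spine$green))
  # zero noise, no artifact -> every trial equals the clean trace
  cfg0 <- imaging_config(noise_sd = 0, artifact_amp = 0)
  z <- simulate_linescan(tpl, cfg0, seed = 1, n_trials = 3)
  clean <- fluorescence_from_ca(tpl$ca$spine, cfg0)
  for (i in 1:3) expect_equal(unname(z$spine$green[i, ]), clean)
  expect_true(all(z$spine$red == cfg0$red))
})

test_that("photoartifact appears only on light trials and is corrected", {
  cfg <- imaging_config(noise_sd = 0)
  light <- simulate_linescan(mk_template(light = TRUE), cfg, seed = 1)
  dark <- simulate_linescan(mk_template(light = FALSE), cfg, seed = 1)
  d <- light$spine$green[1, ] - dark$spine$green[1, ]
  on <- light$time >= light$t_ipsp &
    light$time < light$t_ipsp + cfg$artifact_duration
  expect_true(all(d[on] == cfg$artifact_amp))
  expect_true(all(d[!on] == 0))
})

test_that("trial mean converges to the noiseless trace (law of large numbers)", {
  tpl <- mk_template(dur = 100)
  cfg <- imaging_config(noise_sd = 8)
  e <- simulate_linescan(tpl, cfg, seed = 99, n_trials = 1000)
  clean <- fluorescence_from_ca(tpl$ca$spine, cfg)
  on <- tpl$time >= tpl$t_ipsp & tpl$time < tpl$t_ipsp + cfg$artifact_duration
  clean[on] <- clean[on] + cfg$artifact_amp
  se <- cfg$noise_sd / sqrt(1000)
  expect_true(all(abs(colMeans(e$spine$green) - clean) < 3.5 * se))
})

test_that("dG/Gsat arithmetic matches the normalisation formula", {
  # constant G0 baseline, a step of dG = 50, Gsat = 600, R constant:
  # dG/Gsat = 50/600
  cfg <- imaging_config(noise_sd = 0, artifact_amp = 0, g0 = 50,
                        g_sat = 600, red = 300)
  tt <- seq(0, 220, by = 2)
  step_ca <- ifelse(tt >= 35, cfg$kd * (50 / (600 - 50 - 50)), 0)
  # choose ca so that G - G0 = 50 exactly: (Gsat-G0)*ca/(ca+kd) = 50
  tpl <- structure(list(time = tt,
                        ca = list(spine = step_ca, shaft = step_ca),
                        t_test = 35, t_ipsp = NA_real_, light = FALSE),
                   class = "imaging_template")
  entry <- simulate_linescan(tpl, cfg, seed = 1, n_trials = 2)
  an <- dendka:::entry_dgsat(entry, "spine", cfg)
  expect_equal(max(an), 50 / 600, tolerance = 1e-9)
  expect_equal(min(an), 0, tolerance = 1e-9)
})

test_that("analysis chain is unbiased at zero noise with a linear indicator", {
  trials <- std_trials()
  # near-linear limit: kd huge, dynamic range scaled to keep gain finite
  cfg_lin <- imaging_config(noise_sd = 0, kd = 1e8,
                            g_sat = 50 + 1e8 * 200)
  entries <- lapply(trials, simulate_linescan, cfg = cfg_lin, seed = 1)
  an <- analyze_trials(entries, cfg_lin)
  # ground truth from the calcium templates themselves
  tpls <- lapply(trials, prepare_imaging_template, cfg = cfg_lin)
  gt <- function(site) {
    fl <- function(ty) {
      tpl <- tpls[[ty]]
      ca <- tpl$ca[[site]]
      # pre-event baseline, as the analysis chain defines it
      base <- mean(ca[tpl$time < min(tpl$t_ipsp, tpl$t_test,
                                     na.rm = TRUE) - 5])
      ca_flux_integral(list(time = tpl$time, y = ca - base),
                       tpl$t_test, 100, site = site,
                       rectify = FALSE)$integral
    }
    1 - (fl("IPSP-bAP") - fl("IPSP")) / fl("bAP")
  }
  for (site in c("spine", "shaft")) {
    rec <- an$fractions$fraction[an$fractions$site == site]
    expect_equal(rec, gt(site), tolerance = 1e-6)
  }
})

test_that("indicator saturation biases the recovered fraction one way", {
  trials <- std_trials()
  cfg_sat <- imaging_config(noise_sd = 0)
  cfg_lin <- imaging_config(noise_sd = 0, kd = 1e8,
                            g_sat = 50 + 1e8 * 200)
  an_sat <- analyze_trials(lapply(trials, simulate_linescan,
                                  cfg = cfg_sat, seed = 1), cfg_sat)
  an_lin <- analyze_trials(lapply(trials, simulate_linescan,
                                  cfg = cfg_lin, seed = 1), cfg_lin)
  # saturation compresses large (control) responses more than inhibited
  # ones, so the recovered fraction is biased downward at both sites
  d <- an_sat$fractions$fraction - an_lin$fractions$fraction
  expect_true(all(d < 0))
  expect_true(all(abs(d) < 0.1))  # modest at ~20% saturation
})

test_that("missing trial types are reported", {
  trials <- std_trials()
  cfg <- imaging_config(noise_sd = 0)
  entries <- lapply(trials[c("bAP", "IPSP")], simulate_linescan,
                    cfg = cfg, seed = 1)
  expect_error(analyze_trials(entries, cfg), "incomplete dataset")
})

test_that("exact Wilcoxon matches closed-form and published-table cases", {
  # n = 5, all differences positive: p = 2/32
  w <- wilcoxon_exact(c(1, 2, 3, 4, 5))
  expect_equal(w$p.value, 0.0625)
  expect_equal(w$statistic, 15)
  # antisymmetric differences: p = 1
  expect_equal(wilcoxon_exact(c(-3, -1, 1, 3))$p.value, 1)
  # all zero differences: degenerate
  z <- wilcoxon_exact(rep(0, 6))
  expect_true(z$degenerate)
  expect_equal(z$p.value, 1)
  # n = 10 all positive: the attainable minimum 2/1024
  expect_equal(wilcoxon_exact(1:10)$p.value, 2 / 1024)
})

test_that("exact Wilcoxon equals the brute-force enumeration oracle", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    d <- round(rnorm(n), sample(0:1, 1))  # induces ties and zeros
    if (all(d == 0)) d[1] <- 1
    expect_equal(wilcoxon_exact(d)$p.value, wilcoxon_enum_oracle(d))
  }
})

test_that("exact Wilcoxon agrees with stats::wilcox.test on clean data", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(6:15, 1)
    d <- rnorm(n)  # continuous: no ties, no zeros
    ref <- wilcox.test(d, exact = TRUE)$p.value
    expect_equal(wilcoxon_exact(d)$p.value, ref, tolerance = 1e-12)
  }
})

test_that("Wilcoxon p is invariant to rank-preserving monotone rescaling", {
  set.seed(5)
  d <- rnorm(9)
  p1 <- wilcoxon_exact(d)$p.value
  d2 <- sign(d) * exp(abs(d))  # preserves signs and magnitude ranks
  expect_equal(wilcoxon_exact(d2)$p.value, p1)
})

test_that("population study: determinism, degenerate null, injected effect", {
  trials <- std_trials()
  cfg <- imaging_config()
  a <- population_study(6, cfg, templates_a = trials, seed = 5)
  b <- population_study(6, cfg, templates_a = trials, seed = 5)
  expect_identical(a$cells, b$cells)
  # duplicate conditions at zero noise: all differences zero -> p = 1
  cfg0 <- imaging_config(noise_sd = 0)
  z <- population_study(6, cfg0, templates_a = trials, seed = 5)
  expect_true(all(z$tests$p.value == 1))
  expect_equal(z$cells$fraction_a, z$cells$fraction_b)
  # strong injected effect with small noise: the n = 10 all-positive
  # exact minimum p = 2/1024
  cfg_small <- imaging_config(noise_sd = 1)
  eff <- population_study(10, cfg_small, templates_a = trials,
                          inh_scale_b = 0.5, seed = 5)
  p_frac <- eff$tests$p.value[eff$tests$metric == "fraction"]
  expect_true(all(p_frac <= 0.002))
})

test_that("long-format export is tidy and complete", {
  tpl <- mk_template(dur = 50)
  cfg <- imaging_config()
  e <- simulate_linescan(tpl, cfg, seed = 1, n_trials = 4)
  long <- linescan_to_long(e, cell = 3, type = "IPSP-bAP")
  expect_setequal(names(long),
                  c("cell", "trial", "type", "site", "channel", "time",
                    "value"))
  expect_equal(nrow(long), 4 * length(tpl$time) * 2 * 2)
  expect_setequal(unique(long$site), c("spine", "shaft"))
})
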