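# Synthetic two-photon line-scan stage: maps model calcium currents to
# indicator fluorescence (Hill binding with saturation), emulates the
# two-channel 500-Hz line-scan acquisition with noise and an uncaging
# photoartifact on light trials, and implements the experimental
# analysis chain (dG/R -> dG/Gsat, artifact correction, trial
# averaging, 100-ms integrals, inhibition fraction, exact Wilcoxon).

#' Imaging configuration
#'
#' Defaults emulate a low-affinity green calcium indicator plus a
#' calcium-insensitive red dye. `ca_scale` maps the low-pass-filtered
#' calcium current (nA, 50-ms single-exponential decay), divided by the
#' compartment volume, to concentration; the default puts a single-bAP
#' spine transient of the standard control model (`gka_distal = 70`) at
#' roughly 20% of indicator saturation, emulating the choice of a
#' low-affinity indicator. These are generator settings, not measured
#' values.
#'
#' @param kd Indicator dissociation constant (uM).
#' @param ca_rest Resting calcium concentration (uM).
#' @param ca_scale Concentration per unit of volume-normalised filtered
#'   calcium current (uM um^3 / (nA ms)).
#' @param ca_tau Decay time constant of the calcium transient proxy
#'   (ms).
#' @param g0 Green fluorescence at zero calcium (a.u.).
#' @param g_sat Green fluorescence at saturating calcium (a.u.); must
#'   exceed `g0`.
#' @param red Red-channel fluorescence (a.u.), calcium-insensitive.
#' @param noise_sd Gaussian noise SD per line sample, both channels
#'   (a.u.).
#' @param line_rate Line-scan rate (Hz); default 500.
#' @param trials_per_condition Trials averaged per condition; default
#'   10.
#' @param artifact_amp Photoartifact amplitude on light trials (a.u.).
#' @param artifact_duration Photoartifact duration (ms).
#' @param cell_cv Lognormal SD of the per-cell transient amplitude
#'   factor used in population studies.
#' @return An object of class `imaging_config`.
#' @export
imaging_config <- function(kd = 2.3, ca_rest = 0.05, ca_scale = 5e15,
                           ca_tau = 50, g0 = 50, g_sat = 600,
                           red = 300, noise_sd = 10, line_rate = 500,
                           trials_per_condition = 10,
                           artifact_amp = 40, artifact_duration = 10,
                           cell_cv = 0.2) {
  if (!(g_sat > g0 && g0 > 0)) stop("need g_sat > g0 > 0")
  stopifnot(red > 0, noise_sd >= 0, line_rate > 0, kd > 0,
            ca_rest >= 0, ca_tau > 0, trials_per_condition >= 1)
  structure(list(kd = kd, ca_rest = ca_rest, ca_scale = ca_scale,
                 ca_tau = ca_tau, g0 = g0, g_sat = g_sat, red = red,
                 noise_sd = noise_sd, line_rate = line_rate,
                 trials_per_condition = as.integer(trials_per_condition),
                 artifact_amp = artifact_amp,
                 artifact_duration = artifact_duration,
                 cell_cv = cell_cv),
            class = "imaging_config")
}

#' Indicator fluorescence from calcium concentration
#'
#' Single-site Hill binding:
#' `G = g0 + (g_sat - g0) * ca / (ca + kd)`; monotone and saturating.
#'
#' @param ca Calcium concentration (uM), non-negative.
#' @param cfg An [imaging_config()].
#' @return Green fluorescence (a.u.).
#' @export
fluorescence_from_ca <- function(ca, cfg) {
  stopifnot(inherits(cfg, "imaging_config"), all(ca >= 0))
  cfg$g0 + (cfg$g_sat - cfg$g0) * ca / (ca + cfg$kd)
}

#' Imaging template from a simulated trial
#'
#' Converts the spine and shaft calcium currents of a [run_trial()]
#' result into calcium-concentration time series on the line-scan time
#' base: the current magnitude is low-pass filtered with a
#' single-exponential decay (`ca_tau`) to mimic the time course of the
#' fluorescence transient, scaled by `ca_scale` and offset by
#' `ca_rest`.
#'
#' @param trial A `trial_result`.
#' @param cfg An [imaging_config()].
#' @return An object of class `imaging_template`: `time` (ms), `ca`
#'   (list with `spine` and `shaft`, uM), `t_test`, `t_ipsp`, `light`
#'   (logical: uncaging flash present).
#' @export
prepare_imaging_template <- function(trial, cfg) {
  stopifnot(inherits(trial, "trial_result"),
            inherits(cfg, "imaging_config"))
  tr <- trial$trace
  dt <- tr$dt
  alpha <- exp(-dt / cfg$ca_tau)
  grid <- seq(0, max(tr$time), by = 1000 / cfg$line_rate)
  vols <- trial$site_volumes
  if (is.null(vols)) vols <- c(spine = 1, shaft = 1)
  lp <- function(site, vol) {
    x <- abs(trace_series(tr, paste0("ica.", site)))
    # start the transient filter at its pre-trial steady state so the
    # resting calcium level is flat
    x0 <- x[1] * dt / (1 - alpha)
    xf <- as.numeric(stats::filter(x * dt, alpha,
                                   method = "recursive", init = x0))
    ca <- cfg$ca_rest + cfg$ca_scale * xf / vol
    approx(tr$time, ca, xout = grid)$y
  }
  structure(list(time = grid,
                 ca = list(spine = lp(trial$sites$spine, vols[["spine"]]),
                           shaft = lp(trial$sites$shaft, vols[["shaft"]])),
                 t_test = trial$t_test, t_ipsp = trial$t_ipsp,
                 light = !is.na(trial$t_ipsp)),
            class = "imaging_template")
}

#' Simulate line-scan acquisition of one condition
#'
#' Generates `n_trials` two-channel (green/red) line-scan traces at the
#' spine and shaft for one trial type: indicator fluorescence from the
#' calcium template, i.i.d. Gaussian noise on both channels, and a
#' rectangular blue-light photoartifact added to the green channel on
#' light (uncaging) trials. Identical `seed` gives bit-identical
#' output.
#'
#' @param trial A `trial_result` or a prepared [prepare_imaging_template()].
#' @param cfg An [imaging_config()].
#' @param seed Integer seed for the trial noise.
#' @param n_trials Number of trials; default `cfg$trials_per_condition`.
#' @param scale Multiplicative factor applied to the calcium transient
#'   (concentration above rest); used for per-cell variability and
#'   injected effects.
#' @return An object of class `linescan_entry`: `time`, per site a list
#'   with `green` and `red` matrices (trials in rows), `light`,
#'   `t_test`, `t_ipsp`.
#' @export
simulate_linescan <- function(trial, cfg, seed = 1L,
                              n_trials = cfg$trials_per_condition,
                              scale = 1) {
  tpl <- if (inherits(trial, "imaging_template")) trial
         else prepare_imaging_template(trial, cfg)
  set.seed(seed)
  nt <- length(tpl$time)
  artifact <- numeric(nt)
  if (tpl$light && cfg$artifact_amp != 0) {
    on <- tpl$time >= tpl$t_ipsp &
      tpl$time < tpl$t_ipsp + cfg$artifact_duration
    artifact[on] <- cfg$artifact_amp
  }
  mk_site <- function(site) {
    ca <- cfg$ca_rest + scale * (tpl$ca[[site]] - cfg$ca_rest)
    g_clean <- fluorescence_from_ca(pmax(ca, 0), cfg) + artifact
    green <- matrix(rep(g_clean, each = n_trials), nrow = n_trials) +
      if (cfg$noise_sd > 0)
        matrix(rnorm(n_trials * nt, 0, cfg$noise_sd), nrow = n_trials)
      else 0
    red <- matrix(cfg$red, nrow = n_trials, ncol = nt) +
      if (cfg$noise_sd > 0)
        matrix(rnorm(n_trials * nt, 0, cfg$noise_sd), nrow = n_trials)
      else 0
    list(green = green, red = red)
  }
  structure(list(time = tpl$time, spine = mk_site("spine"),
                 shaft = mk_site("shaft"), light = tpl$light,
                 t_test = tpl$t_test, t_ipsp = tpl$t_ipsp),
            class = "linescan_entry")
}

# trial-averaged dG/Gsat trace for one entry/site; baseline estimated
# per trial from the pre-event window, normalised as (dG/R)/(Gsat/R)
entry_dgsat <- function(entry, site, cfg) {
  g <- entry[[site]]$green
  r <- entry[[site]]$red
  t_first <- min(entry$t_ipsp, entry$t_test, na.rm = TRUE)
  base <- entry$time < t_first - 5
  if (!any(base)) stop("no pre-event baseline window")
  rbar <- rowMeans(r)
  g0hat <- rowMeans(g[, base, drop = FALSE])
  dgr <- sweep(sweep(g, 1, g0hat), 1, rbar, "/")  # dG/R per trial
  dgsat <- sweep(dgr, 1, cfg$g_sat / rbar, "/")   # (dG/R)/(Gsat/R)
  colMeans(dgsat)
}

#' Analyse a cell's line-scan trials
#'
#' Implements the experimental analysis chain on a named list of
#' [simulate_linescan()] entries (names are trial types): per-trial
#' baseline-subtracted dG/R, re-expressed as dG/Gsat; trial averaging;
#' photoartifact/train correction by subtracting the matching reference
#' trace (IPSP for IPSP-bAP, train for train-bAP, train-IPSP for
#' train-IPSP-bAP); 100-ms flux integrals from test-pulse onset; and
#' the inhibition fraction per site.
#'
#' @param entries Named list of `linescan_entry` objects; must contain
#'   `"bAP"`, `"IPSP-bAP"` and `"IPSP"` (train types optional).
#' @param cfg An [imaging_config()].
#' @param window Quantification window (ms); default 100.
#' @return List of class `linescan_analysis`: `responses` (data.frame:
#'   site, type, flux, peak), `fractions` (data.frame: site, condition,
#'   fraction), and the corrected average traces.
#' @export
analyze_trials <- function(entries, cfg, window = 100) {
  need <- c("bAP", "IPSP-bAP", "IPSP")
  if (!all(need %in% names(entries)))
    stop("incomplete dataset: need trial types ",
         paste(setdiff(need, names(entries)), collapse = ", "))
  has_train <- all(c("train-bAP", "train-IPSP-bAP", "train-IPSP",
                     "train") %in% names(entries))
  sites <- c("spine", "shaft")
  correction <- list(
    "bAP" = NA, "IPSP-bAP" = "IPSP",
    "train-bAP" = "train", "train-IPSP-bAP" = "train-IPSP")
  types <- intersect(names(correction), names(entries))
  traces <- list()
  rows <- list()
  for (site in sites) {
    avg <- lapply(entries, entry_dgsat, site = site, cfg = cfg)
    for (ty in types) {
      ref <- correction[[ty]]
      cor_trace <- if (is.na(ref)) avg[[ty]] else avg[[ty]] - avg[[ref]]
      traces[[paste(site, ty, sep = ".")]] <- cor_trace
      tt <- entries[[ty]]$t_test
      fl <- ca_flux_integral(list(time = entries[[ty]]$time,
                                  y = cor_trace),
                             tt, window, site = site, rectify = FALSE)
      in_win <- entries[[ty]]$time >= tt &
        entries[[ty]]$time < tt + window
      rows[[length(rows) + 1L]] <- data.frame(
        site = site, type = ty, flux = fl$integral,
        peak = max(cor_trace[in_win]))
    }
  }
  responses <- do.call(rbind, rows)
  frac_rows <- list()
  for (site in sites) {
    g <- function(ty) responses$flux[responses$site == site &
                                       responses$type == ty]
    frac_rows[[length(frac_rows) + 1L]] <- data.frame(
      site = site, condition = "single",
      fraction = inhibition_fraction(g("bAP"), g("IPSP-bAP")))
    if (has_train)
      frac_rows[[length(frac_rows) + 1L]] <- data.frame(
        site = site, condition = "train",
        fraction = inhibition_fraction(g("train-bAP"),
                                       g("train-IPSP-bAP")))
  }
  structure(list(responses = responses,
                 fractions = do.call(rbind, frac_rows),
                 traces = traces, time = entries[["bAP"]]$time),
            class = "linescan_analysis")
}

#' Exact Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided exact p-value by full enumeration of the `2^n` sign
#' assignments (n <= 20): zero differences are dropped before ranking,
#' tied absolute differences receive average ranks. The p-value is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))` for the positive-rank sum
#' `W`.
#'
#' @param x Numeric vector: first condition, or differences if `y` is
#'   `NULL`.
#' @param y Optional second condition, paired with `x`.
#' @return List of class `wilcoxon_exact`: `statistic` (W+), `p.value`,
#'   `n` (non-zero pairs), `degenerate` (all differences zero).
#' @export
wilcoxon_exact <- function(x, y = NULL) {
  d <- if (is.null(y)) x else {
    stopifnot(length(x) == length(y))
    x - y
  }
  stopifnot(length(d) >= 1)
  d <- d[is.finite(d)]
  d <- d[d != 0]
  if (!length(d)) {
    return(structure(list(statistic = 0, p.value = 1, n = 0L,
                          degenerate = TRUE), class = "wilcoxon_exact"))
  }
  n <- length(d)
  if (n > 20) stop("exact enumeration limited to n <= 20 pairs")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  sums <- 0
  for (ri in r) sums <- c(sums, sums + ri)
  eps <- 1e-9
  p_lo <- mean(sums <= w + eps)
  p_hi <- mean(sums >= w - eps)
  structure(list(statistic = w, p.value = min(1, 2 * min(p_lo, p_hi)),
                 n = n, degenerate = FALSE), class = "wilcoxon_exact")
}

#' @export
print.wilcoxon_exact <- function(x, ...) {
  cat("Exact Wilcoxon matched-pairs signed-rank test\n")
  cat("  W+ =", x$statistic, ", n =", x$n,
      ", two-sided p =", format(x$p.value, digits = 4), "\n")
  if (x$degenerate) cat("  (degenerate: all differences zero)\n")
  invisible(x)
}

#' Synthetic population study
#'
#' Emulates the paired population design: `n_cells` cells, one
#' spine/shaft pair each, imaged in two conditions (e.g. control vs
#' after-train, or control vs drug). Each cell gets a lognormal
#' transient-amplitude factor (shared between conditions, preserving
#' the paired design) and independent trial noise; per cell and site
#' the analysis chain yields the inhibition fraction and peak response,
#' compared across conditions with the exact Wilcoxon test.
#'
#' @param n_cells Number of cells; default 10.
#' @param cfg An [imaging_config()].
#' @param templates_a Named list of `trial_result`s or
#'   [prepare_imaging_template()]s for condition A (needs `bAP`,
#'   `IPSP-bAP`, `IPSP`).
#' @param templates_b Same for condition B; `NULL` (default) reuses
#'   condition A (null effect).
#' @param inh_scale_b Extra multiplicative factor applied in condition B
#'   to the calcium transient of inhibited trial types (`IPSP-bAP`);
#'   `0.5` injects a strong inhibition increase. Default 1 (none).
#' @param seed Master seed; all randomness derives from it.
#' @return List of class `population_study`: `cells` (data.frame: cell,
#'   site, fraction_a, fraction_b, peak_a, peak_b), `tests` (data.frame:
#'   site, metric, p.value), `n_cells`, `seed`.
#' @export
population_study <- function(n_cells = 10, cfg = imaging_config(),
                             templates_a, templates_b = NULL,
                             inh_scale_b = 1, seed = 1L) {
  stopifnot(n_cells >= 2)
  prep <- function(tl) lapply(tl, function(x)
    if (inherits(x, "imaging_template")) x
    else prepare_imaging_template(x, cfg))
  ta <- prep(templates_a)
  tb <- if (is.null(templates_b)) ta else prep(templates_b)
  set.seed(seed)
  cell_scale <- exp(rnorm(n_cells, 0, cfg$cell_cv))
  seeds <- matrix(sample.int(.Machine$integer.max - 1,
                             n_cells * (length(ta) + length(tb))),
                  nrow = n_cells)
  rows <- list()
  for (ci in seq_len(n_cells)) {
    k <- 0
    gen <- function(tpls, extra_inh = 1) {
      out <- list()
      for (ty in names(tpls)) {
        k <<- k + 1
        sc <- cell_scale[ci] *
          (if (grepl("IPSP-bAP", ty)) extra_inh else 1)
        out[[ty]] <- simulate_linescan(tpls[[ty]], cfg,
                                       seed = seeds[ci, k],
                                       scale = sc)
      }
      out
    }
    an_a <- analyze_trials(gen(ta), cfg)
    an_b <- analyze_trials(gen(tb, extra_inh = inh_scale_b), cfg)
    for (site in c("spine", "shaft")) {
      fa <- an_a$fractions
      fb <- an_b$fractions
      ra <- an_a$responses
      rb <- an_b$responses
      rows[[length(rows) + 1L]] <- data.frame(
        cell = ci, site = site,
        fraction_a = fa$fraction[fa$site == site &
                                   fa$condition == "single"],
        fraction_b = fb$fraction[fb$site == site &
                                   fb$condition == "single"],
        peak_a = ra$peak[ra$site == site & ra$type == "bAP"],
        peak_b = rb$peak[rb$site == site & rb$type == "bAP"])
    }
  }
  cells <- do.call(rbind, rows)
  tests <- do.call(rbind, lapply(c("spine", "shaft"), function(site) {
    cc <- cells[cells$site == site, ]
    data.frame(
      site = site,
      metric = c("fraction", "peak"),
      p.value = c(wilcoxon_exact(cc$fraction_b, cc$fraction_a)$p.value,
                  wilcoxon_exact(cc$peak_b, cc$peak_a)$p.value))
  }))
  structure(list(cells = cells, tests = tests, n_cells = n_cells,
                 seed = seed),
            class = "population_study")
}

#' Long-format export of a line-scan entry
#'
#' @param entry A `linescan_entry`.
#' @param cell Cell identifier stored in the output.
#' @param type Trial-type label stored in the output.
#' @return `data.frame` with columns cell, trial, type, site, channel,
#'   time, value.
#' @export
linescan_to_long <- function(entry, cell = 1L, type = "bAP") {
  stopifnot(inherits(entry, "linescan_entry"))
  out <- list()
  for (site in c("spine", "shaft")) {
    for (ch in c("green", "red")) {
      m <- entry[[site]][[ch]]
      out[[length(out) + 1L]] <- data.frame(
        cell = cell, trial = rep(seq_len(nrow(m)), each = ncol(m)),
        type = type, site = site, channel = ch,
        time = rep(entry$time, times = nrow(m)),
        value = as.vector(t(m)))
    }
  }
  do.call(rbind, out)
}
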