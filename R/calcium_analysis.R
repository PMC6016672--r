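# Quantitative metrics: 100-ms calcium flux integral, the inhibition
# fraction (dCa_Ctl - dCa_Inh)/dCa_Ctl, AP waveform metrics, and the
# supralinearity (convexity) characterisation of peak I_Ca vs peak V.

get_xy <- function(trace, series) {
  if (inherits(trace, "dendka_trace")) {
    if (is.null(series)) stop("'series' required for a dendka_trace")
    list(time = trace$time, y = trace_series(trace, series))
  } else if (is.list(trace) && !is.null(trace$time)) {
    y <- if (!is.null(trace$y)) trace$y else trace[[series]]
    list(time = trace$time, y = y)
  } else stop("'trace' must be a dendka_trace or a list with $time")
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Calcium response: flux integral over the quantification window
#'
#' Trapezoidal integral of the magnitude of the (inward) calcium current
#' or fluorescence series over the window `[t0, t0 + window)`. The
#' default window of 100 ms is the quantification window used for all
#' calcium responses in the package.
#'
#' @param trace A `dendka_trace` (give `series`) or a list with `$time`
#'   and `$y`.
#' @param t0 Window start (ms) -- the test-pulse (bAP) onset.
#' @param window Window length (ms); default 100.
#' @param series Series name for a `dendka_trace`, e.g.
#'   `"ica.spine_head"`.
#' @param site Site label stored in the result (defaults to `series`).
#' @param rectify Integrate the magnitude `abs(y)` (appropriate for the
#'   signed inward calcium current); set `FALSE` for series that are
#'   already positive-oriented (fluorescence), where rectification
#'   would bias noise.
#' @return An object of class `ca_response` with fields `site`,
#'   `integral` and `window`.
#' @export
ca_flux_integral <- function(trace, t0, window = 100, series = NULL,
                             site = NULL, rectify = TRUE) {
  xy <- get_xy(trace, series)
  eps <- 1e-9
  if (t0 < xy$time[1] - eps ||
      t0 + window > xy$time[length(xy$time)] + eps)
    stop("invalid window: trace does not cover [t0, t0 + window]")
  keep <- xy$time >= t0 - eps & xy$time <= t0 + window + eps
  y <- if (rectify) abs(xy$y[keep]) else xy$y[keep]
  structure(list(site = if (is.null(site)) series else site,
                 integral = trapz(xy$time[keep], y),
                 window = c(t0, t0 + window)),
            class = "ca_response")
}

#' @export
print.ca_response <- function(x, ...) {
  cat("<ca_response> site ", x$site %||% "?", ": integral ",
      format(x$integral, digits = 6), " over [",
      x$window[1], ", ", x$window[2], ") ms\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' GABAergic inhibition fraction of the calcium response
#'
#' `(dCa_Ctl - dCa_Inh) / dCa_Ctl`: 0 means no inhibition, 1 complete
#' suppression.
#'
#' @param ctl Control response: a [ca_flux_integral()] result or a
#'   positive number.
#' @param inh Inhibited response, same form; sites and windows must
#'   match when both are `ca_response` objects.
#' @return Numeric fraction (dimensionless, at most 1 for non-negative
#'   responses).
#' @export
inhibition_fraction <- function(ctl, inh) {
  if (inherits(ctl, "ca_response") && inherits(inh, "ca_response")) {
    if (!identical(ctl$site, inh$site))
      stop("pairing error: sites differ (", ctl$site, " vs ",
           inh$site, ")")
    if (!isTRUE(all.equal(diff(ctl$window), diff(inh$window))))
      stop("pairing error: windows differ")
  }
  c_val <- if (inherits(ctl, "ca_response")) ctl$integral else ctl
  i_val <- if (inherits(inh, "ca_response")) inh$integral else inh
  if (!is.finite(c_val) || c_val <= 0)
    stop("undefined fraction: control response must be positive")
  (c_val - i_val) / c_val
}

#' Action potential waveform metrics
#'
#' Peak voltage, full width at half amplitude above a fixed baseline
#' (linear interpolation between samples), and optionally the signed
#' extremum of the calcium current. The baseline is fixed at the holding
#' level rather than the pre-spike voltage so that widths are comparable
#' across train conditions.
#'
#' @param trace A `dendka_trace` or a list with `$time`/`$y`.
#' @param baseline Baseline voltage (mV); default -64 (the holding
#'   level).
#' @param series Voltage series name for a `dendka_trace`.
#' @param ica_series Optional calcium-current series name.
#' @param t_range Optional `c(from, to)` (ms) restricting the analysis
#'   window (to isolate the test spike).
#' @param min_amplitude Minimum peak elevation above baseline (mV) for a
#'   spike to count as present; default 10.
#' @return List of class `ap_metrics`: `present`, `peak` (mV),
#'   `half_width` (ms), `peak_ica` (signed extremum), `t_peak`.
#' @export
ap_metrics <- function(trace, baseline = -64, series = NULL,
                       ica_series = NULL, t_range = NULL,
                       min_amplitude = 10) {
  xy <- get_xy(trace, series)
  tt <- xy$time; v <- xy$y
  if (!is.null(t_range)) {
    keep <- tt >= t_range[1] & tt <= t_range[2]
    tt <- tt[keep]; v <- v[keep]
  }
  ipk <- which.max(v)
  peak <- v[ipk]
  if (peak < baseline + min_amplitude) {
    return(structure(list(present = FALSE, peak = NA_real_,
                          half_width = NA_real_, peak_ica = NA_real_,
                          t_peak = NA_real_), class = "ap_metrics"))
  }
  half <- baseline + (peak - baseline) / 2
  # last upward crossing before the peak, first downward after
  cross_t <- function(i, j) {
    # linear interpolation of the time where v crosses `half`
    tt[i] + (half - v[i]) * (tt[j] - tt[i]) / (v[j] - v[i])
  }
  up <- NA_real_
  for (i in seq_len(ipk - 1)) {
    if (v[i] < half && v[i + 1] >= half) up <- cross_t(i, i + 1)
  }
  dn <- NA_real_
  if (ipk < length(v)) {
    for (i in ipk:(length(v) - 1)) {
      if (v[i] >= half && v[i + 1] < half) { dn <- cross_t(i, i + 1); break }
    }
  }
  peak_ica <- NA_real_
  if (!is.null(ica_series) && inherits(trace, "dendka_trace")) {
    ica <- trace_series(trace, ica_series)
    if (!is.null(t_range)) ica <- ica[trace$time >= t_range[1] &
                                        trace$time <= t_range[2]]
    peak_ica <- ica[which.max(abs(ica))]
  }
  structure(list(present = TRUE, peak = peak,
                 half_width = dn - up, peak_ica = peak_ica,
                 t_peak = tt[ipk]), class = "ap_metrics")
}

#' Supralinearity (convexity) check
#'
#' Tests whether `y(x)` has positive curvature throughout: computes the
#' second divided differences of `y` on sorted `x` and reports whether
#' all are strictly positive.
#'
#' @param xs Predictor values (e.g. peak AP voltage), strictly monotone.
#' @param ys Response values (e.g. peak calcium current magnitude).
#' @return List: `verdict` (logical) and `second_differences`.
#' @export
convexity_check <- function(xs, ys) {
  stopifnot(length(xs) == length(ys))
  if (length(xs) < 3) stop("insufficient data: need at least 3 points")
  d <- diff(xs)
  if (!(all(d > 0) || all(d < 0))) stop("'xs' must be strictly monotone")
  o <- order(xs)
  xs <- xs[o]; ys <- ys[o]
  slopes <- diff(ys) / diff(xs)
  d2 <- diff(slopes)
  list(verdict = all(d2 > 0), second_differences = d2)
}
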