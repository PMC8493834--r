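# window extraction: samples of `trace` with window[1] <= t < window[2]
.trace_window <- function(trace, window) {
  t <- trace_times(trace)
  sel <- t >= window[1] - 1e-9 & t < window[2] - 1e-9
  list(t = t[sel], y = trace$current[sel])
}

#' Fit a mono- or bi-exponential decay to a trace segment
#'
#' Least-squares fit of `y(t) = C + sum_i A_i exp(-(t - t0)/tau_i)` over a
#' window, with multi-start initialization (log-linear regression on the
#' segment's head and tail for initial time constants, plus jittered
#' restarts). Time constants are relabelled so `tau_f <= tau_s`; the fast
#' fraction is `A_f / (A_f + A_s)`. Fits whose amplitude ratio is below
#' `1e-3` or whose time-constant ratio is below 1.2 are flagged as
#' effectively mono-exponential.
#'
#' @param trace a [current_trace()].
#' @param n_terms 1 or 2 exponential terms.
#' @param window `c(t_start, t_end)` in trace time, ms; `NULL` fits the
#'   whole trace. At least 50 samples are required.
#' @param n_starts number of jittered restarts.
#' @param seed seed for the deterministic jitter.
#' @return a list of class `exp_fit` with `A_f`, `A_s`, `tau_f`, `tau_s`
#'   (ms), `offset`, `fast_fraction`, `residual` (SSE), `degenerate`,
#'   `t0` (window start).
#' @export
fit_exponential_decay <- function(trace, n_terms = 2, window = NULL,
                                  n_starts = 8, seed = 1L) {
  stopifnot(n_terms %in% 1:2)
  if (is.null(window))
    window <- c(trace$t0, trace$t0 + length(trace$current) * trace$dt)
  w <- .trace_window(trace, window)
  if (length(w$t) < 50) stop("fit window must contain at least 50 samples")
  t <- w$t - w$t[1]; y <- w$y
  if (stats::sd(y) < 1e-12 * (abs(mean(y)) + 1e-12)) {
    return(structure(list(n_terms = n_terms, A_f = 0, A_s = 0,
                          tau_f = NA_real_, tau_s = NA_real_,
                          offset = mean(y), fast_fraction = NA_real_,
                          residual = 0, degenerate = TRUE, t0 = w$t[1]),
                     class = "exp_fit"))
  }
  C0 <- mean(y[t > 0.9 * max(t)])
  A0 <- y[1] - C0
  # log-linear tau guesses from the head and tail of the decay
  tau_guess <- function(sel) {
    zz <- (y - C0) / A0
    ok <- sel & zz > 1e-3
    if (sum(ok) < 3) return(max(t) / 3)
    -1 / stats::coef(stats::lm(log(zz[ok]) ~ t[ok]))[2]
  }
  th <- abs(tau_guess(t <= stats::quantile(t, 0.25)))
  tl <- abs(tau_guess(t >= stats::quantile(t, 0.5)))
  th <- min(max(th, trace$dt, 1e-3), 10 * max(t))
  tl <- min(max(tl, trace$dt, 1e-3), 10 * max(t))
  model <- function(par) {
    k <- n_terms
    amps <- par[seq_len(k)]; ltau <- par[k + seq_len(k)]; C <- par[2 * k + 1]
    f <- rep(C, length(t))
    for (i in seq_len(k)) f <- f + amps[i] * exp(-t / exp(ltau[i]))
    f
  }
  resid_fn <- function(par) model(par) - y
  starts <- with_seed(seed, {
    base <- if (n_terms == 1) list(c(A0, log(sqrt(th * tl)), C0))
    else list(c(0.7 * A0, 0.3 * A0, log(th), log(tl), C0))
    c(base, lapply(seq_len(n_starts - 1), function(i) {
      s <- base[[1]]
      k <- n_terms
      s[k + seq_len(k)] <- s[k + seq_len(k)] + stats::runif(k, -1.2, 1.2)
      s[seq_len(k)] <- s[seq_len(k)] * exp(stats::runif(k, -0.5, 0.5))
      s
    }))
  })
  best <- NULL
  for (s in starts) {
    ft <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(ft)) next
    sse <- sum(ft$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(par = ft$par, sse = sse)
  }
  if (is.null(best)) stop("exponential fit failed to converge from all starts")
  k <- n_terms
  amps <- best$par[seq_len(k)]
  taus <- exp(best$par[k + seq_len(k)])
  C <- best$par[2 * k + 1]
  ord <- order(taus)
  amps <- amps[ord]; taus <- taus[ord]
  if (k == 1) {
    out <- list(n_terms = 1, A_f = amps[1], A_s = 0, tau_f = taus[1],
                tau_s = NA_real_, offset = C, fast_fraction = 1,
                residual = best$sse, degenerate = FALSE, t0 = w$t[1])
  } else {
    degen <- min(abs(amps)) / max(abs(amps), 1e-300) < 1e-3 ||
      taus[2] / taus[1] < 1.2
    out <- list(n_terms = 2, A_f = amps[1], A_s = amps[2],
                tau_f = taus[1], tau_s = taus[2], offset = C,
                fast_fraction = amps[1] / (amps[1] + amps[2]),
                residual = best$sse, degenerate = degen, t0 = w$t[1])
  }
  structure(out, class = "exp_fit")
}

#' Fit a Boltzmann function to a (voltage, response) series
#'
#' Least-squares fit of `y = s / (1 + exp((V_half - V)/k))`. A positive
#' slope factor `k` describes activation (y rising with V); a negative `k`
#' describes inactivation.
#'
#' @param v voltages, mV (>= 5 points spanning the transition).
#' @param y normalized responses.
#' @param fit_scale also fit the saturation scale `s` (default) or fix it
#'   at 1.
#' @return a list of class `boltzmann_fit` with `v_half` (mV), `k` (mV),
#'   `scale`, `residual`, and `transition_inside` (FALSE when the fitted
#'   midpoint falls outside the sampled voltage range).
#' @export
fit_boltzmann <- function(v, y, fit_scale = TRUE) {
  if (length(v) < 5) stop("need at least 5 points to fit a Boltzmann")
  rising <- stats::cor(v, y) >= 0
  s0 <- max(abs(y))
  vh0 <- v[which.min(abs(y / s0 - 0.5))]
  k0 <- (if (rising) 1 else -1) * diff(range(v)) / 8
  resid_fn <- function(par)
    (if (fit_scale) par[3] else 1) / (1 + exp((par[1] - v) / par[2])) - y
  ft <- NULL
  for (mult in c(1, 0.5, 2)) {
    p0 <- c(vh0, k0 * mult, if (fit_scale) s0)
    cand <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(cand) && (is.null(ft) || sum(cand$fvec^2) < sum(ft$fvec^2)))
      ft <- cand
  }
  if (is.null(ft)) stop("Boltzmann fit failed to converge")
  par <- ft$par
  structure(list(v_half = par[1], k = par[2],
                 scale = if (fit_scale) par[3] else 1,
                 residual = sum(ft$fvec^2),
                 transition_inside = par[1] >= min(v) && par[1] <= max(v)),
            class = "boltzmann_fit")
}

# global time window of segment `seg` in sweep `sweep`
.segment_window <- function(protocol, sweep, seg) {
  st <- segment_table(protocol)
  r <- st[st$sweep == sweep & st$seg == seg, ]
  c(r$t_start, r$t_end)
}

#' Normalized conductance-voltage (G-V) series from tail currents
#'
#' For each sweep of an activation protocol, measures the peak tail-current
#' magnitude during the repolarizing tail segment (after a blanking window
#' that excludes the capacitive-transient region) and normalizes the series
#' to its maximum.
#'
#' @param trace a [current_trace()] covering the whole protocol.
#' @param protocol an activation protocol with a `test_voltage` metadata
#'   column.
#' @param tail_seg index of the tail segment within each sweep.
#' @param blank_ms blanking window after the step edge, ms.
#' @return data.frame of class `gv_curve` with columns `test_voltage`,
#'   `peak_tail` (signed, nA) and `g_norm` (max 1).
#' @export
build_gv_from_tails <- function(trace, protocol, tail_seg = 2, blank_ms = 1) {
  stopifnot(!is.null(protocol$meta$test_voltage))
  vt <- protocol$meta$test_voltage
  peaks <- vapply(seq_along(vt), function(i) {
    w <- .segment_window(protocol, i, tail_seg)
    tw <- .trace_window(trace, c(w[1] + blank_ms, w[2]))
    tw$y[which.max(abs(tw$y))]
  }, 0)
  if (all(abs(peaks) < 1e-300)) stop("all tail currents are zero")
  out <- data.frame(test_voltage = vt, peak_tail = peaks,
                    g_norm = abs(peaks) / max(abs(peaks)))
  class(out) <- c("gv_curve", "data.frame")
  out
}

#' Fully activated current-voltage relation from a deactivation protocol
#'
#' The maximal-magnitude current during each repolarizing step (after
#' blanking), plotted against the step voltage.
#'
#' @inheritParams build_gv_from_tails
#' @param protocol a deactivation protocol with `tail_voltage` metadata.
#' @return data.frame with columns `voltage` and `current` (signed, nA).
#' @export
fully_activated_iv <- function(trace, protocol, tail_seg = 2, blank_ms = 1) {
  stopifnot(!is.null(protocol$meta$tail_voltage))
  vt <- protocol$meta$tail_voltage
  cur <- vapply(seq_along(vt), function(i) {
    w <- .segment_window(protocol, i, tail_seg)
    tw <- .trace_window(trace, c(w[1] + blank_ms, w[2]))
    tw$y[which.max(abs(tw$y))]
  }, 0)
  data.frame(voltage = vt, current = cur)
}

#' Whole-cell conductance from the linear region of the I-V relation
#'
#' Ordinary least-squares slope of the fully activated I-V over the
#' strongly hyperpolarized range where conductance is linear (driving-force
#' limited); the slope is analogous to whole-cell conductance.
#'
#' @param iv data.frame with `voltage` (mV) and `current` (nA).
#' @param v_range voltage range used for the regression, mV.
#' @return list with `g` (slope, uS), `intercept` (nA), `n_points`.
#' @export
estimate_linear_conductance <- function(iv, v_range = c(-140, -110)) {
  sel <- iv$voltage >= v_range[1] & iv$voltage <= v_range[2]
  if (sum(sel) < 3) stop("need >= 3 points in the linear-conductance range")
  ft <- stats::lm(current ~ voltage, data = iv[sel, ])
  list(g = unname(stats::coef(ft)[2]), intercept = unname(stats::coef(ft)[1]),
       n_points = sum(sel))
}

#' Rectification factor of the fully activated I-V relation
#'
#' \deqn{R(V_t) = I_{hERG} / [G\,n\,(V_t - E_{rev})]} where `G` is the
#' maximal (whole-cell) conductance, `n` the activation variable at
#' +40 mV, and `E_rev` the reversal potential. Voltages within `mask_mV`
#' of `E_rev` are masked (the denominator vanishes). The rectification
#' factor isolates the inactivation-driven loss of conduction: R tends to
#' 1 in the linear-conductance limit and falls toward 0 at depolarized
#' potentials.
#'
#' @param iv fully activated I-V data.frame (`voltage`, `current`).
#' @param G whole-cell conductance, uS (> 0).
#' @param n_at_plus40 activation variable at +40 mV, in (0, 1].
#' @param E_rev reversal potential, mV.
#' @param mask_mV half-width of the masked region around `E_rev`.
#' @return data.frame of class `rectification_curve` with `voltage`, `R`
#'   (NA where masked), and attributes `G`, `n`, `E_rev`.
#' @export
compute_rectification <- function(iv, G, n_at_plus40, E_rev, mask_mV = 5) {
  stopifnot(G > 0, n_at_plus40 > 0, n_at_plus40 <= 1)
  R <- iv$current / (G * n_at_plus40 * (iv$voltage - E_rev))
  R[abs(iv$voltage - E_rev) < mask_mV] <- NA_real_
  out <- data.frame(voltage = iv$voltage, R = R)
  attr(out, "G") <- G; attr(out, "n") <- n_at_plus40
  attr(out, "E_rev") <- E_rev
  class(out) <- c("rectification_curve", "data.frame")
  out
}

#' Protective-current curve from a premature-stimulation protocol
#'
#' For each sweep, fits a single exponential (with offset) to the decaying
#' current during the 40-ms premature step, after a blanking window, and
#' extrapolates back to the step onset (t = 0 of the step). Amplitudes are
#' normalized to the supplied whole-cell conductance so cells and
#' conditions can be compared. Non-decaying segments are flagged and their
#' amplitude taken as the maximum within the step.
#'
#' @param trace a [current_trace()] covering the protocol.
#' @param protocol a premature-stimulation protocol (metadata columns
#'   `coupling_ms`, `step_onset_ms`).
#' @param G whole-cell conductance for normalization, uS.
#' @param step_ms premature-step width, ms.
#' @param blank_ms blanking window after the step edge, ms.
#' @param extrapolate_to `"onset"` (default) extrapolates the fit to the
#'   step onset; `"blank_end"` reports the fit value at the end of the
#'   blanking window.
#' @return data.frame of class `protective_curve` with columns
#'   `coupling_ms`, `amplitude` (nA), `norm_amplitude` (nA/uS), `flagged`;
#'   attributes `peak_amplitude` and `peak_coupling_ms`.
#' @export
measure_protective_currents <- function(trace, protocol, G, step_ms = 40,
                                        blank_ms = 1,
                                        extrapolate_to = c("onset", "blank_end")) {
  extrapolate_to <- match.arg(extrapolate_to)
  stopifnot(!is.null(protocol$meta$coupling_ms), G > 0)
  ci <- protocol$meta$coupling_ms
  onsets <- protocol$meta$step_onset_ms
  sw <- sweep_times(protocol)
  amp <- flg <- numeric(length(ci))
  for (i in seq_along(ci)) {
    o <- sw$t_start[i] + onsets[i]
    wfit <- c(o + blank_ms, o + step_ms)
    ft <- tryCatch(fit_exponential_decay(trace, n_terms = 1, window = wfit),
                   error = function(e) NULL)
    decaying <- !is.null(ft) && !ft$degenerate && ft$A_f > 0
    if (decaying) {
      # the fit's time origin is its first retained sample; extrapolate
      # back over the actual gap to the step onset
      back <- if (extrapolate_to == "onset") ft$t0 - o else 0
      amp[i] <- ft$offset + ft$A_f * exp(back / ft$tau_f)
      flg[i] <- 0
    } else {
      tw <- .trace_window(trace, c(o + blank_ms, o + step_ms))
      amp[i] <- max(tw$y)
      flg[i] <- 1
    }
  }
  out <- data.frame(coupling_ms = ci, amplitude = amp,
                    norm_amplitude = amp / G, flagged = flg == 1)
  ipk <- which.max(out$norm_amplitude)
  attr(out, "peak_amplitude") <- out$norm_amplitude[ipk]
  attr(out, "peak_coupling_ms") <- out$coupling_ms[ipk]
  class(out) <- c("protective_curve", "data.frame")
  out
}

#' Action-potential-clamp current metrics
#'
#' From a current trace recorded under an AP-train protocol: the peak early
#' transient current (within a window after the upstroke of the selected
#' beat), the peak resurgent current (during that beat's repolarization),
#' and the command voltage at which the resurgent peak occurs. Peaks are
#' signed maxima of outward current, earliest time winning ties.
#'
#' @param trace a [current_trace()].
#' @param protocol an AP-train protocol from [build_ap_train_protocol()].
#' @param beat which beat to analyze (default: the last, i.e. the
#'   rate-adapted one).
#' @param transient_win_ms width of the upstroke window, ms.
#' @param normalization `"none"`, `"conductance"` (divide by `G`), or
#'   `"peak_tail"` (divide by `peak_tail`).
#' @param G,peak_tail normalization denominators.
#' @return a list of class `ap_clamp_metrics` with `peak_transient`,
#'   `peak_resurgent`, `peak_voltage` (mV), `beat`, `normalization`.
#' @export
measure_ap_clamp_metrics <- function(trace, protocol, beat = NULL,
                                     transient_win_ms = 20,
                                     normalization = c("none", "conductance",
                                                       "peak_tail"),
                                     G = NULL, peak_tail = NULL) {
  normalization <- match.arg(normalization)
  beats <- attr(protocol, "beats")
  ap <- attr(protocol, "ap")
  if (is.null(beats) || is.null(ap))
    stop("protocol must carry AP-train beat metadata")
  if (is.null(beat)) beat <- nrow(beats)
  onset <- beats$onset_ms[beat]
  total <- protocol_duration(protocol)
  wtr <- c(onset, min(onset + transient_win_ms, total))
  repol_start <- onset + ap$upstroke_ms + ap$plateau_ms
  wres <- c(repol_start, min(onset + ap_duration(ap), total))
  if (wtr[1] >= total || wres[1] >= total) stop("analysis windows outside trace")
  tw <- .trace_window(trace, wtr)
  peak_transient <- max(tw$y)
  rw <- .trace_window(trace, wres)
  ipk <- which.max(rw$y)
  peak_resurgent <- rw$y[ipk]
  peak_voltage <- voltage_at(protocol, rw$t[ipk])
  denom <- switch(normalization, none = 1, conductance = G,
                  peak_tail = peak_tail)
  if (is.null(denom)) stop("missing normalization denominator")
  structure(list(peak_transient = peak_transient / denom,
                 peak_resurgent = peak_resurgent / denom,
                 peak_voltage = peak_voltage, beat = beat,
                 normalization = normalization),
            class = "ap_clamp_metrics")
}

#' Instantaneous tail I-V relation
#'
#' Mean current in a short window immediately after the blanking period at
#' the start of each repolarizing tail, against the tail voltage. Used for
#' reversal-potential estimation.
#'
#' @inheritParams fully_activated_iv
#' @param win_ms width of the measurement window, ms.
#' @return data.frame with `voltage`, `current`.
#' @export
instantaneous_tail_iv <- function(trace, protocol, tail_seg = 2,
                                  blank_ms = 1, win_ms = 2) {
  stopifnot(!is.null(protocol$meta$tail_voltage))
  vt <- protocol$meta$tail_voltage
  cur <- vapply(seq_along(vt), function(i) {
    w <- .segment_window(protocol, i, tail_seg)
    tw <- .trace_window(trace, c(w[1] + blank_ms, w[1] + blank_ms + win_ms))
    mean(tw$y)
  }, 0)
  data.frame(voltage = vt, current = cur)
}

#' Reversal potential from a tail I-V relation
#'
#' Linear interpolation of the zero crossing between the bracketing
#' voltages of an instantaneous tail I-V series.
#'
#' @param iv data.frame with `voltage` and `current`, spanning a sign
#'   change.
#' @return estimated reversal potential, mV.
#' @export
estimate_reversal_potential <- function(iv) {
  o <- order(iv$voltage)
  v <- iv$voltage[o]; i <- iv$current[o]
  s <- which(i[-length(i)] * i[-1] <= 0 & (i[-length(i)] != 0 | i[-1] != 0))
  if (length(s) == 0) stop("no-reversal: tail currents do not change sign")
  k <- s[1]
  v[k] + (0 - i[k]) * (v[k + 1] - v[k]) / (i[k + 1] - i[k])
}

#' Recovery-from-inactivation time constant at a tail voltage
#'
#' Mono-exponential fit to the rising "hook" phase of the tail current (the
#' transient increase as channels recover from inactivation before
#' deactivating), between the end of the blanking window and the hook peak.
#' An interpretation of the standard hook analysis; the fit window is a
#' declared default.
#'
#' @inheritParams fully_activated_iv
#' @param tail_voltage which sweep's tail voltage to analyze.
#' @return the fitted time constant, ms.
#' @export
measure_recovery_tau <- function(trace, protocol, tail_voltage = -90,
                                 tail_seg = 2, blank_ms = 1) {
  stopifnot(!is.null(protocol$meta$tail_voltage))
  i <- match(tail_voltage, protocol$meta$tail_voltage)
  if (is.na(i)) stop("no sweep with tail voltage ", tail_voltage)
  w <- .segment_window(protocol, i, tail_seg)
  tw <- .trace_window(trace, c(w[1] + blank_ms, w[2]))
  ipk <- which.max(abs(tw$y))
  ft <- fit_exponential_decay(trace, n_terms = 1,
                              window = c(w[1] + blank_ms, tw$t[ipk]))
  ft$tau_f
}
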