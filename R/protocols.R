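#' Voltage-protocol segments
#'
#' A protocol is an ordered list of sweeps, each an ordered list of
#' segments. A segment is a `step` (constant voltage), a `ramp` (linear
#' voltage), or a `sampled` waveform (uniformly sampled voltages, held
#' zero-order between samples).
#'
#' @param kind `"step"`, `"ramp"` or `"sampled"`.
#' @param duration_ms segment duration, ms (> 0).
#' @param v_start,v_end start/end voltage, mV (equal for a step).
#' @param samples numeric voltage series for `kind = "sampled"`.
#' @param sample_dt sampling interval of `samples`, ms; must divide
#'   `duration_ms`.
#' @return a list of class `protocol_segment`.
#' @export
protocol_segment <- function(kind = c("step", "ramp", "sampled"),
                             duration_ms, v_start, v_end = v_start,
                             samples = NULL, sample_dt = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(duration_ms) || duration_ms <= 0)
    stop("segment duration must be > 0 (got ", duration_ms, ")")
  if (kind == "sampled") {
    if (is.null(samples) || is.null(sample_dt))
      stop("sampled segments need 'samples' and 'sample_dt'")
    n <- round(duration_ms / sample_dt)
    if (abs(n * sample_dt - duration_ms) > 1e-9 * duration_ms || n != length(samples))
      stop("sample_dt must divide duration_ms and match length(samples)")
    v_start <- samples[1]; v_end <- samples[length(samples)]
  } else if (kind == "step" && !isTRUE(all.equal(v_start, v_end))) {
    stop("a step has v_start == v_end")
  }
  structure(list(kind = kind, duration_ms = duration_ms,
                 v_start = v_start, v_end = v_end,
                 samples = samples, sample_dt = sample_dt),
            class = "protocol_segment")
}

seg_step <- function(v, dur) protocol_segment("step", dur, v, v)
seg_ramp <- function(v0, v1, dur) protocol_segment("ramp", dur, v0, v1)

#' Assemble a voltage protocol
#'
#' @param holding holding potential, mV.
#' @param sweeps list of sweeps; each sweep a list of [protocol_segment()]s.
#' @param dt output sampling interval, ms.
#' @param meta optional data.frame with one row per sweep (e.g. a
#'   `test_voltage` or `coupling_ms` column).
#' @param id protocol identifier string.
#' @return object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(holding, sweeps, dt = 0.1, meta = NULL, id = "") {
  stopifnot(is.numeric(holding), length(sweeps) >= 1, dt > 0)
  if (!is.null(meta) && nrow(meta) != length(sweeps))
    stop("meta must have one row per sweep")
  obj <- structure(list(holding = holding, sweeps = sweeps, dt = dt,
                        meta = meta, id = id, table = NULL),
                   class = "voltage_protocol")
  obj$table <- .build_segment_table(obj)
  obj
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("<voltage_protocol> %s: %d sweep(s), %.4g ms total, hold %g mV, dt %g ms\n",
              if (nzchar(x$id)) x$id else "(unnamed)",
              length(x$sweeps), protocol_duration(x), x$holding, x$dt))
  invisible(x)
}

#' Total protocol duration in ms
#' @param protocol a `voltage_protocol`.
#' @export
protocol_duration <- function(protocol) {
  sum(vapply(protocol$sweeps,
             function(sw) sum(vapply(sw, `[[`, 0, "duration_ms")), 0))
}

#' Number of sweeps in a protocol
#' @param protocol a `voltage_protocol`.
#' @export
n_sweeps <- function(protocol) length(protocol$sweeps)

#' Segment table with global start/end times
#'
#' Protocol time starts at 0 at the first segment; sweeps run consecutively;
#' segment intervals are half-open `[t_start, t_end)`.
#'
#' @param protocol a `voltage_protocol`.
#' @return data.frame with columns `sweep`, `seg`, `kind`, `t_start`,
#'   `t_end`, `v_start`, `v_end`.
#' @export
segment_table <- function(protocol) {
  if (!is.null(protocol$table)) return(protocol$table)
  .build_segment_table(protocol)
}

.build_segment_table <- function(protocol) {
  ns <- lengths(protocol$sweeps)
  segs <- unlist(protocol$sweeps, recursive = FALSE)
  dur <- vapply(segs, `[[`, 0, "duration_ms")
  tend <- cumsum(dur)
  data.frame(sweep = rep(seq_along(ns), ns),
             seg = unlist(lapply(ns, seq_len)),
             kind = vapply(segs, `[[`, "", "kind"),
             t_start = c(0, tend[-length(tend)]), t_end = tend,
             v_start = vapply(segs, `[[`, 0, "v_start"),
             v_end = vapply(segs, `[[`, 0, "v_end"))
}

#' Sweep start/end times
#' @param protocol a `voltage_protocol`.
#' @return data.frame with columns `sweep`, `t_start`, `t_end`.
#' @export
sweep_times <- function(protocol) {
  st <- segment_table(protocol)
  do.call(rbind, lapply(split(st, st$sweep), function(d)
    data.frame(sweep = d$sweep[1], t_start = min(d$t_start),
               t_end = max(d$t_end))))
}

#' Command voltage at arbitrary protocol times
#'
#' Half-open convention: at a boundary the later segment's voltage applies.
#' Ramps interpolate linearly; sampled segments are zero-order held.
#'
#' @param protocol a `voltage_protocol`.
#' @param t time(s) in ms, `0 <= t < ` [protocol_duration()].
#' @return voltage(s), mV.
#' @export
voltage_at <- function(protocol, t) {
  total <- protocol_duration(protocol)
  if (any(t < 0 | t >= total))
    stop("t out of range [0, ", total, ")")
  st <- segment_table(protocol)
  idx <- findInterval(t, st$t_start)  # half-open: boundary -> later segment
  v <- numeric(length(t))
  segs <- unlist(protocol$sweeps, recursive = FALSE)
  for (u in unique(idx)) {
    sel <- idx == u
    s <- segs[[u]]
    tl <- t[sel] - st$t_start[u]
    v[sel] <- switch(s$kind,
      step = s$v_start,
      ramp = s$v_start + (s$v_end - s$v_start) * tl / s$duration_ms,
      sampled = s$samples[pmin(length(s$samples),
                               floor(tl / s$sample_dt + 1e-12) + 1)])
  }
  v
}

#' Render a protocol to a uniformly sampled voltage series
#'
#' @param protocol a `voltage_protocol`.
#' @param dt sampling interval, ms (default the protocol's own).
#' @return data.frame with `time_ms`, `voltage_mV`; times span
#'   `[0, duration)`.
#' @export
render_protocol <- function(protocol, dt = protocol$dt) {
  total <- protocol_duration(protocol)
  n <- floor(total / dt + 1e-9)
  t <- (seq_len(n) - 1) * dt
  data.frame(time_ms = t, voltage_mV = voltage_at(protocol, t))
}

#' Write / load a sampled-waveform protocol as two-column CSV
#'
#' The file format is `time_ms,voltage_mV` at uniform sampling. Loading
#' yields a protocol with a single sampled segment; rendering a protocol to
#' file and reloading reproduces [voltage_at()] at the sample times.
#'
#' @param protocol a `voltage_protocol` (for writing).
#' @param path file path.
#' @param dt sampling interval used for rendering, ms.
#' @param id protocol id for the loaded object.
#' @return `load_sampled_protocol` returns a `voltage_protocol`.
#' @export
load_sampled_protocol <- function(path, id = basename(path)) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2) stop("expected two columns: time_ms, voltage_mV")
  t <- d[[1]]; v <- d[[2]]
  if (length(t) < 2 || any(diff(t) <= 0))
    stop("time column must be strictly increasing")
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("non-uniform sampling in protocol file")
  dt <- dt[1]
  seg <- protocol_segment("sampled", duration_ms = length(v) * dt,
                          v_start = v[1], samples = v, sample_dt = dt)
  voltage_protocol(holding = v[1], sweeps = list(list(seg)), dt = dt, id = id)
}

#' @rdname load_sampled_protocol
#' @export
write_sampled_protocol <- function(protocol, path, dt = protocol$dt) {
  utils::write.csv(render_protocol(protocol, dt), path, row.names = FALSE)
  invisible(path)
}

#' Read / write protocols as JSON
#'
#' Format: `{"holding": mV, "sampling_ms": dt, "id": ...,
#' "sweeps": [[{"kind","duration_ms","v_start","v_end"},...],...]}`.
#' Sampled segments carry `samples` and `sample_dt` fields.
#'
#' @param protocol a `voltage_protocol`.
#' @param path file path.
#' @export
write_protocol_json <- function(protocol, path) {
  sw <- lapply(protocol$sweeps, function(s) lapply(s, function(seg) {
    out <- list(kind = seg$kind, duration_ms = seg$duration_ms,
                v_start = seg$v_start, v_end = seg$v_end)
    if (seg$kind == "sampled") {
      out$samples <- seg$samples; out$sample_dt <- seg$sample_dt
    }
    out
  }))
  x <- list(holding = protocol$holding, sampling_ms = protocol$dt,
            id = protocol$id, sweeps = sw)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  sweeps <- lapply(x$sweeps, function(s) lapply(s, function(seg)
    protocol_segment(seg$kind, seg$duration_ms, seg$v_start, seg$v_end,
                     samples = if (!is.null(seg$samples)) unlist(seg$samples),
                     sample_dt = seg$sample_dt)))
  voltage_protocol(x$holding, sweeps, dt = x$sampling_ms,
                   id = if (is.null(x$id)) "" else x$id)
}

# ---------------------------------------------------------------- builders

#' Activation voltage protocols
#'
#' `oocyte_21C`: from a holding potential of -100 mV, 250-ms test steps from
#' -100 to +60 mV in 10-mV increments (17 sweeps), each followed by a 750-ms
#' tail at -110 mV. `hek_37C`: from -80 mV, 1,500-ms steps from -50 to
#' +40 mV in 15-mV increments (7 sweeps), each followed by an 800-ms tail at
#' -40 mV and 200 ms at holding.
#'
#' @param variant `"oocyte_21C"` or `"hek_37C"`.
#' @param dt output sampling interval, ms.
#' @return a `voltage_protocol` with a `test_voltage` metadata column.
#' @export
build_activation_protocol <- function(variant = c("oocyte_21C", "hek_37C"),
                                      dt = 0.1) {
  variant <- match.arg(variant)
  if (variant == "oocyte_21C") {
    vt <- seq(-100, 60, by = 10)
    sweeps <- lapply(vt, function(v) list(seg_step(v, 250), seg_step(-110, 750)))
    voltage_protocol(-100, sweeps, dt = dt,
                     meta = data.frame(test_voltage = vt),
                     id = "activation_oocyte_21C")
  } else {
    vt <- seq(-50, 40, by = 15)
    sweeps <- lapply(vt, function(v)
      list(seg_step(v, 1500), seg_step(-40, 800), seg_step(-80, 200)))
    voltage_protocol(-80, sweeps, dt = dt,
                     meta = data.frame(test_voltage = vt),
                     id = "activation_hek_37C")
  }
}

#' Deactivation voltage protocol
#'
#' Per sweep: a 250-ms activating step to +40 mV followed by a 750-ms
#' repolarizing step to the sweep's tail voltage (holding -100 mV). Tails
#' between -140 and -110 mV cover the linear-conductance region used for
#' whole-cell conductance normalization.
#'
#' @param tail_voltages tail voltages, mV, within `[-150, 60]`, no
#'   duplicates.
#' @param dt output sampling interval, ms.
#' @return a `voltage_protocol` with a `tail_voltage` metadata column.
#' @export
build_deactivation_protocol <- function(tail_voltages, dt = 0.1) {
  if (length(tail_voltages) == 0) stop("tail_voltages must be non-empty")
  if (anyDuplicated(tail_voltages)) stop("duplicate tail voltages")
  if (any(tail_voltages < -150 | tail_voltages > 60))
    stop("tail voltages must lie within [-150, 60] mV")
  sweeps <- lapply(tail_voltages, function(v)
    list(seg_step(40, 250), seg_step(v, 750)))
  voltage_protocol(-100, sweeps, dt = dt,
                   meta = data.frame(tail_voltage = tail_voltages),
                   id = "deactivation")
}

#' Inactivation protocol (physiological temperature variant)
#'
#' A 500-ms depolarizing prepulse to +20 mV followed by 800-ms repolarizing
#' steps from -140 to +40 mV in 30-mV increments (7 sweeps; holding -80 mV).
#'
#' @param dt output sampling interval, ms.
#' @return a `voltage_protocol` with a `test_voltage` metadata column.
#' @export
build_inactivation_protocol_37C <- function(dt = 0.1) {
  vt <- seq(-140, 40, by = 30)
  sweeps <- lapply(vt, function(v)
    list(seg_step(20, 500), seg_step(v, 800), seg_step(-80, 200)))
  voltage_protocol(-80, sweeps, dt = dt,
                   meta = data.frame(test_voltage = vt),
                   id = "inactivation_37C")
}

#' Staircase calibration protocol
#'
#' A deterministic staircase of ascending then descending 500-ms steps
#' bracketed by reference steps, covering -120 to +60 mV in a single
#' information-rich sweep (~14.5 s). The step table is configuration, not
#' logic: the default ships as a CSV data file and any table with columns
#' `duration_ms`, `voltage_mV` can be supplied.
#'
#' @param config data.frame with columns `duration_ms` and `voltage_mV`,
#'   or `NULL` for the bundled default table.
#' @param dt output sampling interval, ms.
#' @return a single-sweep `voltage_protocol`.
#' @export
build_staircase_protocol <- function(config = NULL, dt = 0.1) {
  if (is.null(config)) {
    path <- system.file("extdata", "staircase_default.csv",
                        package = "hergkinetics", mustWork = TRUE)
    config <- utils::read.csv(path)
  }
  if (!all(c("duration_ms", "voltage_mV") %in% names(config)))
    stop("malformed step table: need columns duration_ms, voltage_mV")
  if (any(!is.finite(config$duration_ms)) || any(config$duration_ms <= 0))
    stop("malformed step table: durations must be positive")
  if (any(!is.finite(config$voltage_mV)))
    stop("malformed step table: non-finite voltage")
  segs <- mapply(seg_step, config$voltage_mV, config$duration_ms,
                 SIMPLIFY = FALSE)
  voltage_protocol(config$voltage_mV[1], list(segs), dt = dt, id = "staircase")
}

# ------------------------------------------------------ stylized AP shapes

#' Stylized action-potential waveform specification
#'
#' A simple ventricular-like command waveform: a step to the upstroke target,
#' a shallow plateau ramp, and a linear repolarizing ramp back to holding.
#' The time of 90% repolarization (V falling through
#' `upstroke - 0.9 * (upstroke - hold)`) anchors coupling intervals for
#' premature-stimulation protocols. Defaults give an APD-like duration
#' (upstroke to 90% repolarization) of about 350 ms.
#'
#' @param upstroke_mV upstroke target voltage.
#' @param plateau_start_mV,plateau_end_mV plateau ramp start/end voltages.
#' @param plateau_ms plateau ramp duration.
#' @param repol_ms repolarization ramp duration.
#' @param hold_mV pre/post holding potential.
#' @param upstroke_ms duration spent at the upstroke target.
#' @return a list of class `stylized_ap` (with computed `t90_ms`, the 90%
#'   repolarization time measured from waveform onset).
#' @export
stylized_ap_spec <- function(upstroke_mV = 40, plateau_start_mV = 40,
                             plateau_end_mV = 20, plateau_ms = 68,
                             repol_ms = 320, hold_mV = -100,
                             upstroke_ms = 2) {
  if (plateau_end_mV <= hold_mV)
    stop("repolarization must be monotonic: plateau_end_mV > hold_mV")
  spec <- list(upstroke_mV = upstroke_mV, plateau_start_mV = plateau_start_mV,
               plateau_end_mV = plateau_end_mV, plateau_ms = plateau_ms,
               repol_ms = repol_ms, hold_mV = hold_mV,
               upstroke_ms = upstroke_ms)
  v90 <- upstroke_mV - 0.9 * (upstroke_mV - hold_mV)
  segs <- ap_segments_raw(spec)
  t90 <- NA_real_; t0 <- 0
  for (s in segs) {
    vlo <- min(s$v_start, s$v_end); vhi <- max(s$v_start, s$v_end)
    if (s$v_start > v90 && s$v_end <= v90) {
      t90 <- t0 + (s$v_start - v90) / (s$v_start - s$v_end) * s$duration_ms
      break
    }
    t0 <- t0 + s$duration_ms
  }
  if (!is.finite(t90))
    stop("90%-repolarization time must lie within the waveform")
  spec$t90_ms <- t90
  structure(spec, class = "stylized_ap")
}

# segment list of the bare AP waveform (no pre/post holding)
ap_segments_raw <- function(spec) {
  list(seg_step(spec$upstroke_mV, spec$upstroke_ms),
       seg_ramp(spec$plateau_start_mV, spec$plateau_end_mV, spec$plateau_ms),
       seg_ramp(spec$plateau_end_mV, spec$hold_mV, spec$repol_ms))
}

ap_duration <- function(spec) spec$upstroke_ms + spec$plateau_ms + spec$repol_ms

# extract the sub-waveform of a segment list over [t0, t1), splitting
# segments and interpolating ramp voltages at the cut points
.slice_segments <- function(segs, t0, t1) {
  out <- list(); tacc <- 0
  for (s in segs) {
    s0 <- tacc; s1 <- tacc + s$duration_ms; tacc <- s1
    lo <- max(s0, t0); hi <- min(s1, t1)
    if (hi - lo <= 1e-12) next
    vat <- function(t) {
      if (s$kind == "step") s$v_start
      else s$v_start + (s$v_end - s$v_start) * (t - s0) / s$duration_ms
    }
    out[[length(out) + 1]] <-
      if (s$kind == "step") seg_step(s$v_start, hi - lo)
      else protocol_segment("ramp", hi - lo, vat(lo), vat(hi))
  }
  out
}

#' Premature-stimulation (protective-current) protocol
#'
#' Each sweep holds at the AP's holding potential, plays the stylized
#' action-potential waveform, and delivers a 40-ms depolarizing step to
#' 0 mV whose onset is the 90%-repolarization time plus the sweep's
#' coupling interval. The step overrides the underlying waveform, so sweeps
#' differ only within the 40-ms step window. The default coupling-interval
#' grid spans -80 to 380 ms at 20-ms spacing.
#'
#' @param ap a [stylized_ap_spec()].
#' @param intervals coupling intervals, ms, within `[-80, 380]`.
#' @param pre_ms holding time before the AP waveform in each sweep.
#' @param post_ms holding time appended after the latest possible step.
#' @param step_mV,step_ms premature-step amplitude (0 mV) and width (40 ms).
#' @param dt output sampling interval, ms.
#' @return a `voltage_protocol` with a `coupling_ms` metadata column.
#' @export
build_premature_stimulation_protocol <- function(ap = stylized_ap_spec(),
                                                 intervals = seq(-80, 380, by = 20),
                                                 pre_ms = 500, post_ms = 500,
                                                 step_mV = 0, step_ms = 40,
                                                 dt = 0.1) {
  if (any(intervals < -80 | intervals > 380))
    stop("coupling intervals must lie within [-80, 380] ms")
  apsegs <- ap_segments_raw(ap)
  apdur <- ap_duration(ap)
  t90 <- pre_ms + ap$t90_ms
  onsets <- t90 + intervals
  if (any(onsets < pre_ms))
    stop("coupling interval places the step before the AP upstroke")
  total <- pre_ms + max(apdur, max(onsets) - pre_ms + step_ms) + post_ms
  base <- c(list(seg_step(ap$hold_mV, pre_ms)), apsegs,
            list(seg_step(ap$hold_mV, total - pre_ms - apdur)))
  sweeps <- lapply(onsets, function(o) {
    c(.slice_segments(base, 0, o),
      list(seg_step(step_mV, step_ms)),
      .slice_segments(base, o + step_ms, total))
  })
  voltage_protocol(ap$hold_mV, sweeps, dt = dt,
                   meta = data.frame(coupling_ms = intervals,
                                     step_onset_ms = onsets),
                   id = "premature_stimulation")
}

#' Action-potential train protocol
#'
#' A single sweep of `n_beats` stylized action potentials delivered at
#' `rate_hz`, each beat padded with holding time to the pacing period.
#' Beat onsets and per-beat 90%-repolarization times are stored in the
#' `"beats"` attribute.
#'
#' @param ap a [stylized_ap_spec()].
#' @param n_beats number of beats.
#' @param rate_hz pacing rate, Hz.
#' @param dt output sampling interval, ms.
#' @return a single-sweep `voltage_protocol`.
#' @export
build_ap_train_protocol <- function(ap = stylized_ap_spec(), n_beats = 3,
                                    rate_hz = 1, dt = 0.1) {
  period <- 1000 / rate_hz
  apdur <- ap_duration(ap)
  if (period <= apdur)
    stop("pacing period shorter than the AP waveform")
  beat <- c(ap_segments_raw(ap), list(seg_step(ap$hold_mV, period - apdur)))
  segs <- do.call(c, rep(list(beat), n_beats))
  pr <- voltage_protocol(ap$hold_mV, list(segs), dt = dt,
                         id = sprintf("ap_train_%gHz", rate_hz))
  attr(pr, "beats") <- data.frame(
    beat = seq_len(n_beats),
    onset_ms = (seq_len(n_beats) - 1) * period,
    t90_ms = (seq_len(n_beats) - 1) * period + ap$t90_ms)
  attr(pr, "ap") <- ap
  pr
}

#' Complex action-potential train (validation waveform)
#'
#' A deterministic train of action-potential-like waveforms with varied
#' morphology: beats of differing plateau and repolarization durations, a
#' premature depolarizing step arriving early in the refractory period of
#' one beat, and an early-afterdepolarization-like bump in another. Used as
#' the complex-waveform validation protocol for calibrated models. Total
#' duration exceeds 5 s. This waveform is a synthetic stand-in constructed
#' by the package, not a recording-derived trace.
#'
#' @param dt output sampling interval, ms.
#' @return a single-sweep `voltage_protocol`.
#' @export
build_complex_ap_protocol <- function(dt = 0.1) {
  hold <- -100
  ap1 <- stylized_ap_spec()                                  # standard
  ap2 <- stylized_ap_spec(plateau_ms = 40, repol_ms = 200)   # short APD
  ap3 <- stylized_ap_spec(plateau_end_mV = 25, repol_ms = 450) # long APD
  segs <- list(seg_step(hold, 300))
  add <- function(...) segs <<- c(segs, list(...))
  addap <- function(ap) segs <<- c(segs, ap_segments_raw(ap))
  addap(ap1); add(seg_step(hold, 400))
  addap(ap2); add(seg_step(hold, 300))
  # long-APD beat followed by a premature step 100 ms after 90% repolarization
  addap(ap3)
  gap <- ap3$t90_ms + 100 - ap_duration(ap3)
  add(seg_step(hold, max(gap, 1)), seg_step(0, 40), seg_step(hold, 300))
  # EAD-like beat: interrupted repolarization with a depolarizing bump
  add(seg_step(40, 2), seg_ramp(40, 0, 120), seg_ramp(0, 10, 80),
      seg_ramp(10, hold, 250), seg_step(hold, 400))
  addap(ap2); add(seg_step(hold, 350))
  addap(ap1); add(seg_step(hold, 700))
  voltage_protocol(hold, list(segs), dt = dt, id = "complex_ap")
}
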