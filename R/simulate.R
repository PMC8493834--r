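#' Nernst reversal potential for K+
#'
#' \deqn{E_K = (RT/zF)\,\ln([K^+]_o/[K^+]_i)} with valency z = 1,
#' returned in mV.
#'
#' @param K_out,K_in extracellular / intracellular K+ concentration, mM.
#' @param temperature absolute temperature, K.
#' @return reversal potential, mV.
#' @export
nernst_potential <- function(K_out, K_in, temperature) {
  if (any(c(K_out, K_in, temperature) <= 0))
    stop("concentrations and temperature must be positive")
  1000 * 8.314462618 * temperature / 96485.33212 * log(K_out / K_in)
}

#' Cell configuration for current simulation
#'
#' Either supply `E_K` directly, or `K_out`, `K_in` and `temperature` to
#' compute it from the Nernst equation. The voltage offset `v_off` models
#' the per-cell discrepancy between commanded and effective membrane
#' voltage: the channel sees `V = V_cmd - v_off`. An optional linear leak
#' `g_leak * (V_cmd - E_leak)` can be configured.
#'
#' @param g_kr maximal conductance, microsiemens (uS).
#' @param K_out,K_in K+ concentrations, mM.
#' @param temperature temperature, K.
#' @param E_K reversal potential, mV (alternative to concentrations).
#' @param v_off voltage offset, mV.
#' @param g_leak leak conductance, uS.
#' @param E_leak leak reversal, mV.
#' @return a list of class `cell_config` (with `E_K` resolved).
#' @export
cell_config <- function(g_kr, K_out = NULL, K_in = NULL, temperature = NULL,
                        E_K = NULL, v_off = 0, g_leak = 0, E_leak = -80) {
  if (g_kr < 0) stop("g_kr must be >= 0")
  have_conc <- !is.null(K_out) || !is.null(K_in) || !is.null(temperature)
  if (is.null(E_K) == !have_conc)
    stop("supply exactly one of E_K or (K_out, K_in, temperature)")
  if (is.null(E_K)) E_K <- nernst_potential(K_out, K_in, temperature)
  structure(list(g_kr = g_kr, E_K = E_K, K_out = K_out, K_in = K_in,
                 temperature = temperature, v_off = v_off,
                 g_leak = g_leak, E_leak = E_leak),
            class = "cell_config")
}

#' Simulation settings
#'
#' @param atol,rtol absolute/relative integration tolerances for the
#'   adaptive (lsoda) integrator. Default `1e-8` each.
#' @param dt_out output sampling interval, ms; `NULL` uses the protocol's.
#' @param max_step maximum internal step for the adaptive integrator, ms.
#' @param method `"analytic"` (exact closed-form propagation on
#'   piecewise-constant voltage; ramps subdivided at `ramp_dt`) or `"ode"`
#'   (adaptive stiff integration via deSolve::lsoda, restarted at segment
#'   boundaries).
#' @param ramp_dt zero-order-hold subdivision for ramps under the analytic
#'   method, ms.
#' @return a list of class `sim_settings`.
#' @export
sim_settings <- function(atol = 1e-8, rtol = 1e-8, dt_out = NULL,
                         max_step = Inf, method = c("analytic", "ode"),
                         ramp_dt = 0.2) {
  stopifnot(atol > 0, rtol > 0, is.null(dt_out) || dt_out > 0)
  structure(list(atol = atol, rtol = rtol, dt_out = dt_out,
                 max_step = max_step, method = match.arg(method),
                 ramp_dt = ramp_dt),
            class = "sim_settings")
}

#' Initial gating state for a protocol
#'
#' The steady state at the protocol's holding potential, corrected for the
#' cell's voltage offset (`V = V_cmd - v_off`).
#'
#' @param params a [herg_params()].
#' @param cell a [cell_config()].
#' @param protocol a `voltage_protocol`.
#' @return a [gate_state()].
#' @export
initial_state <- function(params, cell, protocol) {
  gate_steady_state(params, protocol$holding - cell$v_off)
}

# exact propagation of the affine (C1a, Oa) system + h gate at constant
# voltage; returns states at query times tq plus the end state at `dur`
.prop_const <- function(rt, x0, tq, dur) {
  a1 <- rt$a1; b1 <- rt$b1; a2 <- rt$a2; b2 <- rt$b2
  A11 <- -(a1 + a2 + b1); A12 <- b2 - a1; A21 <- a2; A22 <- -b2
  det <- a1 * b2 + b1 * b2 + a1 * a2
  if (det <= 0) stop("degenerate-chain: activation chain has no fixed point")
  xinf1 <- a1 * b2 / det   # C1a
  xinf2 <- a1 * a2 / det   # Oa
  d1 <- x0[1] - xinf1; d2 <- x0[2] - xinf2
  tr <- A11 + A22
  disc <- tr * tr - 4 * det
  sq <- sqrt(max(disc, 0))
  tt <- c(tq, dur)
  if (sq > 1e-10 * max(abs(tr), 1)) {
    l1 <- (tr + sq) / 2; l2 <- (tr - sq) / 2
    evec <- function(l) {
      if (abs(A12) >= abs(A21)) {
        if (abs(A12) < 1e-300) c(1, 0) else c(A12, l - A11)
      } else c(l - A22, A21)
    }
    v1 <- evec(l1); v2 <- evec(l2)
    dd <- v1[1] * v2[2] - v2[1] * v1[2]
    al1 <- (d1 * v2[2] - d2 * v2[1]) / dd
    al2 <- (v1[1] * d2 - v1[2] * d1) / dd
    e1 <- exp(l1 * tt); e2 <- exp(l2 * tt)
    C1a <- xinf1 + al1 * v1[1] * e1 + al2 * v2[1] * e2
    Oa  <- xinf2 + al1 * v1[2] * e1 + al2 * v2[2] * e2
  } else {
    l <- tr / 2
    g1 <- (A11 - l) * d1 + A12 * d2
    g2 <- A21 * d1 + (A22 - l) * d2
    el <- exp(l * tt)
    C1a <- xinf1 + el * (d1 + tt * g1)
    Oa  <- xinf2 + el * (d2 + tt * g2)
  }
  eh <- exp(-tt / rt$tau_h)
  h <- rt$h_inf + (x0[3] - rt$h_inf) * eh
  n <- length(tq)
  list(C1a = C1a[seq_len(n)], Oa = Oa[seq_len(n)], h = h[seq_len(n)],
       end = c(C1a[n + 1], Oa[n + 1], h[n + 1]))
}

# break a segment into (voltage, duration) zero-order-hold pieces for the
# analytic method
.segment_pieces <- function(seg, ramp_dt) {
  if (seg$kind == "step") {
    list(v = seg$v_start, dur = seg$duration_ms)
  } else if (seg$kind == "ramp") {
    nsub <- max(1L, ceiling(seg$duration_ms / ramp_dt))
    dsub <- seg$duration_ms / nsub
    mid <- (seq_len(nsub) - 0.5) / nsub
    list(v = seg$v_start + (seg$v_end - seg$v_start) * mid,
         dur = rep(dsub, nsub))
  } else {
    list(v = seg$samples, dur = rep(seg$sample_dt, length(seg$samples)))
  }
}

#' Integrate the gating ODEs over a voltage protocol
#'
#' States are continuous across segment boundaries within a sweep; the
#' integrator is restarted at each boundary so discontinuous voltage steps
#' are not smeared. By default each sweep starts afresh from the
#' holding-potential steady state (full channel closure between sweeps);
#' set `reset_between_sweeps = FALSE` to carry state across sweeps.
#'
#' @param params a [herg_params()].
#' @param protocol a `voltage_protocol`.
#' @param cell a [cell_config()] (only `v_off` affects gating).
#' @param settings a [sim_settings()].
#' @param reset_between_sweeps logical.
#' @return a list of class `gating_trace` with fields `t` (ms), `Oa`,
#'   `C1a`, `C2a`, `h`, `O` (numeric vectors on the output grid), `dt`.
#' @export
simulate_gating <- function(params, protocol, cell = cell_config(1, E_K = -85),
                            settings = sim_settings(),
                            reset_between_sweeps = TRUE) {
  dt <- if (is.null(settings$dt_out)) protocol$dt else settings$dt_out
  total <- protocol_duration(protocol)
  n <- floor(total / dt + 1e-9)
  tout <- (seq_len(n) - 1) * dt
  Oa <- C1a <- h <- numeric(n)
  st <- segment_table(protocol)
  seg_first <- st$seg == 1L
  seg_tend <- st$t_end
  seg_tstart <- st$t_start
  voff <- cell$v_off
  pvec <- unname(params$p)
  segs <- unlist(protocol$sweeps, recursive = FALSE)
  hold_ss <- gate_steady_state(params, protocol$holding - voff)
  x0 <- c(hold_ss[["C1a"]], hold_ss[["Oa"]], hold_ss[["h"]])
  x <- x0
  ptr <- 1L
  for (k in seq_len(nrow(st))) {
    if (seg_first[k] && (k == 1L || reset_between_sweeps)) x <- x0
    seg <- segs[[k]]
    i_hi <- min(n, ceiling(seg_tend[k] / dt - 1e-9))
    idx <- if (i_hi >= ptr) ptr:i_hi else integer(0)
    ptr <- max(ptr, i_hi + 1L)
    tl <- tout[idx] - seg_tstart[k]
    if (settings$method == "analytic" || seg$kind == "sampled") {
      if (seg$kind == "step") {
        rt <- .rates_fast(pvec, seg$v_start - voff)
        pr <- .prop_const(rt, x, tl, seg$duration_ms)
        if (length(idx)) {
          C1a[idx] <- pr$C1a; Oa[idx] <- pr$Oa; h[idx] <- pr$h
        }
        x <- pr$end
      } else {
        pieces <- .segment_pieces(seg, settings$ramp_dt)
        off <- 0
        for (pi in seq_along(pieces$v)) {
          dur <- pieces$dur[pi]
          sel <- tl >= off - 1e-9 & tl < off + dur - 1e-9
          rt <- .rates_fast(pvec, pieces$v[pi] - voff)
          pr <- .prop_const(rt, x, tl[sel] - off, dur)
          if (any(sel)) {
            ii <- idx[sel]
            C1a[ii] <- pr$C1a; Oa[ii] <- pr$Oa; h[ii] <- pr$h
          }
          x <- pr$end
          off <- off + dur
        }
      }
    } else {
      deriv <- if (seg$kind == "step") {
        rt <- evaluate_rates(params, seg$v_start - voff)
        function(t, y, parms) {
          dC1a <- rt$b2 * y[2] + rt$a1 * (1 - y[1] - y[2]) -
            (rt$a2 + rt$b1) * y[1]
          dOa <- rt$a2 * y[1] - rt$b2 * y[2]
          dh <- (rt$h_inf - y[3]) / rt$tau_h
          list(c(dC1a, dOa, dh))
        }
      } else {
        function(t, y, parms) {
          v <- seg$v_start + (seg$v_end - seg$v_start) * t / seg$duration_ms
          rt <- evaluate_rates(params, v - voff)
          dC1a <- rt$b2 * y[2] + rt$a1 * (1 - y[1] - y[2]) -
            (rt$a2 + rt$b1) * y[1]
          dOa <- rt$a2 * y[1] - rt$b2 * y[2]
          dh <- (rt$h_inf - y[3]) / rt$tau_h
          list(c(dC1a, dOa, dh))
        }
      }
      times <- unique(c(0, tl, seg$duration_ms))
      sol <- deSolve::lsoda(y = x, times = times, func = deriv,
                            rtol = settings$rtol, atol = settings$atol,
                            hmax = if (is.finite(settings$max_step))
                              settings$max_step else NULL)
      if (attr(sol, "istate")[1] < 0)
        stop(sprintf("integrator failure at t = %.3f ms (segment %d, state %s)",
                     st$t_start[k], k, paste(signif(x, 4), collapse = ", ")))
      if (length(tl)) {
        m <- sol[match(round(tl, 9), round(sol[, 1], 9)), , drop = FALSE]
        C1a[idx] <- m[, 2]; Oa[idx] <- m[, 3]; h[idx] <- m[, 4]
      }
      x <- sol[nrow(sol), 2:4]
    }
  }
  structure(list(t = tout, Oa = Oa, C1a = C1a, C2a = 1 - Oa - C1a, h = h,
                 O = Oa * h, dt = dt, protocol_id = protocol$id),
            class = "gating_trace")
}

#' Integrate the equivalent six-state Markov model (equivalence oracle)
#'
#' Full master-equation integration of the six-state model with
#' deSolve::lsoda, restarted at segment boundaries. Exists as the
#' independent cross-check of the factorized integrator; the two open
#' probabilities agree to integrator tolerance for any parameter set.
#'
#' @inheritParams simulate_gating
#' @return a list of class `markov_trace` with `t` and an `occupancy`
#'   matrix (columns `O`, `IO`, `C1`, `IC1`, `C2`, `IC2`).
#' @export
simulate_markov <- function(params, protocol, cell = cell_config(1, E_K = -85),
                            settings = sim_settings(atol = 1e-10, rtol = 1e-10),
                            reset_between_sweeps = TRUE) {
  dt <- if (is.null(settings$dt_out)) protocol$dt else settings$dt_out
  total <- protocol_duration(protocol)
  n <- floor(total / dt + 1e-9)
  tout <- (seq_len(n) - 1) * dt
  occ <- matrix(NA_real_, n, 6,
                dimnames = list(NULL, c("O", "IO", "C1", "IC1", "C2", "IC2")))
  st <- segment_table(protocol)
  segs <- unlist(protocol$sweeps, recursive = FALSE)
  voff <- cell$v_off
  m0 <- as.numeric(expand_to_markov(
    gate_steady_state(params, protocol$holding - voff)))
  x <- m0
  ptr <- 1L
  for (k in seq_len(nrow(st))) {
    if (st$seg[k] == 1L && (k == 1L || reset_between_sweeps)) x <- m0
    seg <- segs[[k]]
    i_hi <- min(n, ceiling(st$t_end[k] / dt - 1e-9))
    idx <- if (i_hi >= ptr) ptr:i_hi else integer(0)
    ptr <- max(ptr, i_hi + 1L)
    tl <- tout[idx] - st$t_start[k]
    deriv <- if (seg$kind == "step") {
      Q <- markov_generator(evaluate_rates(params, seg$v_start - voff))
      function(t, y, parms) list(drop(Q %*% y))
    } else {
      vfun <- switch(seg$kind,
        ramp = function(t) seg$v_start + (seg$v_end - seg$v_start) * t / seg$duration_ms,
        sampled = function(t) seg$samples[pmin(length(seg$samples),
                                               floor(t / seg$sample_dt + 1e-12) + 1)])
      function(t, y, parms)
        list(drop(markov_generator(evaluate_rates(params, vfun(t) - voff)) %*% y))
    }
    times <- unique(c(0, tl, seg$duration_ms))
    sol <- deSolve::lsoda(y = x, times = times, func = deriv,
                          rtol = settings$rtol, atol = settings$atol)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("integrator failure at t = %.3f ms (segment %d)",
                   st$t_start[k], k))
    if (length(tl))
      occ[idx, ] <- sol[match(round(tl, 9), round(sol[, 1], 9)), -1, drop = FALSE]
    x <- sol[nrow(sol), -1]
  }
  structure(list(t = tout, occupancy = occ, dt = dt,
                 protocol_id = protocol$id),
            class = "markov_trace")
}

#' Current traces
#'
#' A uniformly sampled current trace in nA, optionally carrying the
#' command-voltage samples and metadata.
#'
#' @param current numeric samples, nA.
#' @param dt sampling interval, ms.
#' @param t0 start time, ms.
#' @param voltage optional command-voltage samples, mV.
#' @param meta named list (cell id, condition, protocol id, ...).
#' @return a list of class `current_trace`.
#' @export
current_trace <- function(current, dt, t0 = 0, voltage = NULL, meta = list()) {
  if (any(!is.finite(current))) stop("current samples must be finite")
  if (!is.null(voltage) && length(voltage) != length(current))
    stop("voltage samples must match current samples in length")
  structure(list(t0 = t0, dt = dt, current = as.numeric(current),
                 voltage = voltage, meta = meta),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %d samples @ %g ms (%.4g ms), range [%.3g, %.3g] nA\n",
              length(x$current), x$dt, length(x$current) * x$dt,
              min(x$current), max(x$current)))
  invisible(x)
}

#' Sample times of a trace
#' @param trace a `current_trace`.
#' @export
trace_times <- function(trace) trace$t0 + (seq_along(trace$current) - 1) * trace$dt

#' @export
as.data.frame.current_trace <- function(x, ...) {
  d <- data.frame(time_ms = trace_times(x), current_nA = x$current)
  if (!is.null(x$voltage)) d$voltage_mV <- x$voltage
  d
}

#' Read / write current traces as CSV
#'
#' Columns: `time_ms`, `current_nA` and optionally `voltage_mV`.
#'
#' @param trace a `current_trace`.
#' @param path file path.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  if (nrow(d) < 2) stop("trace file needs at least two samples")
  dts <- diff(d$time_ms)
  if (max(abs(dts - dts[1])) > 1e-6 * dts[1]) stop("non-uniform trace sampling")
  current_trace(d$current_nA, dt = dts[1], t0 = d$time_ms[1],
                voltage = d$voltage_mV)
}

#' Simulate the IKr current under a voltage protocol
#'
#' \deqn{I(t) = g_{Kr}\,O(t)\,(V(t) - E_K)} with
#' `V(t) = V_cmd(t) - v_off`; a linear leak `g_leak (V_cmd - E_leak)` is
#' added only when configured. Outward current is positive; units
#' uS x mV = nA.
#'
#' @inheritParams simulate_gating
#' @param include_leak add the cell's leak term (if configured).
#' @return a [current_trace()] with command-voltage samples attached.
#' @export
simulate_current <- function(params, protocol, cell,
                             settings = sim_settings(),
                             reset_between_sweeps = TRUE,
                             include_leak = TRUE) {
  g <- simulate_gating(params, protocol, cell, settings, reset_between_sweeps)
  vcmd <- voltage_at(protocol, g$t)
  i <- cell$g_kr * g$O * (vcmd - cell$v_off - cell$E_K)
  if (include_leak && cell$g_leak != 0)
    i <- i + cell$g_leak * (vcmd - cell$E_leak)
  current_trace(i, dt = g$dt, voltage = vcmd,
                meta = list(protocol_id = protocol$id,
                            label = params$label))
}
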