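#' @useDynLib hergkinetics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# decompose a protocol into constant-voltage pieces aligned with the
# output grid, for the compiled propagation core: ramps are zero-order-hold
# subdivided at ramp_dt, sampled segments at their own sampling interval
.protocol_pieces <- function(protocol, dt, ramp_dt = 0.2,
                             reset_between_sweeps = TRUE) {
  total <- protocol_duration(protocol)
  n <- floor(total / dt + 1e-9)
  st <- segment_table(protocol)
  segs <- unlist(protocol$sweeps, recursive = FALSE)
  pv <- pd <- pt0 <- numeric(0)
  pn <- prs <- integer(0)
  ptr <- 1L
  for (k in seq_len(nrow(st))) {
    seg <- segs[[k]]
    i_hi <- min(n, ceiling(st$t_end[k] / dt - 1e-9))
    idx <- if (i_hi >= ptr) ptr:i_hi else integer(0)
    ptr <- max(ptr, i_hi + 1L)
    tl <- (idx - 1) * dt - st$t_start[k]
    pieces <- .segment_pieces(seg, ramp_dt)
    off <- 0
    for (pi in seq_along(pieces$v)) {
      dur <- pieces$dur[pi]
      sel <- tl >= off - 1e-9 & tl < off + dur - 1e-9
      pv <- c(pv, pieces$v[pi]); pd <- c(pd, dur)
      pn <- c(pn, sum(sel))
      pt0 <- c(pt0, if (any(sel)) tl[sel][1] - off else 0)
      prs <- c(prs, as.integer(pi == 1L && st$seg[k] == 1L &&
                                 (k == 1L || reset_between_sweeps)))
      off <- off + dur
    }
  }
  list(v = pv, dur = pd, n = pn, t0 = pt0, reset = prs,
       dt = dt, holding = protocol$holding, n_out = n)
}

# open-probability trace via the compiled closed-form propagation core;
# numerically identical (to machine precision) to simulate_gating()$O with
# the analytic method
.sim_O_fast <- function(pvec, pieces, v_off) {
  .sim_O_cpp(pvec, pieces$v, pieces$dur, pieces$n, pieces$t0, pieces$reset,
             pieces$dt, pieces$holding, v_off)
}
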