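#' Evaluate the six voltage-dependent transition rates
#'
#' The gating model factorizes into a three-state activation chain
#' C2a <-> C1a <-> Oa and an independent availability (inactivation) gate h.
#' Its six transition rates are simple exponentials of voltage:
#' \deqn{a_1 = p_1 e^{p_2 V},\quad b_1 = p_3 e^{-p_4 V},\quad
#'       b_h = p_5 e^{p_6 V},\quad a_h = p_7 e^{-p_8 V},\quad
#'       a_2 = p_9 e^{p_{10} V},\quad b_2 = p_{11} e^{-p_{12} V}.}
#' `a1` drives C2a -> C1a, `b1` C1a -> C2a, `a2` C1a -> Oa, `b2` Oa -> C1a;
#' `bh` is the inactivation rate (h closing) and `ah` the recovery rate.
#' The derived quantities `h_inf = ah/(ah+bh)` and `tau_h = 1/(ah+bh)` are
#' included.
#'
#' @param params a [herg_params()] object.
#' @param V membrane voltage(s), mV. Vectorized.
#' @return a list of class `herg_rates` with numeric fields `a1`, `b1`,
#'   `a2`, `b2`, `ah`, `bh`, `h_inf`, `tau_h` (each the length of `V`),
#'   all rates in ms^-1, `tau_h` in ms.
#' @export
evaluate_rates <- function(params, V) {
  stopifnot(inherits(params, "herg_params"))
  p <- params$p
  V <- as.numeric(V)
  expo <- function(prefac, slope, sign, nm) {
    e <- sign * slope * V
    if (any(abs(e) > 700))
      stop("rate-overflow: exponent for rate '", nm, "' exceeds +/-700 at V = ",
           V[which.max(abs(e))], " mV")
    r <- prefac * exp(e)
    if (any(!is.finite(r)))
      stop("rate-overflow: non-finite value for rate '", nm, "'")
    r
  }
  a1 <- expo(p[["p1"]],  p[["p2"]],  +1, "a1")
  b1 <- expo(p[["p3"]],  p[["p4"]],  -1, "b1")
  bh <- expo(p[["p5"]],  p[["p6"]],  +1, "bh")
  ah <- expo(p[["p7"]],  p[["p8"]],  -1, "ah")
  a2 <- expo(p[["p9"]],  p[["p10"]], +1, "a2")
  b2 <- expo(p[["p11"]], p[["p12"]], -1, "b2")
  structure(list(a1 = a1, b1 = b1, a2 = a2, b2 = b2, ah = ah, bh = bh,
                 h_inf = ah / (ah + bh), tau_h = 1 / (ah + bh)),
            class = "herg_rates")
}

#' Construct an activation-chain + availability gate state
#'
#' @param Oa,C1a,C2a occupancies of the activation chain (must sum to 1).
#' @param h availability gate value in `[0, 1]`.
#' @param tol tolerance on the simplex sum.
#' @return named numeric of class `gate_state` with components
#'   `Oa`, `C1a`, `C2a`, `h`.
#' @export
gate_state <- function(Oa, C1a, C2a = 1 - Oa - C1a, h = 1, tol = 1e-10) {
  s <- c(Oa = Oa, C1a = C1a, C2a = C2a, h = h)
  if (any(!is.finite(s))) stop("non-finite gate state")
  if (any(s < -tol) || any(s > 1 + tol))
    stop("gate state components must lie in [0, 1]")
  if (abs(Oa + C1a + C2a - 1) > tol)
    stop("activation-chain occupancies must sum to 1 (within ", tol, ")")
  structure(s, class = "gate_state")
}

#' Stationary gating state at a fixed voltage
#'
#' Analytic fixed point of the gating ODEs: `h = h_inf(V)` and the
#' activation chain solved from the detailed-balance ratios
#' `C1a/C2a = a1/b1`, `Oa/C1a = a2/b2`, normalized to sum to 1.
#'
#' @inheritParams evaluate_rates
#' @param V voltage, mV (scalar).
#' @return a [gate_state()].
#' @export
gate_steady_state <- function(params, V) {
  rt <- evaluate_rates(params, V)
  ss <- .chain_steady(rt)
  gate_state(Oa = ss[["Oa"]], C1a = ss[["C1a"]], C2a = ss[["C2a"]],
             h = rt$h_inf)
}

# unvalidated scalar-voltage rate evaluation for simulation inner loops;
# the exported evaluate_rates() is the checked public surface
.rates_fast <- function(p, V) {
  ah <- p[7] * exp(-p[8] * V); bh <- p[5] * exp(p[6] * V)
  s <- ah + bh
  list(a1 = p[1] * exp(p[2] * V), b1 = p[3] * exp(-p[4] * V),
       a2 = p[9] * exp(p[10] * V), b2 = p[11] * exp(-p[12] * V),
       ah = ah, bh = bh, h_inf = ah / s, tau_h = 1 / s)
}

# stationary distribution of the 3-state chain from spanning-tree weights;
# robust when single rates are zero, errors when a transition is cut.
.chain_steady <- function(rt) {
  if ((rt$a1 == 0 && rt$b1 == 0) || (rt$a2 == 0 && rt$b2 == 0))
    stop("degenerate-chain: both directions of one transition are zero")
  w_c2 <- rt$b1 * rt$b2
  w_c1 <- rt$a1 * rt$b2
  w_o  <- rt$a1 * rt$a2
  tot <- w_c2 + w_c1 + w_o
  if (tot == 0) stop("degenerate-chain: stationary state undefined")
  c(Oa = w_o / tot, C1a = w_c1 / tot, C2a = w_c2 / tot)
}

#' Time derivatives of the factorized gating system
#'
#' \deqn{\dot C_{1a} = b_2 O_a + a_1 C_{2a} - (a_2 + b_1) C_{1a},\quad
#'       \dot O_a = a_2 C_{1a} - b_2 O_a,\quad
#'       \dot h = (h_\infty - h)/\tau_h,}
#' with `C2a = 1 - Oa - C1a` algebraic.
#'
#' @inheritParams gate_steady_state
#' @param s a [gate_state()].
#' @param tol tolerance for the state-validity check.
#' @return named numeric `c(C1a=, Oa=, h=)` of time derivatives, ms^-1.
#' @export
gate_derivatives <- function(params, V, s, tol = 1e-8) {
  if (any(s < -tol) || any(s[c("Oa", "C1a", "C2a", "h")] > 1 + tol))
    stop("invalid-state: gate state outside [0, 1] beyond tolerance")
  rt <- evaluate_rates(params, V)
  dC1a <- rt$b2 * s[["Oa"]] + rt$a1 * s[["C2a"]] -
    (rt$a2 + rt$b1) * s[["C1a"]]
  dOa <- rt$a2 * s[["C1a"]] - rt$b2 * s[["Oa"]]
  dh <- (rt$h_inf - s[["h"]]) / rt$tau_h
  c(C1a = dC1a, Oa = dOa, h = dh)
}

#' Open probability of a gating state
#'
#' The conducting fraction is `O = Oa * h`: activated and not inactivated.
#'
#' @param s a [gate_state()].
#' @return open probability in `[0, 1]`.
#' @export
open_probability <- function(s) unname(s[["Oa"]] * s[["h"]])

#' Expand a factorized gating state to six Markov occupancies
#'
#' The Hodgkin-Huxley factorization is equivalent to a six-state Markov
#' model with states `O = Oa*h`, `IO = Oa*(1-h)`, `C1 = C1a*h`,
#' `IC1 = C1a*(1-h)`, `C2 = C2a*h`, `IC2 = C2a*(1-h)`.
#'
#' @param s a [gate_state()].
#' @return named numeric of class `markov_occupancy`.
#' @export
expand_to_markov <- function(s) {
  h <- s[["h"]]
  m <- c(O  = s[["Oa"]] * h,  IO  = s[["Oa"]] * (1 - h),
         C1 = s[["C1a"]] * h, IC1 = s[["C1a"]] * (1 - h),
         C2 = s[["C2a"]] * h, IC2 = s[["C2a"]] * (1 - h))
  structure(m, class = "markov_occupancy")
}

#' Collapse six Markov occupancies back to the factorized state
#'
#' Inverse of [expand_to_markov()]: `Oa = O + IO`, etc., and
#' `h = (O + C1 + C2)` (the total non-inactivated occupancy). The collapse
#' is exact whenever the occupancy is a product state, which the dynamics
#' preserve.
#'
#' @param m a `markov_occupancy`.
#' @return a [gate_state()].
#' @export
collapse_from_markov <- function(m) {
  gate_state(Oa = m[["O"]] + m[["IO"]],
             C1a = m[["C1"]] + m[["IC1"]],
             C2a = m[["C2"]] + m[["IC2"]],
             h = m[["O"]] + m[["C1"]] + m[["C2"]],
             tol = 1e-8)
}

#' Master-equation derivatives of the six-state Markov model
#'
#' Horizontal transitions C2 <-> C1 <-> O and IC2 <-> IC1 <-> IO carry the
#' activation rates (`a1`, `b1`, `a2`, `b2`); vertical transitions X <-> IX
#' carry inactivation (`bh`, down) and recovery (`ah`, up).
#'
#' @inheritParams gate_steady_state
#' @param m a `markov_occupancy` (components sum to 1).
#' @param tol state-validity tolerance.
#' @return named numeric of six time derivatives (ms^-1), summing to zero.
#' @export
markov_derivatives <- function(params, V, m, tol = 1e-8) {
  if (any(m < -tol) || any(m > 1 + tol))
    stop("invalid-state: occupancies outside [0, 1] beyond tolerance")
  rt <- evaluate_rates(params, V)
  Q <- markov_generator(rt)
  drop(Q %*% as.numeric(m[c("O", "IO", "C1", "IC1", "C2", "IC2")]))
}

# generator matrix (columns = from-state) in state order O, IO, C1, IC1, C2, IC2
markov_generator <- function(rt) {
  a1 <- rt$a1; b1 <- rt$b1; a2 <- rt$a2; b2 <- rt$b2
  ah <- rt$ah; bh <- rt$bh
  nm <- c("O", "IO", "C1", "IC1", "C2", "IC2")
  Q <- matrix(0, 6, 6, dimnames = list(nm, nm))
  hop <- function(from, to, rate) {
    Q[to, from] <<- Q[to, from] + rate
    Q[from, from] <<- Q[from, from] - rate
  }
  hop("C2", "C1", a1);  hop("C1", "C2", b1)
  hop("C1", "O", a2);   hop("O", "C1", b2)
  hop("IC2", "IC1", a1); hop("IC1", "IC2", b1)
  hop("IC1", "IO", a2);  hop("IO", "IC1", b2)
  for (s in c("O", "C1", "C2")) {
    is <- paste0("I", s)
    hop(s, is, bh); hop(is, s, ah)
  }
  Q
}
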