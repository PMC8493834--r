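#' Evaluate code with a private RNG stream
#'
#' Seeds the random number generator, evaluates `code`, and restores the
#' caller's RNG state, so deterministic data generation does not disturb
#' the surrounding session.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic cell
#'
#' Defines the ground truth of one simulated cell for the three-sweep
#' subtraction design: sweep 1 records channel current under control
#' kinetics plus leak plus noise, sweep 2 the same cell after wash-in of
#' the activator (activator kinetics), and sweep 3 after a full blocker
#' (leak and noise only). Noise is iid Gaussian, `N(0, sigma^2)`, at the
#' output sampling rate.
#'
#' @param kinetics_control,kinetics_rpr [herg_params()] for control and
#'   activator conditions.
#' @param g_kr maximal conductance, uS.
#' @param v_off voltage offset, mV.
#' @param noise_sd noise standard deviation sigma, nA (>= 0).
#' @param g_leak,E_leak linear leak conductance (uS) and reversal (mV).
#' @param rundown conductance rundown rate, fraction per minute, in
#'   `[0, 0.2]`; 0 disables rundown.
#' @param seed integer seed; a fixed seed makes the recording reproducible.
#' @param K_out,K_in,temperature bath/pipette K+ (mM) and temperature (K)
#'   defining the Nernst potential.
#' @return a list of class `synthetic_cell_spec`.
#' @export
synthetic_cell_spec <- function(kinetics_control, kinetics_rpr, g_kr,
                                v_off = 0, noise_sd = 0,
                                g_leak = 0, E_leak = -80,
                                rundown = 0, seed = 1L,
                                K_out = 4, K_in = 130,
                                temperature = 310.15) {
  stopifnot(inherits(kinetics_control, "herg_params"),
            inherits(kinetics_rpr, "herg_params"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (rundown < 0 || rundown > 0.2)
    stop("rundown rate must lie in [0, 0.2] per minute")
  structure(list(kinetics_control = kinetics_control,
                 kinetics_rpr = kinetics_rpr,
                 g_kr = g_kr, v_off = v_off, noise_sd = noise_sd,
                 g_leak = g_leak, E_leak = E_leak, rundown = rundown,
                 seed = as.integer(seed),
                 K_out = K_out, K_in = K_in, temperature = temperature),
            class = "synthetic_cell_spec")
}

#' Default protocol suite for synthetic recordings
#'
#' Calibration staircase (C), activation (V1), inactivation (V2), complex
#' action-potential train (V3), and a repeat of the staircase for quality
#' control.
#'
#' @param dt output sampling interval, ms.
#' @return named list of `voltage_protocol`s.
#' @export
default_protocol_suite <- function(dt = 0.1) {
  list(C = build_staircase_protocol(dt = dt),
       V1 = build_activation_protocol("hek_37C", dt = dt),
       V2 = build_inactivation_protocol_37C(dt = dt),
       V3 = build_complex_ap_protocol(dt = dt),
       C2 = build_staircase_protocol(dt = dt))
}

#' Generate a synthetic three-sweep recording for one cell
#'
#' Each sweep runs the whole protocol suite in order. Sweep 1 simulates
#' control kinetics, sweep 2 activator kinetics (same conductance), and
#' sweep 3 contains no channel current (full block), so that sweep 3 is the
#' channel-free reference for leak subtraction. If rundown is enabled the
#' conductance decays continuously with elapsed experiment time across
#' protocols and sweeps. The embedded `truth` also reports the cell's
#' apparent reversal potential `E_K + v_off`, which is what a reversal
#' measurement on its traces recovers.
#'
#' @param spec a [synthetic_cell_spec()].
#' @param protocols named list of `voltage_protocol`s (default
#'   [default_protocol_suite()]).
#' @param settings a [sim_settings()].
#' @return a list of class `sweep_set` with fields `sweep1`, `sweep2`,
#'   `sweep3` (each a named list of [current_trace()]s) and `truth`.
#' @export
generate_cell_recording <- function(spec, protocols = default_protocol_suite(),
                                    settings = sim_settings()) {
  stopifnot(inherits(spec, "synthetic_cell_spec"))
  if (length(protocols) == 0) stop("protocol list must be non-empty")
  if (is.null(names(protocols)) || any(!nzchar(names(protocols))))
    names(protocols) <- paste0("P", seq_along(protocols))
  E_K <- nernst_potential(spec$K_out, spec$K_in, spec$temperature)
  cell <- cell_config(g_kr = spec$g_kr, E_K = E_K, v_off = spec$v_off,
                      g_leak = spec$g_leak, E_leak = spec$E_leak)
  kin <- list(spec$kinetics_control, spec$kinetics_rpr, NULL)
  durations <- vapply(protocols, protocol_duration, 0)
  sweeps <- with_seed(spec$seed, {
    elapsed <- 0  # ms of experiment clock, across protocols and sweeps
    lapply(1:3, function(sw) {
      out <- lapply(seq_along(protocols), function(ip) {
        pr <- protocols[[ip]]
        vcmd <- voltage_at(pr, (seq_len(floor(protocol_duration(pr) /
          (if (is.null(settings$dt_out)) pr$dt else settings$dt_out) + 1e-9)) - 1) *
          (if (is.null(settings$dt_out)) pr$dt else settings$dt_out))
        leak <- spec$g_leak * (vcmd - spec$E_leak)
        if (is.null(kin[[sw]])) {
          chan <- numeric(length(vcmd))
          dt <- if (is.null(settings$dt_out)) pr$dt else settings$dt_out
        } else {
          tr <- simulate_current(kin[[sw]], pr, cell, settings,
                                 include_leak = FALSE)
          chan <- tr$current
          dt <- tr$dt
        }
        if (spec$rundown > 0) {
          tmin <- (elapsed + (seq_along(chan) - 1) * dt) / 60000
          chan <- chan * pmax(0, 1 - spec$rundown * tmin)
        }
        elapsed <<- elapsed + durations[ip]
        noise <- if (spec$noise_sd > 0)
          stats::rnorm(length(chan), 0, spec$noise_sd) else 0
        current_trace(chan + leak + noise, dt = dt, voltage = vcmd,
                      meta = list(protocol_id = pr$id, sweep = sw))
      })
      names(out) <- names(protocols)
      out
    })
  })
  truth <- spec
  truth$E_K <- E_K
  truth$E_K_measured <- E_K + spec$v_off
  structure(list(sweep1 = sweeps[[1]], sweep2 = sweeps[[2]],
                 sweep3 = sweeps[[3]], truth = truth,
                 protocols = protocols),
            class = "sweep_set")
}

#' Blocker subtraction of a three-sweep recording
#'
#' Subtracts the full-block sweep (3) from the control sweep (1) and the
#' activator sweep (2) pointwise per protocol, isolating channel current
#' from leak and endogenous components.
#'
#' @param s a `sweep_set`.
#' @return list with `control` and `rpr`, each a named list of
#'   [current_trace()]s.
#' @export
subtract_sweeps <- function(s) {
  stopifnot(inherits(s, "sweep_set"))
  sub1 <- function(a, b) {
    if (length(a$current) != length(b$current) ||
        abs(a$dt - b$dt) > 1e-12 || abs(a$t0 - b$t0) > 1e-12)
      stop("misaligned sweep grids")
    current_trace(a$current - b$current, dt = a$dt, t0 = a$t0,
                  voltage = a$voltage, meta = a$meta)
  }
  list(control = Map(sub1, s$sweep1, s$sweep3),
       rpr = Map(sub1, s$sweep2, s$sweep3))
}

#' Generate a cohort of synthetic cells with shared kinetics
#'
#' All cells share the base spec's kinetics; conductance and voltage offset
#' vary per cell. Conductances can be given explicitly (`g_values`) or drawn
#' log-normally around the base value with spread factor `g_spread`;
#' voltage offsets are drawn `N(0, voff_sd)`. Child seeds are derived
#' deterministically from `seed`.
#'
#' @param n_cells number of cells (>= 1).
#' @param base_spec a [synthetic_cell_spec()].
#' @param variability list with any of `g_values` (explicit conductances),
#'   `g_spread` (lognormal sdlog), `voff_sd` (mV), `voff_values`.
#' @param seed cohort seed.
#' @param protocols,settings passed to [generate_cell_recording()].
#' @return list of `sweep_set`s, one per cell.
#' @export
generate_cohort <- function(n_cells, base_spec,
                            variability = list(g_spread = 0, voff_sd = 0),
                            seed = base_spec$seed,
                            protocols = default_protocol_suite(),
                            settings = sim_settings()) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  gs <- variability$g_spread %||% 0
  vs <- variability$voff_sd %||% 0
  if (gs < 0 || vs < 0) stop("invalid spread: must be >= 0")
  draws <- with_seed(seed, list(
    g = if (!is.null(variability$g_values)) {
      if (length(variability$g_values) != n_cells)
        stop("g_values must have one value per cell")
      variability$g_values
    } else base_spec$g_kr * exp(stats::rnorm(n_cells, 0, gs)),
    voff = if (!is.null(variability$voff_values)) variability$voff_values
           else stats::rnorm(n_cells, 0, vs)))
  lapply(seq_len(n_cells), function(i) {
    sp <- base_spec
    sp$g_kr <- draws$g[i]
    sp$v_off <- draws$voff[i]
    sp$seed <- as.integer((seed + 7919 * i) %% 2147483647)
    sp$cell_id <- i
    generate_cell_recording(sp, protocols, settings)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a synthetic cell recording
#'
#' Serializes one cell to a directory: each sweep's traces as CSV files
#' plus a JSON ground-truth block.
#'
#' @param s a `sweep_set`.
#' @param dir output directory (created if needed).
#' @export
write_sweepset <- function(s, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sw in 1:3) for (nm in names(s[[paste0("sweep", sw)]]))
    write_trace_csv(s[[paste0("sweep", sw)]][[nm]],
                    file.path(dir, sprintf("sweep%d_%s.csv", sw, nm)))
  tr <- s$truth
  truth <- list(g_kr = tr$g_kr, v_off = tr$v_off, noise_sd = tr$noise_sd,
                g_leak = tr$g_leak, E_leak = tr$E_leak, rundown = tr$rundown,
                seed = tr$seed, K_out = tr$K_out, K_in = tr$K_in,
                temperature = tr$temperature, E_K = tr$E_K,
                E_K_measured = tr$E_K_measured,
                kinetics_control = as.list(tr$kinetics_control$p),
                kinetics_rpr = as.list(tr$kinetics_rpr$p))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_sweepset
#' @export
read_sweepset <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  files <- list.files(dir, pattern = "^sweep[123]_.*\\.csv$")
  pid <- unique(sub("^sweep[123]_(.*)\\.csv$", "\\1", files))
  sweeps <- lapply(1:3, function(sw) {
    out <- lapply(pid, function(nm)
      read_trace_csv(file.path(dir, sprintf("sweep%d_%s.csv", sw, nm))))
    names(out) <- pid
    out
  })
  spec <- synthetic_cell_spec(
    herg_params(unlist(truth$kinetics_control), label = "control"),
    herg_params(unlist(truth$kinetics_rpr), label = "rpr"),
    g_kr = truth$g_kr, v_off = truth$v_off, noise_sd = truth$noise_sd,
    g_leak = truth$g_leak, E_leak = truth$E_leak, rundown = truth$rundown,
    seed = truth$seed, K_out = truth$K_out, K_in = truth$K_in,
    temperature = truth$temperature)
  spec$E_K <- truth$E_K
  spec$E_K_measured <- truth$E_K_measured
  structure(list(sweep1 = sweeps[[1]], sweep2 = sweeps[[2]],
                 sweep3 = sweeps[[3]], truth = spec, protocols = NULL),
            class = "sweep_set")
}
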