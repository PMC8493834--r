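#' Pipeline configuration
#'
#' Fully serializable description of a characterization run: construct,
#' cohort size, noise and variability, seeds, fitter settings and problem
#' sizes. A saved configuration re-runs to identical outputs given
#' identical seeds.
#'
#' @param construct `"WT"` or `"R56Q"` (selects the bundled reference
#'   kinetics for the generator).
#' @param n_cells cohort size.
#' @param seed master seed.
#' @param noise_frac noise SD as a fraction of each cell's peak staircase
#'   current.
#' @param voff_sd per-cell voltage-offset SD, mV.
#' @param g_values explicit per-cell conductances, uS (`NULL` draws them).
#' @param g_spread lognormal conductance spread when `g_values` is `NULL`.
#' @param dt generation sampling interval, ms.
#' @param thin fitting-grid thinning factor.
#' @param n_starts optimizer multi-starts.
#' @param cma_gens CMA-ES generation budget for the deep global-search
#'   phase (see [fit_settings()]).
#' @param out_dir optional output directory for report CSVs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(construct = "WT", n_cells = 3, seed = 1L,
                            noise_frac = 0.02, voff_sd = 1,
                            g_values = NULL, g_spread = 0.2,
                            dt = 0.5, thin = 2L, n_starts = 10,
                            cma_gens = 250, out_dir = NULL) {
  structure(list(construct = construct, n_cells = n_cells,
                 seed = as.integer(seed), noise_frac = noise_frac,
                 voff_sd = voff_sd, g_values = g_values,
                 g_spread = g_spread, dt = dt, thin = thin,
                 n_starts = n_starts, cma_gens = cma_gens,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Noise SD calibrated to a fraction of the peak staircase current
#'
#' @param params kinetics used for the noise-free simulation.
#' @param g_kr cell conductance, uS.
#' @param noise_frac fraction of the peak absolute staircase current.
#' @param protocol staircase protocol (default built-in).
#' @param E_K reversal potential, mV.
#' @param dt sampling interval, ms.
#' @return noise SD, nA.
#' @export
staircase_noise_sd <- function(params, g_kr, noise_frac,
                               protocol = build_staircase_protocol(),
                               E_K = nernst_potential(4, 130, 310.15),
                               dt = 0.5) {
  cc <- cell_config(g_kr = g_kr, E_K = E_K)
  tr <- simulate_current(params, protocol, cc, sim_settings(dt_out = dt))
  noise_frac * max(abs(tr$current))
}

#' One-command synthetic characterization run
#'
#' Reproduces the computational arc of a rapid-characterization experiment
#' on synthetic data: generate a three-sweep cohort, blocker-subtract, fit
#' the joint model on the staircase calibration protocol only, predict the
#' held-out validation protocols (activation V1, inactivation V2, complex
#' AP train V3), and compute biomarker phenotypes. Deterministic under a
#' fixed seed.
#'
#' @param config a [pipeline_config()].
#' @return list of class `characterization_report`: `recovery` (table of
#'   true vs fitted kinetic parameters), `conductances`, `prediction`
#'   (per cell/protocol normalized RMSE vs the noise floor), `qc`
#'   (staircase-repeat drift), `phenotypes` (deactivation time constants
#'   and AP-clamp metrics for fitted control vs activator kinetics),
#'   `config`, `fit`.
#' @export
run_characterization <- function(config = pipeline_config()) {
  ctrl_name <- config$construct
  rpr_name <- paste0(config$construct, "+RPR")
  kin_c <- herg_reference_params(ctrl_name)
  kin_r <- herg_reference_params(rpr_name)
  g_vals <- config$g_values %||%
    herg_reference_conductances(config$construct)
  if (length(g_vals) != config$n_cells)
    g_vals <- rep_len(g_vals, config$n_cells)
  E_K <- nernst_potential(4, 130, 310.15)

  protos <- default_protocol_suite(dt = config$dt)
  base <- synthetic_cell_spec(kin_c, kin_r, g_kr = g_vals[1],
                              noise_sd = 0, seed = config$seed)
  cohort <- generate_cohort(
    config$n_cells, base,
    variability = list(g_values = g_vals, voff_sd = config$voff_sd),
    seed = config$seed, protocols = protos,
    settings = sim_settings(dt_out = config$dt))
  # per-cell noise: a fixed fraction of that cell's peak staircase current
  cohort <- lapply(seq_along(cohort), function(i) {
    sp <- cohort[[i]]$truth
    sp$noise_sd <- staircase_noise_sd(kin_c, sp$g_kr, config$noise_frac,
                                      protos$C, E_K, config$dt)
    generate_cell_recording(sp, protos,
                            settings = sim_settings(dt_out = config$dt))
  })

  dataset <- build_joint_dataset(cohort, "C", thin = config$thin)
  fit <- fit_joint(dataset,
                   fit_settings(n_starts = config$n_starts,
                                deep_gens = config$cma_gens,
                                screen_gens = min(220, config$cma_gens),
                                seed = config$seed))

  recovery <- data.frame(
    parameter = rep(paste0("p", 1:12), 2),
    block = rep(c("control", "rpr"), each = 12),
    true = c(kin_c$p, kin_r$p),
    fitted = c(fit$theta_control$p, fit$theta_rpr$p))
  recovery$rel_err <- abs(recovery$fitted - recovery$true) / recovery$true
  conductances <- data.frame(
    cell = seq_len(config$n_cells),
    true = vapply(cohort, function(s) s$truth$g_kr, 0),
    fitted = fit$g_kr)
  conductances$rel_err <- abs(conductances$fitted - conductances$true) /
    conductances$true

  prediction <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    sub <- subtract_sweeps(s)
    voff <- fit$v_off[i]
    cc <- cell_config(g_kr = fit$g_kr[i], E_K = E_K, v_off = voff)
    do.call(rbind, lapply(c("V1", "V2", "V3"), function(pn) {
      do.call(rbind, lapply(c("control", "rpr"), function(cond) {
        prm <- if (cond == "control") fit$theta_control else fit$theta_rpr
        pred <- simulate_current(prm, protos[[pn]], cc,
                                 sim_settings(dt_out = config$dt),
                                 include_leak = FALSE)
        obs <- sub[[cond]][[pn]]
        rmse <- sqrt(mean((pred$current - obs$current)^2))
        floor_sd <- s$truth$noise_sd * sqrt(2)
        data.frame(cell = i, protocol = pn, condition = cond,
                   rmse = rmse, noise_floor = floor_sd,
                   rmse_over_floor = rmse / floor_sd)
      }))
    }))
  }))

  qc <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    sub <- subtract_sweeps(cohort[[i]])
    q <- staircase_qc_check(sub$control$C, sub$control$C2,
                            noise_sd = cohort[[i]]$truth$noise_sd * sqrt(2))
    data.frame(cell = i, drift = q$drift, pass = q$pass)
  }))

  phenotypes <- .phenotype_table(fit$theta_control, fit$theta_rpr,
                                 E_K = E_K, dt = config$dt)

  report <- structure(list(recovery = recovery, conductances = conductances,
                           prediction = prediction, qc = qc,
                           phenotypes = phenotypes, config = config,
                           fit = fit),
                      class = "characterization_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("recovery", "conductances", "prediction", "qc", "phenotypes"))
      utils::write.csv(report[[nm]],
                       file.path(config$out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  report
}

# deactivation and AP-clamp phenotype comparison at equal conductance
.phenotype_table <- function(theta_control, theta_rpr, E_K, dt = 0.5,
                             g = 0.1) {
  dea <- build_deactivation_protocol(-60, dt = dt)
  tr_ap <- build_ap_train_protocol(rate_hz = 1, n_beats = 3, dt = dt)
  cc <- cell_config(g_kr = g, E_K = E_K)
  row <- function(label, prm) {
    trc <- simulate_current(prm, dea, cc, sim_settings(dt_out = dt),
                            include_leak = FALSE)
    w <- .segment_window(dea, 1, 2)
    ft <- fit_exponential_decay(trc, n_terms = 2,
                                window = c(w[1] + 5, w[2]))
    apc <- simulate_current(prm, tr_ap, cc, sim_settings(dt_out = dt),
                            include_leak = FALSE, reset_between_sweeps = FALSE)
    m <- measure_ap_clamp_metrics(apc, tr_ap)
    data.frame(condition = label, tau_f = ft$tau_f, tau_s = ft$tau_s,
               fast_fraction = ft$fast_fraction,
               peak_transient = m$peak_transient,
               peak_resurgent = m$peak_resurgent,
               peak_voltage = m$peak_voltage)
  }
  rbind(row("control", theta_control), row("rpr", theta_rpr))
}

#' Export a fitted model as a self-contained description
#'
#' Writes the rate expressions and parameter values as JSON (or a
#' plain-text equation listing) suitable for embedding the channel model in
#' an external action-potential simulator. The JSON form round-trips
#' through [read_params_json()].
#'
#' @param x an `inference_result` or a [herg_params()].
#' @param path output file.
#' @param format `"json"` or `"txt"`.
#' @param which for an `inference_result`: `"control"` or `"rpr"` block.
#' @return `path`, invisibly.
#' @export
export_model <- function(x, path, format = c("json", "txt"),
                         which = c("control", "rpr")) {
  format <- match.arg(format)
  if (inherits(x, "inference_result"))
    x <- if (match.arg(which) == "control") x$theta_control else x$theta_rpr
  stopifnot(inherits(x, "herg_params"))
  exprs <- c(a1 = "a1 = p1 * exp( p2 * V)   # C2 -> C1 (activation)",
             b1 = "b1 = p3 * exp(-p4 * V)   # C1 -> C2 (deactivation)",
             a2 = "a2 = p9 * exp( p10 * V)  # C1 -> O  (activation)",
             b2 = "b2 = p11 * exp(-p12 * V) # O  -> C1 (deactivation)",
             bh = "bh = p5 * exp( p6 * V)   # X  -> IX (inactivation)",
             ah = "ah = p7 * exp(-p8 * V)   # IX -> X  (recovery)")
  if (format == "json") {
    out <- c(as.list(x$p),
             list(label = x$label,
                  model = "IKr = g_Kr * Oa * h * (V - E_K)",
                  rates = as.list(unname(exprs)),
                  units = list(time = "ms", voltage = "mV",
                               rates = "ms^-1", conductance = "uS",
                               current = "nA")))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    lines <- c("# IKr channel model: IKr = g_Kr * Oa * h * (V - E_K)",
               "# dC1a/dt = b2*Oa + a1*C2a - (a2 + b1)*C1a",
               "# dOa/dt  = a2*C1a - b2*Oa ;  C2a = 1 - Oa - C1a",
               "# dh/dt   = (h_inf - h)/tau_h ; h_inf = ah/(ah+bh) ; tau_h = 1/(ah+bh)",
               unname(exprs), "",
               sprintf("%s = %.12g", names(x$p), x$p),
               if (nzchar(x$label)) paste0("label = ", x$label))
    writeLines(lines, path)
  }
  invisible(path)
}
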