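#' Kinetic parameter sets for the hERG gating model
#'
#' A `herg_params` object holds the twelve kinetic parameters `p1`..`p12`
#' that define the six voltage-dependent transition rates of the gating
#' model (see [evaluate_rates()]). Odd-indexed parameters (`p1`, `p3`, `p5`,
#' `p7`, `p9`, `p11`) are rate prefactors in ms^-1; even-indexed parameters
#' (`p2`, `p4`, `p6`, `p8`, `p10`, `p12`) are voltage slopes in mV^-1.
#'
#' @param p numeric vector of length 12 (named or positional, `p1`..`p12`).
#' @param label free-text label (construct / condition), e.g. `"WT"`.
#' @param validate check invariants (positivity, finiteness, plausibility
#'   of the evaluated rates over `v_range`).
#' @param band two-element numeric: plausibility band for every evaluated
#'   rate, in ms^-1. Default `c(1e-7, 1e3)`.
#' @param v_range voltage range (mV) over which the band is enforced.
#' @return an object of class `herg_params`.
#' @export
herg_params <- function(p, label = "", validate = TRUE,
                        band = c(1e-7, 1e3), v_range = c(-120, 60)) {
  p <- as.numeric(p)
  if (length(p) != 12L)
    stop("a kinetic parameter set has exactly 12 parameters, got ", length(p))
  names(p) <- paste0("p", 1:12)
  obj <- structure(list(p = p, label = as.character(label)[1]),
                   class = "herg_params")
  if (validate) {
    if (any(!is.finite(p)))
      stop("non-finite kinetic parameter(s): ",
           paste(names(p)[!is.finite(p)], collapse = ", "))
    odd <- seq(1, 11, by = 2)
    even <- seq(2, 12, by = 2)
    if (any(p[odd] <= 0))
      stop("rate prefactors must be strictly positive: ",
           paste(names(p)[odd][p[odd] <= 0], collapse = ", "))
    if (any(p[even] < 0))
      stop("voltage slopes must be >= 0: ",
           paste(names(p)[even][p[even] < 0], collapse = ", "))
    chk <- check_rate_band(obj, band = band, v_range = v_range)
    if (!chk$ok)
      stop("rate plausibility violated: ", chk$detail)
  }
  obj
}

#' @export
print.herg_params <- function(x, ...) {
  cat("<herg_params>", if (nzchar(x$label)) paste0(" ", x$label), "\n", sep = "")
  pf <- x$p[seq(1, 11, 2)]
  sl <- x$p[seq(2, 12, 2)]
  cat("  prefactors (ms^-1): ",
      paste(sprintf("%s=%.3g", names(pf), pf), collapse = " "), "\n")
  cat("  slopes     (mV^-1): ",
      paste(sprintf("%s=%.3g", names(sl), sl), collapse = " "), "\n")
  invisible(x)
}

#' Check that all six rates stay inside a plausibility band
#'
#' Evaluates the six transition rates on a voltage grid and checks that each
#' lies within `band` everywhere. Rejection (not clipping) of implausible
#' rate sets is standard practice when fitting this model family.
#'
#' @inheritParams herg_params
#' @param params a `herg_params` object.
#' @param n_grid number of voltages in the check grid.
#' @return list with elements `ok` (logical) and `detail` (character).
#' @export
check_rate_band <- function(params, band = c(1e-7, 1e3),
                            v_range = c(-120, 60), n_grid = 41L) {
  v <- seq(v_range[1], v_range[2], length.out = n_grid)
  rt <- evaluate_rates(params, v)
  bad <- character(0)
  for (nm in c("a1", "b1", "a2", "b2", "ah", "bh")) {
    r <- rt[[nm]]
    if (any(r < band[1]) || any(r > band[2])) {
      i <- which(r < band[1] | r > band[2])[1]
      bad <- c(bad, sprintf("%s = %.3g ms^-1 at %g mV", nm, r[i], v[i]))
    }
  }
  list(ok = length(bad) == 0L, detail = paste(bad, collapse = "; "))
}

# Bundled reference kinetics (WT / R56Q hERG1a, with and without the
# activator RPR260243, inferred at physiological temperature). Shipped as
# JSON under inst/extdata/params/.
.bundled_param_files <- c(
  "WT"        = "wt.json",
  "WT+RPR"    = "wt_rpr.json",
  "R56Q"      = "r56q.json",
  "R56Q+RPR"  = "r56q_rpr.json"
)

#' Load a bundled reference kinetic parameter set
#'
#' Four reference parameter sets ship with the package: wild-type (`"WT"`)
#' and LQTS2-associated R56Q mutant (`"R56Q"`) hERG1a kinetics, each in
#' control conditions and in the presence of the type I activator RPR260243
#' (`"WT+RPR"`, `"R56Q+RPR"`).
#'
#' @param name one of `"WT"`, `"WT+RPR"`, `"R56Q"`, `"R56Q+RPR"`.
#' @return a `herg_params` object.
#' @export
herg_reference_params <- function(name = c("WT", "WT+RPR", "R56Q", "R56Q+RPR")) {
  name <- match.arg(name)
  path <- system.file("extdata", "params", .bundled_param_files[[name]],
                      package = "hergkinetics", mustWork = TRUE)
  read_params_json(path)
}

#' Reference whole-cell conductances for the bundled parameter sets
#'
#' Cell-specific maximal conductances (microsiemens) of the three cells used
#' to infer each construct's kinetics.
#'
#' @param construct `"WT"` or `"R56Q"`.
#' @return named numeric vector of length 3.
#' @export
herg_reference_conductances <- function(construct = c("WT", "R56Q")) {
  construct <- match.arg(construct)
  switch(construct,
    "WT"   = c(cell1 = 8.47e-2, cell2 = 7.05e-2, cell3 = 1.23e-1),
    "R56Q" = c(cell1 = 7.96e-2, cell2 = 1.03e-1, cell3 = 4.33e-2))
}

#' Read / write kinetic parameter sets as flat JSON
#'
#' The on-disk format is a flat object `{"p1": ..., ..., "p12": ..., "label": ...}`.
#'
#' @param path file path.
#' @param params a `herg_params` object (for writing).
#' @param validate validate on read (see [herg_params()]).
#' @return `read_params_json` returns a `herg_params`; `write_params_json`
#'   returns `path` invisibly.
#' @export
read_params_json <- function(path, validate = TRUE) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- paste0("p", 1:12)
  if (!all(need %in% names(x)))
    stop("parameter JSON must contain fields p1..p12; missing: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  herg_params(unlist(x[need]), label = if (is.null(x$label)) "" else x$label,
              validate = validate)
}

#' @rdname read_params_json
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "herg_params"))
  x <- c(as.list(params$p), list(label = params$label))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
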