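# Scenario definitions: wild-type and perturbation experiments.

#' Names of the built-in simulation scenarios
#'
#' @return Character vector of valid scenario names.
#' @export
scenario_names <- function() {
  c("wild_type_cib", "ipl1_homogeneous", "ipl1_heterogeneous",
    "bim1_delta", "dyn1_oe", "dynein_puncta_scan")
}

#' Define a simulation scenario
#'
#' A scenario bundles a named perturbation of the wild-type model with
#' replicate bookkeeping. The built-in scenarios are:
#'
#' * `wild_type_cib` — cortical interaction with bias, unmodified parameters.
#' * `ipl1_homogeneous` — Ipl1 depletion as a homogeneous population: every
#'   cell gets the characteristic mutant catastrophe rate (default chosen so
#'   the free-space mean cMT length is 1.3 um), uniform cortical bias.
#' * `ipl1_heterogeneous` — Ipl1 depletion as a heterogeneous population:
#'   per-cell catastrophe frequency drawn uniformly from
#'   `[f_c_min, f_c_max]` (1-21 per min), with the exponential
#'   length-dependent reduction of the cortical bias enabled. The per-cell
#'   bias scale attenuates the whole mother-cortex interaction and the
#'   daughter dynein pull (dynein/Bim1 are delocalised under Ipl1
#'   depletion), and the daughter dynein onset is delayed to budding
#'   index 0.7.
#' * `bim1_delta` — Bim1 deletion: `lambda_bim1 = 0`.
#' * `dyn1_oe` — dynein overexpression: mother-cortex dynein density
#'   multiplied by `dyn1_oe_factor` (default 3).
#' * `dynein_puncta_scan` — punctate daughter-cortex dynein program with a
#'   condensed patch (`lambda_dynein_patch`) and background
#'   (`lambda_dynein_rest`) multiplier, typically driven over a grid by
#'   [run_scan()].
#'
#' @param name One of [scenario_names()].
#' @param overrides Named list of `sim_params` overrides applied on top of
#'   the scenario's own perturbation (validated; unknown names rejected).
#' @param n_reps Replicate (cell) count, >= 1.
#' @param seed Base random seed; cell i uses `seed + i - 1`.
#' @param cutoff_min Migration censoring cutoff in minutes (default 60).
#' @return An object of class `sim_scenario`.
#' @examples
#' make_scenario("wild_type_cib", n_reps = 10, seed = 1)
#' make_scenario("bim1_delta")$param_overrides$lambda_bim1  # 0
#' @export
make_scenario <- function(name, overrides = list(), n_reps = 100L,
                          seed = 1L, cutoff_min = 60) {
  if (!name %in% scenario_names()) {
    stop("unknown scenario name: '", name, "'. Known scenarios: ",
         paste(scenario_names(), collapse = ", "), call. = FALSE)
  }
  if (n_reps < 1) stop("replicate count must be >= 1", call. = FALSE)
  base <- default_params()
  unknown <- setdiff(names(overrides), names(base))
  if (length(unknown) > 0) {
    stop("overrides touch unknown parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sc_overrides <- switch(name,
    wild_type_cib = list(),
    ipl1_homogeneous = list(f_c = 8.0),
    # the diminishing effective bias is mediated by Bim1 AND mother dynein;
    # daughter-bud dynein puncta are delayed/aberrant under Ipl1 depletion
    ipl1_heterogeneous = list(bias_scales_dynein = TRUE,
                              daughter_dynein_onset_bi = 0.7),
    bim1_delta = list(lambda_bim1 = 0),
    dyn1_oe = list(),
    dynein_puncta_scan = list()
  )
  merged <- utils::modifyList(base, utils::modifyList(sc_overrides,
                                                      as.list(overrides)))
  structure(list(
    name = name,
    param_overrides = utils::modifyList(sc_overrides, as.list(overrides)),
    n_reps = as.integer(n_reps),
    seed = as.integer(seed),
    cutoff_min = cutoff_min,
    fc_range = if (name == "ipl1_heterogeneous") c(merged$f_c_min, merged$f_c_max) else NULL,
    length_dependent_bias = name == "ipl1_heterogeneous",
    mother_dyn_mult = if (name == "dyn1_oe") NA_real_ else 1,
    punctate = name == "dynein_puncta_scan"
  ), class = "sim_scenario")
}

#' Resolve a scenario into concrete per-run parameters
#'
#' Applies the scenario's parameter overrides to a base parameter set without
#' mutating it (isolation across replicates).
#'
#' @param scenario A `sim_scenario`.
#' @param params Base `sim_params` (default: full defaults).
#' @return A `sim_params` object.
#' @keywords internal
scenario_params <- function(scenario, params = sim_params()) {
  stopifnot(inherits(scenario, "sim_scenario"))
  ov <- scenario$param_overrides
  if (length(ov) == 0) return(params)
  sim_params(utils::modifyList(unclass(params), ov))
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("<sim_scenario> ", x$name, ": ", x$n_reps, " cells, seed ", x$seed,
      ", cutoff ", x$cutoff_min, " min\n", sep = "")
  if (length(x$param_overrides) > 0) {
    cat("  overrides: ",
        paste(names(x$param_overrides), unlist(x$param_overrides),
              sep = " = ", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
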