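# Model parameters and configuration handling.
#
# Units follow field convention: lengths um, forces pN, stiffnesses pN/um,
# viscosities pN s/um^2, MT speeds um/min, catastrophe/rescue rates 1/min
# (except f_c_stall, which is conventionally quoted in 1/s), times in min.
# Everything is converted to a um-pN-s system internally before simulation.

#' Default model parameter values
#'
#' Published measurements and model constants, plus gap-filling defaults for
#' quantities the underlying mechanical model leaves open (cortex width,
#' integration step, bud growth schedule, kMT length-catastrophe slope,
#' bias length constant, cMT count per MTOC, neck geometry). Gap defaults are
#' flagged in the parameter documentation of [sim_params()].
#'
#' @return Named list of default parameter values.
#' @keywords internal
default_params <- function() {
  list(
    # counts and geometry
    n_kt = 14L,                 # kinetochores (= founding MTOCs)
    r_mother = 3.0,             # um
    r_nuc = 1.0,                # um
    r_spb = 0.125,              # um, single founding MTOC/SPB
    r_kt = 0.1,                 # um (gap default)
    # mechanics
    k_cor = 5.0,                # pN/um, cortex stiffness
    eta_cyt = 5.0,              # pN s/um^2
    eta_nu = 10.0,              # pN s/um^2, nucleoplasm
    eta_ne = 10.0,              # pN s/um^2, effective NE viscosity
    # microtubule dynamic instability
    v_g = 10.4,                 # um/min
    v_s = 28.6,                 # um/min
    f_c = 1.0,                  # 1/min (wild-type)
    f_c_min = 1.0,              # 1/min, mutant range lower edge
    f_c_max = 21.0,             # 1/min, mutant range upper edge
    f_r = 0.02,                 # 1/min
    f_c_stall = 0.04,           # 1/s (!)
    f_stall = 1.7,              # pN
    # cortical force generators
    f_dyn = 1.0,                # pN per dynein
    lambda_dyn = 6.0,           # 1/um
    lambda_bim1 = 6.0,          # 1/um (gap default: = lambda_dyn)
    f_wall = 1.0,               # pN, wall impulse
    # spindle
    lambda_ipmt = 1.0,          # 1/um
    f_kinesin5 = 1.0,           # pN
    k_cohesion = 0.1,           # pN/um
    k_c = 10.0,                 # pN/um, kMT tip - KT spring
    k_fibril = 5.0,             # pN/um, KT fibril
    c_kt_repulsion = 1.0,       # pN/um, KT hard-core repulsion
    h_kmt = 85.0,               # 1/(min um) (gap default; see vignette)
    # model-gap geometry / numerics
    w_cor = 0.3,                # um (gap default)
    dt = 0.05,                  # s (gap default)
    neck_fraction = 0.6,        # neck radius / bud radius (gap default)
    final_budding_index = 0.8,  # dimensionless (gap default, calibrated)
    bud_growth_duration = 46.0, # min (gap default, calibrated)
    sliding_angle_deg = 50.0,   # cortex sliding threshold (gap default)
    kappa_mt = 9 / pi^2,        # pN um^2; buckling force 1 pN at l = 3 um
    n_cmt_per_mtoc = 2L,        # gap default
    n_ipmt_per_spb = 2L,        # gap default
    # cortical bias
    bias_length_const = 0.65,   # um (gap default, calibrated)
    l_wt_ref = 2.63,            # um, wild-type reference mean cMT length
    bias_scales_dynein = FALSE, # scale mother dynein pull by the bias too?
    # punctate dynein program (daughter cortex)
    lambda_dynein_patch = 1.0,  # multiplier of lambda_dyn inside the patch
    lambda_dynein_rest = 1.0,   # multiplier outside the patch
    patch_area_frac = 0.1,      # patch solid angle as fraction of bud cortex
    dyn1_oe_factor = 3.0,       # mother dynein multiplier for overexpression
    daughter_dynein_onset_bi = 0.55, # budding index at which daughter-cortex
                                # dynein puncta appear (large-budded stage)
    # observables / run control
    migration_threshold_factor = 1.0, # threshold = factor * r_nuc past the neck
    sample_interval = 5.0,      # s, trajectory sampling
    nucleus_drag_medium = "cytoplasm" # or "envelope"
  )
}

#' Construct a validated set of simulation parameters
#'
#' Builds the full parameter set for the mitosis simulator: cell and nuclear
#' geometry, microtubule dynamic instability rates, cortical force-generator
#' densities, spindle spring constants, and the numerical/gap defaults that
#' the mechanical model leaves open. Any subset of parameters may be
#' overridden by name; the rest take their documented defaults.
#'
#' Unit conventions: lengths in um, forces in pN, stiffnesses pN/um,
#' viscosities pN s/um^2, speeds um/min, rates 1/min (`f_c_stall` in 1/s),
#' durations in min. [params_internal()] converts to a consistent um-pN-s
#' system for the integrator.
#'
#' @param ... Named parameter overrides (see [default_params()] for names).
#' @return An object of class `sim_params` (named list).
#' @examples
#' p <- sim_params()
#' p$v_g            # 10.4 um/min
#' sim_params(n_kt = 4, f_c = 2)$f_c
#' @export
sim_params <- function(...) {
  defaults <- default_params()
  overrides <- list(...)
  if (length(overrides) == 1 && is.null(names(overrides)) &&
      is.list(overrides[[1]])) {
    overrides <- overrides[[1]]
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p <- utils::modifyList(defaults, overrides)
  p$n_kt <- as.integer(p$n_kt)
  p$n_cmt_per_mtoc <- as.integer(p$n_cmt_per_mtoc)
  p$n_ipmt_per_spb <- as.integer(p$n_ipmt_per_spb)
  validate_params(p)
  structure(p, class = "sim_params")
}

#' @keywords internal
validate_params <- function(p) {
  pos <- c("r_mother", "r_nuc", "r_spb", "r_kt", "k_cor", "eta_cyt", "eta_nu",
           "eta_ne", "v_g", "v_s", "f_c", "f_r", "f_c_stall", "f_stall",
           "f_dyn", "lambda_dyn", "lambda_ipmt", "f_kinesin5", "k_cohesion",
           "k_c", "k_fibril", "c_kt_repulsion", "w_cor", "dt", "h_kmt",
           "bud_growth_duration", "bias_length_const", "l_wt_ref", "kappa_mt",
           "neck_fraction", "sample_interval")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop("parameter '", nm, "' must be a single positive number, got ",
           format(p[[nm]]), call. = FALSE)
    }
  }
  nonneg <- c("lambda_bim1", "lambda_dynein_patch", "lambda_dynein_rest",
              "f_wall")
  for (nm in nonneg) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      stop("parameter '", nm, "' must be a single non-negative number, got ",
           format(p[[nm]]), call. = FALSE)
    }
  }
  if (p$n_kt < 1) stop("parameter 'n_kt' must be >= 1, got ", p$n_kt,
                       call. = FALSE)
  if (p$r_nuc >= p$r_mother) {
    stop("invariant violated: r_nuc (", p$r_nuc,
         ") must be smaller than r_mother (", p$r_mother, ")", call. = FALSE)
  }
  if (p$r_spb >= p$r_nuc) {
    stop("invariant violated: r_spb (", p$r_spb,
         ") must be smaller than r_nuc (", p$r_nuc, ")", call. = FALSE)
  }
  if (p$final_budding_index <= 0 || p$final_budding_index > 1) {
    stop("invariant violated: final_budding_index must be in (0, 1], got ",
         p$final_budding_index, call. = FALSE)
  }
  if (p$daughter_dynein_onset_bi < 0 || p$daughter_dynein_onset_bi > 1) {
    stop("invariant violated: daughter_dynein_onset_bi must be in [0, 1], got ",
         p$daughter_dynein_onset_bi, call. = FALSE)
  }
  if (p$f_c_min > p$f_c_max) {
    stop("invariant violated: f_c_min (", p$f_c_min,
         ") must not exceed f_c_max (", p$f_c_max, ")", call. = FALSE)
  }
  if (!p$nucleus_drag_medium %in% c("cytoplasm", "envelope")) {
    stop("nucleus_drag_medium must be 'cytoplasm' or 'envelope'",
         call. = FALSE)
  }
  invisible(p)
}

#' Load simulation parameters from a configuration document
#'
#' Parses a flat YAML key-value document of parameter overrides; keys absent
#' from the document take the documented defaults, unknown keys are rejected.
#'
#' @param config Either a YAML string or a path to a YAML file. An empty
#'   document yields the full default parameter set.
#' @return A `sim_params` object.
#' @examples
#' load_params("n_kt: 14\nf_c: 2.0")
#' @export
load_params <- function(config = "") {
  if (length(config) == 1 && !grepl("[:\n]", config) && file.exists(config)) {
    vals <- yaml::read_yaml(config)
  } else {
    vals <- yaml::yaml.load(paste(config, collapse = "\n"))
  }
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) {
    stop("configuration must be a flat key-value document", call. = FALSE)
  }
  sim_params(vals)
}

#' Serialize simulation parameters to a configuration document
#'
#' @param params A `sim_params` object.
#' @return A YAML string; `load_params()` of this string reproduces the
#'   identical parameter set (round trip).
#' @export
serialize_params <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  yaml::as.yaml(unclass(params), precision = 15)
}

#' Convert parameters to the internal um-pN-s unit system
#'
#' Per-minute rates and speeds are converted to per-second; durations to
#' seconds. Used by the integrator core; exposed for inspection.
#'
#' @param params A `sim_params` object.
#' @return Named list with additional `*_s` fields (`v_g_s`, `v_s_s`,
#'   `f_c_s`, `f_r_s`, `h_kmt_s`, `bud_growth_s`) and derived geometry
#'   (`sliding_angle_rad`, `patch_cos`, `migration_threshold`,
#'   `eta_nucleus`).
#' @export
params_internal <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- unclass(params)
  p$v_g_s <- p$v_g / 60
  p$v_s_s <- p$v_s / 60
  p$f_c_s <- p$f_c / 60
  p$f_r_s <- p$f_r / 60
  p$h_kmt_s <- p$h_kmt / 60
  p$bud_growth_s <- p$bud_growth_duration * 60
  p$sliding_angle_rad <- p$sliding_angle_deg * pi / 180
  p$patch_cos <- 1 - 2 * p$patch_area_frac
  p$migration_threshold <- p$migration_threshold_factor * p$r_nuc
  p$eta_nucleus <- if (p$nucleus_drag_medium == "cytoplasm") p$eta_cyt else p$eta_ne
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> ", x$n_kt, " kinetochores/MTOCs; mother r = ",
      x$r_mother, " um; v_g/v_s = ", x$v_g, "/", x$v_s,
      " um/min; f_c = ", x$f_c, "/min\n", sep = "")
  invisible(x)
}
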