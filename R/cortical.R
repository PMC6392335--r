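# Spatial program of cortical force generators: dynein density fields
# (uniform and punctate), mother-restricted Bim1 bias toward the septin
# ring, and the length-dependent effective bias.

#' Construct a cortical force-generator field
#'
#' The base (wild-type) field has uniform dynein density `lambda_dyn` on
#' both cortices and Bim1 density `lambda_bim1` restricted to the mother
#' cortex. The punctate refinement concentrates daughter-cortex dynein in a
#' condensed patch — a spherical cap of `patch_area_frac` of the daughter
#' cortex area centred opposite the neck — with multiplier
#' `lambda_dynein_patch`, and background multiplier `lambda_dynein_rest`
#' elsewhere in the daughter.
#'
#' @param params A `sim_params` object.
#' @param mother_dyn_mult Multiplier of the mother-cortex dynein density.
#' @param punctate Use the punctate daughter program?
#' @param bias_B Bias scale factor B in `[0, 1]` (see [effective_bias()]).
#' @return An object of class `cortical_field`.
#' @export
cortical_field <- function(params, mother_dyn_mult = 1, punctate = FALSE,
                           bias_B = 1) {
  stopifnot(mother_dyn_mult >= 0, bias_B >= 0, bias_B <= 1)
  structure(list(
    lambda_dyn = params$lambda_dyn,
    lambda_bim1 = params$lambda_bim1,
    mother_dyn_mult = mother_dyn_mult,
    punctate = punctate,
    patch_mult = params$lambda_dynein_patch,
    rest_mult = params$lambda_dynein_rest,
    patch_cos = 1 - 2 * params$patch_area_frac,
    bias_B = bias_B,
    bias_scales_dynein = isTRUE(params$bias_scales_dynein),
    f_dyn = params$f_dyn
  ), class = "cortical_field")
}

#' Local dynein density at a cortical point
#'
#' Mother cortex: `lambda_dyn * mother_dyn_mult`. Daughter cortex, punctate
#' program: `lambda_dyn * lambda_dynein_patch` inside the condensed patch
#' and `lambda_dyn * lambda_dynein_rest` outside; uniform program:
#' `lambda_dyn`.
#'
#' @param field A `cortical_field`.
#' @param geometry A `cell_geometry`.
#' @param p Point on (in) the cortex, numeric 3-vector.
#' @return Dynein linear density in 1/um.
#' @export
local_dynein_density <- function(field, geometry, p) {
  cls <- classify_point(geometry, p)
  if (!cls$region %in% c("mother_cortex", "daughter_cortex")) {
    stop("point is not in the cortex (region: ", cls$region, ")",
         call. = FALSE)
  }
  if (cls$region == "mother_cortex") {
    mult <- field$mother_dyn_mult
    if (field$bias_scales_dynein) mult <- mult * field$bias_B
    return(field$lambda_dyn * mult)
  }
  if (!field$punctate) return(field$lambda_dyn)
  rel <- p - geometry$bud_center
  rel <- rel / sqrt(sum(rel^2))
  inside_patch <- sum(rel * geometry$axis) > field$patch_cos
  field$lambda_dyn * if (inside_patch) field$patch_mult else field$rest_mult
}

#' Bim1-mediated bias force on a cortical microtubule tip
#'
#' Bim1 acts like a cortical dynein but directed tangentially along the
#' cortex toward the nearest point of the septin ring; it is present only on
#' the mother cortex. The magnitude is `B * l_cor * lambda_bim1 * f_dyn`.
#' Returns the zero vector when the tip is not in the mother cortex or when
#' `lambda_bim1 = 0` (bim1 deletion).
#'
#' @param mt List with `anchor`, `dir`, `length` describing the MT.
#' @param field A `cortical_field`.
#' @param geometry A `cell_geometry`.
#' @param params A `sim_params` object.
#' @return Force 3-vector in pN.
#' @export
bim1_bias_force <- function(mt, field, geometry, params) {
  zero <- c(0, 0, 0)
  if (field$lambda_bim1 <= 0 || field$bias_B <= 0) return(zero)
  tip <- mt$anchor + mt$dir * mt$length
  cls <- classify_point(geometry, tip)
  if (cls$region != "mother_cortex") return(zero)
  l_cor <- min(max(params$w_cor - cls$distance, 0), params$w_cor)
  if (l_cor <= 0) return(zero)
  mag <- field$bias_B * l_cor * field$lambda_bim1 * params$f_dyn
  rp <- ring_point(geometry, tip)
  v <- rp - tip
  n_out <- -cls$normal
  vt <- v - n_out * sum(v * n_out)
  nv <- sqrt(sum(vt^2))
  if (nv < 1e-9) return(zero)
  vt / nv * mag
}

#' Length-dependent effective cortical bias
#'
#' The effective cortical bias decays exponentially as the average cMT
#' length falls below the wild-type reference:
#' \deqn{B = \min(1, \exp((\langle l \rangle - l_{ref}) / l_B))}
#' with `l_ref = l_wt_ref` (2.63 um) and decay constant
#' `l_B = bias_length_const`. At the wild-type reference length B = 1; the
#' limit `l_B -> Inf` recovers the uniform-bias control.
#'
#' @param mean_cmt_length Average cMT length in um (> 0).
#' @param params A `sim_params` object.
#' @return Bias scale B in `[0, 1]`.
#' @examples
#' effective_bias(2.63, sim_params())  # 1
#' effective_bias(1.3, sim_params())   # about 0.13
#' @export
effective_bias <- function(mean_cmt_length, params) {
  stopifnot(mean_cmt_length > 0)
  min(1, exp((mean_cmt_length - params$l_wt_ref) / params$bias_length_const))
}

#' Apply a scenario's perturbation to a cortical field
#'
#' `bim1_delta` zeroes the Bim1 density; `dyn1_oe` multiplies the
#' mother-cortex dynein density by `dyn1_oe_factor`; the `ipl1_*` scenarios
#' enable the length-dependent bias (the per-cell B is supplied at run
#' time); `dynein_puncta_scan` switches on the punctate daughter program.
#'
#' @param field A `cortical_field`.
#' @param scenario A `sim_scenario`.
#' @param params The `sim_params` the field was built from.
#' @return Modified `cortical_field`.
#' @export
apply_scenario_perturbation <- function(field, scenario, params) {
  stopifnot(inherits(scenario, "sim_scenario"))
  f <- field
  switch(scenario$name,
    wild_type_cib = f,
    bim1_delta = { f$lambda_bim1 <- 0; f },
    dyn1_oe = { f$mother_dyn_mult <- f$mother_dyn_mult * params$dyn1_oe_factor; f },
    ipl1_homogeneous = f,
    ipl1_heterogeneous = f,
    dynein_puncta_scan = { f$punctate <- TRUE; f }
  )
}
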