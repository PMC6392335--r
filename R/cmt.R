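# Cytoplasmic microtubule mechanics: dynamic instability, load-dependent
# modulation, and the cortical force menu (elastic push, dynein pull, wall
# impulse, Euler buckling, low-angle sliding).

#' Load-dependent modulation of growth velocity and catastrophe
#'
#' A compressive axial load slows plus-end growth exponentially and raises
#' the catastrophe frequency toward its stalled value:
#' \deqn{v_g = v_{g0} e^{-f_{load}/f_{stall}}}
#' \deqn{f_c = f_c^{stall} / [1 + (f_c^{stall}/f_{c0} - 1) e^{-f_{load}/f_{stall}}]}
#' At zero load both reduce to the free values; under stall the growth
#' velocity vanishes and the catastrophe rate saturates at `f_c_stall`.
#'
#' @param params A `sim_params` object.
#' @param f_load Magnitude of the opposing axial load (pN, >= 0).
#' @param f_c0 Optional free catastrophe rate override in 1/min (defaults to
#'   `params$f_c`); used for length-dependent kMT catastrophe.
#' @return List with `v_g_eff` (um/min) and `f_c_eff` (1/min).
#' @examples
#' modulate_by_load(sim_params(), 0)       # free values
#' modulate_by_load(sim_params(), 1.7)$v_g_eff  # 10.4 / e
#' @export
modulate_by_load <- function(params, f_load, f_c0 = NULL) {
  stopifnot(f_load >= 0)
  if (is.null(f_c0)) f_c0 <- params$f_c
  fcs <- params$f_c_stall * 60 # 1/min
  e <- exp(-f_load / params$f_stall)
  list(
    v_g_eff = params$v_g * e,
    f_c_eff = fcs / (1 + (fcs / f_c0 - 1) * e)
  )
}

#' Stationary mean length of an unconfined dynamic microtubule
#'
#' In the bounded-growth regime (`v_s f_c > v_g f_r`) the stationary length
#' distribution of a two-state (catastrophe/rescue) microtubule with
#' renucleation at zero length is exponential with mean
#' \deqn{\langle l \rangle = v_g v_s / (v_s f_c - v_g f_r).}
#'
#' @param params A `sim_params` object.
#' @param f_c Optional catastrophe rate (1/min) to evaluate at.
#' @return Mean length in um, or `Inf` in the unbounded-growth regime.
#' @examples
#' cmt_stationary_mean_length(sim_params())  # about 10.48 um
#' @export
cmt_stationary_mean_length <- function(params, f_c = NULL) {
  if (is.null(f_c)) f_c <- params$f_c
  denom <- params$v_s * f_c - params$v_g * params$f_r
  if (denom <= 0) return(Inf)
  params$v_g * params$v_s / denom
}

#' Mean elongation rate of an unconfined dynamic microtubule
#'
#' `(v_g f_r - v_s f_c) / (f_c + f_r)`; negative in the bounded regime,
#' positive when growth is unbounded.
#'
#' @inheritParams cmt_stationary_mean_length
#' @return Mean elongation rate in um/min.
#' @export
cmt_mean_elongation_rate <- function(params, f_c = NULL) {
  if (is.null(f_c)) f_c <- params$f_c
  (params$v_g * params$f_r - params$v_s * f_c) / (f_c + params$f_r)
}

#' Sample stationary lengths of a free microtubule by simulation
#'
#' Runs one long stochastic trajectory of an unconfined microtubule
#' (growth/shrinkage with catastrophe and rescue, renucleation at zero
#' length) and records the length at fixed intervals after a burn-in.
#' Used as the empirical counterpart of [cmt_stationary_mean_length()].
#'
#' @param params A `sim_params` object.
#' @param n_samples Number of length samples.
#' @param sample_interval_s Seconds of simulated time between samples.
#' @param burnin_s Burn-in period in seconds.
#' @param seed Random seed.
#' @return Numeric vector of lengths (um).
#' @export
simulate_free_mt <- function(params, n_samples = 1e5, sample_interval_s = 6,
                             burnin_s = 600, seed = 1) {
  set.seed(seed)
  .free_mt_lengths_cpp(as.integer(n_samples), sample_interval_s,
                       params$v_g / 60, params$v_s / 60,
                       params$f_c / 60, params$f_r / 60,
                       params$dt, burnin_s)
}

#' Single-step dynamic instability update for one microtubule
#'
#' Advances one microtubule by `dt_s` seconds: a growing plus end switches
#' to shrinking with probability `1 - exp(-f_c_eff dt)` and otherwise
#' elongates at the load-modulated velocity; a shrinking end rescues with
#' probability `1 - exp(-f_r dt)` and otherwise shortens at `v_s`. A fully
#' depolymerised microtubule renucleates (length zero, growing, fresh
#' orientation drawn from the outward hemisphere around `anchor_normal`).
#'
#' @param mt List with `length` (um), `state` (`"growing"`/`"shrinking"`),
#'   `dir` (unit 3-vector).
#' @param params A `sim_params` object.
#' @param dt_s Time step in seconds.
#' @param f_load Axial load (pN) for [modulate_by_load()].
#' @param anchor_normal Outward NE normal at the anchor, for renucleation.
#' @return Updated `mt` list.
#' @export
step_instability <- function(mt, params, dt_s = params$dt, f_load = 0,
                             anchor_normal = mt$dir) {
  if (mt$state == "growing") {
    mod <- modulate_by_load(params, f_load)
    if (stats::runif(1) < 1 - exp(-mod$f_c_eff / 60 * dt_s)) {
      mt$state <- "shrinking"
    } else {
      mt$length <- mt$length + mod$v_g_eff / 60 * dt_s
    }
  } else {
    mt$length <- mt$length - params$v_s / 60 * dt_s
    if (mt$length <= 0) {
      mt$length <- 0
      mt$state <- "growing"
      v <- stats::rnorm(3)
      v <- v / sqrt(sum(v^2))
      if (sum(v * anchor_normal) < 0) v <- -v
      mt$dir <- v
    } else if (stats::runif(1) < 1 - exp(-params$f_r / 60 * dt_s)) {
      mt$state <- "growing"
    }
  }
  mt
}

#' Incidence angle of a microtubule at the cortex
#'
#' Angle between the plus-end direction and the local tangent plane of the
#' boundary (0 = grazing, 90 deg = head-on).
#'
#' @param dir Unit direction of the MT.
#' @param outward_normal Outward boundary normal at the contact point.
#' @return Angle in degrees.
#' @export
incidence_angle <- function(dir, outward_normal) {
  s <- abs(sum(dir * outward_normal))
  asin(min(1, s)) * 180 / pi
}

#' Cortical force report for one cytoplasmic microtubule
#'
#' Computes the force menu a cortex-penetrating cMT transmits to its anchor
#' (MTOC/SPB) and the nucleus: elastic push `l_cor * K_cor` inward along the
#' MT axis (growth phase only), collective dynein pull
#' `l_cor * lambda_eff * f_dyn` outward along the axis, Bim1 bias (mother
#' cortex, via [bim1_bias_force()]), first-order Euler buckling
#' `pi^2 kappa / l^2` when flagged, and the axial load magnitude fed into
#' [modulate_by_load()]. All vectors are zero when the plus end is not in
#' the cortex.
#'
#' @param mt List with `anchor` (3-vector), `dir` (unit 3-vector), `length`
#'   (um), `state` (`"growing"`/`"shrinking"`), optional `buckled` flag.
#' @param geometry A `cell_geometry`.
#' @param field A `cortical_field` (see [cortical_field()]).
#' @param params A `sim_params` object.
#' @return List with 3-vectors `f_push`, `f_pull`, `f_bim1`, `f_buckling`
#'   (pN), scalars `l_cor` (um) and `f_load` (pN), and the tip `region`.
#' @export
cortex_forces <- function(mt, geometry, field, params) {
  tip <- mt$anchor + mt$dir * mt$length
  cls <- classify_point(geometry, tip)
  l_cor <- min(max(params$w_cor - cls$distance, 0), params$w_cor)
  zero <- c(0, 0, 0)
  out <- list(f_push = zero, f_pull = zero, f_bim1 = zero,
              f_buckling = zero, l_cor = l_cor, f_load = 0,
              region = cls$region)
  buckled <- isTRUE(mt$buckled)
  if (l_cor > 0) {
    lam <- local_dynein_density(field, geometry, tip)
    out$f_pull <- mt$dir * (l_cor * lam * params$f_dyn)
    if (identical(mt$state, "growing")) {
      push <- l_cor * params$k_cor
      out$f_push <- -mt$dir * push
      out$f_load <- out$f_load + push
    }
    out$f_bim1 <- bim1_bias_force(mt, field, geometry, params)
  }
  if (buckled && mt$length > 0) {
    fb <- pi^2 * params$kappa_mt / mt$length^2
    out$f_buckling <- -mt$dir * fb
    out$f_load <- out$f_load + fb
  }
  out
}
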