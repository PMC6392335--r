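# Overdamped (Stokes-drag) Euler integration and force assembly.

#' Stokes drag coefficients for the mobile bodies
#'
#' Each body translates through a viscous medium with drag
#' `xi = 6 pi eta r`: the nucleus through cytoplasm (switchable to the NE
#' effective viscosity via `nucleus_drag_medium`), MTOCs/SPBs through the
#' effective NE viscosity, kinetochores through nucleoplasm.
#'
#' @param params A `sim_params` object.
#' @return Tibble with `body`, `radius_um`, `viscosity`, `drag` (pN s/um).
#' @examples
#' compute_drags(sim_params())
#' @export
compute_drags <- function(params) {
  pi6 <- 6 * pi
  eta_nuc <- if (params$nucleus_drag_medium == "cytoplasm")
    params$eta_cyt else params$eta_ne
  tibble::tibble(
    body = c("nucleus", "mtoc", "spb", "kinetochore"),
    radius_um = c(params$r_nuc, params$r_spb, params$r_spb, params$r_kt),
    viscosity = c(eta_nuc, params$eta_ne, params$eta_ne, params$eta_nu),
    drag = pi6 * .data$viscosity * .data$radius_um
  )
}

#' One overdamped Euler step
#'
#' Advances positions by `x <- x + (F / xi) dt` (Stokes law `v = F / xi`).
#' Asserts the integration-stability bound: if any per-step displacement
#' exceeds `max_disp` the step aborts with a diagnostic suggesting a
#' smaller `dt`.
#'
#' @param positions n x 3 matrix (um).
#' @param forces n x 3 matrix (pN).
#' @param drags Length-n vector of drag coefficients (pN s/um).
#' @param dt Time step in seconds.
#' @param max_disp Stability bound on per-step displacement in um
#'   (default `Inf`; the simulator uses `0.1 * r_spb`).
#' @return Updated n x 3 position matrix.
#' @export
euler_step <- function(positions, forces, drags, dt, max_disp = Inf) {
  stopifnot(dt > 0, nrow(positions) == nrow(forces),
            length(drags) == nrow(positions))
  disp <- forces * (dt / drags)
  dmax <- sqrt(max(rowSums(disp^2)))
  if (dmax > max_disp) {
    stop("integration unstable: per-step displacement ", signif(dmax, 4),
         " um exceeds the bound ", signif(max_disp, 4),
         " um; reduce dt", call. = FALSE)
  }
  positions + disp
}

#' Assemble per-body resultant forces for a state snapshot
#'
#' Reference force assembly used for bookkeeping tests: cMT cortical forces
#' (push, pull, Bim1 bias, buckling) act simultaneously on the nucleus and
#' the anchoring MTOC/SPB; kinesin-5 interpolar forces act on the SPB pair;
#' kinetochore-MT springs act on kinetochore and SPB; cohesin and hard-core
#' repulsion act within the kinetochore set. Internal nuclear forces obey
#' action-reaction and sum to the zero vector.
#'
#' @param state List with `geometry` (a `cell_geometry`), `field` (a
#'   `cortical_field`), `nucleus` (3-vector), optional `cmt` (list of MT
#'   lists with `anchor_body`, `anchor`, `dir`, `length`, `state`),
#'   optional `spindle` (as in [ipmt_force()] / [kmt_kt_forces()], with
#'   `spb` matrix and `kt` tibble including `sister`).
#' @param params A `sim_params` object.
#' @return List with `f_nucleus` (3-vector), `f_body` (matrix over
#'   MTOC/SPB bodies), `f_kt` (matrix or NULL), and
#'   `internal_sum` (3-vector; zero up to round-off).
#' @export
assemble_forces <- function(state, params) {
  n_body <- if (!is.null(state$spindle)) nrow(state$spindle$spb) else
    max(c(1, vapply(state$cmt, function(m) m$anchor_body, 1L)))
  f_nuc <- c(0, 0, 0)
  f_body <- matrix(0, n_body, 3)
  internal <- c(0, 0, 0)
  for (mt in state$cmt) {
    rep <- cortex_forces(mt, state$geometry, state$field, params)
    tot <- rep$f_push + rep$f_pull + rep$f_bim1 + rep$f_buckling
    f_nuc <- f_nuc + tot
    f_body[mt$anchor_body, ] <- f_body[mt$anchor_body, ] + tot
  }
  f_kt <- NULL
  if (!is.null(state$spindle)) {
    sp <- state$spindle
    if (nrow(sp$spb) >= 2 && !is.null(sp$ipmt)) {
      ipf <- ipmt_force(sp, params)
      f_body[1:2, ] <- f_body[1:2, ] + ipf$force
      internal <- internal + colSums(ipf$force)
    }
    if (!is.null(sp$kt)) {
      kf <- kmt_kt_forces(sp, params)
      f_kt <- kf$f_kt
      f_body[seq_len(nrow(kf$f_spb)), ] <-
        f_body[seq_len(nrow(kf$f_spb)), ] + kf$f_spb
      pf <- kt_pair_forces(sp$kt, params)
      f_kt <- f_kt + pf
      internal <- internal + colSums(kf$f_kt) + colSums(kf$f_spb) +
        colSums(pf)
    }
  }
  list(f_nucleus = f_nuc, f_body = f_body, f_kt = f_kt,
       internal_sum = internal)
}
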