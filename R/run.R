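# Orchestration: single-cell runs, populations, and dynein-density scans.

#' Internal: flat parameter vector for the C++ engine
#' @keywords internal
engine_values <- function(p_int, bias_B, mother_dyn_mult, fc_cell_s,
                          punctate, cutoff_s, stop_early, record_series,
                          daughter_trans = 1) {
  c(r_mother = p_int$r_mother, w_cor = p_int$w_cor,
    neck_fraction = p_int$neck_fraction,
    final_budding_index = p_int$final_budding_index,
    bud_growth_s = p_int$bud_growth_s,
    r_nuc = p_int$r_nuc, r_spb = p_int$r_spb, r_kt = p_int$r_kt,
    k_cor = p_int$k_cor, eta_cyt = p_int$eta_cyt, eta_nu = p_int$eta_nu,
    eta_ne = p_int$eta_ne, eta_nucleus = p_int$eta_nucleus,
    v_g_s = p_int$v_g_s, v_s_s = p_int$v_s_s,
    f_c_s = fc_cell_s, f_r_s = p_int$f_r_s,
    f_c_stall = p_int$f_c_stall, f_stall = p_int$f_stall,
    f_dyn = p_int$f_dyn, lambda_dyn = p_int$lambda_dyn,
    lambda_ipmt = p_int$lambda_ipmt, f_kinesin5 = p_int$f_kinesin5,
    k_cohesion = p_int$k_cohesion, k_c = p_int$k_c,
    k_fibril = p_int$k_fibril, c_kt_repulsion = p_int$c_kt_repulsion,
    f_wall = p_int$f_wall, dt = p_int$dt, h_kmt_s = p_int$h_kmt_s,
    lambda_bim1 = p_int$lambda_bim1, kappa_mt = p_int$kappa_mt,
    sliding_angle_rad = p_int$sliding_angle_rad,
    patch_cos = p_int$patch_cos,
    bias_B = bias_B, mother_dyn_mult = mother_dyn_mult,
    lambda_dynein_patch = p_int$lambda_dynein_patch,
    lambda_dynein_rest = p_int$lambda_dynein_rest,
    daughter_dynein_onset_bi = p_int$daughter_dynein_onset_bi,
    daughter_trans = daughter_trans,
    punctate = as.numeric(punctate),
    bias_scales_dynein = as.numeric(isTRUE(p_int$bias_scales_dynein)),
    cutoff_s = cutoff_s,
    migration_threshold = p_int$migration_threshold,
    n_cmt_per_mtoc = p_int$n_cmt_per_mtoc,
    n_ipmt_per_spb = p_int$n_ipmt_per_spb,
    sample_every = max(1, round(p_int$sample_interval / p_int$dt)),
    stop_early = as.numeric(stop_early),
    record_series = as.numeric(record_series))
}

#' Simulate a single cell
#'
#' Runs the full mitotic sequence for one seeded cell: bud growth, cMT
#' dynamics with cortical interaction plus Bim1 bias, MTOC fusion into the
#' SPB, SPB duplication with a minimal kinetochore spindle, and nuclear
#' migration, until the cutoff (or until both clustering and migration have
#' occurred, when `stop_early = TRUE`). Deterministic given the seed.
#'
#' @param scenario A `sim_scenario` (see [make_scenario()]).
#' @param params Base `sim_params` object.
#' @param seed Integer seed for this cell.
#' @param record_series Record the sampled trajectory (attached as the
#'   `trajectory` attribute)?
#' @param stop_early Stop once clustering and migration have both occurred
#'   (used by scans; distance series then ends early).
#' @return A one-row tibble of class `run_record`: seed, scenario, per-cell
#'   catastrophe rate and bias, clustering and migration times (minutes
#'   since bud emergence) with censoring flags (censored times carry the
#'   cutoff value, never a fabricated time), time-averaged mean cMT length,
#'   final neck-to-nucleus distance, fused fraction and integrator
#'   diagnostics. Attributes `trajectory` and `fusion_log` hold the sampled
#'   series and fusion events.
#' @examples
#' \donttest{
#' sc <- make_scenario("wild_type_cib", n_reps = 1, seed = 1)
#' rec <- run_cell(sc, seed = 1)
#' rec$clustering_time_min
#' }
#' @export
run_cell <- function(scenario, params = sim_params(), seed = scenario$seed,
                     record_series = TRUE, stop_early = FALSE) {
  stopifnot(inherits(scenario, "sim_scenario"))
  p <- scenario_params(scenario, params)
  init <- init_cell(p, seed) # seeds the RNG stream; engine continues it
  fc_cell <- if (!is.null(scenario$fc_range)) {
    stats::runif(1, scenario$fc_range[1], scenario$fc_range[2])
  } else p$f_c
  bias_B <- if (scenario$length_dependent_bias) {
    effective_bias(cmt_stationary_mean_length(p, fc_cell), p)
  } else 1
  mother_mult <- if (scenario$name == "dyn1_oe") p$dyn1_oe_factor else 1
  p_int <- params_internal(p)
  # Ipl1 depletion delocalises dynein globally: the per-cell bias scale
  # also attenuates the daughter-cortex dynein pull in that scenario
  d_trans <- if (scenario$length_dependent_bias) bias_B else 1
  vals <- engine_values(p_int, bias_B, mother_mult, fc_cell / 60,
                        scenario$punctate, scenario$cutoff_min * 60,
                        stop_early, record_series, daughter_trans = d_trans)
  a <- init$assembly
  res <- .sim_run_cell_cpp(
    list(axis = init$geometry$axis,
         nucleus = a$nucleus_center,
         mtoc_dirs = cbind(a$mtoc$dx, a$mtoc$dy, a$mtoc$dz),
         cmt_dirs = cbind(a$cmt$dx, a$cmt$dy, a$cmt$dz),
         cmt_anchor = as.integer(a$cmt$anchor)),
    list(values = vals))
  run_end <- scenario$cutoff_min
  clustering_censored <- !isTRUE(res$clustering_complete)
  migration_censored <- !isTRUE(res$migrated)
  rec <- tibble::tibble(
    scenario = scenario$name,
    seed = as.integer(seed),
    f_c_cell = fc_cell,
    bias_b = bias_B,
    clustering_time_min = if (clustering_censored) run_end else res$clustering_time_min,
    clustering_censored = clustering_censored,
    migration_time_min = if (migration_censored) run_end else res$migration_time_min,
    migration_censored = migration_censored,
    mean_cmt_length_um = res$mean_cmt_length_um,
    final_neck_dist_um = res$final_neck_dist_um,
    frac_mtocs_fused = res$frac_mtocs_fused,
    n_bodies_final = res$n_bodies_final,
    max_internal_force_residual = res$max_internal_force_residual,
    max_ne_residual = res$max_ne_residual,
    max_step_displacement = res$max_step_displacement
  )
  attr(rec, "trajectory") <- tibble::as_tibble(res$trajectory)
  attr(rec, "fusion_log") <- tibble::as_tibble(res$fusion_log)
  class(rec) <- c("run_record", class(rec))
  rec
}

#' Simulate a population of cells
#'
#' Runs `scenario$n_reps` independent cells with seeds
#' `seed, seed + 1, ...` and aggregates them with
#' [summarize_population()].
#'
#' @param scenario A `sim_scenario`.
#' @param params Base `sim_params`.
#' @param record_series Keep per-cell trajectories? (memory-heavy; off by
#'   default for populations)
#' @param stop_early Stop each cell once clustering and migration have both
#'   occurred.
#' @param progress Print a progress line every 10 cells?
#' @return Object of class `sim_population`: list with `records` (tibble,
#'   one row per cell), `summary` (one-row tibble), `scenario`, `params`.
#' @examples
#' \donttest{
#' pop <- run_population(make_scenario("wild_type_cib", n_reps = 3, seed = 1))
#' pop$summary$mean_migration_min
#' }
#' @export
run_population <- function(scenario, params = sim_params(),
                           record_series = FALSE, stop_early = FALSE,
                           progress = FALSE) {
  stopifnot(inherits(scenario, "sim_scenario"))
  seeds <- scenario$seed + seq_len(scenario$n_reps) - 1L
  records <- purrr::map(seeds, function(s) {
    if (progress && (s - scenario$seed) %% 10 == 0) {
      message("cell ", s - scenario$seed + 1, "/", scenario$n_reps)
    }
    run_cell(scenario, params, seed = s, record_series = record_series,
             stop_early = stop_early)
  })
  recs <- dplyr::bind_rows(lapply(records, function(r) {
    attr(r, "trajectory") <- NULL; attr(r, "fusion_log") <- NULL
    class(r) <- class(tibble::tibble())
    r
  }))
  structure(list(
    records = recs,
    summary = summarize_population(recs, cutoff_min = scenario$cutoff_min),
    scenario = scenario,
    params = params,
    cell_records = if (record_series) records else NULL
  ), class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  s <- x$summary
  cat("<sim_population> ", x$scenario$name, ", n = ", s$n, "\n", sep = "")
  cat(sprintf("  clustering: %.1f +/- %.1f min (fusion complete in %.0f%%)\n",
              s$mean_clustering_min, s$sem_clustering_min,
              100 * s$frac_fusion_complete))
  cat(sprintf("  migration:  %.1f +/- %.1f min (proper migration in %.0f%%)\n",
              s$mean_migration_min, s$sem_migration_min,
              100 * s$frac_migrated))
  invisible(x)
}

#' Scan the punctate dynein-density plane
#'
#' Runs populations of the punctate daughter-cortex program over a grid of
#' (`lambda_dynein_patch`, `lambda_dynein_rest`) multipliers and reports,
#' per grid point, the mean migration time and the percentage of cells
#' achieving proper migration within the cutoff. The favorable region is
#' where the mean migration time falls inside `window` and the proper
#' migration fraction reaches `frac_threshold`.
#'
#' @param patch_mults,rest_mults Numeric vectors of density multipliers.
#' @param n_per_point Cells per grid point.
#' @param params Base `sim_params`.
#' @param seed Base seed; grid points use disjoint seed blocks.
#' @param cutoff_min Migration cutoff (min).
#' @param window Favorable mean-migration window in minutes.
#' @param frac_threshold Favorable proper-migration fraction.
#' @return Tibble of class `sim_scan`: one row per grid point with
#'   `patch`, `rest`, `n`, `mean_migration_min`, `frac_proper`,
#'   `favorable`.
#' @export
run_scan <- function(patch_mults, rest_mults, n_per_point = 20,
                     params = sim_params(), seed = 1L, cutoff_min = 60,
                     window = c(35, 40), frac_threshold = 0.95) {
  stopifnot(length(patch_mults) > 0, length(rest_mults) > 0)
  grid <- expand.grid(patch = patch_mults, rest = rest_mults,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    sc <- make_scenario(
      "dynein_puncta_scan",
      overrides = list(lambda_dynein_patch = grid$patch[i],
                       lambda_dynein_rest = grid$rest[i]),
      n_reps = n_per_point,
      seed = seed + (i - 1L) * n_per_point,
      cutoff_min = cutoff_min)
    pop <- run_population(sc, params, stop_early = TRUE)
    s <- pop$summary
    tibble::tibble(
      patch = grid$patch[i], rest = grid$rest[i], n = s$n,
      mean_migration_min = s$mean_migration_min,
      frac_proper = s$frac_migrated)
  })
  out <- dplyr::bind_rows(rows)
  out$favorable <- !is.na(out$mean_migration_min) &
    out$mean_migration_min >= window[1] &
    out$mean_migration_min <= window[2] &
    out$frac_proper >= frac_threshold
  class(out) <- c("sim_scan", class(out))
  attr(out, "window") <- window
  attr(out, "frac_threshold") <- frac_threshold
  out
}
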