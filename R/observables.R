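# Event detection and population summaries.

#' MTOC clustering time from a fusion-event log
#'
#' Clustering is complete at the first time a single fused body holds all
#' founding MTOCs (`n_remaining == 1` in the log). A cell that never
#' completes fusion is censored at the end of the run.
#'
#' @param fusion_log Tibble with `time_min` and `n_remaining` (as attached
#'   to a [run_cell()] record), or a `run_record`.
#' @param run_end_min Run length in minutes (censoring value).
#' @param n_founders Number of founding MTOCs (for the trivial
#'   single-founder case, which clusters at time 0).
#' @return List with `time_min` and `censored`.
#' @export
detect_clustering_time <- function(fusion_log, run_end_min = 60,
                                   n_founders = NULL) {
  if (inherits(fusion_log, "run_record")) {
    fusion_log <- attr(fusion_log, "fusion_log")
  }
  if (!is.null(n_founders) && n_founders <= 1) {
    return(list(time_min = 0, censored = FALSE))
  }
  done <- fusion_log$time_min[fusion_log$n_remaining == 1]
  if (length(done) == 0) {
    list(time_min = run_end_min, censored = TRUE)
  } else {
    list(time_min = min(done), censored = FALSE)
  }
}

#' Nuclear migration time from a neck-distance series
#'
#' Migration is complete at the first time the signed neck-to-nucleus
#' distance reaches the threshold (by default one nuclear radius past the
#' septin plane, i.e. the nucleus centre fully inside the daughter);
#' censored at the cutoff otherwise.
#'
#' @param time_min,neck_dist_um Numeric vectors of sample times (min) and
#'   signed distances (um); or pass a `run_record` as `time_min`.
#' @param threshold_um Completion threshold in um.
#' @param cutoff_min Censoring cutoff in minutes.
#' @return List with `time_min` and `censored`.
#' @export
detect_migration_time <- function(time_min, neck_dist_um = NULL,
                                  threshold_um = 1, cutoff_min = 60) {
  if (inherits(time_min, "run_record")) {
    tr <- attr(time_min, "trajectory")
    neck_dist_um <- tr$neck_dist_um
    time_min <- tr$time_min
  }
  hit <- which(time_min <= cutoff_min & neck_dist_um >= threshold_um)
  if (length(hit) == 0) {
    list(time_min = cutoff_min, censored = TRUE)
  } else {
    list(time_min = time_min[min(hit)], censored = FALSE)
  }
}

#' Summarize a population of run records
#'
#' Means and standard errors are computed over uncensored event times;
#' fractions (complete fusion, proper migration within the cutoff) over all
#' records. The final neck-to-nucleus distance histogram is attached as the
#' `histogram` attribute.
#'
#' @param records Tibble of run records (one row per cell).
#' @param cutoff_min Migration cutoff used for the proper-migration
#'   fraction.
#' @param binwidth_um Bin width of the distance histogram.
#' @return One-row tibble: `n`, `mean_clustering_min`, `sem_clustering_min`,
#'   `mean_migration_min`, `sem_migration_min`, `frac_fusion_complete`,
#'   `frac_migrated`, `mean_cmt_length_um`.
#' @export
summarize_population <- function(records, cutoff_min = 60,
                                 binwidth_um = 0.5) {
  if (nrow(records) == 0) stop("no run records to summarize", call. = FALSE)
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  cl <- records$clustering_time_min[!records$clustering_censored]
  mg <- records$migration_time_min[!records$migration_censored &
                                     records$migration_time_min <= cutoff_min]
  both <- !records$clustering_censored & !records$migration_censored
  viol <- if (any(both)) {
    mean(records$clustering_time_min[both] > records$migration_time_min[both])
  } else NA_real_
  out <- tibble::tibble(
    n = nrow(records),
    mean_clustering_min = if (length(cl) > 0) mean(cl) else NA_real_,
    sem_clustering_min = if (length(cl) > 0) sem(cl) else NA_real_,
    mean_migration_min = if (length(mg) > 0) mean(mg) else NA_real_,
    sem_migration_min = if (length(mg) > 0) sem(mg) else NA_real_,
    frac_fusion_complete = mean(!records$clustering_censored),
    frac_migrated = mean(!records$migration_censored &
                           records$migration_time_min <= cutoff_min),
    mean_cmt_length_um = mean(records$mean_cmt_length_um, na.rm = TRUE),
    # clustering is expected to precede full migration; flag populations
    # where the per-cell ordering is violated in more than 5% of runs
    frac_ordering_violated = viol,
    ordering_flag = !is.na(viol) && viol > 0.05
  )
  d <- records$final_neck_dist_um
  breaks <- seq(floor(min(d) / binwidth_um) * binwidth_um,
                ceiling(max(d) / binwidth_um) * binwidth_um + binwidth_um,
                by = binwidth_um)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  attr(out, "histogram") <- tibble::tibble(mid_um = h$mids, count = h$counts)
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-cell records of a simulated population
#' @param x A `sim_population`.
#' @param ... Unused.
#' @return Tibble with one row per simulated cell.
#' @export
tidy.sim_population <- function(x, ...) x$records

#' One-row summary of a simulated population
#' @param x A `sim_population`.
#' @param ... Unused.
#' @return One-row tibble of population statistics.
#' @export
glance.sim_population <- function(x, ...) x$summary

#' Plot event-time distributions of a population
#'
#' Histograms of the uncensored MTOC clustering and nuclear migration times
#' with the population means marked.
#'
#' @param object A `sim_population`.
#' @param binwidth_min Histogram bin width in minutes.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sim_population <- function(object, binwidth_min = 2.5, ...) {
  r <- object$records
  df <- dplyr::bind_rows(
    tibble::tibble(event = "MTOC clustering",
                   time = r$clustering_time_min[!r$clustering_censored]),
    tibble::tibble(event = "nuclear migration",
                   time = r$migration_time_min[!r$migration_censored]))
  means <- dplyr::summarise(dplyr::group_by(df, .data$event),
                            m = mean(.data$time))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_histogram(binwidth = binwidth_min, fill = "grey65",
                            colour = "grey30") +
    ggplot2::geom_vline(data = means,
                        ggplot2::aes(xintercept = .data$m),
                        linetype = 2) +
    ggplot2::facet_wrap(~event, ncol = 1) +
    ggplot2::labs(x = "time since bud emergence (min)", y = "cells",
                  title = paste0(object$scenario$name, " (n = ",
                                 nrow(r), ")")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmaps of a dynein-density scan
#'
#' Mean migration time and proper-migration percentage over the
#' (patch, rest) density-multiplier plane, with the favorable region
#' outlined.
#'
#' @param scan A `sim_scan` tibble from [run_scan()].
#' @param what `"time"` or `"fraction"`.
#' @return A ggplot object.
#' @export
plot_scan <- function(scan, what = c("time", "fraction")) {
  what <- match.arg(what)
  fill <- if (what == "time") "mean_migration_min" else "frac_proper"
  ggplot2::ggplot(scan, ggplot2::aes(x = factor(.data$patch),
                                     y = factor(.data$rest))) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data[[fill]])) +
    ggplot2::geom_point(data = dplyr::filter(scan, .data$favorable),
                        shape = 0, size = 5, colour = "white") +
    ggplot2::scale_fill_viridis_c(name = if (what == "time")
      "migration (min)" else "proper fraction") +
    ggplot2::labs(x = "patch density multiplier",
                  y = "rest density multiplier") +
    ggplot2::theme_minimal()
}
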