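# End-to-end simulator behaviour: determinism, degenerate force pathways,
# record structure.

test_that("identical seed gives bit-identical run records", {
  sc <- make_scenario("wild_type_cib", n_reps = 1, seed = 5, cutoff_min = 25)
  r1 <- run_cell(sc, seed = 5)
  r2 <- run_cell(sc, seed = 5)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_identical(attr(r1, "trajectory"), attr(r2, "trajectory"))
  expect_identical(attr(r1, "fusion_log"), attr(r2, "fusion_log"))
  # different seed gives a different trajectory
  r3 <- run_cell(sc, seed = 6)
  expect_false(identical(r1$final_neck_dist_um, r3$final_neck_dist_um))
})

test_that("non-growing MTs leave migration censored (no force pathway)", {
  sc <- make_scenario("wild_type_cib", overrides = list(v_g = 1e-4),
                      n_reps = 1, seed = 2, cutoff_min = 30)
  r <- run_cell(sc, seed = 2, record_series = FALSE)
  expect_true(r$migration_censored)
  expect_true(r$clustering_censored)
})

test_that("run records carry censoring values, never fabricated times", {
  sc <- make_scenario("wild_type_cib", overrides = list(v_g = 1e-4),
                      n_reps = 1, seed = 3, cutoff_min = 30)
  r <- run_cell(sc, seed = 3, record_series = FALSE)
  expect_equal(r$migration_time_min, 30)
  expect_equal(r$clustering_time_min, 30)
})

test_that("population aggregation matches its single records", {
  sc <- make_scenario("wild_type_cib", n_reps = 3, seed = 21, cutoff_min = 30)
  pop <- run_population(sc)
  expect_equal(nrow(pop$records), 3)
  expect_equal(pop$records$seed, 21:23)
  single <- run_cell(sc, seed = 22, record_series = FALSE)
  expect_equal(pop$records$clustering_time_min[2], single$clustering_time_min)
  expect_equal(pop$records$migration_time_min[2], single$migration_time_min)
  # n = 1 summary equals the record
  sc1 <- make_scenario("wild_type_cib", n_reps = 1, seed = 21, cutoff_min = 30)
  pop1 <- run_population(sc1)
  expect_equal(pop1$summary$n, 1)
  expect_equal(pop1$summary$frac_fusion_complete,
               as.numeric(!pop1$records$clustering_censored))
})

test_that("tidiers and plots expose the records and summary", {
  sc <- make_scenario("wild_type_cib", n_reps = 2, seed = 31, cutoff_min = 20)
  pop <- run_population(sc)
  expect_identical(tidy(pop), pop$records)
  expect_identical(glance(pop), pop$summary)
  pl <- ggplot2::autoplot(pop)
  expect_s3_class(pl, "ggplot")
  scan <- tibble::tibble(patch = c(1, 2), rest = c(1, 1), n = 5,
                         mean_migration_min = c(37, 36), frac_proper = 1,
                         favorable = c(TRUE, TRUE))
  class(scan) <- c("sim_scan", class(scan))
  expect_s3_class(plot_scan(scan), "ggplot")
  expect_s3_class(plot_scan(scan, "fraction"), "ggplot")
})

test_that("per-cell heterogeneity draws honour the mutant range", {
  sc <- make_scenario("ipl1_heterogeneous", n_reps = 25, seed = 41,
                      cutoff_min = 5)
  pop <- run_population(sc)
  fc <- pop$records$f_c_cell
  expect_true(all(fc >= 1 & fc <= 21))
  expect_gt(sd(fc), 2) # genuinely heterogeneous across cells
  # bias scale follows the per-cell mean length
  p <- scenario_params(sc)
  expect_equal(pop$records$bias_b,
               vapply(fc, function(f)
                 effective_bias(cmt_stationary_mean_length(p, f), p), 1))
})
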