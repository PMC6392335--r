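# Overdamped Euler integration, Stokes drags, and force assembly.

test_that("Stokes drags use 6 pi eta r with the documented media", {
  d <- compute_drags(sim_params())
  expect_equal(d$drag[d$body == "nucleus"], 6 * pi * 5 * 1.0) # ~94.25
  expect_equal(d$drag[d$body == "kinetochore"], 6 * pi * 10 * 0.1) # ~18.85
  expect_equal(d$drag[d$body == "mtoc"], 6 * pi * 10 * 0.125)
  # linearity in radius at fixed viscosity
  d2 <- compute_drags(sim_params(r_nuc = 2))
  expect_equal(d2$drag[d2$body == "nucleus"],
               2 * d$drag[d$body == "nucleus"])
})

test_that("euler_step displaces by F dt / xi and asserts stability", {
  pos <- matrix(0, 1, 3)
  f <- matrix(c(1, 0, 0), 1)
  out <- euler_step(pos, f, drags = 10, dt = 0.05)
  expect_equal(out[1, 1], 0.005)
  expect_equal(euler_step(pos, 0 * f, 10, 0.05), pos) # zero force, no motion
  expect_error(euler_step(pos, 100 * f, 10, 0.05, max_disp = 0.0125),
               "reduce dt")
})

test_that("Euler relaxation in a harmonic trap matches the closed form", {
  # overdamped spring: x(t) = x0 exp(-k t / xi)
  k <- 5; xi <- 50; x0 <- 1
  dt <- 0.005 * xi / k
  n <- 400
  x <- x0
  for (i in seq_len(n)) {
    x <- euler_step(matrix(c(x, 0, 0), 1), matrix(c(-k * x, 0, 0), 1),
                    xi, dt)[1, 1]
  }
  expect_equal(x, x0 * exp(-k * n * dt / xi), tolerance = 0.01)
})

test_that("assembled cMT forces reach nucleus and anchor simultaneously", {
  p <- sim_params()
  g <- cell_geometry(p, axis = c(0, 0, 1), t_min = p$bud_growth_duration)
  f <- cortical_field(p)
  mt <- list(anchor_body = 1L, anchor = c(0, -(p$r_mother - 1.5), 0),
             dir = c(0, -1, 0), length = 1.4, state = "growing")
  out <- assemble_forces(list(geometry = g, field = f, nucleus = c(0, 0, 0),
                              cmt = list(mt)), p)
  expect_equal(out$f_nucleus, out$f_body[1, ]) # same contribution to both
  rep <- cortex_forces(mt, g, f, p)
  expect_equal(out$f_nucleus, rep$f_push + rep$f_pull + rep$f_bim1 +
                 rep$f_buckling)
})

test_that("internal nuclear forces sum to the zero vector", {
  p <- sim_params()
  g <- cell_geometry(p, axis = c(0, 0, 1), t_min = 10)
  f <- cortical_field(p)
  set.seed(5)
  kt <- tibble::tibble(
    x = rnorm(6, sd = 0.3), y = rnorm(6, sd = 0.3), z = rnorm(6, sd = 0.3),
    body = rep(1:2, 3), kmt_length = runif(6, 0.2, 1.2),
    kmt_state = sample(c("growing", "shrinking"), 6, TRUE),
    sister = c(2L, 1L, 4L, 3L, 6L, 5L))
  spindle <- list(
    spb = rbind(c(0, 0, 1), c(0.3, 0, -1)),
    ipmt = tibble::tibble(spb = c(1, 1, 2, 2), length = runif(4, 0.5, 2)),
    kt = kt)
  out <- assemble_forces(list(geometry = g, field = f, nucleus = c(0, 0, 0),
                              cmt = list(), spindle = spindle), p)
  expect_equal(out$internal_sum, c(0, 0, 0), tolerance = 1e-9)
})

test_that("full simulation keeps constraint residuals at tolerance", {
  sc <- make_scenario("wild_type_cib", n_reps = 1, seed = 17, cutoff_min = 20)
  r <- run_cell(sc, seed = 17, record_series = FALSE)
  expect_lt(r$max_internal_force_residual, 1e-9)
  expect_lt(r$max_ne_residual, 1e-6)
})
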