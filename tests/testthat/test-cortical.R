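# Cortical force-generator program: dynein density fields, Bim1 bias,
# length-dependent effective bias, scenario perturbations.

test_that("local dynein density: uniform base, punctate daughter program", {
  p <- sim_params(lambda_dynein_patch = 2, lambda_dynein_rest = 0.5)
  g <- cell_geometry(p, axis = c(0, 0, 1), t_min = p$bud_growth_duration)
  mother_pt <- c(0, -(p$r_mother - p$w_cor / 2), 0)
  base <- cortical_field(p)
  expect_equal(local_dynein_density(base, g, mother_pt), 6.0)
  # uniform daughter
  apex <- g$bud_center + c(0, 0, g$bud_radius - p$w_cor / 2)
  expect_equal(local_dynein_density(base, g, apex), 6.0)
  # punctate: apex is inside the condensed patch (opposite the neck)
  punct <- cortical_field(p, punctate = TRUE)
  expect_equal(local_dynein_density(punct, g, apex), 12.0)
  # off-patch daughter point gets the background multiplier
  side <- g$bud_center + c(g$bud_radius - p$w_cor / 2, 0, 0)
  expect_equal(local_dynein_density(punct, g, side), 3.0)
  # zero background
  p0 <- sim_params(lambda_dynein_patch = 2, lambda_dynein_rest = 0)
  punct0 <- cortical_field(p0, punctate = TRUE)
  expect_equal(local_dynein_density(punct0, g, side), 0)
  expect_error(local_dynein_density(base, g, c(0, 0, 0)), "not in the cortex")
})

test_that("punctate field with unit multipliers reduces to the base model", {
  p <- sim_params() # patch = rest = 1
  g <- cell_geometry(p, axis = c(0, 0, 1), t_min = p$bud_growth_duration)
  punct <- cortical_field(p, punctate = TRUE)
  base <- cortical_field(p)
  for (pt in list(g$bud_center + c(0, 0, g$bud_radius - 0.1),
                  g$bud_center + c(g$bud_radius - 0.1, 0, 0),
                  c(0, -(p$r_mother - 0.1), 0))) {
    expect_equal(local_dynein_density(punct, g, pt),
                 local_dynein_density(base, g, pt))
  }
})

test_that("Bim1 bias force: magnitude, direction, and restriction to mother", {
  p <- sim_params()
  g <- cell_geometry(p, axis = c(0, 0, 1), t_min = p$bud_growth_duration)
  f <- cortical_field(p)
  # tip in mother cortex at l_cor = 0.3 (full penetration)
  anchor <- c(0, -(p$r_mother - 1.5), 0)
  mt <- list(anchor = anchor, dir = c(0, -1, 0), length = 1.5)
  fb <- bim1_bias_force(mt, f, g, p)
  expect_equal(sqrt(sum(fb^2)), 0.3 * p$lambda_bim1 * p$f_dyn,
               tolerance = 1e-6) # 1.8 pN
  # tangential (no radial component) and pointing toward the ring (+z side)
  tip <- mt$anchor + mt$dir * mt$length
  n_out <- tip / sqrt(sum(tip^2))
  expect_equal(abs(sum(fb * n_out)), 0, tolerance = 1e-9)
  expect_gt(fb[3], 0)
  # bim1 deletion: zero vector
  fb0 <- bim1_bias_force(mt, cortical_field(sim_params(lambda_bim1 = 0)), g, p)
  expect_equal(fb0, c(0, 0, 0))
  # tip in the daughter cortex: zero vector
  mt_d <- list(anchor = g$bud_center - c(0, 0, 1),
               dir = c(0, 0, 1), length = g$bud_radius + 1 - 0.05)
  expect_equal(bim1_bias_force(mt_d, f, g, p), c(0, 0, 0))
})

test_that("effective bias is 1 at the reference length and decays exponentially", {
  p <- sim_params()
  expect_equal(effective_bias(2.63, p), 1)
  expect_equal(effective_bias(1.3, p), exp((1.3 - 2.63) / 0.65))
  expect_equal(effective_bias(1.3, p), 0.129, tolerance = 3e-3)
  expect_equal(effective_bias(10, p), 1) # capped above the reference
  # infinite length constant recovers the uniform-bias control
  pinf <- sim_params(bias_length_const = 1e9)
  expect_equal(effective_bias(0.1, pinf), 1, tolerance = 1e-6)
  # monotone in the mean length below the reference
  ls <- seq(0.3, 2.63, by = 0.1)
  bs <- vapply(ls, effective_bias, 1, params = p)
  expect_true(all(diff(bs) > 0))
})

test_that("scenario perturbations act on the field as documented", {
  p <- sim_params()
  f <- cortical_field(p)
  idf <- apply_scenario_perturbation(f, make_scenario("wild_type_cib"), p)
  expect_identical(idf, f)
  fb <- apply_scenario_perturbation(f, make_scenario("bim1_delta"), p)
  expect_equal(fb$lambda_bim1, 0)
  fd <- apply_scenario_perturbation(f, make_scenario("dyn1_oe"), p)
  expect_equal(fd$mother_dyn_mult, 3)
  g <- cell_geometry(p, axis = c(0, 0, 1), t_min = p$bud_growth_duration)
  mother_pt <- c(0, -(p$r_mother - p$w_cor / 2), 0)
  expect_equal(local_dynein_density(fd, g, mother_pt), 18)
  apex <- g$bud_center + c(0, 0, g$bud_radius - p$w_cor / 2)
  expect_equal(local_dynein_density(fd, g, apex), 6) # daughter unchanged
  fp <- apply_scenario_perturbation(f, make_scenario("dynein_puncta_scan"), p)
  expect_true(fp$punctate)
})
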