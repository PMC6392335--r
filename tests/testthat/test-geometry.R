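# Two-sphere cell geometry: bud growth law, point classification, septin
# plane queries, and seeded initial conditions.

test_that("bud growth is linear in time and saturates at the final index", {
  p <- sim_params()
  g0 <- cell_geometry(p, t_min = 0)
  expect_equal(g0$budding_index, 0)
  expect_equal(g0$bud_radius, 0)
  mid <- grow_bud(g0, p$bud_growth_duration / 2)
  expect_equal(mid$budding_index, p$final_budding_index / 2)
  late <- grow_bud(g0, p$bud_growth_duration * 3)
  expect_equal(late$budding_index, p$final_budding_index)
  # non-decreasing radius along a time grid
  tt <- seq(0, 90, by = 3)
  rr <- vapply(tt, function(t) grow_bud(g0, t)$bud_radius, 1)
  expect_true(all(diff(rr) >= 0))
})

test_that("septin circle is consistent with the sphere-sphere intersection", {
  p <- sim_params()
  g <- cell_geometry(p, axis = c(0, 0, 1), t_min = 30)
  # ring lies on the mother sphere ...
  expect_equal(g$septin_a^2 + g$septin_r^2, p$r_mother^2,
               tolerance = 1e-9)
  # ... and on the bud sphere
  d <- sqrt(sum(g$bud_center^2)) - g$septin_a
  expect_equal(d^2 + g$septin_r^2, g$bud_radius^2, tolerance = 1e-9)
})

test_that("points are classified into the four regions with distances", {
  p <- sim_params()
  g <- cell_geometry(p, axis = c(0, 0, 1), t_min = p$bud_growth_duration)
  centre <- classify_point(g, c(0, 0, 0))
  expect_equal(centre$region, "mother_interior")
  expect_equal(centre$distance, 3.0)
  shell <- classify_point(g, c(0, -(p$r_mother - p$w_cor / 2), 0))
  expect_equal(shell$region, "mother_cortex")
  expect_equal(shell$distance, p$w_cor / 2, tolerance = 1e-9)
  # along the axis just inside the bud surface
  apex <- g$bud_center + c(0, 0, g$bud_radius - p$w_cor / 2)
  dc <- classify_point(g, apex)
  expect_equal(dc$region, "daughter_cortex")
  expect_equal(dc$distance, p$w_cor / 2, tolerance = 1e-9)
  out <- classify_point(g, c(0, 0, 20))
  expect_equal(out$region, "outside")
  expect_lt(out$distance, 0)
  # inward normal points back inside
  expect_equal(shell$normal, c(0, 1, 0), tolerance = 1e-9)
})

test_that("neck-to-nucleus distance is signed along the axis", {
  p <- sim_params()
  g <- cell_geometry(p, axis = c(0, 0, 1), t_min = 30)
  on_plane <- g$axis * g$septin_a
  expect_equal(neck_to_nucleus_distance(g, on_plane), 0, tolerance = 1e-12)
  expect_equal(neck_to_nucleus_distance(g, c(0, 0, 0)), -g$septin_a)
  expect_gt(neck_to_nucleus_distance(g, g$bud_center), 0)
})

test_that("init_cell places a valid seeded configuration", {
  p <- sim_params()
  init <- init_cell(p, seed = 11)
  a <- init$assembly
  expect_equal(nrow(a$mtoc), 14)
  # MTOC directions are unit vectors (centres on the NE sphere)
  norms <- sqrt(a$mtoc$dx^2 + a$mtoc$dy^2 + a$mtoc$dz^2)
  expect_equal(norms, rep(1, 14), tolerance = 1e-12)
  # no pairwise overlap
  pos <- cbind(a$mtoc$dx, a$mtoc$dy, a$mtoc$dz) * p$r_nuc
  dmin <- min(dist(pos))
  expect_gte(dmin, 2 * p$r_spb - 1e-9)
  # nucleus fully contained in the mother
  expect_lte(sqrt(sum(a$nucleus_center^2)), p$r_mother - p$r_nuc + 1e-12)
  # determinism of the initial state
  init2 <- init_cell(p, seed = 11)
  expect_identical(init$assembly, init2$assembly)
  # degenerate single-MTOC case
  one <- init_cell(sim_params(n_kt = 1), seed = 2)
  expect_equal(nrow(one$assembly$mtoc), 1)
})
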