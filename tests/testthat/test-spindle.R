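# Intranuclear mechanics: MTOC fusion, kinesin-5 sliding, kMT and
# kinetochore-pair springs, SPB duplication.

make_assembly <- function(dirs, radius = 0.125) {
  n <- nrow(dirs)
  list(nucleus_center = c(0, 0, 0), r_nuc = 1,
       mtoc = tibble::tibble(
         id = seq_len(n), dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3],
         radius = radius, founders = 1L, alive = TRUE))
}

test_that("contacting MTOCs merge with volume conservation on the NE", {
  # two bodies 0.25 um apart on the unit sphere: just in contact
  th <- 0.25 # chord ~ angle for small angles; use exact chord placement
  ang <- 2 * asin(0.125)
  dirs <- rbind(c(0, 0, 1),
                c(sin(ang), 0, cos(ang)))
  out <- fuse_mtocs(make_assembly(dirs), time_min = 5)
  expect_true(out$complete)
  m <- out$assembly$mtoc
  live <- m[m$alive, ]
  expect_equal(nrow(live), 1)
  expect_equal(live$radius, 0.125 * 2^(1 / 3), tolerance = 1e-12)
  expect_equal(live$founders, 2L)
  # merged centre re-projected onto the NE sphere
  expect_equal(sqrt(live$dx^2 + live$dy^2 + live$dz^2), 1, tolerance = 1e-12)
  expect_equal(out$events$time_min, 5)
  expect_equal(out$events$n_remaining, 1)
})

test_that("distant MTOCs do not merge; single body is a no-op", {
  dirs <- rbind(c(0, 0, 1), c(0, 0, -1))
  out <- fuse_mtocs(make_assembly(dirs))
  expect_false(out$complete)
  expect_equal(sum(out$assembly$mtoc$alive), 2)
  one <- fuse_mtocs(make_assembly(matrix(c(0, 0, 1), 1)))
  expect_true(one$complete)
  expect_equal(nrow(one$events), 0)
})

test_that("repeated random fusions conserve total MTOC volume exactly", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 10
    dirs <- matrix(rnorm(3 * n), n)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    a <- make_assembly(dirs)
    v0 <- sum(a$mtoc$radius^3)
    out <- fuse_mtocs(a, contact_tol = 0.4) # generous tol forces many merges
    m <- out$assembly$mtoc
    expect_equal(sum(m$radius[m$alive]^3), v0, tolerance = 1e-12)
    expect_equal(sum(m$founders[m$alive]), n)
  }
})

test_that("kinesin-5 force scales with total ipMT overlap", {
  p <- sim_params()
  spindle <- list(
    spb = rbind(c(0, 0, 0), c(2, 0, 0)),
    ipmt = tibble::tibble(spb = c(1, 2), length = c(2, 2)))
  out <- ipmt_force(spindle, p)
  expect_equal(out$l_overlap, 2) # one antiparallel pair fully overlapping
  expect_equal(out$force[1, ], c(-2, 0, 0)) # separating force on SPB 1
  expect_equal(out$force[2, ], c(2, 0, 0))
  expect_equal(colSums(out$force), c(0, 0, 0))
  # zero overlap -> zero force
  short <- spindle; short$ipmt$length <- c(0.5, 0.5)
  expect_equal(ipmt_force(short, p)$l_overlap, 0)
  # doubling the motor density doubles the force
  p2 <- sim_params(lambda_ipmt = 2)
  expect_equal(ipmt_force(spindle, p2)$force[2, 1],
               2 * out$force[2, 1])
  expect_error(ipmt_force(list(spb = matrix(0, 1, 3)), p), "duplicated")
})

test_that("kMT-kinetochore springs push when penetrating, pull across gaps", {
  p <- sim_params()
  spb <- rbind(c(0, 0, 0))
  # KT 1 um away along x; contact distance d_c = 1 - r_kt = 0.9
  kt <- tibble::tibble(x = 1, y = 0, z = 0, body = 1,
                       kmt_length = 0.95, kmt_state = "growing")
  out <- kmt_kt_forces(list(spb = spb, kt = kt), p)
  expect_equal(out$f_kt[1, 1], 0.05 * p$k_fibril) # 0.25 pN push, away from SPB
  expect_equal(out$f_spb[1, 1], -0.05 * p$k_fibril)
  kt$kmt_length <- 0.8; kt$kmt_state <- "shrinking"
  out2 <- kmt_kt_forces(list(spb = spb, kt = kt), p)
  expect_equal(out2$f_kt[1, 1], -0.1 * p$k_c) # 1 pN pull toward the SPB
  expect_equal(out2$f_spb[1, 1], 0.1 * p$k_c)
  kt$kmt_length <- 0.9
  out3 <- kmt_kt_forces(list(spb = spb, kt = kt), p)
  expect_equal(out3$f_kt[1, ], c(0, 0, 0)) # neutral at exact contact
})

test_that("cohesin and hard-core repulsion among kinetochores", {
  p <- sim_params()
  kt <- tibble::tibble(
    x = c(0, 0.5, 0, 0.08), y = c(0, 0, 0.4, 0.4), z = 0,
    sister = c(2L, 1L, NA, NA))
  f <- kt_pair_forces(kt, p)
  # sisters 0.5 um apart attract with 0.05 pN
  expect_equal(f[1, 1] - f[2, 1], 2 * 0.05, tolerance = 1e-9)
  # non-sisters overlapping by 0.12 um repel with c * d_overlap
  ov <- 2 * p$r_kt - 0.08
  expect_equal(f[4, 1] - f[3, 1], 2 * p$c_kt_repulsion * ov, tolerance = 1e-9)
  # internal forces sum to zero
  expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-12)
  # coincident-free, separated non-sisters: nothing
  far <- tibble::tibble(x = c(0, 1), y = 0, z = 0, sister = c(NA, NA))
  expect_equal(kt_pair_forces(far, p), matrix(0, 2, 3))
})

test_that("kMT catastrophe grows linearly with length through the origin", {
  p <- sim_params(h_kmt = 2)
  expect_equal(kmt_length_catastrophe(0, p), 0)
  expect_equal(kmt_length_catastrophe(0.8, p), 1.6)
  expect_equal(kmt_length_catastrophe(1.6, p), 2 * kmt_length_catastrophe(0.8, p))
})

test_that("SPB duplication needs a completed cluster and splits volume", {
  p <- sim_params()
  dirs <- rbind(c(0, 0, 1), c(1, 0, 0))
  expect_error(duplicate_spb(make_assembly(dirs), p), "before")
  a <- make_assembly(matrix(c(0, 0, 1), 1), radius = 0.125 * 14^(1 / 3))
  a$mtoc$founders <- 14L
  set.seed(3)
  out <- duplicate_spb(a, p)
  live <- out$mtoc[out$mtoc$alive, ]
  expect_equal(nrow(live), 2)
  # both on the NE sphere
  expect_equal(sqrt(live$dx^2 + live$dy^2 + live$dz^2), c(1, 1),
               tolerance = 1e-12)
  # volume conserved and split in half
  expect_equal(sum(live$radius^3), 0.125^3 * 14, tolerance = 1e-12)
  expect_equal(live$radius[1], live$radius[2])
  expect_equal(sum(live$founders), 14)
})
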