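# Two-sphere ("snowman") cell geometry: mother sphere, growing daughter bud,
# septin-ring plane at the sphere-sphere intersection, and a cortical shell of
# finite width inside the boundary.

#' Construct the cell geometry at a given time
#'
#' The mother cell is a sphere of radius `r_mother` centred at the origin;
#' the daughter bud grows along `axis` (the mother-to-daughter unit vector).
#' The bud radius increases linearly in time until the final budding index
#' (bud diameter / mother diameter) is reached, then stays constant. The
#' septin ring is the circle where the two spheres intersect; its radius is
#' held at `neck_fraction` times the current bud radius, which fixes the
#' bud-centre position.
#'
#' @param params A `sim_params` object.
#' @param axis Unit 3-vector, mother-to-daughter direction.
#' @param t_min Simulation time in minutes since bud emergence.
#' @return An object of class `cell_geometry` with fields `r_mother`,
#'   `axis`, `bud_radius`, `bud_center`, `septin_a` (axial position of the
#'   septin plane), `septin_r` (ring radius), `budding_index`, `w_cor`.
#' @export
cell_geometry <- function(params, axis = c(0, 0, 1), t_min = 0) {
  stopifnot(inherits(params, "sim_params"))
  axis <- axis / sqrt(sum(axis^2))
  g <- structure(list(
    r_mother = params$r_mother,
    axis = axis,
    w_cor = params$w_cor,
    neck_fraction = params$neck_fraction,
    final_budding_index = params$final_budding_index,
    bud_growth_duration = params$bud_growth_duration,
    bud_radius = 0, bud_center = axis * params$r_mother,
    septin_a = params$r_mother, septin_r = 0,
    budding_index = 0, t_min = 0
  ), class = "cell_geometry")
  grow_bud(g, t_min)
}

#' Advance the daughter bud to time t
#'
#' Linear growth law: the budding index rises linearly from 0 to
#' `final_budding_index` over `bud_growth_duration` minutes, then the bud
#' ceases to grow.
#'
#' @param geometry A `cell_geometry`.
#' @param t_min Time in minutes since bud emergence (>= 0).
#' @return Updated `cell_geometry`.
#' @examples
#' g <- cell_geometry(sim_params())
#' grow_bud(g, 20)$budding_index   # half the final budding index
#' @export
grow_bud <- function(geometry, t_min) {
  stopifnot(inherits(geometry, "cell_geometry"), t_min >= 0)
  g <- geometry
  frac <- min(1, t_min / g$bud_growth_duration)
  bi <- g$final_budding_index * frac
  rb <- g$r_mother * bi
  g$budding_index <- bi
  g$bud_radius <- rb
  g$t_min <- t_min
  if (rb > 1e-9) {
    g$septin_r <- g$neck_fraction * rb
    g$septin_a <- sqrt(g$r_mother^2 - g$septin_r^2)
    g$bud_center <- g$axis * (g$septin_a + sqrt(rb^2 - g$septin_r^2))
  } else {
    g$septin_r <- 0
    g$septin_a <- g$r_mother
    g$bud_center <- g$axis * g$r_mother
  }
  g
}

#' Nearest point of the septin ring to a point
#' @keywords internal
ring_point <- function(geometry, p) {
  ax <- geometry$axis
  s <- sum(p * ax)
  perp <- p - ax * s
  rho <- sqrt(sum(perp^2))
  erho <- if (rho > 1e-12) perp / rho else {
    ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- c(ax[2] * ref[3] - ax[3] * ref[2],
           ax[3] * ref[1] - ax[1] * ref[3],
           ax[1] * ref[2] - ax[2] * ref[1])
    v / sqrt(sum(v^2))
  }
  ax * geometry$septin_a + erho * geometry$septin_r
}

#' Classify a point within the cell
#'
#' Returns the region label, the signed distance to the nearest piece of the
#' cell boundary (positive inside), and the local inward normal. Points
#' within `w_cor` of the boundary are cortex; points outside the cell get
#' region `"outside"` with a negative distance (used for MT boundary
#' handling, not an error).
#'
#' @param geometry A `cell_geometry`.
#' @param p Numeric 3-vector.
#' @return List with `region` (one of `"mother_interior"`, `"mother_cortex"`,
#'   `"daughter_interior"`, `"daughter_cortex"`, `"outside"`), `distance`
#'   (signed, um) and `normal` (inward unit 3-vector).
#' @export
classify_point <- function(geometry, p) {
  g <- geometry
  ax <- g$axis
  s <- sum(p * ax)
  lp <- sqrt(sum(p^2))
  rb <- g$bud_radius
  in_mother <- lp <= g$r_mother
  q <- p - g$bud_center
  lq <- sqrt(sum(q^2))
  in_bud <- rb > 1e-9 && lq <= rb
  inside <- in_mother || in_bud

  # mother boundary cap
  if (lp < 1e-9) {
    dm <- g$r_mother; nm <- c(0, 0, 1)
  } else if (s * g$r_mother / lp <= g$septin_a + 1e-12) {
    dm <- g$r_mother - lp
    nm <- -p / lp
  } else {
    rp <- ring_point(g, p)
    d <- p - rp
    dist <- sqrt(sum(d^2))
    dm <- if (inside) dist else -dist
    nm <- if (dist > 1e-12) d / dist else -ax
    if (!inside) nm <- -nm
  }
  # daughter boundary cap
  if (rb > 1e-9) {
    if (lq < 1e-9) {
      db <- rb; nb <- -ax
    } else {
      s_proj <- sum(g$bud_center * ax) + (s - sum(g$bud_center * ax)) * rb / lq
      if (s_proj >= g$septin_a - 1e-12) {
        db <- rb - lq
        nb <- -q / lq
      } else {
        rp <- ring_point(g, p)
        d <- p - rp
        dist <- sqrt(sum(d^2))
        db <- if (inside) dist else -dist
        nb <- if (dist > 1e-12) d / dist else ax
        if (!inside) nb <- -nb
      }
    }
  } else {
    db <- Inf; nb <- -ax
  }

  if (inside) {
    cand_m <- if (dm >= 0) dm else Inf
    cand_b <- if (is.finite(db) && db >= 0) db else Inf
    if (cand_m <= cand_b) { d_in <- cand_m; n_in <- nm }
    else { d_in <- cand_b; n_in <- nb }
    if (!is.finite(d_in)) { d_in <- max(dm, db, na.rm = TRUE); n_in <- nm }
    daughter <- rb > 1e-9 && s >= g$septin_a
    cortex <- d_in < g$w_cor
    region <- if (daughter) {
      if (cortex) "daughter_cortex" else "daughter_interior"
    } else {
      if (cortex) "mother_cortex" else "mother_interior"
    }
  } else {
    am <- abs(dm); ab <- if (is.finite(db)) abs(db) else Inf
    if (am <= ab) { d_in <- -am; n_in <- nm } else { d_in <- -ab; n_in <- nb }
    region <- "outside"
  }
  list(region = region, distance = d_in, normal = n_in)
}

#' Signed neck-to-nucleus distance
#'
#' Distance from the septin plane to the nucleus centre along the
#' mother-to-daughter axis: negative while the nucleus is inside the mother,
#' positive once it has passed into the daughter.
#'
#' @param geometry A `cell_geometry`.
#' @param nucleus_center Numeric 3-vector.
#' @return Signed distance in um.
#' @export
neck_to_nucleus_distance <- function(geometry, nucleus_center) {
  sum(nucleus_center * geometry$axis) - geometry$septin_a
}

#' Initialize a cell: geometry, nucleus, MTOCs, kinetochores, cMTs
#'
#' The bud site is uniform on the mother surface; the nucleus centre is
#' uniform over the mother interior subject to full containment; the
#' founding MTOCs are placed uniformly on the nuclear envelope with no
#' pairwise overlap (bounded rejection sampling); each MTOC nucleates
#' `n_cmt_per_mtoc` cytoplasmic MTs with outward-hemisphere random
#' orientations, and tethers one kinetochore just beneath the envelope.
#' Deterministic given the seed.
#'
#' @param params A `sim_params` object.
#' @param seed Integer random seed.
#' @return List with `geometry` (a `cell_geometry` at t = 0) and `assembly`:
#'   `nucleus_center`, `mtoc` tibble (id, unit direction, radius, founders),
#'   `kt` tibble (id, position, sister), `cmt` tibble (anchor id, direction).
#' @export
init_cell <- function(params, seed) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  runit <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  axis <- runit()
  geometry <- cell_geometry(params, axis = axis, t_min = 0)
  # nucleus uniform in the ball of radius r_mother - r_nuc
  rmax <- params$r_mother - params$r_nuc
  u <- stats::runif(1)
  nucleus <- runit() * rmax * u^(1 / 3)
  # MTOCs on the NE sphere, non-overlapping
  min_chord <- 2 * params$r_spb
  dirs <- matrix(NA_real_, params$n_kt, 3)
  attempts <- 0
  i <- 1
  while (i <= params$n_kt) {
    attempts <- attempts + 1
    if (attempts > 10000 * params$n_kt) {
      stop("MTOC placement failed after bounded rejection sampling; ",
           "parameters leave too little room on the nuclear envelope",
           call. = FALSE)
    }
    d <- runit()
    ok <- TRUE
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        if (sqrt(sum((d - dirs[j, ])^2)) * params$r_nuc < min_chord) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) {
      dirs[i, ] <- d
      i <- i + 1
    }
  }
  # cMTs: outward-hemisphere directions per MTOC
  n_cmt <- params$n_cmt_per_mtoc
  cmt_anchor <- rep(seq_len(params$n_kt), each = n_cmt)
  cmt_dirs <- matrix(NA_real_, params$n_kt * n_cmt, 3)
  for (k in seq_len(nrow(cmt_dirs))) {
    v <- runit()
    m <- dirs[cmt_anchor[k], ]
    if (sum(v * m) < 0) v <- -v
    cmt_dirs[k, ] <- v
  }
  kt_depth <- params$r_nuc - params$r_spb - params$r_kt
  kt_pos <- sweep(dirs * kt_depth, 2, nucleus, "+")
  sister <- ifelse(seq_len(params$n_kt) %% 2 == 1,
                   seq_len(params$n_kt) + 1, seq_len(params$n_kt) - 1)
  sister[sister > params$n_kt] <- NA_integer_
  assembly <- list(
    nucleus_center = nucleus,
    r_nuc = params$r_nuc,
    mtoc = tibble::tibble(
      id = seq_len(params$n_kt),
      dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3],
      radius = params$r_spb, founders = 1L, alive = TRUE
    ),
    kt = tibble::tibble(
      id = seq_len(params$n_kt),
      x = kt_pos[, 1], y = kt_pos[, 2], z = kt_pos[, 3],
      sister = as.integer(sister)
    ),
    cmt = tibble::tibble(
      anchor = cmt_anchor,
      dx = cmt_dirs[, 1], dy = cmt_dirs[, 2], dz = cmt_dirs[, 3]
    )
  )
  list(geometry = geometry, assembly = assembly)
}

#' Positions of MTOC bodies in the cell frame
#' @keywords internal
mtoc_positions <- function(assembly) {
  m <- assembly$mtoc[assembly$mtoc$alive, , drop = FALSE]
  pos <- cbind(m$dx, m$dy, m$dz) * assembly$r_nuc
  sweep(pos, 2, assembly$nucleus_center, "+")
}
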