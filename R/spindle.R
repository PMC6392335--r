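# Intranuclear mechanics: MTOC fusion into the SPB, SPB duplication,
# interpolar-MT kinesin-5 sliding, kinetochore-MT springs, kinetochore
# cohesion and hard-core repulsion, length-dependent kMT catastrophe.

#' Volume-conserving radius of a merged MTOC pair
#'
#' @param r1,r2 Radii (um) of the fusing bodies.
#' @return Radius of the merged body, `(r1^3 + r2^3)^(1/3)`.
#' @examples
#' merged_radius(0.125, 0.125)  # 0.125 * 2^(1/3)
#' @export
merged_radius <- function(r1, r2) (r1^3 + r2^3)^(1 / 3)

#' Fuse contacting MTOCs on the nuclear envelope
#'
#' Any two live MTOC bodies whose centre distance does not exceed the sum of
#' their radii (plus `contact_tol`) merge into a single body at their
#' volume-weighted midpoint re-projected onto the NE sphere; the merged
#' radius conserves volume. Merging repeats until no contacting pair
#' remains. Clustering is complete when one body holds all founders.
#'
#' @param assembly Assembly list as produced by [init_cell()] (fields
#'   `nucleus_center`, `r_nuc`, `mtoc` tibble with unit directions `dx, dy,
#'   dz`, `radius`, `founders`, `alive`).
#' @param contact_tol Extra contact tolerance in um (default 1e-3).
#' @param time_min Time stamp recorded with the fusion events.
#' @return List with the updated `assembly`, an `events` tibble
#'   (`time_min`, `body_a`, `body_b`, `merged_id`, `n_remaining`), and
#'   `complete` (logical).
#' @export
fuse_mtocs <- function(assembly, contact_tol = 1e-3, time_min = NA_real_) {
  m <- assembly$mtoc
  rn <- assembly$r_nuc
  ctr <- assembly$nucleus_center
  events <- list()
  repeat {
    live <- which(m$alive)
    if (length(live) < 2) break
    pos <- cbind(m$dx[live], m$dy[live], m$dz[live]) * rn
    merged_any <- FALSE
    for (a in seq_along(live)) {
      for (b in seq_along(live)) {
        if (b <= a) next
        i <- live[a]; j <- live[b]
        dist <- sqrt(sum((pos[a, ] - pos[b, ])^2))
        if (dist <= m$radius[i] + m$radius[j] + contact_tol) {
          wi <- m$radius[i]^3; wj <- m$radius[j]^3
          mid <- (pos[a, ] * wi + pos[b, ] * wj) / (wi + wj)
          mid <- mid / sqrt(sum(mid^2)) # re-project onto NE sphere
          m$dx[i] <- mid[1]; m$dy[i] <- mid[2]; m$dz[i] <- mid[3]
          m$radius[i] <- merged_radius(m$radius[i], m$radius[j])
          m$founders[i] <- m$founders[i] + m$founders[j]
          m$alive[j] <- FALSE
          events[[length(events) + 1]] <- tibble::tibble(
            time_min = time_min, body_a = m$id[i], body_b = m$id[j],
            merged_id = m$id[i], n_remaining = sum(m$alive))
          merged_any <- TRUE
          break
        }
      }
      if (merged_any) break
    }
    if (!merged_any) break
  }
  assembly$mtoc <- m
  list(
    assembly = assembly,
    events = if (length(events) > 0) dplyr::bind_rows(events) else
      tibble::tibble(time_min = numeric(), body_a = integer(),
                     body_b = integer(), merged_id = integer(),
                     n_remaining = integer()),
    complete = sum(m$alive) == 1
  )
}

#' Kinesin-5 sliding force between duplicated SPBs
#'
#' The total antiparallel overlap of the interpolar MTs nucleated from the
#' two SPBs generates an outward (SPB-separating) force of magnitude
#' `l_overlap * lambda_ipmt * f_kinesin5`, applied equally and oppositely.
#'
#' @param spindle List with `spb` (2 x 3 matrix of SPB positions) and
#'   `ipmt` tibble (`spb` in \{1, 2\}, `length` um).
#' @param params A `sim_params` object.
#' @return List with `force` (2 x 3 matrix, pN; row i acts on SPB i) and
#'   `l_overlap` (um).
#' @export
ipmt_force <- function(spindle, params) {
  if (is.null(spindle$spb) || nrow(spindle$spb) < 2) {
    stop("ipmt_force requires a duplicated spindle (two SPBs)", call. = FALSE)
  }
  d12 <- spindle$spb[2, ] - spindle$spb[1, ]
  dd <- sqrt(sum(d12^2))
  u <- if (dd > 1e-9) d12 / dd else c(1, 0, 0)
  l1 <- spindle$ipmt$length[spindle$ipmt$spb == 1]
  l2 <- spindle$ipmt$length[spindle$ipmt$spb == 2]
  l_ov <- 0
  for (a in l1) for (b in l2) {
    ov <- min(a, dd) - max(0, dd - b)
    if (ov > 0) l_ov <- l_ov + ov
  }
  f <- l_ov * params$lambda_ipmt * params$f_kinesin5
  list(force = rbind(-u * f, u * f), l_overlap = l_ov)
}

#' Kinetochore-MT spring forces
#'
#' A growing kMT tip penetrating its kinetochore by `l_pen` pushes the
#' kinetochore away from the SPB with `l_pen * K_fibril`; a shrinking tip
#' with gap `l_gap` pulls it toward the SPB with `l_gap * K_c`. The
#' reaction acts on the SPB.
#'
#' @param spindle List with `spb` (matrix of SPB/MTOC positions) and `kt`
#'   tibble (`x, y, z`, `body` = SPB row index, `kmt_length` um,
#'   `kmt_state` `"growing"`/`"shrinking"`).
#' @param params A `sim_params` object.
#' @return List with `f_kt` (n x 3, pN per kinetochore) and `f_spb`
#'   (matrix, reactions per SPB row).
#' @export
kmt_kt_forces <- function(spindle, params) {
  kt <- spindle$kt
  n <- nrow(kt)
  f_kt <- matrix(0, n, 3)
  f_spb <- matrix(0, nrow(spindle$spb), 3)
  for (k in seq_len(n)) {
    b <- kt$body[k]
    d <- c(kt$x[k], kt$y[k], kt$z[k]) - spindle$spb[b, ]
    d_bk <- sqrt(sum(d^2))
    if (d_bk < 1e-9) next
    u <- d / d_bk
    d_c <- d_bk - params$r_kt
    l_pen <- kt$kmt_length[k] - d_c
    if (l_pen > 0) {
      l_pen <- min(l_pen, 2 * params$r_kt)
      f <- l_pen * params$k_fibril
      f_kt[k, ] <- f_kt[k, ] + u * f
      f_spb[b, ] <- f_spb[b, ] - u * f
    } else if (d_c - kt$kmt_length[k] > 0) {
      # pulling state: tip short of the kinetochore leaves a gap l_gap > 0
      l_gap <- d_c - kt$kmt_length[k]
      f <- l_gap * params$k_c
      f_kt[k, ] <- f_kt[k, ] - u * f
      f_spb[b, ] <- f_spb[b, ] + u * f
    }
  }
  list(f_kt = f_kt, f_spb = f_spb)
}

#' Cohesin and hard-core repulsion forces among kinetochores
#'
#' Sister kinetochores attract with a Hookean cohesin force
#' `K_cohesion * d_separation`; any overlapping kinetochore pair repels
#' with `C * d_overlap` (C = `c_kt_repulsion`).
#'
#' @param kt Tibble with `x, y, z` and integer `sister` (NA for unpaired).
#' @param params A `sim_params` object.
#' @return n x 3 matrix of forces (pN); rows sum to the zero vector.
#' @export
kt_pair_forces <- function(kt, params) {
  n <- nrow(kt)
  f <- matrix(0, n, 3)
  pos <- cbind(kt$x, kt$y, kt$z)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      d <- pos[j, ] - pos[i, ]
      dist <- sqrt(sum(d^2))
      if (dist < 1e-9) next
      u <- d / dist
      if (!is.na(kt$sister[i]) && kt$sister[i] == j) {
        fc <- params$k_cohesion * dist
        f[i, ] <- f[i, ] + u * fc
        f[j, ] <- f[j, ] - u * fc
      }
      ov <- 2 * params$r_kt - dist
      if (ov > 0) {
        fr <- params$c_kt_repulsion * ov
        f[i, ] <- f[i, ] - u * fr
        f[j, ] <- f[j, ] + u * fr
      }
    }
  }
  f
}

#' Length-dependent kMT catastrophe rate
#'
#' The catastrophe frequency of a kinetochore MT grows linearly with its
#' length, `f_c = h l`, replacing the free-MT catastrophe rate and keeping
#' the SPB-kinetochore separation bounded.
#'
#' @param l_kmt kMT length in um (>= 0).
#' @param params A `sim_params` object.
#' @return Catastrophe rate in 1/min.
#' @examples
#' kmt_length_catastrophe(0.8, sim_params(h_kmt = 2))  # 1.6 per min
#' @export
kmt_length_catastrophe <- function(l_kmt, params) {
  stopifnot(all(l_kmt >= 0))
  params$h_kmt * l_kmt
}

#' Duplicate the spindle pole body after clustering completes
#'
#' Replaces the single fused SPB by two bodies of equal (volume-halved)
#' size offset by `2 r_spb` along a random tangent of the nuclear envelope;
#' sister kinetochores are attached to opposite SPBs (bi-orientation) with
#' kMTs spanning the current gap.
#'
#' @param assembly Assembly list (as in [fuse_mtocs()]); exactly one live
#'   MTOC body required.
#' @param params A `sim_params` object.
#' @return Updated assembly with two live SPB rows and a `kt$body` column.
#' @export
duplicate_spb <- function(assembly, params) {
  m <- assembly$mtoc
  live <- which(m$alive)
  if (length(live) != 1) {
    stop("duplicate_spb called before MTOC clustering completed (",
         length(live), " bodies remain)", call. = FALSE)
  }
  i0 <- live
  n0 <- c(m$dx[i0], m$dy[i0], m$dz[i0])
  r_half <- (m$radius[i0]^3 / 2)^(1 / 3)
  tv <- stats::rnorm(3)
  tv <- tv - n0 * sum(tv * n0)
  tv <- tv / sqrt(sum(tv^2))
  rn <- assembly$r_nuc
  d1 <- (n0 * rn + tv * params$r_spb); d1 <- d1 / sqrt(sum(d1^2))
  d2 <- (n0 * rn - tv * params$r_spb); d2 <- d2 / sqrt(sum(d2^2))
  new_ids <- max(m$id) + 1:2
  m$alive[i0] <- FALSE
  m <- dplyr::bind_rows(m, tibble::tibble(
    id = new_ids, dx = c(d1[1], d2[1]), dy = c(d1[2], d2[2]),
    dz = c(d1[3], d2[3]), radius = r_half,
    founders = c(m$founders[i0] %/% 2L,
                 m$founders[i0] - m$founders[i0] %/% 2L),
    alive = TRUE))
  assembly$mtoc <- m
  if (!is.null(assembly$kt)) {
    assembly$kt$body <- rep(new_ids, length.out = nrow(assembly$kt))
  }
  assembly
}
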