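## Synthetic dome-aneurysm generator, aneurysm domain container and the
## micro-catheter spline with its tessellated tube obstacle.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}

#' Aneurysm domain
#'
#' Bundles the two-phase wall geometry (neck-cut dome for insertion, full
#' vessel for the final phase), the neck plane and the catheter.
#'
#' @param dome_mesh closed, outward-oriented \code{surface_mesh} of the
#'   neck-cut aneurysm sack (phase 1 wall)
#' @param vessel_mesh \code{surface_mesh} of the full vessel (phase 2 wall)
#' @param neck_plane list(point, normal); normal points into the dome
#' @param neck_radius radius (mm) of the inscribed circle of the neck
#'   opening
#' @param catheter optional \code{catheter_spline}
#' @return object of class \code{aneurysm_domain} with the aneurysm volume
#'   \code{V_A} (mm^3, divergence theorem on the dome mesh) and the neck
#'   opening center
#' @export
aneurysm_domain <- function(dome_mesh, vessel_mesh = NULL, neck_plane,
                            neck_radius, catheter = NULL) {
  validate_mesh(dome_mesh)
  if (is.null(vessel_mesh)) vessel_mesh <- dome_mesh
  structure(list(dome_mesh = dome_mesh, vessel_mesh = vessel_mesh,
                 neck_plane = neck_plane, neck_radius = neck_radius,
                 neck_center = neck_plane$point,
                 V_A = mesh_volume(dome_mesh),
                 catheter = catheter),
            class = "aneurysm_domain")
}

#' @export
print.aneurysm_domain <- function(x, ...) {
  cat(sprintf("<aneurysm_domain> V_A = %.2f mm^3, neck radius %.2f mm, dome mesh %d faces\n",
              x$V_A, x$neck_radius, nrow(x$dome_mesh$faces)))
  invisible(x)
}

#' Generate a synthetic dome aneurysm
#'
#' A spherical sack of radius \code{dome_radius} cut by a circular neck of
#' radius \code{neck_radius}, optionally perturbed by smooth seeded radial
#' bumps for ensemble variety.  The phase-1 dome is capped at the neck; the
#' full-vessel mesh continues into a short parent-vessel stub (a tube of
#' radius \code{parent_radius} below the neck, capped at its far end) so
#' the final simulation phase allows sagging toward the parent artery.
#' Default sizes fall in the clinically most frequent "very small" class
#' (dome diameter 2-7 mm).
#'
#' @param dome_radius sack radius (mm)
#' @param neck_radius neck opening radius (mm), < dome_radius
#' @param parent_radius parent-vessel stub radius (mm); defaults to the
#'   neck radius
#' @param resolution azimuthal segment count of the triangulation
#' @param seed integer seed for the bump perturbation; NULL disables
#' @param bump_amplitude relative amplitude of the radial bumps
#' @param n_bumps number of bumps
#' @param stub_length parent stub length (mm)
#' @return an \code{aneurysm_domain} (without catheter; see
#'   \code{\link{default_catheter}})
#' @export
make_synthetic_aneurysm <- function(dome_radius = 2.5, neck_radius = 1,
                                    parent_radius = NULL, resolution = 40,
                                    seed = NULL, bump_amplitude = 0,
                                    n_bumps = 3, stub_length = 4) {
  R <- dome_radius; rn <- neck_radius
  if (!(rn > 0 && rn < R)) stop("need 0 < neck_radius < dome_radius")
  if (is.null(parent_radius)) parent_radius <- rn
  zn <- sqrt(R^2 - rn^2)            # neck plane at z = -zn
  theta_max <- pi - asin(rn / R)    # polar angle of the neck circle
  nphi <- as.integer(resolution)
  nth <- max(8L, as.integer(round(resolution * theta_max / (2 * pi) * 2)))
  phis <- seq(0, 2 * pi, length.out = nphi + 1L)[-(nphi + 1L)]
  thetas <- seq(0, theta_max, length.out = nth + 1L)[-1L]

  bumps <- NULL
  if (!is.null(seed) && bump_amplitude > 0) {
    bumps <- with_seed(seed, {
      dirs <- matrix(rnorm(3L * n_bumps), ncol = 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      dirs[, 3] <- abs(dirs[, 3])    # keep bumps away from the neck
      dirs <- dirs / sqrt(rowSums(dirs^2))
      list(dir = dirs, amp = runif(n_bumps, 0, bump_amplitude),
           width = runif(n_bumps, 0.4, 0.8))
    })
  }
  radial <- function(th, ph) {
    r <- R
    if (!is.null(bumps)) {
      p <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
      taper <- (theta_max - th) / theta_max
      for (k in seq_along(bumps$amp)) {
        ang <- acos(pmax(-1, pmin(1, sum(p * bumps$dir[k, ]))))
        r <- r + R * bumps$amp[k] * exp(-ang^2 / (2 * bumps$width[k]^2)) * taper
      }
    }
    r
  }

  # ring vertices; last ring lies exactly on the neck circle
  vtx <- matrix(c(0, 0, R), 1, 3)    # top pole
  ring_start <- integer(nth)
  for (i in seq_len(nth)) {
    th <- thetas[i]
    ring_start[i] <- nrow(vtx) + 1L
    ring <- t(vapply(phis, function(ph) {
      r <- if (i == nth) R else radial(th, ph)
      c(r * sin(th) * cos(ph), r * sin(th) * sin(ph), r * cos(th))
    }, numeric(3)))
    if (i == nth) ring[, 3] <- -zn   # exact neck plane
    vtx <- rbind(vtx, ring)
  }

  faces <- list()
  # top fan
  for (j in seq_len(nphi)) {
    j2 <- j %% nphi + 1L
    faces[[length(faces) + 1L]] <- c(1L, ring_start[1] + j - 1L, ring_start[1] + j2 - 1L)
  }
  band <- function(r0, r1, nseg) {
    out <- vector("list", 2L * nseg)
    for (j in seq_len(nseg)) {
      j2 <- j %% nseg + 1L
      a <- r0 + j - 1L; b <- r1 + j - 1L; c3 <- r1 + j2 - 1L; d <- r0 + j2 - 1L
      out[[2L * j - 1L]] <- c(a, b, c3)
      out[[2L * j]] <- c(a, c3, d)
    }
    out
  }
  for (i in seq_len(nth - 1L))
    faces <- c(faces, band(ring_start[i], ring_start[i + 1L], nphi))

  dome_open_v <- vtx
  dome_open_f <- do.call(rbind, faces)
  neck_ring <- ring_start[nth] + seq_len(nphi) - 1L

  # phase-1 dome: cap the neck opening (outward normal -z)
  capc <- nrow(dome_open_v) + 1L
  dv <- rbind(dome_open_v, c(0, 0, -zn))
  df <- dome_open_f
  for (j in seq_len(nphi)) {
    j2 <- j %% nphi + 1L
    df <- rbind(df, c(capc, neck_ring[j2], neck_ring[j]))
  }
  dome <- surface_mesh(dv, df)

  # full vessel: dome + flare to the stub radius + tube + bottom cap
  vv <- dome_open_v
  vf <- faces
  prev_ring <- neck_ring
  zs <- c(-zn - 0.2 * stub_length, -zn - stub_length)
  rs <- c(parent_radius, parent_radius)
  for (q in seq_along(zs)) {
    rs_start <- nrow(vv) + 1L
    ring <- t(vapply(phis, function(ph) c(rs[q] * cos(ph), rs[q] * sin(ph), zs[q]), numeric(3)))
    vv <- rbind(vv, ring)
    vf <- c(vf, band(prev_ring[1], rs_start, nphi))
    prev_ring <- rs_start + seq_len(nphi) - 1L
  }
  bc <- nrow(vv) + 1L
  vv <- rbind(vv, c(0, 0, zs[2]))
  vfm <- do.call(rbind, vf)
  for (j in seq_len(nphi)) {
    j2 <- j %% nphi + 1L
    vfm <- rbind(vfm, c(bc, prev_ring[j2], prev_ring[j]))
  }
  vessel <- surface_mesh(vv, vfm)
  validate_mesh(vessel)

  aneurysm_domain(dome_mesh = dome, vessel_mesh = vessel,
                  neck_plane = list(point = c(0, 0, -zn), normal = c(0, 0, 1)),
                  neck_radius = rn)
}

## ---- catheter ------------------------------------------------------------

#' Micro-catheter spline
#'
#' Quadratic B\\'ezier through three control points, arc-length tabulated,
#' with a tessellated open tube ("cylindrical surface without lids") used as
#' a rigid obstacle for the released part of the coil.
#'
#' @param control_points 3 x 3 matrix, rows = control points (mm); the coil
#'   travels from row 1 toward row 3 (the tip)
#' @param radius tube radius (mm)
#' @param tube_sides,tube_rings tessellation of the obstacle tube
#' @return object of class \code{catheter_spline} with the arc table,
#'   total arc length, tip point/tangent and tube mesh (vertices, faces)
#' @export
catheter_spline <- function(control_points, radius = 0.35,
                            tube_sides = 10, tube_rings = NULL) {
  P <- as.matrix(control_points)
  if (!all(dim(P) == c(3L, 3L))) stop("control_points must be a 3 x 3 matrix")
  tfine <- seq(0, 1, length.out = 2000L)
  bez <- function(t) {
    outer((1 - t)^2, P[1, ]) + outer(2 * (1 - t) * t, P[2, ]) + outer(t^2, P[3, ])
  }
  dbez <- function(t) {
    outer(2 * (1 - t), P[2, ] - P[1, ]) + outer(2 * t, P[3, ] - P[2, ])
  }
  pf <- bez(tfine)
  arc <- c(0, cumsum(sqrt(rowSums(diff(pf)^2))))
  S <- arc[length(arc)]
  if (S <= 0) stop("catheter spline has zero length")
  ns <- 1000L
  sgrid <- seq(0, S, length.out = ns + 1L)
  tg <- approx(arc, tfine, xout = sgrid, rule = 2)$y
  pts <- bez(tg)
  tans <- dbez(tg)
  tans <- tans / sqrt(rowSums(tans^2))
  # open tube mesh along the spline (parallel-transported ring frame)
  if (is.null(tube_rings)) tube_rings <- max(10L, ceiling(S / 0.6))
  ridx <- round(seq(1, ns + 1L, length.out = tube_rings))
  tv <- NULL
  a1 <- tans[1, ]
  ref <- if (abs(a1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * a1) * a1; u <- u / sqrt(sum(u^2))
  ang <- seq(0, 2 * pi, length.out = tube_sides + 1L)[-(tube_sides + 1L)]
  prev_t <- a1
  for (k in ridx) {
    tk <- tans[k, ]
    u <- as.double(rodrigues_rotation(prev_t, tk) %*% u)
    u <- u - sum(u * tk) * tk; u <- u / sqrt(sum(u^2))
    w <- c(tk[2] * u[3] - tk[3] * u[2], tk[3] * u[1] - tk[1] * u[3], tk[1] * u[2] - tk[2] * u[1])
    ring <- t(vapply(ang, function(a) pts[k, ] + radius * (cos(a) * u + sin(a) * w), numeric(3)))
    tv <- rbind(tv, ring)
    prev_t <- tk
  }
  tf <- NULL
  for (i in seq_len(length(ridx) - 1L)) {
    r0 <- (i - 1L) * tube_sides
    for (j in seq_len(tube_sides)) {
      j2 <- j %% tube_sides + 1L
      a <- r0 + j; b <- r0 + tube_sides + j; c3 <- r0 + tube_sides + j2; d <- r0 + j2
      tf <- rbind(tf, c(a, b, c3), c(a, c3, d))
    }
  }
  structure(list(control_points = P, radius = radius,
                 arc_points = pts, arc_tangents = tans,
                 ds = S / ns, arc_length = S,
                 tip = pts[ns + 1L, ], tip_tangent = tans[ns + 1L, ],
                 tube_vertices = tv, tube_faces = tf),
            class = "catheter_spline")
}

#' @export
print.catheter_spline <- function(x, ...) {
  cat(sprintf("<catheter_spline> arc length %.2f mm, radius %.2f mm, tip at (%.2f, %.2f, %.2f)\n",
              x$arc_length, x$radius, x$tip[1], x$tip[2], x$tip[3]))
  invisible(x)
}

#' Default catheter for a synthetic dome
#'
#' Approaches through the parent stub along the neck axis, slightly
#' off-center and tilted, with the tip about half a neck radius past the
#' neck plane.
#'
#' @param domain an \code{aneurysm_domain}
#' @param tip_inset how far past the neck plane the tip sits (mm)
#' @param radius tube radius (mm)
#' @return a \code{catheter_spline}
#' @export
default_catheter <- function(domain, tip_inset = NULL, radius = 0.35) {
  zn <- domain$neck_plane$point[3]
  rn <- domain$neck_radius
  if (is.null(tip_inset)) tip_inset <- 0.6 * rn
  P <- rbind(c(0.15 * rn, 0, zn - 6),
             c(-0.1 * rn, 0.1 * rn, zn - 2),
             c(0.25 * rn, 0.2 * rn, zn + tip_inset))
  catheter_spline(P, radius = radius)
}

#' Perturb the catheter tip
#'
#' Translates the tip control point by a vector drawn uniformly from a ball
#' of the given radius (seeded, reproducible) and rebuilds the spline.
#'
#' @param catheter a \code{catheter_spline}
#' @param radius ball radius (mm)
#' @param seed integer seed
#' @return a perturbed \code{catheter_spline}
#' @export
perturb_catheter_tip <- function(catheter, radius = 1, seed = NULL) {
  if (radius == 0) return(catheter)
  off <- with_seed(seed, {
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    (radius * runif(1)^(1 / 3)) * d
  })
  P <- catheter$control_points
  P[3, ] <- P[3, ] + off
  catheter_spline(P, radius = catheter$radius)
}
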