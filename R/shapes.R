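## Natural-shape programs for coils: straight, helix and complex 3D shapes
## traced as loops on a sphere, all discretized with exactly constant edge
## length and encoded as rest curvatures with zero rest twist.

#' Coil shape program
#'
#' Describes the imprinted natural shape of a coil: \code{"straight"},
#' \code{"helix"} (constant curvature, loop diameter D3) or
#' \code{"complex3d"} (spline loops of varying orientation on a sphere of
#' diameter D3, the typical geometry of framing coils).
#'
#' @param kind one of "straight", "helix", "complex3d"
#' @param D3 imprint diameter (mm)
#' @param length arc length L (mm)
#' @param n_nodes number of centerline nodes N
#' @param loop_spacing axial distance between helix loops (mm); default
#'   \code{1.2 * D2} at realization time
#' @return object of class \code{shape_program}
#' @export
shape_program <- function(kind = c("helix", "straight", "complex3d"),
                          D3, length, n_nodes, loop_spacing = NULL) {
  kind <- match.arg(kind)
  stopifnot(D3 > 0, length > 0, n_nodes >= 3)
  structure(list(kind = kind, D3 = D3, length = length,
                 n_nodes = as.integer(n_nodes), loop_spacing = loop_spacing),
            class = "shape_program")
}

# Equal-chord discretization of a smooth curve given as fun(t) over
# t in [0, 1]: N points on the curve with exactly equal consecutive chords
# (outer bisection on the chord length, inner bisection per point).
equal_chord_resample <- function(fun, n_nodes, t_hint = NULL) {
  tf <- seq(0, 1, length.out = 4000L)
  pf <- fun(tf)
  arc <- c(0, cumsum(sqrt(rowSums(diff(pf)^2))))
  S <- arc[length(arc)]
  next_t <- function(t0, chord) {
    p0 <- fun(t0)
    g <- function(t) sqrt(sum((fun(t) - p0)^2)) - chord
    lo <- t0; hi <- min(1, t0 + 2.5 * chord / S * 1.5 + 1e-3)
    while (g(hi) < 0 && hi < 1) hi <- min(1, hi + (hi - t0))
    if (g(hi) < 0) return(NA_real_)
    for (k in 1:60) {
      mid <- 0.5 * (lo + hi)
      if (g(mid) < 0) lo <- mid else hi <- mid
    }
    0.5 * (lo + hi)
  }
  place <- function(chord) {
    ts <- numeric(n_nodes); ts[1] <- 0
    for (i in 2:n_nodes) {
      ts[i] <- next_t(ts[i - 1], chord)
      if (is.na(ts[i])) return(list(ok = FALSE, short = TRUE, ts = ts))
    }
    list(ok = TRUE, ts = ts)
  }
  lo <- 0.5 * S / (n_nodes - 1); hi <- 1.5 * S / (n_nodes - 1)
  for (k in 1:40) {
    mid <- 0.5 * (lo + hi)
    r <- place(mid)
    if (!r$ok || r$ts[n_nodes] > 1) hi <- mid else lo <- mid
  }
  r <- place(lo)
  if (!r$ok) stop("equal-chord resampling failed")
  fun(r$ts)
}

#' Realize a natural shape from a program and a coil spec
#'
#' Generates the natural centerline with constant edge length and extracts
#' rest curvatures with the package's discrete operators; the natural
#' configuration is parametrized by its Bishop frame, so the rest twist is
#' identically zero.
#'
#' @param program a \code{shape_program}
#' @param spec a \code{coil_spec} (supplies D2 for the default helix loop
#'   spacing)
#' @return a \code{coil_natural_shape}
#' @export
natural_shape <- function(program, spec) {
  N <- program$n_nodes
  L <- program$length
  el <- L / (N - 1)
  verts <- switch(
    program$kind,
    straight = cbind(seq(0, L, length.out = N), 0, 0),
    helix = {
      r <- program$D3 / 2
      spacing <- if (is.null(program$loop_spacing)) 1.2 * spec$D2 else program$loop_spacing
      cpitch <- spacing / (2 * pi)
      speed <- sqrt(r^2 + cpitch^2)     # arc length per unit angle
      Ttot <- L / speed
      th <- seq(0, Ttot, length.out = N)
      cbind(r * cos(th), r * sin(th), cpitch * th)
    },
    complex3d = {
      rho <- program$D3 / 2
      n_loops <- max(2, L / (2 * pi * rho))
      fun <- function(t) {
        u <- 2 * pi * n_loops * t
        chi <- 0.9 * pi * t            # slow tilt of the loop plane
        psi <- 2.2 * pi * t            # slow precession about z
        e1 <- cbind(cos(psi), sin(psi), 0)
        e2 <- cbind(-sin(psi) * cos(chi), cos(psi) * cos(chi), sin(chi))
        rr <- rho * (0.92 + 0.08 * cos(0.5 * u))
        rr * (cos(u) * e1 + sin(u) * e2)
      }
      equal_chord_resample(fun, N)
    })
  ns <- natural_shape_from_vertices(verts)
  # normalize total arc length to L exactly (chord sums differ from the
  # smooth arc length at finite N)
  sc <- L / sum(ns$rest_edge_lengths)
  if (abs(sc - 1) > 1e-12)
    ns <- natural_shape_from_vertices(verts * sc)
  stopifnot(max(abs(ns$rest_edge_lengths - mean(ns$rest_edge_lengths))) <
              1e-6 * mean(ns$rest_edge_lengths) + 1e-9)
  attr(ns, "program") <- program
  ns
}

#' Coil length needed for a target packing density
#'
#' Packing density is the inserted coil volume (cross-section
#' \eqn{\pi (D_2/2)^2} times arc length) relative to the aneurysm sack
#' volume.
#'
#' @param domain an \code{aneurysm_domain}
#' @param D2 coil diameter (mm)
#' @param packing_density target fraction (e.g. 0.2)
#' @return coil length in mm
#' @export
coil_length_for_pd <- function(domain, D2, packing_density) {
  packing_density * domain$V_A / (pi * (D2 / 2)^2)
}
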