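## R-level surface of the contact module: parameter container, detection
## wrappers over the compiled octree kernels, and the individual normal /
## friction force formulas.

#' Contact and friction parameters
#'
#' Penalty spring constants, dissipation coefficients and Coulomb friction
#' coefficients.  Spring constants left NULL are resolved at run time to a
#' multiple of the bending-stiffness scale \eqn{b/\bar\ell^3} of the coil
#' being simulated.  The friction coefficients default to values larger
#' than in compliant-wall models, standing in for the tangential resistance
#' a deformable wall would provide.
#'
#' @param k_sc,gamma_sc coil-coil contact spring (mN/mm) and dissipation
#' @param k_w,gamma_w coil-wall contact spring and dissipation
#' @param mu_slip_cc coil-coil slip friction coefficient
#' @param mu_slip_cw,mu_stick_cw wall slip/stick friction coefficients
#'   (stick >= slip)
#' @param v_eps stick/slip velocity threshold (mm/s)
#' @return object of class \code{friction_params}
#' @export
friction_params <- function(k_sc = NULL, gamma_sc = NULL, k_w = NULL, gamma_w = NULL,
                            mu_slip_cc = 0.4, mu_slip_cw = 0.4, mu_stick_cw = 0.6,
                            v_eps = 1e-3) {
  if (mu_stick_cw < mu_slip_cw) stop("mu_stick_cw must be >= mu_slip_cw")
  structure(list(k_sc = k_sc, gamma_sc = gamma_sc, k_w = k_w, gamma_w = gamma_w,
                 mu_slip_cc = mu_slip_cc, mu_slip_cw = mu_slip_cw,
                 mu_stick_cw = mu_stick_cw, v_eps = v_eps),
            class = "friction_params")
}

# Fill NULL spring constants from the coil's stiffness scale and pack the
# parameter vector for the compiled kernels.
resolve_contact_params <- function(fp, spec, elbar_ref) {
  kscale <- 20 * spec$b / elbar_ref^3
  k_sc <- if (is.null(fp$k_sc)) kscale else fp$k_sc
  k_w <- if (is.null(fp$k_w)) kscale else fp$k_w
  m_ref <- spec$mass_per_length * elbar_ref
  g_sc <- if (is.null(fp$gamma_sc)) sqrt(k_sc * m_ref) / spec$D2 else fp$gamma_sc
  g_w <- if (is.null(fp$gamma_w)) sqrt(k_w * m_ref) else fp$gamma_w
  c(k_sc, g_sc, k_w, g_w, fp$mu_slip_cc, fp$mu_slip_cw, fp$mu_stick_cw,
    fp$v_eps, spec$D2)
}

#' Octree broad-phase candidate pairs for coil self-contact
#'
#' All non-adjacent edge pairs whose centers are within
#' \eqn{\sqrt{(\bar\ell/2)^2 + D_2^2}} of each other -- a guaranteed
#' superset of the true contacts.  The octree over edge centers is rebuilt
#' on every call.
#'
#' @param state a \code{rod_state}
#' @param spec a \code{coil_spec} (for D2)
#' @param rest_len reference rest edge length; default mean current length
#' @param virtual_edge optional integer flags of virtual connector edges
#' @return two-column integer matrix of edge index pairs (i < j)
#' @export
candidate_pairs_coil <- function(state, spec, rest_len = NULL, virtual_edge = NULL) {
  ne <- nrow(state$x) - 1L
  if (is.null(rest_len)) rest_len <- mean(edge_lengths(state))
  if (is.null(virtual_edge)) virtual_edge <- integer(ne)
  cpp_candidate_pairs(state$x, rest_len, spec$D2, as.integer(virtual_edge))
}

#' Minimum distance between two segments
#'
#' Exact minimum distance between the closed segments [p1, q1] and
#' [p2, q2] with the realizing vector and parameters.
#'
#' @param p1,q1,p2,q2 segment endpoints (3-vectors)
#' @return list with \code{distance}, \code{vector} (from segment 1 toward
#'   segment 2), parameters \code{s}, \code{t} and the closest points
#' @export
min_distance_segments <- function(p1, q1, p2, q2) {
  if (sum((q1 - p1)^2) == 0 || sum((q2 - p2)^2) == 0)
    stop("zero-length segment")
  cpp_seg_dist(as.double(p1), as.double(q1), as.double(p2), as.double(q2))
}

#' Detect coil self-collisions
#'
#' Narrow phase over the octree candidates: a pair is in contact iff the
#' centerline distance does not exceed the coil diameter D2; the overlap is
#' \eqn{\epsilon = D_2 - d_{min}}.
#'
#' @inheritParams candidate_pairs_coil
#' @return data frame of contacts (edge indices, distance, overlap,
#'   barycentric parameters, minimum-distance vector)
#' @export
detect_coil_collisions <- function(state, spec, rest_len = NULL, virtual_edge = NULL) {
  ne <- nrow(state$x) - 1L
  if (is.null(rest_len)) rest_len <- mean(edge_lengths(state))
  if (is.null(virtual_edge)) virtual_edge <- integer(ne)
  cpp_detect_coil(state$x, rest_len, spec$D2, as.integer(virtual_edge))
}

#' Detect coil-wall collisions
#'
#' Broad phase via an octree over triangle centers with per-triangle
#' enclosing-sphere radii; narrow phase tests each node against the
#' candidate triangles within reach D2/2.  By default the closest feature
#' (face, edge or vertex) is used; \code{literal = TRUE} restricts to
#' in-triangle plane projections.
#'
#' @param state a \code{rod_state} (or an N x 3 point matrix)
#' @param wall a \code{surface_mesh}
#' @param spec a \code{coil_spec} (for D2)
#' @param literal projection-only narrow phase
#' @return data frame of node-triangle contacts with distance, penetration
#'   and push direction
#' @export
detect_wall_collisions <- function(state, wall, spec, literal = FALSE) {
  P <- if (inherits(state, "rod_state")) state$x else as.matrix(state)
  cpp_detect_wall(P, wall$vertices, wall$faces - 1L, spec$D2, literal)
}

#' Coil-coil contact normal force
#'
#' Penalty force on the edge-i side of a detected pair:
#' \deqn{F = -H(\epsilon)\,(k_{sc}\epsilon + \gamma_{sc}(\dot x_i - \dot
#' x_j)\cdot d_{min})\, d_{min}} with velocities interpolated to the
#' contact points and \eqn{d_{min}} the (unnormalized) minimum-distance
#' vector; the opposite force acts on edge j.
#'
#' @param overlap \eqn{\epsilon = D_2 - d_{min}} (mm); no force if negative
#' @param dmin_vec minimum-distance vector from edge i toward edge j
#' @param v_i,v_j velocities at the two contact points (mm/s)
#' @param params resolved parameter vector or \code{friction_params} with
#'   explicit k_sc, gamma_sc
#' @return list with \code{force_i}, \code{force_j} (mN) and the normal
#'   force magnitude
#' @export
coil_coil_normal_force <- function(overlap, dmin_vec, v_i, v_j, params) {
  k <- params$k_sc; g <- params$gamma_sc
  if (overlap < 0) {
    z <- c(0, 0, 0)
    return(list(force_i = z, force_j = z, magnitude = 0))
  }
  mag <- k * overlap + g * sum((v_i - v_j) * dmin_vec)
  Fi <- -mag * dmin_vec
  list(force_i = Fi, force_j = -Fi,
       magnitude = abs(mag) * sqrt(sum(dmin_vec^2)))
}

#' Coil-wall contact normal force
#'
#' Reaction along the wall normal: cancels the wall-normal part of the
#' node's elastic + coil-coil force and adds the penalty and damping terms,
#' \eqn{F = H(\epsilon)(\|F_\perp\| + k_w\epsilon - \gamma_w \dot x\cdot
#' n)\,n} with \eqn{n} the push direction (away from the surface, toward
#' the node's side).
#'
#' @param overlap penetration \eqn{\epsilon = D_2/2 - d} (mm)
#' @param n unit push direction
#' @param f_node elastic + coil-coil force at the node (mN)
#' @param v velocity of the node (mm/s)
#' @param params \code{friction_params} with explicit k_w, gamma_w
#' @return force 3-vector (mN)
#' @export
wall_normal_force <- function(overlap, n, f_node, v, params) {
  if (overlap < 0) return(c(0, 0, 0))
  Fperp <- sum(f_node * n) * n
  (sqrt(sum(Fperp^2)) + params$k_w * overlap - params$gamma_w * sum(v * n)) * n
}

#' Coil-coil slip friction
#'
#' \eqn{F = -\mu_{slip,CC}\,\|F_\perp\|\, v_\parallel/\|v_\parallel\|}
#' with the relative tangential velocity at the contact point; zero at
#' vanishing tangential velocity (no stick branch in the coil-coil model).
#'
#' @param normal_magnitude \eqn{\|F_\perp\|} of the pair's normal force
#' @param v_rel relative velocity at the contact point
#' @param dmin_vec minimum-distance vector (defines the normal direction)
#' @param params \code{friction_params}
#' @return friction force on the edge-i side (mN)
#' @export
coil_coil_friction <- function(normal_magnitude, v_rel, dmin_vec, params) {
  d2 <- sum(dmin_vec^2)
  vpar <- v_rel - sum(v_rel * dmin_vec) / d2 * dmin_vec
  vn <- sqrt(sum(vpar^2))
  if (vn < 1e-14) return(c(0, 0, 0))
  -params$mu_slip_cc * normal_magnitude * vpar / vn
}

#' Coil-wall stick-slip friction
#'
#' Below the velocity threshold the tangential force is cancelled up to the
#' Coulomb cap (stick); above it, kinetic friction opposes the tangential
#' velocity:
#' \deqn{F = -\min(\|F_\parallel\|, \mu_{stick}\|F_\perp\|)
#' \hat F_\parallel \quad (stick), \qquad
#' F = -\mu_{slip}\|F_\perp\|\,\hat v_\parallel \quad (slip).}
#'
#' @param n unit wall normal (push direction)
#' @param f_node elastic + coil-coil force at the node
#' @param v node velocity
#' @param params \code{friction_params}
#' @return friction force 3-vector (mN)
#' @export
wall_friction <- function(n, f_node, v, params) {
  Fperp <- sum(f_node * n) * n
  Fpar <- f_node - Fperp
  vpar <- v - sum(v * n) * n
  vn <- sqrt(sum(vpar^2))
  Fperp_n <- sqrt(sum(Fperp^2))
  if (vn <= params$v_eps) {
    Fpar_n <- sqrt(sum(Fpar^2))
    if (Fpar_n < 1e-14) return(c(0, 0, 0))
    -min(Fpar_n, params$mu_stick_cw * Fperp_n) * Fpar / Fpar_n
  } else {
    -params$mu_slip_cw * Fperp_n * vpar / vn
  }
}

#' Assemble external contact forces on a rod
#'
#' Sum of coil-coil penalty + friction forces (distributed to the four
#' incident nodes by the contact point's barycentric weights, equal and
#' opposite across each pair) and wall / catheter-tube reactions with
#' stick-slip friction, evaluated by the compiled octree kernels.  Virtual
#' connector edges are excluded.
#'
#' @param state a \code{rod_state}
#' @param natural,spec rod description (for the elastic force decomposition
#'   at wall contacts)
#' @param wall optional \code{surface_mesh}
#' @param catheter optional \code{catheter_spline} whose tube acts as an
#'   obstacle
#' @param params a \code{friction_params}
#' @param literal projection-only wall narrow phase
#' @return list with \code{force} (N x 3, mN) and contact diagnostics
#' @export
assemble_external_forces <- function(state, natural, spec, wall = NULL,
                                     catheter = NULL, params = friction_params(),
                                     literal = FALSE) {
  N <- nrow(state$x)
  g <- grad_energy(state, natural, spec)
  cp <- resolve_contact_params(params, spec, mean(natural$rest_edge_lengths))
  wm <- if (is.null(wall)) NULL else wall
  cpp_external_forces(state$x, state$vel, -g$grad_x,
                      integer(N - 1L), rep(1L, N), cp, literal,
                      max(natural$rest_edge_lengths),
                      if (is.null(wm)) NULL else wm$vertices,
                      if (is.null(wm)) NULL else wm$faces - 1L,
                      if (is.null(catheter)) NULL else catheter$tube_vertices,
                      if (is.null(catheter)) NULL else catheter$tube_faces - 1L)
}
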