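## Geometry and elasticity of the discrete rod: Bishop frames, integrated
## curvatures, twist, strain energy and its analytic gradients.

#' Create a discrete rod state
#'
#' Bundles the degrees of freedom of a discrete elastic rod: vertex
#' positions, per-edge material-frame angles measured against the stored
#' Bishop triads, velocities and release bookkeeping.
#'
#' @param vertices numeric matrix (N x 3), centerline vertices in mm.
#' @param edge_angles numeric vector (N-1), material-frame rotation phi^j in
#'   radians about the tangent, relative to the Bishop frame.  Default all 0
#'   (material frame coincides with the Bishop frame).
#' @param velocities numeric matrix (N x 3) of nodal velocities (mm/s).
#' @param u0 seed vector for the first-edge Bishop director; any vector not
#'   parallel to the first edge.  Default picks a stable one.
#' @param release_step integer vector (N): time-step index at which each
#'   vertex left the catheter, -1 while still inside.
#' @return an object of class \code{rod_state}: list with elements
#'   \code{x}, \code{phi}, \code{u}, \code{v}, \code{vel},
#'   \code{release_step}.
#' @export
rod_state <- function(vertices, edge_angles = NULL, velocities = NULL,
                      u0 = NULL, release_step = NULL) {
  x <- as.matrix(vertices)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L || nrow(x) < 2L)
    stop("vertices must be an N x 3 matrix with N >= 2")
  N <- nrow(x)
  e <- diff(x)
  len <- sqrt(rowSums(e^2))
  if (any(len <= 0)) stop("every edge must have positive length")
  if (is.null(u0)) {
    t1 <- e[1, ] / len[1]
    a <- if (abs(t1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u0 <- a - sum(a * t1) * t1
  }
  fr <- cpp_propagate_bishop(x, as.double(u0))
  if (is.null(edge_angles)) edge_angles <- numeric(N - 1L)
  if (is.null(velocities)) velocities <- matrix(0, N, 3L)
  if (is.null(release_step)) release_step <- rep(-1L, N)
  structure(list(x = x, phi = as.double(edge_angles),
                 u = fr$U, v = fr$V,
                 vel = as.matrix(velocities),
                 release_step = as.integer(release_step)),
            class = "rod_state")
}

#' @export
print.rod_state <- function(x, ...) {
  len <- edge_lengths(x)
  cat(sprintf("<rod_state> %d vertices, arc length %.3f mm, mean edge %.4f mm\n",
              nrow(x$x), sum(len), mean(len)))
  invisible(x)
}

#' Edge vectors, lengths and unit tangents of a rod state
#' @param state a \code{rod_state}
#' @return for \code{edge_lengths}, numeric vector of current edge lengths
#' @export
edge_lengths <- function(state) {
  e <- diff(state$x)
  sqrt(rowSums(e^2))
}

unit_tangents <- function(state) {
  e <- diff(state$x)
  e / sqrt(rowSums(e^2))
}

#' Discrete integrated curvature binormal
#'
#' \eqn{(\kappa b) = 2\, t^- \times t^+ / (1 + t^- \cdot t^+)} for two
#' consecutive unit tangents.  The norm divided by the Voronoi length
#' converges to the centerline curvature.
#'
#' @param t_prev,t_next unit tangent vectors of the two edges meeting at a
#'   node.
#' @param eps_tol tolerance guarding the antiparallel degeneracy.
#' @return numeric 3-vector.
#' @export
curvature_binormal <- function(t_prev, t_next, eps_tol = 1e-10) {
  d <- sum(t_prev * t_next)
  if (d <= -1 + eps_tol)
    stop("degenerate turn: antiparallel tangents (180 degree kink)")
  2 * c(t_prev[2] * t_next[3] - t_prev[3] * t_next[2],
        t_prev[3] * t_next[1] - t_prev[1] * t_next[3],
        t_prev[1] * t_next[2] - t_prev[2] * t_next[1]) / (1 + d)
}

#' Material directors of a rod state
#'
#' \eqn{D_1 = \cos\phi\, U + \sin\phi\, V}, \eqn{D_2 = -\sin\phi\, U +
#' \cos\phi\, V} per edge.
#'
#' @param state a \code{rod_state}
#' @return list with matrices \code{D1}, \code{D2} ((N-1) x 3)
#' @export
material_directors <- function(state) {
  cs <- cos(state$phi); sn <- sin(state$phi)
  list(D1 = cs * state$u + sn * state$v,
       D2 = -sn * state$u + cs * state$v)
}

#' Discrete nodal curvatures
#'
#' Projects the curvature binormal at an interior node onto the averaged
#' material directors of the two adjacent edges:
#' \eqn{\kappa_1 = \tfrac12 (D_2^- + D_2^+)\cdot(\kappa b)},
#' \eqn{\kappa_2 = -\tfrac12 (D_1^- + D_1^+)\cdot(\kappa b)}.
#'
#' @param state a \code{rod_state}
#' @param node_index interior node index (2..N-1 in R's 1-based indexing)
#' @return numeric 2-vector \code{c(kappa1, kappa2)}
#' @export
discrete_curvatures <- function(state, node_index) {
  i <- as.integer(node_index)
  N <- nrow(state$x)
  if (i < 2L || i > N - 1L) stop("node_index must be interior (2..N-1)")
  tt <- unit_tangents(state)
  kb <- curvature_binormal(tt[i - 1L, ], tt[i, ])
  D <- material_directors(state)
  c(0.5 * sum((D$D2[i - 1L, ] + D$D2[i, ]) * kb),
    -0.5 * sum((D$D1[i - 1L, ] + D$D1[i, ]) * kb))
}

#' Rodrigues rotation taking one unit vector to another
#'
#' Returns the 3 x 3 rotation matrix \eqn{R = I + K + K^2/(1 + t_0\cdot
#' t_1)} with \eqn{Kv = (t_0 \times t_1) \times v}; it maps \code{t_from} to
#' \code{t_to} and realizes parallel transport between edge tangents.
#'
#' @param t_from,t_to unit vectors, not antiparallel.
#' @return 3 x 3 rotation matrix.
#' @export
rodrigues_rotation <- function(t_from, t_to) {
  d <- sum(t_from * t_to)
  if (d <= -1 + 1e-10)
    stop("degenerate turn: antiparallel tangents")
  b <- c(t_from[2] * t_to[3] - t_from[3] * t_to[2],
         t_from[3] * t_to[1] - t_from[1] * t_to[3],
         t_from[1] * t_to[2] - t_from[2] * t_to[1])
  K <- matrix(c(0, b[3], -b[2], -b[3], 0, b[1], b[2], -b[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + d)
}

#' Propagate the Bishop frame along a rod
#'
#' Parallel-transports the first edge's reference director along the
#' centerline, producing the unique twist-free adapted frame.  The stored
#' first-edge director is kept (projected onto the new tangent plane).
#'
#' @param state a \code{rod_state}
#' @return the state with \code{u}, \code{v} replaced by the propagated
#'   Bishop triads.
#' @export
propagate_bishop <- function(state) {
  fr <- cpp_propagate_bishop(state$x, state$u[1, ])
  state$u <- fr$U
  state$v <- fr$V
  state
}

#' Measured discrete twist at an edge
#'
#' The angle increment needed to align the material frame of edge
#' \code{j} with the parallel-transported material frame of edge
#' \code{j-1}, wrapped to \eqn{(-\pi, \pi]}.  Against freshly propagated
#' Bishop frames this is the increment \eqn{\phi^j - \phi^{j-1}}; for
#' arbitrary stored frames the reference twist of the stored triads is
#' accounted for.
#'
#' @param state a \code{rod_state}
#' @param edge_index edge index (2..N-1 in 1-based indexing; twist lives at
#'   the junction with the previous edge)
#' @return scalar twist in radians.
#' @export
measure_twist <- function(state, edge_index) {
  j <- as.integer(edge_index)
  ne <- nrow(state$u)
  if (j < 2L || j > ne) stop("edge_index must be in 2..N-1")
  tt <- unit_tangents(state)
  R <- rodrigues_rotation(tt[j - 1L, ], tt[j, ])
  up <- as.double(R %*% state$u[j - 1L, ])
  cr <- c(up[2] * state$u[j, 3] - up[3] * state$u[j, 2],
          up[3] * state$u[j, 1] - up[1] * state$u[j, 3],
          up[1] * state$u[j, 2] - up[2] * state$u[j, 1])
  ref <- atan2(sum(cr * tt[j, ]), sum(up * state$u[j, ]))
  wrap_angle(state$phi[j] - state$phi[j - 1L] + ref)
}

wrap_angle <- function(a) {
  a <- a %% (2 * pi)
  ifelse(a > pi, a - 2 * pi, a)
}

#' Natural (rest) shape of a coil
#'
#' Encodes the stress-free imprinted configuration: rest edge lengths,
#' Voronoi lengths and natural curvatures, with identically zero natural
#' twist (the natural configuration is parametrized by its Bishop frame).
#' The curvatures are extracted from the natural centerline with the same
#' discrete operators used for the current configuration.
#'
#' @param vertices numeric matrix (N x 3): the natural centerline (mm).
#' @return object of class \code{coil_natural_shape}.
#' @export
natural_shape_from_vertices <- function(vertices) {
  st <- rod_state(vertices)
  N <- nrow(st$x)
  len <- edge_lengths(st)
  vor <- c(NA_real_, (len[-(N - 1L)] + len[-1L]) / 2, NA_real_)
  kbar <- matrix(0, N, 2L)
  if (N > 2L) {
    tt <- unit_tangents(st)
    for (i in 2:(N - 1L)) {
      kb <- curvature_binormal(tt[i - 1L, ], tt[i, ])
      # phi = 0: material directors are the Bishop triads themselves
      kbar[i, ] <- c(0.5 * sum((st$v[i - 1L, ] + st$v[i, ]) * kb),
                     -0.5 * sum((st$u[i - 1L, ] + st$u[i, ]) * kb))
    }
  }
  structure(list(natural_vertices = st$x,
                 rest_edge_lengths = len,
                 voronoi_lengths = vor,
                 natural_curvatures = kbar,
                 natural_twist = numeric(N)),
            class = "coil_natural_shape")
}

#' Bending and twisting stiffness of a coil from its microstructure
#'
#' The coil is a stock wire of diameter \code{D1} wound into a helix of
#' diameter \code{D2} with turn spacing \eqn{p_c = D_1 p}; treating it as a
#' torsion spring gives
#' \deqn{b = \frac{E_w D_1^4 p_c}{32 (2 + \mu_w) D_2}, \qquad
#'       \beta = \frac{E_w D_1^4 p_c}{64 D_2}.}
#'
#' @param D1 stock-wire diameter (mm)
#' @param D2 coil diameter (mm)
#' @param E_w Young's modulus of the stock wire (Pa)
#' @param mu_w Poisson ratio of the stock wire
#' @param p pitch factor (> 1), turn spacing in units of \code{D1}
#' @return list with \code{b}, \code{beta} in N mm^2.
#' @export
stiffness_from_microstructure <- function(D1, D2, E_w, mu_w, p = 1.1) {
  if (any(c(D1, D2, E_w, p) <= 0) || mu_w < 0)
    stop("all stiffness inputs must be positive (mu_w >= 0)")
  if (p <= 1) stop("pitch factor p must exceed 1")
  E_nmm <- E_w * 1e-6             # Pa -> N/mm^2
  p_c <- D1 * p
  list(b = E_nmm * D1^4 * p_c / (32 * (2 + mu_w) * D2),
       beta = E_nmm * D1^4 * p_c / (64 * D2))
}

#' Coil specification
#'
#' Physical description of an embolization coil and its derived model
#' constants.  Stiffnesses come from
#' \code{\link{stiffness_from_microstructure}}; the axial penalty weight
#' \code{alpha} is dimensionless and scales an internal reference stiffness
#' proportional to the stock wire's axial rigidity.
#'
#' @param D1,D2,D3 stock-wire, coil and imprint diameters (mm), D1 < D2 < D3
#' @param length coil length (mm)
#' @param E_w Young's modulus (Pa); default platinum 168 GPa
#' @param mu_w Poisson ratio; default 0.38
#' @param pitch pitch factor p > 1; default 1.1
#' @param alpha dimensionless axial penalty weight; default 0.1
#' @param density stock-wire density (kg/mm^3); default platinum
#' @return object of class \code{coil_spec} with derived \code{b},
#'   \code{beta} (mN mm^2 internal units), \code{alpha_abs} (mN),
#'   \code{mass_per_length} (kg/mm).
#' @export
coil_spec <- function(D1, D2, D3, length, E_w = 168e9, mu_w = 0.38,
                      pitch = 1.1, alpha = 0.1, density = .RHO_PLATINUM) {
  if (!(D1 < D2 && D2 < D3)) stop("diameters must satisfy D1 < D2 < D3")
  if (length <= 0) stop("coil length must be positive")
  st <- stiffness_from_microstructure(D1, D2, E_w, mu_w, pitch)
  E_int <- E_w * .PA_TO_INTERNAL       # kPa = mN/mm^2
  A_wire <- pi * D1^2 / 4
  wire_per_len <- pi * D2 / (D1 * pitch)   # wire length per coil length
  structure(list(D1 = D1, D2 = D2, D3 = D3, length = length,
                 E_w = E_w, mu_w = mu_w, pitch = pitch, alpha = alpha,
                 b = st$b * 1e3, beta = st$beta * 1e3,   # N mm^2 -> mN mm^2
                 alpha_abs = alpha * E_int * A_wire / .ALPHA_REF_DIVISOR,
                 mass_per_length = density * A_wire * wire_per_len),
            class = "coil_spec")
}

#' @export
print.coil_spec <- function(x, ...) {
  cat(sprintf(paste0("<coil_spec> D1 = %.0f um, D2 = %.0f um, D3 = %.2f mm, ",
                     "L = %.1f mm\n  b = %.3e N mm^2, beta = %.3e N mm^2, ",
                     "beta/b = %.3f, alpha = %g\n"),
              x$D1 * 1e3, x$D2 * 1e3, x$D3, x$length,
              x$b * 1e-3, x$beta * 1e-3, x$beta / x$b, x$alpha))
  invisible(x)
}

## ---- assembled per-rod parameter arrays (internal) -----------------------

# Per-node / per-edge stiffness arrays for a (possibly multi-coil) chain.
rod_param_arrays <- function(natural, spec, virtual_edge = NULL) {
  N <- nrow(natural$natural_vertices)
  ne <- N - 1L
  if (is.null(virtual_edge)) virtual_edge <- integer(ne)
  vor <- natural$voronoi_lengths
  vor[is.na(vor)] <- mean(natural$rest_edge_lengths)
  list(elbar = natural$rest_edge_lengths,
       vor = vor,
       kbar = natural$natural_curvatures,
       alpha = rep(spec$alpha_abs, ne),
       b = rep(spec$b, N),
       beta = rep(spec$beta, N),
       virt = as.integer(virtual_edge))
}

#' Total discrete strain energy of a rod
#'
#' Sum of the axial penalty, bending and twisting terms
#' \deqn{E = \sum_j \tfrac{\alpha}{2}\Big(\tfrac{\|e^j\|}{\|\bar e^j\|} -
#' 1\Big)^2 \|\bar e^j\| + \sum_i \tfrac{b}{2\bar\ell_i} \|\kappa_i -
#' \bar\kappa_i\|^2 + \sum_i \tfrac{\beta}{2\bar\ell_i} \tau_i^2.}
#' Axial runs over all edges, bending and twist over interior nodes.
#'
#' @param state a \code{rod_state}
#' @param natural a \code{coil_natural_shape} of matching size
#' @param spec a \code{coil_spec}
#' @param parts if TRUE return the three components as an attribute
#' @return energy in mN mm (uJ); zero iff the state is congruent to the
#'   natural shape with zero twist.
#' @export
total_energy <- function(state, natural, spec, parts = FALSE) {
  pa <- rod_param_arrays(natural, spec)
  if (length(pa$elbar) != nrow(state$x) - 1L)
    stop("state and natural shape sizes do not match")
  r <- cpp_rod_energy(state$x, state$phi, state$u, state$v,
                      pa$elbar, pa$vor, pa$kbar, pa$alpha, pa$b, pa$beta, pa$virt)
  if (parts)
    return(structure(r$energy, parts = c(axial = r$axial, bending = r$bending,
                                         twist = r$twist)))
  r$energy
}

#' Analytic gradient of the strain energy
#'
#' Gradient of \code{\link{total_energy}} with respect to vertex positions
#' and edge angles, with free-end ("do nothing") boundary treatment: end
#' nodes and edges simply carry fewer energy terms.  The position gradient
#' accounts for the variation of the reference twist under vertex motion
#' (the frames themselves are data, transported in time, not re-derived).
#'
#' @inheritParams total_energy
#' @return list with \code{grad_x} (N x 3, mN) and \code{grad_phi}
#'   (N-1, mN mm).
#' @export
grad_energy <- function(state, natural, spec) {
  pa <- rod_param_arrays(natural, spec)
  if (length(pa$elbar) != nrow(state$x) - 1L)
    stop("state and natural shape sizes do not match")
  r <- cpp_rod_energy_grad(state$x, state$phi, state$u, state$v,
                           pa$elbar, pa$vor, pa$kbar, pa$alpha, pa$b, pa$beta, pa$virt)
  list(grad_x = r$grad_x, grad_phi = r$grad_phi, energy = r$energy)
}

#' Serialize a rod state to a data frame / CSV
#'
#' Columnar table with vertex positions, velocities, release steps and (for
#' the first N-1 rows) edge angles and Bishop directors.
#'
#' @param state a \code{rod_state}
#' @param path optional file path; when given, written as CSV.
#' @return the data frame, invisibly when written.
#' @export
write_state_csv <- function(state, path = NULL) {
  N <- nrow(state$x)
  df <- data.frame(node = seq_len(N) - 1L,
                   x = state$x[, 1], y = state$x[, 2], z = state$x[, 3],
                   vx = state$vel[, 1], vy = state$vel[, 2], vz = state$vel[, 3],
                   release_step = state$release_step,
                   phi = c(state$phi, NA),
                   ux = c(state$u[, 1], NA), uy = c(state$u[, 2], NA), uz = c(state$u[, 3], NA),
                   vx_f = c(state$v[, 1], NA), vy_f = c(state$v[, 2], NA), vz_f = c(state$v[, 3], NA))
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
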