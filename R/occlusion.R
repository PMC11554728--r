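## Occlusion analysis: coil voxelization, SDF region partitioning, packing
## density volume fractions, ensemble statistics and the Raymond-Roy-type
## classifier.

#' Signed distance to a closed surface mesh
#'
#' Exact point-to-mesh distance with the sign taken from angle-weighted
#' pseudonormals at the closest feature: negative inside, positive
#' outside.
#'
#' @param mesh a closed, outward-oriented \code{surface_mesh}
#' @param points n x 3 matrix of query points
#' @return numeric vector of signed distances (mm)
#' @export
mesh_sdf <- function(mesh, points) {
  P <- as.matrix(points)
  if (is.null(dim(P))) P <- matrix(P, ncol = 3)
  cpp_mesh_sdf(mesh$vertices, mesh$faces - 1L, P)
}

#' Voxel field container
#'
#' A scalar field on a cubic grid: \code{N_V} voxels per axis spanning a
#' bounding cube of edge length \code{a} anchored at \code{origin}.
#' Values in [0, 1]: binary occupancy for single coils, pointwise means for
#' ensembles.
#'
#' @param values numeric array/vector of length \code{N_V^3} (x fastest)
#' @param origin cube corner (mm)
#' @param a cube edge length (mm)
#' @param N_V voxels per axis
#' @return object of class \code{voxel_field}
#' @export
voxel_field <- function(values, origin, a, N_V) {
  stopifnot(length(values) == N_V^3, a > 0)
  structure(list(values = as.double(values), origin = as.double(origin),
                 a = a, N_V = as.integer(N_V), h = a / N_V),
            class = "voxel_field")
}

#' @export
print.voxel_field <- function(x, ...) {
  cat(sprintf("<voxel_field> %d^3 voxels, cube edge %.2f mm, occupied volume %.3f mm^3\n",
              x$N_V, x$a, sum(x$values) * x$h^3))
  invisible(x)
}

voxel_centers <- function(vf) {
  idx <- seq_len(vf$N_V) - 0.5
  g <- expand.grid(x = idx, y = idx, z = idx)   # x fastest, matching C++
  cbind(vf$origin[1] + vf$h * g$x,
        vf$origin[2] + vf$h * g$y,
        vf$origin[3] + vf$h * g$z)
}

# Bounding cube of a mesh with a small margin, keeping the grid cubic.
bounding_cube <- function(mesh, margin = 0.5) {
  lo <- apply(mesh$vertices, 2, min) - margin
  hi <- apply(mesh$vertices, 2, max) + margin
  a <- max(hi - lo)
  ctr <- (lo + hi) / 2
  list(origin = ctr - a / 2, a = a)
}

#' Voxelize a deployed coil
#'
#' Binary occupancy of the volume swept by the coil cross-section (radius
#' D2/2) along the centerline: a voxel is set iff its center lies within
#' D2/2 of the polyline (capsule union).  The occupied voxel volume
#' converges to the swept volume as \eqn{N_V \to \infty}.
#'
#' @param centerline N x 3 polyline (mm); rows with NA break the polyline
#'   (multi-coil chains)
#' @param D2 coil diameter (mm)
#' @param cube list(origin, a) bounding cube; default from \code{domain}
#' @param N_V voxels per axis (default 70)
#' @param domain optional \code{aneurysm_domain} supplying the cube
#' @return a \code{voxel_field}
#' @export
voxelize_coil <- function(centerline, D2, cube = NULL, N_V = 70, domain = NULL) {
  P <- as.matrix(centerline)
  if (is.null(cube)) {
    if (is.null(domain)) stop("either cube or domain must be given")
    cube <- bounding_cube(domain$dome_mesh, margin = D2)
  }
  if (nrow(P) == 0)
    return(voxel_field(numeric(N_V^3), cube$origin, cube$a, N_V))
  fin <- stats::complete.cases(P)
  lo <- cube$origin; hi <- cube$origin + cube$a
  inside <- fin & P[, 1] >= lo[1] & P[, 2] >= lo[2] & P[, 3] >= lo[3] &
    P[, 1] <= hi[1] & P[, 2] <= hi[2] & P[, 3] <= hi[3]
  if (any(fin & !inside))
    stop("coil centerline leaves the bounding cube; enlarge it")
  vals <- numeric(N_V^3)
  runs <- split(which(fin), cumsum(!fin)[fin])
  for (r in runs) {
    if (length(r) < 2) next
    vals <- pmax(vals, cpp_voxelize_polyline(P[r, , drop = FALSE], D2 / 2,
                                             cube$origin, cube$a, as.integer(N_V)))
  }
  voxel_field(vals, cube$origin, cube$a, N_V)
}

#' Partition the aneurysm into equal-volume core and boundary regions
#'
#' Computes the signed distance field of the dome surface on the voxel
#' grid and bisects its level value until the inner (core) region holds
#' half of the interior voxel volume; the boundary region is the remaining
#' interior shell.  The neck region is covered by a sphere centered at the
#' neck opening with the neck radius (configurable).
#'
#' @param domain an \code{aneurysm_domain}
#' @param vf a \code{voxel_field} defining the grid (values unused)
#' @param sphere optional list(center, radius) overriding the neck sphere
#' @return object of class \code{region_partition} with logical masks
#'   \code{core}, \code{boundary}, \code{interior}, \code{sphere}, the SDF
#'   iso-value and the region volumes
#' @export
partition_regions <- function(domain, vf, sphere = NULL) {
  ctr <- voxel_centers(vf)
  sdf <- mesh_sdf(domain$dome_mesh, ctr)
  interior <- sdf < 0
  vol <- vf$h^3
  V_A <- sum(interior) * vol
  target <- sum(interior) / 2
  lo <- min(sdf); hi <- 0
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (sum(sdf <= mid) > target) hi <- mid else lo <- mid
  }
  iso <- (lo + hi) / 2
  core <- interior & sdf <= iso
  boundary <- interior & !core
  if (is.null(sphere))
    sphere <- list(center = domain$neck_center, radius = domain$neck_radius)
  d2 <- (ctr[, 1] - sphere$center[1])^2 + (ctr[, 2] - sphere$center[2])^2 +
    (ctr[, 3] - sphere$center[3])^2
  sph <- interior & d2 <= sphere$radius^2
  structure(list(core = core, boundary = boundary, interior = interior,
                 sphere = sph, iso = iso, sphere_def = sphere,
                 V_C = sum(core) * vol, V_B = sum(boundary) * vol,
                 V_A = V_A, V_S = sum(sph) * vol, voxel_volume = vol),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("<region_partition> V_A = %.2f, V_C = %.2f, V_B = %.2f, V_S = %.2f mm^3 (iso %.3f mm)\n",
              x$V_A, x$V_C, x$V_B, x$V_S, x$iso))
  invisible(x)
}

#' Volume fractions and local packing densities of a coil distribution
#'
#' Region-integrated coil volume over the aneurysm volume
#' (\eqn{\bar\psi_{BA}, \bar\psi_{CA}, \bar\psi_{AA}}) and over the
#' neck-sphere volume restricted to the aneurysm
#' (\eqn{\bar\psi_{SS}}), plus the region-local packing densities
#' (coil volume / region volume) that feed the classifier.
#'
#' @param vf a \code{voxel_field} (binary or ensemble mean)
#' @param part a \code{region_partition} on the same grid
#' @return list with the four fractions and \code{pd_core},
#'   \code{pd_boundary}, \code{pd_sphere}, \code{pd_total}
#' @export
volume_fractions <- function(vf, part) {
  vol <- vf$h^3
  vB <- sum(vf$values[part$boundary]) * vol
  vC <- sum(vf$values[part$core]) * vol
  vA <- sum(vf$values[part$interior]) * vol
  vS <- sum(vf$values[part$sphere]) * vol
  list(psi_BA = vB / part$V_A, psi_CA = vC / part$V_A,
       psi_AA = vA / part$V_A,
       psi_SS = if (part$V_S > 0) vS / part$V_S else 0,
       pd_core = if (part$V_C > 0) vC / part$V_C else 0,
       pd_boundary = if (part$V_B > 0) vB / part$V_B else 0,
       pd_sphere = if (part$V_S > 0) vS / part$V_S else 0,
       pd_total = if (part$V_A > 0) vA / part$V_A else 0)
}

#' Raymond-Roy-type occlusion class from local packing densities
#'
#' Threshold rules (boundary-inclusive): the core counts as full at 20%
#' packing density and above, the boundary and the neck sphere at 18% and
#' above.  Full core + boundary gives class I when the sphere is also full
#' and II otherwise; an empty core with a full boundary is IIIa (either
#' sphere state); a full core with an empty boundary is IIIb; empty core
#' and boundary mark a migrated coil, class Fail.
#'
#' @param pd_core,pd_boundary,pd_sphere local packing densities (fractions)
#' @param thresholds named numeric with \code{core}, \code{boundary},
#'   \code{sphere}
#' @return one of \code{"I"}, \code{"II"}, \code{"IIIa"}, \code{"IIIb"},
#'   \code{"Fail"}
#' @export
classify_rroc <- function(pd_core, pd_boundary, pd_sphere,
                          thresholds = c(core = 0.20, boundary = 0.18, sphere = 0.18)) {
  core_full <- pd_core >= thresholds[["core"]]
  bnd_full <- pd_boundary >= thresholds[["boundary"]]
  sph_full <- pd_sphere >= thresholds[["sphere"]]
  if (bnd_full) {
    if (core_full) (if (sph_full) "I" else "II") else "IIIa"
  } else {
    if (core_full) "IIIb" else "Fail"
  }
}

#' Occlusion report for a deployment
#'
#' Voxelizes the deployed coil(s), partitions the aneurysm and classifies
#' the placement.
#'
#' @param deployment a \code{coil_deployment}
#' @param N_V voxels per axis
#' @param sphere optional neck-sphere override
#' @return object of class \code{occlusion_report}
#' @export
occlusion_report <- function(deployment, N_V = 70, sphere = NULL) {
  domain <- deployment$domain
  if (is.null(domain)) stop("deployment has no aneurysm domain")
  chain <- deployment$chain
  X <- deployment$state$x
  # break the polyline at virtual connector edges
  if (any(chain$virt == 1L)) {
    Xb <- NULL
    for (j in seq_along(chain$virt)) {
      Xb <- rbind(Xb, X[j, ])
      if (chain$virt[j] == 1L) Xb <- rbind(Xb, c(NA, NA, NA))
    }
    X <- rbind(Xb, X[nrow(X), ])
  }
  cube <- bounding_cube(domain$dome_mesh, margin = chain$D2)
  # clip to the cube: parts that migrated far into the parent vessel carry
  # no occlusion information
  lo <- cube$origin; hi <- cube$origin + cube$a
  out <- !is.na(X[, 1]) & (X[, 1] < lo[1] | X[, 2] < lo[2] | X[, 3] < lo[3] |
                             X[, 1] > hi[1] | X[, 2] > hi[2] | X[, 3] > hi[3])
  X[out, ] <- NA
  vf <- voxelize_coil(X, chain$D2, cube = cube, N_V = N_V)
  part <- partition_regions(domain, vf, sphere = sphere)
  fr <- volume_fractions(vf, part)
  cls <- classify_rroc(fr$pd_core, fr$pd_boundary, fr$pd_sphere)
  structure(c(fr, list(class = cls, voxel_field = vf, partition = part)),
            class = "occlusion_report")
}

#' @export
print.occlusion_report <- function(x, ...) {
  cat(sprintf("<occlusion_report> class %s\n", x$class))
  cat(sprintf("  packing densities: core %.1f %%, boundary %.1f %%, sphere %.1f %%, total %.1f %%\n",
              100 * x$pd_core, 100 * x$pd_boundary, 100 * x$pd_sphere, 100 * x$pd_total))
  cat(sprintf("  volume fractions: BA %.3f, CA %.3f, AA %.3f, SS %.3f\n",
              x$psi_BA, x$psi_CA, x$psi_AA, x$psi_SS))
  invisible(x)
}

#' Ensemble statistics of voxelized coil distributions
#'
#' Pointwise empirical mean and variance over a set of voxel fields on the
#' same grid (population convention), and, when a partition is given, the
#' region-integrated mean coil volumes and their standard deviations.
#'
#' @param fields list of \code{voxel_field}s on identical grids
#' @param part optional \code{region_partition}
#' @return list with \code{mean} and \code{variance} voxel fields and,
#'   with a partition, a data frame \code{regions} of
#'   \eqn{\bar\psi_V} and \eqn{\psi_{\sigma,V}} per region
#' @export
ensemble_stats <- function(fields, part = NULL) {
  stopifnot(length(fields) >= 1)
  f1 <- fields[[1]]
  for (f in fields)
    if (!isTRUE(all.equal(c(f$origin, f$a, f$N_V), c(f1$origin, f1$a, f1$N_V))))
      stop("all voxel fields must share the same grid")
  M <- vapply(fields, `[[`, numeric(length(f1$values)), "values")
  mu <- rowMeans(M)
  va <- rowMeans((M - mu)^2)
  out <- list(mean = voxel_field(mu, f1$origin, f1$a, f1$N_V),
              variance = voxel_field(va, f1$origin, f1$a, f1$N_V),
              n = length(fields))
  if (!is.null(part)) {
    vol <- f1$h^3
    reg <- function(mask, name) {
      psiV <- sum(mu[mask]) * vol
      dev <- vapply(seq_len(ncol(M)), function(i) sum((mu - M[, i])[mask]) * vol,
                    numeric(1))
      data.frame(region = name, psi_V = psiV, psi_sigma_V = sqrt(mean(dev^2)))
    }
    out$regions <- rbind(reg(part$core, "core"), reg(part$boundary, "boundary"),
                         reg(part$interior, "aneurysm"), reg(part$sphere, "sphere"))
  }
  out
}
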