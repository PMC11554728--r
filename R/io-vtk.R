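## Plain-text output: legacy-VTK polylines and structured points, CSV
## summaries, JSON reports.

#' Write a polyline to a legacy ASCII VTK file
#'
#' @param points N x 3 matrix; NA rows split the polyline
#' @param path output path (.vtk)
#' @param scalars optional named list of per-point scalar vectors
#' @return \code{path}, invisibly
#' @export
write_vtk_polyline <- function(points, path, scalars = NULL) {
  P <- as.matrix(points)
  ok <- stats::complete.cases(P)
  runs <- split(which(ok), cumsum(!ok)[ok])
  runs <- runs[lengths(runs) >= 2]
  Pk <- P[ok, , drop = FALSE]
  remap <- match(seq_len(nrow(P)), which(ok))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "coildeploy polyline", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", nrow(Pk))), con)
  writeLines(sprintf("%.9g %.9g %.9g", Pk[, 1], Pk[, 2], Pk[, 3]), con)
  sz <- sum(lengths(runs) + 1L)
  writeLines(sprintf("LINES %d %d", length(runs), sz), con)
  for (r in runs)
    writeLines(paste(c(length(r), remap[r] - 1L), collapse = " "), con)
  if (!is.null(scalars) && length(scalars)) {
    writeLines(sprintf("POINT_DATA %d", nrow(Pk)), con)
    for (nm in names(scalars)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", scalars[[nm]][ok]), con)
    }
  }
  invisible(path)
}

#' Write a voxel field as legacy ASCII VTK structured points
#'
#' @param vf a \code{voxel_field}
#' @param path output path (.vtk)
#' @param name scalar field name
#' @return \code{path}, invisibly
#' @export
write_vtk_structured_points <- function(vf, path, name = "psi") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "coildeploy voxel field", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", vf$N_V, vf$N_V, vf$N_V),
               sprintf("ORIGIN %.9g %.9g %.9g",
                       vf$origin[1] + vf$h / 2, vf$origin[2] + vf$h / 2, vf$origin[3] + vf$h / 2),
               sprintf("SPACING %.9g %.9g %.9g", vf$h, vf$h, vf$h),
               sprintf("POINT_DATA %d", length(vf$values)),
               sprintf("SCALARS %s double 1", name), "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.6g", vf$values), con)
  invisible(path)
}

#' Write a voxel field as a plain-text dump with a JSON header
#'
#' @param vf a \code{voxel_field}
#' @param path base path; writes \code{path.json} and \code{path.txt}
#' @return base path, invisibly
#' @export
write_voxel_dump <- function(vf, path) {
  jsonlite::write_json(list(origin = vf$origin, a = vf$a, N_V = vf$N_V,
                            order = "x fastest"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  writeLines(sprintf("%.6g", vf$values), paste0(path, ".txt"))
  invisible(path)
}

#' Write the per-step deployment series to CSV
#'
#' @param deployment a \code{coil_deployment}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_series_csv <- function(deployment, path) {
  utils::write.csv(deployment$series, path, row.names = FALSE)
  invisible(path)
}

#' Export trajectory samples as a VTK polyline series
#'
#' One file per recorded sample, numbered by time step.
#'
#' @param deployment a \code{coil_deployment}
#' @param dir output directory
#' @param prefix file name prefix
#' @return the written paths, invisibly
#' @export
write_trajectory_vtk <- function(deployment, dir, prefix = "coil") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  steps <- deployment$trajectory_steps
  paths <- character(length(steps))
  virt <- deployment$chain$virt
  for (k in seq_along(steps)) {
    X <- deployment$trajectory[[k]]
    if (any(virt == 1L)) {
      Xb <- NULL
      for (j in seq_along(virt)) {
        Xb <- rbind(Xb, X[j, ])
        if (virt[j] == 1L) Xb <- rbind(Xb, c(NA, NA, NA))
      }
      X <- rbind(Xb, X[nrow(X), ])
    }
    paths[k] <- file.path(dir, sprintf("%s_%08d.vtk", prefix, steps[k]))
    write_vtk_polyline(X, paths[k])
  }
  invisible(paths)
}

#' @export
plot.coil_deployment <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  s <- x$series
  etot <- s$axial_energy + s$bending_energy + s$twist_energy
  plot(s$time, etot, type = "l", xlab = "time (s)", ylab = "energy (uJ)",
       main = "strain energy", ...)
  lines(s$time, s$bending_energy, col = "firebrick")
  legend("topleft", c("total", "bending"), col = c("black", "firebrick"),
         lty = 1, bty = "n", cex = 0.8)
  X <- x$state$x
  plot(X[, 1], X[, 3], type = "l", asp = 1, xlab = "x (mm)", ylab = "z (mm)",
       main = "final coil (x-z)")
  if (!is.null(x$domain)) {
    v <- x$domain$dome_mesh$vertices
    sel <- abs(v[, 2]) < 0.3
    points(v[sel, 1], v[sel, 3], pch = ".", col = "grey60")
  }
  invisible(x)
}
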