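## Triangulated surface meshes: ASCII STL/OBJ/PLY input/output, validation,
## volume via the divergence theorem, and cutting at the aneurysm neck.

#' Construct a surface mesh
#'
#' @param vertices numeric matrix (V x 3), mm
#' @param faces integer matrix (F x 3), 1-based vertex indices,
#'   counterclockwise winding viewed from outside
#' @return object of class \code{surface_mesh}
#' @export
surface_mesh <- function(vertices, faces) {
  v <- as.matrix(vertices); storage.mode(v) <- "double"
  f <- as.matrix(faces); storage.mode(f) <- "integer"
  if (ncol(v) != 3L || ncol(f) != 3L) stop("vertices and faces must have 3 columns")
  if (min(f) < 1L || max(f) > nrow(v)) stop("face indices out of range")
  structure(list(vertices = v, faces = f), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, volume %.3f mm^3\n",
              nrow(x$vertices), nrow(x$faces), mesh_volume(x)))
  invisible(x)
}

#' Signed volume of a closed mesh (divergence theorem)
#'
#' One sixth of the sum of triple products over faces; positive for
#' outward-oriented closed surfaces, negated by flipping all faces.
#'
#' @param mesh a \code{surface_mesh}
#' @return volume in mm^3
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]; c3 <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c3[, 3] - b[, 3] * c3[, 2],
              b[, 3] * c3[, 1] - b[, 1] * c3[, 3],
              b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  sum(a * cr) / 6
}

#' Validate a surface mesh
#'
#' Checks that every directed edge appears exactly once with its reverse
#' also present (watertight, consistently wound 2-manifold), that no face is
#' degenerate, and that the signed volume is positive (outward orientation).
#'
#' @param mesh a \code{surface_mesh}
#' @param on_fail "error" (default), "warn" or "none"
#' @return TRUE if valid (invisibly), otherwise errors/warns per
#'   \code{on_fail}
#' @export
validate_mesh <- function(mesh, on_fail = c("error", "warn", "none")) {
  on_fail <- match.arg(on_fail)
  fail <- function(msg) {
    if (on_fail == "error") stop(msg, call. = FALSE)
    if (on_fail == "warn") warning(msg, call. = FALSE)
    invisible(FALSE)
  }
  f <- mesh$faces
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    return(fail("mesh has degenerate faces"))
  ed <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(ed[, 1], ed[, 2])
  rkey <- paste(ed[, 2], ed[, 1])
  if (any(duplicated(key)))
    return(fail("mesh is not a consistently wound 2-manifold (duplicated directed edge)"))
  if (!all(key %in% rkey))
    return(fail("mesh is not watertight (boundary edges present)"))
  if (mesh_volume(mesh) <= 0)
    return(fail("mesh orientation is inverted (non-positive enclosed volume)"))
  invisible(TRUE)
}

## ---- readers -------------------------------------------------------------

dedupe_vertices <- function(v, f, digits = 9) {
  key <- paste(round(v[, 1], digits), round(v[, 2], digits), round(v[, 3], digits))
  idx <- match(key, key)
  keep <- !duplicated(key)
  remap <- cumsum(keep)[idx]
  surface_mesh(v[keep, , drop = FALSE],
               matrix(remap[f], ncol = 3))
}

read_stl_ascii <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", ln, value = TRUE)
  if (!length(vl)) stop("no vertices found in STL file (binary STL is not supported)")
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(s) as.numeric(s[2:4]), numeric(3)))
  if (nrow(nums) %% 3 != 0) stop("malformed STL: vertex count not a multiple of 3")
  f <- matrix(seq_len(nrow(nums)), ncol = 3, byrow = TRUE)
  dedupe_vertices(nums, f)
}

read_obj <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", ln, value = TRUE)
  fl <- grep("^f\\s", ln, value = TRUE)
  v <- t(vapply(strsplit(trimws(vl), "\\s+"),
                function(s) as.numeric(s[2:4]), numeric(3)))
  f <- t(vapply(strsplit(trimws(fl), "\\s+"), function(s) {
    as.integer(vapply(strsplit(s[2:4], "/"), `[[`, "", 1L))
  }, integer(3)))
  surface_mesh(v, f)
}

read_ply_ascii <- function(path) {
  ln <- readLines(path, warn = FALSE)
  endh <- match("end_header", trimws(ln))
  if (is.na(endh)) stop("malformed PLY header")
  hdr <- ln[seq_len(endh)]
  if (!any(grepl("format ascii", hdr))) stop("only ASCII PLY is supported")
  nv <- as.integer(sub(".*element vertex\\s+", "", grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "", grep("element face", hdr, value = TRUE)[1]))
  body <- ln[(endh + 1L):length(ln)]
  vtx <- t(vapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                  function(s) as.numeric(s[1:3]), numeric(3)))
  fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  f <- t(vapply(fl, function(s) {
    if (as.integer(s[1]) != 3L) stop("only triangle faces are supported")
    as.integer(s[2:4]) + 1L
  }, integer(3)))
  surface_mesh(vtx, f)
}

#' Read a triangulated surface mesh
#'
#' Supports ASCII STL, OBJ and ASCII PLY (mm units assumed).  The mesh is
#' validated (watertight, outward orientation) unless \code{validate} is
#' relaxed.
#'
#' @param path file path; format chosen by extension
#' @param validate "error", "warn" or "none"
#' @return a \code{surface_mesh}
#' @export
load_mesh <- function(path, validate = "error") {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
              stl = read_stl_ascii(path),
              obj = read_obj(path),
              ply = read_ply_ascii(path),
              stop("unsupported mesh format: ", ext))
  if (validate != "none") validate_mesh(m, on_fail = validate)
  m
}

#' Write a triangulated surface mesh
#'
#' @param mesh a \code{surface_mesh}
#' @param path output path (.stl, .obj or .ply, ASCII)
#' @return \code{path}, invisibly
#' @export
save_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  if (ext == "stl") {
    a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]; c3 <- v[f[, 3], , drop = FALSE]
    e1 <- b - a; e2 <- c3 - a
    n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    n <- n / pmax(sqrt(rowSums(n^2)), 1e-300)
    writeLines("solid coildeploy", con)
    for (k in seq_len(nrow(f))) {
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[k, 1], n[k, 2], n[k, 3]),
                   "    outer loop",
                   sprintf("      vertex %.9g %.9g %.9g", a[k, 1], a[k, 2], a[k, 3]),
                   sprintf("      vertex %.9g %.9g %.9g", b[k, 1], b[k, 2], b[k, 3]),
                   sprintf("      vertex %.9g %.9g %.9g", c3[k, 1], c3[k, 2], c3[k, 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid coildeploy", con)
  } else if (ext == "obj") {
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else if (ext == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else stop("unsupported mesh format: ", ext)
  invisible(path)
}

#' Cut a vessel mesh at the aneurysm neck plane
#'
#' Clips the mesh to the side of the plane its normal points into, splitting
#' crossing triangles, and caps the (single) cut loop with a triangle fan at
#' its centroid so the dome is watertight again.  Cap triangles are wound so
#' their normals point out of the dome.
#'
#' @param mesh a \code{surface_mesh}
#' @param plane list with \code{point} (3) and \code{normal} (unit 3-vector
#'   pointing toward the dome side that is kept)
#' @return the capped dome as a \code{surface_mesh}
#' @export
cut_at_neck <- function(mesh, plane) {
  v <- mesh$vertices; f <- mesh$faces
  n <- plane$normal / sqrt(sum(plane$normal^2))
  d <- as.numeric((v - matrix(plane$point, nrow(v), 3, byrow = TRUE)) %*% n)
  eps <- 1e-9 * max(abs(d), 1)
  side <- d > eps   # TRUE: keep
  fs <- matrix(side[f], ncol = 3)
  nin <- rowSums(fs)
  if (all(nin == 0L)) stop("cutting plane misses the mesh (nothing on the kept side)")
  outv <- list(); outf <- list()
  newv <- v
  addpt <- function(p) {
    newv <<- rbind(newv, p)
    nrow(newv)
  }
  cutpt <- function(i, j) {
    t <- d[i] / (d[i] - d[j])
    v[i, ] + t * (v[j, ] - v[i, ])
  }
  keepf <- f[nin == 3L, , drop = FALSE]
  boundary <- list()
  cut_cache <- new.env(parent = emptyenv())
  getcut <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    if (!is.null(cut_cache[[key]])) return(cut_cache[[key]])
    id <- addpt(cutpt(i, j))
    cut_cache[[key]] <- id
    id
  }
  extraf <- list()
  for (k in which(nin == 1L | nin == 2L)) {
    tri <- f[k, ]; s <- fs[k, ]
    # rotate to canonical pattern: kept vertex first (one kept) or excluded
    # vertex third (two kept); rotation preserves winding
    rot <- if (sum(s) == 1L) which(s) - 1L else which(!s) %% 3L
    if (rot > 0L) {
      ord <- ((seq_len(3L) - 1L + rot) %% 3L) + 1L
      tri <- tri[ord]; s <- s[ord]
    }
    if (sum(s) == 1L) {
      # one vertex kept: tri[1] in, cut edges 1-2 and 1-3
      p12 <- getcut(tri[1], tri[2]); p13 <- getcut(tri[1], tri[3])
      extraf[[length(extraf) + 1L]] <- c(tri[1], p12, p13)
      boundary[[length(boundary) + 1L]] <- c(p12, p13)
    } else {
      # two vertices kept: tri[1], tri[2] in, cut edges 2-3 and 1-3
      p23 <- getcut(tri[2], tri[3]); p13 <- getcut(tri[1], tri[3])
      extraf[[length(extraf) + 1L]] <- c(tri[1], tri[2], p23)
      extraf[[length(extraf) + 1L]] <- c(tri[1], p23, p13)
      boundary[[length(boundary) + 1L]] <- c(p23, p13)
    }
  }
  faces <- rbind(keepf, do.call(rbind, extraf))
  # cap: fan around the centroid of the boundary loop, normal along -n
  if (length(boundary)) {
    bidx <- unique(unlist(boundary))
    cen <- colMeans(newv[bidx, , drop = FALSE])
    cid <- addpt(cen)
    for (seg in boundary) {
      # boundary segments run (entry, exit) along the kept triangles'
      # winding; the cap must be wound oppositely to point out of the dome
      faces <- rbind(faces, c(cid, seg[2], seg[1]))
    }
  }
  m <- dedupe_vertices(newv, faces)
  # drop unreferenced vertices
  used <- sort(unique(as.vector(m$faces)))
  remap <- match(seq_len(nrow(m$vertices)), used)
  surface_mesh(m$vertices[used, , drop = FALSE],
               matrix(remap[m$faces], ncol = 3))
}
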