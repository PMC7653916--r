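#' Triangle surface meshes
#'
#' The pipeline's meshes are maxillary dental surfaces: an open palatal dome
#' plus dental crowns, in millimetres, right-handed Cartesian coordinates.
#' A `trimesh` stores an n x 3 vertex matrix and an m x 3 integer face matrix
#' (1-based vertex indices).
#'
#' @param vertices n x 3 numeric matrix of coordinates (mm).
#' @param faces m x 3 integer matrix of vertex indices (1-based).
#' @param name optional text label carried through I/O and reports.
#' @return An object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces, name = "") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  mesh <- structure(list(vertices = vertices, faces = faces,
                         name = as.character(name)[1]),
                    class = "trimesh")
  validate_trimesh(mesh)
  mesh
}

#' Validate a trimesh
#'
#' Checks the structural invariants: non-empty, finite coordinates, all face
#' indices valid.
#'
#' @param mesh A [trimesh].
#' @return `mesh`, invisibly; errors on violation.
#' @export
validate_trimesh <- function(mesh) {
  stopifnot(inherits(mesh, "trimesh"))
  if (nrow(mesh$vertices) == 0L || nrow(mesh$faces) == 0L) {
    stop("trimesh: empty mesh", call. = FALSE)
  }
  if (ncol(mesh$vertices) != 3L || ncol(mesh$faces) != 3L) {
    stop("trimesh: vertices and faces must have 3 columns", call. = FALSE)
  }
  if (!all(is.finite(mesh$vertices))) {
    stop("trimesh: non-finite vertex coordinates", call. = FALSE)
  }
  f <- mesh$faces
  if (min(f) < 1L || max(f) > nrow(mesh$vertices)) {
    stop("trimesh: face index out of range", call. = FALSE)
  }
  invisible(mesh)
}

#' @export
print.trimesh <- function(x, ...) {
  cat("<trimesh", if (nzchar(x$name)) paste0("'", x$name, "'") else "", ">",
      nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  invisible(x)
}

#' @export
apply_transform.trimesh <- function(x, transform) {
  x$vertices <- transform_points(x$vertices, transform)
  x
}

face_corner <- function(mesh, k) mesh$vertices[mesh$faces[, k], , drop = FALSE]

#' Per-face areas of a mesh
#' @param mesh A [trimesh].
#' @return Numeric vector of triangle areas (mm^2), one per face.
#' @export
face_areas <- function(mesh) {
  a <- face_corner(mesh, 1L); b <- face_corner(mesh, 2L); c <- face_corner(mesh, 3L)
  u <- b - a; v <- c - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Total surface area of a mesh
#' @param mesh A [trimesh].
#' @return Total area in mm^2.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Face centroids
#' @param mesh A [trimesh].
#' @return m x 3 matrix of barycentres.
#' @export
face_centroids <- function(mesh) {
  (face_corner(mesh, 1L) + face_corner(mesh, 2L) + face_corner(mesh, 3L)) / 3
}

#' Area-weighted vertex normals
#'
#' Used by the phantom generator to displace vertices along the surface
#' normal when simulating scan noise.
#'
#' @param mesh A [trimesh].
#' @return n x 3 matrix of unit normals (zero rows where a vertex has no
#'   incident face area).
#' @export
vertex_normals <- function(mesh) {
  a <- face_corner(mesh, 1L); b <- face_corner(mesh, 2L); c <- face_corner(mesh, 3L)
  u <- b - a; v <- c - a
  fn <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n <- matrix(0, nrow(mesh$vertices), 3L)
  for (k in 1:3) {
    idx <- mesh$faces[, k]
    n[, 1] <- n[, 1] + tapply_add(fn[, 1], idx, nrow(n))
    n[, 2] <- n[, 2] + tapply_add(fn[, 2], idx, nrow(n))
    n[, 3] <- n[, 3] + tapply_add(fn[, 3], idx, nrow(n))
  }
  len <- sqrt(rowSums(n^2))
  ok <- len > 1e-12
  n[ok, ] <- n[ok, ] / len[ok]
  n[!ok, ] <- 0
  n
}

tapply_add <- function(values, index, n) {
  out <- numeric(n)
  acc <- rowsum(values, index)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

#' Restrict a mesh to a face region
#'
#' Returns the sub-mesh containing exactly the requested faces and the
#' vertices they reference; used both to cut the palatal-vault reference
#' region before superimposition and to "copy" a crown patch for landmark
#' transfer.
#'
#' @param mesh A [trimesh].
#' @param region Integer face indices, or a [region_mask].
#' @return A [trimesh] with renumbered faces.
#' @export
restrict_mesh <- function(mesh, region) {
  faces <- if (inherits(region, "region_mask")) region$faces else as.integer(region)
  if (length(faces) == 0L) stop("restrict_mesh: empty region", call. = FALSE)
  if (anyNA(faces) || min(faces) < 1L || max(faces) > nrow(mesh$faces)) {
    stop("restrict_mesh: face index out of range", call. = FALSE)
  }
  f <- mesh$faces[faces, , drop = FALSE]
  keep <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[keep] <- seq_along(keep)
  trimesh(mesh$vertices[keep, , drop = FALSE],
          matrix(remap[f], ncol = 3L),
          name = mesh$name)
}

#' Concatenate meshes into one surface
#'
#' @param meshes List of [trimesh] objects.
#' @param name Label for the combined mesh.
#' @return A [trimesh]; attribute `face_ranges` is a named list of integer
#'   face-index vectors, one per input mesh, usable as region masks.
#' @export
merge_meshes <- function(meshes, name = "") {
  stopifnot(length(meshes) >= 1L)
  voff <- 0L; foff <- 0L
  verts <- list(); faces <- list(); ranges <- list()
  for (i in seq_along(meshes)) {
    m <- meshes[[i]]
    verts[[i]] <- m$vertices
    faces[[i]] <- m$faces + voff
    ranges[[i]] <- seq.int(foff + 1L, foff + nrow(m$faces))
    voff <- voff + nrow(m$vertices)
    foff <- foff + nrow(m$faces)
  }
  nm <- names(meshes)
  if (!is.null(nm)) names(ranges) <- nm
  out <- trimesh(do.call(rbind, verts), do.call(rbind, faces), name = name)
  attr(out, "face_ranges") <- ranges
  out
}

#' Merge duplicate vertices by exact coordinate equality
#'
#' Exact-match welding (not tolerance welding) keeps landmark-to-surface
#' distances stable; STL stores each triangle's corners independently, so
#' reading always welds.
#'
#' @param mesh A [trimesh].
#' @return A [trimesh] with unique vertices.
#' @export
weld_vertices <- function(mesh) {
  key <- paste(mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3],
               sep = "|")
  first <- !duplicated(key)
  remap <- match(key, key[first])
  trimesh(mesh$vertices[first, , drop = FALSE],
          matrix(remap[as.vector(mesh$faces)], ncol = 3L),
          name = mesh$name)
}
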