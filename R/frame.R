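#' Planes in 3D
#'
#' @param point A point on the plane (mm).
#' @param normal Plane normal (normalised internally).
#' @return An object of class `plane3` with unit `normal`.
#' @export
plane3 <- function(point, normal) {
  point <- as.numeric(point); normal <- as.numeric(normal)
  stopifnot(length(point) == 3L, length(normal) == 3L)
  n <- sqrt(sum(normal^2))
  if (!is.finite(n) || n < 1e-12) stop("plane3: zero normal", call. = FALSE)
  structure(list(point = point, normal = normal / n), class = "plane3")
}

#' @export
print.plane3 <- function(x, ...) {
  cat("<plane3> point", paste(format(x$point, digits = 4), collapse = " "),
      "normal", paste(format(x$normal, digits = 4), collapse = " "), "\n")
  invisible(x)
}

#' @export
apply_transform.plane3 <- function(x, transform) {
  plane3(transform_points(x$point, transform),
         as.numeric(transform$rotation %*% x$normal))
}

#' Signed distance of points from a plane
#' @param p n x 3 matrix or numeric(3).
#' @param plane A [plane3].
#' @return Signed distances (positive on the normal side).
#' @export
plane_offset <- function(p, plane) {
  vec <- is.null(dim(p))
  m <- if (vec) matrix(as.numeric(p), ncol = 3L) else as.matrix(p)
  off <- as.numeric(sweep(m, 2L, plane$point) %*% plane$normal)
  if (vec) off[1] else off
}

#' Fit the functional occlusal plane (total least squares)
#'
#' Fits a plane to cusp points by orthogonal least squares (the normal is the
#' singular vector of the centred point cloud with the smallest singular
#' value). The functional occlusal plane (FOP) is fitted to the cusps of the
#' bilateral first premolars, second premolars and first molars, excluding
#' the molars' distal-lingual cusps — 14 points by default.
#'
#' The normal's sign is a convention: it is oriented so that `orient_toward`
#' (typically the posterior palatal-suture point `B`, which lies gingival to
#' the occlusal surface) has positive offset, making "the normal direction of
#' the FOP" — and hence every tip/torque sign — reproducible.
#'
#' @param cusp_points n x 3 matrix (n >= 3, non-collinear).
#' @param orient_toward Optional point given positive offset.
#' @return A [plane3]; attribute `rms` is the orthogonal residual RMS (mm).
#' @export
fit_fop <- function(cusp_points, orient_toward = NULL) {
  p <- as.matrix(cusp_points)
  stopifnot(ncol(p) == 3L)
  if (nrow(p) < 3L) stop("fit_fop: need at least 3 points", call. = FALSE)
  ctr <- colMeans(p)
  sv <- svd(sweep(p, 2L, ctr))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12)) {
    stop("fit_fop: points are collinear - plane undefined", call. = FALSE)
  }
  normal <- sv$v[, 3]
  if (!is.null(orient_toward)) {
    if (sum((as.numeric(orient_toward) - ctr) * normal) < 0) normal <- -normal
  }
  out <- plane3(ctr, normal)
  attr(out, "rms") <- sqrt(mean((sweep(p, 2L, ctr) %*% normal)^2))
  out
}

#' Orthogonal projection of points onto a plane
#' @param p n x 3 matrix or numeric(3).
#' @param plane A [plane3].
#' @return Projected points, same shape as `p`; idempotent.
#' @export
project_point <- function(p, plane) {
  vec <- is.null(dim(p))
  m <- if (vec) matrix(as.numeric(p), ncol = 3L) else as.matrix(p)
  off <- as.numeric(sweep(m, 2L, plane$point) %*% plane$normal)
  out <- m - off %*% t(plane$normal)
  if (vec) as.numeric(out) else out
}

#' Anatomical coordinate frame from suture points and occlusal plane
#'
#' Builds the measurement frame: with `A` (anterior) and `B` (posterior)
#' marked on the palatal suture and `A'`, `B'` their projections on the
#' functional occlusal plane, the origin is `B'`, the x axis is `B' -> A'`
#' (anterior, in the FOP), the y axis is `B' -> B` (the FOP normal,
#' gingival), and the z axis completes a right-handed triad (`z = x cross
#' y`, transverse). The x-y plane is the sagittal plane through `A A' B B'`.
#'
#' @param A,B Suture points, numeric(3) (A anterior, B posterior).
#' @param fop The functional occlusal plane, a [plane3].
#' @return An object of class `coord_frame`: `origin`, and unit `x_axis`,
#'   `y_axis`, `z_axis`.
#' @export
build_frame <- function(A, B, fop) {
  A <- as.numeric(A); B <- as.numeric(B)
  a_p <- project_point(A, fop)
  b_p <- project_point(B, fop)
  x <- a_p - b_p
  nx <- sqrt(sum(x^2))
  if (nx < 1e-9) {
    stop("build_frame: A' and B' coincide (suture perpendicular to the FOP)",
         call. = FALSE)
  }
  x <- x / nx
  yv <- B - b_p
  ny <- sqrt(sum(yv^2))
  if (ny < 1e-9) {
    stop("build_frame: B lies on the FOP - y axis undefined", call. = FALSE)
  }
  y <- yv / ny
  z <- c(x[2] * y[3] - x[3] * y[2],
         x[3] * y[1] - x[1] * y[3],
         x[1] * y[2] - x[2] * y[1])
  structure(list(origin = b_p, x_axis = x, y_axis = y, z_axis = z),
            class = "coord_frame")
}

#' @export
print.coord_frame <- function(x, ...) {
  cat("<coord_frame> origin",
      paste(format(x$origin, digits = 4), collapse = " "), "\n")
  for (ax in c("x_axis", "y_axis", "z_axis")) {
    cat(" ", ax, paste(format(x[[ax]], digits = 4), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
apply_transform.coord_frame <- function(x, transform) {
  structure(list(origin = transform_points(x$origin, transform),
                 x_axis = as.numeric(transform$rotation %*% x$x_axis),
                 y_axis = as.numeric(transform$rotation %*% x$y_axis),
                 z_axis = as.numeric(transform$rotation %*% x$z_axis)),
            class = "coord_frame")
}

frame_rotation <- function(f) cbind(f$x_axis, f$y_axis, f$z_axis)

#' World coordinates to frame coordinates
#' @param p n x 3 matrix or numeric(3) in world (model) coordinates.
#' @param frame A `coord_frame`.
#' @return Coordinates `(x, y, z)` in the frame, same shape as `p`.
#' @export
to_frame <- function(p, frame) {
  vec <- is.null(dim(p))
  m <- if (vec) matrix(as.numeric(p), ncol = 3L) else as.matrix(p)
  out <- sweep(m, 2L, frame$origin) %*% frame_rotation(frame)
  if (vec) as.numeric(out) else out
}

#' Frame coordinates back to world coordinates
#' @param p n x 3 matrix or numeric(3) of frame coordinates.
#' @param frame A `coord_frame`.
#' @return World coordinates, same shape as `p`.
#' @export
from_frame <- function(p, frame) {
  vec <- is.null(dim(p))
  m <- if (vec) matrix(as.numeric(p), ncol = 3L) else as.matrix(p)
  out <- sweep(m %*% t(frame_rotation(frame)), 2L, frame$origin, "+")
  if (vec) as.numeric(out) else out
}

#' Select functional-occlusal-plane cusp landmarks
#'
#' Picks the cusp points used to fit the FOP from a landmark table: buccal
#' and lingual cusps of both first and second premolars plus the
#' mesial-buccal, distal-buccal and mesial-lingual cusps of both first
#' molars (the distal-lingual molar cusp is excluded) — 14 points. With
#' `cusp_set = "buccal"` only buccal cusps are used (8 points).
#'
#' @param lms Landmark tibble.
#' @param cusp_set `"all"` (default) or `"buccal"`.
#' @return n x 3 matrix of cusp coordinates.
#' @export
fop_cusp_points <- function(lms, cusp_set = c("all", "buccal")) {
  cusp_set <- match.arg(cusp_set)
  premolar <- !is.na(lms$tooth) & lms$tooth %in% c("RU4", "LU4", "RU5", "LU5")
  molar <- !is.na(lms$tooth) & lms$tooth %in% c("RU6", "LU6")
  ids_prem <- if (cusp_set == "all") c("BC", "LC") else "BC"
  ids_mol <- if (cusp_set == "all") c("A", "DBC", "MLC") else c("A", "DBC")
  sel <- (premolar & lms$id %in% ids_prem) | (molar & lms$id %in% ids_mol)
  if (sum(sel) < 3L) {
    stop("fop_cusp_points: fewer than 3 cusp landmarks found", call. = FALSE)
  }
  landmark_xyz(lms[sel, ])
}
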