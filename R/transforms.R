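#' Rigid transforms in 3D
#'
#' A rigid transform maps points as `p -> R p + t`, where `R` is a proper
#' rotation (orthonormal, determinant +1 — reflections are rejected) and `t`
#' a translation in millimetres. Rigid transforms carry one acquisition of the
#' maxilla into the space of another: superimposition is, by definition, the
#' estimation of such a transform.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation numeric length-3 translation (mm).
#' @return An object of class `rigid_transform` with elements `rotation` and
#'   `translation`.
#' @examples
#' t1 <- rigid_transform(rotation_about_axis(c(0, 0, 1), 30), c(1, 2, 3))
#' compose_transforms(invert_transform(t1), t1) # ~ identity
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (!all(is.finite(rotation)) || !all(is.finite(translation))) {
    stop("rigid_transform: non-finite entries", call. = FALSE)
  }
  ortho_err <- max(abs(crossprod(rotation) - diag(3)))
  if (ortho_err > 1e-6) {
    stop("rigid_transform: rotation is not orthonormal (error ",
         format(ortho_err), ")", call. = FALSE)
  }
  if (det(rotation) < 0) {
    stop("rigid_transform: reflection (det = -1) is not a rigid motion",
         call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("  rotation angle:", format(rotation_angle_deg(x$rotation), digits = 4),
      "deg\n")
  cat("  translation:  ", paste(format(x$translation, digits = 4),
                                collapse = " "), "mm\n")
  invisible(x)
}

#' Identity rigid transform
#' @return A `rigid_transform` that maps every point to itself.
#' @export
identity_transform <- function() rigid_transform()

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` is the transform applying `b` first, then `a`
#' (function composition `a o b`), so
#' `invert_transform(compose_transforms(a, b))` equals
#' `compose_transforms(invert_transform(b), invert_transform(a))`.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param x A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(x) {
  stopifnot(inherits(x, "rigid_transform"))
  rt <- t(x$rotation)
  rigid_transform(rt, -as.numeric(rt %*% x$translation))
}

#' Apply a rigid transform
#'
#' Generic over the pipeline's spatial objects: point matrices, meshes,
#' landmark tables, planes and coordinate frames all transform with the same
#' `rigid_transform`, which is what makes measurements pose-independent.
#'
#' @param x Object to transform (n x 3 matrix, numeric(3), [trimesh],
#'   landmark tibble, `plane3` or `coord_frame`).
#' @param transform A `rigid_transform`.
#' @return An object of the same kind as `x`.
#' @export
apply_transform <- function(x, transform) UseMethod("apply_transform")

#' @export
apply_transform.default <- function(x, transform) {
  transform_points(x, transform)
}

#' Transform an n x 3 coordinate matrix
#' @param points n x 3 matrix or numeric(3).
#' @param transform A `rigid_transform`.
#' @return Same shape as `points`.
#' @export
transform_points <- function(points, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  vec <- is.null(dim(points))
  p <- if (vec) matrix(as.numeric(points), ncol = 3L) else as.matrix(points)
  stopifnot(ncol(p) == 3L)
  out <- p %*% t(transform$rotation)
  out <- sweep(out, 2L, transform$translation, "+")
  if (vec) as.numeric(out) else out
}

#' Rotation matrix about an axis
#' @param axis numeric(3) rotation axis (normalised internally).
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  a <- as.numeric(axis)
  n <- sqrt(sum(a^2))
  if (n < 1e-12) stop("rotation_about_axis: zero axis", call. = FALSE)
  a <- a / n
  th <- angle_deg * pi / 180
  k <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3L, 3L)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

#' Rotation angle of a rotation matrix
#' @param rotation 3x3 rotation matrix.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
rotation_angle_deg <- function(rotation) {
  tr <- sum(diag(as.matrix(rotation)))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}

#' Discrepancy between two rigid transforms
#'
#' Reports the rotation angle of `a * b^-1` and the translation distance, the
#' natural "how far apart are these two superimpositions" summary used in the
#' transform-recovery checks.
#'
#' @param a,b `rigid_transform` objects.
#' @return Named numeric: `rotation_deg`, `translation_mm`.
#' @export
transform_discrepancy <- function(a, b) {
  d <- compose_transforms(a, invert_transform(b))
  c(rotation_deg = rotation_angle_deg(d$rotation),
    translation_mm = sqrt(sum(d$translation^2)))
}
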