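#' Tooth position and orientation metrics
#'
#' Position is the frame coordinate of a single landmark (mesial-buccal cusp
#' for a first molar, incisal-edge midpoint for a central incisor). Orientation
#' is expressed as two signed angles between the tooth axis's projections and
#' the normal direction of the functional occlusal plane (FOP): the projection
#' onto the tooth's mesiodistal plane gives *torque*, the projection onto its
#' buccolingual plane gives *tip*. (That assignment follows the source
#' measurement protocol literally; conventional orthodontic usage often swaps
#' the two names — see `swap_tip_torque` in [measure_tooth()].)
#'
#' @name tooth-metrics
NULL

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v, what = "vector") {
  n <- sqrt(sum(v^2))
  if (!is.finite(n) || n < 1e-12) stop(what, ": zero length", call. = FALSE)
  v / n
}

#' Mesiodistal plane of a tooth
#'
#' The vertical plane through the tooth's mesial and distal points (central
#' groove for a molar, incisal edge for an incisor) and their projections on
#' the FOP. Contains all four points; its normal is orthogonal to the FOP
#' normal. Orientation-insensitive: swapping mesial and distal gives the same
#' plane.
#'
#' @param distal,mesial numeric(3) landmark coordinates.
#' @param fop The functional occlusal plane ([plane3]).
#' @return A [plane3] through `distal`.
#' @export
mesiodistal_plane <- function(distal, mesial, fop) {
  u <- as.numeric(mesial) - as.numeric(distal)
  n <- fop$normal
  uh <- u - sum(u * n) * n
  if (sqrt(sum(uh^2)) < 1e-9) {
    stop("mesiodistal_plane: mesial-distal segment is perpendicular to the ",
         "FOP (projected points coincide)", call. = FALSE)
  }
  plane3(distal, cross3(unit3(uh), n))
}

#' Buccolingual plane of a tooth
#'
#' The plane perpendicular to both the mesiodistal plane and the FOP, through
#' a given anchor point (the tooth-axis midpoint; the anchor affects only
#' where the plane sits, not any angle measured against it).
#'
#' @param md Mesiodistal plane ([plane3]).
#' @param fop Functional occlusal plane ([plane3]).
#' @param through numeric(3) anchor point on the returned plane.
#' @return A [plane3].
#' @export
buccolingual_plane <- function(md, fop, through) {
  nrm <- cross3(md$normal, fop$normal)
  if (sqrt(sum(nrm^2)) < 1e-9) {
    stop("buccolingual_plane: mesiodistal plane is parallel to the FOP",
         call. = FALSE)
  }
  plane3(through, nrm)
}

#' Tooth axis from its endpoint landmarks
#'
#' @param occlusal_end,gingival_end numeric(3): the most occlusal and most
#'   gingival landmark of the axis (buccal-groove points for a molar,
#'   incisal- and gingival-edge midpoints for an incisor).
#' @return Unit vector oriented gingival -> occlusal.
#' @export
tooth_axis <- function(occlusal_end, gingival_end) {
  unit3(as.numeric(occlusal_end) - as.numeric(gingival_end),
        "tooth_axis: coincident endpoints")
}

# In-plane direction of a vertical tooth plane: perpendicular to both the
# plane normal and the FOP normal, signed toward the first hint direction not
# orthogonal to it (falling back to a fixed component rule), so that angle
# signs are reproducible. Shared by the angle measurements and the phantom
# generator's analytic construction.
inplane_direction <- function(plane_normal, fop_normal, hints = NULL) {
  t <- cross3(plane_normal, fop_normal)
  t <- unit3(t, "inplane_direction: plane parallel to FOP")
  if (!is.null(hints)) {
    if (!is.list(hints)) hints <- list(hints)
    for (h in hints) {
      d <- sum(t * h)
      if (abs(d) > 1e-6) return(t * sign(d))
    }
  }
  for (k in 1:3) if (abs(t[k]) > 1e-6) return(t * sign(t[k]))
  t
}

# Signed angle between the projection of `axis` onto the plane with normal
# `m` and the FOP normal. The projected axis is treated as a line: it is
# canonicalised to the gingival side (positive FOP-normal component) before
# signing, so the result is invariant to the axis's end-to-end orientation
# and lies in (-90, 90].
projected_axis_angle <- function(axis, m, fop, hints = NULL) {
  axis <- as.numeric(axis)
  proj <- axis - sum(axis * m) * m
  if (sqrt(sum(proj^2)) < 1e-9) {
    stop("projected axis has zero length (axis parallel to the plane normal)",
         call. = FALSE)
  }
  t <- inplane_direction(m, fop$normal, hints)
  u <- sum(proj * fop$normal)
  v <- sum(proj * t)
  if (u < 0) { u <- -u; v <- -v }
  atan2(v, u) * 180 / pi
}

#' Torque angle of a tooth axis
#'
#' Signed angle between the projection of the tooth axis onto the mesiodistal
#' plane and the FOP normal. Positive when the projected axis leans toward
#' the first `positive_hints` direction (the frame's +x / anterior axis in
#' [measure_tooth()]).
#'
#' @param axis Unit tooth axis (see [tooth_axis()]).
#' @param md Mesiodistal plane.
#' @param fop Functional occlusal plane.
#' @param positive_hints Vector or list of vectors fixing the positive lean
#'   direction; `NULL` uses a deterministic component rule.
#' @return Signed angle in degrees, in `(-90, 90]`.
#' @export
torque_angle <- function(axis, md, fop, positive_hints = NULL) {
  projected_axis_angle(axis, md$normal, fop, positive_hints)
}

#' Tip angle of a tooth axis
#'
#' As [torque_angle()], with the buccolingual plane; positive toward the
#' first `positive_hints` direction (the frame's +z / transverse axis in
#' [measure_tooth()]).
#'
#' @inheritParams torque_angle
#' @param bl Buccolingual plane.
#' @return Signed angle in degrees, in `(-90, 90]`.
#' @export
tip_angle <- function(axis, bl, fop, positive_hints = NULL) {
  projected_axis_angle(axis, bl$normal, fop, positive_hints)
}

tooth_landmark_roles <- function(tooth) {
  if (grepl("U6$", tooth)) {
    list(position = "A", distal = "B", mesial = "C",
         occlusal = "D", gingival = "E")
  } else if (grepl("U1$", tooth)) {
    list(position = "F", distal = "G", mesial = "H",
         occlusal = "F", gingival = "I")
  } else {
    stop("measure_tooth: unsupported tooth type: ", tooth, call. = FALSE)
  }
}

#' Measure one tooth
#'
#' Computes the tooth's position (frame coordinates of the mesial-buccal cusp
#' for a U6, of the incisal-edge midpoint for a U1) and its tip and torque
#' angles from its landmark set.
#'
#' @param lms Landmark tibble containing the tooth's landmarks.
#' @param tooth Tooth label (`"RU6"`, `"LU6"`, `"RU1"`, `"LU1"`).
#' @param frame Measurement frame ([build_frame()]).
#' @param fop Functional occlusal plane ([fit_fop()]).
#' @param swap_tip_torque If `TRUE`, report the mesiodistal-projection angle
#'   as tip and the buccolingual-projection angle as torque (the common
#'   orthodontic convention); default `FALSE` keeps the protocol-literal
#'   assignment.
#' @return One-row tibble: `tooth`, `x`, `y`, `z` (mm), `tip`, `torque`
#'   (degrees).
#' @export
measure_tooth <- function(lms, tooth, frame, fop, swap_tip_torque = FALSE) {
  roles <- tooth_landmark_roles(tooth)
  pt <- function(role) landmark_point(lms, roles[[role]], tooth)
  pos <- to_frame(pt("position"), frame)
  md <- mesiodistal_plane(pt("distal"), pt("mesial"), fop)
  occl <- pt("occlusal"); ging <- pt("gingival")
  axis <- tooth_axis(occl, ging)
  bl <- buccolingual_plane(md, fop, (occl + ging) / 2)
  hints_md <- list(frame$x_axis, frame$z_axis, frame$y_axis)
  hints_bl <- list(frame$z_axis, frame$x_axis, frame$y_axis)
  ang_md <- torque_angle(axis, md, fop, hints_md)
  ang_bl <- tip_angle(axis, bl, fop, hints_bl)
  tibble::tibble(
    tooth = tooth,
    x = pos[1], y = pos[2], z = pos[3],
    tip = if (swap_tip_torque) ang_md else ang_bl,
    torque = if (swap_tip_torque) ang_bl else ang_md)
}

#' Measure several teeth
#'
#' @inheritParams measure_tooth
#' @param teeth Character vector of tooth labels.
#' @return Tibble with one row per tooth (see [measure_tooth()]).
#' @export
measure_teeth <- function(lms, frame, fop,
                          teeth = c("RU6", "LU6", "RU1", "LU1"),
                          swap_tip_torque = FALSE) {
  purrr::map_dfr(teeth, measure_tooth, lms = lms, frame = frame, fop = fop,
                 swap_tip_torque = swap_tip_torque)
}

#' Transfer a crown patch with bonded landmarks onto another model
#'
#' Copies the crown region of one post-treatment model, registers the patch
#' rigidly onto the other post-treatment model by ICP, and carries the
#' tooth's landmarks with the recovered transform. Measuring both models with
#' the *same* (transferred) landmarks excludes landmark-identification error
#' from the superimposition comparison.
#'
#' @param source_mesh [trimesh] carrying the crown (the reference-route
#'   post-treatment model).
#' @param crown_mask [region_mask] (or face indices) of the crown on
#'   `source_mesh`.
#' @param lms Landmark tibble rows bonded to this crown.
#' @param target_mesh [trimesh] to transfer onto (the palatal-vault-route
#'   post-treatment model).
#' @param init Seed transform (identity: the two models are already in a
#'   common space up to residual superimposition error).
#' @param ... Passed to [icp_region()].
#' @return List: `landmarks` (transferred tibble), `icp` (the `icp_result`).
#' @export
transfer_crown <- function(source_mesh, crown_mask, lms, target_mesh,
                           init = identity_transform(), ...) {
  patch <- restrict_mesh(source_mesh, crown_mask)
  fit <- tryCatch(
    icp_region(patch, target_mesh, region = NULL, init = init,
               min_samples = 300L, ...),
    error = function(e) {
      stop("transfer_crown: registration failed for ",
           paste(unique(stats::na.omit(lms$tooth)), collapse = ","), ": ",
           conditionMessage(e), call. = FALSE)
    })
  list(landmarks = apply_transform(tibble::as_tibble(lms), fit$transform),
       icp = fit)
}
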