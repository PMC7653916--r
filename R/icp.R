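#' Region-restricted trimmed point-to-surface ICP
#'
#' Rigidly registers a masked region of the moving mesh onto the fixed mesh
#' by iterative closest point: sample points are taken from the region
#' (vertices plus face barycentres), each is matched to its nearest point on
#' the fixed surface (point-to-triangle distance), correspondences beyond
#' `gate_factor` times the current RMS are rejected, the worst `trim`
#' fraction of the remainder is discarded, and the rigid update is the
#' least-squares (Kabsch) fit to the surviving foot points. An update is
#' accepted only if it does not increase the trimmed RMS, so the objective is
#' monotone non-increasing across accepted iterations.
#'
#' This is the engine behind both superimposition modes: the palatal-vault
#' (stable-region) model-to-model superimposition, and the dental-crown-area
#' reference superimposition / crown-patch landmark transfer.
#'
#' @param moving,fixed [trimesh] objects.
#' @param region Face indices or [region_mask] on `moving`; defaults to the
#'   whole mesh.
#' @param init A `rigid_transform` seeding the iteration — supply the
#'   [landmark_align()] result (coarse landmark pre-alignment); identity is
#'   appropriate only for already-roughly-aligned models.
#' @param max_iter Maximum iterations (default 100).
#' @param tol Convergence: relative change of trimmed RMS below `tol`
#'   (default 1e-6), or absolute RMS below `abs_tol`.
#' @param abs_tol Absolute RMS floor treated as converged (default 1e-9 mm).
#' @param trim Fraction of worst correspondences discarded per iteration
#'   (default 0.1).
#' @param gate_factor Correspondences farther than `gate_factor` x current
#'   RMS are rejected before trimming (default 5).
#' @param min_samples Minimum number of region sample points; barycentres are
#'   always added so sparse masks still yield a usable set (default 500).
#' @param max_samples Deterministic stride subsampling cap (default 4000).
#' @return An object of class `icp_result`: `transform` (moving into fixed
#'   space), `rms_residual` (mm), `n_correspondences`, `n_iterations`,
#'   `converged`, `degenerate_region` (near-planar region flag) and `history`
#'   (trimmed RMS per accepted iteration).
#' @export
icp_region <- function(moving, fixed, region = NULL,
                       init = identity_transform(),
                       max_iter = 100L, tol = 1e-6, abs_tol = 1e-9,
                       trim = 0.1, gate_factor = 5,
                       min_samples = 500L, max_samples = 4000L) {
  validate_trimesh(moving); validate_trimesh(fixed)
  stopifnot(inherits(init, "rigid_transform"))
  sub <- if (is.null(region)) moving else restrict_mesh(moving, region)
  pts <- icp_samples(sub, min_samples, max_samples)

  # near-planar regions leave a rotational/translational component weakly
  # constrained; flag rather than fail
  sv <- svd(sweep(pts, 2L, colMeans(pts)))$d
  degenerate <- sv[3] < 1e-4 * max(sv[1], 1e-12)

  trans <- init
  rms_prev <- Inf
  history <- numeric(0)
  converged <- FALSE
  n_kept <- nrow(pts)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    cur <- transform_points(pts, trans)
    cp <- cpp_closest_point(cur, fixed$vertices, fixed$faces)
    d <- cp$distance
    rms_all <- sqrt(mean(d^2))
    keep <- d <= gate_factor * rms_all + 1e-12
    if (sum(keep) < 6L) {
      stop("icp_region: no usable correspondences within gating distance - ",
           "registration diverged", call. = FALSE)
    }
    if (trim > 0) {
      idx_keep <- which(keep)
      n_drop <- floor(length(idx_keep) * trim)
      if (n_drop > 0 && length(idx_keep) - n_drop >= 6L) {
        ord <- order(d[idx_keep], decreasing = TRUE)
        keep[idx_keep[ord[seq_len(n_drop)]]] <- FALSE
      }
    }
    rms_cur <- sqrt(mean(d[keep]^2))
    upd <- kabsch_fit(pts[keep, , drop = FALSE],
                      cp$point[keep, , drop = FALSE])
    rms_new <- attr(upd, "rms")
    if (rms_new > rms_cur + 1e-12) {
      # update would increase the trimmed objective: keep current estimate
      converged <- TRUE
      history <- c(history, rms_cur)
      n_kept <- sum(keep)
      rms_prev <- rms_cur
      break
    }
    trans <- upd
    history <- c(history, rms_new)
    n_kept <- sum(keep)
    if (rms_new < abs_tol ||
        (is.finite(rms_prev) &&
         abs(rms_prev - rms_new) < tol * max(rms_prev, abs_tol))) {
      converged <- TRUE
      rms_prev <- rms_new
      break
    }
    rms_prev <- rms_new
  }
  structure(list(transform = trans,
                 rms_residual = if (is.finite(rms_prev)) rms_prev else NA_real_,
                 n_correspondences = n_kept,
                 n_iterations = iter,
                 converged = converged,
                 degenerate_region = degenerate,
                 history = history),
            class = "icp_result")
}

icp_samples <- function(sub, min_samples, max_samples) {
  pts <- rbind(sub$vertices, face_centroids(sub))
  if (nrow(pts) < min_samples) {
    # add edge midpoints so sparse masks still constrain the fit
    f <- sub$faces
    mids <- rbind((sub$vertices[f[, 1], , drop = FALSE] +
                     sub$vertices[f[, 2], , drop = FALSE]) / 2,
                  (sub$vertices[f[, 2], , drop = FALSE] +
                     sub$vertices[f[, 3], , drop = FALSE]) / 2,
                  (sub$vertices[f[, 3], , drop = FALSE] +
                     sub$vertices[f[, 1], , drop = FALSE]) / 2)
    pts <- rbind(pts, mids)
  }
  if (nrow(pts) > max_samples) {
    pts <- pts[seq(1L, nrow(pts), length.out = max_samples), , drop = FALSE]
  }
  pts
}

#' @export
print.icp_result <- function(x, ...) {
  cat("<icp_result>", x$n_iterations, "iterations,",
      x$n_correspondences, "correspondences, rms",
      format(x$rms_residual, digits = 4), "mm,",
      if (x$converged) "converged" else "NOT converged",
      if (x$degenerate_region) "(near-planar region)" else "", "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.icp_result <- function(x, ...) {
  tibble::tibble(
    term = c("rx", "ry", "rz", "tx", "ty", "tz"),
    estimate = c(rotation_to_euler_deg(x$transform$rotation),
                 x$transform$translation),
    unit = c(rep("deg", 3), rep("mm", 3)))
}

#' @export
glance.icp_result <- function(x, ...) {
  tibble::tibble(rms_residual = x$rms_residual,
                 n_correspondences = x$n_correspondences,
                 n_iterations = x$n_iterations,
                 converged = x$converged,
                 degenerate_region = x$degenerate_region)
}

# intrinsic z-y-x Euler angles, reporting convenience only
rotation_to_euler_deg <- function(r) {
  sy <- sqrt(r[1, 1]^2 + r[2, 1]^2)
  if (sy > 1e-9) {
    c(atan2(r[3, 2], r[3, 3]), atan2(-r[3, 1], sy),
      atan2(r[2, 1], r[1, 1])) * 180 / pi
  } else {
    c(atan2(-r[2, 3], r[2, 2]), atan2(-r[3, 1], sy), 0) * 180 / pi
  }
}
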