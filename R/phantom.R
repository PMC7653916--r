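#' Synthetic palate phantom
#'
#' Generates pre-/post-treatment ("T1"/"T2") maxillary digital model pairs
#' with known ground truth, emulating the study inputs end to end: a smooth
#' super-elliptic palatal-vault dome with rugae-like ridges anteriorly, four
#' measurable crowns (right/left first molars and central incisors) built as
#' analytic solids so their landmarks are exact by construction, the
#' functional-occlusal-plane cusp landmarks of the premolars and molars, the
#' palatal-suture points, alignment landmarks for registration seeding,
#' region masks (palatal-vault stable patch, per-tooth crowns), a rigid
#' global pose difference between the two acquisitions, per-tooth rigid
#' "treatment" movements, and Gaussian surface noise along vertex normals.
#'
#' The phantom is built in a canonical space in which the functional occlusal
#' plane is exactly `z = 0` (normal towards the palate) and the measurement
#' frame is axis-aligned, so tooth parameters given in frame coordinates are
#' reproduced *exactly* by the measurement chain on the noiseless phantom.
#'
#' @name phantom
NULL

default_phantom_teeth <- function() {
  tibble::tibble(
    tooth = c("RU6", "LU6", "RU1", "LU1"),
    x = c(4, 4, 34, 34),
    y = c(0, 0, 1.5, 1.5),
    z = c(24, -24, 4.3, -4.3),
    tip = c(4, -4, 2, -2),
    torque = c(-6, -6, 7, 7))
}

default_phantom_treatment <- function() {
  list(
    RU6 = list(translation = c(-1.0, 0.2, 0.4), rotation_deg = 3,
               axis = c(0, 1, 0.3)),
    LU6 = list(translation = c(-0.8, 0.1, -0.3), rotation_deg = -2.5,
               axis = c(0, 1, -0.3)),
    RU1 = list(translation = c(-2.0, 0.3, -0.2), rotation_deg = 5,
               axis = c(0, 0, 1)),
    LU1 = list(translation = c(-2.0, 0.3, 0.2), rotation_deg = 4,
               axis = c(0, 0, 1)))
}

#' Phantom specification
#'
#' All lengths in millimetres, angles in degrees. Tooth positions and the
#' treatment motions are given in measurement-frame coordinates (+x anterior,
#' +y gingival along the FOP normal, +z transverse towards the patient's
#' right). Molar heights (`y`) default to 0, putting all fourteen cusp
#' landmarks exactly on one plane: the fitted FOP is then exact and the
#' measured values equal the input parameters digit for digit. Non-zero
#' molar heights tilt the fitted plane slightly; the stored ground truth
#' follows the fitted plane analytically either way.
#'
#' @param seed Integer RNG seed; fixed seed gives bit-reproducible output.
#' @param dome_length,dome_half_width,vault_height Palatal dome dimensions.
#' @param rugae_amplitude,rugae_wavelength Sinusoidal rugae ridge pattern in
#'   the anterior third of the dome.
#' @param grid_nx,grid_ny Dome mesh grid resolution.
#' @param stable_x_max,stable_half_width Extent of the palatal-vault stable
#'   region (the medial band of the third ruga and the vault dorsal to it).
#' @param suture_A_x,suture_B_x Midline positions of the anterior/posterior
#'   palatal-suture points.
#' @param teeth Tibble `tooth, x, y, z, tip, torque` of per-tooth pose
#'   parameters (frame coordinates / degrees).
#' @param crown_n_eta,crown_n_phi Crown mesh resolution.
#' @param global_transform `rigid_transform`: pose of the T2 acquisition
#'   relative to T1 (the transform the superimposition must recover).
#' @param treatment Named list (by tooth) of
#'   `list(translation =, rotation_deg =, axis =)` rigid treatment motions in
#'   frame coordinates, applied about the crown landmark centroid; `NULL`
#'   for no tooth movement.
#' @param surface_noise_sd,stable_noise_sd Gaussian surface noise SD along
#'   vertex normals on the T2 mesh, outside/inside the stable region.
#' @param drift_amplitude Amplitude of a smooth low-frequency "soft tissue"
#'   deformation of the T2 palate (stress-tests the stable-region
#'   assumption).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L,
                         dome_length = 38, dome_half_width = 22,
                         vault_height = 13,
                         rugae_amplitude = 0.5, rugae_wavelength = 4,
                         grid_nx = 46L, grid_ny = 42L,
                         stable_x_max = 26.5, stable_half_width = 14.5,
                         suture_A_x = 24, suture_B_x = 6,
                         teeth = default_phantom_teeth(),
                         crown_n_eta = 9L, crown_n_phi = 16L,
                         global_transform = rigid_transform(
                           rotation_about_axis(c(0.2, 1, 0.4), 6),
                           c(2.5, -1.8, 3.0)),
                         treatment = default_phantom_treatment(),
                         surface_noise_sd = 0.05,
                         stable_noise_sd = 0.02,
                         drift_amplitude = 0) {
  spec <- list(seed = as.integer(seed), dome_length = dome_length,
               dome_half_width = dome_half_width,
               vault_height = vault_height,
               rugae_amplitude = rugae_amplitude,
               rugae_wavelength = rugae_wavelength,
               grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
               stable_x_max = stable_x_max,
               stable_half_width = stable_half_width,
               suture_A_x = suture_A_x, suture_B_x = suture_B_x,
               teeth = tibble::as_tibble(teeth),
               crown_n_eta = as.integer(crown_n_eta),
               crown_n_phi = as.integer(crown_n_phi),
               global_transform = global_transform,
               treatment = treatment,
               surface_noise_sd = surface_noise_sd,
               stable_noise_sd = stable_noise_sd,
               drift_amplitude = drift_amplitude)
  stopifnot(spec$surface_noise_sd >= 0, spec$stable_noise_sd >= 0,
            spec$grid_nx >= 8L, spec$grid_ny >= 8L,
            inherits(spec$global_transform, "rigid_transform"))
  structure(spec, class = "phantom_spec")
}

# frame <-> canonical construction coordinates: frame x = +X, y = +Z,
# z = -Y; frame origin at (suture_B_x, 0, 0)
frame_vec_to_world <- function(v) c(v[1], -v[3], v[2])
frame_point_to_world <- function(p, spec) {
  c(spec$suture_B_x + p[1], -p[3], p[2])
}

# dental arch (occlusal view): X = a - c * Y^2 through the incisor and
# molar positions; tangent gives each tooth's mesiodistal direction
arch_coef <- function(spec) {
  pos <- spec$teeth
  inc <- pos[pos$tooth == "RU1", ]
  mol <- pos[pos$tooth == "RU6", ]
  yi <- abs(inc$z); ym <- abs(mol$z)
  xi <- spec$suture_B_x + inc$x; xm <- spec$suture_B_x + mol$x
  cc <- (xi - xm) / (ym^2 - yi^2)
  list(a = xi + cc * yi^2, c = cc)
}

arch_tangent <- function(yc, coef) {
  unit3(c(-2 * coef$c * yc, 1, 0))
}

dome_height_fun <- function(spec) {
  L <- spec$dome_length; W <- spec$dome_half_width
  H <- spec$vault_height
  amp <- spec$rugae_amplitude; wl <- spec$rugae_wavelength
  rug_lo <- spec$suture_A_x; rug_hi <- min(L - 2, rug_lo + 10)
  function(x, y) {
    t <- pmin(pmax(x / L, 0), 1)
    base <- H * sin(pi * t)^0.9 * pmax(1 - (y / W)^2, 0)
    win <- ifelse(x > rug_lo & x < rug_hi,
                  0.5 * (1 - cos(2 * pi * (x - rug_lo) / (rug_hi - rug_lo))),
                  0)
    base + amp * sin(2 * pi * (x - rug_lo) / wl) * win * exp(-(y / 10)^2)
  }
}

build_dome_mesh <- function(spec) {
  zf <- dome_height_fun(spec)
  xs <- seq(0, spec$dome_length, length.out = spec$grid_nx)
  ys <- seq(-spec$dome_half_width, spec$dome_half_width,
            length.out = spec$grid_ny)
  g <- expand.grid(y = ys, x = xs)  # y fastest
  verts <- cbind(g$x, g$y, zf(g$x, g$y))
  nx <- spec$grid_nx; ny <- spec$grid_ny
  vid <- function(i, j) (i - 1L) * ny + j  # i over x, j over y
  i <- rep(seq_len(nx - 1L), each = ny - 1L)
  j <- rep(seq_len(ny - 1L), times = nx - 1L)
  f1 <- cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L))
  f2 <- cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L))
  trimesh(verts, rbind(f1, f2), name = "palate")
}

superellipsoid_mesh <- function(center, axes, half, eps = 0.45,
                                n_eta = 9L, n_phi = 16L, name = "crown") {
  f <- function(t, e) sign(t) * abs(t)^e
  eta <- seq(-pi / 2, pi / 2, length.out = n_eta + 2L)
  eta <- eta[-c(1L, length(eta))]
  phi <- seq(-pi, pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  g <- expand.grid(phi = phi, eta = eta)
  lx <- half[1] * f(cos(g$eta), eps) * f(cos(g$phi), eps)
  ly <- half[2] * f(cos(g$eta), eps) * f(sin(g$phi), eps)
  lz <- half[3] * f(sin(g$eta), eps)
  local <- cbind(lx, ly, lz)
  local <- rbind(local, c(0, 0, -half[3]), c(0, 0, half[3]))  # poles
  verts <- sweep(local %*% t(axes), 2L, center, "+")
  vid <- function(i, j) (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  i <- rep(seq_len(n_eta - 1L), each = n_phi)
  j <- rep(seq_len(n_phi), times = n_eta - 1L)
  f1 <- cbind(vid(i, j), vid(i, j + 1L), vid(i + 1L, j + 1L))
  f2 <- cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i + 1L, j))
  south <- n_eta * n_phi + 1L
  north <- n_eta * n_phi + 2L
  jj <- seq_len(n_phi)
  cap_s <- cbind(rep(south, n_phi), vid(1L, jj + 1L), vid(1L, jj))
  cap_n <- cbind(rep(north, n_phi), vid(n_eta, jj), vid(n_eta, jj + 1L))
  trimesh(verts, rbind(f1, f2, cap_s, cap_n), name = name)
}

# Landmark constellation and crown mesh for one tooth, built directly in
# world coordinates so the requested (position, tip, torque) are the exact
# measured values: the groove/edge points are horizontal along the arch
# tangent (so the mesiodistal plane direction is exact) and the axis is
# n + tan(torque) t_torque + tan(tip) t_tip with the same in-plane
# directions the measurement uses.
build_tooth <- function(tooth, pos_frame, tip_deg, torque_deg, spec, coef) {
  n <- c(0, 0, 1)
  hints_x <- list(c(1, 0, 0), c(0, -1, 0), c(0, 0, 1))  # frame x, z, y
  hints_z <- list(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  P <- frame_point_to_world(pos_frame, spec)
  tang <- arch_tangent(P[2], coef)
  m <- unit3(cross3(tang, n))                       # mesiodistal plane normal
  t_torque <- inplane_direction(m, n, hints_x)
  t_tip <- inplane_direction(cross3(m, n), n, hints_z)
  ax_ging <- unit3(n + tan(torque_deg * pi / 180) * t_torque +
                     tan(tip_deg * pi / 180) * t_tip)
  d_out <- unit3(cross3(tang, n))          # buccal = away from the midline
  if (sum(d_out * c(0, P[2], 0)) < 0) d_out <- -d_out
  d_in <- -d_out
  d_dist <- if (abs(tang[1]) > 1e-9) -tang * sign(tang[1]) else tang

  molar <- grepl("U6$", tooth)
  if (molar) {
    m0 <- P + 1.5 * d_dist + 2.75 * d_in
    lms <- rbind(A = P,
                 B = m0 + 4 * d_dist,
                 C = m0 - 4 * d_dist,
                 D = P + 2.75 * d_dist + 0.8 * d_out,
                 E = P + 2.75 * d_dist + 0.8 * d_out + 6.5 * ax_ging,
                 DBC = P + 5.5 * d_dist,
                 MLC = P + 5.0 * d_in)
    ctr <- m0 + 3.2 * ax_ging
    half <- c(5.0, 5.5, 3.75)
  } else {
    lms <- rbind(F = P,
                 G = P + 4.25 * d_dist,
                 H = P - 4.25 * d_dist,
                 I = P + 9 * ax_ging)
    ctr <- P + 0.8 * d_in + 4.7 * ax_ging
    half <- c(4.25, 2.0, 5.0)
  }
  u <- unit3(d_dist - sum(d_dist * ax_ging) * ax_ging)
  v <- cross3(ax_ging, u)
  mesh <- superellipsoid_mesh(ctr, cbind(u, v, ax_ging), half,
                              n_eta = spec$crown_n_eta,
                              n_phi = spec$crown_n_phi, name = tooth)
  list(landmarks = landmark_table(rownames(lms), rep(tooth, nrow(lms)), lms),
       mesh = mesh)
}

premolar_cusp_landmarks <- function(spec, coef) {
  rows <- list()
  for (side in c("R", "L")) {
    sg <- if (side == "R") -1 else 1
    for (tn in c(4, 5)) {
      yc <- sg * (if (tn == 4) 14 else 19)
      xc <- coef$a - coef$c * yc^2
      tang <- arch_tangent(yc, coef)
      d_out <- unit3(cross3(tang, c(0, 0, 1)))
      if (sum(d_out * c(0, yc, 0)) > 0) d_out <- -d_out
      base <- c(xc, yc, 0)
      rows[[paste0(side, tn, "BC")]] <-
        c(id = "BC", tooth = paste0(side, "U", tn), base + 2.2 * d_out)
      rows[[paste0(side, tn, "LC")]] <-
        c(id = "LC", tooth = paste0(side, "U", tn), base - 2.2 * d_out)
    }
  }
  m <- do.call(rbind, rows)
  landmark_table(m[, 1], m[, 2], matrix(as.numeric(m[, 3:5]), ncol = 3L))
}

treatment_transform <- function(motion, centroid) {
  if (is.null(motion)) return(identity_transform())
  tr <- frame_vec_to_world(motion$translation %||% c(0, 0, 0))
  rot <- if (!is.null(motion$rotation_deg) && motion$rotation_deg != 0) {
    rotation_about_axis(frame_vec_to_world(motion$axis %||% c(0, 1, 0)),
                        motion$rotation_deg)
  } else diag(3)
  # rotate about the crown centroid, then translate
  rigid_transform(rot, centroid - as.numeric(rot %*% centroid) + tr)
}

#' Generate a phantom model pair
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom_bundle`:
#' \describe{
#'   \item{t1, t2}{each `list(mesh, landmarks, masks)` — the two
#'     acquisitions. T2 carries the treatment motions, the global pose and
#'     the surface noise.}
#'   \item{truth}{`frame` and `fop` of the canonical T1 space,
#'     `measurements_t1` / `measurements_t2` (analytic ground-truth tooth
#'     measurements in T1 space), `global_transform`, `treatment` (named
#'     list of world-space `rigid_transform`s).}
#'   \item{spec}{the input specification.}
#' }
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  coef <- arch_coef(spec)
  zf <- dome_height_fun(spec)
  dome <- build_dome_mesh(spec)

  teeth <- spec$teeth
  built <- lapply(seq_len(nrow(teeth)), function(i) {
    build_tooth(teeth$tooth[i],
                c(teeth$x[i], teeth$y[i], teeth$z[i]),
                teeth$tip[i], teeth$torque[i], spec, coef)
  })
  names(built) <- teeth$tooth

  meshes <- c(list(palate = dome), lapply(built, `[[`, "mesh"))
  t1_mesh <- merge_meshes(meshes, name = "T1")
  ranges <- attr(t1_mesh, "face_ranges")

  cent <- face_centroids(dome)
  stable <- which(cent[, 1] <= spec$stable_x_max &
                    abs(cent[, 2]) <= spec$stable_half_width)
  masks <- c(list(palatal_vault = region_mask("palatal_vault",
                                              ranges$palate[stable], "T1")),
             stats::setNames(lapply(teeth$tooth, function(tt) {
               region_mask("crown", ranges[[tt]], "T1")
             }), paste0(teeth$tooth, "_crown")))

  on_dome <- function(x) c(x[1], x[2], zf(x[1], x[2]))
  fixed_lms <- landmark_table(
    c("A", "B", "IP", "RugaR", "RugaL"),
    rep(NA_character_, 5),
    rbind(on_dome(c(spec$suture_A_x, 0)),
          on_dome(c(spec$suture_B_x, 0)),
          on_dome(c(min(spec$dome_length - 4, spec$suture_A_x + 9), 0)),
          on_dome(c(spec$suture_A_x + 2, -8)),
          on_dome(c(spec$suture_A_x + 2, 8))))
  t1_lms <- dplyr::bind_rows(fixed_lms, premolar_cusp_landmarks(spec, coef),
                             purrr::map_dfr(built, "landmarks"))
  t1_lms <- validate_landmarks(t1_lms)

  # treatment: per-tooth rigid motion about the crown landmark centroid
  motions <- lapply(teeth$tooth, function(tt) {
    cmat <- landmark_xyz(built[[tt]]$landmarks)
    treatment_transform(spec$treatment[[tt]], colMeans(cmat))
  })
  names(motions) <- teeth$tooth

  # crown overlap check after treatment
  ctrs <- vapply(teeth$tooth, function(tt) {
    transform_points(colMeans(built[[tt]]$mesh$vertices), motions[[tt]])
  }, numeric(3))
  dd <- as.matrix(stats::dist(t(ctrs)))
  diag(dd) <- Inf
  if (min(dd) < 4) {
    stop("generate_phantom: crowns overlap after treatment motion (minimum ",
         "centroid separation ", format(min(dd), digits = 3), " mm)",
         call. = FALSE)
  }

  g <- spec$global_transform
  t2_vertices <- t1_mesh$vertices
  vranges <- vertex_ranges(meshes)
  for (tt in teeth$tooth) {
    idx <- vranges[[tt]]
    t2_vertices[idx, ] <- transform_points(t2_vertices[idx, , drop = FALSE],
                                           motions[[tt]])
  }
  t2_mesh <- trimesh(transform_points(t2_vertices, g), t1_mesh$faces,
                     name = "T2")

  move_lms <- t1_lms
  for (tt in teeth$tooth) {
    sel <- !is.na(move_lms$tooth) & move_lms$tooth == tt
    move_lms[sel, ] <- apply_transform(move_lms[sel, ], motions[[tt]])
  }
  t2_lms_t1space <- move_lms            # T2 anatomy expressed in T1 space
  t2_lms <- apply_transform(move_lms, g)

  # surface noise along vertex normals on the T2 acquisition
  if (spec$surface_noise_sd > 0 || spec$stable_noise_sd > 0 ||
      spec$drift_amplitude > 0) {
    t2_mesh <- add_surface_noise(t2_mesh, spec, ranges, stable)
  }

  # ground truth from the analytic landmark coordinates (never the meshes):
  # with the default coplanar cusps the fitted FOP is exactly z = 0 and the
  # measured values equal the input parameters; with non-coplanar cusps the
  # fitted plane is still analytic and the truth follows it exactly
  truth_fop <- fit_fop(fop_cusp_points(t1_lms),
                       orient_toward = landmark_point(t1_lms, "B"))
  truth_frame <- build_frame(landmark_point(t1_lms, "A"),
                             landmark_point(t1_lms, "B"), truth_fop)
  m_t1 <- measure_teeth(t1_lms, truth_frame, truth_fop, teeth = teeth$tooth)
  m_t2 <- measure_teeth(t2_lms_t1space, truth_frame, truth_fop,
                        teeth = teeth$tooth)

  structure(list(
    t1 = list(mesh = t1_mesh, landmarks = t1_lms, masks = masks),
    t2 = list(mesh = t2_mesh, landmarks = t2_lms, masks = masks),
    truth = list(frame = truth_frame, fop = truth_fop,
                 measurements_t1 = m_t1, measurements_t2 = m_t2,
                 landmarks_t2_in_t1 = t2_lms_t1space,
                 global_transform = g, treatment = motions),
    spec = spec), class = "phantom_bundle")
}

vertex_ranges <- function(meshes) {
  off <- 0L
  out <- list()
  for (nm in names(meshes)) {
    nv <- nrow(meshes[[nm]]$vertices)
    out[[nm]] <- seq.int(off + 1L, off + nv)
    off <- off + nv
  }
  out
}

add_surface_noise <- function(mesh, spec, ranges, stable_dome_faces) {
  nrm <- vertex_normals(mesh)
  stable_faces <- ranges$palate[stable_dome_faces]
  stable_verts <- unique(as.vector(mesh$faces[stable_faces, ]))
  sd_per_vertex <- rep(spec$surface_noise_sd, nrow(mesh$vertices))
  sd_per_vertex[stable_verts] <- spec$stable_noise_sd
  disp <- stats::rnorm(nrow(mesh$vertices), 0, 1) * sd_per_vertex
  if (spec$drift_amplitude > 0) {
    v <- mesh$vertices
    disp <- disp + spec$drift_amplitude *
      sin(pi * v[, 1] / spec$dome_length) *
      cos(0.5 * pi * v[, 2] / spec$dome_half_width)
  }
  trimesh(mesh$vertices + disp * nrm, mesh$faces, name = mesh$name)
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat("<phantom_bundle> seed", x$spec$seed, "-",
      nrow(x$t1$mesh$vertices), "vertices,",
      nrow(x$t1$mesh$faces), "faces per model;",
      nrow(x$spec$teeth), "measured teeth\n")
  invisible(x)
}

#' Generate a phantom cohort
#'
#' `n` independent phantom subjects with per-subject randomised anatomy
#' (tooth placement, dome dimensions), treatment motions and global pose;
#' deterministic given `seed`. Mirrors a 20-patient accuracy cohort with a
#' 10-patient reliability subset.
#'
#' @param n Number of subjects.
#' @param seed Cohort RNG seed.
#' @param base Template [phantom_spec()] (its noise settings are kept).
#' @param randomize_anatomy,randomize_motion Logical switches.
#' @return List of `phantom_bundle` objects.
#' @export
phantom_cohort <- function(n, seed = 1L, base = phantom_spec(),
                           randomize_anatomy = TRUE,
                           randomize_motion = TRUE) {
  stopifnot(n >= 1L)
  withr::with_seed(seed, {
    specs <- lapply(seq_len(n), function(i) {
      sp <- base
      sp$seed <- sample.int(.Machine$integer.max - 1L, 1L)
      if (randomize_anatomy) {
        tw <- sp$teeth
        tw$x <- tw$x + stats::runif(nrow(tw), -1.2, 1.2)
        tw$z <- tw$z + sign(tw$z) * stats::runif(nrow(tw), -0.7, 1.0)
        # per-tooth vertical jitter: molar cusps leave the premolar plane,
        # so the fitted FOP and the measured molar heights vary by subject
        tw$y <- tw$y + stats::runif(nrow(tw), -0.6, 0.6)
        tw$tip <- tw$tip + stats::runif(nrow(tw), -3, 3)
        tw$torque <- tw$torque + stats::runif(nrow(tw), -3, 3)
        sp$teeth <- tw
        sp$vault_height <- sp$vault_height * stats::runif(1, 0.92, 1.08)
        sp$dome_half_width <- sp$dome_half_width * stats::runif(1, 0.95, 1.05)
      }
      if (randomize_motion) {
        sp$treatment <- stats::setNames(lapply(sp$teeth$tooth, function(tt) {
          list(translation = stats::runif(3, -1.2, 1.2) * c(1, 1, 0.6),
               rotation_deg = stats::runif(1, -6, 6),
               axis = unit3(stats::rnorm(3)))
        }), sp$teeth$tooth)
        ax <- unit3(stats::rnorm(3))
        dirv <- unit3(stats::rnorm(3))
        sp$global_transform <- rigid_transform(
          rotation_about_axis(ax, stats::runif(1, 2, 9)),
          dirv * stats::runif(1, 1, 4.5))
      }
      sp
    })
    lapply(specs, generate_phantom)
  })
}

#' Write a phantom bundle to disk
#'
#' Writes the STL meshes, landmark sidecars and mask sidecars consumed by
#' the file-based pipeline entry points.
#'
#' @param bundle A `phantom_bundle`.
#' @param dir Output directory (created if needed).
#' @param dialect STL dialect, see [write_stl()].
#' @return Named character vector of the written paths, invisibly.
#' @export
write_phantom <- function(bundle, dir, dialect = "ascii") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(t1_mesh = file.path(dir, "T1.stl"),
             t2_mesh = file.path(dir, "T2.stl"),
             t1_landmarks = file.path(dir, "T1_landmarks.txt"),
             t2_landmarks = file.path(dir, "T2_landmarks.txt"),
             masks = file.path(dir, "masks.json"))
  write_stl(bundle$t1$mesh, paths["t1_mesh"], dialect)
  write_stl(bundle$t2$mesh, paths["t2_mesh"], dialect)
  write_landmarks(bundle$t1$landmarks, paths["t1_landmarks"])
  write_landmarks(bundle$t2$landmarks, paths["t2_landmarks"])
  write_masks(bundle$t1$masks, paths["masks"])
  invisible(paths)
}
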