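#' Superimposition routes and the validation pipeline
#'
#' Two routes bring the post-treatment model ("T2") into the pre-treatment
#' ("T1") space. The *reference* route stands for the CBCT-based chain: the
#' volumetric (voxel-based) superimposition is a validated external step, so
#' it enters as an injected transform — the phantom's ground-truth global
#' pose — or, alternatively, as a dental-crown-area registration onto a
#' reference surface already expressed in T1 space. The *MDM* route is the
#' method under validation: model-to-model superimposition restricted to the
#' palatal-vault stable region. Comparing tooth measurements between the two
#' superimposed models (T2' minus T2) quantifies the accuracy of the
#' palatal-vault method.
#'
#' @name pipeline
NULL

alignment_landmarks <- function(lms) lms[is.na(lms$tooth), , drop = FALSE]

#' Reference-route superimposition (CBCT-anchored)
#'
#' @param bundle A `phantom_bundle` (or a list with the same structure).
#' @param method `"ground_truth"` — use the injected/ground-truth global
#'   pose (the voxel superimposition treated as a given); `"crown_icp"` —
#'   register the T2 dental-crown areas onto `reference_mesh` by ICP.
#' @param reference_mesh For `"crown_icp"`: a [trimesh] of the T2 anatomy
#'   already expressed in T1 space (defaults to the phantom's ground-truth
#'   reference surface).
#' @param ... Passed to [icp_region()].
#' @return List of class `route_result`: `mesh`, `landmarks` (T2 brought to
#'   T1 space), `transform`, and `icp` (for the crown route).
#' @export
run_reference <- function(bundle, method = c("ground_truth", "crown_icp"),
                          reference_mesh = NULL, ...) {
  method <- match.arg(method)
  if (method == "ground_truth") {
    g <- bundle$truth$global_transform
    if (is.null(g)) {
      stop("run_reference: no ground-truth/injected global transform ",
           "available; supply one or use method = 'crown_icp'",
           call. = FALSE)
    }
    tr <- invert_transform(g)
    fit <- NULL
  } else {
    g <- bundle$truth$global_transform
    if (is.null(reference_mesh)) {
      if (is.null(g)) {
        stop("run_reference: crown_icp needs a reference surface in T1 ",
             "space", call. = FALSE)
      }
      reference_mesh <- apply_transform(bundle$t2$mesh, invert_transform(g))
    }
    crowns <- bundle$t2$masks[vapply(bundle$t2$masks, function(m)
      m$kind == "crown", logical(1))]
    region <- sort(unique(unlist(lapply(crowns, `[[`, "faces"))))
    # seed from the alignment landmarks of the two surfaces
    ref_lms <- if (!is.null(g)) {
      apply_transform(bundle$t2$landmarks, invert_transform(g))
    } else {
      bundle$t1$landmarks
    }
    seed <- landmark_align(alignment_landmarks(bundle$t2$landmarks),
                           alignment_landmarks(ref_lms))
    fit <- icp_region(bundle$t2$mesh, reference_mesh, region = region,
                      init = seed$transform, ...)
    tr <- fit$transform
  }
  structure(list(mesh = apply_transform(bundle$t2$mesh, tr),
                 landmarks = apply_transform(bundle$t2$landmarks, tr),
                 transform = tr, icp = fit, route = "reference"),
            class = "route_result")
}

#' Palatal-vault-route superimposition (MDM)
#'
#' Superimposes T2 onto T1 using the palatal-vault stable region: coarse
#' landmark alignment on the suture/rugae alignment landmarks, then trimmed
#' point-to-surface ICP restricted to the `palatal_vault` mask.
#'
#' @param bundle A `phantom_bundle`-structured list.
#' @param mask_faces Optional face subset overriding the stored
#'   `palatal_vault` mask (used to emulate operator region selection).
#' @param ... Passed to [icp_region()].
#' @return A `route_result` (see [run_reference()]) with `icp` diagnostics.
#' @export
run_mdm <- function(bundle, mask_faces = NULL, ...) {
  mask <- bundle$t2$masks$palatal_vault
  if (is.null(mask)) {
    stop("run_mdm: no palatal_vault mask in the bundle", call. = FALSE)
  }
  region <- if (is.null(mask_faces)) mask$faces else mask_faces
  seed <- landmark_align(alignment_landmarks(bundle$t2$landmarks),
                         alignment_landmarks(bundle$t1$landmarks))
  fit <- icp_region(bundle$t2$mesh, bundle$t1$mesh, region = region,
                    init = seed$transform, ...)
  structure(list(mesh = apply_transform(bundle$t2$mesh, fit$transform),
                 landmarks = apply_transform(bundle$t2$landmarks,
                                             fit$transform),
                 transform = fit$transform, icp = fit, route = "mdm"),
            class = "route_result")
}

t1_measurement_context <- function(bundle, cusp_set = "all") {
  lms <- bundle$t1$landmarks
  fop <- fit_fop(fop_cusp_points(lms, cusp_set),
                 orient_toward = landmark_point(lms, "B"))
  frame <- build_frame(landmark_point(lms, "A"), landmark_point(lms, "B"),
                       fop)
  list(fop = fop, frame = frame)
}

add_landmark_noise <- function(lms, sd) {
  if (sd <= 0) return(lms)
  n <- nrow(lms)
  lms$x <- lms$x + stats::rnorm(n, 0, sd)
  lms$y <- lms$y + stats::rnorm(n, 0, sd)
  lms$z <- lms$z + stats::rnorm(n, 0, sd)
  lms
}

measure_route_pair <- function(bundle, ref, mdm, ctx, teeth,
                               landmark_noise_sd = 0,
                               registration = "icp",
                               swap_tip_torque = FALSE, ...) {
  crown_lms_ref <- ref$landmarks[!is.na(ref$landmarks$tooth) &
                                   ref$landmarks$tooth %in% teeth, ]
  m_ref <- measure_teeth(crown_lms_ref, ctx$frame, ctx$fop, teeth = teeth,
                         swap_tip_torque = swap_tip_torque)
  transferred <- list()
  diag_rows <- list()
  for (tt in teeth) {
    lms_t <- crown_lms_ref[crown_lms_ref$tooth == tt, ]
    if (registration == "icp") {
      res <- transfer_crown(ref$mesh, bundle$t2$masks[[paste0(tt, "_crown")]],
                            lms_t, mdm$mesh, ...)
      transferred[[tt]] <- res$landmarks
      diag_rows[[tt]] <- dplyr::mutate(glance(res$icp), tooth = tt,
                                       .before = 1)
    } else {
      # ground-truth registration: both routes coincide, transfer is exact
      transferred[[tt]] <- lms_t
    }
  }
  lms_test <- dplyr::bind_rows(transferred)
  lms_test <- add_landmark_noise(lms_test, landmark_noise_sd)
  m_test <- measure_teeth(lms_test, ctx$frame, ctx$fop, teeth = teeth,
                          swap_tip_torque = swap_tip_torque)
  list(m_ref = m_ref, m_test = m_test,
       deviations = signed_deviation(m_test, m_ref),
       transfer_diag = dplyr::bind_rows(diag_rows))
}

#' Run the full accuracy/reliability validation on a cohort
#'
#' For each subject: superimpose T2 by the reference route and by the
#' palatal-vault route, transfer each crown with its bonded landmarks from
#' the reference-superimposed model onto the palatal-vault-superimposed
#' model, measure tooth position (x, y, z) and tip/torque on both, and form
#' signed deviations (palatal-vault minus reference). Deviations are then
#' summarised into accuracy tables (mean, SD, one-sample t-test against
#' zero) and, when `reliability = TRUE`, repeated sessions yield intra- and
#' inter-examiner intraclass correlation coefficients per coordinate for
#' both superimposition methods.
#'
#' @param bundles List of `phantom_bundle` objects ([phantom_cohort()]), or
#'   a single bundle.
#' @param registration `"icp"` (full registration pipeline) or
#'   `"ground_truth"` (injected transforms; isolates the measurement and
#'   statistics chain, used for large simulation studies).
#' @param reference_method Passed to [run_reference()].
#' @param landmark_noise_sd SD (mm) of landmark-identification noise
#'   injected on the route under test.
#' @param reliability If `TRUE`, simulate repeat sessions (two examiners,
#'   one repeat) on the first `n_reliability` subjects and compute ICC
#'   tables.
#' @param n_reliability Number of subjects in the reliability subset.
#' @param session_landmark_sd Per-session landmark identification noise SD
#'   (mm; defaults to `landmark_noise_sd`).
#' @param session_mask_drop Fraction of stable-region faces dropped at
#'   random per session, emulating operator region selection in the
#'   palatal-vault method.
#' @param seed RNG seed for all injected noise.
#' @param cusp_set,swap_tip_torque Measurement options, see
#'   [fop_cusp_points()] and [measure_tooth()].
#' @param icc_model See [icc()].
#' @param ... Passed to [icp_region()].
#' @return An object of class `mdm_validation`: `deviations` (per subject x
#'   tooth), `tables` ([deviation_tables()]), `reliability` (ICC tibble or
#'   `NULL`), `diagnostics` (registration summaries), `config`.
#' @export
run_validation <- function(bundles,
                           registration = c("icp", "ground_truth"),
                           reference_method = "ground_truth",
                           landmark_noise_sd = 0,
                           reliability = FALSE,
                           n_reliability = NULL,
                           session_landmark_sd = landmark_noise_sd,
                           session_mask_drop = 0.1,
                           seed = 1L,
                           cusp_set = "all",
                           swap_tip_torque = FALSE,
                           icc_model = "ICC2_1", ...) {
  registration <- match.arg(registration)
  if (inherits(bundles, "phantom_bundle")) bundles <- list(bundles)
  teeth <- bundles[[1]]$spec$teeth$tooth %||% c("RU6", "LU6", "RU1", "LU1")

  withr::with_seed(seed, {
    per_subject <- purrr::imap(bundles, function(b, i) {
      ctx <- t1_measurement_context(b, cusp_set)
      ref <- run_subject_reference(b, registration, reference_method, ...)
      mdm <- run_subject_mdm(b, registration, NULL, ...)
      meas <- measure_route_pair(b, ref, mdm, ctx, teeth,
                                 landmark_noise_sd = landmark_noise_sd,
                                 registration = registration,
                                 swap_tip_torque = swap_tip_torque, ...)
      list(subject = i, ctx = ctx, ref = ref, mdm = mdm, meas = meas)
    })

    deviations <- purrr::map_dfr(per_subject, function(s) {
      dplyr::mutate(s$meas$deviations, subject = s$subject, .before = 1)
    })
    diagnostics <- purrr::map_dfr(per_subject, function(s) {
      rows <- list()
      if (!is.null(s$mdm$icp)) {
        rows$palate <- dplyr::mutate(glance(s$mdm$icp), stage = "palatal_vault",
                                     subject = s$subject, .before = 1)
      }
      if (nrow(s$meas$transfer_diag %||% tibble::tibble())) {
        rows$transfer <- dplyr::mutate(s$meas$transfer_diag,
                                       stage = "crown_transfer",
                                       subject = s$subject, .before = 1)
      }
      dplyr::bind_rows(rows)
    })

    rel <- NULL
    if (reliability) {
      n_rel <- min(n_reliability %||% min(10L, length(bundles)),
                   length(bundles))
      rel <- simulate_reliability(bundles[seq_len(n_rel)], per_subject,
                                  registration, session_landmark_sd,
                                  session_mask_drop, teeth, swap_tip_torque,
                                  icc_model, ...)
    }

    structure(list(
      deviations = deviations,
      tables = deviation_tables(deviations),
      reliability = rel,
      diagnostics = diagnostics,
      config = list(registration = registration,
                    reference_method = reference_method,
                    landmark_noise_sd = landmark_noise_sd,
                    session_landmark_sd = session_landmark_sd,
                    session_mask_drop = session_mask_drop,
                    n_subjects = length(bundles), seed = seed,
                    cusp_set = cusp_set, icc_model = icc_model,
                    swap_tip_torque = swap_tip_torque)),
      class = "mdm_validation")
  })
}

run_subject_reference <- function(b, registration, reference_method, ...) {
  if (registration == "ground_truth") {
    run_reference(b, method = "ground_truth")
  } else {
    run_reference(b, method = reference_method, ...)
  }
}

run_subject_mdm <- function(b, registration, mask_faces, ...) {
  if (registration == "ground_truth") {
    tr <- invert_transform(b$truth$global_transform)
    structure(list(mesh = apply_transform(b$t2$mesh, tr),
                   landmarks = apply_transform(b$t2$landmarks, tr),
                   transform = tr, icp = NULL, route = "mdm"),
              class = "route_result")
  } else {
    run_mdm(b, mask_faces = mask_faces, ...)
  }
}

# Repeat-session simulation: each (examiner, session) re-identifies the
# landmarks (iid noise) and, for the palatal-vault method, re-selects the
# stable region (random boundary subset) and re-runs the superimposition.
# The reference method's injected volumetric transform is deterministic, so
# its sessions differ by landmark identification only — the mechanism behind
# its near-perfect reliability.
simulate_reliability <- function(bundles, per_subject, registration,
                                 session_landmark_sd, session_mask_drop,
                                 teeth, swap_tip_torque, icc_model, ...) {
  sessions <- list()
  combos <- list(c(1L, 1L), c(1L, 2L), c(2L, 1L))
  for (i in seq_along(bundles)) {
    b <- bundles[[i]]
    ctx <- per_subject[[i]]$ctx
    ref <- per_subject[[i]]$ref
    mask <- b$t2$masks$palatal_vault$faces
    for (es in combos) {
      # palatal-vault route, re-registered with jittered region
      if (registration == "icp") {
        keep <- stats::runif(length(mask)) >= session_mask_drop
        if (sum(keep) < 50L) keep[] <- TRUE
        mdm_s <- run_subject_mdm(b, registration, mask[keep], ...)
      } else {
        mdm_s <- run_subject_mdm(b, registration, NULL, ...)
      }
      for (method in c("mdm", "reference")) {
        model_lms <- if (method == "mdm") mdm_s$landmarks else ref$landmarks
        crown <- model_lms[!is.na(model_lms$tooth) &
                             model_lms$tooth %in% teeth, ]
        crown <- add_landmark_noise(crown, session_landmark_sd)
        m <- measure_teeth(crown, ctx$frame, ctx$fop, teeth = teeth,
                           swap_tip_torque = swap_tip_torque)
        long <- tidyr::pivot_longer(m[, c("tooth", "x", "y", "z")],
                                    cols = c("x", "y", "z"),
                                    names_to = "coord")
        sessions[[length(sessions) + 1L]] <- tibble::tibble(
          subject = i, method = method,
          examiner = es[1], session = es[2],
          variable = table_variable(long$tooth, long$coord),
          value = long$value)
      }
    }
  }
  sessions <- dplyr::bind_rows(sessions)
  list(icc = icc_tables(sessions, model = icc_model), sessions = sessions)
}

#' @export
print.mdm_validation <- function(x, ...) {
  cat("<mdm_validation>", x$config$n_subjects, "subjects, registration:",
      x$config$registration, "\n\n")
  print(x$tables)
  if (!is.null(x$reliability)) {
    cat("\nReliability (ICC):\n")
    print(x$reliability$icc, n = Inf)
  }
  invisible(x)
}

#' @export
tidy.mdm_validation <- function(x, ...) x$deviations

#' @export
glance.mdm_validation <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$config$n_subjects,
    registration = x$config$registration,
    max_abs_mean_position = max(abs(x$tables$position$mean[
      !grepl("total$", x$tables$position$variable)])),
    max_abs_mean_orientation = max(abs(x$tables$orientation$mean)),
    min_icc = if (is.null(x$reliability)) NA_real_ else
      min(unlist(x$reliability$icc[, c("icc_intra", "icc_inter")]),
          na.rm = TRUE))
}
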