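fop0 <- plane3(c(0, 0, 0), c(0, 0, 1))

test_that("mesiodistal plane contains the points and their projections", {
  md <- mesiodistal_plane(c(0, 5, 2), c(10, 5, 2), fop0)
  expect_equal(abs(md$normal), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(plane_offset(rbind(c(0, 5, 2), c(10, 5, 2),
                                  c(0, 5, 0), c(10, 5, 0)), md),
               rep(0, 4), tolerance = 1e-12)
  # orientation-insensitive
  md2 <- mesiodistal_plane(c(10, 5, 2), c(0, 5, 2), fop0)
  expect_equal(abs(sum(md$normal * md2$normal)), 1, tolerance = 1e-12)
  expect_error(mesiodistal_plane(c(0, 0, 0), c(0, 0, 4), fop0),
               "perpendicular")
})

test_that("plane constructions satisfy their perpendicularity contracts", {
  withr::local_seed(13)
  for (i in 1:20) {
    fop <- plane3(stats::rnorm(3), stats::rnorm(3))
    b <- stats::rnorm(3, sd = 10); c3 <- stats::rnorm(3, sd = 10)
    md <- tryCatch(mesiodistal_plane(b, c3, fop), error = function(e) NULL)
    if (is.null(md)) next
    expect_lt(abs(sum(md$normal * fop$normal)), 1e-12)
    expect_lt(abs(sum(md$normal * (c3 - b)) / sqrt(sum((c3 - b)^2))), 1e-12)
    anchor <- stats::rnorm(3)
    bl <- buccolingual_plane(md, fop, anchor)
    expect_lt(abs(sum(bl$normal * md$normal)), 1e-12)
    expect_lt(abs(sum(bl$normal * fop$normal)), 1e-12)
    expect_equal(plane_offset(anchor, bl), 0, tolerance = 1e-12)
  }
  md <- mesiodistal_plane(c(0, 5, 0), c(10, 5, 0), fop0)
  bl <- buccolingual_plane(md, fop0, c(0, 0, 0))
  expect_equal(abs(bl$normal), c(1, 0, 0), tolerance = 1e-12)
})

test_that("tooth_axis is the unit gingival-to-occlusal direction", {
  expect_equal(tooth_axis(c(0, 0, 1), c(0, 0, 0)), c(0, 0, 1))
  expect_equal(tooth_axis(c(0, 0, 0), c(0, 0, 1)), c(0, 0, -1))
  withr::local_seed(2)
  for (i in 1:10) {
    a <- stats::rnorm(3); b <- stats::rnorm(3)
    expect_equal(sqrt(sum(tooth_axis(a, b)^2)), 1, tolerance = 1e-12)
  }
  expect_error(tooth_axis(c(1, 1, 1), c(1, 1, 1)), "coincident")
})

test_that("upright and in-plane tilted axes give the expected angles", {
  md <- mesiodistal_plane(c(0, 5, 0), c(10, 5, 0), fop0)
  bl <- buccolingual_plane(md, fop0, c(5, 5, 0))
  # axis along the FOP normal: upright tooth, both angles zero
  expect_equal(torque_angle(c(0, 0, 1), md, fop0), 0, tolerance = 1e-12)
  expect_equal(tip_angle(c(0, 0, 1), bl, fop0), 0, tolerance = 1e-12)
  # 10 deg tilt purely within the mesiodistal plane is preserved
  ax <- c(sin(10 * pi / 180), 0, cos(10 * pi / 180))
  expect_equal(torque_angle(ax, md, fop0, positive_hints = c(1, 0, 0)), 10,
               tolerance = 1e-10)
  # 7 deg tilt purely within the buccolingual plane
  ax <- c(0, sin(7 * pi / 180), cos(7 * pi / 180))
  expect_equal(tip_angle(ax, bl, fop0, positive_hints = c(0, 1, 0)), 7,
               tolerance = 1e-10)
  # axis treated as a line: reversing the axis leaves the angle unchanged
  expect_equal(torque_angle(-ax, md, fop0), torque_angle(ax, md, fop0),
               tolerance = 1e-12)
})

test_that("torque/tip match the brute-force vector-algebra oracle", {
  withr::local_seed(17)
  n_checked <- 0
  while (n_checked < 100) {
    n <- stats::rnorm(3); n <- n / sqrt(sum(n^2))
    v <- stats::rnorm(3)
    m <- v - sum(v * n) * n
    if (sqrt(sum(m^2)) < 1e-3) next
    m <- m / sqrt(sum(m^2))         # plane normal orthogonal to FOP normal
    axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
    if (abs(sum(axis * m)) > 0.99) next
    hint <- stats::rnorm(3)
    tdir <- cross3_test(m, n)
    if (abs(sum(tdir * hint)) < 1e-3) next
    tdir <- tdir * sign(sum(tdir * hint))
    fop <- plane3(c(0, 0, 0), n)
    got <- torque_angle(axis, plane3(stats::rnorm(3), m), fop,
                        positive_hints = hint)
    expect_equal(got, oracle_projected_angle(axis, m, n, tdir),
                 tolerance = 1e-9)
    n_checked <- n_checked + 1
  }
})

test_that("torque and tip decompose the total inclination orthogonally", {
  md <- mesiodistal_plane(c(0, 5, 0), c(10, 5, 0), fop0)
  bl <- buccolingual_plane(md, fop0, c(5, 5, 0))
  withr::local_seed(23)
  for (i in 1:10) {
    ax <- unit_test(c(stats::rnorm(2, sd = 0.2), 1))
    tq <- torque_angle(ax, md, fop0, positive_hints = c(1, 0, 0))
    tp <- tip_angle(ax, bl, fop0, positive_hints = c(0, 1, 0))
    total <- acos(abs(sum(ax * c(0, 0, 1)))) * 180 / pi
    expect_equal(tan(tq * pi / 180)^2 + tan(tp * pi / 180)^2,
                 tan(total * pi / 180)^2, tolerance = 1e-9)
  }
})

test_that("measure_tooth reproduces the phantom's analytic ground truth", {
  b <- phantom_default_small()
  ctx <- list(
    fop = fit_fop(fop_cusp_points(b$t1$landmarks),
                  orient_toward = landmark_point_test(b$t1$landmarks, "B")),
    frame = NULL)
  ctx$frame <- build_frame(landmark_point_test(b$t1$landmarks, "A"),
                           landmark_point_test(b$t1$landmarks, "B"),
                           ctx$fop)
  m <- measure_teeth(b$t1$landmarks, ctx$frame, ctx$fop)
  truth <- b$truth$measurements_t1
  expect_equal(as.matrix(m[, c("x", "y", "z")]),
               as.matrix(truth[, c("x", "y", "z")]),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(as.matrix(m[, c("tip", "torque")]),
               as.matrix(truth[, c("tip", "torque")]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("measurements are invariant under rigid motion of the model", {
  b <- phantom_default_small()
  lms <- b$t1$landmarks
  fop <- fit_fop(fop_cusp_points(lms),
                 orient_toward = landmark_point_test(lms, "B"))
  frame <- build_frame(landmark_point_test(lms, "A"),
                       landmark_point_test(lms, "B"), fop)
  m0 <- measure_teeth(lms, frame, fop)
  withr::local_seed(31)
  tr <- random_rigid()
  lms2 <- apply_transform(lms, tr)
  fop2 <- fit_fop(fop_cusp_points(lms2),
                  orient_toward = landmark_point_test(lms2, "B"))
  frame2 <- build_frame(landmark_point_test(lms2, "A"),
                        landmark_point_test(lms2, "B"), fop2)
  m1 <- measure_teeth(lms2, frame2, fop2)
  expect_equal(as.data.frame(m1), as.data.frame(m0), tolerance = 1e-9)
})

test_that("swapping mesial/distal labels preserves torque magnitude", {
  b <- phantom_default_small()
  lms <- b$t1$landmarks
  fop <- fit_fop(fop_cusp_points(lms),
                 orient_toward = landmark_point_test(lms, "B"))
  frame <- build_frame(landmark_point_test(lms, "A"),
                       landmark_point_test(lms, "B"), fop)
  m0 <- measure_tooth(lms, "RU6", frame, fop)
  swapped <- lms
  i_b <- which(swapped$id == "B" & swapped$tooth %in% "RU6")
  i_c <- which(swapped$id == "C" & swapped$tooth %in% "RU6")
  swapped[c(i_b, i_c), c("x", "y", "z")] <- swapped[c(i_c, i_b), c("x", "y", "z")]
  m1 <- measure_tooth(swapped, "RU6", frame, fop)
  # the mesiodistal plane is orientation-insensitive, so the angle (sign
  # fixed by the frame hint, not the labels) is unchanged
  expect_equal(m1$torque, m0$torque, tolerance = 1e-9)
  expect_equal(m1$tip, m0$tip, tolerance = 1e-9)
})

test_that("crown transfer is exact for identical and rigidly moved targets", {
  b <- phantom_null_small()
  lms_ru6 <- b$t1$landmarks[b$t1$landmarks$tooth %in% "RU6", ]

  # self-transfer: landmarks unchanged
  res <- transfer_crown(b$t1$mesh, b$t1$masks$RU6_crown, lms_ru6, b$t1$mesh)
  expect_lt(max(abs(as.matrix(res$landmarks[, c("x", "y", "z")]) -
                      as.matrix(lms_ru6[, c("x", "y", "z")]))), 1e-9)

  # known rigid displacement of the target model
  tr <- rigid_transform(rotation_about_axis(c(0.3, 1, 0.2), 4), c(1, -2, 1.5))
  moved <- apply_transform(b$t1$mesh, tr)
  res <- transfer_crown(b$t1$mesh, b$t1$masks$RU6_crown, lms_ru6, moved,
                        init = tr)
  expect_lt(max(abs(as.matrix(res$landmarks[, c("x", "y", "z")]) -
                      transform_points(as.matrix(lms_ru6[, c("x", "y", "z")]),
                                       tr))), 0.01)
})
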