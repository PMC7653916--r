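test_that("fit_fop reproduces exact and symmetric planes", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(2, 3, 0))
  fop <- fit_fop(pts)
  expect_equal(abs(fop$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_lt(attr(fop, "rms"), 1e-12)

  # symmetric +/-h perturbation pairs (same footpoint) leave the plane at
  # z = 0
  base <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(4, 4, 0),
                c(2, 1, 0), c(1, 2, 0))
  h <- c(0.3, 0.1, 0.2, 0.15, 0.25, 0.05)
  pert <- rbind(base + cbind(0, 0, h), base - cbind(0, 0, h))
  fop <- fit_fop(pert)
  expect_equal(abs(fop$normal), c(0, 0, 1), tolerance = 1e-9)

  expect_error(fit_fop(cbind(1:5, 1:5, 1:5)), "collinear")
})

test_that("fit_fop equals the covariance-eigenvector oracle", {
  withr::local_seed(3)
  for (i in 1:15) {
    pts <- cbind(stats::runif(14, -20, 20), stats::runif(14, -20, 20),
                 stats::rnorm(14, sd = 0.3))
    tr <- random_rigid()
    pts <- transform_points(pts, tr)
    fop <- fit_fop(pts)
    oracle <- pca_plane(pts)
    expect_equal(abs(sum(fop$normal * oracle$normal)), 1, tolerance = 1e-9)
    expect_equal(attr(fop, "rms"), oracle$rms, tolerance = 1e-9)
  }
})

test_that("fit_fop residual is invariant under rigid motion", {
  withr::local_seed(11)
  pts <- cbind(stats::runif(14, -20, 20), stats::runif(14, -20, 20),
               stats::rnorm(14, sd = 0.3))
  r0 <- attr(fit_fop(pts), "rms")
  for (i in 1:5) {
    r1 <- attr(fit_fop(transform_points(pts, random_rigid())), "rms")
    expect_equal(r1, r0, tolerance = 1e-9)
  }
})

test_that("fit_fop orients the normal towards the reference point", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  up <- fit_fop(pts, orient_toward = c(0, 0, 5))
  expect_equal(up$normal, c(0, 0, 1), tolerance = 1e-12)
  down <- fit_fop(pts, orient_toward = c(0, 0, -5))
  expect_equal(down$normal, c(0, 0, -1), tolerance = 1e-12)
})

test_that("project_point is an idempotent orthogonal projection", {
  pl <- plane3(c(0, 0, 0), c(0, 0, 1))
  expect_equal(project_point(c(3, 2, 0), pl), c(3, 2, 0))
  expect_equal(project_point(c(0, 0, 5), pl), c(0, 0, 0))
  withr::local_seed(5)
  for (i in 1:10) {
    pl <- plane3(stats::rnorm(3), stats::rnorm(3))
    p <- stats::rnorm(3, sd = 10)
    pr <- project_point(p, pl)
    expect_equal(project_point(pr, pl), pr, tolerance = 1e-12)
    # residual is parallel to the normal and has the analytic length
    expect_equal(abs(sum((p - pr) * pl$normal)), sqrt(sum((p - pr)^2)),
                 tolerance = 1e-12)
    expect_equal(sqrt(sum((p - pr)^2)), abs(sum((p - pl$point) * pl$normal)),
                 tolerance = 1e-12)
  }
})

test_that("build_frame produces the documented axis-aligned construction", {
  fop <- plane3(c(0, 0, 0), c(0, 0, 1))
  f <- build_frame(A = c(10, 0, 5), B = c(0, 0, 5), fop)
  expect_equal(f$origin, c(0, 0, 0))
  expect_equal(f$x_axis, c(1, 0, 0))
  expect_equal(f$y_axis, c(0, 0, 1))
  expect_equal(f$z_axis, c(0, -1, 0))

  # antisymmetry: reversing A flips x and z, keeps y
  f2 <- build_frame(A = c(-10, 0, 5), B = c(0, 0, 5), fop)
  expect_equal(f2$x_axis, -f$x_axis)
  expect_equal(f2$z_axis, -f$z_axis)
  expect_equal(f2$y_axis, f$y_axis)

  expect_error(build_frame(c(0, 0, 9), c(0, 0, 5), fop), "coincide")
})

test_that("frames are orthonormal and invert cleanly for random inputs", {
  withr::local_seed(9)
  for (i in 1:15) {
    fop <- plane3(stats::rnorm(3), stats::rnorm(3))
    A <- stats::rnorm(3, sd = 10); B <- stats::rnorm(3, sd = 10)
    f <- tryCatch(build_frame(A, B, fop), error = function(e) NULL)
    if (is.null(f)) next
    expect_lt(abs(sum(f$x_axis * f$y_axis)), 1e-12)
    expect_equal(sqrt(sum(f$z_axis^2)), 1, tolerance = 1e-12)
    expect_equal(f$z_axis, cross3_test(f$x_axis, f$y_axis), tolerance = 1e-12)
    p <- stats::rnorm(3, sd = 20)
    expect_equal(from_frame(to_frame(p, f), f), p, tolerance = 1e-10)
    expect_equal(to_frame(f$origin, f), c(0, 0, 0), tolerance = 1e-10)
    expect_equal(to_frame(f$origin + f$x_axis, f), c(1, 0, 0),
                 tolerance = 1e-10)
  }
})

test_that("frame construction commutes with rigid motion (equivariance)", {
  withr::local_seed(21)
  fop <- plane3(c(1, 2, 0.5), c(0.1, -0.2, 1))
  A <- c(25, 1, 6); B <- c(5, -1, 7)
  f <- build_frame(A, B, fop)
  for (i in 1:5) {
    tr <- random_rigid()
    f_moved <- build_frame(transform_points(A, tr), transform_points(B, tr),
                           apply_transform(fop, tr))
    f_expected <- apply_transform(f, tr)
    expect_equal(f_moved$origin, f_expected$origin, tolerance = 1e-9)
    for (ax in c("x_axis", "y_axis", "z_axis")) {
      expect_equal(f_moved[[ax]], f_expected[[ax]], tolerance = 1e-9)
    }
    # measured coordinates are therefore pose-independent
    p <- c(12, 3, 4)
    expect_equal(to_frame(transform_points(p, tr), f_moved),
                 to_frame(p, f), tolerance = 1e-9)
  }
})

test_that("fop_cusp_points selects the documented cusp sets", {
  lms <- phantom_default_small()$t1$landmarks
  expect_equal(nrow(fop_cusp_points(lms, "all")), 14L)
  expect_equal(nrow(fop_cusp_points(lms, "buccal")), 8L)
})
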