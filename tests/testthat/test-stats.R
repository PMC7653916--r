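measurement_row <- function(tooth, x, y, z, tip, torque) {
  tibble::tibble(tooth = tooth, x = x, y = y, z = z, tip = tip,
                 torque = torque)
}

test_that("signed_deviation subtracts the reference route componentwise", {
  m2 <- measurement_row("RU6", 10, 2, 24, 4, -6)
  m2p <- measurement_row("RU6", 9.88, 2, 24, 4, -6)
  d <- signed_deviation(m2p, m2)
  expect_equal(d$dx, -0.12)          # T2' smaller than T2 gives negative sign
  expect_equal(d$total, 0.12)

  d0 <- signed_deviation(m2, m2)
  expect_true(all(unlist(d0[, c("dx", "dy", "dz", "total", "dtip",
                                "dtorque")]) == 0))

  m2p <- measurement_row("RU6", 13, 6, 24, 4, -6)
  expect_equal(signed_deviation(m2p, m2)$total, 5)  # 3-4-5 triangle

  expect_error(signed_deviation(measurement_row("LU6", 1, 1, 1, 0, 0), m2),
               "tooth sets")
})

test_that("deviation totals dominate every component", {
  withr::local_seed(4)
  for (i in 1:20) {
    m2 <- measurement_row("RU1", stats::rnorm(1), stats::rnorm(1),
                          stats::rnorm(1), 0, 0)
    m2p <- measurement_row("RU1", stats::rnorm(1), stats::rnorm(1),
                           stats::rnorm(1), 0, 0)
    d <- signed_deviation(m2p, m2)
    expect_gte(d$total, max(abs(c(d$dx, d$dy, d$dz))) - 1e-12)
    expect_identical(d$total == 0, all(c(d$dx, d$dy, d$dz) == 0))
  }
})

test_that("one_sample_t matches the analytic t distribution", {
  # symmetric values: mean zero, p exactly 1
  res <- one_sample_t(c(-1, 1, -2, 2))
  expect_equal(res$mean, 0)
  expect_equal(res$p_value, 1)

  # hand-computed three-point example
  v <- c(1, 2, 4)
  res <- one_sample_t(v)
  m <- (1 + 2 + 4) / 3
  s <- sqrt(((1 - m)^2 + (2 - m)^2 + (4 - m)^2) / 2)
  t_hand <- m / (s / sqrt(3))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * stats::pt(-abs(t_hand), df = 2),
               tolerance = 1e-12)

  expect_error(one_sample_t(rep(1, 5)), "constant")
  expect_error(one_sample_t(3), "n >= 2")
})

test_that("one_sample_t p-values are invariant under sign flip", {
  withr::local_seed(8)
  for (i in 1:10) {
    v <- stats::rnorm(15, mean = 0.3)
    expect_equal(one_sample_t(v)$p_value, one_sample_t(-v)$p_value,
                 tolerance = 1e-12)
  }
})

test_that("t-CDF oracle agreement holds on random samples", {
  withr::local_seed(12)
  for (i in 1:20) {
    v <- stats::rnorm(sample(5:40, 1), mean = stats::runif(1, -0.5, 0.5),
                      sd = stats::runif(1, 0.2, 2))
    res <- one_sample_t(v)
    t_hand <- mean(v) / (stats::sd(v) / sqrt(length(v)))
    expect_equal(res$t, t_hand, tolerance = 1e-9)
    expect_equal(res$p_value,
                 2 * stats::pt(-abs(t_hand), df = length(v) - 1),
                 tolerance = 1e-9)
  }
})

test_that("icc is exact in the degenerate limits", {
  m <- cbind(1:10, 1:10)
  expect_equal(icc(m), 1)
  expect_equal(icc(m, model = "ICC3_1"), 1)

  # rater-independent noise much larger than the subject spread
  withr::local_seed(19)
  subj <- stats::rnorm(400, sd = 0.01)
  m <- cbind(subj + stats::rnorm(400, sd = 5), subj + stats::rnorm(400, sd = 5))
  expect_lt(abs(icc(m)), 0.15)

  expect_warning(icc(cbind(rep(1, 5), rep(1, 5))), "degenerate")
  expect_error(icc(cbind(1:5)), ">= 2")
})

test_that("icc matches the aov mean-squares oracle on random matrices", {
  withr::local_seed(29)
  for (i in 1:50) {
    m <- matrix(stats::rnorm(20, sd = stats::runif(1, 0.5, 3)), 10, 2)
    expect_equal(icc(m, "ICC2_1"), aov_icc(m, "ICC2_1"), tolerance = 1e-9)
    expect_equal(icc(m, "ICC3_1"), aov_icc(m, "ICC3_1"), tolerance = 1e-9)
  }
})

test_that("adding rater noise decreases the expected ICC", {
  withr::local_seed(37)
  subj <- stats::rnorm(60, sd = 1)
  icc_clean <- mean(replicate(20, {
    icc(cbind(subj + stats::rnorm(60, sd = 0.1),
              subj + stats::rnorm(60, sd = 0.1)))
  }))
  icc_noisy <- mean(replicate(20, {
    icc(cbind(subj + stats::rnorm(60, sd = 0.8),
              subj + stats::rnorm(60, sd = 0.8)))
  }))
  expect_gt(icc_clean, icc_noisy)
  expect_gt(icc_clean, 0.95)
})

test_that("deviation tables use the published row vocabulary", {
  withr::local_seed(41)
  devs <- tidyr::crossing(subject = 1:6,
                          tooth = c("RU6", "LU6", "RU1", "LU1"))
  n <- nrow(devs)
  devs$dx <- stats::rnorm(n, sd = 0.3)
  devs$dy <- stats::rnorm(n, sd = 0.3)
  devs$dz <- stats::rnorm(n, sd = 0.3)
  devs$total <- sqrt(devs$dx^2 + devs$dy^2 + devs$dz^2)
  devs$dtip <- stats::rnorm(n, sd = 0.5)
  devs$dtorque <- stats::rnorm(n, sd = 0.5)
  tabs <- deviation_tables(devs)
  expect_equal(tabs$position$variable,
               as.vector(t(outer(c("RU6", "LU6", "RU1", "LU1"),
                                 c("x", "y", "z", "total"), paste,
                                 sep = "-"))))
  expect_equal(nrow(tabs$position), 16L)
  expect_equal(tabs$orientation$variable,
               as.vector(t(outer(c("RU6", "LU6", "RU1", "LU1"),
                                 c("tip", "torque"), paste, sep = "-"))))
  expect_equal(nrow(tabs$orientation), 8L)
  # summaries recover the sample statistics
  ru6x <- devs$dx[devs$tooth == "RU6"]
  row <- tabs$position[tabs$position$variable == "RU6-x", ]
  expect_equal(row$mean, mean(ru6x))
  expect_equal(row$sd, stats::sd(ru6x))
  expect_equal(row$p_value, one_sample_t(ru6x)$p_value)
})

test_that("icc_tables pairs sessions into intra and inter coefficients", {
  withr::local_seed(43)
  subjects <- 1:8
  truth <- stats::rnorm(8, sd = 2)
  sess <- tidyr::crossing(subject = subjects,
                          examiner = 1:2, session = 1:2)
  sess <- sess[!(sess$examiner == 2 & sess$session == 2), ]
  sess$method <- "mdm"
  sess$variable <- "RU6-x"
  sess$value <- truth[sess$subject] + stats::rnorm(nrow(sess), sd = 0.1)
  tab <- icc_tables(sess)
  expect_equal(nrow(tab), 1L)
  a <- sess$value[sess$examiner == 1 & sess$session == 1]
  b <- sess$value[sess$examiner == 1 & sess$session == 2]
  expect_equal(tab$icc_intra, icc(cbind(a, b)))
  c2 <- sess$value[sess$examiner == 2 & sess$session == 1]
  expect_equal(tab$icc_inter, icc(cbind(a, c2)))
})
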