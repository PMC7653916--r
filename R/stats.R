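#' Signed deviations between two measurement sets
#'
#' Componentwise difference of the palatal-vault-route measurements minus the
#' reference-route measurements for the same teeth (deviation = T2' - T2),
#' plus the absolute (Euclidean) positional deviation `total`.
#'
#' @param m_test Measurement tibble from the route under test (T2', see
#'   [measure_teeth()]).
#' @param m_ref Measurement tibble from the reference route (T2).
#' @return Tibble: `tooth`, `dx`, `dy`, `dz`, `total` (mm), `dtip`,
#'   `dtorque` (degrees).
#' @export
signed_deviation <- function(m_test, m_ref) {
  if (!setequal(m_test$tooth, m_ref$tooth) ||
      anyDuplicated(m_test$tooth) || anyDuplicated(m_ref$tooth)) {
    stop("signed_deviation: tooth sets do not match one-to-one",
         call. = FALSE)
  }
  m_ref <- m_ref[match(m_test$tooth, m_ref$tooth), ]
  tibble::tibble(
    tooth = m_test$tooth,
    dx = m_test$x - m_ref$x,
    dy = m_test$y - m_ref$y,
    dz = m_test$z - m_ref$z,
    total = sqrt((m_test$x - m_ref$x)^2 + (m_test$y - m_ref$y)^2 +
                   (m_test$z - m_ref$z)^2),
    dtip = m_test$tip - m_ref$tip,
    dtorque = m_test$torque - m_ref$torque)
}

#' One-sample t-test of deviations against zero
#'
#' Two-sided one-sample t-test of the mean against `mu0` (default 0):
#' `t = mean / (sd / sqrt(n))` with `n - 1` degrees of freedom. The
#' conventional direction is used — deviations are "accurate" when the mean
#' is NOT significantly different from zero at `alpha = 0.05`.
#'
#' @param values Numeric vector, `n >= 2`.
#' @param mu0 Null mean (default 0).
#' @return One-row tibble: `n`, `mean`, `sd`, `t`, `df`, `p_value`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("one_sample_t: need n >= 2", call. = FALSE)
  if (stats::sd(values) == 0) {
    stop("one_sample_t: constant input - t statistic undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(values, mu = mu0)
  tibble::tibble(n = n, mean = mean(values), sd = stats::sd(values),
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' Intraclass correlation coefficient
#'
#' Single-measurement ICC from the two-way crossed layout (subjects x
#' raters/sessions, no missing cells), computed from the ANOVA mean squares.
#' The default `"ICC2_1"` is the two-way random-effects, absolute-agreement,
#' single-measurement coefficient; `"ICC3_1"` is the two-way mixed,
#' consistency coefficient.
#'
#' Degenerate layouts are handled explicitly: with zero residual and zero
#' rater variance the raters agree perfectly and the ICC is exactly 1; with
#' zero between-subject variance the coefficient is not meaningful and a
#' warning is raised.
#'
#' @param ratings n x k numeric matrix (n subjects, k raters), no missing
#'   values.
#' @param model `"ICC2_1"` (default) or `"ICC3_1"`.
#' @return ICC value (scalar, `<= 1`).
#' @export
icc <- function(ratings, model = c("ICC2_1", "ICC3_1")) {
  model <- match.arg(model)
  m <- as.matrix(ratings)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("icc: need >= 2 subjects and >= 2 raters",
                             call. = FALSE)
  if (anyNA(m)) stop("icc: missing cells are not supported", call. = FALSE)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_row <- k * sum((row_m - grand)^2)
  ss_col <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_row - ss_col
  msr <- ss_row / (n - 1)
  msc <- ss_col / (k - 1)
  mse <- max(ss_err / ((n - 1) * (k - 1)), 0)
  if (msr <= .Machine$double.eps * max(1, grand^2)) {
    warning("icc: zero between-subject variance - coefficient degenerate")
  }
  if (mse == 0 && msc == 0) return(if (msr > 0) 1 else NA_real_)
  if (model == "ICC2_1") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

table_variable <- function(tooth, what) paste0(tooth, "-", what)

#' Accuracy tables of signed deviations
#'
#' Summarises per-subject deviation records into the two accuracy tables:
#' positional deviations (per tooth: x, y, z and the absolute deviation
#' `total`; 16 rows for the four measured teeth) and orientation deviations
#' (tip and torque; 8 rows), each with mean, SD and the one-sample t-test
#' p-value against zero. No multiple-testing correction is applied. For the
#' `total` rows — non-negative by construction — the t-test against zero is
#' reported as-is; in the error-free limit all rows are zero and the p-value
#' is undefined (`NA`).
#'
#' @param deviations Tibble of per-subject deviation records
#'   ([signed_deviation()] rows with a `subject` column).
#' @return List of class `deviation_tables`: `position` (variable, mean, sd,
#'   p_value), `orientation` (same columns).
#' @export
deviation_tables <- function(deviations) {
  stopifnot(all(c("subject", "tooth") %in% names(deviations)))
  teeth <- c("RU6", "LU6", "RU1", "LU1")
  teeth <- teeth[teeth %in% deviations$tooth]
  summarise_var <- function(tooth, col) {
    v <- deviations[[col]][deviations$tooth == tooth]
    res <- tryCatch(one_sample_t(v), error = function(e) NULL)
    tibble::tibble(
      variable = table_variable(tooth, sub("^d", "", col)),
      mean = mean(v), sd = stats::sd(v),
      p_value = if (is.null(res)) NA_real_ else res$p_value)
  }
  position <- purrr::map_dfr(teeth, function(tt) {
    purrr::map_dfr(c("dx", "dy", "dz", "total"), summarise_var, tooth = tt)
  })
  orientation <- purrr::map_dfr(teeth, function(tt) {
    purrr::map_dfr(c("dtip", "dtorque"), summarise_var, tooth = tt)
  })
  structure(list(position = position, orientation = orientation),
            class = "deviation_tables")
}

#' @export
print.deviation_tables <- function(x, ...) {
  cat("Signed deviation in tooth position (T2' - T2):\n")
  print(x$position, n = Inf)
  cat("\nSigned deviation in tooth orientation (T2' - T2):\n")
  print(x$orientation, n = Inf)
  invisible(x)
}

#' Reliability (ICC) table from repeated sessions
#'
#' Builds the reliability table: for each tooth-coordinate variable, the
#' intra-examiner ICC (examiner 1, session 1 vs session 2) and the
#' inter-examiner ICC (examiner 1 vs examiner 2, first sessions), per
#' superimposition method.
#'
#' @param sessions Tibble with columns `subject`, `method`, `examiner`
#'   (1 or 2), `session` (1 or 2), `variable`, `value`.
#' @param model ICC model, see [icc()].
#' @return Tibble: `method`, `variable`, `icc_intra`, `icc_inter`.
#' @export
icc_tables <- function(sessions, model = "ICC2_1") {
  stopifnot(all(c("subject", "method", "examiner", "session", "variable",
                  "value") %in% names(sessions)))
  pair_icc <- function(df, e1, s1, e2, s2) {
    a <- df[df$examiner == e1 & df$session == s1, c("subject", "value")]
    b <- df[df$examiner == e2 & df$session == s2, c("subject", "value")]
    common <- intersect(a$subject, b$subject)
    if (length(common) < 2L) return(NA_real_)
    icc(cbind(a$value[match(common, a$subject)],
              b$value[match(common, b$subject)]), model = model)
  }
  combos <- dplyr::distinct(sessions[, c("method", "variable")])
  purrr::pmap_dfr(combos, function(method, variable) {
    df <- sessions[sessions$method == method & sessions$variable == variable, ]
    tibble::tibble(
      method = method, variable = variable,
      icc_intra = pair_icc(df, 1L, 1L, 1L, 2L),
      icc_inter = pair_icc(df, 1L, 1L, 2L, 1L))
  })
}
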