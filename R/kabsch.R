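#' Least-squares rigid fit between paired point sets (Kabsch/SVD)
#'
#' Finds the proper rotation and translation minimising
#' `sum_i || R p_i + t - q_i ||^2` (no scaling — dental models are 1:1 with
#' the anatomy). Used internally by ICP each iteration and exposed through
#' [landmark_align()].
#'
#' @param src,dst n x 3 matrices of paired points (rows correspond).
#' @param weights Optional non-negative weights.
#' @return A `rigid_transform`; attribute `rms` holds the residual RMS (mm).
#' @export
kabsch_fit <- function(src, dst, weights = NULL) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(nrow(src) == nrow(dst), ncol(src) == 3L, ncol(dst) == 3L)
  n <- nrow(src)
  if (n < 3L) stop("kabsch_fit: need at least 3 point pairs", call. = FALSE)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  w <- w / sum(w)
  cs <- colSums(src * w); cd <- colSums(dst * w)
  ps <- sweep(src, 2L, cs); pd <- sweep(dst, 2L, cd)
  h <- t(ps * w) %*% pd
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cd - as.numeric(r %*% cs)
  out <- rigid_transform(r, tr)
  res <- transform_points(src, out) - dst
  attr(out, "rms") <- sqrt(sum(w * rowSums(res^2)))
  out
}

#' Landmark-seeded coarse alignment
#'
#' Rigidly aligns matched landmark pairs by least squares, mirroring the
#' landmark pre-alignment step that seeds every surface superimposition (at
#' least three non-collinear landmarks chosen on both acquisitions). The fit
#' is exact when the two constellations are congruent.
#'
#' @param src Landmark tibble (or n x 3 matrix) on the moving model.
#' @param dst Landmark tibble (or n x 3 matrix) on the fixed model; when
#'   tibbles are given, pairs are matched by `(tooth, id)`.
#' @return A list of class `landmark_fit`: `transform` (a `rigid_transform`
#'   mapping src coordinates into dst space), `rms` residual (mm), `n` pairs.
#' @export
landmark_align <- function(src, dst) {
  if (is.data.frame(src) && is.data.frame(dst)) {
    ks <- paste(ifelse(is.na(src$tooth), "-", src$tooth), src$id)
    kd <- paste(ifelse(is.na(dst$tooth), "-", dst$tooth), dst$id)
    common <- intersect(ks, kd)
    p <- as.matrix(src[match(common, ks), c("x", "y", "z")])
    q <- as.matrix(dst[match(common, kd), c("x", "y", "z")])
  } else {
    p <- as.matrix(src); q <- as.matrix(dst)
  }
  if (nrow(p) < 3L) {
    stop("landmark_align: need >= 3 matched landmark pairs (got ", nrow(p),
         ")", call. = FALSE)
  }
  sv <- svd(sweep(p, 2L, colMeans(p)))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12)) {
    stop("landmark_align: landmarks are collinear - degenerate configuration",
         call. = FALSE)
  }
  fit <- kabsch_fit(p, q)
  structure(list(transform = fit, rms = attr(fit, "rms"), n = nrow(p)),
            class = "landmark_fit")
}

#' @export
print.landmark_fit <- function(x, ...) {
  cat("<landmark_fit>", x$n, "pairs, rms", format(x$rms, digits = 4), "mm\n")
  print(x$transform)
  invisible(x)
}
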