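# Independent oracles used to cross-check the package's geometry and
# statistics implementations. These deliberately use different algorithms
# from the package code paths (quaternion eigendecomposition instead of SVD,
# covariance eigenvectors instead of singular vectors, aov() instead of
# direct sums).

# Horn's closed-form absolute orientation: best rotation via the largest
# eigenvector of the 4x4 quaternion matrix.
horn_fit <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  p <- sweep(src, 2, cs); q <- sweep(dst, 2, cd)
  s <- t(p) %*% q
  k <- matrix(c(
    s[1,1]+s[2,2]+s[3,3], s[2,3]-s[3,2],        s[3,1]-s[1,3],        s[1,2]-s[2,1],
    s[2,3]-s[3,2],        s[1,1]-s[2,2]-s[3,3], s[1,2]+s[2,1],        s[3,1]+s[1,3],
    s[3,1]-s[1,3],        s[1,2]+s[2,1],        s[2,2]-s[1,1]-s[3,3], s[2,3]+s[3,2],
    s[1,2]-s[2,1],        s[3,1]+s[1,3],        s[2,3]+s[3,2],        s[3,3]-s[1,1]-s[2,2]),
    4, 4, byrow = TRUE)
  qv <- eigen(k, symmetric = TRUE)$vectors[, 1]
  w <- qv[1]; x <- qv[2]; y <- qv[3]; z <- qv[4]
  r <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
    2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  tr <- cd - as.numeric(r %*% cs)
  res <- sweep(src %*% t(r), 2, tr, "+") - dst
  list(rotation = r, translation = tr, rms = sqrt(mean(rowSums(res^2))))
}

# orthogonal-regression plane via the covariance eigendecomposition
pca_plane <- function(pts) {
  ctr <- colMeans(pts)
  ev <- eigen(stats::cov(pts), symmetric = TRUE)
  normal <- ev$vectors[, 3]
  list(point = ctr, normal = normal,
       rms = sqrt(mean((sweep(pts, 2, ctr) %*% normal)^2)))
}

# brute-force projected-axis angle: project onto the plane, canonicalise to
# the positive FOP-normal side, acos for magnitude, tangential component for
# the sign
oracle_projected_angle <- function(axis, plane_normal, fop_normal, tdir) {
  proj <- axis - sum(axis * plane_normal) * plane_normal
  u <- sum(proj * fop_normal)
  v <- sum(proj * tdir)
  if (u < 0) { u <- -u; v <- -v }
  mag <- acos(min(1, u / sqrt(u^2 + v^2))) * 180 / pi
  if (v < 0) -mag else mag
}

# two-way ANOVA mean squares via stats::aov
aov_icc <- function(m, model = "ICC2_1") {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  if (model == "ICC2_1") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

cross3_test <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit_test <- function(v) v / sqrt(sum(v^2))

landmark_point_test <- function(lms, id) {
  as.numeric(lms[lms$id == id & is.na(lms$tooth), c("x", "y", "z")])
}

random_rigid <- function(max_angle = 180, max_trans = 10) {
  ax <- stats::rnorm(3)
  rigid_transform(rotation_about_axis(ax, stats::runif(1, -max_angle, max_angle)),
                  stats::runif(3, -max_trans, max_trans))
}
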