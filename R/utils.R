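# internal geometry + misc helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalize zero vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# rotation about an arbitrary unit axis (Rodrigues), angle in degrees
rot_axis <- function(axis, angle) {
  u <- .unit(axis)
  a <- .deg2rad(angle)
  ca <- cos(a); sa <- sin(a)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ca + sa * K + (1 - ca) * (u %o% u)
}

rot_x <- function(angle) rot_axis(c(1, 0, 0), angle)
rot_y <- function(angle) rot_axis(c(0, 1, 0), angle)
rot_z <- function(angle) rot_axis(c(0, 0, 1), angle)

# signed angle (degrees) from v1 to v2 about unit axis
.signed_angle <- function(v1, v2, axis) {
  a <- .unit(v1 - sum(v1 * axis) * axis)
  b <- .unit(v2 - sum(v2 * axis) * axis)
  ang <- atan2(sum(.cross(a, b) * axis), sum(a * b))
  .rad2deg(ang)
}

# rotation matrix <-> quaternion (w, x, y, z)
.mat2quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q / .vnorm(q)
}

.quat2mat <- function(q) {
  q <- q / .vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# chordal-mean rotation average via quaternions (sign-aligned to the first)
.mean_rotation <- function(mats) {
  qs <- lapply(mats, .mat2quat)
  q0 <- qs[[1]]
  qs <- lapply(qs, function(q) if (sum(q * q0) < 0) -q else q)
  qm <- Reduce(`+`, qs) / length(qs)
  .quat2mat(qm)
}

# Kabsch: rotation R and translation t with  Q ~= R P + t  (P, Q: n x 3)
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(P - rep(cp, each = nrow(P))) %*% (Q - rep(cq, each = nrow(Q)))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- unname(s$v %*% diag(c(1, 1, d)) %*% t(s$u))
  t <- unname(cq - as.vector(R %*% cp))
  fitted <- t(R %*% t(P)) + rep(t, each = nrow(P))
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

# best-fit plane through points (n x 3): unit normal + rms distance
.fit_plane <- function(X) {
  ctr <- colMeans(X)
  s <- svd(sweep(X, 2, ctr))
  n <- s$v[, 3]
  list(normal = n, center = ctr, rmsd = sqrt(mean((sweep(X, 2, ctr) %*% n)^2)))
}

.pkg_env <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "tetrahelix")
  if (!nzchar(path)) stop("missing package data file: ", file)
  path
}
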