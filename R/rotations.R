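# Small rotation toolbox (3x3 matrices, scalar-first Hamilton quaternions).
# Kept internal; conventions are documented in ?imu_stream.

rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

# Rotation about the longitudinal (y) axis such that a positive angle carries
# the anterior (x) axis toward the lateral (z) axis:
# rot_long(a) %*% c(1,0,0) == c(cos a, 0, sin a).
rot_long <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, s, 0, 1, 0, -s, 0, c), 3, 3)
}

quat_multiply <- function(q, r) {
  # Hamilton product, scalar-first; both arguments N x 4 or length-4.
  q <- matrix(q, ncol = 4); r <- matrix(r, ncol = 4)
  if (nrow(q) == 1 && nrow(r) > 1) q <- q[rep(1, nrow(r)), , drop = FALSE]
  if (nrow(r) == 1 && nrow(q) > 1) r <- r[rep(1, nrow(q)), , drop = FALSE]
  cbind(q[, 1] * r[, 1] - q[, 2] * r[, 2] - q[, 3] * r[, 3] - q[, 4] * r[, 4],
        q[, 1] * r[, 2] + q[, 2] * r[, 1] + q[, 3] * r[, 4] - q[, 4] * r[, 3],
        q[, 1] * r[, 3] - q[, 2] * r[, 4] + q[, 3] * r[, 1] + q[, 4] * r[, 2],
        q[, 1] * r[, 4] + q[, 2] * r[, 3] - q[, 3] * r[, 2] + q[, 4] * r[, 1])
}

quat_from_matrix <- function(R) {
  # Shepperd's method for one 3x3 rotation matrix.
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
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
  q / sqrt(sum(q^2))
}

matrix_from_quat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}
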