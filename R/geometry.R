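#' @keywords internal
"_PACKAGE"

# 3-vector cross product
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v, what = "vector") {
  n <- vnorm(v)
  if (n < 1e-10) {
    stop("mskuq_degenerate_geometry: cannot normalize near-zero ", what,
         call. = FALSE)
  }
  v / n
}

# Rodrigues rotation about unit axis
rot_axis_angle <- function(axis, angle) {
  a <- axis / vnorm(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

skew3 <- function(a) {
  matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
}

# pose: list(R = 3x3 rotation, p = 3-vector origin), maps body coords to world
pose_apply <- function(pose, x) {
  if (is.matrix(x)) pose$R %*% x + pose$p else as.vector(pose$R %*% x) + pose$p
}

pose_invert_apply <- function(pose, x) {
  if (is.matrix(x)) t(pose$R) %*% (x - pose$p) else as.vector(t(pose$R) %*% (x - pose$p))
}

identity_pose <- function() list(R = diag(3), p = c(0, 0, 0))

is_orthonormal <- function(R, tol = 1e-9) {
  max(abs(t(R) %*% R - diag(3))) < tol && det(R) > 0
}

# Build a right-handed rotation matrix from a primary axis and an in-plane hint.
# primary_label/secondary_label in {"x","y","z"}; the remaining axis completes
# the right-handed triad. Gram-Schmidt on the hint.
frame_from_axes <- function(primary, primary_label, hint, hint_label) {
  e1 <- unitv(primary, "primary axis")
  h <- hint - sum(hint * e1) * e1
  e2 <- unitv(h, "secondary axis (collinear landmark configuration?)")
  axes <- list(x = NULL, y = NULL, z = NULL)
  axes[[primary_label]] <- e1
  axes[[hint_label]] <- e2
  missing_lab <- setdiff(c("x", "y", "z"), c(primary_label, hint_label))
  # fill the remaining axis so that x = y cross z (right-handed, columns x,y,z)
  ref <- list(x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  e3 <- cross3(axes[[primary_label]], axes[[hint_label]])
  # sign so that the triad (x,y,z) is right-handed
  sgn <- sum(cross3(ref[[primary_label]], ref[[hint_label]]) * ref[[missing_lab]])
  axes[[missing_lab]] <- sgn * e3
  R <- cbind(axes$x, axes$y, axes$z)
  colnames(R) <- NULL
  stopifnot(is_orthonormal(R, 1e-9))
  R
}
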