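# Shared numerical utilities: deterministic spherical direction sets,
# rotation matrices, rigid superposition, reporting-style rounding.

#' Deterministic quasi-uniform directions on the unit sphere
#'
#' Spherical Fibonacci point set; used for the enclosure rays and for the
#' rigid-body rotation axes of the docking search.
#'
#' @param n number of directions
#' @return n x 3 matrix of unit vectors
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# rotation matrix about unit axis by angle (radians), Rodrigues form
rotation_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# deterministic rigid rotation set: fibonacci axes x evenly spaced spins
rotation_set <- function(n_axes, n_spins) {
  axes <- fibonacci_sphere(n_axes)
  angles <- (seq_len(n_spins) - 1) * 2 * pi / n_spins
  out <- vector("list", n_axes * n_spins)
  k <- 1
  for (i in seq_len(n_axes)) {
    # align +z to axis, then spin about it
    align <- align_z_to(axes[i, ])
    for (a in angles) {
      out[[k]] <- align %*% rotation_about(c(0, 0, 1), a)
      k <- k + 1
    }
  }
  out
}

# rotation taking +z onto unit vector v
align_z_to <- function(v) {
  v <- v / sqrt(sum(v^2))
  z <- c(0, 0, 1)
  c_ <- sum(z * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  axis <- c(z[2] * v[3] - z[3] * v[2],
            z[3] * v[1] - z[1] * v[3],
            z[1] * v[2] - z[2] * v[1])
  rotation_about(axis, acos(c_))
}

# Kabsch superposition: rotation+translation taking mobile (n x 3) onto
# target (n x 3); returns function(coords) applying the fit.
superpose_fit <- function(mobile, target) {
  cm <- colMeans(mobile); ct <- colMeans(target)
  H <- t(sweep(mobile, 2, cm)) %*% sweep(target, 2, ct)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  function(coords) sweep(sweep(coords, 2, cm) %*% t(R), 2, ct, "+")
}

#' Round half away from zero
#'
#' Reporting convention for druggability scores (one decimal by default);
#' unlike [round()], exact halves move away from zero.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# torsion-angle rotation: rotate `coords` rows in `moved` about axis a->b
rotate_torsion <- function(coords, a, b, angle, moved) {
  axis <- b - a
  R <- rotation_about(axis, angle)
  coords[moved, ] <- sweep(sweep(coords[moved, , drop = FALSE], 2, b) %*% t(R), 2, b, "+")
  coords
}

# current dihedral angle (radians) for points p1-p2-p3-p4
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3], b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3], b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3], n1[1] * b2[2] - n1[2] * b2[1])
  b2n <- b2 / sqrt(sum(b2^2))
  atan2(sum(m1 / sqrt(sum(b2^2)) * n2), sum(n1 * n2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
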