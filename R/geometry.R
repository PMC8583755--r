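# Internal 3-D geometry kernel: vector helpers, torsion measurement,
# internal-coordinate (NeRF) atom placement and rigid-body superposition.
# All distances are in nm, all angles in degrees unless noted.

.DEG <- pi / 180

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("degenerate zero-length vector in geometry kernel", call. = FALSE)
  v / n
}

#' Signed torsion angle of four points
#'
#' Standard IUPAC signed dihedral: looking from `p2` towards `p3`, the angle is
#' positive when the far bond (`p3`-`p4`) is rotated clockwise relative to the
#' near bond (`p2`-`p1`). Returns degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (nm).
#' @return Torsion angle in degrees, or `NA` for colinear (degenerate) input.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (.vnorm(n1) < 1e-10 || .vnorm(n2) < 1e-10) return(NA_real_)
  m1 <- .cross3(n1, b2 / .vnorm(b2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) / .DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

# Vectorised torsion over frames: p* are 3 x n_frames matrices.
.dihedral_frames <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  cx <- function(a, b) rbind(a[2L, ] * b[3L, ] - a[3L, ] * b[2L, ],
                             a[3L, ] * b[1L, ] - a[1L, ] * b[3L, ],
                             a[1L, ] * b[2L, ] - a[2L, ] * b[1L, ])
  n1 <- cx(b1, b2)
  n2 <- cx(b2, b3)
  b2n <- sqrt(colSums(b2^2))
  m1 <- cx(n1, sweep(b2, 2L, b2n, "/"))
  ang <- -atan2(colSums(m1 * n2), colSums(n1 * n2)) / .DEG
  bad <- sqrt(colSums(n1^2)) < 1e-10 | sqrt(colSums(n2^2)) < 1e-10
  ang[bad] <- NA_real_
  ang[!is.na(ang) & ang <= -180] <- ang[!is.na(ang) & ang <= -180] + 360
  ang
}

# NeRF placement: position of atom D bonded to C, with bond length |CD|,
# bond angle B-C-D and torsion A-B-C-D (degrees). a, b, c are 3-vectors.
.place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * .DEG
  tor <- torsion * .DEG
  bc <- .unit(c - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  d <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d[1L] * bc + d[2L] * m + d[3L] * n
}

# Unit direction v from a centre with prescribed angles th1 to u1 and th2 to
# u2 (unit vectors); `chir` (+1/-1) selects which side of the (u1, u2) plane.
.solve_direction <- function(u1, u2, th1, th2, chir) {
  d <- sum(u1 * u2)
  ab <- solve(matrix(c(1, d, d, 1), 2L), c(cos(th1 * .DEG), cos(th2 * .DEG)))
  vpar <- ab[1L] * u1 + ab[2L] * u2
  rest <- 1 - sum(vpar * vpar)
  if (rest < 0) rest <- 0
  vpar + chir * sqrt(rest) * .unit(.cross3(u1, u2))
}

# Kabsch superposition: proper rotation R and translation t minimising
# || (x - cx) R + cy - y ||^2 for row-wise coordinate matrices x, y.
.kabsch <- function(x, y) {
  cx <- colMeans(x)
  cy <- colMeans(y)
  xc <- sweep(x, 2L, cx)
  yc <- sweep(y, 2L, cy)
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(rotation = r, center_x = cx, center_y = cy)
}

.apply_kabsch <- function(fit, x) {
  sweep(sweep(x, 2L, fit$center_x) %*% fit$rotation, 2L, fit$center_y, "+")
}

# Least-squares superposed RMSD between two row-wise coordinate matrices.
.fitted_rmsd <- function(x, y) {
  fit <- .kabsch(x, y)
  dx <- .apply_kabsch(fit, x) - y
  sqrt(mean(rowSums(dx^2)))
}
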