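# Rigid-body geometry primitives shared by the ligand, scaffold, matching and
# design machinery.  Angles are degrees throughout; distances are Angstrom.
# Coordinates are numeric length-3 vectors or n x 3 matrices with atom-name
# rownames.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("degenerate geometry: zero-length vector")
  v / n
}

crossp <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap an angle into [-180, 180)
#'
#' @param x Angle(s) in degrees.
#' @return Numeric vector of the same length with every value in
#'   `[-180, 180)`.
#' @export
wrap_angle <- function(x) ((x + 180) %% 360) - 180

#' Bond angle at a central atom
#'
#' @param a,b,c Cartesian coordinates (length-3 numeric). The angle is
#'   measured at `b`.
#' @return Angle in degrees in `[0, 180]`.
#' @export
bond_angle <- function(a, b, c) {
  u <- unitv(a - b)
  v <- unitv(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Dihedral (torsion) angle of four points
#'
#' IUPAC sign convention; the value is reported in `[-180, 180)`.
#'
#' @param p1,p2,p3,p4 Cartesian coordinates (length-3 numeric).
#' @return Torsion angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- crossp(b1, b2)
  n2 <- crossp(b2, b3)
  m1 <- crossp(n1, unitv(b2))
  wrap_angle(rad2deg(atan2(sum(m1 * n2), sum(n1 * n2))))
}

#' Place an atom from internal coordinates
#'
#' Natural-extension (NeRF) placement: returns the position `d` such that
#' `|d - c| = bond`, the angle b-c-d equals `angle` and the torsion
#' a-b-c-d equals `torsion`.
#'
#' @param a,b,c Reference coordinates (length-3 numeric).
#' @param bond Bond length in Angstrom.
#' @param angle Bond angle at `c` in degrees.
#' @param torsion Torsion a-b-c-d in degrees.
#' @return Length-3 numeric coordinate.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  bc <- unitv(c - b)
  n <- unitv(crossp(b - a, bc))
  m <- crossp(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), -bond * sin(ang) * sin(tor))
  c + d[1L] * bc + d[2L] * m + d[3L] * n
}

# Rodrigues rotation of the rows of xyz about the axis through `origin` with
# direction `axis`, by theta degrees (right-hand rule).
rotate_points <- function(xyz, origin, axis, theta) {
  k <- unitv(axis)
  th <- deg2rad(theta)
  ct <- cos(th)
  st <- sin(th)
  p <- sweep(xyz, 2L, origin)
  kx <- cbind(k[2L] * p[, 3L] - k[3L] * p[, 2L],
              k[3L] * p[, 1L] - k[1L] * p[, 3L],
              k[1L] * p[, 2L] - k[2L] * p[, 1L])
  kdp <- drop(p %*% k)
  rot <- p * ct + kx * st + outer(kdp * (1 - ct), k)
  sweep(rot, 2L, -origin)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rotation `R` and translation `t` minimising the RMSD between
#' `mobile %*% R + t` and `target` over matched rows.
#'
#' @param mobile,target Matched m x 3 coordinate matrices, m >= 3.
#' @return List with `R` (3 x 3 rotation), `t` (length-3 translation) and
#'   `rmsd` (Angstrom, over the matched rows after superposition).
#' @export
kabsch_fit <- function(mobile, target) {
  if (!is.matrix(mobile) || !is.matrix(target) ||
      nrow(mobile) != nrow(target) || ncol(mobile) != 3L || ncol(target) != 3L) {
    stop("mobile and target must be matched m x 3 matrices")
  }
  if (nrow(mobile) < 3L) {
    stop("underdetermined superposition: need at least 3 corresponding atoms")
  }
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  p <- sweep(mobile, 2L, cm)
  q <- sweep(target, 2L, ct)
  h <- crossprod(p, q)
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  r <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t_vec <- ct - drop(cm %*% r)
  moved <- sweep(p %*% r, 2L, ct, FUN = "+")
  list(R = r, t = t_vec, rmsd = sqrt(mean(rowSums((moved - target)^2))))
}

apply_transform <- function(xyz, R, t) sweep(xyz %*% R, 2L, t, FUN = "+")

# All pairwise distances between the rows of a (n x 3) and b (m x 3).
cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

rmsd_xyz <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# Run `expr` with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}
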