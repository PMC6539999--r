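# Simplified three-term score used by the design stage: a soft
# Lennard-Jones-like steric term, a geometric hydrogen-bond well, and
# harmonic penalties for constraint violations.  This is deliberately not a
# physical forcefield -- it reproduces the logic of a packing score (clashes
# are expensive, contacts are mildly favourable, declared geometries are
# enforced), with every parameter exposed.

#' Score weights for the design stage
#'
#' @param steric,hbond,constraint Non-negative term weights.
#' @param reference Named numeric vector of per-identity reference energies
#'   (flat 0 by default).
#' @param eps Depth of the steric attraction well (score units).
#' @param soft Overlap softening: repulsion starts below `soft` times the
#'   sum of vdW radii.
#' @param k_dist,k_angle Harmonic constraint spring constants per Angstrom
#'   and per degree of violation.
#' @return An object of class `score_weights`.
#' @export
score_weights <- function(steric = 1, hbond = 1, constraint = 1,
                          reference = stats::setNames(rep(0, length(AA1)), AA1),
                          eps = 0.2, soft = 0.8,
                          k_dist = 1, k_angle = 0.01) {
  stopifnot(steric >= 0, hbond >= 0, constraint >= 0)
  structure(list(steric = steric, hbond = hbond, constraint = constraint,
                 reference = reference, eps = eps, soft = soft,
                 k_dist = k_dist, k_angle = k_angle),
            class = "score_weights")
}

# Split soft Lennard-Jones: repulsion is zero at and beyond `soft * r0`
# (so two atoms at exactly the sum of their vdW radii feel no repulsion);
# attraction is a flat -eps well inside r0 decaying as an LJ tail outside.
lj_repulsion <- function(d, r0, eps = 0.2, soft = 0.8) {
  r <- soft * r0
  out <- numeric(length(d))
  i <- d < r
  if (any(i)) {
    x <- (r[i] / pmax(d[i], 0.3))^6
    out[i] <- eps * (x^2 - 2 * x + 1)
  }
  out
}

lj_attraction <- function(d, r0, eps = 0.2) {
  out <- rep(-eps, length(d))
  i <- d >= r0
  if (any(i)) {
    x <- (r0[i] / d[i])^6
    out[i] <- eps * (x^2 - 2 * x)
  }
  out
}

# Total steric energy between two atom sets (matrices + radii vectors).
steric_energy <- function(xyz_a, rad_a, xyz_b, rad_b, eps = 0.2, soft = 0.8) {
  if (!nrow(xyz_a) || !nrow(xyz_b)) return(0)
  d <- as.vector(cross_dist(xyz_a, xyz_b))
  r0 <- as.vector(outer(rad_a, rad_b, "+"))
  sum(lj_repulsion(d, r0, eps, soft)) + sum(lj_attraction(d, r0, eps))
}

# Geometric hydrogen-bond well: -depth at ideal geometry (distance at the
# range midpoint, both angles at 180), tapering linearly to 0 at the range
# edges.
hbond_energy <- function(distance, donor_angle, acceptor_angle,
                         d_range = c(2.6, 3.2), a_min = 120, depth = 1) {
  mid <- mean(d_range)
  half <- diff(d_range) / 2
  fd <- pmax(0, 1 - abs(distance - mid) / half)
  fa <- pmax(0, pmin(1, (donor_angle - a_min) / (180 - a_min)))
  fb <- pmax(0, pmin(1, (acceptor_angle - a_min) / (180 - a_min)))
  -depth * fd * fa * fb
}

# Harmonic penalty for measured geometry outside a constraint's ranges.
constraint_penalty <- function(geometry, constraint, k_dist = 1,
                               k_angle = 0.01) {
  pen_rng <- function(x, rg, k) {
    if (is.null(rg) || is.null(x)) return(0)
    if (x < rg[1L]) k * (rg[1L] - x)^2
    else if (x > rg[2L]) k * (x - rg[2L])^2
    else 0
  }
  pen_rng(geometry$distance, constraint$distance, k_dist) +
    pen_rng(geometry$donor_angle, constraint$donor_angle, k_angle) +
    pen_rng(geometry$acceptor_angle, constraint$acceptor_angle, k_angle) +
    pen_rng(geometry$torsion, constraint$torsion, k_angle)
}
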