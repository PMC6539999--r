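# Coarse-grained side-chain model used throughout the package.  Each of the
# 20 identities maps to a short chain of pseudo-atoms grown from CB with
# ideal sp3 geometry; one rotatable chi per chain bond.  Radii and
# donor/acceptor flags live on the terminal atom.  This keeps every packing
# and matching problem exhaustively enumerable while preserving the
# size/polarity logic real rotamer libraries encode.

AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# atoms beyond CB (CB itself is backbone-determined); per-atom element and
# vdW radius; `aromatic` marks a bulky ring pseudo-atom at chi2 whose
# rotamers are sampled at {-90, 0, 90}.
STUB_PARAMS <- list(
  G = list(atoms = character(), element = character(), radius = numeric(),
           aromatic = FALSE, donor = FALSE, acceptor = FALSE),
  A = list(atoms = "CB1", element = "C", radius = 1.70,
           aromatic = FALSE, donor = FALSE, acceptor = FALSE),
  S = list(atoms = c("CB1", "OG"), element = c("C", "O"), radius = c(1.70, 1.52),
           aromatic = FALSE, donor = TRUE, acceptor = TRUE),
  C = list(atoms = c("CB1", "SG"), element = c("C", "S"), radius = c(1.70, 1.80),
           aromatic = FALSE, donor = TRUE, acceptor = FALSE),
  T = list(atoms = c("CB1", "OG1"), element = c("C", "O"), radius = c(1.85, 1.52),
           aromatic = FALSE, donor = TRUE, acceptor = TRUE),
  V = list(atoms = c("CB1", "CG1"), element = c("C", "C"), radius = c(1.70, 1.95),
           aromatic = FALSE, donor = FALSE, acceptor = FALSE),
  P = list(atoms = c("CB1", "CG"), element = c("C", "C"), radius = c(1.70, 1.70),
           aromatic = FALSE, donor = FALSE, acceptor = FALSE),
  L = list(atoms = c("CB1", "CG", "CD1"), element = c("C", "C", "C"),
           radius = c(1.70, 1.70, 1.95), aromatic = FALSE,
           donor = FALSE, acceptor = FALSE),
  I = list(atoms = c("CB1", "CG1", "CD1"), element = c("C", "C", "C"),
           radius = c(1.85, 1.70, 1.85), aromatic = FALSE,
           donor = FALSE, acceptor = FALSE),
  D = list(atoms = c("CB1", "CG", "OD1"), element = c("C", "C", "O"),
           radius = c(1.70, 1.70, 1.60), aromatic = FALSE,
           donor = FALSE, acceptor = TRUE),
  N = list(atoms = c("CB1", "CG", "OD1"), element = c("C", "C", "O"),
           radius = c(1.70, 1.70, 1.55), aromatic = FALSE,
           donor = TRUE, acceptor = TRUE),
  H = list(atoms = c("CB1", "CG", "NE2"), element = c("C", "C", "N"),
           radius = c(1.70, 1.90, 1.55), aromatic = TRUE,
           donor = TRUE, acceptor = TRUE),
  F = list(atoms = c("CB1", "CG", "CZ"), element = c("C", "C", "C"),
           radius = c(1.70, 1.90, 2.10), aromatic = TRUE,
           donor = FALSE, acceptor = FALSE),
  M = list(atoms = c("CB1", "CG", "SD", "CE"), element = c("C", "C", "S", "C"),
           radius = c(1.70, 1.70, 1.80, 1.70), aromatic = FALSE,
           donor = FALSE, acceptor = FALSE),
  E = list(atoms = c("CB1", "CG", "CD", "OE1"), element = c("C", "C", "C", "O"),
           radius = c(1.70, 1.70, 1.70, 1.60), aromatic = FALSE,
           donor = FALSE, acceptor = TRUE),
  Q = list(atoms = c("CB1", "CG", "CD", "OE1"), element = c("C", "C", "C", "O"),
           radius = c(1.70, 1.70, 1.70, 1.55), aromatic = FALSE,
           donor = TRUE, acceptor = TRUE),
  K = list(atoms = c("CB1", "CG", "CD", "NZ"), element = c("C", "C", "C", "N"),
           radius = c(1.70, 1.70, 1.70, 1.55), aromatic = FALSE,
           donor = TRUE, acceptor = FALSE),
  R = list(atoms = c("CB1", "CG", "CD", "NH1"), element = c("C", "C", "C", "N"),
           radius = c(1.70, 1.70, 1.70, 1.70), aromatic = FALSE,
           donor = TRUE, acceptor = FALSE),
  W = list(atoms = c("CB1", "CG", "CZ2", "NE1"), element = c("C", "C", "C", "N"),
           radius = c(1.70, 1.90, 2.20, 1.55), aromatic = TRUE,
           donor = TRUE, acceptor = FALSE),
  Y = list(atoms = c("CB1", "CG", "CZ", "OH"), element = c("C", "C", "C", "O"),
           radius = c(1.70, 1.90, 2.05, 1.52), aromatic = TRUE,
           donor = TRUE, acceptor = TRUE)
)

STUB_BOND <- 1.52   # pseudo-bond length, Angstrom
STUB_ANGLE <- 111   # pseudo-bond angle, degrees
CB_BOND <- 1.53
CB_ANGLE <- 110.5   # N-CA-CB
CB_TORSION <- -122  # C-N-CA-CB improper used to place CB

stub_params <- function(aa) {
  p <- STUB_PARAMS[[aa]]
  if (is.null(p)) stop("unknown residue identity '", aa, "'")
  p
}

# Number of rotatable chi angles of a stub (one per atom beyond CB).
stub_n_chi <- function(aa) max(0L, length(stub_params(aa)$atoms) - 1L)

#' Discrete rotamer library for the stub side-chain model
#'
#' sp3 chi angles are sampled at `{-60, 60, 180}` degrees; the chi that
#' positions an aromatic ring pseudo-atom is sampled at `{-90, 0, 90}`.
#' Optional sub-rotamers add `+/-10` degree perturbations of chi1.
#'
#' @param identities Character vector of one-letter identities (default all
#'   20).
#' @param sub_rotamers Add chi1 sub-rotamers at +/-10 degrees.
#' @return Named list mapping identity to a matrix of chi rows (0-column
#'   matrix with one row for identities without rotatable chis).
#' @export
rotamer_library <- function(identities = AA1, sub_rotamers = FALSE) {
  out <- lapply(identities, function(aa) {
    p <- stub_params(aa)
    nchi <- stub_n_chi(aa)
    if (nchi == 0L) return(matrix(numeric(0), nrow = 1L, ncol = 0L))
    grids <- lapply(seq_len(nchi), function(k) {
      if (p$aromatic && k == 2L) c(-90, 0, 90) else c(-60, 60, 180)
    })
    m <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
    if (sub_rotamers) {
      m <- rbind(m,
                 sweep(m, 2L, c(10, rep(0, nchi - 1L)), "+"),
                 sweep(m, 2L, c(-10, rep(0, nchi - 1L)), "+"))
    }
    dimnames(m) <- list(NULL, paste0("chi", seq_len(nchi)))
    m
  })
  names(out) <- identities
  out
}

# Ideal CB from backbone N, CA, C.
ideal_cb <- function(N, CA, C) place_atom(C, N, CA, CB_BOND, CB_ANGLE, CB_TORSION)

#' Build stub side-chain coordinates on a backbone frame
#'
#' Atoms beyond CB are grown by NeRF placement with the stub bond length and
#' angle; `chi[k]` is the torsion placing the k-th atom (chi1 is measured
#' over N-CA-CB-X1).
#'
#' @param N,CA,CB Backbone coordinates (length-3 numeric). `CB` may be `NULL`,
#'   in which case an ideal CB is rebuilt from `C`.
#' @param aa One-letter identity.
#' @param chi Numeric chi vector of length `stub_n_chi(aa)`.
#' @param C Backbone carbonyl carbon, only needed when `CB` is `NULL`.
#' @return Matrix of side-chain atoms beyond CB (possibly 0 rows), rownames
#'   are stub atom names. The first stub atom is CB itself (named `CB1`) so
#'   that identity changes at fixed backbone keep CB.
#' @export
build_side_chain <- function(N, CA, CB, aa, chi = numeric(), C = NULL) {
  p <- stub_params(aa)
  k <- length(p$atoms)
  out <- matrix(numeric(0), 0L, 3L)
  if (k == 0L) return(out)
  if (is.null(CB)) {
    if (is.null(C)) stop("need C to rebuild an ideal CB")
    CB <- ideal_cb(N, CA, C)
  }
  coords <- matrix(0, k, 3L, dimnames = list(p$atoms, NULL))
  coords[1L, ] <- CB
  if (k >= 2L) {
    if (length(chi) < k - 1L) stop("need ", k - 1L, " chi values for ", aa)
    prev2 <- N; prev1 <- CA; cur <- CB
    for (j in 2:k) {
      nxt <- place_atom(prev2, prev1, cur, STUB_BOND, STUB_ANGLE, chi[j - 1L])
      coords[j, ] <- nxt
      prev2 <- prev1; prev1 <- cur; cur <- nxt
    }
  }
  coords
}

# vdW radius lookup for scaffold/ligand atoms by element.
ELEMENT_RADIUS <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.10)

element_radius <- function(element) {
  r <- ELEMENT_RADIUS[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

stub_radii <- function(aa) {
  p <- stub_params(aa)
  stats::setNames(p$radius, p$atoms)
}

# terminal (functional) atom of a stub, or NA for apolar/absent side chains
stub_terminal <- function(aa) {
  p <- stub_params(aa)
  if (!length(p$atoms)) NA_character_ else p$atoms[length(p$atoms)]
}

stub_is_donor <- function(aa) stub_params(aa)$donor
stub_is_acceptor <- function(aa) stub_params(aa)$acceptor

# one- and three-letter conversions (bio3d's tables, behind one seam)
aa_123 <- function(x) bio3d::aa123(x)
aa_321 <- function(x) bio3d::aa321(x)
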