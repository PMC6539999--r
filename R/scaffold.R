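# Active-site scaffold structures: PDB input/output, shell definitions and
# anchoring of ligand conformers onto the wild-type substrate.  Author/PDB
# residue numbering is preserved verbatim; alternate locations keep the
# highest-occupancy copy; waters are dropped; insertion codes are rejected.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Read an active-site scaffold from PDB
#'
#' @param pdb Path to a PDB file, or a character vector of PDB lines.
#' @param anchor List identifying the bound substrate-anchor residue:
#'   `resno` (required), optionally `chain` and `resname`.
#' @param fixed_positions Integer residue numbers never designed (catalytic
#'   set); a config input, not inferred.
#' @param note Free-text numbering-convention note carried in the object.
#' @return An object of class `scaffold`.
#' @export
read_scaffold <- function(pdb, anchor, fixed_positions = integer(),
                          note = "") {
  if (length(pdb) == 1L && file.exists(pdb)) {
    lines <- readLines(pdb)
  } else {
    lines <- unlist(strsplit(pdb, "\n", fixed = TRUE))
  }
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54L) stop("parse error at line ", i, ": record too short")
    for (fld in list(c(31L, 38L), c(39L, 46L), c(47L, 54L))) {
      v <- suppressWarnings(as.numeric(substr(ln, fld[1L], fld[2L])))
      if (is.na(v)) {
        stop("parse error at line ", i, ": malformed coordinate field")
      }
    }
    if (substr(ln, 27L, 27L) != " ") {
      stop("parse error at line ", i, ": insertion codes are not supported")
    }
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdbobj <- bio3d::read.pdb(tmp, verbose = FALSE)
  at <- pdbobj$atom
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  # alternate locations: keep the highest-occupancy copy of each atom
  if (any(nzchar(at$alt) & !is.na(at$alt))) {
    key <- paste(at$chain, at$resno, at$elety)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
      idx[which.max(at$o[idx])]
    }))
    at <- at[sort(keep), , drop = FALSE]
  }
  at$chain[is.na(at$chain)] <- "A"
  sel <- at$resno == anchor$resno
  if (!is.null(anchor$chain)) sel <- sel & at$chain == anchor$chain
  if (!is.null(anchor$resname)) sel <- sel & at$resid == anchor$resname
  if (!any(sel)) {
    stop("anchor error: anchor residue ", anchor$resno, " not found")
  }
  anchor$chain <- at$chain[sel][1L]
  anchor$resname <- at$resid[sel][1L]
  structure(list(atoms = at, anchor = anchor,
                 fixed_positions = as.integer(fixed_positions), note = note),
            class = "scaffold")
}

#' @export
print.scaffold <- function(x, ...) {
  pos <- scaffold_positions(x)
  cat("scaffold:", nrow(pos), "protein residues,",
      "anchor", x$anchor$resname, x$anchor$resno,
      "(chain", paste0(x$anchor$chain, ")"),
      "|", length(x$fixed_positions), "fixed positions\n")
  invisible(x)
}

#' Write a scaffold to PDB
#'
#' @param scaffold A `scaffold`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scaffold <- function(scaffold, path) {
  at <- scaffold$atoms
  bio3d::write.pdb(file = path,
                   type = at$type,
                   xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   elety = at$elety, o = at$o, elesy = at$elesy)
  invisible(path)
}

# Protein residue table: one row per (chain, resno), 1-letter identity.
scaffold_positions <- function(scaffold) {
  at <- scaffold$atoms
  prot <- at[at$type == "ATOM" &
               !(at$resno == scaffold$anchor$resno &
                   at$chain == scaffold$anchor$chain), , drop = FALSE]
  if (!nrow(prot)) {
    return(data.frame(chain = character(), resno = integer(),
                      aa = character()))
  }
  u <- !duplicated(paste(prot$chain, prot$resno))
  data.frame(chain = prot$chain[u], resno = prot$resno[u],
             aa = aa_321(prot$resid[u]), stringsAsFactors = FALSE)
}

residue_atoms <- function(scaffold, resno, chain = NULL) {
  at <- scaffold$atoms
  sel <- at$resno == resno
  if (!is.null(chain)) sel <- sel & at$chain == chain
  at[sel, , drop = FALSE]
}

atoms_xyz <- function(at) {
  m <- as.matrix(at[, c("x", "y", "z")])
  rownames(m) <- at$elety
  m
}

# Backbone frame (named list of coordinates) of a protein residue.
backbone_frame <- function(scaffold, resno, chain = NULL) {
  at <- residue_atoms(scaffold, resno, chain)
  xyz <- atoms_xyz(at)
  get1 <- function(nm) if (nm %in% rownames(xyz)) xyz[nm, ] else NULL
  list(N = get1("N"), CA = get1("CA"), C = get1("C"), O = get1("O"),
       CB = get1("CB"), aa = aa_321(at$resid[1L]))
}

# Side-chain heavy atoms of a residue as stored in the PDB (CB counts as
# side chain).
native_side_xyz <- function(scaffold, resno, chain = NULL) {
  at <- residue_atoms(scaffold, resno, chain)
  at <- at[!(at$elety %in% BACKBONE_ATOMS) &
             toupper(at$elesy) != "H", , drop = FALSE]
  atoms_xyz(at)
}

anchor_atoms <- function(scaffold) {
  residue_atoms(scaffold, scaffold$anchor$resno, scaffold$anchor$chain)
}

#' First- and second-shell positions around a posed ligand
#'
#' A position is in the first shell when any of its side-chain heavy atoms
#' (CB included) lies within `inner` of any ligand heavy atom, and in the
#' second shell when within `outer` but not the first (half-open intervals
#' `[0, inner)` and `[inner, outer)`).  Fixed positions and the anchor
#' residue are excluded from both.
#'
#' @param scaffold A `scaffold`.
#' @param pose A `ligand_pose` (or an n x 3 matrix of ligand heavy-atom
#'   coordinates).
#' @param inner,outer Shell radii in Angstrom, `0 < inner < outer`.
#' @return List with data frames `first` and `second` (columns `chain`,
#'   `resno`, `aa`, `min_dist`).
#' @export
shell_positions <- function(scaffold, pose, inner = 6, outer = 9) {
  stopifnot(inner > 0, inner < outer)
  lig <- pose_heavy_xyz(pose)
  pos <- scaffold_positions(scaffold)
  pos$min_dist <- NA_real_
  keep_first <- keep_second <- logical(nrow(pos))
  for (i in seq_len(nrow(pos))) {
    sc <- native_side_xyz(scaffold, pos$resno[i], pos$chain[i])
    if (!nrow(sc)) next
    d <- min(cross_dist(sc, lig))
    pos$min_dist[i] <- d
    if (pos$resno[i] %in% scaffold$fixed_positions) next
    keep_first[i] <- d < inner
    keep_second[i] <- d >= inner && d < outer
  }
  list(first = pos[keep_first, , drop = FALSE],
       second = pos[keep_second, , drop = FALSE])
}

pose_heavy_xyz <- function(pose) {
  if (inherits(pose, "ligand_pose")) {
    hv <- heavy_names(pose$conformer$template)
    pose$xyz[hv, , drop = FALSE]
  } else if (is.matrix(pose)) {
    pose
  } else {
    stop("pose must be a ligand_pose or a coordinate matrix")
  }
}

#' Superpose a conformer's core onto the scaffold's substrate anchor
#'
#' Least-squares (Kabsch) rigid superposition of the template's core atoms
#' onto the correspondingly named atoms of the anchor residue.
#'
#' @param conformer A `conformer`.
#' @param scaffold A `scaffold`.
#' @param core_map Optional named character vector mapping template core
#'   atom names to anchor atom names (defaults to the identity map).
#' @return An object of class `ligand_pose` with fields `conformer`, `R`,
#'   `t`, `rmsd` (core RMSD in Angstrom) and `xyz` (all posed atoms).
#' @export
anchor_superpose <- function(conformer, scaffold, core_map = NULL) {
  tmpl <- conformer$template
  core <- tmpl$core_atoms
  if (is.null(core_map)) core_map <- stats::setNames(core, core)
  anc <- atoms_xyz(anchor_atoms(scaffold))
  have <- core[core_map[core] %in% rownames(anc)]
  if (length(have) < 3L) {
    stop("underdetermined superposition: fewer than 3 corresponding core atoms")
  }
  fit <- kabsch_fit(conformer$xyz[have, , drop = FALSE],
                    anc[core_map[have], , drop = FALSE])
  structure(list(conformer = conformer, R = fit$R, t = fit$t,
                 rmsd = fit$rmsd,
                 xyz = apply_transform(conformer$xyz, fit$R, fit$t)),
            class = "ligand_pose")
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat(sprintf("ligand_pose: core RMSD to anchor %.4f A, %d atoms\n",
              x$rmsd, nrow(x$xyz)))
  invisible(x)
}
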