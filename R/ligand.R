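# Ligand template machinery: a user-declared atom table plus bonds and
# chi1..chi5 dihedral definitions.  No chemical perception is attempted;
# hydrogens are permitted in templates but ignored by all clash checks.

#' Build a ligand template
#'
#' A template couples a rigid reference geometry with the rotatable-dihedral
#' machinery used to diversify it.  Rotating any chi angle moves only the
#' atoms distal to its central bond, so bond lengths and angles are invariant
#' across the whole conformer ensemble.
#'
#' @param atoms Data frame with columns `name`, `element`, `x`, `y`, `z`
#'   (coordinates in Angstrom). At least 4 atoms; names must be unique.
#' @param bonds Two-column matrix or data frame of bonded atom-name pairs.
#'   The bond graph must be connected.
#' @param dihedral_defs Named list mapping `chi1`, `chi2`, ... to ordered
#'   4-atom-name character vectors; consecutive atoms must be bonded.
#' @param core_atoms Character vector of atom names forming the rigid core
#'   (peptide backbone plus central phenyl ring) that is superposed onto the
#'   scaffold's substrate anchor.
#' @param polar_groups Named list of atom-name sets (e.g. `nitro`,
#'   `m_hydroxy`, `carboxylate`) addressed by geometric constraints.
#' @return An object of class `ligand_template`.
#' @export
ligand_template <- function(atoms, bonds, dihedral_defs = list(),
                            core_atoms = character(), polar_groups = list()) {
  atoms <- as.data.frame(atoms)
  need <- c("name", "element", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("definition error: atom table needs columns ", paste(need, collapse = ", "))
  }
  atoms$name <- as.character(atoms$name)
  if (nrow(atoms) < 4L) stop("definition error: need at least 4 atoms")
  if (anyDuplicated(atoms$name)) {
    stop("definition error: duplicate atom name '",
         atoms$name[duplicated(atoms$name)][1L], "'")
  }
  bonds <- as.matrix(as.data.frame(bonds))[, 1:2, drop = FALSE]
  storage.mode(bonds) <- "character"
  bad <- setdiff(unique(as.vector(bonds)), atoms$name)
  if (length(bad)) stop("definition error: unknown atom name in bonds: ", bad[1L])
  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  g <- g + igraph::vertices(setdiff(atoms$name, igraph::V(g)$name))
  if (igraph::components(g)$no != 1L) {
    stop("topology error: bond graph is disconnected")
  }
  if (!all(core_atoms %in% atoms$name)) {
    stop("definition error: unknown atom name in core_atoms")
  }
  for (grp in names(polar_groups)) {
    if (!all(polar_groups[[grp]] %in% atoms$name)) {
      stop("definition error: unknown atom name in polar group '", grp, "'")
    }
  }
  mobile <- list()
  for (chi in names(dihedral_defs)) {
    def <- as.character(dihedral_defs[[chi]])
    if (length(def) != 4L || anyDuplicated(def)) {
      stop("definition error: ", chi, " must name 4 distinct atoms")
    }
    if (!all(def %in% atoms$name)) {
      stop("definition error: unknown atom name in ", chi)
    }
    for (i in 1:3) {
      if (!igraph::are_adjacent(g, def[i], def[i + 1L])) {
        stop("definition error: ", chi, " atoms are not bonded in sequence")
      }
    }
    # Mobile set: atoms on the far side of the central bond b-c.
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, def[2:3]))
    comp <- igraph::components(g2)$membership
    mob <- names(comp)[comp == comp[def[3L]]]
    mob <- setdiff(mob, def[3L])
    if (def[2L] %in% mob || def[1L] %in% mob) {
      stop("topology error: ", chi, " central bond lies on a ring")
    }
    mobile[[chi]] <- mob
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rownames(xyz) <- atoms$name
  structure(list(atoms = atoms, xyz = xyz, bonds = bonds, graph = g,
                 dihedral_defs = lapply(dihedral_defs, as.character),
                 mobile = mobile, core_atoms = core_atoms,
                 polar_groups = polar_groups),
            class = "ligand_template")
}

#' @export
print.ligand_template <- function(x, ...) {
  cat("ligand_template:", nrow(x$atoms), "atoms,",
      length(x$dihedral_defs), "rotatable dihedrals (",
      paste(names(x$dihedral_defs), collapse = ", "), ")\n")
  cat("  core atoms:", length(x$core_atoms),
      "| polar groups:", paste(names(x$polar_groups), collapse = ", "), "\n")
  invisible(x)
}

# heavy atoms (protons declared in a template are ignored by clash checks)
heavy_names <- function(template) {
  template$atoms$name[toupper(template$atoms$element) != "H"]
}

#' Measure all template dihedrals from coordinates
#'
#' @param xyz Coordinate matrix with the template's atom names as rownames,
#'   or a `conformer`.
#' @param template A `ligand_template` (ignored when `xyz` is a conformer).
#' @return Named numeric vector of chi angles in degrees, in `[-180, 180)`.
#' @export
measure_chi <- function(xyz, template = NULL) {
  if (inherits(xyz, "conformer")) {
    template <- xyz$template
    xyz <- xyz$xyz
  }
  vapply(template$dihedral_defs, function(def) {
    dihedral_angle(xyz[def[1L], ], xyz[def[2L], ], xyz[def[3L], ], xyz[def[4L], ])
  }, numeric(1))
}

# Rotate the mobile set so that the named chi takes `target` degrees.
set_chi <- function(xyz, template, chi, target) {
  def <- template$dihedral_defs[[chi]]
  cur <- dihedral_angle(xyz[def[1L], ], xyz[def[2L], ], xyz[def[3L], ], xyz[def[4L], ])
  delta <- wrap_angle(target - cur)
  if (abs(delta) < 1e-12) return(xyz)
  mob <- template$mobile[[chi]]
  # +theta about axis b->c decreases the measured dihedral, hence -delta.
  xyz[mob, ] <- rotate_points(xyz[mob, , drop = FALSE],
                              xyz[def[2L], ], xyz[def[3L], ] - xyz[def[2L], ],
                              -delta)
  xyz
}

new_conformer <- function(template, xyz, chi = NULL) {
  if (is.null(chi)) chi <- measure_chi(xyz, template)
  structure(list(template = template, xyz = xyz,
                 chi = wrap_angle(chi)), class = "conformer")
}

#' Build a single conformer at given chi values
#'
#' @param template A `ligand_template`.
#' @param chi Named numeric vector (a subset of the template's dihedrals).
#' @return A `conformer` whose bond lengths and angles equal the template's.
#' @export
make_conformer <- function(template, chi = numeric()) {
  xyz <- template$xyz
  for (nm in names(chi)) {
    if (!nm %in% names(template$dihedral_defs)) {
      stop("definition error: template has no dihedral '", nm, "'")
    }
    xyz <- set_chi(xyz, template, nm, chi[[nm]])
  }
  new_conformer(template, xyz)
}

# Intramolecular clash: any heavy-atom pair closer than `cutoff`, excluding
# 1-2 and 1-3 pairs (graph distance <= 2).
conformer_clashes <- function(template, xyz, cutoff = 2.4) {
  hv <- heavy_names(template)
  gd <- template$.graphdist
  if (is.null(gd)) gd <- igraph::distances(template$graph)
  sub <- xyz[hv, , drop = FALSE]
  d <- cross_dist(sub, sub)
  close <- which(d < cutoff, arr.ind = TRUE)
  close <- close[close[, 1L] < close[, 2L], , drop = FALSE]
  if (!nrow(close)) return(FALSE)
  any(gd[cbind(hv[close[, 1L]], hv[close[, 2L]])] > 2)
}

new_ensemble <- function(members, provenance = list()) {
  structure(list(members = members, provenance = provenance),
            class = "conformer_ensemble")
}

#' @export
length.conformer_ensemble <- function(x) length(x$members)

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat("conformer_ensemble of", length(x), "members\n")
  if (length(x$provenance)) {
    cat("  provenance:", paste(names(x$provenance),
                               vapply(x$provenance, function(v)
                                 paste(format(v), collapse = ","), ""),
                               sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

#' Chi-value table of an ensemble
#'
#' @param ensemble A `conformer_ensemble`.
#' @return Matrix (members x chi angles) of dihedral values in degrees.
#' @export
ensemble_chi <- function(ensemble) {
  do.call(rbind, lapply(ensemble$members, function(m) m$chi))
}

#' Sample a dihedral-diversified conformer ensemble
#'
#' The proximal dihedrals (typically chi1/chi2) are pinned to the values the
#' wild-type substrate adopts in the scaffold; the distal dihedrals are drawn
#' from a uniform grid with stratified random jitter.  Conformers with an
#' intramolecular heavy-atom contact below `clash_cutoff` (excluding 1-2/1-3
#' pairs) are rejected and resampled, and chi vectors agreeing within 1 degree
#' on every component count as duplicates.
#'
#' @param template A `ligand_template`.
#' @param fixed_chi Named numeric vector of pinned dihedrals (degrees).
#' @param sampled_chi Named list mapping dihedral names to numeric grids
#'   (degrees).
#' @param n Number of conformers to return.
#' @param seed Integer seed; the same seed reproduces the ensemble member for
#'   member.
#' @param jitter Half-width of the uniform jitter applied around each grid
#'   point, in degrees. Defaults to half the grid spacing (0 for singleton
#'   grids).
#' @param clash_cutoff Heavy-atom contact cutoff in Angstrom.
#' @param max_cycles Number of passes over the full grid before sampling is
#'   declared exhausted.
#' @return A `conformer_ensemble` with exactly `n` members.
#' @export
sample_conformers <- function(template, fixed_chi = numeric(),
                              sampled_chi = list(), n, seed = 1,
                              jitter = NULL, clash_cutoff = 2.4,
                              max_cycles = 25L) {
  stopifnot(n >= 1)
  if (!length(sampled_chi) && n > 1) {
    stop("sampling-exhausted: no sampled dihedrals but n > 1")
  }
  for (g in sampled_chi) if (!length(g)) stop("definition error: empty grid")
  template$.graphdist <- igraph::distances(template$graph)
  base <- template$xyz
  for (nm in names(fixed_chi)) base <- set_chi(base, template, nm, fixed_chi[[nm]])
  grid <- if (length(sampled_chi)) {
    as.matrix(expand.grid(sampled_chi, KEEP.OUT.ATTRS = FALSE))
  } else {
    matrix(numeric(0), nrow = 1L, ncol = 0L)
  }
  if (is.null(jitter)) {
    jitter <- vapply(sampled_chi, function(g) {
      if (length(g) < 2L) 0 else min(diff(sort(g))) / 2
    }, numeric(1))
  } else if (length(jitter) == 1L) {
    jitter <- rep(jitter, length(sampled_chi))
  }
  members <- vector("list", n)
  chi_seen <- matrix(numeric(0), 0L, length(sampled_chi))
  got <- 0L
  with_seed(seed, {
    for (cycle in seq_len(max_cycles)) {
      ord <- if (nrow(grid) > 1L) sample.int(nrow(grid)) else seq_len(nrow(grid))
      for (i in ord) {
        if (got >= n) break
        chi_try <- grid[i, ]
        if (length(chi_try)) {
          chi_try <- wrap_angle(chi_try + stats::runif(length(chi_try),
                                                       -jitter, jitter))
        }
        if (nrow(chi_seen)) {
          diffs <- abs(wrap_angle(sweep(chi_seen, 2L, chi_try)))
          if (ncol(chi_seen) == 0L || any(apply(diffs, 1L, max) <= 1)) next
        }
        xyz <- base
        for (k in seq_along(chi_try)) {
          xyz <- set_chi(xyz, template, names(sampled_chi)[k], chi_try[k])
        }
        if (conformer_clashes(template, xyz, clash_cutoff)) next
        got <- got + 1L
        members[[got]] <- new_conformer(template, xyz)
        chi_seen <- rbind(chi_seen, chi_try)
      }
      if (got >= n) break
    }
  })
  if (got < n) {
    stop("sampling-exhausted: only ", got, " distinct clash-free conformers ",
         "achievable for n = ", n)
  }
  new_ensemble(members,
               provenance = list(seed = seed, n = n,
                                 fixed_chi = fixed_chi,
                                 sampled = names(sampled_chi),
                                 grid_sizes = vapply(sampled_chi, length,
                                                     integer(1))))
}

#' Double an ensemble by flipping chi2 by 180 degrees
#'
#' Every input conformer is preserved (in order) and followed, after the
#' originals, by a copy whose chi2 is rotated by exactly 180 degrees.
#'
#' @param ensemble A `conformer_ensemble`.
#' @param chi Name of the dihedral to flip (default `"chi2"`).
#' @return A `conformer_ensemble` of twice the size.
#' @export
flip_chi2 <- function(ensemble, chi = "chi2") {
  flipped <- lapply(ensemble$members, function(m) {
    xyz <- set_chi(m$xyz, m$template, chi, wrap_angle(m$chi[[chi]] + 180))
    new_conformer(m$template, xyz)
  })
  prov <- ensemble$provenance
  prov$flipped <- chi
  new_ensemble(c(ensemble$members, flipped), prov)
}

## ---- template / ensemble serialization ------------------------------------

#' Write a ligand template to a YAML file
#'
#' The atom block is stored as an embedded TSV string (name, element, x, y,
#' z); bonds, dihedral definitions, core atoms and polar groups are plain
#' YAML keys.
#'
#' @param template A `ligand_template`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ligand_template <- function(template, path) {
  con <- textConnection("atom_tsv", "w", local = TRUE)
  utils::write.table(template$atoms[, c("name", "element", "x", "y", "z")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  doc <- list(atoms = paste(atom_tsv, collapse = "\n"),
              bonds = apply(template$bonds, 1L, as.list),
              dihedral_defs = template$dihedral_defs,
              core_atoms = template$core_atoms,
              polar_groups = template$polar_groups)
  yaml::write_yaml(doc, path, precision = 12L)
  invisible(path)
}

#' Read a ligand template from a YAML file
#'
#' @param path File written by [write_ligand_template()].
#' @return A `ligand_template`.
#' @export
read_ligand_template <- function(path) {
  doc <- yaml::read_yaml(path)
  atoms <- utils::read.delim(text = doc$atoms, stringsAsFactors = FALSE)
  bonds <- do.call(rbind, lapply(doc$bonds, unlist))
  ligand_template(atoms, bonds,
                  dihedral_defs = doc$dihedral_defs,
                  core_atoms = unlist(doc$core_atoms),
                  polar_groups = lapply(doc$polar_groups, unlist))
}

#' Write a conformer ensemble as a multi-model PDB
#'
#' Each conformer becomes one MODEL block (HETATM records, residue LIG); the
#' chi provenance is written to a sidecar TSV (`<path>.chi.tsv`).
#'
#' @param ensemble A `conformer_ensemble`.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_conformers_pdb <- function(ensemble, path) {
  stopifnot(length(ensemble) >= 1L)
  tmpl <- ensemble$members[[1L]]$template
  lines <- character()
  for (i in seq_along(ensemble$members)) {
    m <- ensemble$members[[i]]
    tmp <- tempfile(fileext = ".pdb")
    bio3d::write.pdb(file = tmp, xyz = as.vector(t(m$xyz)),
                     type = rep("HETATM", nrow(m$xyz)),
                     resno = rep(1L, nrow(m$xyz)),
                     resid = rep("LIG", nrow(m$xyz)),
                     chain = rep("X", nrow(m$xyz)),
                     elety = tmpl$atoms$name,
                     elesy = tmpl$atoms$element)
    body <- grep("^(HETATM|ATOM)", readLines(tmp), value = TRUE)
    lines <- c(lines, sprintf("MODEL     %4d", i), body, "ENDMDL")
    unlink(tmp)
  }
  writeLines(c(lines, "END"), path)
  chi <- as.data.frame(ensemble_chi(ensemble))
  chi <- cbind(model = seq_len(nrow(chi)), chi)
  utils::write.table(chi, paste0(path, ".chi.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a multi-model PDB conformer ensemble
#'
#' @param path PDB written by [write_conformers_pdb()].
#' @param template The `ligand_template` the ensemble belongs to.
#' @return A `conformer_ensemble` (chi values re-measured from coordinates).
#' @export
read_conformers_pdb <- function(path, template) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nm <- pdb$atom$elety
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  members <- lapply(seq_len(nrow(xyz)), function(i) {
    m <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE)
    rownames(m) <- nm
    new_conformer(template, m[template$atoms$name, , drop = FALSE])
  })
  new_ensemble(members, provenance = list(source = path))
}
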