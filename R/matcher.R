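# Geometric hydrogen-bond matching: enumerate sequence-unique placements of
# contact residues that satisfy declared distance/angle(/torsion) geometries
# to the posed noncanonical amino acid.

#' Declare a geometric hydrogen-bond constraint
#'
#' Defaults encode a standard hydrogen bond: donor-acceptor heavy-atom
#' distance 2.6-3.2 Angstrom with both flanking angles of at least 120
#' degrees.  All intervals are closed.
#'
#' @param ligand_group Name of the ligand polar group (must exist in the
#'   template's `polar_groups`), or a character vector of explicit ligand
#'   atom names.
#' @param identities Allowed residue identities (one-letter), non-empty.
#' @param distance,donor_angle,acceptor_angle Length-2 `c(min, max)` ranges
#'   (Angstrom / degrees).
#' @param torsion Optional length-2 torsion range in degrees; checked only
#'   when supplied.
#' @param rotamer_policy `"full"` (search the discrete rotamer library) or
#'   `"native"` (only the residue's current side chain, native identity).
#' @param name Optional label used in reports.
#' @return An object of class `geom_constraint`.
#' @export
hbond_constraint <- function(ligand_group, identities,
                             distance = c(2.6, 3.2),
                             donor_angle = c(120, 180),
                             acceptor_angle = c(120, 180),
                             torsion = NULL,
                             rotamer_policy = c("full", "native"),
                             name = NULL) {
  rotamer_policy <- match.arg(rotamer_policy)
  if (!length(identities)) stop("allowed_identities must be non-empty")
  for (rg in list(distance, donor_angle, acceptor_angle, torsion)) {
    if (!is.null(rg) && (length(rg) != 2L || rg[1L] > rg[2L])) {
      stop("constraint ranges must be c(min, max) with min <= max")
    }
  }
  structure(list(ligand_group = ligand_group,
                 identities = unique(identities),
                 distance = distance, donor_angle = donor_angle,
                 acceptor_angle = acceptor_angle, torsion = torsion,
                 rotamer_policy = rotamer_policy,
                 name = if (is.null(name)) ligand_group[1L] else name),
            class = "geom_constraint")
}

#' Evaluate hydrogen-bond geometry against a constraint
#'
#' @param donor_atoms List with `atom` (donor heavy-atom coordinate) and
#'   `base` (the atom it is bonded to).
#' @param acceptor_atoms Same structure for the acceptor side.
#' @param constraint A `geom_constraint`.
#' @return List with `satisfied` (logical) and `geometry` (measured
#'   `distance`, `donor_angle`, `acceptor_angle` and `torsion` when the
#'   constraint declares one).
#' @export
evaluate_constraint <- function(donor_atoms, acceptor_atoms, constraint) {
  d <- donor_atoms$atom
  a <- acceptor_atoms$atom
  geom <- list(distance = vnorm(a - d),
               donor_angle = bond_angle(donor_atoms$base, d, a),
               acceptor_angle = bond_angle(acceptor_atoms$base, a, d))
  if (!is.null(constraint$torsion)) {
    geom$torsion <- dihedral_angle(donor_atoms$base, d, a, acceptor_atoms$base)
  }
  inr <- function(x, rg) x >= rg[1L] && x <= rg[2L]
  ok <- inr(geom$distance, constraint$distance) &&
    inr(geom$donor_angle, constraint$donor_angle) &&
    inr(geom$acceptor_angle, constraint$acceptor_angle) &&
    (is.null(constraint$torsion) || inr(geom$torsion, constraint$torsion))
  list(satisfied = ok, geometry = geom)
}

# Ligand polar atoms addressed by a constraint, with their bonded base atoms.
ligand_group_atoms <- function(template, constraint, xyz) {
  nm <- constraint$ligand_group
  atoms <- if (length(nm) == 1L && nm %in% names(template$polar_groups)) {
    template$polar_groups[[nm]]
  } else {
    nm
  }
  # only N/O (or S) atoms can take part in an H bond; base = bonded neighbor
  el <- stats::setNames(template$atoms$element, template$atoms$name)
  atoms <- atoms[toupper(el[atoms]) %in% c("N", "O", "S")]
  lapply(atoms, function(a) {
    nb <- igraph::neighbors(template$graph, a)$name
    list(name = a, atom = xyz[a, ], base = xyz[nb[1L], ])
  })
}

# Geometry check of a residue functional atom against every atom of a ligand
# polar group; residue donor/acceptor capability decides role mapping.
check_residue_ligand_hbond <- function(term, base, donor_ok, acceptor_ok,
                                       lig_atoms, constraint) {
  for (la in lig_atoms) {
    if (donor_ok) {
      ev <- evaluate_constraint(list(atom = term, base = base),
                                list(atom = la$atom, base = la$base),
                                constraint)
      if (ev$satisfied) {
        return(c(ev, list(ligand_atom = la$name, role = "donor")))
      }
    }
    if (acceptor_ok) {
      ev <- evaluate_constraint(list(atom = la$atom, base = la$base),
                                list(atom = term, base = base),
                                constraint)
      if (ev$satisfied) {
        return(c(ev, list(ligand_atom = la$name, role = "acceptor")))
      }
    }
  }
  NULL
}

sc_clash <- function(xyz_a, rad_a, xyz_b, rad_b, factor = 0.8) {
  if (!nrow(xyz_a) || !nrow(xyz_b)) return(FALSE)
  d <- cross_dist(xyz_a, xyz_b)
  any(d < factor * outer(rad_a, rad_b, "+"))
}

# Enumerate (position x identity x rotamer) candidates satisfying one
# constraint for one pose.  Returns a list of candidate records.
enumerate_candidates <- function(scaffold, pose, constraint, rotamers,
                                 positions = NULL, check_clashes = TRUE,
                                 clash_factor = 0.8) {
  tmpl <- pose$conformer$template
  lig_atoms <- ligand_group_atoms(tmpl, constraint, pose$xyz)
  if (!length(lig_atoms)) return(list())
  hv <- heavy_names(tmpl)
  lig_xyz <- pose$xyz[hv, , drop = FALSE]
  lig_rad <- element_radius(tmpl$atoms$element[match(hv, tmpl$atoms$name)])
  pos <- scaffold_positions(scaffold)
  pos <- pos[!(pos$resno %in% scaffold$fixed_positions) |
               constraint$rotamer_policy == "native", , drop = FALSE]
  if (!is.null(positions)) pos <- pos[pos$resno %in% positions, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(pos))) {
    resno <- pos$resno[i]
    chain <- pos$chain[i]
    if (constraint$rotamer_policy == "native") {
      if (!(pos$aa[i] %in% constraint$identities)) next
      sc <- native_side_xyz(scaffold, resno, chain)
      if (nrow(sc) < 2L) next
      aa <- pos$aa[i]
      term <- sc[nrow(sc), ]
      base <- sc[nrow(sc) - 1L, ]
      hit <- check_residue_ligand_hbond(term, base, stub_is_donor(aa),
                                        stub_is_acceptor(aa), lig_atoms,
                                        constraint)
      if (is.null(hit)) next
      rad <- rep(1.6, nrow(sc))
      p <- tryCatch(stub_params(aa), error = function(e) NULL)
      if (!is.null(p) && length(p$radius) == nrow(sc)) rad <- p$radius
      if (check_clashes && sc_clash(sc, rad, lig_xyz, lig_rad, clash_factor)) next
      out[[length(out) + 1L]] <-
        list(resno = resno, chain = chain, identity = aa, rotamer = NA_integer_,
             chi = measure_stub_chi(scaffold, resno, chain),
             xyz = sc, radii = rad, hit = hit)
      next
    }
    bb <- backbone_frame(scaffold, resno, chain)
    if (is.null(bb$N) || is.null(bb$CA)) next
    for (aa in constraint$identities) {
      rots <- rotamers[[aa]]
      if (is.null(rots)) {
        stop("configuration error: identity '", aa,
             "' has no rotamers in the rotamer set")
      }
      if (!(stub_is_donor(aa) || stub_is_acceptor(aa))) next
      if (is.na(stub_terminal(aa)) || length(stub_params(aa)$atoms) < 2L) next
      rad <- unname(stub_radii(aa))
      for (r in seq_len(nrow(rots))) {
        sc <- build_side_chain(bb$N, bb$CA, bb$CB, aa, rots[r, ], C = bb$C)
        term <- sc[nrow(sc), ]
        base <- sc[nrow(sc) - 1L, ]
        hit <- check_residue_ligand_hbond(term, base, stub_is_donor(aa),
                                          stub_is_acceptor(aa), lig_atoms,
                                          constraint)
        if (is.null(hit)) next
        if (check_clashes && sc_clash(sc, rad, lig_xyz, lig_rad, clash_factor)) next
        out[[length(out) + 1L]] <-
          list(resno = resno, chain = chain, identity = aa, rotamer = r,
               chi = rots[r, ], xyz = sc, radii = rad, hit = hit)
      }
    }
  }
  out
}

measure_stub_chi <- function(scaffold, resno, chain = NULL) {
  bb <- backbone_frame(scaffold, resno, chain)
  sc <- native_side_xyz(scaffold, resno, chain)
  if (nrow(sc) < 2L) return(numeric())
  pts <- rbind(N = bb$N, CA = bb$CA, sc)
  vapply(seq_len(nrow(sc) - 1L), function(k) {
    dihedral_angle(pts[k, ], pts[k + 1L, ], pts[k + 2L, ], pts[k + 3L, ])
  }, numeric(1))
}

match_signature <- function(assignments) {
  paste(sort(paste0(assignments$resno, ":", assignments$identity)),
        collapse = "+")
}

#' Find sequence-unique constraint-satisfying matches
#'
#' For every conformer (anchored onto the scaffold's substrate), enumerates
#' `(position x identity x rotamer)` candidates per constraint and returns
#' every combination in which each constraint is satisfied at a distinct
#' position and no two placed side chains clash with each other or with the
#' ligand.  The output is deduplicated to sequence-unique matches.
#'
#' @param scaffold A `scaffold`.
#' @param ensemble A `conformer_ensemble`.
#' @param constraints List of `geom_constraint`s (non-empty).
#' @param rotamers Rotamer set from [rotamer_library()].
#' @param positions Optional integer vector restricting candidate positions.
#' @param check_clashes Disable to count raw geometric combinations.
#' @param clash_factor Heavy-atom pairs closer than `clash_factor` times the
#'   sum of vdW radii count as clashes.
#' @return List of `match` objects sorted by sequence signature.
#' @export
find_matches <- function(scaffold, ensemble, constraints,
                         rotamers = rotamer_library(),
                         positions = NULL, check_clashes = TRUE,
                         clash_factor = 0.8) {
  stopifnot(length(constraints) >= 1L)
  for (cst in constraints) {
    for (aa in cst$identities) {
      if (cst$rotamer_policy == "full" && is.null(rotamers[[aa]])) {
        stop("configuration error: identity '", aa,
             "' has no rotamers in the rotamer set")
      }
    }
  }
  raw <- list()
  for (ci in seq_along(ensemble$members)) {
    pose <- anchor_superpose(ensemble$members[[ci]], scaffold)
    cand <- lapply(constraints, function(cst) {
      enumerate_candidates(scaffold, pose, cst, rotamers, positions,
                           check_clashes, clash_factor)
    })
    if (any(!vapply(cand, length, integer(1)))) next
    idx <- lapply(cand, seq_along)
    combos <- as.matrix(expand.grid(idx, KEEP.OUT.ATTRS = FALSE))
    for (k in seq_len(nrow(combos))) {
      picks <- lapply(seq_along(cand), function(j) cand[[j]][[combos[k, j]]])
      resnos <- vapply(picks, function(p) p$resno, integer(1))
      if (anyDuplicated(resnos)) next
      if (check_clashes && length(picks) > 1L) {
        bad <- FALSE
        for (a in seq_len(length(picks) - 1L)) {
          for (b in (a + 1L):length(picks)) {
            if (sc_clash(picks[[a]]$xyz, picks[[a]]$radii,
                         picks[[b]]$xyz, picks[[b]]$radii, clash_factor)) {
              bad <- TRUE
              break
            }
          }
          if (bad) break
        }
        if (bad) next
      }
      assignments <- data.frame(
        constraint = vapply(constraints, function(cst) cst$name, ""),
        resno = resnos,
        chain = vapply(picks, function(p) p$chain, ""),
        identity = vapply(picks, function(p) p$identity, ""),
        rotamer = vapply(picks, function(p) p$rotamer, integer(1)),
        stringsAsFactors = FALSE)
      m <- structure(list(conformer = ci, pose = pose,
                          assignments = assignments,
                          chi = lapply(picks, function(p) p$chi),
                          sidechains = lapply(picks, function(p) p$xyz),
                          geometry = lapply(picks, function(p) p$hit),
                          signature = match_signature(assignments)),
                     class = "match")
      raw[[length(raw) + 1L]] <- m
    }
  }
  dedupe_matches(raw)
}

#' Deduplicate matches to sequence-unique representatives
#'
#' Keeps one representative per sequence signature -- the lexicographically
#' smallest `(conformer index, position tuple)` -- and sorts the output by
#' signature.  Idempotent and insensitive to input order.
#'
#' @param matches List of `match` objects.
#' @return List of `match` objects, one per signature, sorted by signature.
#' @export
dedupe_matches <- function(matches) {
  if (!length(matches)) return(list())
  sig <- vapply(matches, function(m) m$signature, "")
  conf <- vapply(matches, function(m) m$conformer, numeric(1))
  ptup <- vapply(matches, function(m)
    paste(sort(m$assignments$resno), collapse = ","), "")
  ord <- order(sig, conf, ptup)
  matches <- matches[ord]
  sig <- sig[ord]
  out <- matches[!duplicated(sig)]
  for (i in seq_along(out)) out[[i]]$id <- i
  out
}

#' @export
print.match <- function(x, ...) {
  cat("match", if (!is.null(x$id)) x$id else "", "| conformer", x$conformer,
      "|", x$signature, "\n")
  invisible(x)
}

## ---- constraint file IO ---------------------------------------------------

#' Write constraints to YAML
#'
#' @param constraints List of `geom_constraint`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_constraints <- function(constraints, path) {
  doc <- lapply(constraints, function(cst) {
    x <- unclass(cst)
    x[!vapply(x, is.null, logical(1))]
  })
  yaml::write_yaml(doc, path, precision = 12L)
  invisible(path)
}

#' Read constraints from YAML
#'
#' @param path File written by [write_constraints()].
#' @return List of `geom_constraint`s.
#' @export
read_constraints <- function(path) {
  doc <- yaml::read_yaml(path)
  lapply(doc, function(x) {
    hbond_constraint(ligand_group = unlist(x$ligand_group),
                     identities = unlist(x$identities),
                     distance = unlist(x$distance),
                     donor_angle = unlist(x$donor_angle),
                     acceptor_angle = unlist(x$acceptor_angle),
                     torsion = if (!is.null(x$torsion)) unlist(x$torsion),
                     rotamer_policy = x$rotamer_policy,
                     name = x$name)
  })
}

#' Measure a native anchor constraint from the scaffold
#'
#' Reads the geometry the scaffold's own residue forms with a ligand atom
#' and returns a constraint centred on it with the given tolerances --
#' the mechanism used both for the catalytic-residue match constraint and
#' for the peptide-backbone anchor constraints enforced during design.
#'
#' @param scaffold A `scaffold`.
#' @param pose A `ligand_pose` in the scaffold frame.
#' @param resno Residue whose side-chain functional atom is measured.
#' @param ligand_atoms Ligand atom name(s) to measure against (nearest one
#'   is used).
#' @param tol_distance,tol_angle Half-widths of the derived ranges
#'   (defaults 0.3 Angstrom, 20 degrees).
#' @param rotamer_policy Passed through to the constraint.
#' @param name Constraint label.
#' @return A `geom_constraint` whose ranges bracket the native geometry.
#' @export
native_constraint <- function(scaffold, pose, resno, ligand_atoms,
                              tol_distance = 0.3, tol_angle = 20,
                              rotamer_policy = "native", name = NULL) {
  pos <- scaffold_positions(scaffold)
  aa <- pos$aa[match(resno, pos$resno)]
  sc <- native_side_xyz(scaffold, resno)
  if (nrow(sc) < 2L) stop("residue ", resno, " has no functional side chain")
  term <- sc[nrow(sc), ]
  base <- sc[nrow(sc) - 1L, ]
  tmpl <- pose$conformer$template
  cst0 <- hbond_constraint(ligand_atoms, aa, rotamer_policy = "native")
  lig <- ligand_group_atoms(tmpl, cst0, pose$xyz)
  dmin <- which.min(vapply(lig, function(la) vnorm(la$atom - term), numeric(1)))
  la <- lig[[dmin]]
  geom <- evaluate_constraint(list(atom = term, base = base),
                              list(atom = la$atom, base = la$base),
                              cst0)$geometry
  hbond_constraint(
    ligand_group = la$name, identities = aa,
    distance = c(geom$distance - tol_distance, geom$distance + tol_distance),
    donor_angle = c(max(0, geom$donor_angle - tol_angle),
                    min(180, geom$donor_angle + tol_angle)),
    acceptor_angle = c(max(0, geom$acceptor_angle - tol_angle),
                       min(180, geom$acceptor_angle + tol_angle)),
    rotamer_policy = rotamer_policy,
    name = if (is.null(name)) paste0("native_", resno) else name)
}
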