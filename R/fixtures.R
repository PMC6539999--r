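# Synthetic fixtures with planted ground truth: a toy photocaged-tyrosine
# ligand, pocket scaffolds whose constraint-satisfiable placements are known
# by construction, and sequence profiles built backwards from target curated
# libraries.  Fixtures are geometric toys -- residues use the stub
# side-chain model -- so every stage of the pipeline stays exhaustively
# enumerable.

#' Recipe for a synthetic pocket fixture
#'
#' @param seed Seed controlling decoy directions and the global rigid
#'   motion applied to the finished pocket.
#' @param nitro_sites Number of planted serine-satisfiable sites for the
#'   nitro-group constraint (1-3).
#' @param hydroxy_sites Number of planted sites for the m-hydroxy
#'   constraint (0-1).
#' @param first_shell_dists,second_shell_dists,distant_dists Minimum
#'   side-chain-to-ligand distances (Angstrom) at which apolar decoy
#'   residues are planted.
#' @param native_chi Ligand chi values adopted by the bound substrate
#'   anchor.
#' @return A list of class `fixture_recipe`.
#' @export
fixture_recipe <- function(seed = 1, nitro_sites = 3, hydroxy_sites = 1,
                           first_shell_dists = c(4.5, 5.0, 5.5),
                           second_shell_dists = c(7.0, 7.6, 8.2),
                           distant_dists = c(12, 14),
                           native_chi = c(chi1 = -167, chi2 = 76,
                                          chi3 = 180, chi4 = 180, chi5 = 90)) {
  stopifnot(nitro_sites >= 1, nitro_sites <= 3,
            hydroxy_sites >= 0, hydroxy_sites <= 1)
  structure(list(seed = seed, nitro_sites = nitro_sites,
                 hydroxy_sites = hydroxy_sites,
                 first_shell_dists = first_shell_dists,
                 second_shell_dists = second_shell_dists,
                 distant_dists = distant_dists,
                 native_chi = native_chi),
            class = "fixture_recipe")
}

#' Toy photocaged-aromatic ligand template
#'
#' A coarse model of an ortho-nitrobenzyl-caged tyrosine-like amino acid:
#' amino-acid backbone (with carboxylate), CB, a phenyl ring carrying a
#' meta-hydroxyl, and (optionally) a para ether-linked caging arm ending in
#' a nitro group.  chi1/chi2 rotate the side chain, chi3-chi5 rotate the
#' caging arm.
#'
#' @param caging_arm Include the arm (chi3-chi5 and the nitro group)?
#' @return A `ligand_template` with polar groups `carboxylate`,
#'   `m_hydroxy` and (with the arm) `nitro`.
#' @export
toy_ligand <- function(caging_arm = TRUE) {
  p <- list()
  p$N <- c(0, 0, 0)
  p$CA <- c(1.458, 0, 0)
  p$C <- p$CA + 1.524 * c(cos(deg2rad(69)), sin(deg2rad(69)), 0)
  p$O <- place_atom(p$N, p$CA, p$C, 1.23, 120, 0)
  p$OXT <- place_atom(p$N, p$CA, p$C, 1.25, 120, 180)
  p$CB <- place_atom(p$C, p$N, p$CA, 1.53, 110.5, -122)
  p$C1 <- place_atom(p$N, p$CA, p$CB, 1.51, 114, 180)
  p$C2 <- place_atom(p$CA, p$CB, p$C1, 1.39, 120, 90)
  p$C3 <- place_atom(p$CB, p$C1, p$C2, 1.39, 120, 180)
  p$C4 <- place_atom(p$C1, p$C2, p$C3, 1.39, 120, 0)
  p$C5 <- place_atom(p$C2, p$C3, p$C4, 1.39, 120, 0)
  p$C6 <- place_atom(p$C3, p$C4, p$C5, 1.39, 120, 0)
  p$OM <- place_atom(p$C1, p$C2, p$C3, 1.36, 120, 180)
  bonds <- rbind(c("N", "CA"), c("CA", "C"), c("C", "O"), c("C", "OXT"),
                 c("CA", "CB"), c("CB", "C1"), c("C1", "C2"), c("C2", "C3"),
                 c("C3", "C4"), c("C4", "C5"), c("C5", "C6"), c("C6", "C1"),
                 c("C3", "OM"))
  dihedrals <- list(chi1 = c("N", "CA", "CB", "C1"),
                    chi2 = c("CA", "CB", "C1", "C2"))
  polar <- list(carboxylate = c("O", "OXT"), m_hydroxy = "OM")
  if (caging_arm) {
    p$O7 <- place_atom(p$C2, p$C3, p$C4, 1.37, 120, 180)
    p$C8 <- place_atom(p$C3, p$C4, p$O7, 1.43, 117, 180)
    p$NN <- place_atom(p$C4, p$O7, p$C8, 1.49, 112, 180)
    p$ON1 <- place_atom(p$O7, p$C8, p$NN, 1.22, 119, 0)
    p$ON2 <- place_atom(p$O7, p$C8, p$NN, 1.22, 119, 180)
    bonds <- rbind(bonds, c("C4", "O7"), c("O7", "C8"), c("C8", "NN"),
                   c("NN", "ON1"), c("NN", "ON2"))
    dihedrals$chi3 <- c("C3", "C4", "O7", "C8")
    dihedrals$chi4 <- c("C4", "O7", "C8", "NN")
    dihedrals$chi5 <- c("O7", "C8", "NN", "ON1")
    polar$nitro <- c("NN", "ON1", "ON2")
  }
  nm <- names(p)
  el <- substr(nm, 1L, 1L)
  atoms <- data.frame(name = nm, element = el,
                      x = vapply(p, `[`, numeric(1), 1L),
                      y = vapply(p, `[`, numeric(1), 2L),
                      z = vapply(p, `[`, numeric(1), 3L),
                      stringsAsFactors = FALSE)
  ligand_template(atoms, bonds, dihedrals,
                  core_atoms = c("N", "CA", "C", "O", "OXT", "CB",
                                 "C1", "C2", "C3", "C4", "C5", "C6"),
                  polar_groups = polar)
}

# residue atom rows for the scaffold table
residue_rows <- function(resno, aa, coords) {
  nm <- names(coords)
  data.frame(type = "ATOM", eleno = 0L, elety = nm, alt = "",
             resid = aa_123(aa), chain = "A", resno = as.integer(resno),
             x = vapply(coords, `[`, numeric(1), 1L),
             y = vapply(coords, `[`, numeric(1), 2L),
             z = vapply(coords, `[`, numeric(1), 3L),
             o = 1, b = 0, elesy = substr(nm, 1L, 1L),
             stringsAsFactors = FALSE)
}

# Backward-build a serine-like residue whose OG sits at `term`, approaching
# along -u (unit), with chi1 exactly on the -60 rotamer grid point.
plant_serine <- function(term, u, ref, torsion_ca = 75) {
  w <- unitv(crossp(u, if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
  v <- cos(deg2rad(150)) * (-u) + sin(deg2rad(150)) * w
  OG <- term
  CB <- OG + STUB_BOND * v
  CA <- place_atom(ref, OG, CB, CB_BOND, STUB_ANGLE, torsion_ca)
  N <- place_atom(OG, CB, CA, 1.46, CB_ANGLE, -60)
  C <- place_atom(OG, CB, CA, 1.52, 112, wrap_angle(-60 + 122))
  O <- place_atom(N, CA, C, 1.23, 120, 0)
  list(N = N, CA = CA, C = C, O = O, CB = CB, OG = OG)
}

# Backward-build a glutamine-like catalytic residue with terminal OE1 at
# `term` (used in its native rotamer only, so torsions are unconstrained).
plant_glutamine <- function(term, u, ref) {
  w <- unitv(crossp(u, if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
  v <- cos(deg2rad(150)) * (-u) + sin(deg2rad(150)) * w
  OE1 <- term
  CD <- OE1 + STUB_BOND * v
  CG <- place_atom(ref, OE1, CD, STUB_BOND, STUB_ANGLE, 65)
  CB <- place_atom(OE1, CD, CG, STUB_BOND, STUB_ANGLE, -170)
  CA <- place_atom(CD, CG, CB, CB_BOND, STUB_ANGLE, 170)
  N <- place_atom(CG, CB, CA, 1.46, CB_ANGLE, -65)
  C <- place_atom(CG, CB, CA, 1.52, 112, wrap_angle(-65 + 122))
  O <- place_atom(N, CA, C, 1.23, 120, 0)
  list(N = N, CA = CA, C = C, O = O, CB = CB, CG = CG, CD = CD, OE1 = OE1)
}

# alanine decoy with CB at min distance `target` from the ligand along a
# sampled direction; rejects placements whose CB could reach any ligand
# polar atom with a serine hydroxyl (distance <= 4.9 A) or that crowd
# previously placed atoms.
plant_decoy <- function(lig_xyz, polar_xyz, placed_xyz, target,
                        max_tries = 400L) {
  centroid <- colMeans(lig_xyz)
  for (i in seq_len(max_tries)) {
    u <- stats::rnorm(3)
    u <- unitv(u)
    lo <- 0
    hi <- target + 30
    for (it in 1:60) {
      s <- (lo + hi) / 2
      d <- min(cross_dist(rbind(centroid + s * u), lig_xyz))
      if (d < target) lo <- s else hi <- s
    }
    CB <- centroid + hi * u
    if (min(cross_dist(rbind(CB), polar_xyz)) <= 4.9) next
    if (!is.null(placed_xyz) && nrow(placed_xyz) &&
        min(cross_dist(rbind(CB), placed_xyz)) < 3.6) next
    w <- unitv(crossp(u, if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
    CA <- CB + CB_BOND * u
    N <- CA + 1.46 * (cos(deg2rad(110.5)) * (-u) + sin(deg2rad(110.5)) * w)
    w2 <- rotate_points(rbind(w), c(0, 0, 0), u, 120)[1L, ]
    C <- CA + 1.52 * (cos(deg2rad(109)) * (-u) + sin(deg2rad(109)) * w2)
    O <- place_atom(N, CA, C, 1.23, 120, 180)
    return(list(N = N, CA = CA, C = C, O = O, CB = CB))
  }
  stop("placement error: could not place a decoy at ", target, " Angstrom")
}

#' Generate a toy pocket scaffold with planted ground truth
#'
#' Builds a pocket around the bound toy ligand: a catalytic glutamine
#' hydrogen-bonding the carboxylate (the native-rotamer match constraint),
#' two fixed serines anchoring the ligand peptide backbone, the requested
#' number of serine-satisfiable sites for the nitro and m-hydroxy
#' constraints (planted exactly on the -60 chi1 rotamer), and apolar decoy
#' residues in declared distance bands that provably cannot satisfy any
#' constraint.  The finished pocket is subjected to a seeded rigid motion.
#'
#' @param recipe A `fixture_recipe`.
#' @return List with `scaffold`, `template`, `native_chi`, `constraints`
#'   (carboxylate + nitro + m-hydroxy), `backbone_constraints` (the two
#'   peptide-backbone anchors), and `manifest` (planted shells, satisfiable
#'   sites, expected match signatures).
#' @export
make_toy_scaffold <- function(recipe = fixture_recipe()) {
  template <- toy_ligand()
  conf <- make_conformer(template, recipe$native_chi)
  lig <- conf$xyz
  hv <- heavy_names(template)
  lig_hv <- lig[hv, , drop = FALSE]
  polar_atoms <- unique(unlist(template$polar_groups))
  polar_xyz <- lig[c(polar_atoms, "N"), , drop = FALSE]

  rows <- list()
  planted <- list()
  add_res <- function(resno, aa, coords) {
    rows[[length(rows) + 1L]] <<- residue_rows(resno, aa, coords)
  }

  with_seed(recipe$seed, {
    # catalytic glutamine vs the carboxylate (native rotamer)
    u <- unitv(lig["OXT", ] - lig["C", ])
    add_res(173, "Q", plant_glutamine(lig["OXT", ] + 2.9 * u, u, lig["C", ]))
    # peptide-backbone anchors (fixed catalytic serines)
    u_o <- unitv(lig["O", ] - lig["C", ])
    add_res(151, "S", plant_serine(lig["O", ] + 2.85 * u_o, u_o, lig["C", ]))
    u_n <- unitv(lig["N", ] - lig["CA", ])
    add_res(155, "S", plant_serine(lig["N", ] + 2.95 * u_n, u_n, lig["CA", ]))
    # serine-satisfiable nitro sites: approach along the N-O bond extensions
    nitro_targets <- list(
      list(atom = "ON1", u = unitv(lig["ON1", ] - lig["NN", ]), tca = 60),
      list(atom = "ON2", u = unitv(lig["ON2", ] - lig["NN", ]), tca = 60),
      list(atom = "ON1",
           u = unitv(rotate_points(rbind(lig["ON1", ] - lig["NN", ]),
                                   c(0, 0, 0),
                                   lig["ON1", ] - lig["ON2", ], 35)[1L, ]),
           tca = -60))
    nitro_resno <- c(167, 165, 180)[seq_len(recipe$nitro_sites)]
    for (j in seq_along(nitro_resno)) {
      tg <- nitro_targets[[j]]
      add_res(nitro_resno[j], "A",
              plant_serine(lig[tg$atom, ] + 2.9 * tg$u, tg$u, lig["NN", ],
                           torsion_ca = tg$tca))
    }
    hydroxy_resno <- integer()
    if (recipe$hydroxy_sites >= 1L) {
      u_m <- unitv(lig["OM", ] - lig["C3", ])
      hydroxy_resno <- 158L
      add_res(158, "A", plant_serine(lig["OM", ] + 2.9 * u_m, u_m,
                                     lig["C3", ], torsion_ca = 120))
    }
    # planted-site wild types are alanine: the satisfiable geometry lives on
    # the backbone, to be discovered by the rotamer search
    placed <- do.call(rbind, lapply(rows, function(r)
      as.matrix(r[, c("x", "y", "z")])))
    decoys <- list(first = list(resno = c(32, 65, 70),
                                d = recipe$first_shell_dists),
                   second = list(resno = c(105, 109, 154),
                                 d = recipe$second_shell_dists),
                   distant = list(resno = c(200, 201),
                                  d = recipe$distant_dists))
    for (band in decoys) {
      for (j in seq_along(band$resno)) {
        if (j > length(band$d)) break
        res <- plant_decoy(lig_hv, polar_xyz, placed, band$d[j])
        add_res(band$resno[j], "A", res)
        placed <- rbind(placed, do.call(rbind, res))
      }
    }
    # ligand as the bound substrate anchor
    tmplat <- template$atoms
    ligrow <- data.frame(type = "HETATM", eleno = 0L, elety = tmplat$name,
                         alt = "", resid = "LIG", chain = "A", resno = 500L,
                         x = lig[tmplat$name, 1L], y = lig[tmplat$name, 2L],
                         z = lig[tmplat$name, 3L], o = 1, b = 0,
                         elesy = tmplat$element, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- ligrow
    planted$nitro <- nitro_resno
    planted$hydroxy <- hydroxy_resno
  })

  scaffold <- structure(list(atoms = recompute_motion(rows, recipe$seed),
                             anchor = list(chain = "A", resno = 500L,
                                           resname = "LIG"),
                             fixed_positions = c(151L, 155L, 173L),
                             note = "synthetic fixture; stub side chains"),
                        class = "scaffold")
  pose <- anchor_superpose(conf, scaffold)
  constraints <- list(
    c1 = native_constraint(scaffold, pose, 173, c("O", "OXT"),
                           rotamer_policy = "native", name = "carboxylate"),
    c2 = hbond_constraint("nitro", "S", name = "nitro"),
    c3 = hbond_constraint("m_hydroxy", "S", name = "m_hydroxy"))
  bb1 <- native_constraint(scaffold, pose, 151, "O", name = "bb_O")
  bb1$position <- 151L
  bb2 <- native_constraint(scaffold, pose, 155, "N", name = "bb_N")
  bb2$position <- 155L
  shells <- shell_positions(scaffold, pose, 6, 9)
  sat <- expand.grid(resno = planted$nitro, constraint = "nitro",
                     identity = "S", stringsAsFactors = FALSE)
  if (length(planted$hydroxy)) {
    sat <- rbind(sat, data.frame(resno = planted$hydroxy,
                                 constraint = "m_hydroxy", identity = "S",
                                 stringsAsFactors = FALSE))
  }
  hyd <- if (length(planted$hydroxy)) planted$hydroxy else integer()
  sigs <- if (length(hyd)) {
    sort(vapply(planted$nitro, function(rn) {
      paste(sort(c("173:Q", paste0(rn, ":S"), paste0(hyd, ":S"))),
            collapse = "+")
    }, ""))
  } else {
    sort(vapply(planted$nitro, function(rn) {
      paste(sort(c("173:Q", paste0(rn, ":S"))), collapse = "+")
    }, ""))
  }
  manifest <- list(first_shell = sort(shells$first$resno),
                   second_shell = sort(shells$second$resno),
                   satisfiable = sat,
                   n_expected_matches = length(planted$nitro),
                   expected_signatures = sigs,
                   seed = recipe$seed)
  out <- list(scaffold = scaffold, template = template,
              native_chi = recipe$native_chi, native_conformer = conf,
              pose = pose, constraints = constraints,
              backbone_constraints = list(bb1, bb2), manifest = manifest)
  # integrity assertion: the planted truth must be recoverable
  ens1 <- new_ensemble(list(conf))
  found <- find_matches(scaffold, ens1,
                        if (length(hyd)) constraints else constraints[1:2])
  if (!identical(sort(vapply(found, function(m) m$signature, "")), sigs)) {
    stop("placement error: planted matches are not recoverable (seed ",
         recipe$seed, ")")
  }
  out
}

recompute_motion <- function(rows, seed) {
  at <- do.call(rbind, rows)
  with_seed(seed + 424243L, {
    ax <- unitv(stats::rnorm(3))
    th <- stats::runif(1, 0, 360)
    tr <- stats::runif(3, -5, 5)
    xyz <- as.matrix(at[, c("x", "y", "z")])
    xyz <- sweep(rotate_points(xyz, colMeans(xyz), ax, th), 2L, tr, "+")
    at$x <- xyz[, 1L]; at$y <- xyz[, 2L]; at$z <- xyz[, 3L]
  })
  at$eleno <- seq_len(nrow(at))
  rownames(at) <- NULL
  at
}

#' Generate a sequence profile with planted curation behaviour
#'
#' @param kind `"table1"` builds a 26-position, 49-model profile constructed
#'   backwards from the published curated library so that
#'   [curate_profile()] under the returned rules reproduces the published
#'   allowed sets exactly; `"raw26"` plants 26 positions whose observed
#'   identity-set sizes multiply to exactly 8.4e17; `"minimal"` is a single
#'   position.
#' @param seed Seed for count jitter.
#' @return List with `profile`, `rules`, `wild_type` and (for `"table1"`)
#'   `target` (the published `library_spec`).
#' @export
make_toy_profile <- function(kind = c("table1", "raw26", "minimal"),
                             seed = 1) {
  kind <- match.arg(kind)
  if (kind == "minimal") {
    prof <- compile_profile(matrix("A", 1, 1, dimnames = list(NULL, "1")),
                            wild_type = c(`1` = "A"))
    return(list(profile = prof, rules = curation_rules(),
                wild_type = c(`1` = "A")))
  }
  if (kind == "raw26") {
    sizes <- c(rep(10L, 16L), 14L, 6L, rep(1L, 8L))  # product = 8.4e17
    seqs <- with_seed(seed, {
      cols <- lapply(seq_along(sizes), function(i) {
        ids <- sample(AA1, sizes[i])
        sample(rep(ids, length.out = 49L))
      })
      do.call(cbind, cols)
    })
    colnames(seqs) <- paste0("p", seq_along(sizes))
    wild <- stats::setNames(seqs[1L, ], colnames(seqs))
    prof <- compile_profile(seqs, wild_type = wild)
    return(list(profile = prof, rules = curation_rules(),
                wild_type = wild))
  }
  # kind == "table1": inverse-construct 49 draws at the 17 published
  # positions (plus 9 positions that curate back to wild type)
  tab <- onby_library_table()
  n_models <- 49L
  counts <- list()
  for (p in names(tab$wild_type)) {
    allowed <- tab$spec$positions[[p]]$allowed
    wt <- tab$wild_type[[p]]
    reinstated <- p == "65"  # wild-type leucine re-added for substrate
                             # compatibility; I would collapse with it
    natural <- if (reinstated) setdiff(allowed, wt) else allowed
    cnt <- stats::setNames(rep(3L, length(natural)), natural)
    cnt[1L] <- cnt[1L] + (n_models - sum(cnt))
    if (p == "70") cnt <- c(cnt, T = 3L)   # similarity collapse: S beats T
    if (p == "70") cnt["A"] <- cnt["A"] - 3L
    if (!(wt %in% names(cnt)) && !reinstated) {
      cnt <- c(cnt, stats::setNames(2L, wt))  # below the 5% threshold
      cnt[which.max(cnt)] <- cnt[which.max(cnt)] - 2L
    }
    # at 70 the S/T collapse resolves by the alphabetical tie-break
    stopifnot(sum(cnt) == n_models, all(cnt >= 1L))
    counts[[p]] <- cnt
  }
  # distal position 66: conservative I removed by rule; rest wild type
  counts[["66"]] <- c(L = 45L, I = 4L)
  extra_wt <- c(`66` = "L", `33` = "G", `68` = "V", `71` = "D", `106` = "E",
                `110` = "K", `160` = "F", `163` = "N", `186` = "P")
  for (p in setdiff(names(extra_wt), "66")) {
    counts[[p]] <- stats::setNames(c(47L, 2L), c(extra_wt[[p]],
                                                 if (extra_wt[[p]] == "A") "G" else "A"))
  }
  wild <- c(tab$wild_type, extra_wt)
  seqs <- do.call(cbind, lapply(names(counts), function(p) {
    rep(names(counts[[p]]), counts[[p]])
  }))
  colnames(seqs) <- names(counts)
  prof <- compile_profile(seqs, wild_type = wild)
  rules <- curation_rules(min_frequency = 0.05,
                          distal_conservative_removals = list(`66` = "I"),
                          wt_reinstatement_positions = "65")
  list(profile = prof, rules = rules, wild_type = wild, target = tab$spec)
}
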