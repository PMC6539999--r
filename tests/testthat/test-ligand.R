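# six-atom chain template used by the topology tests
chain6 <- function() {
  xyz <- matrix(0, 6, 3)
  xyz[1, ] <- c(0, 0, 0)
  for (i in 2:6) {
    xyz[i, ] <- xyz[i - 1, ] + c(1.5, 0, 0)
    if (i %% 2 == 0) xyz[i, ] <- xyz[i, ] + c(0, 0.8, 0)
  }
  atoms <- data.frame(name = paste0("A", 1:6), element = "C",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  bonds <- cbind(paste0("A", 1:5), paste0("A", 2:6))
  list(atoms = atoms, bonds = bonds)
}

test_that("dihedral rotation partitions a chain into fixed and mobile sets", {
  ch <- chain6()
  tl <- ligand_template(ch$atoms, ch$bonds,
                        dihedral_defs = list(chi1 = c("A1", "A2", "A3", "A4")))
  expect_s3_class(tl, "ligand_template")
  expect_length(tl$dihedral_defs, 1)
  expect_setequal(tl$mobile$chi1, c("A4", "A5", "A6"))
  # rotating chi1 moves only the mobile atoms
  cf <- make_conformer(tl, c(chi1 = 55))
  moved <- rowSums(abs(cf$xyz - tl$xyz)) > 1e-9
  expect_setequal(names(which(moved)), c("A4", "A5", "A6"))
})

test_that("template validation rejects malformed definitions", {
  ch <- chain6()
  bad <- ch$atoms
  bad$name[2] <- "A1"
  expect_error(ligand_template(bad, ch$bonds), "duplicate atom name")
  expect_error(ligand_template(ch$atoms, ch$bonds,
                               dihedral_defs = list(chi1 = c("A1", "A2",
                                                             "A3", "ZZ"))),
               "unknown atom")
  expect_error(ligand_template(ch$atoms, ch$bonds[1:3, ]), "disconnected")
  expect_error(ligand_template(ch$atoms, ch$bonds,
                               dihedral_defs = list(chi1 = c("A1", "A3",
                                                             "A2", "A4"))),
               "not bonded in sequence")
})

test_that("photocaged-ligand template declares five dihedrals and core atoms", {
  tl <- toy_ligand()
  expect_named(tl$dihedral_defs, paste0("chi", 1:5))
  expect_true(all(c("N", "CA", "C", "CB", "C1", "C6") %in% tl$core_atoms))
  expect_setequal(tl$polar_groups$nitro, c("NN", "ON1", "ON2"))
  noarm <- toy_ligand(caging_arm = FALSE)
  expect_named(noarm$dihedral_defs, c("chi1", "chi2"))
  expect_null(noarm$polar_groups$nitro)
})

test_that("conformers are rigid and chi values round-trip from coordinates", {
  tl <- toy_ligand()
  ens <- sample_conformers(tl, fixed_chi = c(chi1 = -167, chi2 = 76),
                           sampled_chi = list(chi3 = seq(-180, 120, 60),
                                              chi4 = seq(-180, 120, 60),
                                              chi5 = seq(-180, 120, 60)),
                           n = 40, seed = 3)
  b <- tl$bonds
  ref_len <- vapply(seq_len(nrow(b)), function(i)
    focuslib:::vnorm(tl$xyz[b[i, 1], ] - tl$xyz[b[i, 2], ]), numeric(1))
  for (m in ens$members[c(1, 17, 40)]) {
    len <- vapply(seq_len(nrow(b)), function(i)
      focuslib:::vnorm(m$xyz[b[i, 1], ] - m$xyz[b[i, 2], ]), numeric(1))
    expect_lt(max(abs(len - ref_len)), 1e-6)
    remeasured <- measure_chi(m$xyz, tl)
    expect_lt(max(abs(wrap_angle(remeasured - m$chi))), 1e-3)
  }
  # bond angles are template-identical too (spot check one per member)
  ang <- function(x) bond_angle(x["CA", ], x["CB", ], x["C1", ])
  expect_equal(ang(ens$members[[5]]$xyz), ang(tl$xyz), tolerance = 1e-4)
})

test_that("sampling honours n, fixed chis, distinctness and the seed", {
  tl <- toy_ligand()
  grids <- list(chi3 = seq(-180, 150, 30), chi4 = seq(-180, 150, 30),
                chi5 = seq(-180, 150, 30))
  e1 <- sample_conformers(tl, c(chi1 = -167, chi2 = 76), grids, n = 60,
                          seed = 9)
  e2 <- sample_conformers(tl, c(chi1 = -167, chi2 = 76), grids, n = 60,
                          seed = 9)
  expect_length(e1, 60)
  expect_identical(ensemble_chi(e1), ensemble_chi(e2))
  chi <- ensemble_chi(e1)
  expect_true(all(abs(chi[, "chi1"] + 167) < 1e-9))
  expect_true(all(abs(chi[, "chi2"] - 76) < 1e-9))
  # pairwise distinct within the 1-degree tolerance
  sub <- chi[, c("chi3", "chi4", "chi5")]
  dup <- FALSE
  for (i in seq_len(nrow(sub) - 1)) {
    d <- abs(wrap_angle(sweep(sub[-seq_len(i), , drop = FALSE], 2,
                              sub[i, ])))
    if (any(apply(d, 1, max) <= 1)) dup <- TRUE
  }
  expect_false(dup)
  # single-outcome case
  e3 <- sample_conformers(tl, c(chi1 = -167, chi2 = 76),
                          list(chi3 = 180, chi4 = 180, chi5 = 90), n = 1,
                          seed = 1)
  expect_length(e3, 1)
  expect_equal(unname(wrap_angle(e3$members[[1]]$chi[c("chi3", "chi4",
                                                       "chi5")])),
               c(-180, -180, 90), tolerance = 1e-6)
  # exhaustion reports the achievable count
  expect_error(sample_conformers(tl, c(chi1 = -167, chi2 = 76),
                                 list(chi3 = c(0, 120), chi4 = 0, chi5 = 0),
                                 n = 5, seed = 1, jitter = 0),
               "sampling-exhausted")
})

test_that("clashing chi combinations are rejected, matching a brute-force scan", {
  # four-atom arm on a T-shaped molecule: chi values near 90 swing the tip
  # into a planted blocker atom riding on the same rotation circle
  B1 <- c(0, 0, 0)
  B2 <- c(1.5, 0, 0)
  B3 <- B2 + 1.5 * c(cos(70 * pi / 180), sin(70 * pi / 180), 0)
  T1 <- place_atom(B1, B2, B3, 1.5, 109, 0)
  T2 <- place_atom(B1, B2, B3, 2.6, 109, 90)
  a <- data.frame(name = c("B1", "B2", "B3", "T1", "T2"),
                  element = "C",
                  x = c(B1[1], B2[1], B3[1], T1[1], T2[1]),
                  y = c(B1[2], B2[2], B3[2], T1[2], T2[2]),
                  z = c(B1[3], B2[3], B3[3], T1[3], T2[3]))
  bonds <- rbind(c("B1", "B2"), c("B2", "B3"), c("B3", "T1"), c("B1", "T2"))
  tl <- ligand_template(a, bonds,
                        dihedral_defs = list(chi1 = c("B1", "B2", "B3", "T1")))
  grid <- seq(-180, 150, 30)
  clash_free <- vapply(grid, function(g) {
    cf <- make_conformer(tl, c(chi1 = g))
    # brute-force min distance over non-bonded, non-1-3 pairs: here only
    # T1 vs T2 and T1 vs B1 qualify beyond graph distance 2
    min(focuslib:::vnorm(cf$xyz["T1", ] - cf$xyz["T2", ])) >= 2.4
  }, logical(1))
  n_ok <- sum(clash_free)
  expect_lt(n_ok, length(grid))  # the blocker removes at least one
  ens <- sample_conformers(tl, fixed_chi = numeric(),
                           sampled_chi = list(chi1 = grid), n = n_ok,
                           seed = 4, jitter = 0)
  got <- sort(round(ensemble_chi(ens)[, "chi1"]))
  expect_equal(got, sort(grid[clash_free]))
})

test_that("chi2 flip doubles the ensemble and preserves everything else", {
  tl <- toy_ligand()
  ens <- sample_conformers(tl, c(chi1 = -167, chi2 = 76),
                           list(chi3 = seq(-180, 150, 30),
                                chi4 = seq(-180, 150, 30),
                                chi5 = seq(-180, 150, 30)),
                           n = 25, seed = 5)
  full <- flip_chi2(ens)
  expect_length(full, 50)
  chi <- ensemble_chi(full)
  for (i in 1:25) {
    expect_equal(unname(wrap_angle(chi[25 + i, "chi2"] - chi[i, "chi2"] -
                                     180)), 0, tolerance = 1e-6)
    expect_equal(chi[25 + i, c("chi1", "chi3", "chi4", "chi5")],
                 chi[i, c("chi1", "chi3", "chi4", "chi5")],
                 tolerance = 1e-6)
  }
  # originals preserved in order
  expect_identical(ensemble_chi(ens), chi[1:25, ])
  # empty ensemble flips to empty
  empty <- focuslib:::new_ensemble(list())
  expect_length(flip_chi2(empty), 0)
  # single-conformer arithmetic: 30 flips to -150, bonds identical
  one <- make_conformer(tl, c(chi1 = -167, chi2 = 30, chi3 = 0, chi4 = 0,
                              chi5 = 0))
  pair <- flip_chi2(focuslib:::new_ensemble(list(one)))
  expect_equal(unname(pair$members[[2]]$chi["chi2"]), -150, tolerance = 1e-6)
  b <- tl$bonds
  for (k in c(1, 8, nrow(b))) {
    expect_equal(focuslib:::vnorm(pair$members[[2]]$xyz[b[k, 1], ] -
                                    pair$members[[2]]$xyz[b[k, 2], ]),
                 focuslib:::vnorm(one$xyz[b[k, 1], ] - one$xyz[b[k, 2], ]),
                 tolerance = 1e-6)
  }
})

test_that("template and ensemble serialization round-trip through their readers", {
  tl <- toy_ligand()
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_ligand_template(tl, tf)
  t2 <- read_ligand_template(tf)
  expect_lt(max(abs(t2$xyz - tl$xyz)), 1e-9)
  expect_identical(t2$dihedral_defs, tl$dihedral_defs)
  expect_identical(sort(t2$core_atoms), sort(tl$core_atoms))
  ens <- sample_conformers(tl, c(chi1 = -167, chi2 = 76),
                           list(chi3 = c(-120, 0, 120), chi4 = c(-120, 0, 120),
                                chi5 = c(-120, 0, 120)), n = 6, seed = 2)
  pf <- withr::local_tempfile(fileext = ".pdb")
  write_conformers_pdb(ens, pf)
  expect_true(file.exists(paste0(pf, ".chi.tsv")))
  e2 <- read_conformers_pdb(pf, tl)
  expect_length(e2, 6)
  # PDB coordinates carry 3 decimals, so chi agree to ~0.1 degree
  expect_lt(max(abs(wrap_angle(ensemble_chi(e2) - ensemble_chi(ens)))), 0.1)
})
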