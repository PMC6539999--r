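# designer tests use an uncrowded single-nitro-site pocket so that small
# state spaces stay exhaustively enumerable
quiet_fixture <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- make_toy_scaffold(fixture_recipe(seed = 2,
                                                             nitro_sites = 1))
    fx
  }
})

quiet_match <- local({
  ms <- NULL
  function() {
    if (is.null(ms)) {
      fx <- quiet_fixture()
      ms <<- find_matches(fx$scaffold, get_native_ensemble(fx),
                          fx$constraints)
    }
    ms
  }
})

test_that("designable shell positions honour radius, fixed and match exclusions", {
  fx <- quiet_fixture()
  sh <- shell_positions(fx$scaffold, fx$pose, 6, 9)
  both <- sort(c(sh$first$resno, sh$second$resno))
  m <- quiet_match()[[1]]
  des <- designable_positions(fx$scaffold, fx$pose, radius = 9,
                              exclude = m$assignments$resno)
  expect_setequal(des, setdiff(both, m$assignments$resno))
  # fixed positions can be overridden explicitly
  des2 <- designable_positions(fx$scaffold, fx$pose, radius = 9,
                               fixed = integer())
  expect_true(all(fx$scaffold$fixed_positions %in% des2))
  # a tiny radius leaves nothing designable
  expect_length(designable_positions(fx$scaffold, fx$pose, radius = 2.5), 0)
})

test_that("steric well boundary and constraint midpoints score zero", {
  # repulsion vanishes at (and beyond) the sum of vdW radii
  expect_equal(focuslib:::lj_repulsion(3.4, 3.4), 0)
  expect_equal(focuslib:::lj_repulsion(2.72, 3.4), 0)  # the 0.8 boundary
  expect_gt(focuslib:::lj_repulsion(2.5, 3.4), 0)
  # attraction is the flat well inside r0, an LJ tail outside
  expect_equal(focuslib:::lj_attraction(3.0, 3.4), -0.2)
  expect_equal(focuslib:::lj_attraction(3.4, 3.4), -0.2, tolerance = 1e-9)
  expect_gt(focuslib:::lj_attraction(5.0, 3.4), -0.2)
  # inside every declared range the constraint penalty is exactly zero
  cst <- hbond_constraint("x", "S")
  geom <- list(distance = 2.9, donor_angle = 150, acceptor_angle = 150)
  expect_equal(focuslib:::constraint_penalty(geom, cst), 0)
  geom$distance <- 3.5
  expect_equal(focuslib:::constraint_penalty(geom, cst), 1 * 0.3^2)
})

test_that("component scores agree with a hand-rolled evaluator", {
  fx <- quiet_fixture()
  m <- quiet_match()[[1]]
  mod <- redesign(m, fx$scaffold, params = anneal_params(sweeps = 0),
                  alphabet = c("A", "S"))
  s <- mod$scores
  expect_equal(s$total, s$interface + s$internal + s$constraint,
               tolerance = 1e-9)
  # independent evaluator: plain double loops over the same physical terms
  ctx <- mod$.ctx
  w <- ctx$weights
  lj_pair <- function(d, r0) {
    rep_ <- if (d < 0.8 * r0) {
      x <- (0.8 * r0 / max(d, 0.3))^6
      w$eps * (x^2 - 2 * x + 1)
    } else 0
    atr <- if (d >= r0) {
      x <- (r0 / d)^6
      w$eps * (x^2 - 2 * x)
    } else -w$eps
    rep_ + atr
  }
  steric_sum <- function(xa, ra, xb, rb) {
    tot <- 0
    for (i in seq_len(nrow(xa))) {
      for (j in seq_len(nrow(xb))) {
        tot <- tot + lj_pair(sqrt(sum((xa[i, ] - xb[j, ])^2)),
                             ra[i] + rb[j])
      }
    }
    tot
  }
  interface <- 0
  for (k in names(mod$.state)) {
    e <- mod$.state[[k]]
    if (!nrow(e$xyz)) next
    interface <- interface +
      w$steric * steric_sum(e$xyz, e$radii, ctx$lig_xyz, ctx$lig_rad)
    for (la in ctx$lig_polar) {
      interface <- interface +
        w$hbond * focuslib:::pair_hbond(e, focuslib:::lig_polar_site(la))
    }
  }
  for (f in ctx$fixed_sc) {
    interface <- interface +
      w$steric * steric_sum(f$xyz, f$radii, ctx$lig_xyz, ctx$lig_rad)
    for (la in ctx$lig_polar) {
      interface <- interface +
        w$hbond * focuslib:::pair_hbond(f, focuslib:::lig_polar_site(la))
    }
  }
  expect_equal(s$interface, interface, tolerance = 1e-9)
})

test_that("steric energy is invariant under atom permutation", {
  set.seed(3)
  xa <- matrix(rnorm(12, sd = 3), 4, 3)
  xb <- matrix(rnorm(15, sd = 3), 5, 3)
  ra <- runif(4, 1.5, 2)
  rb <- runif(5, 1.5, 2)
  base <- focuslib:::steric_energy(xa, ra, xb, rb)
  p <- sample(4)
  q <- sample(5)
  expect_equal(focuslib:::steric_energy(xa[p, ], ra[p], xb[q, ], rb[q]),
               base, tolerance = 1e-12)
})

test_that("zero sweeps returns the scored wild-type state", {
  fx <- quiet_fixture()
  m <- quiet_match()[[1]]
  mod <- redesign(m, fx$scaffold, params = anneal_params(sweeps = 0, seed = 1))
  expect_identical(unname(mod$sequence), unname(mod$wild_type))
  expect_true(is.finite(mod$scores$total))
})

test_that("annealing finds the exhaustive-enumeration optimum on a small system", {
  fx <- quiet_fixture()
  m <- quiet_match()[[1]]
  des <- designable_positions(fx$scaffold, fx$pose, radius = 9,
                              exclude = m$assignments$resno)
  restr <- stats::setNames(rep(list("A"), length(des)), as.character(des))
  restr[["32"]] <- c("A", "S")  # 1 + 3 rotamers -> 4 states
  mod <- redesign(m, fx$scaffold, params = anneal_params(sweeps = 40, seed = 6),
                  alphabet = c("A", "S"), position_restrictions = restr)
  # exhaustive oracle over all four states at position 32
  ctx <- mod$.ctx
  best <- Inf
  best_state <- NULL
  cands <- c(list(list(aa = "A", chi = numeric())),
             lapply(c(-60, 60, 180), function(x) list(aa = "S", chi = x)))
  for (cd in cands) {
    st <- mod$.state
    st[["32"]] <- focuslib:::state_entry(ctx, "32", cd$aa, cd$chi)
    tot <- focuslib:::full_components(ctx, st)[["total"]]
    if (tot < best) {
      best <- tot
      best_state <- cd
    }
  }
  expect_equal(mod$scores$total, best, tolerance = 1e-9)
  expect_identical(mod$sequence[["32"]], best_state$aa)
})

test_that("redesign is deterministic and quenching never worsens the start", {
  fx <- quiet_fixture()
  m <- quiet_match()[[1]]
  m1 <- redesign(m, fx$scaffold, params = anneal_params(sweeps = 15, seed = 4),
                 alphabet = c("A", "S", "G"))
  m2 <- redesign(m, fx$scaffold, params = anneal_params(sweeps = 15, seed = 4),
                 alphabet = c("A", "S", "G"))
  expect_identical(serialize(m1, NULL), serialize(m2, NULL))
  init <- redesign(m, fx$scaffold, params = anneal_params(sweeps = 0),
                   alphabet = c("A", "S", "G"))
  for (seed in 1:5) {
    mm <- redesign(m, fx$scaffold,
                   params = anneal_params(sweeps = 10, seed = seed),
                   alphabet = c("A", "S", "G"))
    expect_lte(mm$scores$total, init$scores$total + 1e-9)
  }
})

test_that("a planted clashing bulky residue is designed away", {
  fx <- make_toy_scaffold(fixture_recipe(seed = 5, nitro_sites = 1))
  sc <- fx$scaffold
  # rebuild residue 32 (first shell) as a tryptophan-like stub pointing at
  # the ligand: pick the rotamer that digs deepest into the pocket
  bb <- focuslib:::backbone_frame(sc, 32)
  lib <- rotamer_library("W")$W
  lig <- focuslib:::pose_heavy_xyz(fx$pose)
  dmin <- apply(lib, 1, function(chi) {
    scx <- build_side_chain(bb$N, bb$CA, bb$CB, "W", chi, C = bb$C)
    min(focuslib:::cross_dist(scx, lig))
  })
  chi_bad <- lib[which.min(dmin), ]
  expect_lt(min(dmin), 2.5)  # it really clashes
  scx <- build_side_chain(bb$N, bb$CA, bb$CB, "W", chi_bad, C = bb$C)
  keep <- !(sc$atoms$resno == 32 & !(sc$atoms$elety %in% c("N", "CA", "C",
                                                           "O")))
  side <- scx[-1, , drop = FALSE]  # CB row kept from the backbone build
  cb_row <- sc$atoms[sc$atoms$resno == 32 & sc$atoms$elety == "CB", ]
  new_rows <- do.call(rbind, lapply(rownames(side), function(nm) {
    r <- cb_row
    r$elety <- nm
    r$x <- side[nm, 1]; r$y <- side[nm, 2]; r$z <- side[nm, 3]
    r$elesy <- substr(nm, 1, 1)
    r
  }))
  sc$atoms <- rbind(sc$atoms[keep | sc$atoms$elety == "CB", ], cb_row[0, ],
                    new_rows)
  sc$atoms$resid[sc$atoms$resno == 32] <- "TRP"
  sc$atoms$eleno <- seq_len(nrow(sc$atoms))
  ms <- find_matches(sc, get_native_ensemble(fx), fx$constraints)
  des <- designable_positions(sc, fx$pose, radius = 9,
                              exclude = ms[[1]]$assignments$resno)
  restr <- stats::setNames(rep(list("A"), length(des)), as.character(des))
  restr[["32"]] <- c("A", "W")
  init <- redesign(ms[[1]], sc, params = anneal_params(sweeps = 0),
                   alphabet = c("A", "W"), position_restrictions = restr)
  expect_identical(init$sequence[["32"]], "W")
  fin <- redesign(ms[[1]], sc, params = anneal_params(sweeps = 40, seed = 2),
                  alphabet = c("A", "W"), position_restrictions = restr)
  expect_lt(fin$scores$total, init$scores$total)
  # oracle: enumeration confirms the initial state is not minimal
  ctx <- init$.ctx
  states <- c(list(list(aa = "A", chi = numeric())),
              lapply(seq_len(nrow(rotamer_library("W")$W)), function(r)
                list(aa = "W", chi = rotamer_library("W")$W[r, ])))
  totals <- vapply(states, function(cd) {
    st <- init$.state
    st[["32"]] <- focuslib:::state_entry(ctx, "32", cd$aa, cd$chi)
    focuslib:::full_components(ctx, st)[["total"]]
  }, numeric(1))
  expect_lt(min(totals), init$scores$total - 1e-6)
  expect_equal(fin$scores$total, min(totals), tolerance = 1e-9)
})

test_that("the design stage produces n_matches x n_repeats models with provenance", {
  fx <- quiet_fixture()
  ms <- quiet_match()
  models <- run_design_stage(ms[1], fx$scaffold, n_repeats = 3,
                             params = anneal_params(sweeps = 3,
                                                    quench_passes = 1),
                             alphabet = c("A", "S"), base_seed = 11)
  expect_length(models, 3)
  models2 <- run_design_stage(rep(ms[1], 2), fx$scaffold, n_repeats = 3,
                              params = anneal_params(sweeps = 3,
                                                     quench_passes = 1),
                              alphabet = c("A", "S"), base_seed = 11)
  expect_length(models2, 6)
  prov <- lapply(models2, function(m)
    c(m$provenance$match_id, m$provenance$repeat_id))
  expect_equal(length(unique(prov)), 6)
  seeds <- vapply(models2, function(m) m$provenance$seed, numeric(1))
  expect_equal(length(unique(seeds)), 6)
  expect_length(run_design_stage(list(), fx$scaffold, n_repeats = 5), 0)
})

test_that("variant complex modeling reports planted hydrogen bonds", {
  fx <- quiet_fixture()
  mod <- model_variant_complex(fx$scaffold, c(`167` = "S"),
                               fx$native_conformer,
                               params = anneal_params(sweeps = 30, seed = 2))
  hb <- mod$hbonds
  expect_true(any(hb$a == "S167" & grepl("^LIG:ON", hb$b)))
  # native backbone anchors appear in the report
  expect_true(any(hb$a == "S151" & hb$b == "LIG:O"))
  expect_true(any(hb$a == "S155" & hb$b == "LIG:N"))
  # an all-alanine shell forms no ligand hydrogen bonds from those sites
  v <- c(`167` = "A", `32` = "A", `65` = "A", `70` = "A")
  mod2 <- model_variant_complex(fx$scaffold, v, fx$native_conformer,
                                params = anneal_params(sweeps = 5, seed = 2))
  expect_false(any(grepl("^A(167|32|65|70)$", mod2$hbonds$a) &
                     grepl("^LIG", mod2$hbonds$b)))
  expect_error(model_variant_complex(fx$scaffold, c(`999` = "S"),
                                     fx$native_conformer),
               "sequence error")
})
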