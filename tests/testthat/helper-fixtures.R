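# Shared fixtures (memoized: the pocket build runs its own integrity check,
# so rebuild it once) and independent oracles used across the suite.

.fixture_cache <- new.env()

get_fixture <- function(seed = 1) {
  key <- paste0("fx", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- make_toy_scaffold(fixture_recipe(seed = seed))
  }
  .fixture_cache[[key]]
}

get_native_ensemble <- function(fx) {
  sample_conformers(fx$template,
                    fixed_chi = fx$native_chi[c("chi1", "chi2")],
                    sampled_chi = as.list(fx$native_chi[c("chi3", "chi4",
                                                          "chi5")]),
                    n = 1, seed = 1, jitter = 0)
}

get_matches <- function(seed = 1) {
  key <- paste0("ms", seed)
  if (is.null(.fixture_cache[[key]])) {
    fx <- get_fixture(seed)
    .fixture_cache[[key]] <- find_matches(fx$scaffold,
                                          get_native_ensemble(fx),
                                          fx$constraints)
  }
  .fixture_cache[[key]]
}

## ---- independent geometry oracle ------------------------------------------

# dihedral via projection onto the plane normal to the axis, signed by a
# triple product (different derivation than the package's atan2-of-normals)
oracle_dihedral <- function(p1, p2, p3, p4) {
  axis <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  a <- p1 - p2
  b <- p4 - p3
  a_perp <- a - sum(a * axis) * axis
  b_perp <- b - sum(b * axis) * axis
  cosang <- sum(a_perp * b_perp) /
    sqrt(sum(a_perp^2) * sum(b_perp^2))
  ang <- acos(max(-1, min(1, cosang))) * 180 / pi
  tri <- det(rbind(a_perp, b_perp, axis))
  s <- if (tri < 0) -1 else 1
  v <- -s * ang
  ((v + 180) %% 360) - 180
}

oracle_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

## ---- independent brute-force matcher --------------------------------------

# Exhaustive enumeration over (position x identity x rotamer) tuples with its
# own geometry evaluation, clash test and combination logic.  Shares only the
# stub-world definition (build_side_chain, rotamer_library) with the package.
oracle_match_signatures <- function(scaffold, ensemble, constraints,
                                    rotamers = rotamer_library(),
                                    clash_factor = 0.8) {
  sigs <- character()
  pos <- focuslib:::scaffold_positions(scaffold)
  for (conf in ensemble$members) {
    pose <- anchor_superpose(conf, scaffold)
    tmpl <- conf$template
    el <- setNames(tmpl$atoms$element, tmpl$atoms$name)
    hv <- tmpl$atoms$name[toupper(tmpl$atoms$element) != "H"]
    ligxyz <- pose$xyz[hv, , drop = FALSE]
    ligrad <- unname(c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)[
      toupper(el[hv])])
    ligrad[is.na(ligrad)] <- 1.70
    neighbor1 <- function(a) {
      nb <- tmpl$bonds[tmpl$bonds[, 1] == a, 2]
      nb <- c(nb, tmpl$bonds[tmpl$bonds[, 2] == a, 1])
      nb[1]
    }
    cand_for <- function(cst) {
      grp <- cst$ligand_group
      atoms <- if (length(grp) == 1 && grp %in% names(tmpl$polar_groups)) {
        tmpl$polar_groups[[grp]]
      } else grp
      atoms <- atoms[toupper(el[atoms]) %in% c("N", "O", "S")]
      out <- list()
      for (i in seq_len(nrow(pos))) {
        rn <- pos$resno[i]
        if (cst$rotamer_policy == "native") {
          if (!(pos$aa[i] %in% cst$identities)) next
          sc <- focuslib:::native_side_xyz(scaffold, rn, pos$chain[i])
          if (nrow(sc) < 2) next
          cands <- list(list(aa = pos$aa[i], sc = sc))
        } else {
          if (rn %in% scaffold$fixed_positions) next
          bb <- focuslib:::backbone_frame(scaffold, rn, pos$chain[i])
          cands <- list()
          for (aa in cst$identities) {
            if (!(focuslib:::stub_is_donor(aa) ||
                    focuslib:::stub_is_acceptor(aa))) next
            rots <- rotamers[[aa]]
            for (r in seq_len(nrow(rots))) {
              sc <- build_side_chain(bb$N, bb$CA, bb$CB, aa, rots[r, ],
                                     C = bb$C)
              if (nrow(sc) >= 2) {
                cands[[length(cands) + 1]] <- list(aa = aa, sc = sc)
              }
            }
          }
        }
        for (cd in cands) {
          sc <- cd$sc
          term <- sc[nrow(sc), ]
          base <- sc[nrow(sc) - 1, ]
          scrad <- focuslib:::stub_params(cd$aa)$radius[seq_len(nrow(sc))]
          # own clash test (double loop)
          clash <- FALSE
          for (ai in seq_len(nrow(sc))) {
            for (bi in seq_len(nrow(ligxyz))) {
              if (sqrt(sum((sc[ai, ] - ligxyz[bi, ])^2)) <
                    clash_factor * (scrad[ai] + ligrad[bi])) {
                clash <- TRUE
                break
              }
            }
            if (clash) break
          }
          if (clash) next
          ok <- FALSE
          for (a in atoms) {
            la <- pose$xyz[a, ]
            lb <- pose$xyz[neighbor1(a), ]
            d <- sqrt(sum((term - la)^2))
            ang_res <- oracle_angle(base, term, la)
            ang_lig <- oracle_angle(lb, la, term)
            inr <- function(x, rg) x >= rg[1] && x <= rg[2]
            can_d <- focuslib:::stub_is_donor(cd$aa) &&
              inr(d, cst$distance) && inr(ang_res, cst$donor_angle) &&
              inr(ang_lig, cst$acceptor_angle)
            can_a <- focuslib:::stub_is_acceptor(cd$aa) &&
              inr(d, cst$distance) && inr(ang_lig, cst$donor_angle) &&
              inr(ang_res, cst$acceptor_angle)
            if (!is.null(cst$torsion)) {
              tor <- oracle_dihedral(base, term, la, lb)
              can_d <- can_d && inr(tor, cst$torsion)
              tor2 <- oracle_dihedral(lb, la, term, base)
              can_a <- can_a && inr(tor2, cst$torsion)
            }
            if (can_d || can_a) {
              ok <- TRUE
              break
            }
          }
          if (ok) {
            out[[length(out) + 1]] <- list(resno = rn, aa = cd$aa, sc = sc,
                                           rad = scrad)
          }
        }
      }
      out
    }
    cands <- lapply(constraints, cand_for)
    if (any(vapply(cands, length, 1L) == 0)) next
    recurse <- function(k, chosen) {
      if (k > length(cands)) {
        sig <- paste(sort(vapply(chosen, function(x)
          paste0(x$resno, ":", x$aa), "")), collapse = "+")
        sigs <<- c(sigs, sig)
        return(invisible(NULL))
      }
      for (cd in cands[[k]]) {
        if (any(vapply(chosen, function(x) x$resno, 1L) == cd$resno)) next
        bad <- FALSE
        for (x in chosen) {
          for (ai in seq_len(nrow(cd$sc))) {
            for (bi in seq_len(nrow(x$sc))) {
              if (sqrt(sum((cd$sc[ai, ] - x$sc[bi, ])^2)) <
                    clash_factor * (cd$rad[ai] + x$rad[bi])) {
                bad <- TRUE
                break
              }
            }
            if (bad) break
          }
          if (bad) break
        }
        if (!bad) recurse(k + 1, c(chosen, list(cd)))
      }
    }
    recurse(1, list())
  }
  sort(unique(sigs))
}

## ---- independent big-integer oracle ---------------------------------------

# schoolbook base-10 digit-string multiplication, unrelated to the package's
# base-1e4 representation
oracle_bigmul <- function(s, m) {
  digs <- rev(as.integer(strsplit(s, "")[[1]]))
  carry <- 0
  out <- integer()
  for (d in digs) {
    v <- d * m + carry
    out <- c(out, v %% 10)
    carry <- v %/% 10
  }
  while (carry > 0) {
    out <- c(out, carry %% 10)
    carry <- carry %/% 10
  }
  while (length(out) > 1 && out[length(out)] == 0) out <- out[-length(out)]
  paste(rev(out), collapse = "")
}

oracle_bigproduct <- function(sizes) {
  s <- "1"
  for (m in sizes) s <- oracle_bigmul(s, m)
  s
}

# dummy triage models with planted scores/poses
planted_model <- function(id, interface = -1, constraint = 0, total = NULL,
                          ligand_xyz = NULL) {
  structure(list(id = id,
                 scores = list(interface = interface, internal = 0,
                               constraint = constraint,
                               total = if (is.null(total)) interface
                                       else total),
                 ligand_xyz = ligand_xyz),
            class = "design_model")
}
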