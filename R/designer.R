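# Active-site redesign: simulated-annealing packing of (identity, rotamer)
# choices at designable shell positions around each match, under the
# three-term score, with match assignments and catalytic positions held
# immutable.

#' Annealing parameters
#'
#' @param sweeps Number of annealing sweeps (one proposal per designable
#'   position per sweep). `0` scores the initial state without moving.
#' @param t_start,t_end Geometric cooling schedule endpoints, in score
#'   units.
#' @param quench_passes Maximum greedy zero-temperature passes after
#'   cooling.
#' @param seed Integer seed; identical inputs and seed give byte-identical
#'   results.
#' @return An object of class `anneal_params`.
#' @export
anneal_params <- function(sweeps = 200, t_start = 5, t_end = 0.1,
                          quench_passes = 5, seed = 1) {
  stopifnot(sweeps >= 0, t_start > 0, t_end > 0, t_end <= t_start)
  structure(list(sweeps = as.integer(sweeps), t_start = t_start,
                 t_end = t_end, quench_passes = as.integer(quench_passes),
                 seed = as.integer(seed)),
            class = "anneal_params")
}

#' Designable positions around a posed ligand
#'
#' Positions with any side-chain heavy atom (CB included) within `radius`
#' of any ligand heavy atom, minus fixed positions and minus explicitly
#' excluded (e.g. match-assigned) positions.
#'
#' @param scaffold A `scaffold`.
#' @param pose A `ligand_pose` or ligand coordinate matrix.
#' @param radius Design shell radius in Angstrom (default 9).
#' @param fixed Positions kept constant (defaults to the scaffold's fixed
#'   set).
#' @param exclude Additional excluded positions (e.g. match assignments).
#' @return Integer vector of residue numbers.
#' @export
designable_positions <- function(scaffold, pose, radius = 9,
                                 fixed = scaffold$fixed_positions,
                                 exclude = integer()) {
  stopifnot(radius > 0)
  lig <- pose_heavy_xyz(pose)
  pos <- scaffold_positions(scaffold)
  keep <- logical(nrow(pos))
  for (i in seq_len(nrow(pos))) {
    sc <- native_side_xyz(scaffold, pos$resno[i], pos$chain[i])
    if (!nrow(sc)) next
    keep[i] <- min(cross_dist(sc, lig)) < radius
  }
  setdiff(pos$resno[keep], c(fixed, exclude))
}

## ---- packing context -------------------------------------------------------

# Everything the annealer needs, precomputed: static environment atoms,
# ligand atoms and polar sites, fixed (match) side chains, and per-position
# backbone frames with allowed identities and rotamers.
make_pack_context <- function(scaffold, pose, design_positions, allowed,
                              match_sidechains = list(),
                              match_positions = integer(),
                              constraint_records = list(),
                              weights = score_weights(),
                              rotamers = rotamer_library(),
                              use_ligand = TRUE) {
  pos <- scaffold_positions(scaffold)
  mobile_set <- c(design_positions, match_positions)
  static_xyz <- NULL
  static_rad <- numeric()
  static_resno <- integer()
  for (i in seq_len(nrow(pos))) {
    at <- residue_atoms(scaffold, pos$resno[i], pos$chain[i])
    bb <- at[at$elety %in% BACKBONE_ATOMS, , drop = FALSE]
    add <- atoms_xyz(bb)
    rad <- element_radius(bb$elesy)
    if (!(pos$resno[i] %in% mobile_set)) {
      sc <- at[!(at$elety %in% BACKBONE_ATOMS) &
                 toupper(at$elesy) != "H", , drop = FALSE]
      if (nrow(sc)) {
        add <- rbind(add, atoms_xyz(sc))
        rad <- c(rad, element_radius(sc$elesy))
      }
    }
    static_xyz <- rbind(static_xyz, add)
    static_rad <- c(static_rad, rad)
    static_resno <- c(static_resno, rep(pos$resno[i], nrow(add)))
  }
  lig_xyz <- NULL
  lig_rad <- numeric()
  lig_polar <- list()
  if (use_ligand && !is.null(pose)) {
    tmpl <- pose$conformer$template
    hv <- heavy_names(tmpl)
    lig_xyz <- pose$xyz[hv, , drop = FALSE]
    lig_rad <- element_radius(tmpl$atoms$element[match(hv, tmpl$atoms$name)])
    pol <- hv[toupper(tmpl$atoms$element[match(hv, tmpl$atoms$name)]) %in%
                c("N", "O")]
    lig_polar <- lapply(pol, function(a) {
      nb <- igraph::neighbors(tmpl$graph, a)$name
      list(name = a, atom = pose$xyz[a, ], base = pose$xyz[nb[1L], ])
    })
  }
  positions <- lapply(design_positions, function(rn) {
    bb <- backbone_frame(scaffold, rn)
    aa_wt <- pos$aa[match(rn, pos$resno)]
    alw <- allowed[[as.character(rn)]]
    if (is.null(alw)) alw <- aa_wt
    for (aa in alw) {
      if (is.null(rotamers[[aa]])) {
        stop("configuration error: identity '", aa,
             "' has no rotamers in the rotamer set")
      }
    }
    list(resno = rn, bb = bb, wt = aa_wt, allowed = alw,
         native_chi = measure_stub_chi(scaffold, rn))
  })
  names(positions) <- as.character(design_positions)
  fixed_sc <- lapply(seq_along(match_sidechains), function(k) {
    sc <- match_sidechains[[k]]
    aa <- names(match_sidechains)[k]
    aa <- sub("^[0-9]+:", "", aa)
    list(xyz = sc$xyz, radii = sc$radii, resno = sc$resno, term = sc$term,
         base = sc$base, donor = sc$donor, acceptor = sc$acceptor,
         label = sc$label)
  })
  list(scaffold = scaffold, pose = pose, positions = positions,
       static_xyz = static_xyz, static_rad = static_rad,
       static_resno = static_resno,
       lig_xyz = lig_xyz, lig_rad = lig_rad, lig_polar = lig_polar,
       fixed_sc = fixed_sc, constraint_records = constraint_records,
       weights = weights, rotamers = rotamers)
}


# static environment atoms excluding a residue's own backbone (side chains
# are never scored against atoms of their own residue)
static_excl <- function(ctx, resno) {
  if (is.null(ctx$static_xyz)) {
    return(list(xyz = matrix(numeric(0), 0L, 3L), rad = numeric()))
  }
  keep <- ctx$static_resno != resno
  list(xyz = ctx$static_xyz[keep, , drop = FALSE],
       rad = ctx$static_rad[keep])
}

# One state entry: side-chain coordinates etc. for (position, identity, chi)
state_entry <- function(ctx, key, aa, chi) {
  p <- ctx$positions[[key]]
  sc <- build_side_chain(p$bb$N, p$bb$CA, p$bb$CB, aa, chi, C = p$bb$C)
  n <- nrow(sc)
  list(aa = aa, chi = chi, xyz = sc,
       radii = if (n) unname(stub_radii(aa))[seq_len(n)] else numeric(),
       term = if (n >= 2L && (stub_is_donor(aa) || stub_is_acceptor(aa)))
         sc[n, ] else NULL,
       base = if (n >= 2L) sc[n - 1L, ] else NULL,
       donor = stub_is_donor(aa), acceptor = stub_is_acceptor(aa))
}

# Best hydrogen-bond energy between two functional sites (either may act as
# donor where capable); 0 when no orientation is possible.
pair_hbond <- function(a, b) {
  if (is.null(a$term) || is.null(b$term)) return(0)
  d <- vnorm(a$term - b$term)
  if (d > 3.6) return(0)
  best <- 0
  if (a$donor && b$acceptor) {
    e <- hbond_energy(d, bond_angle(a$base, a$term, b$term),
                      bond_angle(b$base, b$term, a$term))
    best <- min(best, e)
  }
  if (b$donor && a$acceptor) {
    e <- hbond_energy(d, bond_angle(b$base, b$term, a$term),
                      bond_angle(a$base, a$term, b$term))
    best <- min(best, e)
  }
  best
}

lig_polar_site <- function(la) {
  list(term = la$atom, base = la$base, donor = TRUE, acceptor = TRUE)
}

# Energy of one position's side chain against its whole environment,
# split into c(interface, internal); pairs with other design positions are
# counted once here (correct for move deltas).
pos_energy <- function(ctx, state, key, entry) {
  w <- ctx$weights
  interface <- 0
  internal <- 0
  if (nrow(entry$xyz)) {
    if (!is.null(ctx$lig_xyz)) {
      interface <- interface +
        w$steric * steric_energy(entry$xyz, entry$radii, ctx$lig_xyz,
                                 ctx$lig_rad, w$eps, w$soft)
      for (la in ctx$lig_polar) {
        interface <- interface + w$hbond * pair_hbond(entry, lig_polar_site(la))
      }
    }
    env <- static_excl(ctx, ctx$positions[[key]]$resno)
    internal <- internal +
      w$steric * steric_energy(entry$xyz, entry$radii, env$xyz, env$rad,
                               w$eps, w$soft)
    for (f in ctx$fixed_sc) {
      internal <- internal +
        w$steric * steric_energy(entry$xyz, entry$radii, f$xyz, f$radii,
                                 w$eps, w$soft) +
        w$hbond * pair_hbond(entry, f)
    }
    for (other in setdiff(names(state), key)) {
      o <- state[[other]]
      if (!nrow(o$xyz)) next
      internal <- internal +
        w$steric * steric_energy(entry$xyz, entry$radii, o$xyz, o$radii,
                                 w$eps, w$soft) +
        w$hbond * pair_hbond(entry, o)
    }
  }
  internal <- internal + ifelse(is.na(w$reference[entry$aa]), 0,
                                w$reference[entry$aa])
  c(interface = unname(interface), internal = unname(internal))
}

# Full component breakdown of a packing state (pairs counted once).
full_components <- function(ctx, state) {
  w <- ctx$weights
  interface <- 0
  internal <- 0
  keys <- names(state)
  for (i in seq_along(keys)) {
    e <- state[[keys[i]]]
    if (!nrow(e$xyz)) {
      internal <- internal + ifelse(is.na(w$reference[e$aa]), 0,
                                    w$reference[e$aa])
      next
    }
    if (!is.null(ctx$lig_xyz)) {
      interface <- interface +
        w$steric * steric_energy(e$xyz, e$radii, ctx$lig_xyz, ctx$lig_rad,
                                 w$eps, w$soft)
      for (la in ctx$lig_polar) {
        interface <- interface + w$hbond * pair_hbond(e, lig_polar_site(la))
      }
    }
    env <- static_excl(ctx, ctx$positions[[keys[i]]]$resno)
    internal <- internal +
      w$steric * steric_energy(e$xyz, e$radii, env$xyz, env$rad,
                               w$eps, w$soft) +
      ifelse(is.na(w$reference[e$aa]), 0, w$reference[e$aa])
    for (f in ctx$fixed_sc) {
      internal <- internal +
        w$steric * steric_energy(e$xyz, e$radii, f$xyz, f$radii, w$eps, w$soft) +
        w$hbond * pair_hbond(e, f)
    }
    if (i < length(keys)) {
      for (j in (i + 1L):length(keys)) {
        o <- state[[keys[j]]]
        if (!nrow(o$xyz)) next
        internal <- internal +
          w$steric * steric_energy(e$xyz, e$radii, o$xyz, o$radii,
                                   w$eps, w$soft) +
          w$hbond * pair_hbond(e, o)
      }
    }
  }
  # fixed (match) side chains against ligand/static/each other: constant but
  # part of the reported totals
  for (k in seq_along(ctx$fixed_sc)) {
    f <- ctx$fixed_sc[[k]]
    if (!is.null(ctx$lig_xyz)) {
      interface <- interface +
        w$steric * steric_energy(f$xyz, f$radii, ctx$lig_xyz, ctx$lig_rad,
                                 w$eps, w$soft)
      for (la in ctx$lig_polar) {
        interface <- interface + w$hbond * pair_hbond(f, lig_polar_site(la))
      }
    }
    envf <- static_excl(ctx, if (is.null(f$resno)) -1L else f$resno)
    internal <- internal +
      w$steric * steric_energy(f$xyz, f$radii, envf$xyz, envf$rad,
                               w$eps, w$soft)
    if (k < length(ctx$fixed_sc)) {
      for (j in (k + 1L):length(ctx$fixed_sc)) {
        g <- ctx$fixed_sc[[j]]
        internal <- internal +
          w$steric * steric_energy(f$xyz, f$radii, g$xyz, g$radii,
                                   w$eps, w$soft) +
          w$hbond * pair_hbond(f, g)
      }
    }
  }
  cst <- 0
  for (rec in ctx$constraint_records) {
    geom <- evaluate_constraint(list(atom = rec$donor, base = rec$donor_base),
                                list(atom = rec$acceptor,
                                     base = rec$acceptor_base),
                                rec$constraint)$geometry
    cst <- cst + w$constraint *
      constraint_penalty(geom, rec$constraint, w$k_dist, w$k_angle)
  }
  comps <- c(interface = unname(interface), internal = unname(internal),
             constraint = unname(cst))
  c(comps, total = sum(comps))
}

# Core annealer: Metropolis over (identity, rotamer) proposals with a
# geometric cooling schedule, ending in greedy zero-temperature quench.
# Returns the best-scoring state visited.
anneal_pack <- function(ctx, init_state, params, identity_moves = TRUE) {
  keys <- names(ctx$positions)
  state <- init_state
  # running total in the same single-count metric as full_components; move
  # deltas from pos_energy are exact updates of it
  run_total <- full_components(ctx, state)[["total"]]
  best_state <- state
  best_total <- run_total
  sweeps <- params$sweeps
  if (sweeps > 0) {
    with_seed(params$seed, {
      for (s in seq_len(sweeps)) {
        temp <- params$t_start *
          (params$t_end / params$t_start)^(if (sweeps == 1L) 0 else (s - 1) / (sweeps - 1))
        for (k in sample(keys)) {
          p <- ctx$positions[[k]]
          aa <- if (identity_moves) sample(p$allowed, 1L) else state[[k]]$aa
          rots <- ctx$rotamers[[aa]]
          ri <- sample.int(nrow(rots), 1L)
          cand <- state_entry(ctx, k, aa, rots[ri, ])
          e_old <- sum(pos_energy(ctx, state, k, state[[k]]))
          e_new <- sum(pos_energy(ctx, state, k, cand))
          dE <- e_new - e_old
          if (dE <= 0 || stats::runif(1L) < exp(-dE / temp)) {
            state[[k]] <- cand
            run_total <- run_total + dE
            if (run_total < best_total - 1e-12) {
              best_total <- run_total
              best_state <- state
            }
          }
        }
      }
      # zero-temperature quench: greedy best candidate per position
      for (pass in seq_len(params$quench_passes)) {
        improved <- FALSE
        for (k in keys) {
          p <- ctx$positions[[k]]
          e_cur <- sum(pos_energy(ctx, state, k, state[[k]]))
          best_e <- e_cur
          best_cand <- NULL
          ids <- if (identity_moves) p$allowed else state[[k]]$aa
          for (aa in ids) {
            rots <- ctx$rotamers[[aa]]
            for (ri in seq_len(nrow(rots))) {
              cand <- state_entry(ctx, k, aa, rots[ri, ])
              e <- sum(pos_energy(ctx, state, k, cand))
              if (e < best_e - 1e-12) {
                best_e <- e
                best_cand <- cand
              }
            }
          }
          if (!is.null(best_cand)) {
            run_total <- run_total + best_e - e_cur
            state[[k]] <- best_cand
            improved <- TRUE
            if (run_total < best_total - 1e-12) {
              best_total <- run_total
              best_state <- state
            }
          }
        }
        if (!improved) break
      }
    })
    if (run_total > best_total + 1e-12) state <- best_state
  }
  state
}

## ---- design operations ----------------------------------------------------

#' Redesign the shell around one match
#'
#' Simulated annealing over (identity, rotamer) choices at the designable
#' positions, with the match assignments and fixed positions immutable,
#' ending in a zero-temperature quench.  The best-scoring state visited is
#' returned; the same seed reproduces it exactly.
#'
#' @param match A `match` from [find_matches()].
#' @param scaffold The `scaffold` the match was found on.
#' @param weights A `score_weights`.
#' @param params An `anneal_params`.
#' @param radius Design shell radius in Angstrom (default 9).
#' @param rotamers Rotamer set.
#' @param alphabet Identity alphabet at designable positions (default all
#'   20).
#' @param extra_constraints Additional `geom_constraint`s measured on the
#'   scaffold (e.g. peptide-backbone anchor constraints); each must carry a
#'   `position` field naming the scaffold residue it binds.
#' @param position_restrictions Optional named list `position -> identity
#'   vector` narrowing the alphabet at specific positions.
#' @return A `design_model`.
#' @export
redesign <- function(match, scaffold, weights = score_weights(),
                     params = anneal_params(), radius = 9,
                     rotamers = rotamer_library(), alphabet = AA1,
                     extra_constraints = list(),
                     position_restrictions = NULL) {
  pose <- match$pose
  mpos <- match$assignments$resno
  designable <- designable_positions(scaffold, pose, radius,
                                     exclude = mpos)
  if (!length(designable)) stop("no designable positions within the shell")
  allowed <- stats::setNames(rep(list(alphabet), length(designable)),
                             as.character(designable))
  for (nm in names(position_restrictions)) {
    if (nm %in% names(allowed)) allowed[[nm]] <- position_restrictions[[nm]]
  }
  msc <- match_sidechain_records(match)
  crec <- c(match_constraint_records(match),
            lapply(extra_constraints, function(cst) {
              native_anchor_record(scaffold, pose, cst)
            }))
  ctx <- make_pack_context(scaffold, pose, designable, allowed,
                           match_sidechains = msc, match_positions = mpos,
                           constraint_records = crec, weights = weights,
                           rotamers = rotamers)
  init <- init_state_wt(ctx)
  final <- anneal_pack(ctx, init, params)
  finish_model(ctx, final, match_id = match$id, seed = params$seed)
}

init_state_wt <- function(ctx) {
  st <- lapply(ctx$positions, function(p) NULL)
  for (k in names(ctx$positions)) {
    p <- ctx$positions[[k]]
    nchi <- stub_n_chi(p$wt)
    chi <- p$native_chi
    if (length(chi) < nchi) chi <- c(chi, rep(180, nchi - length(chi)))
    st[[k]] <- state_entry(ctx, k, p$wt, chi[seq_len(nchi)])
  }
  st
}

# fixed side-chain records carried from a match into packing
match_sidechain_records <- function(match) {
  out <- list()
  for (i in seq_len(nrow(match$assignments))) {
    aa <- match$assignments$identity[i]
    sc <- match$sidechains[[i]]
    n <- nrow(sc)
    rad <- tryCatch(unname(stub_radii(aa))[seq_len(n)],
                    error = function(e) rep(1.7, n))
    out[[paste0(match$assignments$resno[i], ":", aa)]] <-
      list(xyz = sc, radii = rad, resno = match$assignments$resno[i],
           term = if (n >= 2L) sc[n, ] else NULL,
           base = if (n >= 2L) sc[n - 1L, ] else NULL,
           donor = stub_is_donor(aa), acceptor = stub_is_acceptor(aa),
           label = paste0(aa, match$assignments$resno[i]))
  }
  out
}

match_constraint_records <- function(match) {
  recs <- list()
  for (i in seq_len(nrow(match$assignments))) {
    hit <- match$geometry[[i]]
    sc <- match$sidechains[[i]]
    n <- nrow(sc)
    if (n < 2L) next
    tmpl <- match$pose$conformer$template
    la <- hit$ligand_atom
    nb <- igraph::neighbors(tmpl$graph, la)$name
    cst <- hbond_constraint(la, match$assignments$identity[i],
                            name = paste0("match_", match$assignments$constraint[i]))
    if (identical(hit$role, "donor")) {
      recs[[i]] <- list(constraint = cst, donor = sc[n, ],
                        donor_base = sc[n - 1L, ],
                        acceptor = match$pose$xyz[la, ],
                        acceptor_base = match$pose$xyz[nb[1L], ])
    } else {
      recs[[i]] <- list(constraint = cst, donor = match$pose$xyz[la, ],
                        donor_base = match$pose$xyz[nb[1L], ],
                        acceptor = sc[n, ], acceptor_base = sc[n - 1L, ])
    }
  }
  recs[!vapply(recs, is.null, logical(1))]
}

native_anchor_record <- function(scaffold, pose, cst) {
  rn <- cst$position
  if (is.null(rn)) stop("extra constraint lacks a bound position")
  sc <- native_side_xyz(scaffold, rn)
  n <- nrow(sc)
  la <- cst$ligand_group[1L]
  tmpl <- pose$conformer$template
  nb <- igraph::neighbors(tmpl$graph, la)$name
  list(constraint = cst, donor = sc[n, ], donor_base = sc[n - 1L, ],
       acceptor = pose$xyz[la, ], acceptor_base = pose$xyz[nb[1L], ])
}

finish_model <- function(ctx, state, match_id = NA, repeat_id = NA,
                         seed = NA) {
  scores <- full_components(ctx, state)
  pos <- scaffold_positions(ctx$scaffold)
  model <- structure(list(
    sequence = vapply(state, function(e) e$aa, ""),
    chi = lapply(state, function(e) e$chi),
    sidechains = lapply(state, function(e) e$xyz),
    wild_type = stats::setNames(
      pos$aa[match(as.integer(names(ctx$positions)), pos$resno)],
      names(ctx$positions)),
    designable = names(ctx$positions),
    ligand_xyz = ctx$lig_xyz,
    scores = as.list(scores),
    provenance = list(match_id = match_id, repeat_id = repeat_id,
                      seed = seed),
    .ctx = ctx, .state = state), class = "design_model")
  model
}

#' @export
print.design_model <- function(x, ...) {
  cat("design_model | match", x$provenance$match_id,
      "repeat", x$provenance$repeat_id, "\n")
  cat("  sequence:", paste(paste0(names(x$sequence), x$sequence),
                           collapse = " "), "\n")
  cat(sprintf("  scores: total %.3f (interface %.3f, internal %.3f, constraint %.3f)\n",
              x$scores$total, x$scores$interface, x$scores$internal,
              x$scores$constraint))
  invisible(x)
}

#' Recompute the component scores of a design model
#'
#' @param model A `design_model`.
#' @param weights Optional `score_weights` overriding the model's.
#' @return Named list `interface`, `internal`, `constraint`, `total`
#'   (total is the sum of the three weighted components).
#' @export
score_pose <- function(model, weights = NULL) {
  ctx <- model$.ctx
  if (!is.null(weights)) ctx$weights <- weights
  as.list(full_components(ctx, model$.state))
}

# deterministic seed mixing for (match, repeat) streams; multipliers keep
# every product exactly representable in doubles
mix_seed <- function(base_seed, match_i, repeat_i) {
  as.integer(((base_seed %% 30011) * 65537 + match_i * 211 + repeat_i) %%
               2147483629)
}

#' Run the design stage over all matches
#'
#' @param matches List of `match`es.
#' @param scaffold The `scaffold`.
#' @param n_repeats Independent redesigns per match (default 25).
#' @param weights,params,radius,rotamers,alphabet,extra_constraints,position_restrictions
#'   Passed to [redesign()].
#' @param base_seed Base seed; repeat `r` of match `m` runs at
#'   `mix_seed(base_seed, m, r)`.
#' @return List of `length(matches) * n_repeats` `design_model`s with
#'   (match, repeat, seed) provenance.
#' @export
run_design_stage <- function(matches, scaffold, n_repeats = 25,
                             weights = score_weights(),
                             params = anneal_params(), radius = 9,
                             rotamers = rotamer_library(), alphabet = AA1,
                             extra_constraints = list(),
                             position_restrictions = NULL,
                             base_seed = 1) {
  stopifnot(n_repeats >= 1)
  out <- vector("list", length(matches) * n_repeats)
  n <- 0L
  for (m in seq_along(matches)) {
    for (r in seq_len(n_repeats)) {
      p <- params
      p$seed <- mix_seed(base_seed, m, r)
      model <- redesign(matches[[m]], scaffold, weights, p, radius,
                        rotamers, alphabet, extra_constraints,
                        position_restrictions)
      model$provenance$match_id <- m
      model$provenance$repeat_id <- r
      n <- n + 1L
      model$id <- n
      out[[n]] <- model
    }
  }
  out
}

#' Model a given variant in complex with the ligand
#'
#' Threads the variant identities onto the scaffold, repacks their side
#' chains with the annealer (identities fixed), anchors the ligand
#' conformer, and reports every donor/acceptor pair passing hydrogen-bond
#' geometry.
#'
#' @param scaffold A `scaffold`.
#' @param variant Named character vector `residue number -> identity`.
#' @param conformer Ligand `conformer` to anchor.
#' @param weights,params,rotamers Packing controls.
#' @return A `design_model` with an `hbonds` data frame attached (partner
#'   labels, distance, donor and acceptor angles).
#' @export
model_variant_complex <- function(scaffold, variant, conformer,
                                  weights = score_weights(),
                                  params = anneal_params(),
                                  rotamers = rotamer_library()) {
  pos <- scaffold_positions(scaffold)
  unknown <- setdiff(as.integer(names(variant)), pos$resno)
  if (length(unknown)) {
    stop("sequence error: unknown position ", paste(unknown, collapse = ", "))
  }
  pose <- anchor_superpose(conformer, scaffold)
  keys <- as.integer(names(variant))
  allowed <- stats::setNames(lapply(unname(variant), identity),
                             as.character(keys))
  ctx <- make_pack_context(scaffold, pose, keys, allowed,
                           weights = weights, rotamers = rotamers)
  init <- lapply(names(ctx$positions), function(k) {
    aa <- variant[[k]]
    nchi <- stub_n_chi(aa)
    state_entry(ctx, k, aa, rep(180, nchi))
  })
  names(init) <- names(ctx$positions)
  final <- anneal_pack(ctx, init, params, identity_moves = FALSE)
  model <- finish_model(ctx, final, seed = params$seed)
  model$hbonds <- hbond_report(model)
  model
}

#' Hydrogen-bond report of a modeled complex
#'
#' Lists every residue-ligand and residue-residue donor/acceptor pair whose
#' geometry passes a standard hydrogen bond (distance 2.6-3.2 Angstrom,
#' flanking angles >= 120 degrees).
#'
#' @param model A `design_model`.
#' @return Data frame with columns `a`, `b`, `distance`, `donor_angle`,
#'   `acceptor_angle`.
#' @export
hbond_report <- function(model) {
  ctx <- model$.ctx
  state <- model$.state
  sites <- list()
  for (k in names(state)) {
    e <- state[[k]]
    if (is.null(e$term)) next
    sites[[paste0(e$aa, k)]] <- e
  }
  # native polar side chains not repacked
  pos <- scaffold_positions(ctx$scaffold)
  for (i in seq_len(nrow(pos))) {
    rn <- pos$resno[i]
    if (as.character(rn) %in% names(state)) next
    aa <- pos$aa[i]
    ok <- tryCatch(stub_is_donor(aa) || stub_is_acceptor(aa),
                   error = function(e) FALSE)
    if (!ok) next
    sc <- native_side_xyz(ctx$scaffold, rn, pos$chain[i])
    if (nrow(sc) < 2L) next
    sites[[paste0(aa, rn)]] <- list(term = sc[nrow(sc), ],
                                    base = sc[nrow(sc) - 1L, ],
                                    donor = stub_is_donor(aa),
                                    acceptor = stub_is_acceptor(aa))
  }
  rows <- list()
  addpair <- function(la, lb, a, b) {
    cst <- hbond_constraint("x", "S")
    if (a$donor && b$acceptor) {
      ev <- evaluate_constraint(list(atom = a$term, base = a$base),
                                list(atom = b$term, base = b$base), cst)
      if (ev$satisfied) {
        rows[[length(rows) + 1L]] <<- data.frame(
          a = la, b = lb, distance = ev$geometry$distance,
          donor_angle = ev$geometry$donor_angle,
          acceptor_angle = ev$geometry$acceptor_angle,
          stringsAsFactors = FALSE)
        return(invisible(TRUE))
      }
    }
    if (b$donor && a$acceptor) {
      ev <- evaluate_constraint(list(atom = b$term, base = b$base),
                                list(atom = a$term, base = a$base), cst)
      if (ev$satisfied) {
        rows[[length(rows) + 1L]] <<- data.frame(
          a = la, b = lb, distance = ev$geometry$distance,
          donor_angle = ev$geometry$donor_angle,
          acceptor_angle = ev$geometry$acceptor_angle,
          stringsAsFactors = FALSE)
      }
    }
    invisible(TRUE)
  }
  labs <- names(sites)
  for (i in seq_along(sites)) {
    for (la in ctx$lig_polar) {
      addpair(labs[i], paste0("LIG:", la$name), sites[[i]],
              c(lig_polar_site(la), list()))
    }
    if (i < length(sites)) {
      for (j in (i + 1L):length(sites)) {
        addpair(labs[i], labs[j], sites[[i]], sites[[j]])
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(a = character(), b = character(), distance = numeric(),
                      donor_angle = numeric(), acceptor_angle = numeric()))
  }
  do.call(rbind, rows)
}
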