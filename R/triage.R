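# Triage of design models: the three filters (ligand-interface score,
# constraint score, preorganization RMS) and greedy leader clustering by
# substrate orientation.

#' Filter thresholds
#'
#' @param max_interface Maximum ligand-interface score.
#' @param max_constraint Maximum constraint score.
#' @param max_preorg_rms Maximum repack RMS without ligand, in Angstrom.
#'   Any threshold may be `Inf` (pass-all).
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(max_interface = 0, max_constraint = 1,
                              max_preorg_rms = 1) {
  stopifnot(!is.na(max_interface), !is.na(max_constraint),
            !is.na(max_preorg_rms))
  structure(list(max_interface = max_interface,
                 max_constraint = max_constraint,
                 max_preorg_rms = max_preorg_rms),
            class = "filter_thresholds")
}

#' Preorganization RMS of a design model
#'
#' Removes the ligand, repacks the designable side chains with the same
#' annealer (identities fixed), and returns the heavy-atom RMS between the
#' designed and ligand-free-repacked side-chain coordinates over the active
#' site (designable plus match-assigned positions).
#'
#' @param model A `design_model`.
#' @param params An `anneal_params`; its `seed` controls the repack.
#' @return RMS in Angstrom (`>= 0`; 0 when the ligand-free repack optimum
#'   equals the designed rotamers, or vacuously when nothing is compared).
#' @export
preorganization_rms <- function(model, params = anneal_params(seed = 7)) {
  ctx <- model$.ctx
  if (!length(ctx$positions)) return(0)
  ctx$lig_xyz <- NULL
  ctx$lig_rad <- numeric()
  ctx$lig_polar <- list()
  ctx$constraint_records <- list()
  # identities fixed: allowed set collapses to the designed identity
  for (k in names(ctx$positions)) {
    ctx$positions[[k]]$allowed <- model$.state[[k]]$aa
  }
  repacked <- anneal_pack(ctx, model$.state, params, identity_moves = FALSE)
  pre <- list()
  post <- list()
  for (k in names(model$.state)) {
    pre[[k]] <- model$.state[[k]]$xyz
    post[[k]] <- repacked[[k]]$xyz
  }
  # match-assigned side chains are immutable, so they contribute zero
  # displacement but belong to the compared active site
  for (f in ctx$fixed_sc) {
    pre[[f$label]] <- f$xyz
    post[[f$label]] <- f$xyz
  }
  a <- do.call(rbind, pre)
  b <- do.call(rbind, post)
  if (is.null(a) || !nrow(a)) return(0)
  rmsd_xyz(a, b)
}

#' Filter design models by the three criteria
#'
#' Keeps models whose ligand-interface score, constraint score and
#' preorganization RMS are all at or below their thresholds, in stable
#' input order.
#'
#' @param models List of `design_model`s.
#' @param thresholds A `filter_thresholds`.
#' @param preorg_rms Optional numeric vector of precomputed RMS values
#'   (computed via [preorganization_rms()] when missing and the threshold
#'   is finite).
#' @param params Annealing parameters for the RMS repack.
#' @return The surviving models, stable order.
#' @export
filter_designs <- function(models, thresholds = filter_thresholds(),
                           preorg_rms = NULL,
                           params = anneal_params(seed = 7)) {
  if (!length(models)) return(models)
  if (is.null(preorg_rms)) {
    preorg_rms <- if (is.finite(thresholds$max_preorg_rms)) {
      vapply(models, preorganization_rms, numeric(1), params = params)
    } else {
      rep(0, length(models))
    }
  }
  keep <- vapply(seq_along(models), function(i) {
    s <- models[[i]]$scores
    s$interface <= thresholds$max_interface &&
      s$constraint <= thresholds$max_constraint &&
      preorg_rms[i] <= thresholds$max_preorg_rms
  }, logical(1))
  models[keep]
}

model_ligand_xyz <- function(model) {
  if (is.null(model$ligand_xyz)) {
    stop("comparability error: model carries no ligand coordinates")
  }
  model$ligand_xyz
}

#' Cluster design models by substrate orientation
#'
#' Greedy leader clustering on ligand heavy-atom RMSD in the shared
#' scaffold frame (no re-superposition).  Input is processed in descending
#' total-score order (stable), so leaders are deterministic; clusters are
#' returned sorted by size (ties broken by smallest leader id).
#'
#' @param models List of `design_model`s sharing the ligand atom set.
#' @param rmsd_cutoff Leader RMSD cutoff in Angstrom (default 2).
#' @return List of clusters: each has `leader` (model id), `members`
#'   (model ids), `leader_pose` (ligand coordinates).
#' @export
cluster_by_orientation <- function(models, rmsd_cutoff = 2) {
  if (!length(models)) return(list())
  ids <- vapply(seq_along(models), function(i) {
    if (!is.null(models[[i]]$id)) models[[i]]$id else i
  }, numeric(1))
  ligs <- lapply(models, model_ligand_xyz)
  nat <- vapply(ligs, nrow, integer(1))
  if (length(unique(nat)) != 1L) {
    stop("comparability error: models do not share the ligand atom set")
  }
  totals <- vapply(models, function(m) m$scores$total, numeric(1))
  ord <- order(totals, decreasing = TRUE)
  leaders <- integer()
  members <- list()
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(leaders)) {
      if (rmsd_xyz(ligs[[i]], ligs[[leaders[k]]]) <= rmsd_cutoff) {
        members[[k]] <- c(members[[k]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      leaders <- c(leaders, i)
      members[[length(leaders)]] <- i
    }
  }
  clusters <- lapply(seq_along(leaders), function(k) {
    list(leader = ids[leaders[k]], members = ids[members[[k]]],
         leader_pose = ligs[[leaders[k]]], size = length(members[[k]]))
  })
  sizes <- vapply(clusters, function(cl) cl$size, integer(1))
  lead_ids <- vapply(clusters, function(cl) cl$leader, numeric(1))
  clusters[order(-sizes, lead_ids)]
}

#' Members of the largest orientation cluster
#'
#' @param clusters Output of [cluster_by_orientation()].
#' @param models The model list the clusters index into (by model id);
#'   when omitted, member ids are returned.
#' @return The member models of the first (largest) cluster, or their ids;
#'   empty for an empty cluster list.
#' @export
select_largest_cluster <- function(clusters, models = NULL) {
  if (!length(clusters)) return(if (is.null(models)) numeric() else list())
  ids <- clusters[[1L]]$members
  if (is.null(models)) return(ids)
  mid <- vapply(seq_along(models), function(i) {
    if (!is.null(models[[i]]$id)) models[[i]]$id else i
  }, numeric(1))
  models[match(ids, mid)]
}
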