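# Sequence-profile compilation, curation, exact diversity and coverage
# statistics -- the arithmetic that turns a set of selected design models
# into a focused, synthesizable combinatorial library.

#' Compile a per-position sequence profile from selected design models
#'
#' @param models List of `design_model`s, or a character matrix/data frame
#'   (models x positions) of one-letter identities with position names as
#'   column names.
#' @param wild_type Named character vector of wild-type identities per
#'   position (taken from the first model's scaffold when models are
#'   `design_model`s and omitted here).
#' @return An object of class `sequence_profile`: for every position the
#'   wild-type identity plus observed identity counts and frequencies
#'   (counts / number of models).
#' @export
compile_profile <- function(models, wild_type = NULL) {
  if (is.list(models) && length(models) && inherits(models[[1L]], "design_model")) {
    seqs <- do.call(rbind, lapply(models, function(m) {
      if (!identical(names(m$sequence), names(models[[1L]]$sequence))) {
        stop("completeness error: models do not share the designable position list")
      }
      m$sequence
    }))
    if (is.null(wild_type)) wild_type <- models[[1L]]$wild_type
  } else {
    seqs <- as.matrix(models)
  }
  if (is.null(colnames(seqs))) stop("positions must be named")
  if (anyNA(seqs)) stop("completeness error: missing identity in profile input")
  n <- nrow(seqs)
  positions <- lapply(colnames(seqs), function(p) {
    counts <- table(seqs[, p])
    counts <- stats::setNames(as.integer(counts), names(counts))
    list(position = p,
         wild_type = if (!is.null(wild_type)) unname(wild_type[p]) else NA_character_,
         counts = counts,
         freq = counts / n)
  })
  names(positions) <- colnames(seqs)
  structure(list(positions = positions, n_models = n),
            class = "sequence_profile")
}

#' @export
print.sequence_profile <- function(x, ...) {
  cat("sequence_profile over", length(x$positions), "positions,",
      x$n_models, "models\n")
  for (p in x$positions) {
    cat(sprintf("  %-6s wt=%s  %s\n", p$position,
                ifelse(is.na(p$wild_type), "?", p$wild_type),
                paste(sprintf("%s:%.2f", names(p$freq), p$freq),
                      collapse = " ")))
  }
  invisible(x)
}

#' Curation rules for focusing a raw sequence profile
#'
#' @param min_frequency Identities below this frequency are removed
#'   (default 0.05).
#' @param similarity_groups List of identity sets treated as equivalent
#'   (defaults `{S,T}` and `{V,I,L}`); within a group present at a position
#'   only the highest-frequency member is kept (tie broken alphabetically).
#'   Groups must be pairwise disjoint.
#' @param distal_conservative_removals Named list `position -> identities`
#'   of conservative mutations at distal regions to drop.
#' @param wt_reinstatement_positions Positions whose wild-type identity is
#'   (re)added, to keep the library compatible with the parent substrate.
#' @param target_size Optional advisory target diversity carried in the
#'   object.
#' @return An object of class `curation_rules`.
#' @export
curation_rules <- function(min_frequency = 0.05,
                           similarity_groups = list(c("S", "T"),
                                                    c("V", "I", "L")),
                           distal_conservative_removals = list(),
                           wt_reinstatement_positions = character(),
                           target_size = NULL) {
  stopifnot(min_frequency >= 0, min_frequency < 1)
  all_members <- unlist(similarity_groups)
  if (anyDuplicated(all_members)) {
    stop("similarity groups must be pairwise disjoint")
  }
  structure(list(min_frequency = min_frequency,
                 similarity_groups = similarity_groups,
                 distal_conservative_removals = distal_conservative_removals,
                 wt_reinstatement_positions = as.character(wt_reinstatement_positions),
                 target_size = target_size),
            class = "curation_rules")
}

#' Curate a sequence profile into a library specification
#'
#' Applies, in order: (1) drop identities observed below `min_frequency`;
#' (2) drop listed distal conservative identities; (3) collapse each
#' similarity group present at a position to its highest-frequency member
#' (tie broken alphabetically); (4) add the wild-type identity at the
#' reinstatement positions.  Positions whose allowed set reduces to the
#' wild type alone are dropped from the library table (they are simply not
#' diversified).  Every removal/addition is logged with its rule.
#'
#' @param profile A `sequence_profile` with wild-type identities.
#' @param rules A `curation_rules`.
#' @param fixed_background Character vector of fixed background mutations
#'   (e.g. `"D286R"`) recorded on the spec; not counted in diversity.
#' @return An object of class `library_spec` with per-position allowed sets,
#'   the curation log, and exact diversity as an `exactint`.
#' @export
curate_profile <- function(profile, rules, fixed_background = character()) {
  log <- list()
  note <- function(position, identity, action, rule) {
    log[[length(log) + 1L]] <<- data.frame(position = position,
                                           identity = identity,
                                           action = action, rule = rule,
                                           stringsAsFactors = FALSE)
  }
  spec_positions <- list()
  for (p in profile$positions) {
    wt <- p$wild_type
    if (is.na(wt)) stop("curation requires wild-type identities")
    allowed <- names(p$freq)
    # (1) frequency threshold
    low <- allowed[p$freq[allowed] < rules$min_frequency]
    for (aa in low) note(p$position, aa, "remove", "min_frequency")
    allowed <- setdiff(allowed, low)
    # (2) distal conservative removals
    rm2 <- intersect(allowed,
                     rules$distal_conservative_removals[[p$position]])
    for (aa in rm2) note(p$position, aa, "remove", "distal_conservative")
    allowed <- setdiff(allowed, rm2)
    # (3) similarity collapse
    for (grp in rules$similarity_groups) {
      present <- intersect(allowed, grp)
      if (length(present) > 1L) {
        f <- p$freq[present]
        keep <- present[order(-f, present)][1L]
        for (aa in setdiff(present, keep)) {
          note(p$position, aa, "remove", "similarity_collapse")
        }
        allowed <- setdiff(allowed, setdiff(present, keep))
      }
    }
    # (4) wild-type reinstatement
    if (p$position %in% rules$wt_reinstatement_positions && !(wt %in% allowed)) {
      note(p$position, wt, "add", "wt_reinstatement")
      allowed <- c(allowed, wt)
    }
    if (!length(allowed)) {
      stop("curation error: all identities removed at position ", p$position)
    }
    allowed <- sort(allowed)
    if (identical(allowed, wt)) {
      note(p$position, wt, "drop_position", "wild_type_only")
      next
    }
    spec_positions[[p$position]] <- list(position = p$position,
                                         wild_type = wt, allowed = allowed)
  }
  new_library_spec(spec_positions, fixed_background,
                   log = do.call(rbind, log))
}

new_library_spec <- function(positions, fixed_background = character(),
                             log = NULL) {
  for (p in positions) {
    if (!length(p$allowed)) {
      stop("spec error: empty identity set at position ", p$position)
    }
  }
  structure(list(positions = positions,
                 fixed_background = fixed_background,
                 diversity = exact_product(
                   vapply(positions, function(p) length(p$allowed), integer(1))),
                 curation_log = log),
            class = "library_spec")
}

#' Construct a library specification directly from allowed sets
#'
#' @param allowed Named list `position -> identity vector`.
#' @param wild_type Optional named character vector of wild types.
#' @param fixed_background Fixed background mutations (metadata only).
#' @return A `library_spec`.
#' @export
library_spec <- function(allowed, wild_type = NULL,
                         fixed_background = character()) {
  positions <- lapply(names(allowed), function(p) {
    list(position = p,
         wild_type = if (!is.null(wild_type)) unname(wild_type[p]) else NA_character_,
         allowed = sort(unique(allowed[[p]])))
  })
  names(positions) <- names(allowed)
  new_library_spec(positions, fixed_background)
}

#' @export
print.library_spec <- function(x, ...) {
  cat("library_spec:", length(x$positions), "diversified positions,",
      "diversity", as.character(x$diversity),
      paste0("(", format_sci(x$diversity), ")"), "\n")
  for (p in x$positions) {
    cat(sprintf("  %-6s wt=%s  {%s}\n", p$position,
                ifelse(is.na(p$wild_type), "?", p$wild_type),
                paste(p$allowed, collapse = ", ")))
  }
  if (length(x$fixed_background)) {
    cat("  fixed background:", paste(x$fixed_background, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Exact sequence diversity
#'
#' The exact product of per-position identity-set sizes, computed in
#' arbitrary precision (no floating point, no overflow).
#'
#' @param spec A `library_spec` or a `sequence_profile` (where the per
#'   position sets are the observed identities).
#' @return An `exactint`.
#' @export
profile_diversity <- function(spec) {
  sizes <- if (inherits(spec, "library_spec")) {
    vapply(spec$positions, function(p) length(p$allowed), integer(1))
  } else if (inherits(spec, "sequence_profile")) {
    vapply(spec$positions, function(p) length(p$counts), integer(1))
  } else {
    stop("need a library_spec or sequence_profile")
  }
  if (!length(sizes)) stop("spec error: no positions")
  exact_product(sizes)
}

#' Theoretical design-space size
#'
#' @param n_positions Number of fully randomized positions.
#' @param alphabet_size Identity alphabet size (default 20).
#' @return `alphabet_size ^ n_positions` as an `exactint`.
#' @export
theoretical_diversity <- function(n_positions, alphabet_size = 20) {
  stopifnot(n_positions >= 0)
  exact_pow(alphabet_size, n_positions)
}

#' Expected library coverage by a transformant count
#'
#' The expected fraction of distinct library members present among `N`
#' uniform draws from a library of diversity `V`:
#' `1 - (1 - 1/V)^N`, evaluated stably via `log1p` for large `N` and `V`.
#'
#' @param n_transformants Number of transformants (colonies), `N >= 0`.
#' @param diversity Library diversity `V >= 1` (numeric or `exactint`).
#' @return Fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(n_transformants, diversity) {
  n <- as.numeric(n_transformants)
  v <- if (inherits(diversity, "exactint")) as.numeric(diversity)
       else as.numeric(diversity)
  stopifnot(n >= 0, v >= 1)
  if (n == 0) return(0)
  -expm1(n * log1p(-1 / v))
}

#' Orders-of-magnitude reduction between two sequence-space sizes
#'
#' @param space_before,space_after Positive sizes (`exactint` or numeric).
#' @return `round(log10(before / after))` as an integer.
#' @export
orders_of_magnitude_reduction <- function(space_before, space_after) {
  as.integer(round(exact_log10(space_before) - exact_log10(space_after)))
}

#' Count mutations of a variant relative to wild type
#'
#' @param variant Named character vector `position -> identity` (e.g. the
#'   selected-variant column of a library table).
#' @param wild_type Named character vector of wild-type identities covering
#'   the variant's positions.
#' @param include_background Count the fixed background mutations too.
#' @param background Character vector of background mutations (e.g.
#'   `"D286R"`), used only when `include_background = TRUE`.
#' @return Integer mutation count.
#' @export
mutation_count <- function(variant, wild_type, include_background = FALSE,
                           background = character()) {
  if (!all(names(variant) %in% names(wild_type))) {
    stop("reference error: position without wild-type identity: ",
         paste(setdiff(names(variant), names(wild_type)), collapse = ", "))
  }
  n <- sum(variant != wild_type[names(variant)])
  if (include_background) n <- n + length(background)
  as.integer(n)
}

#' Export a library specification
#'
#' Writes a position table TSV (position, wild type, allowed identities,
#' optional selected-variant column) and optionally the full enumeration as
#' FASTA when the diversity does not exceed `enumerate_cap`.  Fixed
#' background mutations are applied to every enumerated record; record
#' order is deterministic (positions in table order, last position varying
#' fastest, identities alphabetical).
#'
#' @param spec A `library_spec`.
#' @param dir Output directory (created if needed).
#' @param wt_sequence Full-length wild-type sequence (single string) used
#'   for enumeration; positions index into it 1-based. Optional when
#'   `enumerate = FALSE`.
#' @param variant Optional named character vector appended as a variant
#'   column of the TSV.
#' @param enumerate Write `library.fasta` with every member.
#' @param enumerate_cap Refuse enumeration above this diversity
#'   (default 1e5).
#' @return Invisible list of written file paths.
#' @export
export_library <- function(spec, dir, wt_sequence = NULL, variant = NULL,
                           enumerate = FALSE, enumerate_cap = 1e5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- data.frame(
    position = vapply(spec$positions, function(p) p$position, ""),
    wild_type = vapply(spec$positions, function(p) p$wild_type, ""),
    library = vapply(spec$positions,
                     function(p) paste(p$allowed, collapse = ", "), ""),
    stringsAsFactors = FALSE)
  if (!is.null(variant)) tab$variant <- unname(variant[tab$position])
  tsv <- file.path(dir, "library_positions.tsv")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- list(tsv = tsv)
  if (!is.null(spec$curation_log)) {
    logp <- file.path(dir, "curation_log.json")
    jsonlite::write_json(spec$curation_log, logp, dataframe = "rows",
                         auto_unbox = TRUE, pretty = TRUE)
    written$log <- logp
  }
  if (enumerate) {
    if (exact_log10(spec$diversity) > log10(enumerate_cap) + 1e-12) {
      stop("size-guard error: diversity ", format_sci(spec$diversity),
           " exceeds the enumeration cap ", format(enumerate_cap))
    }
    if (is.null(wt_sequence)) stop("enumeration needs wt_sequence")
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("enumeration requires the Biostrings package")
    }
    resno <- as.integer(gsub("[^0-9]", "", tab$position))
    sets <- lapply(spec$positions, function(p) sort(p$allowed))
    combos <- expand.grid(rev(sets), KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
    combos <- combos[, rev(seq_along(sets)), drop = FALSE]
    base <- strsplit(wt_sequence, "")[[1L]]
    for (bg in spec$fixed_background) {
      bpos <- as.integer(gsub("[^0-9]", "", bg))
      baa <- substr(bg, nchar(bg), nchar(bg))
      if (bpos <= length(base)) base[bpos] <- baa
    }
    seqs <- vapply(seq_len(nrow(combos)), function(i) {
      s <- base
      s[resno] <- unlist(combos[i, ])
      paste(s, collapse = "")
    }, "")
    names(seqs) <- sprintf("member_%06d", seq_along(seqs))
    fa <- file.path(dir, "library.fasta")
    Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), fa)
    written$fasta <- fa
  }
  invisible(written)
}

#' Replay a curation log against a raw profile
#'
#' Audit helper: applying the logged removals/additions/position drops to
#' the raw profile must reproduce the curated allowed sets exactly.
#'
#' @param profile The raw `sequence_profile`.
#' @param log The `curation_log` data frame of a `library_spec`.
#' @return A named list `position -> allowed identity vector` (positions
#'   dropped by the log are absent).
#' @export
replay_curation_log <- function(profile, log) {
  allowed <- lapply(profile$positions, function(p) names(p$counts))
  dropped <- character()
  if (!is.null(log)) {
    for (i in seq_len(nrow(log))) {
      p <- log$position[i]
      switch(log$action[i],
             remove = allowed[[p]] <- setdiff(allowed[[p]], log$identity[i]),
             add = allowed[[p]] <- union(allowed[[p]], log$identity[i]),
             drop_position = dropped <- c(dropped, p))
    }
  }
  allowed <- allowed[setdiff(names(allowed), dropped)]
  lapply(allowed, sort)
}

## ---- published library table ----------------------------------------------

#' The curated MjTyrRS/ONBY library table
#'
#' Reads the published 17-position focused-library table (wild-type
#' identity, allowed identities, and the experimentally selected ONBYRS-1
#' variant) shipped with the package, together with the fixed D286R
#' background mutation.
#'
#' @return List with `table` (data frame: position, wild_type, library,
#'   onbyrs1), `spec` (a `library_spec`), `wild_type` and `onbyrs1` (named
#'   character vectors keyed by residue number) and `fixed_background`.
#' @export
onby_library_table <- function() {
  path <- system.file("extdata", "mjtyrrs_onby_library.tsv",
                      package = "focuslib", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  pos <- gsub("[^0-9]", "", tab$position)
  wt <- stats::setNames(substr(tab$position, 1L, 1L), pos)
  allowed <- stats::setNames(lapply(strsplit(tab$library, ","), trimws), pos)
  spec <- library_spec(allowed, wild_type = wt, fixed_background = "D286R")
  list(table = tab, spec = spec, wild_type = wt,
       onbyrs1 = stats::setNames(tab$onbyrs1, pos),
       fixed_background = "D286R")
}
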