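#' Best-bidirectional-hit ortholog groups
#'
#' For every ordered species pair, each protein's best hits (all hits tied
#' at the maximum raw score) are determined; proteins a and b are BBH when
#' each is among the other's best hits. Ortholog groups are the connected
#' components of the BBH graph over all proteins (proteins without any BBH
#' edge form singleton groups). Groups holding several members of one
#' species are trimmed according to `conflict`: drop that species' members
#' from the group (default) or drop the whole group.
#'
#' @param proteomes named list (species -> named protein vector), at least
#'   two.
#' @param evalue_cutoff alignment e-value cutoff (default 1e-5, the
#'   ortholog-inference stage).
#' @param params an [alignment_params()].
#' @param conflict `"drop_species"` (default) or `"drop_group"`.
#' @param hits optional precomputed hit table from [all_vs_all()].
#' @return data.frame ("ortholog table") with `group_id`, `species_id`,
#'   `protein_id`, `monocore` (exactly one member in every species) and
#'   `mean_pident` (mean pairwise pident within the group, used for
#'   conservation ranking).
#' @export
best_bidirectional_hits <- function(proteomes, evalue_cutoff = 1e-5,
                                    params = alignment_params(),
                                    conflict = c("drop_species",
                                                 "drop_group"),
                                    hits = NULL) {
  conflict <- match.arg(conflict)
  if (!is.list(proteomes) || length(proteomes) < 2L)
    stop("best_bidirectional_hits needs at least two proteomes")
  if (is.null(names(proteomes)))
    stop("proteomes must be a named list (species -> proteins)")
  if (is.null(hits)) hits <- all_vs_all(proteomes, evalue_cutoff, params)
  sp_of <- unlist(lapply(names(proteomes), function(s)
    setNames(rep(s, length(proteomes[[s]])), names(proteomes[[s]]))))
  all_prot <- names(sp_of)

  # best (co-best on ties) cross-species hits per query and target species
  h <- hits[sp_of[hits$query_id] != sp_of[hits$subject_id], , drop = FALSE]
  edges <- character(0)
  if (nrow(h)) {
    key <- paste(h$query_id, sp_of[h$subject_id], sep = "\r")
    best_score <- tapply(h$raw_score, key, max)
    is_best <- h$raw_score == best_score[key]
    bh <- h[is_best, c("query_id", "subject_id")]
    fwd <- paste(bh$query_id, bh$subject_id, sep = "\r")
    rev <- paste(bh$subject_id, bh$query_id, sep = "\r")
    bbh <- bh[fwd %in% rev, , drop = FALSE]
    und <- unique(data.frame(a = pmin(bbh$query_id, bbh$subject_id),
                             b = pmax(bbh$query_id, bbh$subject_id)))
    edges <- rbind(und$a, und$b)
  }
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(all_prot), name = all_prot)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)

  # symmetric pident lookup for conservation ranking
  lookup <- pident_lookup(hits)
  n_species <- length(proteomes)
  rows <- list()
  for (mem in members) {
    sp <- sp_of[mem]
    dup_sp <- unique(sp[duplicated(sp)])
    if (length(dup_sp)) {
      if (conflict == "drop_group") next
      mem <- mem[!(sp %in% dup_sp)]
      if (!length(mem)) next
      sp <- sp_of[mem]
    }
    mp <- if (length(mem) >= 2L) {
      prs <- utils::combn(mem, 2L)
      mean(mapply(lookup, prs[1L, ], prs[2L, ]))
    } else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      species_id = unname(sp), protein_id = mem,
      monocore = length(mem) == n_species &&
        length(unique(sp)) == n_species,
      mean_pident = mp, stringsAsFactors = FALSE)
  }
  rows <- rows[order(vapply(rows, function(r) min(r$protein_id), ""))]
  out <- do.call(rbind, lapply(seq_along(rows), function(i)
    cbind(group_id = sprintf("OG%04d", i), rows[[i]],
          stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Select the most conserved monocore groups
#'
#' Monocore groups (exactly one member in every species) ranked by
#' decreasing mean pairwise percent identity; ties broken by group id, so
#' the selection is deterministic and invariant to input ordering.
#'
#' @param groups ortholog table from [best_bidirectional_hits()].
#' @param n number of groups to keep (the published analysis used 200).
#' @return ortholog table restricted to the selected groups.
#' @export
select_monocore <- function(groups, n = 200L) {
  mono <- groups[groups$monocore, , drop = FALSE]
  ids <- unique(mono$group_id)
  if (length(ids) < n)
    stop("only ", length(ids), " monocore group(s) available, need ", n)
  rank <- vapply(ids, function(g)
    mono$mean_pident[mono$group_id == g][1], 1.0)
  keep <- ids[order(-rank, ids)][seq_len(n)]
  out <- mono[mono$group_id %in% keep, , drop = FALSE]
  out[order(out$group_id, out$species_id), , drop = FALSE]
}

#' Concatenate monocore sequences per species
#'
#' Joins each species' member of every selected group into one long
#' protein, in sorted group-id order (identical segment order for every
#' species; no gaps introduced), ready for external alignment and tree
#' building (MAFFT, then Gblocks, then RAxML).
#'
#' @param groups monocore ortholog table from [select_monocore()].
#' @param proteomes named list of named protein vectors.
#' @return named character vector, species -> concatenated sequence.
#' @export
concatenate_monocore <- function(groups, proteomes) {
  if (!nrow(groups)) stop("no groups to concatenate")
  seqs <- unlist(unname(lapply(proteomes, function(p)
    setNames(as.character(p), names(p)))))
  species <- sort(unique(groups$species_id))
  gids <- sort(unique(groups$group_id))
  out <- setNames(character(length(species)), species)
  for (sp in species) {
    segs <- vapply(gids, function(g) {
      pid <- groups$protein_id[groups$group_id == g &
                                 groups$species_id == sp]
      if (length(pid) != 1L)
        stop("group ", g, " has no unique member for species ", sp)
      s <- seqs[pid]
      if (is.na(s)) stop("missing sequence for protein ", pid)
      s
    }, "")
    out[sp] <- paste(segs, collapse = "")
  }
  out
}

#' Export concatenated monocore sequences for external tree building
#'
#' Writes one FASTA record per species plus a run-script template whose
#' comments document the downstream tool settings used in the original
#' analysis (MAFFT v7; Gblocks `-t=p -b4=5 -b5=h`; RAxML PROTGAMMAWAG with
#' 100 bootstraps). Running those tools is outside this package's scope.
#'
#' @param concatenated result of [concatenate_monocore()].
#' @param dir output directory.
#' @return Invisibly, the FASTA path.
#' @export
export_phylogeny_input <- function(concatenated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "monocore_concatenated.faa")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(concatenated), fa,
                              width = 60L)
  script <- file.path(dir, "run_phylogeny.sh")
  writeLines(c(
    "#!/bin/sh",
    "# Downstream phylogeny from the concatenated monocore proteins.",
    "# mafft --thread 16 monocore_concatenated.faa > aligned.faa",
    "# Gblocks aligned.faa -t=p -b4=5 -b5=h",
    "# raxmlHPC-PTHREADS -s aligned.faa-gb -m PROTGAMMAWAG -N 100 -f a \\",
    "#   -x 12345 -p 12345 -n monocore_tree"), script)
  invisible(fa)
}
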