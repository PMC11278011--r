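#' Family detection configuration
#'
#' @param walk_steps random-walk length for the walktrap community
#'   algorithm (default 4).
#' @param max_members communities with more members than this are
#'   re-clustered by a second walktrap round on their induced subgraph;
#'   default `NULL` means "number of species in the network" (the rule is
#'   "more members than species in the analysis").
#' @return list of class `family_config`.
#' @export
family_config <- function(walk_steps = 4L, max_members = NULL) {
  stopifnot(walk_steps >= 1)
  structure(list(walk_steps = as.integer(walk_steps),
                 max_members = max_members),
            class = "family_config")
}

walktrap_partition <- function(g, steps) {
  if (igraph::vcount(g) == 1L) return(list(igraph::V(g)$name))
  wt <- igraph::cluster_walktrap(g, weights = igraph::E(g)$weight,
                                 steps = steps)
  ms <- igraph::membership(wt)
  unname(split(names(ms), ms))
}

#' Collapse the cluster network into SMGC families
#'
#' Walktrap random-walk community detection on the weighted cluster
#' network, run per connected component (isolated clusters become
#' singleton-member families). Any community with more members than
#' `max_members` is re-clustered by one further walktrap round on its
#' induced subgraph; a community still oversized after that is accepted
#' with a warning. The result is a partition of the node set. Family ids
#' are assigned in order of each family's smallest member cluster id, so
#' the labelling is deterministic.
#'
#' @param network igraph graph from [build_network()] (vertex attribute
#'   `species` required for the family table).
#' @param config a [family_config()].
#' @return data.frame ("family table") with `family_id`, `cluster_id`,
#'   `species_id`, `singleton_family` (family confined to one genome) and
#'   `compound_label` (NA until dereplication).
#' @export
detect_families <- function(network, config = family_config()) {
  n_species <- length(unique(igraph::V(network)$species))
  max_members <- config$max_members %||% n_species
  comps <- igraph::components(network)
  groups <- list()
  for (cid in seq_len(comps$no)) {
    verts <- names(comps$membership)[comps$membership == cid]
    if (length(verts) == 1L) { groups[[length(groups) + 1L]] <- verts; next }
    sub <- igraph::induced_subgraph(network, verts)
    part <- walktrap_partition(sub, config$walk_steps)
    for (comm in part) {
      if (length(comm) > max_members) {
        sub2 <- igraph::induced_subgraph(network, comm)
        part2 <- walktrap_partition(sub2, config$walk_steps)
        for (comm2 in part2) {
          if (length(comm2) > max_members)
            warning("community of ", length(comm2),
                    " members still exceeds max_members (", max_members,
                    ") after refinement; accepted as one family")
          groups[[length(groups) + 1L]] <- comm2
        }
      } else groups[[length(groups) + 1L]] <- comm
    }
  }
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[`, "", 1L))]
  species_of <- setNames(igraph::V(network)$species,
                         igraph::V(network)$name)
  rows <- lapply(seq_along(groups), function(i) {
    members <- groups[[i]]
    sp <- unname(species_of[members])
    data.frame(family_id = sprintf("F%03d", i), cluster_id = members,
               species_id = sp,
               singleton_family = length(unique(sp)) == 1L,
               compound_label = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(family_id = character(), cluster_id = character(),
               species_id = character(), singleton_family = logical(),
               compound_label = character())
  rownames(out) <- NULL
  out
}

#' Family and sharing statistics
#'
#' Totals mirroring the headline family statistics: number of families,
#' number of singleton families (present in exactly one genome), and
#' per-species counts of clusters and of unique families (families whose
#' members all come from that one species).
#'
#' @param families family table from [detect_families()].
#' @param clusters the full list of `smgc` objects the families were
#'   detected over; used to verify the family table is a partition.
#' @return list of class `family_stats`.
#' @export
family_statistics <- function(families, clusters) {
  ids <- sort(unname(vapply(clusters, `[[`, "", "cluster_id")))
  if (!identical(sort(unname(families$cluster_id)), ids) ||
      anyDuplicated(families$cluster_id))
    stop("family table is not a partition of the supplied clusters")
  species <- sort(unique(vapply(clusters, `[[`, "", "species_id")))
  fam_split <- split(families$species_id, families$family_id)
  n_fam <- length(fam_split)
  singleton <- vapply(fam_split, function(s) length(unique(s)) == 1L, TRUE)
  unique_counts <- vapply(species, function(sp)
    sum(vapply(fam_split, function(s) all(s == sp), TRUE)), 0L)
  cluster_counts <- vapply(species, function(sp)
    sum(families$species_id == sp), 0L)
  structure(list(n_families = n_fam,
                 n_singleton_families = sum(singleton),
                 unique_families_per_species = unique_counts,
                 clusters_per_species = cluster_counts),
            class = "family_stats")
}

#' @export
print.family_stats <- function(x, ...) {
  cat("SMGC families:", x$n_families, "(", x$n_singleton_families,
      "found in a single genome )\n")
  cat("clusters per species:\n")
  print(x$clusters_per_species)
  cat("unique families per species:\n")
  print(x$unique_families_per_species)
  invisible(x)
}

#' Directional shared-cluster percentage matrix
#'
#' Entry (A, B) is the percentage of species A's clusters whose family
#' also contains at least one cluster from species B. The matrix is
#' directional (nmax differs by row species) and its diagonal is 100.
#'
#' @param families family table from [detect_families()].
#' @return numeric matrix, species x species, values in \[0, 100\].
#' @export
shared_cluster_matrix <- function(families) {
  species <- sort(unique(families$species_id))
  fam_species <- split(families$species_id, families$family_id)
  m <- matrix(0, length(species), length(species),
              dimnames = list(species, species))
  for (a in species) {
    rows_a <- families[families$species_id == a, , drop = FALSE]
    n_a <- nrow(rows_a)
    if (!n_a) next
    for (b in species) {
      shared <- vapply(rows_a$family_id, function(f)
        b %in% fam_species[[f]], TRUE)
      m[a, b] <- 100 * sum(shared) / n_a
    }
  }
  m
}
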