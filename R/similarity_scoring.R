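#' Scoring configuration for cluster-pair similarity
#'
#' The cluster similarity score combines a tailoring-enzyme term (weight
#' 0.3) and a backbone-enzyme term (weight 0.7): each term is the summed
#' percent identity of matched enzyme pairs of that role, divided by the
#' larger of the two clusters' enzyme counts for the role (nmax). Weights
#' must sum to 1 so that identical clusters score exactly 100.
#'
#' @param w_tailoring,w_backbone term weights (defaults 0.3 / 0.7).
#' @param evalue_cutoff e-value cutoff the underlying hit table was built
#'   at (default 1e-10).
#' @param pairing_policy `"optimal_one_to_one"` (default): hits are reduced
#'   to a maximum-weight one-to-one matching between the two clusters'
#'   enzymes of a role, which bounds the score at 100.
#'   `"best_hit_per_query"`: every enzyme (in either cluster) contributes
#'   its best hit into the other cluster; an unbounded, literal "sum of all
#'   hits" reading kept for comparison.
#' @param edge_threshold minimum total score for a network edge (default 0:
#'   any positive score becomes an edge).
#' @return list of class `scoring_config`.
#' @export
scoring_config <- function(w_tailoring = 0.3, w_backbone = 0.7,
                           evalue_cutoff = 1e-10,
                           pairing_policy = c("optimal_one_to_one",
                                              "best_hit_per_query"),
                           edge_threshold = 0) {
  if (abs(w_tailoring + w_backbone - 1) > 1e-9)
    stop("w_tailoring + w_backbone must equal 1")
  structure(list(w_tailoring = w_tailoring, w_backbone = w_backbone,
                 evalue_cutoff = evalue_cutoff,
                 pairing_policy = match.arg(pairing_policy),
                 edge_threshold = edge_threshold),
            class = "scoring_config")
}

# symmetric pident lookup from a hit table; identical ids count as 100
pident_lookup <- function(hits) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  tab <- new.env(parent = emptyenv())
  if (nrow(hits)) {
    k <- key(hits$query_id, hits$subject_id)
    ord <- order(k, -hits$raw_score)
    first <- !duplicated(k[ord])
    for (i in which(first)) {
      j <- ord[i]
      assign(k[j], hits$pident[j], envir = tab)
    }
  }
  function(a, b) {
    if (a == b) return(100)
    v <- get0(key(a, b), envir = tab)
    if (is.null(v)) 0 else v
  }
}

# maximum-weight one-to-one assignment over a (possibly rectangular)
# non-negative matrix; exact bitmask DP over the smaller dimension
max_weight_assignment <- function(m) {
  if (!length(m) || all(m == 0)) return(0)
  if (nrow(m) > ncol(m)) m <- t(m)
  k <- nrow(m); n <- ncol(m)
  if (k > 20L) stop("assignment problem too large (", k, " x ", n, ")")
  best <- rep(0, 2^k)
  for (j in seq_len(n)) {
    prev <- best
    for (mask in seq_len(2^k) - 1L) {
      for (i in seq_len(k)) {
        bit <- bitwShiftL(1L, i - 1L)
        if (bitwAnd(mask, bit)) {
          cand <- prev[bitwXor(mask, bit) + 1L] + m[i, j]
          if (cand > best[mask + 1L]) best[mask + 1L] <- cand
        }
      }
    }
  }
  max(best)
}

role_proteins <- function(cluster, role)
  cluster$genes$protein_id[cluster$genes$role == role]

sum_pident <- function(prot_a, prot_b, lookup, policy) {
  if (!length(prot_a) || !length(prot_b)) return(0)
  m <- outer(prot_a, prot_b, Vectorize(lookup))
  if (policy == "optimal_one_to_one") max_weight_assignment(m)
  else sum(apply(m, 1, max)) / 2 + sum(apply(m, 2, max)) / 2
}

#' Score a pair of clusters
#'
#' Computes the tailoring term (summed pident of matched tailoring pairs /
#' nmax_tailoring, weighted 0.3), the backbone term (same with backbones,
#' weighted 0.7) and their total. Hits are restricted by role: tailoring
#' enzymes only pair with tailoring enzymes, backbones with backbones.
#' When both clusters lack tailoring genes the backbone weight is
#' renormalized to 1 (so self-similarity stays 100); when only one lacks
#' them the tailoring term is 0 with nmax from the other cluster.
#'
#' @param a,b `smgc` objects.
#' @param hits hit table from [all_vs_all()] over the clusters' proteins.
#' @param config a [scoring_config()].
#' @return one-row data.frame with the score components and `total`.
#' @export
score_pair <- function(a, b, hits, config = scoring_config()) {
  stopifnot(inherits(a, "smgc"), inherits(b, "smgc"))
  lookup <- if (is.function(hits)) hits else pident_lookup(hits)
  bb_a <- role_proteins(a, "backbone"); bb_b <- role_proteins(b, "backbone")
  if (!length(bb_a) || !length(bb_b))
    stop("cluster without a backbone gene cannot be scored")
  tl_a <- role_proteins(a, "tailoring"); tl_b <- role_proteins(b, "tailoring")

  nmax_bb <- max(length(bb_a), length(bb_b))
  nmax_tl <- max(length(tl_a), length(tl_b))
  sum_bb <- sum_pident(bb_a, bb_b, lookup, config$pairing_policy)
  sum_tl <- sum_pident(tl_a, tl_b, lookup, config$pairing_policy)

  w_tl <- config$w_tailoring; w_bb <- config$w_backbone
  if (nmax_tl == 0L) { w_bb <- 1; w_tl <- 0 }
  score_tl <- if (nmax_tl > 0L) sum_tl / nmax_tl * w_tl else 0
  score_bb <- sum_bb / nmax_bb * w_bb
  data.frame(cluster_a = a$cluster_id, cluster_b = b$cluster_id,
             sum_pident_tailoring = sum_tl, nmax_tailoring = nmax_tl,
             sum_pident_backbone = sum_bb, nmax_backbone = nmax_bb,
             score_tailoring = score_tl, score_backbone = score_bb,
             total = score_tl + score_bb, stringsAsFactors = FALSE)
}

#' Score all cluster pairs
#'
#' Evaluates [score_pair()] for every unordered pair of clusters. Pairs
#' whose proteins share no hit are skipped (their total is 0).
#'
#' @inheritParams build_network
#' @return data.frame of pair scores (total > 0 rows plus any computed
#'   zero rows omitted).
#' @export
score_all_pairs <- function(clusters, hits, config = scoring_config()) {
  lookup <- pident_lookup(hits)
  # which cluster pairs share at least one hit?
  prot2cl <- do.call(rbind, lapply(clusters, function(cl)
    data.frame(protein_id = cl$genes$protein_id, cluster_id = cl$cluster_id,
               stringsAsFactors = FALSE)))
  rows <- list()
  if (nrow(hits)) {
    map <- setNames(prot2cl$cluster_id, prot2cl$protein_id)
    ca <- map[hits$query_id]; cb <- map[hits$subject_id]
    keep <- !is.na(ca) & !is.na(cb) & ca != cb
    pairs <- unique(data.frame(a = pmin(ca[keep], cb[keep]),
                               b = pmax(ca[keep], cb[keep])))
    byid <- setNames(clusters, vapply(clusters, `[[`, "", "cluster_id"))
    for (i in seq_len(nrow(pairs))) {
      sc <- score_pair(byid[[pairs$a[i]]], byid[[pairs$b[i]]], lookup, config)
      rows[[length(rows) + 1L]] <- sc
    }
  }
  if (!length(rows))
    return(data.frame(cluster_a = character(), cluster_b = character(),
                      sum_pident_tailoring = numeric(),
                      nmax_tailoring = integer(),
                      sum_pident_backbone = numeric(),
                      nmax_backbone = integer(), score_tailoring = numeric(),
                      score_backbone = numeric(), total = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$cluster_a, out$cluster_b), , drop = FALSE]
}

#' Build the weighted cluster similarity network
#'
#' Nodes are all clusters (isolated ones included); undirected edges carry
#' the total pair score for every pair scoring above the configured
#' threshold.
#'
#' @param clusters list of `smgc` objects.
#' @param hits hit table over the clusters' proteins ([all_vs_all()]).
#' @param config a [scoring_config()].
#' @return igraph graph with vertex attribute `species` and edge attribute
#'   `weight`.
#' @export
build_network <- function(clusters, hits, config = scoring_config()) {
  ids <- vapply(clusters, `[[`, "", "cluster_id")
  species <- vapply(clusters, `[[`, "", "species_id")
  ord <- order(ids)
  scores <- score_all_pairs(clusters, hits, config)
  scores <- scores[scores$total > config$edge_threshold, , drop = FALSE]
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids[ord],
                            species = species[ord])
  if (nrow(scores))
    g <- igraph::add_edges(g, rbind(scores$cluster_a, scores$cluster_b),
                           weight = scores$total)
  g
}
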