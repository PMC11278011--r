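BACKBONE_CLASSES <- c("PKS", "PKS-like", "NRPS", "NRPS-like", "HYBRID",
                      "DMATS", "TC")

#' Default backbone rule table
#'
#' Loads the packaged PFAM -> domain-role table that the seven backbone class
#' rules are evaluated against. The table is plain TSV under
#' `inst/extdata/backbone_domain_roles.tsv` and can be replaced by any table
#' with columns `pfam_acc`, `domain_name`, `role`, where role is one of
#' `ks`, `at`, `pks_extra`, `c`, `a`, `carrier`, `te`, `red`, `dmats`, `tc`.
#'
#' @param path alternative role table; default = packaged table.
#' @return data.frame with a `role` per PFAM accession.
#' @export
default_backbone_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "backbone_domain_roles.tsv",
                                package = "smgctools")
  read_tsv(path)
}

#' Default SM-specific PFAM set
#'
#' PFAM domains treated as evidence of secondary-metabolism involvement when
#' extending cluster borders: the backbone domains plus common fungal
#' tailoring activities (P450s, monooxygenases, methyltransferases,
#' oxidoreductases, a halogenase). The list is a packaged, editable TSV; it
#' is a starting set, not a frozen enrichment analysis.
#'
#' @param path alternative TSV with a `pfam_acc` column.
#' @return character vector of PFAM accessions.
#' @export
default_sm_pfams <- function(path = NULL) {
  path <- path %||% system.file("extdata", "sm_pfams.tsv", package = "smgctools")
  read_tsv(path)$pfam_acc
}

#' Predictor configuration
#'
#' @param max_intergenic_bp largest intergenic gap (bp) allowed inside a
#'   cluster; default 3000 (the 3 kb rule). The gap between consecutive
#'   genes is `start(next) - end(prev) - 1`.
#' @param max_non_sm_genes largest run of consecutive genes without an
#'   SM-specific PFAM tolerated during extension; default 6.
#' @param rules domain-role table, see [default_backbone_rules()].
#' @param sm_pfams character vector of SM-specific PFAM accessions.
#' @param domain_evalue_cutoff domain hits above this e-value are ignored.
#' @param nrps_like_requires_condensation if `TRUE` (default) the NRPS-like
#'   rule requires adenylation + condensation + terminal thioesterase or
#'   reductase; if `FALSE` the condensation requirement is dropped.
#' @return list of class `predictor_config`.
#' @export
predictor_config <- function(max_intergenic_bp = 3000L, max_non_sm_genes = 6L,
                             rules = default_backbone_rules(),
                             sm_pfams = default_sm_pfams(),
                             domain_evalue_cutoff = 1e-5,
                             nrps_like_requires_condensation = TRUE) {
  stopifnot(max_intergenic_bp >= 0, max_non_sm_genes >= 0)
  structure(list(max_intergenic_bp = as.integer(max_intergenic_bp),
                 max_non_sm_genes = as.integer(max_non_sm_genes),
                 rules = rules, sm_pfams = sm_pfams,
                 domain_evalue_cutoff = domain_evalue_cutoff,
                 nrps_like_requires_condensation = nrps_like_requires_condensation),
            class = "predictor_config")
}

role_set <- function(rules, roles) rules$pfam_acc[rules$role %in% roles]

#' Classify a gene's PFAM composition into a backbone class
#'
#' Rules are evaluated in the fixed order HYBRID, PKS, NRPS, PKS-like,
#' NRPS-like, DMATS, TC and the first match wins, so a gene carrying both
#' PKS- and NRPS-defining domains (in any order along the protein) is a
#' HYBRID, never a plain PKS or NRPS.
#'
#' @param pfams character vector (multiset) of PFAM accessions on one gene,
#'   already filtered by e-value.
#' @param config a [predictor_config()].
#' @return `NULL` when no rule matches, otherwise a list with `class` and
#'   `matched_domains`.
#' @export
classify_backbone <- function(pfams, config = predictor_config()) {
  if (length(pfams) == 0L) return(NULL)
  rules <- config$rules
  p <- unique(pfams)
  ks <- intersect(p, role_set(rules, "ks"))
  at <- intersect(p, role_set(rules, "at"))
  pks_any <- intersect(p, role_set(rules, c("ks", "at")))
  pks_specific <- intersect(p, role_set(rules, c("ks", "at", "pks_extra")))
  cc <- intersect(p, role_set(rules, "c"))
  aa <- intersect(p, role_set(rules, "a"))
  nrps_any <- intersect(p, role_set(rules, c("c", "a")))
  carrier <- intersect(p, role_set(rules, "carrier"))
  te_red <- intersect(p, role_set(rules, c("te", "red")))
  dmats <- intersect(p, role_set(rules, "dmats"))
  tc <- intersect(p, role_set(rules, "tc"))

  hit <- function(class, matched)
    list(class = class, matched_domains = sort(matched))

  if (length(pks_any) && length(nrps_any))
    return(hit("HYBRID", c(pks_any, nrps_any)))
  if (length(ks) && length(at))
    return(hit("PKS", c(ks, at)))
  if (length(cc) && length(aa) && length(carrier))
    return(hit("NRPS", c(cc, aa, carrier)))
  if (length(pks_specific) >= 2L && length(setdiff(p, pks_specific)) >= 1L)
    return(hit("PKS-like", pks_specific))
  nrps_like <- if (config$nrps_like_requires_condensation)
    length(aa) && length(cc) && length(te_red)
  else
    length(aa) && length(te_red)
  if (nrps_like)
    return(hit("NRPS-like", c(aa, cc, te_red)))
  if (length(dmats)) return(hit("DMATS", dmats))
  if (length(tc)) return(hit("TC", tc))
  NULL
}

# per-gene annotation used by the extension walk
gene_annotations <- function(genome, config) {
  d <- genome$domains
  d <- d[d$evalue <= config$domain_evalue_cutoff, , drop = FALSE]
  by_prot <- split(d$pfam_acc, d$protein_id)
  g <- genome$genes
  pf <- by_prot[g$protein_id]
  calls <- lapply(pf, function(p) classify_backbone(p %||% character(), config))
  sm <- vapply(seq_len(nrow(g)), function(i) {
    length(intersect(pf[[i]] %||% character(), config$sm_pfams)) > 0L ||
      !is.null(calls[[i]])
  }, TRUE)
  list(pfams = pf, calls = calls, is_sm = sm,
       is_backbone = !vapply(calls, is.null, TRUE))
}

#' Predict secondary-metabolite gene clusters in one genome
#'
#' SMURF-style prediction: each backbone gene seeds a cluster that is
#' extended in both directions along its scaffold; extension stops at an
#' intergenic gap larger than `max_intergenic_bp` or once more than
#' `max_non_sm_genes` consecutive genes lack SM-specific PFAMs. Extensions
#' from different seeds that touch are merged, and cluster borders are
#' trimmed so the first and last member carry SM evidence (an SM-specific
#' PFAM or a backbone call).
#'
#' @param genome an [annotated_genome()].
#' @param config a [predictor_config()].
#' @return list of `smgc` objects (possibly empty). Each holds `cluster_id`,
#'   `species_id`, `scaffold`, a per-gene table with `role` (`backbone`,
#'   `tailoring`, `other`) and backbone `class`, and border coordinates.
#' @export
predict_clusters <- function(genome, config = predictor_config()) {
  stopifnot(inherits(genome, "annotated_genome"))
  ann <- gene_annotations(genome, config)
  g <- genome$genes
  clusters <- list()
  for (scf in unique(g$scaffold)) {
    idx <- which(g$scaffold == scf)
    sub <- g[idx, , drop = FALSE]
    n <- nrow(sub)
    is_sm <- ann$is_sm[idx]
    is_bb <- ann$is_backbone[idx]
    seeds <- which(is_bb)
    if (!length(seeds)) next
    gap_after <- if (n > 1L) sub$start[-1L] - sub$end[-n] - 1L else integer()

    extend <- function(seed) {
      lo <- hi <- seed
      run <- 0L
      i <- seed
      while (i < n) {
        if (gap_after[i] > config$max_intergenic_bp) break
        run2 <- if (is_sm[i + 1L]) 0L else run + 1L
        if (run2 > config$max_non_sm_genes) break
        i <- i + 1L; hi <- i; run <- run2
      }
      run <- 0L; i <- seed
      while (i > 1L) {
        if (gap_after[i - 1L] > config$max_intergenic_bp) break
        run2 <- if (is_sm[i - 1L]) 0L else run + 1L
        if (run2 > config$max_non_sm_genes) break
        i <- i - 1L; lo <- i; run <- run2
      }
      c(lo, hi)
    }
    ext <- t(vapply(seeds, extend, integer(2)))
    # merge touching/overlapping extents
    ord <- order(ext[, 1L])
    ext <- ext[ord, , drop = FALSE]
    merged <- list()
    cur <- ext[1L, ]
    for (k in seq_len(nrow(ext))[-1L]) {
      if (ext[k, 1L] <= cur[2L] + 0L) cur[2L] <- max(cur[2L], ext[k, 2L])
      else { merged[[length(merged) + 1L]] <- cur; cur <- ext[k, ] }
    }
    merged[[length(merged) + 1L]] <- cur
    for (ex in merged) {
      lo <- ex[1L]; hi <- ex[2L]
      while (lo < hi && !is_sm[lo]) lo <- lo + 1L
      while (hi > lo && !is_sm[hi]) hi <- hi - 1L
      members <- lo:hi
      roles <- ifelse(is_bb[members], "backbone",
                      ifelse(is_sm[members], "tailoring", "other"))
      classes <- vapply(members, function(m) {
        cl <- ann$calls[[idx[m]]]
        if (is.null(cl)) NA_character_ else cl$class
      }, "")
      gtab <- data.frame(gene_id = sub$gene_id[members],
                         protein_id = sub$protein_id[members],
                         start = sub$start[members], end = sub$end[members],
                         strand = sub$strand[members],
                         role = roles, class = classes,
                         stringsAsFactors = FALSE)
      clusters[[length(clusters) + 1L]] <- structure(
        list(cluster_id = NA_character_, species_id = genome$species_id,
             scaffold = scf, genes = gtab,
             start = min(gtab$start), end = max(gtab$end)),
        class = "smgc")
    }
  }
  if (length(clusters)) {
    ord <- order(vapply(clusters, function(cl) cl$scaffold, ""),
                 vapply(clusters, function(cl) cl$start, 1L))
    clusters <- clusters[ord]
    for (k in seq_along(clusters))
      clusters[[k]]$cluster_id <- sprintf("%s_c%03d", genome$species_id, k)
  }
  clusters
}

#' @export
print.smgc <- function(x, ...) {
  bb <- x$genes[x$genes$role == "backbone", ]
  cat(sprintf("smgc %s [%s:%d-%d] %d genes; backbones: %s\n",
              x$cluster_id, x$scaffold, x$start, x$end, nrow(x$genes),
              paste(sprintf("%s(%s)", bb$gene_id, bb$class), collapse = ", ")))
  invisible(x)
}

#' Flatten a list of clusters to a gene-per-row table
#' @param clusters list of `smgc` objects.
#' @return data.frame with one row per member gene.
#' @export
clusters_to_table <- function(clusters) {
  if (!length(clusters))
    return(data.frame(cluster_id = character(), species_id = character(),
                      scaffold = character(), gene_id = character(),
                      protein_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      role = character(), class = character()))
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(cluster_id = cl$cluster_id, species_id = cl$species_id,
               scaffold = cl$scaffold, cl$genes, stringsAsFactors = FALSE)
  }))
}

#' Backbone gene census by species and class
#'
#' Counts backbone genes (not clusters) per species and backbone class;
#' a cluster holding two PKS backbones contributes 2 to its species' PKS
#' column. Row sums therefore equal the total backbone genes per species.
#'
#' @param clusters list of `smgc` objects, typically pooled across genomes.
#' @return integer matrix, species x the 7 backbone classes.
#' @export
backbone_census <- function(clusters) {
  species <- sort(unique(vapply(clusters, function(cl) cl$species_id, "")))
  m <- matrix(0L, nrow = length(species), ncol = length(BACKBONE_CLASSES),
              dimnames = list(species, BACKBONE_CLASSES))
  for (cl in clusters) {
    bb <- cl$genes$class[cl$genes$role == "backbone"]
    for (b in bb) m[cl$species_id, b] <- m[cl$species_id, b] + 1L
  }
  m
}
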