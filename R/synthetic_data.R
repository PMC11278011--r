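AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")

# background PFAMs: common housekeeping domains, disjoint from the SM set
BACKGROUND_PFAMS <- c("PF00069", "PF00076", "PF00400", "PF00096", "PF00153",
                      "PF07690", "PF00172", "PF04082", "PF00012", "PF00271")

#' Simulation configuration for synthetic pangenomes
#'
#' Defines the study conditions for the generator: a small pangenome of
#' multi-scaffold genomes whose background genes carry only housekeeping
#' PFAMs, with secondary-metabolite cluster families planted at controlled
#' protein identity. Defaults describe six genomes with twelve planted
#' families at 85% cross-genome identity; intra-cluster gaps stay within
#' the 3 kb rule while background gaps exceed it, so planted extents are
#' unambiguous ground truth.
#'
#' @param n_species number of genomes.
#' @param scaffolds_per_genome scaffolds per genome.
#' @param genes_per_scaffold background genes per scaffold.
#' @param n_planted_families number of homologous cluster families.
#' @param family_presence either a probability in (0,1] that a family is
#'   present in a given species (every family is forced into at least one
#'   species), or a list of `n_planted_families` integer vectors of species
#'   indices giving an explicit presence/absence design.
#' @param backbone_class_mix named probability vector over the 7 backbone
#'   classes; default uniform.
#' @param tailoring_genes_per_cluster inclusive integer range.
#' @param intra_cluster_gap_bp inclusive bp range for gaps inside planted
#'   clusters; must stay at or below `max_intergenic_bp` of the predictor
#'   (3000 by default).
#' @param background_gap_bp inclusive bp range for all other gaps; the
#'   lower bound must exceed 3000 so planted borders are unambiguous.
#' @param target_identity percent identity planted between cross-genome
#'   homologs (substitution-only mutation from a family ancestor).
#' @param protein_length inclusive residue-length range.
#' @param seed integer seed; identical (config, seed) gives byte-identical
#'   outputs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_species = 6L, scaffolds_per_genome = 3L,
                       genes_per_scaffold = 30L, n_planted_families = 12L,
                       family_presence = 0.6,
                       backbone_class_mix = NULL,
                       tailoring_genes_per_cluster = c(2L, 4L),
                       intra_cluster_gap_bp = c(200L, 1500L),
                       background_gap_bp = c(3500L, 8000L),
                       target_identity = 85, protein_length = c(120L, 250L),
                       seed = 1L) {
  if (is.null(backbone_class_mix))
    backbone_class_mix <- setNames(rep(1 / 7, 7), BACKBONE_CLASSES)
  stopifnot(n_species >= 1, scaffolds_per_genome >= 1,
            genes_per_scaffold >= 1, n_planted_families >= 0,
            target_identity >= 0, target_identity <= 100,
            all(names(backbone_class_mix) %in% BACKBONE_CLASSES))
  if (min(background_gap_bp) <= max(intra_cluster_gap_bp))
    stop("background_gap_bp must exceed intra_cluster_gap_bp throughout")
  if (is.list(family_presence) &&
      length(family_presence) != n_planted_families)
    stop("family_presence list must have one entry per planted family")
  if (1L + max(tailoring_genes_per_cluster) > genes_per_scaffold)
    stop("largest planted cluster exceeds the per-scaffold gene budget")
  structure(list(n_species = as.integer(n_species),
                 scaffolds_per_genome = as.integer(scaffolds_per_genome),
                 genes_per_scaffold = as.integer(genes_per_scaffold),
                 n_planted_families = as.integer(n_planted_families),
                 family_presence = family_presence,
                 backbone_class_mix = backbone_class_mix,
                 tailoring_genes_per_cluster = tailoring_genes_per_cluster,
                 intra_cluster_gap_bp = intra_cluster_gap_bp,
                 background_gap_bp = background_gap_bp,
                 target_identity = target_identity,
                 protein_length = protein_length, seed = as.integer(seed)),
            class = "sim_config")
}

random_protein <- function(len) paste(sample_from(AA20, len, replace = TRUE),
                                      collapse = "")

#' Mutate a protein to a target percent identity
#'
#' Substitution-only mutation with an exact-count policy:
#' `floor(len * (100 - target_identity) / 100)` positions are substituted,
#' each by one of the 19 alternative residues chosen uniformly. Length is
#' preserved, so the Hamming identity to the input is controlled exactly.
#'
#' @param seq non-empty amino-acid string.
#' @param target_identity percent in `[0, 100]`.
#' @param seed optional seed for a deterministic result; `NULL` uses (and
#'   advances) the current RNG stream.
#' @return mutated amino-acid string.
#' @export
mutate_protein <- function(seq, target_identity, seed = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("cannot mutate an empty sequence")
  stopifnot(target_identity >= 0, target_identity <= 100)
  with_local_seed(seed, {
    len <- nchar(seq)
    n_mut <- floor(len * (100 - target_identity) / 100)
    if (n_mut == 0L) return(seq)
    chars <- strsplit(seq, "")[[1]]
    pos <- sample.int(len, n_mut)
    for (p in pos) {
      alts <- setdiff(AA20, chars[p])
      chars[p] <- sample_from(alts, 1L)
    }
    paste(chars, collapse = "")
  })
}

# substitute the given positions with a uniformly drawn different residue
mutate_at <- function(seq, positions) {
  if (!length(positions)) return(seq)
  chars <- strsplit(seq, "")[[1]]
  for (p in positions) chars[p] <- sample_from(setdiff(AA20, chars[p]), 1L)
  paste(chars, collapse = "")
}

backbone_composition <- function(class) {
  switch(class,
         "PKS" = c("PF00109", "PF02801", "PF00698", "PF00550"),
         "PKS-like" = c("PF00109", "PF08659", "PF00550"),
         "NRPS" = c("PF00668", "PF00501", "PF00550"),
         "NRPS-like" = c("PF00501", "PF00668", "PF00975"),
         "HYBRID" = c("PF00109", "PF00698", "PF00550", "PF00668", "PF00501"),
         "DMATS" = "PF11991",
         "TC" = "PF06330",
         stop("unknown backbone class: ", class))
}

tailoring_pfam_pool <- function() {
  setdiff(default_sm_pfams(), default_backbone_rules()$pfam_acc)
}

#' Generate a synthetic annotated pangenome with planted cluster families
#'
#' Every planted cluster consists of one backbone gene (carrying the full
#' multi-domain PFAM composition of its class) plus tailoring genes carrying
#' SM-specific PFAMs, embedded among background genes that carry only
#' housekeeping PFAMs. Homologous clusters across genomes share gene
#' content, with proteins mutated from a family ancestor to the configured
#' identity. Returns exact ground truth for cluster extents, backbone
#' classes and family labels.
#'
#' @param config a [sim_config()].
#' @return list with `genomes` (list of [annotated_genome()]) and `truth`
#'   (class `truth_table`: `$clusters` with species, family, class;
#'   `$genes` with per-gene family membership and role).
#' @export
generate_pangenome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    n_sp <- config$n_species
    species <- sprintf("sp%02d", seq_len(n_sp))
    tail_pool <- tailoring_pfam_pool()

    # family designs: ancestor proteins + domain compositions + presence
    fams <- lapply(seq_len(config$n_planted_families), function(f) {
      class <- sample_from(names(config$backbone_class_mix), 1L,
                           prob = config$backbone_class_mix)
      n_tail <- draw_range(config$tailoring_genes_per_cluster)
      lens <- draw_range(config$protein_length, n_tail + 1L)
      anc <- vapply(lens, random_protein, "")
      comps <- c(list(backbone_composition(class)),
                 lapply(seq_len(n_tail), function(i)
                   sample_from(tail_pool, draw_range(c(1L, 2L)))))
      roles <- c("backbone", rep("tailoring", n_tail))
      ord <- sample.int(n_tail + 1L)
      present <- if (is.list(config$family_presence)) {
        sort(as.integer(config$family_presence[[f]]))
      } else {
        p <- which(runif(n_sp) < config$family_presence)
        if (!length(p)) p <- sample.int(n_sp, 1L)
        p
      }
      # star design with disjoint per-species substitution sets: any two
      # planted homologs differ at exactly 2m positions, so their pairwise
      # identity is the configured target (up to rounding)
      anc <- anc[ord]; comps <- comps[ord]; roles <- roles[ord]
      lens <- lens[ord]
      mut_positions <- lapply(seq_along(anc), function(k) {
        m <- round(lens[k] * (100 - config$target_identity) / 200)
        if (m * length(present) > lens[k])
          stop("target_identity too low for the number of genomes carrying ",
               "a family (disjoint substitution sets do not fit)")
        perm <- sample.int(lens[k])
        lapply(seq_along(present), function(j)
          if (m == 0L) integer() else perm[((j - 1L) * m + 1L):(j * m)])
      })
      list(family_id = sprintf("fam%02d", f), class = class,
           ancestors = anc, comps = comps, roles = roles,
           present = present, mut_positions = mut_positions)
    })

    genomes <- vector("list", n_sp)
    truth_clusters <- list()
    truth_genes <- list()

    for (s in seq_len(n_sp)) {
      sp <- species[s]
      my_fams <- Filter(function(f) s %in% f$present, fams)
      scf_of <- if (length(my_fams))
        sample.int(config$scaffolds_per_genome, length(my_fams),
                   replace = TRUE) else integer()
      gene_rows <- list(); prot <- c(); dom_rows <- list()
      counter <- 0L
      for (scf in seq_len(config$scaffolds_per_genome)) {
        scf_name <- sprintf("%s_scaffold%d", sp, scf)
        fams_here <- my_fams[scf_of == scf]
        n_bg <- config$genes_per_scaffold
        slots <- if (length(fams_here))
          sort(sample.int(n_bg + 1L, length(fams_here), replace = TRUE) - 1L)
        else integer()
        pos <- 1L + draw_range(config$background_gap_bp)
        emit_gene <- function(seq, pfams, gap_next) {
          counter <<- counter + 1L
          gid <- sprintf("%s_g%04d", sp, counter)
          pid <- sprintf("%s_p%04d", sp, counter)
          len_bp <- 3L * nchar(seq)
          row <- data.frame(gene_id = gid, scaffold = scf_name,
                            start = pos, end = pos + len_bp - 1L,
                            strand = sample_from(c("+", "-"), 1L),
                            protein_id = pid, stringsAsFactors = FALSE)
          gene_rows[[length(gene_rows) + 1L]] <<- row
          prot[pid] <<- seq
          if (length(pfams)) {
            plen <- nchar(seq)
            k <- length(pfams)
            bounds <- floor(seq(1, plen, length.out = k + 1L))
            dom_rows[[length(dom_rows) + 1L]] <<- data.frame(
              protein_id = pid, pfam_acc = pfams,
              ali_start = pmax(1L, bounds[-(k + 1L)]),
              ali_end = pmax(1L, bounds[-1L] - 1L) + 1L,
              evalue = 10^-(draw_range(c(10L, 40L), k)),
              stringsAsFactors = FALSE)
          }
          pos <<- row$end + 1L + gap_next
          gid
        }
        emit_cluster <- function(fam) {
          n_genes <- length(fam$ancestors)
          j <- match(s, fam$present)
          gids <- character(n_genes)
          for (k in seq_len(n_genes)) {
            seq_k <- mutate_at(fam$ancestors[k], fam$mut_positions[[k]][[j]])
            gap <- if (k < n_genes) draw_range(config$intra_cluster_gap_bp)
                   else draw_range(config$background_gap_bp)
            gids[k] <- emit_gene(seq_k, fam$comps[[k]], gap)
          }
          truth_clusters[[length(truth_clusters) + 1L]] <<- data.frame(
            species_id = sp, family_id = fam$family_id,
            backbone_class = fam$class, n_genes = n_genes,
            stringsAsFactors = FALSE)
          truth_genes[[length(truth_genes) + 1L]] <<- data.frame(
            species_id = sp, family_id = fam$family_id, gene_id = gids,
            role = fam$roles, stringsAsFactors = FALSE)
        }
        ci <- 1L
        for (b in 0:n_bg) {
          while (ci <= length(slots) && slots[ci] == b) {
            emit_cluster(fams_here[[ci]]); ci <- ci + 1L
          }
          if (b < n_bg) {
            plen <- draw_range(config$protein_length)
            n_pf <- draw_range(c(0L, 3L))
            pf <- if (n_pf) sample_from(BACKGROUND_PFAMS, n_pf) else character()
            emit_gene(random_protein(plen), pf,
                      draw_range(config$background_gap_bp))
          }
        }
      }
      genomes[[s]] <- annotated_genome(sp, do.call(rbind, gene_rows),
                                       if (length(dom_rows))
                                         do.call(rbind, dom_rows) else NULL,
                                       prot)
    }
    truth <- structure(
      list(clusters = if (length(truth_clusters))
        do.call(rbind, truth_clusters) else
          data.frame(species_id = character(), family_id = character(),
                     backbone_class = character(), n_genes = integer()),
        genes = if (length(truth_genes)) do.call(rbind, truth_genes) else
          data.frame(species_id = character(), family_id = character(),
                     gene_id = character(), role = character())),
      class = "truth_table")
    list(genomes = setNames(genomes, species), truth = truth)
  })
}

#' Write a generated pangenome to disk
#'
#' Emits per-genome GFF3/FASTA/domain-TSV files in the dialects
#' [read_genome()] consumes, plus `truth_clusters.tsv` and
#' `truth_genes.tsv`.
#'
#' @param pangenome result of [generate_pangenome()].
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_pangenome <- function(pangenome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in pangenome$genomes) write_genome(g, dir)
  write_tsv(pangenome$truth$clusters, file.path(dir, "truth_clusters.tsv"))
  write_tsv(pangenome$truth$genes, file.path(dir, "truth_genes.tsv"))
  invisible(dir)
}
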