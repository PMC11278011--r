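#' Run the full SMGC analysis pipeline
#'
#' Wires the stages together: simulate (or load) genomes, predict clusters,
#' score cluster pairs, detect families, optionally dereplicate against a
#' local MIBiG GenBank directory and build ortholog groups, then write all
#' stage outputs plus a run manifest under `out_dir`. A fixed seed makes
#' the whole run byte-reproducible (all analysis stages are deterministic;
#' only the simulator consumes the seed).
#'
#' Config schema (YAML file or R list):
#' \preformatted{
#' simulate: {n_species: 6, n_planted_families: 12, ...}   # OR
#' genomes:
#'   - {species_id: spX, gff: x.gff3, proteins: x.faa, domains: x.tsv}
#' predict: {max_intergenic_bp: 3000, max_non_sm_genes: 6}
#' score: {w_tailoring: 0.3, w_backbone: 0.7, evalue_cutoff: 1.0e-10}
#' families: {walk_steps: 4}
#' dereplicate: {mibig_dir: path}        # optional stage
#' orthologs: {n_monocore: 5}            # optional stage
#' }
#'
#' @param config path to a YAML config or an equivalent named list.
#' @param out_dir output directory.
#' @param seed overrides `simulate$seed` when given.
#' @return the run manifest (named list), invisibly written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) {
    config_path <- config
    config <- yaml::read_yaml(config)
  } else config_path <- NA_character_
  if (is.null(config$simulate) && is.null(config$genomes))
    stop("config must provide either a 'simulate' block or 'genomes' paths")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  input_digests <- character()
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (!is.null(seed)) sim_args$seed <- seed
    scfg <- do.call(sim_config, sim_args)
    pan <- generate_pangenome(scfg)
    genomes <- pan$genomes
    truth <- pan$truth
    write_pangenome(pan, file.path(out_dir, "simulated"))
  } else {
    genomes <- lapply(config$genomes, function(g) {
      input_digests[c(g$gff, g$proteins, g$domains)] <<-
        tools::md5sum(c(g$gff, g$proteins, g$domains))
      read_genome(g$gff, g$proteins, g$domains, species_id = g$species_id)
    })
    names(genomes) <- vapply(genomes, `[[`, "", "species_id")
  }

  pcfg <- do.call(predictor_config, config$predict %||% list())
  clusters <- unlist(lapply(genomes, predict_clusters, config = pcfg),
                     recursive = FALSE)
  census <- backbone_census(clusters)

  proteomes <- lapply(genomes, `[[`, "proteins")
  cluster_prots <- unlist(unname(lapply(clusters, function(cl)
    cl$genes$protein_id)))
  all_seqs <- unlist(unname(proteomes))
  scfg2 <- do.call(scoring_config, config$score %||% list())
  hits <- all_vs_all(all_seqs[cluster_prots],
                     evalue_cutoff = scfg2$evalue_cutoff)
  network <- build_network(clusters, hits, scfg2)
  scores <- score_all_pairs(clusters, hits, scfg2)

  fcfg <- do.call(family_config, config$families %||% list())
  families <- detect_families(network, fcfg)

  if (!is.null(config$dereplicate)) {
    dcfg_args <- config$dereplicate
    mibig_dir <- dcfg_args$mibig_dir
    dcfg_args$mibig_dir <- NULL
    dcfg <- do.call(derep_config, dcfg_args)
    records <- load_mibig(mibig_dir, dcfg)
    families <- dereplicate_families(families, clusters, records,
                                     proteomes, dcfg)
  }

  stats <- family_statistics(families, clusters)
  shared <- shared_cluster_matrix(families)
  paths <- write_outputs(list(clusters = clusters, scores = scores,
                              families = families, shared_matrix = shared),
                         out_dir)
  census_df <- data.frame(species = rownames(census), census,
                          check.names = FALSE)
  paths["census"] <- write_tsv(census_df, file.path(out_dir, "backbone_census.tsv"))

  if (!is.null(config$orthologs)) {
    og <- best_bidirectional_hits(proteomes)
    n_mono <- config$orthologs$n_monocore %||%
      sum(tapply(og$monocore, og$group_id, any))
    sel <- select_monocore(og, n = n_mono)
    concat <- concatenate_monocore(sel, proteomes)
    export_phylogeny_input(concat, file.path(out_dir, "phylogeny"))
    paths["orthologs"] <- write_tsv(og, file.path(out_dir, "ortholog_groups.tsv"))
  }

  jsonlite::write_json(list(n_clusters = length(clusters),
                            n_families = stats$n_families,
                            n_singleton_families = stats$n_singleton_families,
                            clusters_per_species = as.list(stats$clusters_per_species),
                            unique_families_per_species =
                              as.list(stats$unique_families_per_species)),
                       file.path(out_dir, "family_stats.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  # manifest paths are relative to out_dir so identical runs are
  # byte-identical wherever they land
  rel <- function(p) sub("^/", "", sub(normalizePath(out_dir), "",
                                       normalizePath(p), fixed = TRUE))
  digests <- tools::md5sum(unname(paths))
  manifest <- list(tool = "smgctools",
                   version = as.character(utils::packageVersion("smgctools")),
                   seed = seed %||% config$simulate$seed %||% NA,
                   config = config,
                   input_digests = as.list(input_digests),
                   outputs = as.list(setNames(vapply(paths, rel, ""),
                                              names(paths))),
                   output_digests = as.list(setNames(unname(digests),
                                                     vapply(names(digests),
                                                            rel, ""))))
  tmp <- file.path(out_dir, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", force = TRUE)
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
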