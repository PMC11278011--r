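#' Construct an annotated genome
#'
#' The central per-species container: ordered gene models, PFAM domain hits
#' and protein sequences. Genes are sorted by scaffold then start coordinate
#' (1-based, inclusive, GFF3 convention). Every gene must map to exactly one
#' protein sequence; proteins not referenced by any gene are dropped with a
#' warning.
#'
#' @param species_id single string naming the genome.
#' @param genes data.frame with columns `gene_id`, `scaffold`, `start`,
#'   `end`, `strand`, `protein_id`.
#' @param domains data.frame with columns `protein_id`, `pfam_acc`,
#'   `ali_start`, `ali_end`, `evalue`. May have zero rows.
#' @param proteins named character vector of amino-acid sequences, names are
#'   protein ids.
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(species_id, genes, domains, proteins) {
  stopifnot(is.character(species_id), length(species_id) == 1L)
  need <- c("gene_id", "scaffold", "start", "end", "strand", "protein_id")
  if (!all(need %in% names(genes)))
    stop("genes is missing columns: ", paste(setdiff(need, names(genes)), collapse = ", "))
  genes <- as.data.frame(genes)[need]
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  bad <- genes$start > genes$end
  if (any(bad))
    stop("gene(s) with start > end: ", paste(genes$gene_id[bad], collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene_id: ", genes$gene_id[duplicated(genes$gene_id)][1])
  proteins <- vapply(proteins, as.character, "", USE.NAMES = TRUE)
  missing_prot <- setdiff(genes$protein_id, names(proteins))
  if (length(missing_prot))
    stop("no protein sequence for gene(s) ",
         paste(genes$gene_id[genes$protein_id %in% missing_prot], collapse = ", "),
         " (protein ids: ", paste(missing_prot, collapse = ", "), ")")
  unused <- setdiff(names(proteins), genes$protein_id)
  if (length(unused)) {
    warning(length(unused), " protein(s) not referenced by any gene were dropped")
    proteins <- proteins[setdiff(names(proteins), unused)]
  }
  dneed <- c("protein_id", "pfam_acc", "ali_start", "ali_end", "evalue")
  if (is.null(domains) || nrow(as.data.frame(domains)) == 0L) {
    domains <- data.frame(protein_id = character(), pfam_acc = character(),
                          ali_start = integer(), ali_end = integer(),
                          evalue = numeric())
  } else {
    domains <- as.data.frame(domains)
    if (!all(dneed %in% names(domains)))
      stop("domains is missing columns: ",
           paste(setdiff(dneed, names(domains)), collapse = ", "))
    domains <- domains[dneed]
    unk <- setdiff(domains$protein_id, names(proteins))
    if (length(unk))
      stop("domain hit(s) reference absent protein(s): ",
           paste(unique(unk), collapse = ", "))
    odd <- !grepl("^PF\\d{5}$", domains$pfam_acc)
    if (any(odd))
      warning("PFAM accession(s) not matching PF#####: ",
              paste(unique(domains$pfam_acc[odd]), collapse = ", "),
              " (kept)")
    if (any(domains$ali_start > domains$ali_end))
      stop("domain hit with ali_start > ali_end")
  }
  ord <- order(genes$scaffold, genes$start, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(species_id = species_id, genes = genes,
                 domains = domains, proteins = proteins),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("annotated_genome:", x$species_id, "\n")
  cat(" ", nrow(x$genes), "genes on", length(unique(x$genes$scaffold)),
      "scaffold(s);", nrow(x$domains), "domain hits;",
      length(x$proteins), "proteins\n")
  invisible(x)
}

#' Read an annotated genome from GFF3 + protein FASTA + domain table
#'
#' Gene models are taken from GFF3 `gene` features (falling back to `mRNA`
#' when no `gene` features are present); the protein id is read from a
#' `proteinId` or `protein_id` attribute, defaulting to the feature `ID`.
#' Parsing does not depend on feature order within a scaffold: genes are
#' re-sorted by coordinate.
#'
#' @param gff_path path to a GFF3 file.
#' @param protein_fasta_path path to a protein FASTA; ids are the first
#'   whitespace-separated token of each header.
#' @param domain_table_path path to a 5-column TSV with header
#'   `protein_id pfam_acc ali_start ali_end evalue`, or `NULL` for none.
#' @param species_id genome label; defaults to the GFF file name stem.
#' @return An [annotated_genome()].
#' @export
read_genome <- function(gff_path, protein_fasta_path, domain_table_path = NULL,
                        species_id = NULL) {
  species_id <- species_id %||% sub("\\.gff3?$", "", basename(gff_path))
  gr <- tryCatch(rtracklayer::import(gff_path),
                 error = function(e) stop("failed to parse GFF3 '", gff_path,
                                          "': ", conditionMessage(e)))
  df <- as.data.frame(gr)
  if ("type" %in% names(df)) {
    keep <- df$type == "gene"
    if (!any(keep)) keep <- df$type == "mRNA"
    df <- df[keep, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no gene/mRNA features in ", gff_path)
  pid <- df[["proteinId"]] %||% df[["protein_id"]] %||% df[["ID"]]
  genes <- data.frame(gene_id = as.character(df$ID),
                      scaffold = as.character(df$seqnames),
                      start = df$start, end = df$end,
                      strand = as.character(df$strand),
                      protein_id = as.character(pid))
  aa <- Biostrings::readAAStringSet(protein_fasta_path)
  proteins <- setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  domains <- NULL
  if (!is.null(domain_table_path)) {
    domains <- read.delim(domain_table_path, stringsAsFactors = FALSE)
    names(domains) <- tolower(names(domains))
  }
  annotated_genome(species_id, genes, domains, proteins)
}

#' Write an annotated genome to GFF3 + FASTA + domain TSV
#'
#' Emits the same dialects [read_genome()] consumes, with deterministic
#' ordering (genes by scaffold then start, proteins by gene order, domain
#' rows by protein id then accession).
#'
#' @param genome an [annotated_genome()].
#' @param dir output directory (created if absent).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_genome <- function(genome, dir) {
  stopifnot(inherits(genome, "annotated_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- genome$genes
  gff <- file.path(dir, paste0(genome$species_id, ".gff3"))
  lines <- c("##gff-version 3",
             sprintf("%s\tsmgctools\tgene\t%d\t%d\t.\t%s\t.\tID=%s;proteinId=%s",
                     g$scaffold, g$start, g$end, g$strand, g$gene_id, g$protein_id))
  writeLines(lines, gff)
  faa <- file.path(dir, paste0(genome$species_id, "_proteins.faa"))
  aa <- Biostrings::AAStringSet(genome$proteins[g$protein_id])
  Biostrings::writeXStringSet(aa, faa, width = 60L)
  dom <- file.path(dir, paste0(genome$species_id, "_domains.tsv"))
  d <- genome$domains
  d <- d[order(d$protein_id, d$pfam_acc, d$ali_start), , drop = FALSE]
  write_tsv(d, dom)
  invisible(c(gff = gff, proteins = faa, domains = dom))
}

# deterministic TSV writer shared by all modules
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write pipeline result tables as TSV files
#'
#' Accepts any subset of the pipeline's tabular results and writes each with
#' a deterministic row order (sorted by its id columns).
#'
#' @param results named list with any of: `clusters` (gene-per-row cluster
#'   table, see [clusters_to_table()]), `scores` (cluster-pair score table),
#'   `families` (family membership table), `shared_matrix` (species x
#'   species percentage matrix).
#' @param out_dir output directory, created if absent.
#' @return Invisibly, named vector of written paths.
#' @export
write_outputs <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  if (!is.null(results$clusters)) {
    tab <- results$clusters
    if (!is.data.frame(tab)) tab <- clusters_to_table(tab)
    tab <- tab[order(tab$cluster_id, tab$gene_id), , drop = FALSE]
    paths["clusters"] <- write_tsv(tab, file.path(out_dir, "clusters.tsv"))
  }
  if (!is.null(results$scores)) {
    sc <- results$scores
    sc <- sc[order(sc$cluster_a, sc$cluster_b), , drop = FALSE]
    paths["scores"] <- write_tsv(sc, file.path(out_dir, "scores.tsv"))
  }
  if (!is.null(results$families)) {
    fam <- results$families
    fam <- fam[order(fam$family_id, fam$cluster_id), , drop = FALSE]
    paths["families"] <- write_tsv(fam, file.path(out_dir, "families.tsv"))
  }
  if (!is.null(results$shared_matrix)) {
    m <- results$shared_matrix
    df <- data.frame(species = rownames(m), as.data.frame(m),
                     check.names = FALSE)
    paths["shared_matrix"] <- write_tsv(df, file.path(out_dir, "shared_matrix.tsv"))
  }
  invisible(paths)
}

#' Read back tables written by [write_outputs()]
#' @param path file path.
#' @return data.frame (or matrix for the shared matrix).
#' @export
read_cluster_table <- function(path) read_tsv(path)

#' @rdname read_cluster_table
#' @export
read_score_table <- function(path) read_tsv(path)

#' @rdname read_cluster_table
#' @export
read_family_table <- function(path) {
  df <- read_tsv(path)
  if ("singleton_family" %in% names(df))
    df$singleton_family <- as.logical(df$singleton_family)
  df
}

#' @rdname read_cluster_table
#' @export
read_shared_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
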