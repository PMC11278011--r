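AA20_FIX <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
              "S","T","W","Y","V")

random_aa <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA20_FIX, len, replace = TRUE), collapse = "")
}

# substitute fixed positions with a guaranteed-different residue, so the
# resulting pair has an exactly known Hamming identity with interior
# (never terminal) mismatches
substitute_at <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1]]
  for (p in positions) chars[p] <- if (chars[p] == "A") "V" else "A"
  paste(chars, collapse = "")
}

# build an smgc object directly (for scoring tests that bypass prediction)
make_smgc <- function(cluster_id, species_id, backbone_prots, tailoring_prots,
                      scaffold = "scf1") {
  n <- length(backbone_prots) + length(tailoring_prots)
  genes <- data.frame(
    gene_id = paste0(cluster_id, "_g", seq_len(n)),
    protein_id = c(backbone_prots, tailoring_prots),
    start = seq_len(n) * 1000L, end = seq_len(n) * 1000L + 500L,
    strand = "+",
    role = c(rep("backbone", length(backbone_prots)),
             rep("tailoring", length(tailoring_prots))),
    class = c(rep("PKS", length(backbone_prots)),
              rep(NA_character_, length(tailoring_prots))),
    stringsAsFactors = FALSE)
  structure(list(cluster_id = cluster_id, species_id = species_id,
                 scaffold = scaffold, genes = genes,
                 start = min(genes$start), end = max(genes$end)),
            class = "smgc")
}

# hit table with prescribed symmetric pidents; raw_score is a dummy that
# preserves the best-per-pair selection
make_hits <- function(pairs) {
  # pairs: data.frame(query_id, subject_id, pident)
  if (nrow(pairs) == 0L)
    return(data.frame(query_id = character(), subject_id = character(),
                      pident = numeric(), ali_len = integer(),
                      query_cov = numeric(), subject_cov = numeric(),
                      raw_score = integer(), evalue = numeric()))
  fwd <- data.frame(query_id = pairs$query_id, subject_id = pairs$subject_id,
                    pident = pairs$pident, ali_len = 100L, query_cov = 1,
                    subject_cov = 1, raw_score = as.integer(pairs$pident * 5),
                    evalue = 1e-30, stringsAsFactors = FALSE)
  rev <- fwd
  rev$query_id <- fwd$subject_id
  rev$subject_id <- fwd$query_id
  rbind(fwd, rev)
}

read_tsv2 <- function(path) read.delim(path, stringsAsFactors = FALSE)

empty_hits <- function() {
  make_hits(data.frame(query_id = character(), subject_id = character(),
                       pident = numeric()))
}

# toy annotated genome from a compact spec: a list of gene entries
# list(pfams=..., len_bp=..., gap_after=...); coordinates are accumulated
toy_genome <- function(entries, species_id = "toy", scaffold = "scf1") {
  pos <- 1L
  genes <- list(); doms <- list(); prots <- c()
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    len <- e$len_bp %||% 900L
    gid <- sprintf("%s_g%02d", species_id, i)
    pid <- sprintf("%s_p%02d", species_id, i)
    genes[[i]] <- data.frame(gene_id = gid, scaffold = scaffold,
                             start = pos, end = pos + len - 1L,
                             strand = "+", protein_id = pid,
                             stringsAsFactors = FALSE)
    prots[pid] <- random_aa(len %/% 3L)
    if (length(e$pfams))
      doms[[length(doms) + 1L]] <- data.frame(
        protein_id = pid, pfam_acc = e$pfams, ali_start = 1L,
        ali_end = 50L, evalue = 1e-20, stringsAsFactors = FALSE)
    pos <- pos + len + (e$gap_after %||% 1000L)
  }
  annotated_genome(species_id, do.call(rbind, genes),
                   if (length(doms)) do.call(rbind, doms) else NULL, prots)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive maximum one-to-one pairing oracle: enumerate all injective
# assignments of the smaller side into the larger
enum_assignment <- function(m) {
  if (nrow(m) > ncol(m)) m <- t(m)
  k <- nrow(m); n <- ncol(m)
  best <- 0
  rec <- function(i, used, acc) {
    if (i > k) { best <<- max(best, acc); return(invisible()) }
    rec(i + 1L, used, acc)  # row i unmatched
    for (j in seq_len(n)) if (!used[j]) {
      used[j] <- TRUE
      rec(i + 1L, used, acc + m[i, j])
      used[j] <- FALSE
    }
  }
  rec(1L, rep(FALSE, n), 0)
  best
}

# synthetic GenBank record text (minimal MIBiG-like layout)
synthetic_genbank <- function(accession, compound, organism, proteins) {
  wrap_tr <- function(s) {
    out <- c()
    first <- TRUE
    while (nchar(s) > 0) {
      take <- if (first) 44 else 58
      out <- c(out, paste0(if (first) "                     /translation=\""
                           else "                     ",
                           substr(s, 1, take),
                           if (nchar(s) <= take) "\"" else ""))
      s <- substr(s, take + 1, nchar(s))
      first <- FALSE
    }
    out
  }
  lines <- c(
    sprintf("LOCUS       %s             5000 bp    DNA     linear   PLN 01-JAN-2020", accession),
    sprintf("DEFINITION  %s biosynthetic gene cluster.", compound),
    sprintf("ACCESSION   %s", accession),
    sprintf("VERSION     %s.1", accession),
    "SOURCE      synthetic construct",
    sprintf("  ORGANISM  %s", organism),
    "            Eukaryota; Fungi.",
    "FEATURES             Location/Qualifiers",
    "     source          1..5000",
    sprintf("                     /organism=\"%s\"", organism))
  for (i in seq_along(proteins)) {
    pid <- names(proteins)[i]
    lines <- c(lines,
               sprintf("     CDS             %d..%d", i * 100, i * 100 + 99),
               sprintf("                     /protein_id=\"%s\"", pid))
    if (!is.na(proteins[[i]]))
      lines <- c(lines, wrap_tr(proteins[[i]]))
  }
  c(lines, "ORIGIN", "//")
}

write_genbank_dir <- function(records, dir = tempfile("gbk")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(records))
    writeLines(records[[i]], file.path(dir, sprintf("rec%02d.gbk", i)))
  dir
}

# adjusted Rand index between two labelled partitions (named vectors)
ari <- function(a, b) {
  b <- b[names(a)]
  mclust::adjustedRandIndex(unname(a), unname(b))
}

# truth family label per predicted cluster (via its first gene)
truth_labels <- function(clusters, truth) {
  map <- setNames(truth$genes$family_id, truth$genes$gene_id)
  setNames(unname(map[vapply(clusters, function(cl) cl$genes$gene_id[1], "")]),
           vapply(clusters, `[[`, "", "cluster_id"))
}

pooled_predict <- function(pan, config = predictor_config()) {
  unlist(lapply(pan$genomes, predict_clusters, config = config),
         recursive = FALSE)
}

cluster_hit_table <- function(pan, clusters, evalue_cutoff = 1e-10) {
  prots <- unlist(unname(lapply(pan$genomes, function(g) g$proteins)))
  cp <- unlist(lapply(clusters, function(cl) cl$genes$protein_id))
  all_vs_all(prots[cp], evalue_cutoff = evalue_cutoff)
}
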