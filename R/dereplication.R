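#' Dereplication configuration
#'
#' @param min_pident labelling requires a hit strictly above this percent
#'   identity (default 95, i.e. "over 95%").
#' @param min_query_cov minimum fraction of the MIBiG query protein covered
#'   by the alignment (default 0.5); identity over tiny local alignments is
#'   not evidence.
#' @param taxon_filter organism substrings a record must match (default
#'   Aspergillus/Penicillium).
#' @param multi_gene if `TRUE`, a family is labelled only when at least two
#'   distinct record proteins hit it (stricter mode, off by default: a
#'   single qualifying protein hit suffices).
#' @param evalue_cutoff alignment e-value cutoff for the search.
#' @return list of class `derep_config`.
#' @export
derep_config <- function(min_pident = 95, min_query_cov = 0.5,
                         taxon_filter = c("Aspergillus", "Penicillium"),
                         multi_gene = FALSE, evalue_cutoff = 1e-10) {
  stopifnot(min_pident > 0, min_pident <= 100)
  structure(list(min_pident = min_pident, min_query_cov = min_query_cov,
                 taxon_filter = taxon_filter, multi_gene = multi_gene,
                 evalue_cutoff = evalue_cutoff),
            class = "derep_config")
}

# Minimal GenBank flat-file reader: ACCESSION, DEFINITION, ORGANISM and CDS
# /protein_id + /translation qualifiers. No conceptual translation is
# attempted; a CDS without a translation qualifier is skipped with a
# warning. Sufficient for MIBiG region files; not a general GenBank parser.
parse_genbank_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(startsWith(lines, "LOCUS")))
    stop("no LOCUS line")
  field <- function(key) {
    i <- grep(paste0("^", key, "\\b"), lines)
    if (!length(i)) return(NA_character_)
    val <- sub(paste0("^", key, "\\s+"), "", lines[i[1]])
    j <- i[1] + 1L
    while (j <= length(lines) && grepl("^\\s{10,}", lines[j]) &&
           !grepl("^\\s*/", lines[j])) {
      val <- paste(val, trimws(lines[j])); j <- j + 1L
    }
    trimws(val)
  }
  accession <- strsplit(field("ACCESSION"), "\\s+")[[1]][1]
  definition <- field("DEFINITION")
  org_i <- grep("^\\s{2,}ORGANISM", lines)
  organism <- if (length(org_i))
    trimws(sub("^\\s+ORGANISM\\s+", "", lines[org_i[1]])) else NA_character_

  proteins <- character(); pnames <- character()
  cds_i <- grep("^\\s{5}CDS\\s", lines)
  feat_i <- grep("^\\s{5}\\S", lines)
  for (ci in cds_i) {
    nxt <- feat_i[feat_i > ci]
    block <- lines[ci:(if (length(nxt)) nxt[1] - 1L else length(lines))]
    block <- block[!startsWith(block, "ORIGIN")]
    txt <- paste(trimws(block), collapse = "\n")
    pid <- sub('.*?/protein_id="([^"]+)".*', "\\1", txt)
    if (identical(pid, txt)) pid <- NA_character_
    tr_m <- regmatches(txt, regexpr('/translation="[^"]*"', txt))
    if (!length(tr_m)) {
      warning("CDS ", if (is.na(pid)) "(unnamed)" else pid, " in ",
              basename(path), " has no translation qualifier; skipped")
      next
    }
    tr <- gsub("\\s", "", sub('/translation="([^"]*)"', "\\1", tr_m))
    if (is.na(pid)) pid <- sprintf("%s_cds%d", accession, length(proteins) + 1L)
    proteins <- c(proteins, tr); pnames <- c(pnames, pid)
  }
  compound <- sub("\\s+biosynthetic gene cluster.*$", "", definition,
                  ignore.case = TRUE)
  compound <- sub("\\.$", "", compound)
  list(accession = accession, compound_name = compound,
       organism = organism, proteins = setNames(proteins, pnames))
}

#' Load MIBiG-style GenBank records
#'
#' Reads every `.gb`/`.gbk`/`.gbff`/`.genbank` file in a directory,
#' extracts CDS translations, and keeps records whose organism matches the
#' taxon filter. Unparseable files are skipped with a warning; ending up
#' with zero records is an error.
#'
#' @param genbank_dir directory of GenBank files.
#' @param config a [derep_config()].
#' @return list of `mibig_record` objects (accession, compound_name,
#'   organism, named protein vector).
#' @export
load_mibig <- function(genbank_dir, config = derep_config()) {
  files <- list.files(genbank_dir, pattern = "\\.(gb|gbk|gbff|genbank)$",
                      full.names = TRUE)
  records <- list()
  for (f in sort(files)) {
    rec <- tryCatch(parse_genbank_file(f), error = function(e) {
      warning("skipping unparseable GenBank file ", basename(f), ": ",
              conditionMessage(e))
      NULL
    })
    if (is.null(rec)) next
    if (!is.na(rec$organism) &&
        any(vapply(config$taxon_filter, grepl, TRUE, x = rec$organism,
                   fixed = TRUE)) && length(rec$proteins))
      records[[length(records) + 1L]] <- structure(rec,
                                                   class = "mibig_record")
  }
  if (!length(records))
    stop("no MIBiG records left after taxon filtering in ", genbank_dir)
  records
}

#' Dereplicate SMGC families against characterized cluster records
#'
#' Searches every record protein against all cluster proteins. A cluster
#' protein hit with pident strictly above `min_pident` and query coverage
#' at least `min_query_cov` links the record to that cluster's family, and
#' the label propagates to every cluster of the family (family-closed
#' labelling). Labels from multiple records are concatenated sorted by
#' accession.
#'
#' @param families family table from [detect_families()].
#' @param clusters list of `smgc` objects (for protein -> cluster mapping).
#' @param records list from [load_mibig()].
#' @param proteomes named list or vector with the clusters' protein
#'   sequences (protein_id -> sequence).
#' @param config a [derep_config()].
#' @param hits optional precomputed hit table (query = record proteins,
#'   subject = cluster proteins); computed internally when `NULL`.
#' @return the family table with `compound_label` filled in
#'   (`"ACCESSION:compound"`, `"; "`-separated when several).
#' @export
dereplicate_families <- function(families, clusters, records, proteomes,
                                 config = derep_config(), hits = NULL) {
  prot2cl <- do.call(rbind, lapply(clusters, function(cl)
    data.frame(protein_id = cl$genes$protein_id,
               cluster_id = cl$cluster_id, stringsAsFactors = FALSE)))
  cl2fam <- setNames(families$family_id, families$cluster_id)
  seqs <- unlist(unname(lapply(
    if (is.list(proteomes)) proteomes else list(proteomes),
    function(p) setNames(as.character(p), names(p)))))
  cluster_prots <- seqs[intersect(names(seqs), prot2cl$protein_id)]

  labels_by_family <- list()
  for (rec in records) {
    qnames <- paste0("mibigq|", names(rec$proteins))
    queries <- setNames(rec$proteins, qnames)
    h <- if (is.null(hits)) {
      cross_align(queries, cluster_prots,
                  evalue_cutoff = config$evalue_cutoff)
    } else {
      hh <- hits[hits$query_id %in% c(names(rec$proteins), qnames), ,
                 drop = FALSE]
      hh
    }
    ok <- h[h$pident > config$min_pident &
              h$query_cov >= config$min_query_cov, , drop = FALSE]
    if (!nrow(ok)) next
    sub_id <- sub("^mibigq\\|", "", ok$subject_id)
    cls <- prot2cl$cluster_id[match(sub_id, prot2cl$protein_id)]
    fams <- unique(cl2fam[cls[!is.na(cls)]])
    if (config$multi_gene) {
      qok <- sub("^mibigq\\|", "", ok$query_id)
      per_fam <- tapply(qok, cl2fam[cls], function(q) length(unique(q)))
      fams <- names(per_fam)[per_fam >= 2L]
    }
    label <- sprintf("%s:%s", rec$accession, rec$compound_name)
    for (f in fams[!is.na(fams)])
      labels_by_family[[f]] <- union(labels_by_family[[f]], label)
  }
  families$compound_label <- vapply(families$family_id, function(f) {
    l <- labels_by_family[[f]]
    if (is.null(l)) NA_character_ else paste(sort(l), collapse = "; ")
  }, "")
  families
}

#' Compound presence/absence matrix
#'
#' One row per compound label, one column per species; TRUE when the
#' species has a cluster in a family carrying the label.
#'
#' @param families labelled family table from [dereplicate_families()].
#' @return logical matrix (possibly 0-row).
#' @export
compound_presence_matrix <- function(families) {
  lab <- families[!is.na(families$compound_label), , drop = FALSE]
  species <- sort(unique(families$species_id))
  labels <- sort(unique(unlist(strsplit(lab$compound_label, "; ",
                                        fixed = TRUE))))
  m <- matrix(FALSE, length(labels), length(species),
              dimnames = list(labels, species))
  for (i in seq_len(nrow(lab))) {
    for (l in strsplit(lab$compound_label[i], "; ", fixed = TRUE)[[1]])
      m[l, lab$species_id[i]] <- TRUE
  }
  m
}
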