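AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V","B","Z","X")

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      cache <<- m[AA_ALPHABET, AA_ALPHABET]
      storage.mode(cache) <<- "integer"
    }
    cache
  }
})

#' Alignment parameters
#'
#' Local alignment under BLOSUM62 with affine gaps: a gap of length k costs
#' `gap_open + k * gap_extension` (BLAST convention for open 11 / extend 1).
#' E-values use the Karlin-Altschul formula `E = K * m * n * exp(-lambda*S)`
#' with the published gapped BLOSUM62(11,1) parameters.
#'
#' @param gap_open,gap_extension affine gap costs.
#' @param lambda,K Karlin-Altschul parameters.
#' @param evalue_cutoff hits with larger e-value are discarded.
#' @return list of class `alignment_params`.
#' @export
alignment_params <- function(gap_open = 11L, gap_extension = 1L,
                             lambda = 0.267, K = 0.041,
                             evalue_cutoff = 1e-10) {
  structure(list(gap_open = as.integer(gap_open),
                 gap_extension = as.integer(gap_extension),
                 lambda = lambda, K = K, evalue_cutoff = evalue_cutoff),
            class = "alignment_params")
}

check_aa <- function(seqs) {
  ok <- grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), seqs)
  if (!all(ok))
    stop("non-amino-acid characters in sequence(s): ",
         paste(head(names(seqs)[!ok] %||% which(!ok)), collapse = ", "))
  invisible(seqs)
}

ka_evalue <- function(score, m, n, params) {
  params$K * m * n * exp(-params$lambda * score)
}

# core: align the given index pairs of `seqs`; returns a full hit data.frame
align_indexed_pairs <- function(seqs, qi, si, params) {
  res <- sw_align_pairs_cpp(unname(seqs), as.integer(qi), as.integer(si),
                            blosum62_matrix(), params$gap_open,
                            params$gap_extension)
  qlen <- nchar(seqs)[qi]
  slen <- nchar(seqs)[si]
  data.frame(query_id = names(seqs)[qi], subject_id = names(seqs)[si],
             pident = ifelse(res$ali_len > 0, 100 * res$matches / res$ali_len, 0),
             ali_len = res$ali_len,
             query_cov = ifelse(res$ali_len > 0,
                                (res$q_end - res$q_start + 1) / qlen, 0),
             subject_cov = ifelse(res$ali_len > 0,
                                  (res$s_end - res$s_start + 1) / slen, 0),
             raw_score = res$score,
             evalue = ka_evalue(res$score, qlen, slen, params),
             stringsAsFactors = FALSE)
}

#' Align one pair of protein sequences
#'
#' Exact affine-gap Smith-Waterman local alignment. Percent identity is
#' identical columns over aligned columns (gap columns included), as BLAST
#' reports it.
#'
#' @param seq_a,seq_b amino-acid strings.
#' @param params an [alignment_params()].
#' @return one-row data.frame (`query_id`, `subject_id`, `pident`,
#'   `ali_len`, `query_cov`, `subject_cov`, `raw_score`, `evalue`) or `NULL`
#'   when the e-value misses the cutoff.
#' @export
align_pair <- function(seq_a, seq_b, params = alignment_params()) {
  stopifnot(nzchar(seq_a), nzchar(seq_b))
  seqs <- c(a = as.character(seq_a), b = as.character(seq_b))
  check_aa(seqs)
  hit <- align_indexed_pairs(seqs, 1L, 2L, params)
  if (hit$evalue > params$evalue_cutoff) return(NULL)
  hit
}

#' All-vs-all protein comparison
#'
#' Aligns every unordered protein pair within and across the given
#' proteomes (self-hits excluded), keeps pairs meeting the e-value cutoff
#' and mirrors each into both ordered directions, so `hit(a,b)` exists iff
#' `hit(b,a)` exists. Protein ids must be globally unique.
#'
#' @param proteomes named list (species -> named character vector of
#'   protein sequences), or a single named character vector.
#' @param evalue_cutoff e-value threshold (default 1e-10, the cluster
#'   comparison stage; ortholog inference uses 1e-5).
#' @param params an [alignment_params()]; its cutoff is overridden by
#'   `evalue_cutoff`.
#' @return data.frame of hits ("hit table"): at most one row per ordered
#'   pair, best local alignment per pair.
#' @export
all_vs_all <- function(proteomes, evalue_cutoff = 1e-10,
                       params = alignment_params()) {
  if (!is.list(proteomes)) proteomes <- list(proteomes)
  seqs <- unlist(unname(lapply(proteomes, function(p)
    setNames(as.character(p), names(p)))))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("protein ids must be present and globally unique")
  check_aa(seqs)
  params$evalue_cutoff <- evalue_cutoff
  n <- length(seqs)
  if (n < 2L) return(empty_hit_table())
  pairs <- utils::combn(n, 2L)
  hits <- align_indexed_pairs(seqs, pairs[1L, ], pairs[2L, ], params)
  hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (!nrow(hits)) return(empty_hit_table())
  mirror <- hits
  mirror[, c("query_id", "subject_id")] <- hits[, c("subject_id", "query_id")]
  mirror[, c("query_cov", "subject_cov")] <- hits[, c("subject_cov", "query_cov")]
  out <- rbind(hits, mirror)
  out <- out[order(out$query_id, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_hit_table <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pident = numeric(), ali_len = integer(), query_cov = numeric(),
             subject_cov = numeric(), raw_score = integer(),
             evalue = numeric(), stringsAsFactors = FALSE)
}

# cross-set comparison (queries x subjects only), used by dereplication
cross_align <- function(queries, subjects, evalue_cutoff = 1e-10,
                        params = alignment_params()) {
  seqs <- c(queries, subjects)
  names(seqs) <- c(names(queries), names(subjects))
  if (anyDuplicated(names(seqs))) stop("query/subject ids overlap")
  check_aa(seqs)
  nq <- length(queries); ns <- length(subjects)
  if (!nq || !ns) return(empty_hit_table())
  grid <- expand.grid(q = seq_len(nq), s = nq + seq_len(ns))
  hits <- align_indexed_pairs(seqs, grid$q, grid$s, params)
  hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
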