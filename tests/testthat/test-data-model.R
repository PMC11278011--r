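test_that("a toy genome parses from GFF3 + FASTA + domain TSV", {
  d <- tempfile("toy")
  dir.create(d)
  gff <- file.path(d, "g.gff3")
  writeLines(c("##gff-version 3",
               "scf1\tsrc\tgene\t100\t400\t+\t+\t.\tID=g1;proteinId=p1",
               "scf1\tsrc\tgene\t2000\t2400\t.\t-\t.\tID=g2;proteinId=p2",
               "scf2\tsrc\tgene\t50\t350\t.\t+\t.\tID=g3;proteinId=p3"), gff)
  fa <- file.path(d, "p.faa")
  writeLines(c(">p1", "MKVLAATTTR", ">p2", "MHHGGLLKRS", ">p3", "MCCDDEEFFG"),
             fa)
  dt <- file.path(d, "dom.tsv")
  writeLines(c("protein_id\tpfam_acc\tali_start\tali_end\tevalue",
               "p1\tPF00067\t5\t9\t1e-20",
               "p3\tPF00501\t1\t8\t1e-15"), dt)
  g <- read_genome(gff, fa, dt, species_id = "toy")
  expect_s3_class(g, "annotated_genome")
  expect_equal(nrow(g$genes), 3L)
  expect_equal(nrow(g$domains), 2L)
  expect_equal(length(g$proteins), 3L)
  expect_equal(g$genes$gene_id, c("g1", "g2", "g3"))
})

test_that("coordinate and reference violations are hard errors", {
  # start > end in the GFF
  d <- tempfile("bad"); dir.create(d)
  gff <- file.path(d, "g.gff3")
  writeLines(c("##gff-version 3",
               "scf1\tsrc\tgene\t500\t100\t.\t+\t.\tID=g1;proteinId=p1"), gff)
  fa <- file.path(d, "p.faa"); writeLines(c(">p1", "MKV"), fa)
  expect_error(read_genome(gff, fa), "failed to parse GFF3")

  genes <- data.frame(gene_id = "g1", scaffold = "s", start = 500L,
                      end = 100L, strand = "+", protein_id = "p1")
  expect_error(annotated_genome("x", genes, NULL, c(p1 = "MKV")),
               "start > end.*g1")

  # gene without a protein is named in the error
  genes2 <- data.frame(gene_id = "gX", scaffold = "s", start = 1L,
                       end = 10L, strand = "+", protein_id = "pX")
  expect_error(annotated_genome("x", genes2, NULL, c(p1 = "MKV")), "gX")

  # domain row referencing an absent protein names the protein
  genes3 <- data.frame(gene_id = "g1", scaffold = "s", start = 1L,
                       end = 10L, strand = "+", protein_id = "p1")
  doms <- data.frame(protein_id = "pGone", pfam_acc = "PF00067",
                     ali_start = 1L, ali_end = 5L, evalue = 1e-10)
  expect_error(annotated_genome("x", genes3, doms, c(p1 = "MKV")), "pGone")
})

test_that("odd PFAM accessions warn but are kept; unused proteins drop", {
  genes <- data.frame(gene_id = "g1", scaffold = "s", start = 1L,
                      end = 10L, strand = "+", protein_id = "p1")
  doms <- data.frame(protein_id = "p1", pfam_acc = "NOTPFAM",
                     ali_start = 1L, ali_end = 3L, evalue = 1e-10)
  expect_warning(g <- annotated_genome("x", genes, doms, c(p1 = "MKV")),
                 "NOTPFAM")
  expect_equal(nrow(g$domains), 1L)
  expect_warning(g2 <- annotated_genome("x", genes, NULL,
                                        c(p1 = "MKV", orphan = "MMM")),
                 "not referenced")
  expect_equal(names(g2$proteins), "p1")
})

test_that("read-write-read round trip is the identity on all fields", {
  pan <- generate_pangenome(sim_config(n_species = 1, n_planted_families = 2,
                                       genes_per_scaffold = 6,
                                       scaffolds_per_genome = 2, seed = 11))
  g1 <- pan$genomes[[1]]
  d <- tempfile("rt")
  write_genome(g1, d)
  g2 <- read_genome(file.path(d, "sp01.gff3"),
                    file.path(d, "sp01_proteins.faa"),
                    file.path(d, "sp01_domains.tsv"))
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$proteins[g2$genes$protein_id],
                   g2$proteins[g2$genes$protein_id])
  o <- function(d) d[order(d$protein_id, d$pfam_acc, d$ali_start), ]
  expect_equal(o(g1$domains), o(g2$domains), ignore_attr = TRUE)
})

test_that("parsing is insensitive to GFF3 feature ordering", {
  hdr <- "##gff-version 3"
  rows <- c("scf1\tsrc\tgene\t100\t400\t.\t+\t.\tID=g1;proteinId=p1",
            "scf1\tsrc\tgene\t2000\t2400\t.\t-\t.\tID=g2;proteinId=p2",
            "scf1\tsrc\tgene\t5000\t5400\t.\t+\t.\tID=g3;proteinId=p3")
  fa <- tempfile(fileext = ".faa")
  writeLines(c(">p1", "MKVL", ">p2", "MHHG", ">p3", "MCCD"), fa)
  f1 <- tempfile(fileext = ".gff3"); writeLines(c(hdr, rows), f1)
  f2 <- tempfile(fileext = ".gff3"); writeLines(c(hdr, rev(rows)), f2)
  g1 <- read_genome(f1, fa, species_id = "x")
  g2 <- read_genome(f2, fa, species_id = "x")
  expect_identical(g1$genes, g2$genes)
})

test_that("write_outputs emits sorted, round-trippable tables", {
  d <- tempfile("out")
  # empty cluster list -> header-only TSV
  write_outputs(list(clusters = list()), d)
  tab <- read_cluster_table(file.path(d, "clusters.tsv"))
  expect_equal(nrow(tab), 0L)
  expect_true(all(c("cluster_id", "gene_id", "role") %in% names(tab)))

  scores <- data.frame(cluster_a = c("c2", "c1"), cluster_b = c("c3", "c2"),
                       score_tailoring = c(10, 20), score_backbone = c(30, 40),
                       total = c(40, 60))
  write_outputs(list(scores = scores), d)
  back <- read_score_table(file.path(d, "scores.tsv"))
  expect_equal(back$cluster_a, c("c1", "c2"))  # sorted
  expect_equal(back$total, c(60, 40))

  fam <- data.frame(family_id = c("F2", "F1", "F1", "F3"),
                    cluster_id = c("c4", "c2", "c1", "c5"),
                    species_id = "sp", singleton_family = TRUE,
                    compound_label = NA_character_)
  write_outputs(list(families = fam), d)
  fb <- read_family_table(file.path(d, "families.tsv"))
  expect_equal(fb$family_id, c("F1", "F1", "F2", "F3"))
  expect_equal(fb$cluster_id, c("c1", "c2", "c4", "c5"))
})
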