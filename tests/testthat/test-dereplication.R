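test_that("GenBank records parse, filter by taxon, and warn on gaps", {
  p1 <- random_aa(80, seed = 1); p2 <- random_aa(90, seed = 2)
  dir <- write_genbank_dir(list(
    synthetic_genbank("BGC900001", "terrethanone A", "Aspergillus terreus",
                      setNames(list(p1, p2, random_aa(70)),
                               c("AAA01", "AAA02", "AAA03"))),
    synthetic_genbank("BGC900002", "fusarin X", "Fusarium sp.",
                      setNames(list(p1), "BBB01"))))
  recs <- load_mibig(dir)
  expect_length(recs, 1L)  # Fusarium filtered out
  expect_equal(recs[[1]]$accession, "BGC900001")
  expect_equal(recs[[1]]$compound_name, "terrethanone A")
  expect_length(recs[[1]]$proteins, 3L)
  expect_equal(unname(recs[[1]]$proteins["AAA01"]), p1)

  # a CDS without a translation qualifier is skipped with a warning
  dir2 <- write_genbank_dir(list(
    synthetic_genbank("BGC900003", "emodin", "Penicillium sp.",
                      setNames(list(p1, NA), c("CCC01", "CCC02")))))
  expect_warning(recs2 <- load_mibig(dir2), "no translation")
  expect_length(recs2[[1]]$proteins, 1L)

  # zero records after filtering is an error
  dir3 <- write_genbank_dir(list(
    synthetic_genbank("BGC900004", "x", "Fusarium sp.",
                      setNames(list(p1), "DDD01"))))
  expect_error(suppressWarnings(load_mibig(dir3)), "no MIBiG records")

  # an unparseable file is skipped with a warning
  writeLines("not a genbank file", file.path(dir, "junk.gbk"))
  expect_warning(recs3 <- load_mibig(dir), "unparseable")
  expect_length(recs3, 1L)
})

derep_fixture <- function(record_identity_subs) {
  # two-cluster family; the record protein matches cluster c1's backbone at
  # a controlled identity (interior substitutions = exact Hamming pident)
  ref <- random_aa(100, seed = 42)
  mut <- substitute_at(ref, record_identity_subs)
  proteomes <- list(sp1 = c(p_bb1 = ref, p_t1 = random_aa(80, seed = 2)),
                    sp2 = c(q_bb1 = random_aa(100, seed = 3),
                            q_t1 = random_aa(80, seed = 4)))
  cls <- list(make_smgc("c1", "sp1", "p_bb1", "p_t1"),
              make_smgc("c2", "sp2", "q_bb1", "q_t1"))
  fam <- data.frame(family_id = "F001", cluster_id = c("c1", "c2"),
                    species_id = c("sp1", "sp2"), singleton_family = FALSE,
                    compound_label = NA_character_)
  rec <- structure(list(accession = "BGC900010", compound_name = "testolide",
                        organism = "Aspergillus terreus",
                        proteins = c(R01 = mut)), class = "mibig_record")
  list(fam = fam, cls = cls, rec = rec, proteomes = proteomes)
}

test_that("labelling requires pident strictly above 95", {
  # 6 interior substitutions in 100 residues: pident exactly 94 -> no label
  fx94 <- derep_fixture(c(10, 25, 40, 55, 70, 85))
  out94 <- dereplicate_families(fx94$fam, fx94$cls, list(fx94$rec),
                                fx94$proteomes)
  expect_true(all(is.na(out94$compound_label)))

  # 4 substitutions: pident exactly 96 -> the whole family is labelled
  fx96 <- derep_fixture(c(10, 30, 50, 70))
  out96 <- dereplicate_families(fx96$fam, fx96$cls, list(fx96$rec),
                                fx96$proteomes)
  expect_equal(unique(out96$compound_label), "BGC900010:testolide")
  # family-closed: c2 never hit the record but inherits the label
  expect_equal(out96$compound_label[out96$cluster_id == "c2"],
               "BGC900010:testolide")

  # a pident 95.0 hit is not "over 95"
  fx95 <- derep_fixture(c(10, 30, 50, 70, 90))
  out95 <- dereplicate_families(fx95$fam, fx95$cls, list(fx95$rec),
                                fx95$proteomes)
  expect_true(all(is.na(out95$compound_label)))
})

test_that("multiple record hits concatenate sorted by accession", {
  fx <- derep_fixture(c(10, 30))
  rec2 <- structure(list(accession = "BGC100000", compound_name = "aardolide",
                         organism = "Penicillium sp.",
                         proteins = c(R02 = fx$proteomes$sp2[["q_bb1"]])),
                    class = "mibig_record")
  out <- dereplicate_families(fx$fam, fx$cls, list(fx$rec, rec2),
                              fx$proteomes)
  expect_equal(unique(out$compound_label),
               "BGC100000:aardolide; BGC900010:testolide")
})

test_that("lowering min_pident never removes a label", {
  fx <- derep_fixture(c(10, 30, 50, 70))  # pident 96
  lab_at <- function(thr) {
    out <- dereplicate_families(fx$fam, fx$cls, list(fx$rec), fx$proteomes,
                                derep_config(min_pident = thr))
    sum(!is.na(out$compound_label))
  }
  n <- vapply(c(99, 95.5, 90, 50), lab_at, 0L)
  expect_true(all(diff(n) >= 0L))
})

test_that("the coverage floor suppresses short high-identity matches", {
  # record protein = a 20-residue fragment of the cluster backbone:
  # pident 100 but query protein is only a fragment of the 100-mer; with
  # min_query_cov on the record side, labelling still proceeds (coverage
  # is measured on the query), while an implausibly short cluster-side
  # match is caught by raising min_query_cov above 1x fragment coverage
  ref <- random_aa(100, seed = 42)
  frag <- substr(ref, 30, 59)
  fx <- derep_fixture(c(10, 30))
  fx$rec$proteins <- c(R01 = frag)
  out <- dereplicate_families(fx$fam, fx$cls, list(fx$rec), fx$proteomes,
                              derep_config(min_query_cov = 0.5))
  expect_equal(unique(out$compound_label), "BGC900010:testolide")
  out2 <- dereplicate_families(fx$fam, fx$cls, list(fx$rec), fx$proteomes,
                               derep_config(min_query_cov = 1.01))
  expect_true(all(is.na(out2$compound_label)))
})

test_that("the compound presence matrix reflects labelled families", {
  fam <- data.frame(family_id = c("F1", "F1", "F2"),
                    cluster_id = c("c1", "c2", "c3"),
                    species_id = c("sp1", "sp2", "sp1"),
                    singleton_family = c(FALSE, FALSE, TRUE),
                    compound_label = c("B1:x", "B1:x", NA))
  m <- compound_presence_matrix(fam)
  expect_equal(dim(m), c(1L, 2L))
  expect_true(m["B1:x", "sp1"] && m["B1:x", "sp2"])
})
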