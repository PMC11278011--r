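test_that("backbone classification follows the ordered rule table", {
  # KS + AT + carrier is a PKS
  call <- classify_backbone(c("PF00109", "PF00698", "PF00550"))
  expect_equal(call$class, "PKS")
  # PKS-defining plus NRPS-defining domains in any order is a HYBRID
  call <- classify_backbone(c("PF00668", "PF00109", "PF00501", "PF00698"))
  expect_equal(call$class, "HYBRID")
  # full NRPS
  expect_equal(classify_backbone(c("PF00668", "PF00501", "PF00550"))$class,
               "NRPS")
  # two PKS-specific domains + another domain, lacking the full KS+AT set
  expect_equal(classify_backbone(c("PF00109", "PF08659", "PF00550"))$class,
               "PKS-like")
  # adenylation + condensation + thioesterase without a carrier
  expect_equal(classify_backbone(c("PF00501", "PF00668", "PF00975"))$class,
               "NRPS-like")
  expect_equal(classify_backbone("PF11991")$class, "DMATS")
  expect_equal(classify_backbone("PF06330")$class, "TC")
  # empty composition or only non-backbone domains: no call
  expect_null(classify_backbone(character()))
  expect_null(classify_backbone(c("PF00067", "PF00069")))
})

test_that("the NRPS-like condensation requirement is switchable", {
  strict <- predictor_config(nrps_like_requires_condensation = TRUE)
  loose <- predictor_config(nrps_like_requires_condensation = FALSE)
  comp <- c("PF00501", "PF00975")  # A + TE, no condensation
  expect_null(classify_backbone(comp, strict))
  expect_equal(classify_backbone(comp, loose)$class, "NRPS-like")
})

test_that("extension obeys the 3 kb intergenic gap rule", {
  bb <- c("PF00109", "PF00698", "PF00550")
  tailoring <- "PF00067"
  # tailoring, backbone, tailoring with 1 kb gaps -> one 3-gene cluster
  g <- toy_genome(list(
    list(pfams = tailoring, gap_after = 1000L),
    list(pfams = bb, gap_after = 1000L),
    list(pfams = tailoring)))
  cl <- predict_clusters(g)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$genes$gene_id, c("toy_g01", "toy_g02", "toy_g03"))
  expect_equal(cl[[1]]$genes$role, c("tailoring", "backbone", "tailoring"))

  # a 3.5 kb gap excludes the downstream tailoring gene
  g2 <- toy_genome(list(
    list(pfams = bb, gap_after = 3500L),
    list(pfams = tailoring)))
  cl2 <- predict_clusters(g2)
  expect_length(cl2, 1L)
  expect_equal(cl2[[1]]$genes$gene_id, "toy_g01")

  # a gap of exactly 3000 bp is still inside
  g3 <- toy_genome(list(
    list(pfams = bb, gap_after = 3000L),
    list(pfams = tailoring)))
  expect_equal(nrow(predict_clusters(g3)[[1]]$genes), 2L)
})

test_that("extension stops after more than 6 consecutive SM-free genes", {
  bb <- c("PF00668", "PF00501", "PF00550")
  tailoring <- "PF00067"
  non_sm <- lapply(1:7, function(i) list(pfams = "PF00069", gap_after = 500L))
  g <- toy_genome(c(list(list(pfams = bb, gap_after = 500L)), non_sm,
                    list(list(pfams = tailoring))))
  cl <- predict_clusters(g)
  expect_length(cl, 1L)
  # extension stops at the 7th SM-free gene; trailing non-SM trimmed
  expect_equal(cl[[1]]$genes$gene_id, "toy_g01")

  # with only 6 SM-free genes the tailoring gene is reachable and the
  # SM-free run sits inside the cluster
  g6 <- toy_genome(c(list(list(pfams = bb, gap_after = 500L)), non_sm[1:6],
                     list(list(pfams = tailoring))))
  cl6 <- predict_clusters(g6)
  expect_equal(nrow(cl6[[1]]$genes), 8L)
  expect_equal(cl6[[1]]$genes$role[1], "backbone")
  expect_equal(cl6[[1]]$genes$role[8], "tailoring")
  expect_true(all(cl6[[1]]$genes$role[2:7] == "other"))
})

test_that("touching extensions merge and borders are SM-anchored", {
  bb1 <- c("PF00109", "PF00698", "PF00550")
  bb2 <- "PF11991"
  g <- toy_genome(list(
    list(pfams = "PF00069", gap_after = 500L),   # non-SM, must be trimmed
    list(pfams = bb1, gap_after = 500L),
    list(pfams = "PF00069", gap_after = 500L),   # inside after merge
    list(pfams = bb2, gap_after = 500L),
    list(pfams = "PF00069")))                    # non-SM, trimmed
  cl <- predict_clusters(g)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$genes$gene_id, paste0("toy_g0", 2:4))
  expect_equal(sum(cl[[1]]$genes$role == "backbone"), 2L)

  # genome with no backbone gene -> no clusters
  g0 <- toy_genome(list(list(pfams = "PF00067"), list(pfams = "PF00069")))
  expect_length(predict_clusters(g0), 0L)
})

test_that("emitted clusters satisfy the gap and SM-run invariants", {
  pan <- generate_pangenome(sim_config(n_species = 2, seed = 21))
  cfg <- predictor_config()
  for (cl in pooled_predict(pan)) {
    gaps <- cl$genes$start[-1] - cl$genes$end[-nrow(cl$genes)] - 1L
    expect_true(all(gaps <= cfg$max_intergenic_bp))
    runs <- rle(cl$genes$role == "other")
    expect_true(all(runs$lengths[runs$values] <= cfg$max_non_sm_genes))
    expect_true(cl$genes$role[1] != "other")
    expect_true(cl$genes$role[nrow(cl$genes)] != "other")
    expect_gte(sum(cl$genes$role == "backbone"), 1L)
  }
})

test_that("predictions on simulator output equal the planted truth", {
  pan <- generate_pangenome(sim_config(n_species = 4, n_planted_families = 8,
                                       seed = 31))
  cls <- pooled_predict(pan)
  tg <- pan$truth$genes
  pred <- sort(vapply(cls, function(cl)
    paste(sort(cl$genes$gene_id), collapse = ","), ""))
  truth <- sort(vapply(split(tg$gene_id,
                             paste(tg$species_id, tg$family_id)),
                       function(g) paste(sort(g), collapse = ","), ""))
  expect_identical(unname(pred), unname(truth))
  # backbone class calls equal planted classes
  census <- backbone_census(cls)
  tc <- pan$truth$clusters
  planted <- table(factor(tc$species_id, levels = rownames(census)),
                   factor(tc$backbone_class, levels = colnames(census)))
  expect_equal(unclass(census), unclass(planted), ignore_attr = TRUE)
})

test_that("raising max_intergenic_bp never shrinks a cluster", {
  pan <- generate_pangenome(sim_config(n_species = 2, seed = 41))
  g <- pan$genomes[[1]]
  sizes <- function(gap) {
    cls <- predict_clusters(g, predictor_config(max_intergenic_bp = gap))
    sum(vapply(cls, function(cl) nrow(cl$genes), 0L))
  }
  s <- vapply(c(1000L, 2000L, 3000L, 5000L, 10000L), sizes, 0L)
  expect_true(all(diff(s) >= 0L))
})

test_that("backbone census counts genes per species and class", {
  a <- make_smgc("a_c1", "spA", c("p1", "p2"), "p3")
  a$genes$class[1:2] <- c("PKS", "PKS")
  b <- make_smgc("a_c2", "spA", "p4", character())
  b$genes$class[1] <- "TC"
  m <- backbone_census(list(a, b))
  expect_equal(m["spA", "PKS"], 2L)
  expect_equal(m["spA", "TC"], 1L)
  expect_equal(sum(m["spA", ]), 3L)
  expect_equal(nrow(backbone_census(list())), 0L)
})
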