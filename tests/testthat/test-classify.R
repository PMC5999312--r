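random_matrix <- function(n_genes, n_acc, p = 0.8, seed = 1) {
  set.seed(seed)
  matrix(rbinom(n_genes * n_acc, 1L, p), n_genes, n_acc,
         dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                         sprintf("acc%02d", seq_len(n_acc))))
}

test_that("gene classification matches a brute-force row scan", {
  m <- random_matrix(100, 10, seed = 2)
  cls <- classify_genes(m)
  brute <- vapply(seq_len(nrow(m)), function(i)
    if (all(m[i, ] == 1L)) "core" else "variable", character(1))
  expect_equal(cls$label, brute)
  # all-present and one-absent edge cases
  m2 <- m; m2[1, ] <- 1L; m2[2, ] <- 1L; m2[2, 5] <- 0L
  cls2 <- classify_genes(m2)
  expect_equal(cls2$label[1], "core")
  expect_equal(cls2$label[2], "variable")
})

test_that("family rule: core member wins, whole-family loss is variable, middle defaults core", {
  m <- matrix(c(1, 1, 1,   # g1: core
                1, 0, 1,   # g2: variable
                0, 1, 1,   # g3
                1, 0, 1,   # g4: fam2 wholly missing in acc2
                0, 0, 1,
                1, 1, 0,   # g5/g6: fam3, no core member, never wholly lost
                0, 1, 1),
              nrow = 7, byrow = TRUE,
              dimnames = list(paste0("g", 1:7), paste0("acc", 1:3)))
  fams <- data.frame(gene_id = paste0("g", 1:7),
                     family_id = c("f1", "f1", "f1", "f2", "f2", "f3", "f3"))
  cls <- classify_families(m, fams)
  expect_equal(cls$label[cls$family_id == "f1"], "core")
  expect_true(cls$has_core_member[cls$family_id == "f1"])
  expect_equal(cls$label[cls$family_id == "f2"], "variable")
  expect_true(cls$wholly_missing_somewhere[cls$family_id == "f2"])
  expect_equal(cls$label[cls$family_id == "f3"], "core")
  expect_false(cls$has_core_member[cls$family_id == "f3"])
  expect_false(cls$wholly_missing_somewhere[cls$family_id == "f3"])
  # a family with a core gene is never variable (property over random data)
  mr <- random_matrix(200, 6, p = 0.7, seed = 3)
  fr <- data.frame(gene_id = rownames(mr),
                   family_id = sprintf("f%03d", rep(1:50, each = 4)))
  cr <- classify_families(mr, fr)
  core_genes <- classify_genes(mr)
  fam_of <- setNames(fr$family_id, fr$gene_id)
  fams_with_core <- unique(fam_of[core_genes$gene_id[core_genes$label == "core"]])
  expect_true(all(cr$label[cr$family_id %in% fams_with_core] == "core"))
  expect_error(classify_families(mr[1:10, ], fr[1:5, ]), "without family")
})

test_that("homoeolog families on simulated truth are core unless both copies are lost", {
  sim <- cached_study()
  truth <- sim$truth
  cls <- classify_families(truth$truth_pav, truth$families)
  fam_split <- split(truth$families$gene_id, truth$families$family_id)
  both_lost_somewhere <- vapply(fam_split, function(gg)
    any(colSums(truth$truth_pav[gg, , drop = FALSE]) == 0), logical(1))
  expect_equal(cls$label == "variable",
               unname(both_lost_somewhere[cls$family_id]))
})

test_that("unique presence/absence matches the brute-force double loop", {
  m <- random_matrix(200, 8, p = 0.6, seed = 4)
  u <- unique_presence_absence(m)
  for (a in seq_len(ncol(m))) {
    up <- sum(vapply(seq_len(nrow(m)), function(i)
      m[i, a] == 1L && all(m[i, -a] == 0L), logical(1)))
    ua <- sum(vapply(seq_len(nrow(m)), function(i)
      m[i, a] == 0L && all(m[i, -a] == 1L), logical(1)))
    expect_equal(u$uniquely_present[a], up)
    expect_equal(u$uniquely_absent[a], ua)
  }
  all1 <- matrix(1L, 5, 3, dimnames = list(paste0("g", 1:5), paste0("a", 1:3)))
  u1 <- unique_presence_absence(all1)
  expect_true(all(u1$uniquely_present == 0L) && all(u1$uniquely_absent == 0L))
})

test_that("classification is invariant to row and column permutations", {
  m <- random_matrix(120, 7, seed = 6)
  fams <- data.frame(gene_id = rownames(m),
                     family_id = sprintf("f%03d", rep(1:30, each = 4)))
  set.seed(8)
  mp <- m[sample(nrow(m)), sample(ncol(m))]
  g1 <- classify_genes(m); g2 <- classify_genes(mp)
  expect_equal(g2$label[match(g1$gene_id, g2$gene_id)], g1$label)
  f1 <- classify_families(m, fams); f2 <- classify_families(mp, fams)
  expect_equal(f2[match(f1$family_id, f2$family_id), ], f1,
               ignore_attr = TRUE)
})

test_that("family assignment reader fills singletons", {
  f <- withr::local_tempfile()
  writeLines(c("g1\tfamA", "g2\tfamA"), f)
  fam <- read_family_assignments(f, all_genes = c("g1", "g2", "g3"))
  expect_equal(fam$family_id[fam$gene_id == "g3"], "singleton:g3")
  writeLines(c("g1\tfamA", "g1\tfamB"), f)
  expect_error(read_family_assignments(f), "multiple families")
})

test_that("dendrogram merges identical accessions first and bounds supports", {
  m <- matrix(c(rep(c(1L, 1L, 0L), each = 40)), nrow = 40,
              dimnames = list(sprintf("g%02d", 1:40), c("a1", "a2", "b9")))
  m[, "b9"] <- 1L - m[, "a1"]
  d <- pav_dendrogram(m, n_boot = 50, seed = 2)
  expect_equal(d$hclust$merge[1, ], c(-1L, -2L))  # the identical pair
  expect_true(all(d$support >= 0 & d$support <= 1))
})

test_that("accessions cluster by class with strong class-specific HE signal", {
  cfg <- sim_config(
    n_accessions = 12L,
    accession_classes = rep(c("synthetic", "nonsynthetic"), each = 6),
    he_rate = c(synthetic = 1, nonsynthetic = 0),
    he_span_genes = c(20L, 20L), single_gene_deletion_rate = 0,
    seed = 5L)
  sim <- simulate_study(cfg)
  calls <- lapply(sim$tracks, function(tr) call_pav(sim$truth$annotation, tr))
  m <- build_pav_matrix(calls,
                        vapply(sim$tracks, track_mean_depth, numeric(1)))
  d <- pav_dendrogram(m, n_boot = 300, seed = 9)
  nonsyn <- sim$truth$accessions$accession[
    sim$truth$accessions$class == "nonsynthetic"]
  node <- ape::getMRCA(d$tree, nonsyn)
  clade <- ape::extract.clade(d$tree, node)$tip.label
  expect_setequal(clade, nonsyn)
  expect_gte(d$support[node - length(d$tree$tip.label)], 0.9)
  # permuting input columns leaves the topology unchanged
  set.seed(3)
  d2 <- pav_dendrogram(m[, sample(ncol(m))], n_boot = 1, seed = 1)
  expect_equal(ape::dist.topo(ape::unroot(d$tree), ape::unroot(d2$tree))[1], 0)
  # Newick output keeps tips and parses back
  f <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram(d, f)
  expect_setequal(ape::read.tree(f)$tip.label, colnames(m))
})
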