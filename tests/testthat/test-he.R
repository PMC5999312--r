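make_calls <- function(annotation, absent_ids) {
  g <- annotation$genes
  data.frame(gene_id = g$gene_id, chrom = g$chrom, rank = g$rank,
             fraction = ifelse(g$gene_id %in% absent_ids, 0, 1),
             present = !(g$gene_id %in% absent_ids),
             stringsAsFactors = FALSE)
}

test_that("absent runs are maximal and split by min_run_genes", {
  cfg <- sim_config(n_chrom_pairs = 1L, genes_per_chromosome = 60L,
                    n_accessions = 1L, accession_classes = "synthetic",
                    seed = 1L)
  ann <- simulate_reference(cfg)$annotation
  # absent ranks {3,4,5, 9} on A01
  ids <- ann$genes$gene_id[ann$genes$chrom == "A01"][c(4, 5, 6, 10)]
  rr <- absent_runs(make_calls(ann, ids), ann, min_run_genes = 3L)
  expect_equal(nrow(rr$runs), 1L)
  expect_equal(rr$runs$rank_start, 3L)
  expect_equal(rr$runs$rank_end, 6L)
  expect_equal(nrow(rr$short_runs), 1L)
  expect_equal(rr$short_runs$rank_start, 9L)
  # no absent genes -> nothing
  rr0 <- absent_runs(make_calls(ann, character(0)), ann, 3L)
  expect_equal(nrow(rr0$runs) + nrow(rr0$short_runs), 0L)
  # a fully absent chromosome is one maximal run
  all_ids <- ann$genes$gene_id[ann$genes$chrom == "A01"]
  rr1 <- absent_runs(make_calls(ann, all_ids), ann, 3L)
  expect_equal(rr1$runs$n_genes, 60L)
  # brute-force scan oracle on random absence patterns
  set.seed(31)
  for (rep in 1:5) {
    absent <- sample(all_ids, 20)
    rr2 <- absent_runs(make_calls(ann, absent), ann, 1L)
    ranks <- sort(ann$genes$rank[match(absent, ann$genes$gene_id)])
    n_runs <- 1L + sum(diff(ranks) != 1L)
    expect_equal(nrow(rr2$runs), n_runs)
    expect_equal(sum(rr2$runs$n_genes), 20L)
  }
})

test_that("binned coverage tiles bins and matches the per-base mean", {
  ann <- one_gene_annotation(len = 5000L)
  trk <- constant_track(ann, value = 12L)
  bc <- binned_coverage(trk, "A01", c(0, 3500), bin_size = 1000L)
  expect_equal(bc$bins, rep(12, 4))   # last partial bin still averages 12
  expect_equal(bc$mean, 12)
  zero <- constant_track(ann, value = 0L)
  expect_true(all(binned_coverage(zero, "A01", c(100, 900))$bins == 0))
  expect_error(binned_coverage(trk, "A01", c(10, 10)), "interval")
  set.seed(5)
  trk$depth$A01 <- rpois(5000, 9)
  for (iv in list(c(0, 5000), c(17, 4203), c(999, 2001))) {
    bc <- binned_coverage(trk, "A01", iv, 1000L)
    expect_equal(bc$mean, mean(trk$depth$A01[(iv[1] + 1):iv[2]]),
                 tolerance = 1e-9)
  }
})

test_that("a clean C->A exchange is called once with the right direction and genes", {
  cfg <- sim_config(n_accessions = 1L, accession_classes = "synthetic",
                    he_rate = c(synthetic = 1, nonsynthetic = 0),
                    he_direction_c_to_a_prob = 1,
                    single_gene_deletion_rate = 0,
                    n_chrom_pairs = 1L, depth_noise = "exact", seed = 17L)
  sim <- simulate_study(cfg)
  calls <- call_pav(sim$truth$annotation, sim$tracks[[1]])
  res <- detect_hes(calls, sim$truth$annotation, sim$tracks[[1]],
                    sim$truth$homology)
  expect_equal(nrow(res$calls), 1L)
  expect_equal(res$calls$direction, "C->A")
  ev <- sim$truth$events
  expect_equal(res$calls$rank_start, ev$rank_start)
  expect_equal(res$calls$rank_end, ev$rank_end)
  truth_genes <- sim$truth$annotation$genes$gene_id[
    sim$truth$annotation$genes$chrom == ev$recipient_chrom &
      sim$truth$annotation$genes$rank >= ev$rank_start &
      sim$truth$annotation$genes$rank < ev$rank_end]
  expect_setequal(strsplit(res$calls$genes, ",")[[1]], truth_genes)
  expect_length(res$non_he_genes, 0)
})

test_that("runs whose homoeologs are also absent are non-HE (double deletion)", {
  cfg <- sim_config(n_accessions = 1L, accession_classes = "synthetic",
                    he_rate = c(synthetic = 0, nonsynthetic = 0),
                    single_gene_deletion_rate = 0,
                    n_chrom_pairs = 1L, depth_noise = "exact", seed = 4L)
  sim <- simulate_study(cfg)
  ann <- sim$truth$annotation
  # delete ranks 0..4 on both homoeologs: zero depth, presence clause fails
  lost <- ann$genes$gene_id[ann$genes$rank < 5]
  trk <- sim$tracks[[1]]
  for (gid in lost) {
    j <- match(gid, ann$genes$gene_id)
    trk$depth[[ann$genes$chrom[j]]][(ann$genes$start[j] + 1):ann$genes$end[j]] <- 0L
  }
  calls <- call_pav(ann, trk)
  res <- detect_hes(calls, ann, trk, sim$truth$homology)
  expect_equal(nrow(res$calls), 0L)
  expect_setequal(res$non_he_genes, lost)
})

test_that("the coverage test vetoes runs without donor doubling", {
  cfg <- sim_config(n_accessions = 1L, accession_classes = "synthetic",
                    he_rate = c(synthetic = 1, nonsynthetic = 0),
                    he_direction_c_to_a_prob = 1,
                    single_gene_deletion_rate = 0,
                    n_chrom_pairs = 1L, depth_noise = "exact", seed = 17L)
  sim <- simulate_study(cfg)
  ann <- sim$truth$annotation
  trk <- sim$tracks[[1]]
  # flatten the donor chromosome back to 1x: duplication evidence gone
  trk$depth[["C01"]][] <- as.integer(cfg$mean_depth)
  calls <- call_pav(ann, trk)
  res <- detect_hes(calls, ann, trk, sim$truth$homology)
  expect_equal(nrow(res$calls), 0L)
  expect_gt(length(res$non_he_genes), 0)
})

test_that("every absent gene lands in exactly one of HE-recipient or non-HE", {
  sim <- cached_study()
  calls <- cached_calls()
  res <- detect_hes_all(calls, sim$truth$annotation, sim$tracks,
                        sim$truth$homology)
  for (acc in names(calls)) {
    absent <- calls[[acc]]$gene_id[!calls[[acc]]$present]
    he_genes <- unlist(strsplit(
      res$calls$genes[res$calls$accession == acc], ","))
    expect_length(intersect(he_genes, res$non_he_genes[[acc]]), 0)
    expect_setequal(absent, c(he_genes, res$non_he_genes[[acc]]))
  }
})

test_that("raising dup_factor or pid_min never increases the call count", {
  sim <- cached_study()
  calls <- cached_calls()
  count_with <- function(params) {
    nrow(detect_hes_all(calls, sim$truth$annotation, sim$tracks,
                        sim$truth$homology, params)$calls)
  }
  n_dup <- vapply(c(1.2, 1.5, 1.9, 1.99), function(d)
    count_with(he_params(dup_factor = d)), numeric(1))
  expect_true(all(diff(n_dup) <= 0))
  n_pid <- vapply(c(50, 90, 95, 99.5), function(p)
    count_with(he_params(pid_min = p)), numeric(1))
  expect_true(all(diff(n_pid) <= 0))
})
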