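test_that("reference structure: paired chromosomes, equal-rank homoeologs, pid range", {
  cfg <- sim_config(n_chrom_pairs = 1L, genes_per_chromosome = 2L,
                    n_accessions = 2L,
                    accession_classes = c("synthetic", "nonsynthetic"),
                    seed = 3L)
  ref <- simulate_reference(cfg)
  expect_equal(nrow(ref$annotation$chromosomes), 2L)
  expect_equal(nrow(ref$annotation$genes), 4L)
  expect_equal(nrow(ref$homology), 4L)   # both directions per pair
  expect_equal(ref$annotation$homoeolog_pairs[["A01"]], "C01")
  expect_equal(ref$annotation$homoeolog_pairs[["C01"]], "A01")

  ref_d <- simulate_reference(sim_config(seed = 5L))
  expect_true(all(ref_d$homology$pident >= 91 & ref_d$homology$pident <= 99))
  # homoeologs sit at identical ranks: subject positions are collinear with
  # query ranks (Spearman rho exactly 1 along each chromosome)
  g <- ref_d$annotation$genes
  h <- ref_d$homology
  for (chrom in c("A01", "C02")) {
    q <- g$gene_id[g$chrom == chrom]
    hh <- h[match(q, h$query_gene), ]
    rho <- cor(g$rank[match(q, g$gene_id)], hh$subject_start,
               method = "spearman")
    expect_equal(rho, 1)
  }
})

test_that("degenerate rates give deletion-only or all-present truth", {
  cfg0 <- sim_config(he_rate = c(synthetic = 0, nonsynthetic = 0),
                     n_accessions = 4L,
                     accession_classes = rep(c("synthetic", "nonsynthetic"), 2),
                     seed = 9L)
  truth <- simulate_accessions(simulate_reference(cfg0), cfg0)
  expect_equal(nrow(truth$events), 0L)
  expect_equal(sum(truth$truth_pav == 0L), sum(lengths(truth$deletions)))

  cfg00 <- sim_config(he_rate = c(synthetic = 0, nonsynthetic = 0),
                      single_gene_deletion_rate = 0, n_accessions = 4L,
                      accession_classes = rep(c("synthetic", "nonsynthetic"), 2),
                      seed = 9L)
  truth2 <- simulate_accessions(simulate_reference(cfg00), cfg00)
  expect_true(all(truth2$truth_pav == 1L))
})

test_that("simulation is deterministic given the seed", {
  cfg <- tiny_config(seed = 21L)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$truth$events, s2$truth$events)
  expect_identical(s1$truth$truth_pav, s2$truth$truth_pav)
  expect_identical(lapply(s1$tracks, `[[`, "depth"),
                   lapply(s2$tracks, `[[`, "depth"))
})

test_that("direction control: c_to_a_prob = 1 makes every recipient an A chromosome", {
  cfg <- sim_config(he_direction_c_to_a_prob = 1, seed = 13L,
                    he_rate = c(synthetic = 1, nonsynthetic = 1))
  truth <- simulate_accessions(simulate_reference(cfg), cfg)
  expect_gt(nrow(truth$events), 0)
  expect_true(all(startsWith(truth$events$recipient_chrom, "A")))
  expect_true(all(startsWith(truth$events$donor_chrom, "C")))
  expect_true(all(truth$events$direction == "C->A"))
})

test_that("HE spans exceeding the chromosome are truncated with a message", {
  cfg <- sim_config(n_chrom_pairs = 1L, genes_per_chromosome = 4L,
                    he_span_genes = c(10L, 10L),
                    he_rate = c(synthetic = 1, nonsynthetic = 1),
                    n_accessions = 1L, accession_classes = "synthetic",
                    seed = 2L)
  expect_message(
    truth <- simulate_accessions(simulate_reference(cfg), cfg),
    "truncated")
  expect_true(all(truth$events$rank_end - truth$events$rank_start <= 4L))
})

test_that("every truth-absent gene has exactly one explanation", {
  sim <- cached_study()
  truth <- sim$truth
  g <- truth$annotation$genes
  for (ai in seq_len(nrow(truth$accessions))) {
    acc <- truth$accessions$accession[ai]
    ev <- truth$events[truth$events$accession == acc, , drop = FALSE]
    he_lost <- character(0)
    for (i in seq_len(nrow(ev))) {
      sel <- g$chrom == ev$recipient_chrom[i] &
        g$rank >= ev$rank_start[i] & g$rank < ev$rank_end[i]
      he_lost <- c(he_lost, g$gene_id[sel])
    }
    del <- truth$deletions[[acc]]
    absent <- rownames(truth$truth_pav)[truth$truth_pav[, acc] == 0L]
    expect_length(intersect(he_lost, del), 0)
    expect_setequal(absent, union(he_lost, del))
  }
})

test_that("depth tracks have the promised local Poisson structure", {
  sim <- cached_study()
  cfg <- sim$truth$config
  truth <- sim$truth
  ev <- truth$events
  # an HE recipient segment is exactly zero
  stopifnot(nrow(ev) > 0)
  e1 <- ev[which.max(ev$rank_end - ev$rank_start), ]
  trk <- sim$tracks[[e1$accession]]
  g <- truth$annotation$genes
  sel <- g$chrom == e1$recipient_chrom & g$rank >= e1$rank_start &
    g$rank < e1$rank_end
  lo <- min(g$start[sel]); hi <- max(g$end[sel])
  expect_true(all(trk$depth[[e1$recipient_chrom]][(lo + 1):hi] == 0L))
  # the matching donor segment doubles: mean within 3 SE of 24
  don <- trk$depth[[e1$donor_chrom]][(lo + 1):hi]
  se <- sqrt(2 * cfg$mean_depth / length(don))
  expect_lt(abs(mean(don) - 2 * cfg$mean_depth), 3 * se)
  # a neutral chromosome of an event-free accession sits at the mean
  quiet <- setdiff(truth$accessions$accession, ev$accession)
  if (length(quiet)) {
    v <- sim$tracks[[quiet[1]]]$depth[["A01"]]
    gdel <- truth$deletions[[quiet[1]]]
    mask <- rep(TRUE, length(v))
    for (gid in gdel[gdel %in% g$gene_id[g$chrom == "A01"]]) {
      j <- match(gid, g$gene_id)
      mask[(g$start[j] + 1):g$end[j]] <- FALSE
    }
    se <- sqrt(cfg$mean_depth / sum(mask))
    expect_lt(abs(mean(v[mask]) - cfg$mean_depth), 3 * se)
  }
})

test_that("C->A directional bias is recovered over many events", {
  # aggregate events across seeds until >= 200 HEs
  n_c2a <- 0L; n_tot <- 0L
  for (s in 1:6) {
    cfg <- sim_config(seed = 300L + s,
                      he_rate = c(synthetic = 1, nonsynthetic = 0.5))
    truth <- simulate_accessions(simulate_reference(cfg), cfg)
    n_tot <- n_tot + nrow(truth$events)
    n_c2a <- n_c2a + sum(truth$events$direction == "C->A")
  }
  expect_gte(n_tot, 200L)
  ci <- qbinom(c(0.005, 0.995), n_tot, 0.8) / n_tot
  expect_gte(n_c2a / n_tot, ci[1])
  expect_lte(n_c2a / n_tot, ci[2])
})
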