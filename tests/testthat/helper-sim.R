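# Shared simulation fixtures, built once per test run and cached.

.sim_cache <- new.env(parent = emptyenv())

# full default study conditions: 3 chromosome pairs x 60 genes,
# 20 accessions (8 synthetic), ~12x depth
cached_study <- function(seed = 101L, depth_noise = "poisson") {
  key <- paste0("study_", seed, "_", depth_noise)
  if (is.null(.sim_cache[[key]])) {
    cfg <- sim_config(seed = seed, depth_noise = depth_noise)
    .sim_cache[[key]] <- simulate_study(cfg)
  }
  .sim_cache[[key]]
}

cached_calls <- function(seed = 101L, depth_noise = "poisson") {
  key <- paste0("calls_", seed, "_", depth_noise)
  if (is.null(.sim_cache[[key]])) {
    sim <- cached_study(seed, depth_noise)
    .sim_cache[[key]] <- lapply(sim$tracks, function(tr)
      call_pav(sim$truth$annotation, tr, pav_params()))
  }
  .sim_cache[[key]]
}

# a small, fast reference: 1 chromosome pair x 8 genes, 3 accessions
tiny_config <- function(seed = 7L, ...) {
  sim_config(n_chrom_pairs = 1L, genes_per_chromosome = 8L,
             n_accessions = 3L,
             accession_classes = c("synthetic", "nonsynthetic",
                                   "nonsynthetic"),
             seed = seed, ...)
}

# hand-built single-chromosome annotation for direct-count oracles:
# one chromosome "A01" of `len` bp carrying one single-exon gene
one_gene_annotation <- function(gene_start = 100L, gene_end = 1100L,
                                len = 2000L) {
  genome_annotation(
    chromosomes = data.frame(name = c("A01", "C01"), length = len,
                             subgenome = c("A", "C"),
                             stringsAsFactors = FALSE),
    genes = data.frame(gene_id = "g1", chrom = "A01", start = gene_start,
                       end = gene_end, strand = "+",
                       stringsAsFactors = FALSE),
    exons = list(g1 = cbind(start = gene_start, end = gene_end)),
    homoeolog_pairs = c(A01 = "C01", C01 = "A01")
  )
}

constant_track <- function(annotation, accession = "acc", value = 12L) {
  depth <- lapply(annotation$chromosomes$length, function(n)
    rep(as.integer(value), n))
  names(depth) <- annotation$chromosomes$name
  depth_track(accession, depth, annotation)
}
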