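#' Configuration for the synthetic allotetraploid simulator
#'
#' The generator emulates an allotetraploid (A/C subgenome) reference with
#' one-to-one homoeologous gene pairs, accessions carrying homoeologous
#' exchanges (HEs) and independent single-gene deletions, and Poisson
#' per-base read depth (0x over lost segments, doubled over duplicated
#' donor segments). Defaults follow the biology the pipeline targets:
#' ~12x mean coverage, HEs biased towards chromosome ends, more frequent in
#' resynthesised ("synthetic") accessions, and mostly C-to-A.
#'
#' @param n_chrom_pairs number of homoeologous chromosome pairs.
#' @param genes_per_chromosome genes on every chromosome.
#' @param gene_length gene span in bp (genes >= 1200 bp get two exons
#'   separated by a 100-bp intron; shorter genes are single-exon).
#' @param intergenic_gap bp between consecutive genes (and at chromosome
#'   ends).
#' @param n_accessions number of accessions.
#' @param accession_classes character vector (`"synthetic"` /
#'   `"nonsynthetic"`) of length `n_accessions`; the default assigns the
#'   first 40% to the synthetic class.
#' @param mean_depth mean per-base read depth (reads).
#' @param he_rate named numeric, probability of an HE per accession per
#'   chromosome pair for each class.
#' @param he_span_genes length-2 integer range of HE spans (genes),
#'   sampled uniformly.
#' @param he_end_bias probability that an HE is anchored at a chromosome
#'   terminus.
#' @param he_direction_c_to_a_prob probability the exchange runs C -> A
#'   (A-subgenome segment is lost, C copy doubles).
#' @param single_gene_deletion_rate per-gene probability of an independent
#'   deletion (never inside an HE recipient or donor segment).
#' @param homoeolog_pid length-2 percent-identity range for homoeologous
#'   gene pairs.
#' @param depth_noise `"poisson"` for Poisson-sampled depth or `"exact"`
#'   for noise-free constant depth at the local rate.
#' @param seed integer seed; all randomness in the generator derives from
#'   it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chrom_pairs = 3L,
                       genes_per_chromosome = 60L,
                       gene_length = 1500L,
                       intergenic_gap = 1000L,
                       n_accessions = 20L,
                       accession_classes = NULL,
                       mean_depth = 12,
                       he_rate = c(synthetic = 0.5, nonsynthetic = 0.1),
                       he_span_genes = c(5L, 20L),
                       he_end_bias = 0.9,
                       he_direction_c_to_a_prob = 0.8,
                       single_gene_deletion_rate = 0.01,
                       homoeolog_pid = c(91, 99),
                       depth_noise = c("poisson", "exact"),
                       seed = 1L) {
  depth_noise <- match.arg(depth_noise)
  if (is.null(accession_classes)) {
    n_syn <- round(0.4 * n_accessions)
    accession_classes <- c(rep("synthetic", n_syn),
                           rep("nonsynthetic", n_accessions - n_syn))
  }
  stopifnot(
    n_chrom_pairs >= 1, genes_per_chromosome >= 1, gene_length >= 1,
    intergenic_gap >= 0, n_accessions >= 1,
    length(accession_classes) == n_accessions,
    all(accession_classes %in% c("synthetic", "nonsynthetic")),
    mean_depth > 0,
    all(he_rate >= 0 & he_rate <= 1),
    all(c("synthetic", "nonsynthetic") %in% names(he_rate)),
    length(he_span_genes) == 2, he_span_genes[1] >= 1,
    he_span_genes[1] <= he_span_genes[2],
    he_end_bias >= 0 && he_end_bias <= 1,
    he_direction_c_to_a_prob >= 0 && he_direction_c_to_a_prob <= 1,
    single_gene_deletion_rate >= 0 && single_gene_deletion_rate <= 1,
    length(homoeolog_pid) == 2, homoeolog_pid[1] <= homoeolog_pid[2],
    homoeolog_pid[2] <= 100
  )
  structure(list(
    n_chrom_pairs = as.integer(n_chrom_pairs),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    gene_length = as.integer(gene_length),
    intergenic_gap = as.integer(intergenic_gap),
    n_accessions = as.integer(n_accessions),
    accession_classes = accession_classes,
    mean_depth = mean_depth, he_rate = he_rate,
    he_span_genes = as.integer(he_span_genes),
    he_end_bias = he_end_bias,
    he_direction_c_to_a_prob = he_direction_c_to_a_prob,
    single_gene_deletion_rate = single_gene_deletion_rate,
    homoeolog_pid = homoeolog_pid, depth_noise = depth_noise,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate the allotetraploid reference
#'
#' Builds paired chromosomes `A01`/`C01`, `A02`/`C02`, ... with
#' `genes_per_chromosome` genes each. Gene `j` on `A0i` has exactly one
#' homoeolog at the same positional rank on `C0i`; the homology table holds
#' both directed hits per pair, with percent identity drawn uniformly from
#' `homoeolog_pid` and alignment length within +/-10 bp of the gene's
#' exon-union length. Also returns a gene-family assignment with one
#' two-member family per homoeolog pair.
#'
#' @param config a [sim_config()].
#' @return list with elements `annotation` ([genome_annotation()]),
#'   `homology` (data.frame, see [read_homology_table()]) and `families`
#'   (data.frame `gene_id`, `family_id`).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  k <- config$genes_per_chromosome
  glen <- config$gene_length
  gap <- config$intergenic_gap
  chrom_len <- gap + k * (glen + gap)
  nums <- sprintf("%02d", seq_len(config$n_chrom_pairs))
  chrom_names <- c(paste0("A", nums), paste0("C", nums))
  chromosomes <- data.frame(
    name = chrom_names, length = chrom_len,
    subgenome = rep(c("A", "C"), each = config$n_chrom_pairs),
    stringsAsFactors = FALSE
  )
  pairs <- stats::setNames(c(paste0("C", nums), paste0("A", nums)),
                           chrom_names)

  starts <- gap + (seq_len(k) - 1L) * (glen + gap)
  genes_list <- lapply(chrom_names, function(nm) {
    data.frame(gene_id = sprintf("%s_g%03d", nm, seq_len(k)), chrom = nm,
               start = starts, end = starts + glen, strand = "+",
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, genes_list)
  exons <- lapply(seq_len(nrow(genes)), function(i) {
    s <- genes$start[i]; e <- genes$end[i]
    if (glen >= 1200L) {
      # two exons around a fixed 100-bp intron
      cbind(start = c(s, s + 800L), end = c(s + 700L, e))
    } else {
      cbind(start = s, end = e)
    }
  })
  names(exons) <- genes$gene_id
  annotation <- genome_annotation(chromosomes, genes, exons, pairs)

  union_len <- exon_union_lengths(annotation)
  hom_rows <- lapply(nums, function(nn) {
    a <- paste0("A", nn); c_ <- paste0("C", nn)
    ga <- annotation$genes[annotation$genes$chrom == a, ]
    gc <- annotation$genes[annotation$genes$chrom == c_, ]
    pid <- round(stats::runif(k, config$homoeolog_pid[1],
                              config$homoeolog_pid[2]), 2)
    delta <- sample(0:10, k, replace = TRUE) * sample(c(-1L, 1L), k, TRUE)
    aln_a <- as.integer(union_len[ga$gene_id]) + delta
    # both directions share pid and alignment length
    rbind(
      data.frame(query_gene = ga$gene_id, subject_chrom = c_,
                 subject_start = gc$start, subject_end = gc$end,
                 subject_gene = NA_character_, pident = pid, length = aln_a,
                 bitscore = round(2 * aln_a * pid / 100, 1),
                 stringsAsFactors = FALSE),
      data.frame(query_gene = gc$gene_id, subject_chrom = a,
                 subject_start = ga$start, subject_end = ga$end,
                 subject_gene = NA_character_, pident = pid, length = aln_a,
                 bitscore = round(2 * aln_a * pid / 100, 1),
                 stringsAsFactors = FALSE)
    )
  })
  homology <- do.call(rbind, hom_rows)
  rownames(homology) <- NULL

  families <- do.call(rbind, lapply(nums, function(nn) {
    fam <- sprintf("fam%s_%03d", nn, seq_len(k))
    data.frame(
      gene_id = c(sprintf("A%s_g%03d", nn, seq_len(k)),
                  sprintf("C%s_g%03d", nn, seq_len(k))),
      family_id = c(fam, fam), stringsAsFactors = FALSE
    )
  }))

  list(annotation = annotation, homology = homology, families = families)
}

#' Simulate accession event truth (HEs and single-gene deletions)
#'
#' For every accession and chromosome pair an HE is drawn with the
#' class-specific rate; its direction is C -> A with probability
#' `he_direction_c_to_a_prob`, its span uniform in `he_span_genes`
#' (truncated to the chromosome, with a message), and it is anchored at a
#' randomly chosen chromosome terminus with probability `he_end_bias`
#' (otherwise placed uniformly in the interior). Recipient genes are lost;
#' donor homoeologs double in copy number. Single-gene deletions are then
#' drawn per gene outside HE segments. The truth PAV matrix records a gene
#' as absent iff it is an HE-recipient gene or deleted.
#'
#' @param reference output of [simulate_reference()].
#' @param config the same [sim_config()].
#' @return An object of class `sim_truth`: list with `annotation`,
#'   `homology`, `families`, `accessions` (data.frame `accession`,
#'   `class`), `events` (data.frame `accession`, `recipient_chrom`,
#'   `donor_chrom`, `rank_start`, `rank_end` 0-based half-open ranks,
#'   `direction` `"C->A"`/`"A->C"`), `deletions` (named list of gene-id
#'   vectors) and `truth_pav` (genes x accessions 0/1 integer matrix).
#' @export
simulate_accessions <- function(reference, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  ann <- reference$annotation
  k <- config$genes_per_chromosome
  acc_ids <- sprintf("acc%02d", seq_len(config$n_accessions))
  accessions <- data.frame(accession = acc_ids,
                           class = config$accession_classes,
                           stringsAsFactors = FALSE)
  a_chroms <- ann$chromosomes$name[ann$chromosomes$subgenome == "A"]

  events <- list(); deletions <- list()
  gene_ids <- ann$genes$gene_id
  truth <- matrix(1L, nrow = length(gene_ids), ncol = length(acc_ids),
                  dimnames = list(gene_ids, acc_ids))

  gene_id_at <- function(chrom, ranks) sprintf("%s_g%03d", chrom, ranks + 1L)
  # sample one element of a vector (safe for length-1 vectors, unlike sample())
  pick1 <- function(x) x[sample.int(length(x), 1L)]

  for (ai in seq_along(acc_ids)) {
    rate <- config$he_rate[[accessions$class[ai]]]
    he_genes <- character(0)
    for (a in a_chroms) {
      if (stats::runif(1) >= rate) next
      c_ <- ann$homoeolog_pairs[[a]]
      c_to_a <- stats::runif(1) < config$he_direction_c_to_a_prob
      recipient <- if (c_to_a) a else c_
      donor <- if (c_to_a) c_ else a
      span <- pick1(config$he_span_genes[1]:config$he_span_genes[2])
      if (span > k) {
        message(sprintf("HE span %d truncated to %d genes on %s",
                        span, k, recipient))
        span <- k
      }
      if (stats::runif(1) < config$he_end_bias) {
        rs <- if (stats::runif(1) < 0.5) 0L else k - span
      } else {
        rs <- pick1(0:(k - span))
      }
      ranks <- rs:(rs + span - 1L)
      events[[length(events) + 1L]] <- data.frame(
        accession = acc_ids[ai], recipient_chrom = recipient,
        donor_chrom = donor, rank_start = rs, rank_end = rs + span,
        direction = if (c_to_a) "C->A" else "A->C",
        stringsAsFactors = FALSE
      )
      lost <- gene_id_at(recipient, ranks)
      truth[lost, ai] <- 0L
      he_genes <- c(he_genes, lost, gene_id_at(donor, ranks))
    }
    eligible <- setdiff(gene_ids, he_genes)
    del <- eligible[stats::runif(length(eligible)) <
                      config$single_gene_deletion_rate]
    deletions[[acc_ids[ai]]] <- del
    if (length(del)) truth[del, ai] <- 0L
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(accession = character(0), recipient_chrom = character(0),
               donor_chrom = character(0), rank_start = integer(0),
               rank_end = integer(0), direction = character(0),
               stringsAsFactors = FALSE)
  structure(list(
    annotation = ann, homology = reference$homology,
    families = reference$families, accessions = accessions,
    events = events, deletions = deletions, truth_pav = truth,
    config = config
  ), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "sim_truth: %d accessions (%d synthetic), %d HE events, %d single-gene deletions\n",
    nrow(x$accessions), sum(x$accessions$class == "synthetic"),
    nrow(x$events), sum(lengths(x$deletions))))
  invisible(x)
}

# bp interval [lo, hi) of a rank interval, snapped to intergenic midpoints
# (or the chromosome terminus when the segment touches rank 0 or rank k-1)
rank_interval_bp <- function(annotation, chrom, rank_start, rank_end,
                             config) {
  g <- annotation$genes[annotation$genes$chrom == chrom, ]
  k <- nrow(g)
  half <- config$intergenic_gap %/% 2L
  lo <- if (rank_start == 0L) 0L else g$start[g$rank == rank_start] - half
  hi <- if (rank_end == k) {
    annotation$chromosomes$length[annotation$chromosomes$name == chrom]
  } else {
    g$end[g$rank == rank_end - 1L] + half
  }
  c(lo, hi)
}

#' Simulate a per-base depth track for one accession
#'
#' Depth is Poisson with rate `mean_depth` in neutral regions, 0 over HE
#' recipient segments and deleted gene spans, and `2 * mean_depth` over HE
#' donor segments. Segment boundaries are snapped to the midpoints of the
#' flanking intergenic gaps (chromosome termini for terminal segments).
#' With `depth_noise = "exact"` the rate itself (rounded) is returned as a
#' constant, noise-free track.
#'
#' @param truth a `sim_truth` from [simulate_accessions()].
#' @param accession accession id present in `truth`.
#' @param config the same [sim_config()].
#' @return A [depth_track()].
#' @export
simulate_depth <- function(truth, accession, config) {
  ai <- match(accession, truth$accessions$accession)
  if (is.na(ai)) stop("unknown accession: ", accession)
  set.seed(config$seed + 7919L * ai)
  ann <- truth$annotation
  ev <- truth$events[truth$events$accession == accession, , drop = FALSE]
  del <- truth$deletions[[accession]]
  depth <- lapply(seq_len(nrow(ann$chromosomes)), function(ci) {
    nm <- ann$chromosomes$name[ci]
    len <- ann$chromosomes$length[ci]
    lambda <- rep(config$mean_depth, len)
    for (i in which(ev$recipient_chrom == nm)) {
      b <- rank_interval_bp(ann, nm, ev$rank_start[i], ev$rank_end[i], config)
      lambda[(b[1] + 1L):b[2]] <- 0
    }
    for (i in which(ev$donor_chrom == nm)) {
      b <- rank_interval_bp(ann, nm, ev$rank_start[i], ev$rank_end[i], config)
      lambda[(b[1] + 1L):b[2]] <- 2 * config$mean_depth
    }
    g <- ann$genes
    for (gid in del[del %in% g$gene_id[g$chrom == nm]]) {
      j <- match(gid, g$gene_id)
      lambda[(g$start[j] + 1L):g$end[j]] <- 0
    }
    if (config$depth_noise == "exact") as.integer(round(lambda))
    else stats::rpois(len, lambda)
  })
  names(depth) <- ann$chromosomes$name
  depth_track(accession, depth, ann)
}

#' Run the full simulation: reference, event truth and all depth tracks
#'
#' @param config a [sim_config()].
#' @return list with `truth` (a `sim_truth`) and `tracks` (named list of
#'   [depth_track()] objects).
#' @export
simulate_study <- function(config = sim_config()) {
  ref <- simulate_reference(config)
  truth <- simulate_accessions(ref, config)
  tracks <- lapply(truth$accessions$accession, simulate_depth,
                   truth = truth, config = config)
  names(tracks) <- truth$accessions$accession
  list(truth = truth, tracks = tracks)
}
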