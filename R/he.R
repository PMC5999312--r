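#' Parameters for homoeologous exchange detection
#'
#' @param pid_min percent-identity floor for a supporting best hit
#'   (strict `>`), default 90.
#' @param aln_len_tol allowed difference (bp) between a hit's alignment
#'   length and the query gene's exon-union length, default 10.
#' @param min_run_genes minimum length (genes) of an absent run considered
#'   an HE candidate, default 3.
#' @param bin_size coverage bin width in bp, default 1000.
#' @param dup_factor donor interval must exceed `dup_factor` x baseline
#'   coverage, default 1.5.
#' @param zero_factor recipient interval must fall below `zero_factor` x
#'   baseline ("zero or close to zero"), default 0.1.
#' @param order_rho_min minimum |Spearman rho| between query gene ranks and
#'   subject hit positions ("roughly consecutive" order), default 0.8.
#' @param support_frac_min minimum fraction of run genes passing the
#'   homology clauses, default 0.8.
#' @param baseline `"genome-mean"` (default) or `"chromosome-mean"`: the
#'   average coverage against which the zero and doubling tests are judged.
#'   The genome-wide mean is invariant to the exchange itself (the loss on
#'   the recipient offsets the gain on the donor), whereas a donor
#'   chromosome's own mean is inflated by the duplicated segment, which
#'   makes the doubling test unattainable for segments covering more than
#'   about a third of the chromosome.
#' @return list of class `he_params`.
#' @export
he_params <- function(pid_min = 90, aln_len_tol = 10, min_run_genes = 3L,
                      bin_size = 1000L, dup_factor = 1.5, zero_factor = 0.1,
                      order_rho_min = 0.8, support_frac_min = 0.8,
                      baseline = c("genome-mean", "chromosome-mean")) {
  baseline <- match.arg(baseline)
  stopifnot(pid_min > 0, pid_min <= 100, aln_len_tol >= 0,
            min_run_genes >= 1, bin_size >= 1, dup_factor > 1,
            zero_factor < 1, zero_factor >= 0,
            order_rho_min >= 0, order_rho_min <= 1,
            support_frac_min > 0, support_frac_min <= 1)
  structure(list(pid_min = pid_min, aln_len_tol = aln_len_tol,
                 min_run_genes = as.integer(min_run_genes),
                 bin_size = as.integer(bin_size), dup_factor = dup_factor,
                 zero_factor = zero_factor, order_rho_min = order_rho_min,
                 support_frac_min = support_frac_min, baseline = baseline),
            class = "he_params")
}

#' Maximal runs of rank-consecutive absent genes
#'
#' @param calls a [call_pav()] data.frame for one accession (must cover all
#'   annotated genes).
#' @param annotation a [genome_annotation()].
#' @param min_run_genes runs shorter than this are returned separately.
#' @return list with `runs` and `short_runs`, each a data.frame `chrom`,
#'   `rank_start`, `rank_end` (0-based half-open), `n_genes`.
#' @export
absent_runs <- function(calls, annotation, min_run_genes = 3L) {
  stopifnot(setequal(calls$gene_id, annotation$genes$gene_id))
  out <- list()
  for (nm in unique(annotation$genes$chrom)) {
    cc <- calls[calls$chrom == nm, ]
    cc <- cc[order(cc$rank), ]
    absent <- which(!cc$present)
    if (!length(absent)) next
    brk <- c(0L, which(diff(absent) != 1L), length(absent))
    for (j in seq_len(length(brk) - 1L)) {
      seg <- absent[(brk[j] + 1L):brk[j + 1L]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = nm, rank_start = cc$rank[seg[1]],
        rank_end = cc$rank[seg[length(seg)]] + 1L,
        n_genes = length(seg), stringsAsFactors = FALSE
      )
    }
  }
  runs <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), rank_start = integer(0),
               rank_end = integer(0), n_genes = integer(0),
               stringsAsFactors = FALSE)
  list(runs = runs[runs$n_genes >= min_run_genes, , drop = FALSE],
       short_runs = runs[runs$n_genes < min_run_genes, , drop = FALSE])
}

#' Binned mean coverage over an interval
#'
#' Non-overlapping `bin_size` bins tiled from the interval start; the last
#' partial bin is averaged over its true width. The interval mean is the
#' length-weighted mean of the bins (identical to the per-base mean).
#'
#' @param track a [depth_track()].
#' @param chrom chromosome name.
#' @param interval length-2 numeric, 0-based half-open `c(start, end)`.
#' @param bin_size bin width in bp.
#' @return list with `bins` (numeric vector of per-bin means) and `mean`.
#' @export
binned_coverage <- function(track, chrom, interval, bin_size = 1000L) {
  v <- track$depth[[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  s <- as.integer(interval[1]); e <- as.integer(interval[2])
  if (e <= s || s < 0 || e > length(v)) stop("empty or out-of-range interval")
  x <- v[(s + 1L):e]
  grp <- (seq_along(x) - 1L) %/% bin_size
  bins <- as.numeric(tapply(x, grp, mean))
  w <- as.numeric(tapply(x, grp, length))
  list(bins = bins, mean = sum(bins * w) / sum(w))
}

# mean depth of the baseline region per he_params$baseline
baseline_depth <- function(track, chrom, params) {
  if (params$baseline == "genome-mean") track_mean_depth(track)
  else mean(track$depth[[chrom]])
}

#' Detect homoeologous exchanges in one accession
#'
#' Each candidate run of >= `min_run_genes` consecutive absent genes is put
#' through three tests:
#' \enumerate{
#'   \item Homology: every run gene's best hit (bitscore, then pid, then
#'     subject start) must lie on the run chromosome's homoeologous
#'     partner, with pid > `pid_min`, alignment length within
#'     `aln_len_tol` bp of the query's exon-union length, and the annotated
#'     gene overlapping the hit called present. Genes failing any clause
#'     drop out of the run's support; at least `support_frac_min` of the
#'     run must survive.
#'   \item Order: |Spearman rho| between supported query gene ranks and
#'     subject hit start positions >= `order_rho_min` (collinear,
#'     "roughly consecutive" hits).
#'   \item Coverage: recipient interval mean bin coverage <
#'     `zero_factor` x baseline and donor interval (span of the supported
#'     subject hits) mean bin coverage > `dup_factor` x baseline.
#' }
#' Runs passing all three become HE calls with direction donor-subgenome to
#' recipient-subgenome; genes of all other runs (and of runs shorter than
#' `min_run_genes`) are reported as non-HE PAV.
#'
#' @param calls [call_pav()] output for the accession.
#' @param annotation a [genome_annotation()].
#' @param track the accession's [depth_track()].
#' @param homology homology data.frame (see [read_homology_table()]).
#' @param params a [he_params()].
#' @return list with `calls` (data.frame of HE calls: `accession`,
#'   recipient/donor chromosome and bp intervals, rank interval, direction,
#'   gene list, evidence columns) and `non_he_genes` (character vector of
#'   absent gene ids not explained by an HE).
#' @export
detect_hes <- function(calls, annotation, track, homology,
                       params = he_params()) {
  g <- annotation$genes
  union_len <- exon_union_lengths(annotation)
  bh <- best_hits(homology)
  bh_idx <- match(g$gene_id, bh$query_gene)
  present <- stats::setNames(calls$present, calls$gene_id)
  rr <- absent_runs(calls, annotation, params$min_run_genes)
  he_rows <- list()
  non_he <- character(0)
  run_gene_ids <- function(run) {
    gg <- g[g$chrom == run$chrom & g$rank >= run$rank_start &
              g$rank < run$rank_end, ]
    gg$gene_id[order(gg$rank)]
  }
  for (i in seq_len(nrow(rr$short_runs)))
    non_he <- c(non_he, run_gene_ids(rr$short_runs[i, ]))

  for (i in seq_len(nrow(rr$runs))) {
    run <- rr$runs[i, ]
    partner <- annotation$homoeolog_pairs[run$chrom]
    ids <- run_gene_ids(run)
    if (is.na(partner)) {
      warning("no homoeologous partner for ", run$chrom, "; run skipped")
      non_he <- c(non_he, ids)
      next
    }
    hi <- bh[bh_idx[match(ids, g$gene_id)], , drop = FALSE]
    ok <- !is.na(hi$query_gene) &
      hi$subject_chrom == partner &
      hi$pident > params$pid_min &
      abs(hi$length - union_len[ids]) <= params$aln_len_tol
    # the hit must land on a gene called present on the partner chromosome
    subj_gene <- vapply(seq_len(nrow(hi)), function(j) {
      if (!ok[j]) return(NA_character_)
      overlapping_gene(annotation, hi$subject_chrom[j],
                       hi$subject_start[j], hi$subject_end[j])
    }, character(1))
    ok <- ok & !is.na(subj_gene) & present[subj_gene] %in% TRUE
    support <- mean(ok)
    passed <- FALSE
    if (support >= params$support_frac_min && sum(ok) >= 2) {
      q_ranks <- g$rank[match(ids[ok], g$gene_id)]
      s_pos <- hi$subject_start[ok]
      rho <- suppressWarnings(
        stats::cor(q_ranks, s_pos, method = "spearman"))
      if (!is.na(rho) && abs(rho) >= params$order_rho_min) {
        base <- baseline_depth(track, run$chrom, params)
        base_d <- baseline_depth(track, partner, params)
        rec_iv <- c(g$start[match(ids[1], g$gene_id)],
                    g$end[match(ids[length(ids)], g$gene_id)])
        don_iv <- c(min(hi$subject_start[ok]), max(hi$subject_end[ok]))
        rec_cov <- binned_coverage(track, run$chrom, rec_iv,
                                   params$bin_size)$mean
        don_cov <- binned_coverage(track, partner, don_iv,
                                   params$bin_size)$mean
        if (rec_cov < params$zero_factor * base &&
            don_cov > params$dup_factor * base_d) {
          passed <- TRUE
          sub_rec <- annotation$chromosomes$subgenome[
            annotation$chromosomes$name == run$chrom]
          sub_don <- annotation$chromosomes$subgenome[
            annotation$chromosomes$name == partner]
          he_rows[[length(he_rows) + 1L]] <- data.frame(
            accession = track$accession,
            recipient_chrom = run$chrom, recipient_start = rec_iv[1],
            recipient_end = rec_iv[2], rank_start = run$rank_start,
            rank_end = run$rank_end, donor_chrom = unname(partner),
            donor_start = don_iv[1], donor_end = don_iv[2],
            direction = paste0(sub_don, "->", sub_rec),
            n_genes = length(ids), n_supported = sum(ok),
            support_frac = support, order_rho = rho,
            recipient_cov_ratio = rec_cov / base,
            donor_cov_ratio = don_cov / base_d,
            genes = paste(ids, collapse = ","),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    if (!passed) non_he <- c(non_he, ids)
  }
  he_calls <- if (length(he_rows)) do.call(rbind, he_rows) else
    empty_he_calls()
  list(calls = he_calls, non_he_genes = non_he)
}

empty_he_calls <- function() {
  data.frame(accession = character(0), recipient_chrom = character(0),
             recipient_start = integer(0), recipient_end = integer(0),
             rank_start = integer(0), rank_end = integer(0),
             donor_chrom = character(0), donor_start = integer(0),
             donor_end = integer(0), direction = character(0),
             n_genes = integer(0), n_supported = integer(0),
             support_frac = numeric(0), order_rho = numeric(0),
             recipient_cov_ratio = numeric(0), donor_cov_ratio = numeric(0),
             genes = character(0), stringsAsFactors = FALSE)
}

# gene with maximal overlap with [start, end) on chrom, NA if none
overlapping_gene <- function(annotation, chrom, start, end) {
  g <- annotation$genes
  sel <- g$chrom == chrom & g$end > start & g$start < end
  if (!any(sel)) return(NA_character_)
  cand <- g[sel, ]
  ov <- pmin(cand$end, end) - pmax(cand$start, start)
  cand$gene_id[which.max(ov)]
}

#' Detect HEs across all accessions
#'
#' @param calls_list named list (by accession) of [call_pav()] outputs.
#' @param annotation a [genome_annotation()].
#' @param tracks named list of [depth_track()] objects.
#' @param homology homology data.frame.
#' @param params a [he_params()].
#' @return list with `calls` (row-bound HE calls) and `non_he_genes`
#'   (named list by accession).
#' @export
detect_hes_all <- function(calls_list, annotation, tracks, homology,
                           params = he_params()) {
  res <- lapply(names(calls_list), function(acc) {
    detect_hes(calls_list[[acc]], annotation, tracks[[acc]], homology,
               params)
  })
  names(res) <- names(calls_list)
  list(calls = do.call(rbind, c(lapply(res, `[[`, "calls"),
                                list(make.row.names = FALSE))),
       non_he_genes = lapply(res, `[[`, "non_he_genes"))
}

#' Event-level precision/recall of HE calls against simulated truth
#'
#' A detected call matches a truth event when accession and recipient
#' chromosome agree and each edge of the gene-rank interval differs by at
#' most `edge_tol` genes. Each truth event can be matched at most once.
#'
#' @param he_calls data.frame from [detect_hes_all()] (or [detect_hes()]).
#' @param truth a `sim_truth`.
#' @param edge_tol per-edge rank tolerance (genes), default 1.
#' @return list with `precision`, `recall`, `direction_accuracy` (over
#'   matched pairs), `n_true`, `n_called`, `n_matched`.
#' @export
evaluate_he_calls <- function(he_calls, truth, edge_tol = 1L) {
  tr <- truth$events
  matched_truth <- rep(FALSE, nrow(tr))
  matched_call <- rep(FALSE, nrow(he_calls))
  dir_ok <- logical(0)
  for (i in seq_len(nrow(he_calls))) {
    j <- which(!matched_truth &
                 tr$accession == he_calls$accession[i] &
                 tr$recipient_chrom == he_calls$recipient_chrom[i] &
                 abs(tr$rank_start - he_calls$rank_start[i]) <= edge_tol &
                 abs(tr$rank_end - he_calls$rank_end[i]) <= edge_tol)
    if (length(j)) {
      j <- j[1]
      matched_truth[j] <- TRUE
      matched_call[i] <- TRUE
      dir_ok <- c(dir_ok, tr$direction[j] == he_calls$direction[i])
    }
  }
  list(
    precision = if (nrow(he_calls)) mean(matched_call) else NA_real_,
    recall = if (nrow(tr)) mean(matched_truth) else NA_real_,
    direction_accuracy = if (length(dir_ok)) mean(dir_ok) else NA_real_,
    n_true = nrow(tr), n_called = nrow(he_calls),
    n_matched = sum(matched_call)
  )
}

#' Write HE calls as TSV plus BED intervals
#'
#' Emits `<prefix>.tsv` with the full call table and
#' `<prefix>_recipient.bed` / `<prefix>_donor.bed` with the 0-based
#' half-open recipient and donor intervals.
#'
#' @param he_calls HE call data.frame.
#' @param prefix output path prefix.
#' @return character vector of the three paths, invisibly.
#' @export
write_he_calls <- function(he_calls, prefix) {
  paths <- c(paste0(prefix, ".tsv"), paste0(prefix, "_recipient.bed"),
             paste0(prefix, "_donor.bed"))
  data.table::fwrite(he_calls, paths[1], sep = "\t")
  data.table::fwrite(
    data.table::data.table(he_calls$recipient_chrom,
                           he_calls$recipient_start,
                           he_calls$recipient_end,
                           paste0(he_calls$accession, "_",
                                  he_calls$direction)),
    paths[2], sep = "\t", col.names = FALSE)
  data.table::fwrite(
    data.table::data.table(he_calls$donor_chrom, he_calls$donor_start,
                           he_calls$donor_end,
                           paste0(he_calls$accession, "_",
                                  he_calls$direction)),
    paths[3], sep = "\t", col.names = FALSE)
  invisible(paths)
}
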