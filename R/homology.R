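#' Read a BLAST 12-column tabular homology table
#'
#' Expects outfmt-6 columns (`qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore`). Subject ids are resolved to a
#' chromosome either directly (sseqid is a chromosome name; sstart/send are
#' genomic) or through the annotation's gene table (sseqid is a gene id;
#' sstart/send are gene-local and are offset to genomic coordinates).
#' Subject coordinates are normalised so start <= end and converted to
#' 0-based half-open. Unresolvable subjects are skipped with a warning and
#' counted in the `n_skipped` attribute. No identity/length filtering is
#' applied here; that happens in HE detection.
#'
#' @param path BLAST tabular file.
#' @param annotation a [genome_annotation()].
#' @return data.frame with columns `query_gene`, `subject_chrom`,
#'   `subject_start`, `subject_end` (0-based half-open), `subject_gene`
#'   (NA unless sseqid was a gene id), `pident`, `length`, `bitscore`.
#' @export
read_homology_table <- function(path, annotation) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  dt <- tryCatch(
    suppressWarnings(
      data.table::fread(path, header = FALSE, sep = "\t",
                        col.names = cols)),
    error = function(e) data.table::data.table()
  )
  if (!nrow(dt)) return(empty_homology())
  g <- annotation$genes
  is_chrom <- dt$sseqid %in% annotation$chromosomes$name
  is_gene <- !is_chrom & dt$sseqid %in% g$gene_id
  bad <- !(is_chrom | is_gene)
  if (any(bad)) {
    warning(sum(bad), " homology rows with unresolvable subject id skipped")
    dt <- dt[!bad]
    is_chrom <- is_chrom[!bad]; is_gene <- is_gene[!bad]
  }
  if (!nrow(dt)) {
    out <- empty_homology(); attr(out, "n_skipped") <- sum(bad); return(out)
  }
  lo <- pmin(dt$sstart, dt$send); hi <- pmax(dt$sstart, dt$send)
  schrom <- character(nrow(dt)); sgene <- rep(NA_character_, nrow(dt))
  s0 <- integer(nrow(dt)); e0 <- integer(nrow(dt))
  # chromosome-style subjects: 1-based inclusive genomic -> 0-based half-open
  s0[is_chrom] <- lo[is_chrom] - 1L; e0[is_chrom] <- hi[is_chrom]
  schrom[is_chrom] <- dt$sseqid[is_chrom]
  if (any(is_gene)) {
    idx <- match(dt$sseqid[is_gene], g$gene_id)
    schrom[is_gene] <- g$chrom[idx]
    sgene[is_gene] <- g$gene_id[idx]
    s0[is_gene] <- g$start[idx] + lo[is_gene] - 1L
    e0[is_gene] <- g$start[idx] + hi[is_gene]
  }
  out <- data.frame(
    query_gene = dt$qseqid, subject_chrom = schrom,
    subject_start = s0, subject_end = e0, subject_gene = sgene,
    pident = dt$pident, length = as.integer(dt$length),
    bitscore = dt$bitscore, stringsAsFactors = FALSE
  )
  attr(out, "n_skipped") <- sum(bad)
  out
}

empty_homology <- function() {
  data.frame(query_gene = character(0), subject_chrom = character(0),
             subject_start = integer(0), subject_end = integer(0),
             subject_gene = character(0), pident = numeric(0),
             length = integer(0), bitscore = numeric(0),
             stringsAsFactors = FALSE)
}

#' Write a homology table in BLAST 12-column tabular format
#'
#' Subjects are written chromosome-style (sseqid = chromosome, genomic
#' 1-based inclusive coordinates). Fields not represented internally
#' (mismatch, gapopen, qstart/qend, evalue) are emitted as neutral
#' placeholders.
#'
#' @param homology data.frame as returned by [read_homology_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_homology_table <- function(homology, path) {
  h <- homology
  dt <- data.table::data.table(
    qseqid = h$query_gene, sseqid = h$subject_chrom, pident = h$pident,
    length = h$length, mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = h$length,
    sstart = h$subject_start + 1L, send = h$subject_end,
    evalue = 0, bitscore = h$bitscore
  )
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Pick the best hit per query gene
#'
#' Tie-break order: highest bitscore, then highest percent identity, then
#' lowest subject start.
#'
#' @param homology homology data.frame.
#' @return one-row-per-query data.frame.
#' @export
best_hits <- function(homology) {
  if (!nrow(homology)) return(homology)
  o <- order(homology$query_gene, -homology$bitscore, -homology$pident,
             homology$subject_start)
  h <- homology[o, , drop = FALSE]
  h[!duplicated(h$query_gene), , drop = FALSE]
}

#' Partition assembled contigs into retained and contaminant sets
#'
#' A contig is a contaminant when its best database hit is against a
#' non-green-plant, mitochondrial or chloroplast sequence with percent
#' identity above `pid_min` and alignment length covering at least
#' `len_frac_min` of the contig; everything else (including contigs with no
#' hit) is retained.
#'
#' @param records data.frame with columns `contig_id`, `contig_length`,
#'   `pident`, `aln_length`, `taxon` (one of `"green-plant"`, `"nongreen"`,
#'   `"mitochondrial"`, `"chloroplast"`, `"none"`; `pident`/`aln_length`
#'   may be NA when `taxon == "none"`).
#' @param pid_min percent-identity threshold (strict `>`), default 90.
#' @param len_frac_min minimum alignment-length/contig-length fraction
#'   (`>=`), default 0.5.
#' @return list with character vectors `retained` and `contaminant`.
#' @export
filter_contaminant_contigs <- function(records, pid_min = 90,
                                       len_frac_min = 0.5) {
  stopifnot(all(c("contig_id", "contig_length", "pident", "aln_length",
                  "taxon") %in% names(records)))
  if (any(records$contig_length <= 0, na.rm = TRUE) ||
      any(records$aln_length <= 0, na.rm = TRUE))
    stop("contig and alignment lengths must be positive")
  excluded_taxa <- c("nongreen", "mitochondrial", "chloroplast")
  is_cont <- records$taxon %in% excluded_taxa &
    !is.na(records$pident) & records$pident > pid_min &
    !is.na(records$aln_length) &
    records$aln_length / records$contig_length >= len_frac_min
  list(retained = records$contig_id[!is_cont],
       contaminant = records$contig_id[is_cont])
}
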