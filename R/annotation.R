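#' Genome annotation for an allotetraploid reference
#'
#' Container for the chromosome structure (with A/C subgenome labels and
#' homoeologous chromosome pairing), the gene models and their exon
#' intervals, and the positional rank of every gene along its chromosome.
#' All coordinates are held internally as 0-based half-open intervals;
#' file readers/writers convert at the boundary (GFF3 is 1-based inclusive).
#'
#' @param chromosomes data.frame with columns `name`, `length` (bp) and
#'   `subgenome` (one of `"A"`, `"C"`, `"unplaced"`).
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand` and `rank` (0-based positional rank by
#'   start coordinate within each chromosome).
#' @param exons named list (by `gene_id`) of two-column integer matrices
#'   (`start`, `end`; 0-based half-open) holding the union of the gene's
#'   exons. Overlapping exons are merged on construction.
#' @param homoeolog_pairs named character vector mapping each chromosome to
#'   its homoeologous partner; must be symmetric.
#'
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(chromosomes, genes, exons, homoeolog_pairs) {
  stopifnot(
    is.data.frame(chromosomes),
    all(c("name", "length", "subgenome") %in% names(chromosomes)),
    is.data.frame(genes),
    all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes))
  )
  chromosomes$name <- as.character(chromosomes$name)
  chromosomes$length <- as.integer(chromosomes$length)
  if (anyDuplicated(chromosomes$name))
    stop("duplicated chromosome names")
  if (!all(chromosomes$subgenome %in% c("A", "C", "unplaced")))
    stop("subgenome labels must be 'A', 'C' or 'unplaced'")
  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene ids")
  if (!all(genes$chrom %in% chromosomes$name))
    stop("gene on unknown chromosome: ",
         paste(setdiff(genes$chrom, chromosomes$name), collapse = ", "))
  if (any(genes$start < 0) || any(genes$end <= genes$start))
    stop("gene intervals must satisfy 0 <= start < end")

  # order genes by (chromosome, start) and assign 0-based ranks
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  genes$rank <- as.integer(stats::ave(
    genes$start, genes$chrom,
    FUN = function(x) rank(x, ties.method = "first") - 1L))

  exons <- exons[genes$gene_id]
  if (any(vapply(exons, is.null, logical(1))))
    stop("every gene needs an exon set (gene span counts as one exon)")
  exons <- lapply(exons, merge_intervals)
  for (i in seq_len(nrow(genes))) {
    e <- exons[[i]]
    if (e[1, 1] < genes$start[i] || e[nrow(e), 2] > genes$end[i])
      stop("exons outside gene span for ", genes$gene_id[i])
  }

  if (length(homoeolog_pairs)) {
    hp <- homoeolog_pairs
    if (!all(names(hp) %in% chromosomes$name) || !all(hp %in% chromosomes$name))
      stop("homoeolog_pairs refers to unknown chromosomes")
    if (!all(unname(hp[unname(hp)]) == names(hp)))
      stop("homoeolog_pairs must be symmetric")
  }

  structure(
    list(chromosomes = chromosomes, genes = genes, exons = exons,
         homoeolog_pairs = homoeolog_pairs),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d chromosomes (%d homoeologous pairs), %d genes\n",
              nrow(x$chromosomes), length(x$homoeolog_pairs) %/% 2L,
              nrow(x$genes)))
  invisible(x)
}

# union-merge a set of [start, end) intervals into disjoint sorted intervals
merge_intervals <- function(m) {
  m <- matrix(as.integer(m), ncol = 2,
              dimnames = list(NULL, c("start", "end")))
  m <- m[order(m[, 1]), , drop = FALSE]
  if (nrow(m) <= 1L) return(m)
  out <- m[1, , drop = FALSE]
  for (i in 2:nrow(m)) {
    j <- nrow(out)
    if (m[i, 1] <= out[j, 2]) {
      out[j, 2] <- max(out[j, 2], m[i, 2])
    } else {
      out <- rbind(out, m[i, , drop = FALSE])
    }
  }
  out
}

# total bp covered by a merged exon matrix
interval_width <- function(m) sum(m[, 2] - m[, 1])

#' Exon-union length of every gene
#'
#' @param annotation a [genome_annotation()].
#' @return named integer vector of exon-union widths (bp) by gene id.
#' @export
exon_union_lengths <- function(annotation) {
  vapply(annotation$exons, interval_width, numeric(1))
}

default_subgenome_rule <- function(name) {
  ifelse(grepl("^A[0-9]+$", name), "A",
         ifelse(grepl("^C[0-9]+$", name), "C", "unplaced"))
}

default_homoeolog_pairs <- function(chromosomes) {
  sub <- chromosomes$subgenome
  num <- sub("^[AC]", "", chromosomes$name)
  pairs <- character(0)
  for (i in which(sub == "A")) {
    j <- which(sub == "C" & num == num[i])
    if (length(j) == 1L) {
      pairs[chromosomes$name[i]] <- chromosomes$name[j]
      pairs[chromosomes$name[j]] <- chromosomes$name[i]
    }
  }
  pairs
}

#' Read a GFF3 gene annotation
#'
#' Parses `gene` and `exon` features (exons attached to genes directly or
#' through an intermediate mRNA feature). Chromosome lengths are taken from
#' `##sequence-region` pragmas when present, otherwise from the rightmost
#' feature end. Chromosomes whose names match the usual Brassica A/C
#' convention (`A01`..`A10`, `C01`..`C09`, ...) are labelled with their
#' subgenome and paired by number (A01 with C01 and so on) unless
#' `homoeolog_map` overrides the pairing; other chromosomes are `unplaced`.
#'
#' @param path GFF3 file (1-based inclusive coordinates).
#' @param subgenome_rule function mapping chromosome names to subgenome
#'   labels; the default implements the A/C naming convention.
#' @param homoeolog_map optional data.frame (two character columns) or named
#'   character vector overriding the default A/C pairing.
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(path, subgenome_rule = default_subgenome_rule,
                            homoeolog_map = NULL) {
  raw <- readLines(path, warn = FALSE)
  seqreg <- grep("^##sequence-region", raw, value = TRUE)
  body_idx <- which(!grepl("^#", raw) & nzchar(raw))
  fields <- strsplit(raw[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- body_idx[which(nf != 9L)[1]]
    stop(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields, got %d",
                 bad, nf[which(nf != 9L)[1]]))
  }
  if (length(fields)) {
    gff <- data.table::as.data.table(do.call(rbind, fields))
    data.table::setnames(gff, c("seqid", "source", "type", "start", "end",
                                "score", "strand", "phase", "attr"))
    gff[, line := body_idx]
    suppressWarnings({
      gff[, start := as.integer(start)]
      gff[, end := as.integer(end)]
    })
    if (anyNA(gff$start) || anyNA(gff$end)) {
      bad <- gff$line[which(is.na(gff$start) | is.na(gff$end))[1]]
      stop(sprintf("malformed GFF3 line %d: non-numeric coordinates", bad))
    }
  } else {
    stop("GFF3 file contains no features: ", path)
  }

  attr_field <- function(attr, key) {
    m <- regmatches(attr, regexpr(paste0("(^|;)", key, "=[^;]+"), attr))
    out <- rep(NA_character_, length(attr))
    hit <- lengths(regmatches(attr, gregexpr(paste0("(^|;)", key, "=[^;]+"), attr))) > 0
    out[hit] <- sub(paste0("^;?", key, "="), "", m)
    out
  }

  genes_dt <- gff[type == "gene"]
  if (!nrow(genes_dt)) stop("no gene features in ", path)
  gene_ids <- attr_field(genes_dt$attr, "ID")
  if (anyNA(gene_ids))
    stop(sprintf("malformed GFF3 line %d: gene feature without ID",
                 genes_dt$line[which(is.na(gene_ids))[1]]))

  # resolve exon parents, possibly through mRNA features
  mrna <- gff[type == "mRNA"]
  mrna_map <- if (nrow(mrna)) {
    stats::setNames(attr_field(mrna$attr, "Parent"), attr_field(mrna$attr, "ID"))
  } else character(0)
  exon_dt <- gff[type == "exon"]
  exon_parent <- attr_field(exon_dt$attr, "Parent")
  via_mrna <- exon_parent %in% names(mrna_map)
  exon_parent[via_mrna] <- mrna_map[exon_parent[via_mrna]]

  genes <- data.frame(
    gene_id = gene_ids, chrom = genes_dt$seqid,
    start = genes_dt$start - 1L, end = genes_dt$end,
    strand = genes_dt$strand, stringsAsFactors = FALSE
  )
  exons <- lapply(seq_len(nrow(genes)), function(i) {
    sel <- exon_parent == genes$gene_id[i]
    if (!any(sel)) {
      warning("gene without exons, using gene span: ", genes$gene_id[i])
      cbind(start = genes$start[i], end = genes$end[i])
    } else {
      cbind(start = exon_dt$start[sel] - 1L, end = exon_dt$end[sel])
    }
  })
  names(exons) <- genes$gene_id

  chrom_names <- sort(unique(genes$chrom))
  lens <- stats::setNames(rep(NA_integer_, length(chrom_names)), chrom_names)
  if (length(seqreg)) {
    parts <- strsplit(trimws(sub("^##sequence-region\\s+", "", seqreg)), "\\s+")
    for (p in parts) {
      if (length(p) >= 3 && p[1] %in% names(lens)) lens[p[1]] <- as.integer(p[3])
    }
  }
  feat_max <- tapply(gff$end, gff$seqid, max)
  lens[is.na(lens)] <- feat_max[names(lens)[is.na(lens)]]

  chromosomes <- data.frame(
    name = chrom_names, length = as.integer(lens),
    subgenome = subgenome_rule(chrom_names), stringsAsFactors = FALSE
  )
  pairs <- default_homoeolog_pairs(chromosomes)
  if (!is.null(homoeolog_map)) {
    hm <- if (is.data.frame(homoeolog_map)) {
      stats::setNames(as.character(homoeolog_map[[2]]),
                      as.character(homoeolog_map[[1]]))
    } else homoeolog_map
    pairs <- c(hm, stats::setNames(names(hm), unname(hm)))
  }
  genome_annotation(chromosomes, genes, exons, pairs)
}

#' Write a genome annotation to GFF3
#'
#' Emits `##sequence-region` pragmas, one `gene` feature per gene and its
#' exon features (1-based inclusive coordinates). Round-trips exactly
#' through [read_annotation()].
#'
#' @param annotation a [genome_annotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  ch <- annotation$chromosomes
  g <- annotation$genes
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", ch$name, ch$length))
  for (i in seq_len(nrow(g))) {
    lines <- c(lines, sprintf("%s\tpanhe\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$chrom[i], g$start[i] + 1L, g$end[i],
                              g$strand[i], g$gene_id[i]))
    e <- annotation$exons[[g$gene_id[i]]]
    lines <- c(lines, sprintf("%s\tpanhe\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                              g$chrom[i], e[, 1] + 1L, e[, 2],
                              g$strand[i], g$gene_id[i]))
  }
  writeLines(lines, path)
  invisible(path)
}
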