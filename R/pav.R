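#' Parameters for depth-threshold presence/absence calling
#'
#' A gene is called absent when the fraction of its exon-union bases covered
#' at depth >= `min_cov` falls below `lost_cutoff` (strict `<`, so a
#' fraction exactly at the cutoff is present). The defaults are the
#' standard low-coverage setting (`min_cov = 2`, `lost_cutoff = 0.05`); for
#' very deep sequencing a high-depth preset (`min_cov = 300`,
#' `lost_cutoff = 0.70`) with identical semantics is conventional.
#'
#' @param min_cov integer depth threshold (bases at depth >= `min_cov`
#'   count as covered).
#' @param lost_cutoff covered-fraction cutoff in (0, 1].
#' @param region `"exon-union"` (default) or `"gene-span"` for annotations
#'   without usable exon models.
#' @return list of class `pav_params`.
#' @export
pav_params <- function(min_cov = 2L, lost_cutoff = 0.05,
                       region = c("exon-union", "gene-span")) {
  region <- match.arg(region)
  stopifnot(min_cov >= 1, lost_cutoff > 0, lost_cutoff <= 1)
  structure(list(min_cov = as.integer(min_cov), lost_cutoff = lost_cutoff,
                 region = region),
            class = "pav_params")
}

# per-gene base index list (1-based positions into the chromosome vector),
# cached on the annotation via an attribute-free memo in the calling code
gene_base_index <- function(annotation, region = "exon-union") {
  g <- annotation$genes
  lapply(seq_len(nrow(g)), function(i) {
    if (region == "gene-span") {
      m <- cbind(g$start[i], g$end[i])
    } else {
      m <- annotation$exons[[g$gene_id[i]]]
    }
    unlist(lapply(seq_len(nrow(m)), function(r) (m[r, 1] + 1L):m[r, 2]),
           use.names = FALSE)
  })
}

#' Fraction of a gene's exon-union bases covered at or above a depth
#'
#' @param annotation a [genome_annotation()].
#' @param gene_id gene to measure.
#' @param track a [depth_track()] for one accession.
#' @param min_cov depth threshold.
#' @param region `"exon-union"` or `"gene-span"`.
#' @return covered fraction in \[0, 1\].
#' @export
gene_covered_fraction <- function(annotation, gene_id, track, min_cov = 2L,
                                  region = "exon-union") {
  i <- match(gene_id, annotation$genes$gene_id)
  if (is.na(i)) stop("unknown gene: ", gene_id)
  chrom <- annotation$genes$chrom[i]
  m <- if (region == "gene-span") {
    cbind(annotation$genes$start[i], annotation$genes$end[i])
  } else {
    annotation$exons[[gene_id]]
  }
  idx <- unlist(lapply(seq_len(nrow(m)), function(r) (m[r, 1] + 1L):m[r, 2]),
                use.names = FALSE)
  if (!length(idx)) stop("zero-length exon union for ", gene_id)
  mean(track$depth[[chrom]][idx] >= min_cov)
}

#' Call presence/absence for every gene in one accession
#'
#' @param annotation a [genome_annotation()].
#' @param track a [depth_track()].
#' @param params a [pav_params()].
#' @return data.frame with columns `gene_id`, `chrom`, `rank`, `fraction`
#'   (covered fraction at `min_cov`) and `present` (logical; absent iff
#'   `fraction < lost_cutoff`).
#' @export
call_pav <- function(annotation, track, params = pav_params()) {
  g <- annotation$genes
  idx <- gene_base_index(annotation, params$region)
  frac <- vapply(seq_len(nrow(g)), function(i) {
    v <- track$depth[[g$chrom[i]]]
    mean(v[idx[[i]]] >= params$min_cov)
  }, numeric(1))
  data.frame(gene_id = g$gene_id, chrom = g$chrom, rank = g$rank,
             fraction = frac, present = frac >= params$lost_cutoff,
             stringsAsFactors = FALSE)
}

#' Assemble the binary PAV matrix across accessions
#'
#' Accessions whose genome-wide mean depth falls below `min_mean_depth` are
#' excluded before the matrix is built (low-coverage libraries make absence
#' calls unreliable); their ids and depths are reported in the `excluded`
#' attribute and via a message.
#'
#' @param calls named list (by accession) of [call_pav()] outputs sharing
#'   one gene universe.
#' @param mean_depths optional named numeric of genome-wide mean depths (as
#'   from [track_mean_depth()]); required when `min_mean_depth > 0`.
#' @param min_mean_depth exclusion threshold (default 5).
#' @return integer matrix (genes x accessions) with 1 = present,
#'   0 = absent; attributes `fractions` (matching numeric matrix of covered
#'   fractions) and `excluded` (data.frame `accession`, `mean_depth`).
#' @export
build_pav_matrix <- function(calls, mean_depths = NULL, min_mean_depth = 5) {
  stopifnot(length(calls) >= 1, !is.null(names(calls)))
  universe <- calls[[1]]$gene_id
  for (nm in names(calls)) {
    if (!identical(sort(calls[[nm]]$gene_id), sort(universe))) {
      diff <- union(setdiff(calls[[nm]]$gene_id, universe),
                    setdiff(universe, calls[[nm]]$gene_id))
      stop("inconsistent gene universes; symmetric difference: ",
           paste(utils::head(diff, 10), collapse = ", "))
    }
  }
  keep <- names(calls)
  excluded <- data.frame(accession = character(0), mean_depth = numeric(0))
  if (min_mean_depth > 0 && !is.null(mean_depths)) {
    low <- names(calls)[mean_depths[names(calls)] < min_mean_depth]
    if (length(low)) {
      excluded <- data.frame(accession = low,
                             mean_depth = unname(mean_depths[low]))
      message("excluding low-coverage accessions: ",
              paste(sprintf("%s (%.2fx)", low, mean_depths[low]),
                    collapse = ", "))
      keep <- setdiff(keep, low)
    }
  }
  if (!length(keep)) stop("all accessions excluded by min_mean_depth")
  m <- vapply(keep, function(nm) {
    x <- calls[[nm]]
    as.integer(x$present)[match(universe, x$gene_id)]
  }, integer(length(universe)))
  fr <- vapply(keep, function(nm) {
    x <- calls[[nm]]
    x$fraction[match(universe, x$gene_id)]
  }, numeric(length(universe)))
  dimnames(m) <- list(universe, keep)
  dimnames(fr) <- list(universe, keep)
  attr(m, "fractions") <- fr
  attr(m, "excluded") <- excluded
  m
}

#' Write / read a PAV matrix as TSV
#'
#' First column `gene_id`, one column per accession, cells `1` (present) or
#' `0` (absent).
#'
#' @param matrix integer PAV matrix (genes x accessions).
#' @param path file path.
#' @return `write_pav_matrix`: `path` invisibly; `read_pav_matrix`: the
#'   integer matrix.
#' @export
write_pav_matrix <- function(matrix, path) {
  dt <- data.table::data.table(gene_id = rownames(matrix))
  for (nm in colnames(matrix)) dt[[nm]] <- matrix[, nm]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_pav_matrix
#' @export
read_pav_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1])
  storage.mode(m) <- "integer"
  rownames(m) <- dt[[1]]
  if (any(is.na(m)) || !all(m %in% c(0L, 1L)))
    stop("PAV matrix cells must be 0 or 1")
  m
}

#' Agreement between PAV calls and simulated truth
#'
#' @param matrix called PAV matrix (genes x accessions).
#' @param truth_pav truth matrix with the same dimnames.
#' @return list with `accuracy` (fraction of matching cells) and
#'   `n_discordant`.
#' @export
evaluate_pav_calls <- function(matrix, truth_pav) {
  truth <- truth_pav[rownames(matrix), colnames(matrix), drop = FALSE]
  list(accuracy = mean(matrix == truth),
       n_discordant = sum(matrix != truth))
}
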