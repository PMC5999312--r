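#' Read a two-column gene-family assignment table
#'
#' @param path TSV with columns gene id, family id (no header required;
#'   a header line is detected and skipped if the first field is
#'   `gene_id`).
#' @param all_genes optional character vector; genes missing from the file
#'   become singleton families (`singleton:<gene_id>`).
#' @return data.frame with columns `gene_id`, `family_id`.
#' @export
read_family_assignments <- function(path, all_genes = NULL) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (nrow(dt) && dt[[1]][1] == "gene_id") dt <- dt[-1]
  fam <- data.frame(gene_id = as.character(dt[[1]]),
                    family_id = as.character(dt[[2]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(fam$gene_id)) stop("gene assigned to multiple families")
  if (!is.null(all_genes)) {
    miss <- setdiff(all_genes, fam$gene_id)
    if (length(miss))
      fam <- rbind(fam, data.frame(gene_id = miss,
                                   family_id = paste0("singleton:", miss),
                                   stringsAsFactors = FALSE))
  }
  fam
}

#' Classify genes as core or variable
#'
#' Core genes are present in every retained accession; all others are
#' variable.
#'
#' @param matrix binary PAV matrix (genes x accessions).
#' @return data.frame `gene_id`, `n_present`, `label`
#'   (`"core"`/`"variable"`).
#' @export
classify_genes <- function(matrix) {
  stopifnot(nrow(matrix) > 0, ncol(matrix) > 0)
  npres <- rowSums(matrix)
  data.frame(gene_id = rownames(matrix), n_present = npres,
             label = ifelse(npres == ncol(matrix), "core", "variable"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify gene families as core or variable
#'
#' A family is core if at least one member gene is present in all
#' accessions (clause 1); it is variable if the whole family is missing
#' from at least one accession (clause 2). The clauses are neither
#' exhaustive nor exclusive: when both hold, core wins, and families
#' satisfying neither (no always-present member, but never wholly lost)
#' default to core — "variable" certifies a demonstrable whole-family
#' loss. Both raw clause outcomes are reported alongside the label.
#'
#' @param matrix binary PAV matrix.
#' @param families data.frame `gene_id`, `family_id` covering every matrix
#'   gene.
#' @return data.frame `family_id`, `n_genes`, `has_core_member`,
#'   `wholly_missing_somewhere`, `label`.
#' @export
classify_families <- function(matrix, families) {
  miss <- setdiff(rownames(matrix), families$gene_id)
  if (length(miss))
    stop("matrix genes without family assignment: ",
         paste(utils::head(miss, 5), collapse = ", "))
  extra <- setdiff(families$gene_id, rownames(matrix))
  if (length(extra))
    stop("family genes missing from the matrix: ",
         paste(utils::head(extra, 5), collapse = ", "))
  fam <- families$family_id[match(rownames(matrix), families$gene_id)]
  npres <- rowSums(matrix)
  has_core <- tapply(npres == ncol(matrix), fam, any)
  # accession-wise family presence: family present in accession a iff any
  # member present; wholly missing somewhere iff min over accessions == 0
  fam_pres_min <- rep(TRUE, length(unique(fam)))
  names(fam_pres_min) <- sort(unique(fam))
  for (a in seq_len(ncol(matrix))) {
    pres_a <- tapply(matrix[, a] == 1L, fam, any)
    fam_pres_min[names(pres_a)] <- fam_pres_min[names(pres_a)] & pres_a
  }
  ids <- sort(unique(fam))
  has_core <- has_core[ids]
  never_lost <- fam_pres_min[ids]
  data.frame(
    family_id = ids,
    n_genes = as.integer(table(fam)[ids]),
    has_core_member = unname(has_core),
    wholly_missing_somewhere = unname(!never_lost),
    label = ifelse(unname(has_core) | unname(never_lost), "core",
                   "variable"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Per-accession uniquely present / uniquely absent gene counts
#'
#' A gene is uniquely present in accession `a` when it is present in `a`
#' and absent everywhere else; uniquely absent when absent in `a` and
#' present everywhere else.
#'
#' @param matrix binary PAV matrix with >= 2 accessions.
#' @return data.frame `accession`, `uniquely_present`, `uniquely_absent`.
#' @export
unique_presence_absence <- function(matrix) {
  stopifnot(ncol(matrix) >= 2)
  npres <- rowSums(matrix)
  up <- colSums(matrix == 1L & npres == 1L)
  ua <- colSums(matrix == 0L & npres == ncol(matrix) - 1L)
  data.frame(accession = colnames(matrix), uniquely_present = as.integer(up),
             uniquely_absent = as.integer(ua), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Core/variable partition percentages
#'
#' Small arithmetic helper used in summaries: given core and variable
#' counts, returns the counts, total, and the two percentages.
#'
#' @param n_core core count.
#' @param n_variable variable count.
#' @return list with `n_core`, `n_variable`, `total`, `pct_core`,
#'   `pct_variable`.
#' @export
partition_percentages <- function(n_core, n_variable) {
  total <- n_core + n_variable
  list(n_core = n_core, n_variable = n_variable, total = total,
       pct_core = 100 * n_core / total,
       pct_variable = 100 * n_variable / total)
}

#' Bootstrap dendrogram of accessions from the PAV matrix
#'
#' Accessions are clustered by the Hamming distance between their binary
#' PAV columns (fraction of genes with discordant state) with average
#' linkage. Node support is the fraction of `n_boot` gene-resampled (rows,
#' with replacement) trees containing the same accession bipartition.
#' Columns are ordered by accession id before clustering so zero-distance
#' ties resolve deterministically.
#'
#' @param matrix binary PAV matrix with >= 3 accessions.
#' @param n_boot bootstrap resamplings, default 1000.
#' @param seed integer seed for the resampling.
#' @param method linkage method for [stats::hclust()], default
#'   `"average"`.
#' @return list with `tree` (an [ape::as.phylo()] tree whose node labels
#'   hold the support proportions), `support` (numeric vector by internal
#'   node) and `hclust` (the underlying hclust object).
#' @export
pav_dendrogram <- function(matrix, n_boot = 1000L, seed = 1L,
                           method = "average") {
  stopifnot(ncol(matrix) >= 3)
  matrix <- matrix[, order(colnames(matrix)), drop = FALSE]
  ham <- function(m) stats::dist(t(m), method = "manhattan") / nrow(m)
  hc <- stats::hclust(ham(matrix), method = method)
  tree <- ape::as.phylo(hc)
  set.seed(seed)
  boot_trees <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    rows <- sample.int(nrow(matrix), nrow(matrix), replace = TRUE)
    boot_trees[[b]] <- ape::as.phylo(
      stats::hclust(ham(matrix[rows, , drop = FALSE]), method = method))
  }
  class(boot_trees) <- "multiPhylo"
  counts <- ape::prop.clades(tree, boot_trees, rooted = TRUE)
  counts[is.na(counts)] <- 0L
  support <- counts / n_boot
  tree$node.label <- format(round(support, 3), trim = TRUE)
  list(tree = tree, support = support, hclust = hc)
}

#' Write a dendrogram with supports as Newick
#'
#' @param dend result of [pav_dendrogram()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(dend, path) {
  ape::write.tree(dend$tree, file = path)
  invisible(path)
}
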