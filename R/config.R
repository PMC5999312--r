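#' Read a pipeline configuration file
#'
#' YAML file with optional nested sections `sim`, `pav` and `he`, each
#' holding overrides for the corresponding parameter constructor
#' ([sim_config()], [pav_params()], [he_params()]). Unknown keys raise an
#' error; the fully resolved parameter set is logged with `message()` so
#' every run records the thresholds it used.
#'
#' @param path YAML file.
#' @param quiet suppress the resolved-parameter log.
#' @return list with elements `sim`, `pav`, `he`.
#' @export
read_config <- function(path, quiet = FALSE) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  build <- function(section, ctor) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    known <- names(formals(ctor))
    bad <- setdiff(names(args), known)
    if (length(bad))
      stop(sprintf("unknown key(s) in config section '%s': %s",
                   section, paste(bad, collapse = ", ")))
    do.call(ctor, args)
  }
  cfg <- list(sim = build("sim", sim_config),
              pav = build("pav", pav_params),
              he = build("he", he_params))
  if (!quiet) {
    flat <- function(p) paste(names(p), vapply(p, function(v)
      paste(format(v), collapse = ","), character(1)),
      sep = "=", collapse = " ")
    message("resolved sim config: ", flat(cfg$sim))
    message("resolved pav params: ", flat(cfg$pav))
    message("resolved he params:  ", flat(cfg$he))
  }
  cfg
}

#' Reference gene and cluster counts of the B. napus pangenome
#'
#' Headline counts for the 50-accession *Brassica napus* pangenome:
#' core/variable gene and orthologous-cluster partitions and the disease
#' resistance (R-) gene tallies. Used by the summary helpers to reproduce
#' the partition percentages by arithmetic; they are inputs, not outputs,
#' of this package.
#'
#' @return data.frame with columns `quantity` and `count`.
#' @export
reference_counts <- function() {
  path <- system.file("extdata", "bnapus_reference_counts.tsv",
                      package = "panhe", mustWork = TRUE)
  out <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  out
}
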