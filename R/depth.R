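#' Per-base read-depth track for one accession
#'
#' @param accession accession id.
#' @param depth named list (by chromosome) of non-negative integer vectors,
#'   one entry per base.
#' @param annotation a [genome_annotation()]; vector lengths must equal the
#'   annotated chromosome lengths.
#' @return An object of class `depth_track`.
#' @export
depth_track <- function(accession, depth, annotation) {
  ch <- annotation$chromosomes
  if (!setequal(names(depth), ch$name))
    stop("depth track chromosomes do not match the annotation")
  for (nm in ch$name) {
    len <- ch$length[ch$name == nm]
    if (length(depth[[nm]]) != len)
      stop(sprintf("depth vector for %s has length %d, annotated length is %d",
                   nm, length(depth[[nm]]), len))
    if (any(depth[[nm]] < 0)) stop("negative depth on ", nm)
  }
  structure(list(accession = accession, depth = depth[ch$name]),
            class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  tot <- sum(vapply(x$depth, function(v) sum(as.numeric(v)), numeric(1)))
  nb <- sum(lengths(x$depth))
  cat(sprintf("depth_track '%s': %d chromosomes, %d bp, mean depth %.2fx\n",
              x$accession, length(x$depth), nb, tot / nb))
  invisible(x)
}

#' Genome-wide mean depth of a track
#' @param track a [depth_track()].
#' @return mean per-base depth across all chromosomes.
#' @export
track_mean_depth <- function(track) {
  sum(vapply(track$depth, function(v) sum(as.numeric(v)), numeric(1))) /
    sum(lengths(track$depth))
}

#' Read a per-base depth file
#'
#' Accepts either `samtools depth` / `bedtools genomecov -d` style 3-column
#' TSV (chromosome, 1-based position, depth) or 4-column bedGraph
#' (chromosome, 0-based start, end, depth; half-open). The format is chosen
#' by column count. Positions absent from the file get depth 0.
#'
#' @param path depth file.
#' @param annotation a [genome_annotation()] fixing chromosome lengths.
#' @param accession accession id to attach.
#' @return A [depth_track()].
#' @export
read_depth <- function(path, annotation, accession) {
  ch <- annotation$chromosomes
  depth <- lapply(stats::setNames(ch$length, ch$name), function(n) integer(n))
  dt <- tryCatch(
    suppressWarnings(data.table::fread(path, header = FALSE, sep = "\t")),
    error = function(e) data.table::data.table()
  )
  if (nrow(dt)) {
    unknown <- setdiff(unique(dt[[1]]), ch$name)
    if (length(unknown))
      stop("depth file refers to unknown chromosome: ",
           paste(unknown, collapse = ", "))
    lens <- stats::setNames(ch$length, ch$name)
    if (ncol(dt) == 3L) {
      pos <- as.integer(dt[[2]])
      if (any(pos < 1L) || any(pos > lens[dt[[1]]])) {
        bad <- dt[[1]][which(pos < 1L | pos > lens[dt[[1]]])[1]]
        stop("position outside chromosome ", bad)
      }
      for (nm in unique(dt[[1]])) {
        sel <- dt[[1]] == nm
        depth[[nm]][pos[sel]] <- as.integer(dt[[3]][sel])
      }
    } else if (ncol(dt) == 4L) {
      s <- as.integer(dt[[2]]); e <- as.integer(dt[[3]])
      if (any(s < 0L) || any(e > lens[dt[[1]]]) || any(e <= s)) {
        bad <- dt[[1]][which(s < 0L | e > lens[dt[[1]]] | e <= s)[1]]
        stop("interval outside chromosome ", bad)
      }
      for (i in seq_len(nrow(dt))) {
        nm <- dt[[1]][i]
        depth[[nm]][(s[i] + 1L):e[i]] <- as.integer(dt[[4]][i])
      }
    } else {
      stop("depth file must have 3 (TSV) or 4 (bedGraph) columns, got ",
           ncol(dt))
    }
  }
  depth_track(accession, depth, annotation)
}

#' Write a depth track
#'
#' `format = "tsv"` writes 3-column 1-based TSV omitting zero-depth
#' positions; `format = "bedgraph"` writes run-length-compressed 0-based
#' half-open bedGraph including zero runs. Both round-trip exactly through
#' [read_depth()].
#'
#' @param track a [depth_track()].
#' @param path output file.
#' @param format `"tsv"` or `"bedgraph"`.
#' @return `path`, invisibly.
#' @export
write_depth <- function(track, path, format = c("tsv", "bedgraph")) {
  format <- match.arg(format)
  parts <- lapply(names(track$depth), function(nm) {
    v <- track$depth[[nm]]
    if (format == "tsv") {
      nz <- which(v != 0L)
      if (!length(nz)) return(NULL)
      data.table::data.table(chrom = nm, pos = nz, depth = v[nz])
    } else {
      r <- rle(v)
      e <- cumsum(r$lengths)
      data.table::data.table(chrom = nm, start = e - r$lengths, end = e,
                             depth = r$values)
    }
  })
  out <- data.table::rbindlist(parts)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  if (!nrow(out)) cat("", file = path)  # ensure the file exists when empty
  invisible(path)
}
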