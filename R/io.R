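# Plain-text interchange: BED (0-based half-open), bedGraph, BEDPE,
# variant TSV, PAF-like block TSV, expression TSV, and a YAML run manifest.
# All readers return tibbles that round-trip bit-identically through the
# matching writer.

#' Read / write BED intervals
#'
#' @param path File path.
#' @param x Tibble with `chrom`, `start`, `end` and optional `name` (any
#'   fourth column, e.g. domain class or sample id).
#' @return `read_bed`: a tibble (`chrom`, `start`, `end`[, `name`]).
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                        show_col_types = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  tibble::as_tibble(df[, seq_len(min(4, ncol(df)))])
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "class"), names(x))
  readr::write_tsv(x[cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read / write bedGraph tracks
#'
#' Bins with `NA` value are omitted on write (missing, not zero).
#'
#' @param path File path.
#' @param x Track tibble (`chrom`, `start`, `end`, `value`).
#' @return `read_bedgraph`: a tibble (`chrom`, `start`, `end`, `value`).
#' @export
read_bedgraph <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                  col_types = "ciid", progress = FALSE)
}

#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(x, path) {
  readr::write_tsv(x[!is.na(x$value), c("chrom", "start", "end", "value")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read / write BEDPE loop files
#'
#' @param path File path.
#' @param x A `loop_set`.
#' @return `read_bedpe`: a `loop_set`.
#' @export
read_bedpe <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                        show_col_types = FALSE)
  names(df)[1:6] <- c("chrom", "start1", "end1", "chrom2", "start2", "end2")
  if (any(df$chrom != df$chrom2)) stop("inter-chromosomal loops unsupported")
  loop_set(df[c("chrom", "start1", "end1", "start2", "end2")])
}

#' @rdname read_bedpe
#' @export
write_bedpe <- function(x, path) {
  out <- tibble::tibble(chrom1 = x$chrom, start1 = x$start1, end1 = x$end1,
                        chrom2 = x$chrom, start2 = x$start2, end2 = x$end2)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read / write variant TSV
#'
#' Columns `chrom`, `pos0`, `end0`, `type` (`SNP` or `DEL`); SNPs have
#' `end0 = pos0 + 1`.
#'
#' @param path File path.
#' @param x A `variant_set` (list with `snps` and `deletions`).
#' @return `read_variants`: a `variant_set`.
#' @export
read_variants <- function(path) {
  df <- readr::read_tsv(path, col_types = "ciic", progress = FALSE)
  names(df) <- c("chrom", "pos0", "end0", "type")
  structure(list(
    snps = tibble::tibble(chrom = df$chrom[df$type == "SNP"],
                          pos = df$pos0[df$type == "SNP"]),
    deletions = tibble::tibble(chrom = df$chrom[df$type == "DEL"],
                               start = df$pos0[df$type == "DEL"],
                               end = df$end0[df$type == "DEL"])
  ), class = "variant_set")
}

#' @rdname read_variants
#' @export
write_variants <- function(x, path) {
  out <- dplyr::bind_rows(
    tibble::tibble(chrom = x$snps$chrom, pos0 = as.integer(x$snps$pos),
                   end0 = as.integer(x$snps$pos + 1), type = "SNP"),
    tibble::tibble(chrom = x$deletions$chrom,
                   pos0 = as.integer(x$deletions$start),
                   end0 = as.integer(x$deletions$end), type = "DEL")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read / write PAF-like synteny block TSV
#'
#' Columns `qname`, `qstart`, `qend`, `strand`, `tname`, `tstart`, `tend`,
#' `alignable_bp`.
#'
#' @param path File path.
#' @param x Block tibble.
#' @return `read_synteny_blocks`: a tibble of blocks.
#' @export
read_synteny_blocks <- function(path) {
  readr::read_tsv(path, col_types = "cddccddd", progress = FALSE)
}

#' @rdname read_synteny_blocks
#' @export
write_synteny_blocks <- function(x, path) {
  cols <- c("qname", "qstart", "qend", "strand", "tname", "tstart", "tend",
            "alignable_bp")
  readr::write_tsv(x[cols], path, progress = FALSE)
  invisible(path)
}

#' Read / write binned expression TSV
#'
#' `bin_id`, `chrom`, `start`, `end`, then one count column per sample.
#'
#' @param path File path.
#' @param x Expression count tibble.
#' @return `read_expression`: a tibble.
#' @export
read_expression <- function(path) {
  readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
}

#' @rdname read_expression
#' @export
write_expression <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Write a YAML manifest of emitted files
#'
#' @param files Named list of relative file paths.
#' @param seed The seed the run used.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(files, seed, path) {
  yaml::write_yaml(list(seed = seed, files = files), path)
  invisible(path)
}
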