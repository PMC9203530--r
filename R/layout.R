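#' Define a binned genome layout
#'
#' A layout fixes the chromosome names, their lengths and the bin size that
#' every binned object in the package (contact matrices, tracks, expression
#' bins) refers to. All coordinates are 0-based, half-open; bin index of a
#' position is `floor(pos / bin_size)` (1-based in R vectors).
#'
#' @param chrom_names Character vector of chromosome identifiers.
#' @param chrom_lengths Integer vector of chromosome lengths in bp.
#' @param bin_size Bin size in bp.
#' @return An object of class `genome_layout`: a tibble with one row per
#'   chromosome (`chrom`, `length`, `n_bins`) carrying `bin_size` as an
#'   attribute.
#' @examples
#' layout <- genome_layout(c("chr1", "chr2"), c(2e6, 1e6), 4e4)
#' layout_bins(layout)
#' @export
genome_layout <- function(chrom_names, chrom_lengths, bin_size) {
  stopifnot(length(chrom_names) == length(chrom_lengths))
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  if (bin_size <= 0) stop("bin_size must be > 0")
  if (anyDuplicated(chrom_names)) stop("duplicated chromosome names")
  out <- tibble::tibble(
    chrom = as.character(chrom_names),
    length = as.numeric(chrom_lengths),
    n_bins = as.integer(ceiling(chrom_lengths / bin_size))
  )
  attr(out, "bin_size") <- as.numeric(bin_size)
  class(out) <- c("genome_layout", class(out))
  out
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> bin_size =", format(bin_size(x), big.mark = ","), "bp\n")
  NextMethod()
}

#' Bin size of a layout
#' @param layout A `genome_layout`.
#' @return Bin size in bp.
#' @export
bin_size <- function(layout) attr(layout, "bin_size")

#' Enumerate the bins of a layout
#'
#' @param layout A `genome_layout`.
#' @return A tibble with one row per bin: `chrom`, `start`, `end` (bp,
#'   0-based half-open, last bin clipped to the chromosome end), `bin`
#'   (1-based index within the chromosome) and `gbin` (1-based index across
#'   the whole genome).
#' @export
layout_bins <- function(layout) {
  bs <- bin_size(layout)
  out <- purrr::pmap_dfr(layout, function(chrom, length, n_bins) {
    start <- (seq_len(n_bins) - 1) * bs
    tibble::tibble(
      chrom = chrom,
      start = start,
      end = pmin(start + bs, length),
      bin = seq_len(n_bins)
    )
  })
  out$gbin <- seq_len(nrow(out))
  out
}

#' Total number of bins in a layout
#' @param layout A `genome_layout`.
#' @return Integer bin count summed over chromosomes.
#' @export
n_bins <- function(layout) sum(layout$n_bins)

# bin index (1-based, within chromosome) for bp positions
pos_to_bin <- function(pos, layout_or_binsize) {
  bs <- if (inherits(layout_or_binsize, "genome_layout")) {
    bin_size(layout_or_binsize)
  } else {
    layout_or_binsize
  }
  as.integer(floor(pos / bs)) + 1L
}

layout_chrom <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  layout[i, ]
}
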