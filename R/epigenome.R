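#' Binned methylation level from per-cytosine counts
#'
#' The methylation level of a bin is the percentage of heavily methylated
#' sites in it, where a site is heavily methylated when its methylated reads
#' make up at least `heavy_threshold` of all mapped reads. The `"overall"`
#' context pools sites of all three contexts before applying the rule. Bins
#' with no covered sites are `NA` (distinct from 0) and are omitted from
#' bedGraph export.
#'
#' @param sites Tibble of sites: `chrom`, `pos` (0-based), `context`
#'   (`CpG`/`CHG`/`CHH`), `methylated`, `total` (read counts).
#' @param layout A `genome_layout`.
#' @param context One of `"CpG"`, `"CHG"`, `"CHH"`, `"overall"`.
#' @param heavy_threshold Heavy-site threshold on methylated/total
#'   (default 0.25, inclusive).
#' @return A per-bin track tibble: `chrom`, `start`, `end`, `value`
#'   (percent, 0-100, `NA` where no sites).
#' @export
methylation_level <- function(sites, layout,
                              context = c("overall", "CpG", "CHG", "CHH"),
                              heavy_threshold = 0.25) {
  context <- match.arg(context)
  stopifnot(all(sites$methylated <= sites$total), all(sites$total >= 1))
  if (context != "overall") sites <- sites[sites$context == context, ]
  bins <- layout_bins(layout)
  bs <- bin_size(layout)
  heavy <- sites$methylated / sites$total >= heavy_threshold
  keykey <- paste0(sites$chrom, ":", floor(sites$pos / bs))
  bin_key <- paste0(bins$chrom, ":", floor(bins$start / bs))
  n_sites <- tapply(rep(1L, length(keykey)), keykey, sum)
  n_heavy <- tapply(as.integer(heavy), keykey, sum)
  out <- bins[, c("chrom", "start", "end")]
  ns <- as.numeric(n_sites[bin_key])
  nh <- as.numeric(n_heavy[bin_key])
  out$value <- ifelse(!is.na(ns) & ns > 0, 100 * nh / ns, NA_real_)
  out
}

#' Binned coverage in counts per million
#'
#' Each fragment is assigned to the bin holding its midpoint; per-bin counts
#' are scaled to counts per million fragments per sample.
#'
#' @param fragments Tibble: `chrom`, `start`, `end` (bp) and optional
#'   `sample`.
#' @param layout A `genome_layout`.
#' @return A per-bin track tibble (`chrom`, `start`, `end`, `sample`,
#'   `value`); the `value` column sums to 1e6 within each sample.
#' @export
coverage_cpm <- function(fragments, layout) {
  if (!nrow(fragments)) stop("zero fragments")
  if (!"sample" %in% names(fragments)) fragments$sample <- "sample1"
  bins <- layout_bins(layout)
  bs <- bin_size(layout)
  mid <- (fragments$start + fragments$end) / 2
  frag_key <- paste0(fragments$chrom, ":", floor(mid / bs))
  bin_key <- paste0(bins$chrom, ":", floor(bins$start / bs))
  purrr::map_dfr(split(frag_key, fragments$sample), function(keys) {
    counts <- table(keys)
    out <- bins[, c("chrom", "start", "end")]
    n <- as.numeric(counts[bin_key])
    n[is.na(n)] <- 0
    out$value <- n * 1e6 / length(keys)
    out
  }, .id = "sample") |>
    dplyr::relocate("sample", .after = "end")
}
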