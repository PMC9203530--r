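#' Phred-scaled assembly quality (QV)
#'
#' `QV = -10 * log10(n_variant_sites / n_covered_sites)`, the per-base error
#' probability estimated from variant sites over adequately covered assembly
#' positions. Zero variant sites is reported as the capped sentinel QV = 99.
#'
#' @param n_variant_sites Number of variant (error) sites.
#' @param n_covered_sites Number of assembly sites with adequate coverage.
#' @return The QV score (numeric scalar).
#' @examples
#' assembly_qv(1000, 1e6)  # 30
#' @export
assembly_qv <- function(n_variant_sites, n_covered_sites) {
  if (n_covered_sites <= 0) stop("n_covered_sites must be > 0")
  if (n_variant_sites < 0 || n_variant_sites > n_covered_sites) {
    stop("need 0 <= n_variant_sites <= n_covered_sites")
  }
  if (n_variant_sites == 0) return(99)
  -10 * log10(n_variant_sites / n_covered_sites)
}

#' An enrichment result against a permutation null
#'
#' @param observed Observed statistic.
#' @param null Numeric vector of null replicates.
#' @param n_perm Number of permutations.
#' @param seed Seed used to generate the null.
#' @return A tibble of class `enrichment_result` with `observed`,
#'   `null_mean`, `null_sd`, `z`, `p` (add-one empirical p,
#'   `(1 + #\{null >= observed\}) / (n_perm + 1)`), `n_perm`, `seed`.
#' @export
enrichment_result <- function(observed, null, n_perm = length(null),
                              seed = NA_integer_) {
  null_mean <- mean(null)
  null_sd <- stats::sd(null)
  out <- tibble::tibble(
    observed = observed,
    null_mean = null_mean,
    null_sd = null_sd,
    z = if (null_sd > 0) (observed - null_mean) / null_sd else NA_real_,
    p = (1 + sum(null >= observed)) / (n_perm + 1),
    n_perm = as.integer(n_perm),
    seed = as.integer(seed)
  )
  class(out) <- c("enrichment_result", class(out))
  out
}

#' @export
tidy.enrichment_result <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(z = x$z, p = x$p, n_perm = x$n_perm)
}

#' Observed/expected variant profile around domain boundaries
#'
#' Sliding windows of width `window` at offsets `-flank .. +flank` (step
#' `step`) centered on boundary midpoints. Observed is the summed statistic
#' (SNP count or deletion-covered bp) over boundaries per offset; expected
#' assumes variants are homogeneous along the genome: genome-wide density
#' times the summed in-genome window bp (windows clipped at chromosome ends
#' reduce the expectation proportionally).
#'
#' @param variants Tibble of variants: `chrom`, `pos` (0-based SNP position)
#'   for `mode = "SNP_count"`, or `chrom`, `start`, `end` for
#'   `mode = "deletion_bp"`.
#' @param boundaries Boundary tibble (`chrom`, `start`, `end`).
#' @param layout A `genome_layout`.
#' @param window Window width in bp (default 40,000).
#' @param step Offset step in bp (default 5,000).
#' @param flank Maximum |offset| in bp (default 500,000).
#' @param mode `"SNP_count"` or `"deletion_bp"`.
#' @return A tibble of class `obs_exp_profile`: `offset_bp`, `obs`, `exp`,
#'   `ratio`.
#' @export
boundary_variant_profile <- function(variants, boundaries, layout,
                                     window = 40000, step = 5000,
                                     flank = 5e5,
                                     mode = c("SNP_count", "deletion_bp")) {
  mode <- match.arg(mode)
  offsets <- seq(-flank, flank, by = step)
  genome_bp <- sum(layout$length)
  if (mode == "SNP_count") {
    if (!nrow(variants)) warning("no variants: ratio undefined")
    density <- nrow(variants) / genome_bp
    snp_by_chrom <- purrr::map(split(variants$pos, variants$chrom), sort)
  } else {
    if (!nrow(variants)) warning("no variants: ratio undefined")
    density <- sum(variants$end - variants$start) / genome_bp
    del_by_chrom <- split(variants, variants$chrom)
  }
  obs <- exp_ <- numeric(length(offsets))
  half <- window / 2
  for (ch in unique(boundaries$chrom)) {
    clen <- layout_chrom(layout, ch)$length
    mids <- (boundaries$start + boundaries$end)[boundaries$chrom == ch] / 2
    if (!length(mids)) next
    for (oi in seq_along(offsets)) {
      lo <- pmax(0, mids + offsets[oi] - half)
      hi <- pmin(clen, mids + offsets[oi] + half)
      valid <- hi > lo
      lo <- lo[valid]; hi <- hi[valid]
      exp_[oi] <- exp_[oi] + density * sum(hi - lo)
      if (!length(lo)) next
      if (mode == "SNP_count") {
        pos <- snp_by_chrom[[ch]]
        if (!is.null(pos)) {
          obs[oi] <- obs[oi] +
            sum(findInterval(hi - 1e-9, pos) - findInterval(lo - 1e-9, pos))
        }
      } else {
        dels <- del_by_chrom[[ch]]
        if (!is.null(dels) && nrow(dels)) {
          wins <- IRanges::IRanges(lo + 1, hi)
          drng <- IRanges::IRanges(dels$start + 1, dels$end)
          ov <- IRanges::findOverlaps(wins, drng)
          if (length(ov)) {
            obs[oi] <- obs[oi] + sum(IRanges::width(
              IRanges::pintersect(wins[S4Vectors::queryHits(ov)],
                                  drng[S4Vectors::subjectHits(ov)])))
          }
        }
      }
    }
  }
  out <- tibble::tibble(
    offset_bp = offsets, obs = obs, exp = exp_,
    ratio = ifelse(exp_ > 0, obs / exp_, NA_real_)
  )
  class(out) <- c("obs_exp_profile", class(out))
  out
}

#' Detect synteny breaks from alignment blocks
#'
#' Adjacent reference-sorted blocks are chained when they share the query
#' chromosome and strand, keep a consistent query order, and both the
#' reference and query gaps are at most `max_join_gap_bp`. Chains spanning
#' less than `min_block_bp` on the reference are discarded. A break is
#' emitted at the reference midpoint between consecutive chains that differ
#' in query chromosome or strand, or violate query collinearity.
#'
#' @param blocks Tibble of alignment blocks: `tname`, `tstart`, `tend`
#'   (reference), `qname`, `qstart`, `qend`, `strand` (`+`/`-`), optional
#'   `alignable_bp`.
#' @param min_block_bp Minimum chain span on the reference (default 10,000).
#' @param max_join_gap_bp Maximum joinable gap (default 100,000).
#' @return A tibble of breaks: `chrom`, `pos` (bp on the reference), `kind`
#'   (`chrom`, `strand` or `order`).
#' @export
detect_synteny_breaks <- function(blocks, min_block_bp = 10000,
                                  max_join_gap_bp = 1e5) {
  purrr::map_dfr(split(blocks, blocks$tname), function(d) {
    d <- d[order(d$tstart), , drop = FALSE]
    # resolve reference overlaps by keeping the longer block
    keep <- rep(TRUE, nrow(d))
    last_end <- -Inf; last_i <- NA_integer_
    for (i in seq_len(nrow(d))) {
      if (d$tstart[i] < last_end) {
        warning("overlapping reference blocks; keeping the longer")
        if ((d$tend[i] - d$tstart[i]) >
            (d$tend[last_i] - d$tstart[last_i])) {
          keep[last_i] <- FALSE
        } else {
          keep[i] <- FALSE
          next
        }
      }
      last_end <- d$tend[i]; last_i <- i
    }
    d <- d[keep, , drop = FALSE]
    if (nrow(d) < 1) return(tibble::tibble(chrom = character(),
                                           pos = numeric(),
                                           kind = character()))
    # chain adjacent compatible blocks
    chain_id <- integer(nrow(d))
    chain_id[1] <- 1L
    reasons <- character(0)
    for (i in seq_len(nrow(d))[-1]) {
      prev <- i - 1L
      same_q <- d$qname[i] == d$qname[prev]
      same_s <- d$strand[i] == d$strand[prev]
      collinear <- if (!same_q || !same_s) FALSE else if (d$strand[i] == "+") {
        d$qstart[i] >= d$qend[prev] - 1e-9 ||
          d$qstart[i] >= d$qstart[prev]
      } else {
        d$qend[i] <= d$qstart[prev] + 1e-9 || d$qend[i] <= d$qend[prev]
      }
      ref_gap <- d$tstart[i] - d$tend[prev]
      q_gap <- if (!same_q) Inf else if (d$strand[i] == "+") {
        d$qstart[i] - d$qend[prev]
      } else {
        d$qstart[prev] - d$qend[i]
      }
      joins <- same_q && same_s && collinear &&
        ref_gap <= max_join_gap_bp && abs(q_gap) <= max_join_gap_bp
      chain_id[i] <- if (joins) chain_id[prev] else chain_id[prev] + 1L
    }
    chains <- tibble::tibble(
      id = chain_id,
      tstart = d$tstart, tend = d$tend,
      qname = d$qname, strand = d$strand,
      qstart = d$qstart, qend = d$qend
    ) |>
      dplyr::group_by(.data$id) |>
      dplyr::summarise(tstart = min(.data$tstart), tend = max(.data$tend),
                       qname = dplyr::first(.data$qname),
                       strand = dplyr::first(.data$strand),
                       qstart = min(.data$qstart), qend = max(.data$qend),
                       .groups = "drop") |>
      dplyr::filter(.data$tend - .data$tstart >= min_block_bp) |>
      dplyr::arrange(.data$tstart)
    if (nrow(chains) < 2) {
      return(tibble::tibble(chrom = character(), pos = numeric(),
                            kind = character()))
    }
    brk <- purrr::map_dfr(seq_len(nrow(chains) - 1), function(i) {
      a <- chains[i, ]; b <- chains[i + 1, ]
      kind <- if (a$qname != b$qname) {
        "chrom"
      } else if (a$strand != b$strand) {
        "strand"
      } else {
        ok <- if (a$strand == "+") b$qstart >= a$qstart else b$qend <= a$qend
        if (!ok) "order" else NA_character_
      }
      if (is.na(kind)) {
        return(tibble::tibble(chrom = character(), pos = numeric(),
                              kind = character()))
      }
      tibble::tibble(chrom = d$tname[1], pos = (a$tend + b$tstart) / 2,
                     kind = kind)
    })
    brk
  })
}

#' Synteny-break enrichment along scaled domain bodies
#'
#' Each break is mapped to the relative position of its enclosing domain
#' (breaks outside every domain snap to the nearest domain edge), the
#' relative positions are histogrammed into `n_rel_bins` cells, and each
#' cell is divided by the mean alignable fraction of the genomic bins that
#' map to it. The observed statistic is the normalized count in the two
#' terminal (boundary-proximal) cells; the null re-places the same number of
#' breaks on genomic bins with probability proportional to alignable
#' fraction, `n_perm` times.
#'
#' @param breaks Tibble (`chrom`, `pos`) of break positions.
#' @param domains Domain tibble (`chrom`, `start`, `end`).
#' @param alignable_track Per-bin tibble (`chrom`, `start`, `end`, `value` =
#'   alignable fraction in (0, 1]).
#' @param layout A `genome_layout`.
#' @param n_rel_bins Number of relative-position cells (default 10).
#' @param n_perm Number of null replicates (default 100).
#' @param seed Seed for the null.
#' @return A list of class `break_enrichment`: `profile` (tibble:
#'   `rel_cell`, `count`, `alignable`, `normalized`, `fold`) and `result`
#'   (an `enrichment_result` for the terminal cells).
#' @export
break_boundary_enrichment <- function(breaks, domains, alignable_track,
                                      layout, n_rel_bins = 10, n_perm = 100,
                                      seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  bins <- layout_bins(layout)
  align <- alignable_track$value[match(paste0(bins$chrom, ":", bins$start),
                                       paste0(alignable_track$chrom, ":",
                                              alignable_track$start))]
  align[is.na(align)] <- 0
  # relative-position cell of a (chrom, pos) vector
  cell_of <- function(chrom, pos) {
    rel <- numeric(length(pos))
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      dd <- domains[domains$chrom == ch, , drop = FALSE]
      if (!nrow(dd)) { rel[sel] <- NA_real_; next }
      dd <- dd[order(dd$start), , drop = FALSE]
      p <- pos[sel]
      idx <- findInterval(p, dd$start)
      idx[idx < 1] <- 1
      inside <- p >= dd$start[idx] & p < dd$end[idx]
      # snap strays to the nearest domain edge
      r <- (p - dd$start[idx]) / (dd$end[idx] - dd$start[idx])
      r[!inside & p < dd$start[idx]] <- 0
      r[!inside & p >= dd$end[idx]] <- 1
      rel[sel] <- pmin(pmax(r, 0), 1)
    }
    cl <- pmin(floor(rel * n_rel_bins) + 1L, n_rel_bins)
    cl
  }
  bin_mid <- (bins$start + bins$end) / 2
  bin_cell <- cell_of(bins$chrom, bin_mid)
  align_by_cell <- vapply(seq_len(n_rel_bins), function(c) {
    sel <- bin_cell == c & !is.na(bin_cell)
    if (!any(sel)) return(NA_real_)
    mean(align[sel])
  }, numeric(1))
  obs_cell <- cell_of(breaks$chrom, breaks$pos)
  counts <- tabulate(obs_cell, nbins = n_rel_bins)
  normalized <- counts / align_by_cell
  terminal <- c(1L, n_rel_bins)
  statistic <- function(cnt) sum(cnt[terminal] / align_by_cell[terminal])
  obs_stat <- statistic(counts)
  n_breaks <- nrow(breaks)
  prob <- align / sum(align)
  set.seed(seed)
  draw <- sample.int(nrow(bins), n_perm * n_breaks, replace = TRUE,
                     prob = prob)
  draw_cells <- matrix(bin_cell[draw], nrow = n_perm)
  null <- vapply(seq_len(n_perm), function(r) {
    statistic(tabulate(draw_cells[r, ], nbins = n_rel_bins))
  }, numeric(1))
  profile <- tibble::tibble(
    rel_cell = seq_len(n_rel_bins),
    count = counts,
    alignable = align_by_cell,
    normalized = normalized,
    fold = normalized / mean(normalized, na.rm = TRUE)
  )
  structure(list(profile = profile,
                 result = enrichment_result(obs_stat, null, n_perm, seed)),
            class = "break_enrichment")
}

#' Per-bin alignable fraction from synteny blocks
#'
#' @param blocks Block tibble with `tname`, `tstart`, `tend`, `alignable_bp`.
#' @param layout A `genome_layout`.
#' @return A per-bin track tibble (`chrom`, `start`, `end`, `value`).
#' @export
alignable_track_from_blocks <- function(blocks, layout) {
  bins <- layout_bins(layout)
  val <- numeric(nrow(bins))
  for (ch in unique(blocks$tname)) {
    sel_b <- bins$chrom == ch
    if (!any(sel_b)) next
    bb <- blocks[blocks$tname == ch, , drop = FALSE]
    rb <- IRanges::IRanges(bins$start[sel_b] + 1, bins$end[sel_b])
    rk <- IRanges::IRanges(bb$tstart + 1, bb$tend)
    ov <- IRanges::findOverlaps(rb, rk)
    if (!length(ov)) next
    w <- IRanges::width(IRanges::pintersect(rb[S4Vectors::queryHits(ov)],
                                            rk[S4Vectors::subjectHits(ov)]))
    frac <- bb$alignable_bp[S4Vectors::subjectHits(ov)] /
      (bb$tend - bb$tstart)[S4Vectors::subjectHits(ov)]
    contrib <- tapply(w * frac, S4Vectors::queryHits(ov), sum)
    idx <- which(sel_b)[as.integer(names(contrib))]
    val[idx] <- val[idx] + as.numeric(contrib)
  }
  out <- bins[, c("chrom", "start", "end")]
  out$value <- val / (bins$end - bins$start)
  out
}
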