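#' A/B compartment assignment from a correlation matrix
#'
#' PC1 of the covariance of the per-chromosome Hi-C correlation matrix,
#' oriented so that bins with positive PC1 have the higher mean of the
#' orientation track (gene density orients the A compartment). Bins with
#' `pc1 > 0` are labeled `A`, the rest `B`; masked bins are unlabeled.
#'
#' @param corr A `corr_matrix` from [pearson_correlation()].
#' @param orientation_track Tibble with per-bin `value` aligned to the
#'   chromosome's bins (column `value`; row order = bin order), or a bare
#'   numeric vector.
#' @return A tibble of class `compartment_assignment`: `bin`, `pc1`,
#'   `label` (`A`/`B`/`NA`).
#' @export
call_ab <- function(corr, orientation_track) {
  track <- track_values(orientation_track, nrow(corr$corr))
  keep <- !corr$masked
  sub <- corr$corr[keep, keep, drop = FALSE]
  pc1 <- pc1_of_corr(sub)
  if (stats::sd(pc1) < 1e-12) stop("degenerate PC1 (zero variance)")
  pc1 <- orient_pc1(pc1, track[keep])
  n <- length(corr$masked)
  full <- rep(NA_real_, n)
  full[keep] <- pc1
  out <- tibble::tibble(
    bin = seq_len(n),
    pc1 = full,
    label = dplyr::case_when(full > 0 ~ "A", full <= 0 ~ "B",
                             TRUE ~ NA_character_)
  )
  class(out) <- c("compartment_assignment", class(out))
  out
}

# PC1 of the covariance matrix of a correlation matrix (rows = observations)
pc1_of_corr <- function(corr_sub) {
  cv <- stats::cov(corr_sub)
  e <- eigen(cv, symmetric = TRUE)
  v <- e$vectors[, 1]
  # score each bin: projection of its (centered) correlation row on PC1
  ctr <- scale(corr_sub, center = TRUE, scale = FALSE)
  as.numeric(ctr %*% v)
}

orient_pc1 <- function(pc1, track) {
  pos <- mean(track[pc1 > 0])
  neg <- mean(track[pc1 <= 0])
  if (is.nan(pos)) pos <- -Inf
  if (is.nan(neg)) neg <- -Inf
  if (pos < neg) -pc1 else pc1
}

track_values <- function(track, n) {
  v <- if (is.numeric(track)) track else track$value
  if (length(v) != n) stop("orientation track length != number of bins")
  v
}

subcomp_labels <- function() {
  c("B2.2", "B2.1", "B1.2", "B1.1", "A2.2", "A2.1", "A1.2", "A1.1")
}

#' Hierarchical subcompartment assignment by recursive PCA bisection
#'
#' A simplified ranked-subcompartment caller: level 1 is the A/B split of
#' [call_ab()]; each part is then re-bisected by PC1 of the covariance of its
#' own correlation submatrix, with every sub-split oriented by the
#' orientation track (the half with the higher mean track value takes the
#' higher ranks). Three levels give the eight ranked labels A1.1 (rank 8)
#' down to B2.2 (rank 1).
#'
#' @inheritParams call_ab
#' @param levels Number of bisection levels (1, 2 or 3).
#' @return A tibble of class `subcompartment_assignment`: `bin`, `rank`
#'   (1..2^levels), `label`, plus attribute `levels`. With `levels = 3`
#'   labels are A1.1..B2.2; with fewer levels the coarser vocabulary (A/B or
#'   A1/A2/B1/B2) is used.
#' @export
call_subcompartments <- function(corr, orientation_track, levels = 3) {
  stopifnot(levels >= 1, levels <= 3)
  n <- length(corr$masked)
  track <- track_values(orientation_track, n)
  keep <- which(!corr$masked)
  if (length(keep) < 2^levels) stop("need >= ", 2^levels, " unmasked bins")
  n_ranks <- 2L^levels
  rank <- rep(NA_integer_, n)
  # recursive bisection over bin-index subsets; rank_range is the inclusive
  # range of final ranks this subset may take
  bisect <- function(idx, depth, rank_lo, rank_hi) {
    if (depth > levels || length(idx) < 2 || rank_lo == rank_hi) {
      # too small to split further: inherit the top rank of the parent range
      rank[idx] <<- rank_hi
      return(invisible())
    }
    sub <- corr$corr[idx, idx, drop = FALSE]
    pc1 <- tryCatch(pc1_of_corr(sub), error = function(e) rep(0, length(idx)))
    if (stats::sd(pc1) < 1e-12) {
      rank[idx] <<- rank_hi
      return(invisible())
    }
    pc1 <- orient_pc1(pc1, track[idx])
    hi <- idx[pc1 > 0]
    lo <- idx[pc1 <= 0]
    if (!length(hi) || !length(lo)) {
      rank[idx] <<- rank_hi
      return(invisible())
    }
    mid <- (rank_lo + rank_hi - 1L) %/% 2L
    if (depth == levels) {
      rank[hi] <<- rank_hi
      rank[lo] <<- rank_lo
    } else {
      bisect(hi, depth + 1L, mid + 1L, rank_hi)
      bisect(lo, depth + 1L, rank_lo, mid)
    }
    invisible()
  }
  bisect(keep, 1L, 1L, n_ranks)
  labels <- switch(as.character(levels),
    "1" = c("B", "A"),
    "2" = c("B2", "B1", "A2", "A1"),
    "3" = subcomp_labels()
  )
  out <- tibble::tibble(
    bin = seq_len(n),
    rank = rank,
    label = labels[rank]
  )
  attr(out, "levels") <- levels
  class(out) <- c("subcompartment_assignment", class(out))
  out
}

#' Per-subcompartment feature enrichment
#'
#' For each label, log2 of the ratio between the median track value in that
#' label's bins and the genome-wide median, with a small pseudocount guarding
#' zero medians.
#'
#' @param assign A `subcompartment_assignment` (or any tibble with `bin` and
#'   `label`).
#' @param track Per-bin values (numeric vector or tibble with `value`).
#' @param eps Pseudocount (default 1e-9).
#' @return A tibble: `label`, `n_bins`, `median`, `log2_enrichment` (`NA` for
#'   empty labels).
#' @export
subcompartment_enrichment <- function(assign, track, eps = 1e-9) {
  v <- track_values(track, nrow(assign))
  ok <- !is.na(assign$label)
  overall <- stats::median(v[ok])
  all_labels <- if (!is.null(attr(assign, "levels"))) {
    switch(as.character(attr(assign, "levels")),
           "1" = c("A", "B"),
           "2" = c("A1", "A2", "B1", "B2"),
           "3" = rev(subcomp_labels()))
  } else {
    sort(unique(assign$label[ok]))
  }
  purrr::map_dfr(all_labels, function(lab) {
    vals <- v[ok & assign$label == lab]
    if (!length(vals)) {
      return(tibble::tibble(label = lab, n_bins = 0L, median = NA_real_,
                            log2_enrichment = NA_real_))
    }
    med <- stats::median(vals)
    tibble::tibble(label = lab, n_bins = length(vals), median = med,
                   log2_enrichment = log2((med + eps) / (overall + eps)))
  })
}

#' Cross-sample subcompartment switching table
#'
#' Tabulates per-bin rank shifts (`rank2 - rank1`) between two assignments of
#' the same layout into categories `<-2, -2, -1, 0, 1, 2, >2`, and reports
#' the level-1 A/B agreement fraction.
#'
#' @param assign1,assign2 `subcompartment_assignment` objects on the same
#'   bins.
#' @return A tibble of class `switching_table`: `category`, `n`,
#'   `proportion`; attributes `ab_agreement` (fraction of bins keeping their
#'   level-1 A/B side) and `n_bins`.
#' @export
switching_table <- function(assign1, assign2) {
  if (nrow(assign1) != nrow(assign2)) stop("assignments differ in length")
  lv1 <- attr(assign1, "levels"); lv2 <- attr(assign2, "levels")
  if (!is.null(lv1) && !is.null(lv2) && lv1 != lv2) {
    stop("assignments differ in levels")
  }
  ok <- !is.na(assign1$rank) & !is.na(assign2$rank)
  shift <- assign2$rank[ok] - assign1$rank[ok]
  cats <- c("<-2", "-2", "-1", "0", "1", "2", ">2")
  cat_of <- dplyr::case_when(
    shift < -2 ~ "<-2", shift == -2 ~ "-2", shift == -1 ~ "-1",
    shift == 0 ~ "0", shift == 1 ~ "1", shift == 2 ~ "2", TRUE ~ ">2"
  )
  counts <- table(factor(cat_of, levels = cats))
  out <- tibble::tibble(
    category = cats,
    n = as.integer(counts),
    proportion = as.numeric(counts) / sum(counts)
  )
  n_ranks <- max(c(assign1$rank, assign2$rank), na.rm = TRUE)
  half <- 2^ceiling(log2(n_ranks)) / 2
  a1 <- assign1$rank[ok] > half
  a2 <- assign2$rank[ok] > half
  attr(out, "ab_agreement") <- mean(a1 == a2)
  attr(out, "n_bins") <- sum(ok)
  class(out) <- c("switching_table", class(out))
  out
}
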