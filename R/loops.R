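#' Construct / validate a loop set
#'
#' A loop set is a tibble of intra-chromosomal anchor pairs: `chrom`,
#' `start1`, `end1`, `start2`, `end2` (bp, 0-based half-open, anchor 1 left
#' of anchor 2), plus optional `resolution` (bp) and `sample` columns.
#'
#' @param df A data frame with the columns above.
#' @return A validated tibble of class `loop_set`.
#' @export
loop_set <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("chrom", "start1", "end1", "start2", "end2")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  if (any(df$end1 <= df$start1) || any(df$end2 <= df$start2)) {
    stop("degenerate anchors (end <= start)")
  }
  if (any(df$start2 < df$start1)) stop("anchor 2 must not lie left of anchor 1")
  if (!"resolution" %in% names(df)) df$resolution <- df$end1 - df$start1
  if (!"sample" %in% names(df)) df$sample <- NA_character_
  class(df) <- c("loop_set", class(df))
  df
}

anchor_mids <- function(loops) {
  list(m1 = (loops$start1 + loops$end1) / 2,
       m2 = (loops$start2 + loops$end2) / 2)
}

#' Merge loops across resolutions
#'
#' Loops whose two anchors are pairwise within `merge_dist` (anchor-midpoint
#' distance, single-linkage/transitive grouping) collapse to one
#' representative whose anchor midpoints are the group medians, snapped to
#' the grid of the finest contributing resolution. Idempotent.
#'
#' @param sets A `loop_set` or list of loop sets.
#' @param merge_dist Midpoint distance threshold in bp (default 25,000;
#'   inclusive).
#' @return A merged `loop_set` with a `n_merged` column.
#' @export
merge_loops <- function(sets, merge_dist = 25000) {
  if (is.data.frame(sets)) sets <- list(sets)
  all <- dplyr::bind_rows(purrr::map(sets, loop_set))
  if (!nrow(all)) return(loop_set(all))
  out <- purrr::map_dfr(split(all, all$chrom), function(d) {
    mids <- anchor_mids(d)
    n <- nrow(d)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (abs(mids$m1[i] - mids$m1[j]) <= merge_dist &&
            abs(mids$m2[i] - mids$m2[j]) <= merge_dist) {
          parent[find(j)] <- find(i)
        }
      }
    }
    grp <- vapply(seq_len(n), find, integer(1))
    d$grp <- grp
    d |>
      dplyr::group_by(.data$grp) |>
      dplyr::group_map(function(g, key) {
        res <- min(g$resolution)
        m1 <- snap(stats::median((g$start1 + g$end1) / 2), res)
        m2 <- snap(stats::median((g$start2 + g$end2) / 2), res)
        tibble::tibble(
          chrom = g$chrom[1],
          start1 = m1 - res / 2, end1 = m1 + res / 2,
          start2 = m2 - res / 2, end2 = m2 + res / 2,
          resolution = res,
          sample = g$sample[1],
          n_merged = nrow(g)
        )
      }) |>
      dplyr::bind_rows()
  })
  out <- dplyr::arrange(out, .data$chrom, .data$start1, .data$start2)
  loop_set(out)
}

# snap a midpoint to the half-grid of a resolution so the anchor interval
# [mid - res/2, mid + res/2) lies on the res grid
snap <- function(mid, res) (round(mid / res - 0.5) + 0.5) * res

#' Partition loops into tissue-shared and tissue-specific
#'
#' A loop is shared when some loop from a different tissue has both anchor
#' midpoints within `d` of its own.
#'
#' @param per_tissue Named list (tissue -> `loop_set`).
#' @param d Anchor distance threshold in bp (default 25,000; inclusive).
#' @return A tibble of all loops with `tissue` and logical `shared`, of class
#'   `loop_sharing`; attribute `summary` tabulates shared/specific counts and
#'   `union` holds the non-redundant merged union.
#' @export
shared_loops <- function(per_tissue, d = 25000) {
  stopifnot(length(per_tissue) >= 2)
  tissues <- names(per_tissue)
  all <- dplyr::bind_rows(
    purrr::imap(per_tissue, function(x, nm) dplyr::mutate(loop_set(x),
                                                          tissue = nm))
  )
  mids <- anchor_mids(all)
  shared <- logical(nrow(all))
  for (ch in unique(all$chrom)) {
    idx <- which(all$chrom == ch)
    m1 <- mids$m1[idx]; m2 <- mids$m2[idx]; ts <- all$tissue[idx]
    for (a in seq_along(idx)) {
      if (shared[idx[a]]) next
      hit <- abs(m1 - m1[a]) <= d & abs(m2 - m2[a]) <= d & ts != ts[a]
      if (any(hit)) {
        shared[idx[a]] <- TRUE
        shared[idx[which(hit)]] <- TRUE
      }
    }
  }
  all$shared <- shared
  summary <- all |>
    dplyr::count(.data$tissue, .data$shared) |>
    tidyr::pivot_wider(names_from = "shared", values_from = "n",
                       values_fill = 0L,
                       names_prefix = "shared_")
  attr(all, "summary") <- summary
  attr(all, "union") <- merge_loops(all, merge_dist = d)
  class(all) <- c("loop_sharing", class(all))
  all
}

#' Association between loop anchors and domain boundaries
#'
#' Reports (i) the fraction of loop anchors whose bin overlaps a boundary
#' bin, (ii) the expected fraction under chance (share of genome bins that
#' are boundary bins), (iii) a two-sided Fisher's exact test on the 2x2
#' table of anchor / non-anchor bins vs boundary / non-boundary bins, and
#' (iv) when `domains` is supplied, the fraction of domains with at least
#' one anchored boundary against a seeded permutation null that drops the
#' same number of anchors uniformly on bins.
#'
#' @param loops A `loop_set`.
#' @param boundaries Boundary tibble (`chrom`, `start`, `end`).
#' @param layout A `genome_layout`.
#' @param domains Optional domain tibble for the reciprocal statistic.
#' @param n_perm Permutation replicates for the reciprocal null (default
#'   1000).
#' @param seed Seed for the permutation null.
#' @return A list of class `loop_boundary_association`: `anchor_fraction`,
#'   `expected_fraction`, `fisher_p`, `odds_ratio`, `table`, and (with
#'   domains) `domain_fraction`, `domain_null` (an `enrichment_result`).
#' @export
loop_boundary_association <- function(loops, boundaries, layout,
                                      domains = NULL, n_perm = 1000,
                                      seed = 1L) {
  if (!nrow(loops) || !nrow(boundaries)) {
    warning("empty loops or boundaries: fractions undefined")
    return(structure(list(anchor_fraction = NA_real_,
                          expected_fraction = NA_real_,
                          fisher_p = NA_real_, odds_ratio = NA_real_,
                          table = NULL),
                     class = "loop_boundary_association"))
  }
  bins <- layout_bins(layout)
  bs <- bin_size(layout)
  key <- function(chrom, pos) paste0(chrom, ":", floor(pos / bs))
  boundary_keys <- unique(key(boundaries$chrom, boundaries$start))
  mids <- anchor_mids(loops)
  anchor_keys <- unique(c(key(loops$chrom, mids$m1),
                          key(loops$chrom, mids$m2)))
  all_keys <- key(bins$chrom, bins$start)
  is_boundary <- all_keys %in% boundary_keys
  is_anchor <- all_keys %in% anchor_keys
  anchor_on <- c(key(loops$chrom, mids$m1), key(loops$chrom, mids$m2)) %in%
    boundary_keys
  anchor_fraction <- mean(anchor_on)
  expected_fraction <- mean(is_boundary)
  tab <- matrix(c(sum(is_anchor & is_boundary), sum(is_anchor & !is_boundary),
                  sum(!is_anchor & is_boundary),
                  sum(!is_anchor & !is_boundary)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("anchor", "non_anchor"),
                                c("boundary", "non_boundary")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  out <- list(anchor_fraction = anchor_fraction,
              expected_fraction = expected_fraction,
              fisher_p = ft$p.value, odds_ratio = unname(ft$estimate),
              table = tab)
  if (!is.null(domains) && nrow(domains)) {
    dom_b <- domain_boundaries(domains, bs)
    dom_keys <- key(dom_b$chrom, dom_b$start)
    # fraction of domains with >= 1 anchored boundary
    first_k <- key(domains$chrom, domains$start)
    last_k <- key(domains$chrom, domains$end - 1)
    dom_hit <- first_k %in% anchor_keys | last_k %in% anchor_keys
    obs <- mean(dom_hit)
    n_anchor_bins <- length(anchor_keys)
    set.seed(seed)
    null <- vapply(seq_len(n_perm), function(r) {
      rb <- sample(all_keys, n_anchor_bins)
      mean(first_k %in% rb | last_k %in% rb)
    }, numeric(1))
    out$domain_fraction <- obs
    out$domain_null <- enrichment_result(obs, null, n_perm, seed)
  }
  structure(out, class = "loop_boundary_association")
}
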