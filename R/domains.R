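#' Call TAD-like domains from a contact matrix
#'
#' Insulation-style caller: the per-bin signal is the mean contact over the
#' `window_bins x window_bins` submatrix that straddles the diagonal at each
#' bin (upstream rows vs downstream columns). Boundaries are local minima of
#' this signal whose drop below the lower of the two flanking local maxima
#' exceeds `min_drop` of that maximum; consecutive boundaries delimit
#' domains. Runs of `>= window_bins` masked (zero-marginal) bins split
#' domains as gaps.
#'
#' @param x A `contact_matrix` (balanced recommended).
#' @param window_bins Insulation window in bins (default 5).
#' @param min_drop Minimum relative drop at a boundary (default 0.1).
#' @return A list of class `domain_call` with `domains` (tibble: `chrom`,
#'   `start`, `end` in bp) and `boundaries` (tibble: `chrom`, `start`, `end`
#'   — one bin each — and `bin`), plus `signal` (per-bin insulation signal).
#' @export
call_domains <- function(x, window_bins = 5, min_drop = 0.1) {
  stopifnot(window_bins >= 2)
  m <- x$counts
  n <- nrow(m)
  bs <- x$bin_size
  masked <- if (any(x$masked)) x$masked else rowSums(m, na.rm = TRUE) == 0
  if (all(masked)) {
    warning("all bins masked on ", x$chrom)
    return(empty_domain_call(x$chrom, bs))
  }
  w <- window_bins
  signal <- rep(NA_real_, n)
  for (b in seq_len(n - 1)) {
    rows <- max(1, b - w + 1):b
    cols <- (b + 1):min(n, b + w)
    rows <- rows[!masked[rows]]
    cols <- cols[!masked[cols]]
    if (length(rows) && length(cols)) {
      signal[b] <- mean(m[rows, cols, drop = FALSE], na.rm = TRUE)
    }
  }
  bounds <- insulation_minima(signal, min_drop)
  # gaps: runs of masked bins at least window_bins long
  gap <- masked_runs(masked, w)
  domains <- segment_domains(n, bounds, gap, bs, x$chrom)
  boundaries <- tibble::tibble(
    chrom = x$chrom,
    start = (bounds - 1) * bs,
    end = bounds * bs,
    bin = bounds
  )
  structure(list(domains = domains, boundaries = boundaries,
                 signal = tibble::tibble(chrom = x$chrom, bin = seq_len(n),
                                         insulation = signal)),
            class = "domain_call")
}

empty_domain_call <- function(chrom, bs) {
  structure(list(
    domains = tibble::tibble(chrom = character(), start = numeric(),
                             end = numeric()),
    boundaries = tibble::tibble(chrom = character(), start = numeric(),
                                end = numeric(), bin = integer()),
    signal = tibble::tibble(chrom = character(), bin = integer(),
                            insulation = numeric())
  ), class = "domain_call")
}

# local minima of the insulation signal passing the relative-drop rule
insulation_minima <- function(signal, min_drop) {
  n <- length(signal)
  s <- signal
  ok <- which(!is.na(s))
  if (length(ok) < 3) return(integer())
  mins <- integer()
  for (b in ok) {
    left <- s[ok[ok < b]]
    right <- s[ok[ok > b]]
    if (!length(left) || !length(right)) next
    # local minimum among defined neighbours
    ln <- utils::tail(left, 1); rn <- right[1]
    if (!(s[b] <= ln && s[b] <= rn)) next
    # nearest flanking local maxima (climb until the signal turns down)
    lmax <- nearest_peak(s, ok, b, -1L)
    rmax <- nearest_peak(s, ok, b, +1L)
    if (is.na(lmax) || is.na(rmax)) next
    lower_flank <- min(lmax, rmax)
    if (lower_flank > 0 && (lower_flank - s[b]) > min_drop * lower_flank) {
      mins <- c(mins, b)
    }
  }
  # collapse plateaus: keep the first bin of any run of equal adjacent minima
  if (length(mins) > 1) {
    keep <- c(TRUE, diff(mins) > 1 | s[mins[-1]] != s[mins[-length(mins)]])
    mins <- mins[keep]
  }
  mins
}

# climb from bin b in direction dir until the signal stops rising; return the
# peak value reached
nearest_peak <- function(s, ok, b, dir) {
  idx <- if (dir < 0) rev(ok[ok < b]) else ok[ok > b]
  if (!length(idx)) return(NA_real_)
  peak <- s[idx[1]]
  for (i in idx[-1]) {
    if (s[i] >= peak) peak <- s[i] else break
  }
  peak
}

masked_runs <- function(masked, min_len) {
  r <- rle(masked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_len
  tibble::tibble(start_bin = starts[keep], end_bin = ends[keep])
}

segment_domains <- function(n, bounds, gaps, bs, chrom) {
  # breakpoints after these bins (domain ends at the boundary bin, inclusive)
  cut_after <- sort(unique(bounds))
  gap_bins <- integer()
  if (nrow(gaps)) {
    gap_bins <- unlist(purrr::map2(gaps$start_bin, gaps$end_bin, seq))
  }
  in_gap <- rep(FALSE, n)
  in_gap[gap_bins] <- TRUE
  # build domain segments between cuts, dropping gap runs
  seg_id <- cumsum(c(1L, as.integer(seq_len(n)[-1] %in% (cut_after + 1L))))
  df <- tibble::tibble(bin = seq_len(n), seg = seg_id, gap = in_gap)
  df <- df[!df$gap, , drop = FALSE]
  if (!nrow(df)) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric()))
  }
  # split segments further at gap interruptions
  df$sub <- cumsum(c(1L, as.integer(diff(df$bin) > 1 | diff(df$seg) != 0)))
  out <- df |>
    dplyr::group_by(.data$sub) |>
    dplyr::summarise(start = (min(.data$bin) - 1) * bs,
                     end = max(.data$bin) * bs, .groups = "drop") |>
    dplyr::transmute(chrom = chrom, start = .data$start, end = .data$end)
  dplyr::arrange(out, .data$start)
}

#' Boundary bins of a domain set
#'
#' The single bin at each domain edge (first and last bin of every domain),
#' deduplicated.
#'
#' @param domains Tibble with `chrom`, `start`, `end` (bp).
#' @param bin_size Bin size in bp.
#' @return A tibble: `chrom`, `start`, `end` (one bin), `bin`.
#' @export
domain_boundaries <- function(domains, bin_size) {
  if (!nrow(domains)) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), bin = integer()))
  }
  first_bin <- floor(domains$start / bin_size)
  last_bin <- ceiling(domains$end / bin_size) - 1
  out <- tibble::tibble(
    chrom = rep(domains$chrom, 2),
    bin = c(first_bin, last_bin) + 1L
  ) |>
    dplyr::distinct() |>
    dplyr::mutate(start = (.data$bin - 1) * bin_size,
                  end = .data$bin * bin_size) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::select("chrom", "start", "end", "bin")
  out
}

#' Conserved domains by reciprocal overlap
#'
#' A pair is conserved when the overlap exceeds `reciprocal` of BOTH domain
#' lengths; each domain is matched at most once (greedy by overlap length,
#' ties to the leftmost pair).
#'
#' @param a,b Domain tibbles (`chrom`, `start`, `end`).
#' @param reciprocal Reciprocal overlap threshold (default 0.8; strict `>`).
#' @return A list: `pairs` (tibble of matched index pairs with overlap bp),
#'   `shared_frac_a`, `shared_frac_b`.
#' @export
conserved_domains <- function(a, b, reciprocal = 0.8) {
  pairs <- overlap_pairs(a, b)
  if (nrow(pairs)) {
    len_a <- (a$end - a$start)[pairs$i]
    len_b <- (b$end - b$start)[pairs$j]
    pairs <- pairs[pairs$overlap > reciprocal * len_a &
                   pairs$overlap > reciprocal * len_b, , drop = FALSE]
  }
  pairs <- greedy_match(pairs)
  list(
    pairs = pairs,
    shared_frac_a = if (nrow(a)) nrow(pairs) / nrow(a) else NA_real_,
    shared_frac_b = if (nrow(b)) nrow(pairs) / nrow(b) else NA_real_
  )
}

overlap_pairs <- function(a, b) {
  if (!nrow(a) || !nrow(b)) {
    return(tibble::tibble(i = integer(), j = integer(), overlap = numeric()))
  }
  purrr::map_dfr(unique(a$chrom), function(ch) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    if (!length(ia) || !length(ib)) {
      return(tibble::tibble(i = integer(), j = integer(), overlap = numeric()))
    }
    ra <- IRanges::IRanges(a$start[ia] + 1, a$end[ia])
    rb <- IRanges::IRanges(b$start[ib] + 1, b$end[ib])
    ov <- IRanges::findOverlaps(ra, rb)
    if (!length(ov)) {
      return(tibble::tibble(i = integer(), j = integer(), overlap = numeric()))
    }
    w <- IRanges::width(IRanges::pintersect(ra[S4Vectors::queryHits(ov)],
                                            rb[S4Vectors::subjectHits(ov)]))
    tibble::tibble(i = ia[S4Vectors::queryHits(ov)],
                   j = ib[S4Vectors::subjectHits(ov)],
                   overlap = as.numeric(w))
  })
}

greedy_match <- function(pairs) {
  if (!nrow(pairs)) return(pairs)
  pairs <- pairs[order(-pairs$overlap, pairs$i, pairs$j), , drop = FALSE]
  keep <- logical(nrow(pairs))
  ui <- uj <- integer()
  for (k in seq_len(nrow(pairs))) {
    if (!(pairs$i[k] %in% ui) && !(pairs$j[k] %in% uj)) {
      keep[k] <- TRUE
      ui <- c(ui, pairs$i[k])
      uj <- c(uj, pairs$j[k])
    }
  }
  out <- pairs[keep, , drop = FALSE]
  out[order(out$i), , drop = FALSE]
}

#' Shared boundaries between two boundary sets
#'
#' Two single-bin boundaries are shared when their intervals overlap or are
#' apart (edge-to-edge gap) by strictly less than `tol_bins` bin sizes.
#' Matching is one-to-one, nearest pairs first.
#'
#' @param a,b Boundary tibbles (`chrom`, `start`, `end`), both on the same
#'   bin size.
#' @param bin_size Bin size in bp.
#' @param tol_bins Gap tolerance in bins (default 1).
#' @return A list: `pairs` (matched index pairs with midpoint distance),
#'   `shared_frac_a`, `shared_frac_b`.
#' @export
shared_boundaries <- function(a, b, bin_size, tol_bins = 1) {
  wa <- unique(a$end - a$start); wb <- unique(b$end - b$start)
  if (length(wa) && length(wb) && !isTRUE(all.equal(wa, wb))) {
    stop("boundary sets have differing bin sizes")
  }
  if (!nrow(a) || !nrow(b)) {
    return(list(pairs = tibble::tibble(i = integer(), j = integer(),
                                       dist = numeric()),
                shared_frac_a = if (nrow(a)) 0 else NA_real_,
                shared_frac_b = if (nrow(b)) 0 else NA_real_))
  }
  cand <- purrr::map_dfr(unique(a$chrom), function(ch) {
    ia <- which(a$chrom == ch); ib <- which(b$chrom == ch)
    if (!length(ia) || !length(ib)) {
      return(tibble::tibble(i = integer(), j = integer(), dist = numeric()))
    }
    g <- expand.grid(i = ia, j = ib)
    gap <- pmax(a$start[g$i], b$start[g$j]) - pmin(a$end[g$i], b$end[g$j])
    keep <- gap < tol_bins * bin_size  # overlap gives negative gap
    mid <- abs((a$start[g$i] + a$end[g$i]) - (b$start[g$j] + b$end[g$j])) / 2
    tibble::tibble(i = g$i[keep], j = g$j[keep], dist = mid[keep])
  })
  # nearest-first one-to-one matching
  cand <- cand[order(cand$dist, cand$i, cand$j), , drop = FALSE]
  ui <- uj <- integer(); keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!(cand$i[k] %in% ui) && !(cand$j[k] %in% uj)) {
      keep[k] <- TRUE; ui <- c(ui, cand$i[k]); uj <- c(uj, cand$j[k])
    }
  }
  pairs <- cand[keep, , drop = FALSE]
  list(pairs = pairs,
       shared_frac_a = nrow(pairs) / nrow(a),
       shared_frac_b = nrow(pairs) / nrow(b))
}

#' Jaccard similarity of base-pair coverage between two domain sets
#'
#' @param a,b Domain tibbles (`chrom`, `start`, `end`).
#' @return A list: `intersection_bp`, `union_bp`, `similarity`
#'   (|A∩B| / |A∪B|), `distance` (1 - similarity). Both sets empty gives
#'   `NA` similarity.
#' @export
coverage_jaccard <- function(a, b) {
  chroms <- union(a$chrom, b$chrom)
  inter <- 0; uni <- 0
  for (ch in chroms) {
    ra <- IRanges::reduce(IRanges::IRanges(a$start[a$chrom == ch] + 1,
                                           a$end[a$chrom == ch]))
    rb <- IRanges::reduce(IRanges::IRanges(b$start[b$chrom == ch] + 1,
                                           b$end[b$chrom == ch]))
    inter <- inter + sum(IRanges::width(IRanges::intersect(ra, rb)))
    uni <- uni + sum(IRanges::width(IRanges::union(ra, rb)))
  }
  sim <- if (uni > 0) inter / uni else NA_real_
  list(intersection_bp = inter, union_bp = uni,
       similarity = sim, distance = 1 - sim)
}

#' Classify domains into active / inactive / HDF groups
#'
#' Per-domain mean feature values (over covered bins) are z-standardized per
#' feature, domains are clustered by complete-linkage agglomeration on
#' Euclidean distance, and the tree is cut at `k` groups. Groups are
#' auto-labeled: highest mean z of the `active_features` becomes `active`,
#' then highest mean z of the `hdf_features` becomes `HDF`, remainder
#' `inactive`.
#'
#' @param domains Domain tibble (`chrom`, `start`, `end`).
#' @param tracks Named list of per-bin track tibbles (`chrom`, `start`,
#'   `end`, `value`) or a single long tibble with a `feature` column.
#' @param k Number of groups (default 3).
#' @param active_features,hdf_features Feature names used to label groups.
#' @return A list of class `domain_classification`: `domains` (input plus
#'   `class`), `features` (per-domain standardized feature matrix as tibble),
#'   `group_means` (diagnostic per-group feature z-means), `tree` (hclust).
#' @export
classify_domains <- function(domains, tracks, k = 3,
                             active_features = c("gene_density", "H3K4me3"),
                             hdf_features = c("ltr_density", "H3K9me2")) {
  if (k > nrow(domains)) stop("k exceeds the number of domains")
  feat <- domain_feature_matrix(domains, tracks)
  z <- scale(as.matrix(feat))
  z[is.nan(z)] <- 0
  tree <- stats::hclust(stats::dist(z, method = "euclidean"),
                        method = "complete")
  grp <- stats::cutree(tree, k = k)
  gm <- stats::aggregate(z, list(group = grp), mean)
  labels <- label_domain_groups(gm, colnames(z), active_features, hdf_features)
  out_domains <- dplyr::mutate(domains, class = labels[as.character(grp)])
  group_means <- tibble::as_tibble(gm) |>
    dplyr::mutate(class = labels[as.character(.data$group)], .after = "group")
  structure(list(domains = out_domains,
                 features = tibble::as_tibble(as.data.frame(z)),
                 group_means = group_means, tree = tree),
            class = "domain_classification")
}

domain_feature_matrix <- function(domains, tracks) {
  if (is.data.frame(tracks)) {
    tracks <- split(tracks[setdiff(names(tracks), "feature")], tracks$feature)
  }
  feats <- purrr::map(tracks, function(tr) {
    vapply(seq_len(nrow(domains)), function(i) {
      sel <- tr$chrom == domains$chrom[i] & tr$start < domains$end[i] &
        tr$end > domains$start[i]
      if (!any(sel)) stop("a domain overlaps no bin of a feature track")
      mean(tr$value[sel], na.rm = TRUE)
    }, numeric(1))
  })
  tibble::as_tibble(feats)
}

label_domain_groups <- function(gm, features, active_features, hdf_features) {
  grp_ids <- as.character(gm$group)
  score <- function(cols) {
    cols <- intersect(cols, features)
    if (!length(cols)) return(rep(-Inf, nrow(gm)))
    rowMeans(gm[, cols, drop = FALSE])
  }
  labels <- rep("inactive", nrow(gm))
  act <- which.max(score(active_features))
  labels[act] <- "active"
  hdf_score <- score(hdf_features)
  hdf_score[act] <- -Inf
  labels[which.max(hdf_score)] <- "HDF"
  stats::setNames(labels, grp_ids)
}

#' Feature profile centered at domain boundaries
#'
#' For each offset in `[-flank_bp, +flank_bp]` (in bins), the mean and
#' standard error of a per-bin track over all boundaries, where boundaries
#' near chromosome ends contribute only their in-genome offsets.
#'
#' @param boundaries Boundary tibble (`chrom`, `start`, `end`).
#' @param track Per-bin track tibble (`chrom`, `start`, `end`, `value`).
#' @param layout A `genome_layout`.
#' @param flank_bp Flank width in bp (default 500 kb).
#' @return A tibble of class `boundary_profile`: `offset_bp`, `mean`, `se`,
#'   `n`.
#' @export
boundary_profile <- function(boundaries, track, layout, flank_bp = 5e5) {
  bs <- bin_size(layout)
  fl <- as.integer(round(flank_bp / bs))
  offsets <- -fl:fl
  # per-chromosome value vectors indexed by bin
  chrom_vals <- split(track, track$chrom) |>
    purrr::map(function(d) d$value[order(d$start)])
  acc_n <- acc_s <- acc_ss <- stats::setNames(
    rep(0, length(offsets)), offsets)
  for (r in seq_len(nrow(boundaries))) {
    ch <- boundaries$chrom[r]
    vals <- chrom_vals[[ch]]
    if (is.null(vals)) next
    b <- floor(boundaries$start[r] / bs) + 1L
    idx <- b + offsets
    ok <- idx >= 1 & idx <= length(vals)
    v <- vals[idx[ok]]
    fin <- !is.na(v)
    sel <- which(ok)[fin]
    acc_n[sel] <- acc_n[sel] + 1
    acc_s[sel] <- acc_s[sel] + v[fin]
    acc_ss[sel] <- acc_ss[sel] + v[fin]^2
  }
  mean_v <- ifelse(acc_n > 0, acc_s / acc_n, NA_real_)
  var_v <- ifelse(acc_n > 1,
                  pmax(0, (acc_ss - acc_n * mean_v^2) / (acc_n - 1)), NA_real_)
  out <- tibble::tibble(
    offset_bp = offsets * bs,
    mean = unname(mean_v),
    se = unname(sqrt(var_v / acc_n)),
    n = as.integer(unname(acc_n))
  )
  class(out) <- c("boundary_profile", class(out))
  out
}
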