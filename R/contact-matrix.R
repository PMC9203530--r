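#' Construct a per-chromosome contact matrix
#'
#' Wraps a symmetric, non-negative matrix of binned contact counts for one
#' chromosome together with the layout information downstream steps need
#' (bin size, masked bins, balancing weights).
#'
#' @param counts Square numeric matrix of binned contact counts.
#' @param chrom Chromosome identifier.
#' @param bin_size Bin size in bp.
#' @param weights Optional per-bin balancing weights (positive reals, NA for
#'   masked bins).
#' @param masked Optional logical vector of masked bins.
#' @param balanced Logical; whether `counts` is already balanced.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(counts, chrom, bin_size, weights = NULL,
                           masked = NULL, balanced = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (max(abs(counts - t(counts)), na.rm = TRUE) > 1e-8 * (1 + max(abs(counts), na.rm = TRUE))) {
    stop("counts must be symmetric")
  }
  n <- nrow(counts)
  if (is.null(masked)) masked <- rep(FALSE, n)
  structure(
    list(counts = counts, chrom = as.character(chrom),
         bin_size = as.numeric(bin_size), weights = weights,
         masked = masked, balanced = balanced),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "<contact_matrix> %s: %d bins x %s bp, %d masked, %sbalanced\n",
    x$chrom, nrow(x$counts), format(x$bin_size, big.mark = ","),
    sum(x$masked), if (isTRUE(x$balanced)) "" else "not "
  ))
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$counts)

#' Tidy a contact matrix into a triplet tibble
#'
#' @param x A `contact_matrix`.
#' @param ... Unused.
#' @return A tibble with the non-zero upper-triangle entries: `chrom`,
#'   `start1`, `start2` (0-based bin starts) and `count`.
#' @export
tidy.contact_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$counts, diag = TRUE) & x$counts != 0,
               arr.ind = TRUE)
  out <- tibble::tibble(
    chrom = x$chrom,
    start1 = (idx[, 1] - 1) * x$bin_size,
    start2 = (idx[, 2] - 1) * x$bin_size,
    count = x$counts[idx]
  )
  dplyr::arrange(out, .data$start1, .data$start2)
}

#' @export
glance.contact_matrix <- function(x, ...) {
  tibble::tibble(
    chrom = x$chrom, n_bins = nrow(x$counts), bin_size = x$bin_size,
    total_count = sum(x$counts), n_masked = sum(x$masked),
    balanced = isTRUE(x$balanced)
  )
}

#' Read a contact matrix from triplet TSV
#'
#' The triplet format has columns `chrom`, `start1`, `start2`, `count` where
#' starts are 0-based bin starts. Upper- or lower-triangle (or mixed) storage
#' is accepted; entries are canonicalized to a symmetric matrix. Duplicate
#' (i, j) records are summed.
#'
#' @param path Path to a TSV file.
#' @param layout A `genome_layout`.
#' @param chrom Chromosome to read (default: the single chromosome present).
#' @return A `contact_matrix`.
#' @export
read_contacts <- function(path, layout, chrom = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), start1 = readr::col_double(),
    start2 = readr::col_double(), count = readr::col_double()
  ), progress = FALSE)
  if (is.null(chrom)) {
    chroms <- unique(df$chrom)
    if (length(chroms) != 1) {
      stop("file holds ", length(chroms), " chromosomes; pass `chrom`")
    }
    chrom <- chroms
  } else {
    df <- df[df$chrom == chrom, , drop = FALSE]
  }
  contacts_from_triplets(df, layout, chrom, src = path)
}

contacts_from_triplets <- function(df, layout, chrom, src = "input") {
  bs <- bin_size(layout)
  row <- layout_chrom(layout, chrom)
  n <- row$n_bins
  bad_chrom <- which(!df$chrom %in% layout$chrom)
  if (length(bad_chrom)) {
    stop(sprintf("%s line %d: unknown chromosome '%s'",
                 src, bad_chrom[1] + 1L, df$chrom[bad_chrom[1]]))
  }
  neg <- which(df$count < 0)
  if (length(neg)) {
    stop(sprintf("%s line %d: negative count %s", src, neg[1] + 1L,
                 format(df$count[neg[1]])))
  }
  i <- df$start1 / bs + 1
  j <- df$start2 / bs + 1
  off_grid <- which(i != round(i) | j != round(j))
  if (length(off_grid)) {
    stop(sprintf("%s line %d: start not a multiple of bin size %s",
                 src, off_grid[1] + 1L, format(bs)))
  }
  oob <- which(i < 1 | i > n | j < 1 | j > n)
  if (length(oob)) {
    stop(sprintf("%s line %d: bin out of range for %s (n = %d)",
                 src, oob[1] + 1L, chrom, n))
  }
  m <- matrix(0, n, n)
  # canonicalize to upper triangle, then mirror
  lo <- pmin(i, j); hi <- pmax(i, j)
  for (k in seq_along(lo)) m[lo[k], hi[k]] <- m[lo[k], hi[k]] + df$count[k]
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  contact_matrix(m, chrom, bs)
}

#' Write a contact matrix as triplet TSV
#'
#' @param x A `contact_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(x, path) {
  readr::write_tsv(tidy.contact_matrix(x), path, progress = FALSE)
  invisible(path)
}

#' Balance a contact matrix by iterative correction
#'
#' Sinkhorn-style iterative correction: bins with zero marginal or with a
#' marginal in the bottom 1% of non-zero marginals are masked, then per-bin
#' weights are updated until all unmasked row sums agree with their mean to
#' within `tol` (relative). The balanced matrix is rescaled so its total
#' equals the input total over unmasked bins.
#'
#' @param x A `contact_matrix`.
#' @param tol Relative row-sum tolerance (default 1e-5).
#' @param max_iter Maximum iterations (default 200).
#' @param mask_quantile Fraction of lowest non-zero marginals to mask
#'   (default 0.01).
#' @return A `contact_matrix` with `weights` set and `balanced = TRUE`. If
#'   convergence is not reached a warning is raised and the best iterate is
#'   returned with attribute `converged = FALSE`.
#' @export
balance_matrix <- function(x, tol = 1e-5, max_iter = 200, mask_quantile = 0.01) {
  m <- x$counts
  n <- nrow(m)
  marg <- rowSums(m)
  masked <- marg == 0
  nz <- which(!masked)
  if (!length(nz)) stop("no non-zero rows to balance")
  # mask the bottom mask_quantile fraction of non-zero marginals
  k <- floor(mask_quantile * length(nz))
  if (k > 0) masked[nz[order(marg[nz])[seq_len(k)]]] <- TRUE
  keep <- !masked
  b <- rep(1, n)
  w <- m
  w[masked, ] <- 0
  w[, masked] <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- rowSums(w)[keep]
    mu <- mean(s)
    dev <- max(abs(s - mu)) / mu
    if (dev < tol) { converged <- TRUE; break }
    adj <- rep(1, n)
    adj[keep] <- sqrt(s / mu)
    b <- b * adj
    w <- w / outer(adj, adj)
  }
  if (!converged) {
    warning("balance_matrix: no convergence in ", max_iter, " iterations")
  }
  # rescale to preserve the unmasked total
  tot_in <- sum(m[keep, keep])
  tot_out <- sum(w[keep, keep])
  if (tot_out > 0) w <- w * tot_in / tot_out
  weights <- b
  weights[masked] <- NA_real_
  out <- contact_matrix(w, x$chrom, x$bin_size, weights = weights,
                        masked = masked, balanced = TRUE)
  attr(out, "converged") <- converged
  out
}

#' Observed/expected transform of a contact matrix
#'
#' Divides each entry by the mean over all unmasked entries at the same
#' diagonal offset on that chromosome. Offsets whose mean is zero (or with no
#' unmasked entries) yield `NA`.
#'
#' @param x A `contact_matrix` (raw or balanced).
#' @return A `contact_matrix` holding the O/E values (masked entries `NA`).
#' @export
observed_over_expected <- function(x) {
  m <- x$counts
  n <- nrow(m)
  keep <- !x$masked
  oe <- matrix(NA_real_, n, n)
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d)
    j <- i + d
    ok <- keep[i] & keep[j]
    if (!any(ok)) next
    vals <- m[cbind(i[ok], j[ok])]
    mu <- mean(vals)
    if (mu == 0) next
    oe[cbind(i[ok], j[ok])] <- vals / mu
    oe[cbind(j[ok], i[ok])] <- vals / mu
  }
  out <- x
  out$counts <- oe  # fields assigned directly: NA pattern is intentional here
  out
}

#' Pearson correlation matrix of an O/E matrix
#'
#' Entry (i, j) is the Pearson correlation of rows i and j over unmasked
#' columns; the diagonal is 1. Rows with zero variance are masked (`NA`).
#'
#' @param oe A `contact_matrix`, typically from [observed_over_expected()].
#' @return A list of class `corr_matrix`: `corr` (matrix), `masked`, `chrom`,
#'   `bin_size`.
#' @export
pearson_correlation <- function(oe) {
  m <- oe$counts
  keep <- !oe$masked
  if (sum(keep) < 3) stop("need >= 3 unmasked bins")
  sub <- m[keep, keep, drop = FALSE]
  sub[is.na(sub)] <- 0
  v <- apply(sub, 1, stats::var)
  const <- v == 0
  n <- nrow(m)
  corr <- matrix(NA_real_, n, n)
  if (any(!const)) {
    cc <- stats::cor(t(sub[!const, , drop = FALSE]))
    idx <- which(keep)[!const]
    corr[idx, idx] <- cc
  }
  masked <- !keep
  masked[which(keep)[const]] <- TRUE
  ok <- which(!masked)
  corr[cbind(ok, ok)] <- 1
  corr[masked, ] <- NA_real_
  corr[, masked] <- NA_real_
  structure(list(corr = corr, masked = masked, chrom = oe$chrom,
                 bin_size = oe$bin_size),
            class = "corr_matrix")
}

#' Distance-stratified contact statistics
#'
#' Per-offset mean contact plus the ratio of long-range (> `threshold_bp`)
#' to short-range (<= `threshold_bp`, diagonal excluded) summed contacts.
#'
#' @param x A `contact_matrix`.
#' @param threshold_bp Long/short split in bp (default 20 Mb).
#' @return A tibble of class `distance_profile` with columns `chrom`,
#'   `distance_bp`, `mean_contact`, and attributes `long_short_ratio` and
#'   `threshold_bp`.
#' @export
distance_profile <- function(x, threshold_bp = 2e7) {
  m <- x$counts
  n <- nrow(m)
  bs <- x$bin_size
  if (threshold_bp >= n * bs) {
    warning("threshold >= chromosome length; long-range ratio is 0")
  }
  d <- 0:(n - 1)
  mean_contact <- vapply(d, function(k) {
    i <- seq_len(n - k)
    mean(m[cbind(i, i + k)], na.rm = TRUE)
  }, numeric(1))
  sum_contact <- vapply(d, function(k) {
    i <- seq_len(n - k)
    sum(m[cbind(i, i + k)], na.rm = TRUE)
  }, numeric(1))
  dist_bp <- d * bs
  long_sum <- sum(sum_contact[dist_bp > threshold_bp])
  short_sum <- sum(sum_contact[dist_bp <= threshold_bp & d > 0])
  ratio <- if (short_sum > 0) long_sum / short_sum else 0
  out <- tibble::tibble(chrom = x$chrom, distance_bp = dist_bp,
                        mean_contact = mean_contact)
  attr(out, "long_short_ratio") <- ratio
  attr(out, "threshold_bp") <- threshold_bp
  class(out) <- c("distance_profile", class(out))
  out
}

#' Long/short contact ratio
#' @param x A `contact_matrix` or `distance_profile`.
#' @param threshold_bp Split point in bp.
#' @return The scalar ratio.
#' @export
long_short_ratio <- function(x, threshold_bp = 2e7) {
  if (inherits(x, "contact_matrix")) x <- distance_profile(x, threshold_bp)
  attr(x, "long_short_ratio")
}

#' Compare per-chromosome long/short ratios between two samples
#'
#' Paired two-sided Wilcoxon signed-rank test across chromosomes.
#'
#' @param ratios1,ratios2 Numeric vectors of per-chromosome ratios, same
#'   chromosome order.
#' @return A tibble with the test statistic, p-value and per-sample medians.
#' @export
compare_long_short <- function(ratios1, ratios2) {
  stopifnot(length(ratios1) == length(ratios2))
  ht <- suppressWarnings(
    stats::wilcox.test(ratios1, ratios2, paired = TRUE, exact = FALSE)
  )
  p <- if (all(ratios1 == ratios2)) 1 else ht$p.value
  tibble::tibble(
    median1 = stats::median(ratios1), median2 = stats::median(ratios2),
    statistic = unname(ht$statistic), p_value = p, n = length(ratios1)
  )
}
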