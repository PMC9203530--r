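# Shared fixture builders; everything is generated in code at test time.

small_layout <- function(n_chrom = 1, length_bp = 8e6, bin_size = 4e4) {
  genome_layout(paste0("chr", seq_len(n_chrom)),
                rep(length_bp, n_chrom), bin_size)
}

# a contact matrix with block-diagonal planted domains and pure power decay
planted_map <- function(layout, seed, fold = 2, depth = 100,
                        gap_fraction = 0) {
  truth <- simulate_truth(layout, seed = seed)
  list(
    truth = truth,
    map = simulate_contact_map(layout, truth, within_domain_fold = fold,
                               loop_fold = 1, mean_depth = depth,
                               gap_fraction = gap_fraction, seed = seed + 1)
  )
}

# independent Sinkhorn balancing oracle: alternate row/column normalization
# of the masked matrix, then rescale to unit mean row sum
sinkhorn_oracle <- function(m, masked, iters = 5000, tol = 1e-12) {
  keep <- !masked
  x <- m[keep, keep, drop = FALSE]
  for (i in seq_len(iters)) {
    r <- rowSums(x)
    x <- x / r
    cs <- colSums(x)
    x <- sweep(x, 2, cs, "/")
    if (max(abs(rowSums(x) - 1)) < tol && max(abs(colSums(x) - 1)) < tol) {
      break
    }
  }
  # symmetrize (row/col alternation converges to symmetric for symmetric m)
  x <- (x + t(x)) / 2
  x / mean(rowSums(x))
}

# brute-force hypergeometric enumeration of Fisher's two-sided p for a 2x2
# table (a b / c d), fixed margins
fisher_enum <- function(a, b, c, d) {
  m <- a + c; n_ <- b + d; k <- a + b
  lo <- max(0, k - n_); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact rank-sum p (alternative: x < y) by full enumeration of group labels
ranksum_enum <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(nx)])
  combos <- utils::combn(nx + ny, nx)
  w_all <- apply(combos, 2, function(idx) sum(ranks[idx]))
  mean(w_all <= w_obs)
}

# per-bp brute force coverage Jaccard on small toys
jaccard_bp <- function(a, b) {
  cover <- function(d, ch) {
    sel <- d$chrom == ch
    pos <- integer(0)
    for (i in which(sel)) pos <- c(pos, seq(d$start[i], d$end[i] - 1))
    unique(pos)
  }
  chroms <- union(a$chrom, b$chrom)
  inter <- 0; uni <- 0
  for (ch in chroms) {
    ca <- cover(a, ch); cb <- cover(b, ch)
    inter <- inter + length(intersect(ca, cb))
    uni <- uni + length(union(ca, cb))
  }
  inter / uni
}
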