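#' Plant a synthetic ground truth on a genome layout
#'
#' Tiles each chromosome with non-overlapping domains whose sizes are drawn
#' per class (active / inactive / HDF), derives the single-bin boundaries,
#' plants loops anchored near a random subset of boundaries, and assigns a
#' blocky 1-8 subcompartment rank per bin. The truth object seeds every
#' generator so that all pipeline stages can be scored against it.
#'
#' @param layout A `genome_layout`.
#' @param class_mean_bins Named vector of mean domain sizes in bins per class
#'   (defaults: active 8, inactive 15, HDF 20 — HDF domains run large in
#'   repeat-rich plant genomes).
#' @param class_probs Sampling probabilities of the three classes.
#' @param loop_per_mb Expected loops per Mb (default 0.5).
#' @param rank_block_bins Mean length of constant-rank blocks (default 25).
#' @param seed Integer seed.
#' @return A list of class `synthetic_truth`: `domains` (with `class`),
#'   `boundaries`, `loops` (a `loop_set`), `compartment_rank` (per-bin
#'   tibble), `seed`.
#' @export
simulate_truth <- function(layout,
                           class_mean_bins = c(active = 8, inactive = 15,
                                               HDF = 20),
                           class_probs = c(active = 0.25, inactive = 0.35,
                                           HDF = 0.4),
                           loop_per_mb = 0.5,
                           rank_block_bins = 25,
                           seed = 1L) {
  set.seed(seed)
  bs <- bin_size(layout)
  domains <- purrr::pmap_dfr(layout, function(chrom, length, n_bins) {
    sizes <- integer(); classes <- character()
    used <- 0L
    while (used < n_bins) {
      cls <- sample(names(class_probs), 1, prob = class_probs)
      sz <- max(2L, stats::rpois(1, class_mean_bins[[cls]]))
      sz <- min(sz, n_bins - used)
      if (n_bins - used - sz == 1L) sz <- sz + 1L  # no 1-bin remainders
      sizes <- c(sizes, sz); classes <- c(classes, cls)
      used <- used + sz
    }
    ends <- cumsum(sizes)
    starts <- c(0L, ends[-length(ends)])
    tibble::tibble(chrom = chrom,
                   start = starts * bs,
                   end = pmin(ends * bs, length),
                   class = classes)
  })
  boundaries <- domain_boundaries(domains, bs)
  # loops anchored at a sample of internal boundary bins, partner 5-30 bins
  # downstream
  loops <- purrr::map_dfr(unique(domains$chrom), function(ch) {
    row <- layout_chrom(layout, ch)
    n_loops <- stats::rpois(1, loop_per_mb * row$length / 1e6)
    if (n_loops == 0) return(NULL)
    bb <- boundaries$bin[boundaries$chrom == ch]
    bb <- bb[bb > 1 & bb < row$n_bins]
    if (length(bb) < 2) return(NULL)
    a <- sample(bb, n_loops, replace = TRUE)
    span <- sample(5:30, n_loops, replace = TRUE)
    b <- pmin(a + span, row$n_bins)
    ok <- b > a
    tibble::tibble(chrom = ch,
                   start1 = (a[ok] - 1) * bs, end1 = a[ok] * bs,
                   start2 = (b[ok] - 1) * bs, end2 = b[ok] * bs,
                   resolution = bs)
  })
  loops <- if (nrow(loops)) {
    loop_set(dplyr::distinct(loops))
  } else {
    loop_set(tibble::tibble(chrom = character(), start1 = numeric(),
                            end1 = numeric(), start2 = numeric(),
                            end2 = numeric()))
  }
  bins <- layout_bins(layout)
  rank <- integer(nrow(bins))
  for (ch in unique(bins$chrom)) {
    sel <- which(bins$chrom == ch)
    i <- 1L
    while (i <= length(sel)) {
      len <- max(1L, stats::rpois(1, rank_block_bins))
      rank[sel[i:min(i + len - 1L, length(sel))]] <- sample(1:8, 1)
      i <- i + len
    }
  }
  truth <- list(domains = domains, boundaries = boundaries, loops = loops,
                compartment_rank = dplyr::mutate(
                  bins[, c("chrom", "start", "end")], rank = rank),
                seed = seed)
  class(truth) <- "synthetic_truth"
  validate_truth(truth, layout)
  truth
}

validate_truth <- function(truth, layout) {
  d <- truth$domains
  for (ch in unique(d$chrom)) {
    dd <- d[d$chrom == ch, ]
    dd <- dd[order(dd$start), ]
    if (any(dd$end <= dd$start)) stop("degenerate domain")
    if (nrow(dd) > 1 && any(dd$start[-1] < dd$end[-nrow(dd)])) {
      stop("overlapping domains in truth")
    }
  }
  if (any(!truth$compartment_rank$rank %in% 1:8)) stop("rank outside 1-8")
  invisible(truth)
}

#' Simulate a distance-decaying contact map with planted structure
#'
#' Expected count for bin pair (i, j):
#' `mean_depth * (|i-j|+1)^(-decay_exponent) * within_domain_fold^[same domain]
#'  * loop_fold^[loop anchor pair]`; counts are Poisson, the matrix
#' symmetric, and a fraction of bins is zeroed as unmappable gaps.
#'
#' @param layout A `genome_layout`.
#' @param truth A `synthetic_truth`.
#' @param chrom Chromosome to simulate.
#' @param decay_exponent Positive power-law decay exponent (default 1).
#' @param within_domain_fold Multiplicative fold for same-domain pairs
#'   (>= 1, default 2).
#' @param loop_fold Multiplicative fold for loop-anchor bin pairs (>= 1,
#'   default 3).
#' @param mean_depth Expected count at distance 0 before folds (default 50).
#' @param gap_fraction Fraction of bins zeroed as gaps (default 0.02).
#' @param seed Integer seed.
#' @return A `contact_matrix`.
#' @export
simulate_contact_map <- function(layout, truth, chrom = layout$chrom[1],
                                 decay_exponent = 1, within_domain_fold = 2,
                                 loop_fold = 3, mean_depth = 50,
                                 gap_fraction = 0.02, seed = 1L) {
  if (within_domain_fold < 1 || loop_fold < 1) {
    stop("fold parameters must be >= 1")
  }
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (decay_exponent <= 0) stop("decay_exponent must be > 0")
  row <- layout_chrom(layout, chrom)
  n <- row$n_bins
  if (n < 4) stop("need >= 4 bins per chromosome")
  bs <- bin_size(layout)
  set.seed(seed)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  mu <- mean_depth * (d + 1)^(-decay_exponent)
  # domain membership per bin (0 = none)
  dom <- truth$domains[truth$domains$chrom == chrom, , drop = FALSE]
  dom_id <- rep(0L, n)
  for (k in seq_len(nrow(dom))) {
    b0 <- floor(dom$start[k] / bs) + 1L
    b1 <- ceiling(dom$end[k] / bs)
    dom_id[b0:min(b1, n)] <- k
  }
  same <- outer(dom_id, dom_id, "==") & dom_id > 0
  mu[same] <- mu[same] * within_domain_fold
  lp <- truth$loops[truth$loops$chrom == chrom, , drop = FALSE]
  if (nrow(lp)) {
    a <- floor((lp$start1 + lp$end1) / 2 / bs) + 1L
    b <- floor((lp$start2 + lp$end2) / 2 / bs) + 1L
    ok <- a >= 1 & a <= n & b >= 1 & b <= n
    mu[cbind(a[ok], b[ok])] <- mu[cbind(a[ok], b[ok])] * loop_fold
    mu[cbind(b[ok], a[ok])] <- mu[cbind(b[ok], a[ok])] * loop_fold
  }
  up <- upper.tri(mu, diag = TRUE)
  counts <- matrix(0, n, n)
  counts[up] <- stats::rpois(sum(up), mu[up])
  counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
  if (gap_fraction > 0) {
    gaps <- sample(n, max(0, round(gap_fraction * n)))
    counts[gaps, ] <- 0
    counts[, gaps] <- 0
  }
  contact_matrix(counts, chrom, bs)
}

#' Simulate class-correlated genomic and epigenomic tracks
#'
#' Per-bin values are drawn from class-conditional normals: baseline plus the
#' configured per-class shift (defaults follow the usual directionality:
#' active domains run gene- and H3K4me3-rich, HDF domains LTR- and
#' H3K9me2-rich, inactive domains heavily methylated). Methylation tracks
#' are clamped to [0, 1]; `methylation` is the mean of the three context
#' tracks.
#'
#' @param layout A `genome_layout`.
#' @param truth A `synthetic_truth`.
#' @param class_effects Tibble (`class`, `feature`, `shift`) overriding the
#'   default shifts; `NULL` keeps defaults, a tibble with `shift = 0`
#'   everywhere gives the null configuration.
#' @param noise_sd Per-bin Gaussian noise SD (default 0.5).
#' @param seed Integer seed.
#' @return A long tibble: `chrom`, `start`, `end`, `feature`, `value` with
#'   features `gene_density`, `ltr_density`, `mCpG`, `mCHG`, `mCHH`,
#'   `methylation`, `H3K4me3`, `H3K9me2`, `H3K27me3`.
#' @export
simulate_tracks <- function(layout, truth, class_effects = NULL,
                            noise_sd = 0.5, seed = 1L) {
  set.seed(seed)
  defaults <- default_class_effects()
  if (!is.null(class_effects)) {
    bad <- setdiff(class_effects$class, c("active", "inactive", "HDF"))
    if (length(bad)) stop("unknown class label: ", paste(bad, collapse = ", "))
    defaults <- dplyr::bind_rows(
      dplyr::anti_join(defaults, class_effects, by = c("class", "feature")),
      class_effects[c("class", "feature", "shift")]
    )
  }
  bins <- layout_bins(layout)
  bs <- bin_size(layout)
  # class of the domain covering each bin (bins between domains = "inactive")
  cls <- rep("inactive", nrow(bins))
  for (k in seq_len(nrow(truth$domains))) {
    dme <- truth$domains[k, ]
    sel <- bins$chrom == dme$chrom & bins$start < dme$end &
      bins$end > dme$start
    cls[sel] <- dme$class
  }
  baselines <- c(gene_density = 2, ltr_density = 2, mCpG = 0.5, mCHG = 0.4,
                 mCHH = 0.15, H3K4me3 = 2, H3K9me2 = 2, H3K27me3 = 2)
  meth_feats <- c("mCpG", "mCHG", "mCHH")
  tracks <- purrr::map_dfr(names(baselines), function(f) {
    shift <- defaults$shift[match(paste(cls, f),
                                  paste(defaults$class, defaults$feature))]
    shift[is.na(shift)] <- 0
    sdv <- if (f %in% meth_feats) noise_sd * 0.2 else noise_sd
    v <- baselines[[f]] + shift + stats::rnorm(nrow(bins), 0, sdv)
    if (f %in% meth_feats) v <- pmin(pmax(v, 0), 1) else v <- pmax(v, 0)
    tibble::tibble(chrom = bins$chrom, start = bins$start, end = bins$end,
                   feature = f, value = v)
  })
  overall <- tracks |>
    dplyr::filter(.data$feature %in% meth_feats) |>
    dplyr::group_by(.data$chrom, .data$start, .data$end) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::mutate(feature = "methylation")
  dplyr::bind_rows(tracks, overall) |>
    dplyr::arrange(.data$feature, .data$chrom, .data$start)
}

#' Default per-class track shifts used by [simulate_tracks()]
#' @return A tibble (`class`, `feature`, `shift`).
#' @export
default_class_effects <- function() {
  tibble::tribble(
    ~class,     ~feature,       ~shift,
    "active",   "gene_density",  2,
    "active",   "H3K4me3",       2,
    "active",   "mCpG",         -0.2,
    "active",   "mCHG",         -0.2,
    "HDF",      "ltr_density",   2,
    "HDF",      "H3K9me2",       2,
    "inactive", "mCpG",          0.2,
    "inactive", "mCHG",          0.2,
    "inactive", "H3K27me3",      1
  )
}

#' Simulate SNPs and deletions with boundary depletion
#'
#' SNP positions follow an inhomogeneous Poisson process with rate
#' `background_density * depletion_factor` within `boundary_halfwidth` of a
#' boundary midpoint and `background_density` elsewhere (thinning of a
#' homogeneous process). Deletions use the same rate field for their start
#' positions, with geometric lengths of mean `deletion_mean_bp`.
#'
#' @param layout A `genome_layout`.
#' @param boundaries Boundary tibble (`chrom`, `start`, `end`).
#' @param background_density Variants per bp away from boundaries.
#' @param depletion_factor Rate multiplier near boundaries, in (0, 1].
#' @param boundary_halfwidth Half-width of the depleted zone in bp.
#' @param deletion_density Deletion starts per bp (default
#'   `background_density / 10`).
#' @param deletion_mean_bp Mean deletion length (default 300).
#' @param seed Integer seed.
#' @return A list of class `variant_set`: `snps` (`chrom`, `pos`),
#'   `deletions` (`chrom`, `start`, `end`).
#' @export
simulate_variants <- function(layout, boundaries, background_density,
                              depletion_factor, boundary_halfwidth,
                              deletion_density = background_density / 10,
                              deletion_mean_bp = 300, seed = 1L) {
  if (depletion_factor <= 0 || depletion_factor > 1) {
    stop("depletion_factor must be in (0, 1]")
  }
  set.seed(seed)
  thin_positions <- function(dens) {
    purrr::pmap_dfr(layout, function(chrom, length, n_bins) {
      n <- stats::rpois(1, dens * length)
      pos <- sort(stats::runif(n, 0, length))
      mids <- (boundaries$start + boundaries$end)[boundaries$chrom == chrom] / 2
      near <- rep(FALSE, length(pos))
      for (m in mids) {
        near <- near | abs(pos - m) <= boundary_halfwidth
      }
      keep <- !near | stats::runif(length(pos)) < depletion_factor
      tibble::tibble(chrom = chrom, pos = floor(pos[keep]))
    })
  }
  snps <- thin_positions(background_density)
  del_start <- thin_positions(deletion_density)
  len <- stats::rgeom(nrow(del_start), 1 / deletion_mean_bp) + 1
  deletions <- tibble::tibble(
    chrom = del_start$chrom,
    start = del_start$pos,
    end = pmin(del_start$pos + len,
               layout$length[match(del_start$chrom, layout$chrom)])
  )
  structure(list(snps = snps, deletions = deletions),
            class = "variant_set")
}

#' Simulate synteny blocks with boundary-localized breaks
#'
#' Places `n_breaks` break positions on the reference (a fraction
#' `break_boundary_fraction` within one bin of a planted domain boundary, the
#' rest uniform), then tiles each chromosome with abutting collinear blocks
#' split at the breaks; consecutive blocks across a break switch query
#' chromosome (or strand). Per-block alignable coverage follows
#' `alignable_fraction_profile` evaluated at the block midpoint's relative
#' position inside its domain.
#'
#' @param layout A `genome_layout`.
#' @param domains Domain tibble (`chrom`, `start`, `end`).
#' @param n_breaks Total number of breaks (>= 1).
#' @param break_boundary_fraction Fraction of breaks placed within one bin of
#'   a boundary, in [0, 1].
#' @param alignable_fraction_profile Function of relative domain position in
#'   [0, 1] returning the alignable fraction (default: constant 0.6).
#' @param seed Integer seed.
#' @return A list of class `synteny_sim`: `blocks` (tibble: `qname`,
#'   `qstart`, `qend`, `strand`, `tname`, `tstart`, `tend`, `alignable_bp`)
#'   and `breaks` (`chrom`, `pos` — the planted truth).
#' @export
simulate_synteny_blocks <- function(layout, domains, n_breaks,
                                    break_boundary_fraction,
                                    alignable_fraction_profile =
                                      function(rel) rep(0.6, length(rel)),
                                    seed = 1L) {
  if (n_breaks < 1) stop("n_breaks must be >= 1")
  if (break_boundary_fraction < 0 || break_boundary_fraction > 1) {
    stop("break_boundary_fraction must be in [0, 1]")
  }
  set.seed(seed)
  bs <- bin_size(layout)
  boundaries <- domain_boundaries(domains, bs)
  n_at_bound <- round(break_boundary_fraction * n_breaks)
  n_uniform <- n_breaks - n_at_bound
  # boundary-anchored breaks: uniform within +/- one bin of a boundary mid
  bmid <- (boundaries$start + boundaries$end) / 2
  internal <- bmid > bs & bmid < layout$length[match(boundaries$chrom,
                                                     layout$chrom)] - bs
  bsel <- sample(which(internal), n_at_bound, replace = TRUE)
  b_breaks <- tibble::tibble(
    chrom = boundaries$chrom[bsel],
    pos = bmid[bsel] + stats::runif(n_at_bound, -bs, bs)
  )
  # uniform breaks over the genome
  w <- layout$length / sum(layout$length)
  usel <- sample(seq_len(nrow(layout)), n_uniform, replace = TRUE, prob = w)
  u_breaks <- tibble::tibble(
    chrom = layout$chrom[usel],
    pos = stats::runif(n_uniform, bs, layout$length[usel] - bs)
  )
  breaks <- dplyr::arrange(dplyr::bind_rows(b_breaks, u_breaks),
                           .data$chrom, .data$pos)
  # build blocks: abutting segments split at break positions; query identity
  # switches across each break
  queries <- paste0("q", 1:6)
  blocks <- purrr::pmap_dfr(layout, function(chrom, length, n_bins) {
    cuts <- sort(breaks$pos[breaks$chrom == chrom])
    edges <- unique(c(0, cuts, length))
    nb <- length(edges) - 1
    qn <- character(nb); st <- character(nb)
    qn[1] <- sample(queries, 1); st[1] <- "+"
    if (nb > 1) {
      for (i in 2:nb) {
        # switch query chromosome (mostly) or strand at each break
        if (stats::runif(1) < 0.8) {
          qn[i] <- sample(setdiff(queries, qn[i - 1]), 1)
          st[i] <- sample(c("+", "-"), 1)
        } else {
          qn[i] <- qn[i - 1]
          st[i] <- if (st[i - 1] == "+") "-" else "+"
        }
      }
    }
    mid <- (edges[-1] + edges[-(nb + 1)]) / 2
    rel <- rel_domain_position(chrom, mid, domains)
    frac <- pmin(pmax(alignable_fraction_profile(rel), 0.01), 1)
    len <- edges[-1] - edges[-(nb + 1)]
    tibble::tibble(
      qname = qn,
      qstart = round(stats::runif(nb, 0, 5e7)),
      qend = NA_real_,
      strand = st,
      tname = chrom,
      tstart = edges[-(nb + 1)],
      tend = edges[-1],
      alignable_bp = round(len * frac)
    ) |>
      dplyr::mutate(qend = .data$qstart + len)
  })
  structure(list(blocks = blocks, breaks = breaks), class = "synteny_sim")
}

rel_domain_position <- function(chrom, pos, domains) {
  rel <- rep(0.5, length(pos))
  dd <- domains[domains$chrom == chrom[1], , drop = FALSE]
  if (!nrow(dd)) return(rel)
  dd <- dd[order(dd$start), , drop = FALSE]
  idx <- findInterval(pos, dd$start)
  idx[idx < 1] <- 1
  r <- (pos - dd$start[idx]) / (dd$end[idx] - dd$start[idx])
  pmin(pmax(r, 0), 1)
}

#' Simulate replicated multi-tissue binned expression counts
#'
#' Negative-binomial counts around tissue-specific means; a fraction
#' `specific_bins` of bins has one random tissue up-shifted by
#' `effect_log2fc` log2 units. Library sizes vary at most twofold.
#'
#' @param layout A `genome_layout`.
#' @param n_tissues Number of tissues (>= 2, default 5).
#' @param n_reps Replicates per tissue (>= 1, default 3).
#' @param specific_bins Fraction of tissue-specific bins (default 0.1).
#' @param effect_log2fc Log2 up-shift of the specific tissue (default 4).
#' @param base_mean Mean count of a non-specific bin (default 100; a 40-kb
#'   bin pools reads across many genes, so per-bin counts run high).
#' @param dispersion NB size parameter (default 20 — mild overdispersion, as
#'   expected when replicate libraries from one tissue are averaged).
#' @param seed Integer seed.
#' @return A list of class `expression_sim`: `counts` (tibble: `bin_id`,
#'   `chrom`, `start`, `end`, one column per sample), `samples` (tibble:
#'   `sample`, `tissue`), `specific` (logical per bin — the planted truth).
#' @export
simulate_expression <- function(layout, n_tissues = 5, n_reps = 3,
                                specific_bins = 0.1, effect_log2fc = 4,
                                base_mean = 100, dispersion = 20, seed = 1L) {
  stopifnot(n_tissues >= 2, n_reps >= 1)
  set.seed(seed)
  bins <- layout_bins(layout)
  nb <- nrow(bins)
  tissues <- paste0("tissue", seq_len(n_tissues))
  specific <- stats::runif(nb) < specific_bins
  up_tissue <- sample.int(n_tissues, nb, replace = TRUE)
  base <- stats::rgamma(nb, shape = 2, scale = base_mean / 2)
  mu <- matrix(base, nb, n_tissues)
  idx <- cbind(which(specific), up_tissue[specific])
  mu[idx] <- mu[idx] * 2^effect_log2fc
  samples <- tidyr::expand_grid(tissue = tissues,
                                rep = seq_len(n_reps)) |>
    dplyr::mutate(sample = paste0(.data$tissue, "_r", .data$rep)) |>
    dplyr::select("sample", "tissue")
  lib_factor <- stats::runif(nrow(samples), 1, 2)
  counts <- vapply(seq_len(nrow(samples)), function(s) {
    t_idx <- match(samples$tissue[s], tissues)
    stats::rnbinom(nb, mu = mu[, t_idx] * lib_factor[s], size = dispersion)
  }, numeric(nb))
  colnames(counts) <- samples$sample
  out <- dplyr::bind_cols(
    tibble::tibble(bin_id = paste0("bin", seq_len(nb)),
                   chrom = bins$chrom, start = bins$start, end = bins$end),
    tibble::as_tibble(as.data.frame(counts))
  )
  structure(list(counts = out, samples = samples, specific = specific),
            class = "expression_sim")
}
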