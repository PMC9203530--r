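#' CPM-normalize a binned expression matrix and flag testable bins
#'
#' Counts per million per sample, tissue values as replicate means, and the
#' testable mask: a bin is testable when its tissue-mean CPM exceeds 0.5 in
#' at least one tissue (strict `>`).
#'
#' @param counts Tibble: `bin_id`, `chrom`, `start`, `end`, then one integer
#'   count column per sample.
#' @param samples Tibble mapping `sample` to `tissue`.
#' @param testable_cpm Testability threshold (default 0.5).
#' @return A list of class `binned_expression`: `cpm` (bins x samples
#'   tibble), `tissue_cpm` (bins x tissues, replicate means), `testable`
#'   (logical per bin), `bins` (coordinate columns).
#' @export
bin_cpm <- function(counts, samples, testable_cpm = 0.5) {
  coord_cols <- intersect(c("bin_id", "chrom", "start", "end"), names(counts))
  sample_cols <- setdiff(names(counts), coord_cols)
  missing <- setdiff(sample_cols, samples$sample)
  if (length(missing)) stop("samples without tissue: ",
                            paste(missing, collapse = ", "))
  mat <- as.matrix(counts[sample_cols])
  if (any(mat < 0)) stop("negative counts")
  lib <- colSums(mat)
  if (any(lib == 0)) stop("zero library size in sample(s): ",
                          paste(sample_cols[lib == 0], collapse = ", "))
  cpm <- sweep(mat, 2, lib, "/") * 1e6
  tissue_of <- samples$tissue[match(sample_cols, samples$sample)]
  tissues <- unique(tissue_of)
  tcpm <- vapply(tissues, function(t) {
    rowMeans(cpm[, tissue_of == t, drop = FALSE])
  }, numeric(nrow(cpm)))
  testable <- apply(tcpm > testable_cpm, 1, any)
  structure(list(
    cpm = tibble::as_tibble(as.data.frame(cpm)),
    tissue_cpm = tibble::as_tibble(as.data.frame(tcpm)),
    testable = testable,
    bins = counts[coord_cols]
  ), class = "binned_expression")
}

#' Tau tissue-specificity index
#'
#' `tau = sum(1 - r_i) / (n - 1)` where `r_i = x_i / max(x)` over the `n`
#' tissue expression values of a bin. Tau is 0 for uniform expression and 1
#' for single-tissue expression; all-zero bins are `NA`.
#'
#' @param x Either a numeric vector of one bin's tissue values, or a numeric
#'   matrix / data frame (bins x tissues).
#' @return For a vector, a one-row tibble of class `tau_result` (`tau`,
#'   `n_tissues`, plus `r_i` as a list column); for a matrix, the same with
#'   one row per bin.
#' @examples
#' tau_index(c(10, 10, 10, 10, 10))$tau  # 0
#' tau_index(c(10, 0, 0, 0, 0))$tau      # 1
#' @export
tau_index <- function(x) {
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  n <- ncol(x)
  if (n < 2) stop("need >= 2 tissues")
  if (any(x < 0)) stop("expression values must be non-negative")
  mx <- apply(x, 1, max)
  r <- sweep(x, 1, mx, "/")
  tau <- rowSums(1 - r) / (n - 1)
  tau[mx == 0] <- NA_real_
  out <- tibble::tibble(
    tau = tau,
    n_tissues = n,
    r_i = lapply(seq_len(nrow(x)), function(i) r[i, ])
  )
  class(out) <- c("tau_result", class(out))
  out
}

#' Two-tissue fold-change classes
#'
#' Bins change class `up` when the pseudocounted CPM ratio t2/t1 exceeds
#' `fold`, `down` when it falls below `1/fold`, otherwise `stable` (edges
#' inclusive in `stable`).
#'
#' @param cpm_t1,cpm_t2 Per-bin tissue CPM values.
#' @param fold Fold threshold (default 2; strict `>` / `<`).
#' @param pseudocount CPM pseudocount added to both sides (default 0.25).
#' @return A tibble: `class` (`down`/`stable`/`up`), `log2fc`, `abs_log2fc`.
#' @export
fold_change_classes <- function(cpm_t1, cpm_t2, fold = 2, pseudocount = 0.25) {
  stopifnot(length(cpm_t1) == length(cpm_t2))
  ratio <- (cpm_t2 + pseudocount) / (cpm_t1 + pseudocount)
  cls <- dplyr::case_when(ratio > fold ~ "up", ratio < 1 / fold ~ "down",
                          TRUE ~ "stable")
  tibble::tibble(class = cls, log2fc = log2(ratio),
                 abs_log2fc = abs(log2(ratio)))
}

#' Compare expression variability between conserved and tissue-specific
#' chromatin features
#'
#' One-sided Wilcoxon rank-sum test that bins overlapping shared (conserved)
#' boundaries/loops have lower expression variability (|log2 fold change| or
#' tau) than bins overlapping tissue-specific ones. A paired signed-rank
#' variant is available for matched bins.
#'
#' @param group_shared,group_specific Metric values for the two bin groups.
#' @param metric Label for the metric being compared (reported only).
#' @param paired Use a paired signed-rank test instead (groups must align).
#' @return A tibble: `metric`, `median_shared`, `median_specific`,
#'   `statistic`, `p_value` (alternative: shared < specific), `n_shared`,
#'   `n_specific`.
#' @export
conservation_expression_test <- function(group_shared, group_specific,
                                         metric = "abs_log2fc",
                                         paired = FALSE) {
  if (length(group_shared) < 2 || length(group_specific) < 2) {
    stop("each group needs >= 2 bins")
  }
  ht <- suppressWarnings(stats::wilcox.test(
    group_shared, group_specific, alternative = "less", paired = paired
  ))
  tibble::tibble(
    metric = metric,
    median_shared = stats::median(group_shared),
    median_specific = stats::median(group_specific),
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    n_shared = length(group_shared),
    n_specific = length(group_specific)
  )
}

#' Cross-table of subcompartment rank shifts vs expression classes
#'
#' Composes a switching table with two-tissue fold-change classes on the same
#' bins: rows are expression classes (`down`/`stable`/`up`), columns the rank
#' shift categories, values row proportions.
#'
#' @param shift Per-bin integer rank shift (`rank2 - rank1`).
#' @param class Per-bin expression class (`down`/`stable`/`up`).
#' @return A tibble with one row per class and the shift-category
#'   proportions (`<-1`, `-1`, `0`, `1`, `>1`) plus `n`.
#' @export
shift_expression_table <- function(shift, class) {
  stopifnot(length(shift) == length(class))
  cats <- c("<-1", "-1", "0", "1", ">1")
  cat_of <- dplyr::case_when(
    shift < -1 ~ "<-1", shift == -1 ~ "-1", shift == 0 ~ "0",
    shift == 1 ~ "1", TRUE ~ ">1"
  )
  tibble::tibble(class = factor(class, c("down", "stable", "up")),
                 shift = factor(cat_of, cats)) |>
    dplyr::count(.data$class, .data$shift, .drop = FALSE) |>
    dplyr::group_by(.data$class) |>
    dplyr::mutate(total = sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(proportion = ifelse(.data$total > 0,
                                      .data$n / .data$total, NA_real_)) |>
    dplyr::select("class", "shift", "n", "proportion") |>
    tidyr::pivot_wider(names_from = "shift",
                       values_from = c("n", "proportion"))
}
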