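test_that("assembly QV follows the Phred closed form", {
  expect_equal(assembly_qv(1000, 1e6), 30)
  expect_equal(assembly_qv(5, 5e5), -10 * log10(1e-5), tolerance = 1e-12)
  expect_equal(assembly_qv(5, 5e5), 50, tolerance = 1e-12)
  expect_equal(assembly_qv(100, 100), 0)
  expect_equal(assembly_qv(0, 1e6), 99)  # capped sentinel
  expect_error(assembly_qv(1, 0), "covered")
  expect_error(assembly_qv(-1, 10))
})

test_that("homogeneous SNPs give a flat observed/expected boundary profile", {
  layout <- genome_layout(paste0("chr", 1:6), rep(1e7, 6), 4e4)
  truth <- simulate_truth(layout, seed = 71)
  v <- simulate_variants(layout, truth$boundaries, background_density = 4e-4,
                         depletion_factor = 1, boundary_halfwidth = 2e4,
                         seed = 72)
  expect_gt(nrow(v$snps), 15000)
  prof <- boundary_variant_profile(v$snps, truth$boundaries, layout)
  expect_gt(mean(prof$ratio), 0.95)
  expect_lt(mean(prof$ratio), 1.05)
})

test_that("planted depletion is recovered at the boundary, not at the flank", {
  layout <- genome_layout(paste0("chr", 1:6), rep(1e7, 6), 4e4)
  truth <- simulate_truth(layout, seed = 73)
  v <- simulate_variants(layout, truth$boundaries, background_density = 4e-4,
                         depletion_factor = 0.5, boundary_halfwidth = 2e4,
                         seed = 74)
  prof <- boundary_variant_profile(v$snps, truth$boundaries, layout)
  at0 <- prof$ratio[prof$offset_bp == 0]
  far <- mean(prof$ratio[abs(prof$offset_bp) >= 4e5])
  expect_gt(at0, 0.4)
  expect_lt(at0, 0.6)
  expect_gt(far, 0.9)
  expect_lt(far, 1.1)
})

test_that("deletion coverage accounting sums window overlaps in bp", {
  layout <- small_layout(length_bp = 4e6)
  bounds <- tibble::tibble(chrom = "chr1", start = 2e6, end = 2e6 + 4e4)
  # one deletion exactly tiling the window centered at the boundary midpoint
  mid <- 2e6 + 2e4
  dels <- tibble::tibble(chrom = "chr1", start = mid - 2e4, end = mid + 2e4)
  prof <- boundary_variant_profile(dels, bounds, layout,
                                   mode = "deletion_bp")
  expect_equal(prof$obs[prof$offset_bp == 0], 40000)
})

test_that("obs totals are conserved at step = window without clipping", {
  layout <- small_layout(length_bp = 8e6)
  bounds <- tibble::tibble(chrom = "chr1", start = 4e6, end = 4e6 + 4e4)
  set.seed(75)
  snps <- tibble::tibble(chrom = "chr1", pos = floor(runif(5000, 0, 8e6)))
  w <- 4e4
  prof <- boundary_variant_profile(snps, bounds, layout, window = w,
                                   step = w, flank = 10 * w)
  mid <- 4e6 + 2e4
  lo <- mid - 10 * w - w / 2
  hi <- mid + 10 * w + w / 2
  expect_equal(sum(prof$obs), sum(snps$pos >= lo & snps$pos < hi))
})

collinear_blocks <- function(n = 5, chrom = "t1", q = "q1", strand = "+",
                             start = 0, qstart = 0, len = 5e4, gap = 1e4) {
  tibble::tibble(
    qname = q,
    qstart = qstart + (seq_len(n) - 1) * (len + gap),
    qend = qstart + (seq_len(n) - 1) * (len + gap) + len,
    strand = strand,
    tname = chrom,
    tstart = start + (seq_len(n) - 1) * (len + gap),
    tend = start + (seq_len(n) - 1) * (len + gap) + len,
    alignable_bp = len * 0.8
  )
}

test_that("collinear blocks chain without breaks; chrom switch emits one", {
  b <- collinear_blocks()
  expect_equal(nrow(detect_synteny_breaks(b)), 0)
  # two chains on different query chromosomes -> one break at the gap mid
  b2 <- dplyr::bind_rows(
    collinear_blocks(start = 0),
    collinear_blocks(start = 5e5, q = "q2")
  )
  brk <- detect_synteny_breaks(b2)
  expect_equal(nrow(brk), 1)
  gap_mid <- (max(collinear_blocks()$tend) + 5e5) / 2
  expect_equal(brk$pos, gap_mid)
  expect_equal(brk$kind, "chrom")
})

test_that("break detection is invariant to splitting a collinear block", {
  b <- dplyr::bind_rows(
    collinear_blocks(start = 0),
    collinear_blocks(start = 5e5, q = "q2")
  )
  # split the first block into two abutting collinear pieces
  first <- b[1, ]
  left <- dplyr::mutate(first, tend = tstart + 2e4, qend = qstart + 2e4,
                        alignable_bp = 2e4 * 0.8)
  right <- dplyr::mutate(first, tstart = tstart + 2e4, qstart = qstart + 2e4,
                         alignable_bp = (tend - tstart - 2e4) * 0.8)
  b_split <- dplyr::bind_rows(left, right, b[-1, ])
  expect_equal(detect_synteny_breaks(b_split)$pos,
               detect_synteny_breaks(b)$pos)
})

test_that("planted synteny breaks are recovered within one bin", {
  layout <- genome_layout(c("chr1", "chr2"), rep(2e7, 2), 4e4)
  truth <- simulate_truth(layout, seed = 81)
  syn <- simulate_synteny_blocks(layout, truth$domains, n_breaks = 50,
                                 break_boundary_fraction = 0.5, seed = 82)
  brk <- detect_synteny_breaks(syn$blocks)
  rec <- vapply(seq_len(nrow(syn$breaks)), function(i) {
    any(brk$chrom == syn$breaks$chrom[i] &
          abs(brk$pos - syn$breaks$pos[i]) <= 4e4)
  }, logical(1))
  expect_gte(mean(rec), 0.9)
})

test_that("edge-planted breaks give extreme enrichment; normalization is
          scale-free", {
  layout <- small_layout(length_bp = 2e7)
  truth <- simulate_truth(layout, seed = 83)
  bins <- layout_bins(layout)
  flat <- dplyr::mutate(bins[c("chrom", "start", "end")], value = 0.5)
  # all breaks at domain edges
  b <- truth$boundaries
  brk <- tibble::tibble(chrom = b$chrom, pos = (b$start + b$end) / 2)
  enr <- break_boundary_enrichment(brk, truth$domains, flat, layout,
                                   n_perm = 99, seed = 84)
  expect_equal(enr$result$p, 1 / 100)
  terminal <- enr$profile$fold[c(1, 10)]
  interior <- enr$profile$fold[4:7]
  expect_gt(min(terminal), 3 * max(interior, na.rm = TRUE))
  # doubling alignability leaves the normalized profile unchanged
  flat2 <- dplyr::mutate(flat, value = value * 2)
  enr2 <- break_boundary_enrichment(brk, truth$domains, flat2, layout,
                                    n_perm = 99, seed = 84)
  expect_equal(enr2$profile$fold, enr$profile$fold)
  expect_equal(enr2$result$p, enr$result$p)
})

test_that("empirical p respects the add-one rule and its bounds", {
  set.seed(85)
  null <- rnorm(99)
  er_hi <- enrichment_result(10, null, 99)
  expect_equal(er_hi$p, 1 / 100)
  er_lo <- enrichment_result(-10, null, 99)
  expect_equal(er_lo$p, 1)
  # monotone decreasing in the observed statistic
  obs <- seq(-3, 3, length.out = 13)
  ps <- vapply(obs, function(o) enrichment_result(o, null, 99)$p, numeric(1))
  expect_true(all(diff(ps) <= 0))
})
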