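test_that("generators are pure functions of parameters and seed", {
  layout <- small_layout(length_bp = 4e6)
  t1 <- simulate_truth(layout, seed = 7)
  t2 <- simulate_truth(layout, seed = 7)
  expect_identical(t1$domains, t2$domains)
  m1 <- simulate_contact_map(layout, t1, seed = 8)
  m2 <- simulate_contact_map(layout, t1, seed = 8)
  expect_identical(m1$counts, m2$counts)
  e1 <- simulate_expression(layout, seed = 9)
  e2 <- simulate_expression(layout, seed = 9)
  expect_identical(e1$counts, e2$counts)
})

test_that("parameter validation rejects out-of-range generator settings", {
  layout <- small_layout(length_bp = 4e6)
  truth <- simulate_truth(layout, seed = 7)
  expect_error(simulate_contact_map(layout, truth, within_domain_fold = 0.5),
               "fold")
  expect_error(simulate_contact_map(layout, truth, mean_depth = 0), "depth")
  expect_error(simulate_variants(layout, truth$boundaries, 1e-4, 0, 2e4),
               "depletion_factor")
  expect_error(simulate_variants(layout, truth$boundaries, 1e-4, 1.5, 2e4),
               "depletion_factor")
  expect_error(simulate_synteny_blocks(layout, truth$domains, 10, 1.2),
               "fraction")
  expect_error(simulate_tracks(layout, truth,
                               class_effects = tibble::tibble(
                                 class = "bogus", feature = "gene_density",
                                 shift = 1)),
               "unknown class")
})

test_that("planted truth satisfies its own invariants", {
  layout <- small_layout(n_chrom = 2, length_bp = 6e6)
  truth <- simulate_truth(layout, seed = 11)
  for (ch in unique(truth$domains$chrom)) {
    d <- truth$domains[truth$domains$chrom == ch, ]
    expect_true(all(d$end > d$start))
    expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  expect_true(all(truth$compartment_rank$rank %in% 1:8))
  expect_true(all(truth$boundaries$end - truth$boundaries$start ==
                    bin_size(layout)))
})

test_that("track generation matches its class-conditional means", {
  layout <- genome_layout("chr1", 8e7, 4e4)  # 2000 bins
  truth <- simulate_truth(layout, seed = 13)
  tracks <- simulate_tracks(layout, truth, seed = 14)
  expect_equal(nrow(tracks) / length(unique(tracks$feature)),
               n_bins(layout))
  bins <- layout_bins(layout)
  cls <- rep("inactive", nrow(bins))
  for (k in seq_len(nrow(truth$domains))) {
    d <- truth$domains[k, ]
    cls[bins$chrom == d$chrom & bins$start < d$end & bins$end > d$start] <-
      d$class
  }
  ltr <- tracks$value[tracks$feature == "ltr_density"]
  shift <- default_class_effects()
  planted <- shift$shift[shift$class == "HDF" & shift$feature == "ltr_density"]
  observed <- mean(ltr[cls == "HDF"]) - mean(ltr[cls == "active"])
  expect_lt(abs(observed - planted), 0.1 * planted)
  # null configuration: no class separation
  zero <- dplyr::mutate(default_class_effects(), shift = 0)
  tr0 <- simulate_tracks(layout, truth, class_effects = zero, seed = 15)
  g0 <- tr0$value[tr0$feature == "gene_density"]
  pv <- t.test(g0[cls == "active"], g0[cls == "HDF"])$p.value
  expect_gt(pv, 0.01)
})

test_that("variant rates follow the depletion factor and Poisson totals", {
  layout <- genome_layout(paste0("chr", 1:3), rep(1e7, 3), 4e4)
  truth <- simulate_truth(layout, seed = 17)
  hw <- 2e4
  dens <- 5e-4
  near_boundary <- function(v) {
    hit <- rep(FALSE, nrow(v$snps))
    for (ch in unique(v$snps$chrom)) {
      mids <- (truth$boundaries$start +
                 truth$boundaries$end)[truth$boundaries$chrom == ch] / 2
      sel <- v$snps$chrom == ch
      pos <- v$snps$pos[sel]
      nb <- rep(FALSE, length(pos))
      for (m in mids) nb <- nb | abs(pos - m) <= hw
      hit[sel] <- nb
    }
    hit
  }
  zone_bp <- function() {
    # total bp within hw of a boundary midpoint (non-overlapping zones here)
    2 * hw * nrow(truth$boundaries)
  }
  v1 <- simulate_variants(layout, truth$boundaries, dens, 1, hw, seed = 18)
  nb1 <- near_boundary(v1)
  rate_ratio1 <- (sum(nb1) / zone_bp()) /
    ((sum(!nb1)) / (sum(layout$length) - zone_bp()))
  expect_gt(rate_ratio1, 0.9); expect_lt(rate_ratio1, 1.1)
  v5 <- simulate_variants(layout, truth$boundaries, dens, 0.5, hw, seed = 19)
  nb5 <- near_boundary(v5)
  rate_ratio5 <- (sum(nb5) / zone_bp()) /
    ((sum(!nb5)) / (sum(layout$length) - zone_bp()))
  expect_gt(rate_ratio5, 0.4); expect_lt(rate_ratio5, 0.6)
  # total count within 3 SD of the Poisson expectation over effective bp
  expected <- dens * (sum(layout$length) - zone_bp()) + dens * 1 * zone_bp()
  expect_lt(abs(nrow(v1$snps) - expected), 3 * sqrt(expected))
})

test_that("synteny blocks tile the reference and localize breaks on demand", {
  layout <- small_layout(n_chrom = 2, length_bp = 2e7)
  truth <- simulate_truth(layout, seed = 21)
  syn <- simulate_synteny_blocks(layout, truth$domains, n_breaks = 60,
                                 break_boundary_fraction = 1, seed = 22)
  # blocks tile each chromosome without overlap
  for (ch in unique(syn$blocks$tname)) {
    b <- syn$blocks[syn$blocks$tname == ch, ]
    b <- b[order(b$tstart), ]
    expect_equal(b$tstart[-1], b$tend[-nrow(b)])
    expect_equal(min(b$tstart), 0)
    expect_equal(max(b$tend), 2e7)
  }
  # fraction 1: every break within one bin of a boundary
  bs <- bin_size(layout)
  near <- vapply(seq_len(nrow(syn$breaks)), function(i) {
    sel <- truth$boundaries$chrom == syn$breaks$chrom[i]
    mids <- (truth$boundaries$start[sel] + truth$boundaries$end[sel]) / 2
    any(abs(mids - syn$breaks$pos[i]) <= bs)
  }, logical(1))
  expect_true(all(near))
})

test_that("uniform breaks pass a KS test against the uniform law", {
  layout <- genome_layout("chr1", 4e7, 4e4)
  truth <- simulate_truth(layout, seed = 23)
  syn <- simulate_synteny_blocks(layout, truth$domains, n_breaks = 500,
                                 break_boundary_fraction = 0, seed = 24)
  ks <- suppressWarnings(
    ks.test(syn$breaks$pos / 4e7, "punif")
  )
  expect_gt(ks$p.value, 0.01)
})

test_that("null expression is unspecific; planted bins are tissue-specific", {
  layout <- genome_layout("chr1", 4e7, 4e4)  # 1000 bins
  e0 <- simulate_expression(layout, effect_log2fc = 0, specific_bins = 0,
                            seed = 25)
  be0 <- bin_cpm(e0$counts, e0$samples)
  tau0 <- tau_index(as.matrix(be0$tissue_cpm)[be0$testable, ])
  expect_lt(mean(tau0$tau, na.rm = TRUE), 0.2)
  e4 <- simulate_expression(layout, effect_log2fc = 4, specific_bins = 0.2,
                            seed = 26)
  be4 <- bin_cpm(e4$counts, e4$samples)
  tau4 <- tau_index(as.matrix(be4$tissue_cpm))
  expect_gt(mean(tau4$tau[e4$specific], na.rm = TRUE), 0.6)
  # library sizes vary at most twofold
  libs <- colSums(as.matrix(e0$counts[, e0$samples$sample]))
  expect_lt(max(libs) / min(libs), 2.2)
})

test_that("emitted files round-trip through the package readers", {
  layout <- small_layout(length_bp = 4e6)
  truth <- simulate_truth(layout, seed = 27)
  dir <- withr::local_tempdir()
  # BED round trip
  p <- file.path(dir, "domains.bed")
  write_bed(dplyr::rename(truth$domains, name = class), p)
  back <- read_bed(p)
  expect_equal(back$start, truth$domains$start)
  expect_equal(back$name, truth$domains$class)
  # bedGraph round trip (NA bins dropped on write)
  tr <- simulate_tracks(layout, truth, seed = 28)
  g <- tr[tr$feature == "gene_density", c("chrom", "start", "end", "value")]
  p2 <- file.path(dir, "track.bedGraph")
  write_bedgraph(g, p2)
  expect_equal(read_bedgraph(p2)$value, g$value)
  # BEDPE round trip
  p3 <- file.path(dir, "loops.bedpe")
  write_bedpe(truth$loops, p3)
  expect_equal(read_bedpe(p3)$start1, truth$loops$start1)
  # variants round trip
  v <- simulate_variants(layout, truth$boundaries, 1e-4, 0.8, 2e4, seed = 29)
  p4 <- file.path(dir, "variants.tsv")
  write_variants(v, p4)
  v2 <- read_variants(p4)
  expect_equal(v2$snps$pos, v$snps$pos)
  expect_equal(v2$deletions$end, v$deletions$end)
  # synteny blocks round trip
  syn <- simulate_synteny_blocks(layout, truth$domains, 10, 0.5, seed = 30)
  p5 <- file.path(dir, "blocks.tsv")
  write_synteny_blocks(syn$blocks, p5)
  expect_equal(read_synteny_blocks(p5)$tend, syn$blocks$tend)
  # expression round trip
  es <- simulate_expression(layout, seed = 31)
  p6 <- file.path(dir, "expr.tsv")
  write_expression(es$counts, p6)
  expect_equal(as.data.frame(read_expression(p6)),
               as.data.frame(es$counts))
})
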