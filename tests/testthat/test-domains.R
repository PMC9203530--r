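test_that("planted boundaries are recovered within one bin", {
  layout <- small_layout(length_bp = 8e6)
  pm <- planted_map(layout, seed = 11, fold = 2, depth = 100)
  bal <- balance_matrix(pm$map)
  dc <- call_domains(bal)
  n <- layout$n_bins[1]
  internal <- setdiff(unique(pm$truth$boundaries$bin), c(1, n))
  # planted boundaries come in edge pairs (end bin b, start bin b+1); count
  # a planted edge recovered if a call lands within one bin
  hit <- vapply(internal, function(b) {
    any(abs(dc$boundaries$bin - b) <= 1)
  }, logical(1))
  expect_equal(mean(hit), 1)
  # boundaries lie at bin edges; domains tile the chromosome (no gaps here)
  expect_true(all(dc$boundaries$start %% bin_size(layout) == 0))
  expect_equal(sum(dc$domains$end - dc$domains$start), 8e6)
})

test_that("a constant matrix yields one domain and no boundaries", {
  m <- matrix(1, 30, 30)
  dc <- call_domains(contact_matrix(m, "chr1", 4e4))
  expect_equal(nrow(dc$boundaries), 0)
  expect_equal(nrow(dc$domains), 1)
})

test_that("domain calls are invariant to global scaling", {
  layout <- small_layout(length_bp = 4e6)
  pm <- planted_map(layout, seed = 13, fold = 2, depth = 80)
  dc1 <- call_domains(pm$map)
  scaled <- contact_matrix(pm$map$counts * 17, "chr1", 4e4)
  dc2 <- call_domains(scaled)
  expect_equal(dc1$boundaries$bin, dc2$boundaries$bin)
})

test_that("masked runs split domains as gaps", {
  n <- 40
  d <- abs(outer(1:n, 1:n, "-"))
  m <- 100 / (d + 1)
  m[15:20, ] <- 0; m[, 15:20] <- 0  # 6-bin dead zone
  dc <- call_domains(contact_matrix(m, "chr1", 4e4), window_bins = 5)
  # no domain covers the dead zone
  gap_lo <- 14 * 4e4; gap_hi <- 20 * 4e4
  expect_true(all(dc$domains$end <= gap_lo | dc$domains$start >= gap_hi))
})

test_that("reciprocal overlap rule follows the stated arithmetic", {
  d <- function(s, e) tibble::tibble(chrom = "chr1", start = s, end = e)
  # overlap 50 of lengths 100: 50 < 80 -> not conserved
  res <- conserved_domains(d(0, 100), d(50, 150), reciprocal = 0.8)
  expect_equal(nrow(res$pairs), 0)
  # overlap 90 of lengths 100 and 95: 90 > 80 and 90 > 76 -> conserved
  res2 <- conserved_domains(d(0, 100), d(10, 105), reciprocal = 0.8)
  expect_equal(nrow(res2$pairs), 1)
  expect_equal(res2$shared_frac_a, 1)
  # identical sets
  set.seed(3)
  s <- sort(sample(1:100, 8)) * 1000
  many <- tibble::tibble(chrom = "chr1", start = s[1:4] * 10,
                         end = s[1:4] * 10 + 50000)
  res3 <- conserved_domains(many, many)
  expect_equal(res3$shared_frac_a, 1)
  expect_equal(res3$shared_frac_b, 1)
})

test_that("conserved_domains is symmetric in its arguments", {
  set.seed(8)
  mk <- function(seed) {
    set.seed(seed)
    starts <- cumsum(sample(4:10, 12, replace = TRUE)) * 4e4
    tibble::tibble(chrom = "chr1", start = dplyr::lag(starts, default = 0),
                   end = starts)
  }
  a <- mk(1); b <- mk(2)
  ab <- conserved_domains(a, b)
  ba <- conserved_domains(b, a)
  expect_equal(nrow(ab$pairs), nrow(ba$pairs))
  expect_equal(ab$shared_frac_a, ba$shared_frac_b)
})

test_that("boundary sharing uses a strict edge-to-edge gap rule", {
  bs <- 4e4
  b <- function(s) tibble::tibble(chrom = "chr1", start = s, end = s + bs)
  # 39,999 bp apart -> matched
  res <- shared_boundaries(b(0), b(bs + 39999), bs)
  expect_equal(res$shared_frac_a, 1)
  # 40,000 bp apart -> not matched
  res2 <- shared_boundaries(b(0), b(bs + 40000), bs)
  expect_equal(res2$shared_frac_a, 0)
  # overlapping -> matched; identical sets fully shared; empty vs nonempty 0
  expect_equal(shared_boundaries(b(0), b(2e4), bs)$shared_frac_a, 1)
  two <- dplyr::bind_rows(b(0), b(1e6))
  expect_equal(shared_boundaries(two, two, bs)$shared_frac_a, 1)
  empty <- b(0)[0, ]
  expect_equal(shared_boundaries(two, empty, bs)$shared_frac_a, 0)
})

test_that("shared_boundaries matches the same count in both directions", {
  set.seed(21)
  bs <- 4e4
  mk <- function() tibble::tibble(
    chrom = "chr1", start = sort(sample(0:200, 20)) * bs) |>
    dplyr::mutate(end = start + bs)
  a <- mk(); b <- mk()
  ab <- shared_boundaries(a, b, bs)
  ba <- shared_boundaries(b, a, bs)
  expect_equal(nrow(ab$pairs), nrow(ba$pairs))
})

test_that("coverage Jaccard equals interval arithmetic and brute force", {
  d <- function(s, e) tibble::tibble(chrom = "chr1", start = s, end = e)
  expect_equal(coverage_jaccard(d(0, 100), d(50, 150))$similarity, 1 / 3,
               tolerance = 1e-12)
  expect_equal(coverage_jaccard(d(0, 100), d(0, 100))$similarity, 1)
  expect_equal(coverage_jaccard(d(0, 100), d(200, 300))$similarity, 0)
  # brute force on random <= 10 kb toys
  set.seed(12)
  for (rep in 1:5) {
    a <- tibble::tibble(chrom = "chr1",
                        start = sort(sample(0:9000, 4)))
    a$end <- a$start + sample(100:800, 4)
    b <- tibble::tibble(chrom = "chr1",
                        start = sort(sample(0:9000, 4)))
    b$end <- b$start + sample(100:800, 4)
    expect_equal(coverage_jaccard(a, b)$similarity, jaccard_bp(a, b),
                 tolerance = 1e-12)
  }
})

classification_fixture <- function(seed = 31, effect = 2) {
  layout <- small_layout(length_bp = 1.2e7)
  truth <- simulate_truth(layout, seed = seed)
  eff <- default_class_effects()
  eff$shift <- eff$shift * effect / 2  # default shifts are 2 = 2 SD units?
  tracks <- simulate_tracks(layout, truth, seed = seed + 1)
  list(truth = truth,
       tracks = split(tracks[c("chrom", "start", "end", "value")],
                      tracks$feature))
}

test_that("three-class domain classification recovers planted classes", {
  fx <- classification_fixture()
  feats <- fx$tracks[c("gene_density", "ltr_density", "methylation",
                       "H3K4me3", "H3K9me2", "H3K27me3")]
  cls <- classify_domains(fx$truth$domains, feats)
  agreement <- mean(cls$domains$class == fx$truth$domains$class)
  expect_gte(agreement, 0.9)
  expect_s3_class(cls$tree, "hclust")
})

test_that("classification is invariant to rescaling one raw track", {
  fx <- classification_fixture(seed = 33)
  feats <- fx$tracks[c("gene_density", "ltr_density", "methylation",
                       "H3K4me3", "H3K9me2", "H3K27me3")]
  cls1 <- classify_domains(fx$truth$domains, feats)
  feats$gene_density$value <- feats$gene_density$value * 10
  cls2 <- classify_domains(fx$truth$domains, feats)
  expect_equal(cls1$domains$class, cls2$domains$class)
})

test_that("boundary profiles are flat on constant tracks and centered dips", {
  layout <- small_layout(length_bp = 8e6)
  truth <- simulate_truth(layout, seed = 41)
  bins <- layout_bins(layout)
  const <- dplyr::mutate(bins[c("chrom", "start", "end")], value = 3.5)
  prof <- boundary_profile(truth$boundaries, const, layout, flank_bp = 2e5)
  expect_true(all(abs(prof$mean - 3.5) < 1e-12))
  # indicator of boundary bins peaks at offset 0
  ind <- dplyr::mutate(
    bins[c("chrom", "start", "end")],
    value = as.numeric(paste0(chrom, ":", start) %in%
                         paste0(truth$boundaries$chrom, ":",
                                truth$boundaries$start)))
  prof2 <- boundary_profile(truth$boundaries, ind, layout, flank_bp = 2e5)
  expect_equal(prof2$mean[prof2$offset_bp == 0], 1)
  # planted dip of known depth is recovered within 2 SE
  set.seed(42)
  dip <- dplyr::mutate(
    bins[c("chrom", "start", "end")],
    value = 5 - 2 * ind$value + rnorm(nrow(bins), 0, 0.5))
  prof3 <- boundary_profile(truth$boundaries, dip, layout, flank_bp = 2e5)
  at0 <- prof3[prof3$offset_bp == 0, ]
  expect_lt(abs(at0$mean - 3), 2 * at0$se + 1e-9)
})
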