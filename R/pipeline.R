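#' Default pipeline configuration
#'
#' All thresholds used across the pipeline in one nested list, mirroring the
#' analysis parameters: 40-kb bins, 500-kb boundary flanks, 5-kb profile
#' step, 25-kb loop merge/share distance, 0.8 reciprocal domain overlap,
#' twofold expression classes, 0.25 heavy-methylation threshold, 20-Mb
#' long-range split, 100 permutations.
#'
#' @param seed Global seed (forked deterministically per stage).
#' @param n_chrom,chrom_length_bp,bin_size Demo genome shape (default 2
#'   chromosomes x 20 Mb at 40-kb bins).
#' @return A named list accepted by [run_pipeline()].
#' @export
default_config <- function(seed = 1L, n_chrom = 2, chrom_length_bp = 2e7,
                           bin_size = 4e4) {
  list(
    seed = as.integer(seed),
    layout = list(n_chrom = n_chrom, chrom_length_bp = chrom_length_bp,
                  bin_size = bin_size),
    contact = list(decay_exponent = 1, within_domain_fold = 2, loop_fold = 3,
                   mean_depth = 50, gap_fraction = 0.02),
    thresholds = list(
      flank_bp = 5e5, step_bp = 5e3, window_bp = 4e4,
      merge_dist = 25000, reciprocal = 0.8, fold = 2,
      heavy_threshold = 0.25, long_range_threshold = 2e7,
      n_perm = 100, window_bins = 5, min_drop = 0.1,
      n_rel_bins = 10, testable_cpm = 0.5, pseudocount = 0.25
    ),
    variants = list(background_density = 2e-3, depletion_factor = 0.5,
                    boundary_halfwidth = 2e4),
    synteny = list(n_breaks = 80, break_boundary_fraction = 0.5),
    expression = list(n_tissues = 5, n_reps = 3, specific_bins = 0.1,
                      effect_log2fc = 4)
  )
}

known_config_keys <- function() {
  names(default_config())
}

stage_seed <- function(seed, stage) {
  # deterministic per-stage fork of the global seed, kept below 2^31
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Run the full synthetic-data pipeline
#'
#' Generates a genome with planted truth, simulates the contact maps,
#' tracks, variants, synteny blocks and expression, then runs every analysis
#' stage and writes all interchange files plus a machine-readable
#' `summary.json` into `out_dir`. Deterministic given `config$seed`.
#'
#' @param config A configuration list from [default_config()] (unknown
#'   top-level keys are rejected).
#' @param out_dir Output directory (created if needed).
#' @return The summary list, invisibly; files are written under `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempdir()) {
  unknown <- setdiff(names(config), known_config_keys())
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  seed <- config$seed
  lay <- config$layout
  layout <- genome_layout(paste0("chr", seq_len(lay$n_chrom)),
                          rep(lay$chrom_length_bp, lay$n_chrom),
                          lay$bin_size)
  files <- list()
  emit <- function(name, writer, obj) {
    p <- file.path(out_dir, name)
    writer(obj, p)
    files[[name]] <<- name
    p
  }

  ## --- simulate -----------------------------------------------------------
  truth <- simulate_truth(layout, seed = stage_seed(seed, "truth"))
  emit("true_domains.bed", write_bed,
       dplyr::rename(truth$domains, name = "class"))
  emit("true_boundaries.bed", write_bed, truth$boundaries)
  emit("true_loops.bedpe", write_bedpe, truth$loops)
  tracks <- simulate_tracks(layout, truth, seed = stage_seed(seed, "tracks"))
  track_list <- split(tracks[c("chrom", "start", "end", "value")],
                      tracks$feature)
  for (f in names(track_list)) {
    emit(paste0("track_", f, ".bedGraph"), write_bedgraph, track_list[[f]])
  }
  maps <- lapply(layout$chrom, function(ch) {
    simulate_contact_map(
      layout, truth, chrom = ch,
      decay_exponent = config$contact$decay_exponent,
      within_domain_fold = config$contact$within_domain_fold,
      loop_fold = config$contact$loop_fold,
      mean_depth = config$contact$mean_depth,
      gap_fraction = config$contact$gap_fraction,
      seed = stage_seed(seed, paste0("map_", ch))
    )
  })
  names(maps) <- layout$chrom
  for (ch in layout$chrom) {
    emit(paste0("contacts_", ch, ".tsv"), write_contacts, maps[[ch]])
  }
  variants <- simulate_variants(
    layout, truth$boundaries,
    background_density = config$variants$background_density,
    depletion_factor = config$variants$depletion_factor,
    boundary_halfwidth = config$variants$boundary_halfwidth,
    seed = stage_seed(seed, "variants")
  )
  emit("variants.tsv", write_variants, variants)
  syn <- simulate_synteny_blocks(
    layout, truth$domains,
    n_breaks = config$synteny$n_breaks,
    break_boundary_fraction = config$synteny$break_boundary_fraction,
    seed = stage_seed(seed, "synteny")
  )
  emit("synteny_blocks.tsv", write_synteny_blocks, syn$blocks)
  expr <- simulate_expression(
    layout,
    n_tissues = config$expression$n_tissues,
    n_reps = config$expression$n_reps,
    specific_bins = config$expression$specific_bins,
    effect_log2fc = config$expression$effect_log2fc,
    seed = stage_seed(seed, "expression")
  )
  emit("expression.tsv", write_expression, expr$counts)

  ## --- contact statistics + compartments ----------------------------------
  gene_track <- track_list[["gene_density"]]
  ab_frac_a <- numeric(0)
  ratios <- numeric(length(maps))
  all_domains <- list(); all_boundaries <- list()
  for (k in seq_along(maps)) {
    ch <- layout$chrom[k]
    bal <- balance_matrix(maps[[k]])
    ratios[k] <- long_short_ratio(bal, th$long_range_threshold)
    oe <- observed_over_expected(bal)
    corr <- pearson_correlation(oe)
    gtrack <- gene_track$value[gene_track$chrom == ch]
    sub <- call_subcompartments(corr, gtrack, levels = 3)
    ab_frac_a <- c(ab_frac_a, mean(sub$rank > 4, na.rm = TRUE))
    dc <- call_domains(bal, window_bins = th$window_bins,
                       min_drop = th$min_drop)
    all_domains[[ch]] <- dc$domains
    all_boundaries[[ch]] <- dc$boundaries
  }
  domains <- dplyr::bind_rows(all_domains)
  boundaries <- dplyr::bind_rows(all_boundaries)
  emit("called_domains.bed", write_bed, domains)
  emit("called_boundaries.bed", write_bed,
       boundaries[c("chrom", "start", "end")])

  ## --- domain comparison + classification ---------------------------------
  cons <- conserved_domains(domains, truth$domains, th$reciprocal)
  shb <- shared_boundaries(boundaries, truth$boundaries, bin_size(layout))
  jac <- coverage_jaccard(domains, truth$domains)
  cls_tracks <- track_list[c("gene_density", "ltr_density", "methylation",
                             "H3K4me3", "H3K9me2", "H3K27me3")]
  classification <- classify_domains(truth$domains, cls_tracks)
  class_counts <- table(classification$domains$class)

  ## --- loops ---------------------------------------------------------------
  assoc <- loop_boundary_association(truth$loops, boundaries, layout,
                                     domains = domains,
                                     n_perm = th$n_perm,
                                     seed = stage_seed(seed, "loop_assoc"))

  ## --- variants / synteny --------------------------------------------------
  vprof <- boundary_variant_profile(
    variants$snps, truth$boundaries, layout,
    window = th$window_bp, step = th$step_bp, flank = th$flank_bp
  )
  readr::write_tsv(vprof, file.path(out_dir, "variant_profile.tsv"),
                   progress = FALSE)
  files[["variant_profile.tsv"]] <- "variant_profile.tsv"
  brk <- detect_synteny_breaks(syn$blocks)
  atrack <- alignable_track_from_blocks(syn$blocks, layout)
  enr <- break_boundary_enrichment(brk, truth$domains, atrack, layout,
                                   n_rel_bins = th$n_rel_bins,
                                   n_perm = th$n_perm,
                                   seed = stage_seed(seed, "break_enrich"))

  ## --- expression ----------------------------------------------------------
  be <- bin_cpm(expr$counts, expr$samples, testable_cpm = th$testable_cpm)
  tcpm <- as.matrix(be$tissue_cpm)
  taus <- tau_index(tcpm[be$testable, , drop = FALSE])
  fc <- fold_change_classes(tcpm[be$testable, 1], tcpm[be$testable, 2],
                            fold = th$fold, pseudocount = th$pseudocount)
  # conserved vs tissue-specific boundaries: shared = matched against truth
  matched <- shb$pairs$i
  bin_of_boundary <- boundaries$bin +
    c(0, cumsum(layout$n_bins))[match(boundaries$chrom, layout$chrom)]
  shared_bins <- bin_of_boundary[matched]
  specific_bins <- setdiff(bin_of_boundary, shared_bins)
  test_idx <- which(be$testable)
  grp_shared <- fc$abs_log2fc[test_idx %in% shared_bins]
  grp_specific <- fc$abs_log2fc[test_idx %in% specific_bins]
  expr_test <- if (length(grp_shared) >= 2 && length(grp_specific) >= 2) {
    conservation_expression_test(grp_shared, grp_specific)
  } else {
    NULL
  }

  ## --- summary -------------------------------------------------------------
  summary <- list(
    seed = seed,
    thresholds = th,
    n_bins = n_bins(layout),
    long_short_ratio = stats::setNames(as.list(round(ratios, 10)),
                                       layout$chrom),
    ab_fraction_a = round(mean(ab_frac_a), 10),
    n_domains_called = nrow(domains),
    n_boundaries_called = nrow(boundaries),
    domain_truth_shared_frac = round(cons$shared_frac_a, 10),
    boundary_truth_shared_frac = round(shb$shared_frac_a, 10),
    coverage_jaccard = round(jac$similarity, 10),
    domain_classes = as.list(class_counts),
    loop_anchor_fraction = round(assoc$anchor_fraction, 10),
    loop_expected_fraction = round(assoc$expected_fraction, 10),
    loop_fisher_p = signif(assoc$fisher_p, 10),
    loop_odds_ratio = round(assoc$odds_ratio, 10),
    variant_ratio_at_0 = round(vprof$ratio[vprof$offset_bp == 0], 10),
    variant_ratio_far = round(mean(
      vprof$ratio[abs(vprof$offset_bp) >= th$flank_bp * 0.8], na.rm = TRUE
    ), 10),
    n_breaks_detected = nrow(brk),
    break_terminal_z = round(enr$result$z, 10),
    break_terminal_p = round(enr$result$p, 10),
    n_testable_bins = sum(be$testable),
    median_tau = round(stats::median(taus$tau, na.rm = TRUE), 10),
    fc_classes = as.list(table(fc$class)),
    boundary_expression_test = if (!is.null(expr_test)) {
      list(median_shared = round(expr_test$median_shared, 10),
           median_specific = round(expr_test$median_specific, 10),
           p_value = signif(expr_test$p_value, 10))
    } else {
      NULL
    }
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files[["summary.json"]] <- "summary.json"
  write_manifest(files, seed, file.path(out_dir, "manifest.yaml"))
  invisible(summary)
}
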