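# End-to-end orchestration: simulate (or accept) inputs, call peaks, apply
# the filter chain, quantify, test, integrate. Deterministic given the
# seed; per-stage feature counts are reported as messages.

#' Pipeline run configuration
#'
#' Thresholds and knobs of the full analysis, with the study's defaults:
#' FDR-adjusted p < 0.05, fold enrichment > 1, consensus in >= 2
#' replicates, fold change >= 2.
#'
#' @param simulate A [sim_config()] describing the synthetic inputs.
#' @param q_max FDR threshold for peaks.
#' @param fe_min Fold-enrichment threshold (exclusive).
#' @param min_windows,merge_gap,lambda_floor Peak-caller settings
#'   (see [call_sample_peaks()] / [test_windows()]).
#' @param input_floor Floor on input coverage in [compute_fe()].
#' @param exon_overlap_frac Minimum exonic fraction in [filter_exonic()].
#' @param consensus_min Minimum supporting replicates for a consensus peak.
#' @param consensus_min_protein Minimum non-missing replicates for protein
#'   detection in a group.
#' @param fc_cut Fold-change threshold for differential calls.
#' @param alpha Significance threshold.
#' @param rna_use_adjusted Use BH-adjusted p for the RNA layer.
#' @param chrom_blacklist Chromosomes excluded before window testing.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = sim_config(),
                            q_max = 0.05, fe_min = 1,
                            min_windows = 2L, merge_gap = 1L,
                            lambda_floor = 0.5, input_floor = 0.5,
                            exon_overlap_frac = 0.5,
                            consensus_min = 2L, consensus_min_protein = 1L,
                            fc_cut = 2, alpha = 0.05,
                            rna_use_adjusted = TRUE,
                            chrom_blacklist = "chrM") {
  if (!inherits(simulate, "sim_config")) {
    abort("config field 'simulate' must be a sim_config")
  }
  check_scalar_number(q_max, "q_max", lower = 0, upper = 1)
  if (!identical(fe_min, Inf)) check_scalar_number(fe_min, "fe_min", lower = 0)
  check_scalar_number(min_windows, "min_windows", lower = 1, integerish = TRUE)
  check_scalar_number(merge_gap, "merge_gap", lower = 0, integerish = TRUE)
  check_scalar_number(lambda_floor, "lambda_floor", lower = 1e-12)
  check_scalar_number(input_floor, "input_floor", lower = 1e-12)
  check_scalar_number(exon_overlap_frac, "exon_overlap_frac", lower = 0, upper = 1)
  check_scalar_number(consensus_min, "consensus_min", lower = 1, integerish = TRUE)
  check_scalar_number(consensus_min_protein, "consensus_min_protein",
                      lower = 1, integerish = TRUE)
  check_scalar_number(fc_cut, "fc_cut", lower = 1)
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  if (!is.logical(rna_use_adjusted) || length(rna_use_adjusted) != 1L) {
    abort("config field 'rna_use_adjusted' must be TRUE or FALSE")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

stage_msg <- function(stage, ...) {
  inform(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full ac4C multi-omics analysis on synthetic inputs
#'
#' Executes simulate -> window tests -> per-sample peaks -> FE + filters ->
#' IgG calibration -> replicate consensus -> RNA-seq validation -> per-mRNA
#' FE/FC -> layer-wise differential calling -> cross-omics integration.
#' Deterministic given `config$simulate$seed`.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional directory; when given, the result bundle is
#'   written as TSV/BED/JSON plus a resolved config copy.
#' @return Object of class `ac4c_result`: a list with the annotation,
#'   per-sample and consensus peaks, the per-mRNA ac4C gene table, the
#'   protein and RNA tables, per-layer verdicts, the integration summaries
#'   and the ground truth.
#' @export
run_ac4c_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    abort("config must be a pipeline_config")
  }
  scfg <- config$simulate
  ref <- scfg$groups[1]
  case <- scfg$groups[2]

  sim <- simulate_multiomics(scfg)
  stage_msg("simulate", "%d genes, %d windows, %d true peaks",
            scfg$n_genes, nrow(sim$windows), nrow(sim$truth$true_peaks))

  ac_raw <- call_peaks_all(sim$assays$acRIP, sim$assays$input,
                           q_max = config$q_max,
                           min_windows = config$min_windows,
                           merge_gap = config$merge_gap,
                           lambda_floor = config$lambda_floor,
                           chrom_blacklist = config$chrom_blacklist)
  igg_peaks <- call_peaks_all(sim$assays$IgG, sim$assays$input,
                              q_max = config$q_max,
                              min_windows = config$min_windows,
                              merge_gap = config$merge_gap,
                              lambda_floor = config$lambda_floor,
                              chrom_blacklist = config$chrom_blacklist)
  stage_msg("callpeaks", "%d acRIP peaks, %d IgG peaks across samples",
            nrow(ac_raw), nrow(igg_peaks))

  ac <- peak_fe(ac_raw, sim$assays, input_floor = config$input_floor)
  ac <- filter_significant(ac, q_max = config$q_max, fe_min = config$fe_min)
  stage_msg("filter", "%d peaks pass q < %g and FE > %g",
            nrow(ac), config$q_max, config$fe_min)
  ac <- filter_exonic(ac, sim$annotation,
                      min_overlap_frac = config$exon_overlap_frac)
  stage_msg("filter", "%d peaks on protein-coding exons", nrow(ac))
  ac <- calibrate_igg(ac, igg_peaks)
  stage_msg("filter", "%d peaks after IgG calibration", nrow(ac))

  info <- tibble(sample = paste(rep(scfg$groups, each = scfg$n_replicates),
                                rep(seq_len(scfg$n_replicates), 2), sep = "_"))
  info$group <- sub("_[0-9]+$", "", info$sample)
  det <- rna_detected(sim$rna_counts)
  cons <- purrr::map_dfr(scfg$groups, function(g) {
    pk <- filter(ac, .data$sample %in% info$sample[info$group == g])
    cp <- consensus_peaks(pk, consensus_min = config$consensus_min)
    detected <- det$feature[det$group == g & det$detected]
    cp <- validate_by_rnaseq(cp, detected)
    mutate(cp, group = g, .before = 1)
  })
  stage_msg("consensus", "%d consensus peaks (%s: %d, %s: %d)",
            nrow(cons), ref, sum(cons$group == ref),
            case, sum(cons$group == case))

  # ---- per-mRNA ac4C quantification ----
  fe_by_group <- gene_fe(cons)
  fe_wide <- tidyr::pivot_wider(fe_by_group, names_from = "group",
                                values_from = "fe", values_fill = 0)
  for (g in scfg$groups) if (!g %in% names(fe_wide)) fe_wide[[g]] <- numeric(nrow(fe_wide))
  gene_tbl <- tibble(
    feature = fe_wide$gene_id,
    fe_ref = fe_wide[[ref]],
    fe_case = fe_wide[[case]]
  ) |>
    mutate(
      detected_g1 = .data$fe_ref > 0,
      detected_g2 = .data$fe_case > 0,
      fc = gene_fc(.data$fe_case, .data$fe_ref)
    )

  # overlay moderated test on log2(per-replicate gene FE + 1)
  overlay_genes <- gene_tbl$feature[gene_tbl$detected_g1 & gene_tbl$detected_g2]
  ac4c_fit <- NULL
  gene_tbl$p <- NA_real_
  gene_tbl$adj_p <- NA_real_
  if (length(overlay_genes) >= 2L) {
    rep_fe <- replicate_gene_fe(ac, overlay_genes, info$sample)
    vals <- log2(omics_values(omics_matrix(rep_fe, "intensity")) + 1)
    ac4c_fit <- moderated_t(vals, ref = ref, case = case)
    idx <- match(ac4c_fit$table$feature, gene_tbl$feature)
    gene_tbl$p[idx] <- ac4c_fit$table$p_value
    gene_tbl$adj_p[idx] <- ac4c_fit$table$adj_p
  }
  ac4c_verdicts <- call_de(gene_tbl, layer = "ac4c", alpha = config$alpha,
                           fc_cut = config$fc_cut)
  gene_tbl <- left_join(gene_tbl, ac4c_verdicts, by = "feature") |>
    mutate(class = venn_class_of(.data$detected_g1, .data$detected_g2))
  stage_msg("diffexp", "ac4c: %d up, %d down of %d modified mRNAs",
            sum(gene_tbl$verdict == "up"), sum(gene_tbl$verdict == "down"),
            nrow(gene_tbl))

  # ---- protein layer ----
  fot_tbl <- fot(sim$protein)
  pdet <- protein_detected(sim$protein, min_reps = config$consensus_min_protein)
  pdet_wide <- tidyr::pivot_wider(pdet, names_from = "group",
                                  values_from = "detected")
  prot_tbl <- tibble(
    feature = pdet_wide$feature,
    detected_g1 = pdet_wide[[ref]],
    detected_g2 = pdet_wide[[case]]
  ) |>
    filter(.data$detected_g1 | .data$detected_g2)
  prot_fit <- moderated_t(log2(omics_values(fot_tbl)), ref = ref, case = case)
  prot_tbl <- left_join(
    prot_tbl,
    select(prot_fit$table, "feature", "log2fc", "p_value", "adj_p"),
    by = "feature"
  ) |>
    mutate(fc = 2^.data$log2fc, p = .data$p_value) |>
    select(-"p_value")
  prot_verdicts <- call_de(prot_tbl, layer = "protein", alpha = config$alpha,
                           fc_cut = config$fc_cut)
  prot_tbl <- left_join(prot_tbl, prot_verdicts, by = "feature") |>
    mutate(class = venn_class_of(.data$detected_g1, .data$detected_g2))
  stage_msg("diffexp", "protein: %d up, %d down of %d detected",
            sum(prot_tbl$verdict == "up"), sum(prot_tbl$verdict == "down"),
            nrow(prot_tbl))

  # ---- RNA layer ----
  tpm_tbl <- tpm(sim$rna_counts, sim$annotation)
  cnt <- omics_values(sim$rna_counts)
  ref_cols <- info$sample[info$group == ref]
  case_cols <- info$sample[info$group == case]
  c1 <- rowSums(cnt[, ref_cols, drop = FALSE])
  c2 <- rowSums(cnt[, case_cols, drop = FALSE])
  n1 <- sum(c1); n2 <- sum(c2)
  rna_p <- exact_count_test(c1, c2, n1, n2)
  det_wide <- tidyr::pivot_wider(det, names_from = "group",
                                 values_from = "detected")
  rna_tbl <- tibble(
    feature = rownames(cnt),
    count_ref = c1, count_case = c2,
    detected_g1 = det_wide[[ref]][match(rownames(cnt), det_wide$feature)],
    detected_g2 = det_wide[[case]][match(rownames(cnt), det_wide$feature)],
    fc = ((c2 + 0.5) / n2) / ((c1 + 0.5) / n1),
    p = rna_p,
    adj_p = p.adjust(rna_p, method = "BH")
  )
  rna_verdicts <- call_de(rna_tbl, layer = "rna", alpha = config$alpha,
                          fc_cut = config$fc_cut,
                          use_adjusted = config$rna_use_adjusted)
  rna_tbl <- left_join(rna_tbl, rna_verdicts, by = "feature")
  stage_msg("diffexp", "rna: %d up, %d down of %d genes",
            sum(rna_tbl$verdict == "up"), sum(rna_tbl$verdict == "down"),
            nrow(rna_tbl))

  # ---- integration ----
  venn <- list(
    ac4c = venn_classify(gene_tbl$feature[gene_tbl$detected_g1],
                         gene_tbl$feature[gene_tbl$detected_g2]),
    protein = venn_classify(prot_tbl$feature[prot_tbl$detected_g1],
                            prot_tbl$feature[prot_tbl$detected_g2]),
    rna = venn_classify(rna_tbl$feature[rna_tbl$detected_g1],
                        rna_tbl$feature[rna_tbl$detected_g2])
  )
  crossed <- suppressMessages(cross_classify(prot_verdicts, ac4c_verdicts))
  ks <- if (length(overlay_genes) >= 2L) {
    ov <- filter(gene_tbl, .data$feature %in% overlay_genes)
    ks_compare(ov$fe_ref, ov$fe_case)
  }
  fe_fits <- purrr::map(setNames(scfg$groups, scfg$groups), function(g) {
    fes <- cons$fe[cons$group == g & cons$fe > 0]
    if (length(fes) >= 30) fit_fe_distribution(fes) else NULL
  })
  pca <- tryCatch(pca_top_mad(omics_values(fot_tbl), variance_floor = 1),
                  error = function(e) NULL)
  rho <- tryCatch(spearman_matrix(omics_values(fot_tbl)),
                  error = function(e) NULL)

  structure(
    list(
      config = config,
      annotation = sim$annotation,
      truth = sim$truth,
      sample_peaks = ac,
      igg_peaks = igg_peaks,
      consensus = cons,
      gene_table = gene_tbl,
      protein_table = prot_tbl,
      rna_table = rna_tbl,
      fits = list(ac4c = ac4c_fit, protein = prot_fit),
      integration = list(
        venn = venn,
        venn_counts = purrr::map(venn, venn_counts),
        cross = crossed,
        cross_counts = cross_counts(crossed),
        ks_overlay_fe = ks,
        fe_fits = fe_fits,
        pca = pca,
        spearman = rho
      )
    ),
    class = "ac4c_result"
  ) |>
    (\(res) {
      if (!is.null(outdir)) write_result_bundle(res, outdir)
      res
    })()
}

venn_class_of <- function(d1, d2) {
  factor(case_when(d1 & d2 ~ "Overlay", d1 ~ "AD absent", d2 ~ "AD unique"),
         levels = VENN_LEVELS)
}

#' @export
print.ac4c_result <- function(x, ...) {
  cat("ac4C multi-omics pipeline result\n")
  cat(sprintf("  consensus peaks: %d | ac4C mRNAs: %d | proteins: %d | genes: %d\n",
              nrow(x$consensus), nrow(x$gene_table), nrow(x$protein_table),
              nrow(x$rna_table)))
  cat(sprintf("  both-level differential genes: %d\n",
              x$integration$cross_counts$both_de))
  invisible(x)
}

#' Write a pipeline result bundle to disk
#'
#' Emits deterministic TSV/BED/JSON files under `outdir` (subdirectories
#' `peaks/`, `quant/`, `de/`, `integration/`) plus a resolved copy of the
#' configuration, so a fixed seed reproduces the bundle byte for byte.
#'
#' @param result An `ac4c_result`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_result_bundle <- function(result, outdir) {
  for (d in c("peaks", "quant", "de", "integration")) {
    dir.create(file.path(outdir, d), recursive = TRUE, showWarnings = FALSE)
  }
  num <- function(x) round(x, 6)
  w <- function(tbl, path) {
    dbl <- names(tbl)[vapply(tbl, is.double, logical(1))]
    tbl <- dplyr::mutate(tbl, across(all_of(dbl), num))
    readr::write_tsv(tbl, file.path(outdir, path), na = "", progress = FALSE)
  }
  w(arrange(result$sample_peaks, .data$sample, .data$chrom, .data$start),
    "peaks/sample_peaks.tsv")
  w(arrange(result$igg_peaks, .data$sample, .data$chrom, .data$start),
    "peaks/igg_peaks.tsv")
  w(arrange(result$consensus, .data$group, .data$chrom, .data$start),
    "peaks/consensus.tsv")
  for (g in unique(result$consensus$group)) {
    cg <- filter(result$consensus, .data$group == g)
    write_bed(tibble(chrom = cg$chrom, start = cg$start, end = cg$end,
                     name = cg$gene_id, X5 = num(cg$fe), X6 = cg$support,
                     X7 = cg$region),
              file.path(outdir, sprintf("peaks/consensus_%s.bed", g)))
  }
  w(arrange(result$gene_table, .data$feature), "quant/ac4c_gene_table.tsv")
  w(arrange(result$protein_table, .data$feature), "de/protein.tsv")
  w(arrange(result$rna_table, .data$feature), "de/rna.tsv")
  w(arrange(result$integration$cross, .data$feature),
    "integration/cross_classes.tsv")
  venn_tbl <- purrr::imap_dfr(result$integration$venn_counts, function(v, nm) {
    tibble(layer = nm, class = names(v), count = as.integer(v))
  })
  w(venn_tbl, "integration/venn_counts.tsv")
  summ <- list(
    cross_groups = as.list(result$integration$cross_counts$groups),
    both_de = result$integration$cross_counts$both_de,
    ks_overlay_fe = result$integration$ks_overlay_fe,
    fe_fits = purrr::map(result$integration$fe_fits, function(f) {
      if (is.null(f)) NULL else f[c("area", "mean", "sd", "rss", "n")]
    })
  )
  jsonlite::write_json(summ, file.path(outdir, "integration/summary.json"),
                       auto_unbox = TRUE, digits = 6, pretty = TRUE,
                       na = "null")
  cfg <- result$config
  cfg$simulate <- unclass(cfg$simulate)
  yaml::write_yaml(unclass(cfg), file.path(outdir, "config.yaml"))
  invisible(outdir)
}

#' Recovery of planted truth from a pipeline result
#'
#' Compares the result against the simulator's ground truth: the fraction
#' of planted peaks recovered as validated consensus peaks (per group), the
#' fraction of null gene/group pairs acquiring a false consensus peak, and
#' sensitivity / realized FDR of the overlay protein test.
#'
#' @param result An `ac4c_result` from a synthetic run.
#' @return List with `peak_sensitivity`, `false_consensus_rate`,
#'   `protein_sensitivity`, `protein_fdr`.
#' @export
evaluate_recovery <- function(result) {
  truth <- result$truth
  groups <- truth$groups
  tp <- truth$true_peaks
  pairs <- bind_rows(
    mutate(tp[tp$group == "both", ], group = groups[1]),
    mutate(tp[tp$group == "both", ], group = groups[2]),
    tp[tp$group != "both", ]
  )
  recovered <- purrr::pmap_lgl(
    pairs[c("chrom", "start", "end", "group")],
    function(chrom, start, end, group) {
      cg <- result$consensus[result$consensus$group == group, ]
      any(cg$chrom == chrom & cg$start < end & cg$end > start)
    }
  )
  genes <- unique(result$rna_table$feature)
  null_pairs <- tidyr::expand_grid(gene_id = genes, group = groups) |>
    anti_join(pairs[c("gene_id", "group")], by = c("gene_id", "group"))
  false_hit <- semi_join(null_pairs, result$consensus[c("gene_id", "group")],
                         by = c("gene_id", "group"))
  prot <- left_join(result$protein_table, truth$true_protein_lfc,
                    by = "feature")
  ov <- prot[prot$basis == "overlay-test" & !is.na(prot$lfc), ]
  true_de <- ov$lfc != 0
  called <- ov$verdict != "ns"
  list(
    peak_sensitivity = mean(recovered),
    false_consensus_rate = nrow(false_hit) / max(nrow(null_pairs), 1),
    protein_sensitivity = if (any(true_de)) mean(called[true_de]) else NA_real_,
    protein_fdr = if (any(called)) mean(!true_de[called]) else 0
  )
}
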