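test_that("minimal annotation has one transcript, one exon, three segments", {
  ann <- simulate_annotation(sim_config(n_genes = 1, exons_per_gene = 1))
  expect_equal(sum(ann$feature == "transcript"), 1L)
  expect_equal(sum(ann$feature == "exon"), 1L)
  expect_equal(sum(ann$feature %in%
                     c("five_prime_utr", "CDS", "three_prime_utr")), 3L)
})

test_that("segment lengths are conserved across gene structures", {
  for (cfg in list(sim_config(n_genes = 5, exons_per_gene = 1),
                   sim_config(n_genes = 5, exons_per_gene = 3),
                   sim_config(n_genes = 4, exons_per_gene = 5,
                              exon_windows = 3, utr_windows = 2))) {
    ann <- simulate_annotation(cfg)
    for (t in unique(na.omit(ann$transcript_id))) {
      ex <- ann[ann$feature == "exon" & ann$transcript_id %in% t, ]
      seg <- ann[ann$feature %in% c("five_prime_utr", "CDS", "three_prime_utr") &
                   ann$transcript_id %in% t, ]
      expect_equal(sum(seg$end - seg$start), sum(ex$end - ex$start))
    }
  }
})

test_that("fixed seed gives identical outputs on rerun", {
  cfg <- sim_config(n_genes = 50, seed = 7)
  a <- simulate_multiomics(cfg)
  b <- simulate_multiomics(cfg)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$assays, b$assays)
  expect_identical(a$rna_counts, b$rna_counts)
  expect_identical(a$protein, b$protein)
  expect_identical(a$truth, b$truth)
})

test_that("planted enrichment is recovered in the coverage means", {
  # null effect: IP/input ratio at peak windows ~ 1
  cfg0 <- sim_config(n_genes = 150, enrichment_effect = 1, seed = 5,
                     igg_peak_rate = 0)
  sim0 <- simulate_rip_coverage(cfg0, simulate_annotation(cfg0))
  peak_keys <- with(sim0$truth$true_peaks,
                    unlist(purrr::map2(start, end, function(s, e) {
                      region_key("chrS", seq(s, e - 50, by = 50),
                                 seq(s, e - 50, by = 50) + 50)
                    })))
  idx <- sim0$assays$acRIP$feature %in% peak_keys
  smp <- setdiff(names(sim0$assays$acRIP), "feature")
  ratio0 <- sum(as.matrix(sim0$assays$acRIP[idx, smp])) /
    sum(as.matrix(sim0$assays$input[idx, smp]))
  expect_lt(abs(ratio0 - 1), 0.1)

  # 8x effect: pooled ratio within +-10% of 8 at ~10k peak-window draws
  cfg8 <- sim_config(n_genes = 600, enrichment_effect = 8, seed = 5,
                     peak_fraction = 0.5, exclusive_fraction = 0,
                     igg_peak_rate = 0)
  sim8 <- simulate_rip_coverage(cfg8, simulate_annotation(cfg8))
  peak_keys <- with(sim8$truth$true_peaks,
                    unlist(purrr::map2(start, end, function(s, e) {
                      region_key("chrS", seq(s, e - 50, by = 50),
                                 seq(s, e - 50, by = 50) + 50)
                    })))
  idx <- sim8$assays$acRIP$feature %in% peak_keys
  smp <- setdiff(names(sim8$assays$acRIP), "feature")
  ratio8 <- sum(as.matrix(sim8$assays$acRIP[idx, smp])) /
    sum(as.matrix(sim8$assays$input[idx, smp]))
  expect_lt(abs(ratio8 - 8), 0.8)
})

test_that("simulated counts match negative-binomial moments", {
  cfg <- sim_config(n_genes = 400, peak_fraction = 0, igg_peak_rate = 0,
                    background_mean = 20, nb_dispersion = 0.01, seed = 3)
  sim <- simulate_rip_coverage(cfg, simulate_annotation(cfg))
  x <- as.vector(as.matrix(sim$assays$input[-1]))  # ~1e5 null draws
  mu <- 20; v <- mu + 0.01 * mu^2
  expect_lt(abs(mean(x) - mu), 3 * sqrt(v / length(x)))
  expect_lt(abs(var(x) - v) / v, 0.05)
})

test_that("protein layer plants fold changes, exclusives and missingness", {
  cfg <- sim_config(n_genes = 100, protein_de_fraction = 1,
                    protein_lfc = 2, protein_down_fraction = 0,
                    protein_sigma = 0.2, exclusive_fraction = 0, seed = 9)
  sim <- simulate_multiomics(cfg)
  expect_false(anyNA(as.matrix(sim$protein[-1])))  # no exclusives, no missing
  lg <- log2(omics_values(sim$protein))
  est <- rowMeans(lg[, 4:6]) - rowMeans(lg[, 1:3])
  expect_lt(abs(mean(est) - 2), 0.15)  # direct normal-sampling oracle

  cfg0 <- sim_config(n_genes = 200, protein_de_fraction = 0,
                     exclusive_fraction = 0, seed = 9)
  sim0 <- simulate_multiomics(cfg0)
  lg0 <- log2(omics_values(sim0$protein))
  expect_lt(abs(mean(rowMeans(lg0[, 4:6]) - rowMeans(lg0[, 1:3]))), 0.05)

  cfgx <- sim_config(n_genes = 200, exclusive_fraction = 0.3, seed = 9)
  simx <- simulate_multiomics(cfgx)
  det <- simx$truth$true_protein_detection
  m <- omics_values(simx$protein)
  # missingness pattern agrees with the planted detection truth
  expect_identical(unname(rowSums(is.na(m[, 1:3])) == 0), det$detected_g1)
  expect_identical(unname(rowSums(is.na(m[, 4:6])) == 0), det$detected_g2)
})

test_that("ground truth is reachable from the outputs and round-trips", {
  sim <- simulate_multiomics(tiny_sim_config())
  tp <- sim$truth$true_peaks
  exons <- sim$annotation[sim$annotation$feature == "exon", ]
  for (i in seq_len(nrow(tp))) {  # every planted peak inside its gene's exons
    ex <- exons[exons$gene_id == tp$gene_id[i], ]
    expect_true(any(ex$start <= tp$start[i] & ex$end >= tp$end[i]))
  }
  expect_true(all(tp$gene_id %in% sim$rna_counts$feature))
  expect_true(all(sim$truth$true_protein_lfc$feature %in% sim$protein$feature))

  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$true_peaks, sim$truth$true_peaks)
  expect_equal(back$true_protein_lfc, sim$truth$true_protein_lfc)
})

test_that("planted detection patterns have exact component counts", {
  pat <- simulate_detection_pattern(n_ref_only = 7, n_overlay = 20,
                                    n_case_only = 5, overlay_up = 3,
                                    overlay_down = 4)
  expect_equal(nrow(pat), 32L)
  expect_equal(sum(pat$detected_g1 & !pat$detected_g2), 7L)
  expect_equal(sum(pat$detected_g1 & pat$detected_g2), 20L)
  expect_equal(sum(!pat$detected_g1 & pat$detected_g2), 5L)
  ov <- pat[pat$detected_g1 & pat$detected_g2, ]
  expect_equal(sum(ov$fc >= 2 & ov$adj_p < 0.05), 3L)
  expect_equal(sum(ov$fc <= 0.5 & ov$adj_p < 0.05), 4L)
  expect_error(simulate_detection_pattern(1, 2, 1, overlay_up = 2,
                                          overlay_down = 1),
               "exceeds")
})

test_that("invalid configuration errors name the offending field", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(peak_fraction = 1.5), "peak_fraction")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(groups = c("WT", "WT")), "groups")
})
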