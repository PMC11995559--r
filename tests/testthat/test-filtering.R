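test_that("fold enrichment follows the (acRIP - IgG) / Input formula", {
  expect_equal(compute_fe(30, 6, 8), 3)
  expect_equal(compute_fe(5, 5, 8), 0)          # acRIP == IgG: no enrichment
  expect_equal(compute_fe(5, 1, 0, input_floor = 0.5), 8)
  expect_error(compute_fe(1, 1, 1, input_floor = 0), "input_floor")
  # randomized agreement with plain arithmetic
  set.seed(2)
  a <- runif(50, 0, 50); g <- runif(50, 0, 10); i <- runif(50, 0, 20)
  expect_equal(compute_fe(a, g, i), (a - g) / pmax(i, 0.5), tolerance = 1e-12)
})

test_that("exon filter keeps coding peaks and classifies regions", {
  ann <- toy_annotation()
  inside_cds <- toy_peak(200, 300)        # fully inside a CDS exon of gA
  intergenic <- toy_peak(650, 750)
  straddle <- toy_peak(220, 320)          # 80 of 100 bp exonic
  mostly_out <- toy_peak(260, 360)        # 40 of 100 bp exonic -> dropped
  noncoding <- toy_peak(850, 950)         # inside gB exon but lincRNA
  out <- filter_exonic(dplyr::bind_rows(inside_cds, intergenic, straddle,
                                        mostly_out, noncoding),
                       ann)
  expect_equal(out$start, c(200L, 220L))
  expect_equal(out$transcript_id, c("tA", "tA"))
  expect_equal(out$gene_id, c("gA", "gA"))
  expect_equal(out$region, c("CDS", "CDS"))

  utr5 <- filter_exonic(toy_peak(100, 200), ann)   # summit window in 5'UTR
  expect_equal(utr5$region, "5'UTR")
  utr3 <- dplyr::mutate(toy_peak(500, 600), summit_start = 550L,
                        summit_end = 600L)
  expect_equal(filter_exonic(utr3, ann)$region, "3'UTR")
})

test_that("IgG calibration removes any same-sample coordinate overlap", {
  ac <- dplyr::bind_rows(toy_peak(100, 200, "WT_1"),
                         toy_peak(100, 200, "WT_2"),
                         toy_peak(400, 500, "WT_1"))
  igg <- dplyr::bind_rows(toy_peak(150, 160, "WT_1"),
                          toy_peak(200, 300, "WT_2"))
  out <- calibrate_igg(ac, igg)
  # WT_1 [100,200) overlaps IgG [150,160): removed; WT_2 [100,200) vs
  # [200,300): half-open, no overlap, retained
  expect_equal(nrow(out), 2L)
  expect_true(all(out$start[out$sample == "WT_1"] == 400))
  expect_true(any(out$sample == "WT_2" & out$start == 100))
})

test_that("no retained acRIP peak overlaps an IgG peak after calibration", {
  res <- tiny_result()
  for (s in unique(res$sample_peaks$sample)) {
    ac <- res$sample_peaks[res$sample_peaks$sample == s, ]
    ig <- res$igg_peaks[res$igg_peaks$sample == s, ]
    if (nrow(ac) == 0L || nrow(ig) == 0L) next
    for (i in seq_len(nrow(ac))) {
      expect_false(any(ig$chrom == ac$chrom[i] & ig$start < ac$end[i] &
                         ig$end > ac$start[i]))
    }
  }
})

test_that("consensus keeps clusters supported by enough replicates", {
  two_of_three <- dplyr::bind_rows(toy_peak(100, 200, "WT_1", fe = 2),
                                   toy_peak(150, 250, "WT_3", fe = 4))
  out <- consensus_peaks(dplyr::mutate(two_of_three, transcript_id = "tA",
                                       gene_id = "gA", region = "CDS"))
  expect_equal(nrow(out), 1L)
  expect_equal(out$support, 2L)
  expect_equal(out$start, 100L)
  expect_equal(out$end, 250L)
  expect_equal(out$fe, 3)  # mean of contributing sample FEs

  single <- dplyr::mutate(toy_peak(100, 200, "WT_1"), transcript_id = "tA",
                          gene_id = "gA", region = "CDS")
  expect_equal(nrow(consensus_peaks(single)), 0L)
})

test_that("single-linkage chains cluster transitively", {
  # A overlaps B, B overlaps C, A does not overlap C -> one cluster
  chain <- dplyr::bind_rows(toy_peak(0, 100, "WT_1"),
                            toy_peak(80, 220, "WT_2"),
                            toy_peak(200, 300, "WT_3")) |>
    dplyr::mutate(transcript_id = "tA", gene_id = "gA", region = "CDS")
  out <- consensus_peaks(chain)
  expect_equal(nrow(out), 1L)
  expect_equal(out$support, 3L)
  expect_equal(c(out$start, out$end), c(0L, 300L))

  # brute-force oracle: union-find over all pairwise overlaps
  brute_clusters <- function(pk) {
    parent <- seq_len(nrow(pk))
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(nrow(pk))) for (j in seq_len(nrow(pk))) {
      if (pk$start[i] < pk$end[j] && pk$end[i] > pk$start[j]) {
        parent[find(i)] <- find(j)
      }
    }
    length(unique(vapply(seq_len(nrow(pk)), find, integer(1))))
  }
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    st <- as.integer(sort(sample(0:40, n)) * 50L)
    pk <- toy_peak(st, st + sample(c(100L, 150L, 200L), n, replace = TRUE),
                   sample = paste0("WT_", sample(1:3, n, replace = TRUE))) |>
      dplyr::mutate(transcript_id = "tA", gene_id = "gA", region = "CDS")
    expect_equal(nrow(consensus_peaks(pk, consensus_min = 1)),
                 brute_clusters(pk))
  }
})

test_that("RNA-seq validation keeps only detected host genes", {
  cons <- tibble::tibble(gene_id = c("gA", "gB"), fe = c(2, 3))
  expect_equal(validate_by_rnaseq(cons, "gA")$gene_id, "gA")
  expect_equal(nrow(validate_by_rnaseq(cons, character())), 0L)
})

test_that("the filter chain is order-stable", {
  res <- tiny_result()
  cfg <- res$config
  sim <- simulate_multiomics(cfg$simulate)
  raw <- call_peaks_all(sim$assays$acRIP, sim$assays$input)
  igg <- call_peaks_all(sim$assays$IgG, sim$assays$input)
  raw <- peak_fe(raw, sim$assays)
  f_sig <- function(p) filter_significant(p)
  f_ex <- function(p) filter_exonic(p, sim$annotation)
  f_igg <- function(p) calibrate_igg(p, igg)
  orders <- list(c("f_sig", "f_ex", "f_igg"), c("f_igg", "f_sig", "f_ex"),
                 c("f_ex", "f_igg", "f_sig"))
  results <- lapply(orders, function(o) {
    p <- raw
    for (f in o) p <- get(f)(p)
    dplyr::arrange(p, sample, chrom, start)[
      c("sample", "chrom", "start", "end", "fe")]
  })
  expect_equal(results[[1]], results[[2]])
  expect_equal(results[[1]], results[[3]])
})

test_that("peaks planted in the CDS are all classified CDS", {
  res <- tiny_result()
  expect_true(all(res$consensus$region == "CDS"))
})
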