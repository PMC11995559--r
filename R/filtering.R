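# The reliability filter chain applied to per-sample acRIP peaks:
# fold-enrichment computation and thresholds, restriction to protein-coding
# exons, IgG calibration, replicate consensus, and RNA-seq validation.
# Overlap is always >= 1 bp on half-open intervals; strand is ignored.

#' Per-peak fold enrichment
#'
#' The study's per-peak statistic: the IgG-corrected acRIP coverage divided
#' by the input coverage, `FE = (acRIP - IgG) / Input`, with the input
#' floored at `input_floor` to avoid division by zero. All three coverages
#' must be depth-normalized means over the same interval for the same
#' biological sample. FE can be <= 0 (no specific enrichment); such peaks
#' are removed by the `FE > 1` filter downstream.
#'
#' @param acrip,igg,input Depth-normalized mean coverages (vectors recycle).
#' @param input_floor Positive floor applied to the input coverage.
#' @return Numeric vector of fold enrichments.
#' @examples
#' compute_fe(30, 6, 8)            # 3
#' compute_fe(5, 1, 0, input_floor = 0.5)  # 8
#' @export
compute_fe <- function(acrip, igg, input, input_floor = 0.5) {
  check_scalar_number(input_floor, "input_floor", lower = 1e-12)
  (acrip - igg) / pmax(input, input_floor)
}

# mean depth-normalized (counts-per-million) coverage of each peak in one
# assay matrix, for one sample
mean_cpm_over <- function(peaks, assay_tbl, sample) {
  reg <- parse_region(assay_tbl$feature)
  cpm <- assay_tbl[[sample]] / sum(assay_tbl[[sample]]) * 1e6
  ov <- interval_overlaps(peaks[c("chrom", "start", "end")], reg)
  out <- rep(NA_real_, nrow(peaks))
  if (nrow(ov) > 0L) {
    agg <- tibble(q = ov$q, v = cpm[ov$s]) |>
      group_by(.data$q) |>
      summarise(v = mean(.data$v), .groups = "drop")
    out[agg$q] <- agg$v
  }
  out
}

#' Attach assay coverages and fold enrichment to per-sample peaks
#'
#' For each peak, computes the mean counts-per-million coverage over the
#' peak interval in the acRIP, IgG and input matrices of the same sample,
#' then the fold enrichment via [compute_fe()].
#'
#' @param peaks Per-sample peak tibble (with `sample`, `chrom`, `start`,
#'   `end`).
#' @param assays Named list of count `omics_tbl`s: `acRIP`, `IgG`, `input`.
#' @param input_floor Passed to [compute_fe()].
#' @return `peaks` with added columns `acrip_cov`, `igg_cov`, `input_cov`,
#'   `fe`.
#' @export
peak_fe <- function(peaks, assays, input_floor = 0.5) {
  if (nrow(peaks) == 0L) {
    return(mutate(peaks, acrip_cov = double(), igg_cov = double(),
                  input_cov = double(), fe = double()))
  }
  purrr::map_dfr(split(peaks, peaks$sample), function(pk) {
    s <- pk$sample[1]
    pk$acrip_cov <- mean_cpm_over(pk, assays$acRIP, s)
    pk$igg_cov <- mean_cpm_over(pk, assays$IgG, s)
    pk$input_cov <- mean_cpm_over(pk, assays$input, s)
    pk$fe <- compute_fe(pk$acrip_cov, pk$igg_cov, pk$input_cov,
                        input_floor = input_floor)
    pk
  }) |>
    arrange(.data$sample, .data$chrom, .data$start)
}

#' Apply the significance and fold-enrichment thresholds
#'
#' Retains peaks with FDR-adjusted p below `q_max` and fold enrichment
#' above `fe_min` (the study's `adj. p < 0.05` and `FE > 1`).
#'
#' @param peaks Peak tibble with `peak_q` and `fe` columns.
#' @param q_max,fe_min Thresholds.
#' @return Filtered peak tibble.
#' @export
filter_significant <- function(peaks, q_max = 0.05, fe_min = 1) {
  filter(peaks, .data$peak_q < q_max, .data$fe > fe_min)
}

#' Restrict peaks to protein-coding exons and assign host transcripts
#'
#' A peak is retained if at least `min_overlap_frac` of its length overlaps
#' the exons of a protein-coding transcript. The host transcript is the one
#' with maximal exonic overlap (ties to the lexicographically smallest id);
#' the region class (5'UTR / CDS / 3'UTR) is assigned by the position of
#' the peak summit within the host transcript's segments (falling back to
#' whole-peak overlap if the summit window touches no segment).
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `summit_start`,
#'   `summit_end`).
#' @param ann An `ac4c_annotation`.
#' @param min_overlap_frac Minimum exonic fraction of the peak length.
#' @return Filtered peaks with added `transcript_id`, `gene_id`,
#'   `region` columns.
#' @export
filter_exonic <- function(peaks, ann, min_overlap_frac = 0.5) {
  check_scalar_number(min_overlap_frac, "min_overlap_frac", lower = 0, upper = 1)
  if (nrow(peaks) == 0L) {
    return(mutate(peaks, transcript_id = character(), gene_id = character(),
                  region = character()))
  }
  coding_tx <- ann |>
    filter(.data$feature == "transcript", .data$biotype == "protein_coding") |>
    pull("transcript_id")
  exons <- filter(ann, .data$feature == "exon",
                  .data$transcript_id %in% coding_tx)
  ov <- interval_overlaps(peaks[c("chrom", "start", "end")],
                          exons[c("chrom", "start", "end")])
  ov$transcript_id <- exons$transcript_id[ov$s]
  per_tx <- ov |>
    group_by(.data$q, .data$transcript_id) |>
    summarise(width = sum(.data$width), .groups = "drop") |>
    arrange(.data$q, dplyr::desc(.data$width), .data$transcript_id) |>
    group_by(.data$q) |>
    slice(1) |>
    ungroup()
  host <- rep(NA_character_, nrow(peaks))
  host_w <- rep(0L, nrow(peaks))
  host[per_tx$q] <- per_tx$transcript_id
  host_w[per_tx$q] <- per_tx$width
  keep <- !is.na(host) & host_w >= min_overlap_frac * (peaks$end - peaks$start)
  out <- peaks[keep, , drop = FALSE]
  out$transcript_id <- host[keep]
  tx2gene <- ann |>
    filter(.data$feature == "transcript") |>
    distinct(.data$transcript_id, .data$gene_id)
  out <- left_join(out, tx2gene, by = "transcript_id")
  out$region <- assign_region(out, ann)
  out
}

REGION_LABELS <- c(five_prime_utr = "5'UTR", CDS = "CDS",
                   three_prime_utr = "3'UTR")

# region class by maximal segment overlap of the summit window (fallback:
# the whole peak), within the host transcript
assign_region <- function(peaks, ann) {
  if (nrow(peaks) == 0L) return(character())
  segs <- filter(ann, .data$feature %in% names(REGION_LABELS))
  pick <- function(iv, tx) {
    s <- filter(segs, .data$transcript_id == tx)
    ov <- interval_overlaps(iv, s[c("chrom", "start", "end")])
    if (nrow(ov) == 0L) return(NA_character_)
    ov <- arrange(ov, dplyr::desc(.data$width), .data$s)
    REGION_LABELS[[s$feature[ov$s[1]]]]
  }
  vapply(seq_len(nrow(peaks)), function(i) {
    summit <- tibble(chrom = peaks$chrom[i], start = peaks$summit_start[i],
                     end = peaks$summit_end[i])
    r <- pick(summit, peaks$transcript_id[i])
    if (is.na(r)) {
      r <- pick(peaks[i, c("chrom", "start", "end")], peaks$transcript_id[i])
    }
    r
  }, character(1))
}

#' Remove acRIP peaks overlapping same-sample IgG peaks
#'
#' The IgG calibration step: an acRIP peak is excluded if it overlaps
#' (>= 1 bp) any IgG peak called in the same sample, so that non-specific
#' antibody binding does not masquerade as ac4C signal.
#'
#' @param ac_peaks acRIP peak tibble with a `sample` column.
#' @param igg_peaks IgG peak tibble with a `sample` column (called with the
#'   same caller).
#' @return `ac_peaks` without IgG-overlapping rows.
#' @export
calibrate_igg <- function(ac_peaks, igg_peaks) {
  if (nrow(ac_peaks) == 0L || nrow(igg_peaks) == 0L) return(ac_peaks)
  drop <- logical(nrow(ac_peaks))
  for (s in unique(ac_peaks$sample)) {
    ai <- which(ac_peaks$sample == s)
    ig <- filter(igg_peaks, .data$sample == s)
    if (nrow(ig) == 0L) next
    ov <- interval_overlaps(ac_peaks[ai, c("chrom", "start", "end")],
                            ig[c("chrom", "start", "end")])
    drop[ai[unique(ov$q)]] <- TRUE
  }
  ac_peaks[!drop, , drop = FALSE]
}

#' Replicate-consensus peaks for one group
#'
#' Clusters a group's per-sample peaks by coordinate overlap (single
#' linkage, >= 1 bp) and keeps clusters supported by at least
#' `consensus_min` distinct replicates. The consensus interval is the union
#' of the contributing intervals; the group fold enrichment is the
#' arithmetic mean of the contributing sample FEs; the host transcript and
#' region are the most common among contributors (ties to the smallest id /
#' 5'UTR < CDS < 3'UTR order).
#'
#' @param sample_peaks Calibrated per-sample peaks of one group, with
#'   `sample`, `fe`, `transcript_id`, `gene_id`, `region` columns.
#' @param consensus_min Minimum number of supporting replicates.
#' @return Tibble of consensus peaks: `chrom`, `start`, `end`, `support`,
#'   `fe`, `transcript_id`, `gene_id`, `region`, `samples`.
#' @export
consensus_peaks <- function(sample_peaks, consensus_min = 2L) {
  check_scalar_number(consensus_min, "consensus_min", lower = 1,
                      integerish = TRUE)
  empty <- tibble(
    chrom = character(), start = integer(), end = integer(),
    support = integer(), fe = double(), transcript_id = character(),
    gene_id = character(), region = character(), samples = character()
  )
  if (nrow(sample_peaks) == 0L) return(empty)
  pk <- arrange(sample_peaks, .data$chrom, .data$start, .data$end)
  # single-linkage interval clustering: a new cluster starts whenever the
  # next peak does not overlap the running maximum end
  pk <- pk |>
    group_by(.data$chrom) |>
    mutate(maxend = cummax(dplyr::lag(.data$end, default = dplyr::first(.data$end))),
           cluster = cumsum(dplyr::row_number() > 1 & .data$start >= .data$maxend)) |>
    ungroup()
  mode_of <- function(x, order_levels = NULL) {
    tab <- sort(table(x), decreasing = TRUE)
    cand <- names(tab)[tab == tab[1]]
    if (!is.null(order_levels)) {
      cand <- cand[order(match(cand, order_levels))]
    } else {
      cand <- sort(cand)
    }
    cand[1]
  }
  out <- pk |>
    group_by(.data$chrom, .data$cluster) |>
    summarise(
      start = min(.data$start), end = max(.data$end),
      support = n_distinct(.data$sample),
      fe = mean(.data$fe),
      transcript_id = mode_of(.data$transcript_id),
      gene_id = mode_of(.data$gene_id),
      region = mode_of(.data$region, unname(REGION_LABELS)),
      samples = paste(sort(unique(.data$sample)), collapse = ","),
      .groups = "drop"
    ) |>
    filter(.data$support >= consensus_min) |>
    select(-"cluster") |>
    arrange(.data$chrom, .data$start)
  if (nrow(out) == 0L) empty else out
}

#' Keep consensus peaks on RNA-seq-validated mRNAs
#'
#' @param cons_peaks Consensus peak tibble with a `gene_id` column.
#' @param detected_genes Character vector of gene ids detected by RNA-seq
#'   (see [rna_detected()]).
#' @return Filtered consensus peaks.
#' @export
validate_by_rnaseq <- function(cons_peaks, detected_genes) {
  filter(cons_peaks, .data$gene_id %in% detected_genes)
}
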