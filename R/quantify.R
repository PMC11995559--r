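# Per-mRNA ac4C quantification (the study's bespoke FE / FC statistics)
# plus the standard TPM and FOT normalizations.

#' Per-mRNA fold enrichment: the sum rule
#'
#' An mRNA's ac4C fold enrichment is the sum of the FE values of its
#' consensus peaks (a single peak contributes its FE directly); genes
#' without peaks are absent from the result.
#'
#' @param cons_peaks Consensus peak tibble with `gene_id` and `fe` columns
#'   (optionally a `group` column, in which case sums are per group).
#' @return Tibble with `gene_id` (and `group` if present) and `fe`.
#' @examples
#' gene_fe(tibble::tibble(gene_id = c("g1", "g1"), fe = c(2, 3.5)))  # 5.5
#' @export
gene_fe <- function(cons_peaks) {
  keys <- intersect(c("gene_id", "group"), names(cons_peaks))
  cons_peaks |>
    group_by(across(all_of(keys))) |>
    summarise(fe = sum(.data$fe), .groups = "drop") |>
    arrange(across(all_of(keys)))
}

#' Pseudocounted ac4C fold change
#'
#' `FC = (FE_case + 1) / (FE_ref + 1)`. The added 1 avoids a zero
#' denominator when an mRNA is undetected (FE = 0) in one group, so
#' case-exclusive mRNAs get `FC = FE_case + 1` and reference-exclusive
#' mRNAs get `FC = 1 / (FE_ref + 1)`.
#'
#' @param fe_case,fe_ref Per-mRNA fold enrichments (0 when undetected).
#' @return Numeric fold-change vector.
#' @examples
#' gene_fc(3, 1)   # 2
#' gene_fc(0, 3)   # 0.25
#' @export
gene_fc <- function(fe_case, fe_ref) {
  (fe_case + 1) / (fe_ref + 1)
}

#' Per-replicate per-gene fold enrichment
#'
#' Sums each sample's calibrated peak FEs per gene (0 when a replicate has
#' no peak on the gene), producing the replicate-level values used by the
#' moderated overlay test on `log2(FE + 1)`.
#'
#' @param sample_peaks Calibrated per-sample peaks with `sample`,
#'   `gene_id`, `fe`.
#' @param genes Gene universe (rows of the output).
#' @param samples Sample universe (columns of the output).
#' @return Tibble with `feature` and one FE column per sample.
#' @export
replicate_gene_fe <- function(sample_peaks, genes, samples) {
  wide <- sample_peaks |>
    group_by(.data$sample, .data$gene_id) |>
    summarise(fe = sum(.data$fe), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "fe",
                       values_fill = 0)
  out <- tibble(feature = genes) |>
    left_join(rename(wide, feature = "gene_id"), by = "feature")
  for (s in samples) {
    if (!s %in% names(out)) out[[s]] <- 0
    out[[s]][is.na(out[[s]])] <- 0
  }
  out[c("feature", samples)]
}

#' Transcripts-per-million normalization
#'
#' `TPM_g = 1e6 (c_g / L_g) / sum_j (c_j / L_j)` per sample, with gene
#' lengths taken from the annotation (exonic length of the longest
#' transcript).
#'
#' @param counts Count `omics_tbl` (features = gene ids).
#' @param ann An `ac4c_annotation`, or a tibble with `gene_id` and `length`
#'   columns as returned by [gene_lengths()].
#' @return An `omics_tbl` of kind `"tpm"`; columns sum to 1e6.
#' @export
tpm <- function(counts, ann) {
  len_tbl <- if (inherits(ann, "ac4c_annotation")) gene_lengths(ann) else as_tibble(ann)
  len <- len_tbl$length[match(counts$feature, len_tbl$gene_id)]
  if (anyNA(len)) {
    abort(sprintf("no annotated length for gene '%s'",
                  counts$feature[which(is.na(len))[1]]))
  }
  out <- counts
  for (s in setdiff(names(counts), "feature")) {
    rate <- counts[[s]] / len
    tot <- sum(rate)
    if (tot == 0) abort(sprintf("sample '%s' has zero total count", s))
    out[[s]] <- 1e6 * rate / tot
  }
  omics_matrix(out, "tpm")
}

#' Fraction-of-total proteomics normalization
#'
#' Each protein's intensity divided by the sample total over non-missing
#' proteins, times 1e6. Missing values stay missing.
#'
#' @param intensities Intensity `omics_tbl` (missing values allowed).
#' @return An `omics_tbl` of kind `"fot"`; non-missing columns sum to 1e6.
#' @export
fot <- function(intensities) {
  out <- intensities
  for (s in setdiff(names(intensities), "feature")) {
    tot <- sum(intensities[[s]], na.rm = TRUE)
    if (!is.finite(tot) || tot == 0) {
      abort(sprintf("sample '%s' has no quantified proteins", s))
    }
    out[[s]] <- 1e6 * intensities[[s]] / tot
  }
  omics_matrix(out, "fot")
}

#' RNA-seq detection rule
#'
#' A gene is detected in a group when its raw count exceeds `min_count` in
#' at least `min_reps` replicates of that group.
#'
#' @param counts Count `omics_tbl`.
#' @param min_count Count threshold (exclusive).
#' @param min_reps Minimum qualifying replicates.
#' @return Tibble with `feature`, `group`, `detected`.
#' @export
rna_detected <- function(counts, min_count = 1, min_reps = 2L) {
  info <- sample_info(counts)
  purrr::map_dfr(unique(info$group), function(g) {
    cols <- info$sample[info$group == g]
    hits <- rowSums(as.matrix(counts[cols]) > min_count)
    tibble(feature = counts$feature, group = g, detected = hits >= min_reps)
  })
}

#' Group detection rule for proteins
#'
#' A protein is detected in a group when it is non-missing in at least
#' `min_reps` replicates (default 1, configurable).
#'
#' @param intensities Intensity (or FOT) `omics_tbl`.
#' @param min_reps Minimum non-missing replicates.
#' @return Tibble with `feature`, `group`, `detected`.
#' @export
protein_detected <- function(intensities, min_reps = 1L) {
  info <- sample_info(intensities)
  purrr::map_dfr(unique(info$group), function(g) {
    cols <- info$sample[info$group == g]
    hits <- rowSums(!is.na(as.matrix(intensities[cols])))
    tibble(feature = intensities$feature, group = g, detected = hits >= min_reps)
  })
}
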