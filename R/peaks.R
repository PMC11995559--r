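# Window-Poisson enrichment scan: a defined, testable stand-in for a
# read-level peak caller. For each window the IP count is tested against the
# expected count under the null, i.e. the input count scaled by the
# library-size ratio and floored at lambda_floor; p-values are upper-tail
# Poisson probabilities, BH-adjusted across all windows of the sample.
# Significant windows are then merged into per-sample peaks.

#' Test windows for IP enrichment over input
#'
#' @param ip,input Count `omics_tbl`s on the same window grid (features are
#'   `chrom:start-end` keys).
#' @param sample Sample column name (`group_replicate`) to test.
#' @param lambda_floor Minimum null mean; prevents zero-mean nulls at
#'   uncovered windows.
#' @param chrom_blacklist Chromosomes excluded before testing (e.g. `chrM`).
#' @return Tibble with one row per window: `window`, `chrom`, `start`,
#'   `end`, `ip_count`, `input_count`, `scaled_lambda`, `p_value`,
#'   `q_value`.
#' @examples
#' # P(X >= 10) with lambda = 2 is about 4.65e-5
#' @export
test_windows <- function(ip, input, sample, lambda_floor = 0.5,
                         chrom_blacklist = "chrM") {
  if (!identical(ip$feature, input$feature)) {
    abort("ip and input matrices are on different window grids")
  }
  if (!sample %in% names(ip) || !sample %in% names(input)) {
    abort(sprintf("sample '%s' not present in both matrices", sample))
  }
  check_scalar_number(lambda_floor, "lambda_floor", lower = 1e-12)
  reg <- parse_region(ip$feature)
  keep <- !reg$chrom %in% chrom_blacklist
  ipc <- ip[[sample]][keep]
  inc <- input[[sample]][keep]
  ip_lib <- sum(ipc)
  in_lib <- sum(inc)
  lambda <- pmax(inc * (ip_lib / in_lib), lambda_floor)
  p <- ppois(ipc - 1, lambda, lower.tail = FALSE)
  tibble(
    window = ip$feature[keep],
    chrom = reg$chrom[keep], start = reg$start[keep], end = reg$end[keep],
    ip_count = ipc, input_count = inc,
    scaled_lambda = lambda,
    p_value = p,
    q_value = p.adjust(p, method = "BH")
  )
}

#' Merge significant windows into per-sample peaks
#'
#' Windows with `q_value < q_max` are merged when separated by at most
#' `merge_gap` non-significant windows; the peak interval spans the merged
#' run including any bridged windows. Peaks spanning fewer than
#' `min_windows` windows are dropped. The summit is the window with the
#' smallest p-value (ties to the leftmost).
#'
#' @param tests Window test table from [test_windows()] (one sample/assay).
#' @param q_max FDR threshold on window q-values.
#' @param min_windows Minimum peak span, in windows.
#' @param merge_gap Maximum number of bridgeable non-significant windows.
#' @return Tibble with one row per peak: `chrom`, `start`, `end`,
#'   `summit_start`, `summit_end`, `peak_p`, `peak_q`, `n_sig_windows`.
#' @export
call_sample_peaks <- function(tests, q_max = 0.05, min_windows = 2L,
                              merge_gap = 1L) {
  check_scalar_number(q_max, "q_max", lower = 0, upper = 1)
  check_scalar_number(min_windows, "min_windows", lower = 1, integerish = TRUE)
  check_scalar_number(merge_gap, "merge_gap", lower = 0, integerish = TRUE)
  sig <- tests |>
    filter(.data$q_value < q_max) |>
    arrange(.data$chrom, .data$start)
  empty <- tibble(
    chrom = character(), start = integer(), end = integer(),
    summit_start = integer(), summit_end = integer(),
    peak_p = double(), peak_q = double(), n_sig_windows = integer()
  )
  if (nrow(sig) == 0L) return(empty)
  ws <- sig$end[1] - sig$start[1]
  sig <- sig |>
    group_by(.data$chrom) |>
    mutate(gap_windows = (.data$start - dplyr::lag(.data$end,
                                                   default = first(.data$start))) / ws,
           cluster = cumsum(.data$gap_windows > merge_gap)) |>
    ungroup()
  peaks <- sig |>
    group_by(.data$chrom, .data$cluster) |>
    summarise(
      summit_start = .data$start[which.min(.data$p_value)][1],
      peak_p = min(.data$p_value),
      peak_q = .data$q_value[which.min(.data$p_value)][1],
      n_sig_windows = dplyr::n(),
      start = min(.data$start), end = max(.data$end),
      .groups = "drop"
    ) |>
    mutate(summit_end = .data$summit_start + ws,
           span_windows = (.data$end - .data$start) / ws) |>
    filter(.data$span_windows >= min_windows) |>
    select("chrom", "start", "end", "summit_start", "summit_end",
           "peak_p", "peak_q", "n_sig_windows") |>
    arrange(.data$chrom, .data$start)
  if (nrow(peaks) == 0L) empty else peaks
}

#' Call peaks for every sample of an assay
#'
#' Convenience loop over [test_windows()] + [call_sample_peaks()].
#'
#' @param ip,input Count `omics_tbl`s on the same window grid.
#' @param q_max,min_windows,merge_gap,lambda_floor,chrom_blacklist See
#'   [test_windows()] and [call_sample_peaks()].
#' @return Tibble of per-sample peaks with a `sample` column.
#' @export
call_peaks_all <- function(ip, input, q_max = 0.05, min_windows = 2L,
                           merge_gap = 1L, lambda_floor = 0.5,
                           chrom_blacklist = "chrM") {
  smp <- setdiff(names(ip), "feature")
  purrr::map_dfr(smp, function(s) {
    tests <- test_windows(ip, input, s, lambda_floor = lambda_floor,
                          chrom_blacklist = chrom_blacklist)
    mutate(call_sample_peaks(tests, q_max = q_max, min_windows = min_windows,
                             merge_gap = merge_gap),
           sample = s, .before = 1)
  })
}
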