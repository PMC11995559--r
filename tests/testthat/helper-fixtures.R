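# Shared fixtures: built in code, small enough to run everywhere.

tiny_sim_config <- function(seed = 101, ...) {
  sim_config(n_genes = 60L, seed = seed, ...)
}

# one pipeline run cached for the whole test session
.fixture_env <- new.env(parent = emptyenv())

tiny_result <- function() {
  if (is.null(.fixture_env$res)) {
    cfg <- pipeline_config(simulate = tiny_sim_config())
    .fixture_env$res <- suppressMessages(run_ac4c_pipeline(cfg))
  }
  .fixture_env$res
}

# hand-built two-gene annotation on one chromosome, window-aligned (ws = 50):
# gA ('+', protein_coding): exons [100,300) + [400,600);
#   5'UTR [100,150), CDS [150,300)+[400,550), 3'UTR [550,600)
# gB ('+', lincRNA):        exon  [800,1000)
toy_annotation <- function() {
  validate_annotation(tibble::tribble(
    ~chrom, ~feature,          ~start, ~end, ~strand, ~gene_id, ~transcript_id, ~biotype,
    "chr1", "gene",             100L,  600L, "+",     "gA",     NA,             "protein_coding",
    "chr1", "transcript",       100L,  600L, "+",     "gA",     "tA",           "protein_coding",
    "chr1", "exon",             100L,  300L, "+",     "gA",     "tA",           "protein_coding",
    "chr1", "exon",             400L,  600L, "+",     "gA",     "tA",           "protein_coding",
    "chr1", "five_prime_utr",   100L,  150L, "+",     "gA",     "tA",           "protein_coding",
    "chr1", "CDS",              150L,  300L, "+",     "gA",     "tA",           "protein_coding",
    "chr1", "CDS",              400L,  550L, "+",     "gA",     "tA",           "protein_coding",
    "chr1", "three_prime_utr",  550L,  600L, "+",     "gA",     "tA",           "protein_coding",
    "chr1", "gene",             800L, 1000L, "+",     "gB",     NA,             "lincRNA",
    "chr1", "transcript",       800L, 1000L, "+",     "gB",     "tB",           "lincRNA",
    "chr1", "exon",             800L, 1000L, "+",     "gB",     "tB",           "lincRNA"
  ))
}

# peak row builder with the columns the filter chain expects
toy_peak <- function(start, end, sample = "WT_1", fe = 3,
                     peak_q = 1e-4, chrom = "chr1") {
  tibble::tibble(
    sample = sample, chrom = chrom, start = as.integer(start),
    end = as.integer(end),
    summit_start = as.integer(start), summit_end = as.integer(start + 50L),
    peak_p = peak_q / 10, peak_q = peak_q, n_sig_windows = 2L, fe = fe
  )
}
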