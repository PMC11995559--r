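# Readers/writers for the interval formats the pipeline touches.
# BED is 0-based half-open and is preserved exactly. GTF-lite is 1-based
# inclusive on disk and converted (losslessly) to the internal 0-based
# half-open convention on read.

GTF_FEATURES <- c("gene", "transcript", "exon", "CDS",
                  "five_prime_utr", "three_prime_utr")

#' Read a BED file of genomic intervals
#'
#' BED coordinates (0-based half-open) are preserved exactly; a 4th column is
#' read as `name` and any further columns are carried through as `X5`, `X6`,
#' ...
#'
#' @param path Path to a BED file (3+ columns, tab-separated, no header).
#' @return Tibble with columns `chrom`, `start`, `end` and any extra columns.
#'   Empty file gives an empty tibble.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- stringr::str_split(lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort(sprintf("line %d of %s: fewer than 3 BED columns", which(nf < 3L)[1], path))
  }
  ncol <- min(nf)
  mat <- t(vapply(fields, function(f) f[seq_len(ncol)], character(ncol)))
  out <- as_tibble(mat, .name_repair = "minimal")
  names(out) <- c("chrom", "start", "end",
                  if (ncol >= 4L) "name", if (ncol >= 5L) paste0("X", 5:ncol))
  out$start <- suppressWarnings(as.integer(out$start))
  out$end <- suppressWarnings(as.integer(out$end))
  bad <- which(is.na(out$start) | is.na(out$end) | out$start >= out$end |
                 !nzchar(out$chrom))
  if (length(bad) > 0L) {
    abort(sprintf("line %d of %s: invalid interval (need chrom, 0 <= start < end)",
                  bad[1], path))
  }
  out
}

#' Write intervals as BED
#' @param x Tibble with `chrom`, `start`, `end` and optional extra columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- arrange(as_tibble(x), .data$chrom, .data$start, .data$end)
  readr::write_tsv(x, path, col_names = FALSE, na = ".", progress = FALSE)
  invisible(path)
}

#' Read a GTF-lite transcript annotation
#'
#' Parses the GTF dialect written by [write_gtf_lite()] /
#' [simulate_annotation()]: tab-separated GTF with features gene, transcript,
#' exon, CDS, five_prime_utr and three_prime_utr, and `gene_id` /
#' `transcript_id` / `gene_biotype` attributes. GTF's 1-based inclusive
#' coordinates are converted to 0-based half-open; the conversion round-trips
#' exactly.
#'
#' @param path Path to a GTF-lite file.
#' @return Tibble of class `ac4c_annotation` with columns `chrom`, `feature`,
#'   `start`, `end` (0-based half-open), `strand`, `gene_id`,
#'   `transcript_id`, `biotype`.
#' @export
read_gtf_lite <- function(path) {
  raw <- readr::read_tsv(path, col_names = c(
    "chrom", "source", "feature", "start", "end", "score", "strand",
    "frame", "attributes"
  ), col_types = "cccddcccc", comment = "#", progress = FALSE)
  get_attr <- function(attr, key) {
    m <- stringr::str_match(attr, paste0(key, ' "([^"]*)"'))
    m[, 2]
  }
  ann <- tibble(
    chrom = raw$chrom,
    feature = raw$feature,
    start = as.integer(raw$start) - 1L,  # to 0-based half-open
    end = as.integer(raw$end),
    strand = raw$strand,
    gene_id = get_attr(raw$attributes, "gene_id"),
    transcript_id = dplyr::na_if(get_attr(raw$attributes, "transcript_id"), ""),
    biotype = get_attr(raw$attributes, "gene_biotype")
  )
  validate_annotation(ann)
}

#' Write a transcript annotation as GTF-lite
#' @param ann An `ac4c_annotation` tibble (0-based half-open internally).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf_lite <- function(ann, path) {
  ann <- arrange(ann, .data$chrom, .data$start, .data$end,
                 match(.data$feature, GTF_FEATURES))
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                   ann$gene_id,
                   if_else(is.na(ann$transcript_id), "", ann$transcript_id),
                   ann$biotype)
  lines <- sprintf("%s\tacripseq\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   ann$chrom, ann$feature, ann$start + 1L, ann$end,
                   ann$strand, attrs)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Validate a transcript annotation
#'
#' Checks structural invariants: non-empty transcripts, exons sorted and
#' non-overlapping within a transcript, CDS/UTR segments contained in exons.
#'
#' @param ann Annotation tibble (columns as in [read_gtf_lite()]).
#' @return The validated annotation with class `ac4c_annotation`.
#' @export
validate_annotation <- function(ann) {
  ann <- as_tibble(ann)
  needed <- c("chrom", "feature", "start", "end", "strand", "gene_id",
              "transcript_id", "biotype")
  miss <- setdiff(needed, names(ann))
  if (length(miss) > 0L) {
    abort(sprintf("annotation is missing column '%s'", miss[1]))
  }
  if (any(ann$start >= ann$end)) abort("annotation has start >= end")
  tx <- filter(ann, .data$feature == "transcript")
  for (t in tx$transcript_id) {
    ex <- filter(ann, .data$feature == "exon", .data$transcript_id == t)
    if (nrow(ex) == 0L) abort(sprintf("transcript '%s' has no exons", t))
    ex <- arrange(ex, .data$start)
    if (nrow(ex) > 1L && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      abort(sprintf("transcript '%s' has overlapping exons", t))
    }
    seg <- filter(ann, .data$feature %in% c("CDS", "five_prime_utr",
                                            "three_prime_utr"),
                  .data$transcript_id == t)
    if (nrow(seg) > 0L) {
      ov <- interval_overlaps(seg[c("chrom", "start", "end")],
                              ex[c("chrom", "start", "end")])
      covered <- tapply(ov$width, ov$q, sum)
      full <- rep(0L, nrow(seg))
      full[as.integer(names(covered))] <- covered
      if (any(full < seg$end - seg$start)) {
        abort(sprintf("transcript '%s' has a CDS/UTR segment outside its exons", t))
      }
    }
  }
  class(ann) <- unique(c("ac4c_annotation", class(ann)))
  ann
}

#' Exonic gene lengths from an annotation
#'
#' Gene length is the union of exon lengths of the gene's longest transcript
#' (by exonic length), as used for TPM normalization.
#'
#' @param ann An `ac4c_annotation` tibble.
#' @return Tibble with columns `gene_id`, `length`.
#' @export
gene_lengths <- function(ann) {
  ann |>
    filter(.data$feature == "exon") |>
    group_by(.data$gene_id, .data$transcript_id) |>
    summarise(length = sum(.data$end - .data$start), .groups = "drop_last") |>
    summarise(length = max(.data$length), .groups = "drop")
}

#' Read a YAML run configuration
#'
#' Loads a YAML file whose keys mirror [pipeline_config()]; unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- raw$simulate
  raw$simulate <- NULL
  cfg <- do.call(pipeline_config, c(raw, if (!is.null(sim)) {
    list(simulate = do.call(sim_config, sim))
  }))
  cfg
}
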