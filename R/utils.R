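# Internal helpers shared across modules. All interval arithmetic in the
# package is 0-based half-open; only the GTF reader/writer converts.

#' Build a region key string
#'
#' Window and peak identifiers use the `chrom:start-end` convention with
#' 0-based half-open coordinates.
#' @param chrom Chromosome name.
#' @param start,end Integer coordinates, 0-based half-open.
#' @return Character vector of keys.
#' @keywords internal
region_key <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

#' Parse region keys back into a tibble
#' @param keys Character vector of `chrom:start-end` keys.
#' @return Tibble with columns `chrom`, `start`, `end`.
#' @keywords internal
parse_region <- function(keys) {
  m <- stringr::str_match(keys, "^(.+):([0-9]+)-([0-9]+)$")
  if (anyNA(m[, 1])) {
    bad <- keys[is.na(m[, 1])][1]
    abort(sprintf("malformed region key '%s' (expected chrom:start-end)", bad))
  }
  tibble(
    chrom = m[, 2],
    start = as.integer(m[, 3]),
    end = as.integer(m[, 4])
  )
}

# stopifnot-style scalar checks that name the offending field
check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("config field '%s' must be a single number", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("config field '%s' must be in [%s, %s]", name, lower, upper))
  }
  if (integerish && x != as.integer(x)) {
    abort(sprintf("config field '%s' must be an integer", name))
  }
  invisible(x)
}

# Pairwise overlap width between two interval tibbles (chrom/start/end),
# half-open. Returns a tibble of (query row, subject row, overlap width).
interval_overlaps <- function(query, subject, min_width = 1L) {
  if (nrow(query) == 0L || nrow(subject) == 0L) {
    return(tibble(q = integer(), s = integer(), width = integer()))
  }
  hits <- purrr::map_dfr(unique(query$chrom), function(ch) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (length(qi) == 0L || length(si) == 0L) {
      return(tibble(q = integer(), s = integer(), width = integer()))
    }
    qr <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    sr <- IRanges::IRanges(start = subject$start[si] + 1L, end = subject$end[si])
    ov <- IRanges::findOverlaps(qr, sr, minoverlap = min_width)
    if (length(ov) == 0L) {
      return(tibble(q = integer(), s = integer(), width = integer()))
    }
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(qr[qh], sr[sh]))
    tibble(q = qi[qh], s = si[sh], width = as.integer(w))
  })
  hits
}
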