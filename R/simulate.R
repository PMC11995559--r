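# Synthetic multi-omics generator. Emulates the acRIP-seq study design:
# negative-binomial window coverage for acRIP/IgG/input in 3 replicates x 2
# groups, planted exonic enrichment peaks (shared or group-exclusive),
# non-specific "sticky" windows enriched in both the IgG and acRIP assays,
# an RNA-seq count layer, and a log-normal label-free proteomics layer with
# planted log2 fold changes and group-exclusive (missing) proteins.
# Every planted effect is recorded in a ground-truth sidecar.

#' Simulation configuration
#'
#' Collects and validates the parameters of the synthetic multi-omics
#' generator. Defaults describe a desk-scale version of a two-group,
#' three-replicate acRIP-seq + RNA-seq + proteomics experiment.
#'
#' @param n_genes Number of toy genes.
#' @param exons_per_gene Exons per gene.
#' @param window_size Window width in bases; all gene coordinates are
#'   multiples of this so coverage windows tile exons exactly.
#' @param exon_windows Windows per exon.
#' @param utr_windows Windows assigned to each UTR (in exonic space).
#' @param intron_windows Windows per intron.
#' @param gap_windows Intergenic gap between neighbouring genes, in windows.
#' @param n_replicates Biological replicates per group.
#' @param groups Two ordered group labels; the second is the case group.
#' @param background_mean Mean input reads per window.
#' @param nb_dispersion NB dispersion phi (variance = mu + phi mu^2).
#' @param peak_fraction Fraction of genes carrying one true ac4C peak.
#' @param peak_windows Width of each planted peak, in windows.
#' @param enrichment_effect Multiplicative IP enrichment at true peak windows.
#' @param igg_peak_rate Fraction of windows with non-specific binding
#'   (enriched in both IgG and acRIP assays).
#' @param igg_effect Multiplicative enrichment at non-specific windows.
#' @param exclusive_fraction Fraction of planted features (peak genes,
#'   proteins) that are group-exclusive.
#' @param rna_de_fraction Fraction of genes with a planted RNA-seq fold
#'   change (the study's transcriptome is nearly unchanged, so this is small).
#' @param rna_lfc Magnitude of planted RNA log2 fold changes.
#' @param protein_de_fraction Fraction of overlay proteins with a planted
#'   log2 fold change.
#' @param protein_lfc Magnitude of planted protein log2 fold changes.
#' @param protein_down_fraction Share of planted protein effects that are
#'   decreases in the case group.
#' @param protein_sigma Replicate SD of log2 protein intensity.
#' @param seed RNG seed; a fixed seed gives byte-identical outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200L,
                       exons_per_gene = 3L,
                       window_size = 50L,
                       exon_windows = 4L,
                       utr_windows = 1L,
                       intron_windows = 2L,
                       gap_windows = 2L,
                       n_replicates = 3L,
                       groups = c("WT", "FAD"),
                       background_mean = 20,
                       nb_dispersion = 0.01,
                       peak_fraction = 0.3,
                       peak_windows = 2L,
                       enrichment_effect = 8,
                       igg_peak_rate = 0.02,
                       igg_effect = 6,
                       exclusive_fraction = 0.2,
                       rna_de_fraction = 0.005,
                       rna_lfc = 1.5,
                       protein_de_fraction = 0.1,
                       protein_lfc = 2,
                       protein_down_fraction = 0.5,
                       protein_sigma = 0.3,
                       seed = 1L) {
  check_scalar_number(n_genes, "n_genes", lower = 1, integerish = TRUE)
  check_scalar_number(exons_per_gene, "exons_per_gene", lower = 1, integerish = TRUE)
  check_scalar_number(window_size, "window_size", lower = 1, integerish = TRUE)
  check_scalar_number(exon_windows, "exon_windows", lower = 1, integerish = TRUE)
  check_scalar_number(utr_windows, "utr_windows", lower = 0, integerish = TRUE)
  check_scalar_number(intron_windows, "intron_windows", lower = 0, integerish = TRUE)
  check_scalar_number(gap_windows, "gap_windows", lower = 1, integerish = TRUE)
  check_scalar_number(n_replicates, "n_replicates", lower = 1, integerish = TRUE)
  if (!is.character(groups) || length(groups) != 2L || anyDuplicated(groups)) {
    abort("config field 'groups' must be two distinct labels")
  }
  if (any(grepl("_", groups))) {
    abort("config field 'groups' must not contain '_' (reserved for replicate suffix)")
  }
  check_scalar_number(background_mean, "background_mean", lower = 0)
  check_scalar_number(nb_dispersion, "nb_dispersion", lower = 1e-8)
  for (f in c("peak_fraction", "igg_peak_rate", "exclusive_fraction",
              "rna_de_fraction", "protein_de_fraction",
              "protein_down_fraction")) {
    check_scalar_number(get(f), f, lower = 0, upper = 1)
  }
  check_scalar_number(peak_windows, "peak_windows", lower = 1,
                      upper = exon_windows, integerish = TRUE)
  check_scalar_number(enrichment_effect, "enrichment_effect", lower = 0)
  check_scalar_number(igg_effect, "igg_effect", lower = 1)
  check_scalar_number(rna_lfc, "rna_lfc")
  check_scalar_number(protein_lfc, "protein_lfc")
  check_scalar_number(protein_sigma, "protein_sigma", lower = 1e-8)
  check_scalar_number(seed, "seed", integerish = TRUE)
  if (2L * utr_windows >= exons_per_gene * exon_windows) {
    abort("config field 'utr_windows' leaves no room for a CDS")
  }
  cfg <- as.list(environment())
  cfg[c("n_genes", "exons_per_gene", "window_size", "exon_windows",
        "utr_windows", "intron_windows", "gap_windows", "n_replicates",
        "peak_windows", "seed")] <-
    lapply(cfg[c("n_genes", "exons_per_gene", "window_size", "exon_windows",
                 "utr_windows", "intron_windows", "gap_windows",
                 "n_replicates", "peak_windows", "seed")], as.integer)
  structure(cfg, class = "sim_config")
}

# map an exonic-space interval [a, b) to genomic pieces, given exons in
# transcription order (already reversed for minus strand)
exonic_to_genomic <- function(a, b, exons, strand) {
  pieces <- list()
  off <- 0L
  for (i in seq_len(nrow(exons))) {
    w <- exons$end[i] - exons$start[i]
    lo <- max(a - off, 0L)
    hi <- min(b - off, w)
    if (lo < hi) {
      if (strand == "+") {
        pieces[[length(pieces) + 1L]] <-
          c(exons$start[i] + lo, exons$start[i] + hi)
      } else {
        pieces[[length(pieces) + 1L]] <-
          c(exons$end[i] - hi, exons$end[i] - lo)
      }
    }
    off <- off + w
  }
  if (length(pieces) == 0L) return(tibble(start = integer(), end = integer()))
  m <- do.call(rbind, pieces)
  tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
}

#' Simulate a toy transcript annotation
#'
#' Lays `n_genes` non-overlapping gene models on one toy chromosome
#' (`chrS`), each with `exons_per_gene` exons of `exon_windows` windows,
#' a 5'UTR / CDS / 3'UTR split in exonic space, and alternating strands.
#' All coordinates are multiples of `window_size`, so the coverage window
#' grid tiles exons exactly. Deterministic given the configuration.
#'
#' @param cfg A [sim_config()].
#' @return An `ac4c_annotation` tibble (0-based half-open coordinates).
#' @export
simulate_annotation <- function(cfg) {
  if (!inherits(cfg, "sim_config")) abort("cfg must be a sim_config")
  ws <- cfg$window_size
  rows <- vector("list", cfg$n_genes)
  pos <- cfg$gap_windows * ws
  for (i in seq_len(cfg$n_genes)) {
    gid <- sprintf("g%04d", i)
    tid <- sprintf("t%04d", i)
    strand <- if (i %% 2L == 1L) "+" else "-"
    ex_start <- integer(cfg$exons_per_gene)
    ex_end <- integer(cfg$exons_per_gene)
    p <- pos
    for (e in seq_len(cfg$exons_per_gene)) {
      ex_start[e] <- p
      ex_end[e] <- p + cfg$exon_windows * ws
      p <- ex_end[e] + cfg$intron_windows * ws
    }
    gene_start <- ex_start[1]
    gene_end <- ex_end[cfg$exons_per_gene]
    pos <- gene_end + cfg$gap_windows * ws
    exons <- tibble(start = ex_start, end = ex_end)
    tx_exons <- if (strand == "+") exons else exons[rev(seq_len(nrow(exons))), ]
    L <- cfg$exons_per_gene * cfg$exon_windows * ws
    u <- cfg$utr_windows * ws
    segs <- bind_rows(
      mutate(exonic_to_genomic(0L, u, tx_exons, strand),
             feature = "five_prime_utr"),
      mutate(exonic_to_genomic(u, L - u, tx_exons, strand), feature = "CDS"),
      mutate(exonic_to_genomic(L - u, L, tx_exons, strand),
             feature = "three_prime_utr")
    )
    rows[[i]] <- bind_rows(
      tibble(feature = "gene", start = gene_start, end = gene_end,
             transcript_id = NA_character_),
      tibble(feature = "transcript", start = gene_start, end = gene_end,
             transcript_id = tid),
      tibble(feature = "exon", start = exons$start, end = exons$end,
             transcript_id = tid),
      mutate(segs[c("feature", "start", "end")], transcript_id = tid)
    ) |>
      mutate(chrom = "chrS", strand = strand, gene_id = gid,
             biotype = "protein_coding")
  }
  ann <- bind_rows(rows) |>
    select("chrom", "feature", "start", "end", "strand", "gene_id",
           "transcript_id", "biotype")
  validate_annotation(ann)
}

#' The coverage window grid of an annotation
#'
#' Fixed-width windows tiling the toy chromosome from 0 to just past the
#' last gene.
#'
#' @param ann An `ac4c_annotation`.
#' @param window_size Window width in bases.
#' @return Tibble with `feature` (the `chrom:start-end` key), `chrom`,
#'   `start`, `end`.
#' @export
window_grid <- function(ann, window_size) {
  len <- max(ann$end) + window_size * 2L
  nwin <- ceiling(len / window_size)
  start <- as.integer((seq_len(nwin) - 1L) * window_size)
  tibble(
    feature = region_key("chrS", start, start + window_size),
    chrom = "chrS", start = start, end = start + as.integer(window_size)
  )
}

#' Simulate acRIP / IgG / input window coverage
#'
#' Plants one enrichment peak (of `peak_windows` windows, inside an exon) in
#' a `peak_fraction` of genes. A fraction `exclusive_fraction` of peak genes
#' is enriched in only one group; the rest are enriched in both. A fraction
#' `igg_peak_rate` of windows is "sticky": enriched in both the IgG and
#' acRIP assays, emulating non-specific antibody binding that the IgG
#' calibration step must remove. All counts are negative binomial with mean
#' `background_mean` (times the planted effect) and dispersion
#' `nb_dispersion`.
#'
#' @param cfg A [sim_config()].
#' @param ann Annotation from [simulate_annotation()].
#' @return List with elements `assays` (named list of count `omics_tbl`s for
#'   `acRIP`, `IgG`, `input`, one column per group x replicate), `windows`
#'   (the window grid) and `truth` (ground-truth list; see
#'   [write_ground_truth()]).
#' @export
simulate_rip_coverage <- function(cfg, ann) {
  if (!inherits(cfg, "sim_config")) abort("cfg must be a sim_config")
  set.seed(cfg$seed)
  ws <- cfg$window_size
  grid <- window_grid(ann, ws)
  nwin <- nrow(grid)

  # --- plant true peaks (draw order: peak genes, exclusivity, offsets) ---
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  n_peak <- round(cfg$peak_fraction * cfg$n_genes)
  peak_genes <- sort(sample(genes, n_peak))
  n_excl <- round(cfg$exclusive_fraction * n_peak)
  excl_genes <- if (n_excl > 0) sort(sample(peak_genes, n_excl)) else character()
  g1 <- cfg$groups[1]; g2 <- cfg$groups[2]
  peak_group <- ifelse(
    peak_genes %in% excl_genes,
    ifelse(seq_along(peak_genes) %% 2L == 0L, g1, g2),
    "both"
  )
  exons <- filter(ann, .data$feature == "exon")
  empty_peaks <- tibble(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        group = character(), effect = double())
  true_peaks <- purrr::map2_dfr(peak_genes, peak_group, function(g, grp) {
    ex <- filter(exons, .data$gene_id == g)
    ex <- ex[ceiling(nrow(ex) / 2), ]  # middle exon: interior of the CDS
    slots <- cfg$exon_windows - cfg$peak_windows
    off <- if (slots > 0) sample.int(slots + 1L, 1L) - 1L else 0L
    tibble(gene_id = g, chrom = ex$chrom,
           start = ex$start + off * ws,
           end = ex$start + (off + cfg$peak_windows) * ws,
           group = grp, effect = cfg$enrichment_effect)
  })
  if (nrow(true_peaks) == 0L) true_peaks <- empty_peaks

  # --- sticky (non-specific) windows, planted as runs of 2, off-peak ---
  peak_win <- unlist(purrr::map2(true_peaks$start, true_peaks$end,
                                 function(s, e) seq(s %/% ws, e %/% ws - 1L))) + 1L
  n_sticky <- round(cfg$igg_peak_rate * nwin / 2)
  # keep sticky runs far enough from planted peaks that the caller's
  # gap-bridging cannot merge the two (truth labels stay unambiguous)
  guard <- unique(as.integer(outer(peak_win, -4:4, `+`)))
  free <- setdiff(seq_len(nwin - 1L), guard)
  sticky_start <- if (n_sticky > 0) sort(sample(free, n_sticky)) else integer()
  sticky_win <- unique(sort(c(sticky_start, sticky_start + 1L)))
  igg_regions <- if (length(sticky_start) > 0) {
    tibble(chrom = "chrS",
           start = grid$start[sticky_start],
           end = grid$end[pmin(sticky_start + 1L, nwin)])
  } else {
    tibble(chrom = character(), start = integer(), end = integer())
  }

  # --- per-sample NB counts (assay, then group, then replicate order) ---
  mu_base <- rep(cfg$background_mean, nwin)
  peak_win_by_group <- lapply(cfg$groups, function(grp) {
    p <- filter(true_peaks, .data$group %in% c(grp, "both"))
    unique(unlist(purrr::map2(p$start, p$end,
                              function(s, e) seq(s %/% ws, e %/% ws - 1L))) + 1L)
  })
  names(peak_win_by_group) <- cfg$groups
  samples <- paste(rep(cfg$groups, each = cfg$n_replicates),
                   rep(seq_len(cfg$n_replicates), 2), sep = "_")
  size <- 1 / cfg$nb_dispersion
  draw <- function(mu) as.integer(rnbinom(nwin, mu = mu, size = size))
  assays <- list()
  for (assay in c("acRIP", "IgG", "input")) {
    cols <- list()
    for (grp in cfg$groups) {
      mu <- mu_base
      if (assay == "acRIP") {
        mu[peak_win_by_group[[grp]]] <- mu[peak_win_by_group[[grp]]] *
          cfg$enrichment_effect
        mu[sticky_win] <- cfg$background_mean * cfg$igg_effect
      } else if (assay == "IgG") {
        mu[sticky_win] <- cfg$background_mean * cfg$igg_effect
      }
      for (r in seq_len(cfg$n_replicates)) {
        cols[[paste(grp, r, sep = "_")]] <- draw(mu)
      }
    }
    assays[[assay]] <- omics_matrix(
      bind_rows(tibble(feature = grid$feature, !!!cols)), "count"
    )
  }

  truth <- list(
    true_peaks = true_peaks,
    igg_regions = igg_regions,
    groups = cfg$groups,
    enrichment_effect = cfg$enrichment_effect
  )
  list(assays = assays, windows = grid, truth = truth)
}

#' Simulate RNA-seq counts and protein intensities
#'
#' RNA counts are negative binomial around log-normal per-gene means, nearly
#' identical between groups (a small `rna_de_fraction` carries a planted
#' fold change). Protein intensities are log-normal; overlay proteins carry
#' planted log2 fold changes in a `protein_de_fraction` of features, and an
#' `exclusive_fraction` of proteins is detected in only one group (missing
#' in the other group's replicates). Intensities are rounded to 6 decimals
#' so outputs are byte-stable.
#'
#' @param cfg A [sim_config()].
#' @param ann Annotation from [simulate_annotation()].
#' @param truth Ground-truth list from [simulate_rip_coverage()]; extended
#'   in place with expression/protein truth and returned.
#' @return List with `rna_counts` (count `omics_tbl`), `protein`
#'   (intensity `omics_tbl` with missing values) and the extended `truth`.
#' @export
simulate_expression <- function(cfg, ann, truth) {
  if (!inherits(cfg, "sim_config")) abort("cfg must be a sim_config")
  set.seed(cfg$seed + 1L)
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  g1 <- cfg$groups[1]; g2 <- cfg$groups[2]
  size <- 1 / cfg$nb_dispersion

  # RNA layer (draw order: base means, DE genes, counts by group/replicate)
  base_mu <- rlnorm(cfg$n_genes, meanlog = log(100), sdlog = 0.6)
  n_rna_de <- round(cfg$rna_de_fraction * cfg$n_genes)
  rna_de <- if (n_rna_de > 0) sort(sample(genes, n_rna_de)) else character()
  rna_lfc <- setNames(rep(0, cfg$n_genes), genes)
  if (length(rna_de) > 0) {
    rna_lfc[rna_de] <- cfg$rna_lfc * sample(c(-1, 1), length(rna_de),
                                            replace = TRUE)
  }
  cols <- list()
  for (grp in cfg$groups) {
    mu <- base_mu * if (grp == g2) 2^rna_lfc else 1
    for (r in seq_len(cfg$n_replicates)) {
      cols[[paste(grp, r, sep = "_")]] <-
        as.integer(rnbinom(cfg$n_genes, mu = mu, size = size))
    }
  }
  rna_counts <- omics_matrix(tibble(feature = genes, !!!cols), "count")

  # protein layer
  base_log2 <- rnorm(cfg$n_genes, mean = 20, sd = 2)
  n_excl <- round(cfg$exclusive_fraction * cfg$n_genes)
  excl <- if (n_excl > 0) sort(sample(genes, n_excl)) else character()
  excl_group <- setNames(rep(NA_character_, cfg$n_genes), genes)
  if (length(excl) > 0) {
    excl_group[excl] <- ifelse(seq_along(excl) %% 2L == 0L, g1, g2)
  }
  overlay <- setdiff(genes, excl)
  n_de <- round(cfg$protein_de_fraction * length(overlay))
  de_prot <- if (n_de > 0) sort(sample(overlay, n_de)) else character()
  prot_lfc <- setNames(rep(0, cfg$n_genes), genes)
  if (length(de_prot) > 0) {
    sign <- ifelse(runif(length(de_prot)) < cfg$protein_down_fraction, -1, 1)
    prot_lfc[de_prot] <- cfg$protein_lfc * sign
  }
  cols <- list()
  for (grp in cfg$groups) {
    shift <- if (grp == g2) prot_lfc else rep(0, cfg$n_genes)
    for (r in seq_len(cfg$n_replicates)) {
      x <- base_log2 + shift + rnorm(cfg$n_genes, sd = cfg$protein_sigma)
      v <- round(2^x, 6)
      v[!is.na(excl_group) & excl_group != grp] <- NA_real_
      cols[[paste(grp, r, sep = "_")]] <- v
    }
  }
  protein <- omics_matrix(tibble(feature = genes, !!!cols), "intensity")

  truth$true_rna_lfc <- tibble(feature = genes, lfc = unname(rna_lfc))
  truth$true_protein_lfc <- tibble(feature = genes, lfc = unname(prot_lfc))
  truth$true_protein_detection <- tibble(
    feature = genes,
    detected_g1 = unname(is.na(excl_group) | excl_group == g1),
    detected_g2 = unname(is.na(excl_group) | excl_group == g2)
  )
  truth$true_de_labels <- tibble(
    feature = genes,
    rna = unname(rna_lfc) != 0,
    protein = unname(prot_lfc) != 0 | !is.na(unname(excl_group))
  )
  list(rna_counts = rna_counts, protein = protein, truth = truth)
}

#' Simulate a full synthetic multi-omics experiment
#'
#' Convenience wrapper running [simulate_annotation()],
#' [simulate_rip_coverage()] and [simulate_expression()] in order.
#'
#' @param cfg A [sim_config()].
#' @return List with `annotation`, `assays`, `windows`, `rna_counts`,
#'   `protein`, `truth`.
#' @export
simulate_multiomics <- function(cfg) {
  ann <- simulate_annotation(cfg)
  rip <- simulate_rip_coverage(cfg, ann)
  expr <- simulate_expression(cfg, ann, rip$truth)
  list(annotation = ann, assays = rip$assays, windows = rip$windows,
       rna_counts = expr$rna_counts, protein = expr$protein,
       truth = expr$truth)
}

#' Write / read the ground-truth sidecar as JSON
#' @param truth Ground-truth list from the simulator.
#' @param path File path.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns the truth list with tibble elements.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("true_peaks", "igg_regions", "true_rna_lfc",
               "true_protein_lfc", "true_protein_detection",
               "true_de_labels")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- as_tibble(as.data.frame(raw[[nm]]))
  }
  raw
}

#' Plant a detection/differential pattern with fixed component counts
#'
#' Builds a feature table whose composition (group-exclusive and overlay
#' features; up/down calls within the overlay) matches the requested counts
#' exactly. Used to exercise the classification layer's composition
#' arithmetic: the planted table flows through [venn_classify()] and
#' [call_de()] like any measured data.
#'
#' Overlay up features get fold change 4 (adj. p 1e-4), overlay down 0.25
#' (adj. p 1e-4), overlay non-significant 1 (adj. p 0.9). Exclusive features
#' carry a per-group fold enrichment `fe_exclusive`, giving fold change
#' `fe_exclusive + 1` (case-exclusive) or `1/(fe_exclusive + 1)`
#' (reference-exclusive) under the pseudocounted FE rule.
#'
#' @param n_ref_only Features detected only in the reference (WT) group.
#' @param n_overlay Features detected in both groups.
#' @param n_case_only Features detected only in the case group.
#' @param overlay_up,overlay_down Up/down calls within the overlay
#'   (must not exceed `n_overlay`).
#' @param fe_exclusive Planted per-mRNA fold enrichment of exclusive
#'   features.
#' @param prefix Feature id prefix.
#' @return Tibble with columns `feature`, `detected_g1`, `detected_g2`,
#'   `fc`, `p`, `adj_p`.
#' @export
simulate_detection_pattern <- function(n_ref_only, n_overlay, n_case_only,
                                       overlay_up = 0, overlay_down = 0,
                                       fe_exclusive = 3, prefix = "f") {
  for (v in c("n_ref_only", "n_overlay", "n_case_only", "overlay_up",
              "overlay_down")) {
    check_scalar_number(get(v), v, lower = 0, integerish = TRUE)
  }
  if (overlay_up + overlay_down > n_overlay) {
    abort("overlay_up + overlay_down exceeds n_overlay")
  }
  n <- n_ref_only + n_overlay + n_case_only
  id <- sprintf("%s%05d", prefix, seq_len(n))
  cls <- rep(c("ref_only", "overlay", "case_only"),
             c(n_ref_only, n_overlay, n_case_only))
  fc <- rep(1, n)
  adj_p <- rep(NA_real_, n)
  ov <- which(cls == "overlay")
  up <- head(ov, overlay_up)
  down <- head(setdiff(ov, up), overlay_down)
  fc[ov] <- 1; adj_p[ov] <- 0.9
  fc[up] <- 4; adj_p[up] <- 1e-4
  fc[down] <- 0.25; adj_p[down] <- 1e-4
  fc[cls == "case_only"] <- fe_exclusive + 1
  fc[cls == "ref_only"] <- 1 / (fe_exclusive + 1)
  tibble(
    feature = id,
    detected_g1 = cls != "case_only",
    detected_g2 = cls != "ref_only",
    fc = fc, p = adj_p, adj_p = adj_p
  )
}
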