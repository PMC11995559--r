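# Cross-omics layer: Venn detection classes, the 3x3 protein x ac4C
# cross-classification, distribution comparisons (KS), 2x2 association
# (Yates chi-square, phi), PCA with the variance / MAD feature filter,
# sample correlation structure, the log10-FE Gaussian histogram fit, and
# stage specificity across timepoints.

VENN_LEVELS <- c("AD absent", "Overlay", "AD unique")

#' Venn detection classes
#'
#' Partitions features into the study's three detection classes:
#' `"AD absent"` (detected only in the reference/WT group), `"Overlay"`
#' (both groups), `"AD unique"` (only the case group).
#'
#' @param detected_ref,detected_case Character vectors of detected feature
#'   ids per group.
#' @return Tibble with `feature` and `class` (factor with the three
#'   levels), one row per feature of the union.
#' @export
venn_classify <- function(detected_ref, detected_case) {
  feats <- union(detected_ref, detected_case)
  cls <- case_when(
    feats %in% detected_ref & feats %in% detected_case ~ "Overlay",
    feats %in% detected_ref ~ "AD absent",
    TRUE ~ "AD unique"
  )
  tibble(feature = feats, class = factor(cls, levels = VENN_LEVELS)) |>
    arrange(.data$feature)
}

#' Venn class counts
#' @param classes Output of [venn_classify()].
#' @return Named integer vector over the three classes.
#' @export
venn_counts <- function(classes) {
  table(classes$class) |> c()
}

# group index: protein-up row -> 1,2,3 over ac4C (up, ns, down);
# protein-ns row -> 4,5,6; protein-down row -> 7,8,9 over ac4C
# (down, ns, up), so that group 1 = up/up and group 7 = down/down,
# the two classes named in the study.
CROSS_GROUP <- matrix(
  c(1L, 2L, 3L,
    4L, 5L, 6L,
    9L, 8L, 7L),
  nrow = 3, byrow = TRUE,
  dimnames = list(protein = c("up", "ns", "down"),
                  ac4c = c("up", "ns", "down"))
)

#' Cross-classify protein and ac4C verdicts
#'
#' Joins per-gene verdicts from the protein and ac4C layers (genes present
#' in both layers only; others are dropped with a message) and assigns the
#' 3x3 cross-omics group index, with group 1 = protein up & ac4C up and
#' group 7 = protein down & ac4C down. "Differential at both levels" means
#' both verdicts are non-`ns`.
#'
#' @param protein_verdicts,ac4c_verdicts Tibbles with `feature` and
#'   `verdict` columns.
#' @return Tibble with `feature`, `protein`, `ac4c`, `group`,
#'   `both_de` (logical).
#' @export
cross_classify <- function(protein_verdicts, ac4c_verdicts) {
  p <- select(as_tibble(protein_verdicts), "feature", protein = "verdict")
  a <- select(as_tibble(ac4c_verdicts), "feature", ac4c = "verdict")
  n_drop <- length(union(p$feature, a$feature)) -
    length(intersect(p$feature, a$feature))
  if (n_drop > 0) {
    inform(sprintf("cross_classify: %d genes missing from one layer excluded",
                   n_drop))
  }
  inner_join(p, a, by = "feature") |>
    mutate(
      group = CROSS_GROUP[cbind(.data$protein, .data$ac4c)],
      both_de = .data$protein != "ns" & .data$ac4c != "ns"
    ) |>
    arrange(.data$feature)
}

#' Cross-omics group counts
#' @param crossed Output of [cross_classify()].
#' @return List with `table` (3x3 protein x ac4C count matrix), `groups`
#'   (counts by group index 1..9) and `both_de` (genes differential at both
#'   levels).
#' @export
cross_counts <- function(crossed) {
  tab <- table(factor(crossed$protein, c("up", "ns", "down")),
               factor(crossed$ac4c, c("up", "ns", "down")))
  dimnames(tab) <- dimnames(CROSS_GROUP)
  groups <- setNames(integer(9), as.character(1:9))
  cnt <- table(crossed$group)
  groups[names(cnt)] <- cnt
  list(table = tab, groups = groups, both_de = sum(crossed$both_de))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D = sup |F_a - F_b|` with the asymptotic p-value, as used to compare
#' cumulative FE distributions between groups.
#'
#' @param a,b Non-empty numeric vectors.
#' @return List with `statistic` (D) and `p_value`.
#' @export
ks_compare <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) abort("empty vector in KS comparison")
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

check_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) abort("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("table entries must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("zero margin in 2x2 table")
  }
  tab
}

#' Yates-corrected chi-square for a 2x2 table
#'
#' Continuity-corrected statistic `sum((|O - E| - 0.5)^2 / E)`, with the
#' correction capped so cells with `|O - E| < 0.5` contribute zero.
#'
#' @param tab 2x2 table of non-negative integers with positive margins.
#' @return List with `statistic` and `p_value` (chi-square, 1 df).
#' @export
chi2_yates <- function(tab) {
  tab <- check_2x2(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum(pmax(abs(tab - e) - 0.5, 0)^2 / e)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Phi association coefficient for a 2x2 table
#'
#' `phi = (ad - bc) / sqrt(r1 r2 c1 c2)`; the study labels `|phi| < 0.3`
#' as "low relevance".
#'
#' @param tab 2x2 table of non-negative integers with positive margins.
#' @return List with `phi` and `low_relevance` (logical, `|phi| < 0.3`).
#' @export
phi_coef <- function(tab) {
  tab <- check_2x2(tab)
  phi <- (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1]) /
    sqrt(prod(c(rowSums(tab), colSums(tab))))
  list(phi = unname(phi), low_relevance = abs(phi) < 0.3)
}

#' PCA on the most variable features
#'
#' Reproduces the study's feature filter: drop features with variance at or
#' below `variance_floor` across samples, rank the rest by median absolute
#' deviation and keep the top `top_frac` (ties at the cutoff are kept),
#' then run a centered (unscaled) PCA over samples.
#'
#' @param x `omics_tbl` or numeric matrix (features x samples). Features
#'   with missing values are dropped first.
#' @param variance_floor Variance threshold (the study uses 1 for
#'   proteomics; use 0 to disable).
#' @param top_frac Fraction of features kept by MAD rank.
#' @return Object of class `ac4c_pca`: list with `scores` (tibble:
#'   `sample`, `group`, PCs), `loadings`, `var_explained`, `kept_features`.
#' @export
pca_top_mad <- function(x, variance_floor = 1, top_frac = 0.5) {
  m <- if (is_tibble(x) || is.data.frame(x)) omics_values(as_tibble(x) |> omics_matrix("intensity")) else as.matrix(x)
  if (ncol(m) < 3L) abort("PCA needs at least 3 samples")
  m <- m[complete.cases(m), , drop = FALSE]
  v <- apply(m, 1, var)
  m <- m[v > variance_floor, , drop = FALSE]
  if (nrow(m) < 2L) abort("fewer than 2 features pass the variance filter")
  mads <- apply(m, 1, mad)
  k <- ceiling(nrow(m) * top_frac)
  cutoff <- sort(mads, decreasing = TRUE)[k]
  keep <- mads >= cutoff
  m <- m[keep, , drop = FALSE]
  centered <- m - rowMeans(m)
  pc <- prcomp(t(centered), center = FALSE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as_tibble(pc$x)
  scores <- dplyr::bind_cols(
    tibble(sample = colnames(m), group = sub("_[0-9]+$", "", colnames(m))),
    scores
  )
  structure(
    list(scores = scores, loadings = pc$rotation,
         var_explained = ve, kept_features = rownames(m)),
    class = "ac4c_pca"
  )
}

#' Pairwise Spearman correlation between samples
#'
#' Rank correlation on shared non-missing features; pairs with fewer than
#' `min_shared` shared features get `NA` (with a message).
#'
#' @param x `omics_tbl` or numeric matrix (features x samples).
#' @param min_shared Minimum shared non-missing features per pair.
#' @return Sample x sample correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(x, min_shared = 3L) {
  m <- if (is_tibble(x) || is.data.frame(x)) omics_values(as_tibble(x) |> omics_matrix("intensity")) else as.matrix(x)
  if (ncol(m) < 2L) abort("need at least 2 samples")
  rho <- suppressWarnings(cor(m, method = "spearman",
                              use = "pairwise.complete.obs"))
  shared <- crossprod(!is.na(m))
  low <- shared < min_shared
  if (any(low & upper.tri(low))) {
    inform("spearman_matrix: some pairs share too few features; set to NA")
    rho[low] <- NA_real_
  }
  diag(rho) <- 1
  rho
}

#' Gaussian fit to the log10 fold-enrichment histogram
#'
#' Histograms `log10(FE)` at `bin_width` and fits
#' `a * exp(-(x - mean)^2 / (2 sd^2))` to the bin counts by least squares;
#' the area under the curve is `a * sd * sqrt(2 pi)`.
#'
#' @param fes Positive fold-enrichment values.
#' @param bin_width Histogram bin width on the log10 scale.
#' @return Object of class `fe_fit`: list with `histogram` (tibble `mid`,
#'   `count`), `amplitude`, `mean`, `sd`, `area`, `rss`, `n`.
#' @export
fit_fe_distribution <- function(fes, bin_width = 0.1) {
  check_scalar_number(bin_width, "bin_width", lower = 1e-9)
  if (length(fes) == 0L || any(fes <= 0)) {
    abort("fold enrichments must be positive")
  }
  x <- log10(fes)
  if (sd(x) < 1e-12) {
    abort("degenerate input: all fold enrichments identical; sd undefined")
  }
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  dat <- tibble(mid = h$mids, count = h$counts)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      count ~ a * exp(-(mid - mu)^2 / (2 * s^2)),
      data = dat,
      start = list(a = max(dat$count), mu = mean(x), s = max(sd(x), bin_width)),
      lower = c(a = 1e-9, mu = -Inf, s = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      abort(sprintf("degenerate Gaussian fit: %s (residual range %.3g..%.3g)",
                    conditionMessage(e), min(dat$count), max(dat$count)))
    }
  )
  cf <- coef(fit)
  structure(
    list(histogram = dat,
         amplitude = unname(cf["a"]), mean = unname(cf["mu"]),
         sd = unname(cf["s"]),
         area = unname(cf["a"] * cf["s"] * sqrt(2 * pi)),
         rss = sum(resid(fit)^2), n = length(fes)),
    class = "fe_fit"
  )
}

#' @export
print.fe_fit <- function(x, ...) {
  cat(sprintf("log10-FE Gaussian fit on %d peaks: area = %.4g, mean = %.4g, sd = %.4g\n",
              x$n, x$area, x$mean, x$sd))
  invisible(x)
}

#' Stage specificity of differential verdicts across timepoints
#'
#' Counts, per direction, genes carrying the same non-`ns` verdict at both
#' timepoints, and the fraction of timepoint-1 calls NOT reproduced at
#' timepoint 2: `1 - (overlap_up + overlap_down) / (t1_up + t1_down)`.
#'
#' @param de_t1,de_t2 Verdict tibbles (`feature`, `verdict`) for the two
#'   timepoints.
#' @return List with `overlap` (tibble: `direction`, `t1`, `t2`, `shared`)
#'   and `specificity`.
#' @export
stage_specificity <- function(de_t1, de_t2) {
  count_dir <- function(v, d) sum(v$verdict == d)
  shared_dir <- function(d) {
    length(intersect(de_t1$feature[de_t1$verdict == d],
                     de_t2$feature[de_t2$verdict == d]))
  }
  overlap <- tibble(
    direction = c("up", "down"),
    t1 = c(count_dir(de_t1, "up"), count_dir(de_t1, "down")),
    t2 = c(count_dir(de_t2, "up"), count_dir(de_t2, "down")),
    shared = c(shared_dir("up"), shared_dir("down"))
  )
  t1_total <- sum(overlap$t1)
  spec <- if (t1_total == 0) NA_real_ else 1 - sum(overlap$shared) / t1_total
  list(overlap = overlap, specificity = spec)
}
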