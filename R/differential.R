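# Differential calling. The moderated t re-implements the empirical-Bayes
# variance shrinkage of Smyth (2004): per-feature residual variances are
# modelled as scaled inverse-chi-square draws around a prior (d0, s0^2)
# estimated by moment matching on the log variances; posterior variances
# shrink each feature's variance toward the prior. limma is used only as an
# independent cross-check in the test suite, never as the implementation.

# Newton inversion of the trigamma function (monotone decreasing on (0,Inf))
trigamma_inverse <- function(y) {
  if (!is.finite(y) || y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-12) break
  }
  x
}

#' Empirical-Bayes variance shrinkage
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s02` of
#' a scaled inverse-chi-square distribution from observed residual
#' variances by moment matching on the log scale (mean and variance of
#' `log s^2` against the digamma/trigamma moments of the log-chi-square),
#' then forms posterior variances
#' `s2_post = (d0 s02 + df s2) / (d0 + df)`.
#'
#' @param s2 Per-feature residual variances.
#' @param df Residual degrees of freedom (scalar or per-feature).
#' @return List with `d0`, `s02`, `s2_post`. `d0` is `Inf` when the
#'   observed log-variances are no more dispersed than sampling noise.
#' @export
squeeze_var <- function(s2, df) {
  if (length(df) == 1L) df <- rep(df, length(s2))
  if (any(s2 <= 0) || any(df <= 0)) {
    abort("squeeze_var needs positive variances and degrees of freedom")
  }
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(df / 2))
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- exp(emean)
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else {
    (d0 * s02 + df * s2) / (d0 + df)
  }
  list(d0 = d0, s02 = s02, s2_post = s2_post)
}

#' Moderated two-group t-test
#'
#' Smyth-style moderated t for a two-group comparison on (log2) values.
#' Features with any missing value or fewer than 2 replicates per group are
#' excluded from the test (they belong on the exclusive-detection path).
#' Per-feature pooled variances are shrunk via [squeeze_var()]; the
#' moderated t uses `d0 + df` total degrees of freedom and BH adjustment
#' across tested features.
#'
#' @param values Matrix or `omics_tbl` of log2 values with
#'   `group_replicate` columns.
#' @param ref,case Group labels; defaults to the order the groups appear.
#' @return Object of class `moderated_fit`: list with `table` (tibble:
#'   `feature`, `log2fc` = case minus ref mean, `t_mod`, `df_total`,
#'   `p_value`, `adj_p`, `s2`, `s2_post`), hyperparameters `d0`, `s02`,
#'   `df_resid`, and `excluded` (untestable feature ids). [tidy()] returns
#'   the table, [glance()] the hyperparameters.
#' @export
moderated_t <- function(values, ref = NULL, case = NULL) {
  if (is_tibble(values) || is.data.frame(values)) {
    m <- omics_values(omics_matrix(as_tibble(values), "intensity"))
  } else {
    m <- as.matrix(values)
  }
  groups <- sub("_[0-9]+$", "", colnames(m))
  if (is.null(ref)) ref <- unique(groups)[1]
  if (is.null(case)) case <- setdiff(unique(groups), ref)[1]
  if (is.na(case) || !all(c(ref, case) %in% groups)) {
    abort("need two groups with samples present")
  }
  m1 <- m[, groups == ref, drop = FALSE]
  m2 <- m[, groups == case, drop = FALSE]
  n1 <- ncol(m1); n2 <- ncol(m2)
  if (n1 < 2L || n2 < 2L) abort("need >= 2 replicates per group")
  ok <- complete.cases(m1) & complete.cases(m2)
  excluded <- rownames(m)[!ok]
  m1 <- m1[ok, , drop = FALSE]
  m2 <- m2[ok, , drop = FALSE]
  if (nrow(m1) < 2L) abort("need >= 2 testable features")
  mu1 <- rowMeans(m1)
  mu2 <- rowMeans(m2)
  df <- n1 + n2 - 2L
  s2 <- (rowSums((m1 - mu1)^2) + rowSums((m2 - mu2)^2)) / df
  s2 <- pmax(s2, 1e-12)  # guard exactly-constant features
  sq <- squeeze_var(s2, df)
  df_total <- df + sq$d0
  se <- sqrt(sq$s2_post * (1 / n1 + 1 / n2))
  t_mod <- (mu2 - mu1) / se
  p <- 2 * pt(-abs(t_mod), df = df_total)
  tbl <- tibble(
    feature = rownames(m1),
    log2fc = unname(mu2 - mu1),
    t_mod = unname(t_mod),
    df_total = df_total,
    p_value = unname(p),
    adj_p = unname(p.adjust(p, method = "BH")),
    s2 = unname(s2),
    s2_post = unname(sq$s2_post)
  )
  structure(
    list(table = tbl, d0 = sq$d0, s02 = sq$s02, df_resid = df,
         ref = ref, case = case, excluded = excluded),
    class = "moderated_fit"
  )
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat(sprintf("Moderated two-group fit: %s vs %s\n", x$case, x$ref))
  cat(sprintf("  %d features tested, %d excluded (missing values)\n",
              nrow(x$table), length(x$excluded)))
  cat(sprintf("  prior df d0 = %.4g, prior variance s0^2 = %.4g\n",
              x$d0, x$s02))
  invisible(x)
}

#' Exact two-group count test
#'
#' Conditional on the total `n = c1 + c2`, tests `c1 ~ Binomial(n, pi0)`
#' with `pi0 = N1 / (N1 + N2)` given library sizes `N1`, `N2`; the
#' two-sided p-value sums the probabilities of all outcomes no more likely
#' than the observed one. A Poisson-conditional simplification of the
#' count-based differential test; zero totals give p = 1.
#'
#' @param c1,c2 Counts (vectors recycle) for the two groups.
#' @param n1_lib,n2_lib Library sizes (total counts) of the two groups.
#' @return Vector of two-sided p-values.
#' @examples
#' exact_count_test(10, 0, 100, 100)  # 2 * 0.5^10
#' @export
exact_count_test <- function(c1, c2, n1_lib, n2_lib) {
  if (n1_lib <= 0 || n2_lib <= 0) abort("library sizes must be positive")
  pi0 <- n1_lib / (n1_lib + n2_lib)
  n <- c1 + c2
  purrr::map2_dbl(c1, n, function(k, tot) {
    if (tot == 0) return(1)
    d <- dbinom(0:tot, tot, pi0)
    min(1, sum(d[d <= d[k + 1] * (1 + 1e-7)]))
  })
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotone enforcement (delegates to
#' [stats::p.adjust()]); p-values outside (0, 1] are an error.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Layer-specific differential verdicts
#'
#' Applies the study's decision rules per omics layer. For features
#' detected in both groups ("overlay"), a verdict requires the layer's
#' significance rule (adjusted p, or raw p for RNA when
#' `use_adjusted = FALSE`) below `alpha` AND fold change at or beyond
#' `fc_cut` (up) / `1/fc_cut` (down). Features detected exclusively in one
#' group bypass the test: proteins are called by direction of detection
#' unconditionally; ac4C mRNAs are called when their pseudocounted fold
#' change passes `fc_cut` / `1/fc_cut`; RNA exclusives are not called.
#'
#' @param features Tibble with `feature`, `detected_g1` (reference),
#'   `detected_g2` (case), `fc`, and `p` / `adj_p` (NA allowed for
#'   exclusives).
#' @param layer One of `"protein"`, `"ac4c"`, `"rna"`.
#' @param alpha Significance threshold.
#' @param fc_cut Fold-change threshold (>= 1).
#' @param use_adjusted Use BH-adjusted p for the overlay rule.
#' @return Tibble with `feature`, `verdict` (`up` / `down` / `ns`),
#'   `basis` (`overlay-test` / `exclusive-rule`).
#' @export
call_de <- function(features, layer = c("protein", "ac4c", "rna"),
                    alpha = 0.05, fc_cut = 2, use_adjusted = TRUE) {
  if (!is.character(layer) || !layer[1] %in% c("protein", "ac4c", "rna")) {
    abort(sprintf("unknown layer '%s'", layer[1]))
  }
  layer <- layer[1]
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  check_scalar_number(fc_cut, "fc_cut", lower = 1)
  ft <- as_tibble(features)
  pcol <- if (use_adjusted) "adj_p" else "p"
  overlay <- ft$detected_g1 & ft$detected_g2
  sig <- !is.na(ft[[pcol]]) & ft[[pcol]] < alpha
  verdict <- rep("ns", nrow(ft))
  basis <- rep("overlay-test", nrow(ft))
  verdict[overlay & sig & ft$fc >= fc_cut] <- "up"
  verdict[overlay & sig & ft$fc <= 1 / fc_cut] <- "down"
  excl_case <- ft$detected_g2 & !ft$detected_g1
  excl_ref <- ft$detected_g1 & !ft$detected_g2
  if (layer == "protein") {
    verdict[excl_case] <- "up"
    verdict[excl_ref] <- "down"
    basis[excl_case | excl_ref] <- "exclusive-rule"
  } else if (layer == "ac4c") {
    verdict[excl_case & ft$fc >= fc_cut] <- "up"
    verdict[excl_ref & ft$fc <= 1 / fc_cut] <- "down"
    basis[excl_case | excl_ref] <- "exclusive-rule"
  }
  # RNA: exclusives are not part of the count-test rule; they stay ns
  tibble(feature = ft$feature, verdict = verdict, basis = basis)
}
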