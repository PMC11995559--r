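test_that("venn classes partition the detection union", {
  cls <- venn_classify(c("a", "b"), c("b", "c"))
  expect_equal(as.character(cls$class[cls$feature == "a"]), "AD absent")
  expect_equal(as.character(cls$class[cls$feature == "b"]), "Overlay")
  expect_equal(as.character(cls$class[cls$feature == "c"]), "AD unique")
  expect_equal(unname(venn_counts(cls)), c(1L, 1L, 1L))

  same <- venn_classify(letters[1:5], letters[1:5])
  expect_true(all(same$class == "Overlay"))

  set.seed(41)
  for (rep in 1:10) {
    wt <- sample(letters, sample(5:20, 1))
    ad <- sample(letters, sample(5:20, 1))
    cls <- venn_classify(wt, ad)
    expect_equal(nrow(cls), length(union(wt, ad)))
    expect_equal(sum(venn_counts(cls)), length(union(wt, ad)))
  }
})

test_that("cross-classification fixes groups 1 and 7 and counts both-DE", {
  pv <- tibble::tibble(feature = c("g1", "g2", "g3", "g4"),
                       verdict = c("up", "down", "ns", "up"))
  av <- tibble::tibble(feature = c("g1", "g2", "g3", "g5"),
                       verdict = c("up", "down", "up", "down"))
  cc <- suppressMessages(cross_classify(pv, av))
  expect_equal(nrow(cc), 3L)  # g4/g5 present in only one layer
  expect_equal(cc$group[cc$feature == "g1"], 1L)   # up/up
  expect_equal(cc$group[cc$feature == "g2"], 7L)   # down/down
  expect_false(cc$both_de[cc$feature == "g3"])     # protein ns never both-DE
  counts <- cross_counts(cc)
  expect_equal(sum(counts$groups), nrow(cc))
  expect_equal(counts$both_de, 2L)
  # both-DE equals the sum of the four corner cells
  corners <- counts$table[c("up", "down"), c("up", "down")]
  expect_equal(counts$both_de, sum(corners))
})

test_that("KS statistic matches a brute-force ECDF sweep", {
  expect_equal(ks_compare(1:5, 1:5)$statistic, 0)
  expect_equal(ks_compare(1:100, 101:200)$statistic, 1)
  expect_equal(ks_compare(c(1, 2, 3), c(1.5, 2.5, 3.5))$statistic, 1 / 3)
  brute_d <- function(a, b) {
    grid <- sort(unique(c(a, b)))
    max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
  }
  set.seed(42)
  for (rep in 1:15) {
    a <- rnorm(sample(10:60, 1)); b <- rnorm(sample(10:60, 1), mean = 0.3)
    expect_equal(ks_compare(a, b)$statistic, brute_d(a, b),
                 tolerance = 1e-12)
  }
  expect_error(ks_compare(numeric(), 1:3), "empty")
})

test_that("Yates chi-square and phi match hand computation", {
  conc <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(phi_coef(conc)$phi, 1)
  indep <- matrix(c(5, 5, 5, 5), 2)
  expect_equal(chi2_yates(indep)$statistic, 0)
  expect_equal(chi2_yates(indep)$p_value, 1)
  tab <- matrix(c(20, 10, 10, 20), 2)
  expect_equal(chi2_yates(tab)$statistic, 4 * (4.5^2 / 15))  # 5.4
  expect_equal(phi_coef(tab)$phi, 1 / 3)
  expect_false(phi_coef(conc)$low_relevance)
  expect_true(phi_coef(matrix(c(11, 9, 9, 11), 2))$low_relevance)
  expect_error(chi2_yates(matrix(c(0, 0, 5, 5), 2)), "margin")
  # agreement with the standard corrected test
  set.seed(43)
  for (rep in 1:10) {
    t2 <- matrix(rpois(4, 20) + 1, 2)
    expect_equal(chi2_yates(t2)$statistic,
                 unname(chisq.test(t2, correct = TRUE)$statistic),
                 tolerance = 1e-12)
  }
})

test_that("PCA filter keeps the top half by MAD and separates groups", {
  m <- matrix(rnorm(24), 4, 6,
              dimnames = list(paste0("f", 1:4),
                              c(paste0("WT_", 1:3), paste0("FAD_", 1:3))))
  m <- m - rowMeans(m)
  m <- m / apply(m, 1, mad) * c(1e-9, 1, 2, 3)  # MADs ~ (0, 1, 2, 3)
  m <- m + 10  # keep variances above the floor for rows 2..4
  pc <- pca_top_mad(m, variance_floor = 0)
  expect_equal(length(pc$kept_features), 2L)
  expect_setequal(pc$kept_features, c("f3", "f4"))

  dup <- matrix(5, 4, 4,
                dimnames = list(paste0("f", 1:4),
                                c("WT_1", "WT_2", "FAD_1", "FAD_2")))
  pcd <- pca_top_mad(dup + rnorm(4), variance_floor = -1)  # row shifts only
  expect_true(all(abs(pcd$scores$PC1) < 1e-10))  # duplicates separate nothing

  expect_error(pca_top_mad(m[, 1:2]), "3 samples")

  # planted clusters: groups separate on PC1-2
  set.seed(44)
  sig <- matrix(rnorm(600, sd = 0.3), 100, 6)
  sig[1:40, 4:6] <- sig[1:40, 4:6] + 2
  dimnames(sig) <- list(sprintf("f%03d", 1:100),
                        c(paste0("WT_", 1:3), paste0("FAD_", 1:3)))
  pcs <- pca_top_mad(sig, variance_floor = 0)
  sc <- pcs$scores
  centroid_gap <- sqrt(sum((colMeans(sc[sc$group == "WT", c("PC1", "PC2")]) -
                              colMeans(sc[sc$group == "FAD", c("PC1", "PC2")]))^2))
  within <- max(dist(sc[sc$group == "WT", c("PC1", "PC2")]))
  expect_gt(centroid_gap, within)

  # full-rank reconstruction is exact
  recon <- pcs$scores |>
    dplyr::select(dplyr::starts_with("PC")) |>
    as.matrix() %*% t(pcs$loadings)
  centered <- t(sig[pcs$kept_features, ] - rowMeans(sig[pcs$kept_features, ]))
  expect_lt(max(abs(recon - centered)), 1e-8)
})

test_that("Spearman matrix has unit diagonal and detects reversed ranks", {
  m <- matrix(c(1, 2, 3, 4, 4, 3, 2, 1), 4, 2,
              dimnames = list(paste0("f", 1:4), c("WT_1", "WT_2")))
  rho <- spearman_matrix(m)
  expect_equal(diag(rho), c(WT_1 = 1, WT_2 = 1))
  expect_equal(rho[1, 2], -1)

  res <- tiny_result()
  rr <- res$integration$spearman
  grp <- sub("_[0-9]+$", "", colnames(rr))
  intra <- rr[outer(grp, grp, "==") & upper.tri(rr)]
  inter <- rr[outer(grp, grp, "!=") & upper.tri(rr)]
  expect_gt(mean(intra), mean(inter))
})

test_that("the log10-FE Gaussian fit recovers planted parameters", {
  set.seed(45)
  fes <- 10^rnorm(1e4, mean = 0.4, sd = 0.5)
  fit <- fit_fe_distribution(fes)
  expect_lt(abs(fit$sd - 0.5) / 0.5, 0.1)
  expect_lt(abs(fit$mean - 0.4), 0.05)
  # doubling the data doubles the area, sd unchanged
  fit2 <- fit_fe_distribution(c(fes, fes))
  expect_equal(fit2$area / fit$area, 2, tolerance = 0.01)
  expect_equal(fit2$sd, fit$sd, tolerance = 1e-6)
  # area approximates n * bin_width
  expect_lt(abs(fit$area - 1e4 * 0.1) / (1e4 * 0.1), 0.05)

  expect_error(fit_fe_distribution(rep(2, 100)), "degenerate")
  expect_error(fit_fe_distribution(c(-1, 2)), "positive")
})

test_that("stage specificity is the unreproduced fraction of t1 calls", {
  v <- function(ids_up, ids_dn) {
    tibble::tibble(feature = c(ids_up, ids_dn),
                   verdict = rep(c("up", "down"),
                                 c(length(ids_up), length(ids_dn))))
  }
  t1 <- v(sprintf("u%02d", 1:10), sprintf("d%02d", 1:10))
  expect_equal(stage_specificity(t1, t1)$specificity, 0)
  t2_disjoint <- v("x1", "x2")
  expect_equal(stage_specificity(t1, t2_disjoint)$specificity, 1)
  t2 <- v(c("u01", "y1"), c("d01", "y2"))
  ss <- stage_specificity(t1, t2)
  expect_equal(ss$specificity, 0.9)  # 1 - (1+1)/(10+10)
  expect_equal(ss$overlap$shared, c(1L, 1L))
  # direction must match: an up call at t1 reappearing as down is not shared
  t2_flip <- v("d01", "u01")
  expect_equal(stage_specificity(t1, t2_flip)$overlap$shared, c(0L, 0L))
})
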