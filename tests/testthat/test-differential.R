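test_that("moderated t matches an independent closed-form implementation", {
  set.seed(31)
  for (rep in 1:25) {
    m <- rand_mat(50, 4, 4)
    fit <- moderated_t(m, ref = "A", case = "B")
    oracle <- smyth_oracle(m, 4, 4)
    expect_equal(fit$d0, oracle$d0, tolerance = 1e-9)
    expect_equal(fit$s02, oracle$s02, tolerance = 1e-10)
    expect_equal(fit$table$t_mod, oracle$t, tolerance = 1e-10)
    expect_equal(fit$table$p_value, oracle$p, tolerance = 1e-10)
    expect_equal(fit$table$log2fc, oracle$lfc, tolerance = 1e-12)
  }
})

test_that("moderated t agrees with limma on the same data", {
  skip_if_not_installed("limma")
  set.seed(32)
  m <- rand_mat(300, 3, 3)
  fit <- moderated_t(m, ref = "A", case = "B")
  design <- cbind(1, rep(c(0, 1), each = 3))
  lf <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(fit$d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(fit$s02, lf$s2.prior, tolerance = 1e-6)
  expect_equal(fit$table$t_mod, unname(lf$t[, 2]), tolerance = 1e-6)
  expect_equal(fit$table$p_value, unname(lf$p.value[, 2]), tolerance = 1e-6)
})

test_that("with zero prior df the statistic is the pooled two-sample t", {
  set.seed(33)
  m <- rand_mat(40, 3, 4)
  fit <- moderated_t(m, ref = "A", case = "B")
  # d0 -> 0 limit: s2_post collapses to the per-feature pooled variance
  t_d0_zero <- fit$table$log2fc / sqrt(fit$table$s2 * (1 / 3 + 1 / 4))
  classic <- vapply(seq_len(nrow(m)), function(i) {
    unname(t.test(m[i, 4:7], m[i, 1:3], var.equal = TRUE)$statistic)
  }, numeric(1))
  expect_equal(t_d0_zero, classic, tolerance = 1e-10)
})

test_that("equal observed variances are a shrinkage fixed point", {
  # identical s2 for all features: evar <= 0, so d0 = Inf and s2_post = s02
  set.seed(34)
  # copies of one row plus per-feature shifts: every s2 is identical
  m <- matrix(rep(rnorm(8), 30), nrow = 30, byrow = TRUE) + seq_len(30)
  colnames(m) <- c(paste0("A_", 1:4), paste0("B_", 1:4))
  rownames(m) <- sprintf("f%02d", 1:30)
  fit <- moderated_t(m, ref = "A", case = "B")
  expect_true(is.infinite(fit$d0))
  expect_equal(unique(round(fit$table$s2_post, 12)),
               round(fit$s02, 12))
})

test_that("features with missing values are routed off the overlay test", {
  set.seed(35)
  m <- rand_mat(20, 3, 3)
  m[3, 2] <- NA
  m[7, 5] <- NA
  fit <- moderated_t(m, ref = "A", case = "B")
  expect_setequal(fit$excluded, c("f003", "f007"))
  expect_equal(nrow(fit$table), 18L)
  g <- glance(fit)
  expect_equal(g$n_excluded, 2L)
  expect_error(moderated_t(m[, c(1, 4)], ref = "A", case = "B"),
               "2 replicates")
})

test_that("exact count test matches enumeration and binom.test", {
  expect_equal(exact_count_test(5, 5, 1e6, 1e6), 1)
  expect_equal(exact_count_test(10, 0, 1e6, 1e6), 2 * 0.5^10,
               tolerance = 1e-12)
  expect_equal(exact_count_test(0, 0, 1e6, 1e6), 1)
  set.seed(36)
  for (rep in 1:30) {
    n1 <- sample(1e5:2e5, 1); n2 <- sample(1e5:2e5, 1)
    c1 <- rpois(1, 30); c2 <- rpois(1, 30)
    if (c1 + c2 == 0) next
    bt <- binom.test(c1, c1 + c2, n1 / (n1 + n2))$p.value
    expect_equal(exact_count_test(c1, c2, n1, n2), bt, tolerance = 1e-9)
  }
})

test_that("exact count test size never exceeds nominal (totals <= 30)", {
  for (n in 1:30) {
    p <- exact_count_test(0:n, n - (0:n), 1e6, 1e6)
    size <- sum(dbinom(0:n, n, 0.5)[p <= 0.05])
    expect_lte(size, 0.05)
  }
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.03, 5)), rep(0.03, 5))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  step_up <- function(p) {  # brute-force definition
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  set.seed(37)
  for (rep in 1:20) {
    p <- runif(sample(3:50, 1))
    expect_equal(bh_adjust(p), step_up(p), tolerance = 1e-12)
  }
})

test_that("verdict rules combine significance, fold change and exclusivity", {
  ft <- tibble::tibble(
    feature = c("excl_up", "excl_dn", "ov_weak", "ov_up", "ov_dn", "ov_ns"),
    detected_g1 = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    detected_g2 = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    fc = c(4, 0.25, 1.7, 2.5, 0.4, 1.1),
    p = c(NA, NA, 0.03, 0.001, 0.001, 0.8),
    adj_p = c(NA, NA, 0.03, 0.002, 0.002, 0.9)
  )
  prot <- call_de(ft, "protein")
  expect_equal(prot$verdict,
               c("up", "down", "ns", "up", "down", "ns"))
  expect_equal(prot$basis[1:2], rep("exclusive-rule", 2))
  expect_true(all(prot$basis[3:6] == "overlay-test"))

  ac <- call_de(ft, "ac4c")
  expect_equal(ac$verdict[1:2], c("up", "down"))
  # exclusive ac4c needs the fold-change gate
  ft2 <- dplyr::mutate(ft, fc = c(1.5, 0.8, 1.7, 2.5, 0.4, 1.1))
  ac2 <- call_de(ft2, "ac4c")
  expect_equal(ac2$verdict[1:2], c("ns", "ns"))

  rna <- call_de(ft, "rna")
  expect_equal(rna$verdict[1:2], c("ns", "ns"))  # no RNA exclusive rule
  expect_error(call_de(ft, "metabolome"), "unknown layer")

  # an undetected-in-case ac4C gene with reference FE 3 is a 'down' call
  rec <- tibble::tibble(feature = "g", detected_g1 = TRUE, detected_g2 = FALSE,
                        fc = gene_fc(0, 3), p = NA_real_, adj_p = NA_real_)
  expect_equal(call_de(rec, "ac4c")$verdict, "down")
})
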