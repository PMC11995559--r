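# Independent transcription of the empirical-Bayes moderated-t closed
# forms, written as plain loops with a bisection trigamma inverse and
# deliberately sharing no code with the package implementation.
smyth_oracle <- function(m, n1, n2) {
  g1 <- m[, seq_len(n1), drop = FALSE]
  g2 <- m[, n1 + seq_len(n2), drop = FALSE]
  df <- n1 + n2 - 2
  nfeat <- nrow(m)
  s2 <- lfc <- numeric(nfeat)
  for (i in seq_len(nfeat)) {
    s2[i] <- (sum((g1[i, ] - mean(g1[i, ]))^2) +
                sum((g2[i, ] - mean(g2[i, ]))^2)) / df
    lfc[i] <- mean(g2[i, ]) - mean(g1[i, ])
  }
  s2 <- pmax(s2, 1e-12)
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  evar <- sum((e - mean(e))^2) / (nfeat - 1) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    lo <- 1e-8; hi <- 1e8
    for (k in 1:300) {
      mid <- sqrt(lo * hi)
      if (trigamma(mid) > evar) lo <- mid else hi <- mid
    }
    half_d0 <- sqrt(lo * hi)
    d0 <- 2 * half_d0
    s02 <- exp(mean(e) + digamma(half_d0) - log(half_d0))
    s2post <- (d0 * s02 + df * s2) / (d0 + df)
  } else {
    d0 <- Inf
    s02 <- exp(mean(e))
    s2post <- rep(s02, nfeat)
  }
  t <- lfc / sqrt(s2post * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(t), df = df + d0)
  list(d0 = d0, s02 = s02, t = t, p = p, lfc = lfc)
}

rand_mat <- function(nfeat, n1, n2, sd_spread = TRUE) {
  sds <- if (sd_spread) sqrt(1 / rgamma(nfeat, 3, 3)) else rep(1, nfeat)
  m <- matrix(rnorm(nfeat * (n1 + n2), sd = rep(sds, n1 + n2)), nrow = nfeat)
  rownames(m) <- sprintf("f%03d", seq_len(nfeat))
  colnames(m) <- c(paste0("A_", seq_len(n1)), paste0("B_", seq_len(n2)))
  m
}
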