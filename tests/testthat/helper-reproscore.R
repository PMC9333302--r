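# Shared fixtures and independent reference implementations used as
# oracles. The references deliberately take a different code path from
# the package (stats::t.test per feature, hand-rolled step-up) so that
# agreement is evidence, not tautology.

make_dataset <- function(values, labels, positive = NULL,
                         feature_kind = "continuous") {
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  rownames(values) <- paste0("s", seq_len(nrow(values)))
  df <- as.data.frame(values)
  df$outcome <- labels
  labeled_dataset(df, positive = positive,
                  genotype = feature_kind == "genotype")
}

random_small_dataset <- function(seed) {
  set.seed(seed)
  n_p <- sample(2:4, 1)
  n_m <- sample(2:4, 1)
  r <- sample(2:5, 1)
  make_dataset(matrix(rnorm((n_p + n_m) * r), n_p + n_m, r),
               rep(c("a", "b"), c(n_m, n_p)))
}

# straight-from-formula Benjamini-Hochberg step-up
ref_bh <- function(p) {
  r <- length(p)
  o <- order(p)
  adj <- p[o] * r / seq_len(r)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(r)
  out[o] <- adj
  out
}

# per-feature reference discovery via stats::t.test + ref_bh
ref_discover <- function(D, alpha = 0.05,
                         mcc = c("BH", "bonferroni", "none")) {
  mcc <- match.arg(mcc)
  pos <- D$outcomes == D$positive
  stats_tbl <- t(vapply(seq_len(ncol(D$values)), function(j) {
    tt <- stats::t.test(D$values[pos, j], D$values[!pos, j],
                        var.equal = TRUE)
    c(t = unname(tt$statistic), p = tt$p.value)
  }, numeric(2)))
  p_adj <- switch(mcc,
                  BH = ref_bh(stats_tbl[, "p"]),
                  bonferroni = pmin(1, stats_tbl[, "p"] * nrow(stats_tbl)),
                  none = stats_tbl[, "p"])
  list(t = stats_tbl[, "t"], p = stats_tbl[, "p"], p_adj = p_adj,
       biomarkers = colnames(D$values)[p_adj < alpha])
}
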