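#' Configure a biomarker discovery operator
#'
#' The discovery operator is parameterized by a per-feature two-sample
#' statistic, a significance threshold, and a multiple-comparison
#' correction: the canonical configuration is the two-sided
#' pooled-variance t-test at `alpha = 0.05` with Benjamini-Hochberg
#' correction. A feature is declared a biomarker when its corrected
#' p-value is strictly below `alpha`.
#'
#' @param test Per-feature statistic: `"t"` (pooled-variance two-sample
#'   t, the canonical choice) or `"welch"` (unequal-variance alternative,
#'   non-canonical).
#' @param alpha Significance threshold in (0, 1]. `alpha = 1` is allowed
#'   as a degenerate "declare everything" operator but triggers a warning.
#' @param mcc Multiple-comparison correction: `"BH"`, `"bonferroni"` or
#'   `"none"`.
#' @return A `discovery_config` object.
#' @examples
#' discovery_config()                      # BD_{t, 0.05, BH}
#' discovery_config(alpha = 0.01, mcc = "bonferroni")
#' @export
discovery_config <- function(test = c("t", "welch"), alpha = 0.05,
                             mcc = c("BH", "bonferroni", "none")) {
  test <- match.arg(test)
  mcc <- match.arg(mcc)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1)
  if (alpha == 1) {
    warning("alpha = 1 declares (almost) every feature a biomarker; ",
            "such an operator is trivially reproducible", call. = FALSE)
  }
  structure(list(test = test, alpha = alpha, mcc = mcc),
            class = "discovery_config")
}

#' @export
print.discovery_config <- function(x, ...) {
  cat("<discovery_config> BD_{", x$test, ", ", format(x$alpha), ", ",
      x$mcc, "}\n", sep = "")
  invisible(x)
}

#' Pooled-variance two-sample t statistic
#'
#' Computes `t = (mean(x_plus) - mean(x_minus)) / (s_p * sqrt(1/n_+ +
#' 1/n_-))` where `s_p` is the pooled standard deviation from the
#' unbiased per-group sample variances, with `df = n_+ + n_- - 2`.
#' When the pooled variance is exactly zero the continuity limit is
#' taken: equal means give `t = 0`, unequal means give `t = +/-Inf`.
#'
#' @param x_plus,x_minus Numeric value vectors for the two classes, each
#'   of length >= 2.
#' @return A list with elements `t_stat` and `df`.
#' @examples
#' pooled_t(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
pooled_t <- function(x_plus, x_minus) {
  np <- length(x_plus); nm <- length(x_minus)
  if (np < 2 || nm < 2) {
    stop("each class needs at least 2 values for the pooled t-test",
         call. = FALSE)
  }
  mp <- mean(x_plus); mm <- mean(x_minus)
  sp2 <- ((np - 1) * stats::var(x_plus) + (nm - 1) * stats::var(x_minus)) /
    (np + nm - 2)
  denom <- sqrt(sp2 * (1 / np + 1 / nm))
  t_stat <- if (denom == 0) {
    if (mp == mm) 0 else sign(mp - mm) * Inf
  } else {
    (mp - mm) / denom
  }
  list(t_stat = t_stat, df = np + nm - 2)
}

#' Two-sided t-test p-value
#'
#' @param t_stat t statistic (may be infinite).
#' @param df Degrees of freedom, >= 1.
#' @return `2 * P(T_df > |t|)`, in \[0, 1\].
#' @examples
#' two_sided_p(2, 10)
#' @export
two_sided_p <- function(t_stat, df) {
  stopifnot(all(df >= 1))
  2 * stats::pt(abs(t_stat), df = df, lower.tail = FALSE)
}

#' Multiple-comparison correction
#'
#' Benjamini-Hochberg step-up, Bonferroni, or no correction, applied
#' jointly across the family of tested features.
#'
#' @param p_raw Vector of raw p-values in \[0, 1\].
#' @param mcc `"BH"`, `"bonferroni"` or `"none"`.
#' @return Adjusted p-values, same length and order as `p_raw`.
#' @export
adjust_p <- function(p_raw, mcc = c("BH", "bonferroni", "none")) {
  mcc <- match.arg(mcc)
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_raw, method = c(BH = "BH", bonferroni = "bonferroni",
                                    none = "none")[[mcc]])
}

#' Discover biomarkers in a labeled dataset
#'
#' Runs the configured per-feature two-sample test over every feature,
#' corrects across the family of tested features, and returns the set of
#' features whose corrected p-value falls strictly below the threshold.
#' Features with fewer than two finite values in either class cannot be
#' tested; they are excluded from both candidacy and the correction
#' family. The test is two-sided, so the result does not depend on which
#' outcome label is designated positive.
#'
#' @param D A [labeled_dataset()]; each class must have >= 2 subjects.
#' @param config A [discovery_config()].
#' @return A `discovery_result` with `biomarkers` (character vector of
#'   feature ids) and a per-feature results tibble; see [tidy()] and
#'   [glance()] methods.
#' @examples
#' spec <- synthetic_spec(n_plus = 30, n_minus = 30, r = 20,
#'                        n_true = 5, delta = 2)
#' D <- generate_dataset(spec, seed = 1)
#' res <- discover(D)
#' res$biomarkers
#' @export
discover <- function(D, config = discovery_config()) {
  stopifnot(inherits(D, "labeled_dataset"),
            inherits(config, "discovery_config"))
  pos <- D$outcomes == D$positive
  np <- sum(pos); nm <- sum(!pos)
  if (np < 2 || nm < 2) {
    stop("each class needs at least 2 subjects (have ", np, " / ", nm, ")",
         call. = FALSE)
  }
  xp <- D$values[pos, , drop = FALSE]
  xm <- D$values[!pos, , drop = FALSE]

  tested <- rep(TRUE, ncol(D$values))
  if (anyNA(D$values)) {
    tested <- colSums(!is.na(xp)) >= 2 & colSums(!is.na(xm)) >= 2
  }

  mp <- colMeans(xp); mm <- colMeans(xm)
  # unbiased per-class variances, computed centered for stability
  vp <- colSums((xp - rep(mp, each = np))^2) / (np - 1)
  vm <- colSums((xm - rep(mm, each = nm))^2) / (nm - 1)

  if (config$test == "t") {
    sp2 <- ((np - 1) * vp + (nm - 1) * vm) / (np + nm - 2)
    denom <- sqrt(sp2 * (1 / np + 1 / nm))
    df <- rep(np + nm - 2, length(denom))
  } else {  # welch
    se2 <- vp / np + vm / nm
    denom <- sqrt(se2)
    df <- se2^2 / ((vp / np)^2 / (np - 1) + (vm / nm)^2 / (nm - 1))
    df[se2 == 0] <- np + nm - 2  # degenerate zero-variance case
  }
  diff <- mp - mm
  t_stat <- ifelse(denom == 0,
                   ifelse(diff == 0, 0, sign(diff) * Inf),
                   diff / denom)
  p_raw <- two_sided_p(t_stat, pmax(df, 1))
  p_raw[!tested] <- NA_real_
  t_stat[!tested] <- NA_real_

  p_adj <- rep(NA_real_, length(p_raw))
  p_adj[tested] <- adjust_p(p_raw[tested], config$mcc)

  results <- tibble::tibble(
    feature_id = colnames(D$values),
    t_stat = unname(t_stat),
    df = unname(df),
    p_raw = unname(p_raw),
    p_adj = unname(p_adj),
    tested = unname(tested),
    biomarker = !is.na(p_adj) & p_adj < config$alpha
  )
  structure(
    list(biomarkers = results$feature_id[results$biomarker],
         results = results, config = config, counts = class_counts(D)),
    class = "discovery_result"
  )
}

#' @export
print.discovery_result <- function(x, ...) {
  cat("<discovery_result> BD_{", x$config$test, ", ",
      format(x$config$alpha), ", ", x$config$mcc, "}: ",
      length(x$biomarkers), " / ", sum(x$results$tested),
      " tested features declared biomarkers\n", sep = "")
  invisible(x)
}

#' @describeIn discover Per-feature test results as a tibble.
#' @param x A `discovery_result`.
#' @param ... Unused.
#' @export
tidy.discovery_result <- function(x, ...) x$results

#' @describeIn discover One-row summary of the discovery run.
#' @export
glance.discovery_result <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$results),
    n_tested = sum(x$results$tested),
    n_biomarkers = length(x$biomarkers),
    test = x$config$test,
    alpha = x$config$alpha,
    mcc = x$config$mcc
  )
}
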