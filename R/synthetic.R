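#' Specify a synthetic two-class dataset with planted biomarkers
#'
#' Describes per-feature, per-class i.i.d. generating distributions with
#' a designated subset of truly differential ("planted") features, so
#' that ground truth is known. Two modes:
#'
#' * `continuous`: every feature is Gaussian with standard deviation
#'   `sigma` within each class; planted features have class means 0
#'   (negative) and `delta * sigma` (positive), non-planted features
#'   have mean 0 in both classes. Gaussian equal-variance classes are
#'   the canonical model because the pooled t-test assumes exactly
#'   that; `dist = "t"` substitutes unit-variance scaled Student-t
#'   noise (df `t_df`) for robustness experiments.
#' * `genotype`: features are minor-allele counts `Binomial(2, maf)`;
#'   planted features use `maf_plus` in the positive class and
#'   `maf_minus` in the negative class, non-planted features use
#'   `maf_minus` in both.
#'
#' Features are generated independently given the class by default;
#' `rho > 0` adds equicorrelated Gaussian blocks of `block_size`
#' features (continuous mode only) for experiments on correlated
#' designs. The planted features are always the first `n_true` feature
#' identifiers; [true_biomarkers()] returns them.
#'
#' @param n_plus,n_minus Class sizes (>= 2 each).
#' @param r Number of features.
#' @param n_true Number of planted differential features, `0 <= n_true
#'   <= r`.
#' @param delta Standardized mean shift of planted continuous features,
#'   in units of `sigma`.
#' @param sigma Within-class standard deviation (continuous mode).
#' @param mode `"continuous"` or `"genotype"`.
#' @param maf_plus,maf_minus Minor-allele frequencies for the positive /
#'   negative class (genotype mode; planted features only differ).
#' @param dist Continuous noise family: `"gaussian"` (canonical) or
#'   `"t"` (heavy-tailed, scaled to unit variance).
#' @param t_df Degrees of freedom for `dist = "t"` (> 2).
#' @param rho Within-block equicorrelation (continuous mode), default 0.
#' @param block_size Feature-block size used when `rho > 0`.
#' @return A `synthetic_spec` object.
#' @examples
#' synthetic_spec(n_plus = 100, n_minus = 100, r = 200, n_true = 20,
#'                delta = 1)
#' @export
synthetic_spec <- function(n_plus, n_minus, r, n_true = 0, delta = 0,
                           sigma = 1, mode = c("continuous", "genotype"),
                           maf_plus = 0.4, maf_minus = 0.2,
                           dist = c("gaussian", "t"), t_df = 4,
                           rho = 0, block_size = 10) {
  mode <- match.arg(mode)
  dist <- match.arg(dist)
  stopifnot(n_plus >= 2, n_minus >= 2, r >= 1,
            n_true >= 0, n_true <= r, sigma > 0,
            maf_plus >= 0, maf_plus <= 1, maf_minus >= 0, maf_minus <= 1,
            rho >= 0, rho < 1, t_df > 2)
  structure(
    list(n_plus = as.integer(n_plus), n_minus = as.integer(n_minus),
         r = as.integer(r), n_true = as.integer(n_true),
         delta = delta, sigma = sigma, mode = mode,
         maf_plus = maf_plus, maf_minus = maf_minus,
         dist = dist, t_df = t_df, rho = rho,
         block_size = as.integer(block_size)),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> ", x$n_plus, "+", x$n_minus, " subjects x ",
      x$r, " features (", x$mode, "), ", x$n_true, " planted",
      sep = "")
  if (x$mode == "continuous") {
    cat(" at delta = ", x$delta, " sigma", sep = "")
  } else {
    cat(" at maf ", x$maf_plus, " vs ", x$maf_minus, sep = "")
  }
  cat("\n")
  invisible(x)
}

feature_ids <- function(spec) {
  sprintf(paste0("f%0", nchar(spec$r), "d"), seq_len(spec$r))
}

#' Generate a labeled dataset from a synthetic specification
#'
#' Draws one dataset from the generating distributions of `spec`.
#' Deterministic for a fixed `seed`; with `seed = NULL` the current RNG
#' stream is consumed, which is how the Monte-Carlo ground-truth driver
#' produces independent replicates.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Optional integer seed.
#' @return A [labeled_dataset()]; positive subjects first, outcome
#'   labels `"pos"` / `"neg"` with `"pos"` positive.
#' @export
generate_dataset <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_plus + spec$n_minus
  r <- spec$r
  labels <- rep(c("pos", "neg"), c(spec$n_plus, spec$n_minus))

  if (spec$mode == "continuous") {
    noise <- if (spec$dist == "gaussian") {
      matrix(stats::rnorm(n * r), n, r)
    } else {
      # unit-variance scaled Student-t
      matrix(stats::rt(n * r, df = spec$t_df), n, r) /
        sqrt(spec$t_df / (spec$t_df - 2))
    }
    if (spec$rho > 0) {
      # equicorrelated blocks via a shared per-block factor
      blocks <- ceiling(seq_len(r) / spec$block_size)
      z <- matrix(stats::rnorm(n * max(blocks)), n, max(blocks))
      noise <- sqrt(spec$rho) * z[, blocks, drop = FALSE] +
        sqrt(1 - spec$rho) * noise
    }
    values <- noise * spec$sigma
    if (spec$n_true > 0) {
      shift <- spec$delta * spec$sigma
      values[labels == "pos", seq_len(spec$n_true)] <-
        values[labels == "pos", seq_len(spec$n_true)] + shift
    }
  } else {
    maf <- matrix(spec$maf_minus, n, r)
    if (spec$n_true > 0) {
      maf[labels == "pos", seq_len(spec$n_true)] <- spec$maf_plus
    }
    values <- matrix(stats::rbinom(n * r, size = 2, prob = maf), n, r)
  }

  colnames(values) <- feature_ids(spec)
  rownames(values) <- paste0("s", seq_len(n))
  new_labeled_dataset(values, labels, positive = "pos",
                      feature_kind = if (spec$mode == "genotype")
                        "genotype" else "continuous",
                      validate = FALSE)
}

#' Planted differential features of a synthetic specification
#'
#' @param spec A [synthetic_spec()].
#' @return Character vector of the `n_true` planted feature identifiers
#'   (the first `n_true` ids by convention).
#' @export
true_biomarkers <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  feature_ids(spec)[seq_len(spec$n_true)]
}
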