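#' Resampling estimators of the reproducibility score
#'
#' The reproducibility score of a biomarker discovery operator on a
#' dataset is the expected Jaccard overlap between the biomarker sets it
#' would return on two independent comparable datasets. That expectation
#' cannot be computed from a single dataset, but it can be bounded by
#' resampling: `estimate_rs()` repeats a split construction `k` times,
#' runs discovery on both members of each pair, and averages the Jaccard
#' scores.
#'
#' * `method = "oRS"` (overbound): doubling partitions, see
#'   [doubled_balanced_partition()].
#' * `method = "uRS"` (underbound): disjoint half-size partitions, see
#'   [disjoint_half_partition()].
#' * `method = "bRS"` (bootstrap variant): class-stratified bootstrap
#'   pairs; expected to exceed oRS, hence a looser overbound.
#'
#' Repetition `i` seeds the RNG with a child seed derived from `seed`
#' by a fixed counter scheme, so results are reproducible and extending
#' `k` does not reshuffle earlier repetitions.
#'
#' @param D A [labeled_dataset()].
#' @param config A [discovery_config()].
#' @param method One of `"oRS"`, `"uRS"`, `"bRS"`.
#' @param k Number of repetitions (default 50).
#' @param seed Integer root seed; if `NULL`, one is drawn and recorded.
#' @param discover_fun Optional replacement discovery function taking a
#'   `labeled_dataset` and returning a character vector of feature ids;
#'   defaults to [discover()] under `config`. Intended for plugging in
#'   non-canonical discovery operators.
#' @return An `rs_estimate`: method tag, `k`, per-iteration Jaccard
#'   values, their mean and sample standard deviation (denominator
#'   `k - 1`), child seeds, and the parent class counts.
#'
#' @examples
#' D <- generate_dataset(synthetic_spec(20, 20, r = 30, n_true = 5,
#'                                      delta = 2), seed = 7)
#' estimate_rs(D, k = 10, seed = 1, method = "oRS")
#' @export
estimate_rs <- function(D, config = discovery_config(),
                        method = c("oRS", "uRS", "bRS"), k = 50,
                        seed = NULL, discover_fun = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(D, "labeled_dataset"), k >= 1)
  splitter <- switch(method,
                     oRS = doubled_balanced_partition,
                     uRS = disjoint_half_partition,
                     bRS = bootstrap_pair)
  run_estimator(D, config, splitter, method, k, seed, discover_fun)
}

run_estimator <- function(D, config, splitter, method, k, seed,
                          discover_fun = NULL, subset_size = NA_integer_) {
  if (is.null(seed)) seed <- sample.int(2147483629L, 1)
  if (is.null(discover_fun)) {
    discover_fun <- function(d) discover(d, config)$biomarkers
  }
  per <- numeric(k)
  seeds <- integer(k)
  for (i in seq_len(k)) {
    seeds[i] <- child_seed(seed, i)
    set.seed(seeds[i])
    per[i] <- tryCatch({
      pair <- splitter(D)
      jaccard(discover_fun(pair$D1), discover_fun(pair$D2))
    }, error = function(e) {
      stop("repetition ", i, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  new_rs_estimate(method, per, seeds, seed, config,
                  counts = class_counts(D), subset_size = subset_size)
}

new_rs_estimate <- function(method, per, seeds, seed, config, counts,
                            subset_size = NA_integer_) {
  structure(
    list(method = method, k = length(per), per_iteration = per,
         mean = mean(per), sd = if (length(per) > 1) stats::sd(per) else 0,
         seed = seed, child_seeds = seeds, config = config,
         counts = counts, subset_size = subset_size),
    class = "rs_estimate"
  )
}

#' @export
print.rs_estimate <- function(x, ...) {
  cat("<rs_estimate> ", x$method,
      if (!is.na(x$subset_size)) paste0(" (s = ", x$subset_size, ")"),
      ": ", sprintf("%.3f +/- %.3f", x$mean, x$sd),
      " over k = ", x$k, " repetitions (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' @describeIn estimate_rs Per-iteration Jaccard values as a tibble.
#' @param x An `rs_estimate`.
#' @param ... Unused.
#' @export
tidy.rs_estimate <- function(x, ...) {
  tibble::tibble(method = x$method, iteration = seq_len(x$k),
                 child_seed = x$child_seeds, jaccard = x$per_iteration)
}

#' @describeIn estimate_rs One-row mean ± sd summary.
#' @export
glance.rs_estimate <- function(x, ...) {
  tibble::tibble(method = x$method, subset_size = x$subset_size,
                 k = x$k, mean = x$mean, sd = x$sd, seed = x$seed)
}

#' Truth-estimate of reproducibility for half-size datasets
#'
#' The underbound computed on the full dataset is a meaningful estimate
#' of the true reproducibility score of its half-size subsets: its
#' disjoint halves are genuinely independent size-n/2 draws from the
#' cohort. This is the reference value ("RS-hat") that validation
#' protocols compare against the bounds computed on a fixed half-size
#' subset.
#'
#' @inheritParams estimate_rs
#' @return An `rs_estimate` identical to `estimate_rs(D, config, "uRS",
#'   k, seed)` but tagged `"RS_hat"`.
#' @export
rs_hat_half <- function(D, config = discovery_config(), k = 50,
                        seed = NULL) {
  est <- estimate_rs(D, config, method = "uRS", k = k, seed = seed)
  est$method <- "RS_hat"
  est
}

#' Reproducibility as a function of subset size
#'
#' For each requested size `s`, repeatedly draws a pair of disjoint
#' outcome-balanced size-`s` subsets of the parent dataset, runs
#' discovery on each, and records the Jaccard overlap. Per-class counts
#' at size `s` follow the parent's class proportions, rounded by largest
#' remainder. Sizes that do not admit two disjoint subsets with at least
#' two subjects per class are skipped with a warning. On datasets with
#' real signal the resulting curve typically rises with `s`: larger
#' samples identify the underlying differential features more stably.
#'
#' @inheritParams estimate_rs
#' @param sizes Integer subset sizes, each at most `n / 2`.
#' @return An `rs_curve`: list of `rs_estimate`s plus a summary tibble
#'   (`subset_size`, `k`, `mean`, `sd`); see `tidy()`, `glance()` and
#'   `autoplot()` methods.
#' @export
subset_curve <- function(D, config = discovery_config(), sizes, k = 20,
                         seed = NULL) {
  stopifnot(inherits(D, "labeled_dataset"), length(sizes) >= 1)
  if (is.null(seed)) seed <- sample.int(2147483629L, 1)
  cc <- class_counts(D)
  n <- cc$n
  estimates <- list()
  for (j in seq_along(sizes)) {
    s <- as.integer(sizes[j])
    alloc <- allocate_classes(s, cc)
    if (is.null(alloc) || s > n %/% 2L) {
      warning("subset size s = ", s, " skipped: cannot draw two disjoint ",
              "outcome-balanced subsets with >= 2 subjects per class",
              call. = FALSE)
      next
    }
    splitter <- function(d) disjoint_subset_pair(d, alloc)
    est <- run_estimator(D, config, splitter, "subset-curve-point", k,
                         seed = child_seed(seed, 100000 + j),
                         subset_size = s)
    estimates[[as.character(s)]] <- est
  }
  if (length(estimates) == 0) {
    stop("no feasible subset size", call. = FALSE)
  }
  structure(
    list(estimates = estimates,
         summary = dplyr::bind_rows(lapply(estimates, glance.rs_estimate)),
         seed = seed, counts = cc, config = config),
    class = "rs_curve"
  )
}

# per-class counts for a size-s outcome-proportional subset, largest
# remainder rounding; NULL when infeasible (a class below 2 or pairs not
# disjoint within the parent)
allocate_classes <- function(s, cc) {
  n <- cc$n
  quota <- s * c(cc$n_minus, cc$n_plus) / n
  base <- floor(quota)
  rem <- s - sum(base)
  if (rem > 0) {
    ord <- order(quota - base, c(cc$n_minus, cc$n_plus),
                 decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  alloc <- list(minus = base[1], plus = base[2])
  feasible <- alloc$minus >= 2 && alloc$plus >= 2 &&
    2 * alloc$minus <= cc$n_minus && 2 * alloc$plus <= cc$n_plus
  if (!feasible) NULL else alloc
}

disjoint_subset_pair <- function(D, alloc) {
  rows1 <- integer(0); rows2 <- integer(0)
  lev <- levels(D$outcomes)  # negative level first
  want <- c(alloc$minus, alloc$plus)
  for (j in 1:2) {
    idx <- which(D$outcomes == lev[j])
    perm <- sample(idx)
    rows1 <- c(rows1, perm[seq_len(want[j])])
    rows2 <- c(rows2, perm[want[j] + seq_len(want[j])])
  }
  new_split_pair(D, rows1, rows2, "disjoint-subset")
}

#' @describeIn subset_curve All per-iteration values, one row per
#'   (size, iteration).
#' @param x An `rs_curve`.
#' @param ... Unused.
#' @export
tidy.rs_curve <- function(x, ...) {
  dplyr::bind_rows(lapply(x$estimates, function(e) {
    dplyr::mutate(tidy.rs_estimate(e), subset_size = e$subset_size)
  }))
}

#' @describeIn subset_curve Mean ± sd per subset size.
#' @export
glance.rs_curve <- function(x, ...) x$summary

#' @describeIn subset_curve Mean ± sd Jaccard against subset size.
#' @param object An `rs_curve`.
#' @export
autoplot.rs_curve <- function(object, ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subset_size, y = .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(0, .data$mean - .data$sd),
                   ymax = pmin(1, .data$mean + .data$sd)),
      alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "subset size s (subjects per subset)",
                  y = "mean Jaccard over k repetitions",
                  title = "Reproducibility vs. subset size") +
    ggplot2::theme_minimal()
}

#' @export
print.rs_curve <- function(x, ...) {
  cat("<rs_curve> ", nrow(x$summary), " subset sizes, k = ",
      x$estimates[[1]]$k, " (seed ", x$seed, ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Monte-Carlo ground-truth reproducibility score
#'
#' When the generating distribution is known — i.e. for synthetic data —
#' the true reproducibility score is the expected Jaccard overlap of
#' biomarker sets discovered on two *independent* datasets drawn from
#' that distribution. This routine estimates it by simulation: `k`
#' times, generate two independent datasets from `spec`, discover on
#' each, and average the Jaccard scores. It is the yardstick against
#' which the overbound and underbound estimators are validated.
#'
#' @param spec A [synthetic_spec()].
#' @inheritParams estimate_rs
#' @return An `rs_estimate` tagged `"RS_star"`.
#' @export
rs_star_monte_carlo <- function(spec, config = discovery_config(), k = 50,
                                seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"), k >= 1)
  if (is.null(seed)) seed <- sample.int(2147483629L, 1)
  per <- numeric(k)
  seeds <- integer(k)
  for (i in seq_len(k)) {
    seeds[i] <- child_seed(seed, i)
    set.seed(seeds[i])
    D1 <- generate_dataset(spec)
    D2 <- generate_dataset(spec)
    per[i] <- jaccard(discover(D1, config)$biomarkers,
                      discover(D2, config)$biomarkers)
  }
  new_rs_estimate("RS_star", per, seeds, seed, config,
                  counts = tibble::tibble(n_plus = spec$n_plus,
                                          n_minus = spec$n_minus,
                                          n = spec$n_plus + spec$n_minus))
}
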