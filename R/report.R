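#' Full reproducibility analysis of a labeled dataset
#'
#' The end-to-end workflow: run discovery on the complete dataset, then
#' compute the requested resampling estimators of the reproducibility
#' score (and optionally a subset-size curve), all from one root seed so
#' the whole report is regenerable from (input, config, seed).
#'
#' @param D A [labeled_dataset()].
#' @param config A [discovery_config()].
#' @param methods Estimators to run, a subset of `c("oRS", "uRS",
#'   "bRS")`.
#' @param k Repetitions per estimator (default 50).
#' @param subset_sizes Optional sizes for a [subset_curve()].
#' @param subset_k Repetitions per subset-curve point (default 20).
#' @param seed Integer root seed; if `NULL`, one is drawn and recorded.
#' @return An `rs_report` with the dataset summary, the full-data
#'   discovery result, one `rs_estimate` per method, and the optional
#'   curve; see `tidy()`/`glance()` and [write_report()].
#' @examples
#' D <- generate_dataset(synthetic_spec(20, 20, r = 30, n_true = 5,
#'                                      delta = 2), seed = 3)
#' rep <- reproducibility_report(D, k = 10, seed = 1)
#' glance(rep)
#' @export
reproducibility_report <- function(D, config = discovery_config(),
                                   methods = c("oRS", "uRS"), k = 50,
                                   subset_sizes = NULL, subset_k = 20,
                                   seed = NULL) {
  stopifnot(inherits(D, "labeled_dataset"))
  methods <- match.arg(methods, c("oRS", "uRS", "bRS"), several.ok = TRUE)
  if (is.null(seed)) seed <- sample.int(2147483629L, 1)
  full <- discover(D, config)
  estimates <- list()
  for (j in seq_along(methods)) {
    estimates[[methods[j]]] <-
      estimate_rs(D, config, method = methods[j], k = k,
                  seed = child_seed(seed, j * 10000000))
  }
  curve <- NULL
  if (!is.null(subset_sizes)) {
    curve <- subset_curve(D, config, sizes = subset_sizes, k = subset_k,
                          seed = child_seed(seed, 90000000))
  }
  structure(
    list(counts = class_counts(D), r = ncol(D$values),
         feature_kind = D$feature_kind, config = config,
         discovery = full, estimates = estimates, curve = curve,
         k = k, seed = seed,
         version = as.character(utils::packageVersion("reproscore")),
         timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)),
    class = "rs_report"
  )
}

#' @export
print.rs_report <- function(x, ...) {
  cat("<rs_report> ", x$counts$n, " subjects (", x$counts$n_plus, "+ / ",
      x$counts$n_minus, "-) x ", x$r, " ", x$feature_kind,
      " features\n", sep = "")
  cat("  BD_{", x$config$test, ", ", format(x$config$alpha), ", ",
      x$config$mcc, "}: ", length(x$discovery$biomarkers),
      " biomarkers on the full dataset\n", sep = "")
  for (e in x$estimates) {
    cat(sprintf("  %-6s %.3f +/- %.3f  (k = %d)\n",
                e$method, e$mean, e$sd, e$k))
  }
  if (!is.null(x$curve)) {
    cat("  subset curve over s = ",
        paste(x$curve$summary$subset_size, collapse = ", "), "\n",
        sep = "")
  }
  cat("  seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @describeIn reproducibility_report One row per estimator (mean, sd,
#'   k), echoing the layout used for summary tables.
#' @param x An `rs_report`.
#' @param ... Unused.
#' @export
tidy.rs_report <- function(x, ...) {
  dplyr::bind_rows(lapply(x$estimates, glance.rs_estimate))
}

#' @describeIn reproducibility_report One-row run summary.
#' @export
glance.rs_report <- function(x, ...) {
  tibble::tibble(
    n = x$counts$n, n_plus = x$counts$n_plus, n_minus = x$counts$n_minus,
    r = x$r, feature_kind = x$feature_kind,
    test = x$config$test, alpha = x$config$alpha, mcc = x$config$mcc,
    n_biomarkers = length(x$discovery$biomarkers),
    k = x$k, seed = x$seed
  )
}

#' Serialize a reproducibility report
#'
#' Writes the machine-readable JSON form (schema shipped at
#' `system.file("schema", "rs-report.schema.json", package =
#' "reproscore")`) or the human-readable TSV summary, one row per
#' estimator.
#'
#' @param report An [reproducibility_report()] result.
#' @param path Output file path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  stopifnot(inherits(report, "rs_report"))
  format <- match.arg(format)
  if (format == "tsv") {
    df <- dplyr::mutate(tidy.rs_report(report),
                        n = report$counts$n, r = report$r,
                        n_biomarkers = length(report$discovery$biomarkers))
    readr::write_tsv(df, path, progress = FALSE)
    return(invisible(path))
  }
  obj <- list(
    version = report$version,
    timestamp = report$timestamp,
    seed = report$seed,
    dataset = list(n = report$counts$n, n_plus = report$counts$n_plus,
                   n_minus = report$counts$n_minus, r = report$r,
                   feature_kind = report$feature_kind),
    config = list(test = report$config$test, alpha = report$config$alpha,
                  mcc = report$config$mcc),
    full_data_biomarkers = list(
      count = length(report$discovery$biomarkers),
      ids = report$discovery$biomarkers),
    estimates = lapply(report$estimates, function(e) {
      list(method = e$method, k = e$k, mean = e$mean, sd = e$sd,
           seed = e$seed, per_iteration = e$per_iteration,
           child_seeds = e$child_seeds)
    }),
    subset_curve = if (is.null(report$curve)) NULL else
      lapply(report$curve$estimates, function(e) {
        list(subset_size = e$subset_size, k = e$k, mean = e$mean,
             sd = e$sd, per_iteration = e$per_iteration)
      })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
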