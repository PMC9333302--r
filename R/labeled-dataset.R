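#' Construct a labeled two-class dataset
#'
#' A `labeled_dataset` is the unit of analysis throughout the package: an
#' `n` subjects x `r` features value matrix together with a binary outcome
#' per subject. Feature values must be either all continuous measurements
#' (e.g. expression) or all genotype counts in `{0, 1, 2}`; raw two-letter
#' genotype strings are converted with [encode_genotypes()] when
#' `genotype = TRUE`.
#'
#' @param data A data frame with one row per subject: feature columns plus
#'   one outcome column. Row names (or a column selected by `id`) supply
#'   subject identifiers; otherwise `s1 ... sn` are used.
#' @param outcome Column holding the binary outcome (bare name or string).
#'   Default `outcome`.
#' @param positive Which outcome level is the positive class. Default: the
#'   lexicographically larger of the two labels. The canonical two-sided
#'   discovery test makes results invariant to this choice.
#' @param id Optional column with subject identifiers.
#' @param genotype If `TRUE`, feature columns are genotype data: either
#'   two-character allele strings (routed through [encode_genotypes()]) or
#'   integers in `{0, 1, 2}`.
#' @param missing How to treat missing feature values: `"error"` (default)
#'   rejects the dataset; `"drop_features"` removes any feature column
#'   containing a missing entry, with a message.
#'
#' @return An object of class `labeled_dataset` with fields `values`
#'   (numeric matrix, subjects x features), `outcomes` (factor, negative
#'   level first), `positive`, and `feature_kind` (`"continuous"` or
#'   `"genotype"`).
#'
#' @examples
#' d <- data.frame(g1 = rnorm(6), g2 = rnorm(6),
#'                 outcome = rep(c("case", "control"), each = 3))
#' D <- labeled_dataset(d)
#' class_counts(D)
#' @export
labeled_dataset <- function(data, outcome = "outcome", positive = NULL,
                            id = NULL, genotype = FALSE,
                            missing = c("error", "drop_features")) {
  stopifnot(is.data.frame(data))
  missing <- match.arg(missing)
  out_col <- .col_name(rlang::enquo(outcome), data, default = "outcome")
  if (!out_col %in% names(data)) {
    stop("outcome column '", out_col, "' not found in `data`", call. = FALSE)
  }
  id_col <- .col_name_opt(rlang::enquo(id), data)
  if (!is.null(id_col)) {
    if (!id_col %in% names(data)) {
      stop("id column '", id_col, "' not found in `data`", call. = FALSE)
    }
    subject_ids <- as.character(data[[id_col]])
    data[[id_col]] <- NULL
  } else if (tibble::has_rownames(as.data.frame(data))) {
    subject_ids <- rownames(data)
  } else {
    subject_ids <- paste0("s", seq_len(nrow(data)))
  }

  labels <- as.character(data[[out_col]])
  feat <- data[setdiff(names(data), out_col)]
  if (ncol(feat) < 1L) stop("dataset has no feature columns", call. = FALSE)

  if (isTRUE(genotype)) {
    values <- encode_genotypes(feat)
    feature_kind <- "genotype"
  } else {
    non_num <- names(feat)[!vapply(feat, is.numeric, logical(1))]
    if (length(non_num) > 0) {
      stop("non-numeric feature column(s): ", .ellipsize(non_num),
           " (use `genotype = TRUE` for allele strings)", call. = FALSE)
    }
    values <- as.matrix(feat)
    feature_kind <- "continuous"
  }
  storage.mode(values) <- "double"
  rownames(values) <- subject_ids

  if (anyNA(values)) {
    if (missing == "error") {
      stop("dataset contains missing feature values; use ",
           "`missing = \"drop_features\"` to discard affected features",
           call. = FALSE)
    }
    bad <- colnames(values)[apply(values, 2, anyNA)]
    message("dropping ", length(bad), " feature(s) with missing values: ",
            .ellipsize(bad))
    values <- values[, !colnames(values) %in% bad, drop = FALSE]
    if (ncol(values) == 0L) stop("all features dropped", call. = FALSE)
  }

  new_labeled_dataset(values, labels, positive, feature_kind,
                      validate = TRUE)
}

# Internal constructor; `validate = FALSE` skips checks on hot resampling
# paths where the parent dataset is already known valid.
new_labeled_dataset <- function(values, labels, positive = NULL,
                                feature_kind = "continuous",
                                validate = TRUE) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (validate) {
    if (length(lev) != 2L) {
      stop("outcomes must take exactly two distinct values, got: ",
           .ellipsize(lev), call. = FALSE)
    }
    if (nrow(values) != length(labels)) {
      stop("value matrix has ", nrow(values), " rows but ", length(labels),
           " outcomes", call. = FALSE)
    }
    if (anyDuplicated(rownames(values))) {
      stop("subject identifiers must be unique", call. = FALSE)
    }
    if (anyDuplicated(colnames(values))) {
      stop("feature identifiers must be unique", call. = FALSE)
    }
    if (!all(is.finite(values))) {
      stop("feature values must be finite", call. = FALSE)
    }
    if (feature_kind == "genotype" && !all(values %in% c(0, 1, 2))) {
      stop("genotype-encoded values must lie in {0, 1, 2}", call. = FALSE)
    }
  }
  if (is.null(positive)) {
    positive <- lev[2L]  # lexicographically larger label
  } else if (!positive %in% lev) {
    stop("positive label '", positive, "' is not an outcome level (",
         paste(lev, collapse = ", "), ")", call. = FALSE)
  }
  negative <- setdiff(lev, positive)
  outcomes <- factor(labels, levels = c(negative, positive))
  structure(
    list(values = values, outcomes = outcomes, positive = positive,
         feature_kind = feature_kind),
    class = "labeled_dataset"
  )
}

#' Per-class subject counts
#'
#' @param D A [labeled_dataset()].
#' @return A one-row tibble with `n_plus`, `n_minus`, `n`.
#' @export
class_counts <- function(D) {
  stopifnot(inherits(D, "labeled_dataset"))
  pos <- D$outcomes == D$positive
  tibble::tibble(n_plus = sum(pos), n_minus = sum(!pos), n = length(pos))
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cc <- class_counts(x)
  cat("<labeled_dataset> ", cc$n, " subjects x ", ncol(x$values),
      " features (", x$feature_kind, ")\n", sep = "")
  cat("  outcomes: +'", x$positive, "' n=", cc$n_plus, " | -'",
      setdiff(levels(x$outcomes), x$positive), "' n=", cc$n_minus, "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.labeled_dataset <- function(x) dim(x$values)

#' Convert a labeled dataset to a tibble (subjects as rows)
#'
#' The outcome is appended as the final column, so the result round-trips
#' through [labeled_dataset()] / [write_dataset()] / [read_dataset()].
#'
#' @param x A `labeled_dataset`.
#' @param ... Unused.
#' @export
as_tibble.labeled_dataset <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(subject_id = rownames(x$values)),
    tibble::as_tibble(x$values),
    tibble::tibble(outcome = as.character(x$outcomes))
  )
}

# subset by parent row indices (duplicates allowed: ids made unique)
subset_dataset <- function(D, rows) {
  vals <- D$values[rows, , drop = FALSE]
  rownames(vals) <- make.unique(rownames(D$values)[rows])
  new_labeled_dataset(vals, as.character(D$outcomes)[rows],
                      positive = D$positive,
                      feature_kind = D$feature_kind, validate = FALSE)
}

# resolve a column argument given as a bare name, a string, or a
# variable holding a string; bare names matching a column win
.col_name <- function(quo, data, default = NULL) {
  if (rlang::quo_is_null(quo) && !is.null(default)) return(default)
  expr <- rlang::quo_get_expr(quo)
  if (is.character(expr)) return(expr)
  nm <- rlang::as_name(quo)
  if (nm %in% names(data)) return(nm)
  val <- tryCatch(rlang::eval_tidy(quo), error = function(e) NULL)
  if (is.character(val) && length(val) == 1L) return(val)
  nm
}

# as .col_name but NULL-propagating (for optional column arguments)
.col_name_opt <- function(quo, data) {
  if (rlang::quo_is_null(quo)) return(NULL)
  expr <- rlang::quo_get_expr(quo)
  if (is.character(expr)) return(expr)
  nm <- rlang::as_name(quo)
  if (nm %in% names(data)) return(nm)
  val <- tryCatch(rlang::eval_tidy(quo), error = function(e) NULL)
  if (is.null(val)) return(NULL)
  if (is.character(val) && length(val) == 1L) return(val)
  nm
}

.ellipsize <- function(x, k = 5) {
  if (length(x) > k) x <- c(x[seq_len(k)], "...")
  paste(x, collapse = ", ")
}
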