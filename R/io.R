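#' Read a labeled dataset from delimited text
#'
#' Parses a CSV/TSV file into a [labeled_dataset()]. The default layout
#' is subjects as rows with a header of feature names and one outcome
#' column; `orientation = "features"` accepts the transposed layout
#' common for expression matrices (features as rows, first column =
#' feature ids, one row holding the outcomes).
#'
#' @param path Path to a delimited text file with a header.
#' @param outcome Name of the outcome column (or outcome row id in
#'   `"features"` orientation). Default `"outcome"`.
#' @param positive Positive class label; default the lexicographically
#'   larger of the two.
#' @param orientation `"subjects"` (rows are subjects) or `"features"`
#'   (rows are features).
#' @param delim Field delimiter; default guessed from the extension
#'   (`.csv` comma, otherwise tab).
#' @param genotype If `TRUE`, feature values are genotype calls and are
#'   routed through [encode_genotypes()].
#' @param id Name of the subject-id column (subjects orientation only);
#'   default: first column if non-numeric and not a feature, else
#'   generated ids.
#' @param missing Passed to [labeled_dataset()].
#' @return A [labeled_dataset()].
#' @export
read_dataset <- function(path, outcome = "outcome", positive = NULL,
                         orientation = c("subjects", "features"),
                         delim = NULL, genotype = FALSE, id = NULL,
                         missing = c("error", "drop_features")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  # parse everything as text, then convert numerics with base R's
  # correctly-rounded parser so values survive round trips exactly
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(
                            .default = readr::col_character()))
  if (orientation == "features") {
    ids <- as.character(df[[1]])
    if (!outcome %in% ids) {
      stop("outcome row '", outcome, "' not found in first column",
           call. = FALSE)
    }
    mat <- t(as.matrix(df[-1]))
    colnames(mat) <- ids
    df <- tibble::as_tibble(mat, rownames = "subject_id")
    feat_cols <- setdiff(ids, outcome)
    if (!isTRUE(genotype)) {
      df[feat_cols] <- lapply(df[feat_cols], as.numeric)
    }
    id <- "subject_id"
  } else {
    if (!outcome %in% names(df)) {
      stop("outcome column '", outcome, "' not found in ", path,
           call. = FALSE)
    }
    if (is.null(id)) {
      first <- df[[1]]
      looks_feature <- if (isTRUE(genotype)) {
        all(nchar(first) == 2L | first %in% c("0", "1", "2"), na.rm = TRUE)
      } else {
        !anyNA(suppressWarnings(as.numeric(first)))
      }
      if (names(df)[1] != outcome && !looks_feature &&
          !anyDuplicated(first)) {
        id <- names(df)[1]
      }
    }
    if (!isTRUE(genotype)) {
      feat_cols <- setdiff(names(df), c(outcome, id))
      for (nm in feat_cols) {
        conv <- suppressWarnings(as.numeric(df[[nm]]))
        if (any(is.na(conv) & !is.na(df[[nm]]))) {
          stop("feature column '", nm, "' contains non-numeric values; ",
               "use `genotype = TRUE` for allele strings", call. = FALSE)
        }
        df[[nm]] <- conv
      }
    }
  }
  rlang::inject(
    labeled_dataset(df, outcome = !!outcome, positive = positive,
                    id = !!id, genotype = genotype, missing = missing)
  )
}

#' Write a labeled dataset as delimited text
#'
#' Writes subjects as rows, a `subject_id` column, feature columns and a
#' final `outcome` column at full precision, so
#' `read_dataset(write_dataset(D, path))` reproduces `D` exactly.
#'
#' @param D A [labeled_dataset()].
#' @param path Output path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(D, path) {
  stopifnot(inherits(D, "labeled_dataset"))
  df <- as_tibble.labeled_dataset(D)
  # serialize doubles at 17 significant digits so values survive the
  # text round trip bit-for-bit
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(df, path, progress = FALSE)
  } else {
    readr::write_tsv(df, path, progress = FALSE)
  }
  invisible(path)
}
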