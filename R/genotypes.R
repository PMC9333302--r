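#' Encode genotype calls as minor-allele counts
#'
#' Converts a matrix of two-character genotype strings (e.g. `"AA"`,
#' `"Ab"`, `"bb"`) to numeric minor-allele counts in `{0, 1, 2}`, the
#' standard additive SNP encoding. The minor allele of each feature is
#' the allele with the lower total count across all subjects of that
#' column; at an exact 50/50 tie the lexicographically later symbol is
#' taken as minor. A monomorphic column encodes to all zeros. Columns
#' that are already numeric `{0, 1, 2}` pass through unchanged, so the
#' operation is idempotent.
#'
#' @param raw A data frame or matrix, one column per SNP feature; cells
#'   are two-character allele strings or integers in `{0, 1, 2}`.
#' @return A numeric matrix of the same dimension with values in
#'   `{0, 1, 2}`.
#'
#' @examples
#' encode_genotypes(data.frame(snp1 = c("AA", "Ab", "bb", "bb", "bb")))
#' @export
encode_genotypes <- function(raw) {
  if (is.matrix(raw)) raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(raw))
  cols <- lapply(names(raw), function(nm) .encode_genotype_column(raw[[nm]], nm))
  out <- do.call(cbind, cols)
  colnames(out) <- names(raw)
  rownames(out) <- rownames(raw)
  out
}

.encode_genotype_column <- function(x, name) {
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1, 2) | is.na(x))) {
      stop("feature '", name, "': numeric genotype values must be 0, 1 or 2",
           call. = FALSE)
    }
    return(as.double(x))
  }
  x <- as.character(x)
  ok <- !is.na(x)
  if (any(nchar(x[ok]) != 2L)) {
    stop("feature '", name,
         "': genotype strings must have exactly two characters",
         call. = FALSE)
  }
  alleles <- strsplit(x[ok], "", fixed = TRUE)
  symbols <- sort(unique(unlist(alleles)))
  if (length(symbols) > 2L) {
    stop("feature '", name, "': more than two allele symbols (",
         paste(symbols, collapse = ", "), ")", call. = FALSE)
  }
  if (length(symbols) == 1L) {
    # monomorphic: the single observed allele is major, so zero minor copies
    out <- rep(NA_real_, length(x))
    out[ok] <- 0
    return(out)
  }
  counts <- table(factor(unlist(alleles), levels = symbols))
  # minor = lower total frequency; tie -> lexicographically later symbol,
  # which is symbols[2] since `symbols` is sorted ascending
  minor <- if (counts[[1]] < counts[[2]]) symbols[1] else symbols[2]
  out <- rep(NA_real_, length(x))
  out[ok] <- vapply(alleles, function(a) sum(a == minor), numeric(1))
  out
}
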