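#' Jaccard score of two biomarker sets
#'
#' Intersection over union of two feature-identifier sets: 1 if and only
#' if the sets are equal and non-empty, 0 if and only if they are
#' disjoint; by convention two empty sets score 0.
#'
#' @param A,B Character vectors of feature identifiers (duplicates are
#'   ignored).
#' @return A number in \[0, 1\].
#' @examples
#' jaccard(c("g1", "g2"), c("g2", "g3"))  # 1/3
#' jaccard(character(0), character(0))    # 0 by convention
#' @export
jaccard <- function(A, B) {
  A <- unique(as.character(A)); B <- unique(as.character(B))
  u <- length(union(A, B))
  if (u == 0) return(0)
  length(intersect(A, B)) / u
}

# Child-seed schedule: repetition i of a run rooted at `seed` uses
# ((seed - 1 + i * 1000003) mod 2147483629) + 1, so extending k leaves
# earlier repetitions untouched and every child stays below 2^31.
child_seed <- function(seed, i) {
  m <- 2147483629
  as.integer((as.double(seed) - 1 + as.double(i) * 1000003) %% m) + 1L
}

new_split_pair <- function(D, rows1, rows2, construction) {
  structure(
    list(D1 = subset_dataset(D, rows1),
         D2 = subset_dataset(D, rows2),
         rows1 = rows1, rows2 = rows2,
         construction = construction,
         parent_counts = class_counts(D),
         n_parent = nrow(D$values)),
    class = "split_pair"
  )
}

#' @export
print.split_pair <- function(x, ...) {
  cat("<split_pair> ", x$construction, ": |D1| = ", length(x$rows1),
      ", |D2| = ", length(x$rows2), " from ", x$n_parent,
      " parent subjects\n", sep = "")
  invisible(x)
}

#' Resampled dataset pairs for reproducibility estimation
#'
#' Three constructions of "comparable" dataset pairs (identical per-class
#' subject counts) from one parent dataset, each feeding one estimator:
#'
#' * `doubled_balanced_partition()` (overbound oRS): duplicate every
#'   subject, then partition the doubled multiset, per class, into two
#'   full-size halves uniformly at random over the copy slots. Each half
#'   may contain a subject twice; on average about half of the distinct
#'   subjects land in both halves, which is what makes the resulting
#'   Jaccard an overbound.
#' * `disjoint_half_partition()` (underbound uRS): per class, draw
#'   `floor(n_c / 2)` subjects without replacement into each half; the
#'   halves share no subject. With odd class counts one leftover subject
#'   per class sits out that repetition.
#' * `bootstrap_pair()` (bootstrap variant bRS): two independent
#'   class-stratified full-size resamples with replacement.
#'
#' These functions consume the current R random number stream; the
#' estimator drivers ([estimate_rs()]) seed that stream per repetition.
#'
#' @param D A [labeled_dataset()].
#' @return A `split_pair` with members `D1`, `D2` (labeled datasets with
#'   identical class counts), the parent row indices `rows1`, `rows2`,
#'   and the construction tag.
#' @examples
#' D <- generate_dataset(synthetic_spec(10, 10, r = 5), seed = 1)
#' p <- doubled_balanced_partition(D)
#' subject_overlap(p)
#' @export
doubled_balanced_partition <- function(D) {
  stopifnot(inherits(D, "labeled_dataset"))
  rows1 <- integer(0); rows2 <- integer(0)
  for (lev in levels(D$outcomes)) {
    idx <- which(D$outcomes == lev)
    n_c <- length(idx)
    slots <- rep(idx, 2L)                 # two copies of every subject
    pick <- sample.int(2L * n_c, n_c)     # half the copy slots
    rows1 <- c(rows1, slots[pick])
    rows2 <- c(rows2, slots[-pick])
  }
  new_split_pair(D, rows1, rows2, "doubled-disjoint")
}

#' @rdname doubled_balanced_partition
#' @export
disjoint_half_partition <- function(D) {
  stopifnot(inherits(D, "labeled_dataset"))
  cc <- class_counts(D)
  if (min(cc$n_plus, cc$n_minus) < 4L) {
    stop("disjoint halving needs at least 4 subjects per class ",
         "(so each half keeps >= 2)", call. = FALSE)
  }
  rows1 <- integer(0); rows2 <- integer(0)
  for (lev in levels(D$outcomes)) {
    idx <- which(D$outcomes == lev)
    h <- length(idx) %/% 2L
    perm <- sample(idx)
    rows1 <- c(rows1, perm[seq_len(h)])
    rows2 <- c(rows2, perm[h + seq_len(h)])  # odd leftover excluded
  }
  new_split_pair(D, rows1, rows2, "disjoint-half")
}

#' @rdname doubled_balanced_partition
#' @export
bootstrap_pair <- function(D) {
  stopifnot(inherits(D, "labeled_dataset"))
  draw <- function() {
    unlist(lapply(levels(D$outcomes), function(lev) {
      idx <- which(D$outcomes == lev)
      sample(idx, length(idx), replace = TRUE)
    }))
  }
  new_split_pair(D, draw(), draw(), "bootstrap")
}

#' Fraction of distinct parent subjects present in both halves
#'
#' For a doubling partition this averages about 50%; for disjoint halves
#' it is exactly 0; for bootstrap pairs it is governed by the usual
#' `1 - (1 - 1/n)^n` coverage of each resample.
#'
#' @param pair A `split_pair`.
#' @return Shared distinct subjects divided by the parent subject count.
#' @export
subject_overlap <- function(pair) {
  stopifnot(inherits(pair, "split_pair"))
  length(intersect(unique(pair$rows1), unique(pair$rows2))) / pair$n_parent
}
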