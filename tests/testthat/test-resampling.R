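test_that("jaccard matches bitmask brute force over a 4-element universe", {
  expect_equal(jaccard(c("g1", "g2"), c("g1", "g2")), 1)
  expect_equal(jaccard("g1", "g2"), 0)
  expect_equal(jaccard(c("g1", "g2"), c("g2", "g3")), 1 / 3)
  expect_equal(jaccard(character(0), character(0)), 0)
  expect_equal(jaccard(c("a", "a", "b"), c("b", "a")), 1)  # duplicates

  universe <- c("g1", "g2", "g3", "g4")
  popcount <- function(m) sum(bitwAnd(m, 2^(0:3)) > 0)
  for (ma in 0:15) {
    for (mb in 0:15) {
      A <- universe[bitwAnd(ma, 2^(0:3)) > 0]
      B <- universe[bitwAnd(mb, 2^(0:3)) > 0]
      inter <- popcount(bitwAnd(ma, mb))
      uni <- popcount(bitwOr(ma, mb))
      expected <- if (uni == 0) 0 else inter / uni
      expect_identical(jaccard(A, B), expected)
      expect_identical(jaccard(B, A), expected)           # symmetry
      expect_true(expected >= 0 && expected <= 1)
      expect_identical(expected == 1, ma == mb && ma > 0) # 1 iff equal nonempty
      expect_identical(expected == 0, inter == 0)         # 0 iff disjoint/empty
    }
  }
})

test_that("doubling partition conserves the doubled multiset", {
  D <- generate_dataset(synthetic_spec(7, 5, r = 3), seed = 2)
  set.seed(1)
  for (i in 1:20) {
    p <- doubled_balanced_partition(D)
    expect_identical(p$construction, "doubled-disjoint")
    # both halves carry the parent class counts
    expect_identical(class_counts(p$D1), class_counts(D))
    expect_identical(class_counts(p$D2), class_counts(D))
    # multiset union of the two halves = two copies of every subject
    expect_identical(sort(c(p$rows1, p$rows2)),
                     sort(rep(seq_len(12), 2)))
  }
})

test_that("doubling partition with one subject per class is forced", {
  D <- make_dataset(matrix(rnorm(4), 2, 2), c("a", "b"))
  set.seed(9)
  p <- doubled_balanced_partition(D)
  # each half must hold exactly one copy of each subject
  expect_identical(sort(p$rows1), 1:2)
  expect_identical(sort(p$rows2), 1:2)
  expect_equal(subject_overlap(p), 1)
})

test_that("doubling partitions duplicate about half the subjects", {
  D <- generate_dataset(synthetic_spec(50, 50, r = 2), seed = 3)
  set.seed(14)
  ov <- replicate(300, subject_overlap(doubled_balanced_partition(D)))
  # analytic expectation: 2 * (1/2) * (n_c / (2 n_c - 1)) = 50/99
  expect_equal(mean(ov), 50 / 99, tolerance = 0.02)
})

test_that("disjoint halving floors odd classes and never shares subjects", {
  D <- generate_dataset(synthetic_spec(5, 4, r = 3), seed = 5)
  set.seed(2)
  occupancy <- integer(9)
  for (i in 1:500) {
    p <- disjoint_half_partition(D)
    expect_length(intersect(p$rows1, p$rows2), 0)
    cc <- class_counts(p$D1)
    expect_identical(c(cc$n_plus, cc$n_minus), c(2L, 2L))  # floor(5/2), floor(4/2)
    expect_identical(class_counts(p$D2), cc)
    occupancy[unique(c(p$rows1, p$rows2))] <-
      occupancy[unique(c(p$rows1, p$rows2))] + 1L
  }
  # over many repetitions every subject (incl. the odd leftover's peers)
  # appears in some split
  expect_true(all(occupancy > 0))

  Dsmall <- make_dataset(matrix(rnorm(12), 6, 2), rep(c("a", "b"), 3))
  expect_error(disjoint_half_partition(Dsmall), "at least 4")
})

test_that("bootstrap pairs are stratified full-size resamples", {
  D <- generate_dataset(synthetic_spec(40, 25, r = 2), seed = 6)
  set.seed(3)
  cover <- replicate(300, {
    p <- bootstrap_pair(D)
    expect_identical(class_counts(p$D1), class_counts(D))
    expect_identical(class_counts(p$D2), class_counts(D))
    pos_rows <- which(D$outcomes == D$positive)
    mean(pos_rows %in% p$rows1)
  })
  # distinct-subject coverage of one class-stratified resample
  expect_equal(mean(cover), 1 - (1 - 1 / 40)^40, tolerance = 0.02)
})

test_that("estimators reduce to exact values under stub discovery", {
  D <- generate_dataset(synthetic_spec(10, 10, r = 6), seed = 7)
  for (m in c("oRS", "uRS", "bRS")) {
    all_est <- estimate_rs(D, method = m, k = 8, seed = 1,
                           discover_fun = function(d) colnames(d$values))
    expect_equal(all_est$per_iteration, rep(1, 8))
    expect_equal(all_est$mean, 1)
    expect_equal(all_est$sd, 0)
    none_est <- estimate_rs(D, method = m, k = 8, seed = 1,
                            discover_fun = function(d) character(0))
    expect_equal(none_est$mean, 0)  # empty-empty convention
  }
})

test_that("estimators are deterministic and extend without reshuffling", {
  D <- generate_dataset(synthetic_spec(20, 20, r = 40, n_true = 8,
                                       delta = 1.5), seed = 8)
  for (m in c("oRS", "uRS", "bRS")) {
    a <- estimate_rs(D, method = m, k = 12, seed = 31)
    b <- estimate_rs(D, method = m, k = 12, seed = 31)
    expect_identical(a$per_iteration, b$per_iteration)  # bit-for-bit
    longer <- estimate_rs(D, method = m, k = 20, seed = 31)
    expect_identical(longer$per_iteration[1:12], a$per_iteration)
    expect_equal(a$mean, mean(a$per_iteration))
    expect_equal(a$sd, stats::sd(a$per_iteration))
    expect_true(all(a$per_iteration >= 0 & a$per_iteration <= 1))
  }
})

test_that("the overbound estimator equals a straight-line reference", {
  D <- generate_dataset(synthetic_spec(15, 13, r = 30, n_true = 6,
                                       delta = 1.2), seed = 10)
  k <- 10; seed <- 77
  got <- estimate_rs(D, method = "oRS", k = k, seed = seed)

  # literal re-implementation: double, split per class over copy slots,
  # discover via the t.test oracle, Jaccard, average
  per <- numeric(k)
  for (i in seq_len(k)) {
    set.seed(reproscore:::child_seed(seed, i))
    rows1 <- integer(0); rows2 <- integer(0)
    for (lev in levels(D$outcomes)) {
      idx <- which(D$outcomes == lev)
      slots <- rep(idx, 2L)
      pick <- sample.int(2L * length(idx), length(idx))
      rows1 <- c(rows1, slots[pick])
      rows2 <- c(rows2, slots[-pick])
    }
    b1 <- ref_discover(reproscore:::subset_dataset(D, rows1))$biomarkers
    b2 <- ref_discover(reproscore:::subset_dataset(D, rows2))$biomarkers
    u <- union(b1, b2)
    per[i] <- if (length(u) == 0) 0 else length(intersect(b1, b2)) / length(u)
  }
  expect_equal(got$per_iteration, per, tolerance = 1e-12)
  expect_equal(got$mean, mean(per), tolerance = 1e-12)
})

test_that("the half-size truth estimate is the tagged underbound", {
  D <- generate_dataset(synthetic_spec(16, 16, r = 20, n_true = 5,
                                       delta = 1.5), seed = 11)
  hat <- rs_hat_half(D, k = 6, seed = 5)
  u <- estimate_rs(D, method = "uRS", k = 6, seed = 5)
  expect_identical(hat$per_iteration, u$per_iteration)
  expect_identical(hat$method, "RS_hat")
  expect_identical(glance(hat)$method, "RS_hat")
})

test_that("subset curves allocate classes proportionally and skip infeasible sizes", {
  D <- generate_dataset(synthetic_spec(30, 20, r = 30, n_true = 8,
                                       delta = 2), seed = 12)
  expect_warning(
    curve <- subset_curve(D, sizes = c(3, 10, 25), k = 4, seed = 6),
    "s = 3 skipped")
  expect_identical(curve$summary$subset_size, c(10L, 25L))
  # largest-remainder allocation at s = 10 on a 60/40 parent: 6 + 4
  p <- curve$estimates[["10"]]
  expect_identical(p$k, 4L)
  tl <- tidy(curve)
  expect_identical(nrow(tl), 8L)
  expect_true(all(tl$jaccard >= 0 & tl$jaccard <= 1))
  expect_error(suppressWarnings(subset_curve(D, sizes = 2, k = 2, seed = 1)),
               "no feasible")
})

test_that("the s = n/2 curve point uses the disjoint-halving construction", {
  D <- generate_dataset(synthetic_spec(20, 20, r = 20, n_true = 5,
                                       delta = 1), seed = 13)
  curve <- subset_curve(D, sizes = 20, k = 5, seed = 9)
  pair_alloc <- reproscore:::allocate_classes(20, class_counts(D))
  expect_identical(c(pair_alloc$plus, pair_alloc$minus), c(10, 10))
})

test_that("estimator errors carry the repetition index", {
  D <- generate_dataset(synthetic_spec(10, 10, r = 4), seed = 14)
  expect_error(
    estimate_rs(D, method = "oRS", k = 3, seed = 1,
                discover_fun = function(d) stop("boom")),
    "repetition 1: boom")
})

test_that("Monte-Carlo ground truth behaves at the extremes", {
  # saturating effect: both discovered sets equal the planted truth
  strong <- synthetic_spec(200, 200, r = 20, n_true = 5, delta = 5)
  rs_strong <- rs_star_monte_carlo(strong, k = 10, seed = 15)
  expect_gte(rs_strong$mean, 0.9)
  expect_identical(rs_strong$method, "RS_star")

  # zero effect with BH: rare, non-overlapping false positives
  null <- synthetic_spec(30, 30, r = 40, n_true = 0)
  rs_null <- rs_star_monte_carlo(null, k = 40, seed = 16)
  expect_lte(rs_null$mean, 0.05)

  # determinism
  expect_identical(rs_star_monte_carlo(null, k = 10, seed = 4)$per_iteration,
                   rs_star_monte_carlo(null, k = 10, seed = 4)$per_iteration)
})

test_that("bounds bracket the truth in the moderate-power regime", {
  # the heuristics that motivate the bounds presume discovery is not
  # saturated: weak-to-moderate effects at modest n
  ok_order <- 0; ok_sandwich <- 0
  cases <- expand.grid(delta = c(0.5, 1), seed = 1:3)
  for (i in seq_len(nrow(cases))) {
    spec <- synthetic_spec(30, 30, r = 100, n_true = 20,
                           delta = cases$delta[i])
    D <- generate_dataset(spec, seed = 400 + i)
    o <- estimate_rs(D, method = "oRS", k = 30, seed = 500 + i)$mean
    u <- estimate_rs(D, method = "uRS", k = 30, seed = 600 + i)$mean
    s <- rs_star_monte_carlo(spec, k = 30, seed = 700 + i)$mean
    ok_order <- ok_order + (u <= o)
    ok_sandwich <- ok_sandwich + (u <= s + 1e-9)
  }
  expect_equal(ok_order, 6)      # underbound below overbound, every case
  expect_equal(ok_sandwich, 6)   # underbound below the truth, every case
})
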