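# Random score/RMSD tables for metric oracle checks.
random_table <- function(n) {
  ids <- c("native", sprintf("d%02d", seq_len(n - 1L)))
  list(score = setNames(rnorm(n), ids),
       rmsd = setNames(c(0, runif(n - 1L, 0.5, 12)), ids))
}

test_that("native metrics on constructed cases", {
  score <- c(native = -5, d1 = 1, d2 = 2, d3 = 0.5)
  rmsd <- c(native = 0, d1 = 3, d2 = 6, d3 = 1.5)
  m <- native_metrics(score, rmsd, "native")
  expect_equal(m$rank_nat, 1)
  expect_equal(m$rmsd_best, 0)
  expect_equal(m$z_nat, (mean(score) + 5) / sd(score))
  expect_equal(m$fe_nat, 100)  # k = 1: native is lowest-RMSD and best-scoring

  # 20 structures, the 2 lowest-RMSD are the 2 best-scoring: fe = 100 at k = 2
  score20 <- setNames(c(-2, -1, seq(1, 18)), c("native", sprintf("d%d", 1:19)))
  rmsd20 <- setNames(c(0, 0.5, runif(18, 2, 10)), names(score20))
  expect_equal(native_metrics(score20, rmsd20, "native")$fe_nat, 100)
})

test_that("decoy metrics on constructed cases", {
  # best-scoring decoy is also lowest-RMSD
  score <- c(d1 = 0.1, d2 = 5, d3 = 9)
  rmsd <- c(d1 = 1, d2 = 4, d3 = 8)
  m <- decoy_metrics(score, rmsd)
  expect_equal(m$r_b1, 1)
  expect_true(isTRUE(attr(m, "short_b10")))

  # r_b1 = 5 among 500 decoys -> log_p_b1 = -2
  set.seed(120)
  sc <- setNames(rnorm(500), sprintf("d%03d", 1:500))
  rm <- setNames(runif(500, 1, 20), names(sc))
  rm[which.min(sc)] <- sort(rm)[5] + 1e-9  # pin best-scorer near RMSD rank 5
  rm_rank <- rank(rm, ties.method = "min")
  m2 <- decoy_metrics(sc, rm)
  expect_equal(m2$r_b1, unname(rm_rank[which.min(sc)]))
  expect_equal(m2$log_p_b1, log10(m2$r_b1 / 500))
  if (m2$r_b1 == 5) expect_equal(m2$log_p_b1, -2)
})

test_that("all 13 measures match the exhaustive brute-force oracle", {
  locoscore:::with_seed(131, {
    for (k in 1:60) {
      n <- sample(4:12, 1)
      tab <- random_table(n)
      got <- set_metrics(tab$score, tab$rmsd, "native")
      want <- oracle_set_metrics(tab$score, tab$rmsd, "native")
      for (f in names(want))
        expect_equal(got[[f]], unname(want[[f]]), tolerance = 1e-12,
                     label = sprintf("%s (table %d)", f, k))
    }
  })
})

test_that("rank measures respect their ordering invariants", {
  locoscore:::with_seed(137, {
    for (k in 1:40) {
      n <- sample(5:30, 1)
      tab <- random_table(n)
      m <- set_metrics(tab$score, tab$rmsd, "native")
      expect_gte(m$rank_nat, 1)
      expect_lte(m$r_b10, m$r_b1)
      expect_lte(m$log_p_b1, 0)
      expect_lte(m$log_p_b10, 0)
      expect_gte(m$fe_nat, 0); expect_lte(m$fe_nat, 100)
      expect_gte(m$rmsd_decoy, 0)
      # monotone score transforms leave every rank-based measure unchanged
      m2 <- set_metrics(exp(tab$score / 2), tab$rmsd, "native")
      for (f in c("rank_nat", "rmsd_best", "fe_nat", "r_b1", "r_b10",
                  "rmsd_decoy", "fe_decoy", "log_p_b1", "log_p_b10"))
        expect_equal(m2[[f]], m[[f]], label = f)
    }
  })
})

test_that("adding a worse-scoring decoy never improves the native rank", {
  locoscore:::with_seed(139, {
    tab <- random_table(10)
    m <- set_metrics(tab$score, tab$rmsd, "native")
    worse <- c(tab$score, dworse = max(tab$score) + 1)
    rmsd2 <- c(tab$rmsd, dworse = 15)
    m2 <- set_metrics(worse, rmsd2, "native")
    expect_gte(m2$rank_nat, m$rank_nat)
  })
})

test_that("degenerate scored sets flag their undefined measures", {
  score <- c(native = 1, d1 = 1, d2 = 1)
  rmsd <- c(native = 0, d1 = 2, d2 = 4)
  expect_warning(m <- native_metrics(score, rmsd, "native"), "zero score variance")
  expect_true(is.na(m$z_nat))
  expect_true(is.na(m$cc_nat))
})

test_that("aggregation is a field-wise mean with missing values dropped", {
  m1 <- structure(as.list(setNames(as.numeric(1:13),
                                   locoscore:::METRIC_FIELDS)),
                  class = "set_metrics")
  m2 <- structure(as.list(setNames(as.numeric(3:15),
                                   locoscore:::METRIC_FIELDS)),
                  class = "set_metrics")
  agg <- aggregate_metrics(list(m1, m2))
  expect_equal(agg$rank_nat, 2)
  expect_equal(agg$rmsd_decoy, mean(c(8, 10)))
  expect_equal(aggregate_metrics(list(m1))$cc_nat, m1$cc_nat)
  m2$z_nat <- NA_real_
  agg2 <- aggregate_metrics(list(m1, m2))
  expect_equal(agg2$z_nat, m1$z_nat)
  expect_equal(unname(attr(agg2, "n_used")[["z_nat"]]), 1)
  expect_error(aggregate_metrics(list()), "no decoy-set")
})

test_that("paired Wilcoxon: degenerate, dominance and enumeration oracle", {
  # identical inputs: p = 1, flagged
  p_eq <- wilcoxon_compare(1:8, 1:8)
  expect_equal(as.numeric(p_eq), 1)
  expect_true(isTRUE(attr(p_eq, "degenerate")))

  # strict dominance over 8 pairs: exact tail 2^-8
  a <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_equal(wilcoxon_compare(a, a + runif(8, 0.5, 2)), 1 / 256)

  # exact tail equals exhaustive sign-flip enumeration on random cases,
  # including zeros (Pratt) and ties
  locoscore:::with_seed(149, {
    for (k in 1:25) {
      n <- sample(4:10, 1)
      x <- sample(-4:6, n, replace = TRUE)
      y <- sample(-4:6, n, replace = TRUE)
      if (all(x == y)) next
      expect_equal(as.numeric(wilcoxon_compare(x + 0, y + 0)),
                   oracle_wilcoxon(x, y), tolerance = 1e-12,
                   label = sprintf("case %d", k))
    }
  })
})

test_that("paired Wilcoxon agrees with stats::wilcox.test when zero/tie free", {
  locoscore:::with_seed(151, {
    for (k in 1:10) {
      n <- sample(6:20, 1)
      x <- rnorm(n); y <- rnorm(n)
      ours <- as.numeric(wilcoxon_compare(x, y))
      ref <- stats::wilcox.test(x, y, paired = TRUE, alternative = "less",
                                exact = TRUE)$p.value
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  })
  # unpaired mode is the rank-sum test
  x <- c(1.2, 0.8, 2.5); y <- c(3.1, 4.0, 2.9, 5.2)
  expect_equal(wilcoxon_compare(x, y, paired = FALSE),
               stats::wilcox.test(x, y, alternative = "less",
                                  exact = FALSE, correct = TRUE)$p.value)
})

test_that("normal approximation is close to exact near the boundary", {
  locoscore:::with_seed(157, {
    x <- rnorm(26); y <- rnorm(26) + 0.5
    p_exact <- as.numeric(wilcoxon_compare(x, y, exact_max = 40L))
    p_norm <- as.numeric(wilcoxon_compare(x, y, exact_max = 10L))
    expect_equal(p_norm, p_exact, tolerance = 0.02)
  })
})

test_that("the canonical training grid enumerates 84 versions", {
  grid <- parameter_grid()
  expect_length(grid, 84L)
  expect_equal(length(parameter_grid(14, 1, 3)), 1L)
  expect_equal(length(parameter_grid(c(8, 10), c(1, 2, 3), c(1, 2))), 12L)
  # cutoff-major deterministic order
  expect_equal(grid[[1]]$cutoff, 8)
  expect_equal(grid[[84]]$cutoff, 20)
  expect_equal(vapply(grid[1:3], `[[`, numeric(1), "penalty_mult"), c(1, 2, 3))
})

test_that("cross-validation is deterministic and respects fold sizing", {
  corpus <- make_training_corpus(10, c(14, 20), seed = 163)
  natives <- make_training_corpus(10, c(14, 20), seed = 167,
                                  mixture = c(helix = 1))
  sets <- lapply(seq_along(natives), function(k)
    make_decoys(natives[[k]], 6, sigma = 12, seed = 500 + k))
  grid <- parameter_grid(cutoffs = c(10, 14), exclusions = 1, penalty_mults = 3)
  cv1 <- cross_validate(grid, sets, corpus, folds = 5, repeats = 2, seed = 9)
  cv2 <- cross_validate(grid, sets, corpus, folds = 5, repeats = 2, seed = 9)
  expect_identical(cv1$winner_index, cv2$winner_index)
  expect_identical(cv1$report, cv2$report)
  sizes <- table(cv1$report[[1]]$fold_of)
  expect_lte(max(sizes) - min(sizes), 1)

  # a single-version grid wins regardless of partitioning
  cv_single <- cross_validate(grid[1], sets, corpus, folds = 5, repeats = 2,
                              seed = 11)
  expect_equal(cv_single$winner_index, 1L)
  expect_error(cross_validate(list(), sets, corpus), "empty parameter grid")
  expect_error(cross_validate(grid, sets[1:3], corpus, folds = 5),
               "at least as many decoy sets")
})

test_that("a planted dominant version is selected in every repeat", {
  # version 3 of 5 beats every other version on every single decoy set
  locoscore:::with_seed(181, {
    metric <- matrix(runif(5 * 20, 3, 6), nrow = 5, ncol = 20)
    metric[3, ] <- runif(20, 0.5, 1.5)
    sel <- locoscore:::cv_select(metric, folds = 5, repeats = 10, seed = 19)
    expect_true(all(sel$repeat_winners == 3L))
    expect_equal(sel$winner_index, 3L)
    for (rep in sel$report) expect_true(all(rep$fold_selected == 3L))
  })
})

test_that("metrics tables round-trip through the TSV layout", {
  per_set <- list(
    a = structure(as.list(setNames(as.numeric(1:13),
                                   locoscore:::METRIC_FIELDS)),
                  class = "set_metrics"),
    b = structure(as.list(setNames(as.numeric(2:14),
                                   locoscore:::METRIC_FIELDS)),
                  class = "set_metrics"))
  tab <- metrics_table(per_set)
  expect_equal(tab$set, c("a", "b"))
  expect_equal(tab$rank_nat, c(1, 2))
  expect_equal(ncol(tab), 14L)
})
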