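min_rank <- function(x) rank(x, ties.method = "min")

# fraction enrichment (%): overlap of the lowest-RMSD 10% with the
# best-scoring 10%; k = ceiling(0.1 N) so k >= 1, tie-break by position.
fraction_enrichment <- function(score, rmsd) {
  n <- length(score)
  k <- ceiling(0.1 * n)
  top_rmsd <- order(rmsd)[seq_len(k)]
  top_score <- order(score)[seq_len(k)]
  100 * length(intersect(top_rmsd, top_score)) / k
}

safe_cor <- function(score, rmsd) {
  if (stats::sd(score) == 0 || stats::sd(rmsd) == 0) return(NA_real_)
  stats::cor(score, rmsd)
}

#' Native-recognition measures for one scored decoy set
#'
#' Five measures over all structures of a set, native included:
#' the score rank of the native (`rank_nat`, ascending scores, ties get the
#' minimum rank), the C-alpha RMSD of the best-scoring structure
#' (`rmsd_best`), the native's Z-score oriented so better-than-mean natives
#' are positive (`z_nat`, sample SD), the Pearson correlation of score with
#' RMSD (`cc_nat`), and the fraction enrichment of the lowest-RMSD 10%
#' among the best-scoring 10% (`fe_nat`, percent).
#'
#' @param score Named numeric scores for every structure (ascending =
#'   better), native included.
#' @param rmsd Named C-alpha RMSD labels (Angstrom), same names.
#' @param native_id Name of the native structure.
#' @return Named list: rank_nat, rmsd_best, z_nat, cc_nat, fe_nat
#'   (degenerate inputs give NA with a warning).
#' @export
native_metrics <- function(score, rmsd, native_id) {
  stopifnot(length(score) >= 2L, native_id %in% names(score))
  rmsd <- rmsd[names(score)]
  if (anyNA(rmsd)) stop("missing RMSD label")
  nat <- which(names(score) == native_id)
  sdv <- stats::sd(score)
  z <- if (sdv == 0) {
    warning("zero score variance: z_nat undefined", call. = FALSE)
    NA_real_
  } else (mean(score) - score[[nat]]) / sdv
  list(
    rank_nat = unname(min_rank(score)[nat]),
    rmsd_best = unname(rmsd[[which.min(score)]]),
    z_nat = z,
    cc_nat = safe_cor(score, rmsd),
    fe_nat = fraction_enrichment(score, rmsd)
  )
}

#' Decoy-discrimination measures for one scored decoy set
#'
#' Eight measures over the decoys only (native excluded): the RMSD rank of
#' the best-scoring decoy (`r_b1`), the best RMSD rank among the ten
#' best-scoring decoys (`r_b10`), the RMSD of the best-scoring decoy
#' (`rmsd_decoy`), the Z-score of the lowest-RMSD decoy's score
#' (`z_decoy`), score-RMSD correlation (`cc_decoy`) and fraction enrichment
#' (`fe_decoy`), and the common logarithms of the probabilities of reaching
#' the R_B1/R_B10 structures by chance (`log_p_b1` = log10(r_b1 / n),
#' `log_p_b10`). With fewer than 10 decoys, r_b10 uses all of them and the
#' result carries attribute `short_b10`.
#'
#' @param score Named decoy scores (native excluded).
#' @param rmsd Named decoy RMSD labels.
#' @return Named list: r_b1, r_b10, rmsd_decoy, z_decoy, cc_decoy, fe_decoy,
#'   log_p_b1, log_p_b10.
#' @export
decoy_metrics <- function(score, rmsd) {
  stopifnot(length(score) >= 2L)
  rmsd <- rmsd[names(score)]
  if (anyNA(rmsd)) stop("missing RMSD label")
  n <- length(score)
  rr <- min_rank(rmsd)
  best <- which.min(score)
  r_b1 <- unname(rr[best])
  top10 <- order(score)[seq_len(min(10L, n))]
  r_b10 <- min(rr[top10])
  sdv <- stats::sd(score)
  z <- if (sdv == 0) {
    warning("zero score variance: z_decoy undefined", call. = FALSE)
    NA_real_
  } else (mean(score) - score[[which.min(rmsd)]]) / sdv
  out <- list(
    r_b1 = r_b1, r_b10 = r_b10,
    rmsd_decoy = unname(rmsd[[best]]),
    z_decoy = z,
    cc_decoy = safe_cor(score, rmsd),
    fe_decoy = fraction_enrichment(score, rmsd),
    log_p_b1 = log10(r_b1 / n),
    log_p_b10 = log10(r_b10 / n)
  )
  if (n < 10L) attr(out, "short_b10") <- TRUE
  out
}

METRIC_FIELDS <- c("rank_nat", "rmsd_best", "z_nat", "cc_nat", "fe_nat",
                   "r_b1", "r_b10", "rmsd_decoy", "z_decoy", "cc_decoy",
                   "fe_decoy", "log_p_b1", "log_p_b10")

#' All 13 performance measures for one scored decoy set
#'
#' @param score Named scores including the native.
#' @param rmsd Named RMSD labels including the native (0 for the native).
#' @param native_id Name of the native.
#' @return A `set_metrics` list with the five native-recognition and eight
#'   decoy-discrimination fields.
#' @export
set_metrics <- function(score, rmsd, native_id) {
  nm <- native_metrics(score, rmsd, native_id)
  dec <- names(score) != native_id
  dm <- decoy_metrics(score[dec], rmsd[dec])
  structure(c(nm, dm), class = "set_metrics")
}

#' Score a decoy set and compute its metrics
#'
#' @param db A `potential_db`.
#' @param ds A `decoy_set`.
#' @return A `set_metrics` for the set under that potential.
#' @export
evaluate_decoy_set <- function(db, ds) {
  stopifnot(inherits(ds, "decoy_set"))
  structures <- c(list(ds$native), ds$decoys)
  tab <- score_structures(db, structures)
  score <- setNames(tab$total_score, tab$structure_id)
  set_metrics(score, ds$rmsd, ds$native$id)
}

#' Average metrics across decoy sets
#'
#' Field-wise arithmetic mean; missing (flagged) values are excluded
#' per-field and the number contributing is reported alongside.
#'
#' @param per_set Non-empty list of `set_metrics`.
#' @return A `set_metrics` of means, with attribute `n_used` (per-field
#'   contributing counts).
#' @export
aggregate_metrics <- function(per_set) {
  if (!length(per_set)) stop("no decoy-set metrics to aggregate")
  out <- lapply(METRIC_FIELDS, function(f) {
    v <- vapply(per_set, function(m) as.numeric(m[[f]]), numeric(1L))
    c(mean = mean(v, na.rm = TRUE), n = sum(!is.na(v)))
  })
  means <- setNames(lapply(out, `[[`, "mean"), METRIC_FIELDS)
  structure(means, class = "set_metrics",
            n_used = setNames(vapply(out, `[[`, numeric(1L), "n"),
                              METRIC_FIELDS))
}

#' @export
print.set_metrics <- function(x, ...) {
  v <- vapply(METRIC_FIELDS, function(f) as.numeric(x[[f]]), numeric(1L))
  cat("<set_metrics>\n")
  print(round(v, 4L))
  invisible(x)
}

#' Metrics list to data.frame
#' @param per_set List of `set_metrics`, optionally named by set.
#' @return data.frame, one row per set.
#' @export
metrics_table <- function(per_set) {
  df <- as.data.frame(do.call(rbind, lapply(per_set, function(m)
    vapply(METRIC_FIELDS, function(f) as.numeric(m[[f]]), numeric(1L)))))
  names(df) <- METRIC_FIELDS
  df <- cbind(set = if (is.null(names(per_set)))
    sprintf("set%d", seq_along(per_set)) else names(per_set), df)
  rownames(df) <- NULL
  df
}

# Exact distribution tail P(W+ <= w) of the signed-rank sum over the given
# (possibly tied, Pratt-reduced) ranks, by dynamic programming on 2x ranks.
signed_rank_tail <- function(ranks2, w2) {
  total <- sum(ranks2)
  dist <- numeric(total + 1L)  # dist[s+1] = #assignments with W+ = s/2... in 2x units
  dist[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), dist[seq_len(length(dist) - r)])
    dist <- dist + shifted
  }
  sum(dist[seq_len(min(floor(w2), total) + 1L)]) / 2^length(ranks2)
}

#' One-tailed Wilcoxon comparison of two scoring functions
#'
#' Compares the distributions of a per-set measure (canonically R_B1, the
#' RMSD rank of each function's best-scoring decoy) between two functions
#' run on the same decoy sets. The alternative is that `a`'s values are
#' lower (better) than `b`'s. The default is the paired signed-rank test:
#' zero differences are handled by Pratt's method (zeros are ranked with the
#' rest, then dropped from the statistic), ties get average ranks, the tail
#' is exact (dynamic-programming enumeration of all sign assignments) for up
#' to 25 nonzero pairs and a continuity-corrected normal approximation
#' beyond. `paired = FALSE` gives the unpaired rank-sum test instead.
#'
#' @param a,b Numeric vectors of the per-set measure (equal lengths when
#'   paired).
#' @param paired Paired signed-rank (default) or unpaired rank-sum.
#' @param exact_max Largest number of nonzero pairs for the exact tail.
#' @return One-tailed p-value; attribute `degenerate` is TRUE when every
#'   paired difference is zero (p = 1).
#' @export
wilcoxon_compare <- function(a, b, paired = TRUE, exact_max = 25L) {
  if (!paired) {
    return(stats::wilcox.test(a, b, alternative = "less",
                              exact = FALSE, correct = TRUE)$p.value)
  }
  if (length(a) != length(b)) stop("paired comparison needs equal lengths")
  d <- a - b
  nz <- d != 0
  if (!any(nz)) {
    p <- 1
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  # Pratt: rank |d| including zeros, then drop the zeros
  r <- rank(abs(d), ties.method = "average")
  rpos <- r[nz & d > 0]
  rnz <- r[nz]
  w <- sum(rpos)
  m <- sum(nz)
  if (m <= exact_max) {
    # 2x ranks are integers even with .5 average ranks
    p <- signed_rank_tail(as.integer(round(2 * rnz)), round(2 * w))
  } else {
    mu <- sum(rnz) / 2
    sg <- sqrt(sum(rnz^2) / 4)
    p <- stats::pnorm((w + 0.5 - mu) / sg)
  }
  p
}

#' Enumerate the parameter grid
#'
#' Cartesian product of cutoffs, exclusions and penalty multipliers in
#' deterministic cutoff-major order. The canonical training grid — cutoffs
#' 8 to 20 Angstrom in 2 Angstrom steps, 1 to 4 excluded neighbours per
#' side, penalties 1 to 3 times the worst observed score — yields 84
#' versions.
#'
#' @param cutoffs,exclusions,penalty_mults Non-empty positive vectors.
#' @return List of [loco_params()], length = product of the three lengths.
#' @export
parameter_grid <- function(cutoffs = seq(8, 20, by = 2),
                           exclusions = 1:4,
                           penalty_mults = 1:3) {
  stopifnot(length(cutoffs) > 0, length(exclusions) > 0,
            length(penalty_mults) > 0,
            all(cutoffs > 0), all(exclusions > 0 | exclusions == 0),
            all(penalty_mults > 0))
  out <- list()
  for (co in cutoffs) for (ex in exclusions) for (pm in penalty_mults)
    out[[length(out) + 1L]] <- loco_params(co, ex, pm)
  out
}

#' Select parameters by repeated tenfold cross-validation
#'
#' Every grid version is trained on the corpus and used to score every decoy
#' set (the selection metric is `rmsd_decoy`, the RMSD of the best-scoring
#' non-native structure). Sets are partitioned into `folds` random subsets
#' whose sizes differ by at most one; for each fold the version with the
#' lowest mean metric over the held-in sets is selected and then measured
#' on the held-out fold. The winner of a repeat is the selected version
#' with the lowest mean held-out metric; the procedure runs `repeats` times
#' with fresh partitions and the overall winner is the version chosen most
#' often (ties broken by held-out mean). Deterministic given `seed`.
#'
#' @param grid List of [loco_params()] (from [parameter_grid()]).
#' @param decoy_sets List of `decoy_set` (at least `folds` of them).
#' @param corpus Training corpus (list of `mainchain`).
#' @param folds,repeats Cross-validation shape (defaults 10 and 10).
#' @param seed Integer seed.
#' @return A `cv_result`: `winner` (a `loco_params`), `winner_index`,
#'   `repeat_winners`, `version_metric` (version x set matrix of the
#'   selection metric), and `report` (per repeat/fold detail).
#' @export
cross_validate <- function(grid, decoy_sets, corpus, folds = 10L,
                           repeats = 10L, seed = 1L) {
  if (!length(grid)) stop("empty parameter grid")
  nset <- length(decoy_sets)
  if (nset < folds) stop("need at least as many decoy sets as folds")
  # metric matrix: version x set, computed once
  metric <- matrix(NA_real_, length(grid), nset)
  for (v in seq_along(grid)) {
    db <- compile_potential(accumulate_counts(corpus, grid[[v]]),
                            provenance = "cross-validation corpus")
    metric[v, ] <- vapply(decoy_sets, function(ds)
      evaluate_decoy_set(db, ds)$rmsd_decoy, numeric(1L))
  }
  sel <- cv_select(metric, folds = folds, repeats = repeats, seed = seed)
  structure(list(winner = grid[[sel$winner_index]],
                 winner_index = sel$winner_index,
                 repeat_winners = sel$repeat_winners, version_metric = metric,
                 report = sel$report),
            class = "cv_result")
}

# Fold partitioning and winner selection over a precomputed version x set
# metric matrix (lower is better). Separated from the scoring pass so the
# selection logic can be exercised on constructed matrices.
cv_select <- function(metric, folds, repeats, seed) {
  nset <- ncol(metric)
  report <- list()
  repeat_winners <- integer(repeats)
  heldout_means <- numeric(repeats)
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold_of <- sample(rep(seq_len(folds), length.out = nset))
      fold_sel <- integer(folds)
      fold_heldout <- numeric(folds)
      for (f in seq_len(folds)) {
        heldin <- which(fold_of != f)
        heldout <- which(fold_of == f)
        means_in <- rowMeans(metric[, heldin, drop = FALSE])
        fold_sel[f] <- which.min(means_in)  # ties: first in grid order
        fold_heldout[f] <- mean(metric[fold_sel[f], heldout])
      }
      # winner of the repeat: selected version with lowest mean held-out metric
      sel_versions <- unique(fold_sel)
      sel_means <- vapply(sel_versions, function(v)
        mean(fold_heldout[fold_sel == v]), numeric(1L))
      win <- sel_versions[which.min(sel_means)]
      repeat_winners[r] <- win
      heldout_means[r] <- min(sel_means)
      report[[r]] <- list(fold_of = fold_of, fold_selected = fold_sel,
                          fold_heldout = fold_heldout, winner = win)
    }
  })
  tab <- table(repeat_winners)
  top <- as.integer(names(tab)[tab == max(tab)])
  winner_index <- if (length(top) == 1L) top else
    top[which.min(vapply(top, function(v)
      mean(heldout_means[repeat_winners == v]), numeric(1L)))]
  list(winner_index = winner_index, repeat_winners = repeat_winners,
       report = report)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> winner: version %d of %d\n", x$winner_index,
              nrow(x$version_metric)))
  print(x$winner)
  cat(" repeat winners:", paste(x$repeat_winners, collapse = " "), "\n")
  invisible(x)
}
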