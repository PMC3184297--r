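#' @import data.table
NULL

DB_FORMAT_VERSION <- "locoscore-db-1"

#' Scoring-function parameters
#'
#' The three tunable interaction parameters: the partner cutoff distance
#' (C-alpha to C-alpha, Angstrom), the number of immediate chain neighbours
#' excluded on each side of the observing residue, and the zero-count
#' penalty multiplier applied to each pair's worst observed score. The
#' defaults (14 Angstrom, 1 neighbour, 3x) are the values selected by
#' repeated tenfold cross-validation over the 84-version training grid.
#'
#' @param cutoff Positive cutoff distance in Angstrom.
#' @param exclude_neighbors Non-negative integer neighbours per side.
#' @param penalty_mult Positive penalty multiplier.
#' @return A `loco_params` object.
#' @export
loco_params <- function(cutoff = 14, exclude_neighbors = 1L, penalty_mult = 3) {
  stopifnot(is.numeric(cutoff), cutoff > 0,
            exclude_neighbors >= 0, penalty_mult > 0)
  structure(list(cutoff = as.numeric(cutoff),
                 exclude_neighbors = as.integer(exclude_neighbors),
                 penalty_mult = as.numeric(penalty_mult),
                 bin_convention = bin_convention()),
            class = "loco_params")
}

#' @export
print.loco_params <- function(x, ...) {
  cat(sprintf("<loco_params> cutoff %g A, exclude %d neighbour(s)/side, penalty %gx [%s]\n",
              x$cutoff, x$exclude_neighbors, x$penalty_mult, x$bin_convention))
  invisible(x)
}

# Directed observations of one structure: one row per (observer u, partner v)
# eligible pair, with observer/partner types (1..20, alphabetical index) and
# the partner's bin in the observer's frame. Shared by trainer and scorer so
# eligibility can never differ between the two.
structure_observations <- function(s, params) {
  validate_mainchain(s)
  nres <- n_residues(s)
  if (nres < 2L) {
    return(data.table(u = integer(0), v = integer(0), i = integer(0),
                      j = integer(0), bx = integer(0), by = integer(0),
                      bz = integer(0)))
  }
  aa_idx <- match(s$aa, aa_alphabet())
  # candidate pairs within the cutoff (symmetric); brute-force distance scan
  d2 <- as.matrix(stats::dist(s$ca))^2
  cut2 <- params$cutoff^2
  # sequence-neighbour exclusion, vetoed across chain breaks: positions u,v
  # are "neighbours" only if |u-v| <= exclude AND no break lies between them
  excl <- matrix(FALSE, nres, nres)
  ex <- params$exclude_neighbors
  if (ex > 0L && nres > 1L) {
    cumbrk <- c(0L, cumsum(s$breaks))  # breaks before position k+1
    for (u in seq_len(nres)) {
      vs <- seq(max(1L, u - ex), min(nres, u + ex))
      vs <- vs[vs != u]
      for (v in vs) {
        lo <- min(u, v); hi <- max(u, v)
        if (cumbrk[hi] - cumbrk[lo] == 0L) excl[u, v] <- TRUE
      }
    }
  }
  elig <- d2 <= cut2 & !excl
  diag(elig) <- FALSE
  idx <- which(elig, arr.ind = TRUE)  # directed: both (u,v) and (v,u)
  if (!nrow(idx)) {
    return(data.table(u = integer(0), v = integer(0), i = integer(0),
                      j = integer(0), bx = integer(0), by = integer(0),
                      bz = integer(0)))
  }
  rows <- vector("list", nres)
  for (u in unique(idx[, 1L])) {
    partners <- idx[idx[, 1L] == u, 2L]
    fr <- tryCatch(residue_frame(s, u), error = function(e) NULL)
    if (is.null(fr)) next  # degenerate observer: skipped, still a partner
    loc <- to_local(fr, s$ca[partners, , drop = FALSE])
    b <- assign_bin(loc)
    rows[[u]] <- data.table(u = u, v = partners, i = aa_idx[u],
                            j = aa_idx[partners],
                            bx = b[, 1L], by = b[, 2L], bz = b[, 3L])
  }
  rbindlist(rows)
}

#' Eligible interaction partners of one residue
#'
#' Residues whose C-alpha lies within the cutoff of residue `u`'s C-alpha,
#' excluding `u` itself and its immediate chain neighbours (up to
#' `exclude_neighbors` per side; the exclusion does not reach across a chain
#' break, where the fixed peptide geometry it models is absent).
#'
#' @param s A `mainchain` structure.
#' @param u Observer position (1-based).
#' @param params A [loco_params()].
#' @return Sorted integer vector of partner positions.
#' @export
eligible_partners <- function(s, u, params = loco_params()) {
  validate_mainchain(s)
  stopifnot(u >= 1L, u <= n_residues(s))
  obs <- structure_observations(s, params)
  sort(obs$v[obs$u == u])
}

#' Accumulate interaction counts from a training corpus
#'
#' For every structure, every directed eligible (observer, partner) pair
#' contributes one count to the observer-type x partner-type x bin cell of
#' the partner's C-alpha bin in the observer's frame. Both directions of
#' each unordered pair are counted: every interaction is seen from the
#' perspective of each residue.
#'
#' @param corpus Non-empty list of `mainchain` structures.
#' @param params A [loco_params()].
#' @return A `count_table`: data.table `counts` with columns
#'   (i, j, bx, by, bz, n), `params`, `n_structures`, `n_observations`.
#' @export
accumulate_counts <- function(corpus, params = loco_params()) {
  if (!length(corpus)) stop("empty training corpus")
  obs <- rbindlist(lapply(corpus, structure_observations, params = params))
  counts <- if (nrow(obs)) {
    obs[, list(n = .N), by = c("i", "j", "bx", "by", "bz")]
  } else {
    data.table(i = integer(0), j = integer(0), bx = integer(0),
               by = integer(0), bz = integer(0), n = integer(0))
  }
  setkeyv(counts, c("i", "j", "bx", "by", "bz"))
  structure(list(counts = counts, params = params,
                 n_structures = length(corpus),
                 n_observations = nrow(obs)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d structures, %d observations, %d occupied (i,j,bin) cells\n",
              x$n_structures, x$n_observations, nrow(x$counts)))
  invisible(x)
}

#' Per-bin totals of a count table
#' @param ct A `count_table`.
#' @return data.table (bx, by, bz, total).
#' @export
bin_totals <- function(ct) {
  stopifnot(inherits(ct, "count_table"))
  ct$counts[, list(total = sum(n)), by = c("bx", "by", "bz")]
}

#' The mean-over-pairs reference state
#'
#' The expected count at a bin is the total number of observations there for
#' any residue types divided by the number of possible ordered type pairs,
#' 400 (20 x 20); the mean includes the zero-count pairs. Unoccupied bins
#' have expectation 0 and are handled by the zero-count penalty instead.
#'
#' @param ct A `count_table`.
#' @return data.table (bx, by, bz, total, jexp) over occupied bins.
#' @export
reference_state <- function(ct) {
  tot <- bin_totals(ct)
  tot$jexp <- tot$total / 400
  setkeyv(tot, c("bx", "by", "bz"))
  tot[]
}

#' Compile a scoring database from counts
#'
#' Each observed (observer type i, partner type j, bin) cell receives the
#' inverse Boltzmann log-odds score -ln(count / expected), with the expected
#' count from [reference_state()]. Never-observed cells are covered by a
#' per-pair zero-count penalty: `penalty_mult` times the pair's worst (most
#' positive) observed score. Pairs whose worst observed score is not
#' positive, or with no observations at all, fall back to `penalty_mult`
#' times the global worst positive score, so a penalty is never favourable.
#'
#' @param ct A `count_table` with at least one observation.
#' @param provenance Free-text description of the training corpus.
#' @return A `potential_db`: keyed `scores` data.table
#'   (i, j, bx, by, bz, score), 20x20 `penalty` matrix, `params`,
#'   `provenance`.
#' @export
compile_potential <- function(ct, provenance = "unspecified corpus") {
  stopifnot(inherits(ct, "count_table"))
  if (ct$n_observations == 0L) stop("count table has no observations")
  ref <- reference_state(ct)
  sc <- merge(ct$counts, ref[, c("bx", "by", "bz", "jexp")],
              by = c("bx", "by", "bz"))
  sc$score <- -log(sc$n / sc$jexp)
  scores <- sc[, c("i", "j", "bx", "by", "bz", "score")]
  setkeyv(scores, c("i", "j", "bx", "by", "bz"))

  worst <- sc[, list(worst = max(score)), by = c("i", "j")]
  global_worst <- max(c(worst$worst[worst$worst > 0], 0))
  if (global_worst == 0)
    global_worst <- max(abs(sc$score))  # pathological corpus: keep penalty > 0
  pen <- matrix(ct$params$penalty_mult * global_worst, 20L, 20L,
                dimnames = list(aa_alphabet(), aa_alphabet()))
  ok <- worst$worst > 0
  pen[cbind(worst$i[ok], worst$j[ok])] <-
    ct$params$penalty_mult * worst$worst[ok]

  structure(list(scores = scores, penalty = pen, params = ct$params,
                 provenance = provenance,
                 n_structures = ct$n_structures,
                 n_observations = ct$n_observations),
            class = "potential_db")
}

#' @export
print.potential_db <- function(x, ...) {
  cat(sprintf("<potential_db> %d scored cells, params: cutoff %g A / exclude %d / penalty %gx\n",
              nrow(x$scores), x$params$cutoff, x$params$exclude_neighbors,
              x$params$penalty_mult))
  cat(" provenance:", x$provenance, "\n")
  invisible(x)
}

#' Look up scores for (observer type, partner type, bin) triples
#'
#' Returns the compiled score where the cell was observed in training, and
#' the pair's zero-count penalty otherwise. Requesting a bin outside the
#' cutoff cube is an error: eligibility is distance-gated before binning, so
#' a correct scorer can never ask for one.
#'
#' @param db A `potential_db`.
#' @param i,j Amino-acid types: one-letter codes or 1..20 alphabetical
#'   indices (vectors allowed).
#' @param bins Integer 3-vector or n x 3 matrix of bin indices.
#' @return Numeric score vector.
#' @export
db_lookup <- function(db, i, j, bins) {
  stopifnot(inherits(db, "potential_db"))
  if (!is.matrix(bins)) bins <- matrix(as.integer(bins), ncol = 3L)
  if (is.character(i)) i <- match(i, aa_alphabet())
  if (is.character(j)) j <- match(j, aa_alphabet())
  if (anyNA(i) || anyNA(j)) stop("unknown amino-acid type")
  maxbin <- ceiling(db$params$cutoff)
  if (any(abs(bins) > maxbin) || any(bins == 0L))
    stop("bin index outside the cutoff range")
  q <- data.table(i = as.integer(rep_len(i, nrow(bins))),
                  j = as.integer(rep_len(j, nrow(bins))),
                  bx = bins[, 1L], by = bins[, 2L], bz = bins[, 3L])
  hit <- db$scores[q, on = c("i", "j", "bx", "by", "bz")]
  out <- hit$score
  miss <- is.na(out)
  if (any(miss)) out[miss] <- db$penalty[cbind(q$i[miss], q$j[miss])]
  out
}

#' Write a scoring database to disk
#'
#' Single-file JSON container: a header (format version, bin convention,
#' parameters, provenance, payload checksum) plus the full-precision sparse
#' score records and penalty table. The round trip through [read_db()] is
#' lossless to the last bit.
#'
#' @param db A `potential_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_db <- function(db, path) {
  stopifnot(inherits(db, "potential_db"))
  # doubles as %.17g strings: decimal shortest-exact, so the reread double
  # is bit-identical (jsonlite's numeric path rounds to 15 digits)
  payload <- list(
    scores = list(i = db$scores$i, j = db$scores$j, bx = db$scores$bx,
                  by = db$scores$by, bz = db$scores$bz,
                  score = sprintf("%.17g", db$scores$score)),
    penalty = sprintf("%.17g", as.vector(db$penalty)),
    n_structures = db$n_structures,
    n_observations = db$n_observations
  )
  payload_json <- jsonlite::toJSON(payload, digits = NA, auto_unbox = FALSE)
  obj <- list(
    format_version = DB_FORMAT_VERSION,
    bin_convention = db$params$bin_convention,
    params = list(cutoff = db$params$cutoff,
                  exclude_neighbors = db$params$exclude_neighbors,
                  penalty_mult = db$params$penalty_mult),
    provenance = db$provenance,
    checksum = payload_md5(payload_json),
    payload = payload
  )
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                              pretty = FALSE), path)
  invisible(path)
}

payload_md5 <- function(payload_json) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(payload_json), tf)
  unname(tools::md5sum(tf))
}

#' Read a scoring database written by [write_db()]
#'
#' Refuses files with an unknown format version or a checksum mismatch.
#'
#' @param path Path to a database file.
#' @return A `potential_db` identical to the one written.
#' @export
read_db <- function(path) {
  if (!file.exists(path)) stop(sprintf("database file not found: %s", path))
  obj <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyVector = TRUE)
  if (!identical(obj$format_version, DB_FORMAT_VERSION))
    stop(sprintf("unsupported database format version '%s' (expected '%s')",
                 obj$format_version, DB_FORMAT_VERSION))
  payload_json <- jsonlite::toJSON(
    list(scores = as.list(obj$payload$scores),
         penalty = obj$payload$penalty,
         n_structures = obj$payload$n_structures,
         n_observations = obj$payload$n_observations),
    digits = NA, auto_unbox = FALSE)
  if (!identical(payload_md5(payload_json), obj$checksum))
    stop("database payload failed its integrity check (corrupt or truncated file)")
  params <- loco_params(cutoff = obj$params$cutoff,
                        exclude_neighbors = obj$params$exclude_neighbors,
                        penalty_mult = obj$params$penalty_mult)
  if (!identical(obj$bin_convention, params$bin_convention))
    stop(sprintf("database bin convention '%s' does not match this build ('%s')",
                 obj$bin_convention, params$bin_convention))
  scores <- data.table(
    i = as.integer(obj$payload$scores$i),
    j = as.integer(obj$payload$scores$j),
    bx = as.integer(obj$payload$scores$bx),
    by = as.integer(obj$payload$scores$by),
    bz = as.integer(obj$payload$scores$bz),
    score = as.numeric(obj$payload$scores$score)
  )
  setkeyv(scores, c("i", "j", "bx", "by", "bz"))
  pen <- matrix(as.numeric(obj$payload$penalty), 20L, 20L,
                dimnames = list(aa_alphabet(), aa_alphabet()))
  structure(list(scores = scores, penalty = pen, params = params,
                 provenance = obj$provenance,
                 n_structures = obj$payload$n_structures,
                 n_observations = obj$payload$n_observations),
            class = "potential_db")
}

#' Export a database's scored cells as TSV
#'
#' Full-precision plain-text dump (i, j, bx, by, bz, score) for inspection;
#' one-letter amino-acid codes.
#'
#' @param db A `potential_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_db_tsv <- function(db, path) {
  stopifnot(inherits(db, "potential_db"))
  out <- data.frame(
    i = aa_alphabet()[db$scores$i], j = aa_alphabet()[db$scores$j],
    bx = db$scores$bx, by = db$scores$by, bz = db$scores$bz,
    score = sprintf("%.17g", db$scores$score)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
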