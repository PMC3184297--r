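#' Score a structure with a compiled potential database
#'
#' Every residue with a valid local frame observes its eligible partners
#' (cutoff and neighbour exclusion from the database parameters, matching
#' training exactly); each partner's C-alpha bin in the observer's frame is
#' looked up and the scores are summed. Each unordered pair therefore
#' contributes two lookups, one from the perspective of each residue. Lower
#' totals are more native-like.
#'
#' @param db A `potential_db`.
#' @param s A `mainchain` structure.
#' @return A `score_report`: `structure_id`, `total`, `per_residue`
#'   (observer-perspective sums), `n_interactions` (directed lookups).
#' @export
score_structure <- function(db, s) {
  stopifnot(inherits(db, "potential_db"))
  validate_mainchain(s)
  nres <- n_residues(s)
  per <- numeric(nres)
  if (nres < 2L) {
    warning(sprintf("%s: fewer than 2 residues, score is trivially 0", s$id),
            call. = FALSE)
    return(structure(list(structure_id = s$id, total = 0,
                          per_residue = per, n_interactions = 0L),
                     class = "score_report"))
  }
  obs <- structure_observations(s, db$params)
  if (nrow(obs)) {
    val <- db_lookup(db, obs$i, obs$j, as.matrix(obs[, c("bx", "by", "bz")]))
    agg <- rowsum(val, obs$u)
    per[as.integer(rownames(agg))] <- agg[, 1L]
  }
  structure(list(structure_id = s$id, total = sum(per), per_residue = per,
                 n_interactions = nrow(obs)),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report> %s: total %.4f over %d interactions\n",
              x$structure_id, x$total, x$n_interactions))
  invisible(x)
}

#' Score many structures into a table
#'
#' @param db A `potential_db`.
#' @param structures List of `mainchain` structures.
#' @return data.frame with columns structure_id, total_score, n_residues,
#'   n_interactions (stable column order).
#' @export
score_structures <- function(db, structures) {
  reps <- lapply(structures, function(s) score_structure(db, s))
  data.frame(
    structure_id = vapply(reps, `[[`, character(1L), "structure_id"),
    total_score = vapply(reps, `[[`, numeric(1L), "total"),
    n_residues = vapply(structures, n_residues, integer(1L)),
    n_interactions = vapply(reps, function(r) as.integer(r$n_interactions),
                            integer(1L)),
    stringsAsFactors = FALSE
  )
}

#' Peptide omega dihedral angles of a chain
#'
#' The omega angle between consecutive residues k and k+1 is the dihedral
#' over C-alpha(k), C(k), N(k+1), C-alpha(k+1); trans peptides sit near
#' 180 degrees. Pairs separated by a chain break are skipped (NA).
#'
#' @param s A `mainchain` structure.
#' @return Numeric vector of length n-1, degrees in (-180, 180]; empty for a
#'   single-residue chain.
#' @export
omega_angles <- function(s) {
  validate_mainchain(s)
  n <- n_residues(s)
  if (n < 2L) return(numeric(0))
  om <- vapply(seq_len(n - 1L), function(k) {
    if (s$breaks[k]) return(NA_real_)
    dihedral_angle(s$ca[k, ], s$c[k, ], s$n[k + 1L, ], s$ca[k + 1L, ])
  }, numeric(1L))
  om
}

#' Omega-angle baseline scores for a decoy set
#'
#' A deliberately simple discriminator: for each structure take the sample
#' standard deviation of the omega angles within 15 degrees of planar trans
#' (180 degrees; angles are unwrapped around 180 before the SD), then score
#' each structure by the absolute difference between its SD and the mean SD
#' over the whole set. Decoy-generation pipelines leave characteristic
#' omega signatures, so the native tends to stand apart. Structures with
#' fewer than two qualifying angles get a flagged missing score and are
#' excluded from the set mean.
#'
#' @param structures List of `mainchain` structures (>= 2).
#' @param window Qualifying half-width around 180 degrees (default 15).
#' @return Named numeric vector of scores (NA where flagged missing), with
#'   attribute `sd` carrying each structure's omega SD.
#' @export
omega_set_scores <- function(structures, window = 15) {
  stopifnot(length(structures) >= 2L)
  ids <- vapply(structures, `[[`, character(1L), "id")
  sds <- vapply(structures, function(s) {
    om <- omega_angles(s)
    om <- om[!is.na(om)]
    # unwrap around 180: deviation in (-180, 180]
    dev <- ((om - 180) %% 360)
    dev[dev > 180] <- dev[dev > 180] - 360
    dev <- dev[abs(dev) <= window]
    if (length(dev) < 2L) return(NA_real_)
    stats::sd(180 + dev)
  }, numeric(1L))
  mu <- mean(sds, na.rm = TRUE)
  scores <- abs(sds - mu)
  names(scores) <- ids
  attr(scores, "sd") <- setNames(sds, ids)
  scores
}
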