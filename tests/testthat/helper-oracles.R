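# Independent oracles used across the suite. Each deliberately takes a
# different computational route than the package implementation it checks.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Gram-Schmidt-variant local frame: z from the N/C plane normal, x = y x z.
oracle_frame <- function(n, ca, c) {
  y <- n - ca; y <- y / sqrt(sum(y^2))
  z <- cross3(c - ca, n - ca); z <- z / sqrt(sum(z^2))
  x <- cross3(y, z)
  rbind(x, y, z)
}

# Quaternion (Kearsley) superposition RMSD: smallest eigenvalue of the 4x4
# key matrix, no explicit rotation.
oracle_rmsd <- function(P, Q) {
  pc <- sweep(P, 2, colMeans(P)); qc <- sweep(Q, 2, colMeans(Q))
  m <- pc - qc; p <- pc + qc
  xm <- m[, 1]; ym <- m[, 2]; zm <- m[, 3]
  xp <- p[, 1]; yp <- p[, 2]; zp <- p[, 3]
  K <- matrix(0, 4, 4)
  K[1, 1] <- sum(xm^2 + ym^2 + zm^2)
  K[1, 2] <- sum(yp * zm - ym * zp)
  K[1, 3] <- sum(xm * zp - xp * zm)
  K[1, 4] <- sum(xp * ym - xm * yp)
  K[2, 2] <- sum(xm^2 + yp^2 + zp^2)
  K[2, 3] <- sum(xm * ym - xp * yp)
  K[2, 4] <- sum(xm * zm - xp * zp)
  K[3, 3] <- sum(xp^2 + ym^2 + zp^2)
  K[3, 4] <- sum(ym * zm - yp * zp)
  K[4, 4] <- sum(xp^2 + yp^2 + zm^2)
  K[lower.tri(K)] <- t(K)[lower.tri(K)]
  ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(ev, 0) / nrow(P))
}

# Signed dihedral via the projection (praxeolitic) formulation.
oracle_dihedral <- function(p0, p1, p2, p3) {
  b0 <- p0 - p1; b1 <- p2 - p1; b1 <- b1 / sqrt(sum(b1^2)); b2 <- p3 - p2
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  atan2(sum(cross3(b1, v) * w), sum(v * w)) * 180 / pi
}

oracle_bin1 <- function(coord) if (coord >= 0) floor(coord) + 1 else floor(coord)

# Plain double-loop enumeration of directed eligible observations; no
# distance matrix, no data.table. Returns a data.frame (u, v, i, j, bx, by, bz).
oracle_observations <- function(s, params) {
  nres <- locoscore::n_residues(s)
  aa_idx <- match(s$aa, locoscore::aa_alphabet())
  rows <- list()
  for (u in seq_len(nres)) {
    R <- tryCatch(oracle_frame(s$n[u, ], s$ca[u, ], s$c[u, ]),
                  error = function(e) NULL)
    vc <- s$c[u, ] - s$ca[u, ]
    vy <- s$n[u, ] - s$ca[u, ]
    sin2 <- sum(cross3(vy / sqrt(sum(vy^2)), vc / sqrt(sum(vc^2)))^2)
    if (is.null(R) || sqrt(sin2) < 1e-6) next
    for (v in seq_len(nres)) {
      if (v == u) next
      if (sqrt(sum((s$ca[u, ] - s$ca[v, ])^2)) > params$cutoff) next
      lo <- min(u, v); hi <- max(u, v)
      if (hi - lo <= params$exclude_neighbors &&
          !any(s$breaks[lo:(hi - 1)])) next
      loc <- drop(R %*% (s$ca[v, ] - s$ca[u, ]))
      rows[[length(rows) + 1L]] <- data.frame(
        u = u, v = v, i = aa_idx[u], j = aa_idx[v],
        bx = oracle_bin1(loc[1]), by = oracle_bin1(loc[2]),
        bz = oracle_bin1(loc[3]))
    }
  }
  if (!length(rows)) return(data.frame(u = integer(0), v = integer(0),
                                       i = integer(0), j = integer(0),
                                       bx = integer(0), by = integer(0),
                                       bz = integer(0)))
  do.call(rbind, rows)
}

# Tableless brute-force scorer: counts taken straight from the corpus with
# plain loops, scores assembled cell by cell from the -ln(obs/exp) formula
# with the per-pair penalty rule applied on the fly.
oracle_count_env <- function(corpus, params) {
  cnt <- new.env(parent = emptyenv())
  tot <- new.env(parent = emptyenv())
  for (s in corpus) {
    obs <- oracle_observations(s, params)
    for (r in seq_len(nrow(obs))) {
      kb <- paste(obs$bx[r], obs$by[r], obs$bz[r])
      k <- paste(obs$i[r], obs$j[r], kb)
      cnt[[k]] <- (cnt[[k]] %||oracle% 0) + 1
      tot[[kb]] <- (tot[[kb]] %||oracle% 0) + 1
    }
  }
  list(cnt = cnt, tot = tot)
}

`%||oracle%` <- function(a, b) if (is.null(a)) b else a

oracle_score <- function(counts, s, params) {
  # per-pair worst observed score, and global worst positive score; when no
  # observed score is positive anywhere (tiny corpora), the global fallback
  # is the largest score magnitude so that a penalty is never favourable
  pair_worst <- new.env(parent = emptyenv())
  global_worst <- 0
  max_abs <- 0
  for (k in ls(counts$cnt)) {
    parts <- strsplit(k, " ")[[1]]
    kb <- paste(parts[3], parts[4], parts[5])
    sc <- -log(counts$cnt[[k]] / (counts$tot[[kb]] / 400))
    pk <- paste(parts[1], parts[2])
    pair_worst[[pk]] <- max(pair_worst[[pk]] %||oracle% -Inf, sc)
    if (sc > 0) global_worst <- max(global_worst, sc)
    max_abs <- max(max_abs, abs(sc))
  }
  if (global_worst == 0) global_worst <- max_abs
  obs <- oracle_observations(s, params)
  total <- 0
  for (r in seq_len(nrow(obs))) {
    kb <- paste(obs$bx[r], obs$by[r], obs$bz[r])
    k <- paste(obs$i[r], obs$j[r], kb)
    n <- counts$cnt[[k]]
    if (!is.null(n)) {
      total <- total + -log(n / (counts$tot[[kb]] / 400))
    } else {
      pw <- pair_worst[[paste(obs$i[r], obs$j[r])]] %||oracle% -Inf
      pen <- if (is.finite(pw) && pw > 0) params$penalty_mult * pw
      else params$penalty_mult * global_worst
      total <- total + pen
    }
  }
  total
}

# Exhaustive brute-force implementations of the 13 per-set measures, using
# explicit sorting loops rather than rank().
oracle_min_rank <- function(x) {
  vapply(x, function(v) sum(x < v) + 1L, integer(1L))
}

oracle_set_metrics <- function(score, rmsd, native_id) {
  stopifnot(identical(names(score), names(rmsd)))
  nat <- which(names(score) == native_id)
  fe <- function(sc, rm) {
    k <- ceiling(0.1 * length(sc))
    100 * length(intersect(order(rm)[1:k], order(sc)[1:k])) / k
  }
  best_all <- which.min(score)
  out <- list(
    rank_nat = oracle_min_rank(score)[nat],
    rmsd_best = rmsd[[best_all]],
    z_nat = (mean(score) - score[[nat]]) / sd(score),
    cc_nat = suppressWarnings(cor(score, rmsd)),
    fe_nat = fe(score, rmsd)
  )
  sc <- score[-nat]; rm <- rmsd[-nat]
  nd <- length(sc)
  rr <- oracle_min_rank(rm)
  best <- which.min(sc)
  r_b1 <- rr[best]
  r_b10 <- min(rr[order(sc)[1:min(10, nd)]])
  c(out, list(
    r_b1 = r_b1, r_b10 = r_b10,
    rmsd_decoy = rm[[best]],
    z_decoy = (mean(sc) - sc[[which.min(rm)]]) / sd(sc),
    cc_decoy = suppressWarnings(cor(sc, rm)),
    fe_decoy = fe(sc, rm),
    log_p_b1 = log10(r_b1 / nd),
    log_p_b10 = log10(r_b10 / nd)
  ))
}

# Exhaustive sign-flip enumeration of the paired signed-rank tail with
# Pratt zero handling (feasible for <= ~14 nonzero pairs).
oracle_wilcoxon <- function(a, b) {
  d <- a - b
  r <- rank(abs(d), ties.method = "average")
  rnz <- r[d != 0]
  sgn <- d[d != 0] > 0
  m <- length(rnz)
  if (m == 0) return(1)
  w_obs <- sum(rnz[sgn])
  count <- 0L
  for (mask in 0:(2^m - 1)) {
    bits <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1L)))
    if (sum(rnz[bits]) <= w_obs + 1e-9) count <- count + 1L
  }
  count / 2^m
}

# Principal-axis helix fit: rise per residue along the first principal
# component of the C-alpha trace.
oracle_helix_rise <- function(ca) {
  cc <- sweep(ca, 2, colMeans(ca))
  ax <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors[, 1]
  proj <- cc %*% ax
  mean(abs(diff(proj)))
}

# Small random valid backbone for property tests.
random_backbone <- function(n = 12L, seed = NULL, id = "rand") {
  gen <- function() {
    wrap <- function(a) { a <- ((a + 180) %% 360) - 180; a[a == -180] <- 180; a }
    build_backbone(dihedral_spec(
      sample(aa_alphabet(), n, replace = TRUE),
      phi = wrap(runif(n, -180, 180)),
      psi = wrap(runif(n, -180, 180)),
      omega = wrap(180 + rnorm(n, 0, 10))), id = id)
  }
  if (is.null(seed)) gen() else locoscore:::with_seed(seed, gen())
}

random_rigid_transform <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3, 0, 10))
}

apply_rigid <- function(s, tr) {
  s$n <- s$n %*% tr$R + rep(tr$t, each = nrow(s$n))
  s$ca <- s$ca %*% tr$R + rep(tr$t, each = nrow(s$ca))
  s$c <- s$c %*% tr$R + rep(tr$t, each = nrow(s$c))
  s
}

mirror_structure <- function(s) {
  s$n[, 1] <- -s$n[, 1]; s$ca[, 1] <- -s$ca[, 1]; s$c[, 1] <- -s$c[, 1]
  s
}
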