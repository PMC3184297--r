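# Ideal main-chain stereochemistry used by the internal-coordinate builder
# (Engh & Huber-style values; bond lengths in Angstrom, angles in degrees).
IDEAL_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7
)

# Run code with a locally seeded RNG, restoring global state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Per-residue dihedral specification of a backbone
#'
#' Holds one (phi, psi, omega) triple per residue plus the sequence. By
#' placement order, phi of the first residue and psi/omega of the last are
#' not consumed when building coordinates.
#'
#' @param sequence Amino-acid string or character vector (one-letter codes).
#' @param phi,psi,omega Numeric vectors of dihedral angles in degrees, in
#'   (-180, 180], recycled to the sequence length.
#' @return A `dihedral_spec` object.
#' @export
dihedral_spec <- function(sequence, phi, psi, omega = 180) {
  aa <- if (length(sequence) == 1L && nchar(sequence) > 1L)
    strsplit(sequence, "")[[1L]] else as.character(sequence)
  if (!all(aa %in% aa_alphabet())) stop("sequence contains nonstandard codes")
  n <- length(aa)
  spec <- list(aa = aa, phi = rep_len(phi, n), psi = rep_len(psi, n),
               omega = rep_len(omega, n))
  for (f in c("phi", "psi", "omega")) {
    a <- spec[[f]]
    if (any(a <= -180 | a > 180)) stop(sprintf("%s outside (-180, 180]", f))
  }
  structure(spec, class = "dihedral_spec")
}

# NeRF-style placement: position of atom d at distance `bond` from c, bond
# angle a(b,c,d) = `angle`, torsion t(a,b,c,d) = `torsion` (degrees).
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180; ph <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  nrm <- c(
    ab[2L] * bc[3L] - ab[3L] * bc[2L],
    ab[3L] * bc[1L] - ab[1L] * bc[3L],
    ab[1L] * bc[2L] - ab[2L] * bc[1L]
  )
  nrm <- nrm / sqrt(sum(nrm^2))
  m <- c(
    nrm[2L] * bc[3L] - nrm[3L] * bc[2L],
    nrm[3L] * bc[1L] - nrm[1L] * bc[3L],
    nrm[1L] * bc[2L] - nrm[2L] * bc[1L]
  )
  c + bond * (-cos(th) * bc + sin(th) * (cos(ph) * m + sin(ph) * nrm))
}

#' Build ideal-geometry main-chain coordinates from dihedrals
#'
#' Places N/CA/C atoms sequentially with fixed ideal bond lengths and angles;
#' only the phi/psi/omega torsions vary. Recomputing the dihedrals from the
#' returned coordinates recovers the specification to well below 1e-6
#' degrees.
#'
#' @param spec A [dihedral_spec()].
#' @param id Structure identifier.
#' @return A `mainchain` structure.
#' @export
build_backbone <- function(spec, id = "synthetic") {
  stopifnot(inherits(spec, "dihedral_spec"))
  n <- length(spec$aa)
  g <- IDEAL_GEOM
  nmat <- camat <- cmat <- matrix(NA_real_, n, 3L)
  nmat[1L, ] <- c(0, 0, 0)
  camat[1L, ] <- c(g$b_n_ca, 0, 0)
  alpha <- (180 - g$a_n_ca_c) * pi / 180
  cmat[1L, ] <- camat[1L, ] + g$b_ca_c * c(cos(alpha), sin(alpha), 0)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      nmat[i + 1L, ] <- place_atom(nmat[i, ], camat[i, ], cmat[i, ],
                                   g$b_c_n, g$a_ca_c_n, spec$psi[i])
      camat[i + 1L, ] <- place_atom(camat[i, ], cmat[i, ], nmat[i + 1L, ],
                                    g$b_n_ca, g$a_c_n_ca, spec$omega[i])
      cmat[i + 1L, ] <- place_atom(cmat[i, ], nmat[i + 1L, ], camat[i + 1L, ],
                                   g$b_ca_c, g$a_n_ca_c, spec$phi[i + 1L])
    }
  }
  validate_mainchain(new_mainchain(id, spec$aa, nmat, camat, cmat))
}

#' Recompute backbone dihedrals from coordinates
#'
#' @param s A `mainchain` structure without chain breaks.
#' @return A list with `phi` (NA at position 1), `psi` and `omega` (NA at the
#'   last position), all in degrees.
#' @export
backbone_dihedrals <- function(s) {
  validate_mainchain(s)
  n <- n_residues(s)
  phi <- psi <- omega <- rep(NA_real_, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      psi[i] <- dihedral_angle(s$n[i, ], s$ca[i, ], s$c[i, ], s$n[i + 1L, ])
      omega[i] <- dihedral_angle(s$ca[i, ], s$c[i, ], s$n[i + 1L, ], s$ca[i + 1L, ])
      phi[i + 1L] <- dihedral_angle(s$c[i, ], s$n[i + 1L, ], s$ca[i + 1L, ],
                                    s$c[i + 1L, ])
    }
  }
  list(phi = phi, psi = psi, omega = omega)
}

#' Canonical secondary-structure dihedral basins
#'
#' Mean (phi, psi) of the alpha-helical and beta-strand basins used by the
#' generator, plus the coil mixture components.
#' @keywords internal
ss_basins <- function() {
  list(
    helix = c(phi = -57, psi = -47),
    strand = c(phi = -120, psi = 130),
    coil = list(  # Ramachandran-like mixture: alpha, beta/PPII, alpha-L
      list(w = 0.4, phi = -63, psi = -43, sd = 12),
      list(w = 0.45, phi = -100, psi = 140, sd = 20),
      list(w = 0.15, phi = 60, psi = 45, sd = 12)
    )
  )
}

# Draw n (phi, psi) pairs for one secondary-structure state, with jitter.
draw_phipsi <- function(n, state, jitter_sd) {
  b <- ss_basins()
  wrap <- function(a) ((a + 180) %% 360) - 180 + ifelse(((a + 180) %% 360) == 0, 360, 0)
  if (state == "coil") {
    comp <- sample(seq_along(b$coil), n, replace = TRUE,
                   prob = vapply(b$coil, `[[`, numeric(1L), "w"))
    phi <- vapply(comp, function(k) b$coil[[k]]$phi, numeric(1L)) +
      rnorm(n, 0, vapply(comp, function(k) b$coil[[k]]$sd, numeric(1L)))
    psi <- vapply(comp, function(k) b$coil[[k]]$psi, numeric(1L)) +
      rnorm(n, 0, vapply(comp, function(k) b$coil[[k]]$sd, numeric(1L)))
  } else {
    phi <- b[[state]][["phi"]] + rnorm(n, 0, jitter_sd)
    psi <- b[[state]][["psi"]] + rnorm(n, 0, jitter_sd)
  }
  list(phi = wrap(phi), psi = wrap(psi))
}

#' Generate perturbation decoys of a native structure
#'
#' Each decoy is a rebuild of the native's dihedral specification with
#' independent Gaussian noise on phi and psi (and optionally omega).
#' C-alpha RMSD labels are computed against the native. Deterministic given
#' `seed`.
#'
#' @param native A break-free `mainchain` structure.
#' @param n Number of decoys (>= 1).
#' @param sigma Dihedral noise standard deviation in degrees (>= 0).
#' @param seed Integer seed.
#' @param omega_sigma Noise SD for omega angles (default 0: omega untouched).
#' @return A `decoy_set` (decoys named `<id>_d<i>`).
#' @export
make_decoys <- function(native, n, sigma, seed = 1L, omega_sigma = 0) {
  stopifnot(n >= 1L, sigma >= 0, omega_sigma >= 0)
  dih <- backbone_dihedrals(native)
  nr <- n_residues(native)
  wrap <- function(a) {
    a <- ((a + 180) %% 360) - 180
    a[a == -180] <- 180
    a
  }
  decoys <- with_seed(seed, lapply(seq_len(n), function(k) {
    phi <- wrap(ifelse(is.na(dih$phi), 0, dih$phi) + rnorm(nr, 0, sigma))
    psi <- wrap(ifelse(is.na(dih$psi), 0, dih$psi) + rnorm(nr, 0, sigma))
    om <- wrap(ifelse(is.na(dih$omega), 180, dih$omega) +
                 rnorm(nr, 0, omega_sigma))
    build_backbone(dihedral_spec(native$aa, phi, psi, om),
                   id = sprintf("%s_d%d", native$id, k))
  }))
  decoy_set(native, decoys, name = native$id)
}

#' Generate a synthetic training corpus
#'
#' Stand-in for a curated non-redundant domain corpus: each structure is a
#' chain of helix/strand/coil segments with ideal peptide geometry, segment
#' states drawn from `mixture`, basin dihedrals jittered by `jitter_sd`, and
#' a uniformly random amino-acid sequence. Deterministic given `seed`.
#'
#' @param n_structures Number of chains (>= 1).
#' @param length_range Integer two-vector: inclusive residue-count range.
#' @param mixture Named numeric weights for states `helix`, `strand`, `coil`.
#' @param seed Integer seed.
#' @param jitter_sd Gaussian jitter (degrees) on helix/strand basin angles.
#' @return List of `mainchain` structures named by id.
#' @export
make_training_corpus <- function(n_structures, length_range = c(30L, 60L),
                                 mixture = c(helix = 0.5, strand = 0.25,
                                             coil = 0.25),
                                 seed = 1L, jitter_sd = 5) {
  stopifnot(n_structures >= 1L, length(length_range) == 2L)
  states <- c("helix", "strand", "coil")
  mix <- setNames(rep(0, 3L), states)
  mix[names(mixture)] <- mixture
  if (sum(mix) <= 0) stop("mixture weights must sum to a positive value")
  mix <- mix / sum(mix)
  with_seed(seed, {
    lens <- seq(length_range[1L], length_range[2L])
    corpus <- lapply(seq_len(n_structures), function(k) {
      len <- lens[sample.int(length(lens), 1L)]
      phi <- numeric(0); psi <- numeric(0)
      while (length(phi) < len) {
        st <- sample(states, 1L, prob = mix)
        seg <- sample(5:12, 1L)
        pp <- draw_phipsi(seg, st, jitter_sd)
        phi <- c(phi, pp$phi); psi <- c(psi, pp$psi)
      }
      phi <- phi[seq_len(len)]; psi <- psi[seq_len(len)]
      aa <- sample(aa_alphabet(), len, replace = TRUE)
      build_backbone(dihedral_spec(aa, phi, psi, 180),
                     id = sprintf("synth%04d", k))
    })
    names(corpus) <- vapply(corpus, `[[`, character(1L), "id")
    corpus
  })
}

#' An ideal alpha-helix specification
#' @param n Residue count.
#' @param aa Sequence (recycled); default alanine.
#' @return A `dihedral_spec` with phi = -57, psi = -47, omega = 180.
#' @export
helix_spec <- function(n, aa = "A") {
  dihedral_spec(rep_len(if (nchar(aa[1L]) > 1L) strsplit(aa, "")[[1L]] else aa, n),
                phi = -57, psi = -47, omega = 180)
}
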