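#' Build the local coordinate frame of an observing residue
#'
#' The frame is anchored on the residue's main-chain atoms: the C-alpha is the
#' origin, the positive y-axis passes through the N atom, and the C atom lies
#' in the xz = 0 half-plane with positive x. The frame is right-handed
#' (rotation determinant +1), so mirror-image structures produce different
#' local coordinates: the score is chirality-aware.
#'
#' @param n,ca,c Numeric 3-vectors: global coordinates (Angstrom) of the
#'   residue's N, C-alpha and C atoms.
#' @return An object of class `local_frame`: a list with `origin` (the
#'   C-alpha position) and `rotation`, a 3x3 orthonormal matrix mapping
#'   global to local coordinates (rows are the local x, y, z unit axes).
#' @seealso [to_local()], [assign_bin()]
#' @examples
#' fr <- build_frame(n = c(0, 1.46, 0), ca = c(0, 0, 0), c = c(1.49, -0.5, 0))
#' fr$rotation  # identity: the atoms already sit in frame position
#' @export
build_frame <- function(n, ca, c) {
  n <- as.numeric(n); ca <- as.numeric(ca); c <- as.numeric(c)
  stopifnot(length(n) == 3L, length(ca) == 3L, length(c) == 3L)
  if (!all(is.finite(n)) || !all(is.finite(ca)) || !all(is.finite(c)))
    stop("non-finite atom coordinates")
  vy <- n - ca
  vc <- c - ca
  ny <- sqrt(sum(vy^2))
  nc <- sqrt(sum(vc^2))
  if (ny < 1e-6 || nc < 1e-6)
    stop("degenerate residue geometry: coincident main-chain atoms")
  yhat <- vy / ny
  # component of Ca->C orthogonal to the y axis
  vx <- vc - sum(vc * yhat) * yhat
  nx <- sqrt(sum(vx^2))
  if (nx / nc < 1e-6)
    stop("degenerate residue geometry: collinear N/Ca/C")
  xhat <- vx / nx
  zhat <- c(
    xhat[2L] * yhat[3L] - xhat[3L] * yhat[2L],
    xhat[3L] * yhat[1L] - xhat[1L] * yhat[3L],
    xhat[1L] * yhat[2L] - xhat[2L] * yhat[1L]
  )
  structure(
    list(origin = ca, rotation = rbind(xhat, yhat, zhat, deparse.level = 0L)),
    class = "local_frame"
  )
}

#' Local frame of one residue of a structure
#'
#' @param s A [mainchain] structure.
#' @param i Residue position (1-based).
#' @return A `local_frame`, or an error for degenerate geometry.
#' @export
residue_frame <- function(s, i) {
  stopifnot(inherits(s, "mainchain"), i >= 1L, i <= n_residues(s))
  build_frame(s$n[i, ], s$ca[i, ], s$c[i, ])
}

#' Transform points into a residue's local frame
#'
#' @param frame A `local_frame` from [build_frame()].
#' @param points A numeric 3-vector or an n x 3 matrix of global coordinates.
#' @return Coordinates in the frame (same shape as input), in Angstrom.
#' @export
to_local <- function(frame, points) {
  stopifnot(inherits(frame, "local_frame"))
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 3L)
    sweep(points, 2L, frame$origin) %*% t(frame$rotation)
  } else {
    stopifnot(length(points) == 3L)
    drop(frame$rotation %*% (points - frame$origin))
  }
}

#' Assign 1 Angstrom cubic bins to local coordinates
#'
#' Bins are counted from the origin with signed, nonzero labels: on each axis
#' bin +k covers the half-open interval \[k-1, k) and bin -k covers
#' \[-k, -k+1). There is no bin 0, so e.g. local coordinate 0 falls into bin
#' +1 and -0.3 into bin -1. The convention identifier is written into every
#' compiled database header so trainer and scorer can never disagree.
#'
#' @param local A numeric 3-vector or n x 3 matrix of local coordinates.
#' @return Integer bin indices, same shape as the input.
#' @examples
#' assign_bin(c(2.3, 4.1, 3.7))  # bins +3, +5, +4
#' @export
assign_bin <- function(local) {
  if (!all(is.finite(local))) stop("non-finite local coordinate")
  b <- floor(local)
  b[local >= 0] <- b[local >= 0] + 1
  storage.mode(b) <- "integer"
  b
}

#' The bin convention identifier baked into compiled databases
#' @return A string naming the binning convention.
#' @export
bin_convention <- function() "halfopen-signed-nozero-1A-v1"

# Kabsch optimal superposition of P onto Q (both n x 3, already centered):
# proper rotation only (no reflection).
kabsch_rotation <- function(p0, q0) {
  h <- crossprod(p0, q0)           # t(P) %*% Q
  sv <- svd(h)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' C-alpha RMSD after optimal superposition
#'
#' Least-squares optimal rigid superposition (Kabsch algorithm: rotation plus
#' translation, proper rotations only) of the C-alpha traces of two
#' structures, then the root-mean-square deviation over all C-alpha pairs.
#'
#' @param a,b Two [mainchain] structures with equal lengths and sequences, or
#'   two n x 3 coordinate matrices.
#' @return RMSD in Angstrom (>= 0).
#' @export
ca_rmsd <- function(a, b) {
  pa <- if (inherits(a, "mainchain")) a$ca else as.matrix(a)
  pb <- if (inherits(b, "mainchain")) b$ca else as.matrix(b)
  if (inherits(a, "mainchain") && inherits(b, "mainchain")) {
    if (n_residues(a) != n_residues(b))
      stop("structures differ in residue count")
    if (!identical(a$aa, b$aa))
      stop("structures differ in sequence")
  }
  if (!identical(dim(pa), dim(pb)))
    stop("coordinate sets differ in size")
  n <- nrow(pa)
  ca_ <- colMeans(pa); cb_ <- colMeans(pb)
  p0 <- sweep(pa, 2L, ca_)
  q0 <- sweep(pb, 2L, cb_)
  r <- kabsch_rotation(p0, q0)
  diff <- p0 %*% r - q0
  sqrt(sum(diff^2) / n)
}

# Signed dihedral angle (degrees, in (-180, 180]) over four points.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  c12 <- c(
    b1[2L] * b2[3L] - b1[3L] * b2[2L],
    b1[3L] * b2[1L] - b1[1L] * b2[3L],
    b1[1L] * b2[2L] - b1[2L] * b2[1L]
  )
  c23 <- c(
    b2[2L] * b3[3L] - b2[3L] * b3[2L],
    b2[3L] * b3[1L] - b2[1L] * b3[3L],
    b2[1L] * b3[2L] - b2[2L] * b3[1L]
  )
  b2n <- b2 / sqrt(sum(b2^2))
  x <- sum(c12 * c23)
  y <- sum(c(
    c12[2L] * c23[3L] - c12[3L] * c23[2L],
    c12[3L] * c23[1L] - c12[1L] * c23[3L],
    c12[1L] * c23[2L] - c12[2L] * c23[1L]
  ) * b2n)
  ang <- atan2(y, x) * 180 / pi
  # canonical range (-180, 180]: fold the -180 boundary (and float dust
  # just above it) onto +180
  if (ang <= -180 + 1e-9) ang <- ang + 360
  ang
}
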