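# Structural distance metrics: Kabsch RMSD, epsilon-RMSD, and the combined
# RMSD/eRMSD distance used as the pathCV milestone metric.

#' Metric specification
#'
#' Bundles the parameters of the combined structural metric
#' \deqn{d(A,B) = \sqrt{a\,\mathrm{RMSD}^2 + b\,C\,\varepsilon\mathrm{RMSD}^2}}
#' with defaults `a = 0.5`, `b = 2` and the unit-bridging constant
#' `C = 1` A^2, chosen so that an RMSD of 1 A and an eRMSD of 0.5 (the usual
#' similarity cutoffs of the two metrics) contribute equally. The eRMSD block
#' carries the ellipsoidal rescaling constants (5, 5, 3 A) and the rescaled
#' cutoff 2.4 of the standard eRMSD definition.
#'
#' @param kind `"rmsd"`, `"ermsd"` or `"combined"`.
#' @param a RMSD prefactor (dimensionless on A^2).
#' @param b eRMSD prefactor.
#' @param C unit-bridging constant (A^2).
#' @param mask RMSD atom mask (see [coords()]); default all heavy solute atoms.
#' @param scale_plane,scale_normal eRMSD ellipsoid semi-axes (A).
#' @param cutoff rescaled-distance cutoff beyond which base pairs do not
#'   contribute.
#' @return a `metric_spec` object.
#' @export
metric_spec <- function(kind = c("combined", "rmsd", "ermsd"),
                        a = 0.5, b = 2, C = 1, mask = "heavy",
                        scale_plane = 5, scale_normal = 3, cutoff = 2.4) {
  kind <- match.arg(kind)
  if (a <= 0 || b <= 0 || C <= 0 || cutoff <= 0)
    abort("a, b, C and cutoff must all be positive")
  structure(list(kind = kind, a = a, b = b, C = C, mask = mask,
                 scale_plane = scale_plane, scale_normal = scale_normal,
                 cutoff = cutoff), class = "metric_spec")
}

as_xyz_matrix <- function(x, mask = "heavy") {
  if (inherits(x, "dna_structure")) coords(x, mask)
  else as.matrix(x)
}

#' Optimal-superposition (Kabsch) RMSD
#'
#' Minimum mass-unweighted RMSD over all proper rotations and translations,
#' computed by SVD of the covariance matrix with the usual determinant sign
#' correction restricting to proper rotations.
#'
#' @param A,B structures or n x 3 coordinate matrices in atom correspondence.
#' @param mask atom selector applied to structures (see [coords()]).
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(A, B, mask = "heavy") {
  P <- as_xyz_matrix(A, mask); Q <- as_xyz_matrix(B, mask)
  if (nrow(P) != nrow(Q)) abort("selections must have equal atom counts")
  if (nrow(P) < 2) abort("need at least 2 atoms for superposition")
  P <- sweep(P, 2, colMeans(P)); Q <- sweep(Q, 2, colMeans(Q))
  if (nrow(P) == 2) {
    # two points: the optimal rotation aligns the segments exactly
    return(abs(sqrt(sum((P[1, ] - P[2, ])^2)) -
                 sqrt(sum((Q[1, ] - Q[2, ])^2))) / 2)
  }
  s <- svd(crossprod(Q, P))             # H = Q^T P
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((P - Q %*% R)^2)))
}

# ---- eRMSD ------------------------------------------------------------------
# Local base frames from the C2/C4/C6 triangle of the six-membered ring:
# origin at the triangle centroid, x toward one ring atom, z normal to the
# base plane with handedness fixed by the purine/pyrimidine flag so that
# paired bases yield consistent relative geometry.

base_frames <- function(structure) {
  b <- structure$bases[structure$bases$is_base, ]
  a <- structure$atoms
  frames <- purrr::pmap(list(b$res_id, b$purine), function(rid, purine) {
    get <- function(nm) {
      r <- a[a$res_id == rid & a$atom == nm, c("x", "y", "z")]
      if (!nrow(r)) abort(paste0("residue ", rid, " lacks ring atom ", nm))
      as.numeric(r[1, ])
    }
    c2 <- get("C2"); c4 <- get("C4"); c6 <- get("C6")
    origin <- (c2 + c4 + c6) / 3
    # consistent in-plane axes: purines and pyrimidines traverse the ring in
    # opposite sense relative to the glycosidic attachment
    if (purine) { p1 <- c2; p2 <- c4 } else { p1 <- c4; p2 <- c2 }
    x <- p1 - origin; x <- x / sqrt(sum(x^2))
    y0 <- p2 - origin; y0 <- y0 - sum(y0 * x) * x
    y <- y0 / sqrt(sum(y0^2))
    z <- c(x[2] * y[3] - x[3] * y[2], x[3] * y[1] - x[1] * y[3],
           x[1] * y[2] - x[2] * y[1])
    list(origin = origin, R = rbind(x, y, z))
  })
  frames
}

# 4-component G-vector of a rescaled inter-base displacement
gvector <- function(rt, cutoff) {
  r <- sqrt(sum(rt^2))
  if (r >= cutoff || r == 0) return(c(0, 0, 0, 0))
  g <- pi / cutoff
  c(sin(g * r) * rt / r, 1 + cos(g * r))
}

#' Base-arrangement metric (eRMSD)
#'
#' The eRMSD between two structures with identical base-annotated residue
#' lists: inter-base displacement vectors are expressed in each base's local
#' frame, rescaled anisotropically (in-plane semi-axes 5 A, normal 3 A),
#' mapped to 4-component G-vectors that vanish smoothly at the rescaled
#' cutoff 2.4, and compared as a root-mean-square over all ordered base
#' pairs, normalized by the number of bases. Sensitive to stacking and
#' pairing rearrangements that Cartesian RMSD averages away; invariant to
#' rigid motion of either structure.
#'
#' @param A,B structures with identical base annotation.
#' @param spec a [metric_spec()] (ellipsoid constants and cutoff are used).
#' @return dimensionless eRMSD (a.u.), `>= 0`.
#' @export
ermsd <- function(A, B, spec = metric_spec()) {
  nA <- sum(A$bases$is_base); nB <- sum(B$bases$is_base)
  if (nA != nB) abort("structures differ in annotated base count")
  if (nA < 2) abort("need at least 2 annotated bases")
  GA <- gmat(A, spec); GB <- gmat(B, spec)
  sqrt(sum((GA - GB)^2) / nA)
}

gmat <- function(structure, spec) {
  fr <- base_frames(structure)
  n <- length(fr)
  sc <- c(spec$scale_plane, spec$scale_plane, spec$scale_normal)
  G <- matrix(0, n * n, 4)
  k <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    k <- k + 1
    if (i == j) next
    rij <- fr[[i]]$R %*% (fr[[j]]$origin - fr[[i]]$origin)
    G[k, ] <- gvector(as.numeric(rij) / sc, spec$cutoff)
  }
  G
}

#' Combined RMSD/eRMSD distance
#'
#' `sqrt(a*RMSD^2 + b*C*eRMSD^2)` with the equal-contribution defaults
#' `a = 0.5`, `b = 2`, `C = 1` A^2. The square root keeps the metric in
#' distance units so it can serve directly as a pathCV milestone distance.
#'
#' @inheritParams ermsd
#' @return distance in Angstrom.
#' @export
combined_distance <- function(A, B, spec = metric_spec()) {
  r <- kabsch_rmsd(A, B, spec$mask)
  e <- ermsd(A, B, spec)
  sqrt(spec$a * r^2 + spec$b * spec$C * e^2)
}

#' Evaluate the distance selected by a metric_spec
#'
#' @inheritParams ermsd
#' @return the metric value (A for rmsd/combined, a.u. for ermsd).
#' @export
metric_distance <- function(A, B, spec = metric_spec()) {
  switch(spec$kind,
         rmsd = kabsch_rmsd(A, B, spec$mask),
         ermsd = ermsd(A, B, spec),
         combined = combined_distance(A, B, spec))
}

#' Apply a rigid rotation + translation to a structure
#'
#' Utility for invariance testing: rotates all atoms (and ions) by Euler
#' angles and translates them.
#'
#' @param structure a [dna_structure()].
#' @param angles length-3 numeric, rotations about x, y, z (radians).
#' @param shift length-3 translation (A).
#' @return transformed [dna_structure()].
#' @export
transform_rigid <- function(structure, angles = c(0, 0, 0), shift = c(0, 0, 0)) {
  Rx <- function(t) matrix(c(1, 0, 0, 0, cos(t), -sin(t), 0, sin(t), cos(t)), 3, byrow = TRUE)
  Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)), 3, byrow = TRUE)
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, byrow = TRUE)
  R <- Rz(angles[3]) %*% Ry(angles[2]) %*% Rx(angles[1])
  ap <- as.matrix(structure$atoms[, c("x", "y", "z")]) %*% t(R)
  structure$atoms$x <- ap[, 1] + shift[1]
  structure$atoms$y <- ap[, 2] + shift[2]
  structure$atoms$z <- ap[, 3] + shift[3]
  if (nrow(structure$ions)) {
    ip <- as.matrix(structure$ions[, c("x", "y", "z")]) %*% t(R)
    structure$ions$x <- ip[, 1] + shift[1]
    structure$ions$y <- ip[, 2] + shift[2]
    structure$ions$z <- ip[, 3] + shift[3]
  }
  structure
}
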