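## Geometric primitives: dihedral angles, internal-coordinate backbone
## reconstruction, least-squares superposition, fluctuation and distance
## analyses. All lengths in Angstrom, all angles in radians internally.

#' Signed dihedral angle of four points
#'
#' IUPAC convention: 0 for cis (eclipsed), pi for trans, sign by the
#' right-hand rule about the central bond.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return angle in (-pi, pi].
#' @export
compute_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16) {
    .stopf("compute_dihedral: collinear points give a degenerate dihedral")
  }
  m1 <- .cross3(b2 / sqrt(sum(b2^2)), n1)
  wrap_angle(atan2(sum(m1 * n2), sum(n1 * n2)))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# dihedral for all frames at once; P* are nf x 3 matrices
.dihedral_frames <- function(P1, P2, P3, P4) {
  b1 <- P2 - P1; b2 <- P3 - P2; b3 <- P4 - P3
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- cr(b2n, n1)
  wrap_angle(atan2(rowSums(m1 * n2), rowSums(n1 * n2)))
}

## dihedral series -----------------------------------------------------------

#' Construct a dihedral series
#'
#' @param labels data frame with columns `residue_id`, `angle`
#'   (phi/psi/chi1); rows unique.
#' @param values matrix of angles in radians, `n_frames x n_angles`, wrapped
#'   to (-pi, pi].
#' @return an object of class `swi_dihedrals`.
#' @export
dihedral_series <- function(labels, values) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == nrow(labels),
            all(c("residue_id", "angle") %in% names(labels)))
  if (anyDuplicated(labels[, c("residue_id", "angle")]))
    .stopf("dihedral_series: duplicate labels")
  structure(list(labels = labels, values = wrap_angle(values)),
            class = "swi_dihedrals")
}

#' @export
print.swi_dihedrals <- function(x, ...) {
  cat(sprintf("Dihedral series: %d frame(s) x %d angle(s) [%s]\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$labels$angle), collapse = ",")))
  invisible(x)
}

#' Extract backbone/side-chain dihedral series from an ensemble
#'
#' Angles per residue follow standard definitions: phi = C(i-1)-N-CA-C,
#' psi = N-CA-C-N(i+1), chi1 = N-CA-CB-XG with XG from a per-residue-type
#' table (Tyr: CG). Terminal residues lacking a phi or psi neighbour are
#' skipped with a warning; a missing named atom for a requested chi1 is an
#' error naming the residue and atom.
#'
#' @param ens a `swi_ensemble`.
#' @param residues author residue ids to extract.
#' @param angles subset of `c("phi", "psi", "chi1")`.
#' @return a [dihedral_series()] with columns ordered by
#'   (residue_id, phi, psi, chi1).
#' @export
extract_dihedrals <- function(ens, residues, angles = c("phi", "psi")) {
  angles <- match.arg(angles, c("phi", "psi", "chi1"), several.ok = TRUE)
  top <- ens$topology
  prot <- top$group_tag == "protein"
  find_atom <- function(rid, nm) {
    i <- which(prot & top$residue_id == rid & top$atom_name == nm)
    if (length(i)) i[1] else NA_integer_
  }
  residues <- sort(unique(as.integer(residues)))
  lab_res <- integer(0); lab_ang <- character(0); quads <- list()
  for (rid in residues) {
    if (!any(prot & top$residue_id == rid))
      .stopf("extract_dihedrals: residue %d not in ensemble", rid)
    for (ang in c("phi", "psi", "chi1")) {
      if (!(ang %in% angles)) next
      q <- switch(ang,
        phi = c(find_atom(rid - 1L, "C"), find_atom(rid, "N"),
                find_atom(rid, "CA"), find_atom(rid, "C")),
        psi = c(find_atom(rid, "N"), find_atom(rid, "CA"),
                find_atom(rid, "C"), find_atom(rid + 1L, "N")),
        chi1 = {
          rn <- top$residue_name[prot & top$residue_id == rid][1]
          xg <- chi1_atom(rn)
          if (is.na(xg)) .stopf(
            "extract_dihedrals: residue %d (%s) has no chi1", rid, rn)
          c(find_atom(rid, "N"), find_atom(rid, "CA"),
            find_atom(rid, "CB"), find_atom(rid, xg))
        })
      if (anyNA(q)) {
        if (ang %in% c("phi", "psi") &&
            (rid == min(residues) || rid == max(residues) ||
             is.na(q[1]) || is.na(q[4]))) {
          # terminal residue without the flanking peptide partner
          warning(sprintf("extract_dihedrals: skipping %s of residue %d (%s)",
                          ang, rid, "chain terminus"), call. = FALSE)
          next
        }
        .stopf("extract_dihedrals: residue %d: missing atom for %s", rid, ang)
      }
      lab_res <- c(lab_res, rid); lab_ang <- c(lab_ang, ang)
      quads[[length(quads) + 1L]] <- q
    }
  }
  if (!length(quads)) .stopf("extract_dihedrals: no computable angles")
  nf <- n_frames(ens)
  vals <- matrix(NA_real_, nf, length(quads))
  for (j in seq_along(quads)) {
    q <- quads[[j]]
    vals[, j] <- .dihedral_frames(
      matrix(ens$frames[, q[1], ], ncol = 3L),
      matrix(ens$frames[, q[2], ], ncol = 3L),
      matrix(ens$frames[, q[3], ], ncol = 3L),
      matrix(ens$frames[, q[4], ], ncol = 3L))
  }
  dihedral_series(data.frame(residue_id = lab_res, angle = lab_ang,
                             stringsAsFactors = FALSE), vals)
}

## backbone reconstruction ---------------------------------------------------

# ideal peptide geometry (Angstrom / radians)
.bb_geometry <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_ca_cb = 1.530,
  a_n_ca_c = 111.2 * pi / 180, a_ca_c_n = 116.2 * pi / 180,
  a_c_n_ca = 121.7 * pi / 180, a_n_ca_cb = 110.5 * pi / 180,
  t_cb = -122.0 * pi / 180  # improper C..N-CA-CB fixing side-chain chirality
)

# place atom D bonded to C given reference atoms A-B-C (NeRF)
.place_atom <- function(A, B, C, bond, angle, torsion) {
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  n <- .cross3(B - A, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d2 <- bond * c(-cos(angle), sin(angle) * cos(torsion),
                 sin(angle) * sin(torsion))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Rebuild backbone coordinates from phi/psi angles
#'
#' Sequential internal-coordinate chain extension with ideal peptide
#' geometry (N-CA 1.458 A, CA-C 1.525 A, C-N 1.329 A) and the peptide bond
#' fixed trans (omega = pi). phi of the first residue and psi of the last
#' are not used (they are undefined on a chain). Extracting dihedrals from
#' the result recovers the inputs to machine precision.
#'
#' @param phi,psi per-residue angles in radians, length `n_res`.
#' @param n_res number of residues (>= 2).
#' @param residue_ids author numbering to assign (default `1:n_res`).
#' @param residue_names three-letter names, recycled (default "ALA").
#' @param include_cb also place an ideal CB on every residue.
#' @param geometry bond length/angle table; see `swiscape:::.bb_geometry`.
#' @return a single-frame `swi_ensemble` with atoms N, CA, C (, CB).
#' @export
rebuild_backbone <- function(phi, psi, n_res = length(phi),
                             residue_ids = seq_len(n_res),
                             residue_names = "ALA",
                             include_cb = TRUE,
                             geometry = .bb_geometry) {
  if (n_res < 2L) .stopf("rebuild_backbone: need at least 2 residues")
  stopifnot(length(phi) == n_res, length(psi) == n_res)
  g <- geometry
  N <- CA <- CC <- matrix(NA_real_, n_res, 3L)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  CC[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(g$a_n_ca_c), sin(g$a_n_ca_c), 0)
  for (i in seq_len(n_res)[-1]) {
    N[i, ] <- .place_atom(N[i - 1, ], CA[i - 1, ], CC[i - 1, ],
                          g$b_c_n, g$a_ca_c_n, psi[i - 1])
    CA[i, ] <- .place_atom(CA[i - 1, ], CC[i - 1, ], N[i, ],
                           g$b_n_ca, g$a_c_n_ca, pi)   # omega trans
    CC[i, ] <- .place_atom(CC[i - 1, ], N[i, ], CA[i, ],
                           g$b_ca_c, g$a_n_ca_c, phi[i])
  }
  residue_names <- rep_len(residue_names, n_res)
  names_per_res <- if (include_cb) c("N", "CA", "C", "CB") else
    c("N", "CA", "C")
  npr <- length(names_per_res)
  coords <- matrix(NA_real_, n_res * npr, 3L)
  for (i in seq_len(n_res)) {
    base <- (i - 1L) * npr
    coords[base + 1L, ] <- N[i, ]
    coords[base + 2L, ] <- CA[i, ]
    coords[base + 3L, ] <- CC[i, ]
    if (include_cb) {
      coords[base + 4L, ] <- .place_atom(CC[i, ], N[i, ], CA[i, ],
                                         g$b_ca_cb, g$a_n_ca_cb, g$t_cb)
    }
  }
  top <- topology(atom_id = seq_len(n_res * npr),
                  atom_name = rep(names_per_res, n_res),
                  residue_id = rep(residue_ids, each = npr),
                  residue_name = rep(residue_names, each = npr),
                  group_tag = "protein")
  ensemble(top, coords)
}

## superposition and fluctuations --------------------------------------------

#' Optimal superposition and RMSD (Kabsch)
#'
#' Least-squares rigid-body superposition of `mobile` onto `ref` over the
#' given atoms, with a proper rotation (det +1) enforced via SVD sign
#' correction.
#'
#' @param mobile,ref `n_atoms x 3` coordinate matrices (full frames).
#' @param atoms atom indices used for the fit (>= 3, non-collinear).
#' @return list with `rmsd` (Angstrom), `rotation` (3x3), `translation`
#'   (length-3), such that `sweep(mobile, 2, -translation) %*% rotation`...
#'   more precisely `fitted = (mobile - cm_mob) R + cm_ref`, and `fitted`,
#'   the transformed full mobile frame.
#' @export
superpose_rmsd <- function(mobile, ref, atoms = seq_len(nrow(ref))) {
  if (length(atoms) < 3L) .stopf("superpose_rmsd: need >= 3 atoms")
  A <- mobile[atoms, , drop = FALSE]
  B <- ref[atoms, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(crossprod(A0, B0))
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  fitted_sel <- A0 %*% R
  rmsd <- sqrt(mean(rowSums((fitted_sel - B0)^2)))
  fitted <- sweep(sweep(mobile, 2, ca) %*% R, 2, cb, `+`)
  list(rmsd = rmsd, rotation = R, translation = cb - ca %*% R,
       fitted = fitted)
}

#' Root-mean-square fluctuation per atom
#'
#' Frames are iteratively superposed to their mean structure (two passes)
#' over the analysis atoms before measuring each atom's RMS deviation from
#' its mean position.
#'
#' @param ens a `swi_ensemble` with >= 2 frames.
#' @param atoms atom indices to report (also the fit set).
#' @return named numeric vector of per-atom fluctuations (Angstrom).
#' @export
rmsf <- function(ens, atoms = seq_len(n_atoms(ens))) {
  nf <- n_frames(ens)
  if (nf < 2L) .stopf("rmsf: fluctuations undefined for a single frame")
  frames <- lapply(seq_len(nf), function(i) get_frame(ens, i))
  ref <- frames[[1]]
  for (pass in 1:2) {
    aligned <- lapply(frames, function(fr)
      superpose_rmsd(fr, ref, atoms)$fitted)
    ref <- Reduce(`+`, aligned) / nf
  }
  sel <- lapply(aligned, function(fr) fr[atoms, , drop = FALSE])
  mean_pos <- Reduce(`+`, sel) / nf
  ss <- Reduce(`+`, lapply(sel, function(m) rowSums((m - mean_pos)^2))) / nf
  out <- sqrt(ss)
  names(out) <- ens$topology$atom_id[atoms]
  out
}

#' Per-frame minimum distance between two atom groups
#'
#' No periodic imaging: ensembles are treated as whole molecules.
#'
#' @param ens a `swi_ensemble`.
#' @param groupA,groupB disjoint, non-empty atom index sets.
#' @return numeric vector, one minimum cross-pair distance per frame.
#' @export
min_distance_series <- function(ens, groupA, groupB) {
  if (!length(groupA) || !length(groupB))
    .stopf("min_distance_series: empty group")
  if (length(intersect(groupA, groupB)))
    .stopf("min_distance_series: groups overlap")
  nf <- n_frames(ens)
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    A <- matrix(ens$frames[f, groupA, ], ncol = 3L)
    B <- matrix(ens$frames[f, groupB, ], ncol = 3L)
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
    out[f] <- sqrt(max(0, min(d2)))
  }
  out
}
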