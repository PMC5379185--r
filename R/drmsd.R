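## Two-reference conformational comparison: distance-matrix RMSD (DRMSD)
## and the dihedral-similarity collective variable S, each evaluated against
## an inactive ("GDP-bound") and an active ("GTP-bound") reference to give
## the 2-D projection used to map ensembles and crystal structures.

#' Distance-matrix RMSD between a conformation and a reference
#'
#' sqrt of the mean squared difference of all N(N-1)/2 unordered pairwise
#' distances over the selected atoms. Superposition-free by construction:
#' rigid motions of either argument leave the value unchanged.
#'
#' @param conf,ref `n_atoms x 3` coordinate matrices (full frames).
#' @param atoms atom indices of the comparison set (>= 2), resolved in both
#'   frames.
#' @return DRMSD in Angstrom (>= 0).
#' @export
drmsd <- function(conf, ref, atoms = seq_len(nrow(ref))) {
  if (length(atoms) < 2L) .stopf("drmsd: need >= 2 atoms")
  A <- conf[atoms, , drop = FALSE]
  B <- ref[atoms, , drop = FALSE]
  if (nrow(A) != nrow(B)) .stopf("drmsd: selections differ in size")
  sqrt(mean((.pair_dists(A) - .pair_dists(B))^2))
}

# all unordered pair distances, in (1,2),(1,3),...,(2,3),... order
.pair_dists <- function(X) {
  n <- nrow(X)
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  dx <- X[i, 1] - X[j, 1]; dy <- X[i, 2] - X[j, 2]; dz <- X[i, 3] - X[j, 3]
  sqrt(dx * dx + dy * dy + dz * dz)
}

#' Reference pair for two-state projections
#'
#' Bundles the inactive ("GDP-bound") and active ("GTP-bound") reference
#' structures with the atom selection used for DRMSD and the reference
#' dihedral rows used for the S collective variable.
#'
#' @param ref_inactive,ref_active single-frame `swi_ensemble`s.
#' @param selection selection expression for the DRMSD atom set
#'   (default all C-alpha atoms).
#' @param residues residue ids for the dihedral reference (default: all
#'   protein residues shared by both references).
#' @param angles dihedral names used for S (default phi + psi).
#' @return an object of class `swi_refpair`.
#' @export
reference_pair <- function(ref_inactive, ref_active,
                           selection = "name CA",
                           residues = NULL,
                           angles = c("phi", "psi")) {
  stopifnot(n_frames(ref_inactive) == 1L, n_frames(ref_active) == 1L)
  if (is.null(residues)) {
    ri <- ref_inactive$topology$residue_id[
      ref_inactive$topology$group_tag == "protein"]
    ra <- ref_active$topology$residue_id[
      ref_active$topology$group_tag == "protein"]
    residues <- intersect(unique(ri), unique(ra))
  }
  sel_i <- select_atoms(ref_inactive, selection)
  sel_a <- select_atoms(ref_active, selection)
  if (length(sel_i) != length(sel_a))
    .stopf("reference_pair: selection '%s' resolves to %d vs %d atoms",
           selection, length(sel_i), length(sel_a))
  dh_i <- suppressWarnings(extract_dihedrals(ref_inactive, residues, angles))
  dh_a <- suppressWarnings(extract_dihedrals(ref_active, residues, angles))
  if (!identical(dh_i$labels, dh_a$labels))
    .stopf("reference_pair: dihedral labels differ between references")
  structure(list(ref_inactive = ref_inactive, ref_active = ref_active,
                 selection = selection, sel_inactive = sel_i,
                 sel_active = sel_a, residues = residues, angles = angles,
                 dih_inactive = dh_i, dih_active = dh_a),
            class = "swi_refpair")
}

#' @export
print.swi_refpair <- function(x, ...) {
  cat(sprintf(
    "Reference pair: %d selected atoms, %d reference dihedrals (%s)\n",
    length(x$sel_inactive), ncol(x$dih_inactive$values),
    paste(x$angles, collapse = "/")))
  invisible(x)
}

.projection_series <- function(x, y, metric_tag) {
  out <- data.frame(frame = seq_along(x), x = x, y = y,
                    metric = metric_tag, stringsAsFactors = FALSE)
  class(out) <- c("swi_projection", "data.frame")
  out
}

#' Per-frame DRMSD projection against a reference pair
#'
#' x = DRMSD w.r.t. the inactive reference, y = DRMSD w.r.t. the active
#' reference; lower values mean higher similarity to that reference.
#'
#' @param ens a `swi_ensemble`.
#' @param refs a [reference_pair()].
#' @param stride keep every stride-th frame (default 1 = all frames).
#' @return a `swi_projection` data frame with columns frame, x, y, metric.
#' @export
drmsd_projection <- function(ens, refs, stride = 1L) {
  sel <- select_atoms(ens, refs$selection)
  if (length(sel) != length(refs$sel_inactive))
    .stopf("drmsd_projection: selection size mismatch with references")
  fr_i <- get_frame(refs$ref_inactive, 1)
  fr_a <- get_frame(refs$ref_active, 1)
  frames <- seq(1L, n_frames(ens), by = stride)
  x <- y <- numeric(length(frames))
  for (k in seq_along(frames)) {
    fr <- get_frame(ens, frames[k])
    # selections may index different atom positions in ens vs refs
    x[k] <- sqrt(mean((dist(fr[sel, , drop = FALSE]) -
                       dist(fr_i[refs$sel_inactive, , drop = FALSE]))^2))
    y[k] <- sqrt(mean((dist(fr[sel, , drop = FALSE]) -
                       dist(fr_a[refs$sel_active, , drop = FALSE]))^2))
  }
  out <- .projection_series(x, y, "drmsd")
  out$frame <- frames
  out
}

#' Dihedral-similarity score S against a reference
#'
#' Sums a per-angle closeness kernel over the matched dihedral labels.
#' `half_cosine`: sum of (1 + cos(theta - theta_ref))/2 — smooth, bounded,
#' the package default. `gaussian_kernel`: sum of
#' exp(-d(theta,theta_ref)^2 / (2 width^2)) with d the minimum-image angular
#' difference. Both lie in [0, n_angles] and are maximal iff every angle
#' equals its reference.
#'
#' @param dih a [dihedral_series()] (any number of frames).
#' @param ref a single-row [dihedral_series()] with identical labels.
#' @param form `"half_cosine"` or `"gaussian_kernel"`.
#' @param width kernel width in radians (gaussian_kernel only).
#' @return numeric vector, one S value per frame of `dih`.
#' @export
s_similarity <- function(dih, ref, form = c("half_cosine", "gaussian_kernel"),
                         width = NULL) {
  form <- match.arg(form)
  if (!identical(dih$labels[, c("residue_id", "angle")],
                 ref$labels[, c("residue_id", "angle")]))
    .stopf("s_similarity: dihedral labels do not match the reference")
  ref_row <- ref$values[1, ]
  d <- wrap_angle(sweep(dih$values, 2, ref_row))
  if (form == "half_cosine") {
    rowSums((1 + cos(d)) / 2)
  } else {
    if (is.null(width) || width <= 0)
      .stopf("s_similarity: gaussian_kernel needs width > 0 (radians)")
    rowSums(exp(-d^2 / (2 * width^2)))
  }
}

#' Per-frame (S_inactive, S_active) projection
#'
#' The (S_GDP, S_GTP)-style map: x scores dihedral similarity to the
#' inactive reference, y to the active one; larger means more similar.
#'
#' @inheritParams drmsd_projection
#' @inheritParams s_similarity
#' @return a `swi_projection` data frame with metric `"s_similarity"`.
#' @export
s_projection <- function(ens, refs, form = "half_cosine", width = NULL,
                         stride = 1L) {
  dh <- suppressWarnings(extract_dihedrals(ens, refs$residues, refs$angles))
  if (!identical(dh$labels, refs$dih_inactive$labels))
    .stopf("s_projection: ensemble dihedral labels differ from references")
  frames <- seq(1L, n_frames(ens), by = stride)
  dh$values <- dh$values[frames, , drop = FALSE]
  x <- s_similarity(dh, refs$dih_inactive, form, width)
  y <- s_similarity(dh, refs$dih_active, form, width)
  out <- .projection_series(x, y, "s_similarity")
  out$frame <- frames
  out
}

#' Map single structures onto the (S_inactive, S_active) plane
#'
#' One row per input structure, suitable for overlay on a free-energy
#' surface. Structures missing the loop residues are reported as NA rows
#' with a warning; the rest proceed.
#'
#' @param structures named list of single-frame `swi_ensemble`s.
#' @param refs a [reference_pair()].
#' @inheritParams s_similarity
#' @return data frame with columns structure_id, s_inactive, s_active.
#' @export
map_structures <- function(structures, refs, form = "half_cosine",
                           width = NULL) {
  ids <- names(structures)
  if (is.null(ids)) ids <- sprintf("structure_%d", seq_along(structures))
  rows <- lapply(seq_along(structures), function(i) {
    pr <- tryCatch(s_projection(structures[[i]], refs, form, width),
                   error = function(e) {
                     warning(sprintf("map_structures: %s: %s", ids[i],
                                     conditionMessage(e)), call. = FALSE)
                     NULL
                   })
    if (is.null(pr)) data.frame(structure_id = ids[i], s_inactive = NA_real_,
                                s_active = NA_real_)
    else data.frame(structure_id = ids[i], s_inactive = pr$x[1],
                    s_active = pr$y[1])
  })
  do.call(rbind, rows)
}

#' Write a projection series as CSV
#' @param proj a `swi_projection`.
#' @param path output CSV (`frame,x,y,metric`).
#' @export
write_projection <- function(proj, path) {
  write.csv(proj, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
plot.swi_projection <- function(x, ...) {
  lab <- if (x$metric[1] == "drmsd") {
    c("DRMSD vs inactive ref (A)", "DRMSD vs active ref (A)")
  } else c("S vs inactive ref", "S vs active ref")
  plot(x$x, x$y, xlab = lab[1], ylab = lab[2], pch = 16,
       col = grDevices::adjustcolor("steelblue", 0.5), ...)
  invisible(x)
}
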