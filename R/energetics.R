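## Pairwise nonbonded interaction energies of a focal group (the switch
## loop) against named partner groups (protein remainder, water,
## nucleotide, ion), split into Coulomb and Lennard-Jones terms. No
## periodic imaging, no Ewald: a plain distance cutoff on extracted
## whole-molecule systems, and an energy difference Delta E = E_active -
## E_inactive per partner group.

#' Coulomb and Lennard-Jones energy of one atom pair
#'
#' Coulomb: `332.0636 q_i q_j / r` (kcal/mol with charges in e, r in
#' Angstrom). LJ in Rmin form: `eps_ij ((Rmin_ij/r)^12 - 2 (Rmin_ij/r)^6)`
#' with `eps_ij = sqrt(eps_i eps_j)` and `Rmin_ij = Rmin_i/2 + Rmin_j/2`.
#'
#' @param qi,qj partial charges, e.
#' @param eps_i,eps_j LJ well depths, kcal/mol.
#' @param rmin_half_i,rmin_half_j LJ Rmin/2, Angstrom.
#' @param r separation, Angstrom (> 0).
#' @return named numeric: `coulomb`, `lj` (kcal/mol).
#' @export
pair_energy <- function(qi, qj, eps_i, eps_j, rmin_half_i, rmin_half_j, r) {
  if (any(r <= 0)) .stopf("pair_energy: non-positive distance")
  if (anyNA(c(qi, qj, eps_i, eps_j, rmin_half_i, rmin_half_j)))
    .stopf("pair_energy: missing charge or LJ parameter")
  coul <- .kCoulomb * qi * qj / r
  eps <- sqrt(eps_i * eps_j)
  rmin <- rmin_half_i + rmin_half_j
  sr6 <- (rmin / r)^6
  c(coulomb = coul, lj = eps * (sr6^2 - 2 * sr6))
}

#' Group-group interaction energy in one frame
#'
#' Sum of [pair_energy()] over all focal x partner pairs with separation
#' <= cutoff. The groups must be disjoint (intra-focal terms are excluded
#' by construction).
#'
#' @param frame `n_atoms x 3` coordinates.
#' @param top matching `swi_topology` with charges and LJ parameters.
#' @param focal,partner disjoint atom index sets.
#' @param cutoff pair cutoff, Angstrom (default 10 = 1 nm; `Inf` for all
#'   pairs).
#' @return named numeric: `coulomb`, `lj`, `total` (kcal/mol).
#' @export
group_interaction <- function(frame, top, focal, partner, cutoff = 10.0) {
  if (length(intersect(focal, partner)))
    .stopf("group_interaction: focal and partner groups overlap")
  need <- c(focal, partner)
  bad <- need[is.na(top$charge[need]) | is.na(top$lj_epsilon[need]) |
                is.na(top$lj_rmin_half[need])]
  if (length(bad))
    .stopf("group_interaction: missing parameters for atom id %d",
           top$atom_id[bad[1]])
  A <- frame[focal, , drop = FALSE]
  B <- frame[partner, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  r <- sqrt(d2)
  within <- r <= cutoff & r > 0
  if (!any(within)) return(c(coulomb = 0, lj = 0, total = 0))
  qq <- outer(top$charge[focal], top$charge[partner])
  eps <- sqrt(outer(top$lj_epsilon[focal], top$lj_epsilon[partner]))
  rmin <- outer(top$lj_rmin_half[focal], top$lj_rmin_half[partner], `+`)
  coul <- sum((.kCoulomb * qq / r)[within])
  sr6 <- (rmin[within] / r[within])^6
  lj <- sum(eps[within] * (sr6^2 - 2 * sr6))
  c(coulomb = coul, lj = lj, total = coul + lj)
}

#' Ensemble-averaged interaction-energy breakdown of a focal group
#'
#' Mean over frames of the focal group's interaction with each named
#' partner group, split into Coulomb and LJ, plus the grand total.
#'
#' @param ens a `swi_ensemble` with full parameters.
#' @param focal atom indices (or a selection expression) of the focal
#'   group.
#' @param partner_groups named list of atom index sets, or a character
#'   vector of group tags (default: all non-focal tags present).
#' @param cutoff pair cutoff, Angstrom.
#' @return data frame `group, coulomb, lj, total` with a `grand_total`
#'   attribute; class `swi_energy`.
#' @export
energy_breakdown <- function(ens, focal, partner_groups = NULL,
                             cutoff = 10.0) {
  top <- ens$topology
  if (is.character(focal) && length(focal) == 1L)
    focal <- select_atoms(ens, focal)
  if (is.null(partner_groups)) {
    tags <- setdiff(unique(top$group_tag[-focal]), character(0))
    partner_groups <- lapply(tags, function(tg)
      setdiff(which(top$group_tag == tg), focal))
    names(partner_groups) <- tags
  }
  nf <- n_frames(ens)
  rows <- lapply(names(partner_groups), function(g) {
    idx <- partner_groups[[g]]
    if (!length(idx)) return(data.frame(group = g, coulomb = NA_real_,
                                        lj = NA_real_, total = NA_real_))
    per <- vapply(seq_len(nf), function(f)
      group_interaction(get_frame(ens, f), top, focal, idx, cutoff),
      numeric(3))
    data.frame(group = g, coulomb = mean(per["coulomb", ]),
               lj = mean(per["lj", ]), total = mean(per["total", ]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "grand_total") <- sum(out$total, na.rm = TRUE)
  class(out) <- c("swi_energy", "data.frame")
  out
}

# per-frame total interaction energy of focal vs partner index sets
.energy_series <- function(ens, focal, partner, cutoff) {
  if (!length(partner)) return(rep(NA_real_, n_frames(ens)))
  vapply(seq_len(n_frames(ens)), function(fr)
    group_interaction(get_frame(ens, fr), ens$topology, focal, partner,
                      cutoff)[["total"]], numeric(1))
}

.se_block_or_naive <- function(x, block_len) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  if (length(x) >= 2L * block_len && sd(x) > 0) block_se(x, block_len)
  else sd(x) / sqrt(length(x))
}

#' Interaction-energy difference between two ensembles
#'
#' `Delta E_g = <E_g>_active - <E_g>_inactive` per partner group, with the
#' grand total, and per-group standard errors by block averaging of the
#' per-frame energies. A group absent from one system is reported as
#' missing (NA), never silently as zero.
#'
#' @param ens_active,ens_inactive `swi_ensemble`s sharing the group-tag
#'   schema (atom counts may differ, e.g. different nucleotides).
#' @param focal selection expression for the focal group, resolved in each
#'   ensemble.
#' @param partner_groups character vector of partner group tags; each
#'   partner set is the tagged atoms minus the focal set.
#' @param cutoff pair cutoff, Angstrom.
#' @param block_len block length for the standard errors (frames).
#' @return data frame `group, delta_e, se, e_active, e_inactive` plus a
#'   `delta_total` attribute; class `swi_denergy`.
#' @export
delta_energy <- function(ens_active, ens_inactive, focal,
                         partner_groups = c("protein", "water",
                                            "nucleotide", "ion"),
                         cutoff = 10.0, block_len = 10L) {
  per_system <- function(ens) {
    f <- select_atoms(ens, focal)
    lapply(setNames(partner_groups, partner_groups), function(g)
      .energy_series(ens, f,
                     setdiff(which(ens$topology$group_tag == g), f), cutoff))
  }
  ea <- per_system(ens_active)
  ei <- per_system(ens_inactive)
  out <- do.call(rbind, lapply(partner_groups, function(g) {
    a <- ea[[g]]; i <- ei[[g]]
    missing_g <- all(is.na(a)) || all(is.na(i))
    data.frame(group = g,
               delta_e = if (missing_g) NA_real_ else mean(a) - mean(i),
               se = if (missing_g) NA_real_ else
                 sqrt(sum(c(.se_block_or_naive(a, block_len),
                            .se_block_or_naive(i, block_len))^2,
                          na.rm = TRUE)),
               e_active = mean(a), e_inactive = mean(i),
               stringsAsFactors = FALSE)
  }))
  attr(out, "delta_total") <- sum(out$delta_e, na.rm = TRUE)
  class(out) <- c("swi_denergy", "data.frame")
  out
}

#' @export
print.swi_denergy <- function(x, ...) {
  cat("Interaction-energy difference (active - inactive), kcal/mol:\n")
  print.data.frame(x, digits = 4)
  cat(sprintf("grand Delta E total: %.4f kcal/mol\n",
              attr(x, "delta_total")))
  invisible(x)
}

#' Residue-wise interaction-energy differences
#'
#' The loop-level [delta_energy()] split over the loop residues: each
#' residue's atoms act as the focal group against the same partner sets
#' (tagged atoms minus the whole loop). Because the energy is a sum over
#' pairs, the per-residue values sum exactly to the loop-level Delta E for
#' every partner group.
#'
#' @param ens_active,ens_inactive as in [delta_energy()].
#' @param loop_residues author residue ids of the loop.
#' @param partner_groups partner group tags.
#' @param cutoff pair cutoff, Angstrom.
#' @param block_len block length for standard errors.
#' @return data frame `residue, group, delta_e, se`.
#' @export
residue_decomposition <- function(ens_active, ens_inactive, loop_residues,
                                  partner_groups = c("protein", "water",
                                                     "nucleotide", "ion"),
                                  cutoff = 10.0, block_len = 10L) {
  loop_spec <- sprintf("resid %s and group protein",
                       paste(loop_residues, collapse = " "))
  per_system <- function(ens, rid) {
    top <- ens$topology
    loop <- select_atoms(ens, loop_spec)
    f <- intersect(loop, which(top$residue_id == rid))
    lapply(setNames(partner_groups, partner_groups), function(g)
      .energy_series(ens, f,
                     setdiff(which(top$group_tag == g), loop), cutoff))
  }
  rows <- lapply(loop_residues, function(rid) {
    ea <- per_system(ens_active, rid)
    ei <- per_system(ens_inactive, rid)
    do.call(rbind, lapply(partner_groups, function(g) {
      a <- ea[[g]]; i <- ei[[g]]
      missing_g <- all(is.na(a)) || all(is.na(i))
      data.frame(residue = rid, group = g,
                 delta_e = if (missing_g) NA_real_ else mean(a) - mean(i),
                 se = if (missing_g) NA_real_ else
                   sqrt(sum(c(.se_block_or_naive(a, block_len),
                              .se_block_or_naive(i, block_len))^2,
                            na.rm = TRUE)),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
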