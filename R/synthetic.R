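## Seed-deterministic generators for every input class the pipeline
## consumes, each emitting its ground truth alongside the data: multi-state
## loop ensembles with von Mises dihedral noise, noise-free reference
## pairs, Poisson point solvents, and small charged/LJ toy systems whose
## group energies realise a prescribed sign pattern.

#' von Mises random angles
#'
#' Best-Fisher rejection sampler; reduces to uniform on the circle as
#' kappa -> 0.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration (> 0).
#' @return angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa <= 0) .stopf("rvonmises: kappa must be positive")
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nacc <- sum(ok)
    if (nacc) {
      out[got + seq_len(nacc)] <-
        mu + sign(u3[ok] - 0.5) * acos(f[ok])
      got <- got + nacc
    }
  }
  wrap_angle(out)
}

#' von Mises density
#' @param theta angles, radians.
#' @param mu mean direction, radians.
#' @param kappa concentration.
#' @export
dvonmises <- function(theta, mu = 0, kappa = 1) {
  exp(kappa * cos(theta - mu)) / (2 * pi * besselI(kappa, 0))
}

#' Multi-state loop specification
#'
#' Ground-truth description of a synthetic switch-loop ensemble: per-state
#' phi/psi means, a shared von Mises concentration, and mixture weights.
#'
#' @param means list with one element per state, each a list/data frame
#'   with numeric vectors `phi` and `psi` (degrees, one per residue).
#' @param kappa von Mises concentration (shared across states).
#' @param weights state mixture weights, summing to 1.
#' @return an object of class `swi_statespec`.
#' @export
state_spec <- function(means, kappa = 50, weights = NULL) {
  n_states <- length(means)
  if (is.null(weights)) weights <- rep(1 / n_states, n_states)
  if (length(weights) != n_states || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    .stopf("state_spec: weights must be non-negative and sum to 1")
  if (kappa <= 0) .stopf("state_spec: kappa must be positive")
  nr <- length(means[[1]]$phi)
  for (m in means) {
    if (length(m$phi) != nr || length(m$psi) != nr)
      .stopf("state_spec: all states need phi/psi for the same residues")
  }
  structure(list(means = means, kappa = kappa, weights = weights,
                 n_states = n_states, n_res = nr),
            class = "swi_statespec")
}

#' Two-state spec mimicking an inactive/active switch loop
#'
#' Convenience default: `n_res` residues; the inactive state sits in a
#' beta-like basin (phi -120, psi 130), the active state in an
#' alpha-like basin (phi -60, psi -45), with a few residues swapped
#' between basins so the states differ by large dihedral flips, as switch
#' loops do between nucleotide states.
#'
#' @param n_res number of residues (default 13, a Switch-I-sized loop).
#' @param kappa von Mises concentration.
#' @param weights mixture weights for (inactive, active).
#' @param n_states 2, 3 or 4: extra states are interpolations/perturbations
#'   of the first two, for multi-state clustering tests.
#' @return a [state_spec()].
#' @export
two_state_loop_spec <- function(n_res = 13L, kappa = 50,
                                weights = c(0.5, 0.5), n_states = 2L) {
  flip <- seq(2L, n_res - 1L, by = 3L)  # residues that change basin
  inactive <- list(phi = rep(-120, n_res), psi = rep(130, n_res))
  active <- list(phi = rep(-120, n_res), psi = rep(130, n_res))
  active$phi[flip] <- -60; active$psi[flip] <- -45
  means <- list(inactive, active)
  if (n_states >= 3L) {
    third <- inactive; third$phi[flip] <- 60; third$psi[flip] <- 40
    means[[3]] <- third
  }
  if (n_states >= 4L) {
    fourth <- active
    fourth$phi[-flip] <- -75; fourth$psi[-flip] <- -30
    means[[4]] <- fourth
  }
  state_spec(means[seq_len(n_states)], kappa = kappa,
             weights = rep_len(weights, n_states) /
               sum(rep_len(weights, n_states)))
}

#' Generate a multi-state loop ensemble with known state labels
#'
#' Per frame: draw a state by mixture weight, draw phi/psi from von Mises
#' distributions around the state means, rebuild 3-D coordinates by
#' internal-coordinate chain extension.
#'
#' @param spec a [state_spec()].
#' @param n_frames frames to generate.
#' @param seed RNG seed.
#' @param residue_ids author numbering (default 28..(28+n_res-1),
#'   Switch-I style).
#' @param residue_names per-residue names (recycled).
#' @return list: `ensemble` (a `swi_ensemble`), `labels` (true state per
#'   frame, 1-based), `spec`.
#' @export
gen_loop_ensemble <- function(spec, n_frames = 100L, seed = 1L,
                              residue_ids = NULL, residue_names = "ALA") {
  stopifnot(inherits(spec, "swi_statespec"))
  if (spec$n_res < 4L) .stopf("gen_loop_ensemble: need >= 4 residues")
  set.seed(as.integer(seed))
  nr <- spec$n_res
  if (is.null(residue_ids)) residue_ids <- seq(28L, by = 1L,
                                               length.out = nr)
  labels <- sample.int(spec$n_states, n_frames, replace = TRUE,
                       prob = spec$weights)
  frames <- NULL
  for (f in seq_len(n_frames)) {
    st <- spec$means[[labels[f]]]
    # von Mises is a location family: shift zero-mean noise by the state
    # means (mu varies per residue)
    phi <- wrap_angle(deg2rad(st$phi) + rvonmises(nr, 0, spec$kappa))
    psi <- wrap_angle(deg2rad(st$psi) + rvonmises(nr, 0, spec$kappa))
    one <- rebuild_backbone(phi, psi, nr, residue_ids = residue_ids,
                            residue_names = residue_names)
    if (is.null(frames))
      frames <- array(NA_real_, dim = c(n_frames, n_atoms(one), 3L))
    frames[f, , ] <- get_frame(one, 1)
    if (f == 1L) top <- one$topology
  }
  list(ensemble = ensemble(top, frames), labels = labels, spec = spec)
}

#' Noise-free reference pair from a state spec
#'
#' Builds the conformations at the exact means of state 1 ("inactive") and
#' state 2 ("active") and wraps them as a [reference_pair()].
#'
#' @param spec a [state_spec()] with >= 2 states.
#' @param residue_ids author numbering (default Switch-I style).
#' @param residue_names per-residue names.
#' @return a `swi_refpair`.
#' @export
gen_reference_pair <- function(spec, residue_ids = NULL,
                               residue_names = "ALA") {
  stopifnot(inherits(spec, "swi_statespec"))
  if (spec$n_states < 2L)
    .stopf("gen_reference_pair: spec needs >= 2 states")
  nr <- spec$n_res
  if (is.null(residue_ids)) residue_ids <- seq(28L, by = 1L,
                                               length.out = nr)
  build <- function(st) rebuild_backbone(deg2rad(st$phi), deg2rad(st$psi),
                                         nr, residue_ids = residue_ids,
                                         residue_names = residue_names)
  reference_pair(build(spec$means[[1]]), build(spec$means[[2]]))
}

#' Add a Poisson point solvent around a frame
#'
#' Homogeneous Poisson points (oxygen-only water sites, one per molecule)
#' in the axis-aligned bounding box of the coordinates plus a margin.
#' Expected count = density x box volume.
#'
#' @param ens a single-frame `swi_ensemble` (the solute).
#' @param density number density, molecules per cubic Angstrom (bulk water
#'   is about 0.0334).
#' @param margin box margin beyond the solute extent, Angstrom.
#' @param seed RNG seed.
#' @return list: `ensemble` (solute + waters, one frame), `n_waters`,
#'   `box` (3 x 2 matrix), `volume`.
#' @export
gen_solvated_frame <- function(ens, density = 0.0334, margin = 6, seed = 1L) {
  stopifnot(inherits(ens, "swi_ensemble"), n_frames(ens) == 1L)
  if (density < 0) .stopf("gen_solvated_frame: density must be >= 0")
  set.seed(as.integer(seed))
  xyz <- get_frame(ens, 1)
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  vol <- prod(hi - lo)
  nw <- stats::rpois(1, density * vol)
  top <- ens$topology
  if (nw > 0) {
    wxyz <- cbind(runif(nw, lo[1], hi[1]), runif(nw, lo[2], hi[2]),
                  runif(nw, lo[3], hi[3]))
    wtop <- topology(atom_id = max(top$atom_id) + seq_len(nw),
                     atom_name = "OW",
                     residue_id = max(top$residue_id) + seq_len(nw),
                     residue_name = "HOH", element = "O",
                     group_tag = "water")
    all_top <- rbind(top, wtop)
    class(all_top) <- class(top)
    out <- ensemble(all_top, rbind(xyz, wxyz))
  } else {
    out <- ens
  }
  list(ensemble = out, n_waters = nw, box = cbind(lo, hi), volume = vol)
}

#' Toy charged/LJ site system specification
#'
#' @param positions n x 3 site coordinates, Angstrom.
#' @param charges partial charges, e.
#' @param epsilon LJ well depths, kcal/mol.
#' @param rmin_half LJ Rmin/2, Angstrom.
#' @param group_tags group per site.
#' @param residue_id,residue_name,atom_name per-site labels (recycled).
#' @return an object of class `swi_toyspec`.
#' @export
toy_system_spec <- function(positions, charges, epsilon = 0.1,
                            rmin_half = 1.9, group_tags = "other",
                            residue_id = NULL, residue_name = "TOY",
                            atom_name = "X") {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (is.null(residue_id)) residue_id <- seq_len(n)
  structure(list(positions = positions,
                 charges = rep_len(charges, n),
                 epsilon = rep_len(epsilon, n),
                 rmin_half = rep_len(rmin_half, n),
                 group_tags = rep_len(group_tags, n),
                 residue_id = rep_len(residue_id, n),
                 residue_name = rep_len(residue_name, n),
                 atom_name = rep_len(atom_name, n)),
            class = "swi_toyspec")
}

#' Realise a toy spec as a one-frame ensemble with full parameters
#' @param spec a [toy_system_spec()].
#' @param jitter optional Gaussian positional noise sigma, Angstrom.
#' @param n_frames frames to emit (jitter resampled per frame).
#' @param seed RNG seed.
#' @return a `swi_ensemble`.
#' @export
toy_ensemble <- function(spec, jitter = 0, n_frames = 1L, seed = 1L) {
  stopifnot(inherits(spec, "swi_toyspec"))
  set.seed(as.integer(seed))
  n <- nrow(spec$positions)
  top <- topology(atom_id = seq_len(n), atom_name = spec$atom_name,
                  residue_id = spec$residue_id,
                  residue_name = spec$residue_name,
                  charge = spec$charges, lj_epsilon = spec$epsilon,
                  lj_rmin_half = spec$rmin_half,
                  group_tag = spec$group_tags)
  frames <- array(NA_real_, dim = c(n_frames, n, 3L))
  for (f in seq_len(n_frames)) {
    frames[f, , ] <- spec$positions +
      if (jitter > 0) matrix(rnorm(3 * n, sd = jitter), n, 3L) else 0
  }
  ensemble(top, frames)
}

#' Paired toy systems realising the energetic see-saw
#'
#' Two single-state systems with one charged focal site: in the
#' "inactive" system the focal site sits close to favourable water sites
#' and far from the nucleotide charge; in the "active" system it swaps
#' partners, with the nucleotide brought closer than the waters were, so
#' Delta E_water > 0, Delta E_nucleotide < 0 and Delta E_total < 0. The
#' realised energies are verified at generation time by direct summation.
#'
#' @param n_frames frames per system.
#' @param jitter positional noise sigma, Angstrom.
#' @param seed RNG seed.
#' @return list: `active`, `inactive` (ensembles), `check` (generation-time
#'   group energies of frame 1 of each).
#' @export
gen_toy_energetics <- function(n_frames = 40L, jitter = 0.05, seed = 1L) {
  mk <- function(d_water, d_nuc) {
    # focal +0.4e site at origin; 3 water-like dipolar oxygens; one -1e
    # nucleotide site; all with modest LJ
    wat_dirs <- rbind(c(1, 0, 0), c(-0.5, 0.866, 0), c(-0.5, -0.866, 0))
    pos <- rbind(c(0, 0, 0), wat_dirs * d_water, c(0, 0, d_nuc))
    toy_system_spec(pos,
                    charges = c(0.4, rep(-0.4, 3), -1.0),
                    epsilon = c(0.1, rep(0.15, 3), 0.12),
                    rmin_half = c(1.9, rep(1.77, 3), 2.0),
                    group_tags = c("protein", rep("water", 3),
                                   "nucleotide"),
                    residue_id = c(1L, 2L, 3L, 4L, 5L),
                    residue_name = c("FOC", "HOH", "HOH", "HOH", "GTP"),
                    atom_name = c("CA", "OW", "OW", "OW", "PG"))
  }
  spec_inactive <- mk(d_water = 3.2, d_nuc = 9.0)
  spec_active <- mk(d_water = 5.5, d_nuc = 3.0)
  inactive <- toy_ensemble(spec_inactive, jitter, n_frames,
                           seed = .derive_seed(seed, 11L))
  active <- toy_ensemble(spec_active, jitter, n_frames,
                         seed = .derive_seed(seed, 12L))
  chk <- function(ens) {
    f <- which(ens$topology$group_tag == "protein")
    lapply(setNames(c("water", "nucleotide"), c("water", "nucleotide")),
           function(g) group_interaction(get_frame(ens, 1), ens$topology, f,
                                         which(ens$topology$group_tag == g),
                                         cutoff = Inf))
  }
  list(active = active, inactive = inactive,
       check = list(active = chk(active), inactive = chk(inactive)))
}
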