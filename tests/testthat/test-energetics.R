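test_that("pair energies match their closed forms", {
  # zero charge, zero epsilon: nothing
  expect_equal(pair_energy(0, 0, 0, 0, 1.9, 1.9, 3), c(coulomb = 0, lj = 0))
  # unit opposite charges at r equal to the Coulomb constant: exactly -1
  expect_equal(pair_energy(1, -1, 0, 0, 1, 1, 332.0636)[["coulomb"]], -1)
  # LJ minimum: exactly -eps_ij at r = Rmin_ij
  e <- pair_energy(0, 0, 0.2, 0.45, 1.8, 2.2, 4.0)
  expect_equal(e[["lj"]], -sqrt(0.2 * 0.45), tolerance = 1e-12)
  expect_error(pair_energy(1, 1, 0.1, 0.1, 1.9, 1.9, 0), "distance")
  expect_error(pair_energy(NA, 1, 0.1, 0.1, 1.9, 1.9, 1), "missing")
})

test_that("group energies equal the exhaustive double loop without cutoff", {
  set.seed(31)
  n <- 10L
  spec <- toy_system_spec(matrix(runif(3 * 2 * n, -6, 6), 2 * n, 3),
                          charges = runif(2 * n, -0.8, 0.8),
                          epsilon = runif(2 * n, 0.05, 0.3),
                          rmin_half = runif(2 * n, 1.6, 2.2),
                          group_tags = rep(c("protein", "water"), each = n))
  ens <- toy_ensemble(spec)
  fr <- get_frame(ens, 1)
  top <- ens$topology
  focal <- 1:n; partner <- (n + 1):(2 * n)
  got <- group_interaction(fr, top, focal, partner, cutoff = Inf)
  coul <- lj <- 0
  for (i in focal) for (j in partner) {
    r <- sqrt(sum((fr[i, ] - fr[j, ])^2))
    pe <- pair_energy(top$charge[i], top$charge[j], top$lj_epsilon[i],
                      top$lj_epsilon[j], top$lj_rmin_half[i],
                      top$lj_rmin_half[j], r)
    coul <- coul + pe[["coulomb"]]; lj <- lj + pe[["lj"]]
  }
  expect_equal(got[["coulomb"]], coul, tolerance = 1e-10)
  expect_equal(got[["lj"]], lj, tolerance = 1e-10)
  expect_equal(got[["total"]], got[["coulomb"]] + got[["lj"]])
  # halving all charges quarters the Coulomb term
  half <- spec; half$charges <- spec$charges / 2
  got_half <- group_interaction(get_frame(toy_ensemble(half), 1),
                                toy_ensemble(half)$topology, focal, partner,
                                cutoff = Inf)
  expect_equal(got_half[["coulomb"]], coul / 4, tolerance = 1e-10)
  # a partner entirely beyond the cutoff contributes nothing
  expect_equal(group_interaction(fr, top, focal, partner, cutoff = 1e-3),
               c(coulomb = 0, lj = 0, total = 0))
  expect_error(group_interaction(fr, top, 1:3, 3:5), "overlap")
})

test_that("pair sums respect arbitrary partner partitions", {
  set.seed(33)
  n <- 24L
  spec <- toy_system_spec(matrix(runif(3 * n, -5, 5), n, 3),
                          charges = runif(n, -0.5, 0.5),
                          epsilon = 0.15, rmin_half = 1.9)
  ens <- toy_ensemble(spec)
  fr <- get_frame(ens, 1)
  focal <- 1:4; partner <- 5:n
  whole <- group_interaction(fr, ens$topology, focal, partner, Inf)
  for (rep in 1:5) {
    cut <- sample(5:(n - 1), 1)
    p1 <- 5:cut; p2 <- (cut + 1):n
    g1 <- group_interaction(fr, ens$topology, focal, p1, Inf)
    g2 <- group_interaction(fr, ens$topology, focal, p2, Inf)
    expect_equal(g1 + g2, whole, tolerance = 1e-10)
  }
})

test_that("tail contributions vanish as the cutoff grows", {
  # neutral-pair toy: energies converge to the no-cutoff value
  set.seed(35)
  n <- 30L
  spec <- toy_system_spec(matrix(runif(3 * n, -12, 12), n, 3),
                          charges = rep(c(0.3, -0.3), n / 2),
                          epsilon = 0.1, rmin_half = 1.9,
                          group_tags = rep(c("protein", "water"), each = n / 2))
  ens <- toy_ensemble(spec)
  fr <- get_frame(ens, 1)
  focal <- which(ens$topology$group_tag == "protein")
  partner <- which(ens$topology$group_tag == "water")
  full <- group_interaction(fr, ens$topology, focal, partner, Inf)[["total"]]
  errs <- vapply(c(10, 20, 30, 50), function(cc)
    abs(group_interaction(fr, ens$topology, focal, partner,
                          cc)[["total"]] - full), numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_equal(errs[4], 0, tolerance = 1e-12)
})

test_that("ensemble-level breakdowns split into Coulomb/LJ per partner group", {
  toy <- gen_toy_energetics(n_frames = 6L, jitter = 0.02, seed = 19L)
  eb <- energy_breakdown(toy$active, "group protein", cutoff = Inf)
  expect_true(all(c("water", "nucleotide") %in% eb$group))
  expect_equal(eb$total, eb$coulomb + eb$lj, tolerance = 1e-12)
  expect_equal(attr(eb, "grand_total"), sum(eb$total), tolerance = 1e-12)
})

test_that("delta energies vanish on identical ensembles and antisymmetrise", {
  toy <- gen_toy_energetics(n_frames = 12L, jitter = 0.05, seed = 5L)
  same <- delta_energy(toy$active, toy$active, "group protein",
                       partner_groups = c("water", "nucleotide"))
  expect_equal(same$delta_e, c(0, 0), tolerance = 1e-12)
  ab <- delta_energy(toy$active, toy$inactive, "group protein",
                     partner_groups = c("water", "nucleotide"))
  ba <- delta_energy(toy$inactive, toy$active, "group protein",
                     partner_groups = c("water", "nucleotide"))
  expect_equal(ab$delta_e, -ba$delta_e, tolerance = 1e-12)
  expect_equal(attr(ab, "delta_total"), -attr(ba, "delta_total"),
               tolerance = 1e-12)
})

test_that("a group missing from one system is reported as missing", {
  toy <- gen_toy_energetics(n_frames = 4L, jitter = 0, seed = 6L)
  de <- delta_energy(toy$active, toy$inactive, "group protein",
                     partner_groups = c("water", "nucleotide", "ion"))
  expect_true(is.na(de$delta_e[de$group == "ion"]))
  expect_false(any(is.na(de$delta_e[de$group != "ion"])))
})

test_that("the synthetic see-saw reproduces the qualitative energy pattern", {
  toy <- gen_toy_energetics(n_frames = 40L, jitter = 0.05, seed = 7L)
  de <- delta_energy(toy$active, toy$inactive, "group protein",
                     partner_groups = c("water", "nucleotide"))
  d_water <- de$delta_e[de$group == "water"]
  d_nuc <- de$delta_e[de$group == "nucleotide"]
  expect_gt(d_water, 0)   # solvation worsens in the active state
  expect_lt(d_nuc, 0)     # nucleotide interaction improves, and wins
  expect_lt(attr(de, "delta_total"), 0)
  expect_gt(abs(d_nuc), abs(d_water))
})

test_that("per-residue decomposition sums exactly to the loop totals", {
  set.seed(41)
  # two 3-residue loops with waters and a nucleotide site
  mk <- function(seed) {
    loop <- make_loop_ensemble(n_res = 3L, n_frames = 5L, jitter = 0.1,
                               seed = seed, residue_ids = 28:30)
    top <- loop$topology
    nw <- 6L
    extra <- topology(atom_id = max(top$atom_id) + seq_len(nw + 1),
                      atom_name = c(rep("OW", nw), "PB"),
                      residue_id = max(top$residue_id) + seq_len(nw + 1),
                      residue_name = c(rep("HOH", nw), "GDP"),
                      group_tag = c(rep("water", nw), "nucleotide"))
    all_top <- rbind(top, extra)
    class(all_top) <- class(top)
    all_top$charge <- runif(nrow(all_top), -0.5, 0.5)
    all_top$lj_epsilon <- 0.12
    all_top$lj_rmin_half <- 1.85
    frames <- array(NA_real_, c(5, nrow(all_top), 3))
    extra_xyz <- matrix(runif((nw + 1) * 3, -4, 8), nw + 1, 3)
    for (f in 1:5) frames[f, , ] <- rbind(get_frame(loop, f), extra_xyz)
    ensemble(all_top, frames)
  }
  act <- mk(1L); inact <- mk(2L)
  de <- delta_energy(act, inact, "resid 28 29 30 and group protein",
                     partner_groups = c("water", "nucleotide"),
                     cutoff = Inf)
  dec <- residue_decomposition(act, inact, 28:30,
                               partner_groups = c("water", "nucleotide"),
                               cutoff = Inf)
  for (g in c("water", "nucleotide")) {
    expect_equal(sum(dec$delta_e[dec$group == g]),
                 de$delta_e[de$group == g], tolerance = 1e-6)
  }
  # a single-residue focal equals the decomposition row (water and
  # nucleotide partner sets contain no loop atoms, so they coincide)
  one <- delta_energy(act, inact, "resid 29 and group protein",
                      partner_groups = c("water", "nucleotide"),
                      cutoff = Inf)
  for (g in c("water", "nucleotide")) {
    expect_equal(dec$delta_e[dec$residue == 29 & dec$group == g],
                 one$delta_e[one$group == g], tolerance = 1e-10)
  }
})
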