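test_that("dihedral angles follow the IUPAC sign convention", {
  p1 <- c(0, 1, 0); p2 <- c(0, 0, 0); p3 <- c(1, 0, 0)
  expect_equal(compute_dihedral(p1, p2, p3, c(1, 1, 0)), 0)
  expect_equal(compute_dihedral(p1, p2, p3, c(1, -1, 0)), pi)
  # right-handed quarter twist and its mirror image
  expect_equal(compute_dihedral(p1, p2, p3, c(1, 0, 1)), pi / 2)
  expect_equal(compute_dihedral(p1, p2, p3, c(1, 0, -1)), -pi / 2)
  expect_error(compute_dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                c(3, 1, 0)), "collinear")
})

test_that("dihedrals agree with an independent implementation", {
  skip_if_not_installed("bio3d")
  set.seed(7)
  for (i in 1:25) {
    p <- matrix(rnorm(12), 4, 3)
    mine <- compute_dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    ref <- bio3d::torsion.xyz(as.vector(t(p)), atm.inc = 4) * pi / 180
    expect_equal(mine, as.numeric(ref), tolerance = 1e-8)
  }
})

test_that("backbone rebuild and dihedral extraction are inverse maps", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 8L
    phi <- runif(n, -pi, pi); psi <- runif(n, -pi, pi)
    ens <- rebuild_backbone(phi, psi, n)
    dh <- suppressWarnings(extract_dihedrals(ens, 1:n, c("phi", "psi")))
    got_phi <- dh$values[1, dh$labels$angle == "phi"]
    got_psi <- dh$values[1, dh$labels$angle == "psi"]
    expect_equal(got_phi, phi[2:n], tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(got_psi, psi[1:(n - 1)], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("an ideal alpha-helical backbone returns its canonical angles", {
  n <- 10L
  ens <- rebuild_backbone(deg2rad(rep(-57, n)), deg2rad(rep(-47, n)), n)
  dh <- suppressWarnings(extract_dihedrals(ens, 1:n, c("phi", "psi")))
  expect_true(all(abs(dh$values[1, dh$labels$angle == "phi"] -
                        deg2rad(-57)) < 1e-6))
  expect_true(all(abs(dh$values[1, dh$labels$angle == "psi"] -
                        deg2rad(-47)) < 1e-6))
})

test_that("the fully extended chain maximises end-to-end distance", {
  n <- 6L
  ete <- function(phi_psi) {
    ens <- rebuild_backbone(rep(phi_psi[1], n), rep(phi_psi[2], n), n,
                            include_cb = FALSE)
    xyz <- get_frame(ens, 1)
    sqrt(sum((xyz[nrow(xyz), ] - xyz[1, ])^2))
  }
  grid <- seq(-pi, pi, length.out = 13)
  best <- -Inf
  for (a in grid) for (b in grid) best <- max(best, ete(c(a, b)))
  expect_gte(ete(c(pi, pi)) + 1e-9, best)
})

test_that("dihedral series shape accounts for skipped terminal angles", {
  gen <- gen_loop_ensemble(two_state_loop_spec(n_res = 13L), n_frames = 100L,
                           seed = 3L)
  dh <- suppressWarnings(
    extract_dihedrals(gen$ensemble, 28:40, c("phi", "psi")))
  expect_equal(dim(dh$values), c(100L, 24L))  # 2*13 minus terminal phi/psi
})

test_that("dihedrals are invariant under rigid motion of the ensemble", {
  ens <- make_loop_ensemble(n_res = 5L, n_frames = 1L)
  xyz <- get_frame(ens, 1)
  ens2 <- ensemble(ens$topology, rigid_motion(xyz, seed = 5))
  d1 <- suppressWarnings(extract_dihedrals(ens, 28:32, c("phi", "psi")))
  d2 <- suppressWarnings(extract_dihedrals(ens2, 28:32, c("phi", "psi")))
  expect_equal(d1$values, d2$values, tolerance = 1e-9)
})

test_that("chi1 is defined per residue type and refused for glycine", {
  n <- 4L
  ens <- rebuild_backbone(deg2rad(rep(-57, n)), deg2rad(rep(-47, n)), n,
                          residue_names = c("TYR", "GLY", "ALA", "LEU"))
  expect_error(extract_dihedrals(ens, 2L, "chi1"), "no chi1")
  # TYR has a chi1 definition (N-CA-CB-CG) but this backbone lacks CG
  expect_error(extract_dihedrals(ens, 1L, "chi1"), "missing atom")
})

test_that("Kabsch superposition is exact, proper and symmetric", {
  set.seed(21)
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose_rmsd(A, A)$rmsd, 0)
  B <- rigid_motion(A, seed = 22)
  fit <- superpose_rmsd(B, A)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  # symmetry of the metric
  C <- A + matrix(rnorm(30, sd = 0.4), 10, 3)
  expect_equal(superpose_rmsd(A, C)$rmsd, superpose_rmsd(C, A)$rmsd,
               tolerance = 1e-9)
  expect_error(superpose_rmsd(A[1:2, ], A[1:2, ]), ">= 3 atoms")
})

test_that("superposed RMSD matches a rotation-grid brute force on toys", {
  A <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 1))
  B <- rbind(c(0.2, 0, 0), c(2, 0.3, 0), c(1.8, 2, 0.2), c(0, 2.2, 0.8))
  fit <- superpose_rmsd(A, B)
  # brute force: direct minimisation over an axis-angle rotation
  # parameterisation (Rodrigues vector), many random starts
  set.seed(31)
  A0 <- sweep(A, 2, colMeans(A)); B0 <- sweep(B, 2, colMeans(B))
  obj <- function(v) {
    th <- sqrt(sum(v^2))
    R <- if (th < 1e-12) diag(3) else {
      ax <- v / th
      K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                  3, 3, byrow = TRUE)
      diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    }
    sqrt(mean(rowSums((A0 %*% t(R) - B0)^2)))
  }
  best <- Inf
  for (i in 1:40) {
    v0 <- runif(3, -pi, pi)
    best <- min(best, optim(v0, obj, method = "Nelder-Mead",
                            control = list(reltol = 1e-12))$value)
  }
  expect_lte(fit$rmsd, best + 1e-9)
  expect_equal(fit$rmsd, best, tolerance = 1e-6)
})

test_that("RMSF recovers isotropic jitter amplitude and scales linearly", {
  # enough atoms that the 6 rigid dof absorbed by the fit are negligible
  n_frames <- 2000L
  ens1 <- make_loop_ensemble(n_res = 25L, n_frames = n_frames, jitter = 0.5,
                             seed = 41)
  r1 <- rmsf(ens1)
  expect_equal(mean(r1), sqrt(3) * 0.5, tolerance = 0.05)
  ens2 <- make_loop_ensemble(n_res = 25L, n_frames = n_frames, jitter = 1.0,
                             seed = 41)
  r2 <- rmsf(ens2)
  expect_equal(mean(r2) / mean(r1), 2, tolerance = 0.05)
  # identical frames have zero fluctuation, single frame is an error
  rigid <- make_loop_ensemble(n_res = 4L, n_frames = 5L, jitter = 0)
  expect_equal(max(rmsf(rigid)), 0, tolerance = 1e-12)
  expect_error(rmsf(subset_frames(rigid, 1L)), "single frame")
})

test_that("minimum distances equal the exhaustive double loop", {
  ens <- make_loop_ensemble(n_res = 8L, n_frames = 3L, jitter = 1)
  a <- select_atoms(ens, "resid 28-30")
  b <- select_atoms(ens, "resid 33-35")
  got <- min_distance_series(ens, a, b)
  for (f in 1:3) {
    xyz <- get_frame(ens, f)
    best <- Inf
    for (i in a) for (j in b)
      best <- min(best, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
    expect_equal(got[f], best, tolerance = 1e-12)
    # the minimum is a lower bound on any specific pair
    expect_lte(got[f], sqrt(sum((xyz[a[1], ] - xyz[b[1], ])^2)))
  }
  expect_error(min_distance_series(ens, a, a), "overlap")
  # two single atoms at a known distance
  two <- toy_ensemble(toy_system_spec(rbind(c(0, 0, 0), c(3, 0, 0)),
                                      charges = 0))
  expect_equal(min_distance_series(two, 1L, 2L), 3.0)
})
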