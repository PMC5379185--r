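make_angle_series <- function(values, residues = 29L, angle = "phi") {
  dihedral_series(data.frame(residue_id = residues, angle = angle,
                             stringsAsFactors = FALSE),
                  matrix(values, ncol = length(residues)))
}

test_that("sin/cos embedding is periodic and distance-monotone", {
  s0 <- make_angle_series(0)
  f0 <- build_features(s0)
  expect_equal(unname(f0$matrix[1, ]), c(0, 1))
  # theta and theta + 2*pi embed identically
  sa <- make_angle_series(1.1)
  sb <- make_angle_series(1.1 + 2 * pi)
  expect_equal(build_features(sa)$matrix, build_features(sb)$matrix,
               tolerance = 1e-12)
  # chord length 2|sin(d/2)| grows with angular separation on (0, pi)
  ds <- seq(0.1, pi - 0.01, length.out = 30)
  chord <- vapply(ds, function(d) {
    a <- build_features(make_angle_series(0))$matrix
    b <- build_features(make_angle_series(d))$matrix
    sqrt(sum((a - b)^2))
  }, numeric(1))
  expect_true(all(diff(chord) > 0))
  expect_equal(chord, 2 * abs(sin(ds / 2)), tolerance = 1e-9)
})

test_that("feature building aligns systems and rejects mismatched labels", {
  s1 <- make_angle_series(c(0, 1), residues = 29L)
  s2 <- make_angle_series(c(2, 3), residues = 29L)
  fm <- build_features(list(gdp = s1, gtp = s2))
  expect_equal(fm$system, c("gdp", "gdp", "gtp", "gtp"))
  s3 <- make_angle_series(c(0, 1), residues = 30L)
  expect_error(build_features(list(a = s1, b = s3)), "labels differ")
})

test_that("k = 1 clustering gives the column means and total inertia", {
  set.seed(2)
  X <- matrix(rnorm(200), 50, 4)
  km <- cluster_states(X, k = 1L, seed = 3L, n_init = 2L)
  expect_equal(unname(km$centroids[1, ]), colMeans(X), tolerance = 1e-9)
  expect_equal(km$inertia, sum(sweep(X, 2, colMeans(X))^2),
               tolerance = 1e-9)
  # inertia consistency invariant
  recomputed <- sum((X - km$centroids[km$assignments, ])^2)
  expect_equal(km$inertia, recomputed, tolerance = 1e-6)
})

test_that("two well-separated circular states are recovered almost perfectly", {
  set.seed(4)
  n <- 500L
  truth <- rep(1:2, each = n)
  ang <- c(rvonmises(n, deg2rad(0), 50), rvonmises(n, deg2rad(90), 50))
  fm <- build_features(make_angle_series(matrix(ang, ncol = 1)))
  km <- cluster_states(fm, k = 2L, seed = 5L, n_init = 5L)
  m <- match_labels(km$assignments, truth, k = 2L)
  expect_gte(m$accuracy, 0.99)
})

test_that("restarts never worsen inertia and seeds reproduce", {
  set.seed(6)
  X <- rbind(matrix(rnorm(100, 0), 25, 4), matrix(rnorm(100, 3), 25, 4),
             matrix(rnorm(100, -3), 25, 4))
  one <- cluster_states(X, k = 3L, seed = 9L, n_init = 1L)
  many <- cluster_states(X, k = 3L, seed = 9L, n_init = 8L)
  expect_lte(many$inertia, one$inertia + 1e-9)
  again <- cluster_states(X, k = 3L, seed = 9L, n_init = 8L)
  expect_identical(many$assignments, again$assignments)
  expect_error(cluster_states(X[1:2, ], k = 3L), "fewer rows")
  expect_error(cluster_states(X[c(1, 1, 1, 1), ], k = 3L),
               "distinct points")
})

test_that("population tables are per-system fractions, order-invariant", {
  set.seed(8)
  n <- 300L
  ang <- c(rvonmises(n * 0.7, 0, 60), rvonmises(n * 0.3, pi * 0.6, 60))
  sys <- rep("wt", n)
  fm <- build_features(make_angle_series(matrix(ang, ncol = 1)))
  km <- cluster_states(fm, k = 2L, seed = 2L, n_init = 5L)
  pop <- population_table(km)
  expect_equal(sum(pop$fraction), 1, tolerance = 1e-12)
  # recovered weights within 3 binomial SE
  se <- sqrt(0.7 * 0.3 / n)
  expect_lt(abs(max(pop$fraction) - 0.7), 3 * se)
  # permuting frames leaves fractions unchanged
  perm <- sample(n)
  km2 <- km
  km2$assignments <- km$assignments[perm]
  km2$system <- km$system[perm]
  pop2 <- population_table(km2)
  expect_equal(sort(pop2$fraction), sort(pop$fraction), tolerance = 1e-12)
})

test_that("two copies of one state are indistinguishable to the clustering", {
  set.seed(10)
  # two independent systems drawn from the same state: any k = 2 split
  # cuts noise, so it neither aligns with the system tags nor separates
  # centroids anywhere near as far as genuinely distinct states do
  s_a <- make_angle_series(matrix(rvonmises(400, 1.0, 50), ncol = 1))
  s_b <- make_angle_series(matrix(rvonmises(400, 1.0, 50), ncol = 1))
  fm <- build_features(list(copy1 = s_a, copy2 = s_b))
  km <- cluster_states(fm, k = 2L, seed = 3L, n_init = 5L)
  pop <- population_table(km)
  f1 <- pop$fraction[pop$system == "copy1" & pop$cluster == 1]
  f2 <- pop$fraction[pop$system == "copy2" & pop$cluster == 1]
  se <- sqrt(0.5 * 0.5 * (1 / 400 + 1 / 400))
  expect_lt(abs(f1 - f2), 4 * se)
  same_sep <- sqrt(sum((km$centroids[1, ] - km$centroids[2, ])^2))
  # genuinely distinct states (90 degrees apart) for scale
  s_c <- make_angle_series(matrix(rvonmises(400, 1.0 + pi / 2, 50),
                                  ncol = 1))
  fm2 <- build_features(list(a = s_a, b = s_c))
  km2 <- cluster_states(fm2, k = 2L, seed = 3L, n_init = 5L)
  diff_sep <- sqrt(sum((km2$centroids[1, ] - km2$centroids[2, ])^2))
  expect_lt(same_sep, 0.4 * diff_sep)
})

test_that("circular histograms are normalised, periodic and match von Mises", {
  # delta distribution occupies one bin
  h <- chi_histogram(rep(deg2rad(33), 100))
  expect_equal(sum(h$probability), 1)
  expect_equal(sum(h$probability > 0), 1L)
  # shifting by 360 degrees changes nothing
  h2 <- chi_histogram(rep(deg2rad(33) + 2 * pi, 100))
  expect_equal(h, h2)
  expect_error(chi_histogram(numeric(0)), "empty")
  # distributional agreement at n = 1e4: chi-squared gof p > 0.01
  set.seed(12)
  n <- 10000L
  ang <- rvonmises(n, deg2rad(20), 2)
  h3 <- chi_histogram(ang, breaks_deg = seq(-180, 180, by = 20))
  p_theory <- vapply(seq_len(nrow(h3)), function(i)
    integrate(dvonmises, deg2rad(h3$lower_deg[i]), deg2rad(h3$upper_deg[i]),
              mu = deg2rad(20), kappa = 2)$value, numeric(1))
  gof <- chisq.test(h3$probability * n, p = p_theory / sum(p_theory))
  expect_gt(gof$p.value, 0.01)
})

test_that("signature classification separates bimodal contact distances", {
  # two-state reporter geometry: a probe atom near/far from a target
  set.seed(14)
  n <- 400L
  state <- rep(1:2, each = n / 2)
  d_true <- ifelse(state == 1, rnorm(n, 2.8, 0.2), rnorm(n, 6.0, 0.5))
  d_true <- pmax(d_true, 0.5)
  top <- topology(atom_id = 1:2, atom_name = c("CB", "PG"),
                  residue_id = c(34L, 100L), residue_name = c("TYR", "GTP"),
                  group_tag = c("protein", "nucleotide"))
  frames <- array(0, dim = c(n, 2, 3))
  frames[, 2, 1] <- d_true
  ens <- ensemble(top, frames)
  sig <- state_signature("min_distance", groupA = "name CB",
                         groupB = "group nucleotide",
                         closed_below = 4.5, open_above = 4.5 + 1e-9)
  cl <- classify_frames(ens, sig)
  acc <- mean((cl$labels == "closed") == (state == 1))
  expect_gte(acc, 0.99)
  expect_equal(sum(cl$fractions), 1)
  # strict comparators: a frame exactly at the threshold is not "closed"
  frames[1, 2, 1] <- 4.5
  ens2 <- ensemble(top, frames)
  cl2 <- classify_frames(ens2, sig)
  expect_false(cl2$labels[1] == "closed")
  # rule gaps are rejected at construction time
  expect_error(state_signature("min_distance", groupA = "name CB",
                               groupB = "group nucleotide",
                               closed_below = 5, open_above = 4),
               "thresholds")
})

test_that("four-state generator populations are recovered by k = 4 clustering", {
  spec <- two_state_loop_spec(n_res = 13L, kappa = 50,
                              weights = c(0.4, 0.3, 0.2, 0.1),
                              n_states = 4L)
  gen <- gen_loop_ensemble(spec, n_frames = 1200L, seed = 21L)
  dh <- suppressWarnings(
    extract_dihedrals(gen$ensemble, 28:40, c("phi", "psi")))
  fm <- build_features(dh)
  km <- cluster_states(fm, k = 4L, seed = 22L, n_init = 10L)
  m <- match_labels(km$assignments, gen$labels, k = 4L)
  expect_gte(m$accuracy, 0.97)
  for (s in 1:4) {
    w <- spec$weights[s]
    se <- sqrt(w * (1 - w) / 1200)
    got <- mean(m$relabelled == s)
    true_frac <- mean(gen$labels == s)
    expect_lt(abs(got - true_frac), 3 * se + 1e-9)
  }
})
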