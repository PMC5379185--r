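## Sub-state discovery: sin/cos embedding of dihedral features, k-means
## clustering (k-means++ seeding, Lloyd refinement via stats::kmeans),
## per-system population tables, circular histograms and rule-based
## side-chain signature classification.

#' Build a clustering feature matrix from dihedral series
#'
#' Each angle is embedded as (sin, cos), which removes the +/-180 degree
#' seam: Euclidean distance in the embedding is the chord length
#' 2|sin(d/2)| of the angular separation d, monotone in d on (0, pi).
#'
#' @param series a single [dihedral_series()], or a named list of them
#'   (one per system) sharing identical labels.
#' @param raw_angles if TRUE, use raw angles in radians instead of the
#'   embedding (for fidelity comparisons only).
#' @return an object of class `swi_features`: `matrix` (rows = pooled
#'   frames), `system` (tag per row), `labels`.
#' @export
build_features <- function(series, raw_angles = FALSE) {
  if (inherits(series, "swi_dihedrals")) series <- list(system = series)
  if (is.null(names(series)))
    names(series) <- sprintf("system_%d", seq_along(series))
  ref_lab <- series[[1]]$labels
  for (s in series) {
    if (!identical(s$labels[, c("residue_id", "angle")],
                   ref_lab[, c("residue_id", "angle")]))
      .stopf("build_features: dihedral labels differ across systems")
  }
  blocks <- lapply(series, function(s) {
    if (raw_angles) {
      m <- s$values
      colnames(m) <- paste0(ref_lab$angle, "_", ref_lab$residue_id)
      m
    } else {
      m <- cbind(sin(s$values), cos(s$values))[,
        rep(seq_len(ncol(s$values)), each = 2) +
          c(0, ncol(s$values)), drop = FALSE]
      colnames(m) <- paste0(rep(c("sin_", "cos_"), ncol(s$values)),
                            rep(paste0(ref_lab$angle, "_",
                                       ref_lab$residue_id), each = 2))
      m
    }
  })
  structure(list(matrix = do.call(rbind, blocks),
                 system = rep(names(series),
                              vapply(blocks, nrow, integer(1))),
                 labels = ref_lab, raw_angles = raw_angles),
            class = "swi_features")
}

#' @export
print.swi_features <- function(x, ...) {
  cat(sprintf("Feature matrix: %d frames x %d features (%d system(s), %s)\n",
              nrow(x$matrix), ncol(x$matrix), length(unique(x$system)),
              if (x$raw_angles) "raw angles" else "sin/cos embedding"))
  invisible(x)
}

# k-means++ initial centres (Arthur & Vassilvitskii seeding)
.kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  i <- sample.int(n, 1L)
  centers[1, ] <- X[i, ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k)[-1]) {
    if (all(d2 <= 0)) i <- sample.int(n, 1L)
    else i <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- X[i, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

#' k-means clustering of conformational features
#'
#' k-means++ initialisation followed by Lloyd iterations
#' (`stats::kmeans`, algorithm "Lloyd", up to 500 iterations); the best of
#' `n_init` seeded restarts by inertia is returned. Fully reproducible for
#' a given seed.
#'
#' @param features a [build_features()] object or plain numeric matrix.
#' @param k number of clusters (default 4).
#' @param seed RNG seed.
#' @param n_init number of restarts.
#' @return an object of class `swi_clusters`: `k`, `centroids`,
#'   `assignments` (1..k per row), `inertia`, `sizes`, `system`, `seed`.
#' @export
cluster_states <- function(features, k = 4L, seed = 1L, n_init = 10L) {
  X <- if (inherits(features, "swi_features")) features$matrix else
    as.matrix(features)
  if (nrow(X) < k) .stopf("cluster_states: fewer rows (%d) than k (%d)",
                          nrow(X), k)
  if (nrow(unique(X)) < k)
    .stopf("cluster_states: fewer than k distinct points")
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_init)) {
    init <- .kmeanspp_centers(X, k)
    km <- suppressWarnings(
      kmeans(X, centers = init, iter.max = 500L, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  structure(list(k = as.integer(k), centroids = best$centers,
                 assignments = best$cluster, inertia = best$tot.withinss,
                 sizes = as.integer(best$size),
                 system = if (inherits(features, "swi_features"))
                   features$system else rep("system", nrow(X)),
                 seed = as.integer(seed)),
            class = "swi_clusters")
}

#' @export
print.swi_clusters <- function(x, ...) {
  cat(sprintf("k-means sub-states: k = %d, inertia = %.3f, sizes: %s\n",
              x$k, x$inertia, paste(x$sizes, collapse = "/")))
  invisible(x)
}

#' Per-system cluster population fractions
#'
#' @param model a [cluster_states()] result.
#' @param system_tags optional override of the per-row system tags.
#' @return data frame `system, cluster, fraction`; fractions sum to 1
#'   within each system.
#' @export
population_table <- function(model, system_tags = NULL) {
  tags <- if (is.null(system_tags)) model$system else system_tags
  if (length(tags) != length(model$assignments))
    .stopf("population_table: %d tags for %d assignments", length(tags),
           length(model$assignments))
  tab <- table(system = tags, cluster = factor(model$assignments,
                                               levels = seq_len(model$k)))
  frac <- prop.table(tab, margin = 1)
  out <- as.data.frame(frac, responseName = "fraction",
                       stringsAsFactors = FALSE)
  out$cluster <- as.integer(as.character(out$cluster))
  out[order(out$system, out$cluster), ]
}

#' Match cluster labels to reference labels
#'
#' Exhaustive search over label permutations for the assignment that
#' maximises agreement with a reference labelling (feasible for the small
#' k used here). Populations and accuracies should only be compared after
#' this matching, since k-means labels are arbitrary.
#'
#' @param assignments integer cluster labels (1..k).
#' @param reference integer reference labels (1..k).
#' @param k number of clusters.
#' @return list with `accuracy`, `permutation` (index: cluster ->
#'   reference label), `relabelled`.
#' @export
match_labels <- function(assignments, reference, k = max(reference)) {
  perms <- .permutations(k)
  best_acc <- -1; best_perm <- NULL
  for (i in seq_len(nrow(perms))) {
    rel <- perms[i, ][assignments]
    acc <- mean(rel == reference)
    if (acc > best_acc) { best_acc <- acc; best_perm <- perms[i, ] }
  }
  list(accuracy = best_acc, permutation = best_perm,
       relabelled = best_perm[assignments])
}

.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1L)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                   sub[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  out
}

#' Normalised circular histogram of a dihedral column
#'
#' @param values angles in radians (or a one-column `swi_dihedrals`).
#' @param breaks_deg bin edges in degrees partitioning (-180, 180].
#' @return data frame `lower_deg, upper_deg, probability`; probabilities
#'   sum to 1.
#' @export
chi_histogram <- function(values, breaks_deg = seq(-180, 180, by = 10)) {
  if (inherits(values, "swi_dihedrals")) {
    stopifnot(ncol(values$values) == 1L)
    values <- values$values[, 1]
  }
  if (!length(values)) .stopf("chi_histogram: empty series")
  deg <- rad2deg(wrap_angle(values))
  # periodic binning on (-180, 180]
  deg[deg <= breaks_deg[1]] <- deg[deg <= breaks_deg[1]] + 360
  idx <- findInterval(deg, breaks_deg, left.open = TRUE,
                      rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(breaks_deg) - 1L)
  data.frame(lower_deg = breaks_deg[-length(breaks_deg)],
             upper_deg = breaks_deg[-1],
             probability = counts / sum(counts))
}

## side-chain signature classification ---------------------------------------

#' Side-chain state signature
#'
#' Threshold rules on a per-frame observable (a minimum side-chain to
#' partner distance, or a chi angle). The default mirrors a
#' hydrogen-bonding side chain: closed if the distance is strictly below
#' `closed_below`, open if strictly above `open_above`, intermediate
#' otherwise (boundaries fall into intermediate: comparators are strict).
#'
#' @param observable `"min_distance"` or `"chi_angle"`.
#' @param groupA,groupB selection expressions for the two distance groups
#'   (min_distance observable).
#' @param residue,angle residue id and angle name (chi_angle observable).
#' @param closed_below,open_above thresholds (Angstrom or degrees).
#' @return an object of class `swi_signature`.
#' @export
state_signature <- function(observable = c("min_distance", "chi_angle"),
                            groupA = NULL, groupB = NULL,
                            residue = NULL, angle = "chi1",
                            closed_below = 3.5, open_above = 5.5) {
  observable <- match.arg(observable)
  if (closed_below >= open_above)
    .stopf("state_signature: thresholds leave no room (closed_below >= open_above)")
  if (observable == "min_distance" && (is.null(groupA) || is.null(groupB)))
    .stopf("state_signature: min_distance needs groupA and groupB")
  if (observable == "chi_angle" && is.null(residue))
    .stopf("state_signature: chi_angle needs a residue")
  structure(list(observable = observable, groupA = groupA, groupB = groupB,
                 residue = residue, angle = angle,
                 closed_below = closed_below, open_above = open_above),
            class = "swi_signature")
}

#' Classify frames by a side-chain signature
#'
#' @param ens a `swi_ensemble`.
#' @param signature a [state_signature()].
#' @return list with `labels` (closed/intermediate/open per frame),
#'   `fractions` (named, summing to 1) and the observable series.
#' @export
classify_frames <- function(ens, signature) {
  obs <- if (signature$observable == "min_distance") {
    a <- select_atoms(ens, signature$groupA)
    b <- select_atoms(ens, signature$groupB)
    min_distance_series(ens, a, b)
  } else {
    dh <- extract_dihedrals(ens, signature$residue, signature$angle)
    rad2deg(dh$values[, 1])
  }
  labels <- ifelse(obs < signature$closed_below, "closed",
                   ifelse(obs > signature$open_above, "open",
                          "intermediate"))
  fr <- table(factor(labels, levels = c("closed", "intermediate", "open")))
  list(labels = labels,
       fractions = setNames(as.numeric(fr) / length(labels), names(fr)),
       observable = obs)
}
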