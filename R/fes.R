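## Free-energy surfaces: estimation from the accumulated bias, estimation
## by time-dependent reweighting of the biased trajectory, and basin /
## barrier analysis via a water-level flood fill.

#' Construct a free-energy surface object
#'
#' @param grid list of per-CV bin-centre vectors (length 1 or 2).
#' @param values free energies, kcal/mol; vector (1-D) or matrix (2-D).
#'   Shifted so the unmasked minimum is 0.
#' @param mask logical, same shape: TRUE marks unexplored bins.
#' @return an object of class `swi_fes`.
#' @export
free_energy_surface <- function(grid, values, mask = NULL) {
  if (is.numeric(grid)) grid <- list(grid)
  values <- if (length(grid) == 1L) as.numeric(values) else as.matrix(values)
  if (is.null(mask)) mask <- !is.finite(values) | is.na(values)
  values[mask] <- NA_real_
  if (!any(!mask)) .stopf("free_energy_surface: fully masked surface")
  values <- values - min(values[!mask])
  structure(list(grid = grid, values = values, mask = mask, basins = NULL),
            class = "swi_fes")
}

#' @export
print.swi_fes <- function(x, ...) {
  dims <- paste(vapply(x$grid, length, 1L), collapse = " x ")
  cat(sprintf("Free-energy surface: %s bins (%d masked), range 0 - %.2f kcal/mol\n",
              dims, sum(x$mask), max(x$values, na.rm = TRUE)))
  if (!is.null(x$basins)) {
    print(x$basins)
  }
  invisible(x)
}

#' Free-energy surface from the deposited bias
#'
#' Well-tempered estimator `F(s) = -(gamma/(gamma-1)) V(s, t_final) + C`,
#' with C fixing the unmasked minimum at 0. Bins with no hill centre within
#' 3 hill widths are masked as unexplored.
#'
#' @param bias a `swi_bias` with at least one hill.
#' @param grid per-CV bin centres: numeric vector (1 CV) or list of 1-2
#'   vectors; defaults to 200 points spanning the hill centres.
#' @return a `swi_fes`.
#' @export
fes_from_bias <- function(bias, grid = NULL) {
  if (nrow(bias$hills) == 0L) .stopf("fes_from_bias: empty bias")
  if (is.null(grid)) {
    grid <- lapply(seq_len(bias$n_cv), function(k) {
      ck <- bias$hills[[sprintf("center%d", k)]]
      pad <- 3 * bias$widths[k]
      seq(min(ck) - pad, max(ck) + pad, length.out = 200L)
    })
  }
  if (is.numeric(grid)) grid <- list(grid)
  stopifnot(length(grid) == bias$n_cv)
  pts <- if (bias$n_cv == 1L) matrix(grid[[1]], ncol = 1L) else
    as.matrix(expand.grid(grid[[1]], grid[[2]]))
  V <- bias_value(bias, pts)
  gamma <- bias$bias_factor
  scale <- if (is.finite(gamma)) gamma / (gamma - 1) else 1
  FF <- -scale * V
  # unexplored: no hill centre within 3 widths in every CV
  near <- rep(FALSE, nrow(pts))
  h <- bias$hills
  for (i in seq_len(nrow(h))) {
    ok <- abs(pts[, 1] - h$center1[i]) <= 3 * h$sigma1[i]
    if (bias$n_cv == 2L)
      ok <- ok & abs(pts[, 2] - h$center2[i]) <= 3 * h$sigma2[i]
    near <- near | ok
    if (all(near)) break
  }
  if (bias$n_cv == 1L) {
    free_energy_surface(grid, FF, mask = !near)
  } else {
    free_energy_surface(grid,
                        matrix(FF, length(grid[[1]]), length(grid[[2]])),
                        mask = matrix(!near, length(grid[[1]]),
                                      length(grid[[2]])))
  }
}

#' Normalised frame weights for metadynamics reweighting
#'
#' Time-dependent bias-offset weights
#' `w(t) proportional to exp[(V(s(t),t) - c(t)) / kT]`, with c(t) the
#' running offset maintained on the bias grid during the run.
#'
#' @param run a `swi_metad_run`.
#' @return numeric weights summing to 1, one per recorded frame.
#' @export
frame_weights <- function(run) {
  stopifnot(inherits(run, "swi_metad_run"))
  a <- (run$frame_bias - run$frame_c) / run$kT
  w <- exp(a - max(a))
  w / sum(w)
}

#' Free-energy surface by reweighting the biased trajectory
#'
#' Weighted histogram of an observable over the recorded frames with
#' [frame_weights()], then `F = -kT log`. With zero bias throughout this
#' reduces to the plain Boltzmann inversion of the unbiased histogram.
#' Bins receiving no weight are masked, not set to zero.
#'
#' @param run a `swi_metad_run`.
#' @param grid per-observable bin centres (vector, or list of 1-2 vectors);
#'   defaults to 100 bins spanning the sampled CV range.
#' @param observable which quantity to histogram: NULL for the biased CVs,
#'   an integer vector of CV columns, or a function of the state vector
#'   returning 1-2 values per frame.
#' @return a `swi_fes`.
#' @export
reweight <- function(run, grid = NULL, observable = NULL) {
  w <- frame_weights(run)
  obs <- if (is.null(observable)) {
    run$cv_values
  } else if (is.function(observable)) {
    t(apply(run$states, 1, observable))
  } else {
    run$cv_values[, observable, drop = FALSE]
  }
  if (is.null(dim(obs))) obs <- matrix(obs, ncol = 1L)
  if (ncol(obs) > nrow(obs)) obs <- t(obs)  # guard 1-row apply collapse
  nd <- ncol(obs)
  if (is.null(grid)) {
    grid <- lapply(seq_len(nd), function(k)
      seq(min(obs[, k]), max(obs[, k]), length.out = 100L))
  }
  if (is.numeric(grid)) grid <- list(grid)
  stopifnot(length(grid) == nd)
  edges <- lapply(grid, .centers_to_edges)
  i1 <- findInterval(obs[, 1], edges[[1]], rightmost.closed = TRUE)
  keep <- i1 >= 1 & i1 <= length(grid[[1]])
  if (nd == 2L) {
    i2 <- findInterval(obs[, 2], edges[[2]], rightmost.closed = TRUE)
    keep <- keep & i2 >= 1 & i2 <= length(grid[[2]])
  }
  if (nd == 1L) {
    hist_w <- vapply(seq_along(grid[[1]]), function(b)
      sum(w[keep & i1 == b]), numeric(1))
    FF <- -run$kT * log(hist_w)
    free_energy_surface(grid, FF, mask = hist_w <= 0)
  } else {
    hw <- matrix(0, length(grid[[1]]), length(grid[[2]]))
    for (f in which(keep)) hw[i1[f], i2[f]] <- hw[i1[f], i2[f]] + w[f]
    FF <- -run$kT * log(hw)
    free_energy_surface(grid, FF, mask = hw <= 0)
  }
}

.centers_to_edges <- function(centers) {
  d <- diff(centers)
  c(centers[1] - d[1] / 2, centers[-length(centers)] + d / 2,
    centers[length(centers)] + d[length(d)] / 2)
}

#' Locate basins and inter-basin barriers on a free-energy surface
#'
#' Water-level flood fill: bins are flooded in order of increasing free
#' energy; a local minimum starts a basin, and the level at which two
#' basins first connect is their lowest separating saddle. Basins shallower
#' than `min_depth` below their merge level are absorbed into their deeper
#' neighbour. Labels A, B, C, ... are assigned by increasing minimum.
#'
#' @param fes a `swi_fes` (1-D or 2-D).
#' @param min_depth minimum basin persistence, kcal/mol.
#' @return the `swi_fes` with `basins` (data frame: label, per-CV location,
#'   value) plus `barriers` (matrix: barrier\[i,j\] = saddle(i,j) - F_i) and
#'   `delta_g` (matrix F_j - F_i) attached.
#' @export
find_basins_barriers <- function(fes, min_depth = 0.5) {
  vals <- fes$values
  is2d <- length(fes$grid) == 2L
  n1 <- length(fes$grid[[1]])
  n2 <- if (is2d) length(fes$grid[[2]]) else 1L
  flat <- as.numeric(vals)
  ok <- which(!fes$mask & is.finite(flat))
  if (!length(ok)) .stopf("find_basins_barriers: fully masked surface")
  ord <- ok[order(flat[ok])]

  parent <- seq_len(n1 * n2)          # union-find over bins
  root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  comp_min <- rep(Inf, n1 * n2)       # basin minimum value per root
  comp_arg <- integer(n1 * n2)        # bin index of that minimum
  members <- vector("list", n1 * n2)  # kept-basin ids per root
  assigned <- logical(n1 * n2)
  kept_arg <- integer(0)              # bin index of each kept basin minimum
  saddle <- matrix(Inf, 0, 0)

  neighbours <- function(i) {
    r <- ((i - 1L) %% n1) + 1L
    cc <- ((i - 1L) %/% n1) + 1L
    out <- integer(0)
    if (r > 1L) out <- c(out, i - 1L)
    if (r < n1) out <- c(out, i + 1L)
    if (is2d) {
      if (cc > 1L) out <- c(out, i - n1)
      if (cc < n2) out <- c(out, i + n1)
    }
    out
  }

  for (b in ord) {
    nb <- neighbours(b)
    nb <- nb[assigned[nb]]
    roots <- unique(vapply(nb, root, integer(1)))
    assigned[b] <- TRUE
    if (!length(roots)) {
      comp_min[b] <- flat[b]; comp_arg[b] <- b
      parent[b] <- b
      members[[b]] <- integer(0)
      # provisionally a kept basin; demoted on merge if too shallow
      kept_arg <- c(kept_arg, b)
      kid <- length(kept_arg)
      members[[b]] <- kid
      if (kid > 1L) {
        saddle <- rbind(cbind(saddle, Inf), Inf)
      } else saddle <- matrix(Inf, 1, 1)
      diag(saddle) <- NA
      next
    }
    # attach to the deepest neighbouring component
    deepest <- roots[which.min(comp_min[roots])]
    parent[b] <- deepest
    for (r in setdiff(roots, deepest)) {
      persistence <- flat[b] - comp_min[r]
      m1 <- members[[deepest]]; m2 <- members[[r]]
      if (persistence < min_depth) {
        # absorb the shallow basin: its ids lose their separate identity
        members[[deepest]] <- c(m1, -abs(m2))
      } else {
        for (a in m1[m1 > 0]) for (z in m2[m2 > 0]) {
          if (!is.finite(saddle[a, z])) {
            saddle[a, z] <- saddle[z, a] <- flat[b]
          }
        }
        members[[deepest]] <- c(m1, m2)
      }
      members[[r]] <- integer(0)
      parent[r] <- deepest
      if (comp_min[r] < comp_min[deepest]) {
        comp_min[deepest] <- comp_min[r]
        comp_arg[deepest] <- comp_arg[r]
      }
    }
  }
  keep_ids <- sort(unique(unlist(members)[unlist(members) > 0]))
  # also require each kept basin to be deep enough vs its best saddle
  args <- kept_arg[keep_ids]
  mins <- flat[args]
  sub <- saddle[keep_ids, keep_ids, drop = FALSE]
  deep <- vapply(seq_along(keep_ids), function(i) {
    s <- suppressWarnings(min(sub[i, ], na.rm = TRUE))
    !is.finite(s) || (s - mins[i]) >= min_depth
  }, logical(1))
  # the global minimum always stays
  deep[which.min(mins)] <- TRUE
  keep_ids <- keep_ids[deep]
  args <- kept_arg[keep_ids]
  mins <- flat[args]
  o <- order(mins)
  args <- args[o]; mins <- mins[o]
  nb <- length(args)
  loc1 <- fes$grid[[1]][((args - 1L) %% n1) + 1L]
  basins <- data.frame(label = LETTERS[seq_len(nb)], cv1 = loc1,
                       value = mins, stringsAsFactors = FALSE)
  if (is2d) basins$cv2 <- fes$grid[[2]][((args - 1L) %/% n1) + 1L]
  sub <- saddle[keep_ids[o], keep_ids[o], drop = FALSE]
  barriers <- sweep(sub, 1, mins, `-`)
  dg <- outer(mins, mins, function(a, b) b - a)
  dimnames(barriers) <- dimnames(dg) <- list(basins$label, basins$label)
  fes$basins <- basins
  fes$barriers <- barriers
  fes$delta_g <- dg
  fes
}

#' Write a free-energy surface as a whitespace grid table
#'
#' Columns `cv1 [cv2] free_energy`; masked bins written as NA.
#'
#' @param fes a `swi_fes`.
#' @param path output file.
#' @export
write_fes <- function(fes, path) {
  if (length(fes$grid) == 1L) {
    tab <- data.frame(cv1 = fes$grid[[1]], free_energy = fes$values)
  } else {
    g <- expand.grid(cv1 = fes$grid[[1]], cv2 = fes$grid[[2]])
    tab <- data.frame(g, free_energy = as.numeric(fes$values))
  }
  write.table(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
plot.swi_fes <- function(x, ...) {
  if (length(x$grid) == 1L) {
    plot(x$grid[[1]], x$values, type = "l", lwd = 2,
         xlab = "CV", ylab = "free energy (kcal/mol)", ...)
    if (!is.null(x$basins))
      graphics::text(x$basins$cv1, x$basins$value, x$basins$label, pos = 1)
  } else {
    graphics::image(x$grid[[1]], x$grid[[2]], x$values,
                    col = grDevices::hcl.colors(50, "viridis"),
                    xlab = "CV 1", ylab = "CV 2", ...)
    graphics::contour(x$grid[[1]], x$grid[[2]], x$values, add = TRUE,
                      col = "grey30")
    if (!is.null(x$basins))
      graphics::text(x$basins$cv1, x$basins$cv2, x$basins$label,
                     col = "white", font = 2)
  }
  invisible(x)
}
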