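# Shared in-code fixtures. Everything is generated deterministically at
# test time; no binary data on disk.

# a small rigid peptide-like ensemble with optional per-frame jitter
make_loop_ensemble <- function(n_res = 5L, n_frames = 3L, jitter = 0,
                               seed = 1L, residue_ids = seq_len(n_res) + 27L) {
  set.seed(seed)
  base <- rebuild_backbone(deg2rad(rep(-57, n_res)),
                           deg2rad(rep(-47, n_res)), n_res,
                           residue_ids = residue_ids)
  xyz <- get_frame(base, 1)
  frames <- array(NA_real_, dim = c(n_frames, nrow(xyz), 3L))
  for (f in seq_len(n_frames)) {
    frames[f, , ] <- xyz + if (jitter > 0)
      matrix(rnorm(length(xyz), sd = jitter), nrow(xyz), 3L) else 0
  }
  ensemble(base$topology, frames)
}

# apply a random rigid motion to an n x 3 coordinate matrix
rigid_motion <- function(xyz, seed = 1L) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(xyz %*% R, 2, rnorm(3, sd = 5), `+`)
}

# brute-force DRMSD: explicit double loop over unordered pairs, matching
# the pair order of dist() so the comparison can be exact
brute_drmsd <- function(A, B) {
  n <- nrow(A)
  terms <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      da <- sqrt((A[i, 1] - A[j, 1]) * (A[i, 1] - A[j, 1]) +
                   (A[i, 2] - A[j, 2]) * (A[i, 2] - A[j, 2]) +
                   (A[i, 3] - A[j, 3]) * (A[i, 3] - A[j, 3]))
      db <- sqrt((B[i, 1] - B[j, 1]) * (B[i, 1] - B[j, 1]) +
                   (B[i, 2] - B[j, 2]) * (B[i, 2] - B[j, 2]) +
                   (B[i, 3] - B[j, 3]) * (B[i, 3] - B[j, 3]))
      terms <- c(terms, (da - db)^2)
    }
  }
  sqrt(mean(terms))
}

# lowest-saddle (minimax path) oracle by level search + BFS connectivity
brute_barrier_level <- function(vals, from, to) {
  # vals: matrix; from/to: linear indices; returns the lowest level L such
  # that from and to are connected through bins with value <= L
  n1 <- nrow(vals); n2 <- ncol(vals)
  levels <- sort(unique(as.numeric(vals)))
  connected_at <- function(L) {
    open <- vals <= L
    if (!open[from] || !open[to]) return(FALSE)
    seen <- matrix(FALSE, n1, n2)
    queue <- from
    seen[from] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      if (cur == to) return(TRUE)
      r <- ((cur - 1) %% n1) + 1; cc <- ((cur - 1) %/% n1) + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + d[1]; c2 <- cc + d[2]
        if (rr >= 1 && rr <= n1 && c2 >= 1 && c2 <= n2) {
          k <- (c2 - 1) * n1 + rr
          if (open[k] && !seen[k]) { seen[k] <- TRUE; queue <- c(queue, k) }
        }
      }
    }
    FALSE
  }
  for (L in levels) if (connected_at(L)) return(L)
  Inf
}
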