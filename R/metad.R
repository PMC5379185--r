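## Desk-scale sampling engine: overdamped Langevin dynamics on analytic
## landscapes, optionally biased by well-tempered metadynamics hills
## deposited along 1-2 collective variables. The accumulated bias and the
## sampled trajectory both carry free-energy information; fes.R turns them
## into surfaces.

#' Overdamped Langevin sampling of an analytic potential
#'
#' Euler-Maruyama integration of
#' `x <- x - (dt/friction) grad U + sqrt(2 kT dt / friction) eta`.
#'
#' @param pot a `swi_potential`.
#' @param kT thermal energy, kcal/mol (0.5962 at 300 K).
#' @param dt time step, ps.
#' @param n_steps number of steps.
#' @param friction friction coefficient (kcal/mol ps / CV-unit^2).
#' @param x0 initial state (defaults to the domain centre).
#' @param seed RNG seed (mandatory: every run is reproducible).
#' @param record_stride store every n-th state.
#' @return list with `states` (n_rec x dim matrix), `times` (ps), and the
#'   run settings.
#' @export
langevin_sample <- function(pot, kT = 0.5962, dt = 0.005, n_steps = 10000L,
                            friction = 1.0, x0 = NULL, seed,
                            record_stride = 10L) {
  if (missing(seed)) .stopf("langevin_sample: seed is required")
  run <- .run_dynamics(pot, cvs = NULL, W = 0, widths = NULL,
                       stride = Inf, bias_factor = Inf, kT = kT, dt = dt,
                       n_steps = n_steps, friction = friction, x0 = x0,
                       seed = seed, record_stride = record_stride)
  run[c("states", "times", "kT", "dt", "friction", "seed")]
}

#' Well-tempered metadynamics run
#'
#' Every `stride` steps a Gaussian hill of height
#' `W exp(-V(s,t) / ((gamma-1) kT))` is deposited at the current CV value;
#' the bias force enters the dynamics through the chain rule of the CVs.
#' Hills therefore shrink geometrically in well-visited regions and the
#' final bias estimates the free-energy surface up to the factor
#' gamma/(gamma-1).
#'
#' @param pot a `swi_potential`.
#' @param cvs a single `swi_cv` or list of 1-2 of them.
#' @param W initial hill height, kcal/mol.
#' @param widths per-CV Gaussian width sigma (CV units).
#' @param stride steps between hill depositions (deposition period in time
#'   is `stride * dt`).
#' @param bias_factor well-tempering factor gamma > 1 (Inf = standard,
#'   untempered metadynamics).
#' @param grid_n bias-grid points per CV used for force interpolation.
#' @inheritParams langevin_sample
#' @return an object of class `swi_metad_run`: recorded `states`, `times`,
#'   `cv_values`, per-frame bias `frame_bias` and offset `frame_c`, and the
#'   accumulated `bias` (class `swi_bias`).
#' @export
wt_metad <- function(pot, cvs, W = 0.1, widths, stride = 400L,
                     bias_factor = 10, kT = 0.5962, dt = 0.005,
                     n_steps = 200000L, friction = 1.0, x0 = NULL, seed,
                     record_stride = 10L, grid_n = 400L) {
  if (missing(seed)) .stopf("wt_metad: seed is required")
  if (inherits(cvs, "swi_cv")) cvs <- list(cvs)
  if (length(cvs) < 1L || length(cvs) > 2L)
    .stopf("wt_metad: 1 or 2 collective variables supported")
  if (!(bias_factor > 1)) .stopf("wt_metad: bias_factor must exceed 1")
  widths <- rep_len(widths, length(cvs))
  if (any(widths <= 0)) .stopf("wt_metad: hill widths must be positive")
  .run_dynamics(pot, cvs, W, widths, stride, bias_factor, kT, dt, n_steps,
                friction, x0, seed, record_stride, grid_n)
}

# shared integrator; cvs = NULL runs unbiased
.run_dynamics <- function(pot, cvs, W, widths, stride, bias_factor, kT, dt,
                          n_steps, friction, x0, seed, record_stride,
                          grid_n = 400L) {
  set.seed(as.integer(seed))
  d <- pot$dim
  ncv <- length(cvs)
  biased <- ncv > 0L
  if (is.null(x0)) x0 <- vapply(pot$domain, mean, numeric(1))
  x <- as.numeric(x0)
  gradU <- pot$grad
  periodic <- isTRUE(pot$periodic)
  noise_scale <- sqrt(2 * kT * dt / friction)
  mob <- dt / friction
  temperature <- kT / .kB
  dT <- if (is.finite(bias_factor)) (bias_factor - 1) * kT else Inf

  # bias grids per CV (linear force interpolation between grid points)
  if (biased) {
    g0 <- ds <- numeric(ncv); gn <- integer(ncv)
    centers <- vector("list", ncv)
    for (k in seq_len(ncv)) {
      r <- cvs[[k]]$range
      pad <- 0.05 * diff(r)
      centers[[k]] <- seq(r[1] - pad, r[2] + pad, length.out = grid_n)
      g0[k] <- centers[[k]][1]
      ds[k] <- centers[[k]][2] - centers[[k]][1]
      gn[k] <- grid_n
    }
    if (ncv == 1L) {
      Vg <- numeric(gn[1]); G1 <- numeric(gn[1])
    } else {
      Vg <- matrix(0, gn[1], gn[2])
      G1 <- matrix(0, gn[1], gn[2]); G2 <- matrix(0, gn[1], gn[2])
    }
    cv_val <- lapply(cvs, `[[`, "value")
    cv_grad <- lapply(cvs, `[[`, "grad")
    beta_g <- (bias_factor / (bias_factor - 1)) / kT
    beta_1 <- (1 / (bias_factor - 1)) / kT
    hill_t <- hill_h <- numeric(0)
    hill_c <- matrix(0, 0, ncv)
    hill_cvals <- numeric(0)
  }

  n_rec <- n_steps %/% record_stride
  states <- matrix(NA_real_, n_rec, d)
  times <- numeric(n_rec)
  if (biased) {
    cv_rec <- matrix(NA_real_, n_rec, ncv)
    fb <- numeric(n_rec)  # V(s(t), t) at record times
    fc <- numeric(n_rec)  # c(t) at record times (latest hill update)
    cur_c <- 0
  }
  rec <- 0L
  chunk <- 50000L
  step <- 0L
  while (step < n_steps) {
    m <- min(chunk, n_steps - step)
    eta <- matrix(rnorm(m * d), m, d)
    for (i in seq_len(m)) {
      step_i <- step + i
      f <- -gradU(x)
      if (biased) {
        s <- vapply(cv_val, function(v) v(x), numeric(1))
        # interpolate bias value and gradient from the grids
        if (ncv == 1L) {
          u <- (s[1] - g0[1]) / ds[1]
          j <- floor(u)
          if (j < 0) j <- 0 else if (j > gn[1] - 2) j <- gn[1] - 2L
          w <- u - j
          vb <- (1 - w) * Vg[j + 1] + w * Vg[j + 2]
          db <- (1 - w) * G1[j + 1] + w * G1[j + 2]
          f <- f - db * cv_grad[[1]](x)
        } else {
          u1 <- (s[1] - g0[1]) / ds[1]; u2 <- (s[2] - g0[2]) / ds[2]
          j1 <- floor(u1); j2 <- floor(u2)
          if (j1 < 0) j1 <- 0 else if (j1 > gn[1] - 2) j1 <- gn[1] - 2L
          if (j2 < 0) j2 <- 0 else if (j2 > gn[2] - 2) j2 <- gn[2] - 2L
          w1 <- u1 - j1; w2 <- u2 - j2
          i1 <- j1 + 1L; i2 <- j2 + 1L
          vb <- (1 - w1) * ((1 - w2) * Vg[i1, i2] + w2 * Vg[i1, i2 + 1]) +
            w1 * ((1 - w2) * Vg[i1 + 1, i2] + w2 * Vg[i1 + 1, i2 + 1])
          d1 <- (1 - w1) * ((1 - w2) * G1[i1, i2] + w2 * G1[i1, i2 + 1]) +
            w1 * ((1 - w2) * G1[i1 + 1, i2] + w2 * G1[i1 + 1, i2 + 1])
          d2 <- (1 - w1) * ((1 - w2) * G2[i1, i2] + w2 * G2[i1, i2 + 1]) +
            w1 * ((1 - w2) * G2[i1 + 1, i2] + w2 * G2[i1 + 1, i2 + 1])
          f <- f - d1 * cv_grad[[1]](x) - d2 * cv_grad[[2]](x)
        }
      }
      if (!all(is.finite(f)))
        .stopf("dynamics diverged at step %d (non-finite force)", step_i)
      x <- x + mob * f + noise_scale * eta[i, ]
      if (periodic) x <- wrap_angle(x)

      if (biased && step_i %% stride == 0L) {
        s <- vapply(cv_val, function(v) v(x), numeric(1))
        vb_here <- .bias_interp(s, ncv, g0, ds, gn, Vg)
        h <- if (is.finite(dT)) W * exp(-vb_here / dT) else W
        # accumulate hill onto value and gradient grids
        if (ncv == 1L) {
          z <- (centers[[1]] - s[1]) / widths[1]
          e <- h * exp(-0.5 * z * z)
          Vg <- Vg + e
          G1 <- G1 - e * (centers[[1]] - s[1]) / widths[1]^2
        } else {
          z1 <- (centers[[1]] - s[1]) / widths[1]
          z2 <- (centers[[2]] - s[2]) / widths[2]
          e1 <- exp(-0.5 * z1 * z1); e2 <- exp(-0.5 * z2 * z2)
          Vg <- Vg + h * outer(e1, e2)
          G1 <- G1 - h * outer(e1 * (centers[[1]] - s[1]) / widths[1]^2, e2)
          G2 <- G2 - h * outer(e1, e2 * (centers[[2]] - s[2]) / widths[2]^2)
        }
        hill_t <- c(hill_t, step_i * dt)
        hill_h <- c(hill_h, h)
        hill_c <- rbind(hill_c, s)
        # running bias offset c(t) from the grid estimate (refreshed per hill)
        if (is.finite(bias_factor)) {
          mx <- max(Vg)
          cur_c <- kT * (log(sum(exp(beta_g * (Vg - mx)))) -
                           log(sum(exp(beta_1 * (Vg - mx))))) +
            mx * (beta_g - beta_1) * kT
        } else {
          cur_c <- 0
        }
      }
      if (step_i %% record_stride == 0L) {
        rec <- rec + 1L
        states[rec, ] <- x
        times[rec] <- step_i * dt
        if (biased) {
          s_rec <- vapply(cv_val, function(v) v(x), numeric(1))
          cv_rec[rec, ] <- s_rec
          fb[rec] <- .bias_interp(s_rec, ncv, g0, ds, gn, Vg)
          fc[rec] <- cur_c
        }
      }
    }
    step <- step + m
  }
  out <- list(states = states[seq_len(rec), , drop = FALSE],
              times = times[seq_len(rec)], kT = kT, dt = dt,
              friction = friction, seed = seed, pot_kind = pot$kind)
  if (biased) {
    hills <- data.frame(time = hill_t)
    for (k in seq_len(ncv)) hills[[sprintf("center%d", k)]] <- hill_c[, k]
    for (k in seq_len(ncv)) hills[[sprintf("sigma%d", k)]] <- widths[k]
    hills$height <- hill_h
    bias <- structure(list(hills = hills, bias_factor = bias_factor,
                           temperature = temperature, kT = kT,
                           n_cv = ncv,
                           cv_names = vapply(cvs, `[[`, "", "name"),
                           widths = widths),
                      class = "swi_bias")
    out$cv_values <- cv_rec[seq_len(rec), , drop = FALSE]
    out$frame_bias <- fb[seq_len(rec)]
    out$frame_c <- fc[seq_len(rec)]
    out$bias <- bias
    class(out) <- "swi_metad_run"
  }
  out
}

# linear interpolation of the gridded bias at one CV point
.bias_interp <- function(s, ncv, g0, ds, gn, Vg) {
  if (ncv == 1L) {
    u <- (s[1] - g0[1]) / ds[1]
    j <- floor(u)
    if (j < 0) j <- 0 else if (j > gn[1] - 2) j <- gn[1] - 2L
    w <- u - j
    (1 - w) * Vg[j + 1] + w * Vg[j + 2]
  } else {
    u1 <- (s[1] - g0[1]) / ds[1]; u2 <- (s[2] - g0[2]) / ds[2]
    j1 <- floor(u1); j2 <- floor(u2)
    if (j1 < 0) j1 <- 0 else if (j1 > gn[1] - 2) j1 <- gn[1] - 2L
    if (j2 < 0) j2 <- 0 else if (j2 > gn[2] - 2) j2 <- gn[2] - 2L
    w1 <- u1 - j1; w2 <- u2 - j2
    i1 <- j1 + 1L; i2 <- j2 + 1L
    (1 - w1) * ((1 - w2) * Vg[i1, i2] + w2 * Vg[i1, i2 + 1]) +
      w1 * ((1 - w2) * Vg[i1 + 1, i2] + w2 * Vg[i1 + 1, i2 + 1])
  }
}

#' @export
print.swi_metad_run <- function(x, ...) {
  cat(sprintf(
    "Well-tempered metadynamics run: %d recorded frames, %d hills, gamma = %s\n",
    nrow(x$states), nrow(x$bias$hills), format(x$bias$bias_factor)))
  invisible(x)
}

#' @export
print.swi_bias <- function(x, ...) {
  cat(sprintf("Metadynamics bias: %d hills in %d CV(s) [%s], gamma = %s\n",
              nrow(x$hills), x$n_cv, paste(x$cv_names, collapse = ", "),
              format(x$bias_factor)))
  invisible(x)
}

#' Evaluate a hill bias at CV points
#'
#' Exact summation over all deposited hills with time <= t.
#'
#' @param bias a `swi_bias`.
#' @param points numeric vector (1 CV) or n x 2 matrix (2 CVs) of CV values.
#' @param t evaluate the bias as of this time (default: all hills).
#' @return bias potential V(s, t), kcal/mol, per point.
#' @export
bias_value <- function(bias, points, t = Inf) {
  h <- bias$hills[bias$hills$time <= t, , drop = FALSE]
  P <- if (is.null(dim(points))) matrix(points, ncol = 1L) else points
  stopifnot(ncol(P) == bias$n_cv)
  out <- numeric(nrow(P))
  for (i in seq_len(nrow(h))) {
    z <- (P[, 1] - h$center1[i]) / h$sigma1[i]
    e <- exp(-0.5 * z * z)
    if (bias$n_cv == 2L) {
      z2 <- (P[, 2] - h$center2[i]) / h$sigma2[i]
      e <- e * exp(-0.5 * z2 * z2)
    }
    out <- out + h$height[i] * e
  }
  out
}

#' Write hills in PLUMED-like column order
#'
#' Whitespace table `time center1 [center2] sigma1 [sigma2] height
#' biasfactor`, one hill per line.
#'
#' @param bias a `swi_bias`.
#' @param path output file.
#' @export
write_hills <- function(bias, path) {
  h <- bias$hills
  h$biasfactor <- bias$bias_factor
  write.table(format(h, digits = 10, scientific = FALSE, trim = TRUE),
              path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a hills file written by [write_hills()]
#' @param path hills file.
#' @param temperature simulation temperature, K.
#' @return a `swi_bias`.
#' @export
read_hills <- function(path, temperature = 300) {
  h <- read.table(path, header = TRUE)
  ncv <- if ("center2" %in% names(h)) 2L else 1L
  bf <- if ("biasfactor" %in% names(h)) h$biasfactor[1] else Inf
  widths <- if (ncv == 2L) c(h$sigma1[1], h$sigma2[1]) else h$sigma1[1]
  structure(list(hills = h[setdiff(names(h), "biasfactor")],
                 bias_factor = bf, temperature = temperature,
                 kT = .kB * temperature, n_cv = ncv,
                 cv_names = paste0("cv", seq_len(ncv)), widths = widths),
            class = "swi_bias")
}
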