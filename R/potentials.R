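## Analytic toy potentials with known ground truth. These stand in for the
## solvated-protein energy landscape so the sampling and free-energy
## machinery can be validated against closed-form or quadrature oracles.

#' Analytic potential specification
#'
#' @param kind `"double_well_1d"`, `"mueller_like_2d"` or `"dihedral_chain"`.
#' @param ... parameters of the chosen potential; see the constructors
#'   [double_well_1d()], [mueller_like_2d()], [dihedral_chain()].
#' @return an object of class `swi_potential` with elements `U(x)`,
#'   `grad(x)`, `dim`, `domain` (per-dimension range), `periodic`, `params`.
#' @export
potential_spec <- function(kind, ...) {
  switch(kind,
         double_well_1d = double_well_1d(...),
         mueller_like_2d = mueller_like_2d(...),
         dihedral_chain = dihedral_chain(...),
         .stopf("potential_spec: unknown kind '%s'", kind))
}

#' @export
print.swi_potential <- function(x, ...) {
  cat(sprintf("Potential '%s' (%d dof)\n", x$kind, x$dim))
  invisible(x)
}

#' One-dimensional tilted double well
#'
#' U(x) = barrier * ((x/x0)^2 - 1)^2 + (tilt/2) * (x/x0): two wells near
#' x = -x0 (lower) and x = +x0, an energy barrier of about `barrier`
#' kcal/mol at x = 0, and an energy offset of about `tilt` kcal/mol between
#' the wells. Exact well positions/depths and the Boltzmann-weighted basin
#' free energies come from [double_well_reference()].
#'
#' @param barrier barrier height parameter, kcal/mol.
#' @param tilt well asymmetry parameter, kcal/mol.
#' @param x0 half-separation of the wells (CV units).
#' @return a `swi_potential`.
#' @export
double_well_1d <- function(barrier = 4.0, tilt = 2.0, x0 = 1.0) {
  B <- barrier; tl <- tilt
  structure(list(
    kind = "double_well_1d", dim = 1L,
    params = list(barrier = barrier, tilt = tilt, x0 = x0),
    domain = list(c(-2.2 * x0, 2.2 * x0)), periodic = FALSE,
    U = function(x) B * ((x / x0)^2 - 1)^2 + (tl / 2) * (x / x0),
    grad = function(x) 4 * B * (x / x0) * ((x / x0)^2 - 1) / x0 +
      tl / (2 * x0)
  ), class = "swi_potential")
}

#' Exact reference values for the 1-D double well
#'
#' Basin free-energy difference at temperature kT by numerical quadrature
#' of the Boltzmann weight on either side of the dividing barrier, plus the
#' exact minima/saddle from direct optimisation. Independent of any
#' sampling: this is the oracle the metadynamics estimates are tested
#' against.
#'
#' @param pot a [double_well_1d()] potential.
#' @param kT thermal energy, kcal/mol.
#' @return list with `delta_g` (right minus left basin, kcal/mol),
#'   `barrier_left` (saddle minus left minimum), `x_min` (both minima),
#'   `x_saddle`.
#' @export
double_well_reference <- function(pot, kT = 0.5962) {
  stopifnot(inherits(pot, "swi_potential"), pot$kind == "double_well_1d")
  dom <- pot$domain[[1]]
  left <- optimize(pot$U, c(dom[1], 0))
  right <- optimize(pot$U, c(0, dom[2]))
  x0 <- pot$params$x0
  saddle <- optimize(pot$U, c(-0.7 * x0, 0.7 * x0), maximum = TRUE)
  zl <- stats::integrate(function(x) exp(-pot$U(x) / kT), dom[1],
                         saddle$maximum, rel.tol = 1e-10)$value
  zr <- stats::integrate(function(x) exp(-pot$U(x) / kT), saddle$maximum,
                         dom[2], rel.tol = 1e-10)$value
  list(delta_g = -kT * log(zr) + kT * log(zl),
       barrier_left = saddle$objective - left$objective,
       x_min = c(left$minimum, right$minimum),
       x_saddle = saddle$maximum,
       u_min = c(left$objective, right$objective))
}

#' Double well with prescribed basin free-energy difference and barrier
#'
#' Solves for the `barrier`/`tilt` parameters of [double_well_1d()] such
#' that the quadrature oracle of [double_well_reference()] reports exactly
#' the requested basin free-energy difference and energy barrier (saddle
#' minus the lower minimum) at temperature kT. Alternating 1-D root finds;
#' converges to ~1e-6 kcal/mol in a few sweeps.
#'
#' @param delta_g target basin free-energy difference, kcal/mol.
#' @param barrier target barrier from the lower basin, kcal/mol.
#' @param kT thermal energy, kcal/mol.
#' @return a `swi_potential` (with the realised oracle in `$reference`).
#' @export
double_well_calibrated <- function(delta_g = 2.0, barrier = 4.0,
                                   kT = 0.5962) {
  B <- barrier; tl <- delta_g
  for (sweep in 1:6) {
    tl <- stats::uniroot(function(t)
      double_well_reference(double_well_1d(B, t), kT)$delta_g - delta_g,
      c(0, 2 * delta_g + 1), tol = 1e-9)$root
    B <- stats::uniroot(function(b)
      double_well_reference(double_well_1d(b, tl), kT)$barrier_left - barrier,
      c(max(0.2, barrier - delta_g - 1), barrier + 1), tol = 1e-9)$root
  }
  pot <- double_well_1d(B, tl)
  pot$reference <- double_well_reference(pot, kT)
  pot
}

#' Mueller-Brown-style 2-D surface (rescaled)
#'
#' The classic three-basin benchmark surface, scaled so well depths are a
#' few kcal/mol.
#'
#' @param scale multiplier applied to the canonical parameters.
#' @return a `swi_potential` with `dim = 2`.
#' @export
mueller_like_2d <- function(scale = 0.05) {
  A <- scale * c(-200, -100, -170, 15)
  a <- c(-1, -1, -6.5, 0.7); b <- c(0, 0, 11, 0.6)
  cc <- c(-10, -10, -6.5, 0.7)
  px <- c(1, 0, -0.5, -1); py <- c(0, 0.5, 1.5, 1)
  U <- function(x) {
    dx <- x[1] - px; dy <- x[2] - py
    sum(A * exp(a * dx^2 + b * dx * dy + cc * dy^2))
  }
  grad <- function(x) {
    dx <- x[1] - px; dy <- x[2] - py
    e <- A * exp(a * dx^2 + b * dx * dy + cc * dy^2)
    c(sum(e * (2 * a * dx + b * dy)), sum(e * (b * dx + 2 * cc * dy)))
  }
  structure(list(kind = "mueller_like_2d", dim = 2L,
                 params = list(scale = scale),
                 domain = list(c(-1.8, 1.2), c(-0.5, 2.2)), periodic = FALSE,
                 U = U, grad = grad),
            class = "swi_potential")
}

#' Chain of independent dihedral double wells
#'
#' Each of `n_angles` angular degrees of freedom feels
#' U_j = (barrier/2) (1 - cos 2(theta - center)) +
#' (tilt/2) (1 - cos(theta - center)): wells at `center` and `center + pi`,
#' the second raised by about `tilt`. With a dihedral-similarity CV this
#' gives an end-to-end angular analogue of the loop problem.
#'
#' @param n_angles number of angles.
#' @param barrier per-angle barrier, kcal/mol.
#' @param tilt per-angle well offset, kcal/mol.
#' @param center reference well position, radians.
#' @return a periodic `swi_potential` with `dim = n_angles`.
#' @export
dihedral_chain <- function(n_angles = 4L, barrier = 3.0, tilt = 1.0,
                           center = 0) {
  B <- barrier; tl <- tilt; c0 <- center
  structure(list(
    kind = "dihedral_chain", dim = as.integer(n_angles),
    params = list(n_angles = n_angles, barrier = barrier, tilt = tilt,
                  center = center),
    domain = rep(list(c(-pi, pi)), n_angles), periodic = TRUE,
    U = function(x) sum((B / 2) * (1 - cos(2 * (x - c0))) +
                          (tl / 2) * (1 - cos(x - c0))),
    grad = function(x) B * sin(2 * (x - c0)) + (tl / 2) * sin(x - c0)
  ), class = "swi_potential")
}

## collective variables over potential states --------------------------------

#' Coordinate collective variable
#'
#' Picks out one Cartesian component of the sampler state (the identity CV
#' for the analytic landscapes).
#'
#' @param i component index.
#' @param range CV range used for bias grids.
#' @param periodic is the component an angle on (-pi, pi]?
#' @return an object of class `swi_cv` with `value(x)` and `grad(x)`.
#' @export
cv_coordinate <- function(i = 1L, range = c(-2.2, 2.2), periodic = FALSE) {
  force(i)
  structure(list(name = sprintf("x%d", i), value = function(x) x[i],
                 grad = function(x) { g <- numeric(length(x)); g[i] <- 1; g },
                 range = range, periodic = periodic),
            class = "swi_cv")
}

#' Dihedral-similarity collective variable over a chain of angles
#'
#' S(theta) = sum_j (1 + cos(theta_j - ref_j)) / 2, in [0, n_angles];
#' the half-cosine similarity against a fixed reference conformation,
#' differentiable everywhere.
#'
#' @param ref reference angles, radians.
#' @param name CV label.
#' @return an `swi_cv` with range [0, length(ref)].
#' @export
cv_dihedral_similarity <- function(ref, name = "S") {
  force(ref)
  structure(list(
    name = name,
    value = function(x) sum((1 + cos(x - ref)) / 2),
    grad = function(x) -sin(x - ref) / 2,
    range = c(0, length(ref)), periodic = FALSE),
    class = "swi_cv")
}
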