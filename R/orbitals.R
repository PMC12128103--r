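#' Gaussian primitive
#'
#' A normalized atom-centered s or p Cartesian Gaussian primitive. The
#' normalization constant is folded into the evaluation, so `coef` weights a
#' unit-norm primitive.
#'
#' @param center numeric length-3 (bohr).
#' @param alpha exponent (bohr^-2), > 0.
#' @param type one of "s", "px", "py", "pz".
#' @param coef contraction coefficient.
#' @export
gaussian_primitive <- function(center, alpha, type = "s", coef = 1) {
  type <- match.arg(type, c("s", "px", "py", "pz"))
  stopifnot(alpha > 0)
  list(center = as.numeric(center), alpha = alpha, type = type,
       coef = as.numeric(coef))
}

prim_norm <- function(alpha, type) {
  if (type == "s") (2 * alpha / pi)^0.75
  else 2 * sqrt(alpha) * (2 * alpha / pi)^0.75
}

prim_axis <- function(type) match(type, c("px", "py", "pz"))

# value of a normalized primitive at points X (n x 3)
prim_value <- function(p, X) {
  d <- sweep(X, 2, p$center)
  r2 <- rowSums(d * d)
  v <- prim_norm(p$alpha, p$type) * exp(-p$alpha * r2)
  ax <- prim_axis(p$type)
  if (!is.na(ax)) v <- v * d[, ax]
  v
}

# analytic gradient (n x 3) of a normalized primitive at points X
prim_gradient <- function(p, X) {
  d <- sweep(X, 2, p$center)
  r2 <- rowSums(d * d)
  e <- prim_norm(p$alpha, p$type) * exp(-p$alpha * r2)
  ax <- prim_axis(p$type)
  val <- if (is.na(ax)) e else e * d[, ax]
  g <- -2 * p$alpha * d * val
  if (!is.na(ax)) g[, ax] <- g[, ax] + e
  g
}

# analytic overlap of two normalized s/p primitives (Obara-Saika closed forms)
prim_overlap <- function(a, b) {
  p <- a$alpha + b$alpha
  mu <- a$alpha * b$alpha / p
  AB <- a$center - b$center
  s00 <- (pi / p)^1.5 * exp(-mu * sum(AB * AB))
  P <- (a$alpha * a$center + b$alpha * b$center) / p
  PA <- P - a$center
  PB <- P - b$center
  ia <- prim_axis(a$type)
  ib <- prim_axis(b$type)
  ang <- if (is.na(ia) && is.na(ib)) 1
  else if (is.na(ib)) PA[ia]
  else if (is.na(ia)) PB[ib]
  else PA[ia] * PB[ib] + (ia == ib) / (2 * p)
  prim_norm(a$alpha, a$type) * prim_norm(b$alpha, b$type) * s00 * ang
}

#' Molecular orbital as a contraction of Gaussian primitives
#' @param primitives list of [gaussian_primitive()] objects.
#' @param label optional name.
#' @export
orbital <- function(primitives, label = "") {
  stopifnot(length(primitives) >= 1L)
  structure(list(primitives = primitives, label = label), class = "orbital")
}

#' Analytic overlap integral of two orbitals
#' @param o1,o2 `orbital` objects.
#' @export
orbital_overlap <- function(o1, o2) {
  s <- 0
  for (a in o1$primitives)
    for (b in o2$primitives)
      s <- s + a$coef * b$coef * prim_overlap(a, b)
  s
}

scale_orbital <- function(o, f) {
  o$primitives <- lapply(o$primitives, function(p) { p$coef <- p$coef * f; p })
  o
}

add_orbitals <- function(o1, o2) {
  orbital(c(o1$primitives, o2$primitives), label = o1$label)
}

#' Normalize an orbital to unit self-overlap
#' @param o an `orbital`.
#' @export
normalize_orbital <- function(o) scale_orbital(o, 1 / sqrt(orbital_overlap(o, o)))

#' Gram-Schmidt orthonormalization of a list of orbitals
#'
#' Sequential projection with analytic overlaps, so the resulting set is
#' exactly orthonormal and the model density integrates to the occupation sum.
#'
#' @param orbitals list of `orbital` objects (linearly independent).
#' @export
orthonormalize_orbitals <- function(orbitals) {
  out <- list()
  for (o in orbitals) {
    for (q in out)
      o <- add_orbitals(o, scale_orbital(q, -orbital_overlap(q, o)))
    nrm <- orbital_overlap(o, o)
    if (nrm < 1e-12) stop("orbitals are linearly dependent")
    out <- c(out, list(scale_orbital(o, 1 / sqrt(nrm))))
  }
  out
}

#' Orbital model: occupied orbitals with occupations
#'
#' @param orbitals list of `orbital` objects (expected orthonormal; use
#'   [orthonormalize_orbitals()]).
#' @param occupations numeric vector, one per orbital, each in (0, 2].
#' @export
orbital_model <- function(orbitals, occupations) {
  stopifnot(length(orbitals) == length(occupations),
            length(orbitals) >= 1L)
  if (any(occupations <= 0 | occupations > 2))
    stop("occupations must lie in (0, 2]")
  structure(list(orbitals = orbitals, occupations = as.numeric(occupations)),
            class = "orbital_model")
}

#' Evaluate model density, gradient and orbital kinetic term on a grid
#'
#' Computes `rho = sum_i occ_i psi_i^2`, its analytic gradient
#' `sum_i 2 occ_i psi_i grad(psi_i)`, and the occupied-orbital
#' gradient-square sum `sum_i occ_i |grad(psi_i)|^2` needed by the
#' positive-definite Pauli kinetic energy density.
#'
#' @param mol `molecule_spec`; its electron count must equal the occupation
#'   sum.
#' @param orbitals an `orbital_model`.
#' @param grid a `uniform_grid`.
#' @return list with `density` (scalar field, e/bohr^3), `gradient`
#'   (vector field) and `orbital_gradient_sum` (scalar field).
#' @export
evaluate_model_fields <- function(mol, orbitals, grid) {
  if (length(orbitals$orbitals) == 0L) stop("empty orbital set")
  if (abs(sum(orbitals$occupations) - mol$n_electrons) > 1e-8)
    stop(sprintf("occupation sum %.4f does not match N0 = %d",
                 sum(orbitals$occupations), mol$n_electrons))
  X <- grid_points(grid)
  n <- nrow(X)
  rho <- numeric(n)
  grad <- matrix(0, n, 3L)
  tau <- numeric(n)
  for (m in seq_along(orbitals$orbitals)) {
    o <- orbitals$orbitals[[m]]
    occ <- orbitals$occupations[m]
    psi <- numeric(n)
    gpsi <- matrix(0, n, 3L)
    for (p in o$primitives) {
      psi <- psi + p$coef * prim_value(p, X)
      gpsi <- gpsi + p$coef * prim_gradient(p, X)
    }
    rho <- rho + occ * psi * psi
    grad <- grad + 2 * occ * psi * gpsi
    tau <- tau + occ * rowSums(gpsi * gpsi)
  }
  list(density = scalar_field(grid, rho, "rho", "e/bohr^3"),
       gradient = vector_field(grid, grad, "grad_rho"),
       orbital_gradient_sum = scalar_field(grid, tau,
                                           "orbital_gradient_sum",
                                           "e/bohr^5"))
}
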