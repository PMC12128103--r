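#' Uniform volumetric grid
#'
#' A regular grid of points `origin + i*axes[1,] + j*axes[2,] + k*axes[3,]`
#' with `i`, `j`, `k` zero-based. Positions are always in bohr internally.
#'
#' @param origin numeric length-3, grid origin (bohr).
#' @param axes 3x3 numeric matrix; row `m` is the step vector of axis `m`
#'   (bohr per index increment).
#' @param shape integer length-3, number of points along each axis (>= 2).
#' @return an object of class `uniform_grid` with elements `origin`, `axes`,
#'   `shape`, `orthogonal` (logical flag, metadata only; non-orthogonal axes
#'   are accepted but flagged).
#' @export
uniform_grid <- function(origin, axes, shape) {
  origin <- as.numeric(origin)
  axes <- matrix(as.numeric(axes), 3L, 3L)
  shape <- as.integer(shape)
  stopifnot(length(origin) == 3L, length(shape) == 3L)
  if (any(shape < 2L)) stop("grid shape must be >= 2 on every axis")
  if (abs(det(axes)) <= 0) stop("grid cell volume |det(axes)| must be > 0")
  ortho <- all(abs(axes %*% t(axes) - diag(rowSums(axes^2))) < 1e-10)
  structure(
    list(origin = origin, axes = axes, shape = shape, orthogonal = ortho),
    class = "uniform_grid"
  )
}

#' @export
print.uniform_grid <- function(x, ...) {
  cat(sprintf("uniform grid: %d x %d x %d points (%d voxels)\n",
              x$shape[1], x$shape[2], x$shape[3], prod(x$shape)))
  cat(sprintf("  origin  [bohr]: % .4f % .4f % .4f\n",
              x$origin[1], x$origin[2], x$origin[3]))
  for (m in 1:3)
    cat(sprintf("  axis %d  [bohr]: % .4f % .4f % .4f\n",
                m, x$axes[m, 1], x$axes[m, 2], x$axes[m, 3]))
  if (!x$orthogonal) cat("  (non-orthogonal axes)\n")
  invisible(x)
}

#' Voxel volume of a grid (bohr^3)
#' @param grid a `uniform_grid`.
#' @export
voxel_volume <- function(grid) abs(det(grid$axes))

n_points <- function(grid) prod(grid$shape)

#' Cartesian coordinates of every grid point
#'
#' Points are returned in R array order: the first index varies fastest.
#'
#' @param grid a `uniform_grid`.
#' @return an `n x 3` matrix of positions (bohr).
#' @export
grid_points <- function(grid) {
  s <- grid$shape
  i <- rep.int(seq_len(s[1]) - 1L, s[2] * s[3])
  j <- rep.int(rep(seq_len(s[2]) - 1L, each = s[1]), s[3])
  k <- rep(seq_len(s[3]) - 1L, each = s[1] * s[2])
  cbind(i, j, k) %*% grid$axes +
    matrix(grid$origin, prod(s), 3L, byrow = TRUE)
}

#' Default grid around a molecule
#'
#' 0.2 bohr spacing with a 5 bohr margin beyond the molecular bounding box;
#' axes are Cartesian.
#'
#' @param mol a `molecule_spec`.
#' @param spacing grid step (bohr).
#' @param margin padding beyond the atomic bounding box (bohr).
#' @export
default_grid <- function(mol, spacing = 0.2, margin = 5) {
  pos <- atom_positions(mol)
  lo <- apply(pos, 2, min) - margin
  hi <- apply(pos, 2, max) + margin
  shape <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  uniform_grid(lo, diag(spacing, 3), shape)
}

#' Scalar field on a uniform grid
#'
#' @param grid a `uniform_grid`.
#' @param values numeric vector, one value per grid point in R array order
#'   (first index fastest).
#' @param quantity label for the stored quantity (e.g. "rho", "elf").
#' @param units unit string ("e/bohr^3" for densities, "" for dimensionless).
#' @export
scalar_field <- function(grid, values, quantity = "field", units = "") {
  values <- as.numeric(values)
  if (length(values) != n_points(grid))
    stop(sprintf("field has %d values but the grid has %d points",
                 length(values), n_points(grid)))
  if (!all(is.finite(values))) stop("scalar field values must be finite")
  structure(list(grid = grid, values = values, quantity = quantity,
                 units = units),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("scalar field '%s' [%s] on %d x %d x %d grid; range [%g, %g]\n",
              x$quantity, x$units,
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Vector field on a uniform grid
#'
#' @param grid a `uniform_grid`.
#' @param components `n x 3` numeric matrix of vector components per point.
#' @param quantity label.
#' @export
vector_field <- function(grid, components, quantity = "gradient") {
  components <- as.matrix(components)
  if (nrow(components) != n_points(grid) || ncol(components) != 3L)
    stop("vector field components must be n_points x 3")
  if (!all(is.finite(components))) stop("vector field must be finite")
  structure(list(grid = grid, components = components, quantity = quantity),
            class = "vector_field")
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin)) &&
    isTRUE(all.equal(a$axes, b$axes)) && all(a$shape == b$shape)
}

stop_grid_mismatch <- function(...) {
  gs <- list(...)
  for (g in gs[-1]) if (!same_grid(gs[[1]], g)) stop("fields are on different grids")
  invisible(TRUE)
}

#' Integrate a scalar field over its grid
#'
#' Midpoint Riemann sum: `sum(values) * |det(axes)|`. An optional logical
#' mask restricts the domain.
#'
#' @param field a `scalar_field`.
#' @param mask optional logical vector (one entry per voxel); `TRUE` voxels
#'   are included.
#' @return the integral (units of the field times bohr^3).
#' @export
integrate_field <- function(field, mask = NULL) {
  v <- field$values
  if (!is.null(mask)) {
    stopifnot(length(mask) == length(v))
    v <- v[mask]
  }
  sum(v) * voxel_volume(field$grid)
}

#' Reshape field values to a 3-D array
#' @param field a `scalar_field`.
#' @export
field_array <- function(field) array(field$values, dim = field$grid$shape)

#' Numerical gradient of a scalar field (central differences)
#'
#' Second-order central differences in the interior, one-sided at the grid
#' faces. Requires orthogonal axes (the step along each axis is its length).
#'
#' @param field a `scalar_field`.
#' @return a `vector_field` of the gradient.
#' @export
field_gradient <- function(field) {
  g <- field$grid
  if (!g$orthogonal)
    stop("numerical gradients require orthogonal grid axes")
  a <- field_array(field)
  h <- sqrt(rowSums(g$axes^2))
  out <- matrix(0, n_points(g), 3L)
  for (m in 1:3) {
    d <- diff_axis(a, m, h[m])
    # rotate the axis-m derivative into Cartesian components
    dir <- g$axes[m, ] / h[m]
    out <- out + as.vector(d) %o% dir
  }
  vector_field(g, out, quantity = paste0("grad_", field$quantity))
}

# central difference along axis m of 3-D array a with spacing h
diff_axis <- function(a, m, h) {
  n <- dim(a)[m]
  idx_up <- c(2:n, n)
  idx_dn <- c(1L, 1:(n - 1L))
  up <- slice_index(a, m, idx_up)
  dn <- slice_index(a, m, idx_dn)
  span <- array(2 * h, dim = dim(a))
  edge <- slice_assign_span(dim(a), m, h)
  (up - dn) / (span - edge)
}

slice_index <- function(a, m, idx) {
  args <- rep(list(quote(expr = )), 3L)
  args[[m]] <- idx
  do.call(`[`, c(list(a), args, list(drop = FALSE)))
}

# array that is h at the two faces of axis m (one-sided steps), 0 elsewhere
slice_assign_span <- function(dm, m, h) {
  v <- numeric(dm[m])
  v[c(1L, dm[m])] <- h
  perm <- order(c(m, setdiff(1:3, m)))
  aperm(array(v, dim = c(dm[m], dm[-m])), perm)
}
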