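#' Read a Gaussian cube file
#'
#' Parses the standard cube dialect: two comment lines; a record with the
#' atom count and the grid origin; three axis records (points per axis and
#' step vector); one record per atom (Z, nuclear charge, x, y, z); then the
#' scalar values with the innermost (third) index varying fastest. All
#' lengths are bohr (positive axis counts). Non-orthogonal axes are accepted
#' and flagged on the grid.
#'
#' @param path file path.
#' @return list with `molecule` (a [molecule_spec()]) and `field`
#'   (a [scalar_field()]).
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7L) stop("malformed cube file: truncated header")
  toks <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  hd <- toks(lines[3])
  if (length(hd) < 4L || !is.finite(hd[1]))
    stop("malformed cube header: atom/origin record")
  natoms <- as.integer(hd[1])
  orbital_file <- natoms < 0L
  natoms <- abs(natoms)
  if (natoms < 1L) stop("cube file declares no atoms")
  origin <- hd[2:4]
  shape <- integer(3)
  axes <- matrix(0, 3, 3)
  for (m in 1:3) {
    r <- toks(lines[3 + m])
    if (length(r) < 4L) stop("malformed cube header: axis record ", m)
    if (r[1] < 0) stop("cube axis counts in angstrom are not supported")
    shape[m] <- as.integer(r[1])
    axes[m, ] <- r[2:4]
  }
  atoms <- vector("list", natoms)
  for (a in seq_len(natoms)) {
    r <- toks(lines[6 + a])
    if (length(r) < 5L) stop("malformed cube header: atom record ", a)
    atoms[[a]] <- atom_site(z = as.integer(r[1]), position = r[3:5])
  }
  first_val <- 7L + natoms
  if (orbital_file) first_val <- first_val + 1L  # orbital-id record
  raw <- unlist(strsplit(trimws(lines[first_val:length(lines)]), "\\s+"),
                use.names = FALSE)
  vals <- as.numeric(raw[nzchar(raw)])
  if (anyNA(vals)) stop("malformed cube value block")
  nv <- prod(shape)
  if (length(vals) != nv)
    stop(sprintf("cube value count %d does not match grid size %d",
                 length(vals), nv))
  grid <- uniform_grid(origin, axes, shape)
  # cube order: third index fastest -> permute into R order (first fastest)
  arr <- aperm(array(vals, dim = rev(shape)), c(3, 2, 1))
  list(molecule = molecule_spec(atoms),
       field = scalar_field(grid, as.vector(arr), quantity = "cube",
                            units = "e/bohr^3"))
}

#' Write a Gaussian cube file
#'
#' Writes the dialect read by [read_cube()]; the pair round-trips grids,
#' atoms and values to the written precision (%.6E values, %.6f geometry).
#'
#' @param mol a [molecule_spec()].
#' @param field a [scalar_field()].
#' @param path output path.
#' @param comment first comment line.
#' @export
write_cube <- function(mol, field, path,
                       comment = "cube file written by eplbarriers") {
  g <- field$grid
  if (length(mol$atoms) < 1L) stop("cube files require at least one atom")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(comment, field$quantity), con)
  fmt <- function(n, v) sprintf("%5d %11.6f %11.6f %11.6f", n, v[1], v[2], v[3])
  writeLines(fmt(length(mol$atoms), g$origin), con)
  for (m in 1:3) writeLines(fmt(g$shape[m], g$axes[m, ]), con)
  for (a in mol$atoms)
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f",
                       a$z, as.numeric(a$z),
                       a$position[1], a$position[2], a$position[3]), con)
  arr <- aperm(field_array(field), c(3, 2, 1))  # third index fastest
  vals <- sprintf("% .6E", as.vector(arr))
  n <- length(vals)
  idx <- split(seq_len(n), (seq_len(n) - 1L) %/% 6L)
  writeLines(vapply(idx, function(i) paste(vals[i], collapse = " "),
                    character(1)), con)
  invisible(path)
}
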