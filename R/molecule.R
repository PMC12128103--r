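# element <-> atomic number bookkeeping for the light elements the toy
# models and cube files use
.elements <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
               "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar")

element_symbol <- function(z) {
  if (any(z < 1L | z > length(.elements)))
    stop("atomic number outside the supported range (1..18)")
  .elements[z]
}

atomic_number <- function(symbol) {
  z <- match(symbol, .elements)
  if (any(is.na(z))) stop("unknown element symbol: ",
                          paste(symbol[is.na(z)], collapse = ", "))
  z
}

#' Atom site
#'
#' @param element element symbol (or omit and give `z`).
#' @param position numeric length-3 position (bohr).
#' @param z atomic number; derived from `element` if missing.
#' @export
atom_site <- function(element = NULL, position, z = NULL) {
  if (is.null(z)) z <- atomic_number(element)
  if (is.null(element)) element <- element_symbol(z)
  z <- as.integer(z)
  if (z < 1L) stop("atomic number must be >= 1")
  if (atomic_number(element) != z)
    stop("element symbol and atomic number disagree")
  structure(list(element = element, z = z,
                 position = as.numeric(position)),
            class = "atom_site")
}

#' Molecule specification
#'
#' Atoms, net charge and the derived electron count `N0 = sum(Z) - charge`.
#'
#' @param atoms list of [atom_site()] objects.
#' @param charge integer net charge.
#' @export
molecule_spec <- function(atoms, charge = 0L) {
  stopifnot(length(atoms) >= 1L)
  n0 <- sum(vapply(atoms, function(a) a$z, integer(1))) - charge
  if (n0 < 1L) stop("electron count N0 must be >= 1")
  structure(list(atoms = atoms, charge = as.integer(charge),
                 n_electrons = as.integer(n0)),
            class = "molecule_spec")
}

#' @export
print.molecule_spec <- function(x, ...) {
  cat(sprintf("molecule: %d atoms, charge %+d, N0 = %d electrons\n",
              length(x$atoms), x$charge, x$n_electrons))
  for (a in x$atoms)
    cat(sprintf("  %-2s (Z=%2d)  % .4f % .4f % .4f\n", a$element, a$z,
                a$position[1], a$position[2], a$position[3]))
  invisible(x)
}

#' Atom positions as a matrix
#' @param mol a `molecule_spec`.
#' @return `n_atoms x 3` matrix (bohr).
#' @export
atom_positions <- function(mol) {
  t(vapply(mol$atoms, function(a) a$position, numeric(3)))
}
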