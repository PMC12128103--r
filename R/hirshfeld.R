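# single-exponential free-atom radial models, rho_Z(r) = Z zeta^3/(8 pi)
# exp(-zeta r), normalized to Z electrons. The zeta values are crude
# valence-decay constants (2 Zeff/n from Slater screening); the Hirshfeld
# weights depend only on density ratios, for which this level of detail is
# adequate.
.free_atom_zeta <- c(2.00, 3.38, 1.30, 1.95, 2.60, 3.25, 3.90, 4.55,
                     5.20, 5.85, 1.47, 1.90, 2.33, 2.77, 3.20, 3.63,
                     4.07, 4.50)

#' Free-atom density model
#'
#' @param z atomic number (1..18).
#' @return a function of radial distance r (bohr) returning the density
#'   (e/bohr^3); attribute `z` records the element.
#' @export
free_atom_density <- function(z) {
  if (z < 1L || z > length(.free_atom_zeta))
    stop("no free-atom model for Z = ", z)
  zeta <- .free_atom_zeta[z]
  f <- function(r) z * zeta^3 / (8 * pi) * exp(-zeta * r)
  attr(f, "z") <- z
  f
}

# n_points x n_atoms matrix of free-atom densities on a grid
promolecule_components <- function(mol, grid, free_atoms = NULL) {
  X <- grid_points(grid)
  sapply(seq_along(mol$atoms), function(a) {
    fa <- if (is.null(free_atoms)) free_atom_density(mol$atoms[[a]]$z)
          else free_atoms[[a]]
    d <- sweep(X, 2, mol$atoms[[a]]$position)
    fa(sqrt(rowSums(d * d)))
  })
}

#' Hirshfeld stockholder weight fields
#'
#' `w_A(r) = rho_A^free(r) / sum_B rho_B^free(r)`; the weights sum to one at
#' every point, so the condensed populations always close to the total
#' density integral.
#'
#' @param mol `molecule_spec`.
#' @param grid `uniform_grid`.
#' @param free_atoms optional list of [free_atom_density()] models (one per
#'   atom) overriding the packaged ones.
#' @return `n_points x n_atoms` matrix of weights.
#' @export
hirshfeld_weights <- function(mol, grid, free_atoms = NULL) {
  comp <- promolecule_components(mol, grid, free_atoms)
  tot <- rowSums(comp)
  if (any(tot <= 0)) stop("promolecule density vanishes on the grid")
  comp / tot
}

#' Hirshfeld atomic populations for one charge state
#'
#' `N^A = integral of w_A(r) rho(r)` over the grid.
#'
#' @param mol `molecule_spec` (fixed geometry for all states).
#' @param state_density `scalar_field` of the state's density (>= 0).
#' @param free_atoms optional per-atom free-atom models.
#' @param state label for the charge state ("N0", "N0-1", "N0+1").
#' @return object of class `atomic_populations`: numeric vector of per-atom
#'   populations with attributes `state` and `total`.
#' @export
hirshfeld_populations <- function(mol, state_density, free_atoms = NULL,
                                  state = "N0") {
  if (any(state_density$values < 0)) stop("state density must be >= 0")
  w <- hirshfeld_weights(mol, state_density$grid, free_atoms)
  pops <- colSums(w * state_density$values) * voxel_volume(state_density$grid)
  structure(pops, state = state, total = sum(pops),
            class = "atomic_populations")
}

#' Condensed Fukui functions from three vertical charge states
#'
#' `f+_A = N^A(N0+1) - N^A(N0)` (response to nucleophilic attack),
#' `f-_A = N^A(N0) - N^A(N0-1)` (electrophilic attack) and
#' `f0_A = (f+_A + f-_A) / 2` (radical attack). The three populations must
#' come from densities at one fixed geometry (vertical finite differences).
#' Negative condensed values are retained, not clipped. Note the radical
#' index is the standard half-sum of `f+` and `f-`, i.e. the half-difference
#' of the anion and cation populations.
#'
#' @param neutral,cation,anion `atomic_populations` for N0, N0-1, N0+1.
#' @return object of class `condensed_fukui`: data.frame with columns
#'   `f_plus`, `f_minus`, `f_zero` (one row per atom).
#' @export
condensed_fukui <- function(neutral, cation, anion) {
  n <- length(neutral)
  if (length(cation) != n || length(anion) != n)
    stop("charge states have inconsistent atom counts")
  f_plus <- as.numeric(anion) - as.numeric(neutral)
  f_minus <- as.numeric(neutral) - as.numeric(cation)
  out <- data.frame(f_plus = f_plus, f_minus = f_minus,
                    f_zero = (f_plus + f_minus) / 2)
  class(out) <- c("condensed_fukui", "data.frame")
  out
}

#' Fukui cache keyed by site and substitution state
#'
#' Optional refinement for screening many functionalized species: condensed
#' Fukui values of unsubstituted sites are frozen at the parent-sugar values
#' and only sites bearing a functional group are recomputed. Purely
#' bookkeeping: the cache stores and retrieves values, logging every reuse.
#'
#' @return an environment with `put(site, substitution, fukui_row)`,
#'   `get(site, substitution)` and `log()` methods.
#' @export
fukui_cache <- function() {
  store <- new.env(parent = emptyenv())
  events <- character()
  key <- function(site, substitution) paste(site, substitution, sep = "|")
  list(
    put = function(site, substitution = "parent", value) {
      assign(key(site, substitution), value, envir = store)
      invisible(value)
    },
    get = function(site, substitution = "parent") {
      k <- key(site, substitution)
      if (!exists(k, envir = store)) return(NULL)
      events <<- c(events, sprintf("reused %s", k))
      get(k, envir = store)
    },
    log = function() events
  )
}
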