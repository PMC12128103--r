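#' Packaged activation-enthalpy benchmark table
#'
#' The in-package barrier dataset: 30 elementary reactions of xylose,
#' 2-O-acetyl-xylose and 4-O-methyl-D-glucuronic acid, each at five levels
#' of theory (DFT = M06-2X/6-311++G(d,p), CBS = CBS-QB3, G4, DLPNO =
#' DLPNO-CCSD(T)-F12/cc-pVTZ-F12, and DLPNO/CBS) and two temperatures
#' (0 and 298 K). Barriers obtained under relaxed transition-state
#' convergence criteria are flagged; the one reaction whose transition
#' state could never be located (2-O-acetyl-xylose to FFL1) is stored as
#' explicit missing values, never zeros.
#'
#' @param long return the long format (one record per reaction x level x
#'   temperature, 300 rows) instead of the wide table (30 rows).
#' @return data.frame; long format has columns `reactant`, `product`,
#'   `leaving`, `class`, `level`, `temperature_K`, `dH`, `relaxed`.
#' @export
load_table1 <- function(long = TRUE) {
  path <- system.file("extdata", "table1.tsv", package = "eplbarriers",
                      mustWork = TRUE)
  wide <- utils::read.delim(path, stringsAsFactors = FALSE,
                            na.strings = "-", fill = TRUE)
  wide$relaxed[is.na(wide$relaxed)] <- ""
  if (!long) return(wide)
  levels_ <- c(dft = "DFT", cbs = "CBS", g4 = "G4", dlpno = "DLPNO",
               dlpnocbs = "DLPNO/CBS")
  temps <- c("0" = 0, "298" = 298)
  out <- do.call(rbind, lapply(seq_len(nrow(wide)), function(r) {
    flagged <- strsplit(wide$relaxed[r], ";", fixed = TRUE)[[1]]
    do.call(rbind, lapply(names(levels_), function(lv) {
      do.call(rbind, lapply(names(temps), function(tt) {
        col <- paste0(lv, "_", tt)
        data.frame(reactant = wide$reactant[r], product = wide$product[r],
                   leaving = wide$leaving[r], class = wide$class[r],
                   level = unname(levels_[lv]),
                   temperature_K = unname(temps[tt]),
                   dH = wide[[col]][r],
                   relaxed = col %in% flagged,
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Look up one packaged barrier
#'
#' @param reactant,product species and product labels as stored in the
#'   packaged table.
#' @param level `"DFT"`, `"CBS"`, `"G4"`, `"DLPNO"` or `"DLPNO/CBS"`.
#' @param temperature_K 0 or 298.
#' @return the activation enthalpy (kcal/mol), `NA` if missing; attribute
#'   `relaxed` carries the convergence flag.
#' @export
table1_barrier <- function(reactant, product, level = "DFT",
                           temperature_K = 298) {
  tb <- load_table1()
  hit <- tb$reactant == reactant & tb$product == product &
    tb$level == level & tb$temperature_K == temperature_K
  if (!any(hit)) stop("no such record: ", reactant, " -> ", product,
                      " [", level, ", ", temperature_K, " K]")
  structure(tb$dH[hit], relaxed = tb$relaxed[hit])
}

# electron bookkeeping: atomic numbers for composition vectors
.composition_electrons <- c(C = 6, H = 1, O = 8)

comp_electrons <- function(comp) {
  sum(.composition_electrons[names(comp)] * comp)
}

comp_add <- function(a, b) {
  els <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out
}

#' Build a functionalized xylopyranose species
#'
#' Bookkeeping-level species construction (composition, naming, electron
#' count; no 3D geometry): starts from beta-D-xylopyranose (C5H10O5, 80
#' electrons), applies substituent group arithmetic -- acetyl at position 2
#' or 3 (hydroxyl H replaced by the O-linked C2H3O group), methoxy at 4
#' (OH to OCH3) and carboxyl at 5 (ring-carbon H to COOH) -- and optionally
#' condenses with a partner species into a 1,4-linked dimer with loss of
#' one water.
#'
#' @param base base species name (only `"xylose"` is packaged).
#' @param substitutions named character vector mapping position to group,
#'   e.g. `c("2" = "acetyl", "4" = "methoxy")`.
#' @param dimer_partner optional second `species_spec` for 1,4 condensation.
#' @return object of class `species_spec`: `name`, `topology`
#'   (`"monomer"`/`"dimer"`), `substitutions`, `composition` (named counts)
#'   and `electron_count`.
#' @export
build_species <- function(base = "xylose", substitutions = NULL,
                          dimer_partner = NULL) {
  if (base != "xylose") stop("unknown base species: ", base)
  comp <- c(C = 5, H = 10, O = 5)
  name <- "xylose"
  if (!is.null(substitutions)) {
    pos <- names(substitutions)
    if (anyDuplicated(pos)) stop("duplicate substitution positions")
    for (p in sort(pos)) {
      g <- substitutions[[p]]
      delta <- switch(g,
        acetyl = { if (!p %in% c("2", "3"))
            stop("acetyl is legal at positions 2/3 only")
          c(C = 2, H = 2, O = 1) },
        methoxy = { if (p != "4") stop("methoxy is legal at position 4 only")
          c(C = 1, H = 2) },
        carboxyl = { if (p != "5") stop("carboxyl is legal at position 5 only")
          c(C = 1, O = 2) },
        stop("unknown group: ", g))
      comp <- comp_add(comp, delta)
      prefix <- switch(g, acetyl = paste0(p, "-O-acetyl"),
                       methoxy = paste0(p, "-methoxy"),
                       carboxyl = paste0(p, "-carboxyl"))
      name <- paste0(prefix, "-", name)
    }
  }
  topology <- "monomer"
  if (!is.null(dimer_partner)) {
    stopifnot(inherits(dimer_partner, "species_spec"))
    comp <- comp_add(comp_add(comp, dimer_partner$composition),
                     c(H = -2, O = -1))
    name <- paste0(name, ",1,4-", dimer_partner$name)
    topology <- "dimer"
  }
  structure(list(name = name, topology = topology,
                 substitutions = substitutions, composition = comp,
                 electron_count = comp_electrons(comp)),
            class = "species_spec")
}

#' @export
print.species_spec <- function(x, ...) {
  comp <- x$composition[x$composition != 0]
  cat(sprintf("species %s (%s): %s, %d electrons\n", x$name, x$topology,
              paste0(names(comp), comp, collapse = ""), x$electron_count))
  invisible(x)
}

# assemble one toy model entry: neutral/cation/anion variants at a fixed
# geometry, with exactly orthonormal orbitals so each state's density
# integrates analytically to its electron count
toy_entry <- function(atoms, charge, occupied, virtual) {
  orbs <- orthonormalize_orbitals(c(occupied, list(virtual)))
  n_occ <- length(occupied)
  occ_orbs <- orbs[seq_len(n_occ)]
  neutral <- list(mol = molecule_spec(atoms, charge),
                  orbitals = orbital_model(occ_orbs, rep(2, n_occ)))
  cation <- list(mol = molecule_spec(atoms, charge + 1L),
                 orbitals = orbital_model(occ_orbs,
                                          c(rep(2, n_occ - 1), 1)))
  anion <- list(mol = molecule_spec(atoms, charge - 1L),
                orbitals = orbital_model(orbs, c(rep(2, n_occ), 1)))
  list(neutral = neutral, cation = cation, anion = anion)
}

#' Analytic toy density models
#'
#' Four closed-shell Gaussian-orbital models standing in for quantum
#' chemistry wavefunctions in tests: a one-center two-electron atom, a
#' homonuclear two-center sigma bond, a polar two-center cation, and a
#' bent three-center ten-electron molecule. Each entry carries `neutral`,
#' `cation` (one electron removed from the highest orbital) and `anion`
#' (one electron added in an orthogonalized diffuse orbital) variants at a
#' fixed geometry, as the vertical finite-difference Fukui definitions
#' require. Orbitals are Gram-Schmidt orthonormalized with analytic
#' overlaps, so every state's density integrates exactly to its electron
#' count; exponents are kept soft enough for the default 0.2-bohr grid.
#'
#' @return named list of model entries; each variant is a list with `mol`
#'   (a [molecule_spec()]) and `orbitals` (an [orbital_model()]).
#' @export
toy_density_suite <- function() {
  s <- function(center, alpha, coef = 1)
    gaussian_primitive(center, alpha, "s", coef)
  p <- function(center, alpha, type, coef = 1)
    gaussian_primitive(center, alpha, type, coef)

  one_center <- toy_entry(
    atoms = list(atom_site("He", c(0, 0, 0))),
    charge = 0L,
    occupied = list(orbital(list(s(c(0, 0, 0), 1.5, 0.6),
                                 s(c(0, 0, 0), 4.5, 0.5)), "1s")),
    virtual = orbital(list(s(c(0, 0, 0), 0.35)), "2s"))

  a <- c(0, 0, -0.7); b <- c(0, 0, 0.7)
  homonuclear <- toy_entry(
    atoms = list(atom_site("H", a), atom_site("H", b)),
    charge = 0L,
    occupied = list(orbital(list(s(a, 0.5), s(b, 0.5)), "sigma")),
    virtual = orbital(list(s(a, 0.5), s(b, 0.5, -1)), "sigma*"))

  he <- c(0, 0, 0); h <- c(0, 0, 1.5)
  polar <- toy_entry(
    atoms = list(atom_site("He", he), atom_site("H", h)),
    charge = 1L,
    occupied = list(orbital(list(s(he, 1.8, 0.9), s(h, 0.6, 0.35)),
                            "sigma")),
    virtual = orbital(list(s(he, 0.4), s(h, 0.3, -0.8)), "sigma*"))

  o <- c(0, 0, 0)
  h1 <- c(0, 1.42, -1.10); h2 <- c(0, -1.42, -1.10)
  bent <- toy_entry(
    atoms = list(atom_site("O", o), atom_site("H", h1), atom_site("H", h2)),
    charge = 0L,
    occupied = list(
      orbital(list(s(o, 8.0)), "core"),
      orbital(list(s(o, 1.0)), "valence-s"),
      orbital(list(p(o, 1.2, "px")), "lone-pair"),
      orbital(list(p(o, 1.2, "pz", -0.8), s(h1, 0.6, 0.5),
                   s(h2, 0.6, 0.5)), "bond-sym"),
      orbital(list(p(o, 1.2, "py", 0.8), s(h1, 0.6, 0.5),
                   s(h2, 0.6, -0.5)), "bond-asym")),
    virtual = orbital(list(s(o, 0.25)), "diffuse"))

  list(one_center = one_center, homonuclear = homonuclear,
       polar = polar, bent = bent)
}

#' Synthetic EPL regression dataset
#'
#' Rows of aggregated descriptors drawn uniformly from stated ranges with
#' barriers generated from known affine coefficients plus Gaussian noise.
#' Used to validate the fitting pipeline by parameter recovery, since the
#' full descriptor set behind the published coefficients is not
#' distributable. Default ranges bracket plausible descriptor magnitudes
#' for the pyranose systems.
#'
#' @param true_coef named numeric `(f_bar, n_bar, g_bar, intercept)`, e.g.
#'   `coef(epl_model("DFT"))`.
#' @param n number of rows.
#' @param ranges list with elements `f_bar`, `n_bar`, `g_bar`, each
#'   `c(min, max)`.
#' @param sigma Gaussian noise standard deviation (kcal/mol), >= 0.
#' @param seed RNG seed (deterministic output).
#' @return data.frame with columns `f_bar`, `n_bar`, `g_bar`, `dH`.
#' @export
synthetic_regression_dataset <- function(true_coef, n = 200,
                                         ranges = list(f_bar = c(0.02, 0.12),
                                                       n_bar = c(0.8, 1.8),
                                                       g_bar = c(0.2, 1.2)),
                                         sigma = 1, seed = 1L) {
  if (sigma < 0) stop("noise sigma must be >= 0")
  for (r in ranges) if (r[1] > r[2]) stop("descriptor ranges must be ordered")
  with_seed(seed, {
    d <- data.frame(
      f_bar = stats::runif(n, ranges$f_bar[1], ranges$f_bar[2]),
      n_bar = stats::runif(n, ranges$n_bar[1], ranges$n_bar[2]),
      g_bar = stats::runif(n, ranges$g_bar[1], ranges$g_bar[2]))
    d$dH <- true_coef[["f_bar"]] * d$f_bar + true_coef[["n_bar"]] * d$n_bar +
      true_coef[["g_bar"]] * d$g_bar + true_coef[["intercept"]] +
      stats::rnorm(n, 0, sigma)
    d
  })
}
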