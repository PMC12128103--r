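# shared fixtures built in code: small analytic models and field bundles

# H2-like sigma-bond model at separation d (bohr); occ electrons in one MO
h2_model <- function(d = 1.4, alpha = 0.5) {
  a <- c(0, 0, -d / 2)
  b <- c(0, 0, d / 2)
  mol <- molecule_spec(list(atom_site("H", a), atom_site("H", b)))
  orb <- orbital_model(orthonormalize_orbitals(list(orbital(list(
    gaussian_primitive(a, alpha), gaussian_primitive(b, alpha))))), 2)
  list(mol = mol, orbitals = orb)
}

# evaluate density/gradient/kinetic bundle on the default grid
model_fields <- function(m, spacing = 0.2, margin = 5) {
  g <- default_grid(m$mol, spacing = spacing, margin = margin)
  evaluate_model_fields(m$mol, m$orbitals, g)
}

# ELF + basins + populations in one go
elf_basins <- function(m, spacing = 0.2, margin = 5) {
  f <- model_fields(m, spacing, margin)
  elf <- compute_elf(f$density, f$gradient, f$orbital_gradient_sum)
  part <- partition_basins(elf)
  list(fields = f, elf = elf, partition = part,
       report = basin_populations(part, f$density, m$mol))
}

# Hirshfeld populations of the three vertical states of a toy-suite entry
state_populations <- function(entry, spacing = 0.2, margin = 5) {
  g <- default_grid(entry$neutral$mol, spacing = spacing, margin = margin)
  pop <- function(v, st)
    hirshfeld_populations(v$mol,
                          evaluate_model_fields(v$mol, v$orbitals, g)$density,
                          state = st)
  list(neutral = pop(entry$neutral, "N0"),
       cation = pop(entry$cation, "N0-1"),
       anion = pop(entry$anion, "N0+1"))
}
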