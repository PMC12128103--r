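test_that("ELF closed forms: kinetic-energy ratios map to eta exactly", {
  g <- uniform_grid(c(0, 0, 0), diag(1, 3), c(2, 2, 2))
  rho <- rep(0.5, 8)
  tau_h <- 0.6 * (6 * pi^2)^(2 / 3) * rho^(5 / 3)
  zero_grad <- vector_field(g, matrix(0, 8, 3))
  # tau_P = tau_H  =>  eta = 0.5
  elf <- compute_elf(scalar_field(g, rho), zero_grad,
                     scalar_field(g, 2 * tau_h))
  expect_equal(elf$field$values, rep(0.5, 8))
  # tau_P = 3 tau_H  =>  eta = 1 / (1 + 9) = 0.1
  elf3 <- compute_elf(scalar_field(g, rho), zero_grad,
                      scalar_field(g, 6 * tau_h))
  expect_equal(elf3$field$values, rep(0.1, 8))
  # below the density floor eta is zeroed
  low <- compute_elf(scalar_field(g, rep(1e-9, 8)), zero_grad,
                     scalar_field(g, rep(0, 8)))
  expect_equal(low$field$values, rep(0, 8))
  # grids must match
  g2 <- uniform_grid(c(0, 0, 0), diag(1, 3), c(2, 2, 3))
  expect_error(compute_elf(scalar_field(g, rho), zero_grad,
                           scalar_field(g2, rep(1, 12))),
               "different grids")
})

test_that("a single doubly occupied orbital gives tau_P ~ 0 and eta = 1 everywhere live", {
  f <- model_fields(h2_model())
  elf <- compute_elf(f$density, f$gradient, f$orbital_gradient_sum)
  live <- f$density$values >= 1e-6
  expect_lt(max(abs(elf$tau_p$values[live])), 1e-8)
  expect_equal(min(elf$field$values[live]), 1)
  # bounds hold voxelwise on a genuinely multi-orbital model too
  suite <- toy_density_suite()
  fb <- model_fields(suite$bent$neutral, spacing = 0.25, margin = 4)
  eb <- compute_elf(fb$density, fb$gradient, fb$orbital_gradient_sum)
  expect_true(all(eb$field$values >= 0 & eb$field$values <= 1))
})

test_that("watershed partition: surrogate fields resolve the expected attractors", {
  g <- uniform_grid(c(-6, -3, -3), diag(0.3, 3), c(41, 21, 21))
  X <- grid_points(g)
  bump <- function(c0) exp(-rowSums(sweep(X, 2, c0)^2))
  # single Gaussian: one basin holding every assigned voxel
  f1 <- scalar_field(g, bump(c(0, 0, 0)))
  p1 <- partition_basins(f1, density = f1)
  expect_equal(nrow(p1$attractors), 1)
  expect_true(all(p1$labels[p1$labels > 0] == 1))
  # two identical well-separated maxima: two basins split at the midplane
  f2 <- scalar_field(g, bump(c(-3, 0, 0)) + bump(c(3, 0, 0)))
  p2 <- partition_basins(f2, density = f2, rho_min = 1e-10)
  expect_equal(nrow(p2$attractors), 2)
  pops <- vapply(1:2, function(l)
    sum(f2$values[p2$labels == l]), numeric(1))
  expect_lt(abs(pops[1] - pops[2]) / mean(pops), 0.01)
  # monotone ramp: single attractor at the maximal boundary voxel
  ramp <- scalar_field(g, X[, 1])
  pr <- partition_basins(ramp, density = scalar_field(g, rep(1, nrow(X))))
  expect_equal(nrow(pr$attractors), 1)
  expect_equal(pr$attractors$x, max(X[, 1]))
  # all-constant field has no maxima
  const <- scalar_field(g, rep(1, nrow(X)))
  expect_error(partition_basins(const, density = const), "constant")
})

test_that("basin populations close exactly and integrate N0 on fixture models", {
  m <- h2_model()
  eb <- elf_basins(m)
  rep_ <- eb$report
  # closure: populations + below-floor residue = integral of rho, exactly
  expect_equal(sum(rep_$population) + attr(rep_, "residue"),
               attr(rep_, "total_density"))
  expect_lt(abs(attr(rep_, "closure_gap")), 1e-12)
  # total density integral = N0 within 1e-2 electrons at 0.2 bohr
  expect_equal(attr(rep_, "total_density"), 2, tolerance = 5e-3)
  # the single sigma basin is disynaptic V(1,2) with population ~ 2.00
  expect_equal(nrow(rep_), 1)
  expect_equal(rep_$class, "disynaptic")
  expect_equal(rep_$atoms, "1,2")
  expect_equal(rep_$population, 2, tolerance = 1e-2)
})

test_that("symmetric homonuclear basins mirror and survive grid refinement", {
  # two-sigma model (bonding sigma + far-apart lone s orbitals) exercises a
  # multi-basin partition with mirror symmetry
  d <- 4.0
  a <- c(0, 0, -d / 2); b <- c(0, 0, d / 2)
  mol <- molecule_spec(list(atom_site("He", a), atom_site("He", b)))
  orbs <- orthonormalize_orbitals(list(
    orbital(list(gaussian_primitive(a, 1.2))),
    orbital(list(gaussian_primitive(b, 1.2)))))
  m <- list(mol = mol, orbitals = orbital_model(orbs, c(2, 2)))
  eb <- elf_basins(m, spacing = 0.2, margin = 4)
  rep1 <- eb$report
  expect_equal(nrow(rep1), 2)
  expect_lt(abs(rep1$population[1] - rep1$population[2]) /
              mean(rep1$population), 0.01)
  # refinement 0.2 -> 0.15 bohr: basin count stable, populations within 2%
  rep2 <- elf_basins(m, spacing = 0.15, margin = 4)$report
  expect_equal(nrow(rep2), 2)
  expect_equal(sort(rep2$population), sort(rep1$population),
               tolerance = 0.02)
})
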