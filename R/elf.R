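#' Electron localization function (ELF)
#'
#' `eta = 1 / (1 + (tau_P / tau_H)^2)` where `tau_P` is the positive-definite
#' Pauli kinetic energy density,
#' `tau_P = 1/2 sum_i occ_i |grad psi_i|^2 - 1/8 |grad rho|^2 / rho`,
#' and `tau_H = 3/5 (6 pi^2)^(2/3) rho^(5/3)` is the Thomas-Fermi reference.
#' Small negative `tau_P` from finite precision is clamped to zero (theory
#' guarantees `tau_P >= 0`), so `eta` is bounded in [0, 1] by construction.
#' Voxels below the density floor `rho_min` are set to `eta = 0`: there the
#' defining ratio degenerates to 0/0 and ELF carries no information.
#'
#' @param density `scalar_field` of rho (e/bohr^3), >= 0.
#' @param density_gradient `vector_field` of grad rho.
#' @param orbital_gradient_sum `scalar_field` of `sum_i occ_i |grad psi_i|^2`.
#' @param rho_min density floor (e/bohr^3).
#' @return object of class `elf_field`: a dimensionless `scalar_field` in
#'   `$field` plus references to the inputs.
#' @export
compute_elf <- function(density, density_gradient, orbital_gradient_sum,
                        rho_min = 1e-6) {
  stop_grid_mismatch(density$grid, density_gradient$grid,
                     orbital_gradient_sum$grid)
  rho <- density$values
  if (any(rho < 0)) stop("density must be nonnegative")
  live <- rho >= rho_min
  g2 <- rowSums(density_gradient$components^2)
  tau_p <- numeric(length(rho))
  tau_p[live] <- 0.5 * orbital_gradient_sum$values[live] -
    0.125 * g2[live] / rho[live]
  tau_p <- pmax(tau_p, 0)
  tau_h <- 0.6 * (6 * pi^2)^(2 / 3) * rho^(5 / 3)
  eta <- numeric(length(rho))
  eta[live] <- 1 / (1 + (tau_p[live] / tau_h[live])^2)
  structure(
    list(field = scalar_field(density$grid, eta, "elf", ""),
         tau_p = scalar_field(density$grid, tau_p, "tau_P", "hartree/bohr^3"),
         density = density, rho_min = rho_min),
    class = "elf_field")
}

# flat index <-> (i,j,k) helpers operate implicitly through array reshaping

# for each voxel, flat index of its steepest-ascent neighbor (26-connectivity)
# or its own index if no neighbor is higher. Comparison is lexicographic on
# (primary, secondary): exact primary ties (ELF plateaus, e.g. the constant
# eta of a one-orbital model) fall back to the secondary field (density);
# full ties go to the lowest flat index, so partitions are deterministic.
ascent_pointers <- function(arr, active, sec = NULL) {
  dm <- dim(arr)
  n <- length(arr)
  if (is.null(sec)) sec <- array(0, dim = dm)
  flat <- array(seq_len(n), dim = dm)
  best_val <- arr
  best_sec <- sec
  best_idx <- flat
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0 & offs$dk == 0), ]
  # visit neighbors in increasing flat-offset order => lowest-index tie-break
  ord <- order(offs$dk, offs$dj, offs$di)
  pad <- function(a, d) {
    # shift array by offset d, padding with -Inf (values) or 0 (indices)
    i1 <- pmax(1L, 1L - d[1]):pmin(dm[1], dm[1] - d[1])
    j1 <- pmax(1L, 1L - d[2]):pmin(dm[2], dm[2] - d[2])
    k1 <- pmax(1L, 1L - d[3]):pmin(dm[3], dm[3] - d[3])
    list(src = list(i1 + d[1], j1 + d[2], k1 + d[3]),
         dst = list(i1, j1, k1))
  }
  for (m in ord) {
    d <- c(offs$di[m], offs$dj[m], offs$dk[m])
    w <- pad(arr, d)
    nb_val <- array(-Inf, dim = dm)
    nb_sec <- array(-Inf, dim = dm)
    nb_idx <- array(0L, dim = dm)
    nb_val[w$dst[[1]], w$dst[[2]], w$dst[[3]]] <-
      arr[w$src[[1]], w$src[[2]], w$src[[3]]]
    nb_sec[w$dst[[1]], w$dst[[2]], w$dst[[3]]] <-
      sec[w$src[[1]], w$src[[2]], w$src[[3]]]
    nb_idx[w$dst[[1]], w$dst[[2]], w$dst[[3]]] <-
      flat[w$src[[1]], w$src[[2]], w$src[[3]]]
    # strictly higher neighbors win; exact plateaus (both keys tied) chain
    # to the lowest flat index, which funnels each connected plateau to a
    # single representative and keeps the partition deterministic
    take <- nb_val > best_val |
      (nb_val == best_val & nb_sec > best_sec) |
      (nb_val == best_val & nb_sec == best_sec &
         nb_idx > 0L & nb_idx < best_idx)
    best_val[take] <- nb_val[take]
    best_sec[take] <- nb_sec[take]
    best_idx[take] <- nb_idx[take]
  }
  ptr <- as.vector(best_idx)
  idx <- seq_len(n)
  ptr[!active] <- idx[!active]
  # a pointer into a below-floor voxel is cut back to self (basin boundary
  # at the density floor)
  cut <- active & !active[ptr]
  ptr[cut] <- idx[cut]
  ptr
}

#' Partition an ELF field into basins by grid steepest ascent
#'
#' Each voxel with density above the floor follows its highest-valued
#' neighbor (26-connectivity) until a local maximum; voxels draining to the
#' same maximum form one basin (a discrete watershed realization of the
#' gradient-nullity partition). Grid maxima closer than `merge_radius` are
#' fused into a single attractor.
#'
#' @param elf an `elf_field` from [compute_elf()] (or any `scalar_field` to
#'   partition, with `density` supplied).
#' @param density `scalar_field` of rho; defaults to the one stored in `elf`.
#' @param rho_min density floor; voxels below it get label `-1`.
#' @param merge_radius attractor fusion radius (bohr).
#' @return object of class `basin_partition`: integer `labels` per voxel
#'   (1..K, or -1 below the floor), and `attractors` (data.frame: label,
#'   x, y, z, eta).
#' @export
partition_basins <- function(elf, density = NULL, rho_min = 1e-6,
                             merge_radius = 0.3) {
  if (inherits(elf, "elf_field")) {
    if (is.null(density)) density <- elf$density
    rho_min <- elf$rho_min
    fld <- elf$field
  } else fld <- elf
  if (is.null(density)) stop("a density field is required")
  stop_grid_mismatch(fld$grid, density$grid)
  g <- fld$grid
  active <- density$values >= rho_min
  if (!any(active)) stop("no voxel reaches the density floor")
  arr <- array(fld$values, dim = g$shape)
  sec <- array(density$values, dim = g$shape)
  flat_eta <- max(fld$values[active]) == min(fld$values[active])
  flat_rho <- max(density$values[active]) == min(density$values[active])
  if (flat_eta && flat_rho && sum(active) > 1L)
    stop("field is constant over the active region: no maxima to partition")
  ptr <- ascent_pointers(arr, active, sec)
  # pointer jumping until every active voxel reaches its attractor
  repeat {
    nxt <- ptr[ptr]
    if (identical(nxt, ptr)) break
    ptr <- nxt
  }
  roots <- sort(unique(ptr[active]))
  # attractor positions; merge those closer than merge_radius (single link)
  pos <- grid_points(g)[roots, , drop = FALSE]
  k <- length(roots)
  cluster <- seq_len(k)
  if (k > 1L) {
    d <- as.matrix(dist(pos))
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k)
      if (d[a, b] < merge_radius) {
        old <- cluster[b]; cluster[cluster == old] <- cluster[a]
      }
  }
  cl_ids <- unique(cluster)
  label_of_root <- match(cluster, cl_ids)
  labels <- rep.int(-1L, length(ptr))
  labels[active] <- label_of_root[match(ptr[active], roots)]
  # representative attractor of a merged cluster: highest eta among members
  attr_df <- do.call(rbind, lapply(seq_along(cl_ids), function(ci) {
    members <- roots[label_of_root == ci]
    best <- members[which.max(fld$values[members])]
    p <- grid_points(g)[best, ]
    data.frame(label = ci, x = p[1], y = p[2], z = p[3],
               eta = fld$values[best])
  }))
  structure(list(labels = labels, attractors = attr_df, grid = g,
                 rho_min = rho_min),
            class = "basin_partition")
}

#' @export
print.basin_partition <- function(x, ...) {
  cat(sprintf("basin partition: %d basins, %d assigned voxels, %d below floor\n",
              nrow(x$attractors), sum(x$labels > 0), sum(x$labels == -1L)))
  invisible(x)
}

#' Basin electron populations and synaptic classification
#'
#' Populations are masked density integrals per basin; their sum plus the
#' below-floor residue equals the total density integral exactly (the masks
#' are a partition), realizing the population closure over basins. Synaptic
#' class: an attractor within `core_radius` of a nucleus with Z > 2 is a
#' core basin; otherwise the basin is valence and is connected to every atom
#' whose free-atom density at the attractor exceeds `connect_frac` of the
#' promolecule density there (exactly two atoms = disynaptic V(A,B)).
#'
#' @param partition a `basin_partition`.
#' @param density `scalar_field` of rho.
#' @param mol `molecule_spec`.
#' @param core_radius bohr.
#' @param connect_frac promolecule fraction for atom connection.
#' @return object of class `basin_report`: data.frame (label, population,
#'   class, atoms) with attributes `total_density` (integral of rho),
#'   `residue` (below-floor density) and `closure_gap`.
#' @export
basin_populations <- function(partition, density, mol,
                              core_radius = 0.35, connect_frac = 0.05) {
  stop_grid_mismatch(partition$grid, density$grid)
  vol <- voxel_volume(partition$grid)
  labs <- partition$labels
  pops <- vapply(split(density$values[labs > 0], labs[labs > 0]),
                 sum, numeric(1)) * vol
  residue <- sum(density$values[labs == -1L]) * vol
  total <- integrate_field(density)
  att <- partition$attractors
  apos <- atom_positions(mol)
  zs <- vapply(mol$atoms, function(a) a$z, integer(1))
  rows <- lapply(seq_len(nrow(att)), function(i) {
    p <- c(att$x[i], att$y[i], att$z[i])
    dn <- sqrt(colSums((t(apos) - p)^2))
    if (any(dn < core_radius & zs > 2L)) {
      cls <- "core"
      atoms <- which.min(dn)
    } else {
      fa <- vapply(seq_along(mol$atoms), function(a)
        free_atom_density(zs[a])(dn[a]), numeric(1))
      atoms <- which(fa > connect_frac * sum(fa))
      cls <- switch(as.character(length(atoms)),
                    "1" = "monosynaptic", "2" = "disynaptic", "polysynaptic")
    }
    data.frame(label = att$label[i],
               population = unname(pops[as.character(att$label[i])]),
               class = cls,
               atoms = paste(atoms, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("basin_report", "data.frame"),
            total_density = total, residue = residue,
            closure_gap = total - (sum(out$population) + residue))
}
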