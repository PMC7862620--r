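# Independent oracles used by the dual-route tests.  These deliberately
# re-derive each quantity with naive code (double loops, a different SAS
# lattice) so they share no implementation path with the package internals.

# Naive O(N*M) intermolecular Coulomb sum.
oracle_coulomb <- function(cmplx, model, cfg) {
  ar <- cmplx$receptor$atoms; al <- cmplx$ligand$atoms
  total <- 0
  for (i in seq_len(nrow(ar))) {
    for (j in seq_len(nrow(al))) {
      R <- sqrt((ar$x[i] - al$x[j])^2 + (ar$y[i] - al$y[j])^2 +
                  (ar$z[i] - al$z[j])^2)
      eps <- dielectric_constant(R, model)
      total <- total + cfg$coulomb_constant * ar$partial_charge[i] *
        al$partial_charge[j] / (eps * (R + cfg$delta_elec))
    }
  }
  total
}

# Naive buffered 14-7 sum.
oracle_vdw <- function(cmplx, cfg) {
  ar <- cmplx$receptor$atoms; al <- cmplx$ligand$atoms
  total <- 0
  for (i in seq_len(nrow(ar))) {
    for (j in seq_len(nrow(al))) {
      R <- sqrt((ar$x[i] - al$x[j])^2 + (ar$y[i] - al$y[j])^2 +
                  (ar$z[i] - al$z[j])^2)
      e <- sqrt(ar$eps[i] * al$eps[j])
      rs <- (ar$rmin[i] + al$rmin[j]) / 2
      d <- cfg$delta_vdw; g <- cfg$gamma_vdw
      total <- total + e * ((1 + d) * rs / (R + d * rs))^7 *
        ((1 + g) * rs^7 / (R^7 + g * rs^7) - 2)
    }
  }
  total
}

# Naive lipophilic contact sum (charge-window variant).
oracle_lipo <- function(cmplx, cfg) {
  ar <- cmplx$receptor$atoms; al <- cmplx$ligand$atoms
  elig <- function(a) {
    if (cfg$lipo_variant == "carbons") a$element == "C"
    else !a$is_h & a$partial_charge > cfg$lipo_charge_window[1] &
      a$partial_charge < cfg$lipo_charge_window[2]
  }
  total <- 0
  for (i in which(elig(ar))) {
    for (j in which(elig(al))) {
      R <- sqrt((ar$x[i] - al$x[j])^2 + (ar$y[i] - al$y[j])^2 +
                  (ar$z[i] - al$z[j])^2)
      dv <- ar$radius[i] + al$radius[j]
      w <- if (R <= dv + 0.5) 1
           else if (R <= dv + 3.5) 1 - (R - dv - 0.5) / 3
           else 0
      total <- total + max(0, w)
    }
  }
  total
}

# Independent Shrake-Rupley with a seeded *random* direction set -- a
# different quadrature than the package's golden-spiral lattice.
oracle_sasa <- function(coords, radii, probe = 1.4, n_points = 2000,
                        seed = 99) {
  set.seed(seed)
  z <- stats::runif(n_points, -1, 1)
  th <- stats::runif(n_points, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  dirs <- cbind(r * cos(th), r * sin(th), z)
  n <- nrow(coords)
  R <- radii + probe
  area <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(dirs * R[i], 2, coords[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- colSums((t(pts) - coords[j, ])^2)
      free <- free & d2 >= R[j]^2
    }
    area[i] <- 4 * pi * R[i]^2 * mean(free)
  }
  area
}

# Random parameterized complex of nr receptor + nl ligand atoms in a box,
# with charges drawn uniformly; used by the formula-oracle tests.
random_complex <- function(nr = 10, nl = 10, seed = 1, spread = 6) {
  set.seed(seed)
  els <- c("C", "N", "O", "S", "H")
  mk <- function(n, shift) {
    m <- pl_molecule(sample(els, n, replace = TRUE),
                     cbind(stats::runif(n, 0, spread) + shift,
                           stats::runif(n, 0, spread),
                           stats::runif(n, 0, spread)))
    m <- assign_parameters(m)
    m$atoms$partial_charge <- round(stats::runif(n, -1, 1), 3)
    m$net_charge <- round(sum(m$atoms$partial_charge))
    m
  }
  pl_complex(mk(nr, 0), mk(nl, spread + 2))
}

# Tiny SDF text fixture: methane with explicit hydrogens.
methane_sdf <- function(path) {
  writeLines(c(
    "methane", "  test", "",
    "  5  4  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.6294    0.6294    0.6294 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.6294   -0.6294    0.6294 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.6294    0.6294   -0.6294 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.6294   -0.6294   -0.6294 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  1  3  1  0  0  0  0",
    "  1  4  1  0  0  0  0",
    "  1  5  1  0  0  0  0",
    "M  END", "$$$$"), path)
  path
}

# n-butane heavy-skeleton + hydrogens, for rotatable-bond tests.
butane_mol <- function() {
  cc <- 1.53; ch <- 1.1
  heavy <- cbind((0:3) * cc, c(0, 0.5, 0, 0.5), 0)
  hs <- do.call(rbind, lapply(1:4, function(i) {
    sweep(cbind(c(0, 0, 0.9), c(0.9, -0.9, 0), c(-0.6, -0.6, 0.6)) * ch,
          2, heavy[i, ], "+")
  }))
  coords <- rbind(heavy, hs)
  bonds <- rbind(
    data.frame(i = 1:3, j = 2:4, order = 1L),
    data.frame(i = rep(1:4, each = 3), j = 5:16, order = 1L))
  pl_molecule(c(rep("C", 4), rep("H", 12)), coords, bonds = bonds)
}
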