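## Synthetic-data generation: toy protein-ligand complexes with known
## ground-truth descriptor behavior, planted-coefficient feature tables for
## regression-recovery tests, and synthetic screening score sets.
##
## Toy complexes are geometric constructions, not chemistry: heavy-atom
## chains and probe atoms parameterized from the built-in element table,
## with optional per-atom charge/radius overrides.  Every artifact is
## reproducible bitwise from (spec, seed).

## Deterministic golden-spiral points on the unit sphere.
golden_spiral <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (3 - sqrt(5)) * (k - 0.5)
  cbind(r * cos(th), r * sin(th), z)
}

#' Toy complex specification
#'
#' @param ligand_template `"rigid_probe"` (single carbon), `"rotor_chain"`
#'   (linear heavy-atom carbon chain with `n_rotors` rotatable bonds, i.e.
#'   `n_rotors + 3` atoms) or `"charged_pair"` (N and O atoms 3 Angstrom
#'   apart, for polar-solvation fixtures).
#' @param pocket_shape `"none"` (single receptor probe atom at
#'   `pair_distance`), `"shell"` (full golden-spiral sphere of carbon atoms
#'   around the ligand at `gap` beyond its extent), `"slab"` (planar carbon
#'   grid at `gap` below the selected ligand atoms) or `"cage"` (tight
#'   per-atom occluder shells around `enclose_atoms`).
#' @param n_rotors number of rotatable bonds for `rotor_chain`.
#' @param pair_distance requested nearest intermolecular distance for
#'   `pocket_shape = "none"`, Angstrom.
#' @param gap clearance between ligand and pocket atoms, Angstrom.
#' @param pocket_atom_count atoms in a shell pocket.
#' @param enclose_atoms ligand atom indices enclosed by a cage, or covered
#'   by a slab (default: all).
#' @param chain_spacing bond length of the rotor chain, Angstrom.
#' @param charge_overrides named numeric vector: partial-charge overrides,
#'   names like `"ligand.2"` / `"receptor.10"`.
#' @param seed integer seed (orientation jitter of shells is deterministic
#'   anyway; the seed fixes any randomized placement).
#' @return object of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(ligand_template = c("rigid_probe", "rotor_chain",
                                                 "charged_pair"),
                             pocket_shape = c("none", "shell", "slab", "cage"),
                             n_rotors = 3L, pair_distance = 4.0, gap = 1.0,
                             pocket_atom_count = 200L, enclose_atoms = NULL,
                             chain_spacing = 1.53,
                             charge_overrides = NULL, seed = 1L) {
  ligand_template <- match.arg(ligand_template)
  pocket_shape <- match.arg(pocket_shape)
  stopifnot(pair_distance > 0, n_rotors >= 0, gap >= 0)
  structure(list(ligand_template = ligand_template,
                 pocket_shape = pocket_shape, n_rotors = as.integer(n_rotors),
                 pair_distance = pair_distance, gap = gap,
                 pocket_atom_count = as.integer(pocket_atom_count),
                 enclose_atoms = enclose_atoms,
                 chain_spacing = chain_spacing,
                 charge_overrides = charge_overrides,
                 seed = as.integer(seed)),
            class = "toy_complex_spec")
}

make_toy_ligand <- function(spec) {
  switch(spec$ligand_template,
    rigid_probe = pl_molecule("C", matrix(0, 1, 3), name = "probe"),
    rotor_chain = {
      n <- spec$n_rotors + 3L
      coords <- cbind((seq_len(n) - 1L) * spec$chain_spacing, 0, 0)
      bonds <- data.frame(i = seq_len(n - 1L), j = 2:n, order = 1L)
      pl_molecule(rep("C", n), coords, bonds = bonds, name = "rotor_chain")
    },
    charged_pair = {
      pl_molecule(c("N", "O"), rbind(c(0, 0, 0), c(3, 0, 0)),
                  name = "charged_pair")
    })
}

make_toy_pocket <- function(spec, lig) {
  lx <- coords_of(lig)
  center <- colMeans(lx)
  switch(spec$pocket_shape,
    none = {
      # single probe atom at pair_distance from ligand atom 1, along -x
      pl_molecule("C", matrix(lx[1, ] - c(spec$pair_distance, 0, 0), 1, 3),
                  name = "probe_receptor")
    },
    shell = {
      # capsule shell following the ligand surface: per-atom sphere lattices
      # at clearance `gap` between van der Waals surfaces, keeping only the
      # exterior points.  gap < 2.8 A leaves no room for a water probe, so
      # the enclosed ligand is essentially fully buried.
      r_at <- 1.70
      pts <- list()
      for (a in seq_len(nrow(lx))) {
        r_off <- r_at + spec$gap + 1.70
        cand <- sweep(golden_spiral(160L) * r_off, 2, lx[a, ], "+")
        keep <- rep(TRUE, nrow(cand))
        for (b in seq_len(nrow(lx))) {
          if (b == a) next
          db <- sqrt(colSums((t(cand) - lx[b, ])^2))
          keep <- keep & db > r_off - 1e-6
        }
        pts[[length(pts) + 1L]] <- cand[keep, , drop = FALSE]
      }
      pts <- do.call(rbind, pts)
      pl_molecule(rep("C", nrow(pts)), pts, name = "shell_pocket")
    },
    slab = {
      sel <- spec$enclose_atoms
      if (is.null(sel)) sel <- seq_len(nrow(lx))
      sx <- lx[sel, , drop = FALSE]
      z0 <- min(sx[, 3]) - 1.70 - spec$gap - 1.70
      xs <- seq(min(sx[, 1]) - 3, max(sx[, 1]) + 3, by = 1.8)
      ys <- seq(min(sx[, 2]) - 3, max(sx[, 2]) + 3, by = 1.8)
      g <- expand.grid(x = xs, y = ys)
      pl_molecule(rep("C", nrow(g)), cbind(g$x, g$y, z0), name = "slab_pocket")
    },
    cage = {
      # small-radius occluders sitting on the probe-center sphere of each
      # enclosed atom, with candidates near NON-enclosed ligand atoms
      # dropped so their surface stays mostly free
      sel <- spec$enclose_atoms
      if (is.null(sel)) sel <- seq_len(nrow(lx))
      other <- setdiff(seq_len(nrow(lx)), sel)
      pts <- list()
      for (a in sel) {
        cand <- sweep(golden_spiral(120L) * (1.70 + 1.4), 2, lx[a, ], "+")
        keep <- rep(TRUE, nrow(cand))
        for (b in other) {
          db <- sqrt(colSums((t(cand) - lx[b, ])^2))
          keep <- keep & db > 4.0
        }
        pts[[length(pts) + 1L]] <- cand[keep, , drop = FALSE]
      }
      pts <- do.call(rbind, pts)
      m <- pl_molecule(rep("C", nrow(pts)), pts, name = "cage_pocket")
      attr(m, "occluder_radius") <- 0.6
      m
    })
}

#' Build a toy complex with ground-truth annotations
#'
#' Deterministic geometry for a given spec; both molecules are
#' parameterized with the built-in element table, then any radius/charge
#' overrides are applied.  Annotations state per-term expectations that the
#' descriptor engine is tested against: the realized nearest intermolecular
#' distance, the rotatable-bond count, and (for cages) which bonds are
#' intended frozen.
#'
#' @param spec a [toy_complex_spec()].
#' @return list with `complex` (a `plcomplex`) and `annotations`.
#' @export
make_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  lig <- assign_parameters(make_toy_ligand(spec))
  rec <- make_toy_pocket(spec, lig)
  occ_r <- attr(rec, "occluder_radius")
  rec <- assign_parameters(rec)
  if (!is.null(occ_r)) rec$atoms$radius[] <- occ_r
  if (!is.null(spec$charge_overrides)) {
    for (key in names(spec$charge_overrides)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      idx <- as.integer(parts[2])
      if (parts[1] == "ligand") lig$atoms$partial_charge[idx] <- spec$charge_overrides[[key]]
      else rec$atoms$partial_charge[idx] <- spec$charge_overrides[[key]]
    }
    # overrides are test instrumentation; exempt them from the charge-sum
    # invariant by adjusting the nominal net charge
    lig$net_charge <- round(sum(lig$atoms$partial_charge))
    rec$net_charge <- round(sum(rec$atoms$partial_charge))
  }
  cmplx <- pl_complex(rec, lig)
  d <- pair_distances(cmplx)
  rot <- detect_rotatable_bonds(lig)
  ann <- list(nearest_distance = min(d),
              n_rotatable = nrow(rot),
              ligand_template = spec$ligand_template,
              pocket_shape = spec$pocket_shape)
  if (spec$pocket_shape == "cage" && nrow(rot) > 0L) {
    sel <- spec$enclose_atoms
    if (is.null(sel)) sel <- seq_len(n_atoms(lig))
    adj <- adjacency_list(lig)
    both_in <- logical(nrow(rot))
    for (k in seq_len(nrow(rot))) {
      side_i <- c(rot$i[k], setdiff(adj[[rot$i[k]]], rot$j[k]))
      side_j <- c(rot$j[k], setdiff(adj[[rot$j[k]]], rot$i[k]))
      both_in[k] <- all(side_i %in% sel) && all(side_j %in% sel)
    }
    ann$intended_frozen <- sum(both_in)
  }
  if (spec$pocket_shape == "shell") ann$intended_frozen <- nrow(rot)
  if (spec$pocket_shape == "none") ann$intended_frozen <- 0L
  list(complex = cmplx, annotations = ann)
}

#' Synthetic descriptor table with planted linear coefficients
#'
#' Draws descriptor values uniformly in realistic per-term ranges and
#' generates targets from a linear model plus Gaussian noise; the
#' parameter-recovery harness for the regression code.
#'
#' @param n number of rows (`>= 10`).
#' @param coefficients a [linear_coefficients()] object supplying the ground
#'   truth (default: the shipped general-random set).
#' @param noise_sigma Gaussian noise standard deviation, kcal/mol.
#' @param feature_ranges named list of `c(min, max)` per term; defaults span
#'   values typical of drug-like complexes (Coulomb -40..5, vdW -60..-5
#'   kcal/mol, lipophilic contact sum 0..300, 0..10 frozen rotors, 0..5
#'   buried charges, nonpolar solvation -10..-1 kcal/mol).
#' @param seed integer seed.
#' @return data frame with `complex_id`, one column per term, and `dG_exp`.
#' @export
make_feature_table <- function(n, coefficients = published_model("general-random"),
                               noise_sigma = 0.5, feature_ranges = NULL,
                               seed = 1L) {
  stopifnot(n >= 10)
  defaults <- list(E_coul = c(-40, 5), E_vdW = c(-60, -5),
                   E_lipo = c(0, 300), E_entropy = c(0, 10),
                   E_polar_solv = c(0, 5), E_np_solv = c(-10, -1),
                   oneSolv = c(-12, -1))
  terms <- coefficients$term_set
  with_seed(seed, {
    cols <- lapply(terms, function(t) {
      rg <- if (!is.null(feature_ranges[[t]])) feature_ranges[[t]]
            else if (!is.null(defaults[[t]])) defaults[[t]] else c(0, 1)
      v <- stats::runif(n, rg[1], rg[2])
      if (t %in% c("E_entropy", "E_polar_solv")) v <- round(v)
      v
    })
    names(cols) <- terms
    df <- as.data.frame(cols)
    df$dG_exp <- predict_linear(df, coefficients) +
      stats::rnorm(n, 0, noise_sigma)
    cbind(data.frame(complex_id = sprintf("cpx%04d", seq_len(n))), df)
  })
}

#' Synthetic screening score set
#'
#' Actives score `N(-separation, 1)`, inactives `N(0, 1)` (lower = better),
#' the harness for the screening metrics.
#'
#' @param n_active,n_inactive class sizes (`>= 1`).
#' @param separation mean score gap between actives and inactives.
#' @param seed integer seed.
#' @return a [screening_table()].
#' @export
make_screening_scores <- function(n_active, n_inactive, separation = 2,
                                  seed = 1L) {
  stopifnot(n_active >= 1, n_inactive >= 1)
  with_seed(seed, {
    scores <- c(stats::rnorm(n_active, -separation, 1),
                stats::rnorm(n_inactive, 0, 1))
    screening_table(scores, c(rep(TRUE, n_active), rep(FALSE, n_inactive)),
                    ids = sprintf("cmp%05d", seq_len(n_active + n_inactive)))
  })
}
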