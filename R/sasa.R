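## Solvent-accessible surface areas (Shrake-Rupley) and binding-induced
## surface changes.  These feed the nonpolar solvation term, the polar
## burial test and the frozen-rotatable-bond entropy count.

#' Solvent-accessible surface areas of a rigid assembly
#'
#' Numerical SAS by the Shrake-Rupley method on a fixed golden-spiral
#' quadrature lattice: each atom's sphere (contact radius + probe) is sampled
#' at `n_points` deterministic points and a point is accessible when it lies
#' outside every other expanded sphere.  Free-state areas are obtained by
#' passing one molecule; bound-state areas by passing the complex members
#' together.
#'
#' @param molecules a single `plmol` or a list of `plmol` objects treated as
#'   one rigid assembly in a common frame.
#' @param probe probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points quadrature points per atom (default 960; minimum 96).
#' @param include_hydrogens include hydrogens with their radii (default
#'   `TRUE`); when `FALSE` hydrogens get zero area and do not occlude.
#' @return an object of class `sas_result`: list with `per_atom_area`
#'   (Angstrom^2, one entry per atom in input order across molecules),
#'   `total_area`, `probe_radius`, `n_sphere_points`, and `molecule_sizes`.
#' @examples
#' m <- pl_molecule("C", matrix(0, 1, 3))
#' m <- assign_parameters(m)
#' solvent_accessible_areas(m)$total_area  # 4*pi*(1.7+1.4)^2
#' @export
solvent_accessible_areas <- function(molecules, probe = 1.4, n_points = 960L,
                                     include_hydrogens = TRUE) {
  if (inherits(molecules, "plmol")) molecules <- list(molecules)
  stopifnot(length(molecules) >= 1L, n_points >= 96L, probe >= 0)
  sizes <- vapply(molecules, n_atoms, 1L)
  xyz <- do.call(rbind, lapply(molecules, coords_of))
  radii <- unlist(lapply(molecules, function(m) m$atoms$radius))
  is_h <- unlist(lapply(molecules, function(m) m$atoms$is_h))
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop("all atoms need a positive contact_radius; run assign_parameters")
  if (anyDuplicated(round(xyz, 6)) > 0L)
    warning("geometry warning: coincident atom coordinates")
  if (!include_hydrogens && any(is_h)) {
    keep <- !is_h
    a <- numeric(length(is_h))
    a[keep] <- .sasa_cpp(xyz[keep, , drop = FALSE], radii[keep],
                         probe, as.integer(n_points))
  } else {
    a <- .sasa_cpp(xyz, radii, probe, as.integer(n_points))
  }
  structure(list(per_atom_area = a, total_area = sum(a),
                 probe_radius = probe, n_sphere_points = as.integer(n_points),
                 molecule_sizes = sizes),
            class = "sas_result")
}

#' @export
print.sas_result <- function(x, ...) {
  cat(sprintf("<sas_result: %d atoms, total %.2f A^2, probe %.2f A, %d pts>\n",
              length(x$per_atom_area), x$total_area, x$probe_radius,
              x$n_sphere_points))
  invisible(x)
}

#' Surface loss of an atom subset upon binding
#'
#' For a subset of atoms belonging to one side of a complex, computes the
#' summed SAS of the subset with its parent molecule alone (`free`), the
#' summed SAS in the complex (`bound`), and the fraction of surface lost,
#' `(free - bound) / free`.  When the subset is essentially buried already in
#' the free state (`free < degenerate_free`), the fraction is defined as 1.
#'
#' @param cmplx a `plcomplex`.
#' @param atom_subset integer atom indices into the molecule named by `side`.
#' @param side `"ligand"` or `"receptor"`: which molecule owns the subset.
#' @param probe,n_points,include_hydrogens passed to
#'   [solvent_accessible_areas()].
#' @param degenerate_free threshold (Angstrom^2) below which the free-state
#'   area counts as degenerate (default 0.5).
#' @return list with `free`, `bound`, `fraction_lost`.
#' @export
delta_sas <- function(cmplx, atom_subset, side = c("ligand", "receptor"),
                      probe = 1.4, n_points = 960L, include_hydrogens = TRUE,
                      degenerate_free = 0.5) {
  stopifnot(inherits(cmplx, "plcomplex"))
  side <- match.arg(side)
  atom_subset <- as.integer(atom_subset)
  if (length(atom_subset) == 0L) stop("usage error: empty atom subset")
  own <- if (side == "ligand") cmplx$ligand else cmplx$receptor
  if (any(atom_subset < 1L | atom_subset > n_atoms(own)))
    stop("usage error: atom subset outside the ", side,
         " (subsets may not span both molecules)")
  free_sas <- solvent_accessible_areas(own, probe, n_points,
                                       include_hydrogens)
  bound_sas <- solvent_accessible_areas(list(cmplx$receptor, cmplx$ligand),
                                        probe, n_points, include_hydrogens)
  offset <- if (side == "ligand") n_atoms(cmplx$receptor) else 0L
  free <- sum(free_sas$per_atom_area[atom_subset])
  bound <- sum(bound_sas$per_atom_area[atom_subset + offset])
  frac <- if (free < degenerate_free) 1 else (free - bound) / free
  list(free = free, bound = bound, fraction_lost = frac)
}
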