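## Force-field parameterization backend, rotatable-bond perception and
## affinity unit conversion.
##
## Parameter assignment is a pluggable contract.  The built-in backend is a
## minimal element-keyed table (C, H, N, O, S, P, halogens): partial charges
## come from an antisymmetric electronegativity-scaled bond-charge-increment
## scheme applied to the file formal charges, van der Waals well depths and
## minimum-energy separations from a per-element table with Lorentz/Berthelot
## style combination downstream, and contact radii from the Bondi set.  A
## full MMFF94S engine can be substituted by passing custom tables; the
## descriptor code only consumes the per-atom columns, never the backend.

# Bondi van der Waals (contact) radii, Angstrom.
.bondi_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                  P = 1.80, F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98)

# Minimal per-element vdW parameters: well depth (kcal/mol) and
# minimum-energy separation R* of the homoatomic pair (Angstrom).
.vdw_params <- data.frame(
  element = c("H", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I"),
  eps  = c(0.030, 0.070, 0.110, 0.105, 0.250, 0.200, 0.061, 0.276, 0.389, 0.550),
  rmin = c(2.42, 3.88, 3.60, 3.40, 4.03, 4.10, 3.29, 3.92, 4.09, 4.36),
  stringsAsFactors = FALSE
)

# Pauling electronegativities, for the bond-charge increments.
.electroneg <- c(H = 2.20, C = 2.55, N = 3.04, O = 3.44, S = 2.58,
                 P = 2.19, F = 3.98, Cl = 3.16, Br = 2.96, I = 2.66)

# Covalent radii for distance-based bond perception (Angstrom).
.covalent_radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                     P = 1.07, F = 0.57, Cl = 1.02, Br = 1.20, I = 1.39)

covalent_radius <- function(el) {
  r <- .covalent_radii[el]
  r[is.na(r)] <- 1.1
  unname(r)
}

# Charge transferred along a bond per unit electronegativity difference.
.bci_scale <- 0.10

#' Assign force-field parameters to a molecule
#'
#' Populates per-atom partial charges, van der Waals well depth `eps` and
#' minimum-energy separation `rmin`, and the contact radius used in the
#' distance thresholds of the lipophilic and polar-solvation terms.
#'
#' Partial charges follow the bond-charge-increment scheme: each atom starts
#' from its formal charge and receives, for every covalent bond, an increment
#' proportional to the electronegativity difference with its partner
#' (`q_i = q_i0 + sum_k w_ki`).  Because increments are antisymmetric the sum
#' of partial charges equals the net formal charge exactly, and
#' graph-equivalent atoms receive identical charges.
#'
#' @param mol a `plmol` with a valid bond graph and explicit hydrogens.
#' @param radii_table optional named numeric vector of contact radii per
#'   element, overriding the built-in Bondi set.
#' @param vdw_table optional data frame with columns `element`, `eps`, `rmin`
#'   overriding the built-in vdW table.
#' @param recompute_charges if `FALSE` and the file carried partial charges
#'   (MOL2), keep them instead of applying the increment scheme.
#' @return the molecule with `parameterized = TRUE`.
#' @export
assign_parameters <- function(mol, radii_table = NULL, vdw_table = NULL,
                              recompute_charges = TRUE) {
  stopifnot(inherits(mol, "plmol"))
  el <- mol$atoms$element
  radii <- .bondi_radii
  if (!is.null(radii_table)) radii[names(radii_table)] <- radii_table
  vdw <- if (is.null(vdw_table)) .vdw_params else vdw_table
  miss_r <- setdiff(unique(el), names(radii))
  miss_v <- setdiff(unique(el), vdw$element)
  miss_e <- setdiff(unique(el), names(.electroneg))
  if (length(c(miss_r, miss_v, miss_e)) > 0L)
    stop("parameterization error: no parameters for element(s) ",
         paste(unique(c(miss_r, miss_v, miss_e)), collapse = ", "),
         " (first such atom: #",
         which(el %in% unique(c(miss_r, miss_v, miss_e)))[1], ")")
  mol$atoms$radius <- unname(radii[el])
  mol$atoms$eps <- vdw$eps[match(el, vdw$element)]
  mol$atoms$rmin <- vdw$rmin[match(el, vdw$element)]
  if (recompute_charges || all(is.na(mol$atoms$partial_charge))) {
    q <- as.numeric(mol$atoms$formal_charge)
    if (nrow(mol$bonds) > 0L) {
      chi <- .electroneg[el]
      # electrons flow toward the more electronegative partner, so the less
      # electronegative atom of each bond picks up positive charge; the
      # increment is antisymmetric, preserving the net charge exactly
      for (k in seq_len(nrow(mol$bonds))) {
        i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
        w <- .bci_scale * (chi[j] - chi[i])
        q[i] <- q[i] + w
        q[j] <- q[j] - w
      }
    }
    mol$atoms$partial_charge <- q
  }
  mol$parameterized <- TRUE
  validate_molecule(mol)
  mol
}

#' Detect rotatable bonds of a molecule
#'
#' A bond is rotatable iff it is a single (non-aromatic) bond, not in a ring,
#' both atoms are heavy, and each end atom has at least one additional heavy
#' neighbor (so terminal groups such as methyls do not count).  Amide C-N
#' bonds (C double-bonded to O, bonded to N) are excluded by default.
#'
#' @param mol a `plmol` with a bond graph.
#' @param amide_exclusion exclude amide C-N bonds (default `TRUE`).
#' @return the molecule's bond table restricted to rotatable bonds, with the
#'   `rotatable` flag set; also re-stored on the molecule when assigned back.
#' @export
detect_rotatable_bonds <- function(mol, amide_exclusion = TRUE) {
  b <- mol$bonds
  if (nrow(b) == 0L) return(b[0, , drop = FALSE])
  heavy <- !mol$atoms$is_h
  adj <- adjacency_list(mol)
  heavy_deg <- vapply(seq_len(n_atoms(mol)), function(i) {
    sum(heavy[adj[[i]]])
  }, 1L)
  rot <- b$order == BOND_SINGLE & !b$in_ring &
    heavy[b$i] & heavy[b$j] &
    heavy_deg[b$i] >= 2L & heavy_deg[b$j] >= 2L
  if (amide_exclusion && any(rot)) {
    el <- mol$atoms$element
    has_carbonyl <- function(c_idx) {
      any(b$order == BOND_DOUBLE &
            ((b$i == c_idx & el[b$j] == "O") |
             (b$j == c_idx & el[b$i] == "O")))
    }
    for (k in which(rot)) {
      i <- b$i[k]; j <- b$j[k]
      amide <- (el[i] == "C" && el[j] == "N" && has_carbonyl(i)) ||
               (el[j] == "C" && el[i] == "N" && has_carbonyl(j))
      if (amide) rot[k] <- FALSE
    }
  }
  b$rotatable <- rot
  b[rot, , drop = FALSE]
}

#' Assemble a protein-ligand complex
#'
#' Pairs a parameterized receptor and ligand sharing one coordinate frame.
#' All intermolecular descriptors consume this object.
#'
#' @param receptor,ligand `plmol` objects, typically from [read_structure()]
#'   followed by [assign_parameters()].
#' @return an object of class `plcomplex`.
#' @export
pl_complex <- function(receptor, ligand) {
  stopifnot(inherits(receptor, "plmol"), inherits(ligand, "plmol"))
  if (n_atoms(ligand) == 0L || n_atoms(receptor) == 0L)
    stop("usage error: empty receptor or ligand")
  structure(list(receptor = receptor, ligand = ligand), class = "plcomplex")
}

#' @export
print.plcomplex <- function(x, ...) {
  cat(sprintf("<plcomplex: receptor %d atoms, ligand %d atoms>\n",
              n_atoms(x$receptor), n_atoms(x$ligand)))
  invisible(x)
}

require_parameterized <- function(cmplx) {
  if (!cmplx$receptor$parameterized || !cmplx$ligand$parameterized)
    stop("complex must be parameterized (call assign_parameters first)")
  invisible(cmplx)
}

# Gas constant in kcal/(mol K).
.R_kcal <- 1.98720425864083e-3

#' Binding affinity record
#'
#' @param value dissociation/inhibition constant in molar units; must be > 0.
#' @param kind one of `"Kd"`, `"Ki"`, `"IC50"`.  All three are converted
#'   identically (PDBbind practice).
#' @param temperature temperature in Kelvin (default 298.15).
#' @return object of class `binding_affinity`.
#' @export
binding_affinity <- function(value, kind = c("Kd", "Ki", "IC50"),
                             temperature = 298.15) {
  kind <- match.arg(kind)
  if (!is.numeric(value) || any(value <= 0))
    stop("domain error: affinity value must be > 0")
  structure(list(value = value, kind = kind, temperature = temperature),
            class = "binding_affinity")
}

#' Convert a binding constant to a free energy
#'
#' Returns `RT * ln(K)` in kcal/mol with `K` in molar units, so tighter
#' binders map to more negative energies (1 M maps to 0).
#'
#' @param affinity a [binding_affinity()] record, or a bare numeric molar
#'   constant (then `temperature` applies).
#' @param temperature temperature in K, used only for bare numeric input.
#' @return free energy in kcal/mol.
#' @examples
#' affinity_to_energy(binding_affinity(1.2e-12))  # approx -16.26
#' @export
affinity_to_energy <- function(affinity, temperature = 298.15) {
  if (inherits(affinity, "binding_affinity")) {
    value <- affinity$value
    temperature <- affinity$temperature
  } else {
    value <- affinity
    if (!is.numeric(value) || any(value <= 0))
      stop("domain error: affinity value must be > 0")
  }
  .R_kcal * temperature * log(value)
}
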