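## The physics-based interaction descriptors: screened Coulomb
## electrostatics, buffered 14-7 van der Waals, piecewise lipophilic
## contacts, polar (buried-charge count) and nonpolar (delta-SAS) solvation,
## and the frozen-rotatable-bond torsional entropy count.

#' Distance-dependent dielectric model
#'
#' Three dielectric treatments for the screened Coulomb term: a plain
#' constant, the Hingerty sigmoidal function
#' `eps(r) = 78 - 77 (r/2.5)^2 e^(r/2.5) / (e^(r/2.5) - 1)^2`,
#' and the Ramstein-Lavery function
#' `eps(r) = D - ((D - D_i)/2) ((rs)^2 + 2rs + 2) e^(-rs)`,
#' which tends to `D_i` as `r -> 0` and to `D` at long range.  The default is
#' Ramstein-Lavery with `D_i = 4`, the low interior dielectric of protein
#' binding sites.
#'
#' @param kind `"ramstein"`, `"hingerty"` or `"constant"`.
#' @param D long-range dielectric plateau (default 78, bulk water).
#' @param D_i short-range limit of the Ramstein-Lavery function (1 or 4).
#' @param s slope of the sigmoidal segment (default 0.16, 1/Angstrom).
#' @param constant_value value used when `kind = "constant"`.
#' @return object of class `dielectric_model`.
#' @export
dielectric_model <- function(kind = c("ramstein", "hingerty", "constant"),
                             D = 78, D_i = 4, s = 0.16, constant_value = 1) {
  kind <- match.arg(kind)
  stopifnot(D >= D_i, D_i >= 1, s > 0, constant_value > 0)
  structure(list(kind = kind, D = D, D_i = D_i, s = s,
                 constant_value = constant_value),
            class = "dielectric_model")
}

#' Evaluate a dielectric model at a distance
#'
#' @param r distance(s) in Angstrom, `>= 0`; `r = 0` returns the analytic
#'   limit (`D_i` for Ramstein-Lavery, 1 for Hingerty).
#' @param model a [dielectric_model()].
#' @return dielectric constant(s), same length as `r`.
#' @examples
#' dielectric_constant(0, dielectric_model("ramstein", D_i = 4))  # 4
#' @export
dielectric_constant <- function(r, model = dielectric_model()) {
  if (any(r < 0)) stop("domain error: r must be >= 0")
  switch(model$kind,
    constant = rep_len(model$constant_value, length(r)),
    hingerty = {
      x <- r / 2.5
      out <- numeric(length(r))
      small <- x < 1e-6
      out[small] <- 1  # limit: x^2 e^x / (e^x - 1)^2 -> 1
      xs <- x[!small]
      # e^x/(e^x-1)^2 written as e^-x/(1-e^-x)^2 to avoid overflow at large r
      out[!small] <- 78 - 77 * xs^2 * exp(-xs) / (1 - exp(-xs))^2
      out
    },
    ramstein = {
      rs <- r * model$s
      model$D - ((model$D - model$D_i) / 2) *
        ((rs)^2 + 2 * rs + 2) * exp(-rs)
    })
}

#' Descriptor term configuration
#'
#' Collects every tunable constant of the descriptor set.  Defaults follow
#' the published configuration: electrostatic buffering `delta_elec = 0.05`
#' Angstrom, softened van der Waals buffering `delta_vdw = 0.67` (the
#' original buffered 14-7 value is 0.07), `gamma_vdw = 0.12`, lipophilic
#' eligibility by the MMFF94S partial-charge window (-0.4, +0.4) e,
#' polar-solvation charge threshold `|q| > 0.8` e with contact pad 1.0
#' Angstrom, nonpolar solvation `G_np = 0.0092 * SAS + 0.82` (kcal/mol, SAS
#' in Angstrom^2), and the 50% two-sided burial rule for frozen rotatable
#' bonds.
#'
#' @param coulomb_constant Coulomb prefactor, kcal A / (mol e^2).
#' @param delta_elec electrostatic buffering constant, Angstrom.
#' @param delta_vdw vdW buffering constant: 0.67 (softened, default) or 0.07
#'   (original).
#' @param gamma_vdw second vdW buffering constant (0.12).
#' @param lipo_variant `"charge_window"` (non-hydrogen atoms with partial
#'   charge inside `lipo_charge_window`) or `"carbons"` (all carbon atoms).
#' @param lipo_charge_window symmetric charge window, e.
#' @param polar_charge_threshold `|q|` above which a non-H, non-C atom counts
#'   as charged, e.
#' @param polar_contact_pad interaction pad added to the radii sum, Angstrom.
#' @param polar_burial_ratio an atom is "buried" when its bound SAS is at or
#'   below this fraction of its free SAS (default 0.10).
#' @param polar_opposite_sign_only if `TRUE`, clause (b) of the polar term
#'   only considers partners of opposite charge sign (default `FALSE`:
#'   sign-agnostic, following the text literally).
#' @param np_slope,np_intercept coefficients of `G_np`, kcal/(mol A^2) and
#'   kcal/mol.
#' @param entropy_burial_fraction per-side SAS loss fraction at or above
#'   which a side counts as buried (default 0.5).
#' @param entropy_include_hydrogens include hydrogens bonded to side atoms in
#'   the side sets (default `TRUE`).
#' @param amide_exclusion exclude amide C-N bonds from rotatable bonds.
#' @param probe_radius,n_sphere_points,include_hydrogens_in_sas SAS engine
#'   settings (see [solvent_accessible_areas()]).
#' @param cutoff optional nonbonded distance cutoff in Angstrom for the
#'   Coulomb/vdW/lipophilic sums.  `NULL` (default) means no cutoff, the
#'   canonical behavior.
#' @return object of class `term_config`.
#' @export
term_config <- function(coulomb_constant = 332.0716,
                        delta_elec = 0.05,
                        delta_vdw = 0.67,
                        gamma_vdw = 0.12,
                        lipo_variant = c("charge_window", "carbons"),
                        lipo_charge_window = c(-0.4, 0.4),
                        polar_charge_threshold = 0.8,
                        polar_contact_pad = 1.0,
                        polar_burial_ratio = 0.10,
                        polar_opposite_sign_only = FALSE,
                        np_slope = 0.0092,
                        np_intercept = 0.82,
                        entropy_burial_fraction = 0.5,
                        entropy_include_hydrogens = TRUE,
                        amide_exclusion = TRUE,
                        probe_radius = 1.4,
                        n_sphere_points = 960L,
                        include_hydrogens_in_sas = TRUE,
                        cutoff = NULL) {
  lipo_variant <- match.arg(lipo_variant)
  stopifnot(delta_elec > 0, delta_vdw > 0, gamma_vdw > 0,
            polar_charge_threshold > 0, polar_contact_pad > 0,
            polar_burial_ratio > 0, entropy_burial_fraction > 0,
            abs(lipo_charge_window[1] + lipo_charge_window[2]) < 1e-12)
  structure(list(coulomb_constant = coulomb_constant,
                 delta_elec = delta_elec, delta_vdw = delta_vdw,
                 gamma_vdw = gamma_vdw, lipo_variant = lipo_variant,
                 lipo_charge_window = lipo_charge_window,
                 polar_charge_threshold = polar_charge_threshold,
                 polar_contact_pad = polar_contact_pad,
                 polar_burial_ratio = polar_burial_ratio,
                 polar_opposite_sign_only = polar_opposite_sign_only,
                 np_slope = np_slope, np_intercept = np_intercept,
                 entropy_burial_fraction = entropy_burial_fraction,
                 entropy_include_hydrogens = entropy_include_hydrogens,
                 amide_exclusion = amide_exclusion,
                 probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 include_hydrogens_in_sas = include_hydrogens_in_sas,
                 cutoff = cutoff),
            class = "term_config")
}

## Intermolecular pairwise distance matrix: receptor rows, ligand columns.
pair_distances <- function(cmplx) {
  xr <- coords_of(cmplx$receptor)
  xl <- coords_of(cmplx$ligand)
  d2 <- outer(rowSums(xr^2), rowSums(xl^2), "+") - 2 * xr %*% t(xl)
  sqrt(pmax(d2, 0))
}

#' Screened Coulomb interaction energy
#'
#' Sum over all intermolecular atom pairs of
#' `332.0716 q_i q_j / (eps(R_ij) * (R_ij + delta_elec))` in kcal/mol, with
#' `eps` a [dielectric_model()].  No distance cutoff unless configured.
#'
#' @param cmplx a parameterized `plcomplex`.
#' @param model a [dielectric_model()].
#' @param cfg a [term_config()].
#' @return energy in kcal/mol.
#' @export
coulomb_term <- function(cmplx, model = dielectric_model(),
                         cfg = term_config()) {
  require_parameterized(cmplx)
  q_r <- cmplx$receptor$atoms$partial_charge
  q_l <- cmplx$ligand$atoms$partial_charge
  if (any(!is.finite(c(q_r, q_l)))) stop("unparameterized partial charges")
  R <- pair_distances(cmplx)
  qq <- outer(q_r, q_l)
  eps <- dielectric_constant(as.vector(R), model)
  e <- cfg$coulomb_constant * as.vector(qq) / (eps * (as.vector(R) + cfg$delta_elec))
  if (!is.null(cfg$cutoff)) e[as.vector(R) > cfg$cutoff] <- 0
  sum(e)
}

## Buffered 14-7 pair energy; vectorized over R for fixed eps_ij, rstar_ij.
buf147_pair <- function(R, eps_ij, rstar_ij, delta, gamma) {
  f1 <- ((1 + delta) * rstar_ij / (R + delta * rstar_ij))^7
  f2 <- (1 + gamma) * rstar_ij^7 / (R^7 + gamma * rstar_ij^7) - 2
  eps_ij * f1 * f2
}

#' Buffered 14-7 van der Waals interaction energy
#'
#' Sum over intermolecular pairs of the MMFF-style buffered 14-7 potential
#' `eps_ij ((1+d)R*/(R+dR*))^7 ((1+g)R*^7/(R^7+gR*^7) - 2)` with buffering
#' constants `d = delta_vdw` and `g = gamma_vdw`.  Pair parameters come from
#' the backend's combination rules: geometric mean for the well depth,
#' arithmetic mean for the minimum-energy separation.  The pair minimum is
#' exactly `-eps_ij` at `R = R*_ij` for any `delta_vdw`.
#'
#' @inheritParams coulomb_term
#' @return energy in kcal/mol.
#' @export
vdw_term <- function(cmplx, cfg = term_config()) {
  require_parameterized(cmplx)
  ar <- cmplx$receptor$atoms; al <- cmplx$ligand$atoms
  if (any(!is.finite(c(ar$eps, al$eps, ar$rmin, al$rmin))))
    stop("missing vdW pair parameters; run assign_parameters")
  R <- pair_distances(cmplx)
  eps_ij <- sqrt(outer(ar$eps, al$eps))
  rstar_ij <- outer(ar$rmin, al$rmin, function(a, b) (a + b) / 2)
  e <- buf147_pair(R, eps_ij, rstar_ij, cfg$delta_vdw, cfg$gamma_vdw)
  if (!is.null(cfg$cutoff)) e[R > cfg$cutoff] <- 0
  sum(e)
}

## Piecewise lipophilic contact weight; vectorized.
lipo_contact <- function(d, dvdw) {
  w <- numeric(length(d))
  b1 <- d <= dvdw + 0.5
  b2 <- !b1 & d <= dvdw + 3.5
  w[b1] <- 1
  w[b2] <- pmax(0, 1 - (d[b2] - dvdw[b2] - 0.5) / 3)
  w
}

#' Lipophilic contact descriptor
#'
#' Counts (with a linear switch-off) intermolecular contacts between
#' hydrophobic atoms: weight 1 up to `d_vdW + 0.5` Angstrom, decaying
#' linearly to 0 at `d_vdW + 3.5`, where `d_vdW` is the sum of the two
#' contact radii.  Eligibility depends on `cfg$lipo_variant`: either both
#' atoms are carbons, or both are non-hydrogen atoms with partial charge in
#' the window (-0.4, +0.4) e.  Hydrogens are never eligible.
#'
#' @inheritParams coulomb_term
#' @return dimensionless contact sum, `>= 0`.
#' @export
lipophilic_term <- function(cmplx, cfg = term_config()) {
  require_parameterized(cmplx)
  ar <- cmplx$receptor$atoms; al <- cmplx$ligand$atoms
  elig <- function(a) {
    if (cfg$lipo_variant == "carbons") {
      a$element == "C"
    } else {
      w <- cfg$lipo_charge_window
      !a$is_h & a$partial_charge > w[1] & a$partial_charge < w[2]
    }
  }
  er <- which(elig(ar)); el <- which(elig(al))
  if (length(er) == 0L || length(el) == 0L) return(0)
  R <- pair_distances(cmplx)[er, el, drop = FALSE]
  dvdw <- outer(ar$radius[er], al$radius[el], "+")
  w <- lipo_contact(as.vector(R), as.vector(dvdw))
  if (!is.null(cfg$cutoff)) w[as.vector(R) > cfg$cutoff] <- 0
  sum(w)
}

## Per-atom free and bound SAS for the whole complex, computed once and
## shared by the solvation and entropy terms.
complex_sas <- function(cmplx, cfg) {
  list(
    rec_free = solvent_accessible_areas(cmplx$receptor, cfg$probe_radius,
                                        cfg$n_sphere_points,
                                        cfg$include_hydrogens_in_sas),
    lig_free = solvent_accessible_areas(cmplx$ligand, cfg$probe_radius,
                                        cfg$n_sphere_points,
                                        cfg$include_hydrogens_in_sas),
    bound = solvent_accessible_areas(list(cmplx$receptor, cmplx$ligand),
                                     cfg$probe_radius, cfg$n_sphere_points,
                                     cfg$include_hydrogens_in_sas)
  )
}

#' Polar solvation descriptor (buried-charge count)
#'
#' Counts charged atoms (non-hydrogen, non-carbon, `|q| > 0.8` e, in either
#' molecule) that (a) become buried upon binding -- bound-state SAS at or
#' below `polar_burial_ratio` of the free-state SAS -- and (b) are not
#' interacting with any other charged atom in the complex, i.e. have no
#' charged atom (covalent neighbors excluded) within `d_vdW + 1.0` Angstrom.
#' Each such desolvated, unpaired charge is an unfavorable contribution.
#'
#' @inheritParams coulomb_term
#' @param sas optional precomputed result of the internal SAS evaluation
#'   (used by [compute_descriptors()] to share work).
#' @return integer count, `>= 0`.
#' @export
polar_solvation_term <- function(cmplx, cfg = term_config(), sas = NULL) {
  require_parameterized(cmplx)
  if (is.null(sas)) sas <- complex_sas(cmplx, cfg)
  ar <- cmplx$receptor$atoms; al <- cmplx$ligand$atoms
  nr <- nrow(ar)
  atoms <- rbind(ar, al)
  mol_id <- rep(c(1L, 2L), c(nr, nrow(al)))
  charged <- !atoms$is_h & atoms$element != "C" &
    abs(atoms$partial_charge) > cfg$polar_charge_threshold
  if (!any(charged)) return(0L)
  free_area <- c(sas$rec_free$per_atom_area, sas$lig_free$per_atom_area)
  bound_area <- sas$bound$per_atom_area
  # covalent neighbor pairs (within each molecule), excluded from clause (b)
  bond_key <- c(paste(cmplx$receptor$bonds$i, cmplx$receptor$bonds$j),
                paste(cmplx$ligand$bonds$i + nr, cmplx$ligand$bonds$j + nr))
  xyz <- rbind(coords_of(cmplx$receptor), coords_of(cmplx$ligand))
  idx <- which(charged)
  count <- 0L
  for (a in idx) {
    fa <- free_area[a]
    buried <- if (fa < 0.5) TRUE else bound_area[a] <= cfg$polar_burial_ratio * fa
    if (!buried) next
    partners <- setdiff(idx, a)
    if (cfg$polar_opposite_sign_only)
      partners <- partners[sign(atoms$partial_charge[partners]) !=
                             sign(atoms$partial_charge[a])]
    interacting <- FALSE
    for (b in partners) {
      if (mol_id[a] == mol_id[b]) {
        k <- paste(min(a, b), max(a, b))
        if (k %in% bond_key) next
      }
      d <- sqrt(sum((xyz[a, ] - xyz[b, ])^2))
      if (d <= atoms$radius[a] + atoms$radius[b] + cfg$polar_contact_pad) {
        interacting <- TRUE
        break
      }
    }
    if (!interacting) count <- count + 1L
  }
  count
}

#' Nonpolar solvation descriptor
#'
#' Converts the total loss of solvent-accessible surface area upon binding
#' into energy: `E = G_np(SAS_complex) - G_np(SAS_receptor) -
#' G_np(SAS_ligand)` with `G_np(S) = 0.0092 S + 0.82` kcal/mol and free-state
#' areas computed for each molecule alone.  For separated molecules the areas
#' cancel and the constant offset leaves `-0.82` kcal/mol.
#'
#' @inheritParams polar_solvation_term
#' @return energy in kcal/mol.
#' @export
nonpolar_solvation_term <- function(cmplx, cfg = term_config(), sas = NULL) {
  if (is.null(sas)) sas <- complex_sas(cmplx, cfg)
  g <- function(s) cfg$np_slope * s + cfg$np_intercept
  g(sas$bound$total_area) - g(sas$rec_free$total_area) -
    g(sas$lig_free$total_area)
}

#' Merged solvation descriptor ("oneSolv")
#'
#' Same functional form as [nonpolar_solvation_term()] but with the SAS
#' restricted to heavy atoms (polar and nonpolar alike).  Used by the
#' PPI-inhibitor-specific model in place of the two separate solvation terms.
#'
#' @inheritParams coulomb_term
#' @return energy in kcal/mol.
#' @export
one_solv_term <- function(cmplx, cfg = term_config()) {
  cfg2 <- cfg
  cfg2$include_hydrogens_in_sas <- FALSE
  sas <- complex_sas(cmplx, cfg2)
  nonpolar_solvation_term(cmplx, cfg2, sas = sas)
}

#' Ligand torsional entropy descriptor (frozen rotatable bonds)
#'
#' For each rotatable bond (i, j) of the ligand, the two flanking sides are
#' `side_i = {i} + neighbors(i) \ {j}` and `side_j = {j} + neighbors(j) \
#' {i}` (hydrogens bonded to side atoms included by default).  A side's SAS
#' loss fraction is computed from the ligand alone versus the complex; the
#' bond is frozen when both fractions are `>= 0.5`.  The descriptor is the
#' raw count of frozen bonds -- an entropic penalty scaled later by the
#' regression coefficient.
#'
#' @inheritParams polar_solvation_term
#' @return integer count in `[0, n_rotatable]`.
#' @export
torsional_entropy_term <- function(cmplx, cfg = term_config(), sas = NULL) {
  lig <- cmplx$ligand
  rot <- detect_rotatable_bonds(lig, amide_exclusion = cfg$amide_exclusion)
  if (nrow(rot) == 0L) return(0L)
  if (is.null(sas)) sas <- complex_sas(cmplx, cfg)
  lig_free <- sas$lig_free$per_atom_area
  offset <- n_atoms(cmplx$receptor)
  lig_bound <- sas$bound$per_atom_area[offset + seq_len(n_atoms(lig))]
  adj <- adjacency_list(lig)
  side_atoms <- function(root, other) {
    s <- c(root, setdiff(adj[[root]], other))
    if (cfg$entropy_include_hydrogens) {
      hs <- unlist(lapply(s, function(a) adj[[a]][lig$atoms$is_h[adj[[a]]]]))
      s <- union(s, hs)
    } else {
      s <- s[!lig$atoms$is_h[s]]
    }
    s
  }
  frac_lost <- function(s) {
    free <- sum(lig_free[s])
    if (free < 0.5) return(1)
    (free - sum(lig_bound[s])) / free
  }
  frozen <- 0L
  for (k in seq_len(nrow(rot))) {
    i <- rot$i[k]; j <- rot$j[k]
    fi <- frac_lost(side_atoms(i, j))
    fj <- frac_lost(side_atoms(j, i))
    if (fi >= cfg$entropy_burial_fraction && fj >= cfg$entropy_burial_fraction)
      frozen <- frozen + 1L
  }
  frozen
}

#' Compute the full descriptor vector of a complex
#'
#' Evaluates all interaction descriptors on one parameterized complex, with
#' the SAS evaluation shared across the solvation and entropy terms.  The
#' default configuration is the published basic-function pairing: Coulomb
#' with the Ramstein-Lavery dielectric (`D_i = 4`) plus the softened buffered
#' 14-7 van der Waals (`delta_vdw = 0.67`).
#'
#' @param cmplx a parameterized `plcomplex`.
#' @param cfg a [term_config()].
#' @param model a [dielectric_model()].
#' @param solvation `"two_terms"` (default: separate polar count and nonpolar
#'   energy) or `"one_solv"` (merged heavy-atom delta-SAS term, the
#'   PPI-model layout).
#' @return a named numeric vector of class `descriptor_vector` with elements
#'   `E_coul`, `E_vdW`, `E_lipo`, `E_entropy`, and either `E_polar_solv` and
#'   `E_np_solv` or `oneSolv`.
#' @export
compute_descriptors <- function(cmplx, cfg = term_config(),
                                model = dielectric_model(),
                                solvation = c("two_terms", "one_solv")) {
  solvation <- match.arg(solvation)
  require_parameterized(cmplx)
  sas <- complex_sas(cmplx, cfg)
  base <- c(E_coul = coulomb_term(cmplx, model, cfg),
            E_vdW = vdw_term(cmplx, cfg),
            E_lipo = lipophilic_term(cmplx, cfg),
            E_entropy = as.numeric(torsional_entropy_term(cmplx, cfg, sas)))
  out <- if (solvation == "two_terms") {
    c(base,
      E_polar_solv = as.numeric(polar_solvation_term(cmplx, cfg, sas)),
      E_np_solv = nonpolar_solvation_term(cmplx, cfg, sas))
  } else {
    c(base, oneSolv = one_solv_term(cmplx, cfg))
  }
  structure(out, class = c("descriptor_vector", "numeric"))
}

#' @export
print.descriptor_vector <- function(x, ...) {
  cat("<descriptor_vector>\n")
  print(unclass(x), ...)
  invisible(x)
}
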