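## Molecular data model and structure file I/O.
##
## A molecule is a light S3 object ("plmol") holding an atom table and a bond
## table, in the spirit of bio3d's `pdb` object: plain data frames that users
## can inspect and subset.  All coordinates are in Angstrom, charges in
## elementary charge units, energies downstream in kcal/mol.

BOND_SINGLE   <- 1L
BOND_DOUBLE   <- 2L
BOND_TRIPLE   <- 3L
BOND_AROMATIC <- 4L

#' Construct a molecule
#'
#' Builds a `plmol` object from element symbols, coordinates and an optional
#' bond list.  This is the constructor used by the structure readers and the
#' synthetic fixture generators; most users will obtain molecules through
#' [read_structure()].
#'
#' @param elements character vector of element symbols (e.g. `"C"`, `"Cl"`).
#' @param coords numeric matrix `n x 3` of Cartesian coordinates (Angstrom).
#' @param bonds data frame with integer columns `i`, `j` (1-based atom
#'   indices) and `order` (1 = single, 2 = double, 3 = triple, 4 = aromatic),
#'   or `NULL` for a bondless molecule.
#' @param formal_charges integer vector of per-atom formal charges (recycled).
#' @param partial_charges optional numeric vector of per-atom partial charges
#'   (e.g. read from a MOL2 file); `NA` means "not yet parameterized".
#' @param name molecule name used in file headers and messages.
#' @return an object of class `plmol` with components `atoms` (data frame:
#'   `element`, `x`, `y`, `z`, `formal_charge`, `partial_charge`, `eps`,
#'   `rmin`, `radius`, `is_h`), `bonds` (data frame: `i`, `j`, `order`,
#'   `in_ring`, `rotatable`), `net_charge`, `parameterized` and `name`.
#' @examples
#' m <- pl_molecule(c("C", "O"), rbind(c(0, 0, 0), c(1.2, 0, 0)),
#'                  bonds = data.frame(i = 1L, j = 2L, order = 2L))
#' n_atoms(m)
#' @export
pl_molecule <- function(elements, coords, bonds = NULL, formal_charges = 0L,
                        partial_charges = NULL, name = "mol") {
  elements <- normalize_element(elements)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || nrow(coords) != length(elements))
    stop("coords must be an n x 3 matrix matching length(elements)")
  storage.mode(coords) <- "double"
  if (any(!is.finite(coords)))
    stop("non-finite coordinates")
  n <- length(elements)
  fc <- rep_len(as.integer(formal_charges), n)
  pq <- if (is.null(partial_charges)) rep(NA_real_, n)
        else rep_len(as.numeric(partial_charges), n)
  atoms <- data.frame(
    element = elements,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    formal_charge = fc,
    partial_charge = pq,
    eps = rep(NA_real_, n), rmin = rep(NA_real_, n),
    radius = rep(NA_real_, n),
    is_h = elements == "H",
    stringsAsFactors = FALSE
  )
  bonds <- normalize_bonds(bonds, n)
  mol <- structure(
    list(atoms = atoms, bonds = bonds,
         net_charge = sum(fc), parameterized = FALSE, name = name),
    class = "plmol"
  )
  mol$bonds$in_ring <- ring_bond_flags(mol)
  mol
}

normalize_bonds <- function(bonds, n_atoms) {
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    return(data.frame(i = integer(), j = integer(), order = integer(),
                      in_ring = logical(), rotatable = logical()))
  }
  bonds <- as.data.frame(bonds)
  stopifnot(all(c("i", "j") %in% names(bonds)))
  if (is.null(bonds$order)) bonds$order <- BOND_SINGLE
  b <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                  order = as.integer(bonds$order))
  if (any(b$i == b$j)) stop("self-bond in bond table")
  if (any(b$i < 1L | b$j < 1L | b$i > n_atoms | b$j > n_atoms))
    stop("bond atom index out of range")
  swap <- b$i > b$j
  tmp <- b$i[swap]; b$i[swap] <- b$j[swap]; b$j[swap] <- tmp
  b <- b[!duplicated(b[c("i", "j")]), , drop = FALSE]
  b$in_ring <- FALSE
  b$rotatable <- FALSE
  rownames(b) <- NULL
  b
}

## A bond is in a ring iff it is not a bridge of the bond graph.
ring_bond_flags <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(logical(0))
  g <- igraph::graph_from_edgelist(as.matrix(mol$bonds[, c("i", "j")]),
                                   directed = FALSE)
  bridge_eids <- igraph::bridges(g)
  flags <- rep(TRUE, nb)
  flags[as.integer(bridge_eids)] <- FALSE
  flags
}

#' @export
print.plmol <- function(x, ...) {
  cat(sprintf("<plmol '%s': %d atoms (%d heavy), %d bonds, net charge %+d, %s>\n",
              x$name, n_atoms(x), sum(!x$atoms$is_h), nrow(x$bonds),
              x$net_charge,
              if (x$parameterized) "parameterized" else "unparameterized"))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `plmol` object.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

coords_of <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

## Neighbor (adjacency) list from the bond table, 1-based.
adjacency_list <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

normalize_element <- function(el) {
  el <- trimws(as.character(el))
  bad <- !nzchar(el)
  if (any(bad)) stop("empty element symbol")
  paste0(toupper(substr(el, 1, 1)),
         tolower(substr(el, 2, nchar(el))))
}

#' Validate molecule invariants
#'
#' Checks finiteness of coordinates, bond-table consistency, connectivity
#' (atoms unreachable from the bond graph are reported as isolated fragments,
#' which is allowed), and, for parameterized molecules, that partial charges
#' sum to the net formal charge within `charge_tol`.
#'
#' @param mol a `plmol`.
#' @param charge_tol tolerance on `|sum(q) - net_charge|` in e (default 1e-3).
#' @return `mol`, invisibly; stops on violation.
#' @export
validate_molecule <- function(mol, charge_tol = 1e-3) {
  stopifnot(inherits(mol, "plmol"))
  if (any(!is.finite(as.matrix(mol$atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  if (mol$parameterized) {
    q <- mol$atoms$partial_charge
    if (any(!is.finite(q))) stop("non-finite partial charge")
    if (abs(sum(q) - mol$net_charge) > charge_tol)
      stop(sprintf("partial charges sum to %.6f but net charge is %d",
                   sum(q), mol$net_charge))
    if (any(!is.finite(mol$atoms$radius)) || any(mol$atoms$radius <= 0))
      stop("invalid contact radius")
  }
  invisible(mol)
}

#' Read a molecular structure file
#'
#' Reads a receptor or ligand structure with explicit hydrogens from PDB,
#' SDF (V2000) or MOL2.  Formal charges are taken from the file where the
#' format carries them (`M  CHG` in SDF, charge columns in PDB); MOL2 partial
#' charges are stored but the molecule is still flagged unparameterized until
#' [assign_parameters()] is called.  PDB files without CONECT records get
#' their bond graph inferred from covalent radii.
#'
#' @param path path to the file.
#' @param format one of `"auto"` (from extension), `"pdb"`, `"sdf"`, `"mol2"`.
#' @param strict_hydrogens if `TRUE` (default) a molecule with heavy atoms but
#'   no hydrogens is an error; if `FALSE`, a warning.
#' @return a `plmol`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "sdf", "mol2"),
                           strict_hydrogens = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", sdf = "sdf", sd = "sdf",
                     mol = "sdf", mol2 = "mol2",
                     stop("cannot infer format from extension: ", ext))
  }
  mol <- switch(format,
                pdb = read_pdb(path),
                sdf = read_sdf(path),
                mol2 = read_mol2(path))
  if (n_atoms(mol) == 0L) stop("no atoms parsed from ", path)
  if (any(!mol$atoms$is_h) && !any(mol$atoms$is_h)) {
    msg <- paste0("no explicit hydrogens in ", path,
                  "; descriptors assume fully protonated structures")
    if (strict_hydrogens) stop(msg) else warning(msg)
  }
  validate_molecule(mol)
}

## ---- PDB -------------------------------------------------------------------

read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  at <- lines[rec %in% c("ATOM  ", "HETATM")]
  if (length(at) == 0L) stop("format error: no ATOM/HETATM records in ", path)
  serial <- suppressWarnings(as.integer(substr(at, 7, 11)))
  name <- trimws(substr(at, 13, 16))
  x <- suppressWarnings(as.numeric(substr(at, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(at, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(at, 47, 54)))
  if (any(is.na(x) | is.na(y) | is.na(z)))
    stop("format error: missing or unreadable coordinates in ", path)
  el <- trimws(substr(at, 77, 78))
  miss <- !nzchar(el)
  el[miss] <- element_from_pdb_name(name[miss])
  chg <- trimws(substr(at, 79, 80))
  fc <- integer(length(at))
  has <- grepl("^[0-9][+-]$", chg)
  fc[has] <- as.integer(substr(chg[has], 1, 1)) *
    ifelse(substr(chg[has], 2, 2) == "-", -1L, 1L)
  coords <- cbind(x, y, z)
  bonds <- pdb_conect_bonds(lines, serial)
  mol <- pl_molecule(el, coords, bonds = bonds, formal_charges = fc,
                     name = basename(path))
  if (nrow(mol$bonds) == 0L && n_atoms(mol) > 1L)
    mol <- infer_bonds(mol)
  mol
}

element_from_pdb_name <- function(name) {
  # Atom-name fallback: strip leading digits; two-letter elements only when
  # the second character is lower-case-able into a known symbol.
  nm <- sub("^[0-9']+", "", name)
  two <- toupper(substr(nm, 1, 2))
  known2 <- c("CL", "BR", "NA", "MG", "ZN", "FE", "CA", "MN", "SE")
  el <- ifelse(two %in% known2 & nchar(nm) > 1, two, toupper(substr(nm, 1, 1)))
  normalize_element(el)
}

pdb_conect_bonds <- function(lines, serial) {
  con <- lines[substr(lines, 1, 6) == "CONECT"]
  if (length(con) == 0L) return(NULL)
  idx_of <- seq_along(serial)
  names(idx_of) <- as.character(serial)
  out <- list()
  for (ln in con) {
    flds <- suppressWarnings(as.integer(
      substring(ln, seq(7, 27, by = 5), seq(11, 31, by = 5))))
    flds <- flds[!is.na(flds)]
    if (length(flds) < 2L) next
    a <- idx_of[as.character(flds[1])]
    for (b in idx_of[as.character(flds[-1])]) {
      if (!is.na(a) && !is.na(b))
        out[[length(out) + 1L]] <- c(a, b)
    }
  }
  if (length(out) == 0L) return(NULL)
  m <- do.call(rbind, out)
  data.frame(i = m[, 1], j = m[, 2], order = BOND_SINGLE)
}

## Distance-based bond perception: d <= r_cov(i) + r_cov(j) + 0.45 A,
## excluding H-H contacts. Used for PDB files lacking CONECT records.
infer_bonds <- function(mol, tol = 0.45) {
  xyz <- coords_of(mol)
  el <- mol$atoms$element
  rc <- covalent_radius(el)
  n <- nrow(xyz)
  out <- list()
  for (i in seq_len(n - 1L)) {
    d <- sqrt(colSums((t(xyz[(i + 1L):n, , drop = FALSE]) - xyz[i, ])^2))
    cut <- rc[i] + rc[(i + 1L):n] + tol
    hit <- which(d < cut & d > 0.4)
    for (h in hit) {
      j <- i + h
      if (el[i] == "H" && el[j] == "H") next
      out[[length(out) + 1L]] <- c(i, j)
    }
  }
  if (length(out) > 0L) {
    m <- do.call(rbind, out)
    mol$bonds <- normalize_bonds(
      data.frame(i = m[, 1], j = m[, 2], order = BOND_SINGLE), n)
    mol$bonds$in_ring <- ring_bond_flags(mol)
  }
  mol
}

## ---- SDF (V2000) -----------------------------------------------------------

read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4L) stop("format error: truncated SDF ", path)
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || na < 1L)
    stop("format error: bad counts line in ", path)
  if (length(lines) < 4L + na + nb)
    stop("format error: truncated SDF atom/bond block in ", path)
  at <- lines[5:(4 + na)]
  x <- suppressWarnings(as.numeric(substr(at, 1, 10)))
  y <- suppressWarnings(as.numeric(substr(at, 11, 20)))
  z <- suppressWarnings(as.numeric(substr(at, 21, 30)))
  el <- trimws(substr(at, 32, 34))
  if (any(is.na(x) | is.na(y) | is.na(z)) || any(!nzchar(el)))
    stop("format error: bad atom block in ", path)
  ccode <- suppressWarnings(as.integer(substr(at, 37, 39)))
  ccode[is.na(ccode)] <- 0L
  fc <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
          `5` = -1L, `6` = -2L, `7` = -3L)[as.character(ccode)]
  fc[is.na(fc)] <- 0L
  bonds <- NULL
  if (nb > 0L) {
    bl <- lines[(5 + na):(4 + na + nb)]
    bi <- suppressWarnings(as.integer(substr(bl, 1, 3)))
    bj <- suppressWarnings(as.integer(substr(bl, 4, 6)))
    bo <- suppressWarnings(as.integer(substr(bl, 7, 9)))
    if (any(is.na(bi) | is.na(bj) | is.na(bo)))
      stop("format error: bad bond block in ", path)
    bonds <- data.frame(i = bi, j = bj, order = bo)
  }
  # M  CHG overrides the atom-block charge codes entirely.
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines) > 0L) {
    fc <- rep(0L, na)
    for (ln in chg_lines) {
      flds <- as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]])
      nn <- flds[1]
      for (k in seq_len(nn)) {
        fc[flds[2 * k]] <- flds[2 * k + 1]
      }
    }
  }
  if (all(abs(c(x, y, z)) < 1e-8) && na > 1L)
    stop("input error: SDF has no 3D coordinates (all zero)")
  pl_molecule(el, cbind(x, y, z), bonds = bonds, formal_charges = fc,
              name = if (nzchar(trimws(lines[1]))) trimws(lines[1])
                     else basename(path))
}

#' Write a molecule as SDF (V2000)
#'
#' Minimal V2000 writer used for fixtures and round-trip tests.  Formal
#' charges are emitted as `M  CHG` lines.
#'
#' @param mol a `plmol`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mol, path) {
  n <- n_atoms(mol)
  nb <- nrow(mol$bonds)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(mol$name, "  plscore", ""), con)
  writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb), con)
  a <- mol$atoms
  writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     a$x, a$y, a$z, a$element), con)
  if (nb > 0L)
    writeLines(sprintf("%3d%3d%3d  0  0  0  0",
                       mol$bonds$i, mol$bonds$j, mol$bonds$order), con)
  chg <- which(a$formal_charge != 0L)
  for (start in if (length(chg) > 0L) seq(1, length(chg), by = 8) else integer(0)) {
    idx <- chg[start:min(start + 7, length(chg))]
    writeLines(paste0("M  CHG", sprintf("%3d", length(idx)),
                      paste0(sprintf("%4d%4d", idx, a$formal_charge[idx]),
                             collapse = "")), con)
  }
  writeLines(c("M  END", "$$$$"), con)
  invisible(path)
}

## ---- MOL2 ------------------------------------------------------------------

read_mol2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sec <- which(startsWith(lines, "@<TRIPOS>"))
  if (length(sec) == 0L) stop("format error: no TRIPOS sections in ", path)
  get_section <- function(tag) {
    st <- which(lines == paste0("@<TRIPOS>", tag))
    if (length(st) == 0L) return(character(0))
    st <- st[1]
    en <- sec[sec > st]
    en <- if (length(en) == 0L) length(lines) else en[1] - 1L
    out <- lines[(st + 1L):en]
    out[nzchar(trimws(out))]
  }
  at <- get_section("ATOM")
  if (length(at) == 0L) stop("format error: empty ATOM section in ", path)
  parse_row <- function(ln) strsplit(trimws(ln), "\\s+")[[1]]
  rows <- lapply(at, parse_row)
  if (any(vapply(rows, length, 1L) < 6L))
    stop("format error: bad ATOM row in ", path)
  el <- vapply(rows, function(r) sub("\\..*$", "", r[6]), "")
  xyz <- t(vapply(rows, function(r) as.numeric(r[3:5]), numeric(3)))
  if (any(!is.finite(xyz))) stop("format error: bad coordinates in ", path)
  pq <- vapply(rows, function(r) {
    if (length(r) >= 9) suppressWarnings(as.numeric(r[9])) else NA_real_
  }, 1.0)
  bt <- get_section("BOND")
  bonds <- NULL
  if (length(bt) > 0L) {
    brows <- lapply(bt, parse_row)
    order_of <- function(s) switch(s, "1" = 1L, "2" = 2L, "3" = 3L,
                                   ar = BOND_AROMATIC, am = 1L,
                                   du = 1L, un = 1L, 1L)
    bonds <- data.frame(
      i = vapply(brows, function(r) as.integer(r[2]), 1L),
      j = vapply(brows, function(r) as.integer(r[3]), 1L),
      order = vapply(brows, function(r) order_of(r[4]), 1L))
  }
  mol <- pl_molecule(el, xyz, bonds = bonds,
                     partial_charges = if (all(is.na(pq))) NULL else pq,
                     name = basename(path))
  # MOL2 carries no formal charges; approximate net charge from partials when
  # present so the charge-conservation invariant stays meaningful.
  if (!all(is.na(pq))) mol$net_charge <- as.integer(round(sum(pq)))
  mol
}
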