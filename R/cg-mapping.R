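#' Read an atomic structure from a PDB file
#'
#' Thin wrapper around [bio3d::read.pdb()] returning the atom table used by
#' [build_cg_mapping()].  Residue numbering is kept 1-based as in the file;
#' atomic masses are assigned from the element inferred from the atom name.
#'
#' @param path Path to a PDB file.  Multi-model files are accepted; the atom
#'   table is taken from the first model.
#' @return A tibble with columns `atom` (name), `residue` (integer),
#'   `resname` (3-letter code), `mass` (amu) and `x`, `y`, `z` (Angstrom).
#'   For a multi-model file the additional frames are attached as attribute
#'   `"frames"` (array frames x atoms x 3), retrievable with
#'   [structure_frames()].
#' @export
read_structure_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  atoms <- tibble(
    atom = at$elety,
    residue = as.integer(at$resno),
    resname = at$resid,
    mass = atom_masses(at$elety, at$resid, at$elesy),
    x = at$x, y = at$y, z = at$z
  )
  xyz <- pdb$xyz
  if (is.matrix(xyz) && nrow(xyz) > 1) {
    n <- nrow(atoms)
    frames <- array(NA_real_, c(nrow(xyz), n, 3))
    for (f in seq_len(nrow(xyz))) {
      frames[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    }
    attr(atoms, "frames") <- frames
  }
  atoms
}

#' @rdname read_structure_pdb
#' @param atoms An atom tibble returned by [read_structure_pdb()].
#' @export
structure_frames <- function(atoms) {
  fr <- attr(atoms, "frames")
  if (is.null(fr)) {
    fr <- array(as.matrix(atoms[, c("x", "y", "z")]), c(1, nrow(atoms), 3))
    fr[1, , ] <- as.matrix(atoms[, c("x", "y", "z")])
  }
  fr
}

# atomic masses (amu) for the elements seen in protein structures and
# common bound ions/ligands
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305, CA = 40.078,
  NA. = 22.99, K = 39.098, CL = 35.45, MN = 54.938, CU = 63.546, BR = 79.904,
  I = 126.904, F = 18.998
)

# element of each atom: trust the PDB element column when present; inside a
# standard amino acid fall back to the first letter of the atom name
# (digits stripped); otherwise try the whole name as an element symbol
atom_masses <- function(elety, resname, elesy = NULL) {
  n <- length(elety)
  ele <- rep(NA_character_, n)
  if (!is.null(elesy)) {
    ok <- !is.na(elesy) & nzchar(trimws(elesy))
    ele[ok] <- toupper(trimws(elesy[ok]))
  }
  stripped <- toupper(sub("^[0-9']+", "", elety))
  is_aa <- resname %in% .aa3
  miss <- is.na(ele)
  ele[miss & is_aa] <- substr(stripped[miss & is_aa], 1, 1)
  whole <- stripped %in% names(.element_masses)
  ele[miss & !is_aa & whole] <- stripped[miss & !is_aa & whole]
  ele[is.na(ele)] <- substr(stripped[is.na(ele)], 1, 1)
  ele[ele == "NA"] <- "NA."
  mass <- .element_masses[ele]
  if (anyNA(mass)) {
    bad <- unique(elety[is.na(mass)])
    abort(paste0("cannot assign a mass to atom name(s): ",
                 paste(bad, collapse = ", ")))
  }
  unname(mass)
}

validate_atoms <- function(atoms) {
  need <- c("atom", "residue", "resname", "mass", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    abort(paste0("atom table lacks columns: ", paste(miss, collapse = ", ")))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("atom coordinates must be finite")
  }
  if (!all(atoms$mass > 0)) abort("atom masses must be > 0")
  if (is.unsorted(atoms$residue)) {
    abort("atoms must be ordered by non-decreasing residue index")
  }
  invisible(atoms)
}

#' Coarse-grain an atomic structure into backbone and sidechain sites
#'
#' Builds the two-site-per-residue mapping: each amino acid contributes a
#' backbone site pinned at its Calpha and a sidechain site at the
#' mass-weighted centre of its sidechain atoms; glycine contributes a single
#' site; any residue that is not a standard amino acid (a bound ion, a
#' ligand) contributes one site at its centre of mass.  Site masses are the
#' summed masses of the member atoms and every atom belongs to exactly one
#' site.
#'
#' @param atoms Atom tibble as returned by [read_structure_pdb()] (columns
#'   `atom`, `residue`, `resname`, `mass`, `x`, `y`, `z`).
#' @param backbone_atoms Atom names assigned to the backbone site; defaults
#'   to [backbone_atom_names()].
#' @param sidechain_atoms Which sidechain atoms enter the centroid:
#'   `"all"` (default) uses every non-backbone atom present, `"heavy"`
#'   drops hydrogens.
#' @return A `cg_mapping` tibble with one row per site: `site` (1-based id),
#'   `residue`, `kind` (`"backbone"`, `"sidechain"` or `"ligand"`), `mass`,
#'   and list-column `members` of atom row indices; backbone sites carry the
#'   Calpha row index in `ca_atom`.
#' @export
build_cg_mapping <- function(atoms, backbone_atoms = backbone_atom_names(),
                             sidechain_atoms = c("all", "heavy")) {
  sidechain_atoms <- match.arg(sidechain_atoms)
  validate_atoms(atoms)

  rows <- list()
  for (res in unique(atoms$residue)) {
    idx <- which(atoms$residue == res)
    resname <- atoms$resname[idx[1]]
    ca <- idx[atoms$atom[idx] == "CA"]
    is_aa <- resname %in% .aa3
    # a single-atom residue (a bound ion: its atom may be named CA for
    # calcium) is always a ligand site
    if (!is_aa && length(idx) > 1 && length(ca) > 0) {
      warn(sprintf(
        "residue %d has non-standard name '%s'; partitioning by atom names",
        res, resname
      ))
      is_aa <- TRUE
    }
    if (is_aa) {
      if (length(ca) == 0) {
        abort(sprintf("residue %d (%s) lacks a CA atom", res, resname))
      }
      bb <- idx[atoms$atom[idx] %in% backbone_atoms]
      sc <- setdiff(idx, bb)
      if (sidechain_atoms == "heavy") {
        sc <- sc[!grepl("^[0-9]*H", atoms$atom[sc])]
      }
      if (resname == "GLY" || length(sc) == 0) {
        rows[[length(rows) + 1]] <- list(
          residue = res, kind = "backbone", members = idx, ca_atom = ca[1]
        )
      } else {
        rows[[length(rows) + 1]] <- list(
          residue = res, kind = "backbone", members = bb, ca_atom = ca[1]
        )
        rows[[length(rows) + 1]] <- list(
          residue = res, kind = "sidechain", members = sc, ca_atom = NA_integer_
        )
      }
    } else {
      rows[[length(rows) + 1]] <- list(
        residue = res, kind = "ligand", members = idx, ca_atom = NA_integer_
      )
    }
  }

  mapping <- tibble(
    site = seq_along(rows),
    residue = vapply(rows, function(r) as.integer(r$residue), integer(1)),
    kind = vapply(rows, function(r) r$kind, character(1)),
    mass = vapply(rows, function(r) sum(atoms$mass[r$members]), double(1)),
    members = lapply(rows, function(r) r$members),
    ca_atom = vapply(rows, function(r) as.integer(r$ca_atom), integer(1))
  )
  attr(mapping, "atom_masses") <- atoms$mass
  attr(mapping, "n_atoms") <- nrow(atoms)
  class(mapping) <- c("cg_mapping", class(mapping))
  mapping
}

#' Map atomic coordinates onto coarse-grained sites
#'
#' `map_structure()` maps a single frame; `map_trajectory()` maps a stack of
#' frames into a [cg_trajectory()].  Backbone sites take the Calpha position
#' exactly; sidechain and ligand sites take the mass-weighted centroid of
#' their member atoms.
#'
#' @param coords For `map_structure()`, an atoms x 3 coordinate matrix.  For
#'   `map_trajectory()`, an array frames x atoms x 3 or a list of
#'   atoms x 3 matrices.
#' @param mapping A `cg_mapping` from [build_cg_mapping()].
#' @param times Frame times in ns (strictly increasing); defaults to
#'   0, dt, 2 dt with `dt` = 0.001 ns.
#' @param dt Frame spacing in ns used when `times` is not given.
#' @return `map_structure()`: a sites x 3 matrix.  `map_trajectory()`: a
#'   [cg_trajectory()].
#' @export
map_structure <- function(coords, mapping) {
  masses <- attr(mapping, "atom_masses")
  if (nrow(coords) != attr(mapping, "n_atoms")) {
    abort(sprintf(
      "coordinate frame has %d atoms but mapping expects %d",
      nrow(coords), attr(mapping, "n_atoms")
    ))
  }
  out <- matrix(NA_real_, nrow(mapping), 3)
  for (s in seq_len(nrow(mapping))) {
    if (!is.na(mapping$ca_atom[s])) {
      out[s, ] <- coords[mapping$ca_atom[s], ]
    } else {
      m <- mapping$members[[s]]
      w <- masses[m] / sum(masses[m])
      out[s, ] <- colSums(coords[m, , drop = FALSE] * w)
    }
  }
  out
}

#' @rdname map_structure
#' @export
map_trajectory <- function(coords, mapping, times = NULL, dt = 0.001) {
  if (is.list(coords)) {
    frames <- coords
  } else if (is.array(coords) && length(dim(coords)) == 3) {
    frames <- lapply(seq_len(dim(coords)[1]), function(f) coords[f, , ])
  } else {
    abort("`coords` must be a frames x atoms x 3 array or a list of matrices")
  }
  n_atoms <- attr(mapping, "n_atoms")
  cg <- array(NA_real_, c(length(frames), nrow(mapping), 3))
  for (f in seq_along(frames)) {
    if (nrow(frames[[f]]) != n_atoms) {
      abort(sprintf(
        "frame %d has %d atoms but mapping expects %d",
        f, nrow(frames[[f]]), n_atoms
      ))
    }
    cg[f, , ] <- map_structure(frames[[f]], mapping)
  }
  if (is.null(times)) times <- (seq_along(frames) - 1) * dt
  cg_trajectory(cg, times = times, mapping = mapping)
}

#' @export
print.cg_mapping <- function(x, ...) {
  cat(sprintf(
    "<cg_mapping> %d sites over %d residues (%d backbone, %d sidechain, %d ligand)\n",
    nrow(x), length(unique(x$residue)),
    sum(x$kind == "backbone"), sum(x$kind == "sidechain"),
    sum(x$kind == "ligand")
  ))
  NextMethod()
}
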