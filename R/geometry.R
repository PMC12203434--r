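## Geometry data model: a molecule is an S3 object holding element symbols,
## Cartesian coordinates (Angstrom), optional per-atom partial charges and
## per-atom fragment labels.  Atom order is the canonical index used by every
## downstream module; internally 0-based reasoning never leaks -- R indices
## are 1-based and printed reports use the same 1-based convention.

#' Construct a molecule
#'
#' @param element Character vector of element symbols.
#' @param xyz Numeric matrix, one row per atom, columns x, y, z in Angstrom.
#' @param charge Optional numeric vector of per-atom partial charges
#'   (elementary charge units); defaults to 0 for every atom.
#' @param fragment Optional per-atom fragment labels (character); defaults to
#'   a single fragment `"1"`.
#' @return An object of class `molecule`.
#' @export
#' @examples
#' m <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
#' molecular_mass(m)
molecule <- function(element, xyz, charge = NULL, fragment = NULL) {
  element <- as.character(element)
  if (length(element) < 1L) stop("a molecule needs at least one atom")
  if (is.vector(xyz) && length(xyz) == 3L) xyz <- matrix(xyz, nrow = 1L)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L || nrow(xyz) != length(element)) {
    stop("xyz must be an n x 3 matrix matching the element vector")
  }
  if (!all(is.finite(xyz))) stop("all coordinates must be finite")
  storage.mode(xyz) <- "double"
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  z <- atomic_number(element)  # validates the symbols
  if (is.null(charge)) charge <- numeric(length(element))
  if (length(charge) != length(element)) {
    stop("charge vector length (", length(charge),
         ") does not match atom count (", length(element), ")")
  }
  if (is.null(fragment)) fragment <- rep("1", length(element))
  fragment <- as.character(fragment)
  if (length(fragment) != length(element)) {
    stop("fragment label length (", length(fragment),
         ") does not match atom count (", length(element), ")")
  }
  structure(list(element = element, atomic_number = z, xyz = xyz,
                 charge = as.numeric(charge), fragment = fragment),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule> ", n_atoms(x), " atoms, ",
      length(unique(x$fragment)), " fragment(s)\n", sep = "")
  df <- data.frame(atom = seq_len(n_atoms(x)), element = x$element,
                   x$xyz, charge = x$charge, fragment = x$fragment)
  print(utils::head(df, 12), row.names = FALSE)
  if (n_atoms(x) > 12) cat("  ... (", n_atoms(x) - 12, " more atoms)\n", sep = "")
  invisible(x)
}

#' Number of atoms in a molecule
#' @param m A [molecule()].
#' @return Integer atom count.
#' @export
n_atoms <- function(m) length(m$element)

#' Fragment names of a molecule
#' @param m A [molecule()].
#' @return Character vector of unique fragment labels, in order of first
#'   appearance.
#' @export
fragment_names <- function(m) unique(m$fragment)

fragment_indices <- function(m, frag) {
  idx <- which(m$fragment == as.character(frag))
  if (length(idx) == 0L) {
    stop("fragment '", frag, "' selects no atoms (fragments present: ",
         paste(fragment_names(m), collapse = ", "), ")", call. = FALSE)
  }
  idx
}

#' Extract a fragment as a standalone molecule
#'
#' Coordinates are kept frozen at their in-complex values.
#'
#' @param m A [molecule()].
#' @param frag Fragment label.
#' @return A [molecule()] holding only the selected atoms.
#' @export
subset_fragment <- function(m, frag) {
  idx <- fragment_indices(m, frag)
  molecule(m$element[idx], m$xyz[idx, , drop = FALSE],
           charge = m$charge[idx], fragment = m$fragment[idx])
}

#' Molecular (or fragment) mass
#'
#' Sum of standard atomic weights over the selected atoms.
#'
#' @param m A [molecule()].
#' @param selection `"all"` (default), a fragment label, or an integer vector
#'   of atom indices.  An empty integer selection returns 0.
#' @return Mass in amu.
#' @export
molecular_mass <- function(m, selection = "all") {
  idx <- resolve_selection(m, selection, allow_empty = TRUE)
  if (length(idx) == 0L) return(0)
  sum(atomic_mass(m$element[idx]))
}

resolve_selection <- function(m, selection, allow_empty = FALSE) {
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
    if (length(idx) > 0 && (any(idx < 1L) || any(idx > n_atoms(m)))) {
      stop("atom index out of range 1..", n_atoms(m))
    }
    if (!allow_empty && length(idx) == 0L) stop("empty atom selection")
    return(idx)
  }
  if (identical(selection, "all")) return(seq_len(n_atoms(m)))
  fragment_indices(m, selection)
}

#' Center of mass
#'
#' Mass-weighted mean position of the selected atoms.
#'
#' @inheritParams molecular_mass
#' @return Numeric 3-vector, Angstrom.
#' @export
center_of_mass <- function(m, selection = "all") {
  idx <- resolve_selection(m, selection)
  w <- atomic_mass(m$element[idx])
  drop(w %*% m$xyz[idx, , drop = FALSE]) / sum(w)
}

#' Distance between the centers of mass of two fragments
#'
#' @param m A [molecule()].
#' @param fragA,fragB Fragment labels (or integer index vectors).  The two
#'   selections must be disjoint.
#' @return Euclidean distance, Angstrom.
#' @export
com_distance <- function(m, fragA, fragB) {
  ia <- resolve_selection(m, fragA)
  ib <- resolve_selection(m, fragB)
  if (length(intersect(ia, ib)) > 0L) {
    stop("fragments must be disjoint; atoms ",
         paste(intersect(ia, ib), collapse = ", "), " appear in both")
  }
  sqrt(sum((center_of_mass(m, ia) - center_of_mass(m, ib))^2))
}

#' Interatomic distance matrix
#' @param m A [molecule()].
#' @return Symmetric n x n matrix of distances, Angstrom.
#' @export
distance_matrix <- function(m) {
  as.matrix(stats::dist(m$xyz))
}

#' Atom mapping between two molecules
#'
#' A one-to-one, onto correspondence between the atoms of two structures,
#' required by difference contributions and difference densities.  Mapped
#' atoms must share the same element.
#'
#' @param mA,mB Two [molecule()] objects with equal atom counts.
#' @param pairs Integer vector: `pairs[i]` is the atom of `mB` mapped to atom
#'   `i` of `mA`.  Defaults to the identity mapping.
#' @return An object of class `atom_mapping`.
#' @export
atom_mapping <- function(mA, mB, pairs = seq_len(n_atoms(mA))) {
  if (n_atoms(mA) != n_atoms(mB)) {
    stop("cannot map molecules with different atom counts (",
         n_atoms(mA), " vs ", n_atoms(mB), ")")
  }
  pairs <- as.integer(pairs)
  if (length(pairs) != n_atoms(mA) ||
      !identical(sort(pairs), seq_len(n_atoms(mB)))) {
    stop("pairs must be a permutation of 1..", n_atoms(mB))
  }
  mism <- which(mA$element != mB$element[pairs])
  if (length(mism) > 0L) {
    stop("element mismatch under mapping at atom(s) ",
         paste(mism, collapse = ", "), " (", mA$element[mism[1]], " vs ",
         mB$element[pairs[mism[1]]], ")")
  }
  structure(list(pairs = pairs, n = n_atoms(mA)), class = "atom_mapping")
}

#' Apply a rigid transform to a molecule
#'
#' Utility used mostly in invariance tests: rotates by an orthogonal matrix
#' and then translates.
#'
#' @param m A [molecule()].
#' @param rotation 3 x 3 orthogonal matrix (default identity).
#' @param translation Numeric 3-vector, Angstrom (default zero).
#' @return The transformed [molecule()].
#' @export
transform_molecule <- function(m, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- m$xyz %*% t(rotation)
  xyz <- sweep(xyz, 2L, -as.numeric(translation))
  molecule(m$element, xyz, charge = m$charge, fragment = m$fragment)
}
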