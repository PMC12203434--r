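## Atomic decomposition of the dispersion energy: each atom receives half of
## every pair energy it participates in, so the atomic contributions sum to
## the total by construction.  Fragment contributions, the dimer
## intra/intermolecular split, difference contributions between mapped
## structures, and the delimited interchange format for externally computed
## per-atom values (e.g. wavefunction-based decompositions) live here too.

#' Atomic dispersion contributions
#'
#' Assigns half of each pair dispersion energy to each of its two atoms:
#' \deqn{\varepsilon_A = \tfrac{1}{2} \sum_{B \ne A} E_{AB}}
#' so that \eqn{\sum_A \varepsilon_A = E_{tot}}.
#'
#' @param pairs A `dispersion_result` from [total_dispersion()], or a plain
#'   symmetric pair-energy matrix (kcal/mol, zero diagonal).
#' @param molecule The [molecule()] the matrix refers to; taken from the
#'   `dispersion_result` when available.
#' @param provenance Label recording where the pair energies came from.
#' @return An object of class `atomic_contributions`: list with `eps`
#'   (per-atom kcal/mol), `total`, `molecule`, `provenance`.
#' @export
#' @examples
#' ne2 <- molecule(c("Ne", "Ne"), rbind(c(0, 0, 0), c(0, 0, 3.1)))
#' acs <- atomic_contributions(total_dispersion(ne2))
#' sum(acs$eps) == acs$total
atomic_contributions <- function(pairs, molecule = NULL, provenance = NULL) {
  if (inherits(pairs, "dispersion_result")) {
    if (is.null(molecule)) molecule <- pairs$molecule
    if (is.null(provenance)) provenance <- pairs$engine
    pairs <- pairs$pairs
  }
  pairs <- as.matrix(pairs)
  if (nrow(pairs) != ncol(pairs)) stop("pair matrix must be square")
  if (max(abs(pairs - t(pairs))) > 0) stop("pair matrix must be symmetric")
  if (any(diag(pairs) != 0)) stop("pair matrix must have a zero diagonal")
  if (!all(is.finite(pairs))) stop("pair matrix must be finite")
  if (!is.null(molecule) && n_atoms(molecule) != nrow(pairs)) {
    stop("pair matrix size (", nrow(pairs), ") does not match molecule (",
         n_atoms(molecule), " atoms)")
  }
  eps <- 0.5 * rowSums(pairs)
  new_atomic_contributions(eps, molecule,
                           provenance %||% "matrix")
}

new_atomic_contributions <- function(eps, molecule, provenance) {
  structure(list(eps = as.numeric(eps), total = sum(eps),
                 molecule = molecule, provenance = provenance),
            class = "atomic_contributions")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.atomic_contributions <- function(x, ...) {
  cat("<atomic_contributions> provenance =", x$provenance, "\n")
  cat("  total:", format(x$total, digits = 10), "kcal/mol over",
      length(x$eps), "atoms\n")
  if (!is.null(x$molecule)) {
    df <- data.frame(atom = seq_along(x$eps), element = x$molecule$element,
                     eps_kcalmol = x$eps)
    print(utils::head(df, 12), row.names = FALSE)
    if (length(x$eps) > 12) cat("  ...\n")
  }
  invisible(x)
}

#' Fragment dispersion contributions
#'
#' Sums the atomic contributions over each fragment of the molecule; the
#' fragment sums conserve the total exactly as summed and a residual check
#' value is reported.
#'
#' @param acs An [atomic_contributions()] object.
#' @param m Optional [molecule()] providing fragment labels; defaults to the
#'   molecule stored in `acs`.
#' @return A list of class `fragment_contributions`: `table` (data frame
#'   with `fragment`, `n_atoms`, `eps_kcalmol`), `total`, `residual`
#'   (total minus sum of fragment sums).
#' @export
fragment_contributions <- function(acs, m = acs$molecule) {
  if (is.null(m)) stop("no molecule available for fragment labels")
  if (n_atoms(m) != length(acs$eps)) {
    stop("molecule atom count does not match contributions length")
  }
  frags <- fragment_names(m)
  sums <- vapply(frags, function(f) sum(acs$eps[m$fragment == f]), numeric(1))
  counts <- vapply(frags, function(f) sum(m$fragment == f), integer(1))
  tab <- data.frame(fragment = frags, n_atoms = counts, eps_kcalmol = sums,
                    row.names = NULL)
  structure(list(table = tab, total = acs$total,
                 residual = acs$total - sum(sums)),
            class = "fragment_contributions")
}

#' @export
print.fragment_contributions <- function(x, ...) {
  cat("<fragment_contributions> total:", format(x$total, digits = 10),
      "kcal/mol\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Intra/intermolecular split of a dimer's dispersion energy
#'
#' Decomposes the total dispersion energy of a two-fragment system as
#' \eqn{E_{tot} = E_1 + E_2 + E_{int}}.  Two conventions are offered:
#' \describe{
#'   \item{`"pair-classified"`}{pair energies computed on the full system
#'     are classified by fragment membership: `E1` sums pairs within the
#'     first fragment, `E2` within the second, `E_int` the cross pairs.
#'     The identity `E1 + E2 + E_int = E_tot` is exact by construction
#'     (the reported `E_tot` is that sum).}
#'   \item{`"isolated-monomer"`}{`E1` and `E2` are recomputed on each
#'     monomer alone (coordinates frozen at their in-dimer values), so they
#'     are independent of the separation; `E_int` is the remainder
#'     `E_tot - E1 - E2`.  For an environment-free engine (London) the two
#'     conventions coincide; for the CN engine they differ by the
#'     environment-induced shift of the monomer coordination numbers.}
#' }
#'
#' @param m A [molecule()] with exactly two fragments (or pass `fragA`,
#'   `fragB` explicitly).
#' @param fragA,fragB Fragment labels; default to the molecule's two
#'   fragments in order of appearance.
#' @param engine,preset,charges,scaler Passed to [total_dispersion()].
#' @param convention `"pair-classified"` (default) or `"isolated-monomer"`.
#' @return A list of class `supramolecular_split` with `E1`, `E2`, `E_int`,
#'   `E_tot` (all kcal/mol), `convention`, `fragments`.
#' @export
supramolecular_split <- function(m, fragA = NULL, fragB = NULL,
                                 engine = "cnd", preset = "pbe0",
                                 charges = NULL,
                                 scaler = exponential_charge_scaler(),
                                 convention = c("pair-classified",
                                                "isolated-monomer")) {
  convention <- match.arg(convention)
  frags <- fragment_names(m)
  if (is.null(fragA) || is.null(fragB)) {
    if (length(frags) != 2L) {
      stop("molecule has ", length(frags), " fragment(s); the dimer split ",
           "needs exactly two -- for more fragments, apply the split ",
           "pairwise to each fragment pair of interest")
    }
    fragA <- frags[1]
    fragB <- frags[2]
  }
  ia <- fragment_indices(m, fragA)
  ib <- fragment_indices(m, fragB)
  if (length(intersect(ia, ib)) > 0L) stop("fragments must be disjoint")
  if (length(union(ia, ib)) != n_atoms(m)) {
    stop("fragments '", fragA, "' and '", fragB, "' do not cover all atoms")
  }
  res <- total_dispersion(m, engine = engine, charges = charges,
                          preset = preset, scaler = scaler)
  p <- res$pairs
  if (convention == "pair-classified") {
    E1 <- sum(p[ia, ia][upper.tri(diag(length(ia)))])
    E2 <- sum(p[ib, ib][upper.tri(diag(length(ib)))])
    E_int <- sum(p[ia, ib])
    E_tot <- E1 + E2 + E_int
  } else {
    sub_charges <- function(idx) if (is.null(charges)) NULL else charges[idx]
    E1 <- total_dispersion(subset_fragment(m, fragA), engine = engine,
                           charges = sub_charges(ia), preset = preset,
                           scaler = scaler)$total
    E2 <- total_dispersion(subset_fragment(m, fragB), engine = engine,
                           charges = sub_charges(ib), preset = preset,
                           scaler = scaler)$total
    E_tot <- res$total
    E_int <- E_tot - E1 - E2
  }
  structure(list(E1 = E1, E2 = E2, E_int = E_int, E_tot = E_tot,
                 convention = convention, engine = engine,
                 fragments = c(fragA, fragB)),
            class = "supramolecular_split")
}

#' @export
print.supramolecular_split <- function(x, ...) {
  cat("<supramolecular_split> convention =", x$convention,
      " engine =", x$engine, "\n")
  cat(sprintf("  E1 (%s):  %14.8f kcal/mol\n", x$fragments[1], x$E1))
  cat(sprintf("  E2 (%s):  %14.8f kcal/mol\n", x$fragments[2], x$E2))
  cat(sprintf("  E_int:   %14.8f kcal/mol\n", x$E_int))
  cat(sprintf("  E_tot:   %14.8f kcal/mol\n", x$E_tot))
  invisible(x)
}

#' Difference of atomic contributions between two mapped structures
#'
#' \eqn{\Delta\varepsilon_A = \varepsilon_A(\mathrm{A}) -
#' \varepsilon_{map(A)}(\mathrm{B})} for a one-to-one element-preserving
#' atom mapping; the differences sum to the difference of totals.  Reports
#' are anchored to the coordinates of the first structure by default.
#'
#' @param acsA,acsB [atomic_contributions()] for the two structures.
#' @param mapping An [atom_mapping()]; defaults to the identity mapping
#'   between the two stored molecules.
#' @param anchor `"first"` (default) or `"second"`: which structure's
#'   coordinates downstream visualizations are anchored to.
#' @return A list of class `delta_contributions` with `delta_eps` (indexed
#'   by the atoms of the first structure), `total_delta`, `mapping`,
#'   `anchor_molecule`.
#' @export
delta_contributions <- function(acsA, acsB, mapping = NULL,
                                anchor = c("first", "second")) {
  anchor <- match.arg(anchor)
  if (is.null(mapping)) {
    if (is.null(acsA$molecule) || is.null(acsB$molecule)) {
      stop("no molecules stored; supply an explicit atom_mapping")
    }
    mapping <- atom_mapping(acsA$molecule, acsB$molecule)
  }
  if (mapping$n != length(acsA$eps) || mapping$n != length(acsB$eps)) {
    stop("mapping size does not match contribution sets")
  }
  delta <- acsA$eps - acsB$eps[mapping$pairs]
  anchor_mol <- if (anchor == "first") acsA$molecule else acsB$molecule
  structure(list(delta_eps = delta, total_delta = sum(delta),
                 mapping = mapping, anchor = anchor,
                 anchor_molecule = anchor_mol),
            class = "delta_contributions")
}

#' @export
print.delta_contributions <- function(x, ...) {
  cat("<delta_contributions> anchored to the", x$anchor, "structure\n")
  cat("  total delta:", format(x$total_delta, digits = 10), "kcal/mol over",
      length(x$delta_eps), "mapped atoms\n")
  invisible(x)
}

contrib_columns <- c("index", "element", "x", "y", "z", "eps_kcalmol")

#' Write atomic contributions to the interchange table
#'
#' Comma-separated, UTF-8, period decimal separator, `#`-prefixed comment
#' lines, mandatory header `index,element,x,y,z,eps_kcalmol` (1-based
#' indices, Angstrom, kcal/mol).  The same carrier transports externally
#' computed per-atom dispersion values (e.g. wavefunction-based
#' decompositions) into the visualization tools.
#'
#' @param acs An [atomic_contributions()] with a molecule attached.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contributions <- function(acs, path) {
  m <- acs$molecule
  if (is.null(m)) stop("contribution set has no molecule attached")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("# atomic dispersion contributions, provenance: ", acs$provenance),
    paste0("# total_kcalmol: ", format(acs$total, digits = 17)),
    paste(contrib_columns, collapse = ",")
  ), con)
  writeLines(sprintf("%d,%s,%.10f,%.10f,%.10f,%.12e",
                     seq_along(acs$eps), m$element,
                     m$xyz[, 1], m$xyz[, 2], m$xyz[, 3], acs$eps), con)
  invisible(path)
}

#' Read atomic contributions from the interchange table
#'
#' @param path Path to a table written by [write_contributions()] or by an
#'   external decomposition tool following the same schema.
#' @param molecule Optional reference [molecule()]: elements must match and
#'   coordinates must agree within `tol` Angstrom.
#' @param tol Coordinate cross-check tolerance, Angstrom.
#' @return An [atomic_contributions()] with provenance `"external"` and a
#'   molecule rebuilt from the table (or the supplied reference).
#' @export
read_contributions <- function(path, molecule = NULL, tol = 1e-6) {
  if (!file.exists(path)) stop("contributions table not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(contrib_columns, names(df))
  if (length(missing_cols) > 0L) {
    stop("contributions table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[order(df$index), , drop = FALSE]
  tab_mol <- molecule(df$element, as.matrix(df[, c("x", "y", "z")]))
  if (!is.null(molecule)) {
    if (n_atoms(molecule) != nrow(df)) {
      stop("table has ", nrow(df), " atoms but reference molecule has ",
           n_atoms(molecule))
    }
    if (!identical(molecule$element, df$element)) {
      bad <- which(molecule$element != df$element)[1]
      stop("element mismatch vs reference molecule at atom ", bad, " (",
           df$element[bad], " vs ", molecule$element[bad], ")")
    }
    dev <- max(abs(molecule$xyz - tab_mol$xyz))
    if (dev > tol) {
      stop("coordinates in ", path, " deviate from the reference molecule ",
           "by up to ", format(dev), " Angstrom (tolerance ", tol, ")")
    }
    tab_mol <- molecule
  }
  new_atomic_contributions(df$eps_kcalmol, tab_mol, "external")
}
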