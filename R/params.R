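## Packaged parameter tables: masses, polarizabilities, ionization energies,
## covalent radii, <r4>/<r2> ratios, C6(CN) reference points and BJ damping
## presets.  All live as documented TSV files under inst/extdata/params so
## users can inspect or extend coverage without touching code.

.param_cache <- new.env(parent = emptyenv())

param_path <- function(file) {
  p <- system.file("extdata", "params", file, package = "adld", mustWork = FALSE)
  if (!nzchar(p)) {
    # during development (pkgload) inst/ may still be the source layout
    p <- system.file("inst", "extdata", "params", file, package = "adld",
                     mustWork = FALSE)
  }
  if (!nzchar(p) || !file.exists(p)) {
    stop("packaged parameter file not found: ", file, call. = FALSE)
  }
  p
}

read_param_table <- function(file) {
  utils::read.table(param_path(file), header = TRUE, sep = "\t",
                    comment.char = "#", stringsAsFactors = FALSE)
}

#' Packaged dispersion and element parameter tables
#'
#' Loads (and caches) the parameter tables shipped with the package:
#' standard atomic weights, static dipole polarizabilities (including ionic
#' species such as `Li+`), first ionization energies, covalent radii,
#' \eqn{\langle r^4\rangle/\langle r^2\rangle} expectation ratios, homoatomic
#' C6 reference points against reference coordination numbers, Becke-Johnson
#' damping presets, and the dimensionless constants of the coordination
#' number machinery.  Each file documents its literature source in its
#' header.
#'
#' @return A list with components `masses`, `polarizabilities`,
#'   `ionization_energies`, `covalent_radii`, `r4r2`, `c6_reference`,
#'   `damping_presets` and `constants` (a named numeric vector).
#' @export
#' @examples
#' p <- adld_params()
#' p$masses[p$masses$element == "C", "mass_amu"]
adld_params <- function() {
  if (!is.null(.param_cache$params)) return(.param_cache$params)
  const_tab <- read_param_table("model_constants.tsv")
  params <- list(
    masses = read_param_table("atomic_masses.tsv"),
    polarizabilities = read_param_table("polarizabilities.tsv"),
    ionization_energies = read_param_table("ionization_energies.tsv"),
    covalent_radii = read_param_table("covalent_radii.tsv"),
    r4r2 = read_param_table("r4r2.tsv"),
    c6_reference = read_param_table("c6_reference.tsv"),
    damping_presets = read_param_table("damping_presets.tsv"),
    constants = stats::setNames(const_tab$value, const_tab$name)
  )
  .param_cache$params <- params
  params
}

supported_elements <- function() adld_params()$masses$element

lookup_scalar <- function(table, key_col, value_col, key, what) {
  idx <- match(key, table[[key_col]])
  if (anyNA(idx)) {
    missing <- unique(key[is.na(idx)])
    stop("unsupported ", what, ": ", paste(missing, collapse = ", "),
         " (supported: ", paste(table[[key_col]], collapse = ", "), ")",
         call. = FALSE)
  }
  table[[value_col]][idx]
}

#' Standard atomic mass of an element
#'
#' @param element Character vector of element symbols.
#' @return Numeric vector of standard atomic weights, amu.
#' @export
atomic_mass <- function(element) {
  lookup_scalar(adld_params()$masses, "element", "mass_amu", element, "element")
}

#' Atomic number of an element
#'
#' @param element Character vector of element symbols.
#' @return Integer vector of atomic numbers.
#' @export
atomic_number <- function(element) {
  as.integer(lookup_scalar(adld_params()$masses, "element", "atomic_number",
                           element, "element"))
}

element_from_z <- function(z) {
  tab <- adld_params()$masses
  idx <- match(as.integer(z), tab$atomic_number)
  if (anyNA(idx)) {
    stop("unsupported atomic number: ",
         paste(unique(z[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  tab$element[idx]
}

#' Static dipole polarizability of a species
#'
#' Species are element symbols, optionally with a `+` suffix for monocations
#' (e.g. `"Li+"`).
#'
#' @param species Character vector of species labels.
#' @return Numeric vector of polarizabilities, cubic Angstrom.
#' @export
polarizability <- function(species) {
  lookup_scalar(adld_params()$polarizabilities, "species", "polarizability_A3",
                species, "species")
}

#' First ionization energy of a species
#'
#' @param species Character vector of species labels (see [polarizability()]).
#' @return Numeric vector of ionization energies, eV.
#' @export
ionization_energy <- function(species) {
  lookup_scalar(adld_params()$ionization_energies, "species", "ionization_eV",
                species, "species")
}

covalent_radius <- function(element) {
  lookup_scalar(adld_params()$covalent_radii, "element", "covalent_radius_A",
                element, "element")
}

r4r2_ratio <- function(element) {
  lookup_scalar(adld_params()$r4r2, "element", "r4r2", element, "element")
}

#' Becke-Johnson damping preset
#'
#' @param preset Name of a packaged functional preset (`"pbe0"`, `"b3lyp"`).
#' @return Named list with `s6`, `s8`, `a1`, `a2` (`a2` in bohr).
#' @export
damping_preset <- function(preset = "pbe0") {
  tab <- adld_params()$damping_presets
  idx <- match(tolower(preset), tab$preset)
  if (is.na(idx)) {
    stop("unknown damping preset '", preset, "' (available: ",
         paste(tab$preset, collapse = ", "), ")", call. = FALSE)
  }
  list(s6 = tab$s6[idx], s8 = tab$s8[idx], a1 = tab$a1[idx], a2 = tab$a2_bohr[idx])
}
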