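## Dispersion density: atomic contributions smeared with normalized
## Gaussians onto an axis-aligned uniform grid, for visualization in any
## cube-file viewer.  With the default "normalized" prefactor (alpha/pi)^(3/2)
## each atom's term integrates analytically to its contribution, so the
## field integrates to the total dispersion energy; the alternative "plain"
## prefactor (pi*alpha)^(-3/2) reproduces the scale used in some published
## figures but does not integrate to the total for alpha != 1.

#' Smearing parameters for dispersion densities
#'
#' @param alpha Gaussian exponent, 1/Angstrom^2.  Typical values: 0.5 for
#'   single-structure maps, 0.3 for difference maps.
#' @param spacing Grid spacing, Angstrom.
#' @param padding Padding added around the atomic bounding box, Angstrom.
#' @return A list of class `smearing_params`.
#' @export
smearing_params <- function(alpha = 0.5, spacing = 0.2, padding = 4.0) {
  stopifnot(alpha > 0, spacing > 0, padding >= 0)
  structure(list(alpha = alpha, spacing = spacing, padding = padding),
            class = "smearing_params")
}

#' Construct a scalar field on a uniform grid
#'
#' @param origin Numeric 3-vector, Angstrom.
#' @param spacing Numeric 3-vector of axis steps, Angstrom.
#' @param values 3-dimensional numeric array (x, y, z index order).
#' @return A list of class `scalar_field`.
#' @export
scalar_field <- function(origin, spacing, values) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("values must be a 3-d array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("grid spacings must be positive")
  if (!all(is.finite(values))) stop("field values must be finite")
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 counts = dim(values), values = values),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat("<scalar_field> ", paste(x$counts, collapse = " x "), " points, spacing ",
      paste(format(x$spacing, digits = 4), collapse = "/"), " A\n", sep = "")
  cat("  origin:", paste(format(x$origin, digits = 6), collapse = ", "), "A\n")
  cat("  range:", format(min(x$values), digits = 6), "..",
      format(max(x$values), digits = 6), "\n")
  invisible(x)
}

grid_axes <- function(field) {
  lapply(1:3, function(k) field$origin[k] + field$spacing[k] * (seq_len(field$counts[k]) - 1L))
}

gaussian_field <- function(xyz, weights, p, prefactor) {
  lo <- apply(xyz, 2L, min) - p$padding
  hi <- apply(xyz, 2L, max) + p$padding
  counts <- pmax(2L, as.integer(ceiling((hi - lo) / p$spacing)) + 1L)
  if (prod(counts) > 512^3) {
    stop("requested grid has ", paste(counts, collapse = " x "),
         " points (> 512^3); increase the spacing or reduce the padding")
  }
  ax <- lapply(1:3, function(k) lo[k] + p$spacing * (seq_len(counts[k]) - 1L))
  pref <- switch(prefactor,
                 normalized = (p$alpha / pi)^1.5,
                 plain = (pi * p$alpha)^-1.5,
                 stop("unknown prefactor '", prefactor, "'"))
  vals <- array(0, dim = counts)
  for (a in seq_len(nrow(xyz))) {
    if (weights[a] == 0) next
    gx <- exp(-p$alpha * (ax[[1]] - xyz[a, 1])^2)
    gy <- exp(-p$alpha * (ax[[2]] - xyz[a, 2])^2)
    gz <- exp(-p$alpha * (ax[[3]] - xyz[a, 3])^2)
    vals <- vals + (pref * weights[a]) *
      outer(outer(gx, gy), gz)
  }
  scalar_field(lo, rep(p$spacing, 3L), vals)
}

#' Dispersion density field
#'
#' Superposition of one normalized Gaussian per atom, weighted by the
#' atomic dispersion contributions:
#' \deqn{\rho_{disp}(r) = \left(\frac{\alpha}{\pi}\right)^{3/2}
#'   \sum_A \varepsilon_A e^{-\alpha (r - R_A)^2}}
#' With `prefactor = "normalized"` (default) the analytic integral of each
#' term equals \eqn{\varepsilon_A}, so the field integrates to the total.
#' `prefactor = "plain"` uses \eqn{(\pi\alpha)^{-3/2}} instead, matching the
#' scale of some published figures; it conserves the integral only at
#' \eqn{\alpha = 1}.
#'
#' @param m A [molecule()] (defaults to the one stored in `acs`).
#' @param acs An [atomic_contributions()] matching `m`.
#' @param p A [smearing_params()].
#' @param prefactor `"normalized"` or `"plain"`.
#' @return A [scalar_field()], kcal/mol/Angstrom^3, with the grid covering
#'   the atomic bounding box plus the padding.
#' @export
dispersion_density <- function(acs, m = acs$molecule, p = smearing_params(),
                               prefactor = c("normalized", "plain")) {
  prefactor <- match.arg(prefactor)
  if (is.null(m)) stop("no molecule available")
  if (n_atoms(m) != length(acs$eps)) {
    stop("contribution set length does not match molecule")
  }
  gaussian_field(m$xyz, acs$eps, p, prefactor)
}

#' Dispersion difference density field
#'
#' Same Gaussian superposition as [dispersion_density()], with the mapped
#' per-atom differences as weights, placed at the coordinates of the anchor
#' structure chosen when the differences were built.
#'
#' @param dcs A [delta_contributions()] object.
#' @param anchor Optional [molecule()] overriding the stored anchor.
#' @param p A [smearing_params()]; difference maps conventionally use a
#'   softer exponent (`alpha = 0.3`).
#' @param prefactor See [dispersion_density()].
#' @return A [scalar_field()].
#' @export
delta_density <- function(dcs, anchor = dcs$anchor_molecule,
                          p = smearing_params(alpha = 0.3),
                          prefactor = c("normalized", "plain")) {
  prefactor <- match.arg(prefactor)
  if (is.null(anchor)) stop("no anchor molecule available")
  if (n_atoms(anchor) != length(dcs$delta_eps)) {
    stop("anchor molecule does not match the mapped contribution differences")
  }
  weights <- dcs$delta_eps
  if (identical(dcs$anchor, "second")) {
    ## differences indexed by first-structure atoms; re-anchor onto the
    ## mapped atom order of the second structure
    weights <- weights[order(dcs$mapping$pairs)]
  }
  gaussian_field(anchor$xyz, weights, p, prefactor)
}

#' Trapezoidal integral of a scalar field
#'
#' @param field A [scalar_field()].
#' @return The integral over the grid volume (kcal/mol for dispersion
#'   density fields).
#' @export
integrate_field <- function(field) {
  w <- lapply(1:3, function(k) {
    wk <- rep(1, field$counts[k])
    wk[c(1L, field$counts[k])] <- 0.5
    wk
  })
  w3 <- outer(outer(w[[1]], w[[2]]), w[[3]])
  sum(field$values * w3) * prod(field$spacing)
}

#' Write a Gaussian cube file
#'
#' Standard cube layout: two comment lines; atom count and origin; three
#' axis lines (point count and step vector); one line per atom with atomic
#' number, nuclear charge and position; then values with the z index
#' fastest.  All geometry is converted to bohr on write per the cube
#' convention; values are written as-is.
#'
#' @param field A [scalar_field()] (Angstrom-based).
#' @param m The [molecule()] the field belongs to.
#' @param path Output path.
#' @param comment Character vector of up to two comment lines.
#' @return `path`, invisibly.
#' @export
write_cube <- function(field, m, path, comment = c("dispersion density",
                                                   "generated by adld")) {
  comment <- c(comment, "", "")[1:2]
  b <- BOHR_PER_ANGSTROM
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment, con)
  writeLines(sprintf("%5d %15.10f %15.10f %15.10f", n_atoms(m),
                     field$origin[1] * b, field$origin[2] * b,
                     field$origin[3] * b), con)
  step <- diag(field$spacing * b)
  for (k in 1:3) {
    writeLines(sprintf("%5d %15.10f %15.10f %15.10f", field$counts[k],
                       step[k, 1], step[k, 2], step[k, 3]), con)
  }
  writeLines(sprintf("%5d %15.10f %15.10f %15.10f %15.10f",
                     m$atomic_number, as.numeric(m$atomic_number),
                     m$xyz[, 1] * b, m$xyz[, 2] * b, m$xyz[, 3] * b), con)
  ## z fastest: loop order x (outer), y, z (inner); 6 values per line
  ## column-major flattening of the [z, y, x] permutation runs z fastest,
  ## then y, then x -- the cube value order
  flat <- as.numeric(aperm(field$values, c(3, 2, 1)))
  idx <- seq(1, length(flat), by = 6L)
  lines <- vapply(idx, function(i) {
    paste(sprintf("%16.8E", flat[i:min(i + 5L, length(flat))]), collapse = "")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a Gaussian cube file
#'
#' Accepts axis-aligned orthogonal cubes written in bohr (negative axis
#' counts, which some programs use to flag Angstrom units, are rejected).
#'
#' @param path Path to a cube file.
#' @return A list with `field` (a [scalar_field()], Angstrom) and
#'   `molecule` (a [molecule()]).
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop("cube file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7L) stop("malformed cube file (too short): ", path)
  b <- BOHR_PER_ANGSTROM
  head_fields <- function(line) as.numeric(strsplit(trimws(line), "[[:space:]]+")[[1]])
  hdr <- head_fields(lines[3])
  natoms <- as.integer(hdr[1])
  if (is.na(natoms) || natoms < 1L) stop("malformed cube header: ", lines[3])
  origin <- hdr[2:4] / b
  counts <- integer(3)
  spacing <- numeric(3)
  for (k in 1:3) {
    ax <- head_fields(lines[3L + k])
    counts[k] <- as.integer(ax[1])
    if (is.na(counts[k]) || counts[k] < 1L) {
      stop("cube axis ", k, " has a non-positive point count")
    }
    step <- ax[2:4] / b
    if (any(abs(step[-k]) > 1e-12)) {
      stop("only axis-aligned orthogonal cube grids are supported")
    }
    spacing[k] <- step[k]
  }
  atom_lines <- lines[7:(6L + natoms)]
  af <- t(vapply(atom_lines, head_fields, numeric(5)))
  mol <- molecule(element_from_z(af[, 1]), af[, 3:5] / b)
  val_lines <- lines[-(1:(6L + natoms))]
  flat <- as.numeric(unlist(strsplit(trimws(val_lines), "[[:space:]]+")))
  flat <- flat[!is.na(flat)]
  if (length(flat) != prod(counts)) {
    stop("cube value count ", length(flat), " does not match grid ",
         paste(counts, collapse = " x "))
  }
  vals <- aperm(array(flat, dim = rev(counts)), c(3, 2, 1))
  list(field = scalar_field(origin, spacing, vals), molecule = mol)
}
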