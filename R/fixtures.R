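## Deterministic synthetic geometry generators.  Every generator that uses
## randomness takes an explicit integer seed and restores the caller's RNG
## state, so the same spec + seed is bitwise reproducible.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Regular ring of atoms
#'
#' A regular n-gon in the xy plane, centered at the origin -- the scaffold
#' for benzene-like rings.
#'
#' @param n Number of atoms (>= 2).
#' @param element Element symbol.
#' @param radius Circumradius, Angstrom.
#' @return A [molecule()].
#' @export
#' @examples
#' ring <- make_ring(6, "C", 1.39)  # benzene-like carbon skeleton
make_ring <- function(n, element = "C", radius = 1.39) {
  n <- as.integer(n)
  if (n < 2L) stop("a ring needs at least 2 atoms (got ", n, ")")
  stopifnot(radius > 0)
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  molecule(rep(element, n),
           cbind(radius * cos(theta), radius * sin(theta), 0))
}

#' Linear chain of atoms
#'
#' Evenly spaced atoms along the z axis, centered at the origin.
#'
#' @param n Number of atoms (>= 1).
#' @param element Element symbol.
#' @param spacing Nearest-neighbour distance, Angstrom.
#' @return A [molecule()].
#' @export
make_chain <- function(n, element = "C", spacing = 1.5) {
  n <- as.integer(n)
  stopifnot(n >= 1L, spacing > 0)
  z <- spacing * (seq_len(n) - (n + 1) / 2)
  molecule(rep(element, n), cbind(0, 0, z))
}

#' Spherical shell of atoms
#'
#' Atoms quasi-uniformly distributed on a sphere by the Fibonacci (golden
#' angle) construction.  With `radius = NULL` the radius grows as the cube
#' root of the atom count (constant volume density), which keeps the spread
#' of pair distances bounded across a family of increasing size -- the
#' "compact cluster" family used by [compact_cluster_check()].
#'
#' @param n Number of atoms (>= 2).
#' @param element Element symbol.
#' @param radius Shell radius, Angstrom, or `NULL` for
#'   `2.0 * (n / 12)^(1/3)`.
#' @return A [molecule()].
#' @export
make_shell <- function(n, element = "C", radius = NULL) {
  n <- as.integer(n)
  if (n < 2L) stop("a shell needs at least 2 atoms (got ", n, ")")
  if (is.null(radius)) radius <- 2.0 * (n / 12)^(1 / 3)
  stopifnot(radius > 0)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  molecule(rep(element, n),
           radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta),
                          cos(phi)))
}

#' Regular simplex of atoms
#'
#' All pairwise distances equal: a bond (n = 2), equilateral triangle
#' (n = 3) or regular tetrahedron (n = 4).  The closed-form fixture for the
#' compactness argument.
#'
#' @param n Number of atoms, 2..4.
#' @param element Element symbol.
#' @param edge Common pair distance, Angstrom.
#' @return A [molecule()].
#' @export
make_simplex <- function(n, element = "C", edge = 2.0) {
  n <- as.integer(n)
  if (n < 2L || n > 4L) stop("a 3-d regular simplex needs 2 to 4 atoms")
  stopifnot(edge > 0)
  xyz <- switch(n - 1L,
    rbind(c(0, 0, 0), c(1, 0, 0)),
    rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
    rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
          c(0.5, sqrt(3) / 6, sqrt(6) / 3))
  )
  molecule(rep(element, n), xyz * edge)
}

#' Assemble a dimer from a monomer
#'
#' Places two copies of the monomer with their centers of mass separated by
#' `R` along the given axis; atoms of the first copy get fragment label
#' `"A"`, the second `"B"`.  A second monomer may be supplied for
#' hetero-dimers.
#'
#' @param monomer A [molecule()].
#' @param R Center-of-mass separation, Angstrom (> 0).
#' @param axis Direction of the displacement (need not be normalized).
#' @param monomer2 Optional second [molecule()] (defaults to `monomer`).
#' @return A two-fragment [molecule()].
#' @export
#' @examples
#' d <- make_dimer(make_ring(6, "C", 1.39), R = 6)
#' com_distance(d, "A", "B")  # 6
make_dimer <- function(monomer, R, axis = c(0, 0, 1), monomer2 = monomer) {
  if (!is.numeric(R) || R <= 0) stop("dimer separation R must be positive")
  axis <- as.numeric(axis)
  if (sum(axis^2) == 0) stop("axis must be a nonzero vector")
  axis <- axis / sqrt(sum(axis^2))
  center <- function(m) transform_molecule(m, translation = -center_of_mass(m))
  a <- center(monomer)
  b <- transform_molecule(center(monomer2), translation = R * axis)
  molecule(c(a$element, b$element), rbind(a$xyz, b$xyz),
           charge = c(a$charge, b$charge),
           fragment = c(rep("A", n_atoms(a)), rep("B", n_atoms(b))))
}

#' Random compact cluster
#'
#' Rejection-samples `n` points uniformly in a cubic box subject to a
#' minimum pair distance.  Deterministic under the seed; fails explicitly
#' (rather than looping forever) when the packing is infeasible.
#'
#' @param n Number of atoms.
#' @param element Element symbol.
#' @param min_dist Minimum allowed pair distance, Angstrom.
#' @param box Edge length of the sampling cube, Angstrom.
#' @param seed Integer seed.
#' @param max_attempts Attempt budget per atom before giving up.
#' @return A [molecule()].
#' @export
make_cluster <- function(n, element = "C", min_dist = 1.5, box = NULL,
                         seed = 1, max_attempts = 2000L) {
  n <- as.integer(n)
  stopifnot(n >= 1L, min_dist > 0)
  if (is.null(box)) box <- max(4, 2.2 * min_dist * n^(1 / 3))
  with_seed(seed, {
    xyz <- matrix(NA_real_, n, 3)
    xyz[1, ] <- stats::runif(3, 0, box)
    for (a in seq_len(n)[-1]) {
      placed <- FALSE
      for (attempt in seq_len(max_attempts)) {
        cand <- stats::runif(3, 0, box)
        d2 <- rowSums(sweep(xyz[seq_len(a - 1L), , drop = FALSE], 2, cand)^2)
        if (min(d2) >= min_dist^2) {
          xyz[a, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place atom ", a, " of ", n, " after ", max_attempts,
             " attempts: box ", format(box), " A is too small for ",
             "min_dist ", format(min_dist), " A")
      }
    }
    molecule(rep(element, n), xyz)
  })
}

#' Synthetic dimer benchmark for the mass-scaling analysis
#'
#' Eight dimers built from constant-density carbon shells: five homodimers
#' of increasing monomer size (equal masses, narrowly varying separation)
#' and three strongly mass-asymmetric hetero-dimers whose monomer masses
#' differ by at least a factor of 3.  This emulates the structure of a
#' dimer study in which equal-mass pairs follow the gravitational-like
#' M1*M2/R law while heteromass pairs break it but still follow the
#' generalized M1^2 + M2^2 law.
#'
#' @param seed Integer seed (reserved for future randomized variants; the
#'   default benchmark is fully deterministic).
#' @return A list of 8 entries, each a list with `molecule` (two-fragment),
#'   `fragA`, `fragB`, `label` and the logical `equal_mass`.
#' @export
make_dimer_benchmark <- function(seed = 1) {
  sizes_eq <- c(6L, 8L, 10L, 12L, 14L)
  r_eq <- c(6.0, 6.25, 6.5, 6.75, 7.0)
  sizes_het <- list(c(14L, 4L), c(12L, 3L), c(16L, 4L))
  r_het <- c(6.4, 6.6, 6.8)
  out <- list()
  for (k in seq_along(sizes_eq)) {
    mono <- make_shell(sizes_eq[k], "C")
    out[[length(out) + 1L]] <- list(
      molecule = make_dimer(mono, r_eq[k]),
      fragA = "A", fragB = "B",
      label = sprintf("homo_C%d", sizes_eq[k]),
      equal_mass = TRUE
    )
  }
  for (k in seq_along(sizes_het)) {
    nn <- sizes_het[[k]]
    m1 <- make_shell(nn[1], "C")
    m2 <- if (nn[2] >= 2L) make_shell(nn[2], "C") else molecule("C", c(0, 0, 0))
    out[[length(out) + 1L]] <- list(
      molecule = make_dimer(m1, r_het[k], monomer2 = m2),
      fragA = "A", fragB = "B",
      label = sprintf("hetero_C%d_C%d", nn[1], nn[2]),
      equal_mass = FALSE
    )
  }
  out
}
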