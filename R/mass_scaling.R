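## Mass-scaling analysis of dimer dispersion energies.
##
## For a set of dimers the total dispersion energy is regressed on mass
## predictors: the gravitational-like law E_tot ~ M1*M2/R, the generalized
## law E_tot = beta (M1^2 + M2^2) + gamma (whose intercept absorbs the
## average intermolecular contribution), the intramolecular diagnostic
## (E1 + E2) ~ M1*M2, the non-correlation diagnostic E_int ~ M1*M2/R and
## the linear-regime diagnostic E_tot ~ M1 + M2.  When the two monomers
## have equal masses M1^2 + M2^2 = 2 M1 M2, so at a common separation the
## two laws coincide up to a factor -- heteromass dimers are what tells
## them apart.

#' Build dimer records for the mass-scaling analysis
#'
#' For each dimer the intra/intermolecular split, the monomer masses and
#' the center-of-mass separation are collected into one record.
#'
#' @param dimers A list; each element is either a two-fragment [molecule()]
#'   or a list with components `molecule` (and optionally `fragA`, `fragB`,
#'   `label`).
#' @param engine,preset Passed to [supramolecular_split()].
#' @param convention Split convention (default `"pair-classified"`).
#' @return A data frame of class `dimer_records` with columns `label`,
#'   `E_tot`, `E1`, `E2`, `E_int` (kcal/mol), `M1`, `M2` (amu), `R`
#'   (Angstrom).
#' @export
build_records <- function(dimers, engine = "cnd", preset = "pbe0",
                          convention = "pair-classified") {
  rows <- lapply(seq_along(dimers), function(i) {
    d <- dimers[[i]]
    if (inherits(d, "molecule")) d <- list(molecule = d)
    m <- d$molecule
    frags <- fragment_names(m)
    fragA <- d$fragA %||% frags[1]
    fragB <- d$fragB %||% frags[2]
    if (length(frags) != 2L && (is.null(d$fragA) || is.null(d$fragB))) {
      stop("dimer ", i, " does not have exactly two fragments")
    }
    sp <- supramolecular_split(m, fragA, fragB, engine = engine,
                               preset = preset, convention = convention)
    data.frame(
      label = d$label %||% paste0("dimer", i),
      E_tot = sp$E_tot, E1 = sp$E1, E2 = sp$E2, E_int = sp$E_int,
      M1 = molecular_mass(m, fragA), M2 = molecular_mass(m, fragB),
      R = com_distance(m, fragA, fragB),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dimer_records", class(out))
  out
}

#' Read / write dimer record tables
#'
#' CSV with header `label,E_tot,E1,E2,E_int,M1,M2,R` and `#` comments.
#'
#' @param path File path.
#' @return For `read_records`, a `dimer_records` data frame.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("records table not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("label", "E_tot", "E1", "E2", "E_int", "M1", "M2", "R")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("records table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[, need]
  class(df) <- c("dimer_records", class(df))
  df
}

#' @rdname read_records
#' @param records A `dimer_records` data frame.
#' @export
write_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

ols_fit <- function(x, y, predictor, intercept = TRUE) {
  n <- length(x)
  if (n < 3L) {
    stop("need at least 3 records to fit (got ", n, ")")
  }
  if (stats::var(x) == 0) {
    stop("degenerate predictor '", predictor, "': zero variance across records")
  }
  fit <- if (intercept) stats::lm(y ~ x) else stats::lm(y ~ x + 0)
  pred <- stats::fitted(fit)
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) {
    warning("response is constant across records; reporting R^2 = 0")
    0
  } else {
    1 - ss_res / ss_tot
  }
  co <- stats::coef(fit)
  structure(list(
    predictor = predictor,
    slope = unname(co[["x"]]),
    intercept = if (intercept) unname(co[["(Intercept)"]]) else 0,
    r_squared = max(0, min(1, r2)),
    residuals = unname(y - pred),
    n = n
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> E ~ ", x$predictor, "  (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  slope:     %.6e\n  intercept: %.6e\n  R^2:       %.4f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Mass-law regressions over a dimer set
#'
#' Ordinary least squares (with intercept by default) of a dispersion
#' energy component on a mass-derived predictor:
#' \describe{
#'   \item{`fit_gravitational`}{`E_tot` on `M1*M2/R` -- the
#'     gravitational-like law.}
#'   \item{`fit_generalized`}{`E_tot` on `M1^2 + M2^2` -- the generalized
#'     law `E_tot = beta (M1^2 + M2^2) + gamma`; the slope is `beta`
#'     (kcal/(mol amu^2)) and the intercept `gamma` (kcal/mol).}
#'   \item{`fit_intramolecular`}{`E1 + E2` on `M1*M2`.}
#'   \item{`fit_interaction`}{`E_int` on `M1*M2/R` -- a diagnostic of
#'     NON-correlation; a low R^2 here is the expected outcome.}
#'   \item{`fit_mass_sum`}{`E_tot` on `M1 + M2` -- the linear-scaling
#'     regime diagnostic for large systems.}
#' }
#'
#' @param records A `dimer_records` data frame (see [build_records()]).
#' @param intercept Include an intercept (default `TRUE`).
#' @return A `fit_result` with `slope`, `intercept`, `r_squared`,
#'   `residuals`.
#' @export
fit_gravitational <- function(records, intercept = TRUE) {
  ols_fit(records$M1 * records$M2 / records$R, records$E_tot,
          "M1*M2/R", intercept)
}

#' @rdname fit_gravitational
#' @export
fit_generalized <- function(records, intercept = TRUE) {
  ols_fit(records$M1^2 + records$M2^2, records$E_tot, "M1^2+M2^2", intercept)
}

#' @rdname fit_gravitational
#' @export
fit_intramolecular <- function(records, intercept = TRUE) {
  ols_fit(records$M1 * records$M2, records$E1 + records$E2, "M1*M2", intercept)
}

#' @rdname fit_gravitational
#' @export
fit_interaction <- function(records, intercept = TRUE) {
  ols_fit(records$M1 * records$M2 / records$R, records$E_int,
          "M1*M2/R (E_int)", intercept)
}

#' @rdname fit_gravitational
#' @export
fit_mass_sum <- function(records, intercept = TRUE) {
  ols_fit(records$M1 + records$M2, records$E_tot, "M1+M2", intercept)
}

#' Compactness check: does intramolecular dispersion scale as mass squared?
#'
#' For a family of homoatomic clusters whose pair distances stay within a
#' bounded range, the intramolecular dispersion energy is expected to scale
#' with the square of the summed polarizabilities (equivalently, of the
#' mass, since mass and polarizability track each other for neutral atoms).
#' The report gives \eqn{E_1 / (\sum_A \alpha_A)^2} across the family and
#' its relative spread: a small spread is the quantitative content of the
#' \eqn{E_1 \propto M_1^2} step of the mass-scaling argument.
#'
#' @param family A list of homoatomic [molecule()] clusters of increasing
#'   size (e.g. from [make_shell()] at constant volume density).
#' @param engine,preset Passed to [total_dispersion()].
#' @return A list of class `compactness_report` with a per-cluster `table`
#'   (`n`, `mass_amu`, `E1_kcalmol`, `sum_alpha_A3`, `ratio`) and
#'   `relative_spread` = (max - min)/|mean| of the ratio.
#' @export
compact_cluster_check <- function(family, engine = "london", preset = "pbe0") {
  rows <- lapply(family, function(m) {
    e1 <- total_dispersion(m, engine = engine, preset = preset)$total
    sum_alpha <- sum(polarizability(m$element))
    data.frame(n = n_atoms(m), mass_amu = molecular_mass(m),
               E1_kcalmol = e1, sum_alpha_A3 = sum_alpha,
               ratio = e1 / sum_alpha^2)
  })
  tab <- do.call(rbind, rows)
  spread <- if (nrow(tab) > 1L && mean(tab$ratio) != 0) {
    (max(tab$ratio) - min(tab$ratio)) / abs(mean(tab$ratio))
  } else 0
  structure(list(table = tab, relative_spread = spread),
            class = "compactness_report")
}

#' @export
print.compactness_report <- function(x, ...) {
  cat("<compactness_report> E1 / (sum alpha)^2 across the family\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("  relative spread: %.1f%%\n", 100 * x$relative_spread))
  invisible(x)
}
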