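## XYZ reader/writer and the fragment sidecar config.
##
## The comment line of an XYZ file may carry fragment labels in the dialect
##   fragments=A:1-6,B:7-12
## (1-based inclusive atom ranges, comma-separated).  A sidecar config file
## holds one fragment per line, "name: ranges", same range syntax.  When both
## are given the config wins and a warning reports the conflict.

parse_index_ranges <- function(spec) {
  out <- integer(0)
  for (piece in strsplit(spec, "[,;]")[[1]]) {
    piece <- trimws(piece)
    if (!nzchar(piece)) next
    if (grepl("^[0-9]+-[0-9]+$", piece)) {
      ab <- as.integer(strsplit(piece, "-")[[1]])
      if (ab[1] > ab[2]) stop("invalid index range '", piece, "'")
      out <- c(out, seq(ab[1], ab[2]))
    } else if (grepl("^[0-9]+$", piece)) {
      out <- c(out, as.integer(piece))
    } else {
      stop("cannot parse atom range '", piece, "'")
    }
  }
  out
}

parse_fragment_spec <- function(spec, n) {
  ## spec: "A:1-6,B:7-12" -> per-atom labels of length n
  labels <- rep(NA_character_, n)
  for (piece in strsplit(spec, ",(?=[^,]*:)", perl = TRUE)[[1]]) {
    kv <- strsplit(piece, ":", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("cannot parse fragment assignment '", piece, "'")
    idx <- parse_index_ranges(kv[2])
    if (any(idx < 1L | idx > n)) {
      stop("fragment '", trimws(kv[1]), "' references atom outside 1..", n)
    }
    labels[idx] <- trimws(kv[1])
  }
  if (anyNA(labels)) {
    stop("fragment specification leaves atom(s) ",
         paste(which(is.na(labels)), collapse = ", "), " unassigned")
  }
  labels
}

#' Read a fragment sidecar config
#'
#' Plain-text file, one fragment per line: `name: ranges`, where ranges are
#' comma-separated 1-based atom indices or `a-b` inclusive spans.  Lines
#' starting with `#` and blank lines are ignored.
#'
#' @param path Path to the config file.
#' @param n Number of atoms the labels must cover.
#' @return Character vector of per-atom fragment labels.
#' @export
read_fragment_config <- function(path, n) {
  if (!file.exists(path)) stop("fragment config not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parse_fragment_spec(paste(lines, collapse = ","), n)
}

#' Write a fragment sidecar config
#'
#' @param m A [molecule()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragment_config <- function(m, path) {
  lines <- vapply(fragment_names(m), function(f) {
    idx <- which(m$fragment == f)
    paste0(f, ": ", collapse_ranges(idx))
  }, character(1))
  writeLines(c("# fragment assignments (1-based atom indices)", lines), path)
  invisible(path)
}

collapse_ranges <- function(idx) {
  idx <- sort(idx)
  breaks <- c(0, which(diff(idx) != 1L), length(idx))
  pieces <- vapply(seq_len(length(breaks) - 1L), function(k) {
    run <- idx[(breaks[k] + 1L):breaks[k + 1L]]
    if (length(run) == 1L) as.character(run) else paste0(run[1], "-", run[length(run)])
  }, character(1))
  paste(pieces, collapse = ",")
}

#' Read an XYZ geometry file
#'
#' Standard XYZ layout: atom count line, comment line, then one
#' `element x y z` record per atom (Angstrom).  Fragment labels may come
#' from a `fragments=...` token on the comment line or from a sidecar
#' config (`fragment_config`); the config wins on conflict, with a warning.
#'
#' @param path Path to the XYZ file.
#' @param fragment_config Optional path to a fragment sidecar config.
#' @return A [molecule()].
#' @export
read_xyz <- function(path, fragment_config = NULL) {
  if (!file.exists(path)) stop("XYZ file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("malformed XYZ file (fewer than 2 lines): ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) {
    stop("malformed XYZ header at line 1 of ", path,
         ": expected a positive atom count, got '", trimws(lines[1]), "'")
  }
  records <- lines[-(1:2)]
  records <- records[nzchar(trimws(records))]
  if (length(records) < n) {
    stop("XYZ atom-count mismatch in ", path, ": header says ", n,
         " atoms but only ", length(records),
         " coordinate records follow (first missing record would be line ",
         length(records) + 3L, ")")
  }
  records <- records[seq_len(n)]
  fields <- strsplit(trimws(records), "[[:space:]]+")
  bad <- which(lengths(fields) < 4L)
  if (length(bad) > 0L) {
    stop("malformed XYZ coordinate record at line ", bad[1] + 2L, " of ", path)
  }
  element <- vapply(fields, `[[`, character(1), 1L)
  xyz <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
  if (!all(is.finite(xyz))) {
    stop("non-numeric coordinate in XYZ file ", path)
  }
  fragment <- NULL
  comment <- lines[2]
  tok <- regmatches(comment, regexpr("fragments=[^[:space:]]+", comment))
  if (length(tok) == 1L) {
    fragment <- parse_fragment_spec(sub("^fragments=", "", tok), n)
  }
  if (!is.null(fragment_config)) {
    cfg <- read_fragment_config(fragment_config, n)
    if (!is.null(fragment) && !identical(cfg, fragment)) {
      warning("fragment labels in '", path, "' comment line conflict with ",
              "config '", fragment_config, "'; using the config")
    }
    fragment <- cfg
  }
  molecule(element, xyz, fragment = fragment)
}

#' Write an XYZ geometry file
#'
#' Coordinates are printed with 10 decimal places.  Unless the molecule is a
#' single fragment, the comment line carries the `fragments=` dialect so the
#' file round-trips with its fragment labels.
#'
#' @param m A [molecule()].
#' @param path Output path.
#' @param comment Optional comment-line text (fragment token is appended).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(m, path, comment = "") {
  frag_tok <- ""
  if (length(fragment_names(m)) > 1L) {
    frag_tok <- paste0("fragments=", paste(vapply(fragment_names(m), function(f) {
      paste0(f, ":", collapse_ranges(which(m$fragment == f)))
    }, character(1)), collapse = ","))
  }
  comment <- trimws(paste(comment, frag_tok))
  lines <- c(
    as.character(n_atoms(m)),
    comment,
    sprintf("%-3s %20.10f %20.10f %20.10f",
            m$element, m$xyz[, 1], m$xyz[, 2], m$xyz[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}
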