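# Structures: one atom per row, coordinates in Angstrom.

.element_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.973762, F = 18.998403, CL = 35.45, BR = 79.904, I = 126.90447,
  NA_ = 22.98977, MG = 24.305, K = 39.0983, CA = 40.078, MN = 54.938,
  FE = 55.845, ZN = 65.38, CU = 63.546, SE = 78.971
)

.standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "HSD",
  "HSE", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
  "TYR", "VAL"
)

.mass_from_element <- function(element) {
  key <- toupper(trimws(element))
  key[key == "NA"] <- "NA_"
  m <- .element_masses[key]
  unknown <- is.na(m)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(key[unknown]), collapse = ", "),
            "; assigning carbon mass", call. = FALSE)
    m[unknown] <- .element_masses[["C"]]
  }
  unname(m)
}

# Element guessed from the atom name when the PDB element column is blank:
# first alphabetic character, except two-letter names that start with H
# digits (e.g. "1HB") strip leading digits first.
.element_from_name <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  vapply(nm, function(x) {
    if (nchar(x) == 0L) return("C")
    substr(x, 1L, 1L)
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a molecular structure
#'
#' A `structure3d` is a data frame with one row per atom and columns
#' `name`, `resname`, `resno`, `chain`, `x`, `y`, `z` (Angstrom),
#' `mass` (amu) and `charge` (elementary charges). Invariants: residue
#' numbers are non-decreasing within each chain, all coordinates are
#' finite and all masses are strictly positive.
#'
#' @param atoms data frame with at least `name`, `resname`, `resno`,
#'   `chain`, `x`, `y`, `z`; `mass` and `charge` are filled in (from the
#'   element / zero) when absent.
#' @param element optional character vector of element symbols used to
#'   assign masses when `atoms$mass` is missing.
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(atoms, element = NULL) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  needed <- c("name", "resname", "resno", "chain", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols)) {
    stop("structure3d: missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(atoms$mass)) {
    if (is.null(element)) element <- .element_from_name(atoms$name)
    atoms$mass <- .mass_from_element(element)
  }
  if (is.null(atoms$charge)) atoms$charge <- 0
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("structure3d: non-finite coordinates")
  if (any(atoms$mass <= 0)) stop("structure3d: masses must be strictly positive")
  for (ch in unique(atoms$chain)) {
    rn <- atoms$resno[atoms$chain == ch]
    if (is.unsorted(rn)) {
      stop("structure3d: residue numbers decrease within chain '", ch, "'")
    }
  }
  class(atoms) <- c("structure3d", "data.frame")
  atoms
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d: %d atoms, %d residues, %d chain(s)\n",
              nrow(x), length(unique(paste(x$chain, x$resno))),
              length(unique(x$chain))))
  invisible(x)
}

#' Coordinates of a structure as an n x 3 matrix
#' @param structure a `structure3d`.
#' @return numeric matrix (Angstrom).
#' @export
coords3d <- function(structure) {
  unname(as.matrix(structure[, c("x", "y", "z")]))
}

.substr_num <- function(line, start, stop, what, lineno) {
  field <- trimws(substr(line, start, stop))
  val <- suppressWarnings(as.numeric(field))
  if (is.na(val)) {
    stop(sprintf("PDB parse error at line %d: %s field '%s' is not numeric",
                 lineno, what, field), call. = FALSE)
  }
  val
}

#' Read a PDB file (first model)
#'
#' Fixed-column parsing per the wwPDB 3.3 convention. Only the first
#' MODEL is read; atoms whose alternate-location indicator is neither
#' blank nor 'A' are dropped so the atom count is deterministic.
#' Occupancy and B-factor are ignored. Masses come from the element
#' column (columns 77-78) or, if blank, from the atom name; partial
#' charges are set to zero.
#'
#' @param path path to a PDB file.
#' @return A [structure3d()].
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("read_pdb: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  # first model only: cut at the first ENDMDL
  endmdl <- which(trimws(rec) == "ENDMDL")
  if (length(endmdl)) is_atom[seq_along(lines) > endmdl[1]] <- FALSE
  idx <- which(is_atom)
  if (!length(idx)) stop("read_pdb: no ATOM/HETATM records in ", path)
  alt <- substr(lines[idx], 17, 17)
  idx <- idx[alt %in% c(" ", "", "A")]
  n <- length(idx)
  name <- resname <- chain <- element <- character(n)
  resno <- integer(n)
  x <- y <- z <- numeric(n)
  for (k in seq_len(n)) {
    i <- idx[k]
    ln <- lines[i]
    name[k] <- trimws(substr(ln, 13, 16))
    resname[k] <- trimws(substr(ln, 18, 20))
    chain[k] <- substr(ln, 22, 22)
    resno[k] <- as.integer(.substr_num(ln, 23, 26, "resSeq", i))
    x[k] <- .substr_num(ln, 31, 38, "x", i)
    y[k] <- .substr_num(ln, 39, 46, "y", i)
    z[k] <- .substr_num(ln, 47, 54, "z", i)
    element[k] <- trimws(substr(ln, 77, 78))
  }
  blank <- element == ""
  element[blank] <- .element_from_name(name[blank])
  structure3d(
    data.frame(name = name, resname = resname, resno = resno, chain = chain,
               x = x, y = y, z = z, stringsAsFactors = FALSE),
    element = element
  )
}

#' Select atoms of a structure
#'
#' @param structure a [structure3d()].
#' @param selector either a predicate `function(atoms) -> logical`
#'   evaluated on the atom table, or one of the shorthands `"CA"`
#'   (main-chain C-alpha atoms of standard amino acids) and `"N3"`
#'   (azide label atoms named N1/N2/N3 or NZ1/NZ2/NZ3).
#' @return Integer vector of atom indices in structure order.
#'   Selection is order-preserving and idempotent; an empty selection
#'   is an error because downstream stages need at least two sites.
#' @export
select_atoms <- function(structure, selector = "CA") {
  stopifnot(inherits(structure, "structure3d"))
  if (is.character(selector)) {
    key <- match.arg(toupper(selector), c("CA", "N3", "ALL"))
    keep <- switch(key,
      CA  = structure$name == "CA" & structure$resname %in% .standard_aa,
      N3  = structure$name %in% c("N1", "N2", "N3", "NZ1", "NZ2", "NZ3"),
      ALL = rep(TRUE, nrow(structure))
    )
  } else if (is.function(selector)) {
    keep <- selector(structure)
    if (!is.logical(keep) || length(keep) != nrow(structure)) {
      stop("select_atoms: predicate must return one logical per atom")
    }
    keep[is.na(keep)] <- FALSE
  } else {
    stop("select_atoms: selector must be a string or a predicate function")
  }
  out <- which(keep)
  if (!length(out)) {
    stop("select_atoms: empty selection", call. = FALSE)
  }
  out
}

#' Write a structure as a PDB file
#'
#' Minimal fixed-column ATOM records (first model, no occupancy/B-factor
#' semantics: both written as 1.00/0.00).
#'
#' @param structure a [structure3d()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "structure3d"))
  name4 <- vapply(structure$name, function(nm) {
    if (nchar(nm) < 4L) sprintf(" %-3s", nm) else substr(nm, 1, 4)
  }, character(1), USE.NAMES = FALSE)
  el <- .element_from_name(structure$name)
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(structure)), name4, structure$resname,
    substr(structure$chain, 1, 1), structure$resno,
    structure$x, structure$y, structure$z, 1, 0, el)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
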