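# Molecular geometries and XYZ input/output.

# IUPAC 2021 standard atomic weights (conventional values), amu.
.atomic_weights <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.95,
  K = 39.098, Ca = 40.078, Sc = 44.956, Ti = 47.867, V = 50.942, Cr = 51.996,
  Mn = 54.938, Fe = 55.845, Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38,
  Ga = 69.723, Ge = 72.63, As = 74.922, Se = 78.971, Br = 79.904, Kr = 83.798,
  Rb = 85.468, Sr = 87.62, Y = 88.906, Zr = 91.224, Nb = 92.906, Mo = 95.95,
  Ru = 101.07, Rh = 102.91, Pd = 106.42, Ag = 107.87, Cd = 112.41,
  In = 114.82, Sn = 118.71, Sb = 121.76, Te = 127.60, I = 126.90, Xe = 131.29
)

#' Standard atomic weights for element symbols
#'
#' @param symbols character vector of element symbols (case-sensitive,
#'   e.g. `"C"`, `"Cl"`).
#' @return numeric vector of atomic masses in amu.
#' @export
atomic_masses <- function(symbols) {
  m <- .atomic_weights[symbols]
  if (anyNA(m)) {
    bad <- symbols[is.na(m)]
    .stop_validation("unknown element symbol(s): ", paste(unique(bad), collapse = ", "))
  }
  unname(m)
}

#' Construct a molecular geometry
#'
#' A geometry holds element symbols, Cartesian coordinates in Angstrom and
#' per-atom masses in amu. Masses default to standard atomic weights.
#'
#' @param symbols character vector of element symbols.
#' @param coords numeric N x 3 matrix of Cartesian positions (Angstrom).
#' @param masses optional numeric vector of atomic masses (amu).
#' @return an object of class `geometry`.
#' @export
geometry <- function(symbols, coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3)
    .stop_validation("coordinates must be an N x 3 numeric matrix")
  if (length(symbols) != nrow(coords))
    .stop_validation("number of symbols (", length(symbols),
                     ") does not match coordinate rows (", nrow(coords), ")")
  if (is.null(masses)) masses <- atomic_masses(symbols)
  if (length(masses) != length(symbols) || any(!is.finite(masses)) || any(masses <= 0))
    .stop_validation("masses must be finite, positive, one per atom")
  dimnames(coords) <- NULL
  structure(list(symbols = as.character(symbols), coords = coords,
                 masses = as.numeric(masses)),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat("<geometry> ", length(x$symbols), " atoms: ",
      paste(x$symbols, collapse = " "), "\n", sep = "")
  invisible(x)
}

n_atoms <- function(geom) length(geom$symbols)

#' Read an XYZ file
#'
#' Standard XYZ layout: atom count, comment line, then one `symbol x y z`
#' line per atom (coordinates in Angstrom).
#'
#' @param path file path.
#' @return a [geometry()] with masses filled from standard atomic weights.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) .stop_parse("XYZ file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) .stop_parse("XYZ file too short: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1)
    .stop_parse("malformed atom-count line in ", path, ": '", lines[1], "'")
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n)
    .stop_parse("XYZ file ", path, " declares ", n, " atoms but lists ",
                length(body))
  body <- body[seq_len(n)]
  toks <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(toks, length, 1L) < 4)
  if (length(bad))
    .stop_parse("malformed atom line ", bad[1] + 2L, " in ", path)
  syms <- vapply(toks, `[[`, "", 1L)
  xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
  if (anyNA(xyz)) .stop_parse("non-numeric coordinates in ", path)
  unknown <- setdiff(unique(syms), names(.atomic_weights))
  if (length(unknown)) {
    line <- which(syms %in% unknown)[1] + 2L
    .stop_validation("unknown element symbol '", unknown[1], "' at line ",
                     line, " of ", path)
  }
  geometry(syms, xyz)
}

#' Write a geometry to an XYZ file
#'
#' @param geom a [geometry()].
#' @param path output path.
#' @param comment comment line (second line of the file).
#' @param digits decimal places for coordinates.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(geom, path, comment = "", digits = 10) {
  stopifnot(inherits(geom, "geometry"))
  fmt <- sprintf("%%-3s %%%d.%df %%%d.%df %%%d.%df",
                 digits + 6, digits, digits + 6, digits, digits + 6, digits)
  lines <- c(
    as.character(n_atoms(geom)),
    comment,
    vapply(seq_len(n_atoms(geom)), function(i) {
      sprintf(fmt, geom$symbols[i], geom$coords[i, 1],
              geom$coords[i, 2], geom$coords[i, 3])
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

# interatomic distance for given 0-based... pairs are 1-based internally-facing
.pair_distances <- function(geom, pairs) {
  d <- geom$coords[pairs[, 1], , drop = FALSE] - geom$coords[pairs[, 2], , drop = FALSE]
  sqrt(rowSums(d * d))
}

.all_pairs <- function(n) {
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  cbind(i = idx[, "row"], j = idx[, "col"])
}
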