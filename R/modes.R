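# Harmonic normal modes: containers, conventions, and readers for
# Gaussian-style log files and portable JSON sidecars.

#' Construct a set of harmonic normal modes
#'
#' Frequencies are wavenumbers in cm^-1; an imaginary frequency is encoded as
#' a negative value. Each mode carries an N x 3 displacement pattern whose
#' convention is either `"mass_weighted"` (components of the mass-weighted
#' Hessian eigenvector, distributed over Cartesian axes) or
#' `"cartesian_normalized"` (Cartesian displacement normalized to unit length,
#' the convention of Gaussian log output). The mass-weighted form is the
#' canonical one used by all analyses.
#'
#' @param frequencies numeric vector of wavenumbers (cm^-1).
#' @param displacements list of N x 3 numeric matrices, one per mode.
#' @param convention `"mass_weighted"` or `"cartesian_normalized"`.
#' @return an object of class `normal_modes`.
#' @export
normal_modes <- function(frequencies,
                         displacements,
                         convention = c("mass_weighted", "cartesian_normalized")) {
  convention <- match.arg(convention)
  frequencies <- as.numeric(frequencies)
  if (!is.list(displacements))
    .stop_validation("displacements must be a list of N x 3 matrices")
  if (length(frequencies) != length(displacements))
    .stop_validation("got ", length(frequencies), " frequencies but ",
                     length(displacements), " displacement patterns")
  if (any(!is.finite(frequencies)))
    .stop_validation("frequencies must be finite")
  nat <- unique(vapply(displacements, nrow, 1L))
  if (length(displacements) &&
      (length(nat) != 1L || any(vapply(displacements, ncol, 1L) != 3L)))
    .stop_validation("all displacement patterns must be N x 3 with a common N")
  displacements <- lapply(displacements, function(m) {
    m <- as.matrix(m); dimnames(m) <- NULL; m
  })
  structure(list(frequencies = frequencies, displacements = displacements,
                 convention = convention),
            class = "normal_modes")
}

#' @export
print.normal_modes <- function(x, ...) {
  n_im <- sum(x$frequencies < 0)
  cat("<normal_modes> ", length(x$frequencies), " modes (", n_im,
      " imaginary), convention: ", x$convention, "\n", sep = "")
  invisible(x)
}

.check_mode_count_for_role <- function(modes, structure_type, where = "") {
  n_im <- sum(modes$frequencies < 0)
  if (identical(structure_type, "ts") && n_im != 1L)
    .stop_validation("a transition state must carry exactly one imaginary ",
                     "frequency, found ", n_im, where)
  if (identical(structure_type, "minimum") && n_im != 0L)
    .stop_validation("a minimum must carry no imaginary frequency, found ",
                     n_im, where)
  invisible(modes)
}

# canonical analysis form: normalized mass-weighted displacement per mode
.mode_mass_weighted <- function(mode_disp, convention, masses) {
  q <- if (convention == "mass_weighted") mode_disp
       else mode_disp * sqrt(masses)
  nrm <- sqrt(sum(q * q))
  if (nrm < 1e-300) .stop_validation("zero-length mode displacement")
  q / nrm
}

# unit Cartesian direction and reduced mass (amu) of a mode
.mode_cartesian <- function(mode_disp, convention, masses) {
  q <- .mode_mass_weighted(mode_disp, convention, masses)
  l <- q / sqrt(masses)
  mu <- 1 / sum(l * l)
  list(dir = l * sqrt(mu), reduced_mass = mu)
}

#' Read harmonic frequencies and displacements
#'
#' Supported dialects: `"gaussian_log"` (a Gaussian-16-style frequency block;
#' the high-precision block is preferred when present, else the standard
#' three-modes-per-column block) and `"sidecar_json"` (schema:
#' `{"frequencies_cm1": [...], "displacements": [[[dx,dy,dz], ...], ...],
#' "convention": "cartesian_normalized"|"mass_weighted"}`).
#'
#' @param path file path.
#' @param dialect input format.
#' @param geometry optional [geometry()]; when given, the displacement atom
#'   count is checked against it.
#' @param structure_type optional `"ts"` or `"minimum"`; enforces the
#'   imaginary-mode count invariant at read time.
#' @return a [normal_modes()] object. Imaginary frequencies are stored as
#'   negative wavenumbers; the convention tag records the dialect's native
#'   displacement normalization.
#' @export
read_frequency_data <- function(path,
                                dialect = c("gaussian_log", "sidecar_json"),
                                geometry = NULL,
                                structure_type = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stop_parse("frequency file not found: ", path)
  modes <- switch(dialect,
    sidecar_json = .read_sidecar_json(path),
    gaussian_log = .read_gaussian_log(path)
  )
  if (!is.null(geometry) && length(modes$displacements)) {
    nat <- nrow(modes$displacements[[1]])
    if (nat != n_atoms(geometry))
      .stop_validation("displacements in ", path, " cover ", nat,
                       " atoms but the geometry has ", n_atoms(geometry))
  }
  if (!is.null(structure_type))
    .check_mode_count_for_role(modes, structure_type, paste0(" in ", path))
  modes
}

.read_sidecar_json <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) .stop_parse("cannot parse JSON sidecar ",
                                                  path, ": ", conditionMessage(e)))
  need <- c("frequencies_cm1", "displacements", "convention")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    .stop_parse("sidecar ", path, " missing field(s): ", paste(miss, collapse = ", "))
  freqs <- unlist(obj$frequencies_cm1)
  disps <- lapply(obj$displacements, function(mode)
    do.call(rbind, lapply(mode, unlist)))
  normal_modes(freqs, disps, convention = obj$convention)
}

#' Write a normal-mode sidecar file
#'
#' Inverse of [read_frequency_data()] for the `"sidecar_json"` dialect.
#'
#' @param modes a [normal_modes()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mode_sidecar <- function(modes, path) {
  stopifnot(inherits(modes, "normal_modes"))
  obj <- list(
    frequencies_cm1 = modes$frequencies,
    displacements = lapply(modes$displacements, function(m)
      lapply(seq_len(nrow(m)), function(i) m[i, ])),
    convention = modes$convention
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- Gaussian-style log parsing ------------------------------------------

.read_gaussian_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hp <- grep("Frequencies\\s*---", lines)
  if (length(hp)) return(.parse_gaussian_freq(lines, hp, hpmodes = TRUE))
  std <- grep("Frequencies\\s*--", lines)
  if (!length(std)) .stop_parse("no frequency block found in ", path)
  .parse_gaussian_freq(lines, std, hpmodes = FALSE)
}

.num_tokens <- function(line) {
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  suppressWarnings(as.numeric(toks))
}

.parse_gaussian_freq <- function(lines, freq_idx, hpmodes) {
  freqs <- numeric(0)
  disp_cols <- list()
  for (fi in freq_idx) {
    toks <- strsplit(lines[fi], "---?")[[1]]
    block_freqs <- suppressWarnings(as.numeric(
      strsplit(trimws(toks[length(toks)]), "\\s+")[[1]]))
    block_freqs <- block_freqs[!is.na(block_freqs)]
    k <- length(block_freqs)
    if (!k) .stop_parse("unreadable frequency line: '", lines[fi], "'")
    # locate the displacement table that follows this frequency line
    hdr_pat <- if (hpmodes) "Coord\\s+Atom\\s+Element" else "Atom\\s+AN\\s+X\\s+Y\\s+Z"
    rel <- grep(hdr_pat, lines[seq(fi, min(fi + 12, length(lines)))])
    if (!length(rel))
      .stop_parse("no displacement table after frequency line ", fi)
    start <- fi + rel[1]
    rows <- list()
    i <- start
    lead <- if (hpmodes) 3L else 2L
    while (i <= length(lines)) {
      v <- .num_tokens(lines[i])
      if (length(v) != lead + (if (hpmodes) k else 3L * k) || anyNA(v)) break
      rows[[length(rows) + 1L]] <- v
      i <- i + 1L
    }
    if (!length(rows))
      .stop_parse("empty displacement table after line ", fi)
    tab <- do.call(rbind, rows)
    if (hpmodes) {
      # rows are (coord index, atom, atomic number, one column per mode)
      nat <- nrow(tab) / 3L
      if (nat != round(nat))
        .stop_parse("high-precision displacement table rows not divisible by 3")
      for (m in seq_len(k)) {
        col <- tab[, lead + m]
        disp_cols[[length(disp_cols) + 1L]] <-
          matrix(col, ncol = 3, byrow = TRUE)
      }
    } else {
      nat <- nrow(tab)
      for (m in seq_len(k)) {
        cols <- lead + (3L * (m - 1L)) + 1:3
        disp_cols[[length(disp_cols) + 1L]] <- tab[, cols, drop = FALSE]
      }
    }
    freqs <- c(freqs, block_freqs)
  }
  normal_modes(freqs, disp_cols, convention = "cartesian_normalized")
}

#' Write a synthetic frequency log (fixture generator)
#'
#' Writes a Gaussian-16-style frequency block for a synthetic structure, in
#' the high-precision (per-coordinate row) layout but with extended decimal
#' places so that analytic Hessian eigenvectors survive a round trip. This is
#' a fixture writer for testing the log parser; it does not reproduce every
#' section of a real log file.
#'
#' @param geom a [geometry()].
#' @param modes a [normal_modes()] object; displacements are written in the
#'   Cartesian-normalized convention of log files (converted if needed).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_synthetic_gaussian_log <- function(geom, modes, path) {
  stopifnot(inherits(geom, "geometry"), inherits(modes, "normal_modes"))
  k <- length(modes$frequencies)
  nat <- n_atoms(geom)
  cart <- lapply(seq_len(k), function(m) {
    d <- .mode_cartesian(modes$displacements[[m]], modes$convention, geom$masses)
    d$dir
  })
  an <- match(geom$symbols, names(.atomic_weights))
  out <- c(" Entering Gaussian System (synthetic fixture)",
           " Harmonic frequencies (cm**-1)")
  for (b0 in seq(1L, k, by = 5L)) {
    cols <- b0:min(b0 + 4L, k)
    out <- c(out,
      paste0("                     ", paste(sprintf("%10d", cols), collapse = " ")),
      paste0("       Frequencies --- ",
             paste(sprintf("%14.6f", modes$frequencies[cols]), collapse = " ")),
      " Coord Atom Element:")
    for (a in seq_len(nat)) for (x in 1:3) {
      vals <- vapply(cols, function(m) cart[[m]][a, x], 0)
      out <- c(out, paste0(sprintf("%4d %5d %6d    ", x, a, an[a]),
                           paste(sprintf("%14.10f", vals), collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}
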