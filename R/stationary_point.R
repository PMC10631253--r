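# A stationary point = geometry + Gibbs free energy + (optional) normal modes.

.sp_roles <- c("TS0", "TS1", "INT1", "INT2", "INT3", "TS2", "TS3", "product")

.is_ts_role <- function(role) startsWith(role, "TS")

#' Construct a stationary point
#'
#' One optimized structure of the reaction network: a first or second
#' transition state, an intermediate, or a product. Transition-state roles
#' must carry exactly one imaginary mode when modes are present; intermediates
#' and products must carry none. Products may omit modes entirely (only their
#' geometries are consumed downstream).
#'
#' @param label unique identifier, e.g. `"TS1(RS-1)"`.
#' @param role one of `r paste0('"', .sp_roles, '"', collapse = ", ")`.
#' @param geometry a [geometry()].
#' @param gibbs_free_energy Gibbs free energy in kcal/mol on the network's
#'   common reference.
#' @param modes optional [normal_modes()].
#' @param stereochem optional stereodescriptor string (e.g. `"RS"`).
#' @param species optional product identity (e.g. `"ketone"`); defaults to the
#'   label for products.
#' @return an object of class `stationary_point`.
#' @export
stationary_point <- function(label, role, geometry, gibbs_free_energy,
                             modes = NULL, stereochem = NULL, species = NULL) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    .stop_validation("label must be a non-empty string")
  if (!role %in% .sp_roles)
    .stop_validation("unknown role '", role, "' for ", label,
                     "; expected one of ", paste(.sp_roles, collapse = ", "))
  stopifnot(inherits(geometry, "geometry"))
  if (!is.numeric(gibbs_free_energy) || length(gibbs_free_energy) != 1L ||
      !is.finite(gibbs_free_energy))
    .stop_validation("gibbs_free_energy of ", label, " must be a finite number")
  if (!is.null(modes)) {
    stopifnot(inherits(modes, "normal_modes"))
    if (length(modes$displacements) &&
        nrow(modes$displacements[[1]]) != n_atoms(geometry))
      .stop_validation("mode displacements of ", label,
                       " do not match the atom count")
    .check_mode_count_for_role(
      modes, if (.is_ts_role(role)) "ts" else "minimum",
      paste0(" for ", label))
  }
  if (role == "product" && is.null(species)) species <- label
  structure(list(label = label, role = role, geometry = geometry,
                 gibbs_free_energy = as.numeric(gibbs_free_energy),
                 modes = modes,
                 stereochem = if (is.null(stereochem)) NA_character_ else as.character(stereochem),
                 species = if (is.null(species)) NA_character_ else as.character(species)),
            class = "stationary_point")
}

#' @export
print.stationary_point <- function(x, ...) {
  cat("<stationary_point> ", x$label, " [", x$role, "]  G = ",
      sprintf("%.4f", x$gibbs_free_energy), " kcal/mol",
      if (!is.na(x$stereochem)) paste0("  stereochem: ", x$stereochem) else "",
      if (is.null(x$modes)) "  (no modes)" else
        paste0("  (", length(x$modes$frequencies), " modes)"),
      "\n", sep = "")
  invisible(x)
}

# identity key of a product: "species" or "species (stereochem)"
.product_key <- function(sp) {
  if (is.na(sp$stereochem) || !nzchar(sp$stereochem)) sp$species
  else paste0(sp$species, " (", sp$stereochem, ")")
}
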