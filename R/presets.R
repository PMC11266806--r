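#' Material preset table
#'
#' Returns the editable table of dielectric presets shipped with the package
#' (or reads a user-supplied table in the same format). These values are
#' plausible literature-style stand-ins, not measured constants: they are
#' chosen so that the qualitative orderings that drive discrimination hold
#' (tumor cells are larger than WBCs and have higher specific membrane
#' capacitance, hence lower Opacity_2/0.5 in a conductive medium).
#'
#' Columns: `name`, `kind` (medium/bead/cell), `label`, `diameter_um`,
#' `diameter_sd_um`, membrane/cytoplasm dielectric parameters for cells, and
#' bulk `conductivity_S_m` / `relative_permittivity` for media and beads.
#'
#' @param path Optional path to an alternative CSV in the same format.
#' @return A data.frame, one row per material.
#' @export
material_table <- function(path = NULL) {
  if (is.null(path)) {  # shipped table: read once per session
    if (is.null(.preset_cache$default))
      .preset_cache$default <- read.csv(
        system.file("extdata", "materials.csv", package = "impedcyto",
                    mustWork = TRUE), stringsAsFactors = FALSE)
    return(.preset_cache$default)
  }
  read.csv(path, stringsAsFactors = FALSE)
}

.preset_cache <- new.env(parent = emptyenv())

preset_row <- function(name, path = NULL) {
  tab <- material_table(path)
  i <- match(name, tab$name)
  stop_if(is.na(i), "unknown material preset '%s' (known: %s)",
          name, paste(tab$name, collapse = ", "))
  tab[i, ]
}

#' Build a particle or medium from a named preset
#'
#' @param name Preset name from [material_table()] (e.g. "WBC", "MCF-7",
#'   "polystyrene", "PBS").
#' @param diameter Optional diameter override in micrometres (cells/beads).
#' @param path Optional path to an alternative material table.
#' @return A [shelled_cell()], [bead_particle()] or [medium()] as appropriate.
#' @export
#' @examples
#' cell_preset("MCF-7")
#' cell_preset("polystyrene", diameter = 15)
cell_preset <- function(name, diameter = NULL, path = NULL) {
  r <- preset_row(name, path)
  switch(r$kind,
    medium = medium(r$conductivity_S_m, r$relative_permittivity),
    bead = bead_particle(diameter %||% r$diameter_um,
                         r$relative_permittivity, r$conductivity_S_m),
    cell = shelled_cell(
      diameter = diameter %||% r$diameter_um,
      membrane_thickness = r$membrane_thickness_nm,
      membrane_conductivity = r$membrane_conductivity_S_m,
      membrane_relative_permittivity = r$membrane_relative_permittivity,
      cytoplasm_conductivity = r$cytoplasm_conductivity_S_m,
      cytoplasm_relative_permittivity = r$cytoplasm_relative_permittivity,
      label = r$label, subtype = r$name),
    stop("unknown material kind: ", r$kind))
}
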