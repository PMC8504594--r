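# Material definitions: elemental mass-fraction compositions and densities
# for the breast tissues, printing filaments, tube/filter components and air.

#' Construct a material
#'
#' A material is a named elemental composition (mass fractions) with a bulk
#' density. Compositions that sum to anything in (0.95, 1.05) are renormalized
#' to exactly 1; tabulated compositions are commonly printed to a precision
#' that leaves the sum at 99.9--100.1%.
#'
#' @param name Material name.
#' @param composition Named numeric vector of mass fractions by element
#'   symbol (e.g. `c(H = 0.106, C = 0.332, ...)`). Fractions must be
#'   non-negative; symbols must be among the packaged elements.
#' @param density Bulk density in g/cm^3 (> 0).
#' @return An object of class `material`.
#' @export
#' @examples
#' water <- material("water", c(H = 0.1119, O = 0.8881), 1.0)
material <- function(name, composition, density) {
  stopifnot(is.character(name), length(name) == 1L)
  if (is.null(names(composition)) || any(!nzchar(names(composition))))
    stop("composition must be a named vector of element mass fractions")
  if (any(composition < 0))
    stop("mass fractions must be non-negative")
  unknown <- setdiff(names(composition), xs_elements())
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  s <- sum(composition)
  if (s <= 0) stop("composition sums to zero")
  if (abs(s - 1) > 0.05)
    stop(sprintf("composition of '%s' sums to %.4f; expected ~1", name, s))
  if (!is.numeric(density) || length(density) != 1L || density <= 0)
    stop("density must be a single positive number (g/cm^3)")
  structure(
    list(name = name, composition = composition / s, density = density),
    class = "material"
  )
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s (density %.4g g/cm^3)\n", x$name, x$density))
  comp <- sort(x$composition, decreasing = TRUE)
  cat(" ", paste(sprintf("%s %.4g", names(comp), comp), collapse = ", "), "\n")
  invisible(x)
}

# Percent compositions as printed in the tissue/filament tables; the WOOD row
# sums to 100.01% and is renormalized by material().
.builtin_material_specs <- function() {
  list(
    skin = list(
      comp = c(H = 10, C = 20.4, N = 4.2, O = 64.5, Na = 0.2, P = 0.1,
               S = 0.2, Cl = 0.3),
      density = 1.09),
    glandular = list(
      comp = c(H = 10.6, C = 33.2, N = 3, O = 52.7, Na = 0.1, P = 0.1,
               S = 0.2, Cl = 0.1),
      density = 1.02),
    adipose = list(
      comp = c(H = 11.4, C = 59.8, N = 0.7, O = 27.8, Na = 0.1,
               S = 0.1, Cl = 0.1),
      density = 0.95),
    # printing filaments (as printed: no hydrogen listed)
    PLA = list(
      comp = c(C = 54.76, O = 44.99, S = 0.13, K = 0.12),
      density = 1.25),
    PC = list(
      comp = c(C = 76.28, O = 22.79, S = 0.11, Ti = 0.82),
      density = 1.21),
    WOOD = list(
      comp = c(C = 61.48, O = 37.65, Mg = 0.26, Si = 0.47, Cl = 0.15),
      density = 1),
    # tube and filter components
    tungsten = list(comp = c(W = 100), density = 19.25),
    beryllium = list(comp = c(Be = 100), density = 1.85),
    rhodium = list(comp = c(Rh = 100), density = 12.41),
    silver = list(comp = c(Ag = 100), density = 10.49),
    polycarbonate = list(
      # bisphenol-A polycarbonate (C16H14O3) for the paddle/support plates
      comp = c(H = 5.55, C = 75.57, O = 18.88),
      density = 1.2),
    aluminum = list(comp = c(Al = 100), density = 2.699),
    # standard dry air near sea level
    air = list(comp = c(N = 75.5, O = 23.2, Ar = 1.3), density = 1.205e-3)
  )
}

#' Built-in material registry
#'
#' Returns the registry of materials used throughout the pipeline: the three
#' breast components (skin, glandular, adipose), the printing filaments (PLA,
#' PC, WOOD), the tube and filter components (tungsten, beryllium, rhodium,
#' silver, polycarbonate, aluminum) and standard dry air. Percent
#' compositions are renormalized to mass fractions summing to 1.
#'
#' @return Named list of [material] objects.
#' @export
#' @examples
#' mats <- builtin_materials()
#' mats$glandular$density
builtin_materials <- function() {
  specs <- .builtin_material_specs()
  out <- lapply(names(specs), function(nm)
    material(nm, specs[[nm]]$comp / 100, specs[[nm]]$density))
  names(out) <- names(specs)
  out
}

#' Look up one built-in material
#'
#' @param name Material name (see [builtin_materials()]), or a `material`
#'   object which is returned unchanged.
#' @return A [material] object.
#' @export
get_material <- function(name) {
  if (inherits(name, "material")) return(name)
  mats <- builtin_materials()
  if (!name %in% names(mats))
    stop("unknown material '", name, "'; see builtin_materials()")
  mats[[name]]
}

#' Write materials to a human-editable config block
#'
#' Serializes a list of materials to YAML (name, density, element:fraction
#' pairs). [read_materials()] round-trips the result.
#'
#' @param materials Named list of [material] objects.
#' @param path File path to write to.
#' @export
write_materials <- function(materials, path) {
  blocks <- lapply(materials, function(m)
    list(density = m$density, composition = as.list(m$composition)))
  names(blocks) <- vapply(materials, function(m) m$name, character(1))
  yaml::write_yaml(blocks, path)
  invisible(path)
}

#' @rdname write_materials
#' @return `read_materials()` returns a named list of [material] objects.
#' @export
read_materials <- function(path) {
  blocks <- yaml::read_yaml(path)
  out <- lapply(names(blocks), function(nm) {
    b <- blocks[[nm]]
    material(nm, unlist(b$composition), b$density)
  })
  names(out) <- names(blocks)
  out
}
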