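# Photon interaction coefficient lookup: packaged per-element tables over
# 1-50 keV, log-log interpolation, and the mass-fraction mixture rule.

.xs_env <- new.env(parent = emptyenv())

#' Element symbols with packaged coefficient tables
#' @return Character vector of symbols.
#' @export
xs_elements <- function() {
  if (is.null(.xs_env$elements)) {
    dir <- system.file("extdata", "xs", package = "mgdsim")
    .xs_env$elements <- sub("\\.txt$", "", list.files(dir, pattern = "\\.txt$"))
  }
  .xs_env$elements
}

#' Packaged photon coefficient table for one element
#'
#' Mass attenuation coefficients by interaction channel (photoelectric,
#' incoherent, coherent, and their total) and the mass energy-absorption
#' coefficient, on a 1-50 keV grid. Absorption edges appear as paired grid
#' nodes at edge +/- 1 eV so log-log interpolation never crosses an edge.
#'
#' @param symbol Element symbol, e.g. `"Al"`.
#' @return A data.frame with columns `energy`, `photoelectric`, `incoherent`,
#'   `coherent`, `total`, `energy_absorption` (keV and cm^2/g).
#' @export
element_table <- function(symbol) {
  key <- paste0("tab_", symbol)
  if (is.null(.xs_env[[key]])) {
    path <- system.file("extdata", "xs", paste0(symbol, ".txt"),
                        package = "mgdsim")
    if (!nzchar(path) || !file.exists(path))
      stop("no packaged coefficient table for element '", symbol, "'")
    tab <- read.table(path, header = FALSE, comment.char = "#",
                      col.names = c("energy", "photoelectric", "incoherent",
                                    "coherent", "total", "energy_absorption"))
    .xs_env[[key]] <- tab
  }
  .xs_env[[key]]
}

# log-log linear interpolation of one element/channel at energies E (keV);
# exact at grid nodes, error outside [1, 50] keV.
.interp_element <- function(symbol, energy, column) {
  if (any(energy < 1 - 1e-12) || any(energy > 50 + 1e-12))
    stop("energy out of the tabulated 1-50 keV range")
  tab <- element_table(symbol)
  y <- approx(log(tab$energy), log(tab[[column]]), xout = log(energy),
              rule = 2, ties = "ordered")$y
  exp(y)
}

.channel_column <- function(channel) {
  switch(channel,
         total = "total",
         photoelectric = "photoelectric",
         incoherent = "incoherent",
         coherent = "coherent",
         stop("unknown channel '", channel, "'"))
}

#' Mass attenuation coefficient of a material
#'
#' Combines log-log interpolated elemental coefficients with the
#' mass-fraction mixture rule `sum_i w_i (mu/rho)_i`.
#'
#' @param material A [material] object or a built-in material name.
#' @param energy Photon energy (keV), 1-50; vectorized.
#' @param channel One of `"total"`, `"photoelectric"`, `"incoherent"`,
#'   `"coherent"`.
#' @return Mass attenuation coefficient(s) in cm^2/g.
#' @export
#' @examples
#' mass_attenuation("glandular", 20)
mass_attenuation <- function(material, energy,
                             channel = c("total", "photoelectric",
                                         "incoherent", "coherent")) {
  channel <- match.arg(channel)
  m <- get_material(material)
  col <- .channel_column(channel)
  out <- 0
  for (el in names(m$composition)) {
    w <- m$composition[[el]]
    if (w > 0) out <- out + w * .interp_element(el, energy, col)
  }
  unname(out)
}

#' Linear attenuation coefficient of a material
#'
#' @inheritParams mass_attenuation
#' @return Linear attenuation coefficient(s) in 1/cm
#'   (`mass_attenuation * density`).
#' @export
linear_attenuation <- function(material, energy, channel = "total") {
  m <- get_material(material)
  mass_attenuation(m, energy, channel) * m$density
}

#' Mass energy-absorption coefficient of a material
#'
#' Same mixture rule applied to the elemental mass energy-absorption tables;
#' used for air-kerma weighting in half-value-layer work.
#'
#' @inheritParams mass_attenuation
#' @return Coefficient(s) in cm^2/g.
#' @export
mass_energy_absorption <- function(material, energy) {
  m <- get_material(material)
  out <- 0
  for (el in names(m$composition)) {
    w <- m$composition[[el]]
    if (w > 0) out <- out + w * .interp_element(el, energy, "energy_absorption")
  }
  unname(out)
}
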