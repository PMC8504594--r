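# Tungsten-anode mammography spectrum model: Kramers-type continuum with
# anode self-filtration and tungsten L lines, filtration, air kerma, and
# half-value-layer beam quality.

# Tungsten L-series lines (keV) with relative intensities 100:80:30.
.w_l_lines <- function() {
  data.frame(energy = c(8.3976, 9.6724, 11.2852),
             rel = c(100, 80, 30) / 210,
             row.names = c("La1", "Lb1", "Lg1"))
}

# Effective anode production depth (cm) for the exponential self-filtration
# model, calibrated once so the rhodium-filtered beam quality reproduces the
# 0.531 mm Al half-value layer; see calibrate_self_filtration().
.self_filtration_default <- 3.43244e-05

#' Beam configuration
#'
#' Geometry and loading of the simulated mammography unit: 28 kVp tungsten
#' anode at 10 degrees, 0.5 mm beryllium permanent filter, optional 0.06 mm
#' rhodium or silver additional filter, 2 mm polycarbonate compression
#' paddle, 65 cm source-breast distance, 55 mAs, 18 x 24 cm^2 field.
#'
#' @param kvp Tube voltage in kVp (20-40).
#' @param anode_angle_deg Anode (target) angle in degrees.
#' @param focal_spot_mm Focal spot size in mm (metadata only).
#' @param be_mm Permanent beryllium filter thickness, mm.
#' @param filter Additional filter: `"none"`, `"Rh"` or `"Ag"`.
#' @param filter_mm Additional filter thickness, mm.
#' @param paddle_mm Compression paddle (polycarbonate) thickness, mm.
#' @param support_mm Support plate (polycarbonate) thickness, mm. The
#'   equipment table prints 5 cm for the support plate, which is implausibly
#'   thick for a transmissive plate; the default models 5 mm, and the printed
#'   value remains available here.
#' @param sid_cm Source-breast distance, cm.
#' @param mas Tube loading, mAs.
#' @param field_cm Irradiation field, c(width, depth) in cm.
#' @param self_filtration_cm Effective anode production depth for the
#'   exponential self-filtration model (cm); the spectrum model's only tuned
#'   constant.
#' @param line_fraction Tungsten L-line fluence as a fraction of the
#'   post-self-filtration continuum fluence.
#' @return An object of class `beam_config`.
#' @export
beam_config <- function(kvp = 28, anode_angle_deg = 10, focal_spot_mm = 0.3,
                        be_mm = 0.5, filter = c("none", "Rh", "Ag"),
                        filter_mm = 0.06, paddle_mm = 2, support_mm = 5,
                        sid_cm = 65, mas = 55, field_cm = c(18, 24),
                        self_filtration_cm = .self_filtration_default,
                        line_fraction = 0.1) {
  filter <- match.arg(filter)
  if (kvp < 20 || kvp > 40) stop("kvp must be in [20, 40]")
  if (be_mm < 0 || filter_mm < 0 || paddle_mm < 0 || support_mm < 0)
    stop("thicknesses must be >= 0")
  if (sid_cm <= 0) stop("sid_cm must be > 0")
  if (mas <= 0) stop("mas must be > 0")
  if (self_filtration_cm < 0) stop("self_filtration_cm must be >= 0")
  structure(list(kvp = kvp, anode_angle_deg = anode_angle_deg,
                 focal_spot_mm = focal_spot_mm, be_mm = be_mm,
                 filter = filter, filter_mm = filter_mm,
                 paddle_mm = paddle_mm, support_mm = support_mm,
                 sid_cm = sid_cm, mas = mas, field_cm = field_cm,
                 self_filtration_cm = self_filtration_cm,
                 line_fraction = line_fraction),
            class = "beam_config")
}

#' @export
print.beam_config <- function(x, ...) {
  cat(sprintf("<beam_config> %g kVp W anode %g deg, Be %g mm, filter %s %g mm,\n",
              x$kvp, x$anode_angle_deg, x$be_mm, x$filter, x$filter_mm))
  cat(sprintf("  paddle %g mm PC, SID %g cm, %g mAs, field %g x %g cm^2\n",
              x$paddle_mm, x$sid_cm, x$mas, x$field_cm[1], x$field_cm[2]))
  invisible(x)
}

.new_spectrum <- function(edges, fluence, kvp, line_bins = integer()) {
  structure(list(edges = edges, fluence = fluence, bin_width = 0.1,
                 kvp = kvp, line_bins = as.integer(line_bins)),
            class = "energy_spectrum")
}

#' Bin-center energies of a spectrum
#' @param spectrum An `energy_spectrum`.
#' @return Numeric vector of bin centers (keV).
#' @export
bin_centers <- function(spectrum) spectrum$edges + spectrum$bin_width / 2

#' Generate the anode-output spectrum
#'
#' Semi-empirical model: a Kramers-type continuum `N(E) ~ (kVp - E)/E`
#' shaped by anode self-filtration and the permanent beryllium filter, with
#' tungsten L-series characteristic lines added as delta contributions in
#' their containing 0.1 keV bins. Self-filtration assumes an exponential
#' production-depth distribution, giving the closed-form transmission
#' `1 / (1 + mu_W(E) * d / sin(anode angle))` for effective depth `d`.
#' No additional filter or paddle is applied at this stage.
#'
#' @param config A [beam_config].
#' @return An `energy_spectrum` with 0.1 keV bins on `[1 keV, kVp]`, in
#'   relative fluence units.
#' @export
generate_spectrum <- function(config = beam_config()) {
  stopifnot(inherits(config, "beam_config"))
  kvp <- config$kvp
  edges <- seq(1, kvp, by = 0.1)
  centers <- edges + 0.05
  fl <- ifelse(centers < kvp, pmax(kvp - centers, 0) / centers, 0)
  # anode self-filtration (path = depth / sin(angle))
  mu_w <- linear_attenuation("tungsten", centers)
  path_scale <- config$self_filtration_cm / sin(config$anode_angle_deg * pi / 180)
  fl <- fl / (1 + mu_w * path_scale)
  # characteristic L lines, as a fraction of the post-self-filtration fluence
  line_bins <- integer()
  if (config$line_fraction > 0) {
    lines <- .w_l_lines()
    lines <- lines[lines$energy < kvp & lines$energy > 1, ]
    if (nrow(lines)) {
      total <- config$line_fraction * sum(fl)
      idx <- findInterval(lines$energy, edges)
      amp <- total * lines$rel / sum(lines$rel)
      for (i in seq_along(idx)) fl[idx[i]] <- fl[idx[i]] + amp[i]
      line_bins <- sort(unique(idx))
    }
  }
  # permanent beryllium filter
  mu_be <- linear_attenuation("beryllium", centers)
  fl <- fl * exp(-mu_be * config$be_mm / 10)
  .new_spectrum(edges, fl, kvp, line_bins)
}

#' Filter a spectrum through a slab
#'
#' Per-bin Beer-Lambert attenuation at the bin-center energy. Composable and
#' commutative; thickness 0 returns an identical spectrum.
#'
#' @param spectrum An `energy_spectrum`.
#' @param material A [material] or built-in name.
#' @param thickness_mm Slab thickness in mm (>= 0).
#' @return The filtered `energy_spectrum`.
#' @export
filter_spectrum <- function(spectrum, material, thickness_mm) {
  stopifnot(inherits(spectrum, "energy_spectrum"))
  if (thickness_mm < 0) stop("thickness must be >= 0")
  if (thickness_mm == 0) return(spectrum)
  mu <- linear_attenuation(material, bin_centers(spectrum))
  spectrum$fluence <- spectrum$fluence * exp(-mu * thickness_mm / 10)
  spectrum
}

#' The clinical beam at the breast entrance
#'
#' Applies the additional filter and the compression paddle from the beam
#' configuration to the anode-output spectrum. Optionally includes the
#' source-breast air column.
#'
#' @param config A [beam_config].
#' @param include_paddle Apply the compression paddle.
#' @param include_air Attenuate through `sid_cm` of air.
#' @return An `energy_spectrum`.
#' @export
mammography_beam <- function(config = beam_config(), include_paddle = TRUE,
                             include_air = FALSE) {
  s <- generate_spectrum(config)
  if (config$filter != "none") {
    mat <- switch(config$filter, Rh = "rhodium", Ag = "silver")
    s <- filter_spectrum(s, mat, config$filter_mm)
  }
  if (include_paddle) s <- filter_spectrum(s, "polycarbonate", config$paddle_mm)
  if (include_air) s <- filter_spectrum(s, "air", config$sid_cm * 10)
  s
}

#' Air kerma of a spectrum (relative units)
#'
#' `K = sum over bins of fluence * E * (mu_en/rho)_air(E)`; the quantity
#' whose halving defines the half-value layer.
#'
#' @param spectrum An `energy_spectrum` with nonzero total fluence.
#' @return Air kerma per unit fluence scale (relative units).
#' @export
air_kerma <- function(spectrum) {
  stopifnot(inherits(spectrum, "energy_spectrum"))
  if (all(spectrum$fluence == 0))
    stop("air kerma undefined for an all-zero spectrum")
  e <- bin_centers(spectrum)
  sum(spectrum$fluence * e * mass_energy_absorption("air", e))
}

#' Half-value layer
#'
#' The attenuator thickness halving the spectrum's air kerma, found by
#' bracketing and bisection to better than 1e-4 mm. Independent of overall
#' spectrum scaling.
#'
#' @param spectrum An `energy_spectrum` with nonzero fluence.
#' @param attenuator Attenuating material (default aluminum).
#' @param max_mm Upper bracket for the search, mm.
#' @return Thickness in mm.
#' @export
#' @examples
#' s <- mammography_beam(beam_config(filter = "Rh"))
#' hvl(s)
hvl <- function(spectrum, attenuator = "aluminum", max_mm = 10) {
  k0 <- air_kerma(spectrum)
  f <- function(t_mm)
    air_kerma(filter_spectrum(spectrum, attenuator, t_mm)) - k0 / 2
  if (f(max_mm) > 0)
    stop("could not bracket the half-value layer within [0, ", max_mm, "] mm")
  uniroot(f, c(0, max_mm), tol = 1e-5)$root
}

#' Spectrum summary statistics
#'
#' @param spectrum An `energy_spectrum` with nonzero fluence.
#' @return List with `mean_energy` (fluence-weighted bin-center average),
#'   `peak_energy` (center of the maximum bin), `continuum_peak_energy`
#'   (maximum with characteristic-line bins masked), and `total_fluence`.
#'   Ties break toward lower energy.
#' @export
spectrum_stats <- function(spectrum) {
  stopifnot(inherits(spectrum, "energy_spectrum"))
  fl <- spectrum$fluence
  if (all(fl == 0)) stop("statistics undefined for an all-zero spectrum")
  e <- bin_centers(spectrum)
  cont <- fl
  if (length(spectrum$line_bins)) cont[spectrum$line_bins] <- 0
  list(mean_energy = sum(fl * e) / sum(fl),
       peak_energy = e[which.max(fl)],
       continuum_peak_energy = e[which.max(cont)],
       total_fluence = sum(fl))
}

#' Calibrate the anode self-filtration constant
#'
#' Solves for the effective production depth that makes the rhodium-filtered
#' beam (with paddle) reach a target aluminum half-value layer. The packaged
#' default was fixed once with this routine at 0.531 mm Al; the silver-filter
#' beam quality is then a genuine model prediction.
#'
#' @param target_hvl_mm Target half-value layer, mm Al.
#' @param config Base [beam_config]; its filter is set to `"Rh"`.
#' @return Effective depth in cm.
#' @export
calibrate_self_filtration <- function(target_hvl_mm = 0.531,
                                      config = beam_config()) {
  f <- function(log_d) {
    cfg <- config
    cfg$filter <- "Rh"
    cfg$self_filtration_cm <- exp(log_d)
    hvl(mammography_beam(cfg)) - target_hvl_mm
  }
  exp(uniroot(f, log(c(1e-6, 5e-3)), tol = 1e-7)$root)
}

#' Write / read a spectrum as two-column text
#'
#' Columns are the bin lower edge (keV) and the fluence; header comments
#' carry the tube voltage, bin width and characteristic-line bin indices so
#' the round trip is bit-exact.
#'
#' @param spectrum An `energy_spectrum`.
#' @param path File path.
#' @export
write_spectrum <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# kvp %s", format(spectrum$kvp, digits = 17)),
               sprintf("# line_bins %s",
                       paste(spectrum$line_bins, collapse = " ")),
               "# columns: bin_lower_edge_keV fluence"), con)
  writeLines(paste(sprintf("%.17g", spectrum$edges),
                   sprintf("%.17g", spectrum$fluence)), con)
  invisible(path)
}

#' @rdname write_spectrum
#' @return `read_spectrum()` returns the `energy_spectrum`.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  kvp <- as.numeric(sub("^# kvp ", "", hdr[startsWith(hdr, "# kvp")]))
  lb <- sub("^# line_bins ?", "", hdr[startsWith(hdr, "# line_bins")])
  line_bins <- if (nzchar(lb)) as.integer(strsplit(lb, " ")[[1]]) else integer()
  tab <- read.table(text = lines[!startsWith(lines, "#")])
  .new_spectrum(tab[[1]], tab[[2]], kvp, line_bins)
}
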