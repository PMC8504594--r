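# Monte Carlo transport orchestration: scene assembly (paddle above the
# phantom, support plate below, air elsewhere), per-label attenuation tables
# on a uniform energy grid, batching and batch statistics.

#' Transport configuration
#'
#' @param histories Total photon histories (>= batches).
#' @param batches Number of independent batches (>= 2) for batch statistics;
#'   batch `b` uses an RNG substream derived from `(seed, b)`.
#' @param seed Integer master seed.
#' @param kerma Kerma approximation flag: photoelectron and Compton-recoil
#'   energy is deposited at the interaction site (electron ranges below
#'   30 keV are sub-voxel). This is the only deposition model implemented;
#'   `FALSE` is rejected.
#' @param coherent Include coherent (Rayleigh) scattering; when off, the
#'   coherent channel is folded out of both attenuation and channel
#'   selection.
#' @param cutoff_kev Photon cutoff energy; scattered photons below it are
#'   absorbed locally.
#' @return An object of class `transport_config`.
#' @export
transport_config <- function(histories = 1e6, batches = 20, seed = 1,
                             kerma = TRUE, coherent = TRUE, cutoff_kev = 1) {
  if (!isTRUE(kerma))
    stop("only the kerma approximation is implemented; electron transport is not")
  histories <- as.integer(histories); batches <- as.integer(batches)
  if (batches < 2) stop("need at least 2 batches for batch statistics")
  if (histories < batches) stop("histories must be >= batches")
  structure(list(histories = histories, batches = batches,
                 seed = as.integer(seed), kerma = kerma, coherent = coherent,
                 cutoff_kev = cutoff_kev),
            class = "transport_config")
}

# uniform energy grid shared by all transport lookups
.egrid <- function() list(e0 = 1, de = 0.05, n = 981L)

# scene: phantom grid extended with support plate below and paddle above,
# both spanning the full lateral box. Returns labels, origin, and the
# material attached to each label code.
.assemble_scene <- function(phantom, beam) {
  h <- phantom$voxel_cm
  np <- round(beam$paddle_mm / 10 / h)
  ns <- round(beam$support_mm / 10 / h)
  d <- phantom$dims
  nz <- d[3] + np + ns
  labels <- array(.LABELS[["air"]], dim = c(d[1], d[2], nz))
  if (ns > 0) labels[, , seq_len(ns)] <- .LABELS[["support"]]
  labels[, , ns + seq_len(d[3])] <- phantom$labels
  if (np > 0) labels[, , ns + d[3] + seq_len(np)] <- .LABELS[["paddle"]]
  mats <- builtin_materials()
  label_mats <- list(air = mats$air, skin = mats$skin,
                     glandular = mats$glandular, adipose = mats$adipose,
                     interior = if (!is.null(phantom$materials$interior))
                       phantom$materials$interior else mats$air,
                     paddle = mats$polycarbonate, support = mats$polycarbonate)
  list(labels = labels, dims = c(d[1], d[2], nz),
       origin = c(phantom$origin[1], phantom$origin[2], -ns * h),
       voxel_cm = h, label_mats = label_mats,
       z_top = (nz - ns) * h)   # top of scene relative to phantom z = 0
}

# per-label linear attenuation and channel cdfs on the uniform grid
.material_tables <- function(label_mats, coherent = TRUE) {
  g <- .egrid()
  e <- g$e0 + (seq_len(g$n) - 1) * g$de
  nlab <- length(label_mats)
  mu <- pe <- inc <- coh <- matrix(0, g$n, nlab)
  for (i in seq_len(nlab)) {
    m <- label_mats[[i]]
    pe[, i] <- mass_attenuation(m, e, "photoelectric") * m$density
    inc[, i] <- mass_attenuation(m, e, "incoherent") * m$density
    coh[, i] <- if (coherent) mass_attenuation(m, e, "coherent") * m$density else 0
  }
  mu <- pe + inc + coh
  list(mu = mu, cum_pe = pe / mu, cum_inc = (pe + inc) / mu,
       major = apply(mu, 1, max), e0 = g$e0, de = g$de)
}

# source plane geometry: field rectangle clipped to the phantom bounding box,
# projected from the focal spot onto the scene entry plane.
.source_geometry <- function(phantom, beam, scene) {
  R <- phantom$spec$radius_cm
  tt <- phantom$spec$thickness_cm
  fx <- beam$field_cm[2] / 2     # lateral half-extent (24 cm side at chest wall)
  fy <- beam$field_cm[1]         # chest-wall-to-nipple extent
  rect <- c(max(-fx, -R), min(fx, R), 0, min(fy, R))
  focal <- c(0, 0, tt + beam$sid_cm)
  zplane <- scene$z_top
  scale <- (focal[3] - zplane) / (focal[3] - tt)
  list(focal = focal, zplane = zplane,
       rect = c(rect[1:2] * scale, rect[3:4] * scale))
}

.spectrum_cdf <- function(spectrum) {
  p <- spectrum$fluence
  if (sum(p) <= 0) stop("cannot sample from an all-zero spectrum")
  cumsum(p) / sum(p)
}

#' Sample source photons
#'
#' Draws photon energies from the binned spectrum (uniform within each bin)
#' and emission points/directions from the focal spot toward the field
#' rectangle clipped to the phantom bounding box. Reproducible given the
#' seed.
#'
#' @param spectrum An `energy_spectrum` with nonzero fluence.
#' @param beam A [beam_config].
#' @param count Number of photons.
#' @param seed Integer seed.
#' @param phantom Optional `voxel_phantom` fixing the entry geometry; without
#'   it photons are aimed at the full field on the plane z = 0 from
#'   `sid_cm` above.
#' @param parallel If `TRUE`, a parallel beam along -z instead of the
#'   focal-spot fan.
#' @return List with `energy` (keV), `position` (count x 3, cm) and
#'   `direction` (count x 3, unit vectors).
#' @export
sample_source <- function(spectrum, beam, count, seed = 1, phantom = NULL,
                          parallel = FALSE) {
  cdf <- .spectrum_cdf(spectrum)
  if (is.null(phantom)) {
    fx <- beam$field_cm[2] / 2
    geom <- list(focal = c(0, 0, beam$sid_cm), zplane = 0,
                 rect = c(-fx, fx, 0, beam$field_cm[1]))
  } else {
    scene <- .assemble_scene(phantom, beam)
    geom <- .source_geometry(phantom, beam, scene)
  }
  .cpp_sample_source(spectrum$edges, cdf, spectrum$bin_width, geom$focal,
                     geom$rect, geom$zplane, parallel, as.integer(count),
                     as.double(seed))
}

#' Sample Compton (incoherent) scattering
#'
#' Scattering polar angles from the free-electron Klein-Nishina differential
#' cross-section (rejection sampling) and the corresponding scattered
#' energies from the Compton relation
#' `E' = E / (1 + (E / m_e c^2) (1 - cos theta))`.
#'
#' @param energy_kev Incident photon energy, keV (1-50).
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Data.frame with columns `energy` (scattered, keV), `angle`
#'   (polar, rad) and `recoil` (electron recoil energy, keV).
#' @export
sample_compton <- function(energy_kev, n = 1, seed = 1) {
  stopifnot(energy_kev >= 1, energy_kev <= 50)
  m <- .cpp_sample_compton(energy_kev, as.integer(n), as.double(seed))
  data.frame(energy = m[, 1], angle = m[, 2], recoil = energy_kev - m[, 1])
}

#' Sample interaction channels
#'
#' Draws interaction types with probabilities proportional to the partial
#' mass attenuation coefficients of the material at the given energy.
#'
#' @param material A [material] or built-in name.
#' @param energy_kev Photon energy, keV.
#' @param n Number of draws.
#' @param seed Integer seed (R RNG).
#' @param coherent If `FALSE`, the coherent channel is folded out and the
#'   remaining channels renormalized.
#' @return Character vector of channels, with the channel probabilities in
#'   attribute `"probabilities"`.
#' @export
sample_interaction <- function(material, energy_kev, n = 1, seed = 1,
                               coherent = TRUE) {
  parts <- c(photoelectric = mass_attenuation(material, energy_kev, "photoelectric"),
             incoherent = mass_attenuation(material, energy_kev, "incoherent"),
             coherent = if (coherent) mass_attenuation(material, energy_kev, "coherent") else 0)
  if (!coherent) parts <- parts[1:2]
  probs <- parts / sum(parts)
  set.seed(seed)
  out <- sample(names(probs), n, replace = TRUE, prob = probs)
  attr(out, "probabilities") <- probs
  out
}

#' Run Monte Carlo photon transport
#'
#' Delta-tracking transport of source photons through paddle + phantom +
#' support with per-compartment energy-deposition tallies and point tallies
#' in 1.5 mm spheres at the dosimeter positions (non-mixture phantoms).
#' Photoelectric absorption deposits the full photon energy locally;
#' incoherent scattering deposits the recoil energy locally (kerma
#' approximation) and continues the photon, absorbing it locally below the
#' cutoff; coherent scattering only redirects. Deterministic for a given
#' (seed, config, phantom): identical inputs give identical tallies.
#'
#' @param phantom A `voxel_phantom`.
#' @param spectrum The `energy_spectrum` entering the scene from above (the
#'   paddle is part of the scene, so a beam filtered by the additional
#'   filter only is the natural input; see [mammography_beam()] with
#'   `include_paddle = FALSE`).
#' @param beam A [beam_config].
#' @param config A [transport_config].
#' @param parallel Parallel beam instead of the focal-spot fan (used by
#'   slab-geometry validation).
#' @return An object of class `tally_result`: per-batch deposit matrix
#'   (keV, one column per compartment), per-batch point-tally matrix,
#'   emitted energy per batch, history count, seed, livelock-warning count,
#'   and the phantom's compartment masses.
#' @export
run_transport <- function(phantom, spectrum, beam = beam_config(),
                          config = transport_config(), parallel = FALSE) {
  stopifnot(inherits(phantom, "voxel_phantom"),
            inherits(spectrum, "energy_spectrum"),
            inherits(beam, "beam_config"),
            inherits(config, "transport_config"))
  scene <- .assemble_scene(phantom, beam)
  tabs <- .material_tables(scene$label_mats, coherent = config$coherent)
  geom <- .source_geometry(phantom, beam, scene)
  pts <- if (phantom$spec$mode == "non-mixture" &&
             "glandular" %in% names(phantom$masses))
    dosimeter_positions(phantom, 6)
  else matrix(numeric(0), 0, 3)
  cdf <- .spectrum_cdf(spectrum)
  res <- .cpp_run_transport(
    as.integer(scene$labels), as.integer(scene$dims), scene$voxel_cm,
    scene$origin, tabs$mu, tabs$cum_pe, tabs$cum_inc, tabs$major,
    tabs$e0, tabs$de, spectrum$edges, cdf, spectrum$bin_width,
    geom$focal, geom$rect, geom$zplane, parallel, pts, 0.15,
    config$histories, config$batches, as.double(config$seed),
    config$cutoff_kev, 10000L)
  dep <- res$deposit
  colnames(dep) <- names(.LABELS)
  structure(list(deposit = dep, points = res$points, emitted = res$emitted,
                 histories = config$histories, batches = config$batches,
                 seed = config$seed, warnings = res$warnings,
                 masses = phantom$masses, mode = phantom$spec$mode),
            class = "tally_result")
}

#' @export
print.tally_result <- function(x, ...) {
  tot <- colSums(x$deposit)
  cat(sprintf("<tally_result> %d histories in %d batches (seed %d)\n",
              x$histories, x$batches, x$seed))
  keep <- tot > 0
  cat("  deposits (keV):",
      paste(sprintf("%s %.4g", names(tot)[keep], tot[keep]), collapse = ", "),
      "\n")
  if (x$warnings > 0)
    cat("  livelock-guard terminations:", x$warnings, "\n")
  invisible(x)
}

#' Relative error of batch tallies
#'
#' Standard error of the batch means divided by the batch mean, per
#' compartment; the precision statistic held below 2% for the glandular
#' tally.
#'
#' @param tally A `tally_result` (or any matrix of per-batch values).
#' @return Named vector of relative errors; compartments with zero mean are
#'   reported as `NA` (flagged, not an error).
#' @export
relative_error <- function(tally) {
  m <- if (inherits(tally, "tally_result")) tally$deposit else as.matrix(tally)
  means <- colMeans(m)
  se <- apply(m, 2, sd) / sqrt(nrow(m))
  out <- ifelse(means > 0, se / means, NA_real_)
  names(out) <- colnames(m)
  out
}
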