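# Compressed-breast voxel phantom builder. The phantom is a semicircular
# slab (chest wall at y = 0), a 1.5 mm skin shell on every outer face except
# the chest-wall plane, and either spatially separate glandular/adipose
# compartments (non-mixture mode: the glandular region is a paraboloid of
# revolution widening from the nipple toward the chest wall) or a single
# homogeneous glandular/adipose blend filling the interior (mixture mode).

.LABELS <- c(air = 0L, skin = 1L, glandular = 2L, adipose = 3L, interior = 4L,
             paddle = 5L, support = 6L)

#' Phantom specification
#'
#' @param thickness_cm Compressed breast thickness in cm (the study grid uses
#'   4, 4.5 and 5; any value > 2 x skin is accepted).
#' @param glandular_fraction Target glandular fraction of the interior
#'   (non-skin) breast, in (0, 1); the study grid uses 0.25, 0.50, 0.75.
#' @param mode `"non-mixture"` (separate compartments) or `"mixture"`
#'   (homogeneous blend).
#' @param skin_mm Skin shell thickness, mm.
#' @param radius_cm Footprint radius of the chest-wall semicircle, cm.
#' @param voxel_mm Cubic voxel edge, mm.
#' @param fraction_basis Whether `glandular_fraction` is a mass or volume
#'   fraction of the interior.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(thickness_cm, glandular_fraction = 0.5,
                         mode = c("non-mixture", "mixture"), skin_mm = 1.5,
                         radius_cm = 8, voxel_mm = 1,
                         fraction_basis = c("mass", "volume")) {
  mode <- match.arg(mode)
  fraction_basis <- match.arg(fraction_basis)
  if (thickness_cm <= 2 * skin_mm / 10)
    stop("thickness must exceed twice the skin thickness")
  if (glandular_fraction <= 0 || glandular_fraction >= 1)
    stop("glandular_fraction must be in (0, 1)")
  if (radius_cm <= 0 || voxel_mm <= 0) stop("radius and voxel size must be > 0")
  structure(list(thickness_cm = thickness_cm,
                 glandular_fraction = glandular_fraction, mode = mode,
                 skin_mm = skin_mm, radius_cm = radius_cm,
                 voxel_mm = voxel_mm, fraction_basis = fraction_basis),
            class = "phantom_spec")
}

#' Build a voxel phantom
#'
#' Realizes the labeled voxel grid for a [phantom_spec]. In non-mixture mode
#' the glandular paraboloid's lateral scale is solved (by an order-statistic
#' equivalent of a monotone root find on the voxelized mass fraction) so the
#' interior glandular fraction matches the target within +/- 1% absolute.
#' In mixture mode every interior voxel holds a homogeneous blend whose
#' composition is the mass-fraction-weighted glandular/adipose mix and whose
#' density is the mass-weighted specific-volume blend
#' `1 / (g/rho_g + (1-g)/rho_a)` (which conserves component masses).
#'
#' Axes: origin at the chest-wall/support corner, x lateral (centered), y
#' chest wall to nipple, z support to paddle; the beam travels along -z.
#' Voxels are half-open cubes; labels are air/skin/glandular/adipose or
#' air/skin/interior.
#'
#' @param spec A [phantom_spec].
#' @return An object of class `voxel_phantom`: label array, voxel size,
#'   per-compartment masses (g), the material of each label, and the spec.
#' @export
#' @examples
#' ph <- build_phantom(phantom_spec(4, 0.5))
#' glandular_mass_fraction(ph)
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$voxel_mm / 10                      # cm
  R <- spec$radius_cm
  Tt <- spec$thickness_cm
  skin_cm <- spec$skin_mm / 10
  nx <- ceiling(2 * R / h); ny <- ceiling(R / h); nz <- round(Tt / h)
  x <- -R + (seq_len(nx) - 0.5) * h
  y <- (seq_len(ny) - 0.5) * h
  z <- (seq_len(nz) - 0.5) * h
  X <- array(rep(x, times = ny * nz), dim = c(nx, ny, nz))
  Y <- array(rep(rep(y, each = nx), times = nz), dim = c(nx, ny, nz))
  Z <- array(rep(z, each = nx * ny), dim = c(nx, ny, nz))
  rho <- sqrt(X^2 + Y^2)
  inside <- rho <= R
  surf_dist <- pmin(R - rho, Tt - Z, Z)        # chest-wall face is not skin
  labels <- array(.LABELS[["air"]], dim = c(nx, ny, nz))
  skin <- inside & surf_dist < skin_cm
  interior <- inside & !skin
  labels[skin] <- .LABELS[["skin"]]

  mats <- builtin_materials()
  materials <- list(air = mats$air, skin = mats$skin)
  g <- spec$glandular_fraction
  s2 <- NA_real_
  if (spec$mode == "mixture") {
    labels[interior] <- .LABELS[["interior"]]
    # blend over the union of element sets; absent elements contribute 0
    ga <- function(m, nm) {v <- m$composition[nm]; v[is.na(v)] <- 0; v}
    nm <- union(names(mats$glandular$composition),
                names(mats$adipose$composition))
    blend_comp <- g * ga(mats$glandular, nm) + (1 - g) * ga(mats$adipose, nm)
    names(blend_comp) <- nm
    blend_rho <- 1 / (g / mats$glandular$density + (1 - g) / mats$adipose$density)
    materials$interior <- material(sprintf("glandular/adipose blend g=%.3g", g),
                                   blend_comp, blend_rho)
  } else {
    # paraboloid of revolution: apex on the midplane axis at the nipple,
    # x^2 + (z - T/2)^2 <= s^2 * (y_apex - y)
    y_apex <- R - skin_cm
    a <- X[interior]^2 + (Z[interior] - Tt / 2)^2
    b <- y_apex - Y[interior]
    q <- ifelse(b > 0, a / b, Inf)
    n_int <- length(q)
    rho_g <- mats$glandular$density; rho_a <- mats$adipose$density
    n_g <- if (spec$fraction_basis == "mass")
      g * rho_a * n_int / (rho_g * (1 - g) + g * rho_a)
    else g * n_int
    n_g <- round(n_g)
    n_reachable <- sum(is.finite(q))
    if (n_g < 1 || n_g > n_reachable) {
      fmax <- if (spec$fraction_basis == "mass")
        rho_g * n_reachable / (rho_g * n_reachable + rho_a * (n_int - n_reachable))
      else n_reachable / n_int
      stop(sprintf(paste0("glandular target %.3f unreachable at this geometry/",
                          "voxel size; achievable range is (%.4f, %.4f)"),
                   g, 0, fmax))
    }
    s2 <- sort(q, partial = n_g)[n_g]
    gl <- logical(n_int)
    gl[q <= s2] <- TRUE
    lab_int <- ifelse(gl, .LABELS[["glandular"]], .LABELS[["adipose"]])
    labels[interior] <- lab_int
    materials$glandular <- mats$glandular
    materials$adipose <- mats$adipose
  }

  vol <- h^3
  counts <- tabulate(labels + 1L, nbins = 5L)
  names(counts) <- names(.LABELS)[1:5]
  dens <- c(air = mats$air$density, skin = mats$skin$density,
            glandular = mats$glandular$density, adipose = mats$adipose$density,
            interior = if (spec$mode == "mixture") materials$interior$density else NA)
  masses <- counts * vol * dens
  masses <- masses[counts > 0 & names(counts) != "air"]

  structure(list(labels = labels, voxel_cm = h, dims = c(nx, ny, nz),
                 origin = c(-R, 0, 0), masses = masses, materials = materials,
                 paraboloid_s2 = s2, spec = spec),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat(sprintf("<voxel_phantom> %s, %g cm thick, target glandular %.0f%%\n",
              x$spec$mode, x$spec$thickness_cm,
              100 * x$spec$glandular_fraction))
  cat(sprintf("  %d x %d x %d voxels of %.1f mm\n", x$dims[1], x$dims[2],
              x$dims[3], x$voxel_cm * 10))
  cat("  masses (g):",
      paste(sprintf("%s %.1f", names(x$masses), x$masses), collapse = ", "),
      "\n")
  if (x$spec$mode == "non-mixture")
    cat(sprintf("  realized glandular mass fraction %.4f\n",
                glandular_mass_fraction(x)))
  invisible(x)
}

#' Glandular mass fraction of the interior
#'
#' Glandular mass over glandular + adipose mass, skin excluded. For a
#' mixture-mode phantom the specified blend fraction is reported.
#'
#' @param phantom A `voxel_phantom`.
#' @return Fraction in `[0, 1]`.
#' @export
glandular_mass_fraction <- function(phantom) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  if (phantom$spec$mode == "mixture") return(phantom$spec$glandular_fraction)
  mg <- if ("glandular" %in% names(phantom$masses)) phantom$masses[["glandular"]] else 0
  ma <- if ("adipose" %in% names(phantom$masses)) phantom$masses[["adipose"]] else 0
  if (mg + ma == 0) stop("phantom has no interior")
  mg / (mg + ma)
}

#' Dosimeter positions inside the glandular region
#'
#' `n` points inside glandular voxels, spread along the chest-wall-to-nipple
#' axis at evenly spaced stations of the glandular extent, at mid-thickness;
#' the analog of the drilled dosimeter holes in the printed phantoms.
#' Deterministic; points are pairwise distinct and ordered by distance from
#' the chest wall.
#'
#' @param phantom A non-mixture `voxel_phantom` with a nonempty glandular
#'   region.
#' @param n Number of positions (default 6).
#' @return An `n` x 3 matrix of point coordinates (cm).
#' @export
dosimeter_positions <- function(phantom, n = 6) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  if (phantom$spec$mode != "non-mixture" ||
      !"glandular" %in% names(phantom$masses))
    stop("dosimeter positions require a non-mixture phantom with glandular tissue")
  idx <- which(phantom$labels == .LABELS[["glandular"]], arr.ind = TRUE)
  h <- phantom$voxel_cm
  pts <- cbind(phantom$origin[1] + (idx[, 1] - 0.5) * h,
               (idx[, 2] - 0.5) * h,
               (idx[, 3] - 0.5) * h)
  if (nrow(pts) < n) stop("glandular region too small for ", n, " positions")
  targets <- if (n == 1) {
    matrix(colMeans(pts), nrow = 1)
  } else {
    yq <- min(pts[, 2]) + (seq_len(n) - 0.5) / n * diff(range(pts[, 2]))
    cbind(0, yq, phantom$spec$thickness_cm / 2)
  }
  chosen <- integer(n)
  for (i in seq_len(n)) {
    d2 <- (pts[, 1] - targets[i, 1])^2 + (pts[, 2] - targets[i, 2])^2 +
      (pts[, 3] - targets[i, 3])^2
    d2[chosen[seq_len(i - 1)]] <- Inf
    chosen[i] <- which.min(d2)
  }
  if (anyDuplicated(chosen))
    stop("glandular region too small for ", n, " distinct positions")
  out <- pts[chosen, , drop = FALSE]
  out[order(out[, 2]), , drop = FALSE]
}

#' Export / import a phantom
#'
#' Writes the label volume as raw unsigned bytes (`<path>.raw`) with a
#' plain-text sidecar header (`<path>.hdr`) carrying dimensions, voxel size,
#' origin, the label legend with densities, and the building spec. The round
#' trip is bit-exact.
#'
#' @param phantom A `voxel_phantom`.
#' @param path Output path stem (extensions are appended).
#' @export
write_phantom <- function(phantom, path) {
  hdr <- c(sprintf("dims %d %d %d", phantom$dims[1], phantom$dims[2],
                   phantom$dims[3]),
           sprintf("voxel_cm %.17g", phantom$voxel_cm),
           sprintf("origin %.17g %.17g %.17g", phantom$origin[1],
                   phantom$origin[2], phantom$origin[3]),
           sprintf("labels %s", paste(sprintf("%s=%d", names(.LABELS)[1:5],
                                              .LABELS[1:5]), collapse = " ")),
           sprintf("spec thickness_cm=%.17g glandular_fraction=%.17g mode=%s skin_mm=%.17g radius_cm=%.17g voxel_mm=%.17g fraction_basis=%s",
                   phantom$spec$thickness_cm, phantom$spec$glandular_fraction,
                   phantom$spec$mode, phantom$spec$skin_mm,
                   phantom$spec$radius_cm, phantom$spec$voxel_mm,
                   phantom$spec$fraction_basis))
  writeLines(hdr, paste0(path, ".hdr"))
  writeBin(as.raw(phantom$labels), paste0(path, ".raw"))
  invisible(path)
}

#' @rdname write_phantom
#' @return `read_phantom()` returns the `voxel_phantom`.
#' @export
read_phantom <- function(path) {
  hdr <- readLines(paste0(path, ".hdr"))
  getv <- function(key) sub(paste0("^", key, " "), "",
                            hdr[startsWith(hdr, paste0(key, " "))])
  dims <- as.integer(strsplit(getv("dims"), " ")[[1]])
  sp <- strsplit(getv("spec"), " ")[[1]]
  kv <- do.call(rbind, strsplit(sp, "="))
  vals <- as.list(kv[, 2]); names(vals) <- kv[, 1]
  spec <- phantom_spec(as.numeric(vals$thickness_cm),
                       as.numeric(vals$glandular_fraction), vals$mode,
                       as.numeric(vals$skin_mm), as.numeric(vals$radius_cm),
                       as.numeric(vals$voxel_mm), vals$fraction_basis)
  raw <- readBin(paste0(path, ".raw"), what = "raw", n = prod(dims))
  ph <- build_phantom(spec)
  labels <- array(as.integer(raw), dim = dims)
  if (!identical(dim(ph$labels), dim(labels)))
    stop("header dimensions do not match the rebuilt phantom")
  ph$labels <- labels
  # recount masses from the imported grid
  counts <- tabulate(labels + 1L, nbins = 5L)
  names(counts) <- names(.LABELS)[1:5]
  dens <- vapply(names(counts), function(nm)
    if (!is.null(ph$materials[[nm]])) ph$materials[[nm]]$density else NA_real_,
    numeric(1))
  masses <- counts * ph$voxel_cm^3 * dens
  ph$masses <- masses[counts > 0 & names(counts) != "air"]
  ph
}
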