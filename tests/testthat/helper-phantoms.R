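# Hand-built voxel phantoms for transport validation geometries, plus a
# memoized copy of the full-scale study shared by the acceptance tests.

# A rectangular-box phantom assembled directly from a label array (bypassing
# build_phantom), for slab/cube validation scenes. The label array must span
# x in [-radius_cm, radius_cm - ...], y from 0, z from 0 upward.
box_phantom <- function(labels, voxel_cm, thickness_cm, radius_cm,
                        skin_mm = 1.5) {
  mats <- builtin_materials()
  counts <- tabulate(labels + 1L, nbins = 5L)
  names(counts) <- c("air", "skin", "glandular", "adipose", "interior")
  dens <- c(air = mats$air$density, skin = mats$skin$density,
            glandular = mats$glandular$density,
            adipose = mats$adipose$density, interior = NA_real_)
  masses <- (counts * voxel_cm^3 * dens)[counts > 0 & names(counts) != "air"]
  spec <- phantom_spec(thickness_cm, 0.5, "non-mixture", skin_mm = skin_mm,
                       radius_cm = radius_cm, voxel_mm = voxel_cm * 10)
  structure(list(labels = labels, voxel_cm = voxel_cm, dims = dim(labels),
                 origin = c(-radius_cm, 0, 0), masses = masses,
                 materials = list(air = mats$air, skin = mats$skin,
                                  glandular = mats$glandular,
                                  adipose = mats$adipose),
                 paraboloid_s2 = NA_real_, spec = spec),
            class = "voxel_phantom")
}

# 0.5 mm homogeneous glandular slab, 2 x 2 mm footprint, 0.5 mm voxels.
# The footprint is deliberately small so scattered photons leave the slab
# before re-interacting: the first-interaction kerma closed form the tests
# compare against is then exact to well below the statistical tolerance
# (a 1 x 1 cm footprint adds a ~+2% multiple-interaction excess).
thin_slab_phantom <- function() {
  labels <- array(2L, dim = c(4L, 4L, 1L))
  box_phantom(labels, voxel_cm = 0.05, thickness_cm = 0.05,
              radius_cm = 0.1, skin_mm = 0.1)
}

# 10 x 10 x 10 two-material cube (glandular lower half, adipose upper half),
# 2 mm voxels, 2 x 2 x 2 cm.
two_material_phantom <- function() {
  labels <- array(3L, dim = c(10L, 10L, 10L))
  labels[, , 1:5] <- 2L
  box_phantom(labels, voxel_cm = 0.2, thickness_cm = 2, radius_cm = 1)
}

# All-air label grid of the same cube dimensions.
air_phantom <- function() {
  labels <- array(0L, dim = c(10L, 10L, 10L))
  ph <- two_material_phantom()
  ph$labels <- labels
  ph$masses <- ph$masses[0]
  ph
}

# Beam used with the box phantoms: no paddle or support slabs, small field.
box_beam <- function(field_cm = c(2, 2)) {
  beam_config(paddle_mm = 0, support_mm = 0, field_cm = field_cm)
}

# Single-bin (monoenergetic to within one 0.1 keV bin) spectrum.
mono_spectrum <- function(edge_kev, fluence = 1) {
  mgdsim:::.new_spectrum(edge_kev, fluence, kvp = 28)
}

# The full-scale study shared by the acceptance criteria: default 3 x 3 x 2
# grid with the mixture companion, 10^6 histories per cell in 20 batches,
# master seed 1. Memoized so the acceptance file pays for it once.
.test_cache <- new.env(parent = emptyenv())

full_scale_study <- function() {
  if (is.null(.test_cache$study)) {
    .test_cache$study <- run_study(
      transport = transport_config(histories = 1e6, batches = 20, seed = 1),
      mixture_companion = TRUE)
  }
  .test_cache$study
}
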