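# Source sampling, interaction physics, delta tracking, batch statistics.

test_that("transport_config validates and records its fields", {
  expect_error(transport_config(kerma = FALSE), "kerma")
  expect_error(transport_config(batches = 1), "batches")
  expect_error(transport_config(histories = 5, batches = 10), ">=")
  tc <- transport_config(histories = 1000, batches = 4, seed = 7)
  expect_equal(tc$histories, 1000L)
  expect_equal(tc$seed, 7L)
})

test_that("single-bin source sampling stays within the bin", {
  src <- sample_source(mono_spectrum(20), beam_config(), 1000, seed = 5)
  expect_true(all(src$energy >= 20 & src$energy <= 20.1))
  expect_equal(sqrt(rowSums(src$direction^2)), rep(1, 1000),
               tolerance = 1e-9)
  # without a phantom, emission points lie on the z = 0 field plane
  expect_equal(unname(src$position[, 3]), rep(0, 1000))
  expect_true(all(abs(src$position[, 1]) <= 12))
  expect_true(all(src$position[, 2] >= 0 & src$position[, 2] <= 18))
})

test_that("sampled energies follow the bin probabilities within 3 sigma", {
  edges <- c(10, 10.1, 10.2, 10.3, 10.4)
  fl <- c(5, 1, 3, 2, 4)
  s <- mgdsim:::.new_spectrum(edges, fl, kvp = 28)
  n <- 1e5
  src <- sample_source(s, beam_config(), n, seed = 11)
  counts <- tabulate(findInterval(src$energy, edges), nbins = 5)
  p <- fl / sum(fl)
  expect_true(all(abs(counts - n * p) <= 3 * sqrt(n * p * (1 - p))))
})

test_that("source sampling is deterministic in the seed", {
  s <- mammography_beam(beam_config(filter = "Rh"))
  a <- sample_source(s, beam_config(), 500, seed = 42)
  b <- sample_source(s, beam_config(), 500, seed = 42)
  expect_identical(a, b)
  c <- sample_source(s, beam_config(), 500, seed = 43)
  expect_false(identical(a$energy, c$energy))
  expect_error(sample_source(mgdsim:::.new_spectrum(10, 0, 28),
                             beam_config(), 10), "all-zero")
})

test_that("Compton samples obey the scattering relation and its limits", {
  sm <- sample_compton(28, 2e4, seed = 3)
  k <- 28 / 510.99895
  expect_equal(sm$energy, 28 / (1 + k * (1 - cos(sm$angle))),
               tolerance = 1e-12)
  expect_equal(sm$recoil, 28 - sm$energy, tolerance = 1e-12)
  # forward limit E' -> E, backscatter bound E'(pi) = 28/(1 + 2k)
  expect_true(all(sm$energy <= 28 + 1e-12))
  expect_true(all(sm$energy >= 28 / (1 + 2 * k) - 1e-12))
})

test_that("Klein-Nishina mean cosine matches quadrature within 3 sigma", {
  n <- 1e6
  sm <- sample_compton(20, n, seed = 17)
  cost <- cos(sm$angle)
  se <- sd(cost) / sqrt(n)
  expect_lt(abs(mean(cost) - oracle_kn_mean_cost(20)), 3 * se)
})

test_that("interaction channel frequencies match the coefficients", {
  n <- 1e5
  draws <- sample_interaction("glandular", 20, n, seed = 9)
  p <- attr(draws, "probabilities")
  expect_equal(sum(p), 1, tolerance = 1e-12)
  counts <- table(factor(draws, levels = names(p)))
  expect_true(all(abs(counts - n * p) <= 3 * sqrt(n * p * (1 - p))))
  # probabilities proportional to the partial coefficients
  parts <- c(mass_attenuation("glandular", 20, "photoelectric"),
             mass_attenuation("glandular", 20, "incoherent"),
             mass_attenuation("glandular", 20, "coherent"))
  expect_equal(unname(p), parts / sum(parts), tolerance = 1e-12)
})

test_that("disabling coherent folds it out; high-Z low-E is photoelectric", {
  d <- sample_interaction("tungsten", 5, 1000, seed = 2, coherent = FALSE)
  p <- attr(d, "probabilities")
  expect_named(p, c("photoelectric", "incoherent"))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_gt(p[["photoelectric"]], 0.95)
  expect_true(all(d %in% c("photoelectric", "incoherent")))
})

test_that("an air-only phantom deposits nothing in tissue compartments", {
  tal <- run_transport(air_phantom(), mono_spectrum(20), box_beam(),
                       transport_config(histories = 2000, batches = 4,
                                        seed = 1))
  expect_equal(sum(tal$deposit[, "glandular"]), 0)
  expect_equal(sum(tal$deposit[, "adipose"]), 0)
  expect_equal(sum(tal$deposit[, "skin"]), 0)
})

test_that("thin-slab dose per fluence brackets the kerma closed form", {
  ph <- thin_slab_phantom()
  E <- 20.05
  gl <- get_material("glandular")
  tal <- run_transport(ph, mono_spectrum(20), box_beam(c(1, 1)),
                       transport_config(histories = 2e5, batches = 10,
                                        seed = 4),
                       parallel = TRUE)
  t_cm <- 0.05
  mu <- linear_attenuation(gl, E)
  # closed form: E * (mu_en/rho) per unit fluence, with the exact one-pass
  # attenuation factor (1 - exp(-mu t))/(mu t) -> 1 as t -> 0. This counts
  # the FIRST interaction only; scattered photons re-interacting before they
  # leave the slab add a small signed excess, bounded above by the scatter
  # share times the longest-chord interaction probability (with a cascade
  # factor). The MC must land between the closed form (minus noise) and the
  # closed form plus that allowance (plus noise).
  expected <- E * mass_energy_absorption(gl, E) * gl$density * t_cm *
    (1 - exp(-mu * t_cm)) / (mu * t_cm)
  measured <- sum(tal$deposit[, "glandular"]) / tal$histories
  batch_means <- tal$deposit[, "glandular"] / (tal$histories / tal$batches)
  se <- sd(batch_means) / sqrt(tal$batches)
  scat <- (mass_attenuation(gl, E, "incoherent") +
             mass_attenuation(gl, E, "coherent")) / mass_attenuation(gl, E)
  chord <- sqrt(0.2^2 + 0.2^2 + t_cm^2)
  x <- scat * (1 - exp(-mu * chord))
  expect_gte(measured, expected - 3 * se)
  expect_lte(measured, expected * (1 + x / (1 - x)) + 3 * se)
  expect_equal(ncol(tal$points), 6L)
  expect_true(all(tal$points >= 0))
})

test_that("delta tracking agrees with a ray-marching reference within 3 sigma", {
  ph <- two_material_phantom()
  n <- 4000; batches <- 10
  tal <- run_transport(ph, mono_spectrum(20), box_beam(),
                       transport_config(histories = n, batches = batches,
                                        seed = 123),
                       parallel = TRUE)
  per_hist <- n / batches
  mc <- tal$deposit[, "glandular"] / per_hist
  ref <- ray_march_reference(ph, box_beam(), 20.05, n, batches,
                             seed = 321) / per_hist
  se <- sqrt(var(mc) / batches + var(ref) / batches)
  expect_lt(abs(mean(mc) - mean(ref)), 3 * se)
})

test_that("energy is conserved per batch and livelocks are absent", {
  tal <- run_transport(two_material_phantom(), mono_spectrum(20), box_beam(),
                       transport_config(histories = 5000, batches = 5,
                                        seed = 6))
  expect_true(all(tal$deposit >= 0))
  expect_true(all(rowSums(tal$deposit) <= tal$emitted + 1e-9))
  expect_true(all(rowSums(tal$deposit) < tal$emitted))   # some photons escape
  expect_equal(tal$warnings, 0)
})

test_that("identical seeds give bit-identical tallies, different seeds differ", {
  ph <- two_material_phantom()
  cfg <- transport_config(histories = 3000, batches = 3, seed = 77)
  t1 <- run_transport(ph, mono_spectrum(20), box_beam(), cfg)
  t2 <- run_transport(ph, mono_spectrum(20), box_beam(), cfg)
  expect_identical(t1, t2)
  expect_identical(serialize(t1, NULL), serialize(t2, NULL))
  cfg2 <- transport_config(histories = 3000, batches = 3, seed = 78)
  t3 <- run_transport(ph, mono_spectrum(20), box_beam(), cfg2)
  expect_false(identical(t1$deposit, t3$deposit))
})

test_that("relative error follows the direct arithmetic formula", {
  m <- matrix(c(1, 2, 3, 4), ncol = 1, dimnames = list(NULL, "glandular"))
  re <- relative_error(m)
  expect_equal(unname(re), (sd(c(1, 2, 3, 4)) / sqrt(4)) / 2.5)
  expect_equal(unname(relative_error(matrix(rep(2, 4), ncol = 1))), 0)
  expect_true(is.na(relative_error(matrix(0, 4, 1))[1]))
})

test_that("relative error shrinks roughly as one over root N", {
  ph <- two_material_phantom()
  s <- mammography_beam(beam_config(filter = "Rh"))
  r1 <- relative_error(run_transport(ph, s, box_beam(),
                                     transport_config(histories = 5000,
                                                      batches = 40,
                                                      seed = 10)))
  r2 <- relative_error(run_transport(ph, s, box_beam(),
                                     transport_config(histories = 20000,
                                                      batches = 40,
                                                      seed = 10)))
  ratio <- r1[["glandular"]] / r2[["glandular"]]
  # expected 2 for a 4x history increase; bounds are ~3 sigma of the
  # chi-distributed batch-sd estimates at 40 batches
  expect_gt(ratio, 1.25)
  expect_lt(ratio, 3.2)
})
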