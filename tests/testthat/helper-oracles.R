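# Independent reference implementations ("oracles") used by the tests. These
# deliberately re-derive results from first principles or from the raw
# packaged data files, without going through the package's own interpolation,
# sampling or tracking code paths.

# Log-log interpolation of one raw packaged element table, written from
# scratch (manual bracketing, no approx()).
oracle_element_mu <- function(symbol, energy, column = "total") {
  path <- system.file("extdata", "xs", paste0(symbol, ".txt"),
                      package = "mgdsim")
  tab <- utils::read.table(path, comment.char = "#")
  names(tab) <- c("energy", "photoelectric", "incoherent", "coherent",
                  "total", "energy_absorption")
  vapply(energy, function(E) {
    i <- max(which(tab$energy <= E))
    if (tab$energy[i] == E) return(tab[[column]][i])
    j <- i + 1L
    w <- (log(E) - log(tab$energy[i])) /
      (log(tab$energy[j]) - log(tab$energy[i]))
    exp((1 - w) * log(tab[[column]][i]) + w * log(tab[[column]][j]))
  }, numeric(1))
}

# Brute-force mixture rule: per-element summation over the raw tables.
oracle_mixture_mu <- function(composition, energy, column = "total") {
  out <- 0
  for (el in names(composition))
    out <- out + composition[[el]] * oracle_element_mu(el, energy, column)
  out
}

# Klein-Nishina angular distribution (unnormalized) and its quadrature mean
# cosine, independent of the C++ rejection sampler.
kn_pdf_unnorm <- function(cost, energy_kev) {
  k <- energy_kev / 510.99895
  r <- 1 / (1 + k * (1 - cost))
  r^2 * (r + 1 / r - (1 - cost^2))
}

oracle_kn_mean_cost <- function(energy_kev) {
  num <- stats::integrate(function(c) c * kn_pdf_unnorm(c, energy_kev),
                          -1, 1, rel.tol = 1e-10)$value
  den <- stats::integrate(function(c) kn_pdf_unnorm(c, energy_kev),
                          -1, 1, rel.tol = 1e-10)$value
  num / den
}

# Plain R rejection samplers (independent of the C++ kernel) for the
# ray-marching reference transport below.
.r_kn_sample_cost <- function(energy_kev) {
  repeat {
    cost <- stats::runif(1, -1, 1)
    if (stats::runif(1) * 2 <= kn_pdf_unnorm(cost, energy_kev)) return(cost)
  }
}

.r_thomson_sample_cost <- function() {
  repeat {
    cost <- stats::runif(1, -1, 1)
    if (stats::runif(1) * 2 <= 1 + cost^2) return(cost)
  }
}

.r_rotate <- function(w, cost, phi) {
  sint <- sqrt(max(0, 1 - cost^2))
  h <- if (abs(w[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(w[2] * h[3] - w[3] * h[2],
         w[3] * h[1] - w[1] * h[3],
         w[1] * h[2] - w[2] * h[1])
  u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  d <- cost * w + sint * (cos(phi) * u + sin(phi) * v)
  d / sqrt(sum(d^2))
}

# Reference photon transport by direct voxel ray-marching (explicit boundary
# crossings, no delta tracking), monoenergetic parallel beam along -z.
# Returns the per-batch glandular deposit (keV). Uses R's own RNG throughout.
ray_march_reference <- function(phantom, beam, energy_kev, histories,
                                batches, seed, cutoff_kev = 1) {
  set.seed(seed)
  labels <- phantom$labels
  dims <- phantom$dims
  h <- phantom$voxel_cm
  origin <- phantom$origin
  R <- phantom$spec$radius_cm
  fx <- beam$field_cm[2] / 2
  fy <- beam$field_cm[1]
  rect <- c(max(-fx, -R), min(fx, R), 0, min(fy, R))
  ztop <- dims[3] * h
  mats <- list(builtin_materials()$air, builtin_materials()$skin,
               builtin_materials()$glandular, builtin_materials()$adipose)
  mu_at <- function(E) vapply(mats, function(m)
    mass_attenuation(m, E, "total") * m$density, numeric(1))
  channel_probs <- function(lab, E) {
    m <- mats[[lab + 1L]]
    p <- c(mass_attenuation(m, E, "photoelectric"),
           mass_attenuation(m, E, "incoherent"),
           mass_attenuation(m, E, "coherent"))
    p / sum(p)
  }
  # march one flight; returns NULL on escape, else list(pos, lab)
  march <- function(pos, dir, mu_vec) {
    tau <- -log(stats::runif(1))
    repeat {
      ijk <- floor((pos - origin) / h) + 1
      if (any(ijk < 1) || any(ijk > dims)) return(NULL)
      lab <- labels[ijk[1], ijk[2], ijk[3]]
      mu <- mu_vec[lab + 1L]
      tb <- Inf
      for (a in 1:3) if (dir[a] != 0) {
        edge <- origin[a] + (ijk[a] - (dir[a] < 0)) * h
        tb <- min(tb, (edge - pos[a]) / dir[a])
      }
      tb <- max(tb, 0)
      if (mu > 0 && mu * tb >= tau)
        return(list(pos = pos + dir * (tau / mu), lab = lab))
      tau <- tau - mu * tb
      pos <- pos + dir * (tb + 1e-9)
    }
  }
  per_batch <- numeric(batches)
  for (b in seq_len(batches)) {
    dep <- 0
    for (i in seq_len(histories %/% batches)) {
      pos <- c(stats::runif(1, rect[1], rect[2]),
               stats::runif(1, rect[3], rect[4]), ztop - 1e-9)
      dir <- c(0, 0, -1)
      E <- energy_kev
      mu_vec <- mu_at(E)
      repeat {
        hit <- march(pos, dir, mu_vec)
        if (is.null(hit)) break
        pos <- hit$pos
        probs <- channel_probs(hit$lab, E)
        u <- stats::runif(1)
        if (u < probs[1]) {                          # photoelectric
          if (hit$lab == 2L) dep <- dep + E
          break
        } else if (u < probs[1] + probs[2]) {        # incoherent
          cost <- .r_kn_sample_cost(E)
          Es <- E / (1 + E / 510.99895 * (1 - cost))
          if (hit$lab == 2L) dep <- dep + (E - Es)
          if (Es < cutoff_kev) {
            if (hit$lab == 2L) dep <- dep + Es
            break
          }
          dir <- .r_rotate(dir, cost, stats::runif(1, 0, 2 * pi))
          E <- Es
          mu_vec <- mu_at(E)
        } else {                                     # coherent
          dir <- .r_rotate(dir, .r_thomson_sample_cost(),
                           stats::runif(1, 0, 2 * pi))
        }
      }
    }
    per_batch[b] <- dep
  }
  per_batch
}
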