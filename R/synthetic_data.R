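# ---------------------------------------------------------------------------
# Seeded synthetic-data generators: toy membrane complexes with a known
# expansion field and known ring orientations, serial shot sets with known
# twin assignments, unit-cell mixtures, and model ensembles with a known
# angular spread. Every generator is a pure function of (spec, seed).
# ---------------------------------------------------------------------------

#' Specification for a toy membrane-complex pair
#'
#' The toy complex emulates the statistical structure the expansion and
#' pocket pipelines consume: Mg marker "chlorophylls" on a cylindrical
#' lattice about a synthetic P700-FX axis, four Fe markers for the
#' iron-sulfur cluster, and hexagonal ring pairs at prescribed interplanar
#' angles and separations. Marker atoms are named so the shipped
#' `synthetic` registry dialect resolves them; full cofactor chemistry is
#' deliberately absent because the pipelines touch only these atoms.
#'
#' Defaults mirror the scale of the real complex: 96 chlorophylls, an
#' electron-transfer axis of ~30 Angstrom, antenna radii to 55 Angstrom,
#' and an in-plane scale of 1.005 -- the magnitude of thermal expansion a
#' room-temperature structure shows against a cryogenic reference.
#'
#' @param n_chl total chlorophyll count including the two P700 markers.
#' @param axis_length P700-centre to FX-centre distance, Angstrom.
#' @param radial_range antenna radial interval, Angstrom.
#' @param radial_scale in-plane (radial) scale factor of the alternate
#'   structure relative to the reference.
#' @param axial_scale scale along the axis (1 = no perpendicular change).
#' @param ring_pairs data.frame with columns `angle` (degrees, 0-90) and
#'   `separation` (Angstrom); default: six pairs at the characteristic
#'   pocket geometries.
#' @param seed integer RNG seed.
#' @return list of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(n_chl = 96L, axis_length = 30,
                             radial_range = c(10, 55),
                             radial_scale = 1.005, axial_scale = 1.0,
                             ring_pairs = NULL, seed = 1L) {
  if (is.null(ring_pairs)) {
    ring_pairs <- data.frame(
      angle = c(13, 73, 16, 13, 50, 45),
      separation = c(3.9, 3.3, 3.0, 3.0, 3.5, 7.0))
  }
  stopifnot(radial_scale > 0, axial_scale > 0,
            all(ring_pairs$angle >= 0 & ring_pairs$angle <= 90),
            n_chl >= 4L)
  structure(list(n_chl = as.integer(n_chl), axis_length = axis_length,
                 radial_range = radial_range, radial_scale = radial_scale,
                 axial_scale = axial_scale, ring_pairs = ring_pairs,
                 seed = as.integer(seed)),
            class = "toy_complex_spec")
}

hexagon_points <- function(radius = 1.39) {
  th <- (0:5) * pi / 3
  cbind(radius * cos(th), radius * sin(th), 0)
}

atom_row <- function(chain, resid, resno, atom, element, xyz) {
  data.frame(chain = chain, resid = resid, resno = resno, atom = atom,
             element = element, x = xyz[1], y = xyz[2], z = xyz[3],
             o = 1, b = 20, alt = "", hydrogen = FALSE,
             stringsAsFactors = FALSE)
}

#' Generate a reference/alternate toy complex pair
#'
#' The reference structure is built about the z axis (P700 centre at the
#' origin, FX centre at `(0, 0, axis_length)`); the alternate structure
#' multiplies every in-plane coordinate by `radial_scale` and every axial
#' coordinate (about the frame origin) by `axial_scale`, so the
#' ground-truth per-chlorophyll displacements are
#' `delta_parallel = (radial_scale - 1) * radial_ref` exactly.
#'
#' @param spec a [toy_complex_spec()].
#' @return list with `ref` and `alt` (`psi_structure`s, dialect
#'   `synthetic`), and `truth` (per-chlorophyll cylindrical table, the ring
#'   table, and the applied scales).
#' @export
make_toy_complex_pair <- function(spec = toy_complex_spec()) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  L <- spec$axis_length
  rows <- list()
  # P700 special pair: two Mg 6.3 A apart, perpendicular to the axis
  rows[[1]] <- atom_row("A", "CLA", 1L, "MG", "MG", c(-3.15, 0, 0))
  rows[[2]] <- atom_row("B", "CLA", 1L, "MG", "MG", c(3.15, 0, 0))
  # FX: tetrahedron of four Fe about the axis end
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * 1.3
  for (j in 1:4) {
    rows[[length(rows) + 1L]] <-
      atom_row("X", "SF4", 1L, paste0("FE", j), "FE", tet[j, ] + c(0, 0, L))
  }
  n_ant <- spec$n_chl - 2L
  ant <- with_seed(spec$seed, {
    r <- runif(n_ant, spec$radial_range[1], spec$radial_range[2])
    th <- runif(n_ant, 0, 2 * pi)
    z <- runif(n_ant, -8, L + 8)
    list(r = r, th = th, z = z,
         ring_theta = runif(nrow(spec$ring_pairs), 0, 2 * pi))
  })
  for (i in seq_len(n_ant)) {
    rows[[length(rows) + 1L]] <- atom_row(
      "C", "CLA", i, "MG", "MG",
      c(ant$r[i] * cos(ant$th[i]), ant$r[i] * sin(ant$th[i]), ant$z[i]))
  }
  # ring pairs: ring a in the xy-plane orientation (normal along z),
  # ring b tilted by the prescribed angle about the x axis and displaced
  # along ring a's normal by the prescribed separation
  hexa <- hexagon_points()
  for (k in seq_len(nrow(spec$ring_pairs))) {
    ang <- spec$ring_pairs$angle[k]
    sep <- spec$ring_pairs$separation[k]
    ctr <- c(20 * cos(ant$ring_theta[k]), 20 * sin(ant$ring_theta[k]),
             L / 2 + 3 * k - 9)
    rot <- rotation_matrix(c(1, 0, 0), ang)
    pa <- sweep(hexa, 2L, ctr, "+")
    pb <- sweep(hexa %*% t(rot), 2L, ctr + c(0, 0, sep), "+")
    for (j in 1:6) {
      rows[[length(rows) + 1L]] <- atom_row(
        "Q", "RNG", 2L * k - 1L, paste0("C", j), "C", pa[j, ])
      rows[[length(rows) + 1L]] <- atom_row(
        "Q", "RNG", 2L * k, paste0("C", j), "C", pb[j, ])
    }
  }
  at <- do.call(rbind, rows)
  ref <- new_structure(at, identifier = "synthetic_ref")
  at_alt <- at
  at_alt$x <- at$x * spec$radial_scale
  at_alt$y <- at$y * spec$radial_scale
  at_alt$z <- L / 2 + (at$z - L / 2) * spec$axial_scale
  alt <- new_structure(at_alt, identifier = "synthetic_alt")
  chl_truth <- data.frame(
    chl_label = c("eC-A1", "eC-B1", paste0("C", seq_len(n_ant))),
    radial_ref = c(3.15, 3.15, ant$r),
    axial_ref = c(-L / 2, -L / 2, ant$z - L / 2),
    stringsAsFactors = FALSE)
  chl_truth$delta_parallel <- (spec$radial_scale - 1) * chl_truth$radial_ref
  chl_truth$delta_perpendicular <-
    (spec$axial_scale - 1) * chl_truth$axial_ref
  ring_truth <- cbind(spec$ring_pairs,
                      ring_a = paste0("ring", seq_len(nrow(spec$ring_pairs)),
                                      "_a"),
                      ring_b = paste0("ring", seq_len(nrow(spec$ring_pairs)),
                                      "_b"))
  list(ref = ref, alt = alt,
       truth = list(chl = chl_truth, rings = ring_truth,
                    radial_scale = spec$radial_scale,
                    axial_scale = spec$axial_scale))
}

#' Specification for a simulated serial shot set
#'
#' Shots draw a random subset of a common reference intensity table
#' (Wilson-like squared-normal intensities), multiply by lognormal
#' partiality-like noise, and with a fixed probability have their indices
#' transformed by a twin operator -- the inputs of the indexing-ambiguity
#' problem, with ground truth recorded. Defaults reflect a realistic
#' serial experiment on the hexagonal isoform: point group 6, its
#' two-fold twin operator, 30% of the reference observed per shot, and a
#' 20% multiplicative noise level.
#'
#' @param n_reflections reference table size.
#' @param n_shots number of shots.
#' @param observation_rate fraction of the reference observed per shot.
#' @param noise_cv coefficient of variation of the lognormal noise.
#' @param flip_fraction probability a shot is indexed in the twin setting.
#' @param point_group crystal point-group symbol.
#' @param op twin `reindex_op`; default the first non-identity coset
#'   operator of the point group.
#' @param cell unit cell (hexagonal default `285.4, 285.4, 166.5`).
#' @param noise_cv_slope optional resolution dependence of the noise: the
#'   per-reflection coefficient of variation grows linearly in 1/d from
#'   `noise_cv` at the lowest resolution to
#'   `noise_cv * (1 + noise_cv_slope)` at the highest, emulating the
#'   fading of high-resolution signal.
#' @param signal_dmin optional designed diffraction limit: beyond this
#'   d-spacing shots record zero intensity (no Bragg signal), for cutoff
#'   recovery tests.
#' @param seed integer RNG seed.
#' @return list of class `shot_sim_spec`.
#' @export
shot_sim_spec <- function(n_reflections = 2000L, n_shots = 100L,
                          observation_rate = 0.3, noise_cv = 0.2,
                          flip_fraction = 0.5, point_group = "6",
                          op = NULL,
                          cell = c(285.4, 285.4, 166.5, 90, 90, 120),
                          noise_cv_slope = 0, signal_dmin = NULL,
                          seed = 1L) {
  stopifnot(observation_rate >= 0, observation_rate <= 1,
            flip_fraction >= 0, flip_fraction <= 1, noise_cv >= 0)
  if (is.null(op)) {
    ops <- coset_operators(point_group)
    if (length(ops) < 2L) stop("point group ", point_group,
                               " has no indexing ambiguity")
    op <- ops[[2L]]
  }
  structure(list(n_reflections = as.integer(n_reflections),
                 n_shots = as.integer(n_shots),
                 observation_rate = observation_rate, noise_cv = noise_cv,
                 flip_fraction = flip_fraction,
                 point_group = as.character(point_group), op = op,
                 cell = cell, noise_cv_slope = noise_cv_slope,
                 signal_dmin = signal_dmin,
                 seed = as.integer(seed)),
            class = "shot_sim_spec")
}

#' Simulate a serial shot set with a known twin assignment
#'
#' @param spec a [shot_sim_spec()].
#' @return list with `shots` (list of `shot`, `true_operator` = 1 for the
#'   reference setting, 2 for the twin setting) and `reference`
#'   (data.frame `h, k, l, I` of true canonical intensities).
#' @export
simulate_shots <- function(spec = shot_sim_spec()) {
  stopifnot(inherits(spec, "shot_sim_spec"))
  with_seed(spec$seed, {
    n_cand <- spec$n_reflections * 6L
    cand <- cbind(sample.int(60L, n_cand, replace = TRUE) - 1L,
                  sample.int(60L, n_cand, replace = TRUE) - 1L,
                  sample.int(81L, n_cand, replace = TRUE) - 1L)
    cand <- cand[rowSums(abs(cand)) > 0, , drop = FALSE]
    cand <- asu_map(cand, spec$point_group)
    # a measurable reflection set is closed under the twin operator: keep
    # canonical classes in twin-mate pairs (twin-invariant classes carry no
    # assignment information and are dropped from the synthetic reference)
    mate <- asu_map(cand %*% t(spec$op$matrix), spec$point_group)
    key_c <- encode_hkl(cand)
    key_m <- encode_hkl(mate)
    keep <- key_c < key_m  # one row per non-invariant pair
    pairs <- cbind(cand[keep, , drop = FALSE], mate[keep, , drop = FALSE])
    pairs <- pairs[!duplicated(pairs[, 1:3, drop = FALSE]), , drop = FALSE]
    n_pairs <- floor(spec$n_reflections / 2)
    if (nrow(pairs) < n_pairs) {
      stop("could not generate enough distinct reflection pairs")
    }
    pairs <- pairs[seq_len(n_pairs), , drop = FALSE]
    hkl <- rbind(pairs[, 1:3, drop = FALSE], pairs[, 4:6, drop = FALSE])
    if (anyDuplicated(encode_hkl(hkl))) {
      stop("internal error: reflection set not uniquely paired")
    }
    n_refl <- nrow(hkl)
    i_ref <- 100 * rnorm(n_refl)^2  # Wilson-like, heavy-tailed
    d <- d_spacing(spec$cell, hkl)
    dead <- if (!is.null(spec$signal_dmin)) d < spec$signal_dmin
            else rep(FALSE, n_refl)
    q <- 1 / d
    qn <- if (diff(range(q)) > 0) (q - min(q)) / diff(range(q)) else q * 0
    cv <- spec$noise_cv * (1 + spec$noise_cv_slope * qn)
    sdlog <- sqrt(log(1 + cv^2))
    n_obs <- max(3L, round(spec$observation_rate * n_refl))
    shots <- vector("list", spec$n_shots)
    for (s in seq_len(spec$n_shots)) {
      pick <- sort(sample.int(n_refl, n_obs))
      ii <- i_ref[pick]
      if (spec$noise_cv > 0) {
        sl <- sdlog[pick]
        ii <- ii * exp(rnorm(n_obs, -sl^2 / 2, sl))
      }
      ii[dead[pick]] <- 0
      flipped <- runif(1) < spec$flip_fraction
      hh <- hkl[pick, , drop = FALSE]
      if (flipped) hh <- hh %*% t(spec$op$matrix)
      shots[[s]] <- new_shot(
        sprintf("shot%05d", s),
        data.frame(h = hh[, 1L], k = hh[, 2L], l = hh[, 3L], I = ii,
                   sigma = pmax(0.05 * ii, 1e-3)),
        cell = spec$cell,
        true_operator = if (flipped) 2L else 1L)
    }
    list(shots = shots,
         reference = data.frame(h = hkl[, 1L], k = hkl[, 2L],
                                l = hkl[, 3L], I = i_ref))
  })
}

#' Simulate per-lattice unit-cell samples from a Gaussian mixture
#'
#' @param modes list of `list(mean, sd, weight)` components for the chosen
#'   parameter (weights must sum to 1).
#' @param n number of lattices.
#' @param seed integer RNG seed.
#' @param parameter which cell parameter the mixture describes.
#' @param base_cell nominal values of the remaining parameters.
#' @return data.frame of cells `a, b, c, alpha, beta, gamma` with `n`
#'   rows; when `parameter = "a"` on a hexagonal base cell, `b` tracks
#'   `a`.
#' @export
simulate_cells <- function(modes, n, seed = 1L, parameter = "a",
                           base_cell = c(285.4, 285.4, 166.5, 90, 90, 120)) {
  w <- vapply(modes, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9) stop("mode weights must sum to 1")
  cells <- data.frame(a = rep(base_cell[1], n), b = rep(base_cell[2], n),
                      c = rep(base_cell[3], n),
                      alpha = rep(base_cell[4], n),
                      beta = rep(base_cell[5], n),
                      gamma = rep(base_cell[6], n))
  if (n == 0L) return(cells)
  vals <- with_seed(seed, {
    comp <- sample.int(length(modes), n, replace = TRUE, prob = w)
    mu <- vapply(modes, `[[`, numeric(1), "mean")
    sg <- vapply(modes, `[[`, numeric(1), "sd")
    rnorm(n, mu[comp], sg[comp])
  })
  cells[[parameter]] <- vals
  if (parameter == "a" && abs(base_cell[1] - base_cell[2]) < 1e-9) {
    cells$b <- vals
  }
  cells
}

#' Generate a model ensemble with a prescribed angular spread
#'
#' Stands in for re-refinement in the perturbation workflow: each copy of
#' the base structure rotates every designated ring set independently
#' about a random axis lying in its own plane (through its centroid) by an
#' angle drawn from `Normal(0, angular_sd^2)`. When both rings of a
#' stacked pair are designated and their base angle is away from the 0/90
#' degree folds, the interplanar-angle spread across the ensemble equals
#' `angular_sd` (each ring contributes variance `angular_sd^2 / 2`).
#'
#' @param base a `psi_structure` containing the ring sets.
#' @param ring_sets character names of ring sets to jitter.
#' @param registry,dialect cofactor-map context resolving the ring sets.
#' @param angular_sd angular standard deviation, degrees.
#' @param n ensemble size (100 matches the usual perturbation protocol).
#' @param seed integer RNG seed.
#' @return list of `n` `psi_structure` models.
#' @export
make_model_ensemble <- function(base, ring_sets, registry = read_registry(),
                                dialect = "synthetic", angular_sd = 2,
                                n = 100L, seed = 1L) {
  map <- build_cofactor_map(base, registry, dialect)
  missing <- setdiff(ring_sets, names(map$ring_sets))
  if (length(missing) > 0L) {
    stop("base structure lacks ring sets: ", paste(missing, collapse = ", "))
  }
  idx_list <- map$ring_sets[ring_sets]
  with_seed(seed, {
    lapply(seq_len(n), function(model_i) {
      s <- base
      s$identifier <- sprintf("%s_model%03d", base$identifier, model_i)
      for (idx in idx_list) {
        xyz <- atom_xyz(s, idx)
        pl <- fit_plane(xyz)
        # orthonormal in-plane basis
        e1 <- xyz[1L, ] - pl$centroid
        e1 <- e1 - sum(e1 * pl$unit_normal) * pl$unit_normal
        e1 <- e1 / sqrt(sum(e1^2))
        e2 <- c(pl$unit_normal[2] * e1[3] - pl$unit_normal[3] * e1[2],
                pl$unit_normal[3] * e1[1] - pl$unit_normal[1] * e1[3],
                pl$unit_normal[1] * e1[2] - pl$unit_normal[2] * e1[1])
        phi <- runif(1, 0, 2 * pi)
        axis <- cos(phi) * e1 + sin(phi) * e2
        ang <- rnorm(1, 0, angular_sd)
        rot <- rotation_matrix(axis, ang)
        moved <- sweep(sweep(xyz, 2L, pl$centroid) %*% t(rot), 2L,
                       -pl$centroid)
        s$atoms$x[idx] <- moved[, 1L]
        s$atoms$y[idx] <- moved[, 2L]
        s$atoms$z[idx] <- moved[, 3L]
      }
      s
    })
  })
}
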