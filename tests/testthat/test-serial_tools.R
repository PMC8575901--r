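test_that("coset decomposition matches an exhaustive enumeration oracle", {
  # oracle: partition the lattice group into right cosets of the crystal
  # group by brute force and count them
  coset_count_oracle <- function(pg, lg) {
    h <- pg_elements(pg)
    g <- pg_elements(lg)
    key <- function(m) paste(round(m), collapse = ",")
    seen <- character(0)
    n <- 0L
    for (gg in g) {
      ck <- sort(vapply(h, function(hh) key(hh %*% gg), character(1)))[1]
      if (!ck %in% seen) {
        seen <- c(seen, ck)
        n <- n + 1L
      }
    }
    n
  }
  cases <- list(c("1", "1"), c("6", "622"), c("4", "422"), c("3", "622"),
                c("2", "222"), c("32", "622"))
  for (cs in cases) {
    ops <- coset_operators(cs[1], cs[2])
    expect_equal(length(ops), coset_count_oracle(cs[1], cs[2]),
                 info = paste(cs, collapse = " in "))
    expect_equal(ops[[1]]$matrix, diag(3), ignore_attr = TRUE)
    for (op in ops) expect_true(abs(det(op$matrix)) == 1)
  }
  # the hexagonal merohedral case: identity plus the two-fold k,h,-l
  ops6 <- coset_operators("6")
  expect_equal(length(ops6), 2L)
  expect_equal(ops6[[2]]$label, "k,h,-l")
  expect_equal(ops6[[2]]$matrix,
               matrix(c(0, 1, 0, 1, 0, 0, 0, 0, -1), 3, byrow = TRUE),
               ignore_attr = TRUE)
  expect_error(coset_operators("5"), "unsupported")
  expect_error(reindex_op(diag(3) * 2), "determinant")
})

test_that("asu mapping is idempotent and orbit-consistent", {
  set.seed(33)
  hkl <- cbind(sample(-20:20, 200, TRUE), sample(-20:20, 200, TRUE),
               sample(-20:20, 200, TRUE))
  can <- asu_map(hkl, "6")
  expect_identical(asu_map(can, "6"), can)
  # every element of an orbit maps to the same canonical index
  w <- t(pg_elements("6")[[3]])
  expect_identical(asu_map(hkl %*% t(w), "6"), can)
  expect_identical(asu_map(-hkl, "6"), can)  # Friedel
})

test_that("d-spacings agree with closed-form special cases", {
  set.seed(34)
  hkl <- cbind(sample(1:10, 30, TRUE), sample(1:10, 30, TRUE),
               sample(1:10, 30, TRUE))
  cell_o <- c(20, 30, 40, 90, 90, 90)
  oracle_o <- 1 / sqrt(hkl[, 1]^2 / 400 + hkl[, 2]^2 / 900 +
                         hkl[, 3]^2 / 1600)
  expect_equal(d_spacing(cell_o, hkl), oracle_o, tolerance = 1e-12)
  a <- 285.4; c0 <- 166.5
  cell_h <- c(a, a, c0, 90, 90, 120)
  oracle_h <- 1 / sqrt(4 / 3 * (hkl[, 1]^2 + hkl[, 1] * hkl[, 2] +
                                  hkl[, 2]^2) / a^2 + hkl[, 3]^2 / c0^2)
  expect_equal(d_spacing(cell_h, hkl), oracle_h, tolerance = 1e-12)
})

test_that("shot correlations match a longhand Pearson evaluation", {
  ops <- coset_operators("6")
  sim <- simulate_shots(shot_sim_spec(n_reflections = 600, n_shots = 4,
                                      flip_fraction = 0, seed = 35))
  a <- sim$shots[[1]]
  expect_equal(shot_correlation(a, a, ops[[1]], "6"), 1)
  # scale invariance
  b <- a
  b$refl$I <- 2 * b$refl$I
  expect_equal(shot_correlation(a, b, ops[[1]], "6"), 1)
  # longhand oracle on a random pair
  x <- sim$shots[[2]]; y <- sim$shots[[3]]
  got <- shot_correlation(x, y, ops[[2]], "6")
  kx <- apply(asu_map(as.matrix(x$refl[, 1:3]), "6"), 1, paste,
              collapse = ",")
  ky <- apply(asu_map(as.matrix(y$refl[, 1:3]) %*% t(ops[[2]]$matrix), "6"),
              1, paste, collapse = ",")
  common <- intersect(kx, ky)
  xi <- x$refl$I[match(common, kx)]
  yi <- y$refl$I[match(common, ky)]
  mx <- mean(xi); my <- mean(yi)
  oracle <- sum((xi - mx) * (yi - my)) /
    sqrt(sum((xi - mx)^2) * sum((yi - my)^2))
  expect_equal(got, oracle, tolerance = 1e-12)
  # too few common reflections is undefined, not an error
  tiny <- new_shot("t", data.frame(h = 1:3, k = 5L, l = 9L, I = 1:3,
                                   sigma = 1))
  expect_true(is.na(shot_correlation(tiny, a, ops[[1]], "6",
                                     min_common = 50L)))
})

test_that("blockwise pairwise correlations equal cor(pairwise.complete)", {
  set.seed(36)
  a <- matrix(rnorm(600), 10, 60)
  b <- matrix(rnorm(600), 10, 60)
  a[sample(600, 200)] <- NA
  b[sample(600, 200)] <- NA
  got <- psigeom:::pairwise_pearson(a, b, min_common = 3L)
  oracle <- suppressWarnings(cor(t(a), t(b),
                                 use = "pairwise.complete.obs"))
  n_common <- (!is.na(a)) %*% t(!is.na(b))
  oracle[n_common < 3] <- NA
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("a tranche of identical or flipped copies resolves exactly", {
  ops <- coset_operators("6")
  sim <- simulate_shots(shot_sim_spec(n_reflections = 400, n_shots = 6,
                                      noise_cv = 0, flip_fraction = 0,
                                      observation_rate = 1, seed = 37))
  sol <- resolve_tranche(sim$shots, ops, "6", seed = 1)
  expect_true(all(sol$assignment == 1L))
  expect_equal(sol$mean_within_cluster_cc, 1, tolerance = 1e-9)
  # two shots, one the flipped copy of the other
  s1 <- sim$shots[[1]]
  hh <- as.matrix(s1$refl[, 1:3]) %*% t(ops[[2]]$matrix)
  s2 <- new_shot("flip", data.frame(h = hh[, 1], k = hh[, 2], l = hh[, 3],
                                    I = s1$refl$I, sigma = s1$refl$sigma))
  sol2 <- resolve_tranche(list(s1, s2), ops, "6", seed = 1)
  expect_equal(unname(sol2$assignment), c(1L, 2L))
  # disconnected shots: no defined correlations
  t1 <- new_shot("a", data.frame(h = 1:5, k = 2L, l = 3L, I = runif(5),
                                 sigma = 1))
  t2 <- new_shot("b", data.frame(h = 21:25, k = 12L, l = 13L, I = runif(5),
                                 sigma = 1))
  expect_error(resolve_tranche(list(t1, t2), ops, "6", seed = 1),
               "connectivity")
})

test_that("tranche solutions agree with the exhaustive-search oracle", {
  ops <- coset_operators("6")
  for (seed in c(38, 39, 40)) {
    sim <- simulate_shots(shot_sim_spec(n_reflections = 300, n_shots = 10,
                                        noise_cv = 0.3,
                                        observation_rate = 0.5,
                                        seed = seed))
    sol <- resolve_tranche(sim$shots, ops, "6", seed = seed)
    oracle <- exhaustive_ambiguity_oracle(sim$shots, ops, "6")
    agree <- assignment_accuracy(sol$assignment, oracle$assignment, ops,
                                 "6")
    expect_equal(agree$accuracy, 1, info = paste("seed", seed))
  }
})

test_that("ambiguity resolution is gauge-invariant and spec-compliant", {
  ops <- coset_operators("6")
  sim <- simulate_shots(shot_sim_spec(n_reflections = 800, n_shots = 120,
                                      seed = 41))
  truth <- vapply(sim$shots, `[[`, integer(1), "true_operator")
  sol <- resolve_ambiguity(sim$shots, "6", ops, tranche_size = 50,
                           overlap = 10, seed = 2)
  acc <- assignment_accuracy(sol$assignment, truth, ops, "6")
  expect_gte(acc$accuracy, 0.99)
  expect_equal(length(sol$assignment), 120L)
  expect_lte(sol$correlations_evaluated,
             sol$n_tranches * sol$tranche_size^2 * length(ops)^2)
  # global gauge freedom: flipping every shot leaves accuracy unchanged
  flipped <- lapply(sim$shots, function(s) {
    hh <- as.matrix(s$refl[, 1:3]) %*% t(ops[[2]]$matrix)
    s$refl$h <- hh[, 1]; s$refl$k <- hh[, 2]; s$refl$l <- hh[, 3]
    s
  })
  sol_f <- resolve_ambiguity(flipped, "6", ops, tranche_size = 50,
                             overlap = 10, seed = 2)
  acc_f <- assignment_accuracy(sol_f$assignment, truth, ops, "6")
  expect_equal(acc_f$accuracy, acc$accuracy, tolerance = 0.02)
  # a single tranche reduces to resolve_tranche
  sub <- sim$shots[1:30]
  one <- resolve_ambiguity(sub, "6", ops, tranche_size = 50, overlap = 10,
                           seed = 3)
  tr <- resolve_tranche(sub, ops, "6", seed = 3 + 1)
  expect_equal(one$n_tranches, 1L)
  expect_identical(unname(one$assignment), unname(tr$assignment))
  expect_error(resolve_ambiguity(sim$shots, "6", ops, tranche_size = 10,
                                 overlap = 8), "twice the overlap")
})

test_that("correlation workload grows linearly in the number of shots", {
  ops <- coset_operators("6")
  counts <- vapply(c(100L, 200L), function(n) {
    sim <- simulate_shots(shot_sim_spec(n_reflections = 400, n_shots = n,
                                        seed = 42))
    sol <- resolve_ambiguity(sim$shots, "6", ops, tranche_size = 50,
                             overlap = 10, seed = 1)
    sol$correlations_evaluated
  }, numeric(1))
  # measured count, not time: doubling the shots about doubles the work,
  # far below the quadratic full-pairwise growth
  expect_lt(counts[2] / counts[1], 2.6)
  expect_gt(counts[2] / counts[1], 1.6)
})

test_that("merging under the correct assignment restores the reference", {
  ops <- coset_operators("6")
  sim <- simulate_shots(shot_sim_spec(n_reflections = 400, n_shots = 20,
                                      noise_cv = 0, observation_rate = 1,
                                      flip_fraction = 0.5, seed = 43))
  truth <- vapply(sim$shots, `[[`, integer(1), "true_operator")
  merged <- merge_shots(sim$shots, truth, ops, "6")
  ref <- sim$reference
  km <- paste(merged$h, merged$k, merged$l)
  kr <- paste(ref$h, ref$k, ref$l)
  expect_setequal(km, kr)
  expect_equal(merged$I, ref$I[match(km, kr)], tolerance = 1e-12)
  expect_true(all(merged$multiplicity == 20L))
  # one shot merges to itself (canonicalised)
  one <- merge_shots(sim$shots[1], 1L, ops, "6")
  expect_equal(nrow(one), nrow(sim$shots[[1]]$refl))
  expect_true(all(one$multiplicity == 1L))
  # two identical shots double the multiplicity, intensities unchanged
  two <- merge_shots(sim$shots[c(1, 1)], c(1L, 1L), ops, "6")
  expect_true(all(two$multiplicity == 2L))
  expect_equal(two$I, one$I)
})

test_that("CC1/2 is 1 for duplicated noiseless halves and ~0 for noise", {
  ops <- coset_operators("6")
  sim <- simulate_shots(shot_sim_spec(n_reflections = 500, n_shots = 30,
                                      noise_cv = 0, flip_fraction = 0,
                                      observation_rate = 1, seed = 44))
  cc <- cc_half(sim$shots, 1L, ops, "6", n_bins = 5, seed = 3)
  expect_true(all(abs(cc$cc_half[!is.na(cc$cc_half)] - 1) < 1e-9))
  # pure-noise intensities: every shot independent
  hkl <- as.matrix(sim$reference[, 1:3])
  set.seed(45)
  noise_shots <- lapply(1:40, function(i) {
    new_shot(paste0("n", i),
             data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                        I = rnorm(nrow(hkl))^2, sigma = 1),
             cell = c(285.4, 285.4, 166.5, 90, 90, 120))
  })
  ccn <- cc_half(noise_shots, 1L, ops, "6", n_bins = 5, seed = 4)
  expect_true(all(abs(ccn$cc_half) < 0.5, na.rm = TRUE))
  expect_lt(abs(mean(ccn$cc_half, na.rm = TRUE)), 0.25)
})

test_that("CC1/2 decreases with resolution-dependent noise", {
  ops <- coset_operators("6")
  # constructed shot set: bounded true intensities plus additive noise
  # whose sd grows with 1/d, so the per-bin CC1/2 declines by a known
  # margin while its sampling noise stays small
  base <- simulate_shots(shot_sim_spec(n_reflections = 2000, n_shots = 2,
                                       seed = 46))
  hkl <- as.matrix(base$reference[, 1:3])
  cell <- c(285.4, 285.4, 166.5, 90, 90, 120)
  q <- 1 / d_spacing(cell, hkl)
  qn <- (q - min(q)) / diff(range(q))
  set.seed(47)
  tt <- runif(nrow(hkl), 50, 150)
  noise_sd <- 20 + 280 * qn
  shots <- lapply(1:60, function(i) {
    new_shot(paste0("s", i),
             data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                        I = tt + rnorm(nrow(hkl), 0, noise_sd),
                        sigma = noise_sd),
             cell = cell)
  })
  cc <- cc_half(shots, 1L, ops, "6", n_bins = 5, seed = 5)
  v <- cc$cc_half[!is.na(cc$cc_half)]
  # monotone decreasing within sampling noise
  expect_true(all(diff(v) < 0.05))
  expect_lt(v[length(v)], v[1] - 0.3)
})

test_that("the resolution cutoff rule follows the stated scan", {
  expect_equal(resolution_cutoff(c(0.99, 0.9, 0.7, 0.4, 0.1))$bin_index, 5L)
  expect_equal(resolution_cutoff(c(0.99, 0.9, 0.3, 0.35, 0.2))$bin_index,
               3L)
  # undefined bins are skipped, not counted
  expect_equal(resolution_cutoff(c(0.99, NA, 0.9, 0.95, 0.2))$bin_index, 3L)
  expect_error(resolution_cutoff(c(0.5, NA, NA)), "at least 2")
  # strict rule available behind tol = 0
  expect_equal(resolution_cutoff(c(0.99, 0.991, 0.7), tol = 0)$bin_index,
               1L)
  expect_equal(resolution_cutoff(c(0.99, 0.991, 0.7), tol = 0.02)$bin_index,
               3L)
})

test_that("a designed signal-vanishing resolution is recovered", {
  ops <- coset_operators("6")
  sim <- simulate_shots(shot_sim_spec(n_reflections = 4000, n_shots = 120,
                                      flip_fraction = 0, noise_cv = 0.15,
                                      noise_cv_slope = 3,
                                      signal_dmin = 3.0, seed = 47))
  cc <- cc_half(sim$shots, 1L, ops, "6", n_bins = 8, seed = 6)
  rc <- resolution_cutoff(cc)
  # beyond the designed limit the bins are undefined (no signal at all)
  expect_true(all(is.na(cc$cc_half[cc$d_high < 2.8])))
  bin_width <- cc$d_high[rc$bin_index] - cc$d_low[rc$bin_index]
  expect_lt(abs(rc$d_min - 3.0), max(bin_width, 0.5))
})

test_that("isoform classification separates one and two packing modes", {
  uni <- simulate_cells(list(list(mean = 285.0, sd = 0.3, weight = 1)),
                        1000, seed = 48)
  m1 <- classify_isoform(uni, "a")
  expect_equal(m1$verdict, "unimodal")
  expect_equal(m1$means, 285.0, tolerance = 0.05)
  bi <- simulate_cells(list(list(mean = 281.0, sd = 0.5, weight = 0.5),
                            list(mean = 286.2, sd = 0.5, weight = 0.5)),
                       1000, seed = 49)
  m2 <- classify_isoform(bi, "a")
  expect_equal(m2$verdict, "bimodal")
  expect_equal(m2$means, c(281.0, 286.2), tolerance = 0.1)
  expect_equal(sum(m2$weights), 1, tolerance = 1e-9)
  # degenerate constant sample: verdict unimodal, no crash
  const <- simulate_cells(list(list(mean = 285, sd = 0, weight = 1)), 50,
                          seed = 50)
  expect_message(m3 <- classify_isoform(const, "a"), "degenerate")
  expect_equal(m3$verdict, "unimodal")
  expect_error(classify_isoform(uni[1:10, ], "a"), "at least 20")
})

test_that("mixture means are recovered within 3 standard errors", {
  for (seed in 51:55) {
    n <- 600
    sdc <- 0.5
    bi <- simulate_cells(list(list(mean = 281.0, sd = sdc, weight = 0.5),
                              list(mean = 286.2, sd = sdc, weight = 0.5)),
                         n, seed = seed)
    m <- classify_isoform(bi, "a", seed = seed)
    expect_equal(m$verdict, "bimodal")
    se <- sdc / sqrt(n / 2)
    expect_lt(abs(m$means[1] - 281.0), 3 * se)
    expect_lt(abs(m$means[2] - 286.2), 3 * se)
  }
})

test_that("pooled a/c samples expose the monoclinic bimodality", {
  # per-lattice cells with a ~ one mode and c ~ the other: the pooled
  # histogram is the bimodal object
  a_draws <- simulate_cells(list(list(mean = 281.0, sd = 0.5, weight = 1)),
                            400, seed = 56, parameter = "a",
                            base_cell = c(281, 164.6, 286.2, 90, 119.3, 90))
  cells <- a_draws
  cells$c <- simulate_cells(list(list(mean = 286.2, sd = 0.5, weight = 1)),
                            400, seed = 57, parameter = "c",
                            base_cell = c(281, 164.6, 286.2, 90, 119.3,
                                          90))$c
  m <- classify_isoform(cells, "ac_pooled")
  expect_equal(m$verdict, "bimodal")
  expect_equal(m$means, c(281.0, 286.2), tolerance = 0.15)
})

test_that("shot streams round-trip through the text format", {
  sim <- simulate_shots(shot_sim_spec(n_reflections = 100, n_shots = 3,
                                      seed = 58))
  path <- withr::local_tempfile(fileext = ".txt")
  write_shots(sim$shots, path)
  got <- read_shots(path)
  expect_equal(length(got), 3L)
  for (i in 1:3) {
    expect_equal(got[[i]]$shot_id, sim$shots[[i]]$shot_id)
    expect_equal(got[[i]]$refl$h, sim$shots[[i]]$refl$h)
    expect_equal(got[[i]]$refl$I, sim$shots[[i]]$refl$I,
                 tolerance = 1e-5)
    expect_equal(got[[i]]$cell, sim$shots[[i]]$cell, tolerance = 1e-3)
  }
  expect_error(new_shot("d", data.frame(h = c(1, 1), k = 1, l = 1,
                                        I = 1:2, sigma = 1)), "duplicate")
})
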