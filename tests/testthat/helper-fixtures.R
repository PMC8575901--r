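# Fixture builders shared across the suite. All fixtures are generated in
# code at test time; hand-written PDB text is assembled line by line so the
# reader tests are independent of the package's own writer.

write_tiny_pdb <- function(path) {
  lines <- c(
    "CRYST1  285.400  285.400  166.500  90.00  90.00 120.00 P 63",
    "ATOM      1  N   ALA A   1      11.104  13.207   9.100  1.00 20.00           N",
    "ATOM      2  CA  ALA A   1      12.560  13.300   9.000  1.00 21.50           C",
    "HETATM    3 MG   CLA B  11       1.250  -2.500   3.750  1.00 30.00          MG",
    "END")
  writeLines(lines, path)
  path
}

# one atom with two altlocs (occ 0.6 / 0.4), one with a tie (0.5 / 0.5),
# one hydrogen
write_altloc_pdb <- function(path) {
  lines <- c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.60 10.00           C",
    "ATOM      2  CA BALA A   1       1.200   0.000   0.000  0.40 10.00           C",
    "ATOM      3  CB AALA A   1       2.000   1.000   0.000  0.50 10.00           C",
    "ATOM      4  CB BALA A   1       2.200   1.000   0.000  0.50 10.00           C",
    "ATOM      5  HA  ALA A   1       0.500   0.500   0.500  1.00 10.00           H",
    "ATOM      6  N   ALA A   2       3.000   2.000   1.000  1.00 10.00           N",
    "END")
  writeLines(lines, path)
  path
}

test_registry <- function() read_registry()

# regular hexagon of given circumradius in the z = 0 plane
hexagon_xy <- function(radius = 1.39) {
  th <- (0:5) * pi / 3
  cbind(radius * cos(th), radius * sin(th), 0)
}

random_rigid_motion <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3)
  list(rot = rotation_matrix(ax, runif(1, 0, 360)),
       shift = rnorm(3, 0, 20))
}

apply_rigid <- function(xyz, motion) {
  sweep(xyz %*% t(motion$rot), 2L, -motion$shift)
}

rigid_structure <- function(s, motion) {
  xyz <- apply_rigid(atom_xyz(s), motion)
  s$atoms$x <- xyz[, 1L]
  s$atoms$y <- xyz[, 2L]
  s$atoms$z <- xyz[, 3L]
  s
}

# independent exhaustive-search oracle for the ambiguity objective on a
# small shot set: enumerates every gauge-fixed assignment and scores it
# with shot_correlation (the public pairwise primitive), returning the
# best assignment
exhaustive_ambiguity_oracle <- function(shots, ops, point_group) {
  n <- length(shots)
  m <- length(ops)
  stopifnot(m == 2L, n <= 12L)
  cc <- array(NA_real_, c(n, n, 2L))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    for (k in 1:2) {
      cc[i, j, k] <- shot_correlation(shots[[i]], shots[[j]], ops[[k]],
                                      point_group)
    }
  }
  score <- function(s) {
    tot <- 0
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      rel <- if (s[i] == s[j]) 1L else 2L
      v <- cc[i, j, rel]
      if (!is.na(v)) tot <- tot + v
    }
    tot
  }
  best <- NULL
  best_score <- -Inf
  for (code in 0:(2^(n - 1L) - 1L)) {
    s <- c(1L, as.integer(intToBits(code))[seq_len(n - 1L)] + 1L)
    sc <- score(s)
    if (sc > best_score) {
      best_score <- sc
      best <- s
    }
  }
  list(assignment = best, score = best_score)
}
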