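# ---------------------------------------------------------------------------
# Proper point groups as integer matrices, coset decomposition of the
# crystal point group in the lattice point group, and canonical
# (asymmetric-unit) index mapping.
#
# Matrices W act on fractional coordinates (x' = W x); the corresponding
# action on Miller indices is h' = t(W) h. Reindexing operators are stored
# in hkl-action form.
# ---------------------------------------------------------------------------

mat_key <- function(m) paste(as.integer(round(m)), collapse = ",")

group_closure <- function(generators) {
  elems <- list(diag(3L))
  names(elems) <- mat_key(elems[[1L]])
  queue <- elems
  while (length(queue) > 0L) {
    nxt <- list()
    for (g in queue) {
      for (s in generators) {
        p <- g %*% s
        k <- mat_key(p)
        if (is.null(elems[[k]])) {
          elems[[k]] <- p
          nxt[[k]] <- p
        }
      }
    }
    queue <- nxt
    if (length(elems) > 200L) stop("group closure did not terminate")
  }
  unname(elems)
}

# generators of the supported proper rotation point groups, in the
# conventional crystallographic settings (hexagonal axes for 3/32/6/622)
pg_generators <- function(name) {
  r2y <- matrix(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), 3L, byrow = TRUE)
  r2z <- matrix(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), 3L, byrow = TRUE)
  r2x <- matrix(c(1, 0, 0, 0, -1, 0, 0, 0, -1), 3L, byrow = TRUE)
  r4z <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3L, byrow = TRUE)
  r3z <- matrix(c(0, -1, 0, 1, -1, 0, 0, 0, 1), 3L, byrow = TRUE)  # hex
  r6z <- matrix(c(1, -1, 0, 1, 0, 0, 0, 0, 1), 3L, byrow = TRUE)   # hex
  r2a_hex <- matrix(c(1, -1, 0, 0, -1, 0, 0, 0, -1), 3L, byrow = TRUE)
  r3d <- matrix(c(0, 0, 1, 1, 0, 0, 0, 1, 0), 3L, byrow = TRUE)    # cubic
  switch(name,
    "1" = list(diag(3L)),
    "2" = list(r2y),
    "222" = list(r2z, r2x),
    "4" = list(r4z),
    "422" = list(r4z, r2x),
    "3" = list(r3z),
    "32" = list(r3z, r2a_hex),
    "6" = list(r6z),
    "622" = list(r6z, r2a_hex),
    "23" = list(r2z, r3d),
    "432" = list(r4z, r3d),
    stop("unsupported point group: ", name)
  )
}

#' Elements of a proper rotation point group
#'
#' @param name group symbol; one of `1, 2, 222, 4, 422, 3, 32, 6, 622, 23,
#'   432` (hexagonal groups in hexagonal axes).
#' @return list of 3 x 3 integer matrices acting on fractional
#'   coordinates, identity first.
#' @export
pg_elements <- function(name) {
  els <- group_closure(pg_generators(as.character(name)))
  keys <- vapply(els, mat_key, character(1))
  idk <- mat_key(diag(3L))
  ord <- order(keys != idk, keys)
  els[ord]
}

#' Lattice point group implied by a crystal point group
#'
#' The proper rotational symmetry of the lattice that a crystal in the
#' given point group sits on (assuming no accidental metric symmetry):
#' e.g. a crystal in point group 6 (space group P6_3) sits on a hexagonal
#' lattice with proper symmetry 622 -- the source of the merohedral
#' indexing ambiguity.
#'
#' @param point_group crystal point-group symbol.
#' @return lattice point-group symbol.
#' @export
lattice_group_of <- function(point_group) {
  switch(as.character(point_group),
    "1" = "1", "2" = "2", "222" = "222",
    "4" = "422", "422" = "422",
    "3" = "622", "32" = "622", "6" = "622", "622" = "622",
    "23" = "432", "432" = "432",
    stop("unsupported point group: ", point_group)
  )
}

op_label <- function(m) {
  # symbolic hkl triplet for an hkl-action matrix, e.g. "k,h,-l"
  sym <- c("h", "k", "l")
  one <- function(row) {
    parts <- character(0)
    for (j in 1:3) {
      c <- row[j]
      if (c == 0) next
      s <- if (c == 1) sym[j]
           else if (c == -1) paste0("-", sym[j])
           else paste0(c, sym[j])
      if (length(parts) > 0L && c > 0) s <- paste0("+", s)
      parts <- c(parts, s)
    }
    if (length(parts) == 0L) "0" else paste(parts, collapse = "")
  }
  paste(apply(m, 1L, one), collapse = ",")
}

#' Construct a reindexing operator
#' @param matrix 3 x 3 integer matrix acting on `(h, k, l)` as
#'   `h' = matrix %*% h`; determinant must be +1 or -1.
#' @param label optional text label (defaults to the symbolic triplet).
#' @return object of class `reindex_op`.
#' @export
reindex_op <- function(matrix, label = NULL) {
  m <- round(matrix)
  if (max(abs(matrix - m)) > 1e-9) stop("reindexing matrix must be integral")
  if (!round(det(m)) %in% c(-1, 1)) {
    stop("reindexing matrix must have determinant +1 or -1")
  }
  structure(list(matrix = m, label = label %||% op_label(m)),
            class = "reindex_op")
}

#' @export
print.reindex_op <- function(x, ...) {
  cat("reindex_op:", x$label, "\n")
  invisible(x)
}

#' Reindexing operators by coset decomposition
#'
#' Enumerates one representative per right coset of the crystal point
#' group in the lattice point group (proper rotations only; intensities
#' are treated as Friedel-symmetric). These are the candidate index
#' settings of a merohedrally ambiguous serial data set; the identity is
#' always first. For point group 6 on a hexagonal lattice (the P6_3 case)
#' this yields exactly the identity and the two-fold `(h,k,l) -> (k,h,-l)`.
#'
#' @param point_group crystal point-group symbol (see [pg_elements()]).
#' @param lattice_group lattice point-group symbol; defaults to
#'   [lattice_group_of()] of the crystal group.
#' @return list of `reindex_op`, identity first; attribute `normal` says
#'   whether the crystal group is normal in the lattice group (true for
#'   every supported merohedral case).
#' @export
coset_operators <- function(point_group,
                            lattice_group = lattice_group_of(point_group)) {
  h_els <- pg_elements(point_group)
  g_els <- pg_elements(lattice_group)
  g_keys <- vapply(g_els, mat_key, character(1))
  h_keys <- vapply(h_els, mat_key, character(1))
  if (!all(h_keys %in% g_keys)) {
    stop("point group ", point_group, " is not a subgroup of ",
         lattice_group, " in the implemented settings")
  }
  covered <- setNames(rep(FALSE, length(g_els)), g_keys)
  reps <- list()
  for (g in g_els) {
    if (covered[[mat_key(g)]]) next
    members <- lapply(h_els, function(h) h %*% g)
    for (mm in members) covered[[mat_key(mm)]] <- TRUE
    # choose the conventional (simplest) representative of the coset:
    # fewest/smallest entries, then fewest minus signs, then lexicographic
    score <- vapply(members, function(mm) {
      hk <- t(mm)
      sum(abs(hk)) * 100 + sum(hk < 0) * 10
    }, numeric(1))
    keys <- vapply(members, function(mm) mat_key(t(mm)), character(1))
    ord <- order(score, keys)
    reps[[length(reps) + 1L]] <- members[[ord[1L]]]
  }
  # normality: g H g^-1 == H for all g
  normal <- all(vapply(g_els, function(g) {
    all(vapply(h_els, function(h) {
      mat_key(g %*% h %*% solve(g)) %in% h_keys
    }, logical(1)))
  }, logical(1)))
  ops <- lapply(reps, function(w) reindex_op(t(w)))
  attr(ops, "normal") <- normal
  attr(ops, "point_group") <- as.character(point_group)
  ops
}

# coset index of an arbitrary hkl-action matrix among the reps of
# coset_operators(pg): M belongs to coset k iff solve(R_k) %*% M is the
# hkl action of an element of the crystal point group
coset_index <- function(m, ops, pg_hkl_keys) {
  for (k in seq_along(ops)) {
    cand <- solve(ops[[k]]$matrix) %*% m
    if (mat_key(cand) %in% pg_hkl_keys) return(k)
  }
  stop("matrix does not lie in any coset of the operator list")
}

pg_hkl_keys <- function(point_group) {
  vapply(pg_elements(point_group), function(w) mat_key(t(w)), character(1))
}

# quotient composition table: q[a, b] = coset of R_a %*% R_b; requires the
# crystal group to be normal in the lattice group (checked upstream)
coset_mult_table <- function(ops, point_group) {
  keys <- pg_hkl_keys(point_group)
  m <- length(ops)
  q <- matrix(NA_integer_, m, m)
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      q[a, b] <- coset_index(ops[[a]]$matrix %*% ops[[b]]$matrix, ops, keys)
    }
  }
  q
}

coset_inverse <- function(ops, point_group) {
  keys <- pg_hkl_keys(point_group)
  vapply(seq_along(ops), function(a) {
    coset_index(solve(ops[[a]]$matrix), ops, keys)
  }, integer(1))
}

#' Map Miller indices to a canonical asymmetric-unit convention
#'
#' Each index is replaced by the lexicographically smallest member of its
#' orbit under the proper point group plus Friedel inversion (ordering on
#' `(h, k, l)` with `h` most significant). Merging correctness depends on
#' this convention, so it is fixed here once.
#'
#' @param hkl n x 3 integer matrix.
#' @param point_group crystal point-group symbol.
#' @return n x 3 integer matrix of canonical indices.
#' @export
asu_map <- function(hkl, point_group) {
  hkl <- matrix(as.integer(round(hkl)), ncol = 3L)
  tmats <- lapply(pg_elements(point_group), t)
  tmats <- c(tmats, lapply(tmats, function(m) -m))  # Friedel mates
  big <- 4096
  best_score <- rep(Inf, nrow(hkl))
  best <- hkl
  for (m in tmats) {
    cand <- hkl %*% t(m)
    score <- (cand[, 1L] * big + cand[, 2L]) * big + cand[, 3L]
    upd <- score < best_score
    if (any(upd)) {
      best[upd, ] <- cand[upd, , drop = FALSE]
      best_score[upd] <- score[upd]
    }
  }
  best
}

#' d-spacing of reflections
#'
#' General triclinic formula through the reciprocal metric tensor.
#'
#' @param cell length-6 cell `(a, b, c, alpha, beta, gamma)`.
#' @param hkl n x 3 matrix of Miller indices.
#' @return numeric vector of d-spacings in Angstrom.
#' @export
d_spacing <- function(cell, hkl) {
  hkl <- matrix(as.numeric(hkl), ncol = 3L)
  ang <- cell[4:6] * pi / 180
  ca <- cos(ang[1]); cb <- cos(ang[2]); cg <- cos(ang[3])
  g <- matrix(c(
    cell[1]^2, cell[1] * cell[2] * cg, cell[1] * cell[3] * cb,
    cell[1] * cell[2] * cg, cell[2]^2, cell[2] * cell[3] * ca,
    cell[1] * cell[3] * cb, cell[2] * cell[3] * ca, cell[3]^2), 3L)
  gstar <- solve(g)
  inv_d2 <- rowSums((hkl %*% gstar) * hkl)
  1 / sqrt(inv_d2)
}
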