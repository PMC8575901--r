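# ---------------------------------------------------------------------------
# Anisotropic expansion of the chlorophyll lattice between two structures,
# decomposed in each structure's own P700-FX cylindrical frame.
# ---------------------------------------------------------------------------

frame_from_map <- function(structure, map) {
  axial_frame(atom_xyz(structure, map$p700_mg),
              atom_xyz(structure, map$fx_fe))
}

#' Per-chlorophyll expansion profile between two structures
#'
#' Each structure is decomposed in its own P700-FX frame (no global
#' superposition, which removes fit bias), and the radial ("along the
#' membrane plane") and axial ("perpendicular to the membrane") coordinates
#' of every chlorophyll Mg shared between the two cofactor maps are
#' compared. Positive `delta_parallel` is in-plane expansion of the
#' alternate (e.g. room-temperature) structure relative to the reference
#' (e.g. cryogenic) structure.
#'
#' @param ref,alt `psi_structure` objects (reference and alternate).
#' @param map_ref,map_alt their `cofactor_map`s.
#' @param superpose_first logical; if `TRUE` the alternate structure is
#'   first rigid-body superposed onto the reference over the shared Chl Mg
#'   set and both are decomposed in the reference frame (sensitivity check).
#' @return data.frame of class `expansion_profile` with one row per shared
#'   Chl label: `chl_label`, `branch_tag`, `radial_ref`, `radial_alt`,
#'   `delta_parallel`, `axial_ref`, `axial_alt`, `delta_perpendicular`.
#' @export
expansion_profile <- function(ref, alt, map_ref, map_alt,
                              superpose_first = FALSE) {
  common <- intersect(map_ref$chl$label, map_alt$chl$label)
  skipped <- union(setdiff(map_ref$chl$label, common),
                   setdiff(map_alt$chl$label, common))
  if (length(skipped) > 0L) {
    warning("chlorophylls present in only one structure skipped: ",
            paste(skipped, collapse = ", "))
  }
  if (length(common) < 2L) {
    stop("fewer than 2 chlorophyll labels shared between the structures")
  }
  ir <- map_ref$chl[match(common, map_ref$chl$label), ]
  ia <- map_alt$chl[match(common, map_alt$chl$label), ]
  xyz_ref <- atom_xyz(ref, ir$idx)
  xyz_alt <- atom_xyz(alt, ia$idx)
  fr_ref <- frame_from_map(ref, map_ref)
  if (superpose_first) {
    fit <- superpose(xyz_alt, xyz_ref)
    xyz_alt <- sweep(xyz_alt %*% t(fit$rotation), 2L, -fit$translation)
    fr_alt <- fr_ref
  } else {
    fr_alt <- frame_from_map(alt, map_alt)
  }
  cyl_ref <- cylindrical_decompose(fr_ref, xyz_ref)
  cyl_alt <- cylindrical_decompose(fr_alt, xyz_alt)
  out <- data.frame(
    chl_label = common,
    branch_tag = ir$branch,
    radial_ref = cyl_ref$radial,
    radial_alt = cyl_alt$radial,
    delta_parallel = cyl_alt$radial - cyl_ref$radial,
    axial_ref = cyl_ref$axial,
    axial_alt = cyl_alt$axial,
    delta_perpendicular = cyl_alt$axial - cyl_ref$axial,
    stringsAsFactors = FALSE
  )
  class(out) <- c("expansion_profile", "data.frame")
  out
}

theil_sen_slope <- function(x, y) {
  n <- length(x)
  ij <- utils::combn(n, 2L)
  dx <- x[ij[2L, ]] - x[ij[1L, ]]
  dy <- y[ij[2L, ]] - y[ij[1L, ]]
  ok <- abs(dx) > .Machine$double.eps^0.5
  if (!any(ok)) stop("Theil-Sen slope undefined: no distinct abscissae")
  stats::median(dy[ok] / dx[ok])
}

#' Summary statistics of an expansion profile
#'
#' Sample means and standard deviations of the in-plane and perpendicular
#' displacement components, plus the radial gradient of the in-plane
#' expansion: `gradient_per_10A` is 10 times the OLS slope of
#' `delta_parallel` on `radial_ref` (the trend "per 10 Angstrom"). A robust
#' Theil-Sen slope is reported alongside since the trend convention brackets
#' the estimate.
#'
#' @param records an `expansion_profile`.
#' @param include_tags branch tags to keep, or `"all"` (default; the
#'   headline average is over every chlorophyll).
#' @return list of class `expansion_summary`.
#' @export
expansion_summary <- function(records, include_tags = "all") {
  r <- records
  if (!identical(include_tags, "all")) {
    r <- r[r$branch_tag %in% include_tags, , drop = FALSE]
  }
  if (nrow(r) < 2L) stop("fewer than 2 expansion records after filtering")
  if (diff(range(r$radial_ref)) < .Machine$double.eps^0.5) {
    stop("radial gradient undefined: all reference radii coincide")
  }
  slope <- unname(coef(lm(delta_parallel ~ radial_ref, data = r))[2L])
  structure(
    list(
      mean_parallel = mean(r$delta_parallel),
      sd_parallel = sd(r$delta_parallel),
      mean_perpendicular = mean(r$delta_perpendicular),
      sd_perpendicular = sd(r$delta_perpendicular),
      gradient_per_10A = 10 * slope,
      gradient_per_10A_theil_sen =
        10 * theil_sen_slope(r$radial_ref, r$delta_parallel),
      n_cofactors = nrow(r)
    ),
    class = "expansion_summary"
  )
}

#' @export
print.expansion_summary <- function(x, ...) {
  cat(sprintf("expansion over %d chlorophylls\n", x$n_cofactors))
  cat(sprintf("  in-plane:      %+.3f +/- %.3f A (gradient %+.3f A / 10 A)\n",
              x$mean_parallel, x$sd_parallel, x$gradient_per_10A))
  cat(sprintf("  perpendicular: %+.3f +/- %.3f A\n",
              x$mean_perpendicular, x$sd_perpendicular))
  invisible(x)
}

#' Radius-of-gyration comparison between two structures
#'
#' Computes Rg of both structures over the same selection rule:
#' non-hydrogen atoms, optionally restricted to chains, waters excluded by
#' default. Uniform weights are the default convention; mass weighting is
#' available behind a flag.
#'
#' @param ref,alt `psi_structure` objects.
#' @param chains optional chain subset defining the selection.
#' @param exclude_water drop HOH/WAT residues (default `TRUE`).
#' @param mass_weighted weight by approximate atomic mass.
#' @return named numeric vector `c(ref = , alt = )` in Angstrom.
#' @export
rg_comparison <- function(ref, alt, chains = NULL, exclude_water = TRUE,
                          mass_weighted = FALSE) {
  one <- function(s) {
    at <- s$atoms[!s$atoms$hydrogen, , drop = FALSE]
    if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
    if (exclude_water) at <- at[!at$resid %in% c("HOH", "WAT"), , drop = FALSE]
    if (nrow(at) == 0L) stop("empty Rg selection")
    w <- if (mass_weighted) element_mass(at$element) else NULL
    radius_of_gyration(as.matrix(at[, c("x", "y", "z")]), w)
  }
  c(ref = one(ref), alt = one(alt))
}

element_mass <- function(el) {
  tbl <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
           MG = 24.305, FE = 55.845, MN = 54.938, ZN = 65.38, CA = 40.078,
           CL = 35.45, NA2 = 22.990, K = 39.098, H = 1.008)
  m <- tbl[toupper(el)]
  m[is.na(m)] <- 14  # generic heavy-atom fallback
  unname(m)
}

#' Expand a monomer into a trimer by a crystallographic 3-fold
#'
#' Applies rotations of 120 and 240 degrees about the given axis and
#' appends the copies with chain labels suffixed, so that a trimer Rg can
#' be computed when only one monomer of a symmetric trimer is deposited.
#'
#' @param structure a `psi_structure` monomer.
#' @param axis_point a point on the 3-fold axis.
#' @param axis_dir the axis direction.
#' @return a `psi_structure` with three-fold the atoms.
#' @export
expand_trimer <- function(structure, axis_point, axis_dir) {
  at0 <- structure$atoms
  pieces <- list(at0)
  for (k in 1:2) {
    rot <- rotation_matrix(axis_dir, 120 * k)
    xyz <- sweep(as.matrix(at0[, c("x", "y", "z")]), 2L, axis_point)
    xyz <- sweep(xyz %*% t(rot), 2L, -axis_point)
    atk <- at0
    atk$x <- xyz[, 1L]; atk$y <- xyz[, 2L]; atk$z <- xyz[, 3L]
    atk$chain <- paste0(at0$chain, k)
    pieces[[k + 1L]] <- atk
  }
  new_structure(do.call(rbind, pieces),
                identifier = paste0(structure$identifier, "_trimer"),
                cell = structure$cell, space_group = structure$space_group)
}

#' C-alpha superposition RMSD between two structures
#'
#' Matches C-alpha atoms by (chain, residue number) across the two
#' structures and reports the least-squares superposition RMSD over the
#' shared set.
#'
#' @param ref,alt `psi_structure` objects (altloc-collapsed).
#' @return list with `rmsd` (Angstrom) and `n_matched`.
#' @export
ca_rmsd <- function(ref, alt) {
  ca <- function(s) {
    at <- s$atoms[s$atoms$atom == "CA" & s$atoms$element == "C", ,
                  drop = FALSE]
    at$key <- paste(at$chain, at$resno, sep = "|")
    at
  }
  a <- ca(ref)
  b <- ca(alt)
  common <- intersect(a$key, b$key)
  if (length(common) < 3L) stop("fewer than 3 shared C-alpha atoms")
  pa <- as.matrix(a[match(common, a$key), c("x", "y", "z")])
  pb <- as.matrix(b[match(common, b$key), c("x", "y", "z")])
  list(rmsd = superpose(pb, pa)$rmsd, n_matched = length(common))
}
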