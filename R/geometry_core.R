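# ---------------------------------------------------------------------------
# Primitive geometry: planes, angles, contacts, Rg, superposition, the
# P700-FX cylindrical frame.
# ---------------------------------------------------------------------------

as_xyz_matrix <- function(points) {
  m <- as.matrix(points)
  if (ncol(m) != 3L) stop("expected an n x 3 coordinate matrix")
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) stop("non-finite coordinates")
  m
}

#' Total-least-squares plane through a point set
#'
#' Fits the plane minimising the sum of squared perpendicular distances via
#' eigen-decomposition of the centred point covariance (equivalently the SVD
#' of the centred coordinates). The normal is the direction of least
#' variance; its sign is fixed so that the largest-magnitude component is
#' positive, making the fit deterministic.
#'
#' @param points n x 3 coordinate matrix, n >= 3, not collinear.
#' @return object of class `ring_plane`: `centroid`, `unit_normal`,
#'   `rms_out_of_plane` (Angstrom), `n_points`.
#' @export
fit_plane <- function(points) {
  m <- as_xyz_matrix(points)
  if (nrow(m) < 3L) stop("plane fit needs at least 3 points")
  ctr <- colMeans(m)
  cm <- sweep(m, 2L, ctr)
  sv <- svd(cm, nu = 0L)
  if (sv$d[2L] <= max(sv$d[1L], 1) * 1e-9) {
    stop("degenerate plane fit: points are collinear or coincident")
  }
  normal <- sv$v[, 3L]
  k <- which.max(abs(normal))
  if (normal[k] < 0) normal <- -normal
  rms <- sqrt(mean((cm %*% normal)^2))
  structure(
    list(centroid = ctr, unit_normal = normal, rms_out_of_plane = rms,
         n_points = nrow(m)),
    class = "ring_plane"
  )
}

#' Acute angle between two ring planes
#'
#' `arccos(|n_a . n_b|)` folded to the range 0-90 degrees; stacking angles
#' are reported acute, and the result is invariant to normal sign flips.
#'
#' @param a,b `ring_plane` objects (or unit 3-vectors).
#' @return angle in degrees within `[0, 90]`.
#' @export
interplanar_angle <- function(a, b) {
  na <- if (inherits(a, "ring_plane")) a$unit_normal else a / sqrt(sum(a^2))
  nb <- if (inherits(b, "ring_plane")) b$unit_normal else b / sqrt(sum(b^2))
  acos(min(1, abs(sum(na * nb)))) * 180 / pi
}

#' Minimum atom-atom contact distance between two point sets
#'
#' @param set_a,set_b non-empty n x 3 coordinate matrices.
#' @return the minimum pairwise Euclidean distance, in Angstrom.
#' @export
min_contact_distance <- function(set_a, set_b) {
  a <- as_xyz_matrix(set_a)
  b <- as_xyz_matrix(set_b)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty coordinate set")
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Radius of gyration
#'
#' `sqrt(sum w_i |r_i - rbar|^2 / sum w_i)` about the (weighted) centroid.
#' Default weights are uniform; pass atomic masses for a mass-weighted Rg.
#'
#' @param positions n x 3 coordinate matrix.
#' @param weights optional non-negative per-point weights.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(positions, weights = NULL) {
  m <- as_xyz_matrix(positions)
  if (nrow(m) == 0L) stop("radius of gyration of an empty set")
  w <- if (is.null(weights)) rep(1, nrow(m)) else as.numeric(weights)
  if (length(w) != nrow(m)) stop("weights length mismatch")
  ctr <- colSums(m * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(m, 2L, ctr)^2)) / sum(w))
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of
#' `mobile` onto `reference` over matched points, via SVD of the
#' cross-covariance with the usual determinant correction so that the
#' rotation is proper (det +1).
#'
#' @param mobile,reference matched n x 3 coordinate matrices, n >= 3.
#' @return list with `rotation` (3 x 3, applied as `x %*% t(rotation)`),
#'   `translation` (length-3), `rmsd` (Angstrom).
#' @export
superpose <- function(mobile, reference) {
  pm <- as_xyz_matrix(mobile)
  pr <- as_xyz_matrix(reference)
  if (nrow(pm) != nrow(pr)) stop("point lists differ in length")
  if (nrow(pm) < 3L) stop("superposition needs at least 3 points")
  cm <- colMeans(pm)
  cr <- colMeans(pr)
  a <- sweep(pm, 2L, cm)
  b <- sweep(pr, 2L, cr)
  h <- crossprod(a, b)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- a %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - b)^2)))
  list(rotation = rot, translation = as.numeric(cr - rot %*% cm),
       rmsd = rmsd)
}

#' The P700-FX axial frame
#'
#' The analysis frame of the expansion decomposition: origin at the midpoint
#' between the P700 centre (midpoint of its two Mg) and the FX centre
#' (centroid of the four cluster irons); axis the unit vector pointing from
#' the P700 centre toward FX.
#'
#' @param p700_mg_pair 2 x 3 matrix of the two P700 Mg positions.
#' @param fx_fe 4 x 3 matrix of the four FX Fe positions.
#' @return object of class `axial_frame` with `origin` and unit `axis`.
#' @export
axial_frame <- function(p700_mg_pair, fx_fe) {
  p <- as_xyz_matrix(p700_mg_pair)
  f <- as_xyz_matrix(fx_fe)
  if (nrow(p) != 2L) stop("P700 needs exactly 2 Mg positions")
  if (nrow(f) != 4L) stop("FX needs exactly 4 Fe positions")
  p_ctr <- colMeans(p)
  f_ctr <- colMeans(f)
  v <- f_ctr - p_ctr
  len <- sqrt(sum(v^2))
  if (len < 1e-6) stop("degenerate frame: P700 and FX centres coincide")
  structure(
    list(origin = (p_ctr + f_ctr) / 2, axis = v / len),
    class = "axial_frame"
  )
}

#' Cylindrical decomposition relative to an axial frame
#'
#' `axial` is the signed projection onto the frame axis (the
#' membrane-normal direction); `radial` is the distance from the axis (the
#' in-membrane-plane direction).
#'
#' @param frame an `axial_frame`.
#' @param points a 3-vector or n x 3 matrix.
#' @return data.frame with columns `radial` (>= 0) and `axial` (signed),
#'   both in Angstrom.
#' @export
cylindrical_decompose <- function(frame, points) {
  m <- if (is.null(dim(points))) matrix(points, nrow = 1L)
       else as_xyz_matrix(points)
  rel <- sweep(m, 2L, frame$origin)
  axial <- as.numeric(rel %*% frame$axis)
  perp <- rel - outer(axial, frame$axis)
  data.frame(radial = sqrt(rowSums(perp^2)), axial = axial)
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation; used by the synthetic generators and the trimer
#' expansion.
#'
#' @param axis 3-vector (normalised internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3 x 3 rotation matrix (applied as `x %*% t(R)`).
#' @export
rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  k <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3L, 3L, byrow = TRUE)
  diag(3L) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}
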