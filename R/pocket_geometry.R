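# ---------------------------------------------------------------------------
# Phylloquinone-pocket pi-stacking geometry and its change between a
# cryogenic and a room-temperature model.
# ---------------------------------------------------------------------------

#' Default stacking pair list
#'
#' The aromatic-ring / phylloquinone relationships quantified in the
#' pocket analysis: the two pocket phenylalanines, the two pi-stacked
#' tryptophans, and the symmetry-breaking PsaB-Trp673 against both
#' quinones.
#'
#' @return data.frame with columns `ring_a`, `ring_b`.
#' @export
default_stacking_pairs <- function() {
  data.frame(
    ring_a = c("PsaA-Phe689", "PsaB-Phe669", "PsaA-Trp697",
               "PsaB-Trp677", "PsaB-Trp673", "PsaB-Trp673"),
    ring_b = c("PhQ_A", "PhQ_B", "PhQ_A", "PhQ_B", "PhQ_B", "PhQ_A"),
    stringsAsFactors = FALSE
  )
}

#' Stacking geometry report for one structure
#'
#' For each ring-set pair, fits total-least-squares planes and reports the
#' acute interplanar angle plus three distance conventions (the printed
#' convention of stacking distances in the literature varies): minimum
#' atom-atom contact, centroid-centroid separation, and the distance of
#' ring b's centroid from ring a's plane.
#'
#' @param structure a collapsed `psi_structure`.
#' @param map its `cofactor_map`.
#' @param pairs data.frame with columns `ring_a`, `ring_b` naming ring sets
#'   of the map; defaults to every pair of [default_stacking_pairs()] whose
#'   ring sets resolve in the map.
#' @return data.frame of class `stacking_report`: `pair_label`, `angle`
#'   (degrees, 0-90), `min_contact`, `centroid_distance`,
#'   `centroid_to_plane` (Angstrom), `rms_out_of_plane_a`,
#'   `rms_out_of_plane_b`.
#' @export
stacking_report <- function(structure, map, pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- default_stacking_pairs()
    keep <- pairs$ring_a %in% names(map$ring_sets) &
      pairs$ring_b %in% names(map$ring_sets)
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) stop("no stacking pairs to evaluate")
  missing <- setdiff(unique(c(pairs$ring_a, pairs$ring_b)),
                     names(map$ring_sets))
  if (length(missing) > 0L) {
    stop("unresolved ring sets: ", paste(missing, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    xa <- atom_xyz(structure, map$ring_sets[[pairs$ring_a[i]]])
    xb <- atom_xyz(structure, map$ring_sets[[pairs$ring_b[i]]])
    pa <- fit_plane(xa)
    pb <- fit_plane(xb)
    sep <- pb$centroid - pa$centroid
    data.frame(
      pair_label = paste0(pairs$ring_a[i], "/", pairs$ring_b[i]),
      angle = interplanar_angle(pa, pb),
      min_contact = min_contact_distance(xa, xb),
      centroid_distance = sqrt(sum(sep^2)),
      centroid_to_plane = abs(sum(sep * pa$unit_normal)),
      rms_out_of_plane_a = pa$rms_out_of_plane,
      rms_out_of_plane_b = pb$rms_out_of_plane,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("stacking_report", "data.frame")
  out
}

#' Pocket geometry change between two reports
#'
#' Joins two stacking reports on `pair_label` and reports signed changes
#' (alternate minus reference). The headline "rotation out of plane" is
#' the difference of the two acute interplanar angles, not a 3D rotation
#' decomposition.
#'
#' @param ref_report,alt_report `stacking_report`s with matching pair
#'   labels.
#' @return data.frame of class `pocket_delta`: `pair_label`, `angle_ref`,
#'   `angle_alt`, `angle_change` (degrees, alt - ref, signed),
#'   `distance_ref`, `distance_alt` (minimum contact, Angstrom),
#'   `distance_change`.
#' @export
compare_pockets <- function(ref_report, alt_report) {
  unmatched <- c(setdiff(ref_report$pair_label, alt_report$pair_label),
                 setdiff(alt_report$pair_label, ref_report$pair_label))
  if (length(unmatched) > 0L) {
    stop("stacking pair labels do not match: ",
         paste(unique(unmatched), collapse = ", "))
  }
  a <- alt_report[match(ref_report$pair_label, alt_report$pair_label), ]
  out <- data.frame(
    pair_label = ref_report$pair_label,
    angle_ref = ref_report$angle,
    angle_alt = a$angle,
    angle_change = a$angle - ref_report$angle,
    distance_ref = ref_report$min_contact,
    distance_alt = a$min_contact,
    distance_change = a$min_contact - ref_report$min_contact,
    stringsAsFactors = FALSE
  )
  class(out) <- c("pocket_delta", "data.frame")
  out
}
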