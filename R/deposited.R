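# ---------------------------------------------------------------------------
# Analyses over deposited coordinate files (cryo reference vs RT models).
# The package ships no deposited coordinates; place downloaded files under
# the directory returned by deposited_dir() (or set
# options(psigeom.deposited_dir = ...)) to run these.
# ---------------------------------------------------------------------------

#' Directory searched for deposited coordinate files
#'
#' Defaults to the `deposited/` folder of the installed package's
#' `extdata`, overridable with `options(psigeom.deposited_dir = ...)`.
#'
#' @return a directory path (which may not exist).
#' @export
deposited_dir <- function() {
  getOption("psigeom.deposited_dir",
            file.path(system.file("extdata", package = "psigeom"),
                      "deposited"))
}

#' Locate a deposited coordinate file by accession
#'
#' Looks for `<accession>.cif`, `<accession>.pdb` (either case) under
#' [deposited_dir()].
#'
#' @param accession e.g. `"1jb0"` or `"7m75"`.
#' @return the file path, or `NA_character_` when absent.
#' @export
deposited_structure_path <- function(accession) {
  dir <- deposited_dir()
  cand <- c(file.path(dir, paste0(tolower(accession), c(".cif", ".pdb"))),
            file.path(dir, paste0(toupper(accession), c(".cif", ".pdb"))))
  hit <- cand[file.exists(cand)]
  if (length(hit) == 0L) NA_character_ else hit[1L]
}

#' Parse biological-assembly matrices from PDB REMARK 350 records
#'
#' @param path a PDB file.
#' @return list of 3 x 4 matrices (rotation | translation); empty when
#'   the file carries none.
#' @export
parse_biomt <- function(path) {
  lines <- grep("^REMARK 350   BIOMT", readLines(path, warn = FALSE),
                value = TRUE)
  if (length(lines) == 0L) return(list())
  rows <- lapply(lines, function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    # REMARK 350 BIOMTn idx r1 r2 r3 t
    list(row = as.integer(sub("BIOMT", "", tok[3L])),
         idx = as.integer(tok[4L]),
         vals = as.numeric(tok[5:8]))
  })
  idxs <- sort(unique(vapply(rows, `[[`, integer(1), "idx")))
  lapply(idxs, function(i) {
    m <- matrix(NA_real_, 3L, 4L)
    for (r in rows) if (r$idx == i) m[r$row, ] <- r$vals
    if (any(is.na(m))) stop("incomplete BIOMT block ", i, " in ",
                            basename(path))
    m
  })
}

#' Apply assembly matrices to a structure
#'
#' Builds the biological assembly by applying each (rotation |
#' translation) operator and concatenating the copies with suffixed chain
#' labels (the identity copy keeps its labels).
#'
#' @param structure a `psi_structure`.
#' @param matrices list of 3 x 4 matrices, e.g. from [parse_biomt()].
#' @return the expanded `psi_structure`.
#' @export
expand_assembly <- function(structure, matrices) {
  if (length(matrices) == 0L) return(structure)
  at0 <- structure$atoms
  xyz0 <- as.matrix(at0[, c("x", "y", "z")])
  pieces <- lapply(seq_along(matrices), function(i) {
    m <- matrices[[i]]
    xyz <- xyz0 %*% t(m[, 1:3]) + matrix(m[, 4L], nrow(xyz0), 3L,
                                         byrow = TRUE)
    atk <- at0
    atk$x <- xyz[, 1L]; atk$y <- xyz[, 2L]; atk$z <- xyz[, 3L]
    ident <- max(abs(m - cbind(diag(3), 0))) < 1e-9
    if (!ident) atk$chain <- paste0(at0$chain, i)
    atk
  })
  new_structure(do.call(rbind, pieces),
                identifier = paste0(structure$identifier, "_assembly"),
                cell = structure$cell, space_group = structure$space_group)
}

#' Full cryo-vs-RT comparison over two deposited structures
#'
#' Runs the complete desk-scale pipeline on a reference (cryogenic) and an
#' alternate (room-temperature) deposition: C-alpha superposition RMSD,
#' monomer (and, when assembly operators are present, trimer) radii of
#' gyration, the chlorophyll expansion profile in the per-structure
#' P700-FX frames, and the phylloquinone-pocket stacking comparison.
#'
#' @param ref_path,alt_path coordinate files.
#' @param registry cofactor registry.
#' @param ref_dialect,alt_dialect registry dialect keys; default the file
#'   stems.
#' @return list with `ca`, `rg_monomer`, `rg_trimer` (or `NULL`),
#'   `expansion` (profile + summary), `pockets` (two reports + deltas).
#' @export
deposited_comparison <- function(ref_path, alt_path,
                                 registry = read_registry(),
                                 ref_dialect = NULL, alt_dialect = NULL) {
  ref <- collapse_altlocs(read_structure(ref_path))
  alt <- collapse_altlocs(read_structure(alt_path))
  map_ref <- build_cofactor_map(ref, registry, ref_dialect)
  map_alt <- build_cofactor_map(alt, registry, alt_dialect)
  prof <- expansion_profile(ref, alt, map_ref, map_alt)
  rg_tri <- NULL
  if (grepl("\\.pdb$", alt_path, ignore.case = TRUE)) {
    mats <- tryCatch(parse_biomt(alt_path), error = function(e) list())
    if (length(mats) >= 3L) {
      tri <- expand_assembly(alt, mats)
      rg_tri <- unname(rg_comparison(tri, tri)[1L])
      message("trimer built from ", length(mats), " assembly operators")
    }
  }
  rep_ref <- stacking_report(ref, map_ref)
  rep_alt <- stacking_report(alt, map_alt)
  list(
    ca = ca_rmsd(ref, alt),
    rg_monomer = rg_comparison(ref, alt),
    rg_trimer = rg_tri,
    expansion = list(profile = prof, summary = expansion_summary(prof)),
    pockets = list(ref = rep_ref, alt = rep_alt,
                   delta = compare_pockets(rep_ref, rep_alt))
  )
}
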