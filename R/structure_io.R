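#' @importFrom stats sd cor coef lm median rnorm runif setNames aggregate
#' @importFrom utils read.table write.table head tail
#' @importFrom mclust Mclust mclustBIC
NULL

# ---------------------------------------------------------------------------
# Structure container
# ---------------------------------------------------------------------------

#' Construct a structure object
#'
#' A `psi_structure` is the in-memory representation of a macromolecular
#' coordinate file: an ordered atom table plus optional unit cell and space
#' group. Atom order is preserved exactly as read.
#'
#' @param atoms data.frame with columns `chain`, `resid` (residue name),
#'   `resno` (deposited residue number), `atom` (atom name), `element`,
#'   `x`, `y`, `z` (Angstrom), `o` (occupancy), `b` (B-factor, Angstrom^2),
#'   `alt` (altloc character, `""` when absent), `hydrogen` (logical).
#' @param identifier free-text identifier (accession or file stem).
#' @param cell optional numeric length-6 vector `(a, b, c, alpha, beta,
#'   gamma)` in Angstrom / degrees.
#' @param space_group optional space-group symbol.
#' @return an object of class `psi_structure`.
#' @export
new_structure <- function(atoms, identifier = "structure", cell = NULL,
                          space_group = NULL) {
  required <- c("chain", "resid", "resno", "atom", "element",
                "x", "y", "z", "o", "b", "alt", "hydrogen")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  if (any(atoms$o < 0 | atoms$o > 1, na.rm = TRUE)) {
    stop("occupancy outside [0, 1]")
  }
  if (any(!nzchar(atoms$element))) {
    stop("empty element symbol")
  }
  key <- paste(atoms$chain, atoms$resno, atoms$atom, atoms$alt, sep = "|")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate atom record (chain|resno|atom|alt): ", dup)
  }
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms, identifier = identifier, cell = cell,
         space_group = space_group),
    class = "psi_structure"
  )
}

#' @export
print.psi_structure <- function(x, ...) {
  cat("psi_structure:", x$identifier, "\n")
  cat("  atoms:", nrow(x$atoms),
      sprintf("(%d hydrogen)", sum(x$atoms$hydrogen)), "\n")
  cat("  chains:", paste(unique(x$atoms$chain), collapse = " "), "\n")
  if (!is.null(x$cell)) {
    cat("  cell:", paste(sprintf("%.2f", x$cell), collapse = " "), "\n")
  }
  if (!is.null(x$space_group)) cat("  space group:", x$space_group, "\n")
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure a `psi_structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Atom coordinates as a matrix
#' @param structure a `psi_structure`.
#' @param idx optional row indices into the atom table.
#' @return numeric matrix with one row per atom and columns x, y, z.
#' @export
atom_xyz <- function(structure, idx = NULL) {
  at <- structure$atoms
  if (!is.null(idx)) at <- at[idx, , drop = FALSE]
  as.matrix(at[, c("x", "y", "z")])
}

guess_element <- function(atom_name, resid) {
  # PDB element guess when the element column is absent: strip digits and
  # primes, then take the leading one- or two-letter symbol.
  nm <- gsub("[0-9']", "", toupper(atom_name))
  nm[nm == ""] <- "X"
  two <- c("MG", "FE", "MN", "ZN", "CL", "BR", "NA", "CA")
  ifelse(substr(nm, 1, 2) %in% two & nchar(nm) >= 2,
         substr(nm, 1, 2), substr(nm, 1, 1))
}

parse_cryst1 <- function(path) {
  lines <- readLines(path, n = 500L, warn = FALSE)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) == 0L) return(list(cell = NULL, sg = NULL))
  cl <- cl[1L]
  cell <- suppressWarnings(as.numeric(c(
    substr(cl, 7, 15), substr(cl, 16, 24), substr(cl, 25, 33),
    substr(cl, 34, 40), substr(cl, 41, 47), substr(cl, 48, 54))))
  sg <- trimws(substr(cl, 56, 66))
  if (any(is.na(cell))) cell <- NULL
  list(cell = cell, sg = if (nzchar(sg)) sg else NULL)
}

parse_cif_cell <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(tag) {
    ln <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
    if (length(ln) == 0L) return(NA_real_)
    suppressWarnings(as.numeric(strsplit(trimws(ln[1L]), "\\s+")[[1L]][2L]))
  }
  cell <- c(grab("_cell.length_a"), grab("_cell.length_b"),
            grab("_cell.length_c"), grab("_cell.angle_alpha"),
            grab("_cell.angle_beta"), grab("_cell.angle_gamma"))
  sg_ln <- grep("^_symmetry.space_group_name_H-M", lines, value = TRUE)
  sg <- if (length(sg_ln) > 0L) {
    gsub("['\"]", "", sub("^\\S+\\s+", "", trimws(sg_ln[1L])))
  } else NULL
  if (any(is.na(cell))) cell <- NULL
  list(cell = cell, sg = sg)
}

#' Read a macromolecular coordinate file
#'
#' Parses PDB (fixed-column v3.3) or mmCIF (`atom_site` loop) files through
#' bio3d and returns a [new_structure()] object. All ATOM/HETATM records are
#' retained, including hydrogens (flagged in the `hydrogen` column) and
#' alternate locations.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"pdb"`, `"cif"`. `"auto"` dispatches on
#'   the file extension (`.cif`/`.mmcif` vs anything else).
#' @return a `psi_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)(\\.gz)?$", path, ignore.case = TRUE))
      "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
    } else {
      bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE)
    },
    error = function(e) stop("parse error in ", basename(path), " [",
                             format, "]: ", conditionMessage(e))
  )
  at <- pdb$atom
  element <- if (!is.null(at$elesy) && any(nzchar(trimws(at$elesy)))) {
    el <- trimws(toupper(at$elesy))
    el[!nzchar(el)] <- guess_element(at$elety[!nzchar(el)],
                                     at$resid[!nzchar(el)])
    el
  } else {
    guess_element(at$elety, at$resid)
  }
  alt <- as.character(at$alt)
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  occ <- pmin(pmax(occ, 0), 1)
  b <- at$b
  b[is.na(b)] <- 0
  chain <- as.character(at$chain)
  chain[is.na(chain)] <- " "
  atoms <- data.frame(
    chain = chain, resid = as.character(at$resid), resno = at$resno,
    atom = as.character(at$elety), element = element,
    x = at$x, y = at$y, z = at$z, o = occ, b = b, alt = alt,
    hydrogen = element %in% c("H", "D"),
    stringsAsFactors = FALSE
  )
  hdr <- if (format == "pdb") parse_cryst1(path) else parse_cif_cell(path)
  new_structure(atoms, identifier = sub("\\.[^.]*$", "", basename(path)),
                cell = hdr$cell, space_group = hdr$sg)
}

#' Write a structure as a PDB file
#'
#' Fixed-column PDB v3.3 output; coordinates are written with 3 decimals,
#' which bounds the round-trip precision. Standard amino-acid residues are
#' written as ATOM, everything else as HETATM.
#'
#' @param structure a `psi_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  at <- structure$atoms
  aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(structure$cell)) {
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                       structure$cell[1], structure$cell[2],
                       structure$cell[3], structure$cell[4],
                       structure$cell[5], structure$cell[6],
                       if (is.null(structure$space_group)) "P 1"
                       else structure$space_group), con)
  }
  rec <- ifelse(at$resid %in% aa3, "ATOM  ", "HETATM")
  # atom-name column convention: 1-3 character names start in column 14
  nm <- ifelse(nchar(at$atom) < 4L, paste0(" ", at$atom), at$atom)
  lines <- sprintf(
    "%s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, seq_len(nrow(at)) %% 100000L, nm,
    ifelse(nzchar(at$alt), at$alt, " "), at$resid,
    substr(at$chain, 1, 1), at$resno, at$x, at$y, at$z, at$o, at$b,
    substr(at$element, 1, 2))
  writeLines(lines, con)
  writeLines("END", con)
  invisible(path)
}

#' Collapse alternate locations and drop hydrogens
#'
#' For every (chain, residue number, atom name) the record with the highest
#' occupancy is kept; ties are broken toward the lexicographically smallest
#' altloc character. Hydrogens are removed: the downstream geometry operates
#' on heavy atoms only. The operation is idempotent and preserves the
#' original atom order of the survivors.
#'
#' @param structure a `psi_structure`.
#' @return a collapsed `psi_structure`.
#' @export
collapse_altlocs <- function(structure) {
  at <- structure$atoms[!structure$atoms$hydrogen, , drop = FALSE]
  if (nrow(at) == 0L) {
    structure$atoms <- at
    return(structure)
  }
  key <- paste(at$chain, at$resno, at$atom, sep = "|")
  ord <- order(key, -at$o, at$alt)
  keep_sorted <- !duplicated(key[ord])
  keep <- sort(ord[keep_sorted])
  at <- at[keep, , drop = FALSE]
  rownames(at) <- NULL
  structure$atoms <- at
  structure
}

# ---------------------------------------------------------------------------
# Cofactor registry
# ---------------------------------------------------------------------------

#' Path to the shipped cofactor registry
#' @return file path of the default registry YAML.
#' @export
default_registry_path <- function() {
  system.file("extdata", "registry.yaml", package = "psigeom", mustWork = TRUE)
}

#' Read a cofactor registry
#'
#' The registry is a human-editable YAML file keyed by structure dialect
#' (deposition accession or `synthetic`). Each dialect supplies selectors for
#' the P700 Mg pair, the FX iron cluster, the chlorophyll Mg sweep and the
#' named aromatic ring sets, because chain labels and cofactor numbering
#' differ between depositions.
#'
#' @param path registry file; defaults to the shipped registry.
#' @return named list of dialect configurations.
#' @export
read_registry <- function(path = default_registry_path()) {
  yaml::read_yaml(path)
}

# fixed planar atom-name sets; plane fits must be over planar moieties only
ring_atom_sets <- list(
  phe = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  trp = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  # naphthoquinone head: 10 fused-ring carbons + 2 carbonyl oxygens,
  # isoprenoid tail excluded; editable per deposition dialect
  phq = c("C1", "C2", "C3", "C4", "C4A", "C5", "C6", "C7", "C8", "C8A",
          "O1", "O2"),
  hex = c("C1", "C2", "C3", "C4", "C5", "C6")
)

find_atoms <- function(at, chain = NULL, resno = NULL, resname = NULL,
                       atom = NULL, exclude_chains = NULL) {
  sel <- rep(TRUE, nrow(at))
  if (!is.null(chain)) sel <- sel & at$chain %in% chain
  if (!is.null(exclude_chains)) sel <- sel & !(at$chain %in% exclude_chains)
  if (!is.null(resno)) sel <- sel & at$resno %in% resno
  if (!is.null(resname)) sel <- sel & at$resid %in% resname
  if (!is.null(atom)) sel <- sel & at$atom %in% atom
  which(sel)
}

resolve_one_atom <- function(at, spec, what) {
  idx <- find_atoms(at, chain = spec$chain, resno = spec$resno,
                    atom = spec$atom)
  if (length(idx) != 1L) {
    stop("cofactor map: selector for ", what, " (chain ", spec$chain,
         " resno ", spec$resno, " atom ", spec$atom, ") resolved to ",
         length(idx), " atoms")
  }
  idx
}

resolve_ring_set <- function(at, spec) {
  atoms <- if (!is.null(spec$atoms)) unlist(spec$atoms)
           else ring_atom_sets[[spec$type]]
  if (is.null(atoms)) stop("ring set ", spec$name, ": unknown type ",
                           spec$type)
  idx <- find_atoms(at, chain = spec$chain, resno = spec$resno,
                    resname = spec$resname, atom = atoms)
  if (length(idx) < 5L) {
    stop("cofactor map: ring set ", spec$name, " resolved only ",
         length(idx), " of ", length(atoms), " atoms (chain ", spec$chain,
         " resno ", spec$resno %||% spec$resname, ")")
  }
  idx
}

#' Resolve the named analysis targets of a structure
#'
#' Builds a `cofactor_map`: the P700 Mg pair, the four FX irons, the labeled
#' chlorophyll Mg set (tagged ET-chain / connecting / antenna) and the named
#' aromatic ring-atom sets, resolved through a dialect entry of the registry.
#' The structure should be altloc-collapsed first so every selector resolves
#' to exactly one atom.
#'
#' @param structure a collapsed `psi_structure`.
#' @param registry registry list from [read_registry()].
#' @param dialect dialect key in the registry; defaults to the structure
#'   identifier (lower-cased) when present in the registry.
#' @return an object of class `cofactor_map` with elements `p700_mg`
#'   (2 atom indices), `fx_fe` (4 indices), `chl` (data.frame `label`,
#'   `branch`, `idx`), `ring_sets` (named list of index vectors).
#' @export
build_cofactor_map <- function(structure, registry = read_registry(),
                               dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- tolower(structure$identifier)
    if (!dialect %in% names(registry)) {
      stop("no registry dialect for '", dialect,
           "'; available: ", paste(names(registry), collapse = ", "))
    }
  }
  cfg <- registry[[dialect]]
  if (is.null(cfg)) stop("unknown registry dialect: ", dialect)
  at <- structure$atoms

  # --- chlorophyll Mg sweep ------------------------------------------------
  chl_cfg <- cfg$chl
  sweep_idx <- find_atoms(at, resname = unlist(chl_cfg$resname),
                          atom = chl_cfg$atom %||% "MG",
                          chain = if (!is.null(chl_cfg$chains))
                            unlist(chl_cfg$chains) else NULL)
  if (length(sweep_idx) == 0L) stop("cofactor map: no chlorophyll Mg found")
  chl <- data.frame(
    label = paste0(at$chain[sweep_idx], at$resno[sweep_idx]),
    branch = "antenna", idx = sweep_idx, stringsAsFactors = FALSE)
  for (ov in chl_cfg$branch_overrides) {
    hit <- chl$idx %in% find_atoms(at, chain = ov$chain, resno = ov$resno)
    chl$branch[hit] <- ov$branch
    if (!is.null(ov$label)) chl$label[hit] <- ov$label
  }
  if (anyDuplicated(chl$label)) stop("cofactor map: duplicate Chl labels")

  # --- P700 ----------------------------------------------------------------
  p700_cfg <- cfg$p700
  if (identical(p700_cfg$kind, "closest_pair")) {
    # the special pair is the closest Mg-Mg pair in the Chl set
    xyz <- atom_xyz(structure, chl$idx)
    d <- as.matrix(stats::dist(xyz))
    diag(d) <- Inf
    ij <- which(d == min(d), arr.ind = TRUE)[1L, ]
    if (min(d) > (p700_cfg$max_sep %||% 7.0)) {
      stop("cofactor map: no Chl Mg pair within ",
           p700_cfg$max_sep %||% 7.0, " A for P700")
    }
    p700_mg <- chl$idx[sort(ij)]
  } else {
    p700_mg <- vapply(p700_cfg$atoms, resolve_one_atom, integer(1),
                      at = at, what = "P700 Mg")
  }

  # --- FX ------------------------------------------------------------------
  fx_cfg <- cfg$fx
  fx_fe <- if (!is.null(fx_cfg$atoms) && !is.null(fx_cfg$resno)) {
    find_atoms(at, chain = fx_cfg$chain, resno = fx_cfg$resno,
               atom = unlist(fx_cfg$atoms))
  } else {
    find_atoms(at, resname = fx_cfg$resname %||% "SF4",
               exclude_chains = if (!is.null(fx_cfg$exclude_chains))
                 unlist(fx_cfg$exclude_chains) else NULL)
  }
  fx_fe <- fx_fe[at$element[fx_fe] == "FE"]
  if (length(fx_fe) != 4L) {
    stop("cofactor map: FX selector resolved ", length(fx_fe),
         " Fe atoms (need 4)")
  }

  # --- ring sets -----------------------------------------------------------
  ring_sets <- list()
  for (rs in cfg$ring_sets) {
    if (isTRUE(rs$optional)) {
      idx <- tryCatch(resolve_ring_set(at, rs), error = function(e) NULL)
      if (!is.null(idx)) ring_sets[[rs$name]] <- idx
    } else {
      ring_sets[[rs$name]] <- resolve_ring_set(at, rs)
    }
  }

  # --- branch tagging by axial proximity (deposited dialects) --------------
  if (identical(chl_cfg$branch_rule, "axial")) {
    fr <- axial_frame(atom_xyz(structure, p700_mg),
                      atom_xyz(structure, fx_fe))
    cyl <- cylindrical_decompose(fr, atom_xyz(structure, chl$idx))
    ord <- order(cyl$radial)
    chl$branch <- "antenna"
    chl$branch[ord[seq_len(min(6L, nrow(chl)))]] <- "ET-chain"
    if (nrow(chl) > 8L) chl$branch[ord[7:8]] <- "connecting"
  }

  structure(
    list(p700_mg = unname(p700_mg), fx_fe = unname(fx_fe), chl = chl,
         ring_sets = ring_sets, dialect = dialect,
         structure_id = structure$identifier),
    class = "cofactor_map"
  )
}

#' @export
print.cofactor_map <- function(x, ...) {
  cat("cofactor_map [", x$dialect, "] for", x$structure_id, "\n")
  cat("  Chl Mg:", nrow(x$chl),
      sprintf("(ET-chain %d, connecting %d, antenna %d)",
              sum(x$chl$branch == "ET-chain"),
              sum(x$chl$branch == "connecting"),
              sum(x$chl$branch == "antenna")), "\n")
  cat("  ring sets:", paste(names(x$ring_sets), collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
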