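#' @title Structure containers and I/O
#' @name structure_io
#' @description
#' A `pump_structure` holds the ordered atom records of one model of a
#' macromolecular structure: chain, author residue number (1-based,
#' inclusive ranges throughout the package, rabbit SERCA1a numbering for
#' the pump analyses), atom name, element, coordinates in Angstrom,
#' occupancy and HETATM flag. Parsing is delegated to bio3d; this module
#' adds the altloc policy, deterministic sorting, key-based atom pairing
#' across structures, and selection resolution.
NULL

# Backbone atom set used whenever an analysis asks for "main chain".
# Carbonyl O included; override per call with atom_set = "CA" or "all".
MAINCHAIN_ATOMS <- c("N", "CA", "C", "O")

WATER_RESNAMES <- c("HOH", "WAT", "TIP", "TIP3", "SOL", "H2O")

#' Construct a structure from an atom table
#'
#' @param atoms data.frame with columns serial, name, altloc, resname,
#'   chain, resseq, icode, x, y, z, occupancy, element, het
#' @param model_index model number the atoms came from
#' @param source_id free-form identifier (e.g. a PDB code)
#' @return object of class `pump_structure`
#' @export
new_structure <- function(atoms, model_index = 1L, source_id = "") {
  required <- c("serial", "name", "altloc", "resname", "chain", "resseq",
                "icode", "x", "y", "z", "occupancy", "element", "het")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("structure must contain at least one atom")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in atom table")
  }
  atoms$occupancy[!is.finite(atoms$occupancy)] <- 1
  atoms <- atoms[order(atoms$chain, atoms$resseq, atoms$icode, atoms$serial), ,
                 drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms,
                 model_index = as.integer(model_index),
                 source_id = source_id),
            class = "pump_structure")
}

#' @export
print.pump_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<pump_structure> %s model %d: %d atoms, %d residues, chains %s\n",
              if (nzchar(x$source_id)) x$source_id else "(unnamed)",
              x$model_index, nrow(a),
              length(unique(paste(a$chain, a$resseq, a$icode))),
              paste(sort(unique(a$chain)), collapse = ",")))
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a `pump_structure`
#' @return integer atom count
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Coordinate matrix of a structure
#' @param s a `pump_structure`
#' @return numeric n x 3 matrix (Angstrom)
#' @export
coords <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#' @param s a `pump_structure`
#' @param xyz n x 3 matrix matching the atom count
#' @return the structure with new coordinates
#' @export
set_coords <- function(s, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(s$atoms) || ncol(xyz) != 3) {
    stop("coordinate matrix must be ", nrow(s$atoms), " x 3")
  }
  s$atoms$x <- xyz[, 1]
  s$atoms$y <- xyz[, 2]
  s$atoms$z <- xyz[, 3]
  s
}

# Resolve alternate locations: keep the highest-occupancy conformer of each
# (chain, resseq, icode, name); ties broken in favour of altloc "A" (then
# alphabetical), so the result is deterministic.
resolve_altlocs <- function(atoms) {
  alt <- atoms$altloc
  alt[is.na(alt)] <- ""
  atoms$altloc <- alt
  if (all(alt == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name, sep = "\r")
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  key <- key[ord]
  atoms <- atoms[!duplicated(key), , drop = FALSE]
  atoms
}

infer_element <- function(name, resname) {
  elem <- gsub("[^A-Za-z]", "", name)
  # standard PDB convention: first letter after stripping digits; two-letter
  # metals appear in full in the name for the ligands handled here
  up <- toupper(elem)
  two <- substr(up, 1, 2)
  ifelse(two %in% c("AL", "FE", "MG", "ZN", "MN", "NA", "CL", "CA") &
           !(resname %in% c(
             # amino acids where CA/CL.. prefixes are carbon atoms
             "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL")),
         two, substr(up, 1, 1))
}

#' Read a macromolecular structure
#'
#' Reads one model of a PDB or mmCIF file into a `pump_structure`.
#' Alternate locations are resolved by keeping the highest-occupancy
#' conformer (tie -> altloc "A"). Waters and other heteroatoms are
#' retained and flagged in the `het` column; selection helpers exclude
#' them by default.
#'
#' @param path file path
#' @param format one of "auto", "pdb", "mmcif"; "auto" decides from the
#'   file extension
#' @param model_index which model to keep (1-based)
#' @return a `pump_structure`
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           model_index = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    } else {
      suppressWarnings(suppressMessages(bio3d::read.cif(path, verbose = FALSE)))
    },
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  n_models <- max(1L, nrow(pdb$xyz))
  if (model_index < 1 || model_index > n_models) {
    stop("model_index ", model_index, " out of range; file has ",
         n_models, " model(s)")
  }
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- infer_element(at$elety, at$resid)
  } else {
    elem[is.na(elem) | elem == ""] <-
      infer_element(at$elety, at$resid)[is.na(elem) | elem == ""]
  }
  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    altloc = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    resname = at$resid,
    chain = ifelse(is.na(at$chain), "", at$chain),
    resseq = at$resno,
    icode = ifelse(is.na(at$insert) | at$insert == "", "", at$insert),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = ifelse(is.na(at$o), 1, at$o),
    element = toupper(elem),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE)
  atoms <- resolve_altlocs(atoms)
  new_structure(atoms, model_index = model_index,
                source_id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a structure as a PDB file
#'
#' @param s a `pump_structure`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$het, "HETATM", "ATOM"),
    resno = a$resseq,
    resid = a$resname,
    eleno = a$serial,
    elety = a$name,
    chain = ifelse(a$chain == "", " ", a$chain),
    insert = ifelse(a$icode == "", "", a$icode),
    o = a$occupancy,
    b = rep(0, nrow(a)),
    elesy = a$element)
  invisible(path)
}

#' Define an atom selection
#'
#' A selection filters by chain, inclusive author residue-number ranges,
#' atom names, and HETATM status. An empty selection resolves to zero
#' atoms and never errors.
#'
#' @param chains character vector of chain ids, or NULL for all
#' @param ranges list of length-2 integer vectors `c(start, end)`
#'   (inclusive), or NULL for all residues
#' @param atom_names character vector of atom names, or NULL for all
#' @param include_het logical; include HETATM records (waters, ligands)
#' @param include_water logical; include water residues (only relevant
#'   when `include_het` is TRUE)
#' @return object of class `pump_selection`
#' @export
atom_selection <- function(chains = NULL, ranges = NULL, atom_names = NULL,
                           include_het = FALSE, include_water = FALSE) {
  if (!is.null(ranges)) {
    if (is.numeric(ranges) && length(ranges) == 2) ranges <- list(ranges)
    for (r in ranges) {
      if (length(r) != 2 || !is.numeric(r)) stop("each range must be c(start, end)")
      if (r[1] > r[2]) stop("range start exceeds end: ", r[1], "-", r[2])
    }
  }
  structure(list(chains = chains, ranges = ranges, atom_names = atom_names,
                 include_het = include_het, include_water = include_water),
            class = "pump_selection")
}

#' @export
print.pump_selection <- function(x, ...) {
  rng <- if (is.null(x$ranges)) "all" else
    paste(vapply(x$ranges, function(r) paste(r[1], r[2], sep = "-"),
                 character(1)), collapse = ",")
  cat(sprintf("<pump_selection> chains=%s resi=%s atoms=%s het=%s\n",
              if (is.null(x$chains)) "all" else paste(x$chains, collapse = ","),
              rng,
              if (is.null(x$atom_names)) "all" else
                paste(x$atom_names, collapse = ","),
              x$include_het))
  invisible(x)
}

selection_mask <- function(s, sel) {
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chains)) keep <- keep & a$chain %in% sel$chains
  if (!is.null(sel$ranges)) {
    in_range <- rep(FALSE, nrow(a))
    for (r in sel$ranges) {
      in_range <- in_range | (a$resseq >= r[1] & a$resseq <= r[2])
    }
    keep <- keep & in_range
  }
  if (!is.null(sel$atom_names)) keep <- keep & a$name %in% sel$atom_names
  if (!isTRUE(sel$include_het)) keep <- keep & !a$het
  if (!isTRUE(sel$include_water)) keep <- keep & !(a$resname %in% WATER_RESNAMES)
  keep
}

#' Subset a structure by a selection
#'
#' Order-preserving and idempotent; an empty result is allowed (the
#' returned object then has zero atom rows and most downstream operations
#' will refuse it explicitly).
#'
#' @param s a `pump_structure`
#' @param sel a `pump_selection`
#' @return a `pump_structure` (possibly with zero atoms)
#' @export
select_atoms <- function(s, sel) {
  stopifnot(inherits(sel, "pump_selection"))
  a <- s$atoms[selection_mask(s, sel), , drop = FALSE]
  rownames(a) <- NULL
  out <- s
  out$atoms <- a
  out
}

atom_keys <- function(s) {
  paste(s$atoms$chain, s$atoms$resseq, s$atoms$icode, s$atoms$name, sep = "\r")
}

#' Pair equivalent atoms of two structures
#'
#' Atoms are matched by the key (chain, resseq, icode, name); only atoms
#' present in both structures are returned, in the order of `a`. The
#' report lists the identifiers dropped from each side.
#'
#' @param a,b `pump_structure` objects
#' @return list with `xyz_a`, `xyz_b` (equal-sized n x 3 matrices),
#'   `keys` data.frame (chain, resseq, icode, name), `dropped_a`,
#'   `dropped_b` (character vectors of unmatched keys)
#' @export
pair_common_atoms <- function(a, b) {
  if (n_atoms(a) == 0 || n_atoms(b) == 0) stop("both structures must be non-empty")
  ka <- atom_keys(a)
  kb <- atom_keys(b)
  ia <- which(ka %in% kb)
  if (length(ia) == 0) {
    stop("no atoms in common between ", a$source_id, " and ", b$source_id,
         " under key (chain, resseq, icode, name)")
  }
  ib <- match(ka[ia], kb)
  keys <- a$atoms[ia, c("chain", "resseq", "icode", "name")]
  rownames(keys) <- NULL
  list(xyz_a = coords(a)[ia, , drop = FALSE],
       xyz_b = coords(b)[ib, , drop = FALSE],
       keys = keys,
       dropped_a = gsub("\r", "/", setdiff(ka, kb)),
       dropped_b = gsub("\r", "/", setdiff(kb, ka)))
}
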