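#' @title Least-squares superposition and scalar geometric observables
#' @name geometry_core
#' @description
#' Closed-form Kabsch (SVD) rigid-body superposition, segment-decomposed
#' RMSD reports evaluated in a single fitted frame, three-point angles on
#' named residues (headpiece hinge, M1 kink), residue pair distances, and
#' the in-line phosphoryl-transfer geometry at the catalytic aspartate.
#' Coordinates are row vectors: a transform maps `X` to
#' `X %*% rotation + translation`.
NULL

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' paired point sets. The configuration must span at least a plane: for
#' (near-)collinear point sets the rotation about the line is undefined
#' and an error is raised.
#'
#' @param mobile n x 3 matrix to be moved
#' @param reference n x 3 matrix of target positions (same n)
#' @return object of class `pump_transform`: list with `rotation` (3 x 3,
#'   determinant +1), `translation` (length 3), `fit_rmsd` (Angstrom),
#'   `n_fit_atoms`
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) {
    stop("mobile and reference must have the same number of points (",
         nrow(mobile), " vs ", nrow(reference), ")")
  }
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 points to superpose, got ", n)
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  C <- crossprod(P, Q)
  sv <- svd(C)
  if (sv$d[1] <= 0 || sv$d[2] / sv$d[1] < 1e-10) {
    stop("degenerate (collinear) point configuration; rotation undefined")
  }
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  translation <- as.numeric(cr - cm %*% R)
  moved <- mobile %*% R + rep(1, n) %o% translation
  fit_rmsd <- sqrt(mean(rowSums((moved - reference)^2)))
  structure(list(rotation = R, translation = translation,
                 fit_rmsd = fit_rmsd, n_fit_atoms = n),
            class = "pump_transform")
}

#' @export
print.pump_transform <- function(x, ...) {
  ang <- rotation_angle(x)
  cat(sprintf("<pump_transform> rotation %.2f deg, |t| = %.2f A, fit rmsd %.3f A on %d atoms\n",
              ang, sqrt(sum(x$translation^2)), x$fit_rmsd, x$n_fit_atoms))
  invisible(x)
}

#' Rotation angle of a transform
#' @param tr a `pump_transform` or 3 x 3 rotation matrix
#' @return angle in degrees in [0, 180]
#' @export
rotation_angle <- function(tr) {
  R <- if (inherits(tr, "pump_transform")) tr$rotation else tr
  ct <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Apply a rigid transform to coordinates or a structure
#' @param x n x 3 matrix or `pump_structure`
#' @param tr a `pump_transform`
#' @return object of the same type with transformed coordinates
#' @export
apply_transform <- function(x, tr) {
  stopifnot(inherits(tr, "pump_transform"))
  if (inherits(x, "pump_structure")) {
    return(set_coords(x, apply_transform(coords(x), tr)))
  }
  x <- as.matrix(x)
  x %*% tr$rotation + rep(1, nrow(x)) %o% tr$translation
}

rmsd_between <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

atom_set_names <- function(atom_set = c("mainchain", "CA", "all")) {
  atom_set <- match.arg(atom_set)
  switch(atom_set, mainchain = MAINCHAIN_ATOMS, CA = "CA", all = NULL)
}

#' Segment-decomposed RMSD report in a single fitted frame
#'
#' Pairs the two structures atom-by-atom (waters and heteroatoms
#' excluded), computes ONE least-squares fit on the atoms of
#' `fit_segment`, and evaluates the RMSD of every requested segment in
#' that fitted frame without refitting. `fit_segment = "ALL"` fits on all
#' paired atoms of the chosen atom set (the global comparison). The fit
#' segment's own RMSD is always included.
#'
#' @param ref,mobile `pump_structure` objects
#' @param fit_segment segment name, or "ALL"
#' @param report_segments character vector of segment names (may include
#'   "ALL")
#' @param atom_set "mainchain" (N, CA, C, O), "CA" or "all"
#' @param registry a `segment_registry`
#' @return object of class `domain_rmsd_report`: list with `fit_segment`,
#'   `atom_set`, `transform` and `segments` (data.frame of segment, rmsd,
#'   n_atoms, note)
#' @export
compare_structures <- function(ref, mobile, fit_segment = "M5M10",
                               report_segments = fit_segment,
                               atom_set = c("mainchain", "CA", "all"),
                               registry = segment_registry()) {
  atom_set <- match.arg(atom_set)
  an <- atom_set_names(atom_set)
  sel_all <- atom_selection(atom_names = an)
  pr <- pair_common_atoms(select_atoms(ref, sel_all),
                          select_atoms(mobile, sel_all))

  seg_rows <- function(name) {
    if (identical(name, "ALL")) return(seq_len(nrow(pr$keys)))
    sel <- get_segment(name, registry)
    rows <- rep(FALSE, nrow(pr$keys))
    for (r in sel$ranges) {
      rows <- rows | (pr$keys$resseq >= r[1] & pr$keys$resseq <= r[2])
    }
    which(rows)
  }

  fit_rows <- seg_rows(fit_segment)
  if (length(fit_rows) < 3) {
    stop("fit segment '", fit_segment, "' has fewer than 3 paired atoms")
  }
  tr <- kabsch_superpose(pr$xyz_b[fit_rows, , drop = FALSE],
                         pr$xyz_a[fit_rows, , drop = FALSE])
  moved <- apply_transform(pr$xyz_b, tr)

  report_segments <- unique(c(fit_segment, report_segments))
  rows_list <- lapply(report_segments, function(nm) {
    rows <- tryCatch(seg_rows(nm), error = function(e) e)
    if (inherits(rows, "error")) {
      return(data.frame(segment = nm, rmsd = NA_real_, n_atoms = 0L,
                        note = conditionMessage(rows)))
    }
    if (length(rows) == 0) {
      return(data.frame(segment = nm, rmsd = NA_real_, n_atoms = 0L,
                        note = "empty after pairing"))
    }
    data.frame(segment = nm,
               rmsd = rmsd_between(moved[rows, , drop = FALSE],
                                   pr$xyz_a[rows, , drop = FALSE]),
               n_atoms = length(rows), note = "")
  })
  segments <- do.call(rbind, rows_list)
  rownames(segments) <- NULL
  structure(list(fit_segment = fit_segment, atom_set = atom_set,
                 transform = tr, segments = segments,
                 n_paired = nrow(pr$keys),
                 n_dropped_ref = length(pr$dropped_a),
                 n_dropped_mobile = length(pr$dropped_b)),
            class = "domain_rmsd_report")
}

#' @export
print.domain_rmsd_report <- function(x, ...) {
  cat(sprintf("<domain_rmsd_report> fit on %s (%s atoms), %d paired atoms\n",
              x$fit_segment, x$atom_set, x$n_paired))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' RMSD of one segment from a report
#' @param report a `domain_rmsd_report`
#' @param segment segment name present in the report
#' @return numeric RMSD in Angstrom
#' @export
report_rmsd <- function(report, segment) {
  i <- match(segment, report$segments$segment)
  if (is.na(i)) stop("segment '", segment, "' not in report")
  report$segments$rmsd[i]
}

#' Angle defined by three points
#'
#' @param p1,p2,p3 numeric length-3 vectors; the angle is measured at the
#'   vertex `p2`
#' @return angle in degrees in [0, 180]
#' @export
point_angle <- function(p1, p2, p3) {
  v1 <- as.numeric(p1) - as.numeric(p2)
  v2 <- as.numeric(p3) - as.numeric(p2)
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-9 || n2 < 1e-9) stop("zero-length arm in angle computation")
  ct <- sum(v1 * v2) / (n1 * n2)
  acos(max(-1, min(1, ct))) * 180 / pi
}

# Locate one atom; res is a residue spec: either an integer residue number
# or list(chain=, resseq=, icode=).
find_atom <- function(s, res, atom) {
  if (is.numeric(res)) res <- list(resseq = res)
  a <- s$atoms
  keep <- a$resseq == res$resseq & a$name == atom
  if (!is.null(res$chain)) keep <- keep & a$chain == res$chain
  if (!is.null(res$icode)) keep <- keep & a$icode == res$icode
  i <- which(keep)
  if (length(i) == 0) {
    stop("atom ", atom, " of residue ", res$resseq, " not found in ",
         s$source_id)
  }
  i[1]
}

#' Angle between three named residues
#'
#' The vertex is the middle residue (`r2`). With the default `atom =
#' "CA"` this realizes the headpiece-tilt metric (Leu13-Thr86-Leu98) and
#' the M1 kink metric (Trp50-Arg63-Val74): a sharper kink gives a smaller
#' angle.
#'
#' @param s a `pump_structure`
#' @param r1,r2,r3 residue specs (integer residue number or
#'   `list(chain=, resseq=)`)
#' @param atom atom name used for all three points
#' @return angle in degrees
#' @export
residue_triplet_angle <- function(s, r1, r2, r3, atom = "CA") {
  xyz <- coords(s)
  point_angle(xyz[find_atom(s, r1, atom), ],
              xyz[find_atom(s, r2, atom), ],
              xyz[find_atom(s, r3, atom), ])
}

#' Distance between two named atoms
#'
#' @param s a `pump_structure`
#' @param resA,resB residue specs
#' @param atomA,atomB atom names (default CA, the convention used for the
#'   pump's landmark distances such as Pro337-Pro312)
#' @return distance in Angstrom
#' @export
residue_pair_distance <- function(s, resA, resB, atomA = "CA", atomB = "CA") {
  xyz <- coords(s)
  sqrt(sum((xyz[find_atom(s, resA, atomA), ] -
              xyz[find_atom(s, resB, atomB), ])^2))
}

# gamma-phosphate analog centres and the bridging atom of the terminal
# phosphoanhydride per ligand chemistry:
#   ATP/ADP + AlF4: Al centre, O3B bridge; ATP/ATPgS: PG, O3B;
#   AMPPCP (ACP): PG, methylene carbon C3B replaces the bridging oxygen.
.nuc_defaults <- c("ATP", "ACP", "ANP", "AGS", "ADP", "ALF", "AF3")

#' In-line phosphoryl-transfer geometry at the catalytic aspartate
#'
#' Locates the gamma-phosphate analog centre (Pgamma of a nucleotide, or
#' the Al atom of an aluminium fluoride transition-state mimic), picks the
#' catalytic aspartate carboxyl oxygen (OD1/OD2) nearer to it, and
#' returns their distance together with the attack angle at the analog
#' centre between that oxygen and the bridging atom of the terminal
#' phosphoanhydride bond (O3B, or the methylene C3B in AMPPCP). An
#' in-line associative geometry has a short distance and an angle near
#' 180 degrees.
#'
#' @param s a `pump_structure`
#' @param asp residue spec of the catalytic aspartate (default 351)
#' @param nuc_resnames residue names considered nucleotide/analog
#' @return object of class `catalytic_geometry`: list with `d_OdPg`
#'   (Angstrom), `theta` (degrees), and the atom identifiers used
#' @export
catalytic_geometry <- function(s, asp = 351, nuc_resnames = .nuc_defaults) {
  a <- s$atoms
  nuc <- a[a$resname %in% nuc_resnames, , drop = FALSE]
  if (nrow(nuc) == 0) {
    stop("no nucleotide or gamma-phosphate analog found (looked for ",
         paste(nuc_resnames, collapse = ", "), ")")
  }
  # analog centre: Al if an aluminium fluoride is present, else PG
  ctr_rows <- which(nuc$resname %in% c("ALF", "AF3") & nuc$element == "AL")
  if (length(ctr_rows) == 0) ctr_rows <- which(nuc$name == "PG")
  if (length(ctr_rows) == 0) {
    stop("no gamma-phosphate analog centre (PG or Al) among nucleotide atoms")
  }
  if (length(ctr_rows) > 1) {
    ids <- unique(paste(nuc$resname[ctr_rows], nuc$chain[ctr_rows],
                        nuc$resseq[ctr_rows]))
    stop("ambiguous: multiple analog centres found: ",
         paste(ids, collapse = "; "))
  }
  ctr <- nuc[ctr_rows, ]
  # bridging atom of the terminal phosphoanhydride
  br_rows <- which(nuc$name == "O3B")
  if (length(br_rows) == 0) br_rows <- which(nuc$name == "C3B")
  if (length(br_rows) == 0) {
    stop("no bridging atom (O3B/C3B) of the terminal phosphoanhydride found")
  }
  br <- nuc[br_rows[1], ]

  if (is.numeric(asp)) asp <- list(resseq = asp)
  od_keep <- a$resseq == asp$resseq & a$name %in% c("OD1", "OD2")
  if (!is.null(asp$chain)) od_keep <- od_keep & a$chain == asp$chain
  od <- a[od_keep, , drop = FALSE]
  if (nrow(od) == 0) {
    stop("no carboxyl oxygen (OD1/OD2) on aspartate ", asp$resseq)
  }
  p_ctr <- c(ctr$x, ctr$y, ctr$z)
  dists <- sqrt((od$x - p_ctr[1])^2 + (od$y - p_ctr[2])^2 + (od$z - p_ctr[3])^2)
  i <- which.min(dists)
  p_od <- c(od$x[i], od$y[i], od$z[i])
  p_br <- c(br$x, br$y, br$z)
  structure(list(
    d_OdPg = dists[i],
    theta = point_angle(p_br, p_ctr, p_od),
    od_atom = paste0(od$resname[i], od$resseq[i], ":", od$name[i]),
    center_atom = paste0(ctr$resname, ctr$resseq, ":", ctr$name),
    bridge_atom = paste0(br$resname, br$resseq, ":", br$name)),
    class = "catalytic_geometry")
}

#' @export
print.catalytic_geometry <- function(x, ...) {
  cat(sprintf("<catalytic_geometry> d(%s, %s) = %.2f A, angle at %s via %s = %.1f deg\n",
              x$od_atom, x$center_atom, x$d_OdPg, x$center_atom,
              x$bridge_atom, x$theta))
  invisible(x)
}
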