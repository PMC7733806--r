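#' @title Polar contacts and hydrogen bonds
#' @name contacts
#' @description
#' Geometric detection of polar contacts between two named atom groups.
#' For crystal structures without hydrogens the criterion is a
#' heavy-atom donor/acceptor (N, O; S as acceptor) distance cutoff
#' (default 3.5 Angstrom). When hydrogens are present (e.g. simulation
#' frames) a hydrogen-aware criterion is used: H...A <= 2.5 Angstrom and
#' D-H...A angle >= 120 degrees. Single-water bridges (donor-water-
#' acceptor, both legs within the cutoff) can be reported alongside
#' direct contacts.
NULL

#' Contact criterion
#'
#' @param heavy_cutoff donor-acceptor heavy-atom distance cutoff, Angstrom
#' @param h_dist_cutoff H...acceptor distance cutoff when hydrogens are
#'   present, Angstrom
#' @param h_angle_min minimum donor-H...acceptor angle, degrees
#' @param donor_elements,acceptor_elements element symbols allowed as
#'   donor / acceptor heavy atoms
#' @return object of class `contact_criterion`
#' @export
contact_criterion <- function(heavy_cutoff = 3.5, h_dist_cutoff = 2.5,
                              h_angle_min = 120,
                              donor_elements = c("N", "O"),
                              acceptor_elements = c("N", "O", "S")) {
  stopifnot(heavy_cutoff > 0, h_dist_cutoff > 0,
            h_angle_min > 0, h_angle_min <= 180)
  structure(list(heavy_cutoff = heavy_cutoff, h_dist_cutoff = h_dist_cutoff,
                 h_angle_min = h_angle_min,
                 donor_elements = donor_elements,
                 acceptor_elements = acceptor_elements),
            class = "contact_criterion")
}

polar_rows <- function(s, sel, elements) {
  sel$include_het <- TRUE          # ligand polar atoms may participate
  mask <- selection_mask(s, sel) & s$atoms$element %in% elements &
    !(s$atoms$resname %in% WATER_RESNAMES)
  which(mask)
}

atom_label <- function(a, i) {
  paste0(a$chain[i], "/", a$resname[i], a$resseq[i], a$icode[i], ":", a$name[i])
}

cross_distances <- function(xyz_a, xyz_b) {
  # n_a x n_b Euclidean distance matrix
  sq_a <- rowSums(xyz_a^2)
  sq_b <- rowSums(xyz_b^2)
  d2 <- outer(sq_a, sq_b, "+") - 2 * tcrossprod(xyz_a, xyz_b)
  sqrt(pmax(d2, 0))
}

#' Find polar contacts between two atom groups
#'
#' All heavy-atom donor/acceptor pairs across the groups within the
#' cutoff are reported (pairs within one residue are skipped). With
#' `allow_water_bridge` a second pass reports pairs linked through a
#' single water oxygen with both legs within the cutoff, flagged
#' `water_mediated` with the water identifier.
#'
#' @param s a `pump_structure`
#' @param groupA,groupB `pump_selection` objects
#' @param crit a `contact_criterion`
#' @param allow_water_bridge logical
#' @return data.frame with columns atom_a, atom_b, distance,
#'   water_mediated, water_id (zero rows allowed)
#' @export
find_polar_contacts <- function(s, groupA, groupB,
                                crit = contact_criterion(),
                                allow_water_bridge = FALSE) {
  a <- s$atoms
  pol <- union(crit$donor_elements, crit$acceptor_elements)
  ia <- polar_rows(s, groupA, pol)
  ib <- polar_rows(s, groupB, pol)
  out <- data.frame(atom_a = character(), atom_b = character(),
                    distance = numeric(), water_mediated = logical(),
                    water_id = character(), stringsAsFactors = FALSE)
  if (length(ia) > 0 && length(ib) > 0) {
    xyz <- coords(s)
    D <- cross_distances(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
    res_a <- paste(a$chain[ia], a$resseq[ia], a$icode[ia])
    res_b <- paste(a$chain[ib], a$resseq[ib], a$icode[ib])
    hit <- which(D <= crit$heavy_cutoff, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      same_res <- res_a[hit[, 1]] == res_b[hit[, 2]]
      hit <- hit[!same_res, , drop = FALSE]
    }
    if (nrow(hit) > 0) {
      out <- data.frame(
        atom_a = vapply(ia[hit[, 1]], function(i) atom_label(a, i), character(1)),
        atom_b = vapply(ib[hit[, 2]], function(i) atom_label(a, i), character(1)),
        distance = D[hit],
        water_mediated = FALSE, water_id = "",
        stringsAsFactors = FALSE)
    }
  }
  if (allow_water_bridge && length(ia) > 0 && length(ib) > 0) {
    iw <- which(a$resname %in% WATER_RESNAMES & a$element == "O")
    if (length(iw) > 0) {
      xyz <- coords(s)
      DA <- cross_distances(xyz[iw, , drop = FALSE], xyz[ia, , drop = FALSE])
      DB <- cross_distances(xyz[iw, , drop = FALSE], xyz[ib, , drop = FALSE])
      rows <- list()
      for (w in seq_along(iw)) {
        ja <- which(DA[w, ] <= crit$heavy_cutoff)
        jb <- which(DB[w, ] <= crit$heavy_cutoff)
        if (length(ja) == 0 || length(jb) == 0) next
        for (p in ja) for (q in jb) {
          if (ia[p] == ib[q]) next
          rows[[length(rows) + 1]] <- data.frame(
            atom_a = atom_label(a, ia[p]),
            atom_b = atom_label(a, ib[q]),
            distance = DA[w, p] + DB[w, q],   # path length via the water
            water_mediated = TRUE,
            water_id = atom_label(a, iw[w]),
            stringsAsFactors = FALSE)
        }
      }
      if (length(rows) > 0) out <- rbind(out, do.call(rbind, rows))
    }
  }
  rownames(out) <- NULL
  out
}

has_hydrogens <- function(s) any(s$atoms$element == "H")

# hydrogens covalently bound to a heavy atom (distance <= 1.25 A)
bonded_hydrogens <- function(s, heavy_idx) {
  ih <- which(s$atoms$element == "H")
  if (length(ih) == 0) return(rep(list(integer(0)), length(heavy_idx)))
  xyz <- coords(s)
  D <- cross_distances(xyz[heavy_idx, , drop = FALSE],
                       xyz[ih, , drop = FALSE])
  lapply(seq_along(heavy_idx), function(i) ih[which(D[i, ] <= 1.25)])
}

count_hbonds_directed <- function(s, don_sel, acc_sel, crit, use_h) {
  a <- s$atoms
  id <- polar_rows(s, don_sel, crit$donor_elements)
  ic <- polar_rows(s, acc_sel, crit$acceptor_elements)
  if (length(id) == 0 || length(ic) == 0) return(character(0))
  xyz <- coords(s)
  res_d <- paste(a$chain[id], a$resseq[id], a$icode[id])
  res_c <- paste(a$chain[ic], a$resseq[ic], a$icode[ic])
  pairs <- character(0)
  if (use_h) {
    hyds <- bonded_hydrogens(s, id)
    keep_d <- lengths(hyds) > 0          # donors must carry a hydrogen
    for (i in which(keep_d)) {
      for (h in hyds[[i]]) {
        dh <- xyz[h, ]
        dv <- sqrt(colSums((t(xyz[ic, , drop = FALSE]) - dh)^2))
        cand <- which(dv <= crit$h_dist_cutoff & res_c != res_d[i])
        for (j in cand) {
          ang <- point_angle(xyz[id[i], ], dh, xyz[ic[j], ])
          if (ang >= crit$h_angle_min) {
            pairs <- c(pairs, paste(atom_label(a, id[i]),
                                    atom_label(a, ic[j]), sep = " -> "))
          }
        }
      }
    }
  } else {
    D <- cross_distances(xyz[id, , drop = FALSE], xyz[ic, , drop = FALSE])
    hit <- which(D <= crit$heavy_cutoff, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      hit <- hit[res_d[hit[, 1]] != res_c[hit[, 2]], , drop = FALSE]
    }
    if (nrow(hit) > 0) {
      pairs <- paste(vapply(id[hit[, 1]], function(i) atom_label(a, i), character(1)),
                     vapply(ic[hit[, 2]], function(i) atom_label(a, i), character(1)),
                     sep = " -> ")
    }
  }
  unique(pairs)
}

#' Count hydrogen bonds between two groups
#'
#' Counts distinct donor-acceptor pairs satisfying the criterion, with
#' donors taken from either group (each pair counted once). When the
#' structure contains hydrogens the hydrogen-aware criterion is applied;
#' otherwise the heavy-atom distance criterion is the fallback, so the
#' same call works on crystal structures and simulation frames.
#'
#' @param frame a `pump_structure`
#' @param groupA,groupB `pump_selection` objects
#' @param crit a `contact_criterion`
#' @return integer count
#' @export
count_hbonds <- function(frame, groupA, groupB, crit = contact_criterion()) {
  use_h <- has_hydrogens(frame)
  ab <- count_hbonds_directed(frame, groupA, groupB, crit, use_h)
  ba <- count_hbonds_directed(frame, groupB, groupA, crit, use_h)
  # a pair is one bond regardless of which group donates; merge unordered
  unordered <- unique(c(ab, vapply(strsplit(ba, " -> ", fixed = TRUE),
                                   function(p) paste(p[2], p[1], sep = " -> "),
                                   character(1))))
  length(unordered)
}
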