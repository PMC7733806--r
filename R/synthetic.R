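#' @title Synthetic fixtures with known ground truth
#' @name synthetic_data
#' @description
#' Every fixture class the analysis pipeline needs, generated in code
#' with a seed and accompanied by a machine-readable ground-truth
#' record: rigid-body structure pairs with known expected RMSD, hinged
#' structures with prescribed triplet angles, one-way switch traces,
#' bimodal distance traces, two-phase fluorescence transients with an
#' exactly known half-time, hydrogen-bond toy systems with an exact
#' count, and a full synthetic stand-in pair of pump structures whose
#' comparison observables are built in by construction. Synthetic
#' structures are idealized poly-alanine-style chains; only the atoms a
#' tested observable needs are guaranteed chemically meaningful.
NULL

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize zero vector")
  v / n
}

#' Rotation matrix about an axis
#' @param axis length-3 axis vector (normalized internally)
#' @param deg rotation angle in degrees
#' @return 3 x 3 proper rotation matrix (row-vector convention,
#'   `x %*% R`)
#' @export
rotation_about_axis <- function(axis, deg) {
  a <- unit_vec(as.numeric(axis))
  th <- deg * pi / 180
  K <- matrix(c(0, -a[3], a[2],
                a[3], 0, -a[1],
                -a[2], a[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  t(R)   # transpose: column convention -> row convention
}

.atoms_df <- function(name, resname, resseq, xyz, chain = "A",
                      element = NULL, het = FALSE, serial_start = 1L) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  if (is.null(element)) {
    element <- infer_element(name, resname)
  }
  data.frame(serial = seq.int(serial_start, length.out = n),
             name = rep_len(name, n), altloc = "",
             resname = rep_len(resname, n), chain = rep_len(chain, n),
             resseq = rep_len(resseq, n), icode = "",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy = 1, element = rep_len(element, n),
             het = rep_len(het, n), stringsAsFactors = FALSE)
}

#' Rigid-body structure pair with known expected fit RMSD
#'
#' The second structure is the first rotated about an axis, translated,
#' and perturbed with isotropic Gaussian noise. The ground truth records
#' the applied transform and the expected post-fit RMSD
#' `noise_sd * sqrt(3 - 6/n)` (the rigid fit removes six degrees of
#' freedom from the 3n noise coordinates).
#'
#' @param n_atoms number of points (>= 3)
#' @param rotation_deg,axis,translation applied rigid motion
#' @param noise_sd isotropic Gaussian noise, Angstrom
#' @param seed RNG seed
#' @return list with `a`, `b` (`pump_structure`s of one CA pseudo-atom
#'   per residue) and `truth` (rotation_deg, axis, translation,
#'   noise_sd, expected_rmsd, seed)
#' @export
make_rigid_pair <- function(n_atoms, rotation_deg = 0, axis = c(0, 0, 1),
                            translation = c(0, 0, 0), noise_sd = 0,
                            seed = 1) {
  if (n_atoms < 3) stop("need at least 3 atoms")
  set.seed(seed)
  base <- matrix(stats::runif(3 * n_atoms, -20, 20), ncol = 3)
  R <- rotation_about_axis(axis, rotation_deg)
  moved <- base %*% R + rep(1, n_atoms) %o% as.numeric(translation)
  if (noise_sd > 0) {
    moved <- moved + matrix(stats::rnorm(3 * n_atoms, sd = noise_sd), ncol = 3)
  }
  a <- new_structure(.atoms_df("CA", "ALA", seq_len(n_atoms), base),
                     source_id = "rigid_a")
  b <- new_structure(.atoms_df("CA", "ALA", seq_len(n_atoms), moved),
                     source_id = "rigid_b")
  list(a = a, b = b,
       truth = list(rotation_deg = rotation_deg, axis = axis,
                    translation = translation, noise_sd = noise_sd,
                    expected_rmsd = noise_sd * sqrt(3 - 6 / n_atoms),
                    seed = seed))
}

#' Hinged two-segment structure with a prescribed triplet angle
#'
#' Builds a 20-residue CA trace of two straight arms meeting at residue
#' 10; the angle measured at residue 10 between residues 5 and 15 equals
#' `hinge_angle_deg` exactly. The whole structure is placed in a random
#' (seeded) orientation so nothing is axis-aligned.
#'
#' @param hinge_angle_deg angle in (0, 180)
#' @param seed RNG seed
#' @return list with `s` (`pump_structure`) and `truth` (r1, r2, r3,
#'   atom, angle_deg, seed)
#' @export
make_hinged_structure <- function(hinge_angle_deg, seed = 1) {
  if (hinge_angle_deg <= 0 || hinge_angle_deg >= 180) {
    stop("hinge angle must be in (0, 180)")
  }
  set.seed(seed)
  th <- hinge_angle_deg * pi / 180
  u1 <- c(1, 0, 0)
  u2 <- c(cos(th), sin(th), 0)
  # arm 1: residues 1..10 approach the vertex; arm 2: residues 10..20
  xyz <- matrix(0, 20, 3)
  for (i in 1:9) xyz[i, ] <- (10 - i) * 2 * u1
  xyz[10, ] <- c(0, 0, 0)
  for (i in 11:20) xyz[i, ] <- (i - 10) * 2 * u2
  rot <- rotation_about_axis(stats::rnorm(3), stats::runif(1, 0, 360))
  xyz <- xyz %*% rot + rep(1, 20) %o% stats::runif(3, -10, 10)
  s <- new_structure(.atoms_df("CA", "ALA", 1:20, xyz),
                     source_id = "hinged")
  list(s = s, truth = list(r1 = 5, r2 = 10, r3 = 15, atom = "CA",
                           angle_deg = hinge_angle_deg, seed = seed))
}

#' One-way two-state switch trace
#'
#' Frames before `switch_frame` sit at `low_level`, frames from
#' `switch_frame` on at `high_level`, plus Gaussian noise - the
#' statistical shape of a side chain swinging out once and staying out.
#' `switch_frame > n_frames` generates a trace with no switch. Levels
#' inside the classifier's hysteresis band are refused (undetectable by
#' design).
#'
#' @param n_frames trace length
#' @param switch_frame first high frame (use `n_frames + 1` for none)
#' @param low_level,high_level levels in Angstrom (defaults 7 and 13,
#'   the in/out levels of the arginine-swing analysis)
#' @param noise_sd Gaussian noise
#' @param seed RNG seed
#' @param low_thr,high_thr classifier thresholds the levels must clear
#' @return list with `ts` (`pump_timeseries`) and `truth`
#' @export
make_switch_trace <- function(n_frames, switch_frame, low_level = 7,
                              high_level = 13, noise_sd = 0.3, seed = 1,
                              low_thr = 10, high_thr = 12) {
  if (switch_frame <= 0) stop("switch_frame must be positive")
  in_band <- function(x) x > low_thr & x < high_thr
  if (in_band(low_level) || in_band(high_level)) {
    stop("levels inside the hysteresis band (", low_thr, ", ", high_thr,
         ") are undetectable by design")
  }
  set.seed(seed)
  levels <- ifelse(seq_len(n_frames) >= switch_frame, high_level, low_level)
  vals <- levels + stats::rnorm(n_frames, sd = noise_sd)
  ts <- time_series(seq_len(n_frames) - 1, vals, unit = "A",
                    label = "switch trace")
  list(ts = ts,
       truth = list(switch_frame = if (switch_frame <= n_frames)
         switch_frame else NA_integer_,
         low_level = low_level, high_level = high_level,
         noise_sd = noise_sd, tol_frames = 2, seed = seed))
}

#' Gaussian-mixture distance trace
#'
#' Samples from a mixture of normals, emulating uni- or bimodal
#' distance distributions. The truth records component means and a mode
#' tolerance; a warning flag is recorded when adjacent means are closer
#' than one standard deviation (overlapping, possibly unresolvable
#' modes).
#'
#' @param means,sds,weights component parameters (weights sum to 1)
#' @param n sample size
#' @param seed RNG seed
#' @return list with `ts` and `truth`
#' @export
make_bimodal_trace <- function(means, sds, weights, n, seed = 1) {
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (length(means) != length(sds) || length(means) != length(weights)) {
    stop("means, sds, weights must have equal length")
  }
  set.seed(seed)
  comp <- sample.int(length(means), n, replace = TRUE, prob = weights)
  vals <- stats::rnorm(n, mean = means[comp], sd = sds[comp])
  overlap <- FALSE
  if (length(means) > 1) {
    m <- sort(means)
    overlap <- any(diff(m) < max(sds))
  }
  ts <- time_series(seq_len(n) - 1, vals, unit = "A", label = "mixture trace")
  list(ts = ts,
       truth = list(means = means, sds = sds, weights = weights, n = n,
                    mode_tol = pmax(0.1, max(sds) / sqrt(n / 100)),
                    overlap_warning = overlap, seed = seed))
}

#' Two-phase fluorescence transient with exactly known half-time
#'
#' Samples the two-phase association law on a regular grid (default
#' integration time 2 s) and adds Gaussian noise. The truth half-time is
#' computed by bisection on the noiseless generating model.
#'
#' @param F0,A1,k1,A2,k2 model parameters
#' @param noise_sd Gaussian noise on the intensity
#' @param dt sampling interval, s
#' @param duration trace length, s
#' @param seed RNG seed
#' @return list with `data` (data.frame time_s, intensity) and `truth`
#'   (parameters plus exact `t_half`)
#' @export
make_fluorescence_trace <- function(F0 = 1, A1 = 0.5, k1 = 1, A2 = 0.5,
                                    k2 = 0.1, noise_sd = 0, dt = 2,
                                    duration = 120, seed = 1) {
  set.seed(seed)
  t <- seq(0, duration, by = dt)
  f <- two_phase_model(t, F0, A1, k1, A2, k2)
  if (noise_sd > 0) f <- f + stats::rnorm(length(t), sd = noise_sd)
  list(data = data.frame(time_s = t, intensity = f),
       truth = list(F0 = F0, A1 = A1, k1 = k1, A2 = A2, k2 = k2,
                    noise_sd = noise_sd, dt = dt,
                    t_half = two_phase_half_time(F0, A1, k1, A2, k2),
                    seed = seed))
}

#' Rate constants of a two-phase law with a prescribed half-time
#'
#' Keeps the amplitude split and the rate ratio fixed and solves (by
#' bisection on the noiseless model) for the slow rate constant such
#' that the half-time equals `t_half`.
#'
#' @param t_half target half-time, s
#' @param rate_ratio k1/k2 (default 10)
#' @param A1,A2 amplitudes (shape only; scale drops out)
#' @return list with `k1`, `k2`
#' @export
rates_for_half_time <- function(t_half, rate_ratio = 10, A1 = 0.5, A2 = 0.5) {
  stopifnot(t_half > 0, rate_ratio >= 1)
  f <- function(k2) {
    two_phase_half_time(0, A1, rate_ratio * k2, A2, k2) - t_half
  }
  k2 <- stats::uniroot(f, c(1e-6, 1e3), tol = 1e-14)$root
  list(k1 = rate_ratio * k2, k2 = k2)
}

#' Hydrogen-bond toy structure with an exact known count
#'
#' Places `n_pairs_in` donor/acceptor pairs within hydrogen-bonding
#' distance (2.7-3.4 Angstrom) and `n_pairs_out` pairs beyond the
#' criterion (4-8 Angstrom), on a widely spaced grid so no accidental
#' contacts arise. Group A holds the oxygens (residues 1-99), group B
#' the nitrogens (residues 101-199).
#'
#' @param n_pairs_in,n_pairs_out pair counts (>= 0)
#' @param seed RNG seed
#' @return list with `s`, `groupA`, `groupB`, `truth` (count)
#' @export
make_hbond_toy <- function(n_pairs_in, n_pairs_out, seed = 1) {
  stopifnot(n_pairs_in >= 0, n_pairs_out >= 0,
            n_pairs_in + n_pairs_out >= 1, n_pairs_in + n_pairs_out <= 99)
  set.seed(seed)
  n <- n_pairs_in + n_pairs_out
  d <- c(stats::runif(n_pairs_in, 2.7, 3.4), stats::runif(n_pairs_out, 4, 8))
  rows <- list()
  for (i in seq_len(n)) {
    p <- c(25 * i, 0, 0)
    rows[[2 * i - 1]] <- .atoms_df("O", "SER", i, p, element = "O",
                                   serial_start = 2L * i - 1L)
    rows[[2 * i]] <- .atoms_df("N", "GLY", 100L + i, p + c(d[i], 0, 0),
                               element = "N", serial_start = 2L * i)
  }
  s <- new_structure(do.call(rbind, rows), source_id = "hbond_toy")
  list(s = s,
       groupA = atom_selection(ranges = list(c(1, 99))),
       groupB = atom_selection(ranges = list(c(101, 199))),
       truth = list(count = n_pairs_in, n_pairs_out = n_pairs_out,
                    seed = seed))
}

#' Synthetic phosphoryl-transfer site
#'
#' A minimal catalytic-site fixture: an aspartate carboxylate and
#' either a transition-state mimic (ADP plus AlF4, bridging atom O3B)
#' or a non-hydrolyzable nucleotide (AMPPCP, residue ACP, bridging atom
#' C3B), constructed so the analog-centre/carboxyl-oxygen distance and
#' the in-line attack angle equal the prescribed values exactly. The
#' site is placed in a random seeded orientation.
#'
#' @param d_OdPg prescribed distance, Angstrom
#' @param theta prescribed attack angle, degrees
#' @param ligand "ADP_ALF" or "ACP"
#' @param seed RNG seed
#' @return list with `s` and `truth`
#' @export
synthetic_phosphoryl_site <- function(d_OdPg = 2.1, theta = 159,
                                      ligand = c("ADP_ALF", "ACP"),
                                      seed = 1) {
  ligand <- match.arg(ligand)
  stopifnot(d_OdPg > 0, theta >= 0, theta <= 180)
  set.seed(seed)
  th <- theta * pi / 180
  ctr <- c(0, 0, 0)
  br <- c(1.9, 0, 0)                      # bridging atom direction
  od1 <- d_OdPg * c(cos(th), sin(th), 0)  # angle at the centre = theta
  od2 <- (d_OdPg + 1.6) * c(cos(th), sin(th), 0) + c(0, 0, 1)  # farther out
  ca351 <- od1 + c(0, 3, 2)
  rows <- list(.atoms_df("CA", "ASP", 351, ca351, serial_start = 1L),
               .atoms_df("OD1", "ASP", 351, od1, serial_start = 2L),
               .atoms_df("OD2", "ASP", 351, od2, serial_start = 3L))
  if (ligand == "ADP_ALF") {
    rows <- c(rows, list(
      .atoms_df("AL", "ALF", 996, ctr, element = "AL", het = TRUE,
                serial_start = 4L),
      .atoms_df("F1", "ALF", 996, c(0, 0, 1.7), element = "F", het = TRUE,
                serial_start = 5L),
      .atoms_df("O3B", "ADP", 995, br, element = "O", het = TRUE,
                serial_start = 6L),
      .atoms_df("PB", "ADP", 995, br + c(1.6, 0, 0), element = "P",
                het = TRUE, serial_start = 7L)))
  } else {
    rows <- c(rows, list(
      .atoms_df("PG", "ACP", 995, ctr, element = "P", het = TRUE,
                serial_start = 4L),
      .atoms_df("C3B", "ACP", 995, br, element = "C", het = TRUE,
                serial_start = 5L),
      .atoms_df("PB", "ACP", 995, br + c(1.6, 0, 0), element = "P",
                het = TRUE, serial_start = 6L)))
  }
  at <- do.call(rbind, rows)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rot <- rotation_about_axis(stats::rnorm(3), stats::runif(1, 0, 360))
  xyz <- xyz %*% rot + rep(1, nrow(at)) %o% stats::runif(3, -5, 5)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  s <- new_structure(at, source_id = paste0("synthetic_site_", tolower(ligand)))
  list(s = s, truth = list(d_OdPg = d_OdPg, theta = theta, ligand = ligand,
                           seed = seed))
}

# ---------------------------------------------------------------------------
# Full synthetic stand-in pair of pump structures
# ---------------------------------------------------------------------------

# remove the best-fit rigid field (translation + infinitesimal rotation)
# from a displacement field D defined on points X, so that a least-squares
# superposition of X + D onto X is the identity to first order
project_rigid_out <- function(X, D) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  # basis of rigid displacement fields: 3 translations, 3 rotations
  A <- matrix(0, 3 * n, 6)
  A[seq(1, 3 * n, 3), 1] <- 1
  A[seq(2, 3 * n, 3), 2] <- 1
  A[seq(3, 3 * n, 3), 3] <- 1
  # omega x x = (w2 z - w3 y, w3 x - w1 z, w1 y - w2 x)
  A[seq(1, 3 * n, 3), 5] <- Xc[, 3]
  A[seq(1, 3 * n, 3), 6] <- -Xc[, 2]
  A[seq(2, 3 * n, 3), 4] <- -Xc[, 3]
  A[seq(2, 3 * n, 3), 6] <- Xc[, 1]
  A[seq(3, 3 * n, 3), 4] <- Xc[, 2]
  A[seq(3, 3 * n, 3), 5] <- -Xc[, 1]
  dvec <- as.numeric(t(D))
  coef <- stats::lm.fit(A, dvec)$coefficients
  coef[is.na(coef)] <- 0
  matrix(dvec - A %*% coef, ncol = 3, byrow = TRUE)
}

scale_to_rms <- function(D, rms) {
  cur <- sqrt(mean(rowSums(D^2)))
  if (cur < 1e-12) return(D)
  D * (rms / cur)
}

# project point p onto the cone of directions at angle `ang_deg` from the
# axis (vertex -> axis_point), preserving |p - vertex|
cone_project <- function(p, vertex, axis_point, ang_deg) {
  e1 <- unit_vec(axis_point - vertex)
  w <- p - vertex
  L <- sqrt(sum(w^2))
  wpar <- sum(w * e1)
  wperp <- w - wpar * e1
  e2 <- if (sqrt(sum(wperp^2)) > 1e-9) unit_vec(wperp) else {
    ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    unit_vec(ref - sum(ref * e1) * e1)
  }
  th <- ang_deg * pi / 180
  vertex + L * (cos(th) * e1 + sin(th) * e2)
}

# resolved residue layout of the synthetic pump chain: contiguous runs
# placed on a lattice, residues 1..994, straight CA traces with fixed
# local backbone offsets (N, C, O relative to CA)
.pump_layout <- function() {
  runs <- list(
    c(1, 43), c(44, 48), c(49, 73), c(74, 88), c(89, 123), c(124, 235),
    c(236, 253), c(254, 273), c(274, 290), c(291, 313), c(314, 329),
    c(330, 359), c(360, 600), c(601, 739), c(740, 749), c(750, 994))
  n_res <- 994
  ca <- matrix(0, n_res, 3)
  for (k in seq_along(runs)) {
    r <- runs[[k]]
    gx <- ((k - 1) %% 4) * 16
    gy <- ((k - 1) %/% 4) * 16
    dir <- if (k %% 2 == 0) -1 else 1
    idx <- r[1]:r[2]
    ca[idx, 1] <- gx
    ca[idx, 2] <- gy
    ca[idx, 3] <- dir * 1.5 * (idx - r[1])
  }
  ca
}

.offsets <- list(N = c(-0.5, 0.9, 0), C = c(0.6, 0.8, 0),
                 O = c(0.6, 1.9, 0.3))

.pump_resnames <- function() {
  rn <- rep("ALA", 994)
  named <- c("13" = "LEU", "50" = "TRP", "63" = "ARG", "74" = "VAL",
             "86" = "THR", "98" = "LEU", "134" = "ARG", "139" = "ARG",
             "156" = "GLY", "169" = "LYS", "171" = "THR", "213" = "ASN",
             "218" = "LYS", "247" = "THR", "248" = "PRO", "249" = "LEU",
             "312" = "PRO", "337" = "PRO", "341" = "THR", "344" = "CYS",
             "351" = "ASP", "422" = "ASP", "426" = "ASP", "427" = "PHE",
             "435" = "GLU", "484" = "THR", "486" = "GLU", "578" = "LEU",
             "725" = "ALA", "726" = "VAL", "729" = "THR", "809" = "PHE",
             "822" = "ARG", "824" = "PRO", "830" = "SER")
  rn[as.integer(names(named))] <- named
  rn
}

# indices (into 1..994) of main-chain atoms per atom name are implicit:
# the chain table is built residue-major with atoms N, CA, C, O
.mainchain_table <- function(ca, resnames) {
  n_res <- nrow(ca)
  names4 <- c("N", "CA", "C", "O")
  xyz <- matrix(0, 4 * n_res, 3)
  for (j in 1:4) {
    off <- if (names4[j] == "CA") c(0, 0, 0) else .offsets[[names4[j]]]
    xyz[seq(j, 4 * n_res, 4), ] <- sweep(ca, 2, -off)
  }
  data.frame(serial = seq_len(4 * n_res),
             name = rep(names4, n_res),
             altloc = "",
             resname = rep(resnames, each = 4),
             chain = "A",
             resseq = rep(seq_len(n_res), each = 4),
             icode = "",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy = 1,
             element = rep(c("N", "C", "C", "O"), n_res),
             het = FALSE, stringsAsFactors = FALSE)
}

.row_of <- function(resseq, atom) 4L * (resseq - 1L) + match(atom, c("N", "CA", "C", "O"))

# segment atom-row helper over the 4-atoms-per-residue main-chain table
.seg_rows <- function(ranges) {
  unlist(lapply(ranges, function(r) {
    res <- r[1]:r[2]
    as.vector(outer(1:4, 4 * (res - 1), "+"))
  }))
}

.fit_rmsd_rows <- function(wt_xyz, mut_xyz, fit_rows, rep_rows = fit_rows) {
  tr <- kabsch_superpose(mut_xyz[fit_rows, , drop = FALSE],
                         wt_xyz[fit_rows, , drop = FALSE])
  moved <- apply_transform(mut_xyz[rep_rows, , drop = FALSE], tr)
  sqrt(mean(rowSums((moved - wt_xyz[rep_rows, , drop = FALSE])^2)))
}

#' Synthetic stand-in pair of wild-type and mutant pump structures
#'
#' Constructs two full-length (residues 1-994) synthetic structures of a
#' Ca2+-ATPase-like chain that stand in for a wild-type/mutant crystal
#' structure pair. The pair is built so that, by construction, the
#' package's comparison battery recovers prescribed values: the RMSD of
#' the fit segment M5-M10 and of M1-M4 in that fitted frame, the global
#' main-chain RMSD, the headpiece-tilt triplet angle (residues
#' 13/86/98), the M1 kink triplet angle (residues 50/63/74), the
#' Pro337-Pro312 and residue340-Leu249 CA distances, interdomain polar
#' contacts with known kept/lost status between the wild type and the
#' mutant (including a water-mediated link from residue 340 to Arg822
#' present only in the wild type), and a catalytic-site geometry per
#' structure. Displacement noise amplitudes and rigid domain motions are
#' calibrated numerically against the package's own superposition so
#' the RMSD targets hold to ~0.01 Angstrom; angle and distance markers
#' are exact.
#'
#' These are labelled synthetic stand-ins: they emulate the measured
#' quantities of a real structure pair, not protein geometry.
#'
#' @param seed RNG seed
#' @param targets named list overriding the built-in target values
#'   (rmsd_m5m10, rmsd_m1m4, rmsd_global, rmsd_domain_p/n/a, rmsd_np,
#'   rmsd_headpiece, angle_head_wt/mut, angle_kink_wt/mut,
#'   d_p337_p312_wt/mut, d_340_249_wt/mut)
#' @return list with `wt`, `mut` (`pump_structure`s) and `truth`
#' @export
synthetic_pump_pair <- function(seed = 1, targets = list()) {
  tg <- utils::modifyList(list(
    rmsd_m5m10 = 0.49, rmsd_m1m4 = 0.56, rmsd_global = 2.3,
    rmsd_domain_p = 0.37, rmsd_domain_n = 0.37, rmsd_domain_a = 0.32,
    rmsd_np = 0.47, rmsd_headpiece = 1.16,
    angle_head_wt = 152, angle_head_mut = 147,
    angle_kink_wt = 109, angle_kink_mut = 105,
    d_p337_p312_wt = 15.6, d_p337_p312_mut = 12.3,
    d_340_249_wt = 8.0, d_340_249_mut = 6.9,
    linker_rms = 0.8), targets)

  set.seed(seed)
  ca <- .pump_layout()
  # wild-type marker geometry: exact triplet angles and distances
  ca[13, ] <- cone_project(ca[13, ], ca[86, ], ca[98, ], tg$angle_head_wt)
  ca[50, ] <- cone_project(ca[50, ], ca[63, ], ca[74, ], tg$angle_kink_wt)
  ca[337, ] <- ca[312, ] + tg$d_p337_p312_wt * unit_vec(ca[337, ] - ca[312, ])
  ca[340, ] <- ca[249, ] + tg$d_340_249_wt * unit_vec(ca[340, ] - ca[249, ])

  resn_wt <- .pump_resnames(); resn_wt[340] <- "GLU"
  resn_mut <- .pump_resnames(); resn_mut[340] <- "ALA"
  wt_at <- .mainchain_table(ca, resn_wt)
  wt_xyz <- as.matrix(wt_at[, c("x", "y", "z")])

  # rigid/noise groups; residue 124 (shared boundary of M2 and the A
  # domain in the registry) is assigned to M1M4 only so the fitted-frame
  # target is not disturbed by the A-domain rigid motion
  seg <- list(M5M10 = list(c(750, 994)),
              M1M4 = list(c(49, 73), c(89, 124), c(247, 273), c(291, 313)),
              P = list(c(330, 359), c(601, 739)),
              N = list(c(360, 600)),
              A = list(c(1, 43), c(125, 235)),
              LINK = list(c(44, 48), c(74, 88), c(236, 246), c(274, 290),
                          c(314, 329), c(740, 749)))
  rows <- lapply(seg, .seg_rows)
  rows$HEAD <- c(rows$A, rows$N, rows$P)
  rows$NP <- c(rows$N, rows$P)
  rows$ALL <- seq_len(nrow(wt_xyz))
  # marker atoms excluded from the noise fields (positions set deliberately);
  # the carbonyls flanking the Thr171 contact anchor are also kept
  # noise-free so the planted Glu486 partner clears them deterministically
  marker_rows <- c(.row_of(13, "CA"), .row_of(50, "CA"),
                   .row_of(337, "CA"), .row_of(340, "CA"),
                   .row_of(170, "O"), .row_of(171, "O"), .row_of(172, "O"))

  # unit-RMS noise fields, rigid-projected so each group's own fit stays
  # at identity to first order
  field <- function(rws, project = TRUE) {
    rws <- setdiff(rws, marker_rows)
    D <- matrix(stats::rnorm(3 * length(rws)), ncol = 3)
    if (project) D <- project_rigid_out(wt_xyz[rws, , drop = FALSE], D)
    list(rows = rws, D = scale_to_rms(D, 1))
  }
  f_m5 <- field(rows$M5M10)
  f_m1m4 <- field(rows$M1M4, project = FALSE)
  f_p <- field(rows$P)
  f_n <- field(rows$N)
  f_a <- field(rows$A)
  f_link <- field(rows$LINK, project = FALSE)

  # rigid motion axes: headpiece tilts about a pivot at residue 340 in the
  # plane of the headpiece-angle triplet (so the tilt directly closes the
  # hinge angle, as in the conformational change being emulated)
  pivot <- ca[340, ]
  axis_h <- unit_vec(pracma_cross(ca[13, ] - ca[86, ], ca[98, ] - ca[86, ]))
  # sign: rotating Leu13 toward the Leu98 arm must DECREASE the angle
  test_rot <- rotation_about_axis(axis_h, 5)
  p13 <- (ca[13, ] - pivot) %*% test_rot + pivot
  if (point_angle(as.numeric(p13), ca[86, ], ca[98, ]) > tg$angle_head_wt) {
    axis_h <- -axis_h
  }
  centroid_a <- colMeans(wt_xyz[rows$A, ])
  centroid_n <- colMeans(wt_xyz[rows$N, ])
  set.seed(seed + 1)
  axis_a <- unit_vec(stats::rnorm(3))
  axis_n <- unit_vec(stats::rnorm(3))

  build <- function(p) {
    xyz <- wt_xyz
    add <- function(f, s) {
      xyz[f$rows, ] <<- xyz[f$rows, ] + s * f$D
    }
    add(f_m5, p$s_m5); add(f_m1m4, p$s_m1m4); add(f_p, p$s_p)
    add(f_n, p$s_n); add(f_a, p$s_a); add(f_link, tg$linker_rms)
    rot_about <- function(rws, axis, deg, centre) {
      R <- rotation_about_axis(axis, deg)
      xyz[rws, ] <<- sweep(sweep(xyz[rws, , drop = FALSE], 2, centre) %*% R,
                           2, -centre)
    }
    rot_about(rows$N, axis_n, p$th_np, centroid_n)
    rot_about(rows$A, axis_a, p$th_a, centroid_a)
    rot_about(rows$HEAD, axis_h, p$th_h, pivot)
    # deliberate markers, placed on the final frame of their partners
    xyz[.row_of(13, "CA"), ] <- cone_project(
      xyz[.row_of(13, "CA"), ], xyz[.row_of(86, "CA"), ],
      xyz[.row_of(98, "CA"), ], tg$angle_head_mut)
    xyz[.row_of(50, "CA"), ] <- cone_project(
      xyz[.row_of(50, "CA"), ], xyz[.row_of(63, "CA"), ],
      xyz[.row_of(74, "CA"), ], tg$angle_kink_mut)
    p312 <- xyz[.row_of(312, "CA"), ]
    xyz[.row_of(337, "CA"), ] <- p312 +
      tg$d_p337_p312_mut * unit_vec(xyz[.row_of(337, "CA"), ] - p312)
    p249 <- xyz[.row_of(249, "CA"), ]
    xyz[.row_of(340, "CA"), ] <- p249 +
      tg$d_340_249_mut * unit_vec(xyz[.row_of(340, "CA"), ] - p249)
    xyz
  }

  # --- calibration (deterministic; no RNG consumed) ----------------------
  p <- list(s_m5 = tg$rmsd_m5m10, s_m1m4 = tg$rmsd_m1m4, s_p = tg$rmsd_domain_p,
            s_n = tg$rmsd_domain_n, s_a = tg$rmsd_domain_a,
            th_np = 0, th_a = 0, th_h = 0)
  # fit-segment and fitted-frame RMSDs: fixed-point refinement
  for (it in 1:4) {
    m <- .fit_rmsd_rows(wt_xyz, build(p), rows$M5M10)
    p$s_m5 <- p$s_m5 * tg$rmsd_m5m10 / m
  }
  for (it in 1:4) {
    m <- .fit_rmsd_rows(wt_xyz, build(p), rows$M5M10, rows$M1M4)
    p$s_m1m4 <- p$s_m1m4 * tg$rmsd_m1m4 / m
  }
  for (nm in c("p", "n", "a")) {
    key <- paste0("s_", nm)
    rws <- rows[[toupper(nm)]]
    target <- tg[[paste0("rmsd_domain_", nm)]]
    for (it in 1:4) {
      m <- .fit_rmsd_rows(wt_xyz, build(p), rws)
      p[[key]] <- p[[key]] * target / m
    }
  }
  cal_angle <- function(key, rws, target, upper) {
    f <- function(th) {
      p[[key]] <- th
      .fit_rmsd_rows(wt_xyz, build(p), rws) - target
    }
    if (f(0) >= 0) return(0)   # already at/above target without rotation
    stats::uniroot(f, c(0, upper), tol = 1e-6)$root
  }
  p$th_np <- cal_angle("th_np", rows$NP, tg$rmsd_np, 20)
  p$th_a <- cal_angle("th_a", rows$HEAD, tg$rmsd_headpiece, 30)
  p$th_h <- cal_angle("th_h", rows$ALL, tg$rmsd_global, 40)

  mut_xyz <- build(p)
  measured <- list(
    rmsd_m5m10 = .fit_rmsd_rows(wt_xyz, mut_xyz, rows$M5M10),
    rmsd_m1m4 = .fit_rmsd_rows(wt_xyz, mut_xyz, rows$M5M10, rows$M1M4),
    rmsd_global = .fit_rmsd_rows(wt_xyz, mut_xyz, rows$ALL),
    rmsd_headpiece = .fit_rmsd_rows(wt_xyz, mut_xyz, rows$HEAD),
    rmsd_np = .fit_rmsd_rows(wt_xyz, mut_xyz, rows$NP),
    rmsd_na = .fit_rmsd_rows(wt_xyz, mut_xyz, c(rows$N, rows$A)),
    rmsd_domain_p = .fit_rmsd_rows(wt_xyz, mut_xyz, rows$P),
    rmsd_domain_n = .fit_rmsd_rows(wt_xyz, mut_xyz, rows$N),
    rmsd_domain_a = .fit_rmsd_rows(wt_xyz, mut_xyz, rows$A))

  mut_at <- .mainchain_table(ca, resn_mut)
  mut_at[, c("x", "y", "z")] <- mut_xyz

  # --- planted side-chain atoms, waters and nucleotide site --------------
  plants <- .plant_extras(wt_at, mut_at)
  wt <- new_structure(rbind(wt_at, plants$wt), source_id = "synthetic_wt")
  mut <- new_structure(rbind(mut_at, plants$mut), source_id = "synthetic_mut")

  truth <- c(tg[grep("^(rmsd|angle|d_)", names(tg))],
             list(measured = measured, contacts = plants$truth,
                  seed = seed, calibration = p))
  list(wt = wt, mut = mut, truth = truth)
}

# cross product (avoid pulling in a package for one primitive)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# planted polar side-chain atoms, the bridging water, and the nucleotide
# site for the synthetic stand-in pair; positions are explicit per
# structure so contact presence/absence is exact by construction
.plant_extras <- function(wt_at, mut_at) {
  get_pos <- function(at, resseq, name) {
    i <- which(at$resseq == resseq & at$name == name)
    c(at$x[i[1]], at$y[i[1]], at$z[i[1]])
  }
  serial0 <- nrow(wt_at)
  mk <- function(name, resname, resseq, pos, element = NULL, het = FALSE) {
    .atoms_df(name, resname, resseq, pos, element = element, het = het)
  }
  KEEP <- 2.9     # contact leg, within criterion
  KEEP_BB <- 3.3  # leg anchored on a backbone atom: within the 3.5
                  # criterion but > 3.5 from that column's z-neighbours
  LOST <- 6.0     # beyond criterion

  build_side <- function(at, mutant) {
    rows <- list()
    off <- function(kept, keep_d = KEEP) if (kept) keep_d else LOST
    # --- N-to-A interdomain contact set (kept/lost in the mutant) ---
    o427 <- get_pos(at, 427, "O")
    rows$nh1_134 <- mk("NH1", "ARG", 134, o427 + c(0, off(!mutant, KEEP_BB), 0))
    od1_426 <- get_pos(at, 426, "CA") + c(0, -3, 0)
    od2_426 <- od1_426 + c(2.2, 0, 0)
    rows$od1_426 <- mk("OD1", "ASP", 426, od1_426)
    rows$od2_426 <- mk("OD2", "ASP", 426, od2_426)
    rows$nh2_134 <- mk("NH2", "ARG", 134, od1_426 + c(0, -KEEP, 0))  # kept
    rows$nh1_139 <- mk("NH1", "ARG", 139, od2_426 + c(off(!mutant), 0, 0))
    oe1_435 <- get_pos(at, 435, "CA") + c(0, -3, 0)
    rows$oe1_435 <- mk("OE1", "GLU", 435, oe1_435)
    rows$nh2_139 <- mk("NH2", "ARG", 139, oe1_435 + c(0, -off(!mutant), 0))
    og1_484 <- get_pos(at, 484, "CA") + c(0, -3, 0)
    rows$og1_484 <- mk("OG1", "THR", 484, og1_484)
    rows$nz_169 <- mk("NZ", "LYS", 169, og1_484 + c(0, -off(!mutant), 0))
    o578 <- get_pos(at, 578, "O")
    rows$og1_171 <- mk("OG1", "THR", 171, o578 + c(0, off(!mutant, KEEP_BB), 0))
    od1_422 <- get_pos(at, 422, "CA") + c(0, -3, 0)
    rows$od1_422 <- mk("OD1", "ASP", 422, od1_422)
    rows$nz_218 <- mk("NZ", "LYS", 218, od1_422 + c(0, -off(!mutant), 0))
    o171 <- get_pos(at, 171, "O")
    rows$oe1_486 <- mk("OE1", "GLU", 486, o171 + c(0, KEEP_BB, 0))  # kept
    # --- A-to-P contact, intact in both structures ---
    nd2_213 <- get_pos(at, 213, "CA") + c(0, -3, 0)
    rows$nd2_213 <- mk("ND2", "ASN", 213, nd2_213)
    rows$og1_729 <- mk("OG1", "THR", 729, nd2_213 + c(KEEP, 0, 0))  # kept
    # --- local network around residue 340 (P1 helix vs M3 / L6-7) ---
    n249 <- get_pos(at, 249, "N")
    ca340 <- get_pos(at, 340, "CA")
    rows$cb_340 <- mk("CB", if (mutant) "ALA" else "GLU", 340,
                      ca340 + c(0.8, 1.2, 0))
    og1_247 <- get_pos(at, 247, "CA") + c(0, -6, 0)
    rows$og1_247 <- mk("OG1", "THR", 247, og1_247)
    if (!mutant) {
      oe1 <- n249 + c(0, -KEEP_BB, 0)
      oe2 <- og1_247 + c(0, -2.7, 0)
      rows$oe1_340 <- mk("OE1", "GLU", 340, oe1)
      rows$oe2_340 <- mk("OE2", "GLU", 340, oe2)
      w <- oe1 + c(-2.8, 0, 0)
      rows$water <- mk("O", "HOH", 2001, w, element = "O", het = TRUE)
      rows$ne_822 <- mk("NE", "ARG", 822, w + c(-2.9, 0, 0))
    } else {
      cb <- ca340 + c(0.8, 1.2, 0)
      rows$ne_822 <- mk("NE", "ARG", 822, cb + 13 * c(0.707, -0.707, 0))
    }
    # --- nucleotide site: Asp351 carboxylate + AMPPCP gamma-phosphate ---
    g <- get_pos(at, 351, "CA") + c(0, -6, 0)
    th <- (if (mutant) 150 else 120) * pi / 180
    d <- if (mutant) 3.7 else 3.8
    rows$pg <- mk("PG", "ACP", 1001, g, element = "P", het = TRUE)
    rows$c3b <- mk("C3B", "ACP", 1001, g + c(1.8, 0, 0), element = "C",
                   het = TRUE)
    rows$pb <- mk("PB", "ACP", 1001, g + c(3.4, 0, 0), element = "P",
                  het = TRUE)
    rows$od1_351 <- mk("OD1", "ASP", 351, g + d * c(cos(th), sin(th), 0))
    rows$od2_351 <- mk("OD2", "ASP", 351,
                       g + (d + 1.6) * c(cos(th), sin(th), 0) + c(0, 0, 1))
    out <- do.call(rbind, rows)
    out$serial <- seq.int(serial0 + 1L, length.out = nrow(out))
    out
  }

  truth <- list(
    na_kept = c("ARG134:NH2 - ASP426:OD1", "THR171(O) - GLU486:OE1"),
    na_lost = c("ARG134:NH1 - PHE427:O", "ARG139:NH1 - ASP426:OD2",
                "ARG139:NH2 - GLU435:OE1", "LYS169:NZ - THR484:OG1",
                "THR171:OG1 - LEU578:O", "LYS218:NZ - ASP422:OD1"),
    ap_kept = "ASN213:ND2 - THR729:OG1",
    n_na_wt = 8, n_na_mut = 2,
    p1_m3_wt = c("GLU340:OE1 - LEU249:N", "GLU340:OE2 - THR247:OG1"),
    water_bridge_wt = "GLU340:OE1 - HOH - ARG822:NE",
    catalytic = list(wt = list(d_OdPg = 3.8, theta = 120),
                     mut = list(d_OdPg = 3.7, theta = 150)))
  list(wt = build_side(wt_at, FALSE), mut = build_side(mut_at, TRUE),
       truth = truth)
}
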