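#' @title Trajectory observables, distributions, switches, correlation
#' @name trajectory_obs
#' @description
#' A `pump_trajectory` couples a topology structure with per-frame
#' coordinates (multi-model PDB input). Observables (distances, triplet
#' angles, hydrogen-bond counts, catalytic geometry) are evaluated per
#' frame into a `pump_timeseries`, the basis for density estimates, mode
#' finding, hysteretic two-state classification, irreversibility checks
#' and cross-trace correlation - the analyses used to characterize
#' conformational dynamics such as the one-way outward swing of an
#' arginine side chain between two distance levels.
NULL

#' Construct a trajectory
#' @param topology a `pump_structure` providing atom identities
#' @param frames n_frames x (3 * n_atoms) coordinate matrix (rows are
#'   frames; per-frame layout x1,y1,z1,x2,...)
#' @param times frame times in ns (strictly increasing); defaults to
#'   0, 1, 2, ...
#' @return object of class `pump_trajectory`
#' @export
trajectory <- function(topology, frames, times = NULL) {
  frames <- as.matrix(frames)
  if (ncol(frames) != 3 * n_atoms(topology)) {
    stop("frame width ", ncol(frames), " does not match topology (",
         n_atoms(topology), " atoms)")
  }
  if (is.null(times)) times <- seq_len(nrow(frames)) - 1
  if (length(times) != nrow(frames)) stop("times length must equal frame count")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(topology = topology, frames = frames, times = as.numeric(times)),
            class = "pump_trajectory")
}

#' Read a multi-model PDB file as a trajectory
#' @param path multi-model PDB file
#' @param times optional frame times in ns
#' @return a `pump_trajectory`
#' @export
read_trajectory <- function(path, times = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  topo <- read_structure(path, format = "pdb", model_index = 1L)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  trajectory(topo, xyz, times = times)
}

#' Number of frames
#' @param traj a `pump_trajectory`
#' @return integer
#' @export
n_frames <- function(traj) nrow(traj$frames)

frame_structure <- function(traj, i) {
  set_coords(traj$topology, matrix(traj$frames[i, ], ncol = 3, byrow = TRUE))
}

#' Construct a time series
#' @param times numeric vector (ns)
#' @param values numeric vector, same length, finite
#' @param unit unit string ("A", "degrees", "count", ...)
#' @param label human-readable label
#' @return object of class `pump_timeseries`
#' @export
time_series <- function(times, values, unit = "", label = "") {
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (any(!is.finite(values))) stop("non-finite values in time series")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 unit = unit, label = label),
            class = "pump_timeseries")
}

#' @export
print.pump_timeseries <- function(x, ...) {
  cat(sprintf("<pump_timeseries> %s: %d points [%s], range %.3g..%.3g\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$values), x$unit, min(x$values), max(x$values)))
  invisible(x)
}

#' Observable specifications
#'
#' Constructors for the per-frame observables evaluated by
#' [evaluate_observable()]: a pair distance, a three-residue angle, a
#' hydrogen-bond count between two groups, or the catalytic-site
#' geometry (returning the Od-Pgamma distance; use `field = "theta"` for
#' the angle).
#'
#' @param resA,resB,r1,r2,r3 residue specs
#' @param atomA,atomB,atom atom names
#' @param groupA,groupB `pump_selection` objects
#' @param crit a `contact_criterion`
#' @param asp catalytic aspartate residue spec
#' @param field "d_OdPg" or "theta"
#' @param label label attached to the resulting series
#' @return an `obs_spec` object
#' @name observable_specs
NULL

#' @rdname observable_specs
#' @export
obs_distance <- function(resA, resB, atomA = "CA", atomB = "CA", label = "") {
  structure(list(kind = "distance", resA = resA, resB = resB,
                 atomA = atomA, atomB = atomB, label = label,
                 unit = "A"), class = "obs_spec")
}

#' @rdname observable_specs
#' @export
obs_triplet_angle <- function(r1, r2, r3, atom = "CA", label = "") {
  structure(list(kind = "triplet_angle", r1 = r1, r2 = r2, r3 = r3,
                 atom = atom, label = label, unit = "degrees"),
            class = "obs_spec")
}

#' @rdname observable_specs
#' @export
obs_hbond_count <- function(groupA, groupB, crit = contact_criterion(),
                            label = "") {
  structure(list(kind = "hbond_count", groupA = groupA, groupB = groupB,
                 crit = crit, label = label, unit = "count"),
            class = "obs_spec")
}

#' @rdname observable_specs
#' @export
obs_catalytic <- function(asp = 351, field = c("d_OdPg", "theta"), label = "") {
  field <- match.arg(field)
  structure(list(kind = "catalytic", asp = asp, field = field, label = label,
                 unit = if (field == "theta") "degrees" else "A"),
            class = "obs_spec")
}

#' Evaluate an observable over every frame
#'
#' Atom existence is checked on the topology before iterating frames, so
#' a misspecified observable fails fast. On a one-frame trajectory the
#' result equals the corresponding static-structure operation.
#'
#' @param traj a `pump_trajectory`
#' @param spec an `obs_spec`
#' @return a `pump_timeseries` with one value per frame
#' @export
evaluate_observable <- function(traj, spec) {
  stopifnot(inherits(spec, "obs_spec"))
  topo <- traj$topology
  nf <- n_frames(traj)
  if (spec$kind == "distance") {
    i <- find_atom(topo, spec$resA, spec$atomA)
    j <- find_atom(topo, spec$resB, spec$atomB)
    cx <- 3 * (c(i, j) - 1)
    vals <- sqrt((traj$frames[, cx[1] + 1] - traj$frames[, cx[2] + 1])^2 +
                 (traj$frames[, cx[1] + 2] - traj$frames[, cx[2] + 2])^2 +
                 (traj$frames[, cx[1] + 3] - traj$frames[, cx[2] + 3])^2)
  } else if (spec$kind == "triplet_angle") {
    idx <- c(find_atom(topo, spec$r1, spec$atom),
             find_atom(topo, spec$r2, spec$atom),
             find_atom(topo, spec$r3, spec$atom))
    vals <- vapply(seq_len(nf), function(f) {
      xyz <- matrix(traj$frames[f, ], ncol = 3, byrow = TRUE)
      point_angle(xyz[idx[1], ], xyz[idx[2], ], xyz[idx[3], ])
    }, numeric(1))
  } else if (spec$kind == "hbond_count") {
    vals <- vapply(seq_len(nf), function(f) {
      as.numeric(count_hbonds(frame_structure(traj, f),
                              spec$groupA, spec$groupB, spec$crit))
    }, numeric(1))
  } else if (spec$kind == "catalytic") {
    catalytic_geometry(topo, asp = spec$asp)   # fail fast on topology
    vals <- vapply(seq_len(nf), function(f) {
      cg <- catalytic_geometry(frame_structure(traj, f), asp = spec$asp)
      cg[[spec$field]]
    }, numeric(1))
  } else {
    stop("unknown observable kind: ", spec$kind)
  }
  time_series(traj$times, vals, unit = spec$unit, label = spec$label)
}

#' Density estimate of a time series
#'
#' Either a Gaussian KDE with Silverman's rule-of-thumb bandwidth or a
#' fixed-bin histogram; both return a curve normalized to unit area.
#'
#' @param ts a `pump_timeseries` (or numeric vector) with at least 10
#'   samples
#' @param method "kde" or "bins"
#' @param bins number of bins when `method = "bins"`
#' @param bw bandwidth when `method = "kde"` (default Silverman)
#' @return object of class `pump_density`: list with `x`, `y`, `method`
#' @export
histogram_density <- function(ts, method = c("kde", "bins"), bins = 50,
                              bw = "nrd0") {
  method <- match.arg(method)
  v <- if (inherits(ts, "pump_timeseries")) ts$values else as.numeric(ts)
  if (length(v) < 10) stop("need at least 10 samples for a density estimate")
  if (method == "kde") {
    if (stats::sd(v) == 0) {
      # degenerate constant series: one sharp mode at the value
      d <- list(x = v[1] + seq(-1, 1, length.out = 11) * 1e-6,
                y = c(0, 0, 0, 0, 0, 1e6, 0, 0, 0, 0, 0))
    } else {
      kd <- stats::density(v, bw = bw)
      d <- list(x = kd$x, y = kd$y)
    }
    # renormalize numerically to unit trapezoid area on the grid
    area <- sum(diff(d$x) * (utils::head(d$y, -1) + utils::tail(d$y, -1)) / 2)
    if (area > 0) d$y <- d$y / area
    return(structure(list(x = d$x, y = d$y, method = method),
                     class = "pump_density"))
  }
  h <- graphics::hist(v, breaks = seq(min(v) - 1e-9, max(v) + 1e-9,
                                      length.out = bins + 1), plot = FALSE)
  w <- diff(h$breaks)
  y <- h$density / sum(h$density * w)   # exact unit area over the bins
  structure(list(x = h$mids, y = y, widths = w, method = method),
            class = "pump_density")
}

#' Find modes of a density curve
#'
#' Local maxima whose height exceeds `min_prominence` times the global
#' maximum, returned sorted by position. Height-threshold prominence is
#' deliberate: it is invariant under rescaling of the density axis.
#'
#' @param density a `pump_density` (or list with `x`, `y`)
#' @param min_prominence fraction of the maximum density (default 0.05)
#' @return numeric vector of mode positions (possibly length 1)
#' @export
find_modes <- function(density, min_prominence = 0.05) {
  x <- density$x
  y <- density$y
  n <- length(y)
  if (n < 3) return(x[which.max(y)])
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE)
  is_max[1] <- y[1] > y[2]
  is_max[n] <- y[n] > y[n - 1]
  keep <- is_max & y >= min_prominence * max(y)
  sort(x[keep])
}

#' Hysteretic two-state classification of a trace
#'
#' Frames at or below `low_thr` are labelled "low", at or above
#' `high_thr` "high"; frames inside the band inherit the last decided
#' state (hysteresis), so noise inside the band never produces
#' transitions. Frames before the first decided one are "undecided".
#'
#' @param ts a `pump_timeseries`
#' @param low_thr,high_thr thresholds with `low_thr < high_thr`; the
#'   defaults (10, 12 Angstrom) bracket the in/out distance levels of
#'   the arginine-swing analysis (in: ~7-10, out: ~13)
#' @return object of class `state_trace`: list with `states` (character
#'   per frame), `transitions` (data.frame frame, time, direction),
#'   `low_thr`, `high_thr`
#' @export
classify_two_state <- function(ts, low_thr = 10, high_thr = 12) {
  if (low_thr >= high_thr) stop("low_thr must be below high_thr")
  v <- ts$values
  states <- character(length(v))
  cur <- "undecided"
  trans <- list()
  for (i in seq_along(v)) {
    new <- if (v[i] <= low_thr) "low" else if (v[i] >= high_thr) "high" else cur
    if (cur != "undecided" && new != "undecided" && new != cur) {
      trans[[length(trans) + 1]] <- data.frame(
        frame = i, time = ts$times[i],
        direction = paste(cur, new, sep = "->"),
        stringsAsFactors = FALSE)
    }
    cur <- new
    states[i] <- cur
  }
  transitions <- if (length(trans) > 0) do.call(rbind, trans) else
    data.frame(frame = integer(), time = numeric(), direction = character(),
               stringsAsFactors = FALSE)
  structure(list(states = states, transitions = transitions,
                 low_thr = low_thr, high_thr = high_thr),
            class = "state_trace")
}

#' Is a two-state trace a one-way switch?
#'
#' TRUE iff no high-to-low transition occurs after the first low-to-high
#' transition (vacuously TRUE for traces with no transitions, with
#' `first_switch_frame = NA`). This is the formal version of the
#' observation that once the monitored side chain has swung out it never
#' returns within the sampled time.
#'
#' @param st a `state_trace`
#' @return list with `irreversible` (logical) and `first_switch_frame`
#' @export
is_irreversible <- function(st) {
  tr <- st$transitions
  up <- which(tr$direction == "low->high")
  if (length(up) == 0) {
    return(list(irreversible = TRUE, first_switch_frame = NA_integer_))
  }
  first_up <- up[1]
  down_after <- any(tr$direction == "high->low" &
                      seq_len(nrow(tr)) > first_up)
  list(irreversible = !down_after, first_switch_frame = tr$frame[first_up])
}

#' Pearson correlation of two traces
#' @param a,b `pump_timeseries` of equal length >= 3
#' @return Pearson r in [-1, 1]
#' @export
trace_correlation <- function(a, b) {
  va <- a$values
  vb <- b$values
  if (length(va) != length(vb)) stop("series lengths differ")
  if (length(va) < 3) stop("need at least 3 points")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("zero variance in at least one series")
  }
  stats::cor(va, vb)
}

#' Median of a time series
#' @param ts a `pump_timeseries`
#' @return numeric median (mean of central pair for even lengths)
#' @export
series_median <- function(ts) {
  if (length(ts$values) == 0) stop("empty series")
  stats::median(ts$values)
}
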