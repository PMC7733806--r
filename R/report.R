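#' @title Consolidated wild-type vs mutant comparison report
#' @name cli_report
#' @description
#' One call running the full comparison battery on a reference/mutant
#' structure pair: global and segment-decomposed RMSDs (transmembrane
#' frame and own-body fits), the two landmark triplet angles, the named
#' landmark distances, interdomain polar-contact lists with presence
#' flags in both structures, the water-mediated link from the P1 helix
#' to the L6-7 loop, and the catalytic-site geometry of each structure.
#' Every entry is traceable to a single package operation; the report
#' serializes to JSON and renders to a data frame.
NULL

contact_pairs_of <- function(df) {
  if (nrow(df) == 0) return(character(0))
  # reduce atom labels to residue-level pair identifiers
  res_of <- function(lbl) sub(":.*$", "", sub("^[^/]*/", "", lbl))
  unique(paste(res_of(df$atom_a), res_of(df$atom_b), sep = " - "))
}

run_contact_block <- function(s, groupA, groupB, crit, water = FALSE) {
  df <- find_polar_contacts(s, groupA, groupB, crit = crit,
                            allow_water_bridge = water)
  list(contacts = df, pairs = contact_pairs_of(df[!df$water_mediated, ,
                                                  drop = FALSE]),
       water_pairs = contact_pairs_of(df[df$water_mediated, , drop = FALSE]))
}

#' Run the full structure-comparison battery
#'
#' @param ref reference structure: a `pump_structure` or a file path
#' @param mobile comparison (mutant) structure: a `pump_structure` or a
#'   file path
#' @param registry a `segment_registry` (override segment boundaries
#'   here, e.g. from [load_registry_overrides()])
#' @param atom_set atom set for all RMSD computations
#' @param crit contact criterion for the polar-contact blocks
#' @param mut_res340_name atom landmarks of the mutated residue are
#'   looked up by number (340), so both Glu and Ala forms work
#' @return object of class `pump_report`; see Details
#' @details
#' The report contains: `rmsd$tm_frame` (fit on M5-M10; M1-M4 evaluated
#' in that frame), `rmsd$global` (fit on all paired main-chain atoms),
#' `rmsd$bodies` (own-fit RMSD per domain body: A, N, P, HEADPIECE,
#' NP_BODY, NA_BODY), `angles` (headpiece 13/86/98 and M1 kink 50/63/74
#' per structure), `distances` (Pro337-Pro312 and residue340-Leu249 CA
#' distances per structure), `contacts` (A-to-N and A-to-P direct
#' contacts and P1-to-L6-7 water-mediated contacts, with per-structure
#' pair lists), and `catalytic` (per-structure in-line geometry or the
#' error message if no nucleotide is present). Stage failures are
#' recorded as per-stage error entries without aborting the remaining
#' stages.
#' @export
run_compare_report <- function(ref, mobile, registry = segment_registry(),
                               atom_set = "mainchain",
                               crit = contact_criterion(),
                               mut_res340_name = NULL) {
  if (is.character(ref)) ref <- read_structure(ref)
  if (is.character(mobile)) mobile <- read_structure(mobile)

  stage <- function(expr) tryCatch(expr, error = function(e)
    list(error = conditionMessage(e)))

  rmsd <- list(
    tm_frame = stage(compare_structures(ref, mobile, fit_segment = "M5M10",
                                        report_segments = c("M5M10", "M1M4"),
                                        atom_set = atom_set,
                                        registry = registry)),
    global = stage(compare_structures(ref, mobile, fit_segment = "ALL",
                                      report_segments = "ALL",
                                      atom_set = atom_set,
                                      registry = registry)),
    bodies = stage({
      bodies <- c("A", "N", "P", "HEADPIECE", "NP_BODY", "NA_BODY")
      vals <- lapply(bodies, function(b) {
        r <- stage(compare_structures(ref, mobile, fit_segment = b,
                                      atom_set = atom_set,
                                      registry = registry))
        if (!is.null(r$error)) r$error else report_rmsd(r, b)
      })
      names(vals) <- bodies
      vals
    }))

  both <- function(f) list(ref = stage(f(ref)), mobile = stage(f(mobile)))
  angles <- list(
    headpiece = both(function(s) residue_triplet_angle(s, 13, 86, 98)),
    m1_kink = both(function(s) residue_triplet_angle(s, 50, 63, 74)))
  distances <- list(
    p337_p312 = both(function(s) residue_pair_distance(s, 337, 312)),
    res340_l249 = both(function(s) residue_pair_distance(s, 340, 249)))

  a_sel <- get_segment("A", registry)
  n_sel <- get_segment("N", registry)
  p_sel <- get_segment("P", registry)
  p1_sel <- get_segment("P1", registry)
  l67_sel <- get_segment("L6_7", registry)
  contacts <- list(
    a_to_n = both(function(s) run_contact_block(s, a_sel, n_sel, crit)),
    a_to_p = both(function(s) run_contact_block(s, a_sel, p_sel, crit)),
    p1_to_l67 = both(function(s) run_contact_block(s, p1_sel, l67_sel, crit,
                                                   water = TRUE)))
  catalytic <- both(function(s) catalytic_geometry(s))

  structure(list(schema_version = "1.0",
                 ref_id = ref$source_id, mobile_id = mobile$source_id,
                 atom_set = atom_set,
                 rmsd = rmsd, angles = angles, distances = distances,
                 contacts = contacts, catalytic = catalytic),
            class = "pump_report")
}

#' @export
print.pump_report <- function(x, ...) {
  cat(sprintf("<pump_report> %s vs %s (schema %s)\n", x$ref_id, x$mobile_id,
              x$schema_version))
  print(report_table(x), row.names = FALSE)
  invisible(x)
}

num_or_na <- function(v) if (is.numeric(v)) v else NA_real_

#' Flat table of the scalar report quantities
#' @param report a `pump_report`
#' @return data.frame with columns quantity, ref, mobile
#' @export
report_table <- function(report) {
  g <- function(x, field = NULL) {
    if (is.list(x) && !is.null(x$error)) return(NA_real_)
    if (is.null(field)) num_or_na(x) else num_or_na(x[[field]])
  }
  tm <- report$rmsd$tm_frame
  gl <- report$rmsd$global
  rows <- list(
    c("rmsd_M5M10_fit_frame", if (is.null(tm$error)) report_rmsd(tm, "M5M10") else NA, NA),
    c("rmsd_M1M4_fit_frame", if (is.null(tm$error)) report_rmsd(tm, "M1M4") else NA, NA),
    c("rmsd_global_mainchain", if (is.null(gl$error)) report_rmsd(gl, "ALL") else NA, NA))
  for (b in names(report$rmsd$bodies)) {
    rows[[length(rows) + 1]] <- c(paste0("rmsd_ownfit_", b),
                                  num_or_na(report$rmsd$bodies[[b]]), NA)
  }
  pairs <- list(angle_headpiece = report$angles$headpiece,
                angle_m1_kink = report$angles$m1_kink,
                dist_p337_p312 = report$distances$p337_p312,
                dist_res340_l249 = report$distances$res340_l249)
  for (nm in names(pairs)) {
    rows[[length(rows) + 1]] <- c(nm, g(pairs[[nm]]$ref), g(pairs[[nm]]$mobile))
  }
  for (nm in names(report$contacts)) {
    blk <- report$contacts[[nm]]
    count_of <- function(side) {
      if (!is.null(side$error)) return(NA_real_)
      length(side$pairs) + length(side$water_pairs)
    }
    rows[[length(rows) + 1]] <- c(paste0("n_contacts_", nm),
                                  count_of(blk$ref), count_of(blk$mobile))
  }
  rows[[length(rows) + 1]] <- c("catalytic_d_OdPg",
                                g(report$catalytic$ref, "d_OdPg"),
                                g(report$catalytic$mobile, "d_OdPg"))
  rows[[length(rows) + 1]] <- c("catalytic_theta",
                                g(report$catalytic$ref, "theta"),
                                g(report$catalytic$mobile, "theta"))
  out <- data.frame(quantity = vapply(rows, `[[`, character(1), 1),
                    ref = as.numeric(vapply(rows, function(r)
                      as.character(r[2]), character(1))),
                    mobile = as.numeric(vapply(rows, function(r)
                      as.character(r[3]), character(1))),
                    stringsAsFactors = FALSE)
  out
}

strip_for_json <- function(x) {
  if (inherits(x, "domain_rmsd_report")) {
    return(list(fit_segment = x$fit_segment, atom_set = x$atom_set,
                n_paired = x$n_paired,
                segments = x$segments))
  }
  if (inherits(x, "catalytic_geometry")) return(unclass(x))
  if (inherits(x, "pump_selection")) return(NULL)
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    out <- lapply(x, strip_for_json)
    out[!vapply(out, is.null, logical(1))]
  } else x
}

#' Serialize a report to JSON
#'
#' Deterministic for fixed inputs (no timestamps), so re-running the
#' battery with the same structures and configuration yields identical
#' output.
#'
#' @param report a `pump_report`
#' @param path optional output file; when NULL the JSON string is
#'   returned
#' @return JSON string (invisibly when written to a file)
#' @export
report_to_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(strip_for_json(unclass(report)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
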