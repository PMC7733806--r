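test_that("superposition recovers exact transforms", {
  set.seed(1)
  p <- matrix(rnorm(60, sd = 8), 20, 3)
  # identity
  tr <- kabsch_superpose(p, p)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-9)
  expect_equal(tr$fit_rmsd, 0, tolerance = 1e-9)
  # 90 degrees about z plus translation
  R <- rotation_about_axis(c(0, 0, 1), 90)
  q <- p %*% R + rep(1, 20) %o% c(1, 2, 3)
  tr <- kabsch_superpose(p, q)
  expect_equal(tr$fit_rmsd, 0, tolerance = 1e-9)
  expect_equal(rotation_angle(tr), 90, tolerance = 1e-7)
  expect_equal(apply_transform(p, tr), q, tolerance = 1e-9)
})

test_that("superposition is optimal against a random-rotation oracle", {
  set.seed(2)
  p <- matrix(rnorm(60, sd = 6), 20, 3)
  q <- p %*% rotation_about_axis(c(1, 2, 3), 40) +
    matrix(rnorm(60, sd = 0.5), 20, 3)
  fit <- kabsch_superpose(p, q)$fit_rmsd
  # brute force: 10,000 random rotations (translation solved exactly by
  # centroid matching, which is optimal for any fixed rotation)
  qc <- sweep(q, 2, colMeans(q))
  pc <- sweep(p, 2, colMeans(p))
  worst <- min(vapply(seq_len(10000), function(i) {
    R <- rotation_about_axis(rnorm(3), runif(1, 0, 360))
    sqrt(mean(rowSums((pc %*% R - qc)^2)))
  }, numeric(1)))
  expect_lte(fit, worst + 1e-12)
})

test_that("superposition agrees with an independent implementation", {
  set.seed(3)
  p <- matrix(rnorm(90, sd = 5), 30, 3)
  q <- p %*% rotation_about_axis(c(1, 0, 1), 70) +
    matrix(rnorm(90, sd = 0.4), 30, 3)
  ours <- kabsch_superpose(q, p)$fit_rmsd
  # bio3d reports rmsd rounded to three decimals
  theirs <- suppressWarnings(bio3d::rmsd(as.numeric(t(p)),
                                         as.numeric(t(q)), fit = TRUE))
  expect_equal(ours, theirs, tolerance = 1e-3)
})

test_that("degenerate inputs are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "degenerate")
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               "at least 3")
  expect_error(kabsch_superpose(matrix(0, 4, 3), matrix(0, 5, 3)),
               "same number")
})

test_that("segment report uses one fit and matches a closed-form oracle", {
  # two rigid blocks; block B rotated by a known angle about a known axis
  # AFTER block A is held fixed -> with the fit on A (identity), the rmsd
  # of B has the closed form sqrt(mean |x (R - I)|^2)
  set.seed(4)
  xa <- matrix(rnorm(60, sd = 5), 20, 3)
  xb <- matrix(rnorm(60, sd = 5), 20, 3) + 40
  spec <- c(lapply(1:20, function(i) list("CA", "ALA", i, xa[i, 1], xa[i, 2], xa[i, 3])),
            lapply(1:20, function(i) list("CA", "ALA", 100 + i, xb[i, 1], xb[i, 2], xb[i, 3])))
  ref <- mini_structure(spec)
  R <- rotation_about_axis(c(1, 1, 0), 12)
  ctr <- colMeans(xb)
  xb2 <- sweep(sweep(xb, 2, ctr) %*% R, 2, -ctr)
  spec2 <- c(lapply(1:20, function(i) list("CA", "ALA", i, xa[i, 1], xa[i, 2], xa[i, 3])),
             lapply(1:20, function(i) list("CA", "ALA", 100 + i, xb2[i, 1], xb2[i, 2], xb2[i, 3])))
  mob <- mini_structure(spec2)
  reg <- segment_registry(overrides = list(BLKA = c(1, 20), BLKB = c(100, 120)))
  rep <- compare_structures(ref, mob, fit_segment = "BLKA",
                            report_segments = "BLKB", atom_set = "CA",
                            registry = reg)
  closed_form <- sqrt(mean(rowSums((xb2 - xb)^2)))
  expect_equal(report_rmsd(rep, "BLKA"), 0, tolerance = 1e-9)
  expect_equal(report_rmsd(rep, "BLKB"), closed_form, tolerance = 1e-9)
  expect_equal(rep$segments$n_atoms, c(20L, 20L))
})

test_that("structure vs exact copy reports all-zero rmsds", {
  pair <- pump_pair_fixture()
  rep <- compare_structures(pair$wt, pair$wt, fit_segment = "M5M10",
                            report_segments = c("M5M10", "M1M4", "HEADPIECE"))
  expect_true(all(rep$segments$rmsd < 1e-9))
})

test_that("rmsd reports are symmetric in ref and mobile", {
  pair <- pump_pair_fixture()
  f <- compare_structures(pair$wt, pair$mut, "M5M10", c("M5M10", "M1M4"))
  b <- compare_structures(pair$mut, pair$wt, "M5M10", c("M5M10", "M1M4"))
  expect_equal(f$segments$rmsd, b$segments$rmsd, tolerance = 1e-6)
})

test_that("empty report segments yield per-segment errors, not failure", {
  s <- poly_ala(100)
  reg <- segment_registry(overrides = list(HERE = c(1, 100),
                                           GONE = c(500, 600)))
  rep <- compare_structures(s, s, fit_segment = "HERE",
                            report_segments = "GONE", atom_set = "CA",
                            registry = reg)
  row <- rep$segments[rep$segments$segment == "GONE", ]
  expect_true(is.na(row$rmsd))
  expect_match(row$note, "empty")
})

test_that("point angles match the direct arccos formula", {
  expect_equal(point_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(point_angle(c(-2, 0, 0), c(0, 0, 0), c(5, 0, 0)), 180)
  expect_error(point_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "zero-length")
  set.seed(5)
  for (i in 1:25) {
    p <- matrix(rnorm(9, sd = 4), 3, 3)
    v1 <- p[1, ] - p[2, ]
    v2 <- p[3, ] - p[2, ]
    direct <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    expect_equal(point_angle(p[1, ], p[2, ], p[3, ]), direct,
                 tolerance = 1e-10)
    expect_gte(point_angle(p[1, ], p[2, ], p[3, ]), 0)
    expect_lte(point_angle(p[1, ], p[2, ], p[3, ]), 180)
  }
})

test_that("residue triplet angles use the middle residue as vertex", {
  hs <- make_hinged_structure(137, seed = 6)
  expect_equal(residue_triplet_angle(hs$s, hs$truth$r1, hs$truth$r2,
                                     hs$truth$r3),
               137, tolerance = 1e-9)
  expect_error(residue_triplet_angle(hs$s, 5, 10, 99), "not found")
})

test_that("residue pair distances are plain Euclidean distances", {
  s <- mini_structure(list(list("CA", "ALA", 1, 0, 0, 0),
                           list("CA", "ALA", 2, 3, 4, 0)))
  expect_equal(residue_pair_distance(s, 1, 2), 5)
  expect_equal(residue_pair_distance(s, 1, 1), 0)
  expect_error(residue_pair_distance(s, 1, 7), "not found")
})

test_that("catalytic geometry resolves analog centre, bridge and nearer Od", {
  # constructed in-line arrangement: angle exactly 180
  s <- mini_structure(list(list("O3B", "ADP", 995, -1.9, 0, 0),
                           list("PG", "ATP", 995, 0, 0, 0),
                           list("OD1", "ASP", 351, 3, 0, 0),
                           list("OD2", "ASP", 351, 5, 0, 0)))
  cg <- catalytic_geometry(s)
  expect_equal(cg$d_OdPg, 3)
  expect_equal(cg$theta, 180)
  expect_match(cg$od_atom, "OD1")
  # perpendicular placement -> 90 degrees
  s90 <- mini_structure(list(list("O3B", "ADP", 995, -1.9, 0, 0),
                             list("PG", "ATP", 995, 0, 0, 0),
                             list("OD1", "ASP", 351, 0, 2.5, 0)))
  expect_equal(catalytic_geometry(s90)$theta, 90)
  # missing nucleotide -> informative error
  expect_error(catalytic_geometry(poly_ala(5)), "no nucleotide")
})

test_that("all geometric observables are invariant under rigid motions", {
  pair <- pump_pair_fixture()
  s <- pair$wt
  set.seed(8)
  for (i in 1:3) {
    tr <- structure(list(rotation = random_rotation(),
                         translation = rnorm(3, sd = 20)),
                    class = "pump_transform")
    s2 <- apply_transform(s, tr)
    expect_equal(residue_triplet_angle(s2, 13, 86, 98),
                 residue_triplet_angle(s, 13, 86, 98), tolerance = 1e-6)
    expect_equal(residue_pair_distance(s2, 337, 312),
                 residue_pair_distance(s, 337, 312), tolerance = 1e-6)
    cg <- catalytic_geometry(s)
    cg2 <- catalytic_geometry(s2)
    expect_equal(cg2$d_OdPg, cg$d_OdPg, tolerance = 1e-6)
    expect_equal(cg2$theta, cg$theta, tolerance = 1e-6)
    # rmsd decomposition unchanged when the mobile copy is pre-rotated
    r1 <- compare_structures(s, pair$mut, "M5M10", "M1M4")
    r2 <- compare_structures(s, apply_transform(pair$mut, tr), "M5M10", "M1M4")
    expect_equal(r1$segments$rmsd, r2$segments$rmsd, tolerance = 1e-6)
  }
})
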