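test_that("generators are deterministic for a fixed seed", {
  a1 <- make_rigid_pair(30, 45, c(1, 0, 0), c(1, 1, 1), 0.3, seed = 9)
  a2 <- make_rigid_pair(30, 45, c(1, 0, 0), c(1, 1, 1), 0.3, seed = 9)
  expect_identical(a1, a2)
  b1 <- make_fluorescence_trace(noise_sd = 0.05, seed = 9)
  b2 <- make_fluorescence_trace(noise_sd = 0.05, seed = 9)
  expect_identical(b1, b2)
  s1 <- synthetic_pump_pair(seed = 3)
  s2 <- synthetic_pump_pair(seed = 3)
  expect_identical(s1, s2)
  s3 <- synthetic_pump_pair(seed = 4)
  expect_false(identical(s1$mut$atoms, s3$mut$atoms))
})

test_that("rigid pairs recover the applied transform exactly without noise", {
  rp <- make_rigid_pair(100, 90, c(0, 0, 1), c(4, -1, 2), 0, seed = 10)
  tr <- kabsch_superpose(coords(rp$b), coords(rp$a))
  expect_equal(tr$fit_rmsd, 0, tolerance = 1e-9)
  expect_equal(rotation_angle(tr), 90, tolerance = 1e-7)
  rp0 <- make_rigid_pair(10, 0, noise_sd = 0, seed = 10)
  expect_equal(kabsch_superpose(coords(rp0$b), coords(rp0$a))$fit_rmsd, 0,
               tolerance = 1e-12)
})

test_that("mean fitted rmsd over seeds matches the analytic expectation", {
  rmsds <- vapply(1:100, function(s) {
    rp <- make_rigid_pair(1000, 30, c(1, 2, 0), c(1, 0, 0), 0.5, seed = s)
    kabsch_superpose(coords(rp$b), coords(rp$a))$fit_rmsd
  }, numeric(1))
  expected <- make_rigid_pair(1000, 0, noise_sd = 0.5,
                              seed = 1)$truth$expected_rmsd
  expect_equal(mean(rmsds), expected, tolerance = 0.05)
})

test_that("hinged structures realize every prescribed angle", {
  for (ang in seq(10, 170, 10)) {
    hs <- make_hinged_structure(ang, seed = ang)
    got <- residue_triplet_angle(hs$s, hs$truth$r1, hs$truth$r2, hs$truth$r3)
    expect_equal(got, ang, tolerance = 1e-9)
  }
  expect_error(make_hinged_structure(0), "0, 180")
})

test_that("switch traces are recovered by the classifier across seeds", {
  for (s in 1:100) {
    st <- make_switch_trace(150, 80, seed = s)
    tr <- classify_two_state(st$ts)
    r <- is_irreversible(tr)
    expect_true(r$irreversible)
    expect_lte(abs(r$first_switch_frame - st$truth$switch_frame),
               st$truth$tol_frames)
  }
  # zero noise -> exact switch frame
  st0 <- make_switch_trace(100, 40, noise_sd = 0, seed = 1)
  expect_equal(is_irreversible(classify_two_state(st0$ts))$first_switch_frame,
               40)
  # no switch -> no transitions
  stn <- make_switch_trace(100, 101, seed = 1)
  expect_equal(nrow(classify_two_state(stn$ts)$transitions), 0)
  # undetectable levels refused
  expect_error(make_switch_trace(100, 50, low_level = 10.5),
               "hysteresis band")
})

test_that("bimodal generators flag overlapping components", {
  bt <- make_bimodal_trace(c(5, 5.2), c(0.5, 0.5), c(0.5, 0.5), 1000,
                           seed = 12)
  expect_true(bt$truth$overlap_warning)
  bt2 <- make_bimodal_trace(c(5, 9), c(0.5, 0.5), c(0.5, 0.5), 1000,
                            seed = 12)
  expect_false(bt2$truth$overlap_warning)
  expect_error(make_bimodal_trace(c(1, 2), c(1, 1), c(0.6, 0.6), 10),
               "sum to 1")
})

test_that("fluorescence truth half-times obey closed forms", {
  tr <- make_fluorescence_trace(F0 = 0, A1 = 1, k1 = log(2) / 1.6, A2 = 0,
                                k2 = 1, noise_sd = 0, seed = 1)
  expect_equal(tr$truth$t_half, 1.6, tolerance = 1e-9)
  ks <- rates_for_half_time(4.5)
  expect_equal(two_phase_half_time(0, 0.5, ks$k1, 0.5, ks$k2), 4.5,
               tolerance = 1e-9)
})

test_that("hydrogen-bond toys are exact across 100 seeds", {
  for (s in 1:100) {
    n_in <- s %% 7
    n_out <- 1 + s %% 5
    ht <- make_hbond_toy(n_in, n_out, seed = s)
    expect_equal(count_hbonds(ht$s, ht$groupA, ht$groupB), n_in,
                 info = paste("seed", s))
  }
})

test_that("the synthetic pump pair realizes its construction targets", {
  pair <- pump_pair_fixture()
  tg <- pair$truth
  # exact landmark geometry
  expect_equal(residue_triplet_angle(pair$wt, 13, 86, 98),
               tg$angle_head_wt, tolerance = 1e-9)
  expect_equal(residue_triplet_angle(pair$mut, 13, 86, 98),
               tg$angle_head_mut, tolerance = 1e-9)
  expect_equal(residue_triplet_angle(pair$wt, 50, 63, 74),
               tg$angle_kink_wt, tolerance = 1e-9)
  expect_equal(residue_triplet_angle(pair$mut, 50, 63, 74),
               tg$angle_kink_mut, tolerance = 1e-9)
  expect_equal(residue_pair_distance(pair$wt, 337, 312),
               tg$d_p337_p312_wt, tolerance = 1e-9)
  expect_equal(residue_pair_distance(pair$mut, 337, 312),
               tg$d_p337_p312_mut, tolerance = 1e-9)
  # calibrated rmsd targets hold as measured by the package battery
  tm <- compare_structures(pair$wt, pair$mut, "M5M10", c("M5M10", "M1M4"))
  expect_equal(report_rmsd(tm, "M5M10"), tg$rmsd_m5m10, tolerance = 0.01)
  expect_equal(report_rmsd(tm, "M1M4"), tg$rmsd_m1m4, tolerance = 0.01)
  gl <- compare_structures(pair$wt, pair$mut, "ALL")
  expect_equal(report_rmsd(gl, "ALL"), tg$rmsd_global, tolerance = 0.01)
})
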