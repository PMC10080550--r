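# build a one-assignment TOCSY series from a coordinate path
path_series <- function(xy, ratios = seq(0, by = 1, length.out = nrow(xy)),
                        present = rep(TRUE, nrow(xy))) {
  seq1 <- peptide_sequence("AAA")
  pls <- lapply(seq_len(nrow(xy)), function(i) {
    peak_list("TOCSY", ratios[i], data.frame(
      residue_index = 1L, residue_type = "A", atom_f1 = "H", atom_f2 = "HA",
      f1_ppm = if (present[i]) xy[i, 1] else NA_real_,
      f2_ppm = if (present[i]) xy[i, 2] else NA_real_,
      present = present[i], stringsAsFactors = FALSE
    ))
  })
  titration_series(seq1, pls)
}

path_traj <- function(xy, ...) {
  extract_trajectory(path_series(xy, ...), 1L, "H", "HA")
}

test_that("trajectory extraction orders points and flags gaps", {
  xy <- cbind(8 + c(0, 0.02, 0.04, 0.06, 0.08), 4.2)
  tr <- path_traj(xy, ratios = c(0, 0.1, 0.5, 3, 10))
  expect_equal(nrow(tr$points), 5L)
  expect_equal(tr$points$ratio, c(0, 0.1, 0.5, 3, 10))
  expect_equal(tr$axis_weights, c(f1 = 1, f2 = 1))

  tr_gap <- path_traj(xy, ratios = c(0, 0.1, 0.5, 3, 10),
                      present = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(nrow(tr_gap$points), 4L)
  expect_equal(tr_gap$gap_ratios, 0.5)

  expect_error(
    path_traj(xy, present = c(TRUE, TRUE, FALSE, FALSE, FALSE)),
    "insufficient points"
  )
})

test_that("collinear paths never report a break", {
  xy <- cbind(8 + c(0, 0.013, 0.05, 0.21), 4.2 + c(0, 0.013, 0.05, 0.21))
  res <- detect_direction_change(path_traj(xy))
  expect_false(res$has_break)
  expect_lt(res$max_turn_deg, 1e-6)
})

test_that("a right-angle path yields a 90-degree turn at its vertex", {
  xy <- rbind(c(8.0, 4.2), c(8.1, 4.2), c(8.1, 4.3))
  res <- detect_direction_change(path_traj(xy, ratios = c(0, 0.5, 10)))
  expect_true(res$has_break)
  expect_equal(res$max_turn_deg, 90, tolerance = 1e-9)
  expect_equal(res$break_ratio, 0.5)
})

test_that("turning angles are invariant under rotation and uniform scaling", {
  set.seed(7)
  base <- rbind(c(0, 0), c(0.05, 0.01), c(0.08, 0.06), c(0.06, 0.11))
  ref <- detect_direction_change(path_traj(8 + base))
  for (theta in c(0.3, 1.2, 2.8)) {
    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    for (s in c(0.5, 2)) {
      xy <- sweep(s * base %*% rot, 2, c(8, 4.2), "+")
      res <- detect_direction_change(path_traj(xy))
      expect_equal(res$max_turn_deg, ref$max_turn_deg, tolerance = 1e-8)
      expect_equal(res$has_break, ref$has_break)
    }
  }
})

test_that("reversing the titration preserves the turning-angle multiset", {
  xy <- rbind(c(8, 4.2), c(8.05, 4.21), c(8.08, 4.26), c(8.06, 4.31),
              c(8.0, 4.33))
  fwd <- detect_direction_change(path_traj(xy))
  rev <- detect_direction_change(path_traj(xy[5:1, ]))
  expect_equal(sort(fwd$turns$angle_deg), sort(rev$turns$angle_deg),
               tolerance = 1e-9)
})

test_that("sub-threshold jitter steps are merged, pure jitter is zero motion", {
  # straight path with a tiny orthogonal zigzag well below min_step_ppm
  xy <- rbind(c(8.000, 4.200), c(8.0002, 4.2001), c(8.020, 4.200),
              c(8.0202, 4.2001), c(8.040, 4.200))
  res <- detect_direction_change(path_traj(xy), turn_threshold_deg = 30,
                                 min_step_ppm = 0.005)
  expect_false(res$has_break)
  expect_lt(res$max_turn_deg, 5)

  still <- matrix(rep(c(8, 4.2), each = 4), ncol = 2) +
    1e-4 * cbind(c(0, 1, -1, 0), c(0, -1, 1, 0))
  res0 <- detect_direction_change(path_traj(still))
  expect_false(res0$has_break)
  expect_true(res0$zero_motion)
})

test_that("one-site fast-exchange trajectories never trigger the detector", {
  model <- binding_model(kd1 = 5, kd2 = 1e9) # second site effectively absent
  shifts <- data.frame(residue_index = 1:16,
                       d1_f1 = 0.08, d1_f2 = -0.05, d2_f1 = 0, d2_f2 = 0)
  cfg <- nmr_sim_config(sp2_seq(), ratios = c(0, 0.1, 0.5, 1, 3, 10),
                        mode = "equilibrium", site_shifts = shifts,
                        model = model, p_total = 1000, noise_sd = 0)
  ser <- generate_nmr_series(cfg)
  for (i in c(1L, 7L, 14L)) {
    tr <- extract_trajectory(ser, i, "H", "HA")
    res <- detect_direction_change(tr, turn_threshold_deg = 20)
    expect_false(res$has_break)
  }
})

test_that("HSQC trajectories use the alpha-weighted carbon axis", {
  seqp <- peptide_sequence("AAA")
  # carbon moves 1 ppm then proton moves sqrt(0.3) ppm: in the weighted
  # plane both steps have equal length and are orthogonal -> 90 deg turn
  mk <- function(r, ca, ha) peak_list("HSQC_CH", r, data.frame(
    residue_index = 1L, residue_type = "A", atom_f1 = "CA", atom_f2 = "HA",
    f1_ppm = ca, f2_ppm = ha, stringsAsFactors = FALSE
  ))
  ser <- titration_series(seqp, list(
    mk(0, 52.0, 4.20), mk(0.5, 53.0, 4.20), mk(10, 53.0, 4.20 + sqrt(0.3))
  ))
  tr <- extract_trajectory(ser, 1L, "CA", "HA", alpha = 0.3)
  expect_equal(unname(tr$axis_weights["f1"]), sqrt(0.3))
  res <- detect_direction_change(tr)
  expect_equal(res$max_turn_deg, 90, tolerance = 1e-9)
  expect_equal(res$break_ratio, 0.5)
})
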