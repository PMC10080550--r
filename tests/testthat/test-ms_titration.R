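test_that("theoretical m/z follows the one-charge-per-silver convention", {
  m <- peptide_mass(sp3_seq())
  h <- 1.007276
  ag <- 107.86767
  expect_equal(theoretical_mz(m, 1, 0, 1), m + h, tolerance = 1e-9)
  expect_equal(theoretical_mz(m, 1, 1, 1), m + ag, tolerance = 1e-9)
  expect_equal(theoretical_mz(m, 2, 0, 2), m + h, tolerance = 1e-9)
  expect_equal(theoretical_mz(m, 1, 2, 3), (m + 2 * ag + h) / 3,
               tolerance = 1e-9)
  expect_error(theoretical_mz(m, 1, 2, 1), "charge deficit")
})

test_that("assignment matches generated sticks and rejects far centroids", {
  m <- peptide_mass(sp3_seq())
  grid <- expand.grid(n = 0:3, z = 2:3)
  grid <- grid[grid$z >= grid$n, ]
  mzs <- mapply(function(n, z) theoretical_mz(m, 1, n, z), grid$n, grid$z)
  sp <- ms_spectrum(100, 100, data.frame(mz = c(mzs, 900.0),
                                         area = c(rep(50, length(mzs)), 10)))
  asg <- assign_species(sp, sp3_seq(), n_max = 3, z_range = 2:3,
                        k_range = 1:2, tol_ppm = 10)
  stat <- asg$peak_map$status
  expect_equal(sum(stat == "matched"), length(mzs))
  expect_equal(stat[asg$peak_map$mz == 900.0], "unmatched")
  # 4 distinct (k = 1, n) species, max n = 3
  sp_tab <- unique(asg$species[c("oligomer_k", "n_ag")])
  expect_equal(nrow(sp_tab), 4L)
  expect_equal(max(asg$species$n_ag), 3L)
})

test_that("apo-only spectra assign exclusively silver-free species", {
  m <- peptide_mass(sp3_seq())
  sp <- ms_spectrum(100, 0, data.frame(
    mz = c(theoretical_mz(m, 1, 0, 2), theoretical_mz(m, 1, 0, 3),
           theoretical_mz(m, 2, 0, 2)),
    area = c(30, 20, 50)
  ))
  asg <- assign_species(sp, m)
  expect_true(all(asg$peak_map$status == "matched"))
  expect_true(all(asg$species$n_ag == 0L))
})

test_that("quantification computes area shares and dimer equivalents", {
  m <- peptide_mass(sp3_seq())
  mk_asg <- function(areas) {
    # areas: named P, PAg, PAg2, dimer
    sp <- ms_spectrum(100, 100, data.frame(
      mz = c(theoretical_mz(m, 1, 0, 2), theoretical_mz(m, 1, 1, 2),
             theoretical_mz(m, 1, 2, 2), theoretical_mz(m, 2, 0, 2)),
      area = areas
    ))
    assign_species(sp, m)
  }
  q <- quantify(mk_asg(c(50, 30, 20, 0)))
  expect_equal(c(q$f0, q$f1, q$f2), c(0.5, 0.3, 0.2))

  q_apo <- quantify(mk_asg(c(80, 0, 0, 0)))
  expect_equal(c(q_apo$f0, q_apo$f1, q_apo$f2), c(1, 0, 0))

  # dimer weighting oracle: equivalents = k * area, recomputed by hand
  areas <- c(40, 30, 20, 15)
  q_dim <- quantify(mk_asg(areas))
  tot <- 40 + 30 + 20 + 2 * 15
  expect_equal(c(q_dim$f0, q_dim$f1, q_dim$f2),
               c((40 + 2 * 15) / tot, 30 / tot, 20 / tot))

  # scale invariance
  q_scaled <- quantify(mk_asg(areas * 7.3))
  expect_equal(c(q_scaled$f0, q_scaled$f1, q_scaled$f2),
               c(q_dim$f0, q_dim$f1, q_dim$f2), tolerance = 1e-12)

  expect_error(quantify(mk_asg(c(0, 0, 0, 0))), "quantify")
})

test_that("fractions always sum to one across a generated titration", {
  cfg <- sim_preset("sp3-paper")
  specs <- generate_ms_titration(cfg)
  for (s in specs) {
    q <- quantify(assign_species(s, cfg$sequence))
    expect_equal(q$f0 + q$f1 + q$f2, 1, tolerance = 1e-9)
  }
})

test_that("KD fitting recovers ground truth in an identifiable regime", {
  cfg <- ms_sim_config(sp3_seq(), binding_model(50, 50), p_total = 100,
                       ratios = c(0, 0.5, 1, 2), dimer_fraction = 0.2,
                       noise_cv = 0)
  fit <- ms_pipeline_fit(cfg)
  expect_true(fit$converged)
  expect_equal(fit$kd1_hat, 50, tolerance = 0.05)
  expect_equal(fit$kd2_hat, 50, tolerance = 0.05)
})

test_that("forward-inverse recovery of kd2 holds over a parameter grid", {
  for (kd1 in c(0.05, 0.5, 5)) {
    for (kd2 in c(5, 24.5, 100)) {
      cfg <- ms_sim_config(sp3_seq(), binding_model(kd1, kd2),
                           p_total = 100, ratios = c(0, 0.5, 1, 2),
                           dimer_fraction = 0.3, noise_cv = 0)
      fit <- ms_pipeline_fit(cfg)
      expect_lt(abs(fit$kd2_hat - kd2) / kd2, 0.10)
    }
  }
})

test_that("response-factor rescaling leaves fractions unchanged", {
  rf1 <- c(k1n0 = 1, k2n0 = 1, k1n1 = 1, k1n2 = 1)
  rf2 <- rf1 * 3.7
  cfg1 <- ms_sim_config(sp3_seq(), binding_model(0.2, 24.5),
                        response_factors = rf1, noise_cv = 0)
  cfg2 <- ms_sim_config(sp3_seq(), binding_model(0.2, 24.5),
                        response_factors = rf2, noise_cv = 0)
  q1 <- lapply(generate_ms_titration(cfg1),
               function(s) quantify(assign_species(s, cfg1$sequence)))
  q2 <- lapply(generate_ms_titration(cfg2),
               function(s) quantify(assign_species(s, cfg2$sequence)))
  for (i in seq_along(q1)) {
    expect_equal(c(q1[[i]]$f0, q1[[i]]$f1, q1[[i]]$f2),
                 c(q2[[i]]$f0, q2[[i]]$f1, q2[[i]]$f2), tolerance = 1e-12)
  }
})

test_that("an exact theoretical-mz tie is flagged ambiguous and excluded", {
  m <- peptide_mass(sp3_seq())
  # monomer [M+H]+ and doubly protonated dimer share one m/z exactly
  sp <- ms_spectrum(100, 0, data.frame(mz = theoretical_mz(m, 1, 0, 1),
                                       area = 10))
  asg <- assign_species(sp, m, z_range = 1:3, k_range = 1:2)
  expect_equal(asg$peak_map$status, "ambiguous")
  expect_equal(nrow(asg$species), 0L)
})
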