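test_that("CSP formulas match direct arithmetic on random displacements", {
  set.seed(42)
  n <- 1000
  dh <- stats::runif(n, -0.5, 0.5)
  dc <- stats::runif(n, -3, 3)
  alpha <- stats::runif(n, 0.1, 1)
  expect_equal(csp_tocsy(dh, dc), sqrt(dh^2 + dc^2), tolerance = 1e-12)
  expect_equal(csp_hsqc(dh, dc, 0.3), sqrt(dh^2 + 0.3 * dc^2),
               tolerance = 1e-12)
  # elementwise alpha
  one_by_one <- vapply(seq_len(n),
                       function(i) csp_hsqc(dh[i], dc[i], alpha[i]),
                       numeric(1))
  expect_equal(one_by_one, sqrt(dh^2 + alpha * dc^2), tolerance = 1e-12)
})

test_that("CSP special cases: 3-4-5 triangle, symmetry, reductions", {
  expect_equal(csp_tocsy(0.03, 0.04), 0.05)
  expect_equal(csp_tocsy(0, 0), 0)
  expect_equal(csp_tocsy(-0.03, -0.04), csp_tocsy(0.03, 0.04)) # start/end swap
  expect_equal(csp_hsqc(0.1, 0.2, 0.3), sqrt(0.022)) # 0.148324...
  expect_equal(csp_hsqc(0.12, 0.34, 1), csp_tocsy(0.12, 0.34))
  expect_equal(csp_hsqc(0.07, 0, 0.3), 0.07)
})

test_that("csp_hsqc is monotone in |d_h|, |d_c| and alpha", {
  base <- csp_hsqc(0.1, 0.5, 0.3)
  expect_gte(csp_hsqc(0.2, 0.5, 0.3), base)
  expect_gte(csp_hsqc(0.1, 0.9, 0.3), base)
  expect_gte(csp_hsqc(0.1, 0.5, 0.6), base)
})

test_that("compute_csp_table reproduces hand-computed displacements", {
  ser <- two_point_series(shift_f1 = c(0, 0.03, 0.05),
                          shift_f2 = c(0, 0.04, -0.12))
  tab <- compute_csp_table(ser, csp_config())
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$csp, c(0, 0.05, 0.13), tolerance = 1e-12)
  expect_true(all(tab$group == "TOCSY_NH_HA"))

  # identical endpoint -> all zero
  tab0 <- compute_csp_table(two_point_series(c(0, 0, 0), c(0, 0, 0)))
  expect_equal(tab0$csp, rep(0, 3))
})

test_that("HSQC CSP table applies the alpha weighting on the carbon axis", {
  seq3 <- peptide_sequence("ADA")
  start <- tiny_peaks()
  start$atom_f1 <- "CA"
  start$f1_ppm <- c(52.0, 54.0, 52.5)
  end <- start
  end$f1_ppm <- end$f1_ppm + 0.5   # carbon displacement
  end$f2_ppm <- end$f2_ppm + 0.02  # proton displacement
  ser <- titration_series(seq3, list(
    peak_list("HSQC_CH", 0, start), peak_list("HSQC_CH", 10, end)
  ))
  tab <- compute_csp_table(ser, csp_config(alpha = 0.3))
  expect_equal(tab$csp, rep(sqrt(0.02^2 + 0.3 * 0.5^2), 3), tolerance = 1e-12)
  expect_true(all(tab$group == "CA_HA"))
})

test_that("missing endpoint peaks propagate to mover_class missing", {
  ser <- two_point_series()
  ser$points[[2]]$peaks$present[1] <- FALSE
  tab <- classify_movers(compute_csp_table(ser))
  expect_equal(tab$mover_class[1], "missing")
  expect_true(is.na(tab$csp[1]))
  expect_false(any(tab$mover_class[-1] == "missing"))
})

test_that("a missing reference or endpoint ratio is a clear error", {
  ser <- two_point_series()
  expect_error(compute_csp_table(ser, csp_config(endpoint_ratio = 3)),
               "available")
})

test_that("group statistics use the population sigma by default", {
  rec <- data.frame(
    residue_index = 1:4, residue_type = "A", atom_f1 = "H", atom_f2 = "HA",
    csp = c(0.1, 0.1, 0.0, 0.2),
    group = c("G1", "G1", "G2", "G2"),
    mover_class = NA_character_, stringsAsFactors = FALSE
  )
  st <- group_stats(rec)
  expect_equal(st$mean[st$group == "G1"], 0.1)
  expect_equal(st$sigma[st$group == "G1"], 0)
  expect_equal(st$mean[st$group == "G2"], 0.1)
  expect_equal(st$sigma[st$group == "G2"], 0.1) # population: sqrt(mean sq dev)
  expect_equal(st$sigma[st$group == "G2"] * sqrt(2),
               group_stats(rec, sigma = "sample")$sigma[2])

  rec$csp[rec$group == "G2"] <- NA
  expect_warning(st2 <- group_stats(rec), "omitted")
  expect_false("G2" %in% st2$group)
})

test_that("mover classes partition each group with closed lower bounds", {
  rec <- data.frame(
    residue_index = 1:5, residue_type = "A", atom_f1 = "H", atom_f2 = "HA",
    csp = c(0.00, 0.05, 0.10, 0.16, 0.30), group = "G",
    mover_class = NA_character_, stringsAsFactors = FALSE
  )
  st <- group_stats(rec) # mean 0.122, sigma ~0.1017
  out <- classify_movers(rec, st)
  mu <- st$mean
  sg <- st$sigma
  expect_equal(out$mover_class,
               ifelse(rec$csp < mu, "weak",
                      ifelse(rec$csp < mu + sg, "medium", "strong")))
  expect_equal(sum(table(out$mover_class)), st$n)

  # boundary conventions: exactly mu -> medium, exactly mu + sigma -> strong
  rec2 <- rec
  rec2$csp <- c(mu, mu + sg, 0, 0.05, 0.3)
  out2 <- classify_movers(rec2, st)
  expect_equal(out2$mover_class[1:2], c("medium", "strong"))

  # degenerate group: sigma = 0, everything at the mean -> all medium
  rec3 <- rec
  rec3$csp <- rep(0.1, 5)
  out3 <- classify_movers(rec3, group_stats(rec3))
  expect_true(all(out3$mover_class == "medium"))
})

test_that("a single perturbed residue is the unique strong mover", {
  shift_f1 <- rep(0.002, 16)
  shift_f2 <- rep(-0.002, 16)
  shift_f1[7] <- 0.12 # one residue moves far
  shift_f2[7] <- 0.80
  seqp <- sp2_seq()
  start <- data.frame(
    residue_index = 1:16, residue_type = residue_letters(seqp),
    atom_f1 = "H", atom_f2 = "HA",
    f1_ppm = 8 + 0.02 * (1:16), f2_ppm = 4.2 + 0.01 * (1:16),
    stringsAsFactors = FALSE
  )
  end <- start
  end$f1_ppm <- end$f1_ppm + shift_f1
  end$f2_ppm <- end$f2_ppm + shift_f2
  ser <- titration_series(seqp, list(
    peak_list("TOCSY", 0, start), peak_list("TOCSY", 10, end)
  ))
  tab <- classify_movers(compute_csp_table(ser))
  expect_equal(tab$residue_index[tab$mover_class == "strong"], 7L)
  expect_equal(tab$residue_label[tab$mover_class == "strong"], "83Met")
})

test_that("signal grouping distinguishes methyl carbons and TOCSY backbone", {
  expect_equal(signal_group("HSQC_CH", "M", "CA", "HA"), "CA_HA")
  expect_equal(signal_group("HSQC_CH", "M", "CB", "HB"), "CB_HB")
  expect_equal(signal_group("HSQC_CH", "M", "CG", "HG"), "CG_HG")
  expect_equal(signal_group("HSQC_CH", "M", "CE", "HE"), "CH3")  # Met S-CH3
  expect_equal(signal_group("HSQC_CH", "A", "CB", "HB"), "CH3")  # Ala CH3
  expect_equal(signal_group("HSQC_CH", "H", "CE", "HE"), "CG_HG") # His ring
  expect_equal(signal_group("TOCSY", "A", "H", "HA"), "TOCSY_NH_HA")
  expect_equal(signal_group("TOCSY", "A", "HA", "HB"), "TOCSY_OTHER")
})
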