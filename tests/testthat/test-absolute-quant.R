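test_that("tryptic peptide counting follows the KP rule and length window", {
  expect_equal(count_observable_peptides("AAAKAAAAAAR"), 1L)  # AAAK too short
  expect_identical(steadyomics:::tryptic_peptides("AAAKAAAAAAR"),
                   c("AAAK", "AAAAAAR"))
  # no K/R: one peptide, counted iff within the window
  expect_equal(count_observable_peptides("AAAAAAA"), 1L)
  expect_equal(count_observable_peptides("AAAA"), 0L)
  # K before P does not cleave
  expect_identical(steadyomics:::tryptic_peptides("AAAKPAAAR"),
                   c("AAAKPAAAR"))
  expect_equal(count_observable_peptides(strrep("A", 31)), 0L)
  expect_error(count_observable_peptides(""), "empty")
  expect_error(count_observable_peptides("AAB1"), "invalid residue")
})

test_that("iBAQ averages technical replicates then divides by counts", {
  m <- tiny_em(matrix(c(300, 90, 100, 110), 2, 2, byrow = TRUE),
               genes = c("g1", "g2"), samples = c("t1", "t2"),
               unit = "iBAQ", layer = "protein")
  # no grouping: each column kept
  ib <- compute_ibaq(m, c(g1 = 3L, g2 = 10L))
  expect_equal(unname(ib$values["g1", "t1"]), 100)

  m3 <- tiny_em(matrix(c(90, 100, 110), 1, 3), genes = "g1",
                samples = c("t1", "t2", "t3"), unit = "iBAQ",
                layer = "protein")
  ib3 <- compute_ibaq(m3, c(g1 = 10L), tech_groups = rep("s1", 3))
  expect_equal(unname(ib3$values["g1", "s1"]), 10)

  mz <- tiny_em(matrix(c(100, 100), 2, 1), genes = c("g1", "g2"),
                unit = "iBAQ", layer = "protein")
  expect_warning(ibz <- compute_ibaq(mz, c(g1 = 5L, g2 = 0L)), "g2")
  expect_identical(em_genes(ibz), "g1")

  # scale equivariance: doubling intensities doubles iBAQ
  ib2 <- compute_ibaq(tiny_em(2 * m$values, genes = c("g1", "g2"),
                              samples = c("t1", "t2"), unit = "iBAQ",
                              layer = "protein"),
                      c(g1 = 3L, g2 = 10L))
  expect_equal(ib2$values, 2 * ib$values, tolerance = 1e-12)
})

test_that("protein calibration: exact line, peptide filter, failure modes", {
  amounts <- 10^seq(-3, 2, length.out = 10)
  sp <- spikein_table(data.frame(id = sprintf("u%d", 1:10),
                                 amount = amounts, signal = 10 * amounts,
                                 n_unique_peptides = 5L))
  fit <- fit_protein_calibration(sp)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, -1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n, 10L)

  # a standard with a single unique peptide is excluded from the fit
  sp$n_unique_peptides[1] <- 1L
  sp$signal[1] <- 1e6  # would wreck the fit if included
  fit2 <- fit_protein_calibration(sp)
  expect_equal(fit2$n, 9L)
  expect_equal(fit2$slope, 1, tolerance = 1e-12)

  few <- spikein_table(data.frame(id = c("a", "b", "c"),
                                  amount = c(1, 2, 4), signal = c(1, 2, 4),
                                  n_unique_peptides = c(2L, 2L, 1L)))
  expect_error(fit_protein_calibration(few), ">= 3")
})

test_that("power-law signal generation is inverted analytically", {
  # signal = gain * amount^p  =>  log10 amount = (1/p) log10 signal - log10(gain)/p
  amounts <- 10^seq(-8, -4, length.out = 12)
  gain <- 5e10
  p <- 0.8
  sp <- spikein_table(data.frame(id = sprintf("m%d", 1:12), amount = amounts,
                                 signal = gain * amounts^p))
  fit <- fit_mrna_calibration(sp)
  expect_equal(fit$slope, 1 / p, tolerance = 1e-9)
  expect_equal(fit$intercept, -log10(gain) / p, tolerance = 1e-9)
  est <- apply_calibration(tiny_em(matrix(sp$signal, ncol = 1),
                                   genes = sp$id, unit = "FPKM"), fit)
  expect_equal(unname(est$values[, 1]), amounts, tolerance = 1e-9)
})

test_that("mRNA calibration enforces standards count and dynamic range", {
  sp2 <- spikein_table(data.frame(id = c("a", "b"), amount = c(1, 200),
                                  signal = c(2, 400)))
  expect_error(fit_mrna_calibration(sp2), ">= 3")
  narrow <- spikein_table(data.frame(id = letters[1:5],
                                     amount = seq(1, 2, length.out = 5),
                                     signal = seq(2, 4, length.out = 5)))
  expect_error(fit_mrna_calibration(narrow), "decades")
  # FPKM = 2 x concentration: transform maps FPKM 20 -> concentration 10
  sp <- spikein_table(data.frame(id = letters[1:6],
                                 amount = 10^seq(-2, 3, 1),
                                 signal = 2 * 10^seq(-2, 3, 1)))
  fit <- fit_mrna_calibration(sp)
  est <- apply_calibration(tiny_em(matrix(20, 1, 1), genes = "g",
                                   unit = "FPKM"), fit)
  expect_equal(unname(est$values[1, 1]), 10, tolerance = 1e-9)
})

test_that("apply_calibration handles identity, zeros and unit mismatch", {
  idfit <- steadyomics:::new_calibration_fit(1, 0, 1, 5, "log10", "FPKM")
  m <- tiny_em(matrix(c(1, 10, 100, 0), 2, 2), unit = "FPKM")
  out <- apply_calibration(m, idfit)
  expect_equal(out$values[1:3], m$values[1:3], tolerance = 1e-12)
  expect_true(is.na(out$values[2, 2]))  # zero signal -> missing
  expect_equal(out$unit, "mmol_per_gDW")

  tenfit <- steadyomics:::new_calibration_fit(1, -1, 1, 5, "log10", "FPKM")
  expect_equal(unname(apply_calibration(
    tiny_em(matrix(100, 1, 1), unit = "FPKM"), tenfit)$values[1, 1]), 10)

  expect_error(apply_calibration(tiny_em(matrix(1, 1, 1), unit = "iBAQ"),
                                 idfit), "unit mismatch")

  # strict monotonicity on random fits and signals
  set.seed(1)
  for (i in 1:20) {
    fit <- steadyomics:::new_calibration_fit(runif(1, 0.3, 3),
                                             runif(1, -5, 5), 1, 5,
                                             "log10", "FPKM")
    sig <- sort(10^runif(10, -2, 6))
    est <- apply_calibration(tiny_em(matrix(sig, ncol = 1), unit = "FPKM"),
                             fit)$values[, 1]
    expect_true(all(diff(est) > 0))
  }
})

test_that("total RNA scaling matches measured contents relative to reference", {
  m <- tiny_em(matrix(c(1, 2, 1, 2), 2, 2), genes = c("a", "b"),
               samples = c("s1", "s2"))
  eq <- total_content(data.frame(sample = c("s1", "s2"),
                                 rna_fraction = c(0.04, 0.04)))
  out <- scale_to_total_rna(m, eq)
  expect_equal(out$values, m$values, tolerance = 1e-12)

  dbl <- total_content(data.frame(sample = c("s1", "s2"),
                                  rna_fraction = c(0.03, 0.06)))
  out2 <- scale_to_total_rna(m, dbl)
  expect_equal(out2$values[, "s2"], 2 * m$values[, "s2"], tolerance = 1e-12)

  expect_error(scale_to_total_rna(m, total_content(
    data.frame(sample = "s1", rna_fraction = 0.04))), "s2")
})

test_that("calibration + content scaling inverts the generator exactly", {
  cfg <- simulation_config(n_genes = 150, sigma = 0, seed = 21)
  sim <- simulate_chemostat_dataset(cfg)
  fit <- fit_mrna_calibration(sim$spikes_mrna)
  cal <- apply_calibration(sim$mrna_fpkm, fit)
  scaled <- scale_to_total_rna(cal, sim$contents)
  expect_lt(max(abs(scaled$values / sim$mrna$values - 1), na.rm = TRUE), 1e-9)

  pfit <- fit_protein_calibration(sim$spikes_protein)
  pcal <- apply_calibration(sim$protein_ibaq, pfit)
  expect_lt(max(abs(pcal$values / sim$protein$values - 1), na.rm = TRUE),
            1e-9)
})
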