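test_that("spectral density has the right limits and frozen value", {
  tc <- 13.24e-9
  # zero-frequency limit
  expect_equal(spectral_density(0, tc), 0.4 * tc)
  # high-frequency asymptote within 1% at omega*tau = 100
  w <- 100 / tc
  expect_equal(spectral_density(w, tc), 0.4 / (w^2 * tc), tolerance = 1e-2)
  # frozen arithmetic-oracle value at the 15N frequency of a 950 MHz magnet
  wN <- abs(field_context(950)$omega_N)
  expect_equal(spectral_density(wN, tc), 8.1207503860e-11, tolerance = 1e-9)
  # non-negative, non-increasing in |omega|
  ws <- 10^seq(5, 10, length.out = 50)
  js <- spectral_density(ws, tc, S2 = 0.8, tau_e = 50e-12)
  expect_true(all(js >= 0))
  expect_true(all(diff(js) <= 0))
  expect_error(spectral_density(Inf, tc))
})

test_that("predicted rates match the independent oracle and known limits", {
  got <- predict_rates(13.24e-9, 950)
  want <- oracle_rates(13.24e-9, 950)
  expect_equal(got$R1, unname(want["R1"]), tolerance = 1e-12)
  expect_equal(got$R2, unname(want["R2"]), tolerance = 1e-12)
  expect_equal(got$hetNOE, unname(want["hetNOE"]), tolerance = 1e-12)
  # extreme narrowing: R2/R1 -> 1 (at moderate field, where the CSA term's
  # different J-combination stays inside the 1% band)
  nr <- predict_rates(1e-12, 400)
  expect_equal(nr$R2 / nr$R1, 1, tolerance = 1e-2)
  # R2/R1 strictly increasing in tau_c
  ratios <- vapply(seq(1, 50, by = 1) * 1e-9, function(tc) {
    r <- predict_rates(tc, 600); r$R2 / r$R1
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("tau_c estimation inverts predicted rates across fields", {
  for (mhz in c(600, 950)) {
    for (tc in c(2, 13.24, 30)) {
      tab <- simulate_relaxation_table(tc, mhz, n_residues = 10, noise = 0)
      est <- estimate_tau_c(tab, n_mc = 0)
      expect_equal(est$tau_c_ns, tc, tolerance = 1e-3 / tc)
    }
  }
  # monotone in the planted value
  t10 <- estimate_tau_c(simulate_relaxation_table(10, 600, 10), n_mc = 0)
  t20 <- estimate_tau_c(simulate_relaxation_table(20, 600, 10), n_mc = 0)
  expect_lt(t10$tau_c_ns, t20$tau_c_ns)
})

test_that("tau_c estimation fails loudly when nothing survives filtering", {
  tab <- simulate_relaxation_table(13, 600, n_residues = 10, S2 = 0.3)
  expect_error(estimate_tau_c(tab), "hetNOE filter")
})

test_that("R1*R2 and hetNOE flags use strict thresholds", {
  tab <- residue_rates(residue = 1:3,
                       R1 = c(1.2, 1.0, 2.0), R2 = c(20, 10, 10),
                       hetNOE = c(0.82, 0.55, 0.70), field = 600)
  fl <- r1r2_flags(tab)
  expect_equal(fl$r1r2, c(24, 10, 20))
  expect_equal(fl$flagged, c(TRUE, FALSE, FALSE))   # 20.0 is not > 20
  nf <- hetnoe_flags(tab)
  expect_equal(nf$flagged, c(FALSE, TRUE, FALSE))   # 0.70 is not < 0.7
  # flags invariant under row reordering
  perm <- c(3, 1, 2)
  fl2 <- r1r2_flags(tab[perm, ])
  expect_equal(fl2$flagged[order(fl2$residue)], fl$flagged)
})

test_that("chemical shift perturbations combine H and N as specified", {
  apo <- data.frame(residue = 1:4, dH = c(8.1, 8.2, 8.3, NA),
                    dN = c(120, 121, 122, 123))
  bound <- data.frame(residue = 1:4, dH = c(8.1, 8.3, 8.3, 8.0),
                      dN = c(120, 121, 123, 124))
  expect_message(out <- csp(apo, bound), "skipping 1")
  expect_equal(out$csp, c(0, 0.1, 0.14))
  # symmetric under swapping states
  expect_equal(suppressMessages(csp(bound, apo))$csp, out$csp)
})

test_that("relaxation tables round-trip through TSV with sidecar field", {
  tab <- simulate_relaxation_table(13.24, 950, n_residues = 8, noise = 0.02,
                                   seed = 11)
  path <- tempfile(fileext = ".tsv")
  write_rates(tab, path)
  back <- read_rates(path)
  expect_equal(back$R1, tab$R1, tolerance = 1e-9)
  expect_equal(attr(back, "field")$proton_mhz, 950)
  unlink(c(path, paste0(path, ".cfg")))
})
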