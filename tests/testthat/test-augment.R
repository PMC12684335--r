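# The augmentation stage is exercised end-to-end (disconnected blocks +
# noisy two-field curves) in the acceptance suite; here we pin down its
# self-consistency properties on cheaper problems.

test_that("curves generated from the simulation network need no perturbation", {
  st <- make_study_bundle(seed = 21)
  man <- st$manifest
  # single connected block carrying the full true network
  blocks <- list(list(states = 1:3, K = man$K_true, pi = man$pi_true))
  curves <- simulate_dispersion(st$apo$network, man$fields, man$grid,
                                sigma = 0, seed = 1,
                                residue = as.integer(man$loop_residues),
                                offsets_ppm = man$offsets_ppm)
  aug <- augment_with_experiment(blocks, curves,
                                 offsets_ppm = man$offsets_ppm,
                                 r2_0 = man$r2_0, n_states = 3,
                                 seed = 2, n_starts = 2)
  expect_lt(aug$perturbation, 0.05)
  expect_lt(aug$chi2, 1)                       # noise floor is zero here
  expect_equal(aug$pi, man$pi_true, tolerance = 0.02)
})

test_that("augmentation never worsens the experimental chi2", {
  st <- make_study_bundle(seed = 22)
  man <- st$manifest
  curves <- st$apo$dispersion
  # chi2 of the unaugmented (disconnected) simulation picture: blocks with
  # equal weights and no inter-block exchange
  K0 <- matrix(0, 3, 3)
  K0[2:3, 2:3] <- man$K_true[2:3, 2:3]
  diag(K0) <- 0; diag(K0) <- -rowSums(K0)
  pi0 <- c(0.5, 0.5 * 0.57 / 0.97, 0.5 * 0.40 / 0.97)
  sig <- curves$r2eff_err
  calc <- numeric(nrow(curves))
  for (r in unique(curves$residue)) for (f in man$fields) {
    sel <- curves$residue == r & curves$field_mhz == f
    net <- kinetic_network(K0, pi = pi0,
                           offsets_ppm = man$offsets_ppm[as.character(r), ],
                           r2 = rep(man$r2_0, 3))
    calc[sel] <- bm_r2eff(net, f, curves$nu_cpmg[sel], mode = "rate")
  }
  chi2_sim <- sum(((curves$r2eff - calc) / sig)^2)
  aug <- augment_with_experiment(st$apo$blocks, curves,
                                 offsets_ppm = man$offsets_ppm,
                                 r2_0 = man$r2_0, n_states = 3,
                                 seed = 3, n_starts = 3)
  expect_lt(aug$chi2, chi2_sim)
})

test_that("augmented networks satisfy detailed balance by construction", {
  th <- c(log(2), log(0.5), log(3), log(1), log(0.2))
  net <- colchidyn:::.theta_to_network(th, 3)
  flux <- net$pi * net$K
  expect_lt(max(abs(flux - t(flux))), 1e-12)
  expect_equal(sum(net$pi), 1, tolerance = 1e-12)
  expect_true(all(abs(rowSums(net$K)) < 1e-12))
  # round trip through the parametrisation
  back <- colchidyn:::.network_to_theta(net$K, net$pi)
  expect_equal(back, th, tolerance = 1e-9)
})

test_that("kinetic blocks built from an MSM carry its coarse rates", {
  st <- make_study_bundle(seed = 24, traj_frames = 20000L)
  m2 <- estimate_msm(count_matrix(st$apo$dtraj$block2, lag = 5), lag = 5,
                     dt = st$apo$dt)
  blk <- kinetic_block(m2, 2, states = c(2L, 3L))
  expect_equal(blk$states, c(2L, 3L))
  expect_equal(sum(blk$pi), 1, tolerance = 1e-12)
  expect_true(all(abs(rowSums(blk$K)) < 1e-8))
  # within a factor ~1.5 of the planted intra-block rates
  Kt <- st$manifest$K_true[2:3, 2:3]
  # block ordering is by decreasing population: state 2 (0.57) first
  for (i in 1:2) for (j in 1:2) if (i != j) {
    expect_gt(blk$K[i, j] / Kt[i, j], 1 / 1.5)
    expect_lt(blk$K[i, j] / Kt[i, j], 1.5)
  }
})

test_that("unidentifiable problems fail loudly", {
  blocks <- list(list(states = 1L, K = matrix(0, 1, 1), pi = 1),
                 list(states = 2L, K = matrix(0, 1, 1), pi = 1))
  cur <- dispersion_curves(1L, "N", 600, c(50, 100), c(10, 10), 0.3)
  expect_error(augment_with_experiment(blocks, cur, n_states = 2),
               "unidentifiable")
})

test_that("network JSON export carries states, rates and diagnostics", {
  st <- make_study_bundle(seed = 23)
  man <- st$manifest
  blocks <- list(list(states = 1:3, K = man$K_true, pi = man$pi_true))
  curves <- simulate_dispersion(st$apo$network, 600, c(50, 100, 200, 400),
                                sigma = 0, seed = 1,
                                residue = man$loop_residues[1],
                                offsets_ppm = man$offsets_ppm[1, , drop = FALSE])
  aug <- augment_with_experiment(blocks, curves,
                                 offsets_ppm = man$offsets_ppm[1, , drop = FALSE],
                                 r2_0 = man$r2_0, n_states = 3,
                                 seed = 2, n_starts = 1)
  p <- tempfile(fileext = ".json")
  write_network_json(aug, p)
  j <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(length(j$states$population), 3)
  expect_equal(dim(j$rates_rad_s), c(3, 3))
  expect_true(is.numeric(j$chi2))
  unlink(p)
})
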