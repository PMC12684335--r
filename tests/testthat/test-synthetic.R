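test_that("generators are pure functions of their seed", {
  K <- matrix(c(-50, 50, 20, -20), 2, 2, byrow = TRUE)
  expect_identical(simulate_ctmc(K, 1e-3, 500, seed = 4),
                   simulate_ctmc(K, 1e-3, 500, seed = 4))
  net <- two_state_network(0.9, 500, 2, 12)
  expect_identical(
    simulate_dispersion(net, 600, cpmg_grid(), sigma = 0.3, seed = 4),
    simulate_dispersion(net, 600, cpmg_grid(), sigma = 0.3, seed = 4))
  expect_identical(simulate_nh_wobble(100, "cone", seed = 4),
                   simulate_nh_wobble(100, "cone", seed = 4))
  s1 <- make_study_bundle(seed = 4, n_residues = 20, traj_frames = 500L)
  s2 <- make_study_bundle(seed = 4, n_residues = 20, traj_frames = 500L)
  expect_identical(s1$apo$dispersion, s2$apo$dispersion)
  expect_identical(s1$manifest, s2$manifest)
  # generators do not disturb the global RNG stream
  set.seed(123); a <- runif(1)
  set.seed(123); invisible(simulate_ctmc(K, 1e-3, 100, seed = 9))
  expect_identical(runif(1), a)
})

test_that("jump-process sampling honours the planted stationary state", {
  # symmetric two-state: occupancy 1/2 within 3 correlated-sample sigma
  K <- matrix(c(-40, 40, 40, -40), 2, 2, byrow = TRUE)
  d <- simulate_ctmc(K, 1e-3, 1e5, seed = 10)
  n_eff <- 1e5 * 1e-3 / (2 / 80)    # total time over twice the mixing time
  se <- sqrt(0.25 / n_eff)
  expect_lt(abs(mean(d == 0) - 0.5), 3 * se)
  # three-state planted network
  K3 <- matrix(c(-150, 100, 50, 30, -80, 50, 20, 80, -100), 3, 3,
               byrow = TRUE)
  pi3 <- colchidyn:::stationary_from_K(K3)
  d3 <- simulate_ctmc(K3, 5e-4, 1e5, seed = 11)
  lam <- sort(Re(eigen(K3, only.values = TRUE)$values), decreasing = TRUE)
  n_eff3 <- 1e5 * 5e-4 / (2 / abs(lam[2]))
  for (i in 1:3) {
    se <- sqrt(pi3[i] * (1 - pi3[i]) / n_eff3)
    expect_lt(abs(mean(d3 == i - 1) - pi3[i]), 3 * se)
  }
  expect_warning(simulate_ctmc(K3, 1e-2, 10, seed = 1), "coarse")
})

test_that("noiseless dispersion equals the forward model; noise is honest", {
  net <- two_state_network(0.92, 800, 1.5, 11)
  grid <- cpmg_grid()
  clean <- simulate_dispersion(net, 600, grid, sigma = 0, seed = 1)
  expect_equal(clean$r2eff, bm_r2eff(net, 600, grid, mode = "rate"))
  noisy <- simulate_dispersion(net, 600, grid, sigma = 0.3, seed = 1)
  resid <- noisy$r2eff - clean$r2eff
  # i.i.d. Gaussian noise sanity: mean near 0, sd near sigma (10%); one
  # short grid is too few draws, so pool many seeds
  resids <- unlist(lapply(1:30, function(s)
    simulate_dispersion(net, 600, grid, sigma = 0.3, seed = s)$r2eff -
      clean$r2eff))
  expect_lt(abs(mean(resids)), 0.3 / sqrt(length(resids)) * 3)
  expect_equal(stats::sd(resids), 0.3, tolerance = 0.1)
})

test_that("study bundle carries every planted truth in its manifest", {
  st <- make_study_bundle(seed = 31, n_residues = 30, traj_frames = 1000L)
  man <- st$manifest
  expect_equal(man$pi_true, c(0.03, 0.57, 0.40))
  expect_equal(man$tau_c_apo_ns, 13.24)
  expect_equal(man$tau_c_bound_ns, 13.06)
  expect_true(all(c("K_true", "offsets_ppm", "r2_0", "sigma", "grid",
                    "loop_residues", "seed") %in% names(man)))
  expect_true(all(abs(rowSums(man$K_true)) < 1e-9))
  # the blocks really are disconnected: no competent<->closed rates
  expect_equal(st$apo$blocks[[1]]$states, 1L)
  expect_equal(st$apo$blocks[[2]]$states, c(2L, 3L))
  # bundle writes as plain text and the dispersion table reads back
  dir <- tempfile()
  write_study_bundle(st, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_dispersion(file.path(dir, "apo_dispersion.tsv"))
  expect_equal(back$r2eff, st$apo$dispersion$r2eff, tolerance = 1e-9)
  unlink(dir, recursive = TRUE)
})

test_that("toy structure pairs plant exactly what they claim", {
  tp <- make_toy_structure_pair(40, 18:24, 8, seed = 13)
  expect_equal(sqrt(sum(tp$displacement_vec^2)), 8, tolerance = 1e-12)
  moved <- tp$mobile$resno %in% 18:24
  d <- sqrt((tp$mobile$x - tp$ref$x)^2 + (tp$mobile$y - tp$ref$y)^2 +
              (tp$mobile$z - tp$ref$z)^2)
  expect_true(all(abs(d[moved] - 8) < 1e-12))
  expect_true(all(d[!moved] == 0))
})
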