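#' Seeded synthetic-data generators
#'
#' Every generator in this module is a pure function of its arguments and a
#' seed: identical calls give bit-identical output. A single study-level
#' seed fans out to per-generator substreams through fixed offsets
#' (`seed + k`), so each table can be regenerated independently.
#'
#' @name synthetic
NULL

#' Simulate a continuous-time Markov jump trajectory, discretised
#'
#' Exact Gillespie sampling of the jump process with exponential holding
#' times, then discretisation at interval `dt` (the state at each sample
#' time).
#'
#' @param K rate matrix (1/time units consistent with `dt`).
#' @param dt frame interval.
#' @param n_steps number of frames.
#' @param seed RNG seed.
#' @param start initial state (1-based index); default sampled from the
#'   stationary distribution.
#' @return integer vector of 0-based labels, length `n_steps`, with the
#'   frame interval in attribute `dt`.
#' @export
simulate_ctmc <- function(K, dt, n_steps, seed = 20250101, start = NULL) {
  K <- as.matrix(K)
  n <- nrow(K)
  rates <- -diag(K)
  if (any(rates < 0)) stop("invalid generator: negative exit rates")
  if (dt * max(rates) >= 0.1)
    warning("dt * max exit rate >= 0.1: coarse discretisation")
  with_seed(seed, {
    s <- start %||% sample.int(n, 1, prob = stationary_from_K(K))
    out <- integer(n_steps)
    t_now <- 0
    t_next_jump <- if (rates[s] > 0) stats::rexp(1, rates[s]) else Inf
    for (i in seq_len(n_steps)) {
      t_frame <- (i - 1) * dt
      while (t_next_jump <= t_frame) {
        p <- K[s, ]; p[s] <- 0
        s <- sample.int(n, 1, prob = p)
        t_next_jump <- t_next_jump +
          if (rates[s] > 0) stats::rexp(1, rates[s]) else Inf
      }
      out[i] <- s - 1L
    }
    attr(out, "dt") <- dt
    out
  })
}

#' Simulate CPMG dispersion curves from a kinetic network
#'
#' Forward-models R2eff with the Bloch-McConnell propagator and adds i.i.d.
#' Gaussian noise of standard deviation `sigma` (recorded per point). The
#' default read-out is the asymptotic decay rate (`mode = "rate"`), the
#' convention under which fitted Carver-Richards parameters are directly
#' comparable to the planted ones.
#'
#' @param network a [kinetic_network()] (per-residue offsets: see
#'   `offsets_ppm` to override per residue).
#' @param fields proton frequencies, MHz.
#' @param grid CPMG frequencies, Hz.
#' @param trelax relaxation delay, s.
#' @param sigma noise sd, s^-1.
#' @param seed RNG seed.
#' @param residue residue number(s); one curve set per residue.
#' @param offsets_ppm optional matrix (residues x states) overriding the
#'   network offsets per residue.
#' @param nucleus `"N"` or `"C"`.
#' @param mode forwarded to [bm_r2eff()].
#' @return `dispersion_curves` table.
#' @export
simulate_dispersion <- function(network, fields, grid, trelax = 0.04,
                                sigma = 0.3, seed = 20250101, residue = 1L,
                                offsets_ppm = NULL, nucleus = "N",
                                mode = "rate") {
  rows <- list()
  for (ri in seq_along(residue)) {
    net <- network
    if (!is.null(offsets_ppm)) {
      net <- kinetic_network(network$K, pi = network$pi,
                             offsets_ppm = offsets_ppm[ri, ],
                             r2 = network$r2, names = network$names)
    }
    for (fm in fields) {
      r2 <- bm_r2eff(net, fm, grid, trelax, nucleus = nucleus, mode = mode)
      rows[[length(rows) + 1L]] <-
        data.frame(residue = residue[ri], nucleus = nucleus, field_mhz = fm,
                   nu_cpmg = grid, r2eff = r2, r2eff_err = sigma)
    }
  }
  df <- do.call(rbind, rows)
  if (sigma > 0) {
    df$r2eff <- df$r2eff +
      with_seed(seed, stats::rnorm(nrow(df), 0, sigma))
  }
  dispersion_curves(df$residue, df$nucleus, df$field_mhz, df$nu_cpmg,
                    df$r2eff, df$r2eff_err)
}

#' Simulate a per-residue relaxation table at a planted tumbling time
#'
#' Rates for each residue come from [predict_rates()] at the planted
#' `tau_c` with per-residue `S2`; multiplicative Gaussian noise of relative
#' size `noise` is added and recorded as the quoted uncertainty.
#'
#' @param tau_c_ns planted correlation time, ns.
#' @param field MHz or [field_context()].
#' @param n_residues number of residues (numbered 1..n).
#' @param S2 per-residue order parameters (recycled); rigid default.
#' @param tau_e_ns internal correlation time for flexible residues, ns.
#' @param noise relative noise level (e.g. 0.02 for 2 percent).
#' @param seed RNG seed.
#' @return `residue_rates` table.
#' @export
simulate_relaxation_table <- function(tau_c_ns, field, n_residues = 150,
                                      S2 = 1, tau_e_ns = 0.05, noise = 0,
                                      seed = 20250101) {
  S2 <- rep_len(S2, n_residues)
  f <- as_field(field)
  base <- lapply(seq_len(n_residues), function(i)
    predict_rates(tau_c_ns * 1e-9, f, S2 = S2[i],
                  tau_e = if (S2[i] < 1) tau_e_ns * 1e-9 else 0))
  r1 <- vapply(base, `[[`, numeric(1), "R1")
  r2 <- vapply(base, `[[`, numeric(1), "R2")
  noe <- vapply(base, `[[`, numeric(1), "hetNOE")
  if (noise > 0) {
    eps <- with_seed(seed, matrix(stats::rnorm(3 * n_residues), ncol = 3))
    r1n <- r1 * (1 + noise * eps[, 1])
    r2n <- r2 * (1 + noise * eps[, 2])
    noen <- noe + noise * eps[, 3]   # additive on the dimensionless NOE
    residue_rates(seq_len(n_residues), r1n, r2n, pmin(noen, 1.2),
                  R1_err = noise * r1, R2_err = noise * r2,
                  hetNOE_err = noise, field = f)
  } else {
    residue_rates(seq_len(n_residues), r1, r2, noe, field = f)
  }
}

#' Simulate a wobbling bond-vector series
#'
#' `mode = "cone"`: uniform sampling inside a cone of half-angle `theta`
#' about z, for which the order parameter has the closed form
#' `(cos(theta) (1 + cos(theta)) / 2)^2`. `mode = "isotropic"`: uniform on
#' the sphere (S2 -> 0). `mode = "s2"`: cone with half-angle chosen to give
#' the target S2.
#'
#' @param n frames.
#' @param mode `"cone"`, `"isotropic"` or `"s2"`.
#' @param theta cone half-angle, radians (mode `"cone"`).
#' @param S2 target order parameter (mode `"s2"`).
#' @param seed RNG seed.
#' @return n x 3 matrix of unit vectors.
#' @export
simulate_nh_wobble <- function(n, mode = c("cone", "isotropic", "s2"),
                               theta = pi / 3, S2 = NULL, seed = 20250101) {
  mode <- match.arg(mode)
  if (mode == "s2") {
    stopifnot(!is.null(S2), S2 >= 0, S2 <= 1)
    f <- function(th) (cos(th) * (1 + cos(th)) / 2)^2 - S2
    theta <- if (S2 >= 1) 0 else stats::uniroot(f, c(0, pi * 2 / 3))$root
    mode <- "cone"
  }
  with_seed(seed, {
    if (mode == "isotropic") {
      z <- stats::runif(n, -1, 1)
      phi <- stats::runif(n, 0, 2 * pi)
    } else {
      z <- stats::runif(n, cos(theta), 1)   # uniform solid angle in cone
      phi <- stats::runif(n, 0, 2 * pi)
    }
    r <- sqrt(1 - z^2)
    cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  })
}

#' Closed-form order parameter of the uniform cone model
#' @param theta cone half-angle, radians.
#' @return S2.
#' @export
cone_s2 <- function(theta) (cos(theta) * (1 + cos(theta)) / 2)^2

#' Toy structure pair with a planted loop displacement
#'
#' Builds an idealised Calpha trace (a gentle helix-like curve, so the
#' barrel-fit problem is well-conditioned), then displaces the loop residues
#' of the second copy by a planted vector of the given length. Optionally a
#' side-chain-like methyl atom (CD1) is attached to a loop residue and CG1
#' and CG2 atoms to a reference residue so that atom-level displacements and
#' distances have planted values too.
#'
#' @param n_residues chain length.
#' @param loop residue numbers to displace.
#' @param displacement planted displacement magnitude, Angstrom.
#' @param seed RNG seed (orients the displacement vector).
#' @param methyl_at optional residue number to decorate with a CD1 atom.
#' @param pair_at optional residue decorated with CG1/CG2 (in both copies).
#' @return list: `ref`, `mobile` (`structure3d`), `displacement_vec`.
#' @export
make_toy_structure_pair <- function(n_residues = 60, loop = 30:40,
                                    displacement = 8, seed = 20250101,
                                    methyl_at = NULL, pair_at = NULL) {
  t <- seq_len(n_residues)
  xyz <- cbind(10 * cos(t / 4), 10 * sin(t / 4), 1.5 * t)
  atoms <- data.frame(chain = "A", resno = t, resid = "ALA", elety = "CA",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  add_atom <- function(df, resno, elety, offset) {
    base <- df[df$resno == resno & df$elety == "CA", ]
    rbind(df, data.frame(chain = "A", resno = resno, resid = "XXX",
                         elety = elety, x = base$x + offset[1],
                         y = base$y + offset[2], z = base$z + offset[3],
                         stringsAsFactors = FALSE))
  }
  if (!is.null(methyl_at)) atoms <- add_atom(atoms, methyl_at, "CD1",
                                             c(1.2, 0.8, -0.5))
  if (!is.null(pair_at)) {
    atoms <- add_atom(atoms, pair_at, "CG1", c(-1.0, 0.6, 0.4))
    atoms <- add_atom(atoms, pair_at, "CG2", c(0.9, -0.7, 0.6))
  }
  dir <- with_seed(seed, {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  })
  vec <- displacement * dir
  mob <- atoms
  shift <- mob$resno %in% loop
  mob$x[shift] <- mob$x[shift] + vec[1]
  mob$y[shift] <- mob$y[shift] + vec[2]
  mob$z[shift] <- mob$z[shift] + vec[3]
  list(ref = as_structure3d(atoms), mobile = as_structure3d(mob),
       displacement_vec = vec)
}

#' Generate the full synthetic two-arm study
#'
#' A self-contained stand-in for the study's raw inputs, with every planted
#' truth recorded in the manifest. The "apo" arm carries a three-state
#' exchange network (one low-population binding-competent state exchanging
#' with two closed states) driving dispersion at the loop-L3 reporter
#' residues; the "bound" arm is a single-state (flat) model. Both arms get
#' relaxation tables at their planted tumbling times (13.24 / 13.06 ns) and
#' matching discrete trajectories for the Markov-model stage.
#'
#' @param seed master seed; substreams derive from it.
#' @param n_residues residues in the relaxation tables.
#' @param fields MHz values for the dispersion data.
#' @param grid CPMG frequency grid, Hz.
#' @param sigma dispersion noise, s^-1.
#' @param noise relative noise on the relaxation tables.
#' @param loop_residues residues carrying the exchange broadening.
#' @param traj_frames frames per simulated trajectory block.
#' @return list of class `synthetic_study`; see elements `apo`, `bound`,
#'   `manifest`.
#' @export
make_study_bundle <- function(seed = 20250101, n_residues = 150,
                              fields = c(600, 950),
                              grid = c(25, 50, 75, 100, 150, 200, 300,
                                       400, 500, 650, 800, 1000),
                              sigma = 0.3, noise = 0.02,
                              loop_residues = c(96, 97, 98, 106),
                              traj_frames = 20000L) {
  # planted apo network: binding-competent (3%) <-> two closed states
  pi_true <- c(0.03, 0.57, 0.40)
  k12 <- 900; k13 <- 150; k23 <- 250   # rad/s scale, 1e2..1e3 range
  S <- matrix(0, 3, 3)
  S[1, 2] <- S[2, 1] <- k12 * pi_true[1]   # flux convention: S_ij sym
  S[1, 3] <- S[3, 1] <- k13 * pi_true[1]
  S[2, 3] <- S[3, 2] <- k23 * min(pi_true[2], pi_true[3])
  K <- S / pi_true
  diag(K) <- 0; diag(K) <- -rowSums(K)

  offsets <- matrix(0, length(loop_residues), 3,
                    dimnames = list(loop_residues, NULL))
  off_seed <- with_seed(seed + 1,
                        cbind(0, stats::runif(length(loop_residues), 1, 3),
                              stats::runif(length(loop_residues), -2, 2)))
  offsets[] <- off_seed
  r2_0 <- 11

  apo_net <- kinetic_network(K, pi = pi_true, offsets_ppm = c(0, 2, -1),
                             r2 = rep(r2_0, 3))
  apo_disp <- simulate_dispersion(apo_net, fields, grid, sigma = sigma,
                                  seed = seed + 2,
                                  residue = as.integer(loop_residues),
                                  offsets_ppm = offsets)
  flat_net <- kinetic_network(matrix(0, 1, 1), pi = 1, offsets_ppm = 0,
                              r2 = r2_0)
  bound_disp <- simulate_dispersion(flat_net, fields, grid, sigma = sigma,
                                    seed = seed + 3,
                                    residue = as.integer(loop_residues))

  # structured core at S2 = 0.86 (hetNOE ~ 0.8); termini and the distal
  # parts of loops L3/L4 flexible. The CPMG reporter residues stay
  # structured: they must be sharp, observable peaks
  S2_map <- rep(0.86, n_residues)
  flex <- setdiff(unique(c(1:3, (n_residues - 2):n_residues,
                           99:105, 127:131)), loop_residues)
  flex <- flex[flex >= 1 & flex <= n_residues]
  S2_map[flex] <- 0.45
  # 20 ps internal motions keep structured residues near hetNOE 0.8 at both
  # fields while the flexible set drops below the 0.7 cut
  tabs <- function(tc, sd) {
    stats::setNames(lapply(fields, function(fm)
      simulate_relaxation_table(tc, fm, n_residues, S2 = S2_map,
                                tau_e_ns = 0.02, noise = noise,
                                seed = sd + fm)),
      as.character(fields))
  }

  # exchange broadening in the apo arm: the loop reporters carry a
  # field-squared-scaled Rex on top of the model-free R2, so the R1*R2
  # statistic flags them while the bound arm stays clean
  rex_600 <- 6
  apo_rates <- tabs(13.24, seed + 5)
  for (fm in names(apo_rates)) {
    extra <- rex_600 * (as.numeric(fm) / 600)^2
    sel <- apo_rates[[fm]]$residue %in% loop_residues
    apo_rates[[fm]]$R2[sel] <- apo_rates[[fm]]$R2[sel] + extra
  }

  # simulation blocks: delete competent<->incompetent exchange, keep 2<->3
  K_b1 <- matrix(0, 1, 1)                       # competent state alone
  K_b2 <- K[2:3, 2:3]; diag(K_b2) <- 0; diag(K_b2) <- -rowSums(K_b2)
  dt <- 1e-4                                     # 0.1 ms frames
  dtraj_b2 <- simulate_ctmc(K_b2, dt, traj_frames, seed = seed + 4)

  structure(list(
    apo = list(network = apo_net, dispersion = apo_disp,
               offsets_ppm = offsets, r2_0 = r2_0,
               rates = apo_rates,
               blocks = list(
                 list(states = 1L, K = K_b1, pi = 1),
                 list(states = c(2L, 3L), K = K_b2,
                      pi = pi_true[2:3] / sum(pi_true[2:3]))),
               dtraj = list(block2 = dtraj_b2), dt = dt),
    bound = list(network = flat_net, dispersion = bound_disp,
                 rates = tabs(13.06, seed + 6)),
    manifest = list(seed = seed,
                    pi_true = pi_true, K_true = K,
                    tau_c_apo_ns = 13.24, tau_c_bound_ns = 13.06,
                    S2_map = S2_map, offsets_ppm = offsets,
                    r2_0 = r2_0, rex_600 = rex_600,
                    sigma = sigma, noise = noise,
                    fields = fields, grid = grid,
                    loop_residues = loop_residues)),
    class = "synthetic_study")
}

#' Write a synthetic study to a directory (TSV/PDB/JSON, plain text)
#' @param study from [make_study_bundle()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (arm in c("apo", "bound")) {
    a <- study[[arm]]
    write_dispersion(a$dispersion,
                     file.path(dir, paste0(arm, "_dispersion.tsv")))
    for (fm in names(a$rates))
      write_rates(a$rates[[fm]],
                  file.path(dir, sprintf("%s_rates_%sMHz.tsv", arm, fm)))
  }
  writeLines(as.character(study$apo$dtraj$block2),
             file.path(dir, "apo_block2.dtraj"))
  man <- study$manifest
  man$K_true <- unclass(man$K_true)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
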